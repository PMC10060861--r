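#' BPI interference item sets
#'
#' The seven Brief Pain Inventory interference items grouped into the two
#' subdimensions used here: affective (relations with others, enjoyment of
#' life, sleep, mood) and activity (walking, general activity, work). Sleep
#' is treated as part of the affective domain; pass
#' `sleep_domain = "activity"`-style custom maps to explore the 3-domain
#' alternative.
#'
#' @param affective,activity Character vectors of item names.
#' @return Named list with `affective` and `activity` item names.
#' @export
bpi_interference_map <- function(
    affective = c("relations", "enjoyment", "sleep", "mood"),
    activity = c("general_activity", "walking", "work")) {
  if (length(intersect(affective, activity)) > 0) {
    stop("an item cannot belong to both subdimensions")
  }
  list(affective = affective, activity = activity)
}

#' Score BPI pain interference
#'
#' Computes the affective, activity, and total interference composites as
#' arithmetic means of the corresponding 0-10 items. No imputation: any
#' missing item is an error.
#'
#' @param data Data frame with one row per subject containing the seven
#'   interference items as columns `paste0(prefix, item)`.
#' @param prefix Column-name prefix, e.g. `"bpi_t1_"`.
#' @param map Item-to-subdimension map, see [bpi_interference_map()].
#' @return A tibble with columns `affective`, `activity`, `total` (one row
#'   per subject).
#' @examples
#' d <- tibble::tibble(bpi_t1_relations = 4, bpi_t1_enjoyment = 4,
#'   bpi_t1_sleep = 4, bpi_t1_mood = 4, bpi_t1_walking = 1,
#'   bpi_t1_general_activity = 1, bpi_t1_work = 1)
#' score_bpi_interference(d)  # affective 4, activity 1, total 19/7
#' @export
score_bpi_interference <- function(data, prefix = "bpi_t1_",
                                   map = bpi_interference_map()) {
  items <- c(map$affective, map$activity)
  cols <- paste0(prefix, items)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0) {
    stop("missing interference item column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  m <- as.matrix(data[, cols, drop = FALSE])
  if (anyNA(m)) stop("missing interference item values; no imputation is performed")
  if (any(m < 0 | m > 10)) stop("interference items must lie in [0, 10]")
  aff <- m[, paste0(prefix, map$affective), drop = FALSE]
  act <- m[, paste0(prefix, map$activity), drop = FALSE]
  tibble::tibble(
    affective = rowMeans(aff),
    activity = rowMeans(act),
    total = rowMeans(m)
  )
}

#' PCS subscale keying
#'
#' Item membership of the three Pain Catastrophizing Scale subscales,
#' following the original 13-item instrument: rumination items 8-11
#' (maximum 16), magnification items 6, 7, 13 (maximum 12), helplessness
#' items 1-5 and 12 (maximum 24). The keying is configurable for translated
#' or reordered forms.
#'
#' @param rumination,magnification,helplessness Integer item indices.
#' @return Named list of index vectors covering 1:13 exactly once.
#' @export
pcs_keying <- function(rumination = 8:11, magnification = c(6, 7, 13),
                       helplessness = c(1:5, 12)) {
  all_items <- sort(c(rumination, magnification, helplessness))
  if (!identical(as.integer(all_items), 1:13)) {
    stop("keying must assign each of the 13 items to exactly one subscale")
  }
  list(rumination = rumination, magnification = magnification,
       helplessness = helplessness)
}

#' Score the Pain Catastrophizing Scale
#'
#' Sums the 13 items (each rated 0-4) into the total score (0-52) and the
#' rumination, magnification, and helplessness subscale scores.
#'
#' @param data Data frame with item columns `paste0(prefix, 1:13)`.
#' @param prefix Column-name prefix (default `"pcs_"`).
#' @param keying Subscale keying, see [pcs_keying()].
#' @return A tibble with columns `total`, `rumination`, `magnification`,
#'   `helplessness`.
#' @examples
#' d <- tibble::as_tibble(as.list(stats::setNames(rep(4, 13), paste0("pcs_", 1:13))))
#' score_pcs(d)  # total 52, subscales at their maxima 16 / 12 / 24
#' @export
score_pcs <- function(data, prefix = "pcs_", keying = pcs_keying()) {
  cols <- paste0(prefix, 1:13)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0) {
    stop("missing PCS item column(s): ", paste(missing_cols, collapse = ", "))
  }
  m <- as.matrix(data[, cols, drop = FALSE])
  if (anyNA(m)) stop("missing PCS item values; no imputation is performed")
  if (any(m < 0 | m > 4)) stop("PCS items must lie in [0, 4]")
  tibble::tibble(
    total = rowSums(m),
    rumination = rowSums(m[, cols[keying$rumination], drop = FALSE]),
    magnification = rowSums(m[, cols[keying$magnification], drop = FALSE]),
    helplessness = rowSums(m[, cols[keying$helplessness], drop = FALSE])
  )
}

#' Composite pain experience at one timepoint
#'
#' The pain-experience composite combines how strong the pain is with how
#' much it interferes emotionally: the arithmetic mean of pain intensity
#' and affective interference (both 0-10). `variant = "difference"`
#' computes `(intensity - affective) / 2` instead, an alternative
#' formulation retained for comparability.
#'
#' @param intensity Pain intensity rating(s), 0-10.
#' @param affective_interference Affective interference composite(s), 0-10.
#' @param variant `"mean"` (default) or `"difference"`.
#' @return Numeric vector of composite scores.
#' @export
pain_experience <- function(intensity, affective_interference,
                            variant = c("mean", "difference")) {
  variant <- match.arg(variant)
  stopifnot(all(intensity >= 0 & intensity <= 10, na.rm = TRUE),
            all(affective_interference >= 0 & affective_interference <= 10,
                na.rm = TRUE))
  if (variant == "mean") {
    (intensity + affective_interference) / 2
  } else {
    (intensity - affective_interference) / 2
  }
}

#' Longitudinal pain-experience change
#'
#' The second-timepoint composite minus the first: positive values mean a
#' worsening of the pain experience, negative values an amelioration.
#'
#' @param pe_t1,pe_t2 Pain-experience composites at the two timepoints.
#' @return Numeric vector `pe_t2 - pe_t1`.
#' @export
pain_experience_longitudinal <- function(pe_t1, pe_t2) {
  pe_t2 - pe_t1
}

#' Classify subjects into longitudinal pain groups
#'
#' Subjects reporting chronic pain (pain persisting or recurring for more
#' than 3 months) at both surveys form the pain group; subjects denying it
#' at both form the no-pain group. Subjects whose status changed
#' (recovered: yes then no; developed: no then yes) are labelled and
#' excluded from the main two-group analysis.
#'
#' @param cp_t1,cp_t2 Logical (or "yes"/"no") chronic-pain answers at the
#'   two timepoints.
#' @return Factor with levels `pain`, `no_pain`, `recovered`, `developed`;
#'   `NA` where an answer is missing (unclassifiable).
#' @export
classify_pain_group <- function(cp_t1, cp_t2) {
  to_logical <- function(x) {
    if (is.character(x) || is.factor(x)) {
      x <- tolower(as.character(x)) == "yes"
    }
    as.logical(x)
  }
  a <- to_logical(cp_t1); b <- to_logical(cp_t2)
  out <- dplyr::case_when(
    is.na(a) | is.na(b) ~ NA_character_,
    a & b ~ "pain",
    !a & !b ~ "no_pain",
    a & !b ~ "recovered",
    TRUE ~ "developed"
  )
  factor(out, levels = c("pain", "no_pain", "recovered", "developed"))
}

#' Score a phenotype table into the full pain-outcome set
#'
#' Runs the whole scoring layer on a phenotype table holding BPI items at
#' two timepoints, PCS items, and the chronic-pain screening answers:
#' interference composites per timepoint, PCS total and subscales, the
#' pain-experience composite at T1 and T2, its longitudinal change, and the
#' pain-group label. Rows whose instruments are absent (e.g. no-pain
#' subjects never given the BPI) receive `NA` scores rather than errors
#' when `allow_missing_group` identifies them.
#'
#' @param data Phenotype tibble; BPI item columns `bpi_t1_*` / `bpi_t2_*`
#'   with an `bpi_t1_intensity` / `bpi_t2_intensity` rating, PCS columns
#'   `pcs_1` ... `pcs_13`, answers `cp_t1`, `cp_t2`.
#' @param map BPI interference map ([bpi_interference_map()]).
#' @param keying PCS keying ([pcs_keying()]).
#' @param variant Pain-experience composite variant (see
#'   [pain_experience()]).
#' @return The input tibble with scoring columns appended:
#'   `affective_interference_t1/t2`, `activity_interference_t1/t2`,
#'   `total_interference_t1/t2`, `pcs_total`, `rumination`,
#'   `magnification`, `helplessness`, `intensity_t1/t2`,
#'   `pain_experience_t1/t2`, `pain_experience_longitudinal`,
#'   `pain_group`.
#' @export
score_phenotypes <- function(data, map = bpi_interference_map(),
                             keying = pcs_keying(),
                             variant = c("mean", "difference")) {
  variant <- match.arg(variant)
  data <- tibble::as_tibble(data)
  out <- data
  out$pain_group <- classify_pain_group(data$cp_t1, data$cp_t2)
  has_pain_items <- !is.na(data$bpi_t1_intensity)

  score_block <- function(rows, prefix) {
    res <- tibble::tibble(affective = rep(NA_real_, nrow(data)),
                          activity = NA_real_, total = NA_real_)
    if (any(rows)) {
      res[rows, ] <- score_bpi_interference(data[rows, ], prefix, map)
    }
    res
  }
  i1 <- score_block(has_pain_items, "bpi_t1_")
  i2 <- score_block(has_pain_items, "bpi_t2_")
  out$affective_interference_t1 <- i1$affective
  out$activity_interference_t1 <- i1$activity
  out$total_interference_t1 <- i1$total
  out$affective_interference_t2 <- i2$affective
  out$activity_interference_t2 <- i2$activity
  out$total_interference_t2 <- i2$total

  pcs <- tibble::tibble(total = rep(NA_real_, nrow(data)), rumination = NA_real_,
                        magnification = NA_real_, helplessness = NA_real_)
  if (any(has_pain_items)) {
    pcs[has_pain_items, ] <- score_pcs(data[has_pain_items, ], keying = keying)
  }
  out$pcs_total <- pcs$total
  out$rumination <- pcs$rumination
  out$magnification <- pcs$magnification
  out$helplessness <- pcs$helplessness

  out$intensity_t1 <- data$bpi_t1_intensity
  out$intensity_t2 <- data$bpi_t2_intensity
  out$pain_experience_t1 <- ifelse(
    has_pain_items,
    pain_experience(dplyr::coalesce(out$intensity_t1, 0),
                    dplyr::coalesce(out$affective_interference_t1, 0), variant),
    NA_real_)
  out$pain_experience_t2 <- ifelse(
    has_pain_items,
    pain_experience(dplyr::coalesce(out$intensity_t2, 0),
                    dplyr::coalesce(out$affective_interference_t2, 0), variant),
    NA_real_)
  out$pain_experience_longitudinal <-
    pain_experience_longitudinal(out$pain_experience_t1, out$pain_experience_t2)
  out
}
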