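#' Reference cohort summary statistics
#'
#' Group-level summary statistics (mean, SD, n per group, and the women
#' proportions) of the chronic-pain cohort the pipeline is modeled on.
#' They serve two roles: as recomputation fixtures for the
#' summary-statistic contrasts ([anova_f_from_summary()],
#' [chi2_from_proportions()]) and as the default operating point of the
#' synthetic cohort generator.
#'
#' @return A list with `n_no_pain` (214), `n_pain` (133), `prop_women`
#'   (per group), `continuous` (tibble: variable, group means/SDs),
#'   `pain_t1`/`pain_t2` (tibbles of within-pain-group instrument means
#'   and SDs at the two surveys), and `fd_mean` (per-group mean framewise
#'   displacement in mm).
#' @export
cohort_reference_summaries <- function() {
  list(
    n_no_pain = 214L,
    n_pain = 133L,
    prop_women = c(no_pain = 0.472, pain = 0.632),
    continuous = tibble::tribble(
      ~variable, ~mean_no_pain, ~sd_no_pain, ~mean_pain, ~sd_pain,
      "age", 52.87, 7.02, 54.81, 7.04,
      "bmi", 25.36, 3.72, 26.86, 5.40,
      "mental_health", 1.21, 1.59, 2.18, 2.02,
      "cognitive_complaints", 53.26, 6.54, 48.41, 9.28
    ),
    pain_t1 = tibble::tribble(
      ~variable, ~mean, ~sd,
      "intensity", 4.17, 1.89,
      "affective_interference", 2.59, 2.37,
      "activity_interference", 2.76, 2.36,
      "helplessness", 6.41, 4.19,
      "rumination", 6.44, 3.37,
      "magnification", 3.60, 2.26
    ),
    pain_t2 = tibble::tribble(
      ~variable, ~mean, ~sd,
      "intensity", 3.70, 1.95,
      "affective_interference", 2.23, 2.22,
      "activity_interference", 2.44, 2.36
    ),
    fd_mean = c(no_pain = 0.163, pain = 0.179)
  )
}

#' Default planted behavioral effects
#'
#' Standardized coefficients planted by the phenotype generator for the
#' longitudinal pain-experience model, matching the directions and
#' magnitudes observed in the motivating cohort's reduced regression:
#' helplessness 0.325, DMN segregation 0.193, DAN segregation -0.215,
#' baseline intensity -0.428, affective interference -0.678, activity
#' interference 0.255, plus the helplessness-by-DMN-segregation
#' interaction (0.4 by default).
#'
#' @return Named numeric vector of standardized coefficients.
#' @export
default_behavioral_betas <- function() {
  c(helplessness = 0.325,
    sys_default = 0.193,
    sys_dorsoattention = -0.215,
    intensity_t1 = -0.428,
    affective_interference_t1 = -0.678,
    activity_interference_t1 = 0.255,
    interaction = 0.4)
}

#' Simulation configuration
#'
#' Collects every knob of the synthetic cohort generator and validates the
#' combination. The defaults reproduce the emulated acquisition (750
#' volumes at TR = 0.8 s minus 10 dummy scans = 740 analyzed volumes, 100
#' nodes in 7 networks), a segregated connectivity ground truth
#' (within-network correlation 0.5 against 0.1 between networks), the
#' cohort's chronic-pain prevalence (133 of 347), per-group head-motion
#' levels, and the planted behavioral effects.
#'
#' @param n_subjects Number of subjects.
#' @param partition Node-to-network partition ([canonical_partition()]).
#' @param n_volumes Analyzed volumes per subject (default 740).
#' @param tr_seconds Repetition time in seconds (default 0.8).
#' @param r_within Within-network correlation, scalar or named per-network
#'   vector, each in (0, 1).
#' @param r_between Between-network correlation in \[0, 1), strictly below
#'   every within-network value.
#' @param sys_subject_sd SD of the per-subject jitter applied to
#'   `r_within` (truncated so subject values stay inside
#'   `(r_between + 0.02, 0.95)`), creating between-subject segregation
#'   variance. Set 0 for identical subjects.
#' @param fd_target_mm Named per-group (`no_pain`, `pain`) target mean
#'   framewise displacement in mm.
#' @param behavioral_betas Planted standardized effects, see
#'   [default_behavioral_betas()].
#' @param noise_sd SD of the Gaussian noise added to the planted
#'   longitudinal pain-experience change (outcome units).
#' @param prevalence Probability of the pain group (default 133/347).
#' @param seed Integer master seed.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 50,
                       partition = canonical_partition(),
                       n_volumes = 740,
                       tr_seconds = 0.8,
                       r_within = 0.5,
                       r_between = 0.1,
                       sys_subject_sd = 0.04,
                       fd_target_mm = c(no_pain = 0.163, pain = 0.179),
                       behavioral_betas = default_behavioral_betas(),
                       noise_sd = 1,
                       prevalence = 133 / 347,
                       seed = 1L) {
  partition <- validate_partition(partition)
  nets <- unique(as.character(partition$network))
  if (length(r_within) == 1) {
    r_within <- stats::setNames(rep(r_within, length(nets)), nets)
  }
  if (!all(nets %in% names(r_within))) {
    stop("r_within must name every network in the partition")
  }
  r_within <- r_within[nets]
  stopifnot(all(r_within > 0 & r_within < 1),
            r_between >= 0, r_between < 1,
            tr_seconds > 0, n_volumes >= 2, noise_sd >= 0,
            prevalence > 0, prevalence < 1, sys_subject_sd >= 0)
  if (any(r_between >= r_within)) {
    stop("r_between must be strictly below every within-network correlation ",
         "(segregated ground truth)")
  }
  if (n_volumes < 2 * nrow(partition)) {
    warning("n_volumes < 2 * n_nodes: connectivity estimates will be noisy")
  }
  stopifnot(all(c("no_pain", "pain") %in% names(fd_target_mm)))
  structure(
    list(n_subjects = as.integer(n_subjects), partition = partition,
         n_volumes = as.integer(n_volumes), tr_seconds = tr_seconds,
         r_within = r_within, r_between = r_between,
         sys_subject_sd = sys_subject_sd, fd_target_mm = fd_target_mm,
         behavioral_betas = behavioral_betas, noise_sd = noise_sd,
         prevalence = prevalence, seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Block covariance with segregated network structure
#'
#' Builds the N x N covariance (here: correlation) matrix with 1 on the
#' diagonal, `r_within[net]` for node pairs inside the same network, and
#' `r_between` across networks — the population structure whose system
#' segregation is `(atanh(r_within) - atanh(r_between)) / atanh(r_within)`.
#' Rejects combinations that are not positive definite.
#'
#' @param partition Partition table.
#' @param r_within Scalar or named per-network within correlation in
#'   \[0, 1).
#' @param r_between Between-network correlation in \[0, 1).
#' @return N x N positive-definite matrix.
#' @export
make_block_covariance <- function(partition, r_within, r_between) {
  partition <- validate_partition(partition)
  nets <- unique(as.character(partition$network))
  if (length(r_within) == 1) {
    r_within <- stats::setNames(rep(r_within, length(nets)), nets)
  }
  stopifnot(all(r_within >= 0 & r_within < 1), r_between >= 0, r_between < 1)
  n <- nrow(partition)
  membership <- as.character(partition$network)
  sigma <- matrix(r_between, n, n)
  for (net in nets) {
    idx <- which(membership == net)
    sigma[idx, idx] <- r_within[[net]]
  }
  diag(sigma) <- 1
  ev_min <- min(eigen(sigma, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min <= 1e-12) {
    stop("requested correlation structure is not positive definite ",
         sprintf("(smallest eigenvalue %.3g); ", ev_min),
         "lower r_between or the within-network correlations")
  }
  sigma
}

#' Simulate a block-correlated ROI time series
#'
#' Draws `n_volumes` iid samples from a zero-mean multivariate Gaussian
#' with the given covariance (via its Cholesky factor), emulating
#' parcel-averaged BOLD signals whose population correlation structure is
#' exactly the block design.
#'
#' @param sigma Covariance matrix (e.g. from [make_block_covariance()]).
#' @param n_volumes Number of volumes T.
#' @param seed Integer seed; identical seeds give identical matrices.
#' @return T x N matrix.
#' @export
simulate_timeseries <- function(sigma, n_volumes, seed) {
  n <- nrow(sigma)
  R <- chol(sigma)
  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  z <- matrix(stats::rnorm(n_volumes * n), n_volumes, n)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  ts <- z %*% R
  colnames(ts) <- paste0("node_", seq_len(n))
  ts
}

#' Simulate a rigid-body motion trace
#'
#' Generates a 6-parameter trace (3 rotations in radians, then 3
#' translations in mm) whose frame-to-frame increments follow a stationary
#' AR(1) process, scaled so the expected mean framewise displacement
#' equals `fd_target_mm`. Rotations and translations contribute equally to
#' FD at the given sphere radius.
#'
#' @param n_volumes Number of volumes (>= 2).
#' @param fd_target_mm Target mean FD in mm; 0 gives an all-zero trace.
#' @param seed Integer seed.
#' @param ar AR(1) coefficient of the increments (default 0.3).
#' @param sphere_radius_mm Radius used in the FD formula (default 50).
#' @return T x 6 matrix (columns `rot_x..z` rad, `trans_x..z` mm).
#' @export
simulate_motion <- function(n_volumes, fd_target_mm, seed, ar = 0.3,
                            sphere_radius_mm = 50) {
  stopifnot(n_volumes >= 2, fd_target_mm >= 0, abs(ar) < 1)
  if (fd_target_mm == 0) {
    out <- matrix(0, n_volumes, 6)
    colnames(out) <- c("rot_x", "rot_y", "rot_z", "trans_x", "trans_y", "trans_z")
    return(out)
  }
  # E|increment| = s * sqrt(2/pi) per axis; translations and rotations
  # (scaled by the sphere radius) contribute equally: E[FD] = 6 s sqrt(2/pi)
  s_trans <- fd_target_mm / (6 * sqrt(2 / pi))
  s_rot <- s_trans / sphere_radius_mm
  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  innov_sd <- sqrt(1 - ar^2)
  increments <- vapply(seq_len(6), function(j) {
    e <- stats::rnorm(n_volumes - 1, sd = innov_sd)
    x <- numeric(n_volumes - 1)
    x[1] <- stats::rnorm(1)
    for (t in seq_len(n_volumes - 2)) x[t + 1] <- ar * x[t] + e[t]
    x
  }, numeric(n_volumes - 1))
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  increments[, 1:3] <- increments[, 1:3] * s_rot
  increments[, 4:6] <- increments[, 4:6] * s_trans
  trace <- rbind(0, apply(increments, 2, cumsum))
  colnames(trace) <- c("rot_x", "rot_y", "rot_z", "trans_x", "trans_y", "trans_z")
  trace
}

# distribute an integer sum uniformly over k items capped at item_max
distribute_items <- function(total, k, item_max) {
  total <- as.integer(round(total))
  total <- max(0L, min(total, k * item_max))
  items <- integer(k)
  for (i in seq_len(total)) {
    open <- which(items < item_max)
    j <- open[sample.int(length(open), 1)]
    items[j] <- items[j] + 1L
  }
  items
}

# continuous items in [0, 10] with an exact target mean
spread_mean <- function(target_mean, k) {
  target_mean <- min(10, max(0, target_mean))
  d <- stats::runif(k, -1, 1)
  d <- d - mean(d)
  room <- min(10 - target_mean, target_mean)
  if (room <= 0) return(rep(target_mean, k))
  d <- d * min(1, room / max(abs(d)))
  pmin(10, pmax(0, target_mean + d))  # clamp round-off at the bounds
}

rnorm_clipped <- function(n, mean, sd, lo, hi) {
  pmin(hi, pmax(lo, stats::rnorm(n, mean, sd)))
}

#' Simulate phenotypes with a planted longitudinal model
#'
#' Generates a phenotype table (demographics, health questionnaires, PCS
#' items, BPI items at two surveys) whose longitudinal pain-experience
#' change in the pain group equals the planted standardized linear model
#' plus the interaction term plus Gaussian noise. Instrument scores are
#' generated at the item level so the scoring layer is genuinely
#' exercised: PCS items are integers 0-4 distributed uniformly subject to
#' the target subscale sums; BPI interference items are continuous 0-10
#' values with exactly the target subdimension mean. Values are clipped to
#' instrument bounds; the realized clipping rate is attached as the
#' `clip_rate` attribute and a warning is raised above 20%.
#'
#' @param config A [sim_config()].
#' @param true_sys Tibble of per-subject true segregation with columns
#'   `subject`, `group`, and `sys_<network>` columns (as produced inside
#'   [simulate_cohort()]).
#' @return Phenotype tibble, one row per subject, with attributes
#'   `clip_rate` and `planted` (tibble of the per-subject planted
#'   longitudinal change before clipping).
#' @export
simulate_phenotypes <- function(config, true_sys) {
  stopifnot(inherits(config, "sim_config"))
  ref <- cohort_reference_summaries()
  n <- nrow(true_sys)
  group <- true_sys$group
  pain <- group == "pain"
  n_pain <- sum(pain)

  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(config$seed + 104729L)
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })

  gpar <- function(var, field) {
    row <- ref$continuous[ref$continuous$variable == var, ]
    unname(unlist(row[paste0(field, "_", ifelse(pain, "pain", "no_pain"))]))
  }
  pheno <- tibble::tibble(
    subject = true_sys$subject,
    cp_t1 = ifelse(pain, "yes", "no"),
    cp_t2 = ifelse(pain, "yes", "no"),
    age = round(stats::rnorm(n, gpar("age", "mean"), gpar("age", "sd")), 1),
    sex = ifelse(stats::runif(n) < ref$prop_women[ifelse(pain, "pain", "no_pain")],
                 "female", "male"),
    bmi = round(rnorm_clipped(n, gpar("bmi", "mean"), gpar("bmi", "sd"), 15, 50), 1),
    mental_health = round(rnorm_clipped(n, gpar("mental_health", "mean"),
                                        gpar("mental_health", "sd"), 0, 12), 0),
    cognitive_complaints = round(stats::rnorm(n, gpar("cognitive_complaints", "mean"),
                                              gpar("cognitive_complaints", "sd")), 1),
    # QoL: pain-group SD not available in the reference table; 7.0 assumed
    qol = round(rnorm_clipped(n, ifelse(pain, 34.32, 39.90),
                              ifelse(pain, 7.0, 7.93), 13, 65), 1),
    delay_days = round(stats::runif(n, 30, 200))
  )

  t1 <- function(var, field = "mean") {
    ref$pain_t1[[field]][ref$pain_t1$variable == var]
  }
  # latent targets for the pain group
  intensity_t1 <- rnorm_clipped(n_pain, t1("intensity"), t1("intensity", "sd"), 0, 10)
  affective_t1 <- rnorm_clipped(n_pain, t1("affective_interference"),
                                t1("affective_interference", "sd"), 0, 10)
  activity_t1 <- rnorm_clipped(n_pain, t1("activity_interference"),
                               t1("activity_interference", "sd"), 0, 10)
  help_target <- round(rnorm_clipped(n_pain, t1("helplessness"),
                                     t1("helplessness", "sd"), 0, 24))
  rum_target <- round(rnorm_clipped(n_pain, t1("rumination"),
                                    t1("rumination", "sd"), 0, 16))
  mag_target <- round(rnorm_clipped(n_pain, t1("magnification"),
                                    t1("magnification", "sd"), 0, 12))

  # PCS items: integer compositions matching the subscale targets
  keying <- pcs_keying()
  pcs_items <- matrix(NA_real_, n, 13,
                      dimnames = list(NULL, paste0("pcs_", 1:13)))
  for (i in seq_len(n_pain)) {
    row <- numeric(13)
    row[keying$helplessness] <- distribute_items(help_target[i], 6, 4)
    row[keying$rumination] <- distribute_items(rum_target[i], 4, 4)
    row[keying$magnification] <- distribute_items(mag_target[i], 3, 4)
    pcs_items[which(pain)[i], ] <- row
  }
  help_realized <- rowSums(pcs_items[pain, keying$helplessness, drop = FALSE])

  # BPI T1 items with exact subdimension means
  map <- bpi_interference_map()
  bpi_cols <- function(prefix) paste0(prefix, c(map$affective, map$activity))
  bpi_t1 <- matrix(NA_real_, n, 7, dimnames = list(NULL, bpi_cols("bpi_t1_")))
  for (i in seq_len(n_pain)) {
    bpi_t1[which(pain)[i], 1:4] <- spread_mean(affective_t1[i], 4)
    bpi_t1[which(pain)[i], 5:7] <- spread_mean(activity_t1[i], 3)
  }

  # planted longitudinal change: standardized predictors within pain group
  zs <- function(v) {
    s <- stats::sd(v)
    if (is.na(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }
  sys_dmn <- true_sys$sys_default[pain]
  sys_dan <- true_sys$sys_dorsoattention[pain]
  betas <- config$behavioral_betas
  linpred <- betas[["helplessness"]] * zs(help_realized) +
    betas[["sys_default"]] * zs(sys_dmn) +
    betas[["sys_dorsoattention"]] * zs(sys_dan) +
    betas[["intensity_t1"]] * zs(intensity_t1) +
    betas[["affective_interference_t1"]] * zs(affective_t1) +
    betas[["activity_interference_t1"]] * zs(activity_t1) +
    betas[["interaction"]] * zs(help_realized) * zs(sys_dmn)
  noise <- if (config$noise_sd > 0) stats::rnorm(n_pain, 0, config$noise_sd) else 0
  delta <- linpred + noise

  # T2 items: shift intensity and affective by delta plus a cancelling split
  # u (so the composite changes by exactly delta); u is drawn inside the
  # interval keeping both ratings in bounds, when such an interval exists
  u_raw <- stats::runif(n_pain, -0.3, 0.3)
  u_lo <- pmax(-0.3, -(intensity_t1 + delta), (affective_t1 + delta) - 10)
  u_hi <- pmin(0.3, 10 - (intensity_t1 + delta), affective_t1 + delta)
  feasible <- u_lo <= u_hi
  u <- ifelse(feasible, u_lo + (u_raw + 0.3) / 0.6 * (u_hi - u_lo), 0)
  intensity_t2 <- intensity_t1 + delta + u
  affective_t2 <- affective_t1 + delta - u
  activity_t2 <- activity_t1 + delta * 0.8 +
    if (config$noise_sd > 0) stats::rnorm(n_pain, 0, 0.5) else 0

  tol <- 1e-9  # FP round-off at the feasibility edges is not a clip
  pe_clipped <- intensity_t2 < -tol | intensity_t2 > 10 + tol |
    affective_t2 < -tol | affective_t2 > 10 + tol
  clipped <- c(pe_clipped, activity_t2 < -tol | activity_t2 > 10 + tol)
  clip_rate <- mean(clipped)
  if (clip_rate > 0.2) {
    warning(sprintf("%.1f%% of simulated T2 ratings hit the instrument bounds; ",
                    100 * clip_rate),
            "planted effects are attenuated at this operating point")
  }
  intensity_t2 <- pmin(10, pmax(0, intensity_t2))
  affective_t2 <- pmin(10, pmax(0, affective_t2))
  activity_t2 <- pmin(10, pmax(0, activity_t2))

  bpi_t2 <- matrix(NA_real_, n, 7, dimnames = list(NULL, bpi_cols("bpi_t2_")))
  for (i in seq_len(n_pain)) {
    bpi_t2[which(pain)[i], 1:4] <- spread_mean(affective_t2[i], 4)
    bpi_t2[which(pain)[i], 5:7] <- spread_mean(activity_t2[i], 3)
  }

  pheno$bpi_t1_intensity <- NA_real_
  pheno$bpi_t1_intensity[pain] <- intensity_t1
  pheno$bpi_t2_intensity <- NA_real_
  pheno$bpi_t2_intensity[pain] <- intensity_t2
  pheno <- dplyr::bind_cols(pheno, tibble::as_tibble(bpi_t1),
                            tibble::as_tibble(bpi_t2),
                            tibble::as_tibble(pcs_items))
  pheno$n_pain_sites <- NA_integer_
  pheno$n_pain_sites[pain] <- sample(1:4, n_pain, replace = TRUE,
                                     prob = c(0.248, 0.30, 0.25, 0.202))
  pheno$duration_category <- NA_character_
  pheno$duration_category[pain] <- sample(c("<3y", "3-9y", ">9y"), n_pain,
                                          replace = TRUE,
                                          prob = c(0.587, 0.286, 0.127))
  pheno$medication <- NA
  pheno$medication[pain] <- stats::runif(n_pain) < 0.316

  planted <- tibble::tibble(subject = true_sys$subject[pain],
                            linpred = linpred, delta = delta,
                            pe_clipped = pe_clipped)
  attr(pheno, "clip_rate") <- clip_rate
  attr(pheno, "planted") <- planted
  pheno
}

#' Simulate a full cohort with ground truth
#'
#' Generates everything the pipeline consumes for `n_subjects`: per-subject
#' ROI time series drawn from a block covariance whose within-network
#' correlations are jittered per subject (creating true between-subject
#' segregation differences), AR(1) motion traces at the per-group FD
#' targets, and a phenotype table with the planted behavioral model. The
#' per-subject true segregation is the Fisher-z population value
#' `(atanh(r_w) - atanh(r_b)) / atanh(r_w)`.
#'
#' @param config A [sim_config()].
#' @param generate_timeseries Set `FALSE` to skip the (large) time-series
#'   and motion simulation when only phenotypes and true segregation are
#'   needed.
#' @return A list of class `pain_cohort`: `phenotypes`, `ground_truth`
#'   (per-subject tibble with group, per-network `r_within_*` and
#'   `sys_*`), `timeseries` (list of T x N matrices or `NULL`), `motion`
#'   (list of T x 6 matrices or `NULL`), `config`.
#' @export
simulate_cohort <- function(config = sim_config(), generate_timeseries = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  nets <- unique(as.character(config$partition$network))
  n <- config$n_subjects

  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(config$seed)
  group <- ifelse(stats::runif(n) < config$prevalence, "pain", "no_pain")
  # per-subject within-network correlations (jittered, truncated)
  rw <- sapply(nets, function(net) {
    pmin(0.95, pmax(config$r_between + 0.02,
                    stats::rnorm(n, config$r_within[[net]], config$sys_subject_sd)))
  })
  rw <- matrix(rw, nrow = n, dimnames = list(NULL, nets))
  subject_seeds <- sample.int(.Machine$integer.max - 1L, 2L * n)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())

  true_sys <- tibble::as_tibble(
    (atanh(rw) - atanh(config$r_between)) / atanh(rw)
  )
  names(true_sys) <- paste0("sys_", nets)
  ground_truth <- dplyr::bind_cols(
    tibble::tibble(subject = sprintf("sub-%03d", seq_len(n)), group = group),
    stats::setNames(tibble::as_tibble(rw), paste0("r_within_", nets)),
    true_sys
  )

  timeseries <- motion <- NULL
  if (generate_timeseries) {
    timeseries <- purrr::map(seq_len(n), function(i) {
      sigma <- make_block_covariance(config$partition, rw[i, ], config$r_between)
      simulate_timeseries(sigma, config$n_volumes, seed = subject_seeds[i])
    })
    motion <- purrr::map(seq_len(n), function(i) {
      simulate_motion(config$n_volumes,
                      config$fd_target_mm[[group[i]]],
                      seed = subject_seeds[n + i])
    })
    names(timeseries) <- names(motion) <- ground_truth$subject
  }

  phenotypes <- simulate_phenotypes(config, ground_truth)
  structure(
    list(phenotypes = phenotypes, ground_truth = ground_truth,
         timeseries = timeseries, motion = motion, config = config),
    class = "pain_cohort"
  )
}

#' Write a simulated cohort to disk
#'
#' Writes the artifacts in their interchange formats: one TSV of ROI time
#' series per subject (header row of node labels), one whitespace-delimited
#' 6-column `.par` motion trace per subject (rotations in radians first,
#' then translations in mm), the phenotype CSV, the partition TSV, and the
#' ground truth as JSON.
#'
#' @param cohort A `pain_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a character vector of the files written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "pain_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  if (!is.null(cohort$timeseries)) {
    for (s in names(cohort$timeseries)) {
      f <- file.path(dir, paste0(s, "_timeseries.tsv"))
      readr::write_tsv(tibble::as_tibble(cohort$timeseries[[s]]), f)
      fm <- file.path(dir, paste0(s, "_motion.par"))
      utils::write.table(cohort$motion[[s]], fm, row.names = FALSE,
                         col.names = FALSE)
      files <- c(files, f, fm)
    }
  }
  fp <- file.path(dir, "phenotypes.csv")
  readr::write_csv(cohort$phenotypes, fp)
  fa <- file.path(dir, "partition.tsv")
  readr::write_tsv(cohort$config$partition[, c("node_label", "network")], fa)
  fg <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(cohort$ground_truth, fg, digits = NA)
  invisible(c(files, fp, fa, fg))
}
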