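#' Pipeline configuration
#'
#' Bundles every setting of an end-to-end run. Either a simulated cohort
#' (`cohort`) or on-disk inputs (`data_dir` as written by
#' [write_cohort()]) feed the pipeline; thresholds and model
#' specifications mirror the analysis defaults.
#'
#' @param cohort Optional `pain_cohort` (in-memory inputs).
#' @param data_dir Optional directory of on-disk inputs.
#' @param fd_threshold,prop_threshold Motion exclusion rule (mm; fraction).
#' @param n_dummy Dummy scans already removed from simulated series (0) or
#'   to remove from raw-length inputs.
#' @param moderation Named list: `focal`, `moderator`, `covariates`,
#'   `n_boot`, `ci_level`.
#' @param regression Character vector of regressor columns for the
#'   standardized regression of the longitudinal pain-experience change.
#' @param seed Integer seed for the bootstrap stages.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = NULL, data_dir = NULL,
                            fd_threshold = 0.5, prop_threshold = 0.5,
                            n_dummy = 0,
                            regression = c("helplessness", "sys_default",
                                           "sys_dorsoattention", "intensity_t1",
                                           "affective_interference_t1",
                                           "activity_interference_t1"),
                            moderation = list(focal = "sys_default",
                                              moderator = "helplessness",
                                              covariates = character(),
                                              n_boot = 5000, ci_level = 0.95),
                            seed = 1L) {
  if (is.null(cohort) && is.null(data_dir)) {
    stop("provide either a simulated cohort or a data directory")
  }
  structure(
    list(cohort = cohort, data_dir = data_dir, fd_threshold = fd_threshold,
         prop_threshold = prop_threshold, n_dummy = n_dummy,
         regression = regression, moderation = moderation,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

load_inputs <- function(config) {
  if (!is.null(config$cohort)) {
    co <- config$cohort
    return(list(partition = co$config$partition, phenotypes = co$phenotypes,
                timeseries = co$timeseries, motion = co$motion,
                tr_seconds = co$config$tr_seconds))
  }
  dir <- config$data_dir
  partition <- read_partition(file.path(dir, "partition.tsv"))
  phen <- readr::read_csv(file.path(dir, "phenotypes.csv"),
                          show_col_types = FALSE)
  ts_files <- sort(Sys.glob(file.path(dir, "*_timeseries.tsv")))
  subjects <- sub("_timeseries\\.tsv$", "", basename(ts_files))
  timeseries <- stats::setNames(lapply(ts_files, read_roi_timeseries), subjects)
  motion <- stats::setNames(
    lapply(file.path(dir, paste0(subjects, "_motion.par")), read_motion_par),
    subjects)
  list(partition = partition, phenotypes = phen, timeseries = timeseries,
       motion = motion, tr_seconds = 0.8)
}

#' Run the full analysis pipeline
#'
#' Executes the stage chain: motion QC (framewise displacement and the
#' high-motion exclusion rule) -> nuisance-cleaned connectivity and
#' per-network segregation -> instrument scoring -> inferential models
#' (two-group comparison table, covariate-adjusted segregation contrasts,
#' partial correlations of segregation with pain variables, standardized
#' regression of the longitudinal pain-experience change, moderation with
#' bootstrap CI and Johnson-Neyman region). Reruns with the same
#' configuration and seed reproduce the results exactly.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `pain_run`: `scores` (scored per-subject table
#'   joined with segregation and FD), `segregation`, `exclusions`,
#'   `results` (list of model outputs), `manifest` (per-stage record),
#'   `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  inputs <- load_inputs(config)
  manifest <- list()
  stamp <- function(stage, object, note = "") {
    manifest[[length(manifest) + 1]] <<- tibble::tibble(
      stage = stage, hash = rlang::hash(object), note = note,
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
    )
    object
  }
  stamp("inputs", inputs$phenotypes)
  if (nrow(inputs$phenotypes) == 0) stop("no subjects in cohort")

  subjects <- inputs$phenotypes$subject
  have_imaging <- !is.null(inputs$timeseries)

  exclusions <- tibble::tibble(subject = character(), reason = character())
  fd_tab <- tibble::tibble(subject = subjects, fd_mean = NA_real_,
                           prop_above_threshold = NA_real_, excluded = FALSE)
  seg_tab <- NULL
  if (have_imaging) {
    qc <- purrr::map_dfr(subjects, function(s) {
      fd <- framewise_displacement(
        drop_dummy_scans(inputs$motion[[s]],
                         min(config$n_dummy, nrow(inputs$motion[[s]]) - 2)))
      dplyr::mutate(fd_summary(fd, config$fd_threshold, config$prop_threshold),
                    subject = s, .before = 1)
    })
    fd_tab <- qc
    excl <- qc$subject[qc$excluded]
    if (length(excl) > 0) {
      exclusions <- dplyr::bind_rows(exclusions, tibble::tibble(
        subject = excl,
        reason = sprintf(
          "high motion: >=%.0f%% of volumes with FD > %.2f mm",
          100 * config$prop_threshold, config$fd_threshold)
      ))
    }
    stamp("motion_qc", qc, sprintf("%d excluded", length(excl)))

    kept <- setdiff(subjects, excl)
    seg_tab <- purrr::map_dfr(kept, function(s) {
      prof <- segregate_subject(inputs$timeseries[[s]], inputs$partition,
                                motion = inputs$motion[[s]],
                                tr_seconds = inputs$tr_seconds,
                                n_dummy = config$n_dummy)
      dplyr::mutate(prof, subject = s, .before = 1)
    })
    stamp("segregation", seg_tab)
  }

  scores <- score_phenotypes(inputs$phenotypes)
  scores <- dplyr::left_join(scores, fd_tab[, c("subject", "fd_mean")],
                             by = "subject")
  if (!is.null(seg_tab)) {
    wide <- tidyr::pivot_wider(seg_tab[, c("subject", "network", "sys")],
                               names_from = "network", values_from = "sys",
                               names_prefix = "sys_")
    scores <- dplyr::left_join(scores, wide, by = "subject")
    scores <- scores[!scores$subject %in% exclusions$subject, ]
  } else if (!is.null(config$cohort)) {
    # no imaging simulated: fall back to the ground-truth segregation
    gt <- config$cohort$ground_truth
    scores <- dplyr::left_join(
      scores, gt[, c("subject", grep("^sys_", names(gt), value = TRUE))],
      by = "subject")
  }
  stamp("scoring", scores)

  results <- list()
  nets <- unique(as.character(inputs$partition$network))
  sys_cols <- intersect(paste0("sys_", nets), names(scores))
  two_groups <- length(unique(stats::na.omit(
    as.character(scores$pain_group)))) >= 2 &&
    all(c("pain", "no_pain") %in% scores$pain_group)

  if (two_groups) {
    main <- scores[scores$pain_group %in% c("pain", "no_pain"), ]
    main$pain_group <- droplevels(main$pain_group)
    grp_vars <- intersect(c("age", "bmi", "mental_health",
                            "cognitive_complaints", "qol", "fd_mean"),
                          names(main))
    grp_vars <- grp_vars[vapply(grp_vars, function(v) {
      all(tapply(main[[v]], main$pain_group,
                 function(x) sum(!is.na(x)) >= 2 && stats::sd(x, na.rm = TRUE) > 0))
    }, logical(1))]
    results$group_table <- group_compare_table(main, grp_vars, "pain_group")
    results$sex_chi2 <- chi2_from_proportions(
      mean(main$sex[main$pain_group == "no_pain"] == "female"),
      sum(main$pain_group == "no_pain"),
      mean(main$sex[main$pain_group == "pain"] == "female"),
      sum(main$pain_group == "pain"))
    if (length(sys_cols) > 0 && "fd_mean" %in% names(main) &&
        !all(is.na(main$fd_mean))) {
      results$sys_ancova <- purrr::map_dfr(sys_cols, function(sc) {
        a <- ancova_group_compare(main, sc, "pain_group",
                                  c("age", "sex", "fd_mean", "delay_days"))
        dplyr::mutate(a$test, network = sub("^sys_", "", sc), .before = 1)
      })
    }
    stamp("group_comparisons", results$group_table)
  }

  pain_only <- scores[scores$pain_group %in% "pain", ]
  if (nrow(pain_only) > 5 && length(sys_cols) > 0) {
    covs <- intersect(c("age", "sex", "fd_mean"), names(pain_only))
    if (all(is.na(pain_only$fd_mean))) covs <- setdiff(covs, "fd_mean")
    results$partial_correlations <- purrr::map_dfr(sys_cols, function(sc) {
      purrr::map_dfr(intersect(c("intensity_t1", "total_interference_t1",
                                 "n_pain_sites"), names(pain_only)),
                     function(pv) {
        dplyr::mutate(
          partial_correlation(pain_only, sc, pv, covs),
          network = sub("^sys_", "", sc), pain_variable = pv, .before = 1)
      })
    })
    regs <- intersect(config$regression, names(pain_only))
    results$regression <- ols_standardized(
      pain_only, "pain_experience_longitudinal", regs)
    mod <- config$moderation
    results$moderation <- fit_moderation(
      pain_only, "pain_experience_longitudinal", mod$focal, mod$moderator,
      intersect(mod$covariates, names(pain_only)),
      n_boot = mod$n_boot, ci_level = mod$ci_level, seed = config$seed)
    results$johnson_neyman <- johnson_neyman(results$moderation)
    stamp("inference", tidy(results$regression))
  }

  structure(
    list(scores = scores, segregation = seg_tab, fd = fd_tab,
         exclusions = exclusions, results = results,
         manifest = dplyr::bind_rows(manifest), config = config),
    class = "pain_run"
  )
}

#' Render a plain-text report for a pipeline run
#'
#' Produces the human-readable analog of the result tables: group
#' contrasts, per-network segregation summaries, the regression and
#' moderation models, and the Johnson-Neyman region. Every number is taken
#' from the run's results objects (single source of truth).
#'
#' @param run A `pain_run` from [run_pipeline()].
#' @param path Optional file to write the report to.
#' @return Character vector of report lines, invisibly when `path` is
#'   given.
#' @export
make_report <- function(run, path = NULL) {
  stopifnot(inherits(run, "pain_run"))
  if (nrow(run$scores) == 0) stop("no subjects: nothing to report")
  fmt <- function(x, d = 3) formatC(x, digits = d, format = "f")
  lines <- c("Chronic-pain system-segregation pipeline report",
             strrep("=", 48),
             sprintf("Subjects analyzed: %d (excluded: %d)", nrow(run$scores),
                     nrow(run$exclusions)))
  if (nrow(run$exclusions) > 0) {
    lines <- c(lines, paste0("  excluded ", run$exclusions$subject, ": ",
                             run$exclusions$reason))
  }
  res <- run$results
  if (!is.null(res$group_table)) {
    lines <- c(lines, "", "Group comparisons (pain vs no pain)",
               strrep("-", 40))
    gt <- res$group_table
    lines <- c(lines, sprintf("  %-22s %8s (%s) vs %8s (%s)  F = %s, p = %s",
                              gt$variable, fmt(gt$mean_1, 2), fmt(gt$sd_1, 2),
                              fmt(gt$mean_2, 2), fmt(gt$sd_2, 2),
                              fmt(gt$f, 3), fmt(gt$f_p, 4)))
    lines <- c(lines, sprintf("  sex contrast: chi2 = %s, p = %s",
                              fmt(res$sex_chi2$chi2, 3),
                              fmt(res$sex_chi2$p_value, 4)))
  }
  if (!is.null(run$segregation)) {
    seg <- dplyr::summarise(dplyr::group_by(run$segregation, .data$network),
                            mean_sys = mean(.data$sys), .groups = "drop")
    lines <- c(lines, "", "System segregation (cohort means)", strrep("-", 40),
               sprintf("  %-28s %s", seg$network, fmt(seg$mean_sys)))
  }
  if (!is.null(res$sys_ancova)) {
    lines <- c(lines, "", "Covariate-adjusted group contrast per network",
               strrep("-", 40),
               sprintf("  %-28s F = %s, p = %s", res$sys_ancova$network,
                       fmt(res$sys_ancova$f, 3), fmt(res$sys_ancova$p_value, 4)))
  }
  if (!is.null(res$regression)) {
    td <- tidy(res$regression)
    lines <- c(lines, "", "Standardized regression on pain-experience change",
               strrep("-", 40),
               sprintf("  %-28s beta = %s, p = %s, VIF = %s", td$term,
                       fmt(td$estimate), fmt(td$p.value, 4), fmt(td$vif, 2)),
               sprintf("  R^2 = %s (n = %d)", fmt(res$regression$r.squared),
                       res$regression$n))
  }
  if (!is.null(res$moderation)) {
    m <- res$moderation
    b3 <- m$coefficients[m$coefficients$term == "interaction", ]
    lines <- c(lines, "", "Moderation (interaction) model", strrep("-", 40),
               sprintf("  interaction b = %s, p = %s, %d%% bootstrap CI [%s, %s] (%d resamples)",
                       fmt(b3$estimate), fmt(b3$p.value, 4),
                       round(100 * m$ci_level), fmt(m$boot_ci[1]),
                       fmt(m$boot_ci[2]), m$n_boot))
    jn <- res$johnson_neyman
    if (nrow(jn$boundaries) > 0) {
      lines <- c(lines, sprintf("  Johnson-Neyman boundary at moderator = %s",
                                paste(fmt(jn$boundaries$moderator, 3),
                                      collapse = ", ")))
    } else {
      lines <- c(lines, "  Johnson-Neyman: no boundary in the observed moderator range")
    }
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' @export
print.pain_run <- function(x, ...) {
  cat(sprintf("pain_run: %d subjects, %d excluded, %d result objects\n",
              nrow(x$scores), nrow(x$exclusions), length(x$results)))
  invisible(x)
}
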