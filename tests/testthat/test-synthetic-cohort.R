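test_that("block covariance realizes the segregated design exactly", {
  part <- tiny_partition()
  s <- make_block_covariance(part, 0.5, 0.1)
  expect_equal(diag(s), rep(1, 4))
  expect_equal(s[1, 2], 0.5)
  expect_equal(s[3, 4], 0.5)
  expect_equal(s[1, 3], 0.1)
  expect_equal(s[2, 4], 0.1)
  expect_equal(s, t(s))

  # zero correlations give the identity
  expect_equal(make_block_covariance(part, 0, 0), diag(4))

  # canonical 100-node / 7-network structure is positive definite
  s100 <- make_block_covariance(canonical_partition(), 0.5, 0.1)
  expect_gt(min(eigen(s100, symmetric = TRUE, only.values = TRUE)$values), 0)

  # an infeasible combination is rejected with an explanation
  neg_part <- tibble::tibble(node_id = 1:40,
                             network = rep(c("A", "B"), each = 20))
  expect_error(make_block_covariance(neg_part, 0.01, 0.9), "positive definite")
})

test_that("time-series simulation is deterministic and matches its covariance", {
  part <- tiny_partition()
  s <- make_block_covariance(part, 0.5, 0.1)
  a <- simulate_timeseries(s, 100, seed = 42)
  b <- simulate_timeseries(s, 100, seed = 42)
  expect_identical(a, b)
  expect_false(identical(a, simulate_timeseries(s, 100, seed = 43)))

  # law of large numbers: sample correlations converge to the design
  part2 <- tibble::tibble(node_id = 1:12, network = rep(c("A", "B"), each = 6))
  s2 <- make_block_covariance(part2, 0.5, 0)
  ts <- simulate_timeseries(s2, 50000, seed = 7)
  r <- stats::cor(ts)
  within_idx <- rbind(cbind(1:5, 2:6), cbind(7:11, 8:12))
  expect_lt(max(abs(r[within_idx] - 0.5)), 0.01)
  # independent blocks: cross correlations at ~1/sqrt(T)
  expect_lt(max(abs(r[1:6, 7:12])), 4 / sqrt(50000))
})

test_that("motion traces hit the FD target and are reproducible", {
  z <- simulate_motion(100, 0, seed = 1)
  expect_equal(framewise_displacement(z), rep(0, 99))

  expect_identical(simulate_motion(200, 0.2, seed = 3),
                   simulate_motion(200, 0.2, seed = 3))

  # no-pain group target: realized mean FD within 10%
  m <- simulate_motion(740, 0.163, seed = 11)
  fd <- framewise_displacement(m)
  expect_lt(abs(mean(fd) - 0.163) / 0.163, 0.10)
  expect_true(all(fd >= 0))
})

test_that("noise-free phenotypes are exactly linear in the planted predictors", {
  betas <- default_behavioral_betas()
  betas["interaction"] <- 0
  # small effects keep every T2 rating inside the instrument bounds
  betas[] <- betas * 0.2
  cfg <- sim_config(n_subjects = 120, noise_sd = 0,
                    behavioral_betas = betas, seed = 21)
  co <- simulate_cohort(cfg, generate_timeseries = FALSE)
  planted <- attr(co$phenotypes, "planted")
  # the cancelling split keeps the composite change exact unless a rating
  # had to be clipped; those subjects are reported and left out here
  expect_lt(mean(planted$pe_clipped), 0.05)
  sc <- score_phenotypes(co$phenotypes)
  sc <- dplyr::left_join(sc, co$ground_truth[, c("subject", "sys_default",
                                                 "sys_dorsoattention")],
                         by = "subject")
  pain <- sc[sc$pain_group == "pain", ]
  pain <- pain[!planted$pe_clipped[match(pain$subject, planted$subject)], ]
  d <- data.frame(
    y = pain$pain_experience_longitudinal,
    h = zscore(pain$helplessness), dmn = zscore(pain$sys_default),
    dan = zscore(pain$sys_dorsoattention), i1 = zscore(pain$intensity_t1),
    af = zscore(pain$affective_interference_t1),
    ac = zscore(pain$activity_interference_t1))
  fit <- stats::lm(y ~ h + dmn + dan + i1 + af + ac, data = d)
  expect_lt(summary(fit)$sigma, 1e-8)
  expect_equal(unname(coef(fit)[-1]),
               unname(betas[c("helplessness", "sys_default",
                              "sys_dorsoattention", "intensity_t1",
                              "affective_interference_t1",
                              "activity_interference_t1")]),
               tolerance = 1e-6)
})

test_that("a planted interaction is recovered inside its bootstrap CI", {
  co <- simulate_cohort(sim_config(n_subjects = 500, seed = 1003),
                        generate_timeseries = FALSE)
  sc <- score_phenotypes(co$phenotypes)
  sc <- dplyr::left_join(sc, co$ground_truth[, c("subject", "sys_default",
                                                 "sys_dorsoattention")],
                         by = "subject")
  pain <- sc[sc$pain_group == "pain", ]
  d <- data.frame(
    y = pain$pain_experience_longitudinal,
    h = zscore(pain$helplessness), dmn = zscore(pain$sys_default),
    dan = zscore(pain$sys_dorsoattention), i1 = zscore(pain$intensity_t1),
    af = zscore(pain$affective_interference_t1),
    ac = zscore(pain$activity_interference_t1))
  m <- fit_moderation(d, "y", "dmn", "h", covariates = c("dan", "i1", "af", "ac"),
                      n_boot = 1000, seed = 5)
  planted <- default_behavioral_betas()[["interaction"]]
  expect_gt(planted, m$boot_ci[1])
  expect_lt(planted, m$boot_ci[2])
})

test_that("a null generator yields near-zero betas and nominal type-I error", {
  betas <- default_behavioral_betas()
  betas[] <- 0
  n_rep <- 60
  pvals <- numeric(n_rep)
  ests <- matrix(NA_real_, n_rep, 6)
  for (i in seq_len(n_rep)) {
    co <- simulate_cohort(sim_config(n_subjects = 150, behavioral_betas = betas,
                                     seed = 5000 + i),
                          generate_timeseries = FALSE)
    sc <- score_phenotypes(co$phenotypes)
    sc <- dplyr::left_join(sc, co$ground_truth[, c("subject", "sys_default",
                                                   "sys_dorsoattention")],
                           by = "subject")
    pain <- sc[sc$pain_group == "pain", ]
    fit <- ols_standardized(pain, "pain_experience_longitudinal",
                            c("helplessness", "sys_default",
                              "sys_dorsoattention", "intensity_t1",
                              "affective_interference_t1",
                              "activity_interference_t1"))
    td <- tidy(fit)
    ests[i, ] <- td$estimate
    pvals[i] <- td$p.value[td$term == "helplessness"]
  }
  expect_lt(abs(mean(ests)), 0.03)           # betas centered on zero
  rej <- mean(pvals < 0.05)
  expect_lt(abs(rej - 0.05), 0.08)           # binomial tolerance at 60 reps
})

test_that("cohort generation is reproducible and writes readable artifacts", {
  cfg <- suppressWarnings(sim_config(n_subjects = 4, n_volumes = 80, seed = 77))
  a <- suppressWarnings(simulate_cohort(cfg))
  b <- suppressWarnings(simulate_cohort(cfg))
  expect_identical(a$phenotypes, b$phenotypes)
  expect_identical(a$timeseries, b$timeseries)
  expect_identical(a$ground_truth, b$ground_truth)

  dir <- tempfile("cohort")
  on.exit(unlink(dir, recursive = TRUE))
  files <- write_cohort(a, dir)
  expect_true(all(file.exists(files)))
  ts <- read_roi_timeseries(file.path(dir, "sub-001_timeseries.tsv"))
  expect_equal(dim(ts), c(80, 100))
  expect_equal(unname(ts), unname(a$timeseries[[1]]), tolerance = 1e-6)
  part <- read_partition(file.path(dir, "partition.tsv"))
  expect_equal(as.character(part$network),
               as.character(cfg$partition$network))
})
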