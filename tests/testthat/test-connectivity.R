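test_that("framewise displacement matches the hand-computed formula", {
  # all-zero trace
  expect_equal(framewise_displacement(matrix(0, 5, 6)), rep(0, 4))

  # single step: translations (0.1, -0.2, 0.05) mm, rotations (0.002, 0, -0.001) rad
  tr <- matrix(0, 2, 6)
  tr[2, ] <- c(0.002, 0, -0.001, 0.1, -0.2, 0.05)
  expect_equal(framewise_displacement(tr), 0.35 + 50 * 0.003, tolerance = 1e-12)

  # pure rotation of 0.01 rad on one axis -> 0.5 mm at radius 50
  tr2 <- matrix(0, 2, 6); tr2[2, 1] <- 0.01
  expect_equal(framewise_displacement(tr2), 0.5, tolerance = 1e-12)

  # translation-first dialect gives the same answer with columns swapped
  expect_equal(framewise_displacement(tr[, c(4:6, 1:3)], dialect = "spm"),
               framewise_displacement(tr))

  expect_error(framewise_displacement(matrix(0, 5, 5)), "6 columns")
})

test_that("high-motion exclusion fires iff at least half the volumes exceed threshold", {
  fd_bad <- c(rep(0.6, 6), rep(0.1, 4))   # 60% above
  expect_true(exclude_high_motion(fd_bad))
  expect_false(exclude_high_motion(rep(0, 10)))
  fd_edge <- c(rep(0.6, 5), rep(0.1, 5))  # exactly 50% above
  expect_true(exclude_high_motion(fd_edge))
  fd_under <- c(rep(0.6, 4), rep(0.1, 6)) # 40% above
  expect_false(exclude_high_motion(fd_under))
  # threshold is strict on FD (0.5 is not "above 0.5")
  expect_false(exclude_high_motion(rep(0.5, 10)))
})

test_that("DCT drift basis has the prescribed size and orthogonal columns", {
  b <- dct_drift_basis(740, 0.8, 0.01)
  expect_equal(ncol(b), 11)  # floor(2 * 592 s * 0.01 Hz)
  g <- crossprod(b)
  expect_lt(max(abs(g[upper.tri(g)])), 1e-8)
  # frequencies below the cutoff only
  expect_lt(11 / (2 * 740 * 0.8), 0.01)
  expect_gte(12 / (2 * 740 * 0.8), 0.01)
  # cutoff so low that no component fits
  expect_equal(ncol(dct_drift_basis(100, 0.8, 1e-5)), 0)
})

test_that("nuisance regression projects out confounds exactly", {
  set.seed(31)
  n <- 200
  ts <- matrix(rnorm(n * 5), n, 5)
  # intercept only -> mean-centering
  cc <- nuisance_regress(ts, NULL)
  expect_equal(cc, scale(ts, scale = FALSE), ignore_attr = TRUE)

  conf <- cbind(rnorm(n), rnorm(n))
  # a node equal to a confound is annihilated
  ts2 <- cbind(ts, conf[, 1])
  res <- nuisance_regress(ts2, conf)
  expect_lt(max(abs(res[, 6])), 1e-10)
  # residuals orthogonal to every confound
  expect_lt(max(abs(crossprod(res, conf))), 1e-8)
  expect_lt(max(abs(colSums(res))), 1e-8)

  # collinear confounds dropped with a warning, result unchanged
  expect_warning(res2 <- nuisance_regress(ts, cbind(conf, conf[, 1] * 2)),
                 "collinear")
  expect_equal(res2, nuisance_regress(ts, conf))
})

test_that("random-design residuals are orthogonal on a 100-node case", {
  set.seed(77)
  n <- 300
  ts <- matrix(rnorm(n * 100), n, 100)
  conf <- cbind(motion_regressors(matrix(rnorm(n * 6), n, 6)),
                dct_drift_basis(n, 0.8))
  res <- nuisance_regress(ts, conf)
  cors <- abs(stats::cor(res, conf))
  expect_lt(max(cors), 1e-10)
})

test_that("connectivity matrix is Fisher-z, nonnegative, zero-diagonal", {
  set.seed(5)
  t_len <- 400
  a <- rnorm(t_len)
  ts <- cbind(a, -a + rnorm(t_len, sd = 1e-6), rnorm(t_len))
  fc <- compute_fc(ts)
  expect_equal(fc[1, 2], 0)          # anticorrelation truncated to zero
  expect_equal(diag(fc), rep(0, 3), ignore_attr = TRUE)
  expect_true(all(fc >= 0))
  expect_equal(unclass(fc), t(unclass(fc)), ignore_attr = TRUE)

  # r = 0.5 maps to z = atanh(0.5) = 0.5493
  expect_equal(atanh(0.5), 0.5493, tolerance = 1e-4)
  x <- c(1, 2, 3, 4); y <- c(1, 3, 2, 4)  # r = 0.8 -> z = atanh(0.8)
  fc3 <- compute_fc(cbind(x, y, rnorm(4)))
  expect_equal(fc3[1, 2], atanh(0.8), tolerance = 1e-10)

  expect_error(compute_fc(cbind(a, rep(1, t_len))), "zero-variance")
})

test_that("segregation reproduces the hand-worked two-network example", {
  z <- matrix(0.2, 4, 4); diag(z) <- 0
  z[1, 2] <- z[2, 1] <- 0.6931
  z[3, 4] <- z[4, 3] <- 0.4
  seg <- compute_segregation(z, tiny_partition())
  expect_equal(seg$sys[seg$network == "A"], (0.6931 - 0.2) / 0.6931,
               tolerance = 1e-10)
  expect_equal(seg$sys[seg$network == "B"], 0.5, tolerance = 1e-12)

  # all between zero -> sys = 1; W = B -> sys = 0
  z2 <- z; z2[1:2, 3:4] <- 0; z2[3:4, 1:2] <- 0
  expect_equal(compute_segregation(z2, tiny_partition())$sys, c(1, 1))
  z3 <- matrix(0.3, 4, 4); diag(z3) <- 0
  expect_equal(compute_segregation(z3, tiny_partition())$sys, c(0, 0))

  # W = 0 flagged undefined
  z4 <- matrix(0, 4, 4); z4[1, 3] <- z4[3, 1] <- 0.2
  seg4 <- compute_segregation(z4, tiny_partition())
  expect_true(all(is.na(seg4$sys)))
  expect_false(any(seg4$sys_defined))
})

test_that("segregation equals the brute-force pair-loop oracle on random instances", {
  for (case in 1:25) {
    fc <- random_fc(10, seed = case)
    part <- random_partition(10, 3, seed = 1000 + case)
    got <- compute_segregation(fc, part)
    want <- segregation_oracle(fc, part)
    got <- got[match(want$network, got$network), ]
    expect_lt(max(abs(got$sys - want$sys)), 1e-10)
    expect_lt(max(abs(got$w_net - want$w_net)), 1e-10)
    expect_lt(max(abs(got$b_net - want$b_net)), 1e-10)
  }
})

test_that("segregation is invariant to node permutation within the same partition", {
  fc <- random_fc(12, seed = 4)
  part <- random_partition(12, 3, seed = 9)
  base <- compute_segregation(fc, part)
  set.seed(11)
  perm <- sample(12)
  part_p <- part[perm, ]; part_p$node_id <- seq_len(12)
  got <- compute_segregation(fc[perm, perm], part_p)
  got <- got[match(base$network, got$network), ]
  expect_equal(got$sys, base$sys, tolerance = 1e-12)
})

test_that("raising a between-network edge never increases segregation of the touched networks", {
  fc <- random_fc(10, seed = 21)
  part <- random_partition(10, 3, seed = 22)
  membership <- as.character(part$network)
  base <- compute_segregation(fc, part)
  cross <- which(outer(membership, membership, "!=") & upper.tri(fc), arr.ind = TRUE)
  for (k in seq_len(min(10, nrow(cross)))) {
    i <- cross[k, 1]; j <- cross[k, 2]
    fc2 <- fc
    fc2[i, j] <- fc2[j, i] <- fc2[i, j] + 0.3
    bumped <- compute_segregation(fc2, part)
    for (net in c(membership[i], membership[j])) {
      expect_lte(bumped$sys[bumped$network == net],
                 base$sys[base$network == net])
    }
  }
})

test_that("a motion trace read back from .par equals what was written", {
  m <- simulate_motion(50, 0.2, seed = 8)
  f <- tempfile(fileext = ".par")
  on.exit(unlink(f))
  utils::write.table(m, f, row.names = FALSE, col.names = FALSE)
  m2 <- read_motion_par(f)
  expect_equal(unname(m2), unname(m), tolerance = 1e-12)
})
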