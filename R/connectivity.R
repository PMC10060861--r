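#' Discrete-cosine drift basis
#'
#' Builds the low-frequency discrete cosine transform (DCT) regressor set
#' used to model scanner drift. The k-th basis function has frequency
#' `k / (2 * T * tr)` Hz; all components strictly below `cutoff_hz` are
#' retained, giving `K = floor(2 * T * tr * cutoff_hz)` columns (the
#' constant term is handled by the regression intercept, not here). Columns
#' are mutually orthogonal.
#'
#' @param n_volumes Number of volumes T.
#' @param tr_seconds Repetition time in seconds.
#' @param cutoff_hz Drift cutoff frequency in Hz (default 0.01).
#' @return A T x K matrix (K may be 0).
#' @examples
#' dim(dct_drift_basis(740, 0.8)) # 740 x 11
#' @export
dct_drift_basis <- function(n_volumes, tr_seconds, cutoff_hz = 0.01) {
  stopifnot(n_volumes >= 2, tr_seconds > 0)
  if (cutoff_hz <= 0) stop("cutoff_hz must be positive")
  K <- floor(2 * n_volumes * tr_seconds * cutoff_hz)
  K <- min(K, n_volumes - 1)
  t_idx <- seq_len(n_volumes) - 1
  basis <- vapply(
    seq_len(K),
    function(k) cos(pi * k * (2 * t_idx + 1) / (2 * n_volumes)),
    numeric(n_volumes)
  )
  basis <- matrix(basis, nrow = n_volumes, ncol = K)
  if (K > 0) colnames(basis) <- paste0("dct", seq_len(K))
  basis
}

#' Regress nuisance signals out of ROI time series
#'
#' Projects each node's series onto the orthogonal complement of
#' `[intercept | confounds]` by least squares and returns the residuals.
#' Collinear confound columns are dropped with a warning so the projection
#' is well defined.
#'
#' @param ts T x N matrix of ROI time series.
#' @param confounds T x C matrix of nuisance regressors (motion, drift,
#'   tissue signals, ...). May have zero columns, in which case the series
#'   are simply mean-centered.
#' @return T x N matrix of residuals, orthogonal to every retained confound
#'   and to the constant.
#' @export
nuisance_regress <- function(ts, confounds = NULL) {
  ts <- as.matrix(ts)
  if (anyNA(ts)) stop("time series contain missing values")
  n <- nrow(ts)
  X <- cbind(intercept = rep(1, n))
  if (!is.null(confounds) && NCOL(confounds) > 0) {
    confounds <- as.matrix(confounds)
    if (nrow(confounds) != n) {
      stop("confounds have ", nrow(confounds), " rows but time series have ", n)
    }
    X <- cbind(X, confounds)
  }
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    keep <- qrx$pivot[seq_len(qrx$rank)]
    warning("dropping ", ncol(X) - qrx$rank,
            " collinear confound column(s)")
    qrx <- qr(X[, sort(keep), drop = FALSE])
  }
  res <- qr.resid(qrx, ts)
  dimnames(res) <- dimnames(ts)
  res
}

#' Functional connectivity matrix (Fisher-z, nonnegative)
#'
#' Computes the node-by-node Pearson correlation matrix of the time series,
#' Fisher-z transforms it (`z = atanh(r)`, variance-stabilizing so values
#' can be averaged), sets negative values to zero, and zeroes the diagonal
#' (autocorrelations carry no between-region information). Correlations are
#' clipped to +/-(1 - 1e-7) before the transform so numerically perfect
#' correlations do not map to infinity.
#'
#' @param ts T x N matrix of (cleaned) ROI time series.
#' @return N x N symmetric matrix of nonnegative Fisher-z values with a
#'   zero diagonal, of class `connectivity_matrix`.
#' @export
compute_fc <- function(ts) {
  ts <- as.matrix(ts)
  if (anyNA(ts)) stop("time series contain missing values")
  sds <- apply(ts, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- which(sds == 0)
    stop("zero-variance node series: ",
         paste(if (is.null(colnames(ts))) bad else colnames(ts)[bad],
               collapse = ", "))
  }
  if (nrow(ts) <= ncol(ts) / 2) {
    warning("fewer than N/2 volumes for N nodes; connectivity estimates unstable")
  }
  r <- stats::cor(ts)
  r <- pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7)
  z <- atanh(r)
  z[z < 0] <- 0
  diag(z) <- 0
  z <- (z + t(z)) / 2
  class(z) <- c("connectivity_matrix", class(z))
  z
}

#' Per-network system segregation
#'
#' For each network, the within-network connectivity W is the mean Fisher-z
#' value over all unordered node pairs inside the network, and the
#' between-network connectivity B is the mean over all pairs joining a node
#' of the network to a node of any other network ("the rest of the
#' cortex", pooled over networks). System segregation is the normalized
#' difference `SyS = (W - B) / W`: 1 means fully segregated (no external
#' connectivity), 0 means the network is no more connected internally than
#' externally. Pairs whose z was truncated to zero stay in the denominator
#' (truncation substitutes a value, it does not remove the pair). When
#' W = 0 the ratio is undefined and `sys` is returned as `NA` with
#' `sys_defined = FALSE`.
#'
#' @param fc N x N connectivity matrix (see [compute_fc()]).
#' @param partition Partition table mapping the N nodes to networks (see
#'   [canonical_partition()]); row order must match the matrix order.
#' @return A tibble with one row per network: `network`, `n_nodes`,
#'   `w_net`, `b_net`, `sys`, `sys_defined`.
#' @examples
#' z <- matrix(0.2, 4, 4); diag(z) <- 0
#' z[1, 2] <- z[2, 1] <- 0.6931; z[3, 4] <- z[4, 3] <- 0.4
#' part <- tibble::tibble(node_id = 1:4,
#'                        network = c("A", "A", "B", "B"))
#' compute_segregation(z, part)
#' @export
compute_segregation <- function(fc, partition) {
  fc <- unclass(as.matrix(fc))
  partition <- validate_partition(partition)
  n <- nrow(fc)
  if (ncol(fc) != n) stop("connectivity matrix must be square")
  if (nrow(partition) != n) {
    stop("partition has ", nrow(partition), " nodes but matrix is ", n, " x ", n)
  }
  if (max(abs(fc - t(fc))) > 1e-8) stop("connectivity matrix must be symmetric")
  nets <- if (is.factor(partition$network)) {
    levels(droplevels(partition$network))
  } else {
    unique(as.character(partition$network))
  }
  membership <- as.character(partition$network)
  rows <- purrr::map(nets, function(net) {
    inside <- which(membership == net)
    outside <- which(membership != net)
    w_block <- fc[inside, inside, drop = FALSE]
    # mean over unordered within pairs = mean of off-diagonal block entries
    w <- sum(w_block[upper.tri(w_block)]) / (length(inside) * (length(inside) - 1) / 2)
    b <- mean(fc[inside, outside, drop = FALSE])
    defined <- w > 0
    tibble::tibble(
      network = net, n_nodes = length(inside),
      w_net = w, b_net = b,
      sys = if (defined) (w - b) / w else NA_real_,
      sys_defined = defined
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("segregation_profile", class(out))
  out
}

#' One-call segregation for a single subject
#'
#' Convenience wrapper running the full per-subject connectivity chain:
#' optional dummy-scan removal, nuisance regression (motion parameters with
#' derivatives plus a DCT drift basis and any extra signals such as WM/CSF),
#' Fisher-z connectivity, and per-network segregation.
#'
#' @param ts T x N ROI time-series matrix (raw length; dummy scans are
#'   removed here when `n_dummy > 0`).
#' @param partition Node-to-network partition table.
#' @param motion Optional T x 6 motion trace (same raw length as `ts`).
#' @param tr_seconds Repetition time, needed for the drift basis.
#' @param extra_confounds Optional additional nuisance columns (e.g. WM and
#'   CSF signals), same raw length as `ts`.
#' @param n_dummy Dummy scans to drop from the front (default 10; use 0 for
#'   inputs already trimmed).
#' @param drift_cutoff_hz DCT drift cutoff (default 0.01 Hz).
#' @return A `segregation_profile` tibble (see [compute_segregation()]).
#' @export
segregate_subject <- function(ts, partition, motion = NULL, tr_seconds = 0.8,
                              extra_confounds = NULL, n_dummy = 10,
                              drift_cutoff_hz = 0.01) {
  ts <- drop_dummy_scans(ts, n_dummy)
  conf <- dct_drift_basis(nrow(ts), tr_seconds, drift_cutoff_hz)
  if (!is.null(motion)) {
    motion <- drop_dummy_scans(motion, n_dummy)
    conf <- cbind(conf, motion_regressors(motion))
  }
  if (!is.null(extra_confounds)) {
    extra_confounds <- drop_dummy_scans(as.matrix(extra_confounds), n_dummy)
    conf <- cbind(conf, extra_confounds)
  }
  # all-zero columns (e.g. a motionless trace) carry no signal to remove
  conf <- conf[, colSums(abs(conf)) > 0, drop = FALSE]
  clean <- nuisance_regress(ts, conf)
  compute_segregation(compute_fc(clean), partition)
}

#' Read an ROI time-series table
#'
#' Reads a TSV/CSV with one column per parcel (header row of node labels).
#'
#' @param path Path to the file.
#' @return T x N numeric matrix with node labels as column names.
#' @export
read_roi_timeseries <- function(path) {
  reader <- if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::read_csv
  } else {
    readr::read_tsv
  }
  as.matrix(reader(path, show_col_types = FALSE))
}
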