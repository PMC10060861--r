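#' Framewise displacement from a rigid-body motion trace
#'
#' Computes the per-volume framewise displacement (FD) index from the six
#' rigid-body realignment parameters, as the sum of the absolute backward
#' differences of the three translations (mm) plus the absolute rotation
#' differences (radians) converted to arc length on a sphere:
#' `FD_t = sum(|d trans|) + radius * sum(|d rot|)`. The conventional sphere
#' radius of 50 mm approximates the distance from the centre of the head to
#' the cortex.
#'
#' @param trace A T x 6 numeric matrix or data frame of realignment
#'   parameters. With `dialect = "mcflirt"` (default) the first three
#'   columns are rotations in radians and the last three translations in mm;
#'   `dialect = "spm"` expects translations first.
#' @param sphere_radius_mm Radius used to convert rotations to displacement.
#' @param dialect Column order convention, `"mcflirt"` or `"spm"`.
#' @return Numeric vector of length T - 1 of FD values in mm.
#' @examples
#' tr <- matrix(0, 5, 6); tr[3, 4] <- 0.1
#' framewise_displacement(tr)
#' @export
framewise_displacement <- function(trace, sphere_radius_mm = 50,
                                   dialect = c("mcflirt", "spm")) {
  dialect <- match.arg(dialect)
  trace <- as.matrix(trace)
  if (ncol(trace) != 6) {
    stop("motion trace must have 6 columns (", dialect, " dialect: ",
         if (dialect == "mcflirt") "3 rotations [rad] then 3 translations [mm]"
         else "3 translations [mm] then 3 rotations [rad]",
         "); got ", ncol(trace))
  }
  if (nrow(trace) < 2) stop("motion trace needs at least 2 volumes")
  rot_cols <- if (dialect == "mcflirt") 1:3 else 4:6
  d <- abs(diff(trace))
  rowSums(d[, -rot_cols, drop = FALSE]) +
    sphere_radius_mm * rowSums(d[, rot_cols, drop = FALSE])
}

#' Summarize framewise displacement for motion QC
#'
#' @param fd Numeric FD vector (mm), as from [framewise_displacement()].
#' @param fd_threshold Per-volume FD threshold in mm (default 0.5).
#' @param prop_threshold Exclusion rule: a subject is excluded when at least
#'   this fraction of volumes exceeds `fd_threshold` (default 0.5).
#' @return A one-row tibble with `fd_mean`, `prop_above_threshold`,
#'   `n_frames`, and the logical `excluded`.
#' @export
fd_summary <- function(fd, fd_threshold = 0.5, prop_threshold = 0.5) {
  stopifnot(is.numeric(fd), length(fd) >= 1, all(fd >= 0))
  prop <- mean(fd > fd_threshold)
  tibble::tibble(
    fd_mean = mean(fd),
    prop_above_threshold = prop,
    n_frames = length(fd),
    excluded = prop >= prop_threshold
  )
}

#' High-motion exclusion rule
#'
#' A subject is excluded when at least `prop_threshold` of the FD series
#' exceeds `fd_threshold` (>= on the proportion: exactly half qualifying
#' volumes already excludes).
#'
#' @param summary A tibble from [fd_summary()], or a raw FD vector.
#' @inheritParams fd_summary
#' @return Logical, `TRUE` means exclude.
#' @export
exclude_high_motion <- function(summary, fd_threshold = 0.5,
                                prop_threshold = 0.5) {
  if (is.numeric(summary)) {
    summary <- fd_summary(summary, fd_threshold, prop_threshold)
  }
  mean_above <- summary$prop_above_threshold
  mean_above >= prop_threshold
}

#' Motion regressors with temporal derivatives
#'
#' Expands a 6-parameter trace into the 12-column nuisance set of the
#' parameters and their backward-difference derivatives (first row of the
#' derivative zero-padded).
#'
#' @param trace T x 6 motion matrix.
#' @return T x 12 numeric matrix.
#' @export
motion_regressors <- function(trace) {
  trace <- as.matrix(trace)
  if (ncol(trace) != 6) stop("motion trace must have 6 columns")
  deriv <- rbind(0, diff(trace))
  out <- cbind(trace, deriv)
  colnames(out) <- c(paste0("mp", 1:6), paste0("mp", 1:6, "_d"))
  out
}

#' Remove dummy scans
#'
#' Drops the leading volumes acquired before magnetization equilibrium from
#' a time series or motion trace.
#'
#' @param x T x k matrix (ROI time series or motion trace).
#' @param n_dummy Number of initial volumes to drop (default 10).
#' @return The matrix without its first `n_dummy` rows.
#' @export
drop_dummy_scans <- function(x, n_dummy = 10) {
  x <- as.matrix(x)
  stopifnot(n_dummy >= 0, nrow(x) > n_dummy)
  if (n_dummy == 0) return(x)
  x[-seq_len(n_dummy), , drop = FALSE]
}

#' Read a 6-parameter realignment trace
#'
#' Reads whitespace-delimited `.par` realignment output (six columns; the
#' default dialect stores rotations in radians first, then translations in
#' mm).
#'
#' @param path Path to the text file.
#' @return T x 6 numeric matrix.
#' @export
read_motion_par <- function(path) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  if (ncol(m) != 6) {
    stop("expected 6 whitespace-separated columns in ", path, "; got ", ncol(m))
  }
  colnames(m) <- c("rot_x", "rot_y", "rot_z", "trans_x", "trans_y", "trans_z")
  m
}
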