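#' Kabsch least-squares superposition
#'
#' Finds the proper rotation and translation minimizing the (optionally
#' weighted) RMSD between two conformations, via SVD of the weighted
#' covariance matrix with the usual determinant correction so that only
#' proper rotations (det = +1) are returned.
#'
#' @param mobile,reference n x 3 coordinate matrices, n >= 3.
#' @param weights per-atom weights (default uniform).
#' @return list with `rotation` (3 x 3), `translation` (length 3), `rmsd`
#'   (Angstrom), and `coords`, the transformed mobile coordinates
#'   (`coords = mobile %*% rotation`, then shifted).
#' @export
kabsch_superpose <- function(mobile, reference, weights = NULL) {
  stopifnot(is.matrix(mobile), is.matrix(reference),
            ncol(mobile) == 3L, ncol(reference) == 3L)
  n <- nrow(mobile)
  if (n != nrow(reference)) stop("atom counts differ")
  if (n < 3L) stop("superposition needs at least 3 atoms")
  if (is.null(weights)) weights <- rep(1, n)
  w <- weights / sum(weights)
  cm <- colSums(mobile * w)
  cr <- colSums(reference * w)
  a <- sweep(mobile, 2L, cm)
  b <- sweep(reference, 2L, cr)
  h <- t(a * w) %*% b
  s <- svd(h)
  if (sum(s$d > max(s$d) * 1e-10) < 2L)
    stop("degenerate (collinear) coordinates: superposition undefined")
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  fitted <- a %*% rot
  rmsd <- sqrt(sum(w * rowSums((fitted - b)^2)))
  list(rotation = rot, translation = as.numeric(cr - cm %*% rot),
       rmsd = rmsd, coords = sweep(fitted, 2L, cr, `+`))
}

#' Best-fit RMSD between two conformations
#' @inheritParams kabsch_superpose
#' @return RMSD in Angstrom after optimal superposition.
#' @export
fit_rmsd <- function(mobile, reference, weights = NULL)
  kabsch_superpose(mobile, reference, weights)$rmsd

#' RMSD time series against a reference frame
#'
#' Per-frame best-fit (Kabsch) RMSD of the selected atoms to the reference
#' frame, typically the starting structure.
#'
#' @param traj a `traj`.
#' @param selection atom selection string (default all C-alpha).
#' @param reference reference frame index (default 1, the starting frame).
#' @return an `rmsd_series` data.frame with columns `frame` and `rmsd` (A).
#' @export
rmsd_series <- function(traj, selection = "name CA", reference = 1L) {
  idx <- select_atoms(traj, selection)
  if (length(idx) == 0L) stop("empty selection for RMSD")
  nf <- nframes(traj)
  ref <- matrix(traj$coords[reference, idx, ], ncol = 3L)
  r <- numeric(nf)
  for (f in seq_len(nf))
    r[f] <- fit_rmsd(matrix(traj$coords[f, idx, ], ncol = 3L), ref)
  out <- data.frame(frame = seq_len(nf), rmsd = r)
  class(out) <- c("rmsd_series", "data.frame")
  attr(out, "reference") <- reference
  out
}

#' Windowed mean and population standard deviation of an RMSD series
#'
#' @param series an `rmsd_series` (or any data.frame with an `rmsd` column).
#' @param window integer vector of frame indices, e.g.
#'   [equilibration_window()].
#' @return named numeric vector `c(mean = , sd = )` in Angstrom (population
#'   standard deviation, denominator n).
#' @export
mean_rmsd <- function(series, window = seq_len(nrow(series))) {
  if (length(window) == 0L) stop("empty window")
  if (min(window) < 1L || max(window) > nrow(series))
    stop("window outside series")
  v <- series$rmsd[window]
  c(mean = mean(v), sd = sqrt(mean((v - mean(v))^2)))
}

#' Post-equilibration analysis window
#'
#' By default the first 12.5\% of frames are discarded as equilibration
#' (the fraction a 200 ns production run loses when its first 25 ns are
#' dropped) and statistics are taken over the remainder.
#'
#' @param n_frames total frame count.
#' @param equil_frac fraction of initial frames to discard, in `[0, 1)`.
#' @return integer frame indices of the analysis window.
#' @export
equilibration_window <- function(n_frames, equil_frac = 0.125) {
  stopifnot(equil_frac >= 0, equil_frac < 1)
  start <- floor(n_frames * equil_frac) + 1L
  start:n_frames
}

# Iteratively superpose window frames onto their mean structure.
# Returns list(coords = frames x atoms x 3 fitted, mean = atoms x 3).
align_to_mean <- function(traj, idx, window, passes = 2L) {
  nf <- length(window)
  fitted <- traj$coords[window, idx, , drop = FALSE]
  ref <- matrix(fitted[1L, , ], ncol = 3L)
  for (p in seq_len(passes + 1L)) {
    for (f in seq_len(nf)) {
      fitted[f, , ] <- kabsch_superpose(matrix(fitted[f, , ], ncol = 3L),
                                        ref)$coords
    }
    if (p > passes) break
    ref <- apply(fitted, c(2L, 3L), mean)
  }
  list(coords = fitted, mean = apply(fitted, c(2L, 3L), mean))
}

#' Per-residue RMSF about the mean structure
#'
#' Frames in the analysis window are superposed onto their iteratively
#' refined mean structure (two refinement passes), and the root-mean-square
#' fluctuation of each selected atom about its mean position is reported.
#' Using the mean structure (rather than frame 1) as the fluctuation
#' reference keeps slow drift out of the per-residue amplitudes.
#'
#' @param traj a `traj`.
#' @param selection atom selection (default all C-alpha).
#' @param window frame indices; default the full trajectory.
#' @return an `rmsf_profile` data.frame with columns `resid`, `chain`,
#'   `rmsf` (A).
#' @export
rmsf <- function(traj, selection = "name CA",
                 window = seq_len(nframes(traj))) {
  if (length(window) < 2L) stop("RMSF needs at least 2 frames")
  idx <- select_atoms(traj, selection)
  if (length(idx) == 0L) stop("empty selection for RMSF")
  al <- align_to_mean(traj, idx, window)
  dev2 <- sweep(al$coords, c(2L, 3L), al$mean)
  msf <- apply(dev2^2, 2L, sum) / length(window)  # sums over frames & xyz
  out <- data.frame(resid = traj$topology$resid[idx],
                    chain = traj$topology$chain[idx],
                    rmsf = sqrt(msf))
  class(out) <- c("rmsf_profile", "data.frame")
  out
}

#' @param x an `rmsf_profile`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.rmsf_profile <- function(x, ...) {
  graphics::plot(x$resid, x$rmsf, type = "l", xlab = "residue",
                 ylab = "RMSF (Å)", ...)
  invisible(x)
}

#' @param x an `rmsd_series`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.rmsd_series <- function(x, ...) {
  graphics::plot(x$frame, x$rmsd, type = "l", xlab = "frame",
                 ylab = "RMSD (Å)", ...)
  invisible(x)
}
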