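#' Dynamic cross-correlation matrix of C-alpha motions
#'
#' For each atom pair, the normalized time-averaged inner product of
#' displacement vectors about the mean structure,
#' `C_ij = <dr_i . dr_j> / sqrt(<|dr_i|^2> <|dr_j|^2>)`,
#' with the average spanning the analysis window.  Frames are superposed
#' onto the iteratively refined mean structure first so that rigid-body
#' motion does not masquerade as internal correlation (`fit = FALSE`
#' skips this, e.g. for pre-aligned or sub-superposable systems).
#'
#' @param traj a `traj`.
#' @param selection atom selection (default all C-alpha).
#' @param window frame indices; default the full trajectory.  Use the same
#'   post-equilibration window as the RMSF analysis.
#' @param fit superpose frames onto the mean structure first (default
#'   TRUE; requires >= 3 selected atoms).
#' @return a `dccm_matrix`: residues x residues correlation matrix with
#'   `resid` dimnames; symmetric, unit diagonal, entries in `[-1, 1]`.
#'   Zero-variance atoms yield a zero row/column (diagonal kept at 1) and
#'   a warning.
#' @export
dccm <- function(traj, selection = "name CA",
                 window = seq_len(nframes(traj)), fit = TRUE) {
  if (length(window) < 2L) stop("DCCM needs at least 2 frames")
  idx <- select_atoms(traj, selection)
  if (length(idx) == 0L) stop("empty selection for DCCM")
  if (fit) {
    al <- align_to_mean(traj, idx, window)
    coords <- al$coords
    mu <- al$mean
  } else {
    coords <- traj$coords[window, idx, , drop = FALSE]
    mu <- apply(coords, c(2L, 3L), mean)
  }
  dev <- sweep(coords, c(2L, 3L), mu)
  nf <- length(window)
  cross <- matrix(0, length(idx), length(idx))
  for (k in 1:3) cross <- cross + crossprod(dev[, , k]) / nf
  v <- diag(cross)
  zero <- v < 1e-12
  if (any(zero))
    warning(sum(zero), " zero-variance atom(s) in DCCM; rows zeroed")
  denom <- sqrt(pmax(v, 1e-300))
  C <- cross / outer(denom, denom)
  C[zero, ] <- 0
  C[, zero] <- 0
  diag(C) <- 1
  C <- pmin(pmax(C, -1), 1)
  dimnames(C) <- list(traj$topology$resid[idx], traj$topology$resid[idx])
  class(C) <- c("dccm_matrix", "matrix")
  C
}

#' Mask weak correlations for display
#'
#' Entries with `|C|` strictly below the threshold are set to `NA` in the
#' returned copy (the conventional white-out of near-zero couplings in
#' correlation heat maps); the input matrix is untouched.
#'
#' @param matrix a `dccm_matrix` (or plain numeric matrix).
#' @param threshold masking threshold in `[0, 1]` (default 0.3).
#' @return the masked matrix.
#' @export
mask_low <- function(matrix, threshold = 0.3) {
  if (threshold < 0 || threshold > 1)
    stop("mask threshold must lie in [0, 1]")
  out <- matrix
  out[abs(out) < threshold] <- NA_real_
  out
}

#' @param x a `dccm_matrix`.
#' @param mask optional display mask threshold (see [mask_low()]).
#' @param ... passed to [graphics::image()].
#' @export
plot.dccm_matrix <- function(x, mask = NULL, ...) {
  z <- unclass(x)
  if (!is.null(mask)) z <- mask_low(z, mask)
  r <- as.integer(rownames(x))
  graphics::image(r, r, z, zlim = c(-1, 1), xlab = "residue",
                  ylab = "residue",
                  col = grDevices::hcl.colors(64, "Blue-Red 2"), ...)
  invisible(x)
}
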