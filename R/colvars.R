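#' Collective variables: pocket perimeter and side-chain bend angle
#'
#' The conformational state of the APC armadillo-repeat binding site is
#' summarized by two geometric collective variables (CVs): the perimeter of
#' the triangle formed by the C-alpha atoms of the three hydrophobic-pocket
#' residues (F458, R463, F510 by default), and the bend angle of the R549
#' side chain, measured at the C-gamma vertex between the guanidino carbon
#' (PDB atom CZ) and the C-alpha.  Together they separate the equatorial
#' and axial arginine conformers and track pocket breathing.
#'
#' @param frame an atoms x 3 coordinate matrix (see [frame_coords()]).
#' @param topology the matching `topology`.
#' @param resids the three pocket residue ids.
#' @return `pocket_perimeter`: triangle perimeter in Angstrom (sum of the
#'   three pairwise C-alpha distances).
#' @export
pocket_perimeter <- function(frame, topology, resids = c(458L, 463L, 510L)) {
  stopifnot(length(resids) == 3L)
  p <- matrix(NA_real_, 3L, 3L)
  for (k in 1:3) {
    i <- which(topology$resid == resids[k] & topology$name == "CA")
    if (length(i) != 1L)
      stop("residue ", resids[k], " has no unique CA atom")
    p[k, ] <- frame[i, ]
  }
  d <- function(a, b) sqrt(sum((a - b)^2))
  d(p[1, ], p[2, ]) + d(p[2, ], p[3, ]) + d(p[1, ], p[3, ])
}

#' @param resid residue carrying the CA/CG/CZ triplet (default 549).
#' @return `bend_angle`: the CA--CG--CZ angle in degrees, vertex at CG.
#' @rdname pocket_perimeter
#' @export
bend_angle <- function(frame, topology, resid = 549L) {
  at <- function(nm) {
    i <- which(topology$resid == resid & topology$name == nm)
    if (length(i) != 1L)
      stop("residue ", resid, " is missing atom ", nm)
    frame[i, ]
  }
  ca <- at("CA"); cg <- at("CG"); cz <- at("CZ")
  v1 <- cz - cg
  v2 <- ca - cg
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 < 1e-12 || n2 < 1e-12)
    stop("zero-length vector in bend angle for residue ", resid)
  cosang <- sum(v1 * v2) / (n1 * n2)
  acos(min(1, max(-1, cosang))) * 180 / pi
}

#' Compute the CV series for a whole trajectory
#'
#' @param traj a `traj`.
#' @param pocket_resids,bend_resid residue ids forwarded to the two CVs.
#' @param dt optional time step (ns per frame) to stamp the series.
#' @return a `cv_series` data.frame with columns `frame`, `perimeter` (A),
#'   `angle` (degrees), and `time` when `dt` is given.
#' @export
cv_series <- function(traj, pocket_resids = c(458L, 463L, 510L),
                      bend_resid = 549L, dt = NULL) {
  nf <- nframes(traj)
  if (nf < 1L) stop("empty trajectory")
  top <- traj$topology
  perim <- numeric(nf)
  ang <- numeric(nf)
  for (f in seq_len(nf)) {
    fr <- frame_coords(traj, f)
    perim[f] <- pocket_perimeter(fr, top, pocket_resids)
    ang[f] <- bend_angle(fr, top, bend_resid)
  }
  out <- data.frame(frame = seq_len(nf), perimeter = perim, angle = ang)
  if (!is.null(dt)) out$time <- (out$frame - 1L) * dt
  class(out) <- c("cv_series", "data.frame")
  out
}

#' @param x a `cv_series`.
#' @param ... ignored.
#' @export
print.cv_series <- function(x, ...) {
  cat(sprintf(
    "CV series: %d frames | perimeter %.2f-%.2f A | angle %.1f-%.1f deg\n",
    nrow(x), min(x$perimeter), max(x$perimeter), min(x$angle), max(x$angle)))
  invisible(x)
}

#' Write / read a CV series as delimited text
#' @param cv a `cv_series`.
#' @param path file path.
#' @param sep field separator.
#' @export
write_cv_series <- function(cv, path, sep = "\t") {
  utils::write.table(as.data.frame(cv), path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_cv_series
#' @export
read_cv_series <- function(path, sep = "\t") {
  d <- utils::read.table(path, header = TRUE, sep = sep)
  if (!all(c("frame", "perimeter", "angle") %in% names(d)))
    stop("CV table must have columns frame, perimeter, angle")
  class(d) <- c("cv_series", "data.frame")
  d
}
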