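#' 2D joint histogram of a CV series
#'
#' Bins the (perimeter, angle) pairs on a regular grid spanning the data
#' range with 2\% padding per axis, and normalizes counts to a joint
#' probability `g` (counts / n).
#'
#' @param cv a `cv_series`.
#' @param bins_per_axis number of bins along each axis (default 200).
#' @return a `pmf_grid` without the free-energy surface filled in yet;
#'   fields `xedges`, `yedges`, `xmids`, `ymids`, `counts`, `g`.
#' @export
joint_histogram <- function(cv, bins_per_axis = 200L) {
  n <- nrow(cv)
  if (is.null(n) || n < 1L) stop("CV series has no frames")
  pad_range <- function(v) {
    r <- range(v)
    w <- diff(r)
    if (w == 0) w <- max(abs(r[1]), 1) * 0.01
    c(r[1] - 0.02 * w, r[2] + 0.02 * w)
  }
  xr <- pad_range(cv$perimeter)
  yr <- pad_range(cv$angle)
  xedges <- seq(xr[1], xr[2], length.out = bins_per_axis + 1L)
  yedges <- seq(yr[1], yr[2], length.out = bins_per_axis + 1L)
  ix <- pmin(pmax(findInterval(cv$perimeter, xedges,
                               rightmost.closed = TRUE), 1L), bins_per_axis)
  iy <- pmin(pmax(findInterval(cv$angle, yedges,
                               rightmost.closed = TRUE), 1L), bins_per_axis)
  counts <- matrix(0, bins_per_axis, bins_per_axis)
  tab <- table(factor(ix, levels = seq_len(bins_per_axis)),
               factor(iy, levels = seq_len(bins_per_axis)))
  counts[] <- as.numeric(tab)
  structure(list(xedges = xedges, yedges = yedges,
                 xmids = (xedges[-1] + xedges[-length(xedges)]) / 2,
                 ymids = (yedges[-1] + yedges[-length(yedges)]) / 2,
                 counts = counts, g = counts / n, n = n),
            class = "pmf_grid")
}

#' Boltzmann-inversion free-energy surface
#'
#' Converts the normalized joint probability into a relative free energy
#' by the conventional Boltzmann inversion `dG = -kB * T * ln g`, then
#' shifts so the minimum over non-empty bins is zero.  Empty bins carry
#' `NA` (no finite free energy is defined for unvisited states).
#'
#' @param grid a `pmf_grid` from [joint_histogram()].
#' @param kB Boltzmann constant, kcal mol^-1 K^-1 (default 3.30e-4, the
#'   value the landscape convention here inherits).
#' @param T temperature in K (default 300).
#' @return the `pmf_grid` with fields `dG` (kcal/mol, min-shifted), `kB`,
#'   `T` filled in.
#' @export
pmf <- function(grid, kB = 3.30e-4, T = 300) {
  stopifnot(inherits(grid, "pmf_grid"))
  dG <- matrix(NA_real_, nrow(grid$g), ncol(grid$g))
  nz <- grid$g > 0
  dG[nz] <- -kB * T * log(grid$g[nz])
  dG <- dG - min(dG, na.rm = TRUE)
  grid$dG <- dG
  grid$kB <- kB
  grid$T <- T
  grid
}

#' @param x a `pmf_grid`.
#' @param ... ignored.
#' @export
print.pmf_grid <- function(x, ...) {
  cat(sprintf("PMF grid %dx%d, %d frames", length(x$xmids),
              length(x$ymids), x$n))
  if (!is.null(x$dG))
    cat(sprintf(", dG range 0-%.2f kcal/mol", max(x$dG, na.rm = TRUE)))
  cat("\n")
  invisible(x)
}

#' @param x a `pmf_grid` with `dG` computed.
#' @param ... passed to [graphics::image()].
#' @export
plot.pmf_grid <- function(x, ...) {
  z <- if (is.null(x$dG)) x$g else x$dG
  graphics::image(x$xmids, x$ymids, z, xlab = "perimeter (Å)",
                  ylab = "angle (°)",
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(x)
}

# Gaussian-smoothed count field (separable kernel); used by basin
# detection only -- the raw g and dG are never altered.
smooth_counts <- function(counts, sigma) {
  if (sigma <= 0) return(counts)
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-half:half, sd = sigma)
  k <- k / sum(k)
  pad_conv <- function(m) {  # convolve each column with k (edge-replicated)
    np <- nrow(m)
    mp <- rbind(m[rep(1L, half), , drop = FALSE], m,
                m[rep(np, half), , drop = FALSE])
    out <- matrix(0, np, ncol(m))
    for (j in seq_along(k))
      out <- out + k[j] * mp[j:(j + np - 1L), , drop = FALSE]
    out
  }
  t(pad_conv(t(pad_conv(counts))))
}

#' Detect free-energy basins
#'
#' Local minima of the (lightly smoothed) free-energy surface lying within
#' `depth_cut` of the global minimum, merged greedily (the deeper minimum
#' absorbs the shallower) when either closer than `min_separation` bins or
#' not separated by a free-energy barrier of at least `barrier_cut` along
#' the straight path between them — minima on one shot-noise-rippled
#' plateau belong to one basin, while genuinely distinct conformers keep a
#' real barrier between their wells.  The result is sorted by depth.
#' Smoothing of the count field before inversion suppresses the Poisson
#' shot noise a finely binned histogram carries; the returned centers are
#' bin centers of the smoothed surface.
#'
#' @param pmfgrid a `pmf_grid` with `dG` computed.
#' @param depth_cut maximum `dG` (kcal/mol above the global minimum) a
#'   local minimum may have to count as a basin.
#' @param min_separation merge radius in bins (Chebyshev distance).
#' @param smooth_sigma Gaussian smoothing width in bins applied to the
#'   counts before basin detection (0 disables).
#' @param barrier_cut minimum barrier height (kcal/mol above the shallower
#'   minimum) for two minima to count as distinct basins; about kB*T/2 at
#'   the default landscape temperature.
#' @param merge_widths physical merge radius `c(perimeter, angle)` in
#'   (A, degrees): minima closer than this on both axes collapse into one
#'   basin.  Defaults to the membership half-widths of [assign_frames()],
#'   below which two minima could not be assigned separately anyway.
#' @return a `basin_set` data.frame: `label`, `center_perimeter`,
#'   `center_angle`, `dG`, `ix`, `iy`; possibly 0 rows (with a warning).
#' @export
find_basins <- function(pmfgrid, depth_cut = 0.2, min_separation = 20L,
                        smooth_sigma = 2, barrier_cut = 0.05,
                        merge_widths = c(0.75, 20)) {
  stopifnot(inherits(pmfgrid, "pmf_grid"), !is.null(pmfgrid$dG))
  sm <- smooth_counts(pmfgrid$counts, smooth_sigma)
  dG <- matrix(NA_real_, nrow(sm), ncol(sm))
  pos <- sm > 0
  dG[pos] <- -pmfgrid$kB * pmfgrid$T * log(sm[pos] / sum(pmfgrid$counts))
  dG <- dG - min(dG, na.rm = TRUE)

  nb <- nrow(dG)
  # local minima over the 8-neighborhood
  big <- max(dG, na.rm = TRUE) + 1
  dGf <- dG
  dGf[is.na(dGf)] <- big
  shift <- function(m, di, dj) {
    out <- matrix(big, nb, nb)
    si <- seq_len(nb) + di; sj <- seq_len(nb) + dj
    ok_i <- si >= 1 & si <= nb; ok_j <- sj >= 1 & sj <= nb
    out[which(ok_i), which(ok_j)] <- m[si[ok_i], sj[ok_j]]
    out
  }
  is_min <- matrix(TRUE, nb, nb)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    is_min <- is_min & (dGf <= shift(dGf, di, dj))
  }
  cand <- which(is_min & !is.na(dG) & dG <= depth_cut, arr.ind = TRUE)
  if (nrow(cand) == 0L) {
    warning("no basins under depth cut ", depth_cut, " kcal/mol")
    out <- data.frame(label = character(0), center_perimeter = numeric(0),
                      center_angle = numeric(0), dG = numeric(0),
                      ix = integer(0), iy = integer(0))
    class(out) <- c("basin_set", "data.frame")
    return(out)
  }
  depth <- dG[cand]
  ord <- order(depth)
  cand <- cand[ord, , drop = FALSE]
  depth <- depth[ord]
  # max dG along the straight grid path between two minima (empty bins do
  # not raise the barrier: sparse sampling is no evidence of one)
  path_barrier <- function(a, b) {
    steps <- max(abs(a - b), 1L)
    ii <- round(seq(a[1], b[1], length.out = steps + 1L))
    jj <- round(seq(a[2], b[2], length.out = steps + 1L))
    v <- dG[cbind(ii, jj)]
    if (all(is.na(v))) return(Inf)
    max(v, na.rm = TRUE)
  }
  keep <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(cand))) {
      if (j <= i || !keep[j]) next
      close_by <- max(abs(cand[i, ] - cand[j, ])) < min_separation ||
        (abs(pmfgrid$xmids[cand[i, 1]] - pmfgrid$xmids[cand[j, 1]]) <=
           merge_widths[1] &&
         abs(pmfgrid$ymids[cand[i, 2]] - pmfgrid$ymids[cand[j, 2]]) <=
           merge_widths[2])
      if (close_by ||
          path_barrier(cand[i, ], cand[j, ]) - depth[j] < barrier_cut)
        keep[j] <- FALSE  # deeper basin absorbs the shallower
    }
  }
  cand <- cand[keep, , drop = FALSE]
  depth <- depth[keep]
  out <- data.frame(label = paste0("B", seq_len(nrow(cand))),
                    center_perimeter = pmfgrid$xmids[cand[, 1]],
                    center_angle = pmfgrid$ymids[cand[, 2]],
                    dG = depth,
                    ix = cand[, 1], iy = cand[, 2])
  class(out) <- c("basin_set", "data.frame")
  out
}

#' Assign frames to basins and report occupancies
#'
#' A frame belongs to the nearest basin whose axis-aligned rectangle
#' (center +/- half-widths) contains it; frames in no rectangle are
#' `"unassigned"`.  Overlap ties go to the deeper basin.
#'
#' @param cv a `cv_series`.
#' @param basins a `basin_set` from [find_basins()].
#' @param half_widths `c(perimeter, angle)` membership half-widths
#'   (default 0.75 A and 20 degrees).
#' @return list with `labels` (per-frame basin label or `"unassigned"`)
#'   and `occupancy`, a data.frame of per-basin counts and fractions plus
#'   an `unassigned` row; fractions sum to 1.
#' @export
assign_frames <- function(cv, basins, half_widths = c(0.75, 20)) {
  if (nrow(basins) == 0L) stop("empty basin set")
  n <- nrow(cv)
  lab <- rep("unassigned", n)
  best <- rep(Inf, n)  # dG of current assignment; deeper basin wins ties
  for (i in seq_len(nrow(basins))) {
    inside <- abs(cv$perimeter - basins$center_perimeter[i]) <= half_widths[1] &
              abs(cv$angle - basins$center_angle[i]) <= half_widths[2]
    take <- inside & basins$dG[i] < best
    lab[take] <- basins$label[i]
    best[take] <- basins$dG[i]
  }
  lv <- c(basins$label, "unassigned")
  cnt <- table(factor(lab, levels = lv))
  occ <- data.frame(basin = lv, count = as.integer(cnt),
                    fraction = as.numeric(cnt) / n)
  class(occ) <- c("occupancy_report", "data.frame")
  list(labels = lab, occupancy = occ)
}

#' @param x an `occupancy_report`.
#' @param ... ignored.
#' @export
print.occupancy_report <- function(x, ...) {
  cat("Basin occupancy:\n")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-12s %8d frames  %6.2f%%\n", x$basin[i], x$count[i],
                100 * x$fraction[i]))
  invisible(x)
}

#' Representative frame of a basin
#'
#' Member frames (evenly subsampled to at most `max_frames`) are clustered
#' by average-linkage hierarchical agglomeration on the pairwise best-fit
#' C-alpha RMSD matrix; within the largest cluster the frame minimizing
#' the summed RMSD to its co-members is returned.  Ties break to the
#' lowest frame index.
#'
#' @param traj a `traj`.
#' @param labels per-frame basin labels from [assign_frames()].
#' @param basin the basin label to summarize.
#' @param selection atoms used for the RMSD metric.
#' @param max_frames subsampling cap on the clustered member set.
#' @param k number of clusters to cut the tree into (capped at member
#'   count).
#' @return a frame index into `traj`.
#' @export
representative_frame <- function(traj, labels, basin,
                                 selection = "name CA", max_frames = 500L,
                                 k = 5L) {
  members <- which(labels == basin)
  if (length(members) == 0L) stop("basin '", basin, "' has no member frames")
  if (length(members) == 1L) return(members)
  if (length(members) > max_frames)
    members <- members[unique(round(seq(1L, length(members),
                                        length.out = max_frames)))]
  idx <- select_atoms(traj, selection)
  m <- length(members)
  sets <- lapply(members, function(f) matrix(traj$coords[f, idx, ], ncol = 3L))
  dm <- matrix(0, m, m)
  for (i in seq_len(m - 1L)) for (j in (i + 1L):m)
    dm[i, j] <- dm[j, i] <- fit_rmsd(sets[[i]], sets[[j]])
  hc <- stats::hclust(stats::as.dist(dm), method = "average")
  cl <- stats::cutree(hc, k = min(k, m))
  main <- as.integer(names(which.max(table(cl))))
  inset <- which(cl == main)
  ssum <- rowSums(dm[inset, inset, drop = FALSE])
  members[inset[which.min(ssum)]]  # which.min takes the first = lowest index
}

#' Residue-pair contact map between two selections
#'
#' Residue pairs whose minimum inter-atom distance does not exceed the
#' cutoff.  Plumbing for interface inspection; symmetric in its arguments.
#'
#' @param frame atoms x 3 coordinate matrix.
#' @param topology the matching `topology`.
#' @param sel_a,sel_b integer atom index vectors (e.g. from
#'   [select_atoms()]).
#' @param cutoff contact distance cutoff in Angstrom (default 4.5).
#' @return data.frame `resid_a`, `resid_b`, `min_dist`.
#' @export
contact_map <- function(frame, topology, sel_a, sel_b, cutoff = 4.5) {
  if (length(sel_a) == 0L || length(sel_b) == 0L)
    stop("empty selection in contact map")
  pa <- frame[sel_a, , drop = FALSE]
  pb <- frame[sel_b, , drop = FALSE]
  d2 <- outer(rowSums(pa^2), rowSums(pb^2), `+`) - 2 * pa %*% t(pb)
  d <- sqrt(pmax(d2, 0))
  ra <- topology$resid[sel_a]
  rb <- topology$resid[sel_b]
  agg <- stats::aggregate(as.vector(d),
                          list(resid_a = ra[row(d)], resid_b = rb[col(d)]),
                          min)
  names(agg)[3] <- "min_dist"
  out <- agg[agg$min_dist <= cutoff, , drop = FALSE]
  rownames(out) <- NULL
  out
}
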