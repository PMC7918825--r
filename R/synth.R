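#' Specify one basin of a synthetic CV-space mixture
#'
#' A basin is a 2D normal in collective-variable space: perimeter (x, in
#' Angstrom) by side-chain bend angle (y, in degrees).  `split_perimeter`
#' turns the component into a symmetric bimodal pair along the perimeter
#' axis (centers at `center_perimeter +/- split_perimeter`), which is how
#' the sporadically distributed, non-basin density flanking the dominant
#' conformers on both sides of the pocket-perimeter axis is emulated
#' without inventing internal structure for it.
#'
#' @param center_perimeter,center_angle basin center (A, degrees).
#' @param width_perimeter,width_angle standard deviations (A, degrees).
#' @param weight mixture weight in `[0, 1]`.
#' @param label basin label (e.g. "M1"); `"background"` marks density that
#'   belongs to no conformational basin.
#' @param split_perimeter half-separation of an optional symmetric bimodal
#'   split along the perimeter axis (A); 0 for a plain 2D normal.
#' @return a `basin_spec` list.
#' @export
basin_spec <- function(center_perimeter, center_angle, width_perimeter,
                       width_angle, weight, label = NA_character_,
                       split_perimeter = 0) {
  stopifnot(width_perimeter > 0, width_angle > 0,
            weight >= 0, weight <= 1, split_perimeter >= 0)
  structure(list(center_perimeter = center_perimeter,
                 center_angle = center_angle,
                 width_perimeter = width_perimeter,
                 width_angle = width_angle,
                 weight = weight, label = label,
                 split_perimeter = split_perimeter),
            class = "basin_spec")
}

#' Specify a full synthetic ensemble
#'
#' Parameterizes a seeded synthetic C-alpha trajectory: a CV-space mixture
#' (the conformational basins), per-residue fluctuation amplitudes
#' (target RMSF, in Angstrom), optional block-correlation impositions, and
#' a calibrated mean displacement from the starting structure.
#'
#' @param basins list of [basin_spec()]s; weights must sum to 1 (1e-9).
#' @param n_frames number of frames to generate.
#' @param n_residues number of residues.  When >= 149 the residue ids run
#'   `401:(400 + n_residues)` (covering the pocket residues 458/463/510 and
#'   the arginine 549); smaller systems keep those four ids and pad with
#'   filler ids from 401 up.
#' @param fluct_amplitude either a single default amplitude (A) or a named
#'   numeric vector of per-residue overrides keyed by residue id, with the
#'   default in the unnamed/`"default"` entry.
#' @param corr_blocks list of correlation impositions, each a list with
#'   `a` and `b` (integer residue-id vectors) and `sign` (+1 or -1).
#' @param corr_strength fraction of block residues' displacement variance
#'   carried by the shared latent motion (0-1).  The raw inter-block
#'   correlation equals this value; superposition absorbs part of the
#'   coherent motion, so the default 0.85 yields DCCM entries near
#'   +/-0.6 after fitting.
#' @param mean_rmsd_target calibrated post-equilibration mean C-alpha RMSD
#'   to the starting frame (A); 0 disables the drift field.
#' @param equil_frac equilibration fraction over which the drift ramps in.
#' @param seed RNG seed; every draw the generator makes flows from it.
#' @return an `ensemble_spec` list.
#' @export
ensemble_spec <- function(basins, n_frames, n_residues = 160L,
                          fluct_amplitude = 1.0, corr_blocks = list(),
                          corr_strength = 0.85, mean_rmsd_target = 0,
                          equil_frac = 0.125, seed = 1L) {
  stopifnot(n_frames >= 1, n_residues >= 4)
  w <- vapply(basins, `[[`, 0, "weight")
  if (abs(sum(w) - 1) > 1e-9)
    stop("basin weights must sum to 1 (got ", format(sum(w)), ")")
  if (any(unlist(fluct_amplitude) < 0))
    stop("fluct_amplitude entries must be >= 0")
  stopifnot(corr_strength >= 0, corr_strength < 1)
  structure(list(basins = basins, n_frames = as.integer(n_frames),
                 n_residues = as.integer(n_residues),
                 fluct_amplitude = fluct_amplitude,
                 corr_blocks = corr_blocks, corr_strength = corr_strength,
                 mean_rmsd_target = mean_rmsd_target,
                 equil_frac = equil_frac, seed = as.integer(seed)),
            class = "ensemble_spec")
}

# residue ids used by the CVs
.cv_resids <- c(458L, 463L, 510L, 549L)

spec_resids <- function(spec) {
  n <- spec$n_residues
  if (n >= 149L) return(401L:(400L + n))
  fill <- setdiff(401L:(401L + n), .cv_resids)[seq_len(n - 4L)]
  sort(c(.cv_resids, fill))
}

# per-residue amplitude vector in resid order
spec_amplitudes <- function(spec, resids) {
  fa <- spec$fluct_amplitude
  if (is.null(names(fa))) {
    if (length(fa) != 1L)
      stop("unnamed fluct_amplitude must be a single default value")
    return(rep(fa, length(resids)))
  }
  default <- if ("default" %in% names(fa)) fa[["default"]] else 1.0
  out <- rep(default, length(resids))
  ov <- fa[names(fa) != "default"]
  hit <- match(as.integer(names(ov)), resids)
  out[hit[!is.na(hit)]] <- ov[!is.na(hit)]
  out
}

#' Build the C-alpha template structure an ensemble is embedded around
#'
#' One CA pseudo-atom per residue laid out on a smooth helical curve, with
#' three exceptions: the pocket residues (458/463/510) are placed as a
#' triangle of perimeter 24 A, and residue 549 additionally carries CG and
#' CZ pseudo-atoms so the bend-angle CV is defined.
#'
#' @param spec an `ensemble_spec` (or integer residue-id vector).
#' @return a one-frame `traj` to use as embedding template.
#' @export
synthetic_template <- function(spec) {
  resids <- if (inherits(spec, "ensemble_spec")) spec_resids(spec)
            else sort(as.integer(spec))
  if (!all(.cv_resids %in% resids))
    stop("template must contain residues ",
         paste(.cv_resids, collapse = ", "))
  n <- length(resids)
  t <- seq_len(n)
  # loose helix, ~3.8 A between consecutive CA
  ca <- cbind(9.5 * cos(t / 3), 9.5 * sin(t / 3), 2.9 * t / 3)
  rownames(ca) <- NULL
  # pocket triangle: equilateral, side 8 A (perimeter 24 A), near the chain
  ctr <- colMeans(ca[match(c(458L, 463L, 510L), resids), , drop = FALSE])
  s <- 8 / sqrt(3)  # circumradius of an equilateral triangle of side 8
  tri <- rbind(c(s, 0, 0),
               c(-s / 2,  s * sqrt(3) / 2, 0),
               c(-s / 2, -s * sqrt(3) / 2, 0))
  ca[match(c(458L, 463L, 510L), resids), ] <- sweep(tri, 2L, ctr, `+`)
  name <- rep("CA", n)
  resid <- resids
  # side-chain pseudo-atoms of the arginine
  i549 <- match(549L, resids)
  cg <- ca[i549, ] + c(1.5, 0.4, 0.2)
  cg <- ca[i549, ] + 1.5 * (cg - ca[i549, ]) / sqrt(sum((cg - ca[i549, ])^2))
  cz <- cg + 2.4 * c(0.2, 0.9, 0.4) / sqrt(sum(c(0.2, 0.9, 0.4)^2))
  xyz <- rbind(ca, cg, cz)
  top <- topology(name = c(name, "CG", "CZ"),
                  resname = c(ifelse(resids %in% .cv_resids,
                                     c("PHE", "ARG", "PHE", "ARG")[
                                       match(resids, .cv_resids)], "ALA")[
                                         seq_len(n)], "ARG", "ARG"),
                  resid = c(resid, 549L, 549L))
  trajectory(top, xyz)
}

#' Sample a CV series from a basin mixture
#'
#' Each frame picks a basin by weight, then draws (perimeter, angle) from
#' that basin's 2D normal; a `split_perimeter` component additionally picks
#' the left or right lobe with equal probability.  Angles are reflected
#' into the geometric range (0, 180] degrees.
#'
#' @param spec an `ensemble_spec`.
#' @param seed overrides `spec$seed` when given.
#' @return a `cv_series` with an extra column `basin` (the generating
#'   component's label; `"none"` for background components).
#' @export
sample_cv_series <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "ensemble_spec"))
  set.seed(seed)
  n <- spec$n_frames
  w <- vapply(spec$basins, `[[`, 0, "weight")
  comp <- sample.int(length(w), n, replace = TRUE, prob = w)
  perim <- numeric(n)
  ang <- numeric(n)
  for (k in seq_along(w)) {
    i <- which(comp == k)
    if (!length(i)) next
    b <- spec$basins[[k]]
    mu_x <- b$center_perimeter
    if (b$split_perimeter > 0)
      mu_x <- mu_x + sample(c(-1, 1), length(i), TRUE) * b$split_perimeter
    perim[i] <- stats::rnorm(length(i), mu_x, b$width_perimeter)
    ang[i] <- stats::rnorm(length(i), b$center_angle, b$width_angle)
  }
  # reflect into the geometric range (0, 180]: a bend drawn past 180
  # degrees is the same geometry as its mirror image, so folding (rather
  # than clamping, which would pile a probability atom onto the boundary
  # bin of the landscape) keeps the density smooth at the edge
  ang <- abs(ang)
  ang <- ifelse(ang > 180, 360 - ang, ang)
  ang <- pmin(pmax(ang, 1e-6), 180)
  perim <- pmax(perim, 1e-6)
  labels <- vapply(spec$basins, function(b) {
    if (is.na(b$label) || identical(b$label, "background")) "none"
    else b$label
  }, "")
  out <- data.frame(frame = seq_len(n), perimeter = perim, angle = ang,
                    basin = labels[comp])
  class(out) <- c("cv_series", "data.frame")
  out
}

# rotate CZ about CG, in the CA-CG-CZ plane, to the requested angle
place_cz <- function(ca, cg, cz_template, angle_deg) {
  u <- ca - cg
  u <- u / sqrt(sum(u^2))
  v <- cz_template - cg
  len <- sqrt(sum(v^2))
  w <- v - sum(v * u) * u
  nw <- sqrt(sum(w^2))
  if (nw < 1e-12) {  # template collinear: pick any perpendicular
    w <- c(u[2] - u[3], u[3] - u[1], u[1] - u[2])
    nw <- sqrt(sum(w^2))
  }
  w <- w / nw
  th <- angle_deg * pi / 180
  cg + len * (cos(th) * u + sin(th) * w)
}

# realize one frame's displacement noise (atoms x 3) given per-frame draws;
# internal helper shared by embed_coordinates and its calibration pass
.build_noise <- function(spec, resids, amps, n_frames) {
  n_res <- length(resids)
  rho <- spec$corr_strength
  # per-axis std so that per-residue RMSF -> amplitude
  sd_axis <- amps / sqrt(3)
  # membership: latent factor per corr block pair, CV residues excluded
  block_of <- integer(n_res)          # 0 = free
  block_sign <- numeric(n_res)
  for (bi in seq_along(spec$corr_blocks)) {
    bl <- spec$corr_blocks[[bi]]
    ia <- which(resids %in% setdiff(bl$a, .cv_resids))
    ib <- which(resids %in% setdiff(bl$b, .cv_resids))
    block_of[ia] <- bi; block_sign[ia] <- 1
    block_of[ib] <- bi; block_sign[ib] <- sign(bl$sign)
  }
  latent <- array(stats::rnorm(n_frames * length(spec$corr_blocks) * 3L),
                  c(n_frames, max(1L, length(spec$corr_blocks)), 3L))
  own <- array(stats::rnorm(n_frames * n_res * 3L), c(n_frames, n_res, 3L))
  noise <- array(0, c(n_frames, n_res, 3L))
  for (i in seq_len(n_res)) {
    if (block_of[i] == 0L) {
      noise[, i, ] <- own[, i, ] * sd_axis[i]
    } else {
      noise[, i, ] <- (sqrt(1 - rho) * own[, i, ] +
                       sqrt(rho) * block_sign[i] *
                         latent[, block_of[i], ]) * sd_axis[i]
    }
  }
  noise
}

#' Embed a CV series into C-alpha coordinates
#'
#' Realizes a sampled CV series geometrically: per frame the pocket
#' triangle is the template triangle rescaled about its centroid so its
#' perimeter equals the frame's x, and the arginine CZ pseudo-atom is
#' rotated about CG so the CA-CG-CZ angle equals the frame's y.  All other
#' residues receive independent isotropic Gaussian displacements with
#' per-axis standard deviation `amplitude / sqrt(3)`; correlation blocks
#' share (or negate) a common latent displacement.  The CV-defining
#' residues move only rigidly (a common translation for the pocket trio, a
#' common translation for residue 549), so recomputing the CVs from the
#' coordinates reproduces the requested series to numerical precision.  A
#' fixed random drift field, ramped in over the equilibration fraction and
#' scaled by a short calibration pass, sets the post-equilibration mean
#' RMSD to `mean_rmsd_target`.
#'
#' @param cv a `cv_series` (typically from [sample_cv_series()]).
#' @param spec the `ensemble_spec`.
#' @param template one-frame template `traj`; built by
#'   [synthetic_template()] when `NULL`.
#' @return a `synthetic_traj`: list with `trajectory` (a `traj`),
#'   `cv_truth` (the input series) and `labels_truth`.
#' @export
embed_coordinates <- function(cv, spec, template = NULL) {
  stopifnot(inherits(spec, "ensemble_spec"))
  if (is.null(template)) template <- synthetic_template(spec)
  top <- template$topology
  for (r in c(458L, 463L, 510L))
    if (sum(top$resid == r & top$name == "CA") != 1L)
      stop("template missing CA of residue ", r)
  for (nm in c("CA", "CG", "CZ"))
    if (sum(top$resid == 549L & top$name == nm) != 1L)
      stop("template missing atom ", nm, " of residue 549")

  resids <- sort(unique(top$resid))
  amps <- spec_amplitudes(spec, resids)
  n <- nrow(cv)
  tmpl <- frame_coords(template, 1L)
  ica <- match(paste(resids, "CA"), paste(top$resid, top$name))
  ipocket <- match(c(458L, 463L, 510L), resids)
  i549 <- match(549L, resids)
  icg <- which(top$resid == 549L & top$name == "CG")
  icz <- which(top$resid == 549L & top$name == "CZ")

  # template pocket triangle, centered
  tri0 <- tmpl[ica[ipocket], , drop = FALSE]
  tric <- colMeans(tri0)
  tri0c <- sweep(tri0, 2L, tric)
  d <- function(a, b) sqrt(sum((a - b)^2))
  perim0 <- d(tri0[1, ], tri0[2, ]) + d(tri0[2, ], tri0[3, ]) +
            d(tri0[1, ], tri0[3, ])

  set.seed(spec$seed + 1L)  # noise stream distinct from the CV stream
  noise <- .build_noise(spec, resids, amps, n)
  # one rigid displacement per pocket trio / per arginine: reuse the drawn
  # per-residue streams of 458 and 549 respectively
  pocket_amp <- mean(amps[ipocket])
  noise[, ipocket[2], ] <- noise[, ipocket[1], ] *
    (pocket_amp / max(amps[ipocket[1]], 1e-12))
  noise[, ipocket[3], ] <- noise[, ipocket[2], ]
  noise[, ipocket[1], ] <- noise[, ipocket[2], ]

  # fixed drift field (unit RMS per atom), common within CV residue groups
  drift <- matrix(stats::rnorm(length(resids) * 3L), ncol = 3L)
  drift[ipocket[2], ] <- drift[ipocket[1], ]
  drift[ipocket[3], ] <- drift[ipocket[1], ]
  drift <- drift / sqrt(mean(rowSums(drift^2)))
  ramp <- pmin(1, (seq_len(n) - 1L) / max(1, ceiling(n * spec$equil_frac)))

  build <- function(drift_scale, frames) {
    coords <- array(NA_real_, c(length(frames), nrow(top), 3L))
    for (fi in seq_along(frames)) {
      f <- frames[fi]
      xyz <- tmpl
      # pocket triangle scaled to the requested perimeter
      sc <- cv$perimeter[f] / perim0
      xyz[ica[ipocket], ] <- sweep(tri0c * sc, 2L, tric, `+`)
      # arginine bend angle
      xyz[icz, ] <- place_cz(xyz[ica[i549], ], xyz[icg, ], xyz[icz, ],
                             cv$angle[f])
      disp <- noise[f, , ] + drift * (drift_scale * ramp[f])
      xyz[ica, ] <- xyz[ica, ] + disp
      # side-chain pseudo-atoms ride rigidly with their residue
      xyz[icg, ] <- xyz[icg, ] + disp[i549, ]
      xyz[icz, ] <- xyz[icz, ] + disp[i549, ]
      coords[fi, , ] <- xyz
    }
    coords
  }

  drift_scale <- 0
  if (spec$mean_rmsd_target > 0) {
    # calibrate on an even subsample: post-window mean RMSD ~ target
    win <- equilibration_window(n, spec$equil_frac)
    sub <- win[unique(pmax(1L, round(seq(1L, length(win),
                                         length.out = min(400L, length(win))))))]
    ref <- build(0, 1L)[1L, ica, ]  # ramp is 0 at frame 1: true start frame
    base <- build(0, sub)
    r0 <- vapply(seq_along(sub), function(k)
      fit_rmsd(matrix(base[k, ica, ], ncol = 3L), ref), 0)
    target <- spec$mean_rmsd_target
    # RMSD^2 adds in quadrature for a drift orthogonal to the noise
    guess <- sqrt(max(target^2 - mean(r0^2), 0))
    # one secant refinement against the actually superposed subsample
    measure <- function(s) {
      cc <- build(s, sub)
      mean(vapply(seq_along(sub), function(k)
        fit_rmsd(matrix(cc[k, ica, ], ncol = 3L), ref), 0))
    }
    m1 <- measure(guess)
    drift_scale <- if (abs(m1 - target) < 0.01 || guess == 0) guess else {
      m2 <- measure(guess * target / m1)
      s2 <- guess * target / m1
      if (abs(m2 - m1) > 1e-9)
        max(0, s2 + (target - m2) * (s2 - guess) / (m2 - m1))
      else s2
    }
  }

  coords <- build(drift_scale, seq_len(n))
  tr <- trajectory(top, coords)
  structure(list(trajectory = tr,
                 cv_truth = cv[, c("frame", "perimeter", "angle")],
                 labels_truth = if ("basin" %in% names(cv)) cv$basin
                                else rep(NA_character_, n)),
            class = "synthetic_traj")
}

#' Generate a complete synthetic trajectory from a spec
#'
#' Convenience wrapper: [sample_cv_series()] then [embed_coordinates()].
#' @inheritParams embed_coordinates
#' @param spec an `ensemble_spec`.
#' @return a `synthetic_traj`.
#' @export
generate_ensemble <- function(spec, template = NULL) {
  embed_coordinates(sample_cv_series(spec), spec, template)
}

#' @param x a `synthetic_traj`.
#' @param ... ignored.
#' @export
print.synthetic_traj <- function(x, ...) {
  cat("Synthetic trajectory\n  ")
  print(x$trajectory)
  tab <- table(x$labels_truth)
  cat("  truth labels:",
      paste(names(tab), sprintf("%.1f%%", 100 * tab / sum(tab)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Presets encoding the four simulated APC systems
#'
#' Named ensemble specifications whose basin centers, occupancies,
#' per-residue fluctuation amplitudes and mean displacements encode the
#' reported ensemble statistics of the four systems: apo APC (two
#' conformers M1/M2 plus a broad sporadic background), the MAI-108
#' complex, the Asef-peptide complex, and the truncated-peptide (ΔAsef)
#' complex.
#'
#' @param name one of `"apo"`, `"apc108"`, `"apcasef"`, `"apcdasef"`;
#'   `NULL` lists all presets.
#' @param n_frames,seed override the preset's frame count / seed.
#' @return an `ensemble_spec` (or a named list of them when `name` is
#'   `NULL`).
#' @examples
#' spec <- apc_presets("apo", n_frames = 1000)
#' cv <- sample_cv_series(spec)
#' table(cv$basin)
#' @export
apc_presets <- function(name = NULL, n_frames = 40000L, seed = 20260101L) {
  presets <- list(
    apo = ensemble_spec(
      basins = list(
        basin_spec(23.5, 170, 0.25, 5, 0.1264, label = "M1"),
        basin_spec(24.5, 110, 0.25, 5, 0.3752, label = "M2"),
        basin_spec(24.0, 140, 0.80, 35, 0.4984, label = "background",
                   split_perimeter = 3.0)),
      n_frames = n_frames, n_residues = 160L,
      fluct_amplitude = c(default = 1.0, "549" = 1.10, "458" = 1.31,
                          "463" = 1.06, "510" = 1.16),
      corr_blocks = list(list(a = 410:430, b = 470:490, sign = +1),
                         list(a = 520:545, b = 435:455, sign = -1)),
      mean_rmsd_target = 3.45, seed = seed),
    apc108 = ensemble_spec(
      basins = list(basin_spec(24.0, 170, 1.2, 5, 1.0, label = "M1")),
      n_frames = n_frames, n_residues = 160L,
      fluct_amplitude = c(default = 0.85, "549" = 0.73, "458" = 1.08,
                          "463" = 1.17, "510" = 0.79),
      corr_blocks = list(list(a = 410:430, b = 470:490, sign = +1)),
      mean_rmsd_target = 2.43, seed = seed),
    apcasef = ensemble_spec(
      basins = list(basin_spec(24.0, 113, 0.3, 4, 1.0, label = "M2")),
      n_frames = n_frames, n_residues = 160L,
      fluct_amplitude = c(default = 0.80, "549" = 0.80, "458" = 0.90,
                          "463" = 0.90, "510" = 0.85),
      corr_blocks = list(list(a = 410:430, b = 470:490, sign = +1)),
      mean_rmsd_target = 2.49, seed = seed),
    apcdasef = ensemble_spec(
      basins = list(basin_spec(24.0, 110, 0.8, 6, 1.0, label = "M2")),
      n_frames = n_frames, n_residues = 160L,
      fluct_amplitude = c(default = 1.15, "549" = 1.20, "458" = 1.30,
                          "463" = 1.20, "510" = 1.50),
      corr_blocks = list(list(a = 410:430, b = 470:490, sign = +1),
                         list(a = 520:545, b = 435:455, sign = -1)),
      mean_rmsd_target = 3.41, seed = seed))
  if (is.null(name)) return(presets)
  if (!name %in% names(presets))
    stop("unknown preset '", name, "'; available: ",
         paste(names(presets), collapse = ", "))
  presets[[name]]
}

#' Write the truth tables of a synthetic trajectory
#' @param straj a `synthetic_traj`.
#' @param path output path (tab-delimited, header row).
#' @export
write_truth_table <- function(straj, path) {
  d <- straj$cv_truth
  d$basin <- straj$labels_truth
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
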