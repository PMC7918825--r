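#' Self-contained toy molecular-mechanics energy backend
#'
#' A minimal, fully specified energy function used to exercise the
#' MM/GBSA aggregation and decomposition machinery on systems whose
#' energies are known in closed form.  Terms:
#' \itemize{
#'   \item electrostatics: `E_ele = sum_{i<j} 332.06 q_i q_j / r_ij`
#'     (kcal/mol, Angstrom, elementary charges);
#'   \item van der Waals: `E_vdw = sum_{i<j} 4 eps [(sig/r)^12 -
#'     (sig/r)^6]`, Lorentz--Berthelot combining rules;
#'   \item polar solvation: Still-form Generalized Born with fixed input
#'     Born radii, `G_P = -166.03 (1 - 1/eps_w) sum_{i,j} q_i q_j /
#'     f_GB(r, R_i, R_j)`, `f_GB = sqrt(r^2 + R_i R_j exp(-r^2 / (4 R_i
#'     R_j)))`, water dielectric `eps_w = 78.5` (full double sum,
#'     including the `i = j` self terms);
#'   \item nonpolar solvation: `G_np = gamma * SASA + b` with
#'     `gamma = 0.00542` kcal mol^-1 A^-2 and `b = 0.92` kcal/mol, SASA
#'     by Shrake--Rupley (960 sphere points, 1.4 A probe).
#' }
#'
#' @name toy_backend
NULL

#' Define a toy system for the energy backend
#'
#' @param resid per-atom residue id.
#' @param molecule per-atom membership, `"receptor"` or `"ligand"`.
#' @param charge partial charges (elementary charges).
#' @param sigma,eps Lennard-Jones parameters (A, kcal/mol).
#' @param born fixed Born radii (A).
#' @param radius SASA atomic radii (A); 0 excludes an atom's sphere.
#' @return a `toy_system` data.frame.
#' @export
toy_system <- function(resid, molecule, charge, sigma = 3.4, eps = 0.1,
                       born = 1.7, radius = 1.7) {
  n <- length(resid)
  d <- data.frame(resid = as.integer(resid), molecule = molecule,
                  charge = charge, sigma = sigma, eps = eps, born = born,
                  radius = radius)
  if (nrow(d) != n) stop("toy system fields must share one length")
  for (cl in c("charge", "sigma", "eps", "born", "radius"))
    if (anyNA(d[[cl]]))
      stop("missing ", cl, " for atom ", which(is.na(d[[cl]]))[1])
  if (!all(d$molecule %in% c("receptor", "ligand")))
    stop("molecule must be 'receptor' or 'ligand'")
  class(d) <- c("toy_system", "data.frame")
  d
}

.kcoul <- 332.06    # kcal A mol^-1 e^-2
.kgb <- 166.03      # .kcoul / 2
.eps_w <- 78.5
.gamma_np <- 0.00542
.b_np <- 0.92

#' Shrake--Rupley solvent-accessible surface area
#'
#' Deterministic spiral point set on each atomic sphere of radius
#' `radius + probe`; a point is accessible when outside every other
#' atom's probe-inflated sphere.  Atoms with `radius = 0` contribute no
#' sphere and occlude nothing.
#'
#' @param coords atoms x 3 matrix (A).
#' @param radius per-atom radii (A).
#' @param probe probe radius (A, default 1.4).
#' @param n_points sphere points per atom (default 960).
#' @return per-atom SASA vector (A^2); `sum()` gives the molecular SASA.
#' @export
shrake_rupley <- function(coords, radius, probe = 1.4, n_points = 960L) {
  coords <- rbind(coords)
  n <- nrow(coords)
  stopifnot(length(radius) == n)
  k <- seq_len(n_points)
  z <- (2 * k - 1) / n_points - 1            # golden-spiral point set
  th <- acos(z)
  ph <- k * pi * (3 - sqrt(5))
  unit <- cbind(sin(th) * cos(ph), sin(th) * sin(ph), z)
  out <- numeric(n)
  rr <- radius + probe
  for (i in seq_len(n)) {
    if (radius[i] <= 0) next
    pts <- sweep(unit * rr[i], 2L, coords[i, ], `+`)
    acc <- rep(TRUE, n_points)
    for (j in seq_len(n)) {
      if (j == i || radius[j] <= 0) next
      d2 <- colSums((t(pts) - coords[j, ])^2)
      acc <- acc & d2 > rr[j]^2
    }
    out[i] <- 4 * pi * rr[i]^2 * mean(acc)
  }
  out
}

# pairwise distance matrix
.pdist <- function(a) {
  d2 <- outer(rowSums(a^2), rowSums(a^2), `+`) - 2 * a %*% t(a)
  sqrt(pmax(d2, 0))
}

# one molecule's energies + partitions at one set of coordinates
.toy_molecule_energy <- function(coords, sys, solvation = TRUE) {
  n <- nrow(sys)
  r <- .pdist(coords)
  q <- sys$charge
  # pairwise vacuum terms, upper triangle
  sig <- outer(sys$sigma, sys$sigma, `+`) / 2
  epsm <- sqrt(outer(sys$eps, sys$eps))
  ele_p <- vdw_p <- gp_p <- matrix(0, n, n)
  if (n > 1L) {
    ut <- upper.tri(r)
    sr6 <- (sig[ut] / r[ut])^6
    vdw_p[ut] <- 4 * epsm[ut] * (sr6^2 - sr6)
    ele_p[ut] <- .kcoul * (q %o% q)[ut] / r[ut]
  }
  gp_self <- numeric(n)
  if (solvation) {
    bb <- sys$born %o% sys$born
    fgb <- sqrt(r^2 + bb * exp(-r^2 / (4 * bb)))
    gmat <- -.kgb * (1 - 1 / .eps_w) * (q %o% q) / fgb
    gp_self <- diag(gmat)
    if (n > 1L) gp_p[upper.tri(r)] <- 2 * gmat[upper.tri(r)]
    sasa <- shrake_rupley(coords, sys$radius)
  } else sasa <- NULL

  # fold atom pairs into residue pairs (res_i <= res_j)
  res <- sys$resid
  fold <- function(pm, self = NULL) {
    idx <- which(upper.tri(pm) & pm != 0, arr.ind = TRUE)
    ri <- pmin(res[idx[, 1]], res[idx[, 2]])
    rj <- pmax(res[idx[, 1]], res[idx[, 2]])
    agg <- if (nrow(idx))
      stats::aggregate(pm[idx], list(res_i = ri, res_j = rj), sum)
    else data.frame(res_i = integer(0), res_j = integer(0), x = numeric(0))
    if (!is.null(self)) {
      sagg <- stats::aggregate(self, list(res_i = res, res_j = res), sum)
      agg <- rbind(agg, sagg)
      agg <- stats::aggregate(agg$x, list(res_i = agg$res_i,
                                          res_j = agg$res_j), sum)
    }
    agg
  }
  list(E_int = 0,
       E_vdw = sum(vdw_p), E_ele = sum(ele_p),
       G_P = if (solvation) sum(gp_p) + sum(gp_self) else 0,
       G_np = if (solvation) .gamma_np * sum(sasa) + .b_np else 0,
       pair_vdw = fold(vdw_p), pair_ele = fold(ele_p),
       pair_gp = if (solvation) fold(gp_p, gp_self) else NULL,
       res_np = if (solvation) {
         s <- stats::aggregate(.gamma_np * sasa, list(resid = res), sum)
         s$x <- s$x + .b_np / nrow(s)  # intercept spread over residues
         s
       } else NULL)
}

#' Evaluate the toy backend over frames (single-trajectory protocol)
#'
#' For each frame the complex energies are computed on all atoms, and the
#' receptor/ligand energies on the same coordinates with the partner
#' removed — the single-trajectory protocol, under which every
#' intramolecular term cancels in the difference.
#'
#' @param sys a [toy_system()].
#' @param coords_list list of atoms x 3 coordinate matrices (one per
#'   frame), or a single matrix.
#' @param solvation include GB and SASA terms (default TRUE); with
#'   `FALSE` the solvation terms are zero (vacuum bookkeeping).
#' @return an [energy_table()] with pair and per-residue partitions.
#' @export
toy_energy_backend <- function(sys, coords_list, solvation = TRUE) {
  stopifnot(inherits(sys, "toy_system"))
  if (is.matrix(coords_list)) coords_list <- list(coords_list)
  terms <- NULL; pairs <- NULL; residues <- NULL
  subsets <- list(complex = seq_len(nrow(sys)),
                  receptor = which(sys$molecule == "receptor"),
                  ligand = which(sys$molecule == "ligand"))
  for (f in seq_along(coords_list)) {
    xyz <- rbind(coords_list[[f]])
    if (nrow(xyz) != nrow(sys))
      stop("frame ", f, ": coordinate rows do not match the system")
    for (mol in names(subsets)) {
      ii <- subsets[[mol]]
      if (length(ii) == 0L) stop("molecule '", mol, "' has no atoms")
      e <- .toy_molecule_energy(xyz[ii, , drop = FALSE],
                                sys[ii, , drop = FALSE], solvation)
      terms <- rbind(terms, data.frame(
        frame = f, molecule = mol, E_int = e$E_int, E_vdw = e$E_vdw,
        E_ele = e$E_ele, G_P = e$G_P, G_np = e$G_np))
      pp <- rbind(
        if (nrow(e$pair_vdw)) cbind(e$pair_vdw, term = "E_vdw"),
        if (nrow(e$pair_ele)) cbind(e$pair_ele, term = "E_ele"),
        if (!is.null(e$pair_gp) && nrow(e$pair_gp))
          cbind(e$pair_gp, term = "G_P"))
      if (!is.null(pp) && nrow(pp))
        pairs <- rbind(pairs, data.frame(
          frame = f, molecule = mol, res_i = pp$res_i, res_j = pp$res_j,
          term = pp$term, value = pp$x))
      if (!is.null(e$res_np))
        residues <- rbind(residues, data.frame(
          frame = f, molecule = mol, resid = e$res_np$resid,
          term = "G_np", value = e$res_np$x))
    }
  }
  # vacuum runs still need residue rows so decomposition knows ownership
  if (is.null(residues)) {
    own <- unique(sys[, c("resid", "molecule")])
    residues <- do.call(rbind, lapply(seq_along(coords_list), function(f)
      rbind(data.frame(frame = f, molecule = "complex", resid = own$resid,
                       term = "G_np", value = 0),
            data.frame(frame = f, molecule = own$molecule,
                       resid = own$resid, term = "G_np", value = 0))))
  }
  energy_table(terms, pairs, residues)
}
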