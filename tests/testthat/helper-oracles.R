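# Independent oracles and small fixture builders used across tests.

# Horn quaternion superposition RMSD: independent of the SVD route the
# package uses.  Returns the least-squares RMSD between two point sets.
quaternion_rmsd <- function(a, b, weights = NULL) {
  n <- nrow(a)
  if (is.null(weights)) weights <- rep(1, n)
  w <- weights / sum(weights)
  a <- sweep(a, 2, colSums(a * w))
  b <- sweep(b, 2, colSums(b * w))
  m <- t(a * w) %*% b
  sxx <- m[1, 1]; sxy <- m[1, 2]; sxz <- m[1, 3]
  syx <- m[2, 1]; syy <- m[2, 2]; syz <- m[2, 3]
  szx <- m[3, 1]; szy <- m[3, 2]; szz <- m[3, 3]
  K <- matrix(c(
    sxx + syy + szz, syz - szy,       szx - sxz,       sxy - syx,
    syz - szy,       sxx - syy - szz, sxy + syx,       szx + sxz,
    szx - sxz,       sxy + syx,      -sxx + syy - szz, syz + szy,
    sxy - syx,       szx + sxz,       syz + szy,      -sxx - syy + szz),
    4, 4, byrow = TRUE)
  lam <- max(eigen(K, symmetric = TRUE)$values)
  ga <- sum(w * rowSums(a^2))
  gb <- sum(w * rowSums(b^2))
  sqrt(max(ga + gb - 2 * lam, 0))
}

# random proper rotation matrix
random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

apply_rigid <- function(xyz, rot, shift) sweep(xyz %*% rot, 2, shift, `+`)

# tiny template trajectory (the 4 CV residues + a few fillers)
small_template <- function(n_residues = 12L) {
  spec <- ensemble_spec(
    basins = list(basin_spec(24, 120, 0.5, 5, 1)),
    n_frames = 1L, n_residues = n_residues)
  synthetic_template(spec)
}

small_spec <- function(n_frames, n_residues = 12L, seed = 99L, ...) {
  ensemble_spec(basins = list(basin_spec(24, 120, 0.5, 5, 1, label = "B")),
                n_frames = n_frames, n_residues = n_residues, seed = seed,
                ...)
}

# minimal single-frame energy table from component means
energy_table_from_means <- function(vdw, ele, gp, gnp) {
  energy_table(data.frame(
    frame = 1, molecule = c("complex", "receptor", "ligand"),
    E_int = 0, E_vdw = c(vdw, 0, 0), E_ele = c(ele, 0, 0),
    G_P = c(gp, 0, 0), G_np = c(gnp, 0, 0)))
}
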