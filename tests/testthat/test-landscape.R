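fake_cv <- function(perimeter, angle) {
  d <- data.frame(frame = seq_along(perimeter), perimeter = perimeter,
                  angle = angle)
  class(d) <- c("cv_series", "data.frame")
  d
}

test_that("joint histogram normalizes to a probability and spans the data", {
  cv <- fake_cv(rep(24, 100), rep(120, 100))
  g <- joint_histogram(cv, bins_per_axis = 10)
  expect_equal(sum(g$g), 1)
  expect_equal(max(g$g), 1)  # all frames in one bin
  set.seed(2)
  cv <- fake_cv(runif(5000, 20, 28), runif(5000, 60, 170))
  g <- joint_histogram(cv, bins_per_axis = 20)
  expect_equal(sum(g$g), 1)
  expect_true(min(g$xedges) < 20 && max(g$xedges) > 28)
  expect_error(joint_histogram(fake_cv(numeric(0), numeric(0))), "frames")
})

test_that("uniform sampling fills bins within the multinomial bound", {
  set.seed(77)
  n <- 40000; bins <- 10
  cv <- fake_cv(runif(n, 20, 28), runif(n, 60, 170))
  g <- joint_histogram(cv, bins_per_axis = bins)
  # interior bins (padding leaves edge bins underfilled by construction)
  inner <- g$counts[2:(bins - 1), 2:(bins - 1)]
  p <- (1.04 / bins)^2  # each axis padded to 1.04x the data range
  expect_lt(max(abs(inner - n * p)), 4 * sqrt(n * p * (1 - p)))
})

test_that("Boltzmann inversion gives the closed-form free-energy gap", {
  # two occupied bins: dG difference is kB T log(count ratio), min at mode
  cv <- fake_cv(c(rep(21, 272), rep(27, 100)), rep(120, 372))
  g <- pmf(joint_histogram(cv, bins_per_axis = 4))
  occupied <- sort(g$dG[g$counts > 0])
  expect_equal(occupied[1], 0)
  expect_equal(occupied[2], 3.30e-4 * 300 * log(272 / 100))
  expect_equal(3.30e-4 * 300, 0.099)  # the kB T scale itself
  # uniform probability: flat landscape at zero
  cvu <- fake_cv(c(20, 20, 28, 28), c(100, 140, 100, 140))
  gu <- pmf(joint_histogram(cvu, bins_per_axis = 2))
  expect_true(all(abs(gu$dG) < 1e-12))
  # most probable bin is always the zero of the surface
  expect_equal(g$dG[which.max(g$g)], 0)
  expect_true(all(is.na(g$dG[g$counts == 0])))
})

test_that("basin detection recovers mixture structure", {
  spec <- apc_presets("apo", n_frames = 20000, seed = 12)
  cv <- sample_cv_series(spec)
  b <- find_basins(pmf(joint_histogram(cv, 200)))
  expect_equal(nrow(b), 2L)
  angles <- sort(b$center_angle)
  expect_lt(abs(angles[1] - 110), 10)
  expect_lt(abs(angles[2] - 170), 10)
  # deeper basin first
  expect_true(all(diff(b$dG) >= 0))

  single <- apc_presets("apc108", n_frames = 20000, seed = 12)
  bs <- find_basins(pmf(joint_histogram(sample_cv_series(single), 200)))
  expect_equal(nrow(bs), 1L)
  expect_lt(abs(bs$center_perimeter - 24), 0.5)

  # single-basin recovery: center within one bin of truth on a calm grid
  calm <- ensemble_spec(list(basin_spec(24, 120, 0.4, 4, 1)),
                        n_frames = 30000, seed = 4)
  gg <- pmf(joint_histogram(sample_cv_series(calm), 50))
  bb <- find_basins(gg, min_separation = 10)
  expect_equal(nrow(bb), 1L)
  expect_lt(abs(bb$center_perimeter - 24), diff(gg$xedges[1:2]) * 1.5)
  expect_lt(abs(bb$center_angle - 120), diff(gg$yedges[1:2]) * 1.5)
})

test_that("flat landscapes never yield basins within the merge radius", {
  set.seed(9)
  cv <- fake_cv(runif(20000, 20, 28), runif(20000, 60, 170))
  b <- find_basins(pmf(joint_histogram(cv, 40)), min_separation = 15)
  if (nrow(b) > 1) {
    for (i in 1:(nrow(b) - 1)) for (j in (i + 1):nrow(b))
      expect_gte(max(abs(c(b$ix[i] - b$ix[j], b$iy[i] - b$iy[j]))), 15)
  }
  expect_warning(find_basins(pmf(joint_histogram(cv, 40)),
                             depth_cut = -1), "no basins")
})

test_that("frame assignment uses rectangles with deeper-basin ties", {
  basins <- data.frame(label = c("deep", "shallow"),
                       center_perimeter = c(24, 25), center_angle = c(120, 130),
                       dG = c(0, 0.5), ix = 1L, iy = 1L)
  class(basins) <- c("basin_set", "data.frame")
  cv <- fake_cv(c(24, 24.6, 30, 25.7), c(120, 125, 120, 112))
  a <- assign_frames(cv, basins, half_widths = c(0.75, 20))
  # frame 2 sits in both rectangles -> deeper basin wins
  expect_equal(a$labels, c("deep", "deep", "unassigned", "shallow"))
  expect_equal(sum(a$occupancy$fraction), 1)

  all_in <- fake_cv(rep(24, 10), rep(120, 10))
  aa <- assign_frames(all_in, basins)
  expect_equal(aa$occupancy$fraction[aa$occupancy$basin == "deep"], 1)
})

test_that("apo occupancies are recovered through the full landscape path", {
  spec <- apc_presets("apo", n_frames = 20000, seed = 3)
  cv <- sample_cv_series(spec)
  b <- find_basins(pmf(joint_histogram(cv, 200)))
  a <- assign_frames(cv, b)
  m1 <- b$label[which.max(b$center_angle)]
  m2 <- b$label[which.min(b$center_angle)]
  occ <- stats::setNames(a$occupancy$fraction, a$occupancy$basin)
  tol <- function(p) 3 * sqrt(p * (1 - p) / 20000) + 0.003  # + leakage
  expect_lt(abs(occ[[m1]] - 0.1264), tol(0.1264))
  expect_lt(abs(occ[[m2]] - 0.3752), tol(0.3752))
  expect_lt(abs(occ[["unassigned"]] - 0.4984), tol(0.4984))
})

test_that("representative frame comes from the dominant cluster", {
  set.seed(41)
  tmpl <- small_template()
  base <- frame_coords(tmpl, 1)
  shape_shift <- matrix(rnorm(length(base), sd = 5), nrow(base), 3)
  nf <- 10
  coords <- array(NA_real_, c(nf, nrow(base), 3))
  for (f in 1:8) coords[f, , ] <- base + matrix(rnorm(length(base), sd = 0.05),
                                                nrow(base), 3)
  for (f in 9:10) coords[f, , ] <- base + shape_shift +
    matrix(rnorm(length(base), sd = 0.05), nrow(base), 3)
  tr <- trajectory(tmpl$topology, coords)
  labels <- rep("b", nf)
  rep_frame <- representative_frame(tr, labels, "b", k = 2)
  expect_true(rep_frame %in% 1:8)
  # brute-force oracle: frame of the 8-cluster minimizing summed RMSD
  dm <- matrix(0, 8, 8)
  for (i in 1:7) for (j in (i + 1):8)
    dm[i, j] <- dm[j, i] <- quaternion_rmsd(
      matrix(coords[i, tmpl$topology$name == "CA", ], ncol = 3),
      matrix(coords[j, tmpl$topology$name == "CA", ], ncol = 3))
  expect_equal(rep_frame, which.min(rowSums(dm)))

  # identical frames tie-break to the lowest index; singleton returns itself
  same <- trajectory(tmpl$topology,
                     array(rep(base, each = 4), c(4, nrow(base), 3)))
  expect_equal(representative_frame(same, rep("b", 4), "b"), 1L)
  expect_equal(representative_frame(tr, c("x", rep("b", 9)), "x"), 1L)
  expect_error(representative_frame(tr, labels, "missing"), "no member")
})

test_that("contact maps apply the distance cutoff symmetrically", {
  top <- topology(name = c("CA", "CA"), resname = "GLY", resid = c(1L, 2L))
  near <- trajectory(top, rbind(c(0, 0, 0), c(4, 0, 0)))
  fr <- frame_coords(near, 1)
  cm <- contact_map(fr, top, 1L, 2L, cutoff = 4.5)
  expect_equal(nrow(cm), 1L)
  expect_equal(cm$min_dist, 4)
  far <- rbind(c(0, 0, 0), c(5, 0, 0))
  expect_equal(nrow(contact_map(far, top, 1L, 2L, cutoff = 4.5)), 0L)
  expect_equal(nrow(contact_map(fr, top, 1L, 2L, cutoff = 0)), 0L)
  expect_error(contact_map(fr, top, integer(0), 2L), "empty")
})
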