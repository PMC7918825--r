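test_that("spec validation rejects bad mixtures and amplitudes", {
  b <- basin_spec(24, 120, 0.5, 5, 0.6)
  expect_error(ensemble_spec(list(b, b), n_frames = 10),
               "sum to 1")
  expect_error(basin_spec(24, 120, -1, 5, 1))
  expect_error(ensemble_spec(list(basin_spec(24, 120, 0.5, 5, 1)),
                             n_frames = 10, fluct_amplitude = -0.1),
               ">= 0")
})

test_that("a degenerate single-basin mixture collapses to its center", {
  spec <- ensemble_spec(
    basins = list(basin_spec(24, 120, 1e-12, 1e-12, 1, label = "B")),
    n_frames = 50, seed = 5)
  cv <- sample_cv_series(spec)
  expect_equal(cv$perimeter, rep(24, 50), tolerance = 1e-9)
  expect_equal(cv$angle, rep(120, 50), tolerance = 1e-9)
  expect_true(all(cv$basin == "B"))
})

test_that("empirical component fractions recover mixture weights", {
  # binomial 3-sigma bound at the generated size, several seeds
  for (seed in c(1, 202, 4004)) {
    spec <- apc_presets("apo", n_frames = 8000, seed = seed)
    cv <- sample_cv_series(spec)
    for (want in list(c("M1", 0.1264), c("M2", 0.3752),
                      c("none", 0.4984))) {
      p <- as.numeric(want[2])
      got <- mean(cv$basin == want[1])
      expect_lt(abs(got - p), 3 * sqrt(p * (1 - p) / 8000))
    }
  }
})

test_that("the same spec and seed reproduce the identical ensemble", {
  spec <- apc_presets("apo", n_frames = 300, seed = 17)
  a <- generate_ensemble(spec)
  b <- generate_ensemble(spec)
  expect_identical(a$trajectory$coords, b$trajectory$coords)
  expect_identical(a$cv_truth, b$cv_truth)
})

test_that("angles fold back into the geometric range (0, 180]", {
  spec <- ensemble_spec(
    basins = list(basin_spec(24, 175, 0.3, 30, 1)), n_frames = 2000,
    seed = 3)
  cv <- sample_cv_series(spec)
  expect_true(all(cv$angle > 0 & cv$angle <= 180))
  # reflection folds the over-180 tail back instead of piling it onto
  # the boundary: plenty of mass near, but none exactly at, 180
  expect_gt(mean(cv$angle > 170), 0.2)
  expect_lt(mean(cv$angle == 180), 0.01)
})

test_that("CV round trip through embedding is exact for every frame", {
  spec <- apc_presets("apcdasef", n_frames = 120, seed = 8)
  st <- generate_ensemble(spec)
  cv <- cv_series(st$trajectory)
  expect_lt(max(abs(cv$perimeter - st$cv_truth$perimeter)), 1e-6)
  expect_lt(max(abs(cv$angle - st$cv_truth$angle)), 1e-4)
})

test_that("zero amplitudes and zero displacement target freeze the structure", {
  spec <- small_spec(30, fluct_amplitude = 0, mean_rmsd_target = 0)
  spec$basins[[1]]$width_perimeter <- 1e-12
  spec$basins[[1]]$width_angle <- 1e-12
  st <- generate_ensemble(spec)
  prof <- rmsf(st$trajectory, window = seq_len(30))
  expect_lt(max(prof$rmsf), 1e-9)
})

test_that("per-residue RMSF converges to the requested amplitude", {
  # isotropic Gaussian with per-axis std a/sqrt(3) has RMSF a; Monte Carlo
  spec <- small_spec(20000, n_residues = 100L, seed = 21,
                     fluct_amplitude = c(default = 0.9, "403" = 1.6))
  spec$basins[[1]]$width_perimeter <- 0.05
  spec$basins[[1]]$width_angle <- 0.5
  st <- generate_ensemble(spec)
  prof <- rmsf(st$trajectory)
  got <- prof$rmsf[prof$resid == 403]
  expect_lt(abs(got - 1.6) / 1.6, 0.05)
  filler <- prof$rmsf[!prof$resid %in% c(458, 463, 510, 549, 403)]
  expect_lt(max(abs(filler - 0.9) / 0.9), 0.10)
})

test_that("preset catalog encodes the reported ensemble statistics", {
  apo <- apc_presets("apo")
  expect_length(apo$basins, 3L)
  w <- vapply(apo$basins, `[[`, 0, "weight")
  expect_equal(sum(w), 1)
  expect_equal(w[1:2], c(0.1264, 0.3752))
  expect_equal(apo$basins[[1]]$center_angle, 170)
  expect_equal(apo$basins[[2]]$center_angle, 110)
  a108 <- apc_presets("apc108")
  expect_length(a108$basins, 1L)
  expect_equal(a108$fluct_amplitude[["549"]], 0.73)
  expect_equal(a108$mean_rmsd_target, 2.43)
  for (nm in c("apo", "apc108", "apcasef", "apcdasef")) {
    p <- apc_presets(nm)
    expect_equal(sum(vapply(p$basins, `[[`, 0, "weight")), 1)
  }
  expect_error(apc_presets("nope"), "apcasef")
})

test_that("an embedding template missing a CV atom fails naming it", {
  spec <- small_spec(3)
  tmpl <- synthetic_template(spec)
  cv <- sample_cv_series(spec)
  broken <- subset_traj(tmpl,
                        atoms = which(!(tmpl$topology$resid == 549 &
                                          tmpl$topology$name == "CZ")))
  expect_error(embed_coordinates(cv, spec, broken), "CZ")
})
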