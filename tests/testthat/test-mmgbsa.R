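test_that("component means chain to the reported binding free energies", {
  # MAI-108: -62.26 - 185.94 + 190.25 - 9.00
  r <- aggregate_gbsa(energy_table_from_means(-62.26, -185.94, 190.25, -9.00))
  g <- r$summary
  expect_equal(g$mean[g$term == "G_binding"], -66.95, tolerance = 1e-9)
  # Asef heptapeptide parent protein
  r <- aggregate_gbsa(energy_table_from_means(-158.43, -999.05, 1083.73,
                                              -21.77))
  g <- r$summary
  expect_equal(g$mean[g$term == "G_binding"], -95.52, tolerance = 1e-9)
  # truncated peptide: component rounding leaves a 0.01 residual
  r <- aggregate_gbsa(energy_table_from_means(-50.67, -139.41, 161.53,
                                              -6.64))
  g <- r$summary
  expect_equal(g$mean[g$term == "G_binding"], -35.18, tolerance = 0.02)
  # all-zero terms
  r <- aggregate_gbsa(energy_table_from_means(0, 0, 0, 0))
  expect_equal(r$summary$mean, rep(0, 8))
})

test_that("per-frame identity chains hold for every aggregated result", {
  set.seed(71)
  terms <- do.call(rbind, lapply(1:6, function(f)
    data.frame(frame = f, molecule = c("complex", "receptor", "ligand"),
               E_int = rnorm(3), E_vdw = rnorm(3), E_ele = rnorm(3),
               G_P = rnorm(3), G_np = rnorm(3))))
  r <- aggregate_gbsa(energy_table(terms), protocol = "separate-trajectory")
  d <- r$per_frame
  expect_equal(d$E_MM, d$E_int + d$E_vdw + d$E_ele)
  expect_equal(d$G_solv, d$G_P + d$G_np)
  expect_equal(d$G_binding, d$E_MM + d$G_solv)
  # k identical frames: sd 0, mean = the frame value
  one <- terms[terms$frame == 1, ]
  rep5 <- do.call(rbind, lapply(1:5, function(f) transform(one, frame = f)))
  r5 <- aggregate_gbsa(energy_table(rep5), protocol = "separate-trajectory")
  expect_equal(r5$summary$sd, rep(0, 8), tolerance = 1e-12)
  expect_equal(r5$summary$mean[r5$summary$term == "G_binding"],
               r$per_frame$G_binding[1])
  expect_match(r5$entropy, "omitted")
  # a frame lacking one molecule fails citing the frame
  expect_error(aggregate_gbsa(energy_table(terms[-2, ])), "frame 1")
})

test_that("toy-backend vacuum electrostatics match Coulomb's law", {
  sys <- toy_system(resid = c(1, 2), molecule = c("receptor", "ligand"),
                    charge = c(1, 1), eps = 0)
  et <- toy_energy_backend(sys, rbind(c(0, 0, 0), c(3.3206, 0, 0)),
                           solvation = FALSE)
  d <- aggregate_gbsa(et)$per_frame
  expect_equal(d$E_ele, 100)  # 332.06 / 3.3206
  expect_equal(d$E_vdw, 0)
})

test_that("decomposition splits pair terms half-and-half and closes", {
  sys <- toy_system(resid = c(10, 20), molecule = c("receptor", "ligand"),
                    charge = c(1, -1), eps = 0)
  et <- toy_energy_backend(sys, rbind(c(0, 0, 0), c(3, 0, 0)),
                           solvation = FALSE)
  dec <- decompose_gbsa(et)
  half <- 332.06 * 1 * -1 / 3 / 2
  expect_equal(dec$ele[dec$resid == 10], half)
  expect_equal(dec$ele[dec$resid == 20], half)
  expect_equal(sum(dec$total), attr(dec, "total_binding"),
               tolerance = 1e-6)
})

test_that("decomposition closure holds for a multi-residue solvated system", {
  set.seed(73)
  nrec <- 6; nlig <- 3
  sys <- toy_system(resid = c(rep(1:3, each = 2), 11:13),
                    molecule = c(rep("receptor", nrec), rep("ligand", nlig)),
                    charge = round(rnorm(nrec + nlig, sd = 0.4), 2),
                    born = 1.5, radius = 1.6)
  xyz1 <- rbind(matrix(rnorm(nrec * 3, sd = 3), nrec, 3),
                matrix(rnorm(nlig * 3, sd = 2), nlig, 3) +
                  matrix(rep(c(6, 0, 0), each = nlig), nlig, 3))
  xyz2 <- xyz1 + matrix(rnorm((nrec + nlig) * 3, sd = 0.3), nrec + nlig, 3)
  et <- toy_energy_backend(sys, list(xyz1, xyz2))
  dec <- decompose_gbsa(et)
  expect_equal(sum(dec$total), attr(dec, "total_binding"),
               tolerance = 1e-6)
  expect_setequal(dec$molecule[dec$resid %in% 1:3], "receptor")
  # a residue with no contacts and no desolvation change contributes ~0
  far_sys <- toy_system(resid = c(1, 2, 9),
                        molecule = c("receptor", "receptor", "ligand"),
                        charge = c(0, 1, -1), eps = c(0, 0.1, 0.1))
  far_xyz <- rbind(c(0, 0, 500), c(0, 0, 0), c(4, 0, 0))
  et2 <- toy_energy_backend(far_sys, far_xyz, solvation = FALSE)
  dec2 <- decompose_gbsa(et2)
  expect_equal(dec2$total[dec2$resid == 1], 0)
})

test_that("inconsistent partitions are rejected with the residual", {
  sys <- toy_system(resid = c(1, 2), molecule = c("receptor", "ligand"),
                    charge = c(1, -1), eps = 0)
  et <- toy_energy_backend(sys, rbind(c(0, 0, 0), c(3, 0, 0)),
                           solvation = FALSE)
  et$pairs$value[1] <- et$pairs$value[1] + 0.5
  expect_error(decompose_gbsa(et), "inconsistent")
})

test_that("nonpolar model: intercept, sphere SASA, and separated limits", {
  # zero-SASA atom still pays the intercept b
  sys <- toy_system(resid = c(1, 2), molecule = c("receptor", "ligand"),
                    charge = 0, radius = 0)
  et <- toy_energy_backend(sys, rbind(c(0, 0, 0), c(900, 0, 0)))
  expect_equal(et$terms$G_np[et$terms$molecule == "receptor"], 0.92)
  # isolated sphere: SASA equals the closed form (deterministic points)
  expect_equal(shrake_rupley(matrix(0, 1, 3), 1.7),
               4 * pi * (1.7 + 1.4)^2, tolerance = 0.01 * 4 * pi * 3.1^2)
  # occlusion: two overlapping spheres lose area
  two <- shrake_rupley(rbind(c(0, 0, 0), c(2, 0, 0)), c(1.7, 1.7))
  expect_lt(sum(two), 2 * 4 * pi * 3.1^2)
  # infinitely separated rigid partners: dE terms vanish, dG_np = -b
  sep <- toy_system(resid = c(1, 2), molecule = c("receptor", "ligand"),
                    charge = c(0.5, -0.5), born = 1.8, radius = 1.6)
  d <- aggregate_gbsa(
    toy_energy_backend(sep, rbind(c(0, 0, 0), c(1e6, 0, 0))))$per_frame
  expect_equal(d$E_vdw, 0, tolerance = 1e-9)
  expect_equal(d$E_ele, 0, tolerance = 1e-4)
  expect_equal(d$G_P, 0, tolerance = 1e-4)
  expect_equal(d$G_np, -0.92, tolerance = 1e-9)
})

test_that("GB self energy reaches the Born-ion limit", {
  sys <- toy_system(resid = c(1, 2), molecule = c("receptor", "ligand"),
                    charge = c(1, 0), born = c(2.0, 1.5), radius = 0)
  et <- toy_energy_backend(sys, rbind(c(0, 0, 0), c(800, 0, 0)))
  gp <- et$terms$G_P[et$terms$molecule == "receptor"]
  expect_equal(gp, -166.03 * (1 - 1 / 78.5) * 1 / 2.0, tolerance = 1e-9)
})

test_that("energy tables round-trip through delimited text", {
  sys <- toy_system(resid = c(1, 2, 11),
                    molecule = c("receptor", "receptor", "ligand"),
                    charge = c(0.3, -0.2, 0.1))
  et <- toy_energy_backend(sys, rbind(c(0, 0, 0), c(3, 1, 0), c(6, 0, 0)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_energy_table(et, path)
  back <- load_energy_table(path)
  expect_equal(back$terms$G_P, et$terms$G_P, tolerance = 1e-9)
  expect_equal(aggregate_gbsa(back)$summary, aggregate_gbsa(et)$summary,
               tolerance = 1e-9)
  expect_equal(sum(decompose_gbsa(back)$total),
               attr(decompose_gbsa(et), "total_binding"), tolerance = 1e-6)
  # schema violations
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  utils::write.table(d[, setdiff(names(d), "G_P")], path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  expect_error(load_energy_table(path), "G_P")
  d$bogus <- 1
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(load_energy_table(path), "bogus")
  # minimal one-frame file
  one <- energy_table_from_means(-1, -2, 3, -0.5)
  write_energy_table(one, path)
  expect_equal(nrow(load_energy_table(path)$terms), 3L)
})
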