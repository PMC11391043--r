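test_that("generators are pure functions of their seed", {
  a <- make_toy_complex(toy_complex_spec(seed = 1))
  b <- make_toy_complex(toy_complex_spec(seed = 1))
  expect_identical(a, b)
  c_ <- make_toy_complex(toy_complex_spec(seed = 2))
  expect_false(isTRUE(all.equal(coords(a), coords(c_))))

  t1 <- simulate_trajectory(a, fluctuation_spec(n_frames = 5, seed = 7))
  t2 <- simulate_trajectory(a, fluctuation_spec(n_frames = 5, seed = 7))
  expect_identical(t1$frames, t2$frames)

  e1 <- simulate_energy_series(-30, 2, 50, seed = 7)
  e2 <- simulate_energy_series(-30, 2, 50, seed = 7)
  expect_identical(e1$total, e2$total)

  s1 <- simulate_titration(2, 100, seed = 5)
  s2 <- simulate_titration(2, 100, seed = 5)
  expect_identical(s1$data, s2$data)
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(123)
  before <- rnorm(1)
  set.seed(123)
  invisible(simulate_titration(2, 100, seed = 99))
  after <- rnorm(1)
  expect_identical(before, after)
})

test_that("toy complex geometry and charges satisfy construction rules", {
  sys <- make_toy_complex(toy_complex_spec(seed = 11))
  expect_lt(abs(sum(sys$atoms$charge[sys$receptor])), 1e-6)
  expect_lt(abs(sum(sys$atoms$charge[sys$ligand])), 1e-6)
  expect_true(all(sys$atoms$epsilon > 0))
  expect_true(all(sys$atoms$rmin_half > 0))
  # ligand centroid near the receptor centroid (pocket placement)
  lig_c <- colMeans(coords(sys)[sys$ligand, , drop = FALSE])
  rec_c <- colMeans(coords(sys)[sys$receptor, , drop = FALSE])
  expect_lt(sqrt(sum((lig_c - rec_c)^2)), 10)
  # pocket: ligand centroid < 6 A from >= 3 residue anchors
  ca <- coords(sys)[select_calpha(sys), , drop = FALSE]
  d <- sqrt(rowSums(sweep(ca, 2, lig_c)^2))
  expect_gte(sum(d < 6), 3)
})

test_that("zero-sigma trajectories are static and energy series constant", {
  sys <- make_toy_complex(toy_complex_spec(seed = 1))
  tr <- simulate_trajectory(sys, fluctuation_spec(
    n_frames = 4, sigma_core = 0, sigma_loose = 0, seed = 1))
  for (f in tr$frames) expect_equal(f, coords(sys), ignore_attr = TRUE)
  e <- simulate_energy_series(-30, 0, 10, seed = 1)
  expect_equal(e$total, rep(-30, 10))
})

test_that("per-atom RMSF approaches sqrt(3) sigma for iid displacements", {
  # enough C-alphas that the ~6 rigid-body degrees of freedom absorbed by
  # superposition are a small share of the 3N coordinate variance
  sys <- make_toy_complex(toy_complex_spec(
    n_receptor_residues = 40, atoms_per_residue = 1, ligand_atoms = 1,
    seed = 2))
  sigma <- 0.4
  tr <- simulate_trajectory(sys, fluctuation_spec(
    n_frames = 2500, sigma_core = sigma, sigma_loose = sigma, seed = 3))
  prof <- rmsf_profile(tr)
  expect_equal(mean(prof$rmsf), sqrt(3) * sigma, tolerance = 0.05)
  # homogeneous sigma: profile flat across residues within 10%
  expect_lt((max(prof$rmsf) - min(prof$rmsf)) / mean(prof$rmsf), 0.10 * 2)
})

test_that("loose residues fluctuate more than core residues", {
  sys <- make_toy_complex(toy_complex_spec(seed = 2))
  loose <- 1:4
  tr <- simulate_trajectory(sys, fluctuation_spec(
    n_frames = 600, sigma_core = 0.3, sigma_loose = 0.9,
    loose_selection = loose, seed = 5))
  prof <- rmsf_profile(tr)
  expect_gt(mean(prof$rmsf[prof$resnum %in% loose]),
            mean(prof$rmsf[!prof$resnum %in% loose]))
})

test_that("energy series sample mean respects the CLT bound", {
  e <- simulate_energy_series(-30, 1, 5000, seed = 3)
  expect_lt(abs(mean(e$total) + 30), 4 * 1 / sqrt(5000))
  # component sum identity
  expect_equal(e$ele + e$vdw, e$total, tolerance = 1e-12)
})

test_that("noiseless titration and competition curves follow the models", {
  s <- simulate_titration(kd = 2, bmax = 100, concentrations = c(0.5, 1, 2, 200),
                          noise_cv = 0, n_replicates = 1, seed = 1)
  y <- s$data$intensity[s$data$conc_uM == 2]
  expect_equal(y, 50)  # X = Kd gives half-saturation
  expect_equal(s$data$intensity[s$data$conc_uM == 200], 100 * 200 / 202)

  ec50 <- 3
  cmp <- simulate_competition(ki = 3, kd_probe = 2, radioligand_conc = 0,
                              top = 100, bottom = 20,
                              concentrations = c(0, ec50, 10),
                              noise_cv = 0, n_replicates = 1, seed = 1)
  expect_equal(cmp$data$intensity[cmp$data$conc_uM == ec50], 60)  # midpoint
  expect_equal(cmp$data$intensity[cmp$data$conc_uM == 0], 100)
})

test_that("the standard assay concentration designs are the defaults", {
  s <- simulate_titration(2.33, 1e6, seed = 1)
  expect_equal(sort(unique(s$data$conc_uM)),
               c(0, 0.5, 1, 2, 4, 6, 8, 10, 12))
  expect_equal(s$n_replicates, 3L)
  cmp <- simulate_competition(0.72, 2.33, seed = 1)
  expect_equal(sort(unique(cmp$data$conc_uM)),
               c(0, 2, 4, 6, 8, 10, 12, 14, 20, 24, 28, 32))
})

test_that("AR(1) mode preserves the stationary displacement variance", {
  sys <- point_system(matrix(0, 4, 3))
  tr <- simulate_trajectory(sys, fluctuation_spec(
    n_frames = 4000, sigma_core = 0.5, sigma_loose = 0.5, rho = 0.6,
    seed = 8))
  disp <- vapply(tr$frames, function(f) f[1, 1], numeric(1))
  expect_equal(sd(disp), 0.5, tolerance = 0.1)
  # successive displacements are correlated at roughly rho
  expect_equal(cor(disp[-1], disp[-length(disp)]), 0.6, tolerance = 0.12)
})

test_that("demo fixtures materialise a complete, readable dataset", {
  dir <- withr::local_tempdir()
  files <- write_demo_fixtures(dir, seed = 1)
  expect_true(all(c("complex.pdb", "topology.csv", "traj_pH7.4.pdb",
                    "saturation_pH7.4.csv", "competition_pH5.5.csv",
                    "pka_predictions.csv") %in% names(files)))
  sys <- read_topology(file.path(dir, "topology.csv"),
                       read_pdb(file.path(dir, "complex.pdb")))
  expect_gt(length(sys$ligand), 0)
  tr <- read_pdb(file.path(dir, "traj_pH5.5.pdb"), "all")
  expect_equal(n_frames(tr), 100L)
  expect_s3_class(read_titration_csv(file.path(dir, "saturation_pH7.4.csv")),
                  "titration_series")
})
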