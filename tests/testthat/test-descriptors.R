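test_that("Kabsch superposition removes rigid motion exactly", {
  set.seed(1)
  ref <- matrix(rnorm(30), 10, 3)
  fit0 <- kabsch_superpose(ref, ref)
  expect_equal(fit0$rmsd, 0, tolerance = 1e-10)
  expect_equal(fit0$rotation, diag(3), tolerance = 1e-8)

  # 90-degree rotation about z plus translation (3, 4, 0)
  Rz <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)
  moved <- ref %*% t(Rz) + matrix(c(3, 4, 0), 10, 3, byrow = TRUE)
  expect_lt(kabsch_superpose(moved, ref)$rmsd, 1e-10)
})

test_that("Kabsch RMSD matches a grid-search oracle on perturbed clouds", {
  set.seed(2)
  ref <- matrix(rnorm(30, sd = 2), 10, 3)
  mobile <- ref + matrix(rnorm(30, sd = 0.1), 10, 3)
  kab <- kabsch_superpose(mobile, ref)$rmsd
  oracle <- grid_search_rmsd(mobile, ref)
  expect_lte(kab, oracle + 1e-12)  # least-squares optimum can't be beaten
  expect_equal(kab, oracle, tolerance = 1e-3)
})

test_that("Kabsch returns proper rotations and validates input", {
  set.seed(3)
  ref <- matrix(rnorm(30), 10, 3)
  mirrored <- ref %*% diag(c(-1, 1, 1))
  R <- kabsch_superpose(mirrored, ref)$rotation
  expect_equal(det(R), 1, tolerance = 1e-8)  # reflection excluded
  expect_error(kabsch_superpose(ref[1:2, ], ref[1:2, ]), ">= 3")
})

test_that("RMSD series is zero for static or rigidly moved trajectories", {
  sys <- make_toy_complex(toy_complex_spec(seed = 1))
  static <- simulate_trajectory(sys, fluctuation_spec(
    n_frames = 4, sigma_core = 0, sigma_loose = 0, seed = 1))
  expect_equal(rmsd_series(static)$values, rep(0, 4), tolerance = 1e-10)

  # growing translations are removed by superposition
  frames <- lapply(1:4, function(i) coords(sys) + i * 5)
  shifted <- trajectory(sys, frames)
  expect_equal(rmsd_series(shifted)$values, rep(0, 4), tolerance = 1e-10)

  # and so are arbitrary per-frame rigid motions of a fluctuating trajectory
  set.seed(4)
  tr <- simulate_trajectory(sys, fluctuation_spec(n_frames = 6, seed = 2))
  moved <- trajectory(sys, lapply(tr$frames, function(f)
    f %*% random_rotation() + matrix(rnorm(3, sd = 10), nrow(f), 3,
                                     byrow = TRUE)), tr$times)
  expect_equal(rmsd_series(moved)$values, rmsd_series(tr)$values,
               tolerance = 1e-8)
})

test_that("mean RMSD of a Gaussian trajectory matches a Monte-Carlo oracle", {
  sys <- make_toy_complex(toy_complex_spec(seed = 5))
  sel <- select_backbone(sys)
  sigma <- 0.5
  ref <- coords(sys)[sel, ]
  tr <- simulate_trajectory(sys, fluctuation_spec(
    n_frames = 400, sigma_core = sigma, sigma_loose = sigma, seed = 6))
  # measure against the clean structure so the oracle shares the reference
  measured <- rmsd_series(tr, selection = sel, reference = ref)$mean

  # oracle: fresh Gaussian clouds, superposed onto the same reference
  set.seed(99)
  oracle <- mean(replicate(1000, {
    noisy <- ref + matrix(rnorm(length(ref), sd = sigma), nrow(ref), 3)
    kabsch_superpose(noisy, ref)$rmsd
  }))
  expect_equal(measured, oracle, tolerance = 0.05)
})

test_that("RMSF isolates a single oscillating atom", {
  # rigid centro-symmetric scaffold, probe at its centroid oscillating
  # +/- d along x: superposition absorbs exactly the d/n translation
  # share and no rotation, so the two-state closed form holds
  bp <- balanced_probe_system(n_pairs = 10, seed = 7)
  n <- nrow(bp$base)
  sel <- seq_len(n)
  d <- 0.8
  frames <- lapply(1:40, function(i) {
    f <- bp$base
    f[1, 1] <- f[1, 1] + d * (-1)^i
    f
  })
  prof <- rmsf_profile(trajectory(bp$system, frames), selection = sel)
  expect_equal(prof$rmsf[1], d * (n - 1) / n, tolerance = 1e-8)
  expect_equal(max(prof$rmsf[-1]), d / n, tolerance = 1e-8)

  static <- trajectory(bp$system, list(bp$base, bp$base, bp$base))
  expect_equal(rmsf_profile(static, selection = sel)$rmsf, rep(0, n),
               tolerance = 1e-10)
  expect_error(rmsf_profile(trajectory(bp$system, list(bp$base)),
                            selection = sel), ">= 2")
})

test_that("RMSF of a trajectory concatenated with itself is unchanged", {
  sys <- make_toy_complex(toy_complex_spec(seed = 3))
  tr <- simulate_trajectory(sys, fluctuation_spec(n_frames = 30, seed = 4))
  doubled <- trajectory(sys, c(tr$frames, tr$frames))
  expect_equal(rmsf_profile(doubled)$rmsf, rmsf_profile(tr)$rmsf,
               tolerance = 1e-8)
})

test_that("radius of gyration matches hand-computed cases", {
  # two unit masses 2 A apart: Rg = 1 A = 0.1 nm
  two <- point_system(rbind(c(0, 0, 0), c(2, 0, 0)), mass = 1)
  tr2 <- trajectory(two, list(coords(two)))
  expect_equal(radius_of_gyration(tr2)$values, 0.1, tolerance = 1e-12)

  # four unit masses at the corners of a 2 A square: Rg = sqrt(2) A
  sq <- point_system(rbind(c(0, 0, 0), c(2, 0, 0), c(2, 2, 0), c(0, 2, 0)),
                     mass = 1)
  trs <- trajectory(sq, list(coords(sq)))
  expect_equal(radius_of_gyration(trs)$values, sqrt(2) / 10,
               tolerance = 1e-12)

  # homogeneity: uniform expansion by 2 doubles Rg
  tr2x <- trajectory(sq, list(coords(sq) * 2))
  expect_equal(radius_of_gyration(tr2x)$values,
               2 * radius_of_gyration(trs)$values, tolerance = 1e-12)

  # mass weighting shifts Rg toward the heavy atom
  heavy <- point_system(rbind(c(0, 0, 0), c(2, 0, 0)), mass = c(3, 1))
  trh <- trajectory(heavy, list(coords(heavy)))
  expect_lt(radius_of_gyration(trh)$values, 0.1)
  expect_equal(radius_of_gyration(trh, mass_weighted = FALSE)$values, 0.1,
               tolerance = 1e-12)
})

test_that("SASA reproduces closed-form sphere areas", {
  # isolated atom r 1.9 A, probe 1.4 A: 4 pi 3.3^2 = 136.85 A^2
  one <- sasa(matrix(0, 1, 3), radii = 1.9, n_sphere_points = 960)
  expect_equal(one$total, 4 * pi * 3.3^2 / 100, tolerance = 0.01)

  # additivity at large separation
  two_far <- sasa(rbind(c(0, 0, 0), c(100, 0, 0)), radii = c(1.9, 1.9),
                  n_sphere_points = 960)
  expect_equal(two_far$total, 2 * one$total, tolerance = 1e-9)

  # complete mutual burial: coincident atoms share one sphere
  two_same <- sasa(rbind(c(0, 0, 0), c(0, 0, 0)), radii = c(1.9, 1.9),
                   n_sphere_points = 960)
  expect_equal(two_same$total, one$total, tolerance = 0.02)
  expect_equal(two_same$per_atom[1], two_same$per_atom[2], tolerance = 0.04)
})

test_that("SASA decreases monotonically as two atoms approach", {
  dists <- seq(7, 0.5, length.out = 10)
  totals <- vapply(dists, function(d)
    sasa(rbind(c(0, 0, 0), c(d, 0, 0)), radii = c(1.9, 1.9),
         n_sphere_points = 960)$total, numeric(1))
  expect_true(all(diff(totals) <= 1e-9))
})

test_that("Rg and SASA are invariant under rigid motion", {
  sys <- make_toy_complex(toy_complex_spec(seed = 7))
  set.seed(11)
  xyz <- coords(sys)
  moved <- xyz %*% random_rotation() +
    matrix(rnorm(3, sd = 20), nrow(xyz), 3, byrow = TRUE)
  tr <- trajectory(sys, list(xyz))
  trm <- trajectory(sys, list(moved))
  expect_equal(radius_of_gyration(trm)$values, radius_of_gyration(tr)$values,
               tolerance = 1e-9)
  expect_equal(sasa(moved, sys$atoms$radius, n_sphere_points = 480)$total,
               sasa(xyz, sys$atoms$radius, n_sphere_points = 480)$total,
               tolerance = 1e-3)
})

test_that("Kabsch and PCA agree with bio3d on a shared example", {
  skip_if_not_installed("bio3d")
  set.seed(13)
  ref <- matrix(rnorm(36, sd = 3), 12, 3)
  mobile <- ref %*% random_rotation() + 5 + matrix(rnorm(36, sd = 0.3), 12, 3)
  ours <- kabsch_superpose(mobile, ref)$rmsd
  theirs <- bio3d::rmsd(as.vector(t(ref)), as.vector(t(mobile)),
                        fit = TRUE)
  expect_equal(ours, theirs, tolerance = 1e-3)
})
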