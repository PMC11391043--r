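test_that("Coulomb and LJ kernels match direct arithmetic", {
  # +1 and -1 e at 3.320636 A with no LJ: ele = -100 kcal/mol exactly
  pair <- point_system(rbind(c(0, 0, 0), c(3.320636, 0, 0)),
                       charge = c(1, -1), epsilon = 0,
                       receptor = 1L, ligand = 2L)
  e <- interaction_energy(system = pair)
  expect_equal(unname(e["ele"]), -100, tolerance = 1e-6)
  expect_equal(unname(e["vdw"]), 0)

  # single LJ pair at its minimum distance: vdw = -eps_ij exactly
  lj <- point_system(rbind(c(0, 0, 0), c(3.0, 0, 0)), charge = 0,
                     epsilon = c(0.2, 0.05), rmin_half = 1.5,
                     receptor = 1L, ligand = 2L)
  e2 <- interaction_energy(system = lj)
  expect_equal(unname(e2["vdw"]), -sqrt(0.2 * 0.05), tolerance = 1e-12)

  # asymptotic decay
  far <- point_system(rbind(c(0, 0, 0), c(1e6, 0, 0)), charge = c(1, -1),
                      epsilon = 0.1, receptor = 1L, ligand = 2L)
  expect_lt(abs(interaction_energy(system = far)["total"]), 1e-3)
})

test_that("coincident charged atoms raise a singularity error", {
  bad <- point_system(rbind(c(0, 0, 0), c(0, 0, 0)), charge = c(1, -1),
                      receptor = 1L, ligand = 2L)
  expect_error(interaction_energy(system = bad), "singular")
})

test_that("vectorised kernel agrees with the naive double loop to 1e-9", {
  for (seed in 1:3) {
    sys <- make_toy_complex(toy_complex_spec(
      n_receptor_residues = 15, atoms_per_residue = 6, ligand_atoms = 10,
      seed = seed))  # 100 atoms, well under the 200-atom oracle bound
    xyz <- coords(sys)
    expect_equal(interaction_energy(xyz, sys),
                 naive_interaction_energy(xyz, sys), tolerance = 1e-9)
  }
})

test_that("energy series mean obeys the CLT on the Gaussian generator", {
  e <- simulate_energy_series(-30, 1, 5000, seed = 3)
  expect_lt(abs(mean(e$total) - (-30)), 4 * 1 / sqrt(5000))
  expect_equal(e$beta * phbind_constants$kB * 300, 1, tolerance = 1e-12)

  sys <- make_toy_complex(toy_complex_spec(seed = 1))
  static <- trajectory(sys, list(coords(sys), coords(sys)))
  es <- energy_series(static)
  expect_equal(es$total[1], es$total[2])
  expect_length(es$total, 2L)
})

test_that("interaction entropy matches closed forms", {
  # constant series: no fluctuation, -TdS = 0 exactly
  expect_equal(interaction_entropy(raw_energy_series(rep(-30, 100))), 0)

  # two-point series {+a, -a}: -TdS = kBT log cosh(beta a)
  a <- 1; T <- 300
  kBT <- phbind_constants$kB * T
  two <- raw_energy_series(rep(c(a, -a), 50), temperature = T)
  expect_equal(interaction_entropy(two), kBT * log(cosh(a / kBT)),
               tolerance = 1e-10)

  # Gaussian sigma = 1 kcal/mol: -TdS -> beta sigma^2 / 2 = 0.8387
  g <- simulate_energy_series(-30, 1, 1e5, temperature = 300, seed = 42)
  expect_equal(interaction_entropy(g), 0.5 / kBT, tolerance = 0.03)
  expect_equal(0.5 / kBT, 0.8387, tolerance = 1e-4)
})

test_that("interaction entropy invariances and positivity hold", {
  set.seed(7)
  for (i in 1:5) {
    vals <- rnorm(200, mean = runif(1, -50, 0), sd = runif(1, 0.1, 1.5))
    s <- raw_energy_series(vals)
    ie <- interaction_entropy(s)
    expect_gte(ie, 0)  # Jensen
    # invariant to constant offsets
    expect_equal(interaction_entropy(raw_energy_series(vals + 123.4)), ie,
                 tolerance = 1e-9)
    # invariant to frame order
    expect_equal(interaction_entropy(raw_energy_series(sample(vals))), ie,
                 tolerance = 1e-12)
  }
  expect_error(interaction_entropy(raw_energy_series(c(1, NA, 2))), "NaN|NA")
})

test_that("the literal uncentered form equals centered plus beta mean inside the log", {
  vals <- rnorm(500, mean = -5, sd = 0.8)
  s <- raw_energy_series(vals)
  kBT <- 1 / s$beta
  expect_equal(interaction_entropy(s, center = FALSE),
               interaction_entropy(s, center = TRUE) + mean(vals),
               tolerance = 1e-9)
})

test_that("GB polar energy reduces to the Born equation for a single ion", {
  ion <- point_system(c(0, 0, 0), charge = 1, radius = 2)
  pol <- solvation_energy(system = ion, subset = "receptor")[["dG_pb"]]
  born <- -166.0318 * (1 - 1 / 80) / 2
  expect_equal(pol, born, tolerance = 0.001 * abs(born))
  expect_equal(born, -81.98, tolerance = 0.01)
})

test_that("neutral systems have zero polar and positive nonpolar energy", {
  sys <- point_system(matrix(rnorm(15), 5, 3), charge = 0, radius = 1.7)
  sol <- solvation_energy(system = sys, subset = "receptor")
  expect_equal(sol[["dG_pb"]], 0)
  expect_gt(sol[["dG_np"]], 0)
})

test_that("GB pair energy approaches the screened Coulomb limit", {
  for (r in c(50, 100)) {
    pair <- point_system(rbind(c(0, 0, 0), c(r, 0, 0)),
                         charge = c(1, -1), radius = 2)
    tot <- solvation_energy(system = pair, subset = "receptor")[["dG_pb"]]
    iso <- 2 * (-166.0318 * (1 - 1 / 80) / 2)
    screened <- 332.0636 * 1 * (-1) * (1 / 80 - 1) / r
    expect_equal(tot - iso, screened, tolerance = 0.02 * abs(screened))
  }
})

test_that("free-energy composition identities hold exactly", {
  fes <- free_energy_summary(dG_ele = -12.3, dG_vdw = -25.0, dG_np = 1.1,
                             dG_pb = 6.5, minus_TdS = 40.0)
  expect_identical(fes$dG_gas, -12.3 + -25.0)
  expect_identical(fes$dG_sol, 1.1 + 6.5)
  expect_identical(fes$dG_mmpbsa, fes$dG_gas + fes$dG_sol)
  expect_identical(fes$dG_bind, fes$dG_mmpbsa + fes$minus_TdS)

  # printed-table aggregation: dG_gas -37.29 + dG_sol 7.58 -> -29.71
  t1 <- free_energy_summary(dG_gas = -37.29, dG_sol = 7.58, minus_TdS = 78.45)
  expect_equal(t1$dG_mmpbsa, -29.71)
  t2 <- free_energy_summary(dG_gas = -25.99, dG_sol = 7.45, minus_TdS = 26.99)
  expect_equal(t2$dG_mmpbsa, -18.54)

  # paper-sign convention mirrors the published bind column
  ps <- free_energy_summary(dG_gas = -37.29, dG_sol = 7.58,
                            minus_TdS = 78.45, convention = "paper-sign")
  expect_equal(ps$dG_bind, -48.74)

  zero <- free_energy_summary(dG_ele = 0, dG_vdw = 0, dG_np = 0, dG_pb = 0,
                              minus_TdS = 0)
  expect_true(all(unlist(zero[c("dG_gas", "dG_sol", "dG_mmpbsa",
                                "dG_bind")]) == 0))
})

test_that("mmpbsa_summary composes its stage outputs consistently", {
  sys <- make_toy_complex(toy_complex_spec(seed = 2))
  tr <- simulate_trajectory(sys, fluctuation_spec(n_frames = 10, seed = 3))
  fes <- mmpbsa_summary(tr, solvation_stride = 5, n_sphere_points = 240)
  es <- energy_series(tr)
  expect_equal(fes$dG_ele, mean(es$ele), tolerance = 1e-12)
  expect_equal(fes$dG_vdw, mean(es$vdw), tolerance = 1e-12)
  expect_equal(fes$minus_TdS, interaction_entropy(es), tolerance = 1e-12)
  expect_equal(fes$dG_mmpbsa, fes$dG_gas + fes$dG_sol, tolerance = 1e-12)
})

test_that("residue decomposition conserves the total interaction energy", {
  sys <- make_toy_complex(toy_complex_spec(seed = 4))
  tr <- simulate_trajectory(sys, fluctuation_spec(n_frames = 8, seed = 5))
  dec <- residue_decomposition(tr)
  es <- energy_series(tr)
  expect_equal(sum(dec$energy), mean(es$total), tolerance = 1e-6)
  expect_equal(nrow(dec), length(unique(
    sys$atoms$resnum[sys$receptor])))
})

test_that("a residue hosting the only interaction carries all of it", {
  # receptor of 3 residues; only residue 2 is charged, ligand nearby
  xyz <- rbind(c(0, 0, 0), c(6, 0, 0), c(12, 0, 0), c(6, 4, 0))
  sys <- point_system(xyz, charge = c(0, 0.5, 0, -0.5), epsilon = 0,
                      receptor = 1:3, ligand = 4L, resnum = c(1, 2, 3, 4))
  tr <- trajectory(sys, list(xyz))
  dec <- residue_decomposition(tr)
  expect_equal(dec$energy[dec$resnum == 2],
               unname(interaction_energy(system = sys)["total"]),
               tolerance = 1e-12)
  expect_equal(dec$energy[dec$resnum != 2], c(0, 0))
  # and it ranks first
  expect_equal(rank_contributors(dec, 1)$resnum, 2)
})

test_that("rank_contributors sorts by most-negative energy with number ties", {
  dec <- structure(data.frame(resnum = c(1, 2, 3), resname = "GLY",
                              energy = c(-2, -1, 0.5)),
                   class = c("residue_contribution", "data.frame"))
  expect_equal(rank_contributors(dec, 2)$resnum, c(1, 2))
  expect_equal(nrow(rank_contributors(dec, 99)), 3L)  # k capped
  tie <- structure(data.frame(resnum = c(5, 3), resname = "GLY",
                              energy = c(-1, -1)),
                   class = c("residue_contribution", "data.frame"))
  expect_equal(rank_contributors(tie, 2)$resnum, c(3, 5))
})

test_that("pocket residues dominate when charges live only in the pocket", {
  sys <- make_toy_complex(toy_complex_spec(seed = 6))
  # zero out charges and LJ outside the pocket (5 A of the ligand centroid)
  lig_c <- colMeans(coords(sys)[sys$ligand, , drop = FALSE])
  d <- sqrt(rowSums(sweep(coords(sys), 2, lig_c)^2))
  pocket_atoms <- which(d < 5 & seq_len(n_atoms(sys)) %in% sys$receptor)
  a <- sys$atoms
  outside <- setdiff(sys$receptor, pocket_atoms)
  a$charge[outside] <- 0
  a$epsilon[outside] <- 0
  a$group <- c("R", "L")[1 + seq_len(nrow(a)) %in% sys$ligand]
  sys2 <- molecular_system(a)
  tr <- trajectory(sys2, list(coords(sys2)))
  dec <- residue_decomposition(tr)
  pocket_res <- unique(sys2$atoms$resnum[pocket_atoms])
  share <- sum(abs(dec$energy[dec$resnum %in% pocket_res])) /
    sum(abs(dec$energy))
  expect_gte(share, 0.9)
})
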