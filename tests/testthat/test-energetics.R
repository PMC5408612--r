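table1_dg <- c(s1 = -1.75, s2 = -2.78, s3 = -1.29,
               s4 = -1.66, s5 = -3.13, s6 = -2.43)
table1_K <- c(s1 = 0.0188, s2 = 0.1060, s3 = 0.0087,
              s4 = 0.0162, s5 = 0.1906, s6 = 0.0589)

test_that("free-energy / binding-constant conversion is exact and invertible", {
  expect_equal(round(delta_g_to_K(table1_dg, 300), 4), table1_K)
  expect_equal(K_to_delta_g(table1_K, 300), table1_dg, tolerance = 0.005 / 1.29)
  expect_equal(round(delta_g_to_K(0), 4), 0.0010)      # K = 1 M^-1 at dG = 0

  dg <- seq(-10, 10, by = 0.5)
  expect_equal(K_to_delta_g(delta_g_to_K(dg)), dg, tolerance = 1e-10)

  # monotone decreasing: negative dG <=> K > 0.001 mM^-1
  expect_true(all(diff(delta_g_to_K(dg)) < 0))
  expect_true(all((dg < 0) == (delta_g_to_K(dg) > 0.001)))

  expect_error(K_to_delta_g(0), "positive")
  expect_error(delta_g_to_K(-1, temperature = -5), "positive")
})

test_that("lie_delta_g matches hand arithmetic and flags mislabeled states", {
  b <- energy_series(rep(-20, 4), rep(-10, 4), "bound")
  f <- energy_series(rep(-15, 4), rep(-6, 4), "free")
  est <- lie_delta_g(b, f, lie_params(0.18, 0.5, 0))
  expect_equal(est$delta_g, 0.18 * (-5) + 0.5 * (-4))  # -2.9
  expect_equal(est$se, 0)

  # identical bound and free series -> dG = gamma
  b2 <- energy_series(c(-1, 2, 0), c(3, -2, 1), "bound")
  f2 <- energy_series(c(-1, 2, 0), c(3, -2, 1), "free")
  est2 <- lie_delta_g(b2, f2, lie_params(0.3, 0.4, 1.7))
  expect_equal(est2$delta_g, 1.7)

  expect_error(lie_delta_g(b, b, lie_params()), "mislabel")
})

test_that("LIE estimates are unbiased and their block SEs are calibrated", {
  # z = (estimate - truth)/se should be ~standard normal-ish (t with ~36 df
  # from 4 x 10 block means); check bias, dispersion calibration and coverage
  # on a planted dG = -3.00 world across 100 seeds.
  dg_true <- -3.00
  z <- numeric(100)
  hits <- 0L
  for (seed in seq_along(z)) {
    spec <- energy_series_spec(
      mean_vdw = c(bound = -20, free = -15),               # alpha term: -0.9
      mean_el = c(bound = -10.2, free = -6),               # beta term: -2.1
      seed = seed)
    pair <- gen_energy_series(spec)
    est <- lie_delta_g(pair$bound, pair$free)
    z[seed] <- (est$delta_g - dg_true) / est$se
    if (abs(z[seed]) <= 2) hits <- hits + 1L
  }
  expect_equal(unname(true_delta_g(energy_series_spec(
    mean_vdw = c(bound = -20, free = -15),
    mean_el = c(bound = -10.2, free = -6)))), dg_true)
  expect_lt(abs(mean(z)), 0.4)          # no bias (4 x MC error of the mean)
  expect_lt(abs(stats::sd(z) - 1), 0.25)  # SEs neither inflated nor deflated
  expect_gte(hits / length(z), 0.85)    # ~94% nominal 2-SE coverage
})

test_that("block standard error behaves on constant, iid and AR(1) input", {
  expect_equal(block_standard_error(rep(3.2, 100)), 0)
  expect_error(block_standard_error(rnorm(15), 10), "insufficient")

  # iid: block SE within 50% of sigma/sqrt(n), most seeds
  sigma <- 2; n <- 1e4
  ok <- 0L
  for (seed in 1:20) {
    set.seed(seed)
    se <- block_standard_error(rnorm(n, sd = sigma))
    if (abs(se - sigma / sqrt(n)) < 0.5 * sigma / sqrt(n)) ok <- ok + 1L
  }
  expect_gte(ok, 18)

  # AR(1) phi = 0.9: block SE exceeds the naive estimate
  spec <- energy_series_spec(n_frames = 1e4, sd = 1, ar1_coefficient = 0.9,
                             seed = 3)
  x <- gen_energy_series(spec)$bound$frames$e_vdw
  expect_gt(block_standard_error(x), sd(x) / sqrt(length(x)))
})

test_that("stoichiometry reports exact concentration ratios", {
  r <- ligand_stoichiometry(100e-6, 60e-9, 36)
  expect_equal(r$ligands_per_particle, 100e-6 / 60e-9)
  expect_equal(round(r$ligands_per_particle, 2), 1666.67)
  expect_equal(round(r$ligands_per_subunit, 2), 46.30)
  expect_equal(r$ligands_per_subunit,
               r$ligands_per_particle / r$subunits_per_particle)

  r1 <- ligand_stoichiometry(1e-6, 1e-6, 1)
  expect_equal(r1$ligands_per_particle, 1)
  expect_equal(r1$ligands_per_subunit, 1)

  r2 <- ligand_stoichiometry(200e-6, 60e-9, 36)
  expect_equal(r2$ligands_per_particle, 2 * r$ligands_per_particle)
  expect_equal(r2$ligands_per_subunit, 2 * r$ligands_per_subunit)

  expect_error(ligand_stoichiometry(0, 1e-9, 36), "positive")
})

test_that("energy tables round-trip through CSV", {
  pair <- gen_energy_series(energy_series_spec(n_frames = 50, seed = 8))
  f <- withr::local_tempfile(fileext = ".csv")
  write_energy_csv(pair[c("bound", "free")], f)
  back <- read_energy_csv(f)
  expect_equal(back$bound$frames$e_vdw, pair$bound$frames$e_vdw, tolerance = 1e-12)
  expect_equal(back$free$frames$e_el, pair$free$frames$e_el, tolerance = 1e-12)
  expect_equal(back$bound$state, "bound")
})
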