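test_that("unit conversions and thermal energy match spectroscopic constants", {
  expect_equal(thermal_energy_cm1(300), 208.510428, tolerance = 1e-8)
  expect_equal(radfs_to_cm1(cm1_to_radfs(1234.5)), 1234.5, tolerance = 1e-12)
})

test_that("exciton_system validates couplings and groups", {
  expect_error(exciton_system(c(0, 100), matrix(c(0, 50, 51, 0), 2)),
               "asymmetric")
  expect_error(exciton_system(c(0, 100), matrix(c(1, 50, 50, 0), 2)),
               "zero diagonal")
  expect_error(exciton_system(c(0, 100), 50, groups = list(g = 3)),
               "invalid site indices")
  sys <- exciton_system(c(0, 100), 50, groups = list(a = 1L, b = 2L))
  expect_s3_class(sys, "exciton_system")
  expect_equal(n_sites(sys), 2)
})

test_that("max_exciton_gap matches the closed-form dimer splitting", {
  expect_equal(max_exciton_gap(exciton_system(c(0, 100), 50)),
               sqrt(100^2 + 4 * 50^2), tolerance = 1e-12)
  expect_equal(max_exciton_gap(exciton_system(c(0, 70), 0)), 70)
  expect_error(max_exciton_gap(exciton_system(5, matrix(0, 1, 1))), "2 sites")
})

test_that("max_exciton_gap is invariant under energy shifts and permutations", {
  set.seed(42)
  for (rep in 1:5) {
    n <- sample(3:8, 1)
    J <- matrix(rnorm(n^2, sd = 60), n)
    J <- (J + t(J)) / 2
    diag(J) <- 0
    eps <- rnorm(n, sd = 300)
    sys <- exciton_system(eps, J)
    g0 <- max_exciton_gap(sys)
    expect_equal(max_exciton_gap(exciton_system(eps + 123.4, J)), g0,
                 tolerance = 1e-9)
    p <- sample(n)
    expect_equal(max_exciton_gap(exciton_system(eps[p], J[p, p])), g0,
                 tolerance = 1e-9)
  }
})

test_that("total reorganization energy is additive and exact", {
  expect_equal(total_reorganization(spectral_density(
    data.frame(omega_cm1 = 1000, huang_rhys = 0.5))), 500)
  expect_equal(total_reorganization(spectral_density()), 0)
  sd <- spectral_density(
    data.frame(omega_cm1 = c(100, 100), huang_rhys = c(1, 1)),
    continuous_component("debye", 35, 50)
  )
  expect_equal(total_reorganization(sd), 235)
})

test_that("broadened reorganization density integrates to the mode reorganization", {
  expect_equal(reorganization_density(spectral_density(), seq(1, 100, 1)),
               rep(0, 100))
  grid <- seq(0.5, 5000, by = 0.5)
  sd <- spectral_density(data.frame(omega_cm1 = 1000, huang_rhys = 0.5))
  lam <- reorganization_density(sd, grid, broadening = 10)
  integral <- pracma::trapz(grid, lam)
  expect_lt(abs(integral - 500) / 500, 0.005)
  expect_lt(abs(grid[which.max(lam)] - 1000), 10)
  expect_error(reorganization_density(sd, numeric(0)), "non-empty")
})

test_that("bath partition routes modes by kT and omega_max", {
  sd <- spectral_density(data.frame(omega_cm1 = c(100, 300, 1600),
                                    huang_rhys = rep(0.1, 3)),
                         continuous_component("debye", 35, 50))
  p <- partition_bath(sd, 300, 1488)
  expect_equal(p$low, 1L)         # 100 < kT ~ 208.5
  expect_equal(p$high, 2L)        # kT <= 300 <= 1488
  expect_equal(p$nonresonant, 3L) # 1600 > 1488
  # exhaustive and exclusive
  expect_setequal(c(p$low, p$high, p$nonresonant), 1:3)
})

test_that("reorg_fraction reproduces simple ratios and stays in [0, 1]", {
  kT <- thermal_energy_cm1(300)
  sd <- spectral_density(data.frame(
    omega_cm1 = c(150, 600), huang_rhys = c(90 / 150, 10 / 600)))
  expect_equal(reorg_fraction(sd, 300, 1000), 0.10, tolerance = 1e-12)
  sd_low <- spectral_density(data.frame(omega_cm1 = c(50, 120),
                                        huang_rhys = c(0.5, 0.2)))
  expect_equal(reorg_fraction(sd_low, 300, 1000), 0)
  sd_mix <- spectral_density(data.frame(omega_cm1 = 500, huang_rhys = 0.2),
                             continuous_component("debye", 35, 50))
  f <- reorg_fraction(sd_mix, 300, 1300)
  expect_gte(f, 0); expect_lte(f, 1)
  expect_error(reorg_fraction(spectral_density(
    data.frame(omega_cm1 = 2000, huang_rhys = 0.2)), 300, 1000),
    "undefined")
})

test_that("equal-reorganization discretization conserves lambda and orders modes", {
  comp <- continuous_component("debye", lambda_cm1 = 100, omega_c_cm1 = 60)
  for (n in c(1, 7, 40)) {
    d <- discretize_continuous(comp, n)
    expect_equal(nrow(d), n)
    expect_lt(abs(sum(d$omega_cm1 * d$huang_rhys) - 99.9) / 99.9, 0.001)
    expect_true(all(diff(d$omega_cm1) > 0) || n == 1)
  }
  d1 <- discretize_continuous(comp, 1)
  # single mode sits at the median of the cumulative reorganization profile
  expect_equal(d1$omega_cm1, 60 * tan(0.4995 * pi / 2), tolerance = 1e-9)
})

test_that("discretized bath reproduces the classical bath correlation function", {
  # classical energy-gap autocorrelation of one site is proportional to
  # int Lambda(omega) cos(omega t) domega; for the Debye form this integral
  # has the closed form lambda * exp(-omega_c t)
  comp <- continuous_component("debye", lambda_cm1 = 100, omega_c_cm1 = 60)
  corr_dev <- function(n, t_fs) {
    d <- discretize_continuous(comp, n)
    wd <- cm1_to_radfs(d$omega_cm1)
    Cd <- sapply(t_fs, function(t) sum(d$omega_cm1 * d$huang_rhys * cos(wd * t)))
    max(abs(Cd - 100 * exp(-cm1_to_radfs(60) * t_fs))) / 100
  }
  # over the decay of the correlation function the match is tight
  expect_lt(corr_dev(200, seq(0, 250, by = 5)), 0.025)
  # over a full picosecond the dephased residual of an n-mode bath is
  # bounded by its statistical floor ~ lambda/sqrt(2n), and halves when
  # the mode count is quadrupled
  t_fs <- seq(0, 1000, by = 5)
  d200 <- corr_dev(200, t_fs)
  expect_lt(d200, 1.5 / sqrt(2 * 200))
  expect_lt(corr_dev(800, t_fs), 0.6 * d200)
})

test_that("model files round-trip through load_model / write_model", {
  path <- withr::local_tempfile(fileext = ".json")
  sys <- exciton_system(c(0, 100), 50, groups = list(donor = 1L, acceptor = 2L))
  sd <- fixture_dimer_sd()
  write_model(sys, sd, path, temperature_K = 300)
  m <- load_model(path)
  expect_equal(m$system$site_energies, sys$site_energies)
  expect_equal(m$system$couplings, sys$couplings)
  expect_equal(m$system$groups, sys$groups)
  expect_equal(m$sd$discrete, sd$discrete)
  expect_equal(m$sd$continuous[[1]]$lambda_cm1, 35)
  expect_equal(m$meta$temperature_K, 300)
  # second round trip is the identity
  path2 <- withr::local_tempfile(fileext = ".json")
  write_model(m$system, m$sd, path2, temperature_K = 300)
  m2 <- load_model(path2)
  expect_equal(m2$system, m$system)
  expect_equal(m2$sd, m$sd)
})

test_that("load_model rejects malformed files with named fields", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines('{"system": {"energies_cm1": [0, 100]}}', path)
  expect_error(load_model(path), "bath")
  writeLines(paste0('{"system": {"energies_cm1": [0, 100], ',
                    '"couplings_cm1": [[0, 50], [50, 0]]}, ',
                    '"bath": {"discrete": [{"omega_cm1": -5, "huang_rhys": 0.1}]}}'),
              path)
  expect_error(load_model(path), "omega_cm1")
  expect_error(load_model("no/such/file.json"), "not found")
})
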