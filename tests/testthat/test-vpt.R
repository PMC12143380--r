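test_that("band narrowing reduces to known closed forms", {
  # zero displacement: no narrowing
  expect_equal(band_narrowing(matrix(0, 3, 2), c(800, 1200), 300),
               matrix(1, 3, 3))
  # single mode, f = 0.3 on both sites, low-T limit coth -> 1:
  # <B_nm> = exp(-(0.3^2 + 0.3^2)/2) = exp(-0.09)
  B <- band_narrowing(matrix(0.3, 2, 1), 2000, 1)  # T = 1 K: coth ~ 1
  expect_equal(B[1, 2], exp(-0.09), tolerance = 1e-10)
  # narrowing strengthens (B decreases) with temperature
  temps <- c(50, 150, 300, 600)
  vals <- vapply(temps, function(T)
    band_narrowing(matrix(0.3, 2, 1), 800, T)[1, 2], numeric(1))
  expect_true(all(diff(vals) < 0))
  # symmetry
  f <- matrix(runif(6), 3, 2)
  B3 <- band_narrowing(f, c(500, 900), 300)
  expect_equal(B3, t(B3))
  expect_true(all(B3 > 0 & B3 <= 1))
})

test_that("renormalized energies and couplings follow the polaron shifts", {
  hm <- fixture_high_mode(1000, 0.25)  # g = 0.5
  sys <- exciton_system(c(0, 200), 100)
  # f = g: full polaron, energies shift by -lambda_high
  rn <- renormalize(sys, hm, matrix(0.5, 2, 1), 300)
  expect_equal(rn$eps_prime, sys$site_energies - 1000 * 0.25)
  # f = 0: identity
  rn0 <- renormalize(sys, hm, matrix(0, 2, 1), 300)
  expect_equal(rn0$eps_prime, sys$site_energies)
  expect_equal(rn0$J_prime, sys$couplings)
  # intermediate displacement: shift = omega (2 f g - f^2)
  rn2 <- renormalize(sys, hm, matrix(0.25, 2, 1), 300)
  expect_equal(rn2$eps_prime - sys$site_energies,
               rep(-1000 * (2 * 0.25 * 0.5 - 0.25^2), 2))
  expect_equal(rn2$eps_prime[1], 0 - 187.5)
  # couplings renormalized elementwise by the narrowing matrix
  expect_equal(rn2$J_prime[1, 2], 100 * rn2$narrowing[1, 2])
})

test_that("gamma matrix has the right limits", {
  sys <- exciton_system(c(0, 150), 60)
  # near-infinite temperature: P uniform, row orthonormality kills off-diagonals
  g_inf <- gamma_matrix(sys$site_energies, sys$couplings, 1e9)
  expect_equal(g_inf$gamma[1, 2], 0, tolerance = 1e-6)
  expect_equal(diag(g_inf$gamma), c(1, 1))
  # near-zero temperature: only the ground state contributes,
  # Gamma_nm = U_m0 / U_n0
  g_0 <- gamma_matrix(sys$site_energies, sys$couplings, 0.5)
  H <- sys$couplings; diag(H) <- sys$site_energies
  ee <- eigen(H, symmetric = TRUE)
  U0 <- ee$vectors[, which.min(ee$values)]
  expect_equal(g_0$gamma[1, 2], U0[2] / U0[1], tolerance = 1e-6)
  # symmetric dimer at finite T: Gamma symmetric
  gs <- gamma_matrix(c(0, 0), matrix(c(0, -50, -50, 0), 2), 300)
  expect_equal(gs$gamma[1, 2], gs$gamma[2, 1])
  expect_equal(sum(gs$boltzmann), 1)
})

test_that("solve_vpt handles degenerate inputs exactly", {
  sys <- exciton_system(c(0, 200), 100)
  # no coupling to high modes: f = 0, identity transformation
  v0 <- solve_vpt(sys, discretized_bath(1000, 0), 300)
  expect_equal(v0$f, matrix(0, 2, 1))
  expect_equal(v0$eps_prime, sys$site_energies)
  expect_equal(v0$J_prime, sys$couplings)
  expect_true(v0$converged)
  expect_lte(v0$iterations, 2L)
  # empty mode set: identity solution
  ve <- solve_vpt(sys, discretized_bath(numeric(0), numeric(0)), 300)
  expect_equal(ve$narrowing, matrix(1, 2, 2))
  expect_true(ve$converged)
  # J = 0: full polaron, f = g exactly, couplings stay zero
  sysj0 <- exciton_system(c(0, 200), 0)
  vj <- solve_vpt(sysj0, fixture_high_mode(1200, 0.3), 300)
  expect_equal(vj$f, matrix(sqrt(0.3), 2, 1), tolerance = 1e-9)
  expect_equal(vj$J_prime, matrix(0, 2, 2))
})

test_that("fixed-point displacements minimize the free-energy bound", {
  hm <- fixture_high_mode(1200, 0.3)
  # symmetric dimer: 1-D scan by symmetry
  sys <- exciton_system(c(0, 0), -100)
  v <- solve_vpt(sys, hm, 300)
  expect_true(v$converged)
  expect_lte(v$iterations, 10L)
  fgrid <- seq(0, sqrt(0.3), length.out = 2001)
  F0 <- vapply(fgrid, function(f)
    excimash:::vpt_free_energy(sys, hm, matrix(f, 2, 1), 300), numeric(1))
  expect_lt(abs(v$f[1, 1] - fgrid[which.min(F0)]), diff(fgrid[1:2]))
  # asymmetric dimer: 2-D grid oracle
  sys2 <- exciton_system(c(0, 200), 100)
  v2 <- solve_vpt(sys2, hm, 300)
  g2 <- seq(0, sqrt(0.3) * 1.05, length.out = 231)
  FF <- outer(g2, g2, Vectorize(function(f1, f2)
    excimash:::vpt_free_energy(sys2, hm, matrix(c(f1, f2), 2, 1), 300)))
  ix <- which(FF == min(FF), arr.ind = TRUE)
  h <- diff(g2[1:2])
  expect_lt(abs(v2$f[1, 1] - g2[ix[1]]), h)
  expect_lt(abs(v2$f[2, 1] - g2[ix[2]]), h)
  # Bogoliubov direction: converged F0 below both f = 0 and f = g
  Fc <- excimash:::vpt_free_energy(sys2, hm, v2$f, 300)
  expect_lte(Fc, excimash:::vpt_free_energy(sys2, hm, matrix(0, 2, 1), 300))
  expect_lte(Fc, excimash:::vpt_free_energy(sys2, hm, matrix(sqrt(0.3), 2, 1), 300))
  # stationarity defect is small at the fixed point
  expect_lt(v2$residual, 1e-5)
})

test_that("solution is insensitive to the initial guess and equivariant", {
  hm <- discretized_bath(c(900, 1400), c(0.2, 0.1))
  sys <- exciton_system(c(0, 150, 350), matrix(c(0, 80, 20, 80, 0, 60, 20, 60, 0), 3))
  g <- hm$g
  v1 <- solve_vpt(sys, hm, 300)
  for (scale in c(0.5, 0.9)) {
    vi <- solve_vpt(sys, hm, 300,
                    f_init = matrix(g * scale, 3, 2, byrow = TRUE))
    expect_equal(vi$f, v1$f, tolerance = 1e-7)
  }
  # displacements stay within [0, g] on this fixture
  expect_true(all(v1$f >= 0 & sweep(v1$f, 2, g, `<=`)))
  # site permutation permutes the solution
  p <- c(3, 1, 2)
  sysp <- exciton_system(sys$site_energies[p], sys$couplings[p, p])
  vp <- solve_vpt(sysp, hm, 300)
  expect_equal(vp$f, v1$f[p, ], tolerance = 1e-8)
  expect_equal(vp$eps_prime, v1$eps_prime[p], tolerance = 1e-8)
  expect_equal(vp$J_prime, v1$J_prime[p, p], tolerance = 1e-8)
})

test_that("VPT solutions serialize to JSON and back", {
  v <- solve_vpt(exciton_system(c(0, 200), 100), fixture_high_mode(), 300)
  path <- withr::local_tempfile(fileext = ".json")
  write_vpt(v, path)
  v2 <- load_vpt(path)
  expect_equal(v2$f, v$f)
  expect_equal(v2$eps_prime, v$eps_prime)
  expect_equal(v2$J_prime, v$J_prime)
  expect_equal(v2$narrowing, v$narrowing)
})
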