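test_that("population estimator identities hold exactly", {
  # alpha_N and magnitudes from closed forms
  expect_equal(alpha_mash(2), 2)                    # 1/(H_2 - 1)* (2-1) = 2
  expect_equal(alpha_mash(3), 2.4)                  # 2 / (11/6 - 1)
  for (N in c(2, 3, 8, 24)) {
    expect_equal(alpha_mash(N), (N - 1) / (sum(1 / seq_len(N)) - 1))
    set.seed(N)
    c0 <- focused_init(1, N)
    expect_equal(sum(Mod(c0)^2), 1, tolerance = 1e-12)
    phi <- population_estimator(c0)
    expect_equal(phi, c(1, rep(0, N - 1)), tolerance = 1e-12)
    expect_equal(sum(phi), 1, tolerance = 1e-12)
    # magnitudes match the closed-form focusing radii
    a <- alpha_mash(N)
    expect_equal(Mod(c0)[1]^2, (N - 1 + a) / (N * a), tolerance = 1e-12)
    expect_equal(Mod(c0)[2]^2, (a - 1) / (N * a), tolerance = 1e-12)
  }
  # uniform coefficients give uniform estimator
  expect_equal(population_estimator(rep(1 / 3, 3)), rep(1 / 3, 3))
  # N = 2 corner: estimator can leave [0, 1] but sums to one
  expect_equal(population_estimator(c(1, 0) + 0i), c(3 / 2, -1 / 2))
  expect_error(population_estimator(c(1, 1)), "not normalized")
})

test_that("potential matrix reduces to H_s at the vertical-excitation origin", {
  sys <- exciton_system(c(0, 150), 60)
  bath <- fixture_high_mode(800, 0.2)
  V0 <- potential_matrix(matrix(0, 2, 1), sys, bath)
  expect_equal(V0, matrix(c(0, 60, 60, 150), 2))
  # zero coupling: V independent of q
  b0 <- discretized_bath(800, 0)
  expect_equal(potential_matrix(matrix(3, 2, 1), sys, b0), V0)
  # single site + single mode: completing the square puts the minimum of
  # V_11(q) + omega^2 q^2/2 at depth -lambda below V_11(0)
  sys1 <- exciton_system(1000, matrix(0, 1, 1))
  b1 <- fixture_high_mode(900, 0.4)
  w <- cm1_to_radfs(900)
  qgrid <- seq(-40, 10, length.out = 20001)
  vtot <- vapply(qgrid, function(q)
    potential_matrix(matrix(q, 1, 1), sys1, b1)[1, 1] +
      radfs_to_cm1(0.5 * w^2 * q^2), numeric(1))
  expect_equal(min(vtot) - 1000, -900 * 0.4, tolerance = 0.01)
})

test_that("nuclear sampling has the prescribed variances and limits", {
  bath <- discretized_bath(c(50, 1500), c(0.1, 0.1))
  w <- cm1_to_radfs(bath$omega_cm1)
  kT <- cm1_to_radfs(thermal_energy_cm1(300))
  set.seed(1)
  s <- sample_nuclei(bath, 300, "classical_boltzmann", n_sites = 1e5)
  expect_equal(apply(s$q, 2, var), kT / w^2, tolerance = 0.02)
  expect_equal(apply(s$p, 2, var), rep(kT, 2), tolerance = 0.02)
  sw <- sample_nuclei(bath, 300, "wigner", n_sites = 1e5)
  cth <- 1 / tanh(w / (2 * kT))
  expect_equal(apply(sw$q, 2, var), cth / (2 * w), tolerance = 0.02)
  expect_equal(apply(sw$p, 2, var), w * cth / 2, tolerance = 0.02)
  # Wigner widths: classical limit at low frequency, zero point at high
  expect_equal(cth[1] / (2 * w[1]), kT / w[1]^2, tolerance = 0.01)
  expect_equal(cth[2] / (2 * w[2]), 1 / (2 * w[2]), tolerance = 0.01)
})

test_that("zero-coupling ensembles reproduce exact quantum dynamics", {
  bath <- discretized_bath(200, 0)
  cfg <- mash_config(t_max = 150, n_traj = 3000, dt = 0.25, dt_out = 5, seed = 7)
  # dimer
  dm <- make_dimer(100, 50)
  ts <- run_ensemble(dm$system, bath, cfg)
  exact <- exact_quantum_pops(dm$system, ts$times, 1)
  expect_lt(max(abs(ts$phi - exact)), 4 * max(ts$sem))
  # estimator normalization is exact at every time
  expect_equal(colSums(ts$phi), rep(1, ncol(ts$phi)), tolerance = 1e-12)
  # 3-site system
  sys3 <- exciton_system(c(0, 120, 260),
                         matrix(c(0, 60, 15, 60, 0, 45, 15, 45, 0), 3))
  ts3 <- run_ensemble(sys3, bath, cfg)
  exact3 <- exact_quantum_pops(sys3, ts3$times, 1)
  expect_lt(max(abs(ts3$phi - exact3)), 4 * max(ts3$sem))
  # no-back-action dynamics at g = 0 evolves c under the bare H_s exactly;
  # its raw |c_n|^2 average is the focused-initial-condition image of the
  # quantum populations, which the Phi transform inverts exactly
  tsn <- run_no_backaction(sys3, bath, cfg)
  phi_n <- 1 / 3 + alpha_mash(3) * (tsn$phi - 1 / 3)
  expect_lt(max(abs(phi_n - exact3)), 4 * alpha_mash(3) * max(tsn$sem) + 1e-10)
})

test_that("single trajectories conserve norm and energy", {
  sdens <- fixture_dimer_sd()
  dm <- make_dimer(300, 50, sdens)
  bath <- dynamical_bath(sdens, n_per_component = 16)
  cfg <- mash_config(t_max = 1000, n_traj = 5, dt = 0.25, dt_out = 5, seed = 21)
  drift_rates <- c()
  for (j in 0:4) {
    tr <- mash_trajectory(dm$system, bath, cfg, traj_index = j)
    expect_true(tr$ok)
    # unitary coefficient propagation
    expect_lt(max(abs(tr$norm - 1)), 1e-9)
    # energy is conserved across accepted hops by construction and drifts
    # only through the velocity-Verlet error between them
    drift_rates <- c(drift_rates, abs(tr$energy_cm1[length(tr$energy_cm1)] -
                                        tr$energy_cm1[1]))
  }
  kT <- thermal_energy_cm1(300)
  expect_lt(median(drift_rates), 0.02 * kT)  # per ps
  # quartering the timestep cuts the energy drift by about an order of
  # magnitude (second-order integrator)
  cfg2 <- mash_config(t_max = 1000, n_traj = 5, dt = 0.0625, dt_out = 5, seed = 21)
  tr1 <- mash_trajectory(dm$system, bath, cfg, traj_index = 1)
  tr2 <- mash_trajectory(dm$system, bath, cfg2, traj_index = 1)
  d1 <- max(abs(tr1$energy_cm1 - tr1$energy_cm1[1]))
  d2 <- max(abs(tr2$energy_cm1 - tr2$energy_cm1[1]))
  expect_lt(d2, d1)
})

test_that("hop bookkeeping records accepted and frustrated events", {
  sdens <- fixture_dimer_sd()
  dm <- make_dimer(417, 50, sdens)
  bath <- dynamical_bath(sdens, n_per_component = 16)
  cfg <- mash_config(t_max = 2000, n_traj = 5, dt = 0.25, dt_out = 10, seed = 5)
  hops <- do.call(rbind, lapply(0:7, function(j)
    mash_trajectory(dm$system, bath, cfg, traj_index = j)$hops))
  expect_gt(nrow(hops), 0)
  expect_true(all(hops$from != hops$to))
  # uphill hops need kinetic energy; some should be frustrated in a biased dimer
  expect_true(any(hops$accepted == 0))
  expect_true(any(hops$accepted == 1))
})

test_that("ensembles are reproducible and invariant under energy shifts", {
  sdens <- fixture_dimer_sd()
  dm <- make_dimer(200, 60, sdens)
  bath <- dynamical_bath(sdens, n_per_component = 8)
  cfg <- mash_config(t_max = 200, n_traj = 200, dt = 0.25, dt_out = 10, seed = 13)
  ts1 <- run_ensemble(dm$system, bath, cfg)
  ts2 <- run_ensemble(dm$system, bath, cfg)
  expect_identical(ts1$phi, ts2$phi)
  # uniform site-energy shift leaves populations unchanged bit-for-bit
  sys_shift <- exciton_system(dm$system$site_energies + 5000,
                              dm$system$couplings)
  ts3 <- run_ensemble(sys_shift, bath, cfg)
  expect_equal(ts3$phi, ts1$phi, tolerance = 1e-9)
})

test_that("symmetric dimer equilibrates to equal populations", {
  sdens <- fixture_dimer_sd()
  dm <- make_dimer(0, 50, sdens)
  bath <- dynamical_bath(sdens, n_per_component = 12)
  cfg <- mash_config(t_max = 2500, n_traj = 2000, dt_out = 25, seed = 17)
  ts <- run_ensemble(dm$system, bath, cfg)
  lt <- longtime_populations(ts, window = 0.3)
  expect_lt(abs(lt$populations[1] - 0.5), 2 * lt$sem[1] + 0.005)
})

test_that("halving the timestep changes populations within ensemble error", {
  sdens <- fixture_dimer_sd()
  dm <- make_dimer(300, 60, sdens)
  bath <- dynamical_bath(sdens, n_per_component = 12)
  cfg1 <- mash_config(t_max = 1500, n_traj = 1500, dt = 0.25, dt_out = 25, seed = 29)
  cfg2 <- mash_config(t_max = 1500, n_traj = 1500, dt = 0.125, dt_out = 25, seed = 29)
  ts1 <- run_ensemble(dm$system, bath, cfg1)
  ts2 <- run_ensemble(dm$system, bath, cfg2)
  comb <- sqrt(ts1$sem^2 + ts2$sem^2)
  expect_lt(mean(abs(ts1$phi - ts2$phi)), 2 * mean(comb))
})

test_that("no-back-action dynamics heats the exciton system to 1/N", {
  sdens <- fixture_dimer_sd()
  dm <- make_dimer(417, 50, sdens)   # strongly biased dimer
  bath <- dynamical_bath(sdens, n_per_component = 12)
  cfg <- mash_config(t_max = 4000, n_traj = 1500, dt_out = 40, seed = 19)
  ts <- run_no_backaction(dm$system, bath, cfg)
  expect_equal(ts$estimator, "c2")
  lt <- longtime_populations(ts, window = 0.25)
  # equal populations despite the 2 kT site-energy bias
  expect_lt(abs(lt$populations[1] - 0.5), 2 * lt$sem[1] + 0.01)
})
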