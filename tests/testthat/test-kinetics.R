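test_that("swelling rate follows the first-order uptake law", {
  p <- swelling_params(k_v = 0.00335, V_max = 1.27e-3, V_ads0 = 0)
  # equilibrium fixed point
  expect_identical(swelling_rate(p$V_max, p), 0)
  # dry-particle rate is k_v * V_max
  expect_equal(swelling_rate(0, p), 4.25450e-6, tolerance = 1e-6)
  # rate is linear in remaining capacity
  expect_equal(swelling_rate(p$V_max / 2, p), swelling_rate(0, p) / 2)
  expect_error(swelling_rate(2 * p$V_max, p), "exceeds V_max")
})

test_that("closed-form swelling curve hits its boundary conditions", {
  p <- swelling_params(k_v = 0.00335, V_max = 1.27e-3, V_ads0 = 0)
  expect_identical(swelling_closed_form(0, p), p$V_ads0)
  # saturated limit
  t_sat <- 30 / p$k_v
  expect_equal(swelling_closed_form(t_sat, p), p$V_max, tolerance = 1e-12)
  # one day of swelling: V_max * (1 - e^(-4.824))
  expect_equal(swelling_closed_form(1440, p), 1.2599e-3, tolerance = 1e-4)
  expect_error(swelling_closed_form(-1, p), ">= 0")
  # nonzero initial volume enters the transient
  p2 <- swelling_params(k_v = 0.01, V_max = 1, V_ads0 = 0.5)
  expect_identical(swelling_closed_form(0, p2), 0.5)
})

test_that("phase concentrations are per-phase quotients", {
  cfg <- make_batch1()
  st <- make_state(V_ads = 0.01, V_b = 40, n_s = 1.6e-7, n_ads = 0, n_b = 0)
  C <- concentrations(st, cfg)
  expect_equal(C[["C_s"]], 6.667e-4, tolerance = 1e-4)
  expect_identical(C[["C_ads"]], 0)
  # homogeneity: doubling every amount doubles every concentration
  st2 <- make_state(0.01, 40, 3.2e-7, 0, 0)
  expect_equal(concentrations(st2, cfg), 2 * C)
  # all-zero load gives zero concentrations
  st0 <- make_state(0.01, 40, 0, 0, 0)
  expect_equal(unname(concentrations(st0, cfg)), c(0, 0, 0))
  # degenerate volume is an error
  expect_error(concentrations(make_state(0, 40, 0, 0, 0), cfg), "degenerate")
})

test_that("film fluxes have the partition-equilibrium zero and right signs", {
  cfg <- make_batch1()
  # solid-liquid flux vanishes at C_s = H * C_ads
  C_eq <- c(C_s = cfg$H_Lf * 2e-9, C_ads = 2e-9, C_b = 0)
  expect_equal(flux_sl(C_eq, cfg), 0)
  # dry-start flux, direct arithmetic
  C0 <- c(C_s = 6.667e-4, C_ads = 0, C_b = 0)
  expect_equal(flux_sl(C0, cfg), 1.4819e4, tolerance = 1e-3)
  # back-transfer when the adsorbed phase is richer
  expect_lt(flux_sl(c(C_s = 0, C_ads = 1e-9, C_b = 0), cfg), 0)
  # liquid-liquid flux
  expect_equal(flux_ll(c(C_s = 0, C_ads = 2e-9, C_b = 2e-9), cfg), 0)
  expect_equal(flux_ll(c(C_s = 0, C_ads = 2e-9, C_b = 0), cfg), 2.0255e-9,
               tolerance = 1e-4)
  # linear in the coefficient
  cfg2 <- make_batch1(beta_ll = 2 * 1.01277)
  expect_equal(flux_ll(c(C_s = 0, C_ads = 2e-9, C_b = 0), cfg2),
               2 * flux_ll(c(C_s = 0, C_ads = 2e-9, C_b = 0), cfg))
})

test_that("conservative rhs conserves moles and volume; as-printed does not", {
  cfg <- make_batch1()
  st <- make_state(V_ads = 0.01, V_b = 39.99, n_s = 1e-7, n_ads = 4e-8,
                   n_b = 2e-8)
  d <- release_rhs(0, st, cfg, mode = "conservative")
  expect_equal(d[["dV_ads"]] + d[["dV_b"]], 0)
  expect_equal(d[["dn_s"]] + d[["dn_ads"]] + d[["dn_b"]], 0)

  # as printed, the mole balance closes only when the two fluxes coincide:
  # the residual is 2 (J_ll - J_sl) V_ads
  dp <- release_rhs(0, st, cfg, mode = "as_printed")
  C <- concentrations(st, cfg)
  resid <- 2 * (flux_ll(C, cfg) - flux_sl(C, cfg)) * st$V_ads
  expect_equal(dp[["dn_s"]] + dp[["dn_ads"]] + dp[["dn_b"]], resid)
  expect_true(abs(resid) > 0)

  # mutual equilibrium at full swelling is a fixed point
  c0 <- 4e-9
  stq <- make_state(V_ads = v_max(cfg), V_b = 39.9,
                    n_s = cfg$H_Lf * c0 * cfg$V_s,
                    n_ads = c0 * v_max(cfg), n_b = c0 * 39.9)
  dq <- release_rhs(0, stq, cfg, mode = "conservative")
  expect_equal(max(abs(dq)), 0, tolerance = 1e-20)

  expect_error(release_rhs(0, st, cfg, mode = "nonsense"), "arg")
})

test_that("simulated trajectories conserve volume and moles", {
  cfg <- make_batch1()
  times <- c(seq(0, 60, by = 2), seq(90, 600, by = 30))
  traj <- simulate_release(cfg, times = times)
  N <- total_moles(cfg)
  expect_true(all(abs(traj$V_ads_cm3 + traj$V_b_cm3 -
                        (cfg$V_ads0 + cfg$V_b0)) <= 1e-9 * cfg$V_b0))
  expect_true(all(abs(traj$n_s_mol + traj$n_ads_mol + traj$n_b_mol - N)
                  <= 1e-6 * N))
  # swelling is monotone and within bounds
  expect_true(all(diff(traj$V_ads_cm3) >= 0))
  expect_true(all(traj$V_ads_cm3 <= v_max(cfg) * (1 + 1e-12)))
  expect_true(all(traj$release_fraction >= 0 & traj$release_fraction <= 1))
})

test_that("bulk amount rises monotonically up to the swelling-dilution overshoot", {
  # concentrations equalize across the films within minutes, but swelling
  # keeps diluting the adsorbed phase for hours, pulling a small back-flux
  # out of the bulk: n_b may decline after its peak, by well under 0.5%
  cfg <- make_batch1()
  traj <- simulate_release(cfg, times = c(0:10, seq(20, 2000, by = 20)))
  peak <- which.max(traj$n_b_mol)
  expect_true(all(diff(traj$n_b_mol[1:peak]) >= 0))
  post <- traj$n_b_mol[peak:nrow(traj)]
  expect_true(all(post >= traj$n_b_mol[peak] * (1 - 5e-3)))
})

test_that("no transfer path to the bulk keeps the bulk load frozen", {
  cfg <- make_batch1(beta_ll = 1e-300)
  traj <- simulate_release(cfg, times = seq(0, 100, by = 10))
  expect_true(all(abs(traj$n_b_mol - cfg$n_b0) <= 1e-12 * total_moles(cfg)))
})

test_that("dissolution sends every remaining mole to the bulk and freezes", {
  cfg <- make_batch1(t_dissolve = 10)
  traj <- simulate_release(cfg, times = c(0, 2, 5, 10, 20, 50))
  expect_identical(traj$dissolved, c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
  post <- traj[traj$t_min >= 10, ]
  expect_equal(post$release_fraction, rep(1, nrow(post)), tolerance = 1e-12)
  expect_equal(post$n_s_mol, rep(0, nrow(post)))
  # dissolution before the first positive sample time
  cfg2 <- make_batch1(t_dissolve = 0.5)
  traj2 <- simulate_release(cfg2, times = c(0, 1, 2))
  expect_equal(traj2$release_fraction[-1], c(1, 1), tolerance = 1e-12)
})

test_that("long-horizon simulation reaches the analytic partition equilibrium", {
  cfg <- make_batch1()
  eq <- equilibrium_state(cfg)
  # plug-in equilibrium values for the 40 cm^3 stirred run
  expect_equal(eq$c_eq_mol_per_cm3, 4.0e-9, tolerance = 1e-3)
  expect_equal(eq$bulk_fraction, 0.9976, tolerance = 1e-3)
  traj <- simulate_release(cfg, times = c(0, 10^(1:4)))
  last <- traj[nrow(traj), ]
  expect_rel_equal(last$n_b_mol, eq$n_b_mol, 1e-6)
  expect_rel_equal(last$V_ads_cm3, eq$V_ads_cm3, 1e-6)
  expect_rel_equal(last$n_ads_mol, eq$n_ads_mol, 1e-6)
})

test_that("a strong-partition solid retains its load at equilibrium", {
  cfg <- make_batch1(H_Lf = 1)
  frac_1 <- equilibrium_state(cfg)$n_s_mol / total_moles(cfg)
  cfg_strong <- make_batch1(H_Lf = 1, V_s = 1e6)
  eq <- equilibrium_state(cfg_strong)
  # with H * V_s >> all liquid volumes nearly everything stays in the solid
  expect_gt(eq$n_s_mol / total_moles(cfg_strong), 0.999)
  expect_lt(eq$bulk_fraction, 1e-3)
  expect_gt(frac_1, 0)
})

test_that("integrated swelling matches the closed form across random draws", {
  set.seed(7)
  for (i in 1:25) {
    k_v <- 10^stats::runif(1, -4, 0)
    V_max <- 10^stats::runif(1, -4, 2)
    cfg <- batch_config(W_s = 1, V_s = 1e-4, V_ads0 = 1e-8, V_h = V_max,
                        V_b0 = 10 * V_max + 1, k_v = k_v, n_s0 = 1e-7,
                        H_Lf = 1e-4, beta_sl = 10, beta_ll = 0.5)
    p <- swelling_params(k_v, V_max, 1e-8)
    times <- seq(0, 5 / k_v, length.out = 100)
    traj <- simulate_release(cfg, times = times)
    expect_true(all(abs(traj$V_ads_cm3 - swelling_closed_form(times, p))
                    <= 1e-6 * V_max),
                label = sprintf("draw %d (k_v=%.3g, V_max=%.3g)", i, k_v, V_max))
  }
})
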