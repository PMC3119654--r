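# The coupled membrane-potential / cytosolic-pH cell model.

test_that("gating midpoint, limits, and pH_o tracking are exact", {
  hv <- hv_channel_params(g_max_ns = 1, delta_mv = 15, slope_k_mv = 8)
  e_h <- -46.5
  expect_equal(hv_steady_open(e_h + 15, e_h, hv), 0.5)
  expect_equal(hv_steady_open(-1e4, e_h, hv), 0)
  expect_equal(hv_steady_open(1e4, e_h, hv), 1)
  # strictly increasing in v
  v <- seq(-100, 80, by = 5)
  expect_true(all(diff(hv_steady_open(v, e_h, hv)) > 0))
  # a one-unit pH_o drop moves E_H by the slope and the activation curve
  # with it, one-to-one
  slope <- nernst_slope_mv(20)
  expect_equal(hv_steady_open(v + slope, e_h + slope, hv),
               hv_steady_open(v, e_h, hv))
})

test_that("channel current reverses at E_H and scales as g*p*(v - E_H)", {
  hv <- hv_channel_params(g_max_ns = 2)
  for (p in c(0, 0.3, 1)) expect_equal(hv_current(-46.5, p, -46.5, hv), 0)
  expect_equal(hv_current(3.5, 0.5, -46.5, hv), 50)
  # full Zn block with no background: zero at any voltage
  hvb <- hv_channel_params(g_max_ns = 2, zn_block_fraction = 1)
  for (v in c(-80, 0, 60)) {
    expect_equal(hv_current(v, 1, -46.5, hvb, zn_applied = TRUE), 0)
  }
})

test_that("Cl- rectifier activates with hyperpolarisation only", {
  cl <- cl_channel_params(g_max_ns = 1, e_cl_mv = -20, v_half_mv = -60,
                          slope_k_mv = 12)
  expect_equal(cl_current(-20, cl), 0)
  # essentially no current at depolarised potentials
  expect_lt(abs(cl_current(60, cl)), 1e-2)
  # inward current grows monotonically below v_half
  v <- seq(-60, -120, by = -5)
  i <- cl_current(v, cl)
  expect_true(all(i < 0))
  expect_true(all(diff(i) < 0))
})

test_that("background H+ pathway rectifies like a GHK flux", {
  # near-zero inward current at -110 mV under sea-water pH (few external
  # protons), substantial outward current at depolarised potentials
  inward <- ghk_h_factor(-110, 7.2, 8.0)
  outward <- ghk_h_factor(70, 7.2, 8.0)
  # an ohmic pathway with these driving forces would give |in|/|out| of
  # (110 - 46.5)/(70 + 46.5) = 0.545; GHK rectification more than halves it
  expect_lt(abs(inward) / abs(outward), 0.27)
  # reverses at E_H
  e_h <- nernst_slope_mv(20) * (7.2 - 8.0)
  expect_equal(ghk_h_factor(e_h, 7.2, 8.0), 0, tolerance = 1e-12)
  expect_lt(ghk_h_factor(e_h - 1, 7.2, 8.0), 0)
  expect_gt(ghk_h_factor(e_h + 1, 7.2, 8.0), 0)
})

test_that("leak-only membrane rests exactly at the leak reversal", {
  cfg <- native_default_config(g_max_ns = 0,
                               background_permeability_pl_s = 0,
                               g_cl_ns = 0, g_leak_ns = 0.5,
                               e_leak_mv = -63)
  expect_equal(as.numeric(resting_potential(cfg)), -63, tolerance = 1e-6)
})

test_that("outward current is monotone in pH_o and pH_i as observed", {
  cfg <- native_default_config()
  steady_i_h <- function(v, ph_i, ph_o) {
    c2 <- native_default_config(ph_o = ph_o, ph_i = ph_i)
    e_h <- config_e_h(c2, ph_i)
    p <- hv_steady_open(v, e_h, c2$hv)
    hv_current(v, p, e_h, c2$hv, ph_i = ph_i, ph_o = ph_o)
  }
  # at fixed v above threshold, outward I_H falls as pH_o falls
  for (v in c(-20, 0, 40, 60)) {
    i <- vapply(c(8.0, 7.5, 7.0, 6.5), function(po)
      steady_i_h(v, 7.2, po), numeric(1))
    expect_true(all(diff(i) <= 1e-9))
  }
  # lowering pH_i at fixed pH_o raises outward I_H at every voltage
  v <- seq(-60, 60, by = 10)
  i_75 <- vapply(v, function(vv) steady_i_h(vv, 7.5, 8.0), numeric(1))
  i_65 <- vapply(v, function(vv) steady_i_h(vv, 6.5, 8.0), numeric(1))
  expect_true(all(i_65 >= i_75 - 1e-9))
})

test_that("proton budget closes on every kind of run", {
  cfg <- native_default_config()
  runs <- list(
    clamp_step(cfg, 70),
    clamp_step(cfg, -110),
    simulate_free_running(cfg, duration_s = 30),
    simulate_free_running(
      scenario_config(cfg, scenario_registry()$zn_block),
      scenario_registry()$zn_block, duration_s = 240, init = "steady"))
  for (r in runs) {
    expect_lt(proton_budget(r)$relative_residual, 1e-5)
  }
})

test_that("channel budget term matches an independent trapezoidal integral", {
  cfg <- native_default_config()
  r <- clamp_step(cfg, 70, hold_s = 0.5, step_s = 8, record_dt_s = 5e-4)
  chan_mol <- r$cum_channel_mol[nrow(r)]
  oracle <- oracle_trapz(r$time_s, r$i_h_gated_pa) * 1e-12 / 96485.33212
  expect_equal(chan_mol, oracle, tolerance = 1e-6)
})

test_that("quiescent non-calcifying cell at rest moves no protons", {
  cfg <- native_default_config(j_calc_mol_s = 0, k_sec_per_s = 0)
  v0 <- as.numeric(resting_potential(cfg))
  r <- simulate_free_running(cfg, duration_s = 20)
  b <- proton_budget(r)
  # at the zero-current rest the H+ pathways are static and tiny
  # (sub-0.1 pA currents over 20 s)
  expect_lt(max(abs(b$terms_mol)), 3e-17)
  expect_lt(abs(delta_ph(r)), 2e-3)
  expect_equal(r$v_m_mv[nrow(r)], v0, tolerance = 0.5)
})

test_that("depolarisation above E_H alkalinises; hyperpolarisation is pH-neutral", {
  cfg <- native_default_config()
  up <- clamp_step(cfg, 70)
  expect_gt(delta_ph(up, 2, 12), 0.2)
  for (level in c(-90, -110)) {
    down <- clamp_step(cfg, level)
    expect_lt(abs(delta_ph(down, 2, 12)), 0.005)
  }
})

test_that("post-pulse pH recovery is exponential on the 30-60 s scale", {
  cfg <- native_default_config()
  pr <- data.frame(level_mv = c(-50, 70, -50), duration_s = c(2, 10, 150))
  r <- simulate_voltage_clamp(pr, cfg, record_dt_s = 0.1)
  rec <- r[r$time_s >= 12, ]
  ph_inf <- rec$ph_i[nrow(rec)]
  excess <- rec$ph_i - ph_inf
  sel <- excess > 1e-4
  fit <- stats::lm(log(excess[sel]) ~ rec$time_s[sel])
  tau_s <- -1 / unname(coef(fit)[2])
  expect_gt(tau_s, 30)
  expect_lt(tau_s, 60)
})

test_that("Zn2+ acidifies the calcifying cell but not the Ca-free cell", {
  reg <- scenario_registry()
  run <- function(sc) {
    cfg <- scenario_config(native_default_config(), sc)
    simulate_free_running(cfg, sc, duration_s = 240, init = "steady")
  }
  zn <- run(reg$zn_block)
  d_zn <- delta_ph(zn, 60, 210)
  # monotone fall during the application window
  win <- zn$ph_i[zn$time_s >= 60 & zn$time_s <= 210]
  expect_true(all(diff(win) <= 1e-9))
  expect_lt(abs(d_zn - -0.13), 0.04)
  cafree <- run(reg$ca_free)
  expect_lte(abs(delta_ph(cafree, 60, 210)), 0.04)
  # the complete (Gd3+-like) block acidifies at least as much as Zn2+
  gd <- run(reg$gd_block)
  expect_lte(delta_ph(gd, 60, 210), d_zn + 1e-6)
  # mutant presets block less, so acidify less
  mut <- run(reg$mutant_H197A)
  expect_gt(delta_ph(mut, 60, 210), d_zn)
})

test_that("an external pH drop acidifies the cytosol reversibly", {
  reg <- scenario_registry()
  sc <- reg$`ph_o_6.5`
  cfg <- scenario_config(native_default_config(), sc)
  r <- simulate_free_running(cfg, sc, duration_s = 600, init = "steady")
  base <- r$ph_i[which.min(abs(r$time_s - 60))]
  low <- min(r$ph_i[r$time_s > 60 & r$time_s <= 360])
  final <- r$ph_i[nrow(r)]
  expect_lt(low, base - 0.05)
  expect_equal(final, base, tolerance = 0.02)
})

test_that("scenario plumbing validates events and applies deltas", {
  expect_error(scenario("x", events = scenario_event(10, "teleport")),
               class = "hvchan_domain_error")
  expect_error(scenario("x", events = rbind(scenario_event(10, "zn_on"),
                                            scenario_event(5, "zn_off"))),
               class = "hvchan_domain_error")
  cfg <- native_default_config()
  sc <- scenario("x", config_deltas = list(ph_o = 6.5,
                                           hv = list(tau_act_ms = 107)))
  cfg2 <- scenario_config(cfg, sc)
  expect_equal(cfg2$ph_o, 6.5)
  expect_equal(cfg2$hv$tau_act_ms, 107)
  expect_equal(cfg2$hv$g_max_ns, cfg$hv$g_max_ns)
  # events outside the run are refused
  expect_error(simulate_free_running(cfg, scenario_registry()$zn_block,
                                     duration_s = 100),
               class = "hvchan_domain_error")
})

test_that("simulated clamp families round-trip through the trace analysis", {
  # forward-model a sweep family from the cell model's channel parameters,
  # then recover them with the ephys pipeline (closed loop)
  hv <- hv_channel_params(g_max_ns = 2, tau_act_ms = 220)
  e_h <- ph_equilibrium_potential(8.0, 7.2, temperature_c = 20)$value
  syn <- gen_sweep_family(hv = hv, e_rev_mv = e_h,
                          seal_resistance_gohm = 2, noise_sigma_pa = 0.5,
                          seed = 21)
  fam <- leak_subtract(syn$family)
  # tau from the +60 mV sweep
  s <- which(fam$protocol$sweep_levels == 60)
  t_ms <- protocol_times(fam$protocol)
  fit <- fit_activation_tau(t_ms, fam$traces[, s],
                            fit_start_ms = step_onset(fam$protocol, 1))
  expect_equal(fit$tau_ms, 220, tolerance = 220 * 0.05)
  # conductance from the steady-state IV slope well above activation
  iv <- steady_state_iv(fam, 40)
  top <- iv[iv$voltage_mv >= 20, ]
  g_hat <- unname(coef(stats::lm(current_pa ~ voltage_mv, top))[2])
  expect_equal(g_hat, 2, tolerance = 0.1)
})
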