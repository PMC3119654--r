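# Voltage-clamp trace processing.

# always-open ohmic channel: gate pinned at 1 by a very negative midpoint
ohmic_hv <- function(g_ns) {
  hv_channel_params(g_max_ns = g_ns, delta_mv = -500, tau_act_ms = 1,
                    tau_deact_ms = 1)
}

test_that("leak subtraction removes the commanded-step leak exactly", {
  prot <- iv_protocol(-80, 20, 100, duration_ms = 200)  # single step sweep set
  n <- length(protocol_times(prot))
  fam <- sweep_family(prot, matrix(0, n, n_sweeps(prot)),
                      metadata = list(seal_resistance_gohm = 2))
  out <- leak_subtract(fam)
  t_ms <- protocol_times(prot)
  during <- t_ms >= prot$pre_ms
  # dV = +100 mV sweep (level +20 from -80): 50 pA subtracted during step
  s <- which(prot$sweep_levels == 20)
  expect_equal(unique(out$traces[during, s]), -50)
  expect_equal(unique(out$traces[!during, s]), 0)
  # infinite seal resistance leaves traces untouched
  fam2 <- sweep_family(prot, matrix(5, n, n_sweeps(prot)),
                       metadata = list(seal_resistance_gohm = Inf))
  expect_equal(leak_subtract(fam2)$traces, fam2$traces)
  # no double subtraction
  expect_error(leak_subtract(out), class = "hvchan_domain_error")
})

test_that("leak-subtracted pure-leak family is zero at every voltage", {
  syn <- gen_sweep_family(hv = hv_channel_params(g_max_ns = 0),
                          e_rev_mv = -46.5, seal_resistance_gohm = 1,
                          noise_sigma_pa = 0.5, cap_transients = FALSE,
                          seed = 11)
  iv <- steady_state_iv(leak_subtract(syn$family), 40)
  # mean of ~40 noise samples, sigma 0.5
  expect_true(all(abs(iv$current_pa) < 3 * 0.5 / sqrt(40)))
})

test_that("steady-state IV averages the end-of-step window", {
  prot <- iv_protocol(-20, 20, 20, duration_ms = 1000)
  t_ms <- protocol_times(prot)
  n <- length(t_ms)
  # flat traces at 100 pA
  fam <- sweep_family(prot, matrix(100, n, n_sweeps(prot)),
                      metadata = list(leak_subtracted = TRUE))
  iv <- steady_state_iv(fam, 40)
  expect_equal(iv$current_pa, rep(100, 3))
  expect_equal(iv$voltage_mv, c(-20, 0, 20))
  # saturating exponential: closed-form window mean over [960, 1000) ms
  onset <- step_onset(prot, 1)
  tr <- ifelse(t_ms < onset, 0, 100 * (1 - exp(-(t_ms - onset) / 220)))
  fam2 <- sweep_family(prot, matrix(tr, n, 3),
                       metadata = list(leak_subtracted = TRUE))
  iv2 <- steady_state_iv(fam2, 40)
  expect_equal(iv2$current_pa[1], 98.8, tolerance = 0.01)
  # window must lie inside the step and inside the documented bounds
  expect_error(steady_state_iv(fam, 60), class = "hvchan_domain_error")
  prot_short <- iv_protocol(-20, 20, 20, duration_ms = 30)
  fam3 <- sweep_family(prot_short,
                       matrix(1, length(protocol_times(prot_short)), 3),
                       metadata = list())
  expect_error(steady_state_iv(fam3, 40), class = "hvchan_domain_error")
})

test_that("steady-state IV estimate under noise follows sampling theory", {
  prot <- iv_protocol(0, 0, 10, duration_ms = 1000)
  t_ms <- protocol_times(prot)
  set.seed(99)
  tr <- 100 + rnorm(length(t_ms), 0, 5)
  fam <- sweep_family(prot, matrix(tr, ncol = 1),
                      metadata = list(leak_subtracted = TRUE))
  iv <- steady_state_iv(fam, 40)
  expect_lt(abs(iv$current_pa - 100), 3 * 5 / sqrt(40))
})

test_that("tail regression recovers a known ohmic reversal potential", {
  syn <- gen_tail_family(hv = ohmic_hv(1), e_rev_mv = -30,
                         seal_resistance_gohm = Inf, noise_sigma_pa = 0,
                         cap_transients = FALSE)
  est <- tail_reversal(syn$family)
  expect_equal(est$e_rev_mv, -30, tolerance = 0.1)
  expect_equal(est$slope_conductance_ns, 1, tolerance = 0.02)
  expect_gt(est$r_squared, 0.999)
  expect_true(est$reliable)
})

test_that("tail regression handles degenerate and thin inputs", {
  prot <- tail_protocol(test_levels_mv = seq(-60, 20, 20))
  n <- length(protocol_times(prot))
  zeros <- sweep_family(prot, matrix(0, n, 5),
                        metadata = list(leak_subtracted = TRUE))
  expect_error(tail_reversal(zeros), class = "hvchan_domain_error")
  prot2 <- tail_protocol(test_levels_mv = c(-40, 0))
  thin <- sweep_family(prot2, matrix(1, length(protocol_times(prot2)), 2),
                       metadata = list())
  expect_error(tail_reversal(thin), class = "hvchan_domain_error")
  # family without tail levels
  prot3 <- voltage_protocol(-80, data.frame(level_mv = 40,
                                            duration_ms = 500))
  fam3 <- sweep_family(prot3, matrix(0, length(protocol_times(prot3)), 1),
                       metadata = list())
  expect_error(tail_reversal(fam3), class = "hvchan_domain_error")
})

test_that("tail reversal tracks the H+ gradient for a selective channel", {
  # pH_i 7.5 / pH_o 8.0 at 20 degC: E_H = -29.09 mV
  e_h <- ph_equilibrium_potential(8.0, 7.5, temperature_c = 20)$value
  syn <- gen_tail_family(hv = hv_channel_params(g_max_ns = 2),
                         e_rev_mv = e_h, seal_resistance_gohm = 2,
                         noise_sigma_pa = 0.5, seed = 3)
  est <- tail_reversal(leak_subtract(syn$family))
  expect_equal(est$e_rev_mv, -29.09, tolerance = 2)
})

test_that("tail reversal is invariant to an added-then-subtracted leak", {
  mk <- function(rs, seed) gen_tail_family(
    hv = hv_channel_params(g_max_ns = 2), e_rev_mv = -30,
    seal_resistance_gohm = rs, noise_sigma_pa = 0, cap_transients = FALSE,
    seed = seed)
  clean <- tail_reversal(leak_subtract(mk(Inf, 1)$family,
                                       seal_resistance_gohm = 1e9))
  leaky <- tail_reversal(leak_subtract(mk(1, 1)$family,
                                       seal_resistance_gohm = 1))
  expect_equal(leaky$e_rev_mv, clean$e_rev_mv, tolerance = 1e-6)
})

test_that("activation fitting recovers known time constants", {
  t_ms <- seq(0, 1000, by = 1)
  for (tau in c(220, 22.9)) {
    y <- 5 + 120 * (1 - exp(-t_ms / tau))
    fit <- fit_activation_tau(t_ms, y, fit_start_ms = 0)
    expect_equal(fit$tau_ms, tau, tolerance = tau * 0.01)
    expect_equal(fit$amplitude_pa, 120, tolerance = 1)
    expect_false(fit$flagged)
  }
  # flat trace: amplitude ~ 0, tau unidentifiable
  flat <- fit_activation_tau(t_ms, rep(7, length(t_ms)))
  expect_true(flat$flagged)
  expect_equal(flat$amplitude_pa, 0)
})

test_that("activation fitting tolerates noise at realistic SNR", {
  t_ms <- seq(0, 1000, by = 1)
  set.seed(5)
  y <- 200 * (1 - exp(-t_ms / 220)) + rnorm(length(t_ms), 0, 5)
  fit <- fit_activation_tau(t_ms, y)
  expect_equal(fit$tau_ms, 220, tolerance = 220 * 0.05)
})

test_that("Nernst-slope regression of reversal on pH gradient works", {
  dph <- c(-1.5, -1.0, -0.5, 0)
  # ideal H+ selectivity: e_rev = 58.17*(pH_i - pH_o) = -58.17 * dph
  fit <- nernst_slope(dph, -58.17 * dph)
  expect_equal(fit$slope_mv_per_ph, -58.17, tolerance = 0.01)
  expect_equal(fit$r_squared, 1)
  expect_error(nernst_slope(c(0.5, 0.5), c(-20, -25)),
               class = "hvchan_domain_error")
})

test_that("ideal tail estimates regress to the Nernstian slope", {
  ph_i <- 7.5
  ph_os <- c(6.5, 7.0, 7.5, 8.0)
  e_rev <- vapply(ph_os, function(po) {
    truth <- ph_equilibrium_potential(po, ph_i, temperature_c = 20)$value
    syn <- gen_tail_family(hv = ohmic_hv(1.5), e_rev_mv = truth,
                           seal_resistance_gohm = Inf, noise_sigma_pa = 0,
                           cap_transients = FALSE)
    tail_reversal(syn$family)$e_rev_mv
  }, numeric(1))
  fit <- nernst_slope(ph_os - ph_i, e_rev)
  expect_equal(fit$slope_mv_per_ph, -58.17, tolerance = 0.6)
  # the native-cell measured slope is sub-Nernstian; it is carried as a
  # reference expectation, not recomputed from ideal synthetic data
  expect_gt(abs(fit$slope_mv_per_ph),
            abs(reference_measurements()$nernst_slope_mv_per_ph))
})

test_that("recording QC applies the 15% series-resistance rule", {
  expect_true(qc_recording(list(series_resistance_mohm = c(10, 10.5, 11.2)))$pass)
  bad <- qc_recording(c(10, 12))
  expect_false(bad$pass)
  expect_match(bad$reasons, "20")
  single <- qc_recording(5)
  expect_true(single$pass)
  expect_length(single$warnings, 1)
  expect_error(qc_recording(list()), class = "hvchan_domain_error")
})
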