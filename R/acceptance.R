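# End-to-end acceptance runner: recomputes the package's headline
# quantities from scratch and compares them with their reference values.

#' Run the acceptance computations
#'
#' Recomputes, from scratch, the quantities the package is calibrated and
#' validated against: the activation time constant recovered by the
#' exponential fitter from a noiseless synthetic native-kinetics trace
#' (+50 mV step); the 10 s clamp-step alkalinisations of the default cell
#' model at +70 and +20 mV; the resting potential of the default model at
#' bath pH 8.0; and the percent inhibition of calcification returned by
#' the windowed-regression pipeline on the packaged low-pH and
#' ammonium-pulse synthetic birefringence scenarios.
#'
#' @param seed Integer seed forwarded to every generator (the
#'   computations here are noiseless, so the seed only fixes RNG
#'   plumbing).
#' @param out_dir Optional directory; when given, the report is written
#'   there as `acceptance_report.json`.
#' @return Data frame with columns `id`, `value`, `n`, `expected`,
#'   `tolerance`, `pass`.
#' @export
run_acceptance <- function(seed = 1, out_dir = NULL) {
  results <- list()

  # activation kinetics: noiseless native-preset trace, +50 mV step
  prot <- voltage_protocol(-80,
                           data.frame(level_mv = 50, duration_ms = 1000),
                           sampling_interval_ms = 1)
  hv <- hv_channel_params(g_max_ns = 2,
                          tau_act_ms = kinetics_presets()$native)
  e_h <- ph_equilibrium_potential(8.0, 7.2, temperature_c = 20)$value
  syn <- gen_sweep_family(protocol = prot, hv = hv, e_rev_mv = e_h,
                          seal_resistance_gohm = Inf, noise_sigma_pa = 0,
                          cap_transients = FALSE, seed = seed)
  t_ms <- protocol_times(prot)
  fit <- fit_activation_tau(t_ms, syn$family$traces[, 1],
                            fit_start_ms = step_onset(prot, 1))
  results$t3 <- list(value = fit$tau_ms, n = length(t_ms),
                     expected = 220, tolerance = 220 * 0.02)

  # clamp-step alkalinisation, default cell model
  cfg <- native_default_config()
  clamp_dph <- function(level) {
    pr <- data.frame(level_mv = c(-50, level), duration_s = c(2, 10))
    r <- simulate_voltage_clamp(pr, cfg, record_dt_s = 0.05)
    list(dph = delta_ph(r, 2, 12), n = nrow(r))
  }
  r70 <- clamp_dph(70)
  results$t4 <- list(value = r70$dph, n = r70$n,
                     expected = 0.36, tolerance = 0.05)
  r20 <- clamp_dph(20)
  results$t5 <- list(value = r20$dph, n = r20$n,
                     expected = 0.22, tolerance = 0.04)

  # resting membrane potential at bath pH 8.0
  vr <- resting_potential(cfg)
  results$t7 <- list(value = as.numeric(vr),
                     n = nrow(attr(vr, "roots")),
                     expected = -45.7, tolerance = 1)

  # calcification inhibition, packaged synthetic scenarios (noiseless)
  for (tgt in list(list(id = "t8", scen = "ph6.5", expected = 69.0),
                   list(id = "t9", scen = "nh4cl", expected = 67.0))) {
    syn <- gen_birefringence(tgt$scen, noise_sigma = 0, seed = seed)
    rates <- calcification_rates(syn$series)
    results[[tgt$id]] <- list(
      value = inhibition_percent(rates, treatment_window = 2L),
      n = length(syn$series$time_min),
      expected = tgt$expected, tolerance = 0.1)
  }

  report <- do.call(rbind, lapply(names(results), function(id) {
    r <- results[[id]]
    data.frame(id = id, value = r$value, n = r$n, expected = r$expected,
               tolerance = r$tolerance,
               pass = abs(r$value - r$expected) <= r$tolerance)
  }))
  rownames(report) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report,
                         file.path(out_dir, "acceptance_report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  report
}
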