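# Ground-truth synthetic data generators.  Every generator returns its
# output together with a truth manifest recording the seed and every true
# parameter, and is bit-reproducible from (seed, manifest).

# run code with a locally seeded RNG, restoring global state afterwards
with_local_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Build a truth manifest
#'
#' @param generator Generator name.
#' @param seed Seed used (or `NULL`).
#' @param truth Named list of all true parameters.
#' @return A `truth_manifest`.
#' @export
truth_manifest <- function(generator, seed, truth) {
  structure(list(generator = generator, seed = seed, truth = truth,
                 package_version =
                   as.character(utils::packageVersion("hvchan"))),
            class = "truth_manifest")
}

#' @export
print.truth_manifest <- function(x, ...) {
  cat(sprintf("<truth manifest: %s> seed %s, hvchan %s\n", x$generator,
              if (is.null(x$seed)) "none" else x$seed, x$package_version))
  utils::str(x$truth, give.attr = FALSE, no.list = TRUE, indent.str = "  ")
  invisible(x)
}

# analytic forward model: gated H+ current under an ideal clamp with
# pipette-buffered (fixed) pH_i -- the closed-form solution of the gate
# ODE over piecewise-constant command segments
forward_clamp_current <- function(protocol, sweep, hv, e_rev_mv,
                                  ph_i = NULL, ph_o = NULL,
                                  temperature_c = 20) {
  t_ms <- protocol_times(protocol)
  levels <- protocol$steps$level_mv
  if (!is.na(protocol$varied_step)) {
    levels[protocol$varied_step] <- protocol$sweep_levels[sweep]
  }
  seg_v <- c(protocol$holding_mv, levels)
  seg_on <- c(0, protocol$pre_ms + c(0, cumsum(protocol$steps$duration_ms)))
  seg_on <- seg_on[seq_along(seg_v)]
  seg_off <- c(seg_on[-1], max(t_ms) + protocol$sampling_interval_ms)
  current <- numeric(length(t_ms))
  p_open <- numeric(length(t_ms))
  p0 <- hv_steady_open(seg_v[1], e_rev_mv, hv)
  for (i in seq_along(seg_v)) {
    v <- seg_v[i]
    sel <- t_ms >= seg_on[i] & t_ms < seg_off[i]
    p_inf <- hv_steady_open(v, e_rev_mv, hv)
    tau <- if (p_inf > p0) hv$tau_act_ms else hv$tau_deact_ms
    p_t <- p_inf + (p0 - p_inf) * exp(-(t_ms[sel] - seg_on[i]) / tau)
    p_open[sel] <- p_t
    current[sel] <- hv_current(v, p_t, e_rev_mv, hv,
                               ph_i = ph_i, ph_o = ph_o,
                               temperature_c = temperature_c)
    p0 <- p_inf + (p0 - p_inf) * exp(-(seg_off[i] - seg_on[i]) / tau)
  }
  list(current_pa = current, p_open = p_open)
}

# decaying-exponential capacitance transients at command edges
capacitance_transients <- function(protocol, sweep, t_ms,
                                   amplitude_pa_per_mv, tau_ms = 0.5) {
  v <- command_voltage(protocol, sweep, t_ms)
  out <- numeric(length(t_ms))
  edges <- which(diff(v) != 0)
  for (e in edges) {
    dv <- v[e + 1] - v[e]
    t0 <- t_ms[e + 1]
    sel <- t_ms >= t0
    out[sel] <- out[sel] +
      amplitude_pa_per_mv * dv * exp(-(t_ms[sel] - t0) / tau_ms)
  }
  out
}

#' Generate a synthetic voltage-clamp sweep family
#'
#' Forward-models the gated H+ current (closed-form gate relaxation under
#' an ideal clamp at pipette-buffered pH), adds linear seal leak,
#' optional capacitance transients at step edges, and seeded additive
#' Gaussian noise.
#'
#' @param protocol A [voltage_protocol()] (default: the standard
#'   incrementing family, 1 s steps -80..+60 mV).
#' @param hv An [hv_channel_params()] truth (default 2 nS, native
#'   kinetics).
#' @param e_rev_mv True H+ reversal potential in mV; alternatively give
#'   `inside`/`outside` [solution_composition()]s from which it is
#'   derived with the temperature slope; with neither, the native
#'   pH_o 8.0 / pH_i 7.2 value is used.
#' @param inside,outside Optional solution compositions.
#' @param seal_resistance_gohm Seal (leak) resistance in GOhm; `Inf` = no
#'   leak.
#' @param noise_sigma_pa Additive Gaussian noise SD in pA.
#' @param cap_transients Inject capacitance transients (default `TRUE`).
#' @param cap_amplitude_pa_per_mv Transient amplitude scale (default 1
#'   pA per mV of step).
#' @param temperature_c Temperature in degrees C (default 20).
#' @param seed Integer seed (`NULL` = leave RNG untouched, only valid
#'   with zero noise).
#' @return List with `family` (a [sweep_family()], not leak-subtracted)
#'   and `manifest` (a [truth_manifest()]).
#' @export
gen_sweep_family <- function(protocol = iv_protocol(-80, 60, 10),
                             hv = hv_channel_params(g_max_ns = 2),
                             e_rev_mv = NULL, inside = NULL, outside = NULL,
                             seal_resistance_gohm = 2,
                             noise_sigma_pa = 1, cap_transients = TRUE,
                             cap_amplitude_pa_per_mv = 1,
                             temperature_c = 20, seed = 1) {
  if (is.null(e_rev_mv)) {
    if (is.null(inside) || is.null(outside)) {
      # native condition: pH_o 8.0 / pH_i 7.2 at the given temperature
      e_rev_mv <- ph_equilibrium_potential(
        8.0, 7.2, temperature_c = temperature_c)$value
    } else {
      e_rev_mv <- ph_equilibrium_potential(
        outside$pH, inside$pH, temperature_c = temperature_c)$value
    }
  }
  t_ms <- protocol_times(protocol)
  ns <- n_sweeps(protocol)
  traces <- matrix(0, nrow = length(t_ms), ncol = ns)
  for (s in seq_len(ns)) {
    fwd <- forward_clamp_current(protocol, s, hv, e_rev_mv,
                                 temperature_c = temperature_c)
    tr <- fwd$current_pa
    if (is.finite(seal_resistance_gohm)) {
      dv <- command_voltage(protocol, s, t_ms) - protocol$holding_mv
      tr <- tr + dv / seal_resistance_gohm
    }
    if (cap_transients) {
      tr <- tr + capacitance_transients(protocol, s, t_ms,
                                        cap_amplitude_pa_per_mv)
    }
    traces[, s] <- tr
  }
  if (noise_sigma_pa > 0) {
    traces <- traces + with_local_seed(seed, {
      matrix(stats::rnorm(length(traces), 0, noise_sigma_pa), nrow(traces))
    })
  }
  fam <- sweep_family(
    protocol, traces,
    metadata = list(seal_resistance_gohm = seal_resistance_gohm,
                    series_resistance_mohm = c(10, 10.4, 10.8),
                    capacitance_pf = 3, temperature_c = temperature_c,
                    solution_inside = if (is.null(inside)) "" else inside$label,
                    solution_outside = if (is.null(outside)) "" else
                      outside$label,
                    leak_subtracted = FALSE))
  man <- truth_manifest(
    "gen_sweep_family", seed,
    list(hv = unclass(hv), e_rev_mv = e_rev_mv,
         seal_resistance_gohm = seal_resistance_gohm,
         noise_sigma_pa = noise_sigma_pa,
         cap_transients = cap_transients,
         cap_amplitude_pa_per_mv = cap_amplitude_pa_per_mv,
         temperature_c = temperature_c,
         protocol = list(holding_mv = protocol$holding_mv,
                         steps = protocol$steps,
                         sweep_levels = protocol$sweep_levels,
                         sampling_interval_ms =
                           protocol$sampling_interval_ms,
                         pre_ms = protocol$pre_ms)))
  list(family = fam, manifest = man)
}

#' Generate a synthetic tail-current family
#'
#' [gen_sweep_family()] on a [tail_protocol()]: an activating prepulse
#' followed by test steps spanning the reversal potential.
#'
#' @param hv,e_rev_mv,inside,outside,seal_resistance_gohm,noise_sigma_pa,cap_transients,temperature_c,seed
#'   As in [gen_sweep_family()].
#' @param prepulse_mv,test_levels_mv Tail protocol shape.
#' @return List with `family` and `manifest`.
#' @export
gen_tail_family <- function(hv = hv_channel_params(g_max_ns = 2),
                            e_rev_mv = NULL, inside = NULL, outside = NULL,
                            prepulse_mv = 40,
                            test_levels_mv = seq(-75, 25, by = 10),
                            seal_resistance_gohm = 2, noise_sigma_pa = 1,
                            cap_transients = TRUE, temperature_c = 20,
                            seed = 1) {
  out <- gen_sweep_family(
    protocol = tail_protocol(prepulse_mv = prepulse_mv,
                             test_levels_mv = test_levels_mv),
    hv = hv, e_rev_mv = e_rev_mv, inside = inside, outside = outside,
    seal_resistance_gohm = seal_resistance_gohm,
    noise_sigma_pa = noise_sigma_pa, cap_transients = cap_transients,
    temperature_c = temperature_c, seed = seed)
  out$manifest$generator <- "gen_tail_family"
  out
}

#' Generate a synthetic BCECF ratio trace
#'
#' Maps a pH trajectory through the inverse calibration and applies
#' multiplicative Gaussian noise to the fluorescence channels.
#'
#' @param ph Either a numeric pH series or a `simulation_result` (its
#'   `ph_i` column is used).
#' @param time_s Times in s (taken from the simulation result when one is
#'   given).
#' @param cal A [calibrate_two_point()] calibration.
#' @param noise_fraction Multiplicative noise SD as a fraction of signal
#'   (applied independently to F488 and F458).
#' @param f458_au Mean reference-channel intensity (default 1000 a.u.).
#' @param seed Integer seed.
#' @return List with `trace` (a [ratio_trace()]) and `manifest`.
#' @export
gen_ratio_trace <- function(ph, time_s = NULL,
                            cal = calibrate_two_point(2.0, 1.2),
                            noise_fraction = 0.01, f458_au = 1000,
                            seed = 1) {
  if (inherits(ph, "simulation_result")) {
    time_s <- ph$time_s
    ph <- ph$ph_i
  }
  if (is.null(time_s)) time_s <- seq_along(ph) - 1
  stopifnot(all(is.finite(ph)))
  ratio_true <- ph_to_ratio_value(cal, ph)
  n <- length(ph)
  noise <- with_local_seed(seed, {
    matrix(stats::rnorm(2 * n, 0, noise_fraction), ncol = 2)
  })
  f458 <- f458_au * (1 + if (noise_fraction > 0) noise[, 1] else 0)
  f488 <- ratio_true * f458_au * (1 + if (noise_fraction > 0) noise[, 2] else 0)
  tr <- ratio_trace(time_s, f488, f458)
  man <- truth_manifest(
    "gen_ratio_trace", seed,
    list(ph = ph, r75 = cal$r75, r65 = cal$r65,
         noise_fraction = noise_fraction, f458_au = f458_au))
  list(trace = tr, manifest = man)
}

#' Generate a synthetic birefringence (calcification) series
#'
#' Piecewise-linear cross-polarised intensity over the standard windows
#' (0--150, 150--300, 300--600 min) with scenario-specific true slope
#' ratios, plus additive Gaussian noise.  Scenario truths: `control`
#' keeps the initial rate in every window; `ph6.5` drops the treatment
#' window to 31% of the initial rate with partial (80%) third-window
#' recovery (the post-treatment lag); `nh4cl` drops it to 33% with 85%
#' recovery.
#'
#' @param scenario `"control"`, `"ph6.5"`, or `"nh4cl"`.
#' @param noise_sigma Additive intensity noise SD in a.u.
#' @param frame_interval_min Sampling interval (default 3 min, the 20
#'   frames/h rate).
#' @param initial_slope_au_min First-window true slope (default 10).
#' @param baseline_au Intensity at t = 0 (default 100).
#' @param seed Integer seed.
#' @return List with `series` (a [birefringence_series()]) and
#'   `manifest` (truth includes per-window slopes and the true
#'   inhibition percentage).
#' @export
gen_birefringence <- function(scenario = c("control", "ph6.5", "nh4cl"),
                              noise_sigma = 0, frame_interval_min = 3,
                              initial_slope_au_min = 10, baseline_au = 100,
                              seed = 1) {
  scenario <- match.arg(scenario)
  rel <- switch(scenario,
                control = c(1, 1, 1),
                `ph6.5` = c(1, 0.31, 0.80),
                nh4cl = c(1, 0.33, 0.85))
  slopes <- initial_slope_au_min * rel
  edges <- c(0, 150, 300, 600)
  time_min <- seq(0, 600, by = frame_interval_min)
  base_at <- cumsum(c(baseline_au, slopes * diff(edges)))
  idx <- findInterval(time_min, edges, rightmost.closed = TRUE)
  intensity <- base_at[idx] + slopes[idx] * (time_min - edges[idx])
  if (noise_sigma > 0) {
    intensity <- intensity + with_local_seed(seed, {
      stats::rnorm(length(intensity), 0, noise_sigma)
    })
  }
  ser <- birefringence_series(time_min, intensity,
                              windows = list(c(0, 150), c(150, 300),
                                             c(300, 600)))
  man <- truth_manifest(
    "gen_birefringence", seed,
    list(scenario = scenario, slopes_au_min = slopes,
         normalized_rates = rel,
         inhibition_percent = 100 * (1 - rel[2]),
         noise_sigma = noise_sigma,
         frame_interval_min = frame_interval_min,
         baseline_au = baseline_au))
  list(series = ser, manifest = man)
}
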