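# Deterministic simulation of the cell model: ideal voltage clamp and
# free-running membrane potential, with scenario events and per-pathway
# H+ budgets.

# pack a cell_config (+ instantaneous block/load state) for the C++ core
pack_pars <- function(config, zn = FALSE, gd = FALSE, extra_acid_mol_s = 0,
                      j_calc_override = NULL) {
  hv <- config$hv; cl <- config$cl
  g_gated <- hv$g_max_ns
  if (gd) g_gated <- 0
  if (zn) g_gated <- g_gated * (1 - hv$zn_block_fraction)
  g_cl <- cl$g_max_ns * if (zn) 1 - cl$zn_sensitivity else 1
  j_calc <- if (is.null(j_calc_override)) config$j_calc_mol_s else
    j_calc_override
  list(slope_mv = nernst_slope_mv(config$temperature_c),
       ph_o = config$ph_o,
       delta_mv = hv$delta_mv, slope_k_mv = hv$slope_k_mv,
       tau_act_s = hv$tau_act_ms / 1000,
       tau_deact_s = hv$tau_deact_ms / 1000,
       g_gated_ns = g_gated, ghk_gated = as.integer(hv$ghk_gated),
       p_bg_pl_s = hv$background_permeability_pl_s,
       g_cl_ns = g_cl, e_cl_mv = cl$e_cl_mv,
       v_half_cl_mv = cl$v_half_mv, k_cl_mv = cl$slope_k_mv,
       g_leak_ns = config$g_leak_ns, e_leak_mv = config$e_leak_mv,
       c_m_pf = config$c_m_pf, v_cyt_l = config$v_cyt_l,
       beta = config$beta, j_calc_mol_s = j_calc + extra_acid_mol_s,
       k_sec_per_s = config$k_sec_per_s, ph_set = config$ph_set)
}

# fixed integration step (s): min(tau_act, tau_deact, membrane tau)/20,
# capped at 0.5 ms.  For GHK (permeability) pathways the equivalent slope
# conductance near the operating point is P * F * [H+]_i / (RT/F).
integration_dt_s <- function(config) {
  ghk_equiv_ns <- function(perm_pl_s) {
    perm_pl_s * FARADAY * 10^(-config$ph_i) /
      rt_over_f_mv(config$temperature_c)
  }
  g_hv <- if (config$hv$ghk_gated) ghk_equiv_ns(config$hv$g_max_ns) else
    config$hv$g_max_ns
  g_bg <- ghk_equiv_ns(config$hv$background_permeability_pl_s)
  g_tot <- g_hv + g_bg + config$cl$g_max_ns + config$g_leak_ns
  tau_m_ms <- if (g_tot > 0) config$c_m_pf / g_tot else Inf
  dt_ms <- min(config$hv$tau_act_ms, config$hv$tau_deact_ms, tau_m_ms) / 20
  min(max(dt_ms, 1e-3), 0.5) / 1000
}

segment_to_df <- function(m) {
  df <- as.data.frame(m)
  names(df) <- c("time_s", "v_m_mv", "p_open", "ph_i", "i_h_gated_pa",
                 "i_h_bg_pa", "i_cl_pa", "i_leak_pa", "cum_channel_mol",
                 "cum_background_mol", "cum_calcification_mol",
                 "cum_secondary_mol")
  df
}

run_segments <- function(segments, config, state0, dt_s, record_dt_s) {
  save_every <- max(1L, round(record_dt_s / dt_s))
  rtf <- rt_over_f_mv(config$temperature_c)
  out <- vector("list", length(segments))
  state <- state0
  first <- TRUE
  for (i in seq_along(segments)) {
    seg <- segments[[i]]
    n_steps <- max(1L, round(seg$duration_s / dt_s))
    if (!is.null(seg$v_mv)) state[1] <- seg$v_mv
    m <- .rk4_segment(state, seg$pars, rtf, seg$t0, dt_s, n_steps,
                      save_every, !is.null(seg$v_mv), first)
    out[[i]] <- segment_to_df(m)
    state <- attr(m, "final_state")
    first <- FALSE
  }
  res <- do.call(rbind, out)
  res$i_h_pa <- res$i_h_gated_pa + res$i_h_bg_pa
  attr(res, "final_state") <- state
  res
}

finish_result <- function(res, config, dt_s, mode) {
  structure(res, config = config, dt_s = dt_s, mode = mode,
            class = c("simulation_result", "data.frame"))
}

#' Simulate an ideal voltage clamp
#'
#' The membrane potential follows the command protocol exactly; the gate
#' relaxes to its steady state with `tau_act`/`tau_deact`, and cytosolic
#' pH follows the buffered H+ balance (outward H+ current alkalinises the
#' cytosol, the calcification load acidifies it, secondary regulation
#' relaxes it toward its set point).  Fixed-step RK4; results are
#' bit-stable across runs.
#'
#' @param protocol A [voltage_protocol()] (times in ms) or a data frame
#'   with columns `level_mv` and `duration_s` for long cell-scale steps.
#' @param config A [cell_config()].
#' @param sweep Sweep index if the protocol has a varied step.
#' @param record_dt_s Output sampling interval in s (default 0.01).
#' @return A `simulation_result` data frame with time, voltage, gate,
#'   pH_i, the per-conductance currents (pA) and the cumulative
#'   per-pathway H+ budgets (mol).
#' @export
simulate_voltage_clamp <- function(protocol, config, sweep = 1L,
                                   record_dt_s = 0.01) {
  if (inherits(protocol, "voltage_protocol")) {
    levels <- protocol$steps$level_mv
    if (!is.na(protocol$varied_step)) {
      levels[protocol$varied_step] <- protocol$sweep_levels[sweep]
    }
    seg_df <- data.frame(
      level_mv = c(protocol$holding_mv, levels),
      duration_s = c(protocol$pre_ms, protocol$steps$duration_ms) / 1000)
  } else {
    stopifnot(is.data.frame(protocol),
              all(c("level_mv", "duration_s") %in% names(protocol)))
    seg_df <- protocol
  }
  dt_s <- integration_dt_s(config)
  pars <- pack_pars(config)
  t0 <- 0
  segments <- lapply(seq_len(nrow(seg_df)), function(i) {
    seg <- list(v_mv = seg_df$level_mv[i], duration_s = seg_df$duration_s[i],
                pars = pars, t0 = t0)
    t0 <<- t0 + seg_df$duration_s[i]
    seg
  })
  e_h0 <- config_e_h(config)
  p0 <- hv_steady_open(seg_df$level_mv[1], e_h0, config$hv)
  state0 <- c(seg_df$level_mv[1], p0, config$ph_i, 0, 0, 0, 0)
  res <- run_segments(segments, config, state0, dt_s, record_dt_s)
  finish_result(res, config, dt_s, "voltage_clamp")
}

#' Simulate the free-running membrane
#'
#' `C_m dV/dt = -(I_H + I_Cl + I_leak)` coupled to the cytosolic pH
#' balance, with scenario events applied at their scheduled times
#' (external pH shifts, Zn2+ or Gd3+ application, Ca2+-free medium,
#' square-pulse acid loads).
#'
#' @param config A [cell_config()].
#' @param scenario Optional [scenario()] whose events to apply (its
#'   config deltas must already be applied -- use [scenario_config()]).
#' @param duration_s Total simulated time in s.
#' @param init `"config"` starts from the resting potential at the
#'   configured initial pH_i; `"steady"` starts from the coupled
#'   voltage/pH steady state (see [steady_state()]).
#' @param record_dt_s Output sampling interval in s (default 0.05).
#' @return A `simulation_result` data frame (see
#'   [simulate_voltage_clamp()]).
#' @export
simulate_free_running <- function(config, scenario = NULL, duration_s,
                                  init = c("config", "steady"),
                                  record_dt_s = 0.05) {
  init <- match.arg(init)
  events <- if (is.null(scenario)) empty_events() else
    expand_events(scenario$events)
  if (nrow(events) && any(events$time_s > duration_s)) {
    domain_error("scenario events fall outside the simulated duration")
  }
  if (init == "steady") {
    ss <- steady_state(config)
    v0 <- ss$v_mv; ph0 <- ss$ph_i
  } else {
    v0 <- as.numeric(resting_potential(config))
    ph0 <- config$ph_i
  }
  # event times partition the run into constant-parameter segments
  times <- sort(unique(c(0, events$time_s, duration_s)))
  state <- list(zn = FALSE, gd = FALSE, extra_acid = 0,
                j_calc_override = NULL, config = config)
  segments <- list()
  for (i in seq_len(length(times) - 1)) {
    now <- times[i]
    for (j in which(events$time_s == now)) {
      state <- apply_event(state, events[j, ])
    }
    segments[[i]] <- list(
      v_mv = NULL, duration_s = times[i + 1] - now, t0 = now,
      pars = pack_pars(state$config, zn = state$zn, gd = state$gd,
                       extra_acid_mol_s = state$extra_acid,
                       j_calc_override = state$j_calc_override))
  }
  dt_s <- integration_dt_s(config)
  e_h0 <- config_e_h(config, ph0)
  p0 <- hv_steady_open(v0, e_h0, config$hv)
  state0 <- c(v0, p0, ph0, 0, 0, 0, 0)
  res <- run_segments(segments, config, state0, dt_s, record_dt_s)
  finish_result(res, config, dt_s, "free_running")
}

#' Coupled voltage/pH steady state
#'
#' Solves for the cytosolic pH at which the net buffered H+ balance is
#' zero with the membrane simultaneously at its zero-current potential,
#' i.e. the operating point of an undisturbed (e.g. calcifying) cell.
#'
#' @param config A [cell_config()].
#' @return List with `v_mv` and `ph_i`.
#' @export
steady_state <- function(config) {
  net_acid <- function(ph) {
    v <- as.numeric(resting_potential(config, ph_i = ph))
    e_h <- config_e_h(config, ph)
    p <- hv_steady_open(v, e_h, config$hv)
    i_h <- hv_current(v, p, e_h, config$hv, ph_i = ph, ph_o = config$ph_o,
                      temperature_c = config$temperature_c)
    i_h * 1e-12 / FARADAY - config$j_calc_mol_s +
      config$k_sec_per_s * (config$ph_set - ph) * config$beta * config$v_cyt_l
  }
  ph <- stats::uniroot(net_acid, c(5.5, 9), tol = 1e-10)$root
  list(v_mv = as.numeric(resting_potential(config, ph_i = ph)), ph_i = ph)
}

#' Per-pathway proton budget of a simulation
#'
#' Conservation audit: the buffered pH change `beta * V_cyt * dpH_i` must
#' equal the summed cumulative pathway contributions (gated channel,
#' background permeability, calcification source, secondary regulation),
#' all in mol H+ removed from the cytosol.  The relative closure residual
#' verifies the integrator.
#'
#' @param result A `simulation_result`.
#' @return A `proton_budget` list with `terms_mol` (named), `buffer_mol`,
#'   `residual_mol` and `relative_residual`.
#' @export
proton_budget <- function(result) {
  stopifnot(inherits(result, "simulation_result"))
  config <- attr(result, "config")
  last <- result[nrow(result), ]
  terms <- c(channel = last$cum_channel_mol,
             background = last$cum_background_mol,
             calcification = last$cum_calcification_mol,
             secondary = last$cum_secondary_mol)
  buffer <- config$beta * config$v_cyt_l * (last$ph_i - result$ph_i[1])
  residual <- buffer - sum(terms)
  denom <- max(abs(c(terms, buffer)), 1e-300)
  structure(list(terms_mol = terms, buffer_mol = buffer,
                 residual_mol = residual,
                 relative_residual = abs(residual) / denom),
            class = "proton_budget")
}

#' @export
print.proton_budget <- function(x, ...) {
  cat("<proton budget> (mol H+ removed from cytosol)\n")
  for (nm in names(x$terms_mol)) {
    cat(sprintf("  %-14s %+.4e\n", nm, x$terms_mol[[nm]]))
  }
  cat(sprintf("  %-14s %+.4e\n", "buffer change", x$buffer_mol))
  cat(sprintf("  closure residual %.2e (relative %.2e)\n",
              x$residual_mol, x$relative_residual))
  invisible(x)
}

#' Net pH change over a simulated interval
#'
#' @param result A `simulation_result`.
#' @param from_s,to_s Interval bounds in s (defaults: whole run).  Values
#'   at the nearest recorded samples are used.
#' @return `ph_i(to) - ph_i(from)`.
#' @export
delta_ph <- function(result, from_s = NULL, to_s = NULL) {
  t <- result$time_s
  i0 <- if (is.null(from_s)) 1L else which.min(abs(t - from_s))
  i1 <- if (is.null(to_s)) length(t) else which.min(abs(t - to_s))
  result$ph_i[i1] - result$ph_i[i0]
}
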