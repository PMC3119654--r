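# The coupled membrane-potential / cytosolic-pH cell model: a
# depolarisation-activated H+ conductance whose gating tracks the H+
# electrochemical gradient, a hyperpolarisation-activated inward Cl-
# rectifier, an ohmic leak, cytosolic buffering, a calcification acid
# load, and first-order secondary pH regulation.

#' H+ channel parameters
#'
#' @param g_max_ns Maximal gated conductance in nS (>= 0).  When
#'   `ghk_gated = TRUE` this is instead a permeability in pL/s and the
#'   open-channel current follows the GHK flux equation.
#' @param delta_mv Activation midpoint offset above E_H in mV
#'   (`V_half = E_H + delta_mv`): the channel opens at voltages positive
#'   of the H+ equilibrium potential and its activation curve shifts
#'   one-to-one with E_H.
#' @param slope_k_mv Boltzmann slope factor in mV (> 0).
#' @param tau_act_ms,tau_deact_ms Activation/deactivation time constants
#'   in ms (> 0); see [kinetics_presets()] for the native and
#'   heterologous values.
#' @param zn_block_fraction Fraction of the gated conductance blocked
#'   while Zn2+ is applied (0--1; wild-type 0.84, the Zn-site mutants
#'   H197A/H203A 0.27/0.28).
#' @param background_permeability_pl_s Background H+ permeability in pL/s.
#'   This ungated pathway carries GHK (flux-equation) current, so inward
#'   H+ current is limited by the nanomolar external free H+: external
#'   acidification depolarises the resting cell and acidifies the
#'   cytosol, while strong hyperpolarisation at sea-water pH moves almost
#'   no H+.
#' @param ghk_gated Use the GHK flux form for the open gated channel
#'   (default `FALSE`: ohmic in `v - E_H`).
#' @return An `hv_channel_params` list.
#' @export
hv_channel_params <- function(g_max_ns, delta_mv = 15, slope_k_mv = 8,
                              tau_act_ms = 220, tau_deact_ms = 40,
                              zn_block_fraction = 0.84,
                              background_permeability_pl_s = 0,
                              ghk_gated = FALSE) {
  stopifnot(g_max_ns >= 0, slope_k_mv > 0, tau_act_ms > 0, tau_deact_ms > 0,
            zn_block_fraction >= 0, zn_block_fraction <= 1,
            background_permeability_pl_s >= 0)
  structure(list(g_max_ns = g_max_ns, delta_mv = delta_mv,
                 slope_k_mv = slope_k_mv, tau_act_ms = tau_act_ms,
                 tau_deact_ms = tau_deact_ms,
                 zn_block_fraction = zn_block_fraction,
                 background_permeability_pl_s = background_permeability_pl_s,
                 ghk_gated = ghk_gated),
            class = "hv_channel_params")
}

#' Cl- channel parameters (inward rectifier)
#'
#' Hyperpolarisation-activated anion conductance:
#' `I = g_max * s_inf(v) * (v - e_cl)` with
#' `s_inf = 1 / (1 + exp((v - v_half)/k))`, so activation grows as the
#' membrane hyperpolarises.
#'
#' @param g_max_ns Maximal conductance in nS (>= 0).
#' @param e_cl_mv Cl- reversal potential in mV.
#' @param v_half_mv Half-activation voltage in mV.
#' @param slope_k_mv Boltzmann slope in mV (> 0).
#' @param zn_sensitivity Fraction of the conductance lost under Zn2+
#'   (0--1).
#' @return A `cl_channel_params` list.
#' @export
cl_channel_params <- function(g_max_ns, e_cl_mv = -20, v_half_mv = -60,
                              slope_k_mv = 12, zn_sensitivity = 0.3) {
  stopifnot(g_max_ns >= 0, slope_k_mv > 0,
            zn_sensitivity >= 0, zn_sensitivity <= 1)
  structure(list(g_max_ns = g_max_ns, e_cl_mv = e_cl_mv,
                 v_half_mv = v_half_mv, slope_k_mv = slope_k_mv,
                 zn_sensitivity = zn_sensitivity),
            class = "cl_channel_params")
}

#' Whole-cell model configuration
#'
#' @param c_m_pf Membrane capacitance in pF (> 0).
#' @param v_cyt_l Cytosolic volume in L (> 0).
#' @param beta Cytosolic buffering capacity in mol L^-1 pH^-1 (> 0).
#' @param j_calc_mol_s Calcification H+ production in mol s^-1 (>= 0).
#' @param k_sec_per_s First-order rate of secondary pH regulation toward
#'   `ph_set`, in s^-1 (>= 0); its reciprocal sets the post-pulse pH
#'   recovery time.
#' @param ph_set Set point of the secondary regulation.
#' @param g_leak_ns,e_leak_mv Ohmic leak conductance (nS) and reversal
#'   (mV).
#' @param ph_o External pH.
#' @param ph_i Initial cytosolic pH.
#' @param temperature_c Temperature in degrees Celsius.
#' @param hv An [hv_channel_params()].
#' @param cl A [cl_channel_params()].
#' @return A `cell_config` list.
#' @export
cell_config <- function(c_m_pf, v_cyt_l, beta, j_calc_mol_s, k_sec_per_s,
                        ph_set, g_leak_ns, e_leak_mv, ph_o, ph_i,
                        temperature_c = 20, hv, cl) {
  stopifnot(c_m_pf > 0, v_cyt_l > 0, beta > 0, j_calc_mol_s >= 0,
            k_sec_per_s >= 0, g_leak_ns >= 0,
            inherits(hv, "hv_channel_params"),
            inherits(cl, "cl_channel_params"))
  structure(list(c_m_pf = c_m_pf, v_cyt_l = v_cyt_l, beta = beta,
                 j_calc_mol_s = j_calc_mol_s, k_sec_per_s = k_sec_per_s,
                 ph_set = ph_set, g_leak_ns = g_leak_ns,
                 e_leak_mv = e_leak_mv, ph_o = ph_o, ph_i = ph_i,
                 temperature_c = temperature_c, hv = hv, cl = cl),
            class = "cell_config")
}

#' @export
print.cell_config <- function(x, ...) {
  cat(sprintf(
    "<cell config> pH_o %.2f, pH_i %.2f, %.0f degC, C_m %.3g pF\n",
    x$ph_o, x$ph_i, x$temperature_c, x$c_m_pf))
  cat(sprintf("  Hv: g %.3g nS, delta %+.3g mV, k %.3g mV, tau %g/%g ms, bg %.3g pL/s\n",
              x$hv$g_max_ns, x$hv$delta_mv, x$hv$slope_k_mv,
              x$hv$tau_act_ms, x$hv$tau_deact_ms,
              x$hv$background_permeability_pl_s))
  cat(sprintf("  Cl: g %.3g nS, E_Cl %g mV; leak %.3g nS -> %g mV\n",
              x$cl$g_max_ns, x$cl$e_cl_mv, x$g_leak_ns, x$e_leak_mv))
  cat(sprintf("  cytosol: V %.3g L, beta %.3g mol/L/pH, J_calc %.3g mol/s, k_sec %.3g /s -> pH %g\n",
              x$v_cyt_l, x$beta, x$j_calc_mol_s, x$k_sec_per_s, x$ph_set))
  invisible(x)
}

#' H+ equilibrium potential of a configuration
#'
#' `E_H = slope * (pH_i - pH_o)` with the slope from the configuration's
#' temperature.
#'
#' @param config A [cell_config()].
#' @param ph_i Cytosolic pH (default: the configuration's).
#' @return E_H in mV.
#' @export
config_e_h <- function(config, ph_i = config$ph_i) {
  nernst_slope_mv(config$temperature_c) * (ph_i - config$ph_o)
}

#' Steady-state open probability of the H+ channel
#'
#' Boltzmann activation tied to the H+ equilibrium potential:
#' `p_inf = 1 / (1 + exp(-(v - (e_h + delta))/k))`.  Strictly increasing
#' in `v`; shifts one-to-one with `e_h`, so lowering pH_o by one unit
#' moves the half-activation voltage positive by the Nernst slope.
#'
#' @param v_mv Membrane potential(s) in mV.
#' @param e_h_mv H+ equilibrium potential in mV.
#' @param params An [hv_channel_params()].
#' @return Open probability in (0, 1).
#' @export
hv_steady_open <- function(v_mv, e_h_mv, params) {
  1 / (1 + exp(-(v_mv - (e_h_mv + params$delta_mv)) / params$slope_k_mv))
}

#' H+ channel current
#'
#' Gated current `(1 - zn_block) * g_max * p * (v - e_h)` (ohmic open
#' channel; GHK form if the parameter set enables it) plus the ungated
#' background GHK component.  Outward positive.
#'
#' @param v_mv Membrane potential(s) in mV.
#' @param p Open probability (0--1).
#' @param e_h_mv H+ equilibrium potential in mV (used for the ohmic
#'   driving force).
#' @param params An [hv_channel_params()].
#' @param zn_applied Is Zn2+ present (applies `zn_block_fraction`)?
#' @param ph_i,ph_o,temperature_c Needed for the GHK background (and GHK
#'   gated) component; if `ph_i` is `NULL` the background is omitted.
#' @return Current in pA.
#' @export
hv_current <- function(v_mv, p, e_h_mv, params, zn_applied = FALSE,
                       ph_i = NULL, ph_o = NULL, temperature_c = 20) {
  stopifnot(all(p >= 0 & p <= 1))
  block <- if (zn_applied) params$zn_block_fraction else 0
  if (params$ghk_gated) {
    if (is.null(ph_i)) domain_error("GHK-gated current needs ph_i and ph_o")
    gated <- (1 - block) * params$g_max_ns * p *
      ghk_h_factor(v_mv, ph_i, ph_o, temperature_c)
  } else {
    gated <- (1 - block) * params$g_max_ns * p * (v_mv - e_h_mv)
  }
  bg <- 0
  if (!is.null(ph_i) && params$background_permeability_pl_s > 0) {
    bg <- params$background_permeability_pl_s *
      ghk_h_factor(v_mv, ph_i, ph_o, temperature_c)
  }
  gated + bg
}

#' GHK H+ flux factor
#'
#' `F * u * (c_i - c_o * exp(-u)) / (1 - exp(-u))` with `u = vF/RT` and
#' concentrations in mol/L derived from the two pH values.  Multiplied by
#' a permeability in pL/s it gives a current in pA (outward positive).
#'
#' @param v_mv Membrane potential(s), mV.
#' @param ph_i,ph_o Inside and outside pH.
#' @param temperature_c Temperature in degrees Celsius.
#' @return Flux factor in pA per (pL/s).
#' @export
ghk_h_factor <- function(v_mv, ph_i, ph_o, temperature_c = 20) {
  rtf <- rt_over_f_mv(temperature_c)
  u <- v_mv / rtf
  ci <- 10^(-ph_i); co <- 10^(-ph_o)
  small <- abs(u) < 1e-6
  out <- numeric(length(u))
  out[small] <- FARADAY * (ci - co)
  em <- exp(-u[!small])
  out[!small] <- FARADAY * u[!small] * (ci - co * em) / (1 - em)
  out
}

#' Cl- inward-rectifier current
#'
#' `I = g_max * s_inf(v) * (v - e_cl)` with
#' `s_inf = 1/(1 + exp((v - v_half)/k))`: the conductance activates with
#' hyperpolarisation, so there is essentially no Cl--mediated current at
#' depolarised potentials.
#'
#' @param v_mv Membrane potential(s) in mV.
#' @param params A [cl_channel_params()].
#' @param zn_applied Is Zn2+ present (scales `g_max` by
#'   `1 - zn_sensitivity`)?
#' @return Current in pA (outward positive).
#' @export
cl_current <- function(v_mv, params, zn_applied = FALSE) {
  scale <- if (zn_applied) 1 - params$zn_sensitivity else 1
  s_inf <- 1 / (1 + exp((v_mv - params$v_half_mv) / params$slope_k_mv))
  scale * params$g_max_ns * s_inf * (v_mv - params$e_cl_mv)
}

# total steady-state membrane current at fixed pH_i (gates at steady state)
total_steady_current <- function(v_mv, config, ph_i = config$ph_i,
                                 zn_applied = FALSE, gd_applied = FALSE) {
  e_h <- config_e_h(config, ph_i)
  p <- hv_steady_open(v_mv, e_h, config$hv)
  hv <- config$hv
  if (gd_applied) hv$g_max_ns <- 0
  i_h <- hv_current(v_mv, p, e_h, hv, zn_applied = zn_applied,
                    ph_i = ph_i, ph_o = config$ph_o,
                    temperature_c = config$temperature_c)
  i_cl <- cl_current(v_mv, config$cl, zn_applied = zn_applied)
  i_leak <- config$g_leak_ns * (v_mv - config$e_leak_mv)
  i_h + i_cl + i_leak
}

#' Resting membrane potential
#'
#' Zero of the total steady-state membrane current
#' `I_H + I_Cl + I_leak = 0` (all gates at their voltage steady state,
#' pH_i fixed at the configuration value), located by scanning
#' [-120, +80] mV for sign changes and polishing each root with
#' [stats::uniroot()].  A root is stable when the total current-voltage
#' slope there is positive.  The most negative stable root is returned;
#' all roots are attached as an attribute.
#'
#' @param config A [cell_config()].
#' @param ph_i Cytosolic pH at which to evaluate (default: config's).
#' @param zn_applied,gd_applied Evaluate under Zn2+ / Gd3+ block.
#' @return Resting potential in mV with attribute `roots` (data frame of
#'   `v_mv`, `stable`).
#' @export
resting_potential <- function(config, ph_i = config$ph_i,
                              zn_applied = FALSE, gd_applied = FALSE) {
  f <- function(v) total_steady_current(v, config, ph_i,
                                        zn_applied, gd_applied)
  grid <- seq(-120, 80, by = 0.5)
  fv <- vapply(grid, f, numeric(1))
  idx <- which(fv[-length(fv)] * fv[-1] <= 0 & fv[-length(fv)] != 0)
  roots <- vapply(idx, function(i) {
    stats::uniroot(f, c(grid[i], grid[i + 1]), tol = 1e-10)$root
  }, numeric(1))
  if (length(roots) == 0L) {
    if (any(fv == 0)) roots <- grid[fv == 0] else
      domain_error("no zero crossing of total current in [-120, 80] mV")
  }
  roots <- sort(unique(roots))
  eps <- 1e-4
  stable <- vapply(roots, function(r) f(r + eps) - f(r - eps) > 0, logical(1))
  if (!any(stable)) {
    domain_error("no stable zero-current potential in [-120, 80] mV")
  }
  structure(min(roots[stable]),
            roots = data.frame(v_mv = roots, stable = stable))
}
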