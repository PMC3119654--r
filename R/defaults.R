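# Default model configurations.
#
# The native patched-cell configuration is calibrated so that one
# parameter set simultaneously reproduces the four measured anchors:
# resting potential -45.7 mV at pH_o 8.0 and -29.0 mV at pH_o 6.5, and
# 10 s clamp-step alkalinisations of +0.22 (to +20 mV) and +0.36 pH
# units (to +70 mV) from a -50 mV holding potential.  The calibration
# procedure (two nested 1-D/2-D root solves) and the sensitivity of the
# anchors to delta/k are described in the methods vignette.  The
# `calcifying` deltas encode the intact, actively calcifying cell used
# for the Zn2+ / Ca2+-free experiments: a substantial calcification acid
# load and slower secondary regulation, so that at its operating point
# the gated channel carries most of the calcification H+ export.

# frozen calibration constants (see vignette "Model calibration")
.cal <- new.env(parent = emptyenv())
.cal$g_max_ns <- 0.61421      # gated H+ conductance, clamp-anchor fit
.cal$delta_mv <- 15            # activation midpoint offset above E_H
.cal$slope_k_mv <- 8           # Boltzmann slope
.cal$k_sec_per_s <- 0.017      # secondary regulation (recovery 30-60 s)
.cal$beta <- 0.034             # mol/L/pH, clamp-anchor scale
.cal$g_cl_ns <- 0.419247       # rest anchor at pH_o 8.0
.cal$p_bg_pl_s <- 79.7809      # rest anchor at pH_o 6.5
.cal$j_calc_native <- 8.2992e-19 # mol/s, balances the patched cell at rest
.cal$j_calc_calcifying <- 2.17973e-16 # mol/s, Zn-response scale
.cal$k_sec_calcifying <- 0.017 # s^-1 (recovery ~60 s)
.cal$nh4cl_load <- 1.54386e-16 # mol/s square-pulse acid load

#' Default native-cell model configuration
#'
#' The calibrated whole-cell configuration of the patched coccolithophore
#' protoplast: pH_o 8.0, initial pH_i 7.2, 20 degrees C, native
#' activation kinetics (tau 220 ms).  Any field can be overridden.
#'
#' @param ... Overrides: any [cell_config()] argument, or `g_max_ns`,
#'   `delta_mv`, `slope_k_mv`, `tau_act_ms`, `background_permeability_pl_s`,
#'   `g_cl_ns` as shortcuts into the channel parameter blocks.
#' @return A [cell_config()].
#' @examples
#' cfg <- native_default_config()
#' resting_potential(cfg)
#' @export
native_default_config <- function(...) {
  ov <- list(...)
  take <- function(nm, default) if (!is.null(ov[[nm]])) ov[[nm]] else default
  hv <- hv_channel_params(
    g_max_ns = take("g_max_ns", .cal$g_max_ns),
    delta_mv = take("delta_mv", .cal$delta_mv),
    slope_k_mv = take("slope_k_mv", .cal$slope_k_mv),
    tau_act_ms = take("tau_act_ms", kinetics_presets()$native),
    tau_deact_ms = take("tau_deact_ms", 40),
    zn_block_fraction = take("zn_block_fraction", 0.84),
    background_permeability_pl_s =
      take("background_permeability_pl_s", .cal$p_bg_pl_s),
    ghk_gated = take("ghk_gated", FALSE))
  cl <- cl_channel_params(
    g_max_ns = take("g_cl_ns", .cal$g_cl_ns),
    e_cl_mv = take("e_cl_mv", -20),
    v_half_mv = take("v_half_cl_mv", -60),
    slope_k_mv = take("k_cl_mv", 12),
    zn_sensitivity = take("cl_zn_sensitivity", 0.3))
  cell_config(
    c_m_pf = take("c_m_pf", 3),
    v_cyt_l = take("v_cyt_l", 5e-13),
    beta = take("beta", .cal$beta),
    j_calc_mol_s = take("j_calc_mol_s", .cal$j_calc_native),
    k_sec_per_s = take("k_sec_per_s", .cal$k_sec_per_s),
    ph_set = take("ph_set", 7.2),
    g_leak_ns = take("g_leak_ns", 0.1),
    e_leak_mv = take("e_leak_mv", -70),
    ph_o = take("ph_o", 8.0),
    ph_i = take("ph_i", 7.2),
    temperature_c = take("temperature_c", 20),
    hv = hv, cl = cl)
}

# configuration deltas for the intact, actively calcifying cell
calcifying_deltas <- function() {
  list(j_calc_mol_s = .cal$j_calc_calcifying,
       k_sec_per_s = .cal$k_sec_calcifying)
}

# acid load of the packaged ammonium-pulse scenario (mol H+/s)
nh4cl_acid_load_mol_s <- function() .cal$nh4cl_load

#' Measured reference values
#'
#' The measured quantities the model and pipelines are validated against,
#' kept in one place: resting potentials, clamp-step pH responses, the
#' native (sub-Nernstian) reversal-vs-pH-gradient slope, activation time
#' constants, Zn2+ responses, block fractions, and calcification
#' inhibition percentages.  These are reference expectations, not values
#' the package recomputes.
#'
#' @return Nested named list.
#' @export
reference_measurements <- function() {
  list(
    resting_potential_mv = c(ph_o_8.0 = -45.7, ph_o_6.5 = -29.0),
    clamp_dph = c(step_20mv = 0.22, step_70mv = 0.36),
    nernst_slope_mv_per_ph = -43,
    tau_act_ms = c(native = 220, ehhv1 = 107, cphv1 = 22.9),
    zn_dph = -0.13,
    ca_free_zn_dph = -0.02,
    zn_block_fraction = c(wild_type = 0.84, H197A = 0.27, H203A = 0.28),
    inhibition_percent = c(ph6.5 = 69.0, nh4cl = 67.0)
  )
}
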