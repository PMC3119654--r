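# Independent oracles used across the suite.  These deliberately avoid
# the package's own code paths.

# GHK reversal potential written out directly (monovalent; concentrations
# in mM, H+ from pH), independent of ghk_reversal()
oracle_ghk_mv <- function(p_h, p_k, k_in_mM, k_out_mM, ph_in, ph_out,
                          temperature_c = 20) {
  rtf <- 8.31446262 * (temperature_c + 273.15) / 96485.33212 * 1000
  h_out <- 10^(-ph_out) * 1000
  h_in <- 10^(-ph_in) * 1000
  rtf * log((p_h * h_out + p_k * k_out_mM) / (p_h * h_in + p_k * k_in_mM))
}

# grid-search oracle for the minimum selectivity ratio: smallest r on a
# log10 grid (step 0.01) with |GHK - E_H| <= tol
oracle_min_ratio <- function(k_in_mM, k_out_mM, ph_in, ph_out, tol_mv,
                             temperature_c = 20) {
  rtf <- 8.31446262 * (temperature_c + 273.15) / 96485.33212 * 1000
  e_h <- rtf * log(10^(-ph_out) / 10^(-ph_in))
  for (lr in seq(0, 12, by = 0.01)) {
    dev <- abs(oracle_ghk_mv(10^lr, 1, k_in_mM, k_out_mM, ph_in, ph_out,
                             temperature_c) - e_h)
    if (dev <= tol_mv) return(10^lr)
  }
  NA_real_
}

# trapezoidal integral of y over x
oracle_trapz <- function(x, y) {
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

# standard clamp-step run used by the model tests
clamp_step <- function(config, level_mv, hold_s = 2, step_s = 10,
                       record_dt_s = 0.05) {
  pr <- data.frame(level_mv = c(-50, level_mv),
                   duration_s = c(hold_s, step_s))
  simulate_voltage_clamp(pr, config, record_dt_s = record_dt_s)
}
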