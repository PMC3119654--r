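# Voltage-clamp trace processing: leak subtraction, I-V extraction,
# tail-current reversal potentials, activation kinetics, Nernst-slope
# regression, and recording QC.

#' Linear leak subtraction
#'
#' Removes the resistive seal-leak component from every trace:
#' `I_leak(t) = (V_command(t) - holding) / R_seal`, i.e. the leak is
#' referenced to the holding potential so holding-level current is left
#' untouched.  mV / GOhm = pA, so units work out directly.
#'
#' @param family A [sweep_family()].
#' @param seal_resistance_gohm Pre-test seal resistance in GOhm (> 0).
#'   `Inf` is accepted as a sentinel for "no leak" and returns the family
#'   unchanged (apart from the leak-subtracted mark).
#' @return The family with leak removed and `metadata$leak_subtracted`
#'   set; subtracting twice is an error.
#' @export
leak_subtract <- function(family,
                          seal_resistance_gohm =
                            family$metadata$seal_resistance_gohm) {
  stopifnot(inherits(family, "sweep_family"))
  if (isTRUE(family$metadata$leak_subtracted)) {
    domain_error("family is already leak-subtracted")
  }
  if (is.null(seal_resistance_gohm) || !is.numeric(seal_resistance_gohm) ||
      seal_resistance_gohm <= 0) {
    domain_error("seal resistance must be > 0 GOhm")
  }
  t_ms <- protocol_times(family$protocol)
  if (is.finite(seal_resistance_gohm)) {
    for (s in seq_len(ncol(family$traces))) {
      dv <- command_voltage(family$protocol, s, t_ms) -
        family$protocol$holding_mv
      family$traces[, s] <- family$traces[, s] - dv / seal_resistance_gohm
    }
  }
  family$metadata$leak_subtracted <- TRUE
  family
}

#' Steady-state current-voltage relation
#'
#' For each sweep, the mean current over the final `window_length_ms` of
#' the (varied) depolarising step, paired with that sweep's step voltage.
#' The averaging window is anchored to the end of the step, where the
#' current has reached steady state.
#'
#' @param family A [sweep_family()] (normally leak-subtracted first).
#' @param window_length_ms Averaging window length in ms, between 10 and
#'   50 (default 40).
#' @return An `iv_curve`: data frame with columns `voltage_mv`,
#'   `current_pa` (sorted by voltage), plus attributes `window_ms`.
#' @export
steady_state_iv <- function(family, window_length_ms = 40) {
  stopifnot(inherits(family, "sweep_family"))
  if (window_length_ms < 10 || window_length_ms > 50) {
    domain_error("window_length_ms must be between 10 and 50 ms")
  }
  p <- family$protocol
  step <- if (!is.na(p$varied_step)) p$varied_step else nrow(p$steps)
  dur <- p$steps$duration_ms[step]
  if (window_length_ms > dur) {
    domain_error("averaging window is longer than the step")
  }
  onset <- step_onset(p, step)
  t_ms <- protocol_times(p)
  sel <- t_ms >= onset + dur - window_length_ms & t_ms < onset + dur
  volts <- if (!is.na(p$varied_step)) p$sweep_levels else
    rep(p$steps$level_mv[step], ncol(family$traces))
  out <- data.frame(voltage_mv = volts,
                    current_pa = colMeans(family$traces[sel, , drop = FALSE]))
  out <- out[order(out$voltage_mv), ]
  rownames(out) <- NULL
  structure(out, window_ms = c(onset + dur - window_length_ms, onset + dur),
            class = c("iv_curve", "data.frame"))
}

#' Tail-current reversal potential
#'
#' For each tail test level, the tail peak is the signed extremum (largest
#' absolute value) of the current in the window
#' `(test onset + blank_ms, test onset + search_ms)`; the initial
#' `blank_ms` is skipped to avoid the capacitance transient.  The reversal
#' potential is the zero-crossing of a single ordinary-least-squares line
#' of peak against test voltage.
#'
#' @param family A leak-subtracted [sweep_family()] built on a protocol
#'   with a varied test step (see [tail_protocol()]).
#' @param blank_ms Capacitance blanking after the test-step edge (default
#'   2 ms).
#' @param search_ms End of the peak-search window after the edge (default
#'   20 ms; must exceed `blank_ms`).
#' @return A `reversal_estimate` with fields `e_rev_mv`,
#'   `slope_conductance_ns`, `r_squared`, `n_points`, `standard_error_mv`,
#'   `peaks` (data frame of voltage/peak), and `reliable` with `reasons`.
#' @export
tail_reversal <- function(family, blank_ms = 2, search_ms = 20) {
  stopifnot(inherits(family, "sweep_family"))
  if (blank_ms < 0 || search_ms <= blank_ms) {
    domain_error("need blank_ms >= 0 and search_ms > blank_ms")
  }
  p <- family$protocol
  if (is.na(p$varied_step)) {
    domain_error("protocol has no varied test step (no tail levels)")
  }
  if (length(p$sweep_levels) < 3L) {
    domain_error("at least 3 tail test levels are required")
  }
  onset <- step_onset(p, p$varied_step)
  t_ms <- protocol_times(p)
  sel <- t_ms > onset + blank_ms & t_ms < onset + search_ms
  if (!any(sel)) domain_error("peak-search window contains no samples")
  peaks <- vapply(seq_len(ncol(family$traces)), function(s) {
    w <- family$traces[sel, s]
    w[which.max(abs(w))]
  }, numeric(1))
  df <- data.frame(voltage_mv = p$sweep_levels, peak_pa = peaks)
  if (stats::sd(df$peak_pa) == 0) {
    domain_error("tail peaks are constant; regression is degenerate")
  }
  fit <- stats::lm(peak_pa ~ voltage_mv, data = df)
  b <- stats::coef(fit)
  if (abs(b[["voltage_mv"]]) < .Machine$double.eps) {
    domain_error("zero regression slope; no reversal potential")
  }
  e_rev <- -b[["(Intercept)"]] / b[["voltage_mv"]]
  r2 <- 1 - sum(stats::residuals(fit)^2) /
    sum((df$peak_pa - mean(df$peak_pa))^2)
  # delta-method standard error of the x-intercept (covariance computed
  # directly so that a noiseless, exactly linear fit stays silent)
  x <- cbind(1, df$voltage_mv)
  sigma2 <- sum(stats::residuals(fit)^2) / (nrow(df) - 2)
  vc <- sigma2 * solve(crossprod(x))
  g <- c(-1 / b[["voltage_mv"]], b[["(Intercept)"]] / b[["voltage_mv"]]^2)
  se <- sqrt(drop(t(g) %*% vc %*% g))
  reasons <- character(0)
  if (b[["voltage_mv"]] <= 0 && length(unique(sign(df$peak_pa))) == 1L) {
    reasons <- c(reasons,
                 "all peaks share one sign and slope <= 0: no crossing in range")
  }
  structure(
    list(e_rev_mv = e_rev,
         slope_conductance_ns = b[["voltage_mv"]],
         r_squared = r2,
         n_points = nrow(df),
         standard_error_mv = se,
         peaks = df,
         reliable = length(reasons) == 0L,
         reasons = reasons,
         window_ms = c(onset + blank_ms, onset + search_ms)),
    class = "reversal_estimate"
  )
}

#' @export
print.reversal_estimate <- function(x, ...) {
  cat(sprintf(
    "<reversal estimate> E_rev %.2f mV (SE %.2f), g %.3g nS, r2 %.4f, n %d%s\n",
    x$e_rev_mv, x$standard_error_mv, x$slope_conductance_ns, x$r_squared,
    x$n_points, if (x$reliable) "" else " [UNRELIABLE]"))
  if (length(x$reasons)) cat("  ", paste(x$reasons, collapse = "; "), "\n")
  invisible(x)
}

#' Fit a single-exponential activation time constant
#'
#' Levenberg--Marquardt least-squares fit of
#' `I(t) = offset + amplitude * (1 - exp(-(t - fit_start)/tau))`
#' to a current trace from `fit_start_ms` onward.
#'
#' @param time_ms,current_pa Trace samples (equal-length vectors).
#' @param fit_start_ms Fit origin in ms (typically the step onset); data
#'   before it is ignored.
#' @return A `tau_fit` with fields `tau_ms`, `amplitude_pa`, `offset_pa`,
#'   `rmse_pa`, `fit_window_ms`, and `flagged`/`flag_reason` when the
#'   amplitude is indistinguishable from zero (tau unidentifiable).
#'   Non-convergence raises an `hvchan_fit_error` with diagnostics.
#' @export
fit_activation_tau <- function(time_ms, current_pa, fit_start_ms = 0) {
  stopifnot(length(time_ms) == length(current_pa))
  sel <- time_ms >= fit_start_ms
  if (sum(sel) < 5L) domain_error("too few samples after fit_start_ms")
  t <- time_ms[sel] - fit_start_ms
  y <- current_pa[sel]
  offset0 <- y[1]
  amp0 <- mean(utils::tail(y, max(3L, length(y) %/% 20))) - offset0
  flat <- abs(amp0) < max(1e-9, 1e-3 * stats::sd(y) + 1e-12)
  if (stats::sd(y) < 1e-12 || flat && abs(amp0) < 1e-9) {
    return(structure(
      list(tau_ms = NA_real_, amplitude_pa = 0, offset_pa = offset0,
           rmse_pa = stats::sd(y), fit_window_ms = range(time_ms[sel]),
           flagged = TRUE,
           flag_reason = "flat trace: amplitude ~ 0, tau unidentifiable"),
      class = "tau_fit"))
  }
  # crude tau start value: time to reach 63% of the asymptotic rise
  frac <- (y - offset0) / amp0
  i63 <- which(frac >= 0.632)[1]
  tau0 <- if (is.na(i63) || t[i63] <= 0) diff(range(t)) / 5 else t[i63]
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ offset + amplitude * (1 - exp(-t / tau)),
      start = list(offset = offset0, amplitude = amp0, tau = tau0),
      lower = c(-Inf, -Inf, 1e-6),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) {
      stop(errorCondition(
        sprintf("activation fit failed to converge: %s (starts: offset %.3g, amplitude %.3g, tau %.3g)",
                conditionMessage(e), offset0, amp0, tau0),
        class = c("hvchan_fit_error", "error")))
    })
  cf <- stats::coef(fit)
  rmse <- sqrt(mean(stats::residuals(fit)^2))
  flagged <- abs(cf[["amplitude"]]) < 5 * rmse + 1e-9
  structure(
    list(tau_ms = cf[["tau"]], amplitude_pa = cf[["amplitude"]],
         offset_pa = cf[["offset"]], rmse_pa = rmse,
         fit_window_ms = range(time_ms[sel]),
         flagged = flagged,
         flag_reason = if (flagged) "amplitude within noise of zero" else NULL),
    class = "tau_fit"
  )
}

#' @export
print.tau_fit <- function(x, ...) {
  cat(sprintf(
    "<tau fit> tau %.4g ms, amplitude %.4g pA, offset %.4g pA, rmse %.3g pA%s\n",
    x$tau_ms, x$amplitude_pa, x$offset_pa, x$rmse_pa,
    if (isTRUE(x$flagged)) paste0(" [", x$flag_reason, "]") else ""))
  invisible(x)
}

#' Nernst-slope regression of reversal potential on pH gradient
#'
#' Ordinary-least-squares regression of measured reversal potentials on
#' the transmembrane pH gradient `dpH = pH_o - pH_i` (package-wide
#' convention).  An ideally H+-selective conductance at 20 degrees C gives
#' -58.17 mV per pH unit.
#'
#' @param dph Vector of pH gradients (pH_o - pH_i).
#' @param e_rev_mv Vector of reversal potentials in mV.
#' @return List with `slope_mv_per_ph`, `intercept_mv`, `r_squared`, `n`.
#' @export
nernst_slope <- function(dph, e_rev_mv) {
  stopifnot(length(dph) == length(e_rev_mv))
  if (length(dph) < 2L || length(unique(dph)) < 2L) {
    domain_error("need at least 2 distinct pH gradients")
  }
  fit <- stats::lm(e_rev_mv ~ dph)
  list(slope_mv_per_ph = unname(stats::coef(fit)[2]),
       intercept_mv = unname(stats::coef(fit)[1]),
       r_squared = 1 - sum(stats::residuals(fit)^2) /
         sum((e_rev_mv - mean(e_rev_mv))^2),
       n = length(dph))
}

#' Recording quality control
#'
#' A recording passes if its series resistance varied by less than 15%
#' over the experiment: `(max - min) / first <= 0.15`.
#'
#' @param metadata A metadata list with `series_resistance_mohm` (ordered
#'   readings), or the readings vector itself.
#' @return List with `pass` (logical), `reasons` (character), `warnings`
#'   (character; e.g. a single reading cannot show drift), and
#'   `series_resistance_change` (fraction).
#' @export
qc_recording <- function(metadata) {
  rs <- if (is.list(metadata)) metadata$series_resistance_mohm else metadata
  if (is.null(rs) || length(rs) == 0L) {
    domain_error("series_resistance_mohm readings are required")
  }
  warnings <- character(0)
  if (length(rs) == 1L) {
    warnings <- "single series-resistance reading; drift cannot be assessed"
    change <- 0
  } else {
    change <- (max(rs) - min(rs)) / rs[1]
  }
  reasons <- character(0)
  if (change > 0.15) {
    reasons <- sprintf("series resistance varied by %.1f%% (> 15%%)",
                       100 * change)
  }
  list(pass = length(reasons) == 0L, reasons = reasons,
       warnings = warnings, series_resistance_change = change)
}
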