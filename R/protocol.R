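# Voltage protocols and sweep families: the containers for whole-cell
# voltage-clamp recordings.

#' Construct a voltage protocol
#'
#' A protocol is a holding potential plus an ordered list of command steps
#' applied identically on every sweep, except for one optional *varied*
#' step (level `NA`) whose per-sweep level is taken from `sweep_levels`.
#' An incrementing I--V family varies its main depolarising step; a tail
#' protocol keeps a fixed activating prepulse and varies the test step.
#'
#' @param holding_mv Holding potential in mV.
#' @param steps Data frame with columns `level_mv` (mV; `NA` marks the
#'   varied step, at most one) and `duration_ms` (> 0).
#' @param sweep_levels Numeric vector of per-sweep levels for the varied
#'   step (required iff a varied step exists).  For a tail protocol these
#'   are the tail test levels.
#' @param sampling_interval_ms Sampling interval in ms (> 0).
#' @param pre_ms Holding-level period recorded before the first step (ms).
#' @return A `voltage_protocol` object.
#' @examples
#' # 1 s depolarisations from -80 to +60 mV in 10 mV increments
#' iv_protocol(-80, 60, 10)
#' @export
voltage_protocol <- function(holding_mv, steps, sweep_levels = NULL,
                             sampling_interval_ms = 1, pre_ms = 10) {
  stopifnot(is.data.frame(steps),
            all(c("level_mv", "duration_ms") %in% names(steps)))
  if (nrow(steps) == 0L) domain_error("steps must be non-empty")
  if (any(steps$duration_ms <= 0)) domain_error("step durations must be > 0")
  if (sampling_interval_ms <= 0) domain_error("sampling interval must be > 0")
  varied <- which(is.na(steps$level_mv))
  if (length(varied) > 1L) domain_error("at most one varied (NA-level) step")
  if (length(varied) == 1L) {
    if (is.null(sweep_levels) || length(sweep_levels) < 1L) {
      domain_error("sweep_levels required when a step level is NA")
    }
  } else if (!is.null(sweep_levels)) {
    domain_error("sweep_levels given but no NA-level step to vary")
  }
  structure(
    list(holding_mv = holding_mv, steps = steps,
         sweep_levels = sweep_levels,
         varied_step = if (length(varied)) varied else NA_integer_,
         sampling_interval_ms = sampling_interval_ms, pre_ms = pre_ms),
    class = "voltage_protocol"
  )
}

#' Incrementing depolarisation protocol
#'
#' Convenience constructor for the standard I--V family: 1 s steps from
#' `from_mv` to `to_mv` in `by_mv` increments from a holding potential.
#'
#' @param from_mv,to_mv,by_mv Step level range and increment (mV).
#' @param holding_mv Holding potential (default -80 mV).
#' @param duration_ms Step duration (default 1000 ms).
#' @param sampling_interval_ms Sampling interval (default 1 ms).
#' @return A `voltage_protocol`.
#' @export
iv_protocol <- function(from_mv, to_mv, by_mv, holding_mv = -80,
                        duration_ms = 1000, sampling_interval_ms = 1) {
  voltage_protocol(
    holding_mv,
    data.frame(level_mv = NA_real_, duration_ms = duration_ms),
    sweep_levels = seq(from_mv, to_mv, by = by_mv),
    sampling_interval_ms = sampling_interval_ms
  )
}

#' Tail-current protocol
#'
#' Activating prepulse followed by test steps at a range of voltages, the
#' standard protocol for locating a reversal potential from tail currents.
#'
#' @param prepulse_mv Prepulse level (e.g. +40 mV).
#' @param prepulse_ms Prepulse duration (default 1000 ms).
#' @param test_levels_mv Vector of test-step levels (e.g. -75 to +25 mV).
#' @param test_ms Test-step duration (default 500 ms).
#' @param holding_mv Holding potential (default -80 mV).
#' @param sampling_interval_ms Sampling interval (default 0.5 ms).
#' @return A `voltage_protocol` whose varied step is the test step.
#' @export
tail_protocol <- function(prepulse_mv = 40, prepulse_ms = 1000,
                          test_levels_mv = seq(-75, 25, by = 10),
                          test_ms = 500, holding_mv = -80,
                          sampling_interval_ms = 0.5) {
  voltage_protocol(
    holding_mv,
    data.frame(level_mv = c(prepulse_mv, NA_real_),
               duration_ms = c(prepulse_ms, test_ms)),
    sweep_levels = test_levels_mv,
    sampling_interval_ms = sampling_interval_ms
  )
}

#' Number of sweeps implied by a protocol
#' @param protocol A `voltage_protocol`.
#' @return Integer sweep count.
#' @export
n_sweeps <- function(protocol) {
  if (is.null(protocol$sweep_levels)) 1L else length(protocol$sweep_levels)
}

#' Sample times of a protocol
#' @param protocol A `voltage_protocol`.
#' @return Vector of sample times in ms (t = 0 at sweep start).
#' @export
protocol_times <- function(protocol) {
  total <- protocol$pre_ms + sum(protocol$steps$duration_ms)
  dt <- protocol$sampling_interval_ms
  seq(0, total - dt, by = dt)
}

#' Onset time of a protocol step
#' @param protocol A `voltage_protocol`.
#' @param step Step index.
#' @return Onset time in ms.
#' @export
step_onset <- function(protocol, step) {
  protocol$pre_ms + c(0, cumsum(protocol$steps$duration_ms))[step]
}

#' Command voltage at given times
#'
#' @param protocol A `voltage_protocol`.
#' @param sweep Sweep index (1-based).
#' @param t_ms Times in ms (t = 0 at sweep start); windows are half-open,
#'   a sample at a step boundary belongs to the later step.
#' @return Command voltage in mV at each time.
#' @export
command_voltage <- function(protocol, sweep, t_ms) {
  levels <- protocol$steps$level_mv
  if (!is.na(protocol$varied_step)) {
    levels[protocol$varied_step] <- protocol$sweep_levels[sweep]
  }
  edges <- protocol$pre_ms + c(0, cumsum(protocol$steps$duration_ms))
  v <- rep(protocol$holding_mv, length(t_ms))
  for (i in seq_along(levels)) {
    v[t_ms >= edges[i] & t_ms < edges[i + 1]] <- levels[i]
  }
  v
}

#' Construct a sweep family
#'
#' A sweep family bundles a voltage protocol with the recorded current
#' traces (one column per sweep, pA, outward positive) and the recording
#' metadata used for leak subtraction and quality control.
#'
#' @param protocol A [voltage_protocol()].
#' @param traces Numeric matrix, `length(protocol_times(protocol))` rows by
#'   `n_sweeps(protocol)` columns, in pA.  All values must be finite.
#' @param metadata List; recognised fields: `seal_resistance_gohm`,
#'   `series_resistance_mohm` (ordered readings), `capacitance_pf`,
#'   `temperature_c`, `solution_inside`, `solution_outside`,
#'   `leak_subtracted` (logical, default `FALSE`).
#' @return A `sweep_family` object.
#' @export
sweep_family <- function(protocol, traces, metadata = list()) {
  stopifnot(inherits(protocol, "voltage_protocol"))
  traces <- as.matrix(traces)
  nt <- length(protocol_times(protocol))
  if (nrow(traces) != nt || ncol(traces) != n_sweeps(protocol)) {
    domain_error(sprintf(
      "traces must be %d samples x %d sweeps (got %d x %d)",
      nt, n_sweeps(protocol), nrow(traces), ncol(traces)))
  }
  if (!all(is.finite(traces))) domain_error("currents must all be finite")
  if (is.null(metadata$leak_subtracted)) metadata$leak_subtracted <- FALSE
  structure(list(protocol = protocol, traces = traces, metadata = metadata),
            class = "sweep_family")
}

#' @export
print.sweep_family <- function(x, ...) {
  p <- x$protocol
  cat(sprintf(
    "<sweep family> %d sweeps x %d samples (dt %.3g ms), holding %g mV\n",
    ncol(x$traces), nrow(x$traces), p$sampling_interval_ms, p$holding_mv))
  if (!is.na(p$varied_step)) {
    cat(sprintf("  varied step %d: %s mV\n", p$varied_step,
                paste(range(p$sweep_levels), collapse = " to ")))
  }
  cat(sprintf("  leak subtracted: %s\n",
              isTRUE(x$metadata$leak_subtracted)))
  invisible(x)
}
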