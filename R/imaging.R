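# Single-cell imaging quantification: ratiometric BCECF pH calibration
# and conversion, and birefringence-based calcification-rate regression.

#' Two-point BCECF ratio calibration
#'
#' Linear map between the F488/F458 emission ratio and cytosolic pH,
#' anchored at the mean steady-state ratios measured at pH_i 7.5 and 6.5:
#' `pH(R) = 6.5 + (R - R65) / (R75 - R65)`.  The BCECF ratio increases
#' with pH, so `R75 > R65` is required.
#'
#' @param r75 Mean ratio at pH_i 7.5 (> `r65`).
#' @param r65 Mean ratio at pH_i 6.5 (> 0).
#' @param extrapolation_fraction Ratios outside the anchor span extended
#'   by more than this fraction of the span are flagged out-of-range
#'   (default 0.2).
#' @return A `ratio_calibration` object (mode `"two-point-linear"`).
#' @examples
#' cal <- calibrate_two_point(2.0, 1.2)
#' ratio_to_ph_value(cal, 1.6)  # 7.0
#' @export
calibrate_two_point <- function(r75, r65, extrapolation_fraction = 0.2) {
  if (!is.numeric(r75) || !is.numeric(r65) || r65 <= 0 || r75 <= r65) {
    stop(errorCondition("calibration requires R75 > R65 > 0",
                        class = c("hvchan_calibration_error", "error")))
  }
  structure(list(anchors = c(ph = 7.5, ratio = r75, ph2 = 6.5, ratio2 = r65),
                 r75 = r75, r65 = r65,
                 extrapolation_fraction = extrapolation_fraction,
                 mode = "two-point-linear"),
            class = "ratio_calibration")
}

#' @export
print.ratio_calibration <- function(x, ...) {
  cat(sprintf("<ratio calibration, %s> R(7.5)=%.4g, R(6.5)=%.4g\n",
              x$mode, x$r75, x$r65))
  invisible(x)
}

#' Convert a ratio to pH through a calibration
#'
#' @param cal A [calibrate_two_point()] calibration.
#' @param ratio Ratio value(s).
#' @return pH value(s) with attribute `out_of_range` (logical vector)
#'   flagging ratios beyond the bounded extrapolation range.
#' @export
ratio_to_ph_value <- function(cal, ratio) {
  stopifnot(inherits(cal, "ratio_calibration"))
  span <- cal$r75 - cal$r65
  ph <- 6.5 + (ratio - cal$r65) / span
  oor <- ratio < cal$r65 - cal$extrapolation_fraction * span |
    ratio > cal$r75 + cal$extrapolation_fraction * span
  structure(ph, out_of_range = oor)
}

#' Inverse calibration: pH to ratio
#' @param cal A [calibrate_two_point()] calibration.
#' @param ph pH value(s).
#' @return Ratio value(s).
#' @export
ph_to_ratio_value <- function(cal, ph) {
  stopifnot(inherits(cal, "ratio_calibration"))
  cal$r65 + (ph - 6.5) * (cal$r75 - cal$r65)
}

#' Construct a fluorescence ratio trace
#'
#' @param time_s Strictly increasing times in s.
#' @param f488,f458 Fluorescence intensities (a.u.); `f458` must be
#'   positive wherever the ratio is used.
#' @return A `ratio_trace` data frame with a `ratio` column.
#' @export
ratio_trace <- function(time_s, f488, f458) {
  stopifnot(length(time_s) == length(f488), length(f488) == length(f458))
  if (is.unsorted(time_s, strictly = TRUE)) {
    domain_error("times must be strictly increasing")
  }
  if (any(f458 <= 0)) domain_error("f458 must be > 0")
  structure(data.frame(time_s = time_s, f488 = f488, f458 = f458,
                       ratio = f488 / f458),
            class = c("ratio_trace", "data.frame"))
}

#' Convert a ratio trace to a pH time series, with event dpH summaries
#'
#' For dye-ester-loaded cells the absolute calibration does not transfer,
#' so only pH *changes* are meaningful: set `ester_loaded = TRUE` to
#' report the dpH summary without absolute values.  For an event at
#' `event_time_s`, `dpH = mean(pH in post window) - mean(pH in pre
#' window)`; windows must not overlap.
#'
#' @param trace A [ratio_trace()].
#' @param cal A [calibrate_two_point()] calibration.
#' @param event_time_s Optional event time for the dpH summary.
#' @param pre_window_s,post_window_s Window lengths in s (default 60 s
#'   each): pre ends at the event, post starts at
#'   `event_time_s + post_start_s`.
#' @param post_start_s Delay before the post window opens (default: the
#'   post window ends at `event_time_s + post_window_s`... i.e. 0).
#' @param ester_loaded Report only dpH (absolute pH omitted).
#' @return List with `ph` (data frame time_s/ph, `NULL` when
#'   `ester_loaded`), `dph` (or `NA` when no event given), window
#'   definitions, and `out_of_range_fraction`.
#' @export
ratio_to_ph <- function(trace, cal, event_time_s = NULL,
                        pre_window_s = 60, post_window_s = 60,
                        post_start_s = 0, ester_loaded = FALSE) {
  stopifnot(inherits(trace, "ratio_trace"))
  ph <- ratio_to_ph_value(cal, trace$ratio)
  oor <- attr(ph, "out_of_range")
  dph <- NA_real_
  windows <- NULL
  if (!is.null(event_time_s)) {
    if (pre_window_s <= 0 || post_window_s <= 0) {
      domain_error("window lengths must be > 0")
    }
    if (post_start_s < 0) {
      domain_error("pre and post windows overlap (post_start_s < 0)")
    }
    pre <- trace$time_s >= event_time_s - pre_window_s &
      trace$time_s < event_time_s
    post <- trace$time_s >= event_time_s + post_start_s &
      trace$time_s < event_time_s + post_start_s + post_window_s
    if (!any(pre) || !any(post)) {
      domain_error("empty pre or post window for the dpH summary")
    }
    dph <- mean(ph[post]) - mean(ph[pre])
    windows <- list(pre = c(event_time_s - pre_window_s, event_time_s),
                    post = c(event_time_s + post_start_s,
                             event_time_s + post_start_s + post_window_s))
  }
  list(ph = if (ester_loaded) NULL else
         data.frame(time_s = trace$time_s, ph = as.numeric(ph)),
       dph = dph, windows = windows,
       ester_loaded = ester_loaded,
       calibration_mode = cal$mode,
       out_of_range_fraction = mean(oor))
}

#' Construct a birefringence intensity series
#'
#' Cross-polarised light intensity is proportional to the quantity of
#' birefringent calcite in the field, so its slope over time measures the
#' calcification rate.
#'
#' @param time_min Increasing times in minutes.
#' @param intensity Grey-scale intensity (a.u.).
#' @param windows List of `c(start, end)` windows in minutes (default the
#'   standard periods 0--150, 150--300, 300--600).
#' @return A `birefringence_series` object.
#' @export
birefringence_series <- function(time_min, intensity,
                                 windows = list(c(0, 150), c(150, 300),
                                                c(300, 600))) {
  stopifnot(length(time_min) == length(intensity))
  if (is.unsorted(time_min, strictly = TRUE)) {
    domain_error("times must be strictly increasing")
  }
  structure(list(time_min = time_min, intensity = intensity,
                 windows = windows),
            class = "birefringence_series")
}

#' Windowed calcification-rate regression
#'
#' Ordinary-least-squares slope of intensity against time within each
#' window (half-open, `start <= t < end`; the final window also includes
#' its endpoint), normalised to the slope of the first window.
#'
#' @param series A [birefringence_series()].
#' @return A data frame with `window_start_min`, `window_end_min`,
#'   `slope_au_min`, `normalized_rate`, `n`.
#' @export
calcification_rates <- function(series) {
  stopifnot(inherits(series, "birefringence_series"))
  nw <- length(series$windows)
  out <- lapply(seq_len(nw), function(i) {
    w <- series$windows[[i]]
    sel <- series$time_min >= w[1] &
      (series$time_min < w[2] | (i == nw & series$time_min <= w[2]))
    if (sum(sel) < 3L) {
      domain_error(sprintf("window %g-%g min has fewer than 3 samples",
                           w[1], w[2]))
    }
    fit <- stats::lm(series$intensity[sel] ~ series$time_min[sel])
    data.frame(window_start_min = w[1], window_end_min = w[2],
               slope_au_min = unname(stats::coef(fit)[2]), n = sum(sel))
  })
  out <- do.call(rbind, out)
  if (out$slope_au_min[1] <= 0) {
    stop(errorCondition(
      "first-window slope is not positive; cannot normalise rates",
      class = c("hvchan_normalization_error", "error")))
  }
  out$normalized_rate <- out$slope_au_min / out$slope_au_min[1]
  out[, c("window_start_min", "window_end_min", "slope_au_min",
          "normalized_rate", "n")]
}

#' Percent inhibition of calcification
#'
#' `100 * (1 - normalized_rate[treatment_window])`: the loss of
#' calcification rate in the treatment window relative to the initial
#' window.
#'
#' @param rates Output of [calcification_rates()] (or a numeric vector of
#'   normalised rates).
#' @param treatment_window Index of the treatment window (default 2, the
#'   150--300 min period).
#' @return Inhibition in percent.
#' @export
inhibition_percent <- function(rates, treatment_window = 2L) {
  norm <- if (is.data.frame(rates)) rates$normalized_rate else rates
  if (treatment_window < 1L || treatment_window > length(norm)) {
    domain_error("treatment_window index out of range")
  }
  100 * (1 - norm[treatment_window])
}
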