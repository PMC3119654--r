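# Named experimental scenarios: parameter/event bundles encoding the
# manipulations applied to the model cell (Zn2+ or Gd3+ block, external
# pH shifts, Ca2+-free medium, ammonium-pulse acid loads).

#' Construct a scenario
#'
#' A scenario is a named bundle of configuration deltas (applied on top
#' of a base [cell_config()]) and timed events.
#'
#' Event kinds: `set_ph_o` (value = new external pH), `zn_on`/`zn_off`,
#' `gd_on`/`gd_off`, `ca_free`/`ca_restore` (suspend/restore the
#' calcification load), `acid_on`/`acid_off` (value = extra acid load in
#' mol H+/s), and `nh4cl_pulse` (value = acid load, `duration_s` =
#' pulse length; expands to an `acid_on`/`acid_off` pair).
#'
#' @param name Scenario name.
#' @param config_deltas Named list of configuration overrides; nested
#'   lists `hv` and `cl` override channel parameters.
#' @param events Data frame with columns `time_s`, `kind`, `value`,
#'   `duration_s` (use [scenario_event()] + `rbind`).
#' @param duration_s Suggested run length in s.
#' @param description One-line description.
#' @return A `scenario` object.
#' @export
scenario <- function(name, config_deltas = list(), events = empty_events(),
                     duration_s = 600, description = "") {
  stopifnot(is.data.frame(events),
            all(c("time_s", "kind", "value", "duration_s") %in% names(events)))
  if (is.unsorted(events$time_s)) {
    domain_error("scenario events must be time-ordered")
  }
  known <- c("set_ph_o", "zn_on", "zn_off", "gd_on", "gd_off", "ca_free",
             "ca_restore", "acid_on", "acid_off", "nh4cl_pulse")
  bad <- setdiff(events$kind, known)
  if (length(bad)) {
    domain_error(sprintf("unknown event kind(s): %s",
                         paste(bad, collapse = ", ")))
  }
  structure(list(name = name, config_deltas = config_deltas,
                 events = events, duration_s = duration_s,
                 description = description),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("<scenario %s> %s\n", x$name, x$description))
  if (nrow(x$events)) {
    for (i in seq_len(nrow(x$events))) {
      e <- x$events[i, ]
      cat(sprintf("  t=%gs %s%s\n", e$time_s, e$kind,
                  if (!is.na(e$value)) sprintf(" (%g)", e$value) else ""))
    }
  }
  invisible(x)
}

#' Build one scenario event row
#' @param time_s Event time in s.
#' @param kind Event kind (see [scenario()]).
#' @param value Numeric payload (pH, acid load, ...), or `NA`.
#' @param duration_s Pulse duration for `nh4cl_pulse`, else `NA`.
#' @return One-row data frame.
#' @export
scenario_event <- function(time_s, kind, value = NA_real_,
                           duration_s = NA_real_) {
  data.frame(time_s = time_s, kind = kind, value = value,
             duration_s = duration_s)
}

empty_events <- function() {
  data.frame(time_s = numeric(0), kind = character(0),
             value = numeric(0), duration_s = numeric(0))
}

# expand compound events (nh4cl_pulse) into primitive on/off pairs
expand_events <- function(events) {
  if (!nrow(events)) return(events)
  rows <- lapply(seq_len(nrow(events)), function(i) {
    e <- events[i, ]
    if (e$kind == "nh4cl_pulse") {
      if (is.na(e$duration_s) || is.na(e$value)) {
        domain_error("nh4cl_pulse needs value (mol/s) and duration_s")
      }
      rbind(scenario_event(e$time_s, "acid_on", e$value),
            scenario_event(e$time_s + e$duration_s, "acid_off"))
    } else e
  })
  out <- do.call(rbind, rows)
  out[order(out$time_s), ]
}

# apply one primitive event to the running simulation state
apply_event <- function(state, event) {
  switch(event$kind,
    set_ph_o = { state$config$ph_o <- event$value },
    zn_on = { state$zn <- TRUE },
    zn_off = { state$zn <- FALSE },
    gd_on = { state$gd <- TRUE },
    gd_off = { state$gd <- FALSE },
    ca_free = { state$j_calc_override <- 0 },
    ca_restore = { state$j_calc_override <- NULL },
    acid_on = { state$extra_acid <- state$extra_acid + event$value },
    acid_off = { state$extra_acid <- 0 },
    domain_error(sprintf("unhandled event kind '%s'", event$kind))
  )
  state
}

#' Apply a scenario's configuration deltas to a base configuration
#'
#' @param config A base [cell_config()].
#' @param scenario A [scenario()].
#' @return The modified `cell_config`.
#' @export
scenario_config <- function(config, scenario) {
  d <- scenario$config_deltas
  for (nm in names(d)) {
    if (nm %in% c("hv", "cl")) {
      for (sub in names(d[[nm]])) config[[nm]][[sub]] <- d[[nm]][[sub]]
    } else {
      config[[nm]] <- d[[nm]]
    }
  }
  config
}

#' Activation-kinetics presets
#'
#' Activation time constants for the native coccolithophore conductance
#' and the two channel homologues expressed in HEK293 cells, in ms.
#'
#' @return Named list: `native` 220 ms, `ehhv1` 107 ms, `cphv1` 22.9 ms.
#' @export
kinetics_presets <- function() {
  list(native = 220, ehhv1 = 107, cphv1 = 22.9)
}

#' Registry of named scenarios
#'
#' Returns the named scenario bundles encoding the model experiments:
#' \describe{
#'   \item{native_default}{the unperturbed patched-cell configuration}
#'   \item{hek_ehhv1, hek_cphv1}{heterologous kinetics presets}
#'   \item{zn_block}{intact calcifying cell, 2.5 min of Zn2+}
#'   \item{gd_block}{complete gated-channel block}
#'   \item{ph_o_6.5}{external pH step 8.0 -> 6.5 and back}
#'   \item{nh4cl_pulse}{square-pulse cytosolic acid load at constant
#'     external pH}
#'   \item{ca_free}{calcification suspended, then Zn2+}
#'   \item{mutant_H197A, mutant_H203A}{reduced Zn2+ block fractions}
#' }
#' Times: perturbations start at t = 60 s after a baseline; the Zn2+
#' window is 150 s; pH/NH4Cl exposures are 600 s runs with a 10-min
#' exposure where applicable.
#'
#' @param base Base configuration the deltas apply to (default
#'   [native_default_config()]).
#' @return Named list of [scenario()] objects.
#' @export
scenario_registry <- function(base = native_default_config()) {
  calc <- calcifying_deltas()
  list(
    native_default = scenario(
      "native_default", duration_s = 120,
      description = "unperturbed patched-cell model"),
    hek_ehhv1 = scenario(
      "hek_ehhv1", config_deltas = list(hv = list(tau_act_ms = 107)),
      duration_s = 120, description = "EhHv1-in-HEK kinetics preset"),
    hek_cphv1 = scenario(
      "hek_cphv1", config_deltas = list(hv = list(tau_act_ms = 22.9)),
      duration_s = 120, description = "CpHv1-in-HEK kinetics preset"),
    zn_block = scenario(
      "zn_block", config_deltas = calc,
      events = rbind(scenario_event(60, "zn_on"),
                     scenario_event(210, "zn_off")),
      duration_s = 360,
      description = "calcifying cell, 2.5 min Zn2+ application"),
    gd_block = scenario(
      "gd_block", config_deltas = calc,
      events = rbind(scenario_event(60, "gd_on"),
                     scenario_event(210, "gd_off")),
      duration_s = 360,
      description = "calcifying cell, complete channel block (Gd3+)"),
    `ph_o_6.5` = scenario(
      "ph_o_6.5",
      events = rbind(scenario_event(60, "set_ph_o", 6.5),
                     scenario_event(360, "set_ph_o", 8.0)),
      duration_s = 600,
      description = "external pH step 8.0 -> 6.5 -> 8.0"),
    nh4cl_pulse = scenario(
      "nh4cl_pulse",
      events = scenario_event(60, "nh4cl_pulse",
                              value = nh4cl_acid_load_mol_s(),
                              duration_s = 300),
      duration_s = 600,
      description = "square-pulse acid load at constant external pH"),
    ca_free = scenario(
      "ca_free", config_deltas = modifyList(calc, list(j_calc_mol_s = 0)),
      events = rbind(scenario_event(60, "zn_on"),
                     scenario_event(210, "zn_off")),
      duration_s = 360,
      description = "non-calcifying cell, 2.5 min Zn2+"),
    mutant_H197A = scenario(
      "mutant_H197A",
      config_deltas = modifyList(calc,
                                 list(hv = list(zn_block_fraction = 0.27))),
      events = rbind(scenario_event(60, "zn_on"),
                     scenario_event(210, "zn_off")),
      duration_s = 360,
      description = "Zn-site mutant: 27% block"),
    mutant_H203A = scenario(
      "mutant_H203A",
      config_deltas = modifyList(calc,
                                 list(hv = list(zn_block_fraction = 0.28))),
      events = rbind(scenario_event(60, "zn_on"),
                     scenario_event(210, "zn_off")),
      duration_s = 360,
      description = "Zn-site mutant: 28% block")
  )
}
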