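# Closed-form electrochemistry: equilibrium potentials, GHK reversal
# potentials, inverse selectivity bounds, and acid-load arithmetic.

#' Nernst equilibrium potential
#'
#' Equilibrium potential of a single ion across a membrane,
#' `E = (2.303 R T / (z F)) * log10(c_out / c_in)` in mV.
#'
#' @param z Integer ionic charge (non-zero; negative for anions).
#' @param c_out,c_in Outside/inside concentrations (any common unit, both
#'   positive; only the ratio matters).
#' @param temperature_c Temperature in degrees Celsius (default 20).
#' @param ion Optional ion label carried through to the result.
#' @return An object of class `equilibrium_potential` with fields `ion`,
#'   `value` (mV), `slope_used` (mV per tenfold ratio for the given `z`),
#'   and `temperature_c`.
#' @examples
#' nernst_potential(1, c_out = 8, c_in = 200)      # K+, approx -81.3 mV
#' nernst_potential(2, c_out = 46, c_in = 5)       # Mg2+, approx +28 mV
#' @export
nernst_potential <- function(z, c_out, c_in, temperature_c = 20, ion = "") {
  if (!is.numeric(z) || length(z) != 1L || z != round(z) || z == 0) {
    domain_error("z must be a non-zero integer charge")
  }
  if (!is.numeric(c_out) || !is.numeric(c_in) || c_out <= 0 || c_in <= 0) {
    domain_error("concentrations must be > 0")
  }
  slope <- nernst_slope_mv(temperature_c) / z
  structure(
    list(ion = ion, value = slope * log10(c_out / c_in),
         slope_used = slope, temperature_c = temperature_c),
    class = "equilibrium_potential"
  )
}

#' @export
print.equilibrium_potential <- function(x, ...) {
  cat(sprintf("<E%s> %.2f mV (slope %.2f mV/decade, %.0f degC)\n",
              if (nzchar(x$ion)) paste0("_", x$ion) else "",
              x$value, x$slope_used, x$temperature_c))
  invisible(x)
}

#' H+ equilibrium potential from a pH gradient
#'
#' `E_H = slope * (pH_i - pH_o)` in mV, equivalent to the Nernst relation
#' on the derived `10^-pH` proton concentrations.  The slope is chosen
#' explicitly by the caller: either directly in mV/decade (e.g. the rounded
#' 60 mV/decade that reproduces the -48 mV resting estimate for
#' pH_o 8.0 / pH_i 7.2) or via the temperature (58.17 mV/decade at 20
#' degrees C).  It is never chosen silently.
#'
#' @param pH_o,pH_i Outside and inside pH (each in 0--14).
#' @param slope_mv Slope in mV per pH unit; exactly one of `slope_mv` and
#'   `temperature_c` must be supplied.
#' @param temperature_c Temperature in degrees Celsius used to derive the
#'   slope.
#' @return An `equilibrium_potential` for H+.
#' @examples
#' ph_equilibrium_potential(8.0, 7.2, slope_mv = 60)      # -48 mV
#' ph_equilibrium_potential(8.0, 7.5, temperature_c = 20) # -29.1 mV
#' @export
ph_equilibrium_potential <- function(pH_o, pH_i, slope_mv = NULL,
                                     temperature_c = NULL) {
  for (p in c(pH_o, pH_i)) {
    if (!is.numeric(p) || p < 0 || p > 14) {
      domain_error("pH values must lie in [0, 14]")
    }
  }
  if (is.null(slope_mv) == is.null(temperature_c)) {
    domain_error("supply exactly one of slope_mv or temperature_c")
  }
  tc <- if (is.null(temperature_c)) NA_real_ else temperature_c
  slope <- if (is.null(slope_mv)) nernst_slope_mv(temperature_c) else slope_mv
  structure(
    list(ion = "H", value = slope * (pH_i - pH_o),
         slope_used = slope, temperature_c = tc),
    class = "equilibrium_potential"
  )
}

#' Goldman-Hodgkin-Katz reversal potential
#'
#' Multi-ion reversal potential from relative permeabilities and the two
#' solution compositions,
#' `V = (RT/F) ln((sum P_cat c_out + sum P_an c_in) /
#'                (sum P_cat c_in + sum P_an c_out))`.
#' Only monovalent ions are supported (H+, Na+, K+ as cations, Cl- as the
#' anion); a divalent ion given non-zero permeability is an error, since
#' the monovalent GHK voltage form does not treat divalents consistently.
#' H+ concentrations are derived from each side's pH.
#'
#' @param permeabilities Named numeric vector of relative permeabilities
#'   (any non-negative scale), names among `H`, `K`, `Na`, `Cl`, `Ca`, `Mg`.
#'   At least one must be positive; `Ca`/`Mg` must be zero or absent.
#' @param inside,outside [solution_composition()] objects.
#' @param temperature_c Temperature in degrees Celsius (default: the
#'   outside solution's temperature).
#' @return Reversal potential in mV.
#' @examples
#' sol <- solution_registry()
#' ghk_reversal(c(H = 1e6, K = 1), inside = sol$P1a, outside = sol$E1)
#' @export
ghk_reversal <- function(permeabilities, inside, outside,
                         temperature_c = NULL) {
  stopifnot(inherits(inside, "solution_composition"),
            inherits(outside, "solution_composition"))
  p <- permeabilities
  if (is.null(names(p)) || any(!nzchar(names(p)))) {
    domain_error("permeabilities must be a named vector")
  }
  known <- c("H", "K", "Na", "Cl", "Ca", "Mg")
  if (!all(names(p) %in% known)) {
    domain_error(sprintf("unknown ion(s): %s",
                         paste(setdiff(names(p), known), collapse = ", ")))
  }
  if (any(p < 0)) domain_error("permeabilities must be >= 0")
  if (all(p == 0)) domain_error("at least one permeability must be > 0")
  divalent <- intersect(names(p)[p > 0], c("Ca", "Mg"))
  if (length(divalent)) {
    stop(errorCondition(
      sprintf("GHK voltage form is monovalent-only; divalent ion(s) %s unsupported",
              paste(divalent, collapse = ", ")),
      class = c("hvchan_unsupported_ion", "error")))
  }
  if (is.null(temperature_c)) temperature_c <- outside$temperature_c
  conc <- function(sol, ion) ion_concentration(sol, ion)
  num <- 0; den <- 0
  for (ion in names(p)[p > 0]) {
    if (ion == "Cl") {                 # anion: sides swapped
      num <- num + p[[ion]] * conc(inside, ion)
      den <- den + p[[ion]] * conc(outside, ion)
    } else {
      num <- num + p[[ion]] * conc(outside, ion)
      den <- den + p[[ion]] * conc(inside, ion)
    }
  }
  rt_over_f_mv(temperature_c) * log(num / den)
}

#' Minimum selectivity ratio consistent with an H+-like reversal potential
#'
#' Inverse GHK problem: the smallest relative permeability ratio
#' `P_H / P_x` for a contaminant ion `x` such that the two-ion GHK reversal
#' potential deviates from the pure H+ Nernst potential by at most
#' `tolerance_mv`.  The deviation is monotone non-increasing in the ratio,
#' so the bound is located by bisection on `log10(ratio)` over [0, 12].
#'
#' @param inside,outside [solution_composition()] objects.
#' @param contaminant_ion `"K"`, `"Na"`, or `"Cl"`.
#' @param tolerance_mv Maximum allowed deviation from E_H in mV (> 0).
#' @param temperature_c Temperature in degrees Celsius (default: outside
#'   solution's).
#' @return The minimum ratio `P_H / P_contaminant` (>= 1).
#' @examples
#' sol <- solution_registry()
#' min_selectivity_ratio(sol$P1a, sol$E1, "K", tolerance_mv = 10)
#' @export
min_selectivity_ratio <- function(inside, outside, contaminant_ion,
                                  tolerance_mv, temperature_c = NULL) {
  if (!is.numeric(tolerance_mv) || tolerance_mv <= 0) {
    domain_error("tolerance_mv must be > 0")
  }
  if (!contaminant_ion %in% c("K", "Na", "Cl")) {
    domain_error("contaminant_ion must be one of K, Na, Cl")
  }
  if (is.null(temperature_c)) temperature_c <- outside$temperature_c
  e_h <- nernst_potential(1, h_concentration_mM(outside),
                          h_concentration_mM(inside),
                          temperature_c, ion = "H")$value
  dev <- function(log10_ratio) {
    p <- stats::setNames(c(10^log10_ratio, 1), c("H", contaminant_ion))
    abs(ghk_reversal(p, inside, outside, temperature_c) - e_h)
  }
  lo <- 0; hi <- 12
  if (dev(hi) > tolerance_mv) {
    stop(errorCondition(
      sprintf("no ratio in [1, 1e12] brings the GHK reversal within %.3g mV of E_H",
              tolerance_mv),
      class = c("hvchan_not_found", "error")))
  }
  if (dev(lo) <= tolerance_mv) return(1)
  for (i in seq_len(200)) {
    mid <- (lo + hi) / 2
    if (dev(mid) <= tolerance_mv) hi <- mid else lo <- mid
  }
  10^hi
}

#' Calcification acid-load rate
#'
#' Converts a cytosolic H+ production flux into a pH drift rate through the
#' buffer capacity: `rate = flux / (beta * volume) * 60` in pH min^-1.
#' This is the back-of-envelope acidosis estimate for an unbuffered,
#' unexported calcification proton load.
#'
#' @param proton_flux_mol_s H+ production in mol s^-1 (>= 0).
#' @param cytosolic_volume_l Cytosolic volume in L (> 0).
#' @param buffer_capacity Buffering capacity in mol L^-1 pH^-1 (> 0).
#' @return An object of class `acid_load_estimate` with the inputs and the
#'   `rate_ph_min` field.
#' @examples
#' acid_load_rate(2.5e-17, 5e-13, 0.01)  # approx 0.3 pH/min
#' @export
acid_load_rate <- function(proton_flux_mol_s, cytosolic_volume_l,
                           buffer_capacity) {
  if (proton_flux_mol_s < 0) domain_error("proton flux must be >= 0")
  if (cytosolic_volume_l <= 0 || buffer_capacity <= 0) {
    domain_error("volume and buffer capacity must be > 0")
  }
  structure(
    list(proton_flux_mol_s = proton_flux_mol_s,
         cytosolic_volume_l = cytosolic_volume_l,
         buffer_capacity = buffer_capacity,
         rate_ph_min = proton_flux_mol_s /
           (buffer_capacity * cytosolic_volume_l) * 60),
    class = "acid_load_estimate"
  )
}

#' @export
print.acid_load_estimate <- function(x, ...) {
  cat(sprintf(
    "<acid load> %.3g mol H+/s into %.3g L at beta %.3g mol/L/pH -> %.3g pH/min\n",
    x$proton_flux_mol_s, x$cytosolic_volume_l, x$buffer_capacity,
    x$rate_ph_min))
  invisible(x)
}

#' Convert a membrane current to a proton flux
#'
#' `flux = I / F`: 1 pA of H+ current moves 1.0364e-17 mol H+ per second.
#' Sign is preserved (outward positive current = H+ leaving the cell).
#'
#' @param current_pa Current in pA.
#' @return Flux in mol s^-1.
#' @examples
#' current_to_proton_flux(96.485)  # 1e-15 mol/s
#' @export
current_to_proton_flux <- function(current_pa) {
  current_pa * 1e-12 / FARADAY
}
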