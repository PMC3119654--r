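# Solution compositions: the per-side ionic environments that all
# equilibrium-potential arithmetic runs on.

#' Construct a solution composition
#'
#' A `solution_composition` records the ionic composition of one side of the
#' membrane (bath or pipette): concentrations of the major ions in mM, the
#' pH, the temperature, and the buffer used.  The free H+ concentration is
#' never stored; it is always derived from the pH as `10^-pH` mol/L.
#'
#' @param label Short identifier, e.g. `"E1"` or `"P1a"`.
#' @param ions Named numeric vector of concentrations in mM.  Recognised
#'   names: `Na`, `K`, `Cl`, `Ca`, `Mg`.  Missing ions default to 0.
#' @param pH Solution pH (0--14).
#' @param temperature_c Temperature in degrees Celsius (default 20, the
#'   recording temperature).
#' @param buffer Buffer description, e.g. `"HEPES 20"`.
#' @return An object of class `solution_composition`.
#' @examples
#' asw <- solution_composition("E1", c(Na = 450, K = 8, Cl = 546,
#'                                     Ca = 10, Mg = 46), pH = 8.0)
#' h_concentration_mM(asw)
#' @export
solution_composition <- function(label, ions, pH, temperature_c = 20,
                                 buffer = "") {
  known <- c("Na", "K", "Cl", "Ca", "Mg")
  full <- stats::setNames(numeric(length(known)), known)
  if (length(ions)) {
    if (is.null(names(ions)) || !all(names(ions) %in% known)) {
      domain_error(sprintf("ion names must be among: %s",
                           paste(known, collapse = ", ")))
    }
    full[names(ions)] <- as.numeric(ions)
  }
  if (any(full < 0)) domain_error("ion concentrations must be >= 0")
  if (!is.numeric(pH) || length(pH) != 1L || pH < 0 || pH > 14) {
    domain_error("pH must be a single value in [0, 14]")
  }
  structure(
    list(label = as.character(label), ions = full, pH = pH,
         temperature_c = temperature_c, buffer = buffer),
    class = "solution_composition"
  )
}

#' @export
print.solution_composition <- function(x, ...) {
  nz <- x$ions[x$ions > 0]
  cat(sprintf("<solution %s> pH %.2f, %.0f degC, buffer: %s\n",
              x$label, x$pH, x$temperature_c,
              if (nzchar(x$buffer)) x$buffer else "none"))
  if (length(nz)) {
    cat("  ", paste(sprintf("%s %g mM", names(nz), nz), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Free H+ concentration of a solution in mM
#'
#' @param x A `solution_composition` (or a bare pH value).
#' @return Free proton concentration in mM, `10^-pH * 1000`.
#' @export
h_concentration_mM <- function(x) {
  pH <- if (inherits(x, "solution_composition")) x$pH else x
  10^(-pH) * 1000
}

#' Ion concentration accessor
#'
#' @param x A `solution_composition`.
#' @param ion Ion name: `"Na"`, `"K"`, `"Cl"`, `"Ca"`, `"Mg"`, or `"H"`
#'   (derived from pH).
#' @return Concentration in mM.
#' @export
ion_concentration <- function(x, ion) {
  stopifnot(inherits(x, "solution_composition"))
  if (ion == "H") return(h_concentration_mM(x))
  if (!ion %in% names(x$ions)) domain_error(sprintf("unknown ion '%s'", ion))
  unname(x$ions[[ion]])
}

#' Registry of electrophysiology solutions
#'
#' Loads the packaged registry of bath (`E*`) and pipette (`P*`) solution
#' compositions used for the coccolithophore and HEK293 recordings,
#' transcribed from the recording descriptions (artificial seawater E1,
#' HEK bath solutions E3--E5, pipette solutions P1a, P1b, P2--P4 and the
#' K+-varied tail-protocol pipettes).  Chloride is tallied from the
#' chloride salts of each recipe.
#'
#' @param path Optional path to an alternative YAML registry with the same
#'   schema (`label: {ions: {...}, pH: , buffer: }`).
#' @return Named list of [solution_composition()] objects.
#' @examples
#' sol <- solution_registry()
#' names(sol)
#' sol$E1
#' @export
solution_registry <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "solutions.yaml", package = "hvchan",
                        mustWork = TRUE)
  }
  raw <- yaml::read_yaml(path)
  out <- lapply(names(raw), function(lab) {
    rec <- raw[[lab]]
    solution_composition(
      label = lab,
      ions = unlist(rec$ions),
      pH = rec$pH,
      temperature_c = if (is.null(rec$temperature_c)) 20 else rec$temperature_c,
      buffer = if (is.null(rec$buffer)) "" else rec$buffer
    )
  })
  stats::setNames(out, names(raw))
}
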