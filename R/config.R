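#' Read an energetics run configuration from YAML
#'
#' The configuration carries the endmember composition and the seawater
#' background. Concentrations are given as `{value, unit}` pairs with units
#' `M`, `mM`, `uM`, `nM` or `mol/kg` (seawater density is taken as 1 kg/L).
#'
#' Expected layout:
#' ```yaml
#' endmember:
#'   label: Irinovskoe
#'   concentrations:
#'     H2:  {value: 7.5, unit: mM}
#'     H2S: {value: 3.2, unit: mM}
#' seawater:
#'   oxygen:  {value: 250, unit: uM}
#'   sulfate: {value: 28, unit: mM}
#'   pH: 8.0
#'   temperature_K: 275.9
#'   pressure_bar: 265
#'   activity_coefficients: {SO4: 0.12}
#' ```
#' All seawater keys are optional and default to [seawater_background()]
#' values.
#'
#' @param path Path to a YAML file.
#' @return A list with elements `endmember` ([endmember_fluid()]) and
#'   `seawater` ([seawater_background()]).
#' @examples
#' cfg <- read_energetics_config(
#'   system.file("extdata", "irinovskoe.yaml", package = "hydroplume"))
#' cfg$endmember$label
#' @export
read_energetics_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$endmember$concentrations)) {
    stop("config must define endmember: concentrations", call. = FALSE)
  }
  conc <- vapply(cfg$endmember$concentrations, parse_quantity, numeric(1))
  em <- endmember_fluid(conc, label = cfg$endmember$label %||% "endmember")

  sw_args <- list()
  sw <- cfg$seawater
  if (!is.null(sw$oxygen))  sw_args$oxygen  <- parse_quantity(sw$oxygen)
  if (!is.null(sw$sulfate)) sw_args$sulfate <- parse_quantity(sw$sulfate)
  if (!is.null(sw$pH)) sw_args$pH <- sw$pH
  if (!is.null(sw$temperature_K)) sw_args$temperature <- sw$temperature_K
  if (!is.null(sw$pressure_bar))  sw_args$pressure <- sw$pressure_bar
  if (!is.null(sw$activity_coefficients)) {
    sw_args$activity_coefficients <- unlist(sw$activity_coefficients)
  }
  list(endmember = em, seawater = do.call(seawater_background, sw_args))
}

# value + unit -> mol/kg
parse_quantity <- function(q) {
  if (is.numeric(q) && length(q) == 1L) return(q)  # bare number = mol/kg
  if (is.null(q$value) || is.null(q$unit)) {
    stop("concentration entries need {value, unit}", call. = FALSE)
  }
  scale <- switch(q$unit,
                  "M" = 1, "mol/kg" = 1, "mM" = 1e-3, "uM" = 1e-6,
                  "µM" = 1e-6, "nM" = 1e-9,
                  stop("unknown concentration unit: ", q$unit, call. = FALSE))
  q$value * scale
}

`%||%` <- function(a, b) if (is.null(a)) b else a
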