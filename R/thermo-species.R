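#' Standard-state thermodynamic properties of plume species
#'
#' Formation properties at 298.15 K and 1 bar for the aqueous species (and
#' liquid water) involved in plume catabolic reactions. Gibbs energies and
#' enthalpies of formation (kJ/mol) follow the CODATA key values and the
#' slop-style compilations conventionally used in marine geochemical
#' energetics; aqueous-species values refer to the hypothetical 1 molal
#' standard state.
#'
#' @return A data.frame with columns `name`, `phase` (one of `"aqueous"`,
#'   `"liquid-water"`), `charge`, `gibbs_formation_298` and
#'   `enthalpy_formation_298` (both kJ/mol).
#' @examples
#' thermo_species_table()
#' @export
thermo_species_table <- function() {
  data.frame(
    name = c("H2", "O2", "H2S", "CO", "CH4", "SO4", "H+", "H2O"),
    phase = c(rep("aqueous", 7L), "liquid-water"),
    charge = c(0L, 0L, 0L, 0L, 0L, -2L, 1L, 0L),
    gibbs_formation_298 = c(17.72, 16.54, -27.92, -119.90, -34.35,
                            -744.00, 0, -237.14),
    enthalpy_formation_298 = c(-4.04, -12.01, -37.66, -120.96, -87.81,
                               -909.34, 0, -285.83),
    stringsAsFactors = FALSE
  )
}

#' Look up species thermodynamic data
#'
#' @param names Character vector of species names.
#' @return Rows of [thermo_species_table()] for `names`, in that order.
#' @keywords internal
species_data <- function(names) {
  tab <- thermo_species_table()
  idx <- match(names, tab$name)
  if (anyNA(idx)) {
    stop("unknown species: ", paste(names[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  tab[idx, , drop = FALSE]
}

#' Construct a balanced catabolic reaction
#'
#' A reaction is a signed stoichiometry over named species (reactants
#' negative, products positive), the number of electrons transferred per mole
#' of electron donor, and the name of the donor. Charge balance is enforced
#' at construction.
#'
#' @param name Reaction label.
#' @param stoichiometry Named numeric vector of signed coefficients.
#' @param electrons_transferred Positive integer, electrons per mole of donor.
#' @param donor Species name of the electron donor; must appear with a
#'   negative coefficient.
#' @return An object of class `plume_reaction`.
#' @examples
#' reaction("knallgas", c(H2 = -1, O2 = -0.5, H2O = 1), 2L, "H2")
#' @export
reaction <- function(name, stoichiometry, electrons_transferred, donor) {
  stopifnot(is.numeric(stoichiometry), !is.null(names(stoichiometry)))
  sp <- species_data(names(stoichiometry))
  net_charge <- sum(stoichiometry * sp$charge)
  if (abs(net_charge) > 1e-9) {
    stop("reaction '", name, "' is not charge balanced (net charge ",
         net_charge, ")", call. = FALSE)
  }
  if (!donor %in% names(stoichiometry) || stoichiometry[[donor]] >= 0) {
    stop("donor '", donor, "' must appear as a reactant (negative coefficient)",
         call. = FALSE)
  }
  if (!is.numeric(electrons_transferred) || electrons_transferred <= 0) {
    stop("electrons_transferred must be a positive number", call. = FALSE)
  }
  structure(
    list(name = name,
         stoichiometry = stoichiometry,
         electrons_transferred = as.integer(electrons_transferred),
         donor = donor),
    class = "plume_reaction"
  )
}

#' @export
print.plume_reaction <- function(x, ...) {
  nu <- x$stoichiometry
  lhs <- nu[nu < 0]
  rhs <- nu[nu > 0]
  fmt <- function(v) paste(ifelse(abs(v) == 1, names(v),
                                  paste0(abs(v), " ", names(v))),
                           collapse = " + ")
  cat(sprintf("<plume_reaction> %s: %s -> %s  (donor %s, %d e-)\n",
              x$name, fmt(lhs), fmt(rhs), x$donor, x$electrons_transferred))
  invisible(x)
}

#' Built-in plume catabolic reactions
#'
#' Aerobic oxidation of dissolved hydrogen (`h2_oxidation`, 2 electrons) and
#' of dissolved sulfide to sulfate (`h2s_oxidation`, 8 electrons), the two
#' dominant catabolisms of plume chemolithoautotrophs such as *Sulfurimonas*
#' and SUP05.
#'
#' @return A `plume_reaction`.
#' @examples
#' h2_oxidation()
#' h2s_oxidation()
#' @export
h2_oxidation <- function() {
  reaction("H2_oxidation", c(H2 = -1, O2 = -0.5, H2O = 1), 2L, "H2")
}

#' @rdname h2_oxidation
#' @export
h2s_oxidation <- function() {
  reaction("H2S_oxidation", c(H2S = -1, O2 = -2, SO4 = 1, `H+` = 2), 8L, "H2S")
}

#' Endmember hydrothermal fluid composition
#'
#' @param concentrations Named numeric vector, mol per kg fluid; all values
#'   must be non-negative and species names must be known to
#'   [thermo_species_table()].
#' @param label Text label for the vent field.
#' @return An object of class `plume_endmember`.
#' @examples
#' endmember_fluid(c(H2 = 7.5e-3, H2S = 3.2e-3), "example vent")
#' @export
endmember_fluid <- function(concentrations, label = "endmember") {
  stopifnot(is.numeric(concentrations), !is.null(names(concentrations)))
  species_data(names(concentrations))  # errors on unknown species
  if (any(concentrations < 0)) {
    stop("endmember concentrations must be non-negative", call. = FALSE)
  }
  structure(list(concentrations = concentrations, label = label),
            class = "plume_endmember")
}

#' Irinovskoe endmember fluid
#'
#' Dissolved gas composition of the Irinovskoe high-temperature endmember
#' fluid (Mid-Atlantic Ridge, ultramafic-hosted): H2 7.5 mM, H2S 3.2 mM,
#' CH4 0.78 mM, CO 1.9 uM.
#'
#' @return A `plume_endmember` with concentrations in mol/kg.
#' @export
irinovskoe_endmember <- function() {
  endmember_fluid(c(H2 = 7.5e-3, H2S = 3.2e-3, CH4 = 0.78e-3, CO = 1.9e-6),
                  label = "Irinovskoe")
}

#' Deep-seawater background for plume mixing
#'
#' Ambient bottom-seawater composition and conditions into which the vent
#' fluid dilutes. Defaults describe cold, oxygenated deep Atlantic water:
#' O2 250 umol/kg, sulfate 28 mmol/kg, pH 8.0, potential temperature 2.75 C
#' (275.9 K, matching plume bottle temperatures), pressure 265 bar
#' (~2600 m depth). Activity coefficients default to 1 for neutral aqueous
#' species and 0.12 for sulfate at seawater ionic strength; the proton
#' activity is taken directly from pH and liquid water has unit activity.
#'
#' @param oxygen Dissolved O2, mol/kg.
#' @param sulfate Sulfate, mol/kg.
#' @param pH Seawater pH.
#' @param temperature Kelvin; must lie in 271-300 K.
#' @param pressure Bar (recorded; the energetics neglect the pressure
#'   correction, see the package vignette).
#' @param activity_coefficients Named numeric vector of dimensionless gamma;
#'   species not listed default to 1.
#' @return An object of class `plume_seawater`.
#' @examples
#' seawater_background()
#' @export
seawater_background <- function(oxygen = 250e-6,
                                sulfate = 28e-3,
                                pH = 8.0,
                                temperature = 275.9,
                                pressure = 265,
                                activity_coefficients = c(SO4 = 0.12)) {
  if (oxygen <= 0) stop("seawater oxygen must be positive", call. = FALSE)
  if (pH < 7 || pH > 9) stop("seawater pH must lie in [7, 9]", call. = FALSE)
  if (temperature < 271 || temperature > 300) {
    stop("seawater temperature must lie in [271, 300] K", call. = FALSE)
  }
  if (length(activity_coefficients) &&
      (any(activity_coefficients <= 0) || any(activity_coefficients > 1.5))) {
    stop("activity coefficients must lie in (0, 1.5]", call. = FALSE)
  }
  structure(
    list(oxygen = oxygen, sulfate = sulfate, pH = pH,
         temperature = temperature, pressure = pressure,
         activity_coefficients = activity_coefficients),
    class = "plume_seawater"
  )
}

# Seawater concentration (mol/kg) of a species; reduced vent gases are taken
# as absent from the ambient background.
seawater_concentration <- function(seawater, species) {
  vapply(species, function(s) {
    switch(s, O2 = seawater$oxygen, SO4 = seawater$sulfate, 0)
  }, numeric(1))
}

# Activity coefficient with default gamma = 1.
activity_coefficient <- function(seawater, species) {
  gam <- seawater$activity_coefficients
  vapply(species, function(s) {
    if (!is.null(gam) && s %in% names(gam)) gam[[s]] else 1
  }, numeric(1))
}
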