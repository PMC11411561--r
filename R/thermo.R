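# Gas constant, kJ mol^-1 K^-1
.R_KJ <- 8.314462618e-3
.T_REF <- 298.15

#' Conservatively mix endmember fluid with background seawater
#'
#' Two-endmember conservative mixing at a seawater:fluid dilution factor
#' `d >= 1`: for every species, `c_mix = c_sw + (c_em - c_sw) / d`. The mixed
#' state carries the seawater temperature — by `d >= 1e3` a plume is thermally
#' equilibrated with ambient water, and the energetics are evaluated in that
#' regime (plume potential temperature anomalies are a few hundredths of a
#' degree).
#'
#' @param endmember A [endmember_fluid()] object.
#' @param seawater A [seawater_background()] object.
#' @param dilution Seawater:fluid ratio, `d >= 1`. `d = 1` is pure endmember.
#' @return An object of class `plume_mixture` with fields `dilution`,
#'   `concentrations` (mol/kg; endmember species plus O2 and SO4) and
#'   `temperature` (K).
#' @examples
#' mix_conservative(irinovskoe_endmember(), seawater_background(), 1e4)
#' @export
mix_conservative <- function(endmember, seawater, dilution) {
  stopifnot(inherits(endmember, "plume_endmember"),
            inherits(seawater, "plume_seawater"))
  if (!is.numeric(dilution) || length(dilution) != 1L || dilution < 1) {
    stop("invalid dilution: d must be a single number >= 1", call. = FALSE)
  }
  species <- union(names(endmember$concentrations), c("O2", "SO4"))
  species_data(species)  # unknown-species error
  c_em <- vapply(species, function(s) {
    if (s %in% names(endmember$concentrations))
      endmember$concentrations[[s]] else 0
  }, numeric(1))
  c_sw <- seawater_concentration(seawater, species)
  c_mix <- c_sw + (c_em - c_sw) / dilution
  structure(
    list(dilution = dilution,
         concentrations = c_mix,
         temperature = seawater$temperature),
    class = "plume_mixture"
  )
}

#' Standard Gibbs energy of reaction at temperature
#'
#' `dG0(298.15) = sum(nu_i * dGf_i)`; the temperature correction uses the
#' Gibbs-Helmholtz relation with a constant reaction enthalpy:
#' `dG0(T) = dH0_298 - (T / 298.15) * (dH0_298 - dG0_298)`. The pressure
#' correction is neglected (see the package vignette).
#'
#' @param reaction A [reaction()] object.
#' @param temperature Kelvin.
#' @return Standard Gibbs energy, kJ per mole of electron donor (the built-in
#'   reactions are written per mole of donor).
#' @examples
#' standard_gibbs(h2_oxidation(), 298.15)
#' @export
standard_gibbs <- function(reaction, temperature) {
  stopifnot(inherits(reaction, "plume_reaction"))
  nu <- reaction$stoichiometry
  sp <- species_data(names(nu))
  if (anyNA(sp$gibbs_formation_298) || anyNA(sp$enthalpy_formation_298)) {
    stop("incomplete thermodynamic data for reaction '", reaction$name, "'",
         call. = FALSE)
  }
  dG298 <- sum(nu * sp$gibbs_formation_298)
  dH298 <- sum(nu * sp$enthalpy_formation_298)
  dH298 - (temperature / .T_REF) * (dH298 - dG298)
}

# Activities of the reaction species in a mixed-fluid state:
# gamma * molality for aqueous solutes, 10^-pH for the proton, 1 for liquid
# water. Errors if an aqueous solute has zero (or missing) concentration,
# because ln(0) would make the quotient degenerate.
reaction_activities <- function(reaction, state, seawater) {
  species <- names(reaction$stoichiometry)
  sp <- species_data(species)
  vapply(seq_along(species), function(i) {
    s <- species[i]
    if (sp$phase[i] == "liquid-water") return(1)
    if (s == "H+") return(10^(-seawater$pH))
    m <- if (s %in% names(state$concentrations))
      state$concentrations[[s]] else NA_real_
    if (is.na(m) || m <= 0) {
      stop("degenerate activity: species '", s,
           "' has no positive concentration in the mixed state",
           call. = FALSE)
    }
    activity_coefficient(seawater, s) * m
  }, numeric(1))
}

#' In-situ Gibbs energy of reaction in a diluted plume
#'
#' `dGr = dG0(T) + R * T * ln(Q)` with `Q = prod(a_i ^ nu_i)`, evaluated at
#' the mixed-fluid temperature. Activities are `gamma * molality` for aqueous
#' solutes, `10^-pH` for the proton and 1 for liquid water. Returned per mole
#' of electron donor.
#'
#' @param reaction A [reaction()] object.
#' @param state A `plume_mixture` from [mix_conservative()].
#' @param seawater The [seawater_background()] supplying pH and activity
#'   coefficients.
#' @return Gibbs energy of reaction, kJ per mole of donor (negative = energy
#'   available to chemolithotrophs).
#' @examples
#' sw <- seawater_background()
#' st <- mix_conservative(irinovskoe_endmember(), sw, 1e6)
#' delta_rG(h2_oxidation(), st, sw)
#' @export
delta_rG <- function(reaction, state, seawater) {
  stopifnot(inherits(state, "plume_mixture"),
            inherits(seawater, "plume_seawater"))
  nu <- reaction$stoichiometry / abs(reaction$stoichiometry[[reaction$donor]])
  a <- reaction_activities(reaction, state, seawater)
  lnQ <- sum(nu * log(a))
  standard_gibbs(reaction, state$temperature) +
    .R_KJ * state$temperature * lnQ
}

#' Gibbs energy per mole of electrons transferred
#'
#' @param delta_r_G Gibbs energy, kJ per mole of donor.
#' @param reaction The [reaction()] supplying `electrons_transferred`.
#' @return kJ per mole of electrons.
#' @examples
#' per_electron(-222.67, h2_oxidation())
#' @export
per_electron <- function(delta_r_G, reaction) {
  stopifnot(inherits(reaction, "plume_reaction"),
            reaction$electrons_transferred > 0)
  delta_r_G / reaction$electrons_transferred
}

#' Energy density per litre of vent fluid
#'
#' The per-mole Gibbs energy multiplied by the endmember donor concentration
#' (mol/L; fluid density taken as 1 kg/L). Reported alongside — never in
#' place of — the per-mole value.
#'
#' @param delta_r_G Gibbs energy, kJ per mole of donor.
#' @param endmember The [endmember_fluid()] supplying the donor concentration.
#' @param reaction The [reaction()] naming the donor.
#' @return kJ per litre of undiluted vent fluid.
#' @examples
#' energy_density(-212.12, irinovskoe_endmember(), h2_oxidation())
#' @export
energy_density <- function(delta_r_G, endmember, reaction) {
  stopifnot(inherits(endmember, "plume_endmember"),
            inherits(reaction, "plume_reaction"))
  donor <- reaction$donor
  if (!donor %in% names(endmember$concentrations)) {
    stop("unknown species: donor '", donor, "' absent from endmember",
         call. = FALSE)
  }
  delta_r_G * endmember$concentrations[[donor]]
}

#' Plume energetics across a dilution series
#'
#' One row per reaction x dilution (reaction-major, dilution ascending) with
#' the in-situ Gibbs energy per mole of donor, per mole of electrons, and the
#' endmember-based energy density.
#'
#' @param endmember A [endmember_fluid()]; defaults to the Irinovskoe fluid.
#' @param seawater A [seawater_background()].
#' @param reactions List of [reaction()] objects; defaults to aerobic H2 and
#'   H2S oxidation.
#' @param dilutions Numeric vector of seawater:fluid ratios, each `>= 1`.
#' @param digits If non-NULL, round the report columns half-away-from-zero to
#'   this many decimals (2 matches conventional table precision); `NULL`
#'   returns full precision.
#' @return A data.frame with columns `reaction`, `dilution`,
#'   `delta_rG_kJ_per_mol`, `delta_rG_per_e`, `energy_density_kJ_per_L`.
#' @examples
#' energetics_table(dilutions = c(1e4, 1e5, 1e6))
#' @export
energetics_table <- function(endmember = irinovskoe_endmember(),
                             seawater = seawater_background(),
                             reactions = list(h2_oxidation(), h2s_oxidation()),
                             dilutions = c(1e4, 1e5, 1e6),
                             digits = NULL) {
  if (!length(dilutions) || any(dilutions < 1)) {
    stop("dilutions must be a non-empty vector of values >= 1", call. = FALSE)
  }
  dilutions <- sort(dilutions)
  rows <- lapply(reactions, function(rxn) {
    vals <- vapply(dilutions, function(d) {
      st <- mix_conservative(endmember, seawater, d)
      delta_rG(rxn, st, seawater)
    }, numeric(1))
    data.frame(
      reaction = rxn$name,
      dilution = dilutions,
      delta_rG_kJ_per_mol = vals,
      delta_rG_per_e = vals / rxn$electrons_transferred,
      energy_density_kJ_per_L =
        vapply(vals, energy_density, numeric(1),
               endmember = endmember, reaction = rxn),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(digits)) {
    num <- c("delta_rG_kJ_per_mol", "delta_rG_per_e", "energy_density_kJ_per_L")
    out[num] <- lapply(out[num], round_half_out, digits = digits)
  }
  out
}

#' Shift a Gibbs energy by one dilution decade
#'
#' When only the donor concentration is diluted, consecutive decade dilutions
#' change the in-situ Gibbs energy by exactly `R * T * ln(10)` (about
#' +5.28 kJ/mol at 275.9 K). This reconstructs the value at 10x greater
#' dilution from a known one.
#'
#' @param delta_r_G Gibbs energy at dilution `d`, kJ per mole of donor.
#' @param temperature Kelvin.
#' @return Gibbs energy at dilution `10 * d`, kJ per mole of donor.
#' @examples
#' decade_shift(-222.67, 275.9)
#' @export
decade_shift <- function(delta_r_G, temperature = 275.9) {
  delta_r_G + .R_KJ * temperature * log(10)
}

#' Round half away from zero
#'
#' Report-style rounding (half-up in magnitude), as used in printed
#' energetics tables, rather than R's round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @examples
#' round_half_out(c(-111.335, 2.5), 2)
#' @export
round_half_out <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
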