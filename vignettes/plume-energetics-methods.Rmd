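---
title: "Methods: plume energetics, classification and profiling in hydroplume"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: plume energetics, classification and profiling in hydroplume}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hydroplume)
```

This vignette documents the models behind `hydroplume`, the parameters that
matter and their defaults, the design choices made where the design was
genuinely open, and what the synthetic-data generators do and do not
emulate.

## 1. Catabolic energetics under plume dilution

### Model

A hydrothermal plume is treated as a two-endmember conservative mixture:
hot vent fluid diluted `d`-fold (seawater:fluid ratio) into ambient
seawater, so every dissolved species follows
`c_mix = c_sw + (c_em − c_sw)/d`. Because plume temperature anomalies are a
few hundredths of a degree by the time `d` exceeds ~10³, the mixture takes
the ambient seawater temperature; the same value is used at lower dilutions
too, since the endmember temperature is not part of the model — energetics
at `d < 10³` should be read with that caveat.

For a reaction with signed stoichiometry ν (per mole of electron donor) the
available energy is

$$\Delta_r G = \Delta_r G^\circ(T) + RT \ln Q, \qquad
  Q = \prod_i a_i^{\nu_i},$$

with $\Delta_r G^\circ(T)$ from 298.15 K formation data corrected by
Gibbs–Helmholtz at constant reaction enthalpy:
$\Delta G^\circ(T) = \Delta H^\circ_{298} - (T/298.15)\,
(\Delta H^\circ_{298} - \Delta G^\circ_{298})$. Over the ~22 K span between
the reference and deep-water temperature the constant-enthalpy assumption
is a sub-percent effect, and the pressure correction (a few kJ/mol at
265 bar for these reactions) is deliberately neglected: the dilution-driven
$RT\ln Q$ term is what structures the result, and absolute values are
quoted with a matching tolerance.

### Activity model and defaults

The simplest model consistent with deep-seawater conditions: unit activity
coefficients for neutral aqueous species (H₂, O₂, H₂S, CO, CH₄),
$\gamma_{SO_4} = 0.12$ at seawater ionic strength, $a_{H^+} = 10^{-pH}$ and
$a_{H_2O} = 1$. A full ion-interaction (Pitzer/Debye–Hückel) model is out
of scope. Defaults, all overridable through `seawater_background()` or a
YAML config (`read_energetics_config()`):

| parameter | default | unit | rationale |
|---|---|---|---|
| O₂ | 250 | µmol/kg | oxygenated deep Atlantic water |
| SO₄²⁻ | 28 | mmol/kg | mean seawater sulfate |
| pH | 8.0 | — | deep-seawater pH |
| T | 275.9 | K | 2.75 °C, matching plume bottle potential temperatures |
| P | 265 | bar | ~2600 m depth; recorded, not used |
| γ(SO₄²⁻) | 0.12 | — | seawater ionic strength |

Formation data (`thermo_species_table()`) follow CODATA key values and the
slop-style aqueous compilations used in marine geochemistry. With these
inputs the built-in H₂ and H₂S oxidations at 10⁴–10⁶-fold dilution of the
Irinovskoe endmember (H₂ 7.5 mM, H₂S 3.2 mM) give per-mole energies within
a fraction of a percent of published dilution tables for this system, and
successive decades differ by exactly $RT\ln 10 \approx 5.28$ kJ/mol when
only the donor dilutes — the signature spacing such tables print.

```{r energetics}
energetics_table(digits = 2)
```

### Units: per mole versus per litre

Published plume-energetics tables sometimes label these values kJ L⁻¹
although they behave as kJ per mole of donor (decade spacing $= RT\ln 10$;
per-electron rows are per-mole rows divided by the electron number). The
package computes per-mole values as primary and reports the product with
the endmember donor concentration (`energy_density`, kJ per litre of
undiluted vent fluid, density 1 kg/L) as the explicit litre-basis quantity.
CO oxidation energetics are not computed: million-fold dilution of a
~2 µM endmember leaves picomolar CO, and plume CO is better explained by
in-plume microbial production than by the fluid itself.

### Numerical choices

Zero donor concentration raises a degenerate-activity error rather than
returning `-Inf`. Report rounding is half-away-from-zero to 2 decimals
(`round_half_out()`), matching printed-table conventions; computations are
never rounded internally. `decade_shift()` exposes the exact
$+RT\ln 10$ reconstruction of one dilution decade.

## 2. CTD plume staging

Turbidity-anomaly thresholds (ΔNTU): background < 0.01, above/below plume
< 0.02, non-buoyant plume > 0.02, rising plume > 0.06. The published
inequalities are strict and overlap, so the package fixes disjoint
intervals — background [0, 0.01), near-plume [0.01, 0.02), non-buoyant
[0.02, 0.06], rising (0.06, ∞) — honouring every strict inequality while
letting rising take precedence where ranges would overlap.

Two open design points, decided as follows:

* **Vertical context.** Field tables label near-plume bottles "above" or
  "below" without stating a rule. The package uses the deepest bottle with
  plume-level turbidity (ΔNTU > 0.02) as the plume-layer reference depth —
  the laterally spreading non-buoyant layer, not a rising-stem bottle
  higher in the water column, is what "above/below" refer to. Near-plume
  bottles shallower than (or tied with) the reference are above, deeper are
  below; a cast with a single bottle, or no turbidity at all, yields
  `unclassified` with an explanatory note.
* **Label discordance.** On the packaged 20-bottle table from four
  Mid-Atlantic Ridge vent fields, field labels occasionally disagree with
  the thresholds. Labels asserting *low* plume influence carry a turbidity
  ceiling (background 0.01; above/below 0.02) and are flagged with a
  warning when ΔNTU strictly exceeds it — two bottles trip this. Labels
  asserting plume influence at low ΔNTU are not flagged: such calls can
  legitimately rest on the Eh or δ³He evidence the same casts carry, which
  turbidity cannot refute. Eh is accepted as corroborating evidence but
  never overrides turbidity.

## 3. Genome-equivalent functional profiling

Genome equivalents (GE) are the arithmetic mean per-base depth of 16
universal single-copy ribosomal genes; `100 × depth(gene)/GE` is the
percent of genomes carrying the gene. The identity of the 16 markers is
configuration — the module operates on whatever 16 depths the input
supplies (defaults name 16 ribosomal protein families). Depths are the
normalization currency; raw counts are converted with
`counts_to_depth(count, length, read_length = 250)`, the read length
matching 2×250 bp paired-end sequencing. Two further choices: depths of a
gene family are **summed** over variants before dividing by GE (not
averaged per variant), and fractions above 100% are reported with a
multi-copy flag, never clipped — multi-copy hydrogenases are real.

## 4. RPKM, TPM and the housekeeping baseline

`RPKM = reads × 10⁹ / (length × library)` and
`TPM = 10⁶ × (reads/length) / Σ(reads/length)`; fragments (read pairs) are
the intended count unit. TPM denominators are computed over the whole
supplied table (a per-MAG denominator is obtained by subsetting the table
first). Mapping-identity cutoffs belong to the upstream mapper and are
metadata only. The housekeeping baseline is the mean TPM of a configurable
reference gene set; a pathway is called highly transcribed iff its TPM
exceeds that mean. `niche_contrast()` reports per-sample TPM ratios of two
genes in input order (undefined ratios as `NA`), the shape of the
hydrogen-to-sulfur transition analyses across plume stages.

## 5. CODH form classification

Candidate operons are cox genes on one contig and strand with intergenic
gaps ≤ 500 bp (standard prokaryotic heuristic; configurable) and at least
two structural subunits; gene order follows transcription. Classification
order is **structure before motif**: (1) missing any of coxS/M/L ⇒
`partial`; (2) coxL with exact `AYRGAGR` ⇒ `form_II`; (3) coxL with
`AY·CSFR` (one wildcard; literature convention, configurable) ⇒
`putative_form_I`; (4) otherwise `unknown`. The S-L-M order and accessory
coxD/E/F/G genes are recorded as evidence only and never change the call;
the accessory search is genome-wide by default because form II accessory
genes are commonly scattered outside the operon. Coordinates are 1-based
inclusive (GFF3 convention) throughout; classification is deterministic,
independent of input listing order, and invariant under contig reversal.

## 6. Synthetic data: what it does and does not emulate

Each generator is a pure function of its configuration including the seed,
draws from its own RNG stream derived from the master seed (adding a
generator never perturbs the others), restores the caller's RNG state, and
emits machine-readable ground truth alongside the data.

* `gen_ctd_cast()`: a depth grid with background
  ΔNTU ~ |Normal(0.005, 0.002)| plus a Gaussian anomaly (default peak 0.5,
  width 100 m, centre 2650 m); true categories derive from the noise-free
  signal.
* `gen_mock_community()`: default 500 genomes; carriage defaults (coxS
  0.51, NiFe-hydrogenase 0.38, soxY 0.25) follow gene carriage observed in
  non-buoyant plume communities; coverages are log-normal with sdlog 0.5
  (a moderately uneven mock community, chosen so planted-fraction recovery
  stays within its sampling-error bounds at the default sizes); observed
  depths are noise-free sums by default since depth tables are aggregated
  means, with opt-in multiplicative noise.
* `gen_operon_fixtures()`: plants operons of all four classification
  outcomes plus beyond-gap singleton pairs, with motif-free background
  sequence guaranteed by rejection sampling and optional strand-flipped
  duplicates of every contig.
* `gen_transcriptome_counts()`: multinomial counts over length-weighted
  log-normal rates (`exact = TRUE` gives expected counts for noise-free
  rank tests), with a labelled housekeeping subset.

What passing tests on these generators shows is that the estimators invert
the generative models they assume: conservative mixing, single-copy
markers, length-proportional read sampling, clean operon structure. Real
plume data violate these in ways the generators do not emulate — assembly
and binning error, chimeric contigs, non-uniform coverage along genes,
marker mis-annotation, tow-yo casts that sample the plume laterally, and
fluid chemistry that is not conservative (CO in particular is produced in
the plume). Results on real data inherit those upstream uncertainties.

Default problem sizes (500-genome mocks, 10-seed recovery checks, 5-seed
operon suites of ~40 contigs) keep the whole test suite in seconds while
leaving the statistical checks well-powered.

## Known limitations

* No geochemical speciation, ion-interaction activity model, pressure
  correction, or redox kinetics; absolute ΔrG carries a few-percent
  database/assumption uncertainty even though dilution spacing is exact.
* No plume-rise modelling; the vertical-context rule is a per-cast
  heuristic and degrades to `unclassified` on sparse casts.
* Functional profiling trusts upstream annotation and taxonomy; it does
  not detect multi-copy markers or chimeras.
* The CODH module classifies; it does not predict activity, and the form I
  motif is a convention, not an experimental determination.
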