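---
title: "Branched ubiquitin chains: nomenclature, mass-tagged DUB assays and binder profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Branched ubiquitin chains: nomenclature, mass-tagged DUB assays and binder profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(branchedub)
```

## Background

Polyubiquitin signals are trees, not strings. A distal ubiquitin's
C-terminal G76 condenses onto one of eight attachment sites of a more
proximal ubiquitin — the N-terminal methionine (M1) or one of seven
lysines (K6, K11, K27, K29, K33, K48, K63) — and when two or more sites of
the same moiety are occupied the chain branches. Branched chains are a
substantial minority of cellular polyubiquitin and carry signaling
information that linear (unbranched) chains do not, but tools to ask which
enzymes build, read and disassemble them are scarce. This package
implements the computational side of three such tools:

1. a **formal nomenclature** and tree data model for chain architectures;
2. the **mass-tagged DUB assay** readout: substrates in which every moiety
   is a distinct-mass sequence variant, so that the m/z of a released
   monoUb identifies exactly which linkage a deubiquitinase (DUB) cleaved
   in intact-protein MALDI-TOF spectra;
3. the **pulldown binder-profiling statistics** that turn quadruplicate
   chain-type pulldown intensity matrices into clustered binding-preference
   profiles.

Seeded synthetic-data generators stand in for the instrument: they produce
reflectron-mode spectra and pulldown matrices with the statistical
structure the analyses assume, which is what makes every stage testable on
a laptop.

## The chain model and its nomenclature

A `ub_chain` is a rooted tree: units are `ub_unit` objects (sequence
variants of the canonical 76-residue ubiquitin), edges are site-labelled
linkages pointing from the distal unit to a site on the proximal unit, and
the root is the proximal-most moiety. Validation enforces the chemistry:
one use per (unit, site), no linkage through a substituted site, and no
distal role for a C-terminally truncated unit (its G76 is gone).

The ASCII notation reads distal to proximal. A bracketed site list before
a unit attaches everything written to its left — the chain so far, then
any parenthesised arm groups — to that unit:

```{r notation}
x <- parse_chain("(Ub)2-[48,63]Ub-[48]Ub")
x
linkage_composition(x)
classify_topology(x)
```

`format_chain()` renders a canonical form (arms sorted by site, identical
arms collapsed, unit ids ignored), so isomorphic trees print identically
and `parse_chain(format_chain(x))` is isomorphic to `x`. Homotypic
unbranched chains additionally get a compact alias such as `"48Ub3"`.
Literature renderings with superscript site lists, subscript repeat counts
and en-dashes are normalized on a best-effort basis; the ASCII dialect is
the defined source of truth, since the adapted superscript nomenclature
exists in the literature only as examples, not as a grammar.

Two modelling choices are worth making explicit. M1 linkages are ordinary
edges on site M1 even though they are peptide rather than isopeptide
bonds — chain topology does not depend on the bond chemistry. And
repetition groups `(X)2` are expanded at parse time; the tree, not the
notation, is the data structure, which sidesteps the ambiguity of nested
counts.

Enumerating minimal branched chains is a one-liner: one architecture per
unordered pair of distinct sites on a single proximal unit, hence
`choose(8, 2) = 28` branched trimers over the full site set:

```{r enumerate}
length(enumerate_branched_trimers())
```

## The mass engine

`moiety_mass()` sums residue masses over the unit's actual sequence
(substitutions applied, truncation removed, tags appended) plus one water;
`chain_mass()` subtracts one water per linkage. Average masses are the
working default: an intact ~8.5 kDa protein in reflectron mode is an
unresolved isotope envelope whose centroid tracks the average mass.
Monoisotopic mode is kept for testing and completeness.

```{r masses}
moiety_mass(ub_unit())$mz                  # wild type
moiety_mass(ub_unit(isotope = "15N"))$mz   # uniform 15N
```

Uniform ^15^N labelling adds one per-nitrogen shift per nitrogen atom (105
for wild-type ubiquitin); in average mode the shift baseline is the
natural-abundance atomic weight of nitrogen, which is what reproduces the
conventional "8,670 Da" value for heavy ubiquitin. The internal-standard
*calibrant* position, `UB15N_CALIBRANT_MZ` = 8,669.470 m/z, is an
instrument-calibrated empirical convention ~0.6 Da below the computed
average [M+H]^+^; the package treats the calibrant value as the reference
and keeps the computed value for mass arithmetic.

A substrate design is valid when every released moiety and the standard
are pairwise separated: `check_distinguishability()` reports the minimum
gap (default threshold 20 Da — comfortably above the ~8.5 Da envelope
FWHM at this mass and below the ~30–60 Da spacings that K→R substitutions,
truncations and tags provide). `design_substrate()` searches variant
assignments exhaustively and returns the admissible assignment maximizing
the minimum gap; admissibility means truncations sit only at the root and
substitutions never remove a site a position needs for its arms.

The built-in `ultimat_substrate()` layouts use: root Ub 1–72 (8,182.3
m/z), trunk/branch moieties with K6R/K11R (8,621.8), a wild-type K48 arm
(8,565.8) and a K63 arm with five K→R substitutions (8,705.8); with the
standard the minimum gap is 36.4 Da.

## The MALDI-TOF quantification pipeline

Processing follows the standard intact-protein recipe, each step a
documented, testable function:

* **Savitzky–Golay smoothing** (`smooth_spectrum()`): default window of
  twice the expected envelope FWHM plus one point, order 3 — wide enough
  to suppress noise, polynomial enough to preserve envelope shape and
  area.
* **Top-hat baseline subtraction** (`subtract_baseline()`): signal minus
  its morphological opening with a 30 Da flat element; offsets and slow
  chemical baseline go to ~0 while peaks narrower than the element keep
  their area within a few percent.
* **Peak detection** (`detect_peaks()`): local maxima, retained at
  signal-to-noise ≥ 5. Noise is 1.4826 × MAD of the raw-minus-smoothed
  residual — a robust estimate that peak regions barely perturb. Candidate
  envelopes must also have a FWHM within 0.5–2× the width predicted from
  the mass and the resolving power; this width validation is the package's
  documented surrogate for proprietary vendor peak detection (the
  published method names the stages and the S/N threshold, not the
  algorithm internals). Centroids are intensity-weighted means over the
  envelope support, areas trapezoidal integrals.
* **Internal calibration** (`calibrate_internal()`): a single-point
  constant offset that places the heavy-standard centroid exactly on
  8,669.470 m/z. One reference peak exists in the window, so a constant
  shift is the most that can be estimated. A spectrum without the standard
  is rejected outright — without the anchor there is no quantification.
* **Assignment and quantification** (`assign_peaks()`,
  `quantify_cleavage()`): nearest theoretical m/z within ±2 Da (far below
  the ≥20 Da design gaps, far above centroid jitter); percent cleaved =
  (moiety area / standard area) × ([standard]/[substrate]) × 100. Values
  above 100% are flagged, never clipped — they indicate response-factor
  mismatch and should stay visible.

Default concentrations follow the assay format: 1.2 µM substrate diluted
10:12.5 by the acid stop solution carrying the standard, giving 0.96 µM
substrate and 0.8 µM standard; only the ratio enters the formula.

```{r pipeline}
sub <- ultimat_substrate("branched_48")
spec <- reaction_spec(sub, fractions = c(0.5, 0.75, 0.25))
pars <- spectrum_params(noise_sd = 1, calibration_offset = -1.2)
ultimat_measurement(spec, pars, seed = 3)
```

Panel-level reporting mirrors the two published normalization modes:
`"control_substrate"` (each enzyme relative to its own control substrate)
and `"distal_48Ub3"` (relative to the distal moiety of the homotypic K48
trimer, the mode used for debranching-enzyme panels), with
`aggregate_replicates()` keeping the individual technical-replicate points
alongside cell means.

## What the spectrum generator emulates — and what it does not

`simulate_spectrum()` produces Gaussian envelopes (FWHM = m/z / R, default
R = 1,000 at 8.5 kDa, i.e. ≈ 8.5 Da — a plausible figure for unresolved
envelopes; no resolution is published for the assay), areas proportional
to concentration × response factor, an exponentially decaying chemical
baseline, additive Gaussian noise, a constant calibration offset, and
metastable-ion satellites. Satellite defaults (one per parent at 0.985 ×
parent m/z, 5% relative amplitude) are synthetic: published spectra mark
such artifact peaks but give no positions, so the defaults are arbitrary,
configurable, and exist to exercise the pipeline's robustness to
near-lying artifact peaks.

`simulate_reaction()` treats linkages as cleaved independently with
per-edge probabilities and enumerates all cut subsets, so released and
residual species concentrations are exact expectations and total moiety
concentration is conserved. Real DUB kinetics are of course not
independent per edge (processivity, chain-length preference); the
generator models the end-point composition the readout sees, not the
enzymology.

Consequences for interpretation: passing round-trip tests show that the
*readout* recovers what the *generator* injected under realistic noise,
baseline and miscalibration — they do not validate detector saturation
behaviour, shot-to-shot variability, or matrix effects, none of which are
modelled. A small known bias: the morphological baseline over-subtracts a
roughly constant ~1% of the baseline level under each peak (areas are
integrated over a fixed ±3σ window precisely so that this loss is a
constant per peak rather than proportionally worse for small peaks), so
ratios of a large to a small percentage run ~1–3% high; this sits well
inside the ±5-point recovery tolerance and the ±0.3 fold-change band the
tests assert.

## Binder profiling

The statistics mirror the published workflow exactly, with each step its
own function:

1. `preprocess_intensity()`: drop proteins with <2 unique peptides, log2,
   center each sample at zero median.
2. `impute_missing()`: missing entries drawn per sample from
   Normal(median − 1.8·sd, (0.3·sd)²) of that sample's observed values —
   the left-censoring assumption: what is missing was probably low.
   Observed values are never touched; draws are seeded.
3. `test_differential()`: classic fixed-effects one-way ANOVA per protein
   across chain-type groups (vectorized; cross-checked against
   `stats::aov` in the tests), Benjamini–Hochberg across proteins,
   significance at adjusted p < 0.05. "ANOVA" is stated without
   qualification in the source workflow, so no Welch correction and no
   variance-moderation fudge factor are applied; that ambiguity is noted
   here deliberately.
4. `zscore_profiles()` + `cluster_profiles()`: row standardization of the
   significant proteins, then agglomerative clustering on Euclidean
   distances for proteins and samples, protein tree cut at k = 6. The
   published analysis reports six main clusters but not the linkage
   criterion; average linkage is the default (stable for profile data)
   and single/complete/Ward remain available. k is an explicit parameter,
   not auto-selected — the cluster count is presentational.

```{r profiling}
m <- simulate_dia_matrix(dia_design(), seed = 101)
pre <- preprocess_intensity(m)
imp <- impute_missing(pre, seed = 102)
res <- test_differential(imp)
sum(res$significant)
z <- zscore_profiles(imp, subset = res$protein[res$significant])
cluster_profiles(z, k = 6)
```

The generator (`simulate_dia_matrix()`) produces three chain-type groups
in quadruplicate, a 15% differential fraction spread over six
binding-preference clusters (each preferring a different subset of baits,
effect 3 log2 units ≈ 6 replicate SDs), and logistic intensity-dependent
missingness — the structure the imputation model assumes. The default
1,000 proteins are a scaled-down stand-in for the thousands of isoforms a
real pulldown identifies; the statistical guarantees the tests assert
(null FDR within its binomial band, recall ≥ 0.9, cluster ARI ≥ 0.8) are
properties of the method under this generator, not reproductions of any
particular biological dataset, which would require the deposited
instrument data.

## Numerical choices and edge cases

* Tolerances: computed vs published masses at ±0.3 Da (published values
  may be instrument-calibrated); assignment at ±2 Da post-calibration;
  design threshold 20 Da.
* Degenerate inputs fail loudly, not silently: missing internal standard,
  all-missing samples, samples with <3 observed values (imputation sd
  undefined), constant rows under Z-scoring, zero/absent normalization
  references (flagged rows, not dropped), k larger than the protein
  count.
* Determinism: every stochastic function is a pure function of its inputs
  and a seed; RNG state is saved and restored around seeded draws so
  library calls never perturb a caller's stream.
* Problem sizes used by the automated checks — 100 round-trip spectra,
  100 noise-only traces, 200 null simulations at 200 proteins, one
  1,000-protein differential run — were chosen as the smallest sizes at
  which the asserted bands are statistically meaningful.

## Known limitations

* The nomenclature dialect is this package's own formalization; it
  accepts common literature renderings but is not a transcription of any
  published grammar.
* Average-mass arithmetic ignores isotope fine structure, adducts other
  than +H, and multiply charged species.
* The spectrum model is phenomenological (Gaussian envelopes, additive
  noise); it is not a physical MALDI plume or detector model.
* Binder profiling starts from the protein-level intensity matrix;
  peptide-to-protein rollup, spectral library search and gene-ontology
  enrichment are out of scope.
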