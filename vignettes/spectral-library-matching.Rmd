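---
title: "Methods: in silico IR ion spectral libraries and their evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: in silico IR ion spectral libraries and their evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irisearch)
```

## The identification problem

An LC-MS feature gives an accurate mass and, with infrared ion spectroscopy
(IRIS), an IR spectrum of the m/z-isolated ion. Identification then reduces
to a retrieval problem: which candidate structure, ionized the same way,
would produce this spectrum? `irisearch` operates on libraries of
*computed* reference spectra so that no physical standard is needed, and
evaluates how reliably such libraries retrieve correct structures.

The pipeline has four stages, each with explicit, inspectable
intermediates:

1. **Adduct enumeration.** For each neutral molecule, candidate ions are
   formed by H⁺/Na⁺ addition at every N, O and S atom, and H⁺ removal at
   every N, O or S atom that carries a hydrogen. C–H deprotonation is
   excluded: in electrospray-generated even-electron ions the mobile proton
   chemistry is essentially confined to heteroatoms, and this choice also
   keeps the per-molecule ion counts interpretable. Sites that are
   graph-equivalent (determined by iterative Morgan-style neighbourhood
   refinement of atom classes) necessarily produce identical ion
   structures and are merged, so e.g. hydroquinone contributes one
   protonation site, not two.
2. **Spectrum generation.** Each ion geometry is represented by its
   harmonic stick spectrum (frequency in cm⁻¹, intensity in km mol⁻¹),
   ingested from tabular text. Frequencies are multiplied by a scaling
   factor (default 0.975) that empirically compensates the harmonic
   approximation's overestimation of vibrational frequencies, then
   convolved with a unit-area Gaussian of 45 cm⁻¹ full width at half
   maximum — the typical bandwidth observed in room-temperature
   multiple-photon dissociation spectra — onto a regular grid.
3. **Scoring.** Query and reference spectra are compared with the
   square-root cosine score
   $S_{spec} = 1000\,\sum_i \sqrt{a_i b_i}\,/\sqrt{\sum_i a_i \sum_i b_i}$,
   i.e. the cosine of the elementwise square-root-transformed intensity
   vectors. IRMPD band intensities deviate from computed linear-absorption
   intensities far more than band positions do; the square root compresses
   those deviations so the score is dominated by frequency overlap. The
   score is invariant to overall intensity scaling of either spectrum.
4. **Ranking and evaluation.** Candidates are ranked per molecule (not per
   geometry); retrieval over a validation set is summarized by top-k
   curves, the rank product (geometric mean of true-structure ranks), an
   analytic random-annotation baseline, and the structural-similarity
   profile of the ranked lists.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `scale` | 0.975 | — | harmonic frequency correction; appropriate for B3LYP-quality sticks |
| `fwhm` | 45 | cm⁻¹ | Gaussian band width of the convolution |
| `grid` | 600–1850, step 1 | cm⁻¹ | matching range; covers the mid-IR fingerprint region interrogated by free-electron-laser IRIS |
| `energy_filter` | 40 | kJ mol⁻¹ | geometries above this relative energy are excluded at library build |
| `tol_ppm` | 10 | ppm | isomer-search window on the precursor m/z |
| `energy_tol` | 0 | kJ mol⁻¹ | search-time tolerance: 0 scores only each ion's lowest-energy geometry; 10 is a documented alternative that admits kinetically trapped tautomers/conformers |

Relative energies are re-zeroed to the minimum of each (molecule, adduct)
group before filtering, so the threshold always measures energy above the
best geometry, and the best geometry always survives. The filter boundary
is inclusive (retain ≤ 40): the exclusion rule is stated as "above
threshold".

The proton mass used for adduct m/z is 1.007276 Da and the sodiation shift
22.989221 Da — both are the neutral-atom masses corrected by the electron
mass, so theoretical values line up with calibrated instrument readings.
Atomic monoisotopic masses are pinned in a single exported table
(`atomic_masses`).

## Numerical choices

* Gaussians are truncated at ±5 FWHM; the neglected tail area is below
  10⁻⁷ of a band, far under the 0.1% area-conservation tolerance the test
  suite enforces.
* Scoring is restricted to the intersection of the query's measured
  coverage and the library grid, so a spectrum recorded over a narrower
  range is never penalized for bands it could not observe.
* Negative experimental intensities (baseline noise after power
  correction) are clipped to zero before scoring; the square-root
  transform requires non-negative values.
* The laser power correction divides each intensity by the pulse energy
  linearly interpolated at its wavenumber — the first-order correction for
  the nonlinear dependence of multiple-photon dissociation yield on pulse
  energy. The yield itself uses the first-order survival form
  $Y = -\ln(\text{parent}/\text{total})$; a simple fragment-fraction form
  is available via `irmpd_yield(..., form = "fraction")`.
* Ties in ranked lists are broken deterministically: descending score,
  then ascending relative energy, then lexicographic entry id. Ranks are
  therefore identical across platforms and library storage orders (tested
  by shuffling).
* The rank product is computed in log space, so 10⁴-record validation
  sets cannot overflow.
* Degenerate inputs are handled explicitly: an empty stick spectrum
  broadens to an all-zero grid with a warning; an all-zero spectrum is a
  scoring error (undefined cosine); a corrupted or wrong-schema library
  file fails loudly on load.

## Design choices where the design was open

* **Molecule-level identification.** All tautomers/conformers of the true
  molecule count as correct: the analytical question is "which compound",
  not "which geometry".
* **Isomer matching by m/z window, not formula string.** Measured
  precursor masses can be queried directly; a formula-exact mode exists
  for curated inputs. At 10 ppm the window is far narrower than typical
  isobaric spacings below 210 Da.
* **Multi-adduct combination by score product**, restricted to molecules
  present in every queried adduct's candidate list so the products stay
  comparable. With one list the ranking is unchanged.
* **Random baseline as an analytic expectation**
  $100\cdot\text{mean}_i(\min(k, n_i)/n_i)$ rather than a single random
  draw; a seeded Monte-Carlo mode reproduces the draw-based phrasing and
  is tested to agree within sampling error.
* **Structural similarity** uses Open Babel FP2 path fingerprints (1024
  bits) with the Tanimoto coefficient. Any standard substructure
  fingerprint would serve; similarity values are used comparatively (rank
  profiles, correlations), never as absolute assertions. Identical
  canonical structures score 1 even when the path fingerprint is empty
  (single-heavy-atom molecules).
* **On-disk format**: one JSON document with a schema tag, the build
  parameters, per-molecule blocks (canonical SMILES, formula, mass,
  fingerprint bits, graph) and per-entry stick spectra. Grid spectra are
  deliberately *not* stored: they are caches, recomputed through the
  standard build path on load, which makes stick→grid reproducibility a
  structural invariant rather than a promise.

## What the synthetic benchmark emulates — and what it does not

Quantum-chemical spectrum prediction is outside this package's scope, so
the benchmark generator supplies the role of the computed library plus the
experimental validation set:

* `generate_family(n, seed)` draws molecules from a fragment grammar
  (benzene rings and C₂–C₆ alkyl chains decorated with OH, COOH, NH₂,
  carbonyl, methoxy and methyl groups). Families contain close homologues
  (Tanimoto > 0.5) and unrelated scaffolds (< 0.2), giving the graded
  structure-similarity range that the unsupervised-search analysis needs.
* `band_rules()` maps substructures (SMARTS) and adducts to
  literature-plausible diagnostic bands: carboxylate O–C–O stretches near
  1300/1650 cm⁻¹ for deprotonated acids, C=O stretches at 1700–1750 cm⁻¹
  for the protonated/neutral forms, O–H bend near 1450 cm⁻¹, phenoxide
  C–O near 1600 cm⁻¹, aromatic ring modes, and so on. Shared substructures
  therefore produce shared bands — the mechanism behind the
  structure–spectrum correlation — while per-molecule offsets (drawn
  deterministically from each rule's stated spread) and three weak
  molecule-specific skeletal modes keep homologues distinguishable.
  Intensities scale with the substructure match count.
* Each (molecule, adduct) receives one to three geometry variants with
  re-zeroed relative energies up to 60 kJ mol⁻¹, exercising the energy
  filter and the energy-tolerance search.
* `noise_model()` perturbs the truth's own spectrum into a query:
  per-band Gaussian frequency jitter (cm⁻¹), lognormal intensity factors,
  extra Gaussian broadening of the convolution, and a smooth additive
  baseline clipped at zero. The moderate setting used throughout the tests
  (jitter 5 cm⁻¹, σ 0.3, broadening 1.1, baseline 2%) reflects that IRMPD
  intensity errors dominate position errors.

Because queries derive from the truth's own stick spectrum, the benchmark
does **not** model systematic theory–experiment mismatch (anharmonicity
beyond the global scaling, mode coupling, shared-proton broadening) or
chemically realistic band intensities. Passing the benchmark therefore
demonstrates that the retrieval machinery — enumeration, filtering,
scoring, ranking, combination, evaluation — behaves correctly and
degrades gracefully with noise; it does not certify identification rates
on real biofluid data, which depend on the quality of the underlying
quantum chemistry.

All stochastic steps take explicit seeds; one master seed derives
per-molecule and per-record seeds by stable string hashing, so a benchmark
is bit-reproducible from `(n, noise, seed)` and insensitive to evaluation
order.

## Problem sizes

The package's own evaluations use an n = 150 molecule family (about 1500
library spectra after variant generation and energy filtering, about 440
queries), which exhibits the full qualitative behaviour: perfect noise-free
retrieval, high single-adduct isomer retrieval under moderate noise,
combined-adduct improvement, monotone degradation with frequency jitter
(e.g. unsupervised top-1 falls from 100% to roughly 70% at 20 cm⁻¹
jitter), and a steeply decreasing similarity-vs-rank profile. The
jitter-sweep analysis averages five independently seeded families.

## Known limitations

* No conformational search or quantum chemistry: stick spectra are inputs.
  A converter from quantum-chemistry engine output to the frequency-table
  format is the user's responsibility (the expected format is documented
  in `read_stick_table()`).
* One global scaling factor; no element- or mode-dependent scaling.
* No linear-combination fitting of conformer mixtures: each candidate is
  scored through its single best geometry within the energy tolerance.
* Tanimoto/FP2 structural similarity is one of many plausible metrics;
  absolute similarity values should not be compared across fingerprint
  types.
* The JCAMP-DX reader covers the common `(X++(Y..Y))` AFFN tables, not
  compressed (SQZ/DIF/DUP) encodings.

```{r session}
sessionInfo()
```
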