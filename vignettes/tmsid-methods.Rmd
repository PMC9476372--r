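---
title: "Methods: identification of TMS derivatives from GC-EI-MS spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: identification of TMS derivatives from GC-EI-MS spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Semi-volatile and thermolabile compounds are commonly trimethylsilylated
before GC-MS analysis: active hydrogens on hydroxyl, carboxyl, amine and
thiol groups are replaced by Si(CH₃)₃, improving volatility and peak shape.
The derivatives, however, are poorly represented in spectral libraries, so
classical library search often cannot identify them. `tmsid` implements a
learning-based alternative: a kernel regression from electron-ionization
(EI) spectra to molecular fingerprints, followed by a pre-image step that
ranks formula-matched candidate structures by the similarity of their
fingerprints to the predicted one. This vignette records the model, its
assumptions, the tunable parameters, and the design decisions taken where
the procedure was genuinely open.

## Model and assumptions

**Input kernel.** The probability product kernel treats each peak of a
spectrum as a bivariate normal distribution in (m/z, intensity) with shared
diagonal covariance diag(σₘ², σᵢ²) and the spectrum as the equally weighted
mixture of its peak components. The kernel between two spectra is the
integral of the product of the two mixture densities, which has the closed
form implemented in `ppk()`. Two choices are not fixed by the formulation
and are explicit parameters of `ppk_params()`:

* **Bandwidths.** σₘ = 0.5 Da by default — half a nominal mass unit, the
  natural scale of unit-resolution quadrupole EI data, so that peaks in the
  same nominal bin interact strongly and neighbouring bins weakly
  (the relative kernel between two unit-separated peaks is e^(−1/4σₘ²) ≈ 0.37).
  σᵢ = 0.05 by default, on intensities max-normalized per spectrum: EI
  abundances are instrument-arbitrary, so spectra are rescaled to [0, 1]
  before kernel evaluation and the intensity bandwidth is a twentieth of
  the base-peak height.
* **Mixture weights.** Peak components are weighted 1/N per spectrum, so
  the kernel is a mean rather than a sum and is not dominated by peak-rich
  spectra.

Gram matrices are centered and then cosine-normalized (`process_kernel()`);
cross blocks for test spectra are centered with the training means and
normalized with the training diagonal, i.e. test points live in the
training feature space. The order (center, then normalize) is exposed by
the lower-level `center_kernel()`/`normalize_kernel()` if the reverse is
wanted. Centering a Gram matrix necessarily introduces one zero eigenvalue
(the constant direction); numerically this is handled by a 10⁻¹² floor on
centered self-similarities before normalization, which only matters for
exactly duplicated spectra.

**Output space.** Structures are described by four concatenated binary
property families with the published family sizes — substructure (307),
MACCS-type (166), PubChem-type (881) and Klekota-Roth-type (4,860), 6,214
bits in total — and the output kernel is linear on these vectors. A column
mask (`build_mask()`) removes bits that are constant across the training
set and, within every group of identical columns, all but the lowest-index
one; candidate fingerprints are reduced with the training mask before
scoring, and mask identifiers are checked at prediction time so a model is
never scored against fingerprints from a different mask.

**Fingerprint definitions.** The family definitions are the package's own
property keys: an explicit set of 51 isomorphism-invariant structural
descriptors (element counts, bond and ring statistics, atom environments,
silyl-group classification; `mol_features()`) expanded by a versioned,
deterministic grammar into cumulative keys (`feature ≥ t`), exact-count
keys (`feature == t`) and, for the largest family, two-feature
conjunctions, to exactly the published family lengths
(`fingerprint_definitions()`, exportable as TSV with
`write_fp_definitions()`). Bit-level parity with any specific toolkit's
pattern sets is not a goal and is not assumed anywhere: the contract is
the family sizes and the behavioural properties (pure function of the
structure, canonicalization stability, Tanimoto 1 for identical
structures), which the test suite asserts. This also keeps the fingerprint
computation fast enough to fingerprint hundreds of candidate structures
per query.

**Regression and ranking.** `iokr_fit()` solves the kernel ridge system
(K + λI)C = I against the masked training fingerprints; the predicted
output-feature vector for a query is Yᵀ(K + λI)⁻¹k, and candidates are
scored by the linear kernel ⟨ψ(c), h(x)⟩. λ is chosen by internal
cross-validation (`select_lambda()`) minimizing mean squared error between
predicted and true output features, the cheaper of the two natural
objectives; ties go to the smallest λ. The default grid is
10⁻⁴ … 10⁰: after cosine normalization the kernel has unit diagonal and
mean eigenvalue 1, so λ > 1 puts the regularizer above every eigenvalue of
the kernel and leaves only heavily over-smoothed predictors — the useful
regime is sub-unit. Two open choices are resolved as follows:

* **Scoring variant.** Candidates are ranked by the raw linear-kernel
  score, matching the stated output kernel; a norm-corrected variant
  (score divided by the candidate's fingerprint norm, equivalent to cosine
  in output space) is available via `predict_scores(score = "normalized")`
  for candidate sets with very heterogeneous bit counts.
* **Tie-breaking.** Equal scores are ordered lexicographically by candidate
  identifier, and tie groups are recorded in the `ranking_result`;
  determinism is required for reproducible evaluation.

## Curation of silylated spectral libraries

`run_curation()` applies three steps in a fixed order, then the m/z clamp;
each removed record is attributed to exactly one rule (first match wins)
and the report reconciles n_input = n_output + Σ removals.

1. **Structural exclusion** (`classify_structure()`). Thirteen ordered
   categories of silicon chemistry that do not represent clean TMS
   derivatization: Si–Si bonds; C–Si bonds outside intact silyl groups;
   O–Si other than hydroxyl/carboxyl-TMS; N–Si other than
   primary/secondary-amine TMS (imines, amides and N-oxide linkages are
   excluded; cyclic secondary amines are retained); N–O–Si and N–N–Si;
   S–Si other than thiol-TMS; phosphorus–silyl linkages; TMS bound through
   carbon (rearrangement products); TBDMS; mixed TMS/TBDMS; derivatization
   agents (chloro- and aminosilanes, N-silylacetamides); inorganic
   (no carbon skeleton outside silyl groups); and structures containing
   elements outside the organic set C/H/N/O/P/S/halogens/Si. Every
   category is an explicit rule on the parsed molecular graph rather than a
   case-by-case judgement, so runs are reproducible; the test suite
   cross-checks the graph rules against an independent SMARTS matcher.
   Since every intact TMS group necessarily contains three C–Si bonds, the
   C–Si category is interpreted as silicon outside intact TMS/TBDMS
   groups — otherwise it would exclude every derivative.
   The erroneous-entry check compares the stored InChIKey's skeleton block
   with one recomputed from the structure (both must be present); name
   heuristics are out of scope.
2. **High-mass removal** (`filter_high_mass()`): default strictly above
   1000 Da, the upper end of common quadrupole working ranges; the
   comparison mode (`>` vs `>=`) is configurable because both conventions
   appear in practice. Records with unknown MW go to a needs-review
   bucket, never silently through.
3. **Quality criteria** (`quality_filter()`): acquisition range reaching
   MW + 10 (taken from scan-range metadata when present, otherwise proxied
   by the maximum observed peak — a peak list does not carry the
   acquisition range); molecular ion and its ¹³C isotope peak within
   ±0.5 Da (unit-resolution tolerance); at least one TMS marker fragment
   among m/z 73/147/221/295, with a strict mode requiring the marker for
   min(n_TMS, 4) groups; and at least five fragment-ion peaks outside the
   molecular-ion cluster. All four criteria are evaluated and all
   violations reported, though only the first names the removal rule.

The m/z window [50, MW + 10] is applied after filtering, as the final
modification to surviving spectra; `run_curation(clamp = FALSE)` exposes
the order should a library require clamping first.

## Spectral similarity

Replicate acquisitions are compared by cosine similarity after binning into
1.0 Da bins (`bin_spectrum()`), with the bin value defined as the *average*
intensity of the peaks falling in the half-open bin [i, i+1) — averaging,
not summing, so that split peaks do not double-count. Consensus spectra are
per-bin means of max-normalized member vectors, so high-abundance runs do
not dominate; with zero replicate noise the consensus equals each member's
normalized vector, which the tests assert. Clustering of consensus spectra
is agglomerative with average linkage on the distance 1 − cosine, with the
cluster count supplied by the user. A cosine of 0.50 is the conventional
reproducibility threshold and is used as a QC flag only — low-similarity
replicates are kept, flagged, and visible in the similarity matrices.

## Evaluation conventions

`summarize_rankings()` reports top-k accuracy, mean ARP and mean RRP per
group and merged. Two conventions deserve emphasis because they change the
numbers:

* Queries whose candidate set lacks the true structure ("missing") stay in
  the **top-k denominators** — they can never be in the top k — but are
  **excluded from the ARP/RRP means**, which are undefined for them.
* RRP is undefined at TC = 1 (division by TC − 1); the package returns 0
  with a warning, since the sole candidate is the correct one. Ties
  contribute to neither BC nor WC ("better" is strict), so a fully tied
  list has RRP 0.5.

## The synthetic benchmark generator

Training data for this kind of model come from licensed libraries that
cannot be redistributed, so the package ships a generator
(`generator_config()`, `make_benchmark()`) that emulates the statistical
structure the pipeline assumes, and every stage is tested against it.

* **Structures** are drawn from a template grammar of TMS-derivatizable
  scaffolds — aliphatic alcohols and diols, phenols and diphenols,
  aliphatic/aromatic acids, alicyclic alcohols, amines, bisphenols, amino
  acids and other poly-silylated scaffolds — fully derivatized at every
  active site, restricted to 1–5 silyl groups and derivative masses of
  182–575 Da, the range typical of derivatized environmental contaminants.
  Scaffold family and attachment-moiety class are recorded as designed
  cluster and class labels for grouped evaluation.
* **Spectra** are generated *from the fingerprints*: a seeded hash maps a
  fixed fraction (default 8%) of active bits to characteristic fragment
  m/z positions in the instrument scan range 50–800 Da (capped below the
  molecular ion), yielding the few-dozen-peak spectra typical of EI data.
  On top of this deterministic core the generator adds the TMS marker ions
  for min(n_TMS, 4) markers with decreasing intensities, the molecular ion
  with a ¹³C isotope peak scaled by carbon count, multiplicative lognormal
  intensity noise (sd 0.05), per-peak dropout (2%), and uniform background
  clutter (3 peaks); diagnostic peaks (markers, molecular-ion cluster) are
  exempt from dropout so that compliant spectra satisfy the quality
  criteria by construction. The scan range is recorded as spectrum
  metadata, which the quality filter prefers over the max-peak proxy.
  This is deliberately *not* a physical fragmentation model: the
  learnability assumption of the pipeline is precisely that spectra carry
  fingerprint information, and the generator is the minimal faithful
  stand-in for that assumption. Consequently, passing the synthetic
  benchmark demonstrates that the implementation learns and ranks
  correctly when the assumption holds; it does not validate the assumption
  itself on real EI data.
* **Candidate sets** contain one truth (omitted with probability
  `p_missing`) plus decoys sampled at controlled Tanimoto similarity to
  the truth. The similarity screen operates on the *masked* fingerprints
  of the training set — the space in which candidates are actually
  scored — with default range [0, 0.4]; raising the lower bound produces
  strictly harder benchmarks, which the identifiability tests exploit.
  Infeasible ranges fail loudly with the achieved-range report.
* **Design** mirrors a train/test split with partial overlap: by default
  60% of test compounds also have (independently drawn) spectra in the
  training set, giving the presence-in-training Yes/No grouping of the
  evaluation tables.

Everything is derived from `master_seed` through a deterministic integer
hash, so identical configurations reproduce bit-identical bundles,
kernels, models and rankings.

A planted-violation mode (`make_planted_library()`) injects records that
violate specific curation rules in known numbers (siloxanes, TBDMS ethers,
high-mass derivatives, peak-poor or marker-free spectra, scrambled
InChIKeys) to verify curation reports against the planting plan.

## Problem sizes and tolerances used by the tests

The study-scale end-to-end check trains on 300 synthetic pairs, tests 50
queries against 50-candidate sets at the low-noise defaults, and requires
top-1 ≥ 80% with mean RRP ≤ 0.1; difficulty-monotonicity checks run at 150
training pairs with 25-candidate sets; replicate reproducibility uses 15
replicates of 60 compounds (minimum pairwise cosine above 0.95 for at
least 95% of compounds). The PPK closed form is verified against Simpson
tensor-grid quadrature of the explicit mixture product to 10⁻⁶ on random
small spectra; Gram-matrix PSD is asserted to eigenvalue −10⁻⁸; the
interpolation identity of the ridge solution is checked to 10⁻⁶ at
λ = 10⁻¹⁰ on well-separated (hence invertible) normalized kernels.

## Known limitations

* Structure handling (parsing, implicit hydrogens, ring perception) is
  graph-based and intentionally minimal; exotic valences, charged species
  and stereochemistry are out of scope (stereoisomers are not
  distinguished by EI-MS in any case).
* The fingerprint families are property-key families with the published
  sizes, not reimplementations of any toolkit's exact pattern sets;
  absolute bit indices are not comparable across software.
* The curation rule set encodes the thirteen exclusion categories as
  documented graph rules; borderline chemistry (e.g. aromatic N-silylation)
  follows the documented interpretation rather than expert judgement.
* Candidate retrieval from compound databases is consumed from files or
  generated synthetically; live database queries are not part of the
  tested surface.
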