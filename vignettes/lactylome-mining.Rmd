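---
title: "Methods: diagnostic-ion-gated mining of lysine lactylation sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diagnostic-ion-gated mining of lysine lactylation sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lactylmine)
```

## The problem and the model

Lysine lactylation adds a lactyl group (net C3H4O2, +72.0211 Da
monoisotopic) to a lysine ε-amine. Identifying it confidently in shotgun
proteomics data needs more than a mass shift: search engines will happily
place a +72.02 delta on the wrong lysine, on a co-eluting isobaric peptide,
or on noise. The package composes three orthogonal lines of evidence into a
single validation gate:

* **statistical** — a peptide-spectrum match accepted at a 1% target-decoy
  false discovery rate;
* **positional** — an AScore above 20, meaning the observed site-determining
  fragments discriminate the assigned lysine from the best alternative
  placement by more than two orders of magnitude in binomial probability;
* **chemical** — the cyclic immonium ion of lactyllysine (CycIm, C8H14NO2+)
  observed in the same spectrum. This low-mass fragment forms only from an
  intra-peptide lactylated lysine, which makes it a modification-specific
  diagnostic rather than a sequence-specific one.

Validated peptide-level sites are mapped to protein coordinates
(`protein_position = peptide_start + site − 1`) and summarized across a
cohort by detection frequency, summed precursor intensity (ranked over sites
detected more than 10 times), and occupancy.

All masses are monoisotopic; the sub-0.05 Da tolerances involved leave no
role for average masses. Fragment m/z values use proton addition
(m/z = (M + z·p)/z); the electron mass enters only diagnostic-ion masses
computed from cation compositions, where it matters at the 0.0005 Da level.
Only b/y series are modelled, matching HCD fragmentation; a/c/x/z series,
neutral losses and isotope envelopes are out of scope. The CycIm m/z is
never hard-coded: it is derived from its composition
(`formula_mass("C8H14NO2")` minus one electron = 156.1019), and the open
immonium form (C8H17N2O2+, 173.1285) exceeds it by exactly one ammonia —
an identity the tests assert. The detection filter defaults to the cyclic
form, with the open form exposed for users who prefer to require both.

## Scoring and localization

The matcher and the localizer share one binomial engine. For a spectrum
filtered to the top-N most intense peaks per 100 Da window, the probability
that a random theoretical ion lands within ±tol of an observed peak is
approximated as p = N·(2·tol)/100. Matching k of n theoretical ions then has
survival probability P[X ≥ k], X ~ Binom(n, p), and the reported score is
−10·log₁₀ of it. PSM scoring fixes N = 10; a closed-form check (k = n = 6,
p = 0.05 → 78.06) pins the implementation to the formula at 1e-9.

AScore localizes the lactyl over the peptide's lysines. For each peak depth
d = 1..10 the two best placements (ranked by whole-ladder score summed over
depths) are compared on their site-determining ions — the b/y fragments whose
m/z differ between the placements — and AScore is the difference of their
−10·log₁₀ binomial tails at the most discriminating depth, with
p = d·(2·tol)/100. Symmetric evidence gives exactly 0. Peptides with a
single candidate lysine bypass the contrast and carry the sentinel score
1000, following common practice for forced localizations; the sentinel is
reported, not compared to thresholds (it passes any finite cut, which is the
intended semantics of a forced site). Peptides carrying more than one lactyl
are not localized and never become validated sites.

The "manual MS/MS confirmation" step of interactive workflows is
operationalized as a testable rule: at least 3 matched sequence ions whose
backbone break falls within ±2 residues of the assigned site, in addition to
the AScore and CycIm gates. A manual step that cannot be executed by a rule
cannot be benchmarked.

A CycIm call distinguishes `absent` from `undetectable`: when the
acquisition first mass lies above the diagnostic m/z the spectrum could
never have recorded the ion, and treating that as absence would silently
discard valid chemistry. Undetectable spectra are excluded from validation
but counted separately in the run report. Presence additionally requires 1%
of the base peak by default (configurable to 0); the threshold guards
against crediting electronic noise in an otherwise empty region.

## FDR control

Decoys are full sequence reversals, searched concatenated with targets and
counted separately: FDR(t) = #decoys ≥ t / max(1, #targets ≥ t), with
q-values as the running minimum over decreasing score thresholds. This is
the simplest published estimator; decoy-fusion variants of commercial
engines are deliberately not imitated. Control is at PSM level. A threshold
of q ≤ 0 is defined to accept nothing — a zero error budget admits no
non-empty estimated set even when all estimated q-values are exactly zero.

Calibration is tested two ways: on default cohorts with known truth the
empirical false fraction among accepted PSMs must stay within twice the
nominal 1%; and on pure-null spectra — fragments simulated from held-out
reversed sequences present in neither database, precursors drawn from the
database mass distribution so every spectrum is scored — the accepted-target
fraction must sit at or below 1% up to binomial error. Under a pure null the
target-decoy gate accepts close to nothing (acceptance requires a 100:1
target:decoy excess among top scores), so the bound, not an equality, is the
correct property.

## The synthetic cohort generator

The generator stands in for multi-cell-line lactylproteome panels and
emulates: centroided HCD spectra of tryptic peptides (singly-charged b/y
ladders, Gaussian m/z jitter, lognormal intensities, a detection probability
per fragment), the CycIm peak for lactylated precursors, uniform noise
peaks, an acquisition low-mass cutoff, and a cohort structure with per-site
occupancy and presence plans. Defaults and their reasons:

* `n_samples = 12` — the benchmark emulates a 12-cell-line panel.
* The ubiquitous planted site sits at occupancy 0.50 with ~10× the intensity
  of the other sites, reproducing the pattern of a dominant, fully penetrant
  site that motivates this kind of mining.
* `first_mass = 110` Da — the acquisition setting that keeps the CycIm
  region (m/z 156.10) observable; raising it above 156.12 makes every CycIm
  call `undetectable`, which the tests exercise.
* `fragment_sigma = 0.003` Da, `fragment_detection_prob = 0.9`,
  `cycim_emission_prob = 0.95` — realistic high-resolution Orbitrap MS2
  behavior; chosen once as study conditions, not tuned.
* Noise peaks are kept ≥0.05 Da away from true fragment and diagnostic m/z
  by default so oracle tests are unambiguous; `hostile = TRUE` lifts the
  guard.
* The occupancy split between modified and unmodified forms is deterministic
  (expected-value) by default, so occupancy recovery is exact and any
  downstream discrepancy is attributable to the estimator; a binomial mode
  over `n_copies` precursor copies provides the sampling-noise regime.
* One precursor charge state (2+).

Because the modified peptide of a lactylated lysine necessarily carries a
missed cleavage at that lysine (trypsin does not cut after acylated K), the
generator hosts each planted site in the shortest missed-cleavage tryptic
peptide covering it, and emits the same peptide sequence for the unmodified
share — which is also what the occupancy formula pools.

What passing tests on this generator do **not** show about real data:
chimeric spectra, co-eluting isobaric modifications (trimethylation at
+42.047 vs acetylation; succinylation vs two oxidations), retention-time
information, isotope envelopes, charge-state heterogeneity and
fractionation-dependent intensity normalization are all absent. Results on
the benchmark bound the machinery's correctness, not its real-data
sensitivity.

## Conservation phylogenetics

Homologs are aligned pairwise to the reference (Needleman–Wunsch, BLOSUM62,
gap open 11 / extend 1 — standard protein-search costs; the underlying
aligner is `Biostrings::pairwiseAlignment`, whose score is pinned to a
brute-force affine-gap DP oracle in the tests). The multiple alignment is
reference-pivoted: one column per reference residue, homolog insertions
relative to the reference dropped. That is adequate for curated homolog
families of a single protein and is the documented limitation; a pre-aligned
FASTA bypasses it.

Distances use pairwise deletion (gapped columns excluded per pair) and the
Poisson correction d = −ln(1 − p); saturation (p = 1) is an error rather
than a clamp, except inside bootstrap replicates where p is capped just
below 1 to keep resampled matrices finite. Trees are classical
Neighbor-Joining (`ape::nj`) with negative branch lengths clamped to zero
and the deficit reported; supports come from `n_reps = 1000` column
resamples by default, counted as the percentage of replicate trees
containing each original split. Branch lengths are substitutions per site.

## Numerical choices and degenerate inputs

* Score ties in matching break lexicographically by peptide sequence then
  modification string; ranking ties break by accession then position — all
  outputs are invariant to input order, which the tests assert.
* Variable modifications per peptide are capped at 3 to bound the search
  space expansion.
* The intensity-rank filter is strictly `n_detected > min_detections`
  (default 10): a site detected exactly 10 times is excluded.
* Empty digest results, spectra with no candidate in precursor tolerance,
  zero-target FDR inputs and occupancy with a zero denominator all return
  empty/NA results with warnings rather than errors.
* Tolerance presets: 5 ppm/0.02 Da, 10 ppm/0.05 Da, 7 ppm/0.02 Da and
  10 ppm/0.02 Da (default), covering the common acquisition regimes.

## Problem sizes

The shipped benchmark sizes are chosen so the whole suite runs in minutes on
one CPU: 20 replicate cohorts of 12 samples and 6 sites (~190 spectra each)
for the end-to-end benchmark; 20 × 300 null spectra for FDR calibration;
200 random proteins (≤60 residues) for the digestion oracle; 1000 bootstrap
replicates on a 4 × 300 alignment for the sister-pair support check. All are
package choices, reproducible from seeds, and scale linearly if enlarged.

## Known limitations

Semi-specific digestion requires at least one enzymatic terminus — peptides
with both termini non-enzymatic are never generated, which may diverge from
some engines' "semi" definition for short peptides. The N-terminal
methionine is never clipped; positions are 1-based on the deposited
sequence. CycIm presence is required per PSM, not once per site; users who
prefer site-level aggregation can disable the gate (`cycim_gate = FALSE`)
and filter the validated table themselves. Co-occurring non-lactyl variable
modifications are searched but not localized. Occupancy uses precursor
intensities as abundance surrogates; XIC integration from raw data is out of
scope, as are profile-mode spectra, retention-time modelling and
maximum-likelihood phylogenetics.
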