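---
title: "Complexome profiling of BN-PAGE migration profiles: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Complexome profiling of BN-PAGE migration profiles: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comigrate)
```

## The experiment this package analyzes

Complexome profiling separates native protein complexes along a blue-native
PAGE lane, cuts the lane into consecutive slices (36 throughout this
package's defaults), and quantifies every protein in every slice by LC-MS/MS.
A protein's intensity vector across the slices — its *migration profile* —
encodes which complexes and assembly intermediates it is part of: subunits of
one complex comigrate, and a protein that joins an assembly intermediate only
in a mutant shows a mutant-specific peak at that intermediate's position.

The package implements the downstream analysis of such an experiment with
two strains (a reference, e.g. wild type, and a test strain, e.g. a mutant
blocked in photosystem II assembly) and several biological replicates per
strain: sample normalization, migration-profile statistics, band-window
abundance ratio tables, and a screen for candidate assembly factors that
comigrate with early intermediates in the mutant only.

The central container is the `intensity_cube`: non-negative intensities
indexed by protein x strain x replicate x slice, plus per-protein metadata
(peptide count, proteotypic flag, complex annotation). Non-detection is
stored as zero — every downstream sum and threshold treats absence as zero
intensity, which is also how the not-detected convention of the ratio tables
is defined.

## Sample normalization: anchor-set median of ratios

Total ion intensity varies between samples for reasons unrelated to biology
(loading, extraction efficiency). When the two strains differ grossly in
composition — a PSII mutant lacks a large fraction of its thylakoid protein
mass — normalizing on whole-lane totals would be biased, so the package
normalizes on an *anchor complex* assumed equally abundant in both strains
(canonically the eight ATP synthase subunits).

For anchor $a$ with lane total $T_{as}$ in sample $s$, the reference value is
the geometric mean across samples, and the sample's correction factor is the
median over anchors of the ratios to the reference:

$$ f_s = \operatorname{median}_a \frac{T_{as}}{\left(\prod_{s'} T_{as'}\right)^{1/m}} $$

This is the median-of-ratios size-factor estimator familiar from count-based
differential expression. Every intensity is then divided by its sample's
$f_s$. Choices worth stating:

* The reference is the per-anchor geometric mean; with all anchors usable
  this gives the gauge $\prod_s f_s^{1/m} = 1$ on noise-free data.
* Factors are computed from protein lane totals, not per-slice values: one
  correction factor per sample.
* Anchors with a zero lane total in any sample are dropped (and reported)
  rather than pseudo-counted; anchor complexes are abundant, so a zero
  signals a data problem, not a small number.
* The median of an even number of anchors is the midpoint of the central
  pair.

On noise-free simulated data with planted loading factors the estimator
recovers the factors exactly up to the gauge constant, and re-estimating
factors after applying them returns 1 (idempotence); both are asserted in the
test suite at 1e-9.

## Migration profiles, heat maps, clustering

Profiles are replicate means computed *after* normalization (all statistics
operate on normalized intensities). Heat-map rows are max-normalized — each
profile divided by its highest slice value, so every row peaks at 1 and
all-zero rows stay zero.

Rows are ordered by agglomerative hierarchical clustering of the
max-normalized profiles (Euclidean distance, average linkage by default;
both are config knobs, since no single convention is canonical for
complexome heat maps). Rows are sorted by protein id before clustering, so
the ordering depends only on the data, not the input order; identical
profiles merge at height zero and end up adjacent.

## Differential statistics

**Lane-level Welch test.** For each protein the 36 normalized slice
intensities of each replicate lane are summed and the reference strain's
replicate sums are tested against the test strain's with a two-sided
unequal-variance (Welch) t test on the raw sums — no log transform, matching
the convention of testing summed normalized intensities directly. Per-band
tests apply the same machinery to sums within a band window; a
pooled-variance variant is available (`var_equal = TRUE`).

Zero-variance degenerate groups get a documented total-function policy
instead of `NaN`: both groups constant and equal means gives p = 1, constant
with different means gives p = 0, flagged in the output, so downstream
filters never meet missing values.

With three replicates per group and multiplicative log-normal noise the
Welch test on raw sums is slightly conservative (skewed sums, small n). The
acceptance script measures the realized type-I error under the simulator's
null; the test suite asserts it stays within 0.02–0.08 at the 0.05 level.
Because size factors are estimated per dataset, all proteins of one dataset
share the factors' estimation error and their tests are correlated;
calibration is therefore measured pooled over five independent simulated
datasets of 1000 null proteins, normalized on the eight-subunit anchor
complex of the standard design.

**Amplitude-adjusted profile distance.** The Euclidean distance between the
two strains' averaged profiles, divided by the maximal average slice
intensity over both profiles. The adjusted distance is zero iff the profiles
are identical and is invariant under joint positive scaling. The phrase
"maximum of reference or test" admits two readings; the default uses the
single joint maximum (one scalar per protein), and `amplitude = "per_strain"`
reports the two per-strain denominators instead.

**Multiple testing.** Band and lane screens use raw p < 0.05 by default, as
is conventional for hypothesis-generating comigration screens; Bonferroni–
Holm (`holm_adjust()`, a thin validated wrapper over the standard step-down
procedure) is applied where a small family of planned comparisons is tested,
e.g. immunoblot quantifications.

**Immunoblot normalization.** `blot_normalize()` implements the two-step
scheme for densitometric signals: divide by the median of all signals of the
same antiserum in the same experiment, then by the mean of the reference
strain's scaled signals, so the reference maps to 1 on average and each
blot's arbitrary exposure scale cancels.

**Per-cell stoichiometry.** `abundance_per_cell()` converts a protein's mass
fraction of total cellular protein into attomol/cell:
amount = fraction/100 x total protein [pg] / molar mass [kDa] x 1000
(1 pg at 1 kDa is 1 amol x 1000). The bundled worked example (0.0034% of
25 pg at 12.5 kDa) gives 0.068 ~ 0.07 amol/cell.

## Ratio tables and detection flags

For every protein and scope — the whole lane and each band window — the
normalized intensities are summed over all replicates and the scope's
slices per strain, and the test/reference ratio is reported. The default
band windows of the 36-slice layout are SC 7–11, Dimers 13–15,
Monomers/RC47 17–18, RCII 22–23, CP43_mod 25–26 and D1_mod/PsbE/F 28–30.

A ratio is defined only where the protein is *detected* in both strains.
Detection uses one numeric rule: a sum counts as detected iff it reaches
0.05% (config: `threshold_fraction`) of the strain's total intensity over
all proteins, replicates and slices. The boundary is strict-below: exactly
0.05% is detected. Undefined ratios carry the conventional flag `ND` (not
detected in the reference), `nd` (not detected in the test strain), or
`nd/ND`.

Complex-level summaries are medians over the members' defined ratios
(midpoint for even counts), with undefined or explicitly excluded members
listed with reasons. Non-canonical members whose abundance is not
co-regulated with the complex (e.g. accessory subunits) can be excluded per
summary — published tables differ in whether such members enter the median,
so both behaviors are expressible. Ratios are carried at full precision; an
optional `round_digits` pre-rounds member ratios to reproduce tables typeset
at fixed precision. Note that a median recomputed from printed rounded
values can differ from one computed before rounding, so not every printed
median is reproducible from a printed table.

## The comigration screen

Candidate early-assembly factors are proteins that accumulate in designated
early-intermediate band windows (defaults: Monomers/RC47 and RCII) in the
test strain but not the reference. The screen's criteria:

1. detected (positive lane sum) in at least `min_replicates_detected`
   (default 3) replicates of each strain — a real factor is present in the
   reference too, just not in the intermediate windows;
2. at least `min_peptides` (default 3) peptides;
3. in at least one screened window, the window sum is detected in the test
   strain and not detected in the reference under the 0.05% rule — the one
   numeric detection rule the analysis defines is reused here, since no
   separate numeric criterion for "specifically accumulating" exists;
4. optionally (default on), a raw band-test p < 0.05 in such a window.

Every rejected protein's report lists the violated criteria. Candidates can
be ranked by Pearson correlation of their max-normalized test-strain
profiles against known reference factors; a flat profile has no defined
correlation and yields `NA` rather than a spurious rank.

## The synthetic complexome generator

Every downstream stage is testable without external data because the
package ships a generator with known ground truth. The model:

* A complex is a set of subunits with stoichiometry weights and a list of
  *assembly states*; each state is a discretized Gaussian peak (evaluated at
  slice centers 1..36 and renormalized to sum 1, so edge truncation loses no
  mass) with its own abundance per strain. Expected intensity of protein
  $p$ in strain $c$ at slice $k$ is
  $\sum_{\text{states} \ni p} w_p \, A_c \, g(k)$. A peak width below 1e-8
  collapses to a delta at the peak slice.
* Replicate values multiply the expected value by a per-sample loading
  factor and mean-one log-normal noise with configured CV
  ($\sigma^2 = \log(1+\mathrm{CV}^2)$, mean-log $-\sigma^2/2$); MS intensity
  noise is multiplicative, hence log-normal. The default CV of 0.2 is a
  plausible stand-in for replicate-to-replicate intensity scatter of
  label-free quantification; real noise is not characterized here and the
  value is a config knob, chosen once.
* Dropout is a hard intensity floor (below it, zero), matching the
  pipeline's treatment of non-detection as absent intensity; stochastic
  dropout is available but off by default.
* All randomness flows from one seed through one RNG stream in a fixed cell
  order: one seed, one bit-identical dataset.
* An optional per-peptide table splits each protein value by fixed
  per-protein proportions so peptide sums reproduce the protein value
  exactly; the protein-level cube is the primary currency.
* A *planted factor* materializes the screen's target class: an unassembled
  pool in both strains plus a pool comigrating with a named intermediate
  state in the test strain only, with a configurable peptide count.

The demonstration complexome (`demo_complex_specs()`) models a thylakoid
membrane: an equal-abundance 8-subunit anchor complex, an overaccumulating
cytochrome b6f, PSII whose large assemblies collapse in the mutant while
RCII/CP43/D1 intermediates accumulate, PSI-LHCI, and free LHCII. Its
abundances are round numbers chosen to place realistic mass in each band
window; they are illustrative, not fitted.

What the generator does *not* emulate: peptide-level measurement error and
shared-peptide protein inference, position-dependent smearing or
compression of the gel, correlated noise between neighboring slices,
between-replicate migration shifts, and interference between comigrating
complexes. Passing tests therefore demonstrate the correctness and
calibration of the analysis under an idealized noise model, not performance
on any real dataset.

## Problem sizes and numerical choices

The shipped statistical checks use: 1000 null proteins x 5 datasets for
Welch calibration; 200 simulated datasets of 100 null proteins plus the
planted factor for screen sensitivity/specificity; exact (1e-9 to 1e-12)
tolerances for the deterministic identities (normalization recovery, scale
invariance, discretized-Gaussian mass conservation). These sizes give
standard errors comfortably below the asserted margins while keeping a full
run in the order of a minute.

Tie-breaks and degenerate inputs are all total and documented: zero-variance
tests (p in {0, 1}, flagged), all-zero profiles (max-normalize to zero,
adjusted distance 0, flagged), median of an even count (midpoint), cluster
ordering (rows pre-sorted by id), detection boundary (exactly at threshold
is detected).

## Limitations

* The screen's numeric operationalization of "accumulating in the mutant
  but not the wild type" (the 0.05% window rule plus band significance) is a
  reconstruction; no external criterion exists to validate it against, and
  its thresholds are config for that reason.
* The Welch test at n = 3 is approximate; its realized type-I error under
  multiplicative noise is slightly conservative rather than nominal.
* Anchor-set normalization assumes the anchor complex is genuinely
  condition-invariant; violations bias every downstream ratio.
* The clustering defaults (Euclidean, average linkage) are conventional, not
  optimal in any formal sense.
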