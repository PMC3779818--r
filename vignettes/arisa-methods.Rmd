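---
title: "Taxon-targeted ARISA: models, parameters and design notes"
author: "tarisa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Taxon-targeted ARISA: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tarisa)
```

## The method in brief

Automated ribosomal intergenic spacer analysis (ARISA) fingerprints a
community by PCR-amplifying a length-variable rDNA spacer with a
fluorescently labelled primer and sizing the products on a capillary
sequencer. In the taxon-targeted variant implemented here, degenerate primers
(forward `RCGAAYTGCAGAACCTCG`, reverse `TACTYAATCTGAGATYCA`) amplify the
5.8S–ITS2 region of Thalassiosiroid diatoms; because ITS2 length is
species-diagnostic within the group, the sized peak pattern doubles as a
species-level screen. The package covers the computational half of the
workflow:

1. **Reference prediction** — in-silico PCR of reference ITS2 sequences to
   predict the diagnostic fragment length of each taxon and merge those
   lengths into a bin table (`find_binding_sites()`, `predict_amplicons()`,
   `build_bin_table()`).
2. **Peak processing** — sized peak tables are window-filtered (320–420
   bases, both ends inclusive), QC-flagged, binned against the table, heights
   normalized to relative abundances, replicate runs averaged, and assembled
   into a samples × bins matrix whose rows sum to 1 (`peaks_to_matrix()`).
3. **Diversity** — Shannon–Wiener \(H' = -\sum p_i \log_{10} p_i\), richness
   \(S\), Pielou \(J' = H'/\log_{10} S\) (`diversity_table()`).
4. **Community structure** — Bray–Curtis dissimilarity
   \(d_{ij} = \sum_k |x_{ik}-x_{jk}| / \sum_k (x_{ik}+x_{jk})\), group-average
   (UPGMA) clustering with percent-similarity cuts, and 2-D non-metric MDS
   minimizing Kruskal stress-1 (`bray_curtis()`, `upgma()`,
   `cut_clusters()`, `nmds()`).
5. **Environment association** — a tie-corrected Spearman matrix among the
   station variables, and the BIOENV/BEST search: for every non-empty subset
   of environmental variables, the rank correlation \(\rho_s\) between the
   biotic dissimilarities and Euclidean distances on the z-scored subset,
   with a label-permutation test for the best subset
   (`env_correlation_matrix()`, `bioenv()`, `bioenv_permutation_p()`,
   `sensitivity_drop()`).

## Coordinate, rounding and windowing conventions

* Template coordinates are 0-based half-open internally; reports are 1-based
  inclusive. An amplicon's length includes **both primer footprints**,
  because the FAM label rides on the forward primer and the capillary sizes
  the full labelled product. (Phylogenetic workflows that trim the primer
  region do not apply here.)
* Fractional instrument sizes are rounded **half-up** to the nearest integer
  base before binning (348.5 always becomes 349; banker's rounding would
  split bin boundaries inconsistently). A global calibration offset (default
  0) is added first, since capillary sizing can be systematically shifted
  from true length.
* The sizing window 320–420 is inclusive at both ends; the bound itself is a
  configuration value.
* The default mismatch budget for primer binding is 0; it is configurable
  because closely related genera are known to amplify with one forward-primer
  mismatch.
* Bin merging radius is 1 base (diagnostic bins are 2-base ranges); with the
  merged bins 4+ bases apart, binning fractional sizes with a ±1-base
  tolerance is unambiguous and is the recommended setting for jittered real
  data (see the noise analysis below).
* Ambiguous assignments possible when tolerance > 0 break ties to the
  nearest bin centre, then to the lower bin id — deterministic by
  construction.

## QC thresholds

`OFFSCALE` is raised at ≥ 32000 RFU, a typical capillary saturation level;
`LOW_SIGNAL` when a strict majority of peaks sit below 1000 RFU. Both mirror
laboratory re-run rules (dilution and re-amplification respectively), which
software cannot perform, so the flags are advisory and processing continues.
Dilution re-runs of the same extract are treated as independent replicate
runs of the sample; replicates are averaged on the **normalized** scale, not
on raw heights, so a diluted run contributes equally.

Unassigned peak mass (sizes matching no bin) is excluded before
normalization: the assay normalizes over diagnostic lengths only. The
excluded mass is reported per run so heavy losses are visible.

## Clustering and ordination choices

* UPGMA is implemented in-package so tie-breaking is deterministic: equal
  minimum distances merge the pair whose member labels sort first. The
  implementation is cross-checked against `stats::hclust(method =
  "average")` and against a brute-force average-linkage recomputation in the
  tests. Merge heights are checked non-decreasing on every run.
* Dissimilarity is stored in [0, 1]; "≥ 70 % similarity" cuts are the
  presentation transform \(100(1-d)\), and a cut at threshold \(t\) keeps
  subtrees whose merge heights are all ≤ \((100-t)/100\) — a merge exactly
  at the cut height is kept.
* nMDS uses `vegan::monoMDS` (global model, Kruskal stress-1) under a
  restart wrapper: first start from the metric configuration, then 49 seeded
  random starts (defaults `restarts = 50`, `maxit = 300`, `seed = 42`), best
  stress kept, coordinates centred. The restart policy and seed are
  reported in the result, since ordination software conventions differ and
  the reference workflow does not document its own.

## BIOENV details

The biotic matrix enters as dissimilarity (percent-similarity input is
converted by \(d = 1 - s/100\)). Environmental subsets are z-scored per
variable over the stations complete for that subset — a station is dropped
only for subsets that contain its missing variable, matching the reference
treatment of stations without dissolved-Fe measurements. \(\rho_s\) is the
unweighted tie-corrected Spearman correlation of the strictly-lower-triangle
entries. The search is exhaustive over all \(2^k - 1\) subsets (k ≤ 5 in
the intended use); a greedy forward/backward mode exists for large k and
warns that it may miss the optimum.

The permutation test permutes station labels of the environmental table and
re-runs the **full** subset search per permutation,
\(p = (1 + \#\{\rho_{perm} \ge \rho_{obs}\})/(1 + n_{perm})\), default
999 permutations, seed required. Within the permutation loop the stations
are first reduced to those complete for all candidate variables: permuting
labels across stations with differing missingness patterns would otherwise
change which stations each subset retains, making null replicates
incomparable. (The observed search reported to the user still uses
per-subset deletion.) Under a simulated null this p value is uniform on the
achievable grid, which the test suite verifies with a KS test over 500
seeded trials.

The two-tailed p values of the station correlation matrix use
\(t = \rho\sqrt{(n-2)/(1-\rho^2)}\) with \(n-2\) degrees of freedom — the
standard large-sample approximation, cross-checked against
`cor.test(method = "spearman", exact = FALSE)`.

## The synthetic generator

`simulate_community()` + `simulate_peak_profiles()` provide ground-truthed
inputs for every stage. Defaults were chosen once to mirror the intended
field scale: 27 samples, 16 bins, five environmental variables with
exchangeable correlation 0.3 (field variables are strongly intercorrelated),
compositions from gamma baselines modulated log-linearly by a designated
driver (default temperature, `gradient_strength = 1.5`), a 1 % detection
floor producing realistic richness (a handful of dominant peaks per sample),
duplicate runs, ~20000 RFU total height, 0.2 multiplicative height CV,
0.15-base size jitter, and 0.5 spurious low peaks (50–400 RFU) per profile.
All randomness flows from one mandatory seed through derived per-run
sub-seeds, so any sample/run is independently replayable.

What the generator emulates: mixed-species profiles, sampling noise,
capillary size jitter around bin centres, spurious peaks, replicate runs,
correlated environmental gradients with a known driver. What it does not:
electrophoretic trace shapes, pull-up artefacts, size-standard
miscalibration beyond a constant offset, PCR amplification bias between
taxa, and chimeras. Passing tests therefore demonstrate correctness of the
computational pipeline under its stated error model, not robustness to every
instrument artefact.

Two measured properties of the generator worth knowing:

* The rank correlation between Bray–Curtis distance and driver separation is
  **not** monotone in `gradient_strength`: Bray–Curtis saturates at 1 once
  compositions become disjoint, so extreme gradients lose rank resolution.
  The strong-signal regime used in the tests is `gradient_strength = 4`
  (median Spearman ≈ 0.85 over seeds), asserted as a median over 10 seeded
  replicates because single draws fluctuate roughly 0.73–0.94.
* With 0.3-base size jitter and tolerance-0 binning, a peak escapes its
  2-base bin with probability ≈ 9×10⁻⁴ (it must jitter a full base), and one
  escaped dominant peak moves a row by L1 ≈ twice its abundance. Binning
  jittered sizes with the ±1-base tolerance removes this failure mode
  (escape would need 1.5 bases ≈ 5σ); the round-trip error is then bounded
  well under 0.05 per row, as the tests measure over 100 seeded runs.

## Reproducibility of the published reference tables

The package ships the three printed reference tables as fixtures
(`arisa_fixtures()`): the 16-bin fragment table, the 27-row diversity table
and the 22-station environmental table. Two reproduction limits are inherent
to the printed data and are deliberately left visible as failing
expectations in the acceptance tests rather than papered over:

* **Station correlations.** The published Spearman matrix was evidently
  computed over all 27 ARISA samples, including two stations whose
  environmental rows are not printed (dissolved Fe was not measured there)
  and three stations sampled in duplicate. From the 22 printed rows, five of
  the ten published coefficients reproduce within ±0.03; the remaining five
  deviate by 0.034–0.082 (worst: depth–fluorescence). Replicating the
  duplicated stations or dropping the tie correction both worsen agreement,
  so the printed rows simply under-determine the published matrix.
* **Evenness identity.** The printed \(H'\) values carry ±0.005 rounding;
  dividing by \(\log_{10} S\) (as small as 0.30 at \(S = 2\)) propagates up
  to ±0.017 of it. Recomputing \(J'\) from printed \(H'\) and \(S\) agrees
  to ±0.005 for 17 of 27 rows (including the three spot-check stations 7,
  32 and 26) and to within the propagated rounding bound for all 27; the
  strict ±0.005 full-table expectation fails at a maximum deviation of
  0.0104, exactly as interval arithmetic predicts.

## Problem sizes used in the test suite

Simulation-based checks run at deliberately modest sizes chosen as
representative of the assay (6–20 samples, 8–16 bins, 99 permutations, 100
replicate searches, 500 null trials for the p-value calibration); all are
package choices balancing statistical resolution against a comfortably fast
check, and each is stated in the corresponding test.

## Known limitations

* No thermodynamic primer evaluation (melting temperature, dimers) and no
  chimera handling; binding is sequence-combinatorial only.
* The tool starts from sized peak tables; raw `.fsa` traces and
  size-standard fitting are out of scope.
* No rarefaction or richness estimators: ARISA peak data do not support
  them.
* Relative peak height is a within-sample proxy; nothing here estimates
  absolute abundance, and cross-taxon amplification bias is unmodelled.
* The greedy subset search is heuristic; exhaustive mode is authoritative
  for k ≤ 15.
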