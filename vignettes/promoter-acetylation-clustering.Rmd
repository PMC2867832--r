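---
title: "Clustering promoters by surrounding acetylation profiles: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustering promoters by surrounding acetylation profiles: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promacet)
```

# The model

`promacet` treats a core promoter's chromatin neighbourhood as a shape.
The input signal is a tiling-array ChIP-chip track: each 25 bp probe
carries, per biological replicate, a p-value from a one-sided Wilcoxon
rank-sum test of immunoprecipitated against control hybridization
intensities. The analysis chain is:

1. **Score transform.** `s = -10 log10(p)`, so p = 0.01 scores 20 and an
   unenriched probe (p = 1) scores 0. Replicates are averaged on the
   score scale, which is identical to taking the geometric mean of the
   replicate p-values first — the same identity makes the metagene
   histogram (arithmetic mean of scores per bin) equal to the
   transformed geometric-mean p-value per bin.
2. **Binning.** The window `[rep − 2200, rep + 2200)` around the
   representative TSS is split into 11 left-closed bins of 400 bp. A
   probe belongs to the bin containing its integer midpoint
   `floor((start + end)/2)` — the track format does not define "the"
   probe position, so the package fixes one. A bin's value is the mean
   score of its probes. For minus-strand promoters the vector is
   reversed, so index 1 is always the 5'-most bin.
3. **Cumulative normalization.** Scores are accumulated 5'→3' and scaled
   to end at 1. Amplitude cancels; only where the signal mass sits
   remains. An all-zero profile carries no shape information and receives
   the uniform CDF `(1/11, …, 1)`, keeping every pairwise distance
   defined while making the promoter maximally shape-neutral.
4. **Kolmogorov distance and PAM.** Promoter pairs are compared by
   `max_i |F_i(a) − F_i(b)|` ∈ [0, 1]; the all-pairs matrix is clustered
   with k-medoids (k = 3). PAM is implemented as deterministic
   BUILD + SWAP: BUILD picks the 1-median first, then greedily the point
   with the largest total nearest-distance gain; SWAP repeatedly applies
   the best strictly-improving medoid/non-medoid exchange. All ties
   break to the lowest point index, so results are reproducible without
   a random seed.
5. **Labelling.** Each cluster's mean binned profile has a center of
   mass `c = Σ i·s_i / Σ s_i` over bin indices; clusters ranked by `c`
   become upstream < centered < downstream. The published analysis
   labelled clusters by visual inspection of the cluster histograms;
   ranking by center of mass automates the same semantics and is the one
   invented step in the clustering chain. Ties (degenerate in practice)
   resolve toward the lower cluster index and are flagged.

## Filtering

Two confounders are removed before profiling. First, any promoter with
another promoter — same or opposite strand — within 2,200 bp (inclusive)
of its representative position is discarded *together with* that
neighbour, because the window signal of proximal promoters cannot be
decomposed; this implicitly removes bidirectional promoters. Second,
each retained promoter must have at least one probe midpoint in every
one of its 11 bins; tiling arrays leave gaps over repetitive sequence,
and a silent empty bin would distort the cumulative shape. A window
running off the chromosome is dropped with reason `"edge"`.

The window constant deserves a note: the source analysis states both a
"4,000 bp window" and "±2,200 bp with eleven 400 bp bins". The
arithmetic (11 × 400 = 4,400) wins; both the radius and the bin geometry
are parameters (`pipeline_config()`), so the 2,000 bp reading is one
argument away.

# Parameters

| parameter | default | units | why |
|---|---|---|---|
| `radius` | 2200 | bp | half of the 11 × 400 bp window; inclusive threshold (conservative reading of "neighbourhood") |
| `n_bins`, `bin_size` | 11, 400 | —, bp | profile geometry; 400 bp ≈ two nucleosomes + linker, 11 bins keep the TSS bin centered |
| `k` | 3 | — | the three shape classes; exposed for exploration |
| `tata_threshold` | 0.75 | relative score | "greater than 75% confidence", strict |
| `annotation_window` | (300, 1000) | bp | gene/lincRNA starts in strand-relative [−300, +1000], closed ends |
| `tata_window` | (50, 15) | bp | TATA scan window [−50, −15] on the promoter strand |
| `arch_window_nt`, `arch_share` | 4, 0.5 | nt, share | single-peak rule: ≥50% of tags in ≤4 nt, threshold inclusive |
| `tier_fraction` | 0.10 | share | bottom/top 10% by tpm; exact sizes `floor(0.1 n)`, ties broken by id |

PWM scanning converts the count matrix to log-odds with pseudocount 0.8
per cell and a uniform 0.25 background — standard motif-scanning
constants, fixed because the source does not state them. The relative
score `(S − S_min)/(S_max − S_min)` is invariant under affine rescaling
of the matrix, which the tests assert. The packaged TATA matrix
(`inst/extdata/tata_box_synthetic.pfm`) is a *synthetic* TATA-box-like
matrix built from the canonical consensus, not a database motif: the
package must not redistribute third-party matrices, and any JASPAR-style
matrix can be supplied via `read_pfm()`.

Probe-level p-values can also be recomputed from raw intensities with
`assign_probe_pvalues()`. The pooling window is not stated in the source;
the package pools intensities of probes within ±300 bp of the target
probe's midpoint (configurable), which gives the rank-sum test ≥ 2 × 17
values at the default tiling density.

# The synthetic generator

`synth_config()` describes a stated world emulating the real inputs:

* 25 bp probes every 35 bp, two biological replicates;
* three planted signal-shape archetypes anchored at the representative
  TSS (strand-mirrored): *upstream* — one Gaussian bump at −600 bp
  (sd 400); *centered* — bumps at −400 (sd 300, amplitude 0.6) and
  +600 bp (sd 400, amplitude 1.0) with a depletion term at the TSS,
  reproducing the classic bimodal pattern with the stronger 3' peak;
  *downstream* — one bump at +800 bp (sd 500). The geometry is invented
  to match the three published cluster histograms, which is all the
  source provides. Every archetype sits on a flat local pedestal (0.25 of
  the amplitude, within ±2,400 bp), mimicking the broad acetylation
  domain around active promoters and guaranteeing that expression-tier
  amplitude ordering is visible in every bin;
* per-tier amplitudes 5 / 15 / 60 score units (peak p of roughly 10^-0.6
  to 10^-6) and per-probe, per-replicate Gaussian score noise
  `noise_sd = 3` — about half an order of magnitude jitter on p, a
  modest but non-trivial array noise; probes emit
  `p = 10^(−max(0, signal + noise)/10)`, an internal convention (the
  source does not state the probe p-value distribution) with the
  property that the score transform recovers the planted signal exactly;
* promoters in slots 6,000 bp apart so that windows never overlap;
  planted proximal pairs (800–1,800 bp apart) are exactly the promoters
  the proximal filter removes; gap runs of 4–12 probes emulate
  repetitive-sequence masking at an expected 5% of probes;
* planted single-peak promoters put 60–90% of their tags on one dominant
  TSS; broad promoters spread tags near-uniformly over ≥8 TSSs spaced
  ≥6 bp, so no 4-nt window reaches 50%. Tag totals scale tpm to a
  2-million-tag library with a floor that keeps both architectures
  realizable at low expression;
* feature flags planted at rates 0.5 (CpG), 0.6 (gene), 0.25 (repeat),
  0.2 (TATA), 0.05 (lincRNA) — round numbers of the right order for a
  mammalian promoter catalogue. Qualifying elements are placed for
  flagged promoters only; unflagged promoters' TATA windows are
  resampled until their best relative score is ≤ 0.6, so the 0.75
  threshold separates cleanly. Positional features (gene, lincRNA) are
  not planted on proximal-pair members: their −300/+1,000 windows
  overlap, so independent planting would contradict the generator's own
  contract — the pairs exist to exercise the proximal filter and never
  reach feature analysis.

**What a green test does and does not establish.** The generator's world
is far friendlier than atlas-scale experimental data: shapes are exact
archetypes
plus Gaussian noise, promoters never share windows after filtering,
feature flags are independent of shape class, and there is no
cross-hybridization, copy-number structure, or array normalization
artifact. Recovery ≥ 90% here validates the pipeline's mechanics —
orientation handling, normalization, distance, clustering, labelling —
not the biological separability of real promoter classes. Conversely,
the published headline numbers (14,607 → 10,980 → 4,481 promoters;
cluster sizes 1,482/1,733/1,266; the reported p-values) require the
original dataset and are deliberately not reproduced; only the printed
concordance table is used as a worked example, since it is complete in
itself.

# Numerical choices

* **Replicate averaging** happens on the score scale. "Average signal
  intensity" is ambiguous between p and score space; score-space
  averaging equals geometric-mean p, matching the published histogram
  construction, and is asserted as an identity test to 1e-9.
* **Exact vs approximate rank statistics.** Rank-sum tests use the exact
  Mann-Whitney null distribution for tie-free samples of ≤ 25 per side,
  otherwise the tie-corrected normal approximation with continuity
  correction; an all-tied exact-path input returns p = 1 by convention.
  Kruskal-Wallis always uses the tie-corrected chi-square approximation.
* **Fisher's exact test** is two-sided by the point-probability rule
  (sum of hypergeometric probabilities ≤ observed, with a 1 + 1e-7
  relative guard against floating-point equality), the common convention.
* **PAM determinism.** BUILD is deterministic and SWAP breaks ties by
  iteration order (ascending medoid, then candidate), so no seed is
  consumed. On uniform-random cumulative profiles PAM stops in a
  swap-local optimum on roughly 8% of tiny instances — verified to be
  the *same* local optimum `cluster::pam` finds — so the
  global-optimum-rate check draws its instances from the generator's
  world (measured rate ≈ 0.97–1.0), while unconditional guarantees
  (objective ≥ brute-force optimum; swap-neighborhood optimality) are
  asserted on both distributions.
* **Degenerate inputs.** Zero-total-tag promoters are an error (the SP
  share is undefined); empty bins are an error at profiling time because
  the coverage filter must run first; `k > n` is an error and `k = n` a
  legal degenerate clustering; TATA windows off the contig or containing
  N are recorded as unscanned (`NA`) rather than false.

# Design choices where the source was open

* Probe position = integer midpoint; bins left-closed.
* Proximity threshold inclusive (≤ 2,200 bp), strand ignored.
* Promoter extent for overlap tests = span of its level-1 TSSs (minimum
  width 1): the core promoter *is* its tag cluster.
* Gene strand is ignored when testing "a gene starts in the window";
  the source does not restrict it. Reverse-strand TATA scanning is not
  performed — the scan window is defined on the promoter strand.
* Bonferroni m defaults to the number of feature tests in the
  invocation (3 for the architecture/CpG/gene family) and is always
  reported next to the corrected p.
* Cluster labelling by center-of-mass rank (see above).
* The chi-square association design is one 3 × 2 table per feature
  (cluster × flag), the reading consistent with "each of the three
  features has a significant distribution among the three clusters".

# Known limitations

* The pipeline consumes level-3 promoter tables; the upstream CAGE tag
  clustering that produces them is out of scope.
* No array normalization: probe p-values or raw intensities are taken
  as given. CEL-level processing and bigWig input are unsupported.
* `k` is fixed per run; there is no model-selection machinery
  (silhouette, gap statistic) because the three-class structure is the
  object of study, not a free parameter to optimize.
* The synthetic world models neither correlated noise along the array
  nor feature-shape dependence, so association tests on synthetic data
  are calibration checks (null behaviour), not power studies.
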