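# promacet

Clustering core promoters by the spatial distribution of surrounding
histone-acetylation signal.

## The problem

Histone H3 lysine 9 acetylation (H3K9ac) marks open chromatin at actively
initiated promoters. Around an individual transcription start site (TSS)
the acetylation signal is not always the textbook bimodal bump: it may sit
mostly 5' (upstream) of the TSS, straddle it, or sit mostly 3'
(downstream). `promacet` classifies CAGE-defined core promoters by this
spatial pattern and asks how the resulting classes relate to promoter
architecture and genomic context. It is written for regulatory-genomics
analyses that combine a CAGE promoter catalogue (level-3 tag clusters with
a representative TSS) with tiling-array ChIP-chip p-values for a
chromatin mark or polymerase.

## Method

For each promoter, probe-level p-values `p` become enrichment scores
`s = -10 log10(p)` and biological replicates are averaged on the score
scale (equivalently, the geometric mean of the replicate p-values). The
±2,200 bp window around the representative TSS is cut into 11 bins of
400 bp; the mean probe score per bin, read 5'→3' in promoter orientation,
gives the binned profile `s_1..s_11`. Its normalized cumulative form

    F_i = (s_1 + … + s_i) / (s_1 + … + s_11)

discards amplitude and keeps shape. Any two promoters are compared by the
Kolmogorov distance `D(a, b) = max_i |F_i(a) - F_i(b)|`, and the all-pairs
distance matrix is partitioned with k-medoids (PAM, deterministic
BUILD + SWAP) into k = 3 clusters, labelled **upstream / centered /
downstream** by the rank of each cluster's mean-profile center of mass.

Before profiling, two filters remove confounded promoters: any promoter
with another promoter (either strand) within ±2,200 bp is discarded
together with its neighbour, and every remaining promoter must have at
least one probe in each of its 11 bins (tiling arrays skip repetitive
sequence).

The clusters are then associated with per-promoter features:

* **architecture** — single peak (SP) if a ≤4-nt window holds ≥50% of the
  promoter's CAGE tags, else broad (BR);
* **CpG island / repeat overlap** of the promoter's level-1 span;
* **gene / lincRNA annotation** — a start inside the strand-relative
  −300/+1,000 bp window;
* **TATA box** — PWM scan of the −50/−15 window at >75% relative score;
* **expression tiers** — bottom/top 10% by tags-per-million.

Association tests: Pearson chi-square, Fisher's exact (two-sided,
point-probability rule) with Bonferroni correction, Kruskal-Wallis and
Wilcoxon rank-sum (tie-corrected, exact for small samples).

A synthetic-data module generates promoter tables, probe tracks (25 bp
probes every 35 bp), annotation intervals and genome sequence with
planted ground truth — signal-shape classes, SP/BR architectures,
feature flags, proximal pairs, coverage gaps — so the whole pipeline is
testable without any external download.

## Worked example

```r
library(promacet)
report <- run_synthetic_pipeline(synth_config(n_promoters = 300, seed = 7))
print(report)
#> filter_report: 300 -> 270 (proximal) -> 264 (coverage)
#> cluster_result: k = 3, objective = 7.8029
#>   upstream   centered downstream
#>         91         94         79
#> pearson_chi_square: statistic = 0.66, df = 2, p = 0.719 (Bonferroni x3: 1)
#> ...
planted_class_recovery(report)
#> [1] 0.9848485
round(metagene_histogram(report$profiles)$score, 2)
#>  [1]  5.98  6.36  8.62 14.35 16.70 12.68 17.55 19.30 13.75  8.44  6.46
```

Reading the output: of 300 synthetic promoters, 30 are dropped as
proximal pairs and 6 more for probe-coverage gaps; the 264 survivors
cluster into three labelled classes of comparable size, and 98.5% of
them land in the cluster matching their planted shape class. The
metagene histogram (bins −2,200…+2,200 bp, 5'→3') shows the mixture of
the three planted archetypes: elevated signal both sides of the TSS with
the stronger mass 3' of it. The chi-square/Fisher p-values are
non-significant here because the synthetic generator plants feature
flags independently of the shape class — the test machinery is exercised,
not a biological association.

On file-based inputs, use the readers plus `run_pipeline()`:

```r
promoters <- read_promoters("promoters.tsv")
track     <- read_probe_track("probes.tsv")
ann <- list(cpg = read_intervals("cpg.bed"),
            repeats = read_intervals("repeats.bed"),
            genes = read_genes("genes.tsv"),
            lincrna = read_intervals("lincrna.bed"),
            genome = read_genome("genome.fa"))
report <- run_pipeline(promoters, track, ann, pipeline_config(k = 3))
write_run_report(report, "report.json")
```

A small command-line front end lives at `inst/cli/promacet.R`
(`synth` and `run` subcommands).

## Vignette

`vignettes/promoter-acetylation-clustering.Rmd` documents the model,
every tunable constant, what the synthetic generator does and does not
emulate, and the package's numerical and design choices.
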