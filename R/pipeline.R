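# End-to-end orchestration: synthesize (or load) inputs, filter, build
# profiles, cluster, annotate, run the association statistics, and return
# a run report with provenance. Also the two-time-point concordance
# comparison.

#' Pipeline configuration
#'
#' Centralizes every analysis constant as a named, defaulted parameter.
#'
#' @param radius proximal-filter half-width in bp (default 2200).
#' @param n_bins,bin_size profile window geometry (defaults 11, 400).
#' @param k number of clusters (default 3).
#' @param tata_threshold TATA relative-score threshold (default 0.75).
#' @param annotation_window `c(upstream, downstream)` for the gene /
#'   lincRNA windows (default `c(300, 1000)`).
#' @param tata_window `c(upstream, downstream)` for the TATA scan window
#'   (default `c(50, 15)`).
#' @param tier_fraction expression-tier fraction (default 0.10).
#' @param timepoint tpm column used for expression (default `"tpm_0h"`).
#' @param arch_window_nt,arch_share single-peak rule: window width and
#'   minimum expression share (defaults 4 nt, 0.5).
#' @param seed RNG seed for synthetic-data generation (default 1).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(radius = 2200, n_bins = 11, bin_size = 400,
                            k = 3, tata_threshold = 0.75,
                            annotation_window = c(300, 1000),
                            tata_window = c(50, 15),
                            tier_fraction = 0.10, timepoint = "tpm_0h",
                            arch_window_nt = 4, arch_share = 0.5,
                            seed = 1) {
  cfg <- list(radius = radius, n_bins = n_bins, bin_size = bin_size, k = k,
              tata_threshold = tata_threshold,
              annotation_window = annotation_window,
              tata_window = tata_window, tier_fraction = tier_fraction,
              timepoint = timepoint, arch_window_nt = arch_window_nt,
              arch_share = arch_share, seed = as.integer(seed))
  stopifnot(radius > 0, n_bins > 0, bin_size > 0, k >= 1,
            tata_threshold > 0, tier_fraction > 0, tier_fraction < 0.5,
            length(annotation_window) == 2, length(tata_window) == 2)
  structure(cfg, class = "pipeline_config")
}

#' Run the full analysis on one promoter set / probe track
#'
#' Filters (proximal then bin coverage), builds strand-oriented binned
#' and cumulative profiles, clusters with k-medoids on the Kolmogorov
#' distance matrix, labels the clusters, annotates features when
#' annotation inputs are given, and computes the association statistics
#' (per-feature chi-square over the three clusters, Fisher's exact for
#' SP x TATA, Kruskal-Wallis of expression across clusters, Wilcoxon
#' rank-sum SP vs BR, expression tiers and per-tier repeat fractions).
#'
#' @param promoters a [promoter_table()].
#' @param track a [probe_track()].
#' @param annotations optional list with any of `cpg`, `repeats`,
#'   `genes`, `lincrna`, `genome`, `pfm` (as produced by
#'   [generate_annotations()]).
#' @param config a [pipeline_config()].
#' @return a `run_report` list: `filter_report`, `profiles`,
#'   `cumulative`, `clusters` (labelled `cluster_result`),
#'   `cluster_sizes`, `annotations` (feature table or NULL), `tests`,
#'   `tiers`, `repeat_fraction_by_tier`, `provenance`.
#' @export
run_pipeline <- function(promoters, track, annotations = NULL,
                         config = pipeline_config()) {
  filt <- filter_promoters(promoters, track, radius = config$radius,
                           n_bins = config$n_bins,
                           bin_size = config$bin_size)
  kept <- filt$promoters
  if (nrow(kept) < config$k)
    abort("only %d promoters survive filtering; cannot form %d clusters",
          nrow(kept), config$k)
  profiles <- bin_scores(kept, track, n_bins = config$n_bins,
                         bin_size = config$bin_size)
  cumulative <- cumulative_normalize(profiles)
  dm <- build_distance_matrix(cumulative)
  clusters <- label_clusters(k_medoids(dm, k = config$k), profiles)
  ann <- NULL
  tests <- list()
  tiers <- NULL
  rep_frac <- NULL
  if (!is.null(annotations)) {
    ann <- annotate_promoters(
      kept,
      cpg = annotations$cpg, repeats = annotations$repeats,
      genes = annotations$genes, lincrna = annotations$lincrna,
      genome = annotations$genome, pfm = annotations$pfm,
      tata_threshold = config$tata_threshold)
    if (!is.null(clusters$labels)) {
      feats <- c("architecture", "cpg", "gene")
      m <- length(feats)
      for (f in feats)
        tests[[paste0("chisq_", f)]] <-
          chi_square_test(feature_by_cluster_table(clusters, ann, f), m = m)
      tests$chisq_repeat <-
        chi_square_test(feature_by_cluster_table(clusters, ann, "repeat"),
                        m = 1)
      sp_tata <- table(factor(ann$architecture, c("SP", "BR")),
                       factor(ann$tata, c(TRUE, FALSE)))
      if (all(rowSums(sp_tata) > 0) && all(colSums(sp_tata) > 0))
        tests$fisher_sp_tata <- fisher_exact(matrix(as.integer(sp_tata), 2),
                                             m = 1)
    }
  }
  tpm <- kept[[config$timepoint]]
  if (!is.null(clusters$labels)) {
    groups <- split(tpm, clusters$labelled_assignment[kept$id])
    tests$kw_expression_clusters <- kruskal_wallis(groups)
  }
  if (!is.null(ann)) {
    arch <- split(tpm, ann$architecture)
    if (length(arch) == 2L)
      tests$ranksum_expression_sp_br <-
        wilcoxon_rank_sum(arch$SP, arch$BR)
  }
  tiers <- expression_tiers(kept, timepoint = config$timepoint,
                            fraction = config$tier_fraction)
  if (!is.null(ann) && !all(is.na(ann$repeat_flag)))
    rep_frac <- repeat_fraction_by_tier(tiers, ann)
  provenance <- list(
    config_hash = content_hash(paste(deparse(unclass(config)),
                                     collapse = "")),
    n_input = filt$report$n_input,
    package_version = as.character(utils::packageVersion("promacet")))
  structure(list(filter_report = filt$report, promoters = kept,
                 profiles = profiles, cumulative = cumulative,
                 clusters = clusters,
                 cluster_sizes = cluster_sizes(clusters),
                 annotations = ann, tests = tests, tiers = tiers,
                 repeat_fraction_by_tier = rep_frac,
                 provenance = provenance),
            class = "run_report")
}

#' Run the pipeline end-to-end on synthetic data
#'
#' Convenience wrapper: generates the synthetic dataset, runs
#' [run_pipeline()], and attaches the planted truth for recovery checks.
#'
#' @param synth a [synth_config()].
#' @param config a [pipeline_config()].
#' @return a `run_report` with an extra `truth` element.
#' @export
run_synthetic_pipeline <- function(synth = synth_config(),
                                   config = pipeline_config()) {
  ds <- generate_synthetic_dataset(synth)
  report <- run_pipeline(ds$promoters, ds$track, ds$annotations, config)
  report$truth <- ds$truth
  report
}

#' Agreement between recovered cluster labels and planted shape classes
#'
#' @param report a `run_report` from [run_synthetic_pipeline()].
#' @return fraction of clustered promoters whose label equals the
#'   planted class.
#' @export
planted_class_recovery <- function(report) {
  la <- report$clusters$labelled_assignment
  truth <- report$truth
  planted <- truth$shape_class[match(names(la), truth$id)]
  mean(la == planted)
}

#' Compare two runs of the pipeline (e.g. two time points)
#'
#' Computes the per-promoter cluster agreement after the best matching
#' of cluster labels between the two runs (all 3! label permutations are
#' tried; labelled runs start from the identity since labels are already
#' semantic), plus the concordance table.
#'
#' @param a,b `run_report`s over the same promoter universe.
#' @return list with `agreement` (fraction of promoters in matched
#'   clusters), `matching` (label map b -> a), `table` (cross
#'   tabulation).
#' @export
compare_timepoints <- function(a, b) {
  ga <- cluster_groups(a$clusters)
  gb <- cluster_groups(b$clusters)
  if (!setequal(names(ga), names(gb)))
    abort("compare_timepoints: promoter universes differ")
  gb <- gb[names(ga)]
  lev <- cluster_levels(a$clusters)
  perms <- perm3(cluster_levels(b$clusters))
  best <- NULL
  for (p in perms) {
    mapped <- setNames(lev, p)[gb]
    agree <- mean(mapped == ga)
    if (is.null(best) || agree > best$agreement)
      best <- list(agreement = agree, matching = setNames(lev, p))
  }
  best$table <- cross_tabulate_clusterings(a$clusters, b$clusters)
  best
}

#' @noRd
perm3 <- function(x) {
  if (length(x) == 1L) return(list(x))
  out <- list()
  for (i in seq_along(x))
    for (rest in perm3(x[-i])) out[[length(out) + 1L]] <- c(x[i], rest)
  out
}

#' Serialize a run report's summary as JSON
#'
#' @param report a `run_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_run_report <- function(report, path) {
  summary <- list(
    filter = list(n_input = report$filter_report$n_input,
                  n_after_proximal = report$filter_report$n_after_proximal,
                  n_after_coverage = report$filter_report$n_after_coverage),
    cluster_sizes = as.list(report$cluster_sizes),
    objective = report$clusters$objective,
    tests = lapply(report$tests, function(t)
      list(test = t$test, statistic = t$statistic, df = t$df, p = t$p,
           p_bonferroni = t$p_bonferroni, m = t$m)),
    repeat_fraction_by_tier = as.list(report$repeat_fraction_by_tier),
    provenance = report$provenance)
  jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @export
print.run_report <- function(x, ...) {
  print(x$filter_report)
  print(x$clusters)
  if (length(x$tests)) for (t in x$tests) print(t)
  invisible(x)
}
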