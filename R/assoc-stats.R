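# Contingency-table and rank statistics tying cluster membership to
# promoter features: Pearson chi-square, Fisher's exact (two-sided, sum
# of hypergeometric point probabilities), Bonferroni correction,
# Kruskal-Wallis and Wilcoxon rank-sum, plus the 10%/80%/10% expression
# tiers and per-tier repeat fractions.

#' Feature-by-cluster contingency table
#'
#' @param result a labelled `cluster_result` (see [label_clusters()]).
#' @param annotations feature table from [annotate_promoters()].
#' @param feature one of `"architecture"`, `"cpg"`, `"gene"`, `"lincrna"`,
#'   `"repeat"` (binary overlap), `"repeat_class"` (one column per class,
#'   unflagged promoters excluded), `"tata"`.
#' @return integer matrix, rows = cluster labels, columns = feature
#'   categories.
#' @export
feature_by_cluster_table <- function(result, annotations, feature) {
  groups <- cluster_groups(result)
  if (!setequal(names(groups), annotations$id))
    abort("feature_by_cluster_table: promoter universes differ")
  ann <- annotations[match(names(groups), annotations$id), ]
  values <- switch(feature,
    architecture = factor(ann$architecture, levels = c("SP", "BR")),
    cpg = factor(ann$cpg, levels = c(TRUE, FALSE),
                 labels = c("cpg", "no_cpg")),
    gene = factor(ann$gene, levels = c(TRUE, FALSE),
                  labels = c("annotated", "novel")),
    lincrna = factor(ann$lincrna, levels = c(TRUE, FALSE),
                     labels = c("lincrna", "no_lincrna")),
    "repeat" = factor(ann$repeat_flag, levels = c(TRUE, FALSE),
                      labels = c("repeat", "no_repeat")),
    repeat_class = factor(ann$repeat_class),
    tata = factor(ann$tata, levels = c(TRUE, FALSE),
                  labels = c("tata", "no_tata")),
    abort("unknown feature '%s'", feature))
  keep <- !is.na(values)
  tab <- table(factor(groups[keep], levels = cluster_levels(result)),
               values[keep])
  matrix(as.integer(tab), nrow = nrow(tab), dimnames = dimnames(tab))
}

#' Pearson chi-square test of independence
#'
#' Classic statistic `sum((O - E)^2 / E)` with expected counts from the
#' row/column marginals, `df = (r - 1)(c - 1)`, upper-tail chi-square
#' p-value. No continuity correction.
#'
#' @param table integer matrix of counts; all marginals must be positive.
#' @param m number of tests for the Bonferroni field (default 1).
#' @return a `test_result` list: `test`, `statistic`, `df`, `p`,
#'   `p_bonferroni`, `m`.
#' @export
chi_square_test <- function(table, m = 1) {
  table <- as.matrix(table)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    abort("chi_square_test: zero row or column marginal")
  n <- sum(table)
  expected <- outer(rowSums(table), colSums(table)) / n
  stat <- sum((table - expected)^2 / expected)
  df <- (nrow(table) - 1L) * (ncol(table) - 1L)
  p <- pchisq(stat, df, lower.tail = FALSE)
  test_result("pearson_chi_square", stat, df, p, m)
}

#' Fisher's exact test for a 2x2 table (two-sided)
#'
#' With margins fixed, sums the hypergeometric probabilities of all
#' tables whose point probability does not exceed that of the observed
#' table (the standard point-probability two-sided rule).
#'
#' @param table 2x2 integer matrix.
#' @param m number of tests for the Bonferroni field (default 1).
#' @return a `test_result` (df is `NA`).
#' @export
fisher_exact <- function(table, m = 1) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L)))
    abort("fisher_exact: table must be 2x2 (use chi_square_test otherwise)")
  r1 <- sum(table[1, ]); c1 <- sum(table[, 1]); n <- sum(table)
  support <- max(0L, r1 + c1 - n):min(r1, c1)
  probs <- dhyper(support, c1, n - c1, r1)
  p_obs <- dhyper(table[1, 1], c1, n - c1, r1)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  test_result("fisher_exact", table[1, 1], NA_integer_, min(1, p), m)
}

#' Bonferroni correction
#' @param p raw p-value(s).
#' @param m number of tests corrected over (>= 1).
#' @return `min(1, m * p)`.
#' @export
bonferroni <- function(p, m) {
  if (any(m < 1)) abort("bonferroni: m must be >= 1")
  pmin(1, m * p)
}

#' Kruskal-Wallis rank test across groups
#'
#' Tie-corrected H statistic with a chi-square approximation on
#' `g - 1` degrees of freedom.
#'
#' @param groups list of numeric vectors, each non-empty.
#' @param m number of tests for the Bonferroni field (default 1).
#' @return a `test_result`.
#' @export
kruskal_wallis <- function(groups, m = 1) {
  if (length(groups) < 2L || any(lengths(groups) == 0))
    abort("kruskal_wallis: need >= 2 non-empty groups")
  x <- unlist(groups, use.names = FALSE)
  n <- length(x)
  r <- rank(x)
  sizes <- lengths(groups)
  idx <- rep(seq_along(groups), sizes)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, idx, sum)^2 / sizes) - 3 * (n + 1)
  ties <- table(x)
  corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (corr > 0) h <- h / corr
  df <- length(groups) - 1L
  test_result("kruskal_wallis", h, df, pchisq(h, df, lower.tail = FALSE), m)
}

#' Wilcoxon rank-sum test between two samples
#'
#' Exact (via the null Mann-Whitney distribution) for tie-free samples of
#' at most `exact_max` per side, otherwise the tie-corrected normal
#' approximation with continuity correction.
#'
#' @param a,b numeric samples.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`
#'   (shift of `a` relative to `b`).
#' @param m number of tests for the Bonferroni field (default 1).
#' @param exact_max exact-path size limit per side (default 25).
#' @return a `test_result` whose statistic is the Mann-Whitney U of `a`.
#' @export
wilcoxon_rank_sum <- function(a, b, alternative = "two.sided", m = 1,
                              exact_max = 25) {
  if (!length(a) || !length(b))
    abort("wilcoxon_rank_sum: both samples must be non-empty")
  alternative <- match.arg(alternative, c("two.sided", "greater", "less"))
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  ties <- anyDuplicated(pooled) > 0L
  if (!ties && na <= exact_max && nb <= exact_max) {
    p_greater <- pwilcox(na * nb - u, na, nb)
    p_less <- pwilcox(u, na, nb)
    p <- switch(alternative,
                greater = p_greater, less = p_less,
                two.sided = min(1, 2 * min(p_greater, p_less)))
  } else {
    mu <- na * nb / 2
    tie_tab <- table(pooled)
    sig2 <- na * nb / 12 * ((na + nb + 1) -
      sum(tie_tab^3 - tie_tab) / ((na + nb) * (na + nb - 1)))
    if (sig2 <= 0) {
      p <- 1
    } else {
      z_hi <- (u - mu - 0.5) / sqrt(sig2)
      z_lo <- (u - mu + 0.5) / sqrt(sig2)
      p <- switch(alternative,
                  greater = pnorm(z_hi, lower.tail = FALSE),
                  less = pnorm(z_lo),
                  two.sided = min(1, 2 * min(pnorm(z_hi, lower.tail = FALSE),
                                             pnorm(z_lo))))
    }
  }
  test_result(paste0("wilcoxon_rank_sum_", alternative), u, NA_integer_, p, m)
}

#' @noRd
test_result <- function(test, statistic, df, p, m) {
  structure(list(test = test, statistic = unname(statistic), df = df,
                 p = unname(p), p_bonferroni = unname(bonferroni(p, m)),
                 m = m),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g%s, p = %.3g (Bonferroni x%d: %.3g)\n",
              x$test, x$statistic,
              if (is.na(x$df)) "" else sprintf(", df = %d", x$df),
              x$p, x$m, x$p_bonferroni))
  invisible(x)
}

#' Split promoters into low / medium / high expression tiers
#'
#' Promoters are stably sorted by `(tpm, id)`; the bottom `floor(f * n)`
#' form the low tier, the top `floor(f * n)` the high tier, the rest the
#' medium tier. Tier sizes are exact regardless of ties (ties at a cut
#' resolve by id order). Display of tiered expression conventionally uses
#' `log10(tpm + 1)` (pseudo-count of 1 tpm).
#'
#' @param promoters a [promoter_table()].
#' @param timepoint tpm column name (default `"tpm_0h"`).
#' @param fraction tier fraction (default 0.10).
#' @return an `expression_tiers` list: `tier` (named character vector
#'   id -> low/medium/high), `cuts` (tpm range per tier), `fraction`.
#' @export
expression_tiers <- function(promoters, timepoint = "tpm_0h",
                             fraction = 0.10) {
  if (!timepoint %in% names(promoters))
    abort("expression_tiers: no column '%s'", timepoint)
  n <- nrow(promoters)
  k <- floor(fraction * n)
  if (k < 1L)
    abort("expression_tiers: n = %d too small for fraction %.2f", n, fraction)
  ord <- order(promoters[[timepoint]], promoters$id)
  tier <- rep("medium", n)
  tier[ord[seq_len(k)]] <- "low"
  tier[ord[seq.int(n - k + 1L, n)]] <- "high"
  tier <- setNames(tier, promoters$id)
  cuts <- vapply(c(low = "low", medium = "medium", high = "high"),
                 function(t) range(promoters[[timepoint]][tier == t]),
                 numeric(2))
  structure(list(tier = tier, cuts = cuts, fraction = fraction,
                 timepoint = timepoint),
            class = "expression_tiers")
}

#' Fraction of promoters overlapping repeats, per expression tier
#'
#' @param tiers an [expression_tiers()] result.
#' @param annotations feature table from [annotate_promoters()].
#' @return named numeric vector (low, medium, high); `NA` for an empty
#'   tier.
#' @export
repeat_fraction_by_tier <- function(tiers, annotations) {
  ann <- annotations[match(names(tiers$tier), annotations$id), ]
  vapply(c(low = "low", medium = "medium", high = "high"), function(t) {
    sel <- tiers$tier == t
    if (!any(sel)) return(NA_real_)
    mean(ann$repeat_flag[sel])
  }, numeric(1))
}
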