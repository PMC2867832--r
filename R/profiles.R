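# Probe p-values -> scores -> strand-oriented binned profiles ->
# normalized cumulative profiles, plus metagene histograms.
#
# Score scale: s = -10 * log10(p), so p = 0.01 scores 20 and p = 1 scores
# 0. Replicates are averaged on the score scale, which equals taking the
# geometric mean of the replicate p-values before transforming.

#' Convert ChIP-chip probe p-values to enrichment scores
#'
#' @param p numeric vector of p-values in (0, 1]; `NA` passes through.
#' @return `-10 * log10(p)`, all values >= 0.
#' @export
pvalue_to_score <- function(p) {
  bad <- which(!is.na(p) & (p <= 0 | p > 1))
  if (length(bad))
    abort("p-values must lie in (0,1]; element %d is %g", bad[1], p[bad[1]])
  -10 * log10(p)
}

#' One-sided Wilcoxon rank-sum p-value for probe enrichment
#'
#' Tests whether treatment (ChIP) hybridization intensities are shifted
#' above control intensities. Exact when the pooled sample is small and
#' tie-free; otherwise the normal approximation with tie correction.
#' When every pooled value is identical the exact path returns 1 by
#' convention (no evidence of a shift).
#'
#' @param treatment,control numeric intensity vectors (each non-empty).
#' @param exact_max use the exact null distribution when both sides have
#'   at most this many values and there are no ties (default 25).
#' @return one-sided p-value, P(rank sum >= observed) under the null.
#' @export
rank_sum_pvalue <- function(treatment, control, exact_max = 25) {
  if (!length(treatment) || !length(control))
    abort("rank_sum_pvalue: both sides need at least one value")
  n <- length(treatment); m <- length(control)
  pooled <- c(treatment, control)
  ties <- anyDuplicated(pooled) > 0L
  if (!ties && n <= exact_max && m <= exact_max) {
    r <- rank(pooled)
    w <- sum(r[seq_len(n)]) - n * (n + 1) / 2   # Mann-Whitney U
    # P(U >= w) = P(U <= n*m - w) by symmetry of the exact null
    return(pwilcox(n * m - w, n, m))
  }
  if (all(pooled == pooled[1])) return(1)
  r <- rank(pooled)
  w <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  mu <- n * m / 2
  tie_tab <- table(pooled)
  sig2 <- n * m / 12 * ((n + m + 1) -
    sum(tie_tab^3 - tie_tab) / ((n + m) * (n + m - 1)))
  if (sig2 <= 0) return(1)
  # continuity-corrected upper tail
  pnorm((w - mu - 0.5) / sqrt(sig2), lower.tail = FALSE)
}

#' Assign per-probe p-values from raw intensities
#'
#' For each probe, treatment and control intensities of all probes whose
#' midpoint lies within `window_bp` of the probe's midpoint (on the same
#' chromosome) are pooled and compared by a one-sided Wilcoxon rank-sum
#' test ([rank_sum_pvalue()]). The resulting p-value is stored as a single
#' `p_1` replicate column unless the intensity columns are split by
#' biological replicate (`treat_<rep>_*`), in which case one p column per
#' replicate is produced.
#'
#' @param track a [probe_track()] with `treat_*` / `ctrl_*` columns.
#' @param window_bp half-width of the pooling window (default 300).
#' @return a `probe_track` with refreshed `p_*` columns.
#' @export
assign_probe_pvalues <- function(track, window_bp = 300) {
  tcols <- grep("^treat_", names(track), value = TRUE)
  ccols <- grep("^ctrl_", names(track), value = TRUE)
  if (!length(tcols) || !length(ccols))
    abort("assign_probe_pvalues: track has no treat_*/ctrl_* columns")
  reps <- sort(unique(sub("^treat_([0-9]+)_.*$", "\\1", tcols)))
  mids <- probe_midpoints(track)
  pv <- matrix(NA_real_, nrow(track), length(reps))
  for (ch in unique(track$chrom)) {
    idx <- which(track$chrom == ch)
    mch <- mids[idx]
    for (j in seq_along(idx)) {
      in_win <- idx[abs(mch - mch[j]) <= window_bp]
      for (r in seq_along(reps)) {
        tc <- grep(sprintf("^treat_%s_", reps[r]), names(track), value = TRUE)
        cc <- grep(sprintf("^ctrl_%s_", reps[r]), names(track), value = TRUE)
        tv <- unlist(track[in_win, tc], use.names = FALSE)
        cv <- unlist(track[in_win, cc], use.names = FALSE)
        tv <- tv[!is.na(tv)]; cv <- cv[!is.na(cv)]
        if (length(tv) && length(cv))
          pv[idx[j], r] <- max(rank_sum_pvalue(tv, cv), 1e-300)
      }
    }
  }
  out <- track[, !grepl("^p_[0-9]+$", names(track)), drop = FALSE]
  for (r in seq_along(reps)) out[[paste0("p_", r)]] <- pv[, r]
  class(out) <- c("probe_track", "data.frame")
  validate_probe_track(out)
}

#' Average replicate p-values into one score per probe
#'
#' Each replicate p-value becomes a score via [pvalue_to_score()]; the
#' per-probe signal is the arithmetic mean of the available replicate
#' scores (equivalently, minus ten times the log10 geometric-mean
#' p-value). Probes with no replicate measurement get `NA` and surface
#' later as coverage gaps, never as an imputed zero.
#'
#' @param track a [probe_track()].
#' @return numeric vector of per-probe scores (NA where unmeasured).
#' @export
average_replicates <- function(track) {
  pc <- pvalue_columns(track)
  scores <- vapply(pc, function(cn) pvalue_to_score(track[[cn]]),
                   numeric(nrow(track)))
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = nrow(track))
  rowMeans(scores, na.rm = TRUE) -> m
  m[is.nan(m)] <- NA_real_
  m
}

#' Bin per-probe scores around each promoter, strand-oriented
#'
#' The window `[rep - n_bins*bin_size/2, rep + n_bins*bin_size/2)` is cut
#' into `n_bins` left-closed bins; a bin's value is the mean score of the
#' probes whose midpoint falls inside. For minus-strand promoters the
#' genomic bin vector is reversed so index 1 is always the 5'-most bin.
#' Promoters must already pass [filter_bin_coverage()]; an empty bin is
#' an error here.
#'
#' @param promoters a [promoter_table()].
#' @param track a [probe_track()].
#' @param n_bins,bin_size window geometry (defaults 11 x 400 bp).
#' @param scores optional precomputed per-probe scores (from
#'   [average_replicates()]); computed on the fly when omitted.
#' @return a `binned_profiles` object: numeric matrix (promoters x bins,
#'   rownames = promoter ids) with attributes `n_bins`, `bin_size`,
#'   `strand`.
#' @export
bin_scores <- function(promoters, track, n_bins = 11, bin_size = 400,
                       scores = NULL) {
  if (is.null(scores)) scores <- average_replicates(track)
  half <- n_bins * bin_size / 2
  mids <- probe_midpoints(track)
  keep <- !is.na(scores)
  by_chrom <- split(data.frame(mid = mids[keep], score = scores[keep]),
                    track$chrom[keep])
  out <- matrix(NA_real_, nrow(promoters), n_bins,
                dimnames = list(promoters$id, NULL))
  for (i in seq_len(nrow(promoters))) {
    d <- by_chrom[[promoters$chrom[i]]]
    lo <- promoters$rep_pos[i] - half
    if (is.null(d)) abort("promoter '%s': no probes on its chromosome",
                          promoters$id[i])
    inwin <- d$mid >= lo & d$mid < lo + n_bins * bin_size
    bin <- (d$mid[inwin] - lo) %/% bin_size
    v <- vapply(seq_len(n_bins) - 1L, function(b) {
      s <- d$score[inwin][bin == b]
      if (!length(s))
        abort("promoter '%s': bin %d holds no probe (run filter_bin_coverage first)",
              promoters$id[i], b + 1L)
      mean(s)
    }, numeric(1))
    if (promoters$strand[i] == "-") v <- rev(v)
    out[i, ] <- v
  }
  structure(out, n_bins = n_bins, bin_size = bin_size,
            strand = setNames(promoters$strand, promoters$id),
            class = c("binned_profiles", "matrix", "array"))
}

#' Normalized cumulative profiles (5' to 3')
#'
#' Bin scores are accumulated from the 5'-most to the 3'-most bin and
#' scaled so the final value is 1. A promoter whose bins are all zero has
#' no shape information; it receives the uniform cumulative profile
#' `(1/n, 2/n, ..., 1)` so the Kolmogorov distance stays defined and the
#' promoter is maximally shape-neutral.
#'
#' @param profiles a `binned_profiles` matrix from [bin_scores()].
#' @return a `cumulative_profiles` matrix of the same shape; each row is
#'   non-decreasing, within \[0, 1\], ending at 1.
#' @export
cumulative_normalize <- function(profiles) {
  if (any(profiles < 0, na.rm = TRUE))
    abort("binned scores must be non-negative")
  n <- ncol(profiles)
  out <- t(apply(profiles, 1L, function(v) {
    tot <- sum(v)
    if (tot == 0) seq_len(n) / n else cumsum(v) / tot
  }))
  dimnames(out) <- dimnames(profiles)
  structure(out, n_bins = attr(profiles, "n_bins"),
            bin_size = attr(profiles, "bin_size"),
            class = c("cumulative_profiles", "matrix", "array"))
}

#' Metagene histogram: aggregate binned signal over a promoter set
#'
#' Averages the strand-oriented bin vectors of all promoters, yielding the
#' classic TSS-anchored histogram (negative coordinates are 5' of the
#' representative position). Averaging scores arithmetically equals
#' taking the geometric mean of the underlying p-values and transforming,
#' since the score is a log of p.
#'
#' @param profiles a `binned_profiles` matrix.
#' @param aggregate aggregation function over promoters per bin
#'   (default `mean`).
#' @return data.frame with `bin_start`, `bin_end` (bp relative to the
#'   representative position, 5' negative) and `score`.
#' @export
metagene_histogram <- function(profiles, aggregate = mean) {
  if (!nrow(profiles)) abort("metagene_histogram: empty promoter set")
  n_bins <- ncol(profiles)
  bin_size <- attr(profiles, "bin_size") %||% 400
  half <- n_bins * bin_size / 2
  data.frame(bin_start = -half + bin_size * (seq_len(n_bins) - 1L),
             bin_end = -half + bin_size * seq_len(n_bins),
             score = apply(profiles, 2L, aggregate))
}
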