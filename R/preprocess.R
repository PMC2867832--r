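# Two-stage promoter filtering: (1) drop every promoter with another
# promoter within +/- radius of its representative position (both members
# of a proximal pair go, on either strand — this also removes bidirectional
# promoters); (2) keep only promoters whose +/- (n_bins*bin_size/2) window
# has at least one probe midpoint in every bin.

#' Remove proximal promoters
#'
#' A promoter is discarded when any other promoter — same or opposite
#' strand — has its representative position within `radius` bp on the
#' same chromosome (inclusive threshold). Both members of every proximal
#' pair are removed, so the retained windows carry the ChIP signal of a
#' single promoter only.
#'
#' @param promoters a [promoter_table()].
#' @param radius neighbourhood half-width in bp (default 2200, half of the
#'   11 x 400 bp profile window).
#' @return list with `promoters` (retained subset) and `report`
#'   (a `filter_report`: counts plus removed ids with reasons).
#' @export
filter_proximal <- function(promoters, radius = 2200) {
  n <- nrow(promoters)
  prox <- logical(n)
  for (ch in unique(promoters$chrom)) {
    idx <- which(promoters$chrom == ch)
    ord <- idx[order(promoters$rep_pos[idx])]
    pos <- promoters$rep_pos[ord]
    if (length(pos) > 1L) {
      gap_left <- c(Inf, diff(pos))
      gap_right <- c(diff(pos), Inf)
      prox[ord] <- gap_left <= radius | gap_right <= radius
    }
  }
  keep <- promoters[!prox, , drop = FALSE]
  report <- filter_report(
    n_input = n, n_after_proximal = nrow(keep), n_after_coverage = NA_integer_,
    removed = data.frame(id = promoters$id[prox],
                         reason = rep("proximal", sum(prox)),
                         stringsAsFactors = FALSE))
  list(promoters = keep, report = report)
}

#' Keep promoters with probe coverage in every bin
#'
#' The window `[rep - n_bins*bin_size/2, rep + n_bins*bin_size/2)` around
#' each representative position is split into `n_bins` equal bins; a
#' promoter is retained only if every bin contains at least one probe
#' midpoint (probes lost to repetitive regions leave gaps). A window that
#' runs off the chromosome is dropped with reason `"edge"`.
#'
#' @param promoters a [promoter_table()].
#' @param probes a [probe_track()].
#' @param n_bins number of bins (default 11).
#' @param bin_size bin width in bp (default 400).
#' @param chrom_lengths optional named vector of chromosome lengths; when
#'   omitted, the maximal probe end per chromosome is used as its length.
#' @return list with `promoters` and `report` as in [filter_proximal()].
#' @export
filter_bin_coverage <- function(promoters, probes, n_bins = 11,
                                bin_size = 400, chrom_lengths = NULL) {
  half <- n_bins * bin_size / 2
  if (is.null(chrom_lengths)) {
    chrom_lengths <- tapply(probes$end, probes$chrom, max)
  }
  mids <- split(probe_midpoints(probes), probes$chrom)
  n <- nrow(promoters)
  status <- character(n)
  for (i in seq_len(n)) {
    lo <- promoters$rep_pos[i] - half
    hi <- promoters$rep_pos[i] + half
    clen <- chrom_lengths[[promoters$chrom[i]]] %||% NA_real_
    if (lo < 0 || (!is.na(clen) && hi > clen)) {
      status[i] <- "edge"
      next
    }
    m <- mids[[promoters$chrom[i]]]
    if (is.null(m)) {
      status[i] <- "coverage"
      next
    }
    m <- m[m >= lo & m < hi]
    covered <- unique((m - lo) %/% bin_size)
    status[i] <- if (length(covered) == n_bins) "ok" else "coverage"
  }
  keep <- promoters[status == "ok", , drop = FALSE]
  report <- filter_report(
    n_input = n, n_after_proximal = n, n_after_coverage = nrow(keep),
    removed = data.frame(id = promoters$id[status != "ok"],
                         reason = status[status != "ok"],
                         stringsAsFactors = FALSE))
  list(promoters = keep, report = report)
}

#' Run both filters in order and merge the bookkeeping
#'
#' @inheritParams filter_proximal
#' @inheritParams filter_bin_coverage
#' @return list with `promoters` and a merged `report` whose counts track
#'   input -> after-proximal -> after-coverage attrition.
#' @export
filter_promoters <- function(promoters, probes, radius = 2200, n_bins = 11,
                             bin_size = 400, chrom_lengths = NULL) {
  s1 <- filter_proximal(promoters, radius = radius)
  s2 <- filter_bin_coverage(s1$promoters, probes, n_bins = n_bins,
                            bin_size = bin_size,
                            chrom_lengths = chrom_lengths)
  report <- filter_report(
    n_input = s1$report$n_input,
    n_after_proximal = s1$report$n_after_proximal,
    n_after_coverage = s2$report$n_after_coverage,
    removed = rbind(s1$report$removed, s2$report$removed))
  list(promoters = s2$promoters, report = report)
}

#' @noRd
filter_report <- function(n_input, n_after_proximal, n_after_coverage,
                          removed) {
  structure(list(n_input = n_input, n_after_proximal = n_after_proximal,
                 n_after_coverage = n_after_coverage, removed = removed),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("filter_report: %d -> %d (proximal) -> %s (coverage)\n",
              x$n_input, x$n_after_proximal,
              ifelse(is.na(x$n_after_coverage), "-", x$n_after_coverage)))
  invisible(x)
}
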