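# Per-promoter architecture and genomic-context annotation: single-peak /
# broad classification from level-1 tag counts, interval overlap (CpG,
# repeats), gene / lincRNA starts in the strand-relative -300/+1000
# window, and a TATA-box PWM scan of the -50/-15 window.

#' Classify promoter architecture: single peak (SP) vs broad (BR)
#'
#' A promoter is single peak when some window of at most 4 consecutive
#' bases contains level-1 TSSs whose summed tag counts make up 50% or
#' more (inclusive) of the promoter's total tags; otherwise broad.
#'
#' @param promoters a [promoter_table()].
#' @param window_nt window width in nucleotides (default 4).
#' @param share minimum expression share in the window (default 0.5).
#' @return character vector `"SP"` / `"BR"`, one per promoter.
#' @export
classify_architecture <- function(promoters, window_nt = 4, share = 0.5) {
  vapply(seq_len(nrow(promoters)), function(i) {
    l1 <- promoters$level1[[i]]
    total <- sum(l1$tags)
    if (total <= 0) abort("promoter '%s': zero total tags", promoters$id[i])
    # an optimal window can always start at a member position
    best <- max(vapply(l1$pos, function(p)
      sum(l1$tags[l1$pos >= p & l1$pos <= p + window_nt - 1L]), numeric(1)))
    if (best / total >= share) "SP" else "BR"
  }, character(1))
}

#' Overlap of promoter extents with an interval set
#'
#' A promoter is flagged when its extent (level-1 span, see
#' [promoter_extent()]) intersects at least one interval; half-open
#' intervals, so an element ending exactly at the extent start does not
#' count. For classed elements (repeats), the class of the element with
#' the largest overlap is reported; ties break to the element earliest in
#' genomic coordinate.
#'
#' @param promoters a [promoter_table()].
#' @param elements an [interval_set()].
#' @return data.frame with `flag` (logical) and `class` (character, `NA`
#'   when unflagged).
#' @export
overlaps_element <- function(promoters, elements) {
  ext <- promoter_extent(promoters)
  flag <- logical(nrow(promoters))
  klass <- rep(NA_character_, nrow(promoters))
  for (ch in intersect(unique(ext$chrom), unique(elements$chrom))) {
    pi <- which(ext$chrom == ch)
    ei <- which(elements$chrom == ch)
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(ext$start[pi] + 1L, ext$end[pi]),
      IRanges::IRanges(elements$start[ei] + 1L, elements$end[ei]))
    if (!length(hits)) next
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    ov <- pmin(ext$end[pi][qh], elements$end[ei][sh]) -
      pmax(ext$start[pi][qh], elements$start[ei][sh])
    for (q in unique(qh)) {
      sel <- which(qh == q)
      # largest overlap wins; ties -> earliest element by coordinate
      sel <- sel[order(-ov[sel], elements$start[ei][sh[sel]])]
      flag[pi[q]] <- TRUE
      klass[pi[q]] <- elements$name[ei[sh[sel[1]]]]
    }
  }
  data.frame(flag = flag, class = klass, stringsAsFactors = FALSE)
}

#' Strand-relative annotation window around the representative position
#' @noRd
strand_window <- function(rep_pos, strand, up, down) {
  if (strand == "+") c(rep_pos - up, rep_pos + down)
  else c(rep_pos - down, rep_pos + up)
}

#' Flag promoters with a gene TSS in the -300/+1000 window
#'
#' True when at least one gene transcription start (txStart for `+`
#' genes, txEnd - 1 for `-` genes) lies within the strand-relative window
#' \[rep - 300, rep + 1000\] (both ends inclusive; reflected for
#' minus-strand promoters). Gene strand is not required to match the
#' promoter strand.
#'
#' @param promoters a [promoter_table()].
#' @param genes a [gene_table()].
#' @param upstream,downstream window bounds in bp (defaults 300 / 1000).
#' @return logical vector, one per promoter.
#' @export
gene_annotated <- function(promoters, genes, upstream = 300,
                           downstream = 1000) {
  positions_in_window(promoters, genes$chrom, genes$tss, upstream, downstream)
}

#' Flag promoters with a lincRNA start in the -300/+1000 window
#'
#' @param promoters a [promoter_table()].
#' @param lincrna_starts an [interval_set()] whose `start` column holds
#'   the lincRNA start positions (width-1 intervals).
#' @inheritParams gene_annotated
#' @return logical vector, one per promoter.
#' @export
lincrna_start <- function(promoters, lincrna_starts, upstream = 300,
                          downstream = 1000) {
  positions_in_window(promoters, lincrna_starts$chrom, lincrna_starts$start,
                      upstream, downstream)
}

#' @noRd
positions_in_window <- function(promoters, chrom, pos, upstream, downstream) {
  vapply(seq_len(nrow(promoters)), function(i) {
    w <- strand_window(promoters$rep_pos[i], promoters$strand[i],
                       upstream, downstream)
    any(chrom == promoters$chrom[i] & pos >= w[1] & pos <= w[2])
  }, logical(1))
}

#' Convert a position-frequency matrix to a log-odds weight matrix
#'
#' Adds a pseudocount to every cell, normalizes columns to probabilities
#' and takes log2 odds against a uniform 0.25 background.
#'
#' @param pfm count matrix, rows A, C, G, T.
#' @param pseudocount added per cell before normalization (default 0.8).
#' @param background per-base background probability (default 0.25).
#' @return numeric log-odds matrix of the same shape.
#' @export
pfm_to_pwm <- function(pfm, pseudocount = 0.8, background = 0.25) {
  m <- pfm + pseudocount
  probs <- sweep(m, 2L, colSums(m), `/`)
  log2(probs / background)
}

#' Relative PWM score of a sequence placement
#'
#' `(S - S_min) / (S_max - S_min)` where `S` is the summed log-odds of
#' the placed letters and `S_min`/`S_max` are the sums of per-position
#' minima/maxima. Invariant under affine rescaling of the matrix; 1 for
#' the consensus, 0 for the anti-consensus.
#'
#' @param pwm log-odds matrix (rows A, C, G, T).
#' @param seq character scalar of length `ncol(pwm)`.
#' @return relative score in \[0, 1\].
#' @export
pwm_relative_score <- function(pwm, seq) {
  letters <- strsplit(toupper(seq), "")[[1]]
  if (length(letters) != ncol(pwm))
    abort("pwm_relative_score: sequence length %d != matrix width %d",
          length(letters), ncol(pwm))
  if (!all(letters %in% rownames(pwm)))
    abort("pwm_relative_score: non-ACGT letter in '%s'", seq)
  s <- sum(pwm[cbind(match(letters, rownames(pwm)), seq_along(letters))])
  smin <- sum(apply(pwm, 2L, min))
  smax <- sum(apply(pwm, 2L, max))
  (s - smin) / (smax - smin)
}

#' Scan promoters for a TATA-box motif in the -50/-15 window
#'
#' Extracts the strand-relative window \[rep - 50, rep - 15\] (both ends
#' inclusive) on the promoter strand — for minus-strand promoters the
#' reverse complement of genomic \[rep + 15, rep + 50\] — and slides the
#' full matrix over every offset, recording the best relative score. The
#' flag is TRUE when that score strictly exceeds `rel_threshold`.
#' Windows that run off the contig or contain non-ACGT letters are left
#' unscanned (`NA` flag and score).
#'
#' @param promoters a [promoter_table()].
#' @param genome named character vector or `DNAStringSet` of chromosomes.
#' @param pfm position-frequency count matrix (rows A, C, G, T); see
#'   [read_pfm()]. The packaged synthetic TATA matrix is used by default.
#' @param rel_threshold confidence threshold (default 0.75, strict).
#' @param upstream,downstream window bounds relative to the
#'   representative position (defaults 50 / 15, i.e. \[-50, -15\]).
#' @param pseudocount passed to [pfm_to_pwm()].
#' @return data.frame with `flag` (logical, `NA` if unscanned) and
#'   `score` (best relative score).
#' @export
scan_tata <- function(promoters, genome, pfm = NULL, rel_threshold = 0.75,
                      upstream = 50, downstream = 15, pseudocount = 0.8) {
  if (is.null(pfm))
    pfm <- read_pfm(system.file("extdata", "tata_box_synthetic.pfm",
                                package = "promacet", mustWork = TRUE))
  if (methods::is(genome, "DNAStringSet")) {
    genome <- setNames(as.character(genome), names(genome))
  }
  pwm <- pfm_to_pwm(pfm, pseudocount = pseudocount)
  w <- ncol(pwm)
  flag <- rep(NA, nrow(promoters))
  score <- rep(NA_real_, nrow(promoters))
  for (i in seq_len(nrow(promoters))) {
    if (!promoters$chrom[i] %in% names(genome)) next
    chrom_seq <- genome[[promoters$chrom[i]]]
    rp <- promoters$rep_pos[i]
    if (promoters$strand[i] == "+") {
      lo <- rp - upstream; hi <- rp - downstream       # inclusive bases
    } else {
      lo <- rp + downstream; hi <- rp + upstream
    }
    if (lo < 0 || hi >= nchar(chrom_seq)) next
    win <- substr(chrom_seq, lo + 1L, hi + 1L)          # to 1-based substr
    if (promoters$strand[i] == "-") win <- revcomp(win)
    if (grepl("[^ACGTacgt]", win)) next
    n_off <- nchar(win) - w + 1L
    if (n_off < 1L) next
    best <- max(vapply(seq_len(n_off), function(o)
      pwm_relative_score(pwm, substr(win, o, o + w - 1L)), numeric(1)))
    score[i] <- best
    flag[i] <- best > rel_threshold
  }
  data.frame(flag = flag, score = score)
}

#' @noRd
revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Consensus sequence of a position-frequency matrix
#' @param pfm count matrix, rows A, C, G, T.
#' @return character scalar; per-column argmax letters (ties to the first
#'   of A, C, G, T).
#' @export
pfm_consensus <- function(pfm) {
  paste(rownames(pfm)[apply(pfm, 2L, which.max)], collapse = "")
}

#' Annotate promoters with every feature at once
#'
#' Convenience wrapper producing the full feature table used by the
#' association statistics: architecture, CpG overlap, gene annotation,
#' lincRNA start, repeat overlap (+ class), TATA flag (+ score).
#' Individual annotations are skipped when their input is `NULL`.
#'
#' @param promoters a [promoter_table()].
#' @param cpg,repeats [interval_set()]s (or `NULL`).
#' @param genes a [gene_table()] (or `NULL`).
#' @param lincrna an [interval_set()] of start positions (or `NULL`).
#' @param genome,pfm sequence inputs for [scan_tata()] (or `NULL`).
#' @param tata_threshold relative-score threshold (default 0.75).
#' @return data.frame keyed by `id` with columns `architecture`, `cpg`,
#'   `gene`, `lincrna`, `repeat_flag`, `repeat_class`, `tata`,
#'   `tata_score` (absent inputs give NA columns).
#' @export
annotate_promoters <- function(promoters, cpg = NULL, repeats = NULL,
                               genes = NULL, lincrna = NULL, genome = NULL,
                               pfm = NULL, tata_threshold = 0.75) {
  n <- nrow(promoters)
  out <- data.frame(id = promoters$id,
                    architecture = classify_architecture(promoters),
                    stringsAsFactors = FALSE)
  out$cpg <- if (!is.null(cpg)) overlaps_element(promoters, cpg)$flag else NA
  if (!is.null(repeats)) {
    r <- overlaps_element(promoters, repeats)
    out$repeat_flag <- r$flag
    out$repeat_class <- r$class
  } else {
    out$repeat_flag <- NA
    out$repeat_class <- NA_character_
  }
  out$gene <- if (!is.null(genes)) gene_annotated(promoters, genes) else NA
  out$lincrna <- if (!is.null(lincrna))
    lincrna_start(promoters, lincrna) else NA
  if (!is.null(genome)) {
    tt <- scan_tata(promoters, genome, pfm = pfm,
                    rel_threshold = tata_threshold)
    out$tata <- tt$flag
    out$tata_score <- tt$score
  } else {
    out$tata <- NA
    out$tata_score <- NA_real_
  }
  out
}
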