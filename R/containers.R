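# In-memory containers shared by all pipeline stages. Plain data.frames
# carrying a lightweight S3 class; every constructor validates the type
# invariants so downstream code can assume them. All coordinates are
# 0-based half-open (BED convention) unless a field is documented as a
# single base position (rep_pos, gene TSS, lincRNA start).

#' Construct a promoter table
#'
#' A promoter table holds one row per level-3 core promoter: its anchor
#' (representative TSS, the member TSS carrying the most tags), its
#' level-1 member TSS positions with tag counts, and normalized expression
#' (tags per million) at one or more time points.
#'
#' @param id character vector of unique promoter ids.
#' @param chrom chromosome name per promoter.
#' @param strand `"+"` or `"-"` per promoter.
#' @param rep_pos 0-based base position of the representative TSS. Must
#'   equal the level-1 member with the maximal tag count (ties broken to
#'   the 5'-most, i.e. smallest genomic position).
#' @param level1 list of data.frames with columns `pos`, `tags`
#'   (tags > 0), one per promoter.
#' @param tpm data.frame (or named list) of expression columns, one per
#'   time point, e.g. `tpm_0h`, `tpm_96h`; all values >= 0.
#' @return A `promoter_table` (data.frame subclass).
#' @export
promoter_table <- function(id, chrom, strand, rep_pos, level1, tpm) {
  if (is.list(tpm) && !is.data.frame(tpm)) tpm <- as.data.frame(tpm)
  x <- data.frame(id = as.character(id), chrom = as.character(chrom),
                  strand = as.character(strand),
                  rep_pos = as.integer(rep_pos),
                  stringsAsFactors = FALSE)
  x$level1 <- level1
  for (nm in names(tpm)) x[[nm]] <- as.numeric(tpm[[nm]])
  class(x) <- c("promoter_table", "data.frame")
  validate_promoter_table(x)
}

#' @noRd
validate_promoter_table <- function(x) {
  if (anyDuplicated(x$id))
    abort("promoter ids must be unique (first duplicate: '%s')",
          x$id[duplicated(x$id)][1])
  bad <- !x$strand %in% c("+", "-")
  if (any(bad))
    abort("unknown strand symbol '%s' for promoter '%s'",
          x$strand[bad][1], x$id[bad][1])
  if (!length(tpm_columns(x)))
    abort("promoter table needs at least one tpm_* column")
  for (i in seq_len(nrow(x))) {
    l1 <- x$level1[[i]]
    if (!is.data.frame(l1) || !all(c("pos", "tags") %in% names(l1)) ||
        nrow(l1) == 0)
      abort("promoter '%s': level1 members missing", x$id[i])
    if (any(l1$tags <= 0))
      abort("promoter '%s': level-1 tag counts must be positive", x$id[i])
    top <- l1$pos[l1$tags == max(l1$tags)]
    if (x$rep_pos[i] != min(top))
      abort(paste0("promoter '%s': rep_pos (%d) must be the level-1 ",
                   "position with maximal tag count, 5'-most on ties (%d)"),
            x$id[i], x$rep_pos[i], min(top))
  }
  tpmv <- unlist(x[tpm_columns(x)], use.names = FALSE)
  if (any(!is.finite(tpmv)) || any(tpmv < 0))
    abort("tpm values must be finite and >= 0")
  x
}

#' Names of the expression (tpm) columns of a promoter table
#' @param x a `promoter_table`.
#' @return character vector of column names.
#' @export
tpm_columns <- function(x) grep("^tpm_", names(x), value = TRUE)

#' Construct a tiling-array probe track
#'
#' One row per probe; probes are sorted and non-overlapping within each
#' chromosome and share a common width. Each replicate contributes one
#' p-value column `p_1`, `p_2`, ... with p in (0, 1]; `NA` marks a probe
#' with no measurement in that replicate. Optional raw hybridization
#' intensities (used by [assign_probe_pvalues()]) travel in columns
#' `treat_<rep>_<tech>` / `ctrl_<rep>_<tech>`.
#'
#' @param chrom,start,end probe coordinates (0-based half-open).
#' @param pvalues matrix or data.frame of per-replicate p-values.
#' @param intensities optional data.frame of `treat_*` / `ctrl_*` columns.
#' @return A `probe_track` (data.frame subclass).
#' @export
probe_track <- function(chrom, start, end, pvalues, intensities = NULL) {
  pvalues <- as.data.frame(pvalues)
  names(pvalues) <- paste0("p_", seq_along(pvalues))
  x <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                  end = as.integer(end), stringsAsFactors = FALSE)
  for (nm in names(pvalues)) x[[nm]] <- as.numeric(pvalues[[nm]])
  if (!is.null(intensities))
    for (nm in names(intensities)) x[[nm]] <- as.numeric(intensities[[nm]])
  class(x) <- c("probe_track", "data.frame")
  validate_probe_track(x)
}

#' @noRd
validate_probe_track <- function(x) {
  pc <- pvalue_columns(x)
  if (!length(pc)) abort("probe track needs at least one p_* column")
  pv <- unlist(x[pc], use.names = FALSE)
  bad <- which(!is.na(pv) & (pv <= 0 | pv > 1))
  if (length(bad))
    abort("probe p-values must lie in (0,1]; offending record %d (p=%g)",
          (bad[1] - 1L) %% nrow(x) + 1L, pv[bad[1]])
  if (any(x$end <= x$start))
    abort("probe %d: end must exceed start", which(x$end <= x$start)[1])
  w <- x$end - x$start
  if (length(unique(w)) > 1L)
    abort("probes must share one width (saw %s)",
          paste(unique(w), collapse = ", "))
  for (ch in unique(x$chrom)) {
    s <- x$start[x$chrom == ch]
    e <- x$end[x$chrom == ch]
    if (is.unsorted(s, strictly = TRUE))
      abort("probes on '%s' must be sorted by start and non-duplicated", ch)
    if (any(e[-length(e)] > s[-1]))
      abort("probes on '%s' overlap", ch)
  }
  x
}

#' Names of the replicate p-value columns of a probe track
#' @param x a `probe_track`.
#' @return character vector of `p_*` column names.
#' @export
pvalue_columns <- function(x) grep("^p_[0-9]+$", names(x), value = TRUE)

#' Probe midpoint positions (floor of the coordinate mean)
#'
#' Profile binning assigns each probe's p-value to one genomic
#' position; the track does not define it, so the package uses the
#' integer midpoint `floor((start + end) / 2)` throughout.
#'
#' @param x a `probe_track`.
#' @return integer vector of midpoints.
#' @export
probe_midpoints <- function(x) as.integer((x$start + x$end) %/% 2L)

#' Construct a BED-like interval set
#'
#' @param chrom,start,end intervals, 0-based half-open, start < end.
#' @param name feature name / class (e.g. repeat class); defaults to ".".
#' @return An `interval_set` (data.frame subclass).
#' @export
interval_set <- function(chrom, start, end, name = ".") {
  x <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                  end = as.integer(end),
                  name = rep_len(as.character(name), length(chrom)),
                  stringsAsFactors = FALSE)
  class(x) <- c("interval_set", "data.frame")
  validate_interval_set(x)
}

#' @noRd
validate_interval_set <- function(x) {
  bad <- which(x$end <= x$start)
  if (length(bad))
    abort("interval %d (%s:%d-%d): start must be < end",
          bad[1], x$chrom[bad[1]], x$start[bad[1]], x$end[bad[1]])
  x
}

#' Construct a refGene-like gene table
#'
#' @param chrom,strand,txStart,txEnd,name transcript records; the TSS is
#'   `txStart` for `+` genes and `txEnd - 1` for `-` genes.
#' @return A `gene_table` (data.frame subclass) with a derived `tss` column.
#' @export
gene_table <- function(chrom, strand, txStart, txEnd, name) {
  x <- data.frame(chrom = as.character(chrom), strand = as.character(strand),
                  txStart = as.integer(txStart), txEnd = as.integer(txEnd),
                  name = as.character(name), stringsAsFactors = FALSE)
  if (any(!x$strand %in% c("+", "-")))
    abort("gene strand must be '+' or '-'")
  if (any(x$txEnd <= x$txStart)) abort("gene txEnd must exceed txStart")
  x$tss <- ifelse(x$strand == "+", x$txStart, x$txEnd - 1L)
  class(x) <- c("gene_table", "data.frame")
  x
}

#' Genomic extent of each promoter for overlap tests
#'
#' The core promoter's extent is the span of its level-1 member TSSs,
#' expanded to a minimum width of one base: `[min(pos), max(pos) + 1)`.
#'
#' @param promoters a `promoter_table`.
#' @return data.frame with `chrom`, `start`, `end` per promoter.
#' @export
promoter_extent <- function(promoters) {
  lo <- vapply(promoters$level1, function(l) min(l$pos), numeric(1))
  hi <- vapply(promoters$level1, function(l) max(l$pos), numeric(1))
  data.frame(chrom = promoters$chrom, start = as.integer(lo),
             end = as.integer(hi + 1L), stringsAsFactors = FALSE)
}

#' @export
print.promoter_table <- function(x, ...) {
  cat(sprintf("promoter_table: %d promoters on %d chromosome(s); tpm: %s\n",
              nrow(x), length(unique(x$chrom)),
              paste(tpm_columns(x), collapse = ", ")))
  invisible(x)
}

#' @export
print.probe_track <- function(x, ...) {
  cat(sprintf("probe_track: %d probes (%d bp) on %d chromosome(s), %d replicate(s)\n",
              nrow(x), if (nrow(x)) x$end[1] - x$start[1] else 0L,
              length(unique(x$chrom)), length(pvalue_columns(x))))
  invisible(x)
}
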