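# Readers and writers for every external file the pipeline touches.
# All on-disk interval coordinates are 0-based half-open; writers emit the
# same convention the readers expect, so write -> read is the identity.

# -- promoter tables ---------------------------------------------------------

#' Read a level-3 promoter table
#'
#' Tab-separated with header: `id`, `chrom`, `strand`, `rep_pos`,
#' `level1` (comma-separated `pos:count` pairs), then one or more
#' `tpm_*` expression columns.
#'
#' @param path file path.
#' @return A [promoter_table()].
#' @export
read_promoters <- function(path) {
  x <- read.table(path, header = TRUE, sep = "\t", quote = "",
                  colClasses = "character", check.names = FALSE)
  need <- c("id", "chrom", "strand", "rep_pos", "level1")
  if (!all(need %in% names(x)))
    abort("promoter table '%s' must have columns %s", path,
          paste(need, collapse = ", "))
  level1 <- lapply(seq_len(nrow(x)), function(i) {
    parsed <- parse_level1(x$level1[i])
    if (is.null(parsed))
      abort("%s line %d: malformed level1 field '%s'", path, i + 1L,
            x$level1[i])
    parsed
  })
  tpm_cols <- grep("^tpm_", names(x), value = TRUE)
  tpm <- lapply(x[tpm_cols], as.numeric)
  names(tpm) <- tpm_cols
  promoter_table(x$id, x$chrom, x$strand, as.integer(x$rep_pos),
                 level1, tpm)
}

#' @noRd
parse_level1 <- function(s) {
  parts <- strsplit(s, ",", fixed = TRUE)[[1]]
  m <- regmatches(parts, regexec("^([0-9]+):([0-9]+)$", parts))
  if (any(lengths(m) != 3L)) return(NULL)
  data.frame(pos = as.integer(vapply(m, `[`, "", 2L)),
             tags = as.integer(vapply(m, `[`, "", 3L)))
}

#' Write a promoter table
#' @param x a `promoter_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_promoters <- function(x, path) {
  out <- data.frame(id = x$id, chrom = x$chrom, strand = x$strand,
                    rep_pos = x$rep_pos,
                    level1 = vapply(x$level1, function(l)
                      paste(sprintf("%d:%d", l$pos, l$tags), collapse = ","),
                      character(1)),
                    stringsAsFactors = FALSE)
  for (nm in tpm_columns(x)) out[[nm]] <- x[[nm]]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# -- probe tracks ------------------------------------------------------------

#' Read a tiling-array probe track
#'
#' Tab-separated with header: `chrom`, `start`, `end`, one `p_<rep>`
#' column per replicate (p in (0,1], `NA` allowed), and optionally raw
#' intensity columns `treat_*` / `ctrl_*`.
#'
#' @param path file path.
#' @return A [probe_track()].
#' @export
read_probe_track <- function(path) {
  x <- read.table(path, header = TRUE, sep = "\t", quote = "",
                  check.names = FALSE)
  pc <- grep("^p_[0-9]+$", names(x), value = TRUE)
  if (!all(c("chrom", "start", "end") %in% names(x)) || !length(pc))
    abort("probe track '%s' must have chrom/start/end and p_<rep> columns",
          path)
  ic <- grep("^(treat|ctrl)_", names(x), value = TRUE)
  probe_track(x$chrom, x$start, x$end, x[pc],
              if (length(ic)) x[ic] else NULL)
}

#' Write a probe track
#' @param x a `probe_track`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_probe_track <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

# -- BED intervals, genes, lincRNA starts ------------------------------------

#' Read a BED4 interval file (0-based half-open)
#' @param path file path; columns chrom, start, end, name (no header).
#' @return An [interval_set()].
#' @export
read_intervals <- function(path) {
  x <- read.table(path, header = FALSE, sep = "\t", quote = "",
                  col.names = c("chrom", "start", "end", "name"),
                  colClasses = c("character", "integer", "integer",
                                 "character"))
  bad <- which(x$end <= x$start)
  if (length(bad))
    abort("%s line %d: empty or inverted interval (%d >= %d)", path, bad[1],
          x$start[bad[1]], x$end[bad[1]])
  interval_set(x$chrom, x$start, x$end, x$name)
}

#' Write a BED4 interval file
#' @param x an `interval_set`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(x, path) {
  write.table(x[, c("chrom", "start", "end", "name")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a refGene-like gene table
#' @param path tab-separated with header chrom, strand, txStart, txEnd, name.
#' @return A [gene_table()].
#' @export
read_genes <- function(path) {
  x <- read.table(path, header = TRUE, sep = "\t", quote = "",
                  check.names = FALSE)
  need <- c("chrom", "strand", "txStart", "txEnd", "name")
  if (!all(need %in% names(x)))
    abort("gene table '%s' must have columns %s", path,
          paste(need, collapse = ", "))
  gene_table(x$chrom, x$strand, x$txStart, x$txEnd, x$name)
}

#' Write a gene table
#' @param x a `gene_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genes <- function(x, path) {
  write.table(x[, c("chrom", "strand", "txStart", "txEnd", "name")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# -- genome FASTA ------------------------------------------------------------

#' Read a genome FASTA into a DNAStringSet
#' @param path FASTA file.
#' @return A [Biostrings::DNAStringSet-class] keyed by chromosome name.
#' @export
read_genome <- function(path) Biostrings::readDNAStringSet(path)

#' Write a genome (named character vector or DNAStringSet) as FASTA
#' @param x named character vector of sequences, or a `DNAStringSet`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(x, path) {
  if (!methods::is(x, "DNAStringSet")) x <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

# -- position-frequency matrices ---------------------------------------------

#' Read a position-frequency matrix (JASPAR text layout)
#'
#' Accepts the JASPAR flat-file layout: an optional `>` header line, then
#' four rows `A [ 4 17 0 ... ]` (brackets optional) in A, C, G, T order.
#'
#' @param path file path.
#' @return numeric matrix, rows named A, C, G, T.
#' @export
read_pfm <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines[nzchar(trimws(lines))])
  lines <- lines[!startsWith(lines, ">")]
  if (length(lines) != 4L)
    abort("PFM '%s': expected 4 base rows, found %d", path, length(lines))
  rows <- lapply(seq_along(lines), function(i) {
    ln <- gsub("[][]", " ", lines[i])
    toks <- strsplit(ln, "[[:space:]]+")[[1]]
    base <- toks[1]
    vals <- suppressWarnings(as.numeric(toks[-1]))
    if (!base %in% c("A", "C", "G", "T") || any(is.na(vals)))
      abort("PFM '%s' line %d: cannot parse '%s'", path, i, lines[i])
    list(base = base, vals = vals)
  })
  bases <- vapply(rows, `[[`, "", "base")
  if (!identical(sort(bases), c("A", "C", "G", "T")))
    abort("PFM '%s': need one row each for A, C, G, T", path)
  n <- unique(lengths(lapply(rows, `[[`, "vals")))
  if (length(n) != 1L) abort("PFM '%s': ragged rows", path)
  m <- do.call(rbind, lapply(rows, `[[`, "vals"))
  rownames(m) <- bases
  m[c("A", "C", "G", "T"), , drop = FALSE]
}

#' Write a position-frequency matrix in JASPAR text layout
#' @param pfm numeric matrix with rows A, C, G, T.
#' @param path output file path.
#' @param name motif name for the `>` header.
#' @return `path`, invisibly.
#' @export
write_pfm <- function(pfm, path, name = "motif") {
  stopifnot(identical(rownames(pfm), c("A", "C", "G", "T")))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(">%s", name), con)
  for (b in rownames(pfm))
    writeLines(sprintf("%s [ %s ]", b,
                       paste(format(pfm[b, ], trim = TRUE), collapse = " ")),
               con)
  invisible(path)
}
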