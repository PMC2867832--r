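# Shared fixtures and independent oracles. Oracles are deliberately
# naive (brute force / enumeration) and never call the code paths they
# check.

# single-promoter constructor with one dominant TSS
mk_promoter <- function(id, chrom = "chr1", strand = "+", rep_pos = 10000L,
                        level1 = NULL, tpm = 10) {
  if (is.null(level1))
    level1 <- data.frame(pos = rep_pos, tags = 100L)
  promoter_table(id, chrom, strand, rep_pos, list(level1),
                 list(tpm_0h = tpm, tpm_96h = tpm))
}

# several promoters at given rep positions (single-TSS each)
mk_promoters <- function(pos, chrom = "chr1", strand = NULL, tpm = NULL) {
  n <- length(pos)
  if (is.null(strand)) strand <- rep("+", n)
  if (is.null(tpm)) tpm <- rep(10, n)
  promoter_table(sprintf("q%03d", seq_len(n)), rep(chrom, n), strand,
                 pos, lapply(pos, function(p) data.frame(pos = p, tags = 50L)),
                 list(tpm_0h = tpm, tpm_96h = tpm))
}

# dense probe tiling with constant p-value
mk_track <- function(chrom = "chr1", from = 0L, to = 30000L, spacing = 35L,
                     width = 25L, p = 0.5, n_rep = 1L) {
  starts <- seq.int(from, to - width, by = spacing)
  pv <- matrix(p, length(starts), n_rep)
  probe_track(rep(chrom, length(starts)), starts, starts + width, pv)
}

small_synth <- function(n = 60, seed = 1, ...) {
  synth_config(n_promoters = n, genome_length = 400000, n_chromosomes = 2,
               seed = seed, ...)
}

# --- oracles ----------------------------------------------------------------

# all-pairs proximity: TRUE for promoters with any neighbour within radius
oracle_proximal <- function(promoters, radius) {
  n <- nrow(promoters)
  vapply(seq_len(n), function(i) {
    any(promoters$chrom[-i] == promoters$chrom[i] &
          abs(promoters$rep_pos[-i] - promoters$rep_pos[i]) <= radius)
  }, logical(1))
}

# brute-force per-bin probe midpoint counts for one promoter
oracle_bin_counts <- function(rep_pos, mids, n_bins = 11, bin_size = 400) {
  lo <- rep_pos - n_bins * bin_size / 2
  vapply(seq_len(n_bins), function(b) {
    sum(mids >= lo + (b - 1) * bin_size & mids < lo + b * bin_size)
  }, numeric(1))
}

# exhaustive k-medoids optimum over all medoid subsets
oracle_pam_optimum <- function(dm, k) {
  n <- nrow(dm)
  best <- Inf
  for (med in asplit(utils::combn(n, k), 2L)) {
    obj <- sum(apply(dm[, med, drop = FALSE], 1L, min))
    if (obj < best) best <- obj
  }
  best
}

# is a medoid set swap-local-optimal?
oracle_swap_optimal <- function(dm, medoids) {
  n <- nrow(dm)
  obj <- sum(apply(dm[, medoids, drop = FALSE], 1L, min))
  for (m in medoids) for (h in setdiff(seq_len(n), medoids)) {
    med2 <- c(setdiff(medoids, m), h)
    if (sum(apply(dm[, med2, drop = FALSE], 1L, min)) < obj - 1e-12)
      return(FALSE)
  }
  TRUE
}

# exact one-sided rank-sum p by enumeration of all group assignments
oracle_ranksum_p <- function(treatment, control) {
  pooled <- c(treatment, control)
  n <- length(treatment)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n)])
  combs <- utils::combn(length(pooled), n)
  ws <- apply(combs, 2L, function(idx) sum(r[idx]))
  mean(ws >= w_obs)
}

# two-sided Fisher p by enumeration of all tables with the same margins
oracle_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- vapply(support, function(a) {
    b <- r1 - a; c <- c1 - a; d <- n - a - b - c
    exp(lchoose(r1, a) + lchoose(n - r1, c) - lchoose(n, c1))
  }, numeric(1))
  p_obs <- probs[support == tab[1, 1]]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# best SP window share by enumerating every 4-nt window start
oracle_sp_share <- function(level1, window_nt = 4) {
  total <- sum(level1$tags)
  starts <- (min(level1$pos) - window_nt):max(level1$pos)
  max(vapply(starts, function(s)
    sum(level1$tags[level1$pos >= s & level1$pos <= s + window_nt - 1]),
    numeric(1))) / total
}

# exhaustive PWM scan over every offset of a sequence
oracle_pwm_best <- function(pwm, seq) {
  w <- ncol(pwm)
  offs <- seq_len(nchar(seq) - w + 1)
  max(vapply(offs, function(o) {
    letters <- strsplit(substr(seq, o, o + w - 1), "")[[1]]
    s <- sum(vapply(seq_along(letters), function(j)
      pwm[letters[j], j], numeric(1)))
    (s - sum(apply(pwm, 2, min))) / (sum(apply(pwm, 2, max)) -
                                       sum(apply(pwm, 2, min)))
  }, numeric(1)))
}
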