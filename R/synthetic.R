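# Synthetic stand-in for the DeepCAGE + tiling-array inputs: promoter
# tables with planted single-peak/broad tag architectures, probe tracks
# with planted upstream / centered / downstream signal shapes, annotation
# intervals and genome sequence with planted feature flags. Every
# generated object carries its ground truth so recovery is testable.
#
# Geometry: promoters sit in slots 6,000 bp apart (with a 3,000 bp
# chromosome-edge margin) so that non-paired promoters always survive the
# proximal filter and their profile windows never overlap. Planted
# proximal pairs share a slot at 800-2,000 bp separation and are exactly
# the promoters the proximal filter removes.

SLOT_WIDTH <- 6000L
EDGE_MARGIN <- 3000L

# signal shape archetypes, x = strand-oriented offset from the
# representative position (negative = 5'). Each archetype is a unit-peak
# bump mix on top of a flat local pedestal covering the profile window;
# the pedestal keeps tier amplitude ordering visible in every bin.
SHAPE_PEDESTAL <- 0.25
shape_archetype <- function(kind, x) {
  g <- function(mu, sd) exp(-(x - mu)^2 / (2 * sd^2))
  bump <- switch(kind,
    upstream = g(-600, 400),
    centered = 0.6 * g(-400, 300) + 1.0 * g(600, 400) - 0.35 * g(0, 200),
    downstream = g(800, 500),
    abort("unknown shape archetype '%s'", kind))
  pmax(0, SHAPE_PEDESTAL * (abs(x) <= 2400) + bump)
}

# amplitude (score units, -10*log10 p) by expression tier
TIER_AMPLITUDE <- c(low = 5, medium = 15, high = 60)

#' Configuration for the synthetic dataset generator
#'
#' Defaults describe a plausible desk-scale version of a tiling-array +
#' CAGE experiment: 25 bp probes every 35 bp, two biological replicates,
#' three planted signal-shape classes in equal parts, and a modest probe
#' noise of a few score units.
#'
#' @param n_promoters number of level-3 promoters (default 300).
#' @param genome_length bp per synthetic chromosome (default 1e6).
#' @param n_chromosomes number of chromosomes (default 2).
#' @param probe_length probe width in bp (default 25).
#' @param probe_spacing probe start-to-start distance in bp (default 35).
#' @param shape_mix named proportions over upstream/centered/downstream
#'   (must sum to 1; default equal thirds).
#' @param sp_fraction fraction of single-peak promoters (default 0.3:
#'   SP promoters are the minority class overall, rising to ~40% only in
#'   the upstream signal class).
#' @param tier_probs sampling proportions of the low/medium/high
#'   expression tiers (default 0.25/0.50/0.25).
#' @param expression_tiers tpm range per tier (low 0.5-5, medium 5-50,
#'   high 50-500 by default).
#' @param noise_sd per-probe, per-replicate Gaussian noise on the score
#'   scale (default 3: about half an order of magnitude jitter on p).
#' @param gap_rate expected fraction of probes masked as "repetitive"
#'   gaps (default 0.05), realized as runs of 4-12 missing probes.
#' @param proximal_pair_rate fraction of promoters planted within
#'   2,200 bp of a partner (default 0.1; both members of each pair are
#'   what the proximal filter removes).
#' @param feature_probs planting probabilities for the cpg / gene /
#'   repeat / tata / lincrna flags.
#' @param n_replicates biological replicates in the probe track
#'   (default 2).
#' @param seed RNG seed; every generator operation derives its own
#'   stream from it, so outputs are reproducible and order-independent.
#' @return a validated `synth_config` list.
#' @export
synth_config <- function(n_promoters = 300, genome_length = 1e6,
                         n_chromosomes = 2, probe_length = 25,
                         probe_spacing = 35,
                         shape_mix = c(upstream = 1/3, centered = 1/3,
                                       downstream = 1/3),
                         sp_fraction = 0.3,
                         tier_probs = c(low = 0.25, medium = 0.5,
                                        high = 0.25),
                         expression_tiers = list(low = c(0.5, 5),
                                                 medium = c(5, 50),
                                                 high = c(50, 500)),
                         noise_sd = 3, gap_rate = 0.05,
                         proximal_pair_rate = 0.1,
                         feature_probs = c(cpg = 0.5, gene = 0.6,
                                           repeat_ = 0.25, tata = 0.2,
                                           lincrna = 0.05),
                         n_replicates = 2, seed = 1) {
  cfg <- list(n_promoters = as.integer(n_promoters),
              genome_length = as.integer(genome_length),
              n_chromosomes = as.integer(n_chromosomes),
              probe_length = as.integer(probe_length),
              probe_spacing = as.integer(probe_spacing),
              shape_mix = shape_mix, sp_fraction = sp_fraction,
              tier_probs = tier_probs, expression_tiers = expression_tiers,
              noise_sd = noise_sd, gap_rate = gap_rate,
              proximal_pair_rate = proximal_pair_rate,
              feature_probs = feature_probs,
              n_replicates = as.integer(n_replicates),
              seed = as.integer(seed))
  validate_synth_config(cfg)
}

#' @noRd
validate_synth_config <- function(cfg) {
  if (abs(sum(cfg$shape_mix) - 1) > 1e-9)
    abort("shape_mix must sum to 1")
  if (!identical(sort(names(cfg$shape_mix)),
                 c("centered", "downstream", "upstream")))
    abort("shape_mix needs names upstream/centered/downstream")
  if (cfg$probe_spacing < cfg$probe_length)
    abort("probe_spacing (%d) must be >= probe_length (%d)",
          cfg$probe_spacing, cfg$probe_length)
  rates <- c(cfg$sp_fraction, cfg$gap_rate, cfg$proximal_pair_rate,
             cfg$feature_probs)
  if (any(rates < 0 | rates > 1)) abort("all rates must lie in [0,1]")
  if (cfg$noise_sd < 0) abort("noise_sd must be >= 0")
  if (cfg$n_promoters < 1) abort("need at least one promoter")
  structure(cfg, class = "synth_config")
}

#' Generate a promoter table with planted shape / architecture truth
#'
#' Places promoters in well-separated slots (see module notes), plants
#' the requested fraction of proximal pairs, draws strand, signal-shape
#' class, single-peak vs broad architecture, expression tier and feature
#' flags, and constructs level-1 member TSSs realizing the architecture:
#' SP promoters put >= 50% of tags on one dominant TSS, BR promoters
#' spread tags over >= 8 TSSs at >= 6 bp spacing so no 4-nt window
#' reaches 50%. Tag totals are the tpm scaled to a 2-million-tag library,
#' floored so the planted architecture stays realizable at low
#' expression.
#'
#' @param config a [synth_config()].
#' @return list with `promoters` (a [promoter_table()]) and `truth`
#'   (data.frame: id, shape_class, architecture, tier, proximal flag and
#'   partner, one column per planted feature flag).
#' @export
generate_promoters <- function(config) {
  cfg <- validate_synth_config(config)
  set.seed(derive_seed(cfg$seed, "promoters"))
  n <- cfg$n_promoters
  n_pairs <- floor(cfg$proximal_pair_rate * n / 2)
  n_slots <- n - n_pairs
  cap_per_chrom <- (cfg$genome_length - 2L * EDGE_MARGIN) %/% SLOT_WIDTH
  if (cap_per_chrom < 1L || n_slots > cap_per_chrom * cfg$n_chromosomes)
    abort(paste0("genome too short: %d slots needed but only %d available ",
                 "(%d chromosomes x %d slots)"),
          n_slots, cap_per_chrom * cfg$n_chromosomes, cfg$n_chromosomes,
          cap_per_chrom)
  slot_chrom <- rep(seq_len(cfg$n_chromosomes), each = cap_per_chrom,
                    length.out = n_slots)
  slot_idx <- unlist(lapply(seq_len(cfg$n_chromosomes),
                            function(c) seq_len(sum(slot_chrom == c))))
  centers <- EDGE_MARGIN + (slot_idx - 1L) * SLOT_WIDTH + SLOT_WIDTH %/% 2L +
    sample(-400:400, n_slots, replace = TRUE)
  # pair slots host two promoters 800-2,000 bp apart
  pair_slot <- seq_len(n_pairs)
  anchor <- centers
  # pair separation capped at 1,800 bp: level-1 members may shift the
  # representative position by up to 150 bp each, and the pair must stay
  # within the 2,200 bp proximal radius
  rep_pos <- c(anchor, anchor[pair_slot] +
                 sample(800:1800, n_pairs, replace = TRUE))
  chrom <- paste0("chr", c(slot_chrom, slot_chrom[pair_slot]))
  proximal <- c(seq_len(n_slots) %in% pair_slot, rep(TRUE, n_pairs))
  partner <- rep(NA_character_, n)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  shape <- sample(names(cfg$shape_mix), n, replace = TRUE,
                  prob = cfg$shape_mix)
  arch <- ifelse(runif(n) < cfg$sp_fraction, "SP", "BR")
  tier <- sample(names(cfg$tier_probs), n, replace = TRUE,
                 prob = cfg$tier_probs)
  tpm <- vapply(tier, function(t)
    runif(1, cfg$expression_tiers[[t]][1], cfg$expression_tiers[[t]][2]),
    numeric(1))
  flag_names <- c("cpg", "gene", "repeat_", "tata", "lincrna")
  flags <- vapply(flag_names, function(f) runif(n) < cfg$feature_probs[[f]],
                  logical(n))
  flags <- matrix(flags, nrow = n, dimnames = list(NULL, flag_names))
  # proximal-pair members share overlapping -300/+1000 windows, so a gene
  # or lincRNA start planted for one would silently flag the other; the
  # pairs exist to exercise the proximal filter (and are removed before
  # any feature analysis), so positional features stay unplanted on them
  flags[proximal, c("gene", "lincrna")] <- FALSE
  ids <- sprintf("P%04d", seq_len(n))
  if (n_pairs) {
    partner[pair_slot] <- ids[n_slots + seq_len(n_pairs)]
    partner[n_slots + seq_len(n_pairs)] <- ids[pair_slot]
  }
  level1 <- vector("list", n)
  rep_out <- integer(n)
  for (i in seq_len(n)) {
    total <- round(2 * tpm[i])
    l1 <- if (arch[i] == "SP") build_sp_members(rep_pos[i], max(total, 4L))
          else build_br_members(rep_pos[i], max(total, 30L))
    level1[[i]] <- l1
    top <- l1$pos[l1$tags == max(l1$tags)]
    rep_out[i] <- min(top)
  }
  promoters <- promoter_table(ids, chrom, strand, rep_out, level1,
                              list(tpm_0h = round(tpm, 3),
                                   tpm_96h = round(tpm *
                                     runif(n, 0.8, 1.25), 3)))
  truth <- data.frame(id = ids, shape_class = shape, architecture = arch,
                      tier = tier, proximal = proximal, partner = partner,
                      stringsAsFactors = FALSE)
  truth <- cbind(truth, as.data.frame(flags))
  ord <- order(promoters$chrom, promoters$rep_pos)
  list(promoters = promoters[ord, ], truth = truth[ord, ])
}

#' @noRd
build_sp_members <- function(center, total) {
  f <- runif(1, 0.6, 0.9)
  dominant <- max(ceiling(f * total), ceiling(total / 2), 2L)
  rest <- total - dominant
  if (rest <= 0) return(data.frame(pos = center, tags = dominant))
  n_extra <- min(sample(2:5, 1), rest)
  offs <- sample(seq(6, 120, by = 6), n_extra)
  per <- rep(rest %/% n_extra, n_extra)
  per[seq_len(rest %% n_extra)] <- per[seq_len(rest %% n_extra)] + 1L
  # no satellite may rival the dominant TSS
  per <- pmin(per, dominant - 1L)
  keep <- per > 0
  d <- data.frame(pos = c(center, center + offs[keep] *
                            sample(c(-1L, 1L), sum(keep), replace = TRUE)),
                  tags = c(dominant, per[keep]))
  d <- d[order(d$pos), ]
  rownames(d) <- NULL
  d
}

#' @noRd
build_br_members <- function(center, total) {
  n_pos <- min(sample(8:12, 1), max(8L, total %/% 3L))
  offs <- sort(sample(seq(-150L, 150L, by = 6L), n_pos))
  q <- total %/% n_pos
  tags <- rep(q, n_pos)
  r <- total %% n_pos
  if (r) tags[seq_len(r)] <- tags[seq_len(r)] + 1L
  data.frame(pos = center + offs, tags = tags)
}

#' Generate a tiling probe track with planted signal shapes
#'
#' Tiles every chromosome with `probe_length` bp probes every
#' `probe_spacing` bp, masks "repetitive" gap runs at the configured
#' rate, and emits per-replicate p-values `p = 10^(-s/10)` where the
#' score `s = max(0, A * shape(offset) + N(0, noise_sd))` combines the
#' promoter's planted shape archetype (anchored at its representative
#' position, mirrored for minus-strand promoters) with tier-dependent
#' amplitude A (5 / 15 / 60 score units for low / medium / high).
#'
#' @param promoters,truth output of [generate_promoters()].
#' @param config the same [synth_config()].
#' @return a [probe_track()].
#' @export
generate_probe_track <- function(promoters, truth, config) {
  cfg <- validate_synth_config(config)
  set.seed(derive_seed(cfg$seed, "probes"))
  chroms <- paste0("chr", seq_len(cfg$n_chromosomes))
  pieces <- lapply(chroms, function(ch) {
    starts <- seq.int(0L, cfg$genome_length - cfg$probe_length,
                      by = cfg$probe_spacing)
    keep <- !mask_gap_runs(length(starts), cfg$gap_rate)
    starts <- starts[keep]
    mids <- starts + cfg$probe_length %/% 2L
    base <- numeric(length(starts))
    sel <- promoters$chrom == ch
    for (i in which(sel)) {
      x <- mids - promoters$rep_pos[i]
      if (promoters$strand[i] == "-") x <- -x
      near <- abs(x) <= 3000
      if (!any(near)) next
      ti <- truth$tier[match(promoters$id[i], truth$id)]
      sh <- truth$shape_class[match(promoters$id[i], truth$id)]
      base[near] <- base[near] +
        TIER_AMPLITUDE[[ti]] * shape_archetype(sh, x[near])
    }
    pv <- vapply(seq_len(cfg$n_replicates), function(r) {
      s <- pmax(0, base + rnorm(length(base), 0, cfg$noise_sd))
      10^(-s / 10)
    }, numeric(length(starts)))
    pv <- matrix(pv, nrow = length(starts),
                 dimnames = list(NULL, paste0("p_", seq_len(cfg$n_replicates))))
    cbind(data.frame(chrom = ch, start = starts,
                     end = starts + cfg$probe_length,
                     stringsAsFactors = FALSE),
          as.data.frame(pv))
  })
  all <- do.call(rbind, pieces)
  probe_track(all$chrom, all$start, all$end,
              all[, grep("^p_", names(all)), drop = FALSE])
}

#' @noRd
mask_gap_runs <- function(n, gap_rate) {
  mask <- logical(n)
  if (gap_rate <= 0) return(mask)
  run_mean <- 8
  start_prob <- gap_rate / run_mean
  starts <- which(runif(n) < start_prob)
  for (s in starts) {
    len <- sample(4:12, 1)
    mask[s:min(n, s + len - 1L)] <- TRUE
  }
  mask
}

#' Generate annotation intervals and genome sequence matching the truth
#'
#' For every promoter whose truth record carries a feature flag, a
#' qualifying element is planted so the annotation stage must recover the
#' flag: a CpG island / repeat interval overlapping the promoter extent,
#' a gene (or lincRNA) start inside the strand-relative -300/+1000
#' window, and the TATA consensus (argmax letters of the supplied count
#' matrix) at a random admissible offset of the strand-relative -50/-15
#' window. Unflagged promoters get no qualifying element; their TATA
#' windows are resampled until the best relative PWM score stays below
#' 0.6, so the 0.75 threshold cleanly separates planted from background.
#' A handful of decoy elements are placed far enough from every promoter
#' to never change a flag.
#'
#' @param promoters,truth output of [generate_promoters()].
#' @param config the same [synth_config()].
#' @param pfm TATA count matrix (default: the packaged synthetic matrix).
#' @return list with `cpg`, `repeats`, `lincrna` ([interval_set()]s),
#'   `genes` (a [gene_table()]), `genome` (named character vector).
#' @export
generate_annotations <- function(promoters, truth, config, pfm = NULL) {
  cfg <- validate_synth_config(config)
  set.seed(derive_seed(cfg$seed, "annotations"))
  if (is.null(pfm))
    pfm <- read_pfm(system.file("extdata", "tata_box_synthetic.pfm",
                                package = "promacet", mustWork = TRUE))
  consensus <- pfm_consensus(pfm)
  w <- nchar(consensus)
  truth <- truth[match(promoters$id, truth$id), ]
  chroms <- paste0("chr", seq_len(cfg$n_chromosomes))
  genome <- setNames(lapply(chroms, function(ch)
    sample(c("A", "C", "G", "T"), cfg$genome_length, replace = TRUE)),
    chroms)
  ext <- promoter_extent(promoters)
  cpg <- list(); rpt <- list(); genes <- list(); linc <- list()
  repeat_classes <- c("Simple_repeat", "Low_complexity", "SINE", "LINE")
  for (i in seq_len(nrow(promoters))) {
    ch <- promoters$chrom[i]; rp <- promoters$rep_pos[i]
    st <- promoters$strand[i]
    if (rp - 2500 < 0 || rp + 2500 > cfg$genome_length)
      abort("promoter '%s': feature window runs off chromosome end",
            promoters$id[i])
    if (truth$cpg[i])
      cpg[[length(cpg) + 1L]] <- data.frame(
        chrom = ch, start = ext$start[i] - sample(20:150, 1),
        end = ext$end[i] + sample(20:150, 1), name = "CpG")
    if (truth$repeat_[i])
      rpt[[length(rpt) + 1L]] <- data.frame(
        chrom = ch, start = ext$start[i] - sample(0:30, 1),
        end = ext$end[i] + sample(0:30, 1),
        name = sample(repeat_classes, 1))
    if (truth$gene[i]) {
      tss <- strand_offset(rp, st, sample(-300:1000, 1))
      gs <- sample(c("+", "-"), 1)
      len <- sample(2000:8000, 1)
      genes[[length(genes) + 1L]] <- gene_record(ch, gs, tss, len,
                                                 cfg$genome_length,
                                                 promoters$id[i])
    }
    if (truth$lincrna[i]) {
      s0 <- strand_offset(rp, st, sample(-300:1000, 1))
      linc[[length(linc) + 1L]] <- data.frame(
        chrom = ch, start = s0, end = s0 + 1L,
        name = paste0("linc_", promoters$id[i]))
    }
    # TATA window on the promoter strand
    genome[[ch]] <- plant_tata_window(genome[[ch]], rp, st, consensus, w,
                                      pfm, planted = truth$tata[i])
  }
  # decoy elements in inter-slot deserts (>= 2,500 bp from every rep_pos)
  decoys <- desert_positions(promoters, cfg, n_per_chrom = 3)
  for (j in seq_len(nrow(decoys))) {
    cpg[[length(cpg) + 1L]] <- data.frame(
      chrom = decoys$chrom[j], start = decoys$pos[j],
      end = decoys$pos[j] + 400L, name = "CpG")
    genes[[length(genes) + 1L]] <- gene_record(
      decoys$chrom[j], "+", decoys$pos[j] + 500L, 1500L,
      cfg$genome_length, paste0("decoy", j))
  }
  as_iset <- function(lst) {
    if (!length(lst)) return(interval_set(character(0), integer(0),
                                          integer(0), character(0)))
    d <- do.call(rbind, lst)
    interval_set(d$chrom, pmax(0L, d$start), d$end, d$name)
  }
  gd <- do.call(rbind, genes)
  list(cpg = as_iset(cpg), repeats = as_iset(rpt),
       lincrna = as_iset(linc),
       genes = gene_table(gd$chrom, gd$strand, gd$txStart, gd$txEnd,
                          gd$name),
       genome = vapply(genome, paste, character(1), collapse = ""))
}

#' @noRd
strand_offset <- function(rep_pos, strand, offset) {
  if (strand == "+") rep_pos + offset else rep_pos - offset
}

#' @noRd
gene_record <- function(chrom, gstrand, tss, len, glen, tag) {
  if (gstrand == "+") {
    txStart <- tss; txEnd <- min(tss + len, glen)
  } else {
    txEnd <- tss + 1L; txStart <- max(0L, tss + 1L - len)
  }
  data.frame(chrom = chrom, strand = gstrand, txStart = txStart,
             txEnd = txEnd, name = paste0("gene_", tag),
             stringsAsFactors = FALSE)
}

#' @noRd
plant_tata_window <- function(chrom_seq, rep_pos, strand, consensus, w,
                              pfm, planted) {
  if (strand == "+") {
    lo <- rep_pos - 50L
  } else {
    lo <- rep_pos + 15L
  }
  win_idx <- (lo + 1L):(lo + 36L)   # 1-based indices of the 36-base window
  if (planted) {
    off <- sample.int(36L - w + 1L, 1) - 1L
    motif <- if (strand == "+") consensus else revcomp(consensus)
    # for '-' promoters any placement works: the scan reverse-complements
    pos <- win_idx[1] + off
    chrom_seq[pos:(pos + w - 1L)] <- strsplit(motif, "")[[1]]
  } else {
    pwm <- pfm_to_pwm(pfm)
    repeat {
      cand <- sample(c("A", "C", "G", "T"), 36L, replace = TRUE)
      s <- paste(cand, collapse = "")
      scan_seq <- if (strand == "+") s else revcomp(s)
      best <- max(vapply(seq_len(36L - w + 1L), function(o)
        pwm_relative_score(pwm, substr(scan_seq, o, o + w - 1L)),
        numeric(1)))
      if (best <= 0.6) break
    }
    chrom_seq[win_idx] <- cand
  }
  chrom_seq
}

#' @noRd
desert_positions <- function(promoters, cfg, n_per_chrom = 3) {
  out <- list()
  for (c in seq_len(cfg$n_chromosomes)) {
    ch <- paste0("chr", c)
    reps <- promoters$rep_pos[promoters$chrom == ch]
    cand <- seq(500L, cfg$genome_length - 2500L, by = 1000L)
    ok <- vapply(cand, function(p)
      !length(reps) || min(abs(reps - p)) > 2600, logical(1))
    take <- head(cand[ok], n_per_chrom)
    if (length(take))
      out[[ch]] <- data.frame(chrom = ch, pos = take,
                              stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Generate the full synthetic dataset in one call
#'
#' @param config a [synth_config()].
#' @return list with `promoters`, `truth`, `track`, `annotations`
#'   (see the individual generators) and the `config` used.
#' @export
generate_synthetic_dataset <- function(config = synth_config()) {
  pr <- generate_promoters(config)
  track <- generate_probe_track(pr$promoters, pr$truth, config)
  ann <- generate_annotations(pr$promoters, pr$truth, config)
  list(promoters = pr$promoters, truth = pr$truth, track = track,
       annotations = ann, config = config)
}

#' Write a synthetic dataset to a directory of plain-text files
#'
#' Emits `promoters.tsv`, `probes.tsv`, `cpg.bed`, `repeats.bed`,
#' `lincrna.bed`, `genes.tsv`, `genome.fa` and `truth.tsv`.
#'
#' @param dataset result of [generate_synthetic_dataset()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_synthetic_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_promoters(dataset$promoters, file.path(dir, "promoters.tsv"))
  write_probe_track(dataset$track, file.path(dir, "probes.tsv"))
  write_intervals(dataset$annotations$cpg, file.path(dir, "cpg.bed"))
  write_intervals(dataset$annotations$repeats, file.path(dir, "repeats.bed"))
  write_intervals(dataset$annotations$lincrna, file.path(dir, "lincrna.bed"))
  write_genes(dataset$annotations$genes, file.path(dir, "genes.tsv"))
  write_genome(dataset$annotations$genome, file.path(dir, "genome.fa"))
  write.table(dataset$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
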