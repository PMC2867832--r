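# architecture classification, interval overlap, gene/lincRNA windows,
# TATA PWM scan; translation invariance and the planted-truth round trip.

test_that("architecture classifier follows the 4-nt / 50% rule", {
  p_single <- mk_promoter("a", level1 = data.frame(pos = 100L, tags = 37L),
                          rep_pos = 100L)
  expect_identical(classify_architecture(p_single), "SP")
  p_sixty <- mk_promoter("b", rep_pos = 100L,
                         level1 = data.frame(pos = c(100L, 150L),
                                             tags = c(60L, 40L)))
  expect_identical(classify_architecture(p_sixty), "SP")
  p_spread <- mk_promoter("c", rep_pos = 100L,
                          level1 = data.frame(pos = seq(100L, 190L, 10L),
                                              tags = rep(10L, 10)))
  expect_identical(classify_architecture(p_spread), "BR")
  # threshold inclusive at exactly 50%
  p_half <- mk_promoter("d", rep_pos = 100L,
                        level1 = data.frame(pos = c(100L, 110L),
                                            tags = c(50L, 50L)))
  expect_identical(classify_architecture(p_half), "SP")
  # window may combine adjacent TSSs (4-nt span)
  p_adj <- mk_promoter("e", rep_pos = 100L,
                       level1 = data.frame(pos = c(100L, 103L, 110L, 120L,
                                                   130L, 140L),
                                           tags = c(30L, 25L, 12L, 11L,
                                                    11L, 11L)))
  expect_identical(classify_architecture(p_adj), "SP")  # 55/100 in [100,103]
  # random cases against the window-enumeration oracle
  set.seed(61)
  for (i in 1:25) {
    npos <- sample(2:8, 1)
    l1 <- data.frame(pos = sort(sample(100:160, npos)),
                     tags = sample(1:30, npos, replace = TRUE))
    top <- l1$pos[l1$tags == max(l1$tags)]
    pr <- promoter_table("r", "chr1", "+", min(top), list(l1),
                         list(tpm_0h = 1))
    expect_identical(classify_architecture(pr),
                     ifelse(oracle_sp_share(l1) >= 0.5, "SP", "BR"))
  }
  # SP and BR partition the promoter set
  ds <- generate_promoters(small_synth(n = 40, seed = 62))
  arch <- classify_architecture(ds$promoters)
  expect_true(all(arch %in% c("SP", "BR")))
})

test_that("interval overlap is half-open and reports the largest-overlap class", {
  pr <- mk_promoter("a", rep_pos = 1000L,
                    level1 = data.frame(pos = c(990L, 1000L, 1020L),
                                        tags = c(1L, 5L, 1L)))
  # extent = [990, 1021)
  covering <- interval_set("chr1", 995L, 1005L, "CpG")
  expect_true(overlaps_element(pr, covering)$flag)
  touching <- interval_set("chr1", 900L, 990L, "CpG")   # ends at extent start
  expect_false(overlaps_element(pr, touching)$flag)
  inside_end <- interval_set("chr1", 1020L, 1100L, "CpG") # overlaps last base
  expect_true(overlaps_element(pr, inside_end)$flag)
  # two repeats: larger overlap wins; tie -> earlier element
  two <- interval_set(c("chr1", "chr1"), c(985L, 1000L), c(995L, 1021L),
                      c("SINE", "LINE"))
  got <- overlaps_element(pr, two)
  expect_identical(got$class, "LINE")   # overlaps 21 bp vs 5 bp
  tie <- interval_set(c("chr1", "chr1"), c(990L, 1011L), c(1000L, 1021L),
                      c("SINE", "LINE"))
  expect_identical(overlaps_element(pr, tie)$class, "SINE")
})

test_that("gene and lincRNA windows are strand-relative and inclusive", {
  genes_at <- function(pos, gstrand = "+")
    gene_table("chr1", gstrand, pos, pos + 2000L, "g")
  plus <- mk_promoter("a", strand = "+", rep_pos = 10000L)
  expect_true(gene_annotated(plus, genes_at(10500L)))
  expect_false(gene_annotated(plus, genes_at(9500L)))    # outside -300
  expect_true(gene_annotated(plus, genes_at(9700L)))     # boundary -300
  expect_true(gene_annotated(plus, genes_at(11000L)))    # boundary +1000
  expect_false(gene_annotated(plus, genes_at(11001L)))
  minus <- mk_promoter("b", strand = "-", rep_pos = 10000L)
  expect_true(gene_annotated(minus, genes_at(9500L)))    # relative +500
  expect_false(gene_annotated(minus, genes_at(10500L)))  # relative -500
  # minus-strand gene: TSS = txEnd - 1
  g <- gene_table("chr1", "-", 8000L, 10501L, "g")       # TSS at 10500
  expect_true(gene_annotated(plus, g))
  # lincRNA starts behave identically
  linc <- interval_set("chr1", 10500L, 10501L, "l1")
  expect_true(lincrna_start(plus, linc))
  expect_false(lincrna_start(minus, linc))
})

test_that("TATA scan: consensus scores 1, anti-consensus 0, oracle agreement", {
  pfm <- read_pfm(system.file("extdata", "tata_box_synthetic.pfm",
                              package = "promacet"))
  pwm <- pfm_to_pwm(pfm)
  consensus <- pfm_consensus(pfm)
  anti <- paste(rownames(pwm)[apply(pwm, 2, which.min)], collapse = "")
  expect_equal(pwm_relative_score(pwm, consensus), 1)
  expect_equal(pwm_relative_score(pwm, anti), 0)
  # relative score invariant under affine rescaling of the matrix
  set.seed(63)
  seqs <- vapply(1:5, function(i)
    paste(sample(c("A", "C", "G", "T"), ncol(pwm), TRUE), collapse = ""),
    character(1))
  for (s in seqs)
    expect_equal(pwm_relative_score(3.7 * pwm + 0.9, s),
                 pwm_relative_score(pwm, s), tolerance = 1e-9)
  # fixed 36-bp window vs exhaustive scan oracle
  win <- paste(sample(c("A", "C", "G", "T"), 36, TRUE), collapse = "")
  genome <- c(chr1 = paste0(strrep("C", 50),
                            paste(rep("A", 14), collapse = ""), win,
                            strrep("C", 100)))
  # promoter with rep at 114: window [64, 99] == positions 65..100 (1-based)
  pr <- mk_promoter("a", rep_pos = 114L)
  got <- scan_tata(pr, genome, pfm)
  expected <- oracle_pwm_best(pwm, substr(genome[["chr1"]], 65, 100))
  expect_equal(got$score, expected, tolerance = 1e-12)
  expect_identical(got$flag, expected > 0.75)
})

test_that("TATA scan respects strand and reports unscannable windows", {
  pfm <- read_pfm(system.file("extdata", "tata_box_synthetic.pfm",
                              package = "promacet"))
  consensus <- pfm_consensus(pfm)
  # plant consensus on the promoter strand of a '-' promoter:
  # genomic [rep+15, rep+50] must contain revcomp(consensus)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(consensus)))
  chrom <- strrep("C", 300)
  rep_pos <- 150L
  substr(chrom, rep_pos + 16, rep_pos + 15 + nchar(rc)) <- rc
  pr <- mk_promoter("a", strand = "-", rep_pos = rep_pos)
  got <- scan_tata(pr, c(chr1 = chrom), pfm)
  expect_equal(got$score, 1)
  expect_true(got$flag)
  # window off the contig -> unscanned
  edge <- mk_promoter("b", strand = "+", rep_pos = 30L)
  expect_true(is.na(scan_tata(edge, c(chr1 = chrom), pfm)$flag))
  # N in the window -> unscanned
  chromN <- paste0(strrep("A", 120), "N", strrep("A", 120))
  prN <- mk_promoter("c", strand = "+", rep_pos = 150L)
  expect_true(is.na(scan_tata(prN, c(chr1 = chromN), pfm)$flag))
})

test_that("flags are invariant under a constant genomic shift", {
  ds <- generate_synthetic_dataset(small_synth(n = 20, seed = 64))
  pr <- ds$promoters
  ann <- ds$annotations
  shift <- 1234L
  pr2 <- pr
  pr2$rep_pos <- pr$rep_pos + shift
  pr2$level1 <- lapply(pr$level1, function(l) transform(l, pos = pos + shift))
  class(pr2) <- class(pr)
  ann2 <- ann
  for (f in c("cpg", "repeats", "lincrna")) {
    ann2[[f]]$start <- ann[[f]]$start + shift
    ann2[[f]]$end <- ann[[f]]$end + shift
  }
  ann2$genes$txStart <- ann$genes$txStart + shift
  ann2$genes$txEnd <- ann$genes$txEnd + shift
  ann2$genes$tss <- ann$genes$tss + shift
  ann2$genome <- vapply(ann$genome, function(s)
    paste0(strrep("A", shift), s), character(1))
  a1 <- annotate_promoters(pr, ann$cpg, ann$repeats, ann$genes, ann$lincrna,
                           ann$genome)
  a2 <- annotate_promoters(pr2, ann2$cpg, ann2$repeats, ann2$genes,
                           ann2$lincrna, ann2$genome)
  expect_identical(a1$cpg, a2$cpg)
  expect_identical(a1$gene, a2$gene)
  expect_identical(a1$repeat_flag, a2$repeat_flag)
  expect_identical(a1$lincrna, a2$lincrna)
  expect_identical(a1$tata, a2$tata)
  expect_identical(a1$architecture, a2$architecture)
})

test_that("noiseless feature round trip recovers every planted flag", {
  ds <- generate_synthetic_dataset(small_synth(n = 60, seed = 65))
  ann <- annotate_promoters(ds$promoters, ds$annotations$cpg,
                            ds$annotations$repeats, ds$annotations$genes,
                            ds$annotations$lincrna, ds$annotations$genome)
  tr <- ds$truth[match(ann$id, ds$truth$id), ]
  expect_identical(ann$architecture, tr$architecture)
  expect_identical(ann$cpg, tr$cpg)
  expect_identical(ann$gene, tr$gene)
  expect_identical(ann$repeat_flag, tr$repeat_)
  expect_identical(ann$lincrna, tr$lincrna)
  expect_identical(ann$tata, tr$tata)
})
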