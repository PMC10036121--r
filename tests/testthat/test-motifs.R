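test_that("motif-hit pooling filters at the q threshold and unions overlaps", {
  v1 <- gr1(c(101, 501), c(110, 510)); v1$q <- c(0.01, 0.2)
  v2 <- gr1(c(105, 901), c(114, 910)); v2$q <- c(0.05, 0.09)
  merged <- mergeMotifHits(list(v1, v2), qThreshold = 0.1)
  # q=0.2 hit excluded; 101-110 and 105-114 union into one interval
  expect_equal(asDf(merged),
               data.frame(start = c(101, 901), end = c(114, 910)))
  # identical hits from two variants collapse to one
  dup <- mergeMotifHits(list(v1[1], v1[1]), qThreshold = 0.1)
  expect_equal(length(dup), 1L)
  # disjoint passing hits -> union of both
  expect_equal(length(mergeMotifHits(list(v1[1], v2[2]), 0.1)), 2L)
  expect_error(mergeMotifHits(list(gr1(1, 10)), 0.1), "q")
})

test_that("interval shuffling preserves lengths, chromosomes and non-overlap", {
  gm <- genomeModel(c(a = 5000L, b = 3000L))
  set.seed(2)
  gr <- GRanges(sample(c("a", "b"), 30, TRUE),
                IRanges(start = sample(2000, 30), width = sample(10:80, 30, TRUE)))
  gr$id <- seq_along(gr)
  for (s in 1:10) {
    sh <- shuffleIntervals(gr, gm, seed = s)
    expect_equal(width(sh), width(gr))           # lengths, in element order
    expect_equal(as.character(seqnames(sh)), as.character(seqnames(gr)))
    expect_equal(sh$id, gr$id)                   # metadata travels along
    expect_true(all(countOverlaps(sh, sh) == 1L))  # pairwise non-overlap
    expect_true(all(start(sh) >= 1 &
                      end(sh) <= chromLengths(gm)[as.character(seqnames(sh))]))
  }
  # determinism
  expect_equal(asDf(shuffleIntervals(gr, gm, seed = 4)),
               asDf(shuffleIntervals(gr, gm, seed = 4)))
  # infeasible placement errors, naming the chromosome
  big <- GRanges("a", IRanges(start = c(1, 1), width = c(3000, 2500)))
  expect_error(shuffleIntervals(big, gm, seed = 1), "a")
})

test_that("single-interval shuffle start positions are uniform", {
  gm <- genomeModel(c(c1 = 1000L))
  one <- gr1(300, 309, chrom = "c1")   # width 10 -> starts 1..991
  starts <- vapply(1:2000, function(s)
    start(shuffleIntervals(one, gm, seed = s)), numeric(1))
  expect_gte(min(starts), 1)
  expect_lte(max(starts), 991)
  bins <- cut(starts, breaks = seq(0.5, 991.5, length.out = 11))
  p <- stats::chisq.test(table(bins))$p.value
  expect_gt(p, 0.01)
})

test_that("the enrichment p-value hits the add-one floor on a saturated design", {
  gm <- genomeModel(c(chrT = 100000L))
  hits <- gr1(seq(5000, 95000, by = 10000), seq(5000, 95000, by = 10000) + 9,
              chrom = "chrT")
  enr <- overlapEnrichment(hits, hits, gm, nResamples = 100, seed = 5)
  expect_equal(enr$observed_overlap, 10L)
  expect_true(all(enr$permuted_overlaps < 10))
  expect_equal(enr$p_emp, 1 / 101)
  expect_equal(round(enr$p_emp, 4), 0.0099)
  expect_gt(enr$l2fc, 0)
})

test_that("features avoiding all hits give negative fold enrichment", {
  gm <- genomeModel(c(c1 = 100000L))
  hits <- gr1(seq(1, 99001, by = 1000), seq(1, 99001, by = 1000) + 99,
              chrom = "c1")
  # features in the complement of hit-bearing kilobases
  feats <- gr1(seq(301, 99301, by = 2000), seq(301, 99301, by = 2000) + 199,
               chrom = "c1")
  expect_equal(sum(countOverlaps(feats, hits)), 0L)
  enr <- overlapEnrichment(feats, hits, gm, nResamples = 50, seed = 2)
  expect_equal(enr$observed_overlap, 0L)
  expect_gte(enr$expected_mean, enr$observed_overlap)
  expect_lt(enr$l2fc, 0)
  expect_error(overlapEnrichment(GRanges(), hits, gm), "empty")
})

test_that("both shuffle modes run and record their provenance", {
  gm <- genomeModel(c(c1 = 50000L))
  set.seed(3)
  f <- randomIntervals(1, n = 20, L = 49000, chrom = "c1")
  h <- randomIntervals(2, n = 40, L = 49900, maxW = 10, chrom = "c1")
  e1 <- overlapEnrichment(f, h, gm, nResamples = 30, mode = "shuffle_motifs",
                          seed = 9)
  e2 <- overlapEnrichment(f, h, gm, nResamples = 30,
                          mode = "shuffle_features", seed = 9)
  expect_equal(e1$mode, "shuffle_motifs")
  expect_equal(e2$mode, "shuffle_features")
  expect_equal(e1$observed_overlap, e2$observed_overlap)
  expect_equal(e1$n_resamples, 30)
  expect_gte(e1$p_emp, 1 / 31)
})

test_that("TSS density is ~1 under uniform hits and recovers planted folds", {
  cfg <- simConfig(seed = 41, nChroms = 3L, chromLength = 1e6, nGenes = 400L,
                   motifBackgroundRate = 1e-3, motifTssEnrichment = 1)
  gm <- makeGenome(cfg)
  genes <- makeGenes(gm, cfg)
  mo <- plantMotifs(gm, genes, character(0), cfg)
  pr <- tssDensityProfile(genes, mo$hits, gm)
  expect_equal(nrow(pr), 50L)
  expect_lt(abs(mean(pr$normalized_density) - 1), 0.05)
  expect_true(all(pr$normalized_density >= 0))

  cfg10 <- simConfig(seed = 42, nChroms = 3L, chromLength = 1e6,
                     nGenes = 400L, motifBackgroundRate = 1e-3,
                     motifTssEnrichment = 10)
  gm10 <- makeGenome(cfg10)
  genes10 <- makeGenes(gm10, cfg10)
  tg <- genes10$gene_id[seq(1, 400, by = 4)]
  mo10 <- plantMotifs(gm10, genes10, tg, cfg10)
  pr10 <- tssDensityProfile(genes10[genes10$gene_id %in% tg], mo10$hits, gm10)
  up <- summarizeWindow(pr10, c(-500, 0))
  distal <- summarizeWindow(pr10, c(1000, 2500))
  expect_gt(up / distal, 6)
  expect_lt(up / distal, 14)
})

test_that("profile with no hits is zero and observed bp are conserved", {
  gm <- uniformGenome(100000L, 500L)
  genes <- gr1(c(20001, 60001), c(24000, 64000), strand = c("+", "-"))
  genes$gene_id <- c("gA", "gB"); genes$tss <- tssOf(genes)
  empty <- GRanges(seqinfo = seqinfo(fragments(gm)))
  pr0 <- tssDensityProfile(genes, empty, gm)
  expect_true(all(pr0$observed_bp == 0))
  hits <- gr1(c(19750, 20501, 60995), c(19759, 20510, 61004))
  pr <- tssDensityProfile(genes, hits, gm)
  win <- function(g, fl = 2500) {
    plus <- as.character(strand(g)) == "+"
    GRanges(seqnames(g), IRanges(start = tssOf(g) - fl, width = 2 * fl))
  }
  manual <- sum(width(GenomicRanges::intersect(win(genes), hits)))
  expect_equal(sum(pr$observed_bp), manual)
})

test_that("strand-aware binning mirrors minus-strand genes", {
  gm <- uniformGenome(100000L, 500L)
  # one plus gene and one minus gene with a hit 100 bp upstream of each TSS
  genes <- gr1(c(20001, 60001), c(24000, 64000), strand = c("+", "-"))
  genes$gene_id <- c("gP", "gM"); genes$tss <- tssOf(genes)
  hits <- gr1(c(20001 - 100, 64000 + 91), c(20001 - 91, 64000 + 100))
  pr <- tssDensityProfile(genes, hits, gm, flank = 500, binsize = 100)
  upBin <- which(pr$offset == -50)   # bin [-100, 0)
  expect_equal(pr$observed_bp[upBin], 20)   # both hits land there
  expect_true(all(pr$observed_bp[-upBin] == 0))
})

test_that("summarizeWindow validates alignment and averages the named bins", {
  gm <- uniformGenome(50000L, 500L)
  genes <- gr1(25001, 30000, strand = "+")
  genes$gene_id <- "g"; genes$tss <- tssOf(genes)
  hits <- gr1(seq(1, 49001, by = 1000), seq(1, 49001, by = 1000) + 9)
  pr <- tssDensityProfile(genes, hits, gm)
  expect_equal(summarizeWindow(pr, c(-2500, 2500)),
               mean(pr$normalized_density))
  expect_error(summarizeWindow(pr, c(-130, 0)), "aligned")
  expect_error(summarizeWindow(pr, c(-5000, 0)), "flank")
})

test_that("enrichment p-values are super-uniform under independence", {
  gm <- genomeModel(c(c1 = 200000L))
  ps <- vapply(1:60, function(s) {
    set.seed(s)
    f <- GRanges("c1", IRanges(start = sample(199000, 30), width = 300))
    h <- GRanges("c1", IRanges(start = sample(199900, 100), width = 10))
    overlapEnrichment(f, h, gm, nResamples = 60, seed = s)$p_emp
  }, numeric(1))
  expect_lte(mean(ps <= 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / 60))
  expect_gte(min(ps), 1 / 61)
})
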