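test_that("generators are pure functions of the seed", {
  cfg <- simConfig(seed = 11, chromLength = 2e5, nGenes = 50L)
  gm1 <- makeGenome(cfg); gm2 <- makeGenome(cfg)
  expect_identical(gatcSites(gm1), gatcSites(gm2))
  g1 <- makeGenes(gm1, cfg); g2 <- makeGenes(gm2, cfg)
  expect_identical(asDf(g1), asDf(g2))
  expect_identical(as.character(strand(g1)), as.character(strand(g2)))
  m1 <- plantMotifs(gm1, g1, g1$gene_id[1:5], cfg)
  m2 <- plantMotifs(gm2, g2, g2$gene_id[1:5], cfg)
  expect_identical(asDf(m1$hits), asDf(m2$hits))
  p1 <- plantPeaks(gm1, cfg); p2 <- plantPeaks(gm2, cfg)
  expect_identical(asDf(p1), asDf(p2))
  c1 <- simulateDamidCounts(gm1, p1, cfg)
  c2 <- simulateDamidCounts(gm2, p2, cfg)
  expect_identical(trackValues(c1$fusion[[2]]), trackValues(c2$fusion[[2]]))
  d1 <- simulateDeTable(cfg); d2 <- simulateDeTable(cfg)
  expect_identical(d1$baseline, d2$baseline)
  # different seeds give different draws
  expect_false(identical(gatcSites(makeGenome(simConfig(seed = 12,
    chromLength = 2e5))), gatcSites(gm1)))
})

test_that("GATC site count matches the Poisson expectation and spacing >= 4", {
  cfg <- simConfig(seed = 2)   # 1 Mbp, rate 1/256
  gm <- makeGenome(cfg)
  s <- gatcSites(gm)[[1]]
  expected <- 1e6 / 256
  expect_lt(abs(length(s) - expected), 3 * sqrt(expected))
  expect_true(all(diff(s) >= 4))
  expect_true(all(s >= 1 & s <= 1e6 - 3))
  expect_error(makeGenome(simConfig(chromLength = 6)), "too short")
})

test_that("simulated genes are pairwise disjoint with balanced strands", {
  cfg <- simConfig(seed = 5, nGenes = 400L, chromLength = 2e6)
  gm <- makeGenome(cfg)
  genes <- makeGenes(gm, cfg)
  expect_equal(length(genes), 400L)
  expect_true(all(countOverlaps(granges(genes), granges(genes),
                                ignore.strand = TRUE) == 1L))
  frPlus <- mean(as.character(strand(genes)) == "+")
  expect_lt(abs(frPlus - 0.5), 3 * sqrt(0.25 / 400))
  expect_true(all(genes$tss >= start(genes) & genes$tss <= end(genes)))
  # too many genes for the genome errors out
  tiny <- simConfig(seed = 5, nGenes = 400L, chromLength = 1e4)
  expect_error(makeGenes(makeGenome(tiny), tiny), "cannot place")
})

test_that("domain tiling is exact with exponential block lengths and uniform colours", {
  gm <- makeGenome(simConfig(seed = 3, nChroms = 2L, chromLength = 1e6))
  dom <- makeDomains(gm, meanLen = 5000, seed = 9)
  for (ch in names(chromLengths(gm))) {
    d <- dom[seqnames(dom) == ch]
    expect_equal(sum(width(d)), 1e6)
    expect_equal(start(d)[1], 1L)
    expect_true(all(start(d)[-1] == end(d)[-length(d)] + 1L))
  }
  # mean block length within 3 SD of the exponential mean
  nb <- length(dom)
  expect_lt(abs(mean(width(dom)) - 5000), 3 * 5000 / sqrt(nb))
  # colour marginals roughly uniform
  pr <- table(dom$label) / nb
  expect_true(all(abs(pr - 0.2) < 3 * sqrt(0.2 * 0.8 / nb) + 0.02))
  # no two adjacent blocks share a colour within a chromosome
  same <- tapply(dom$label, as.character(seqnames(dom)),
                 function(l) any(l[-1] == l[-length(l)]))
  expect_false(any(same))
})

test_that("fusion and dam are exchangeable when no enrichment is planted", {
  # KS on pooled values, 20 seeds; reject at alpha=0.01 in at most 2
  rejections <- 0L
  for (s in 1:20) {
    cfg <- simConfig(seed = 100 + s, peakEnrichment = 1, chromLength = 2e5,
                     sequencingDepth = 4e5)
    gm <- makeGenome(cfg)
    cnt <- simulateDamidCounts(gm, plantPeaks(gm, cfg), cfg)
    f <- unlist(lapply(cnt$fusion, trackValues))
    d <- unlist(lapply(cnt$dam, trackValues))
    p <- suppressWarnings(stats::ks.test(f, d)$p.value)
    rejections <- rejections + (p < 0.01)
  }
  expect_lte(rejections, 2L)
})

test_that("planted fragments carry the configured fold enrichment in the mean", {
  cfg <- simConfig(seed = 4)
  gm <- makeGenome(cfg)
  planted <- plantPeaks(gm, cfg)
  cnt <- simulateDamidCounts(gm, planted, cfg)
  fr <- fragments(gm)
  inP <- countOverlaps(fr, planted) > 0
  f <- rowMeans(sapply(cnt$fusion, trackValues))
  d <- rowMeans(sapply(cnt$dam, trackValues))
  expect_gt(sum(inP), 0)
  ratio <- mean(f[inP]) / mean(d[inP])
  expect_lt(abs(ratio - cfg@peakEnrichment), 0.75)
  # outside planted regions the two means agree
  expect_lt(abs(mean(f[!inP]) / mean(d[!inP]) - 1), 0.05)
  # counts are non-negative integers (FragmentTrack validity enforces it)
  expect_true(all(trackValues(cnt$fusion[[1]]) ==
                    round(trackValues(cnt$fusion[[1]]))))
  # zero sequencing depth is rejected at configuration time
  expect_error(simConfig(seed = 4, sequencingDepth = 0), "must be > 0")
})

test_that("planted regions sit on the fragment lattice, separated and in range", {
  cfg <- simConfig(seed = 6, nChroms = 2L)
  gm <- makeGenome(cfg)
  planted <- plantPeaks(gm, cfg)
  fr <- fragments(gm)
  expect_equal(length(planted), 2L * cfg@nPeaks)
  expect_true(all(start(planted) %in% start(fr)))
  expect_true(all(end(planted) %in% end(fr)))
  for (ch in c("chrS1", "chrS2")) {
    p <- planted[seqnames(planted) == ch]
    expect_true(all(start(p)[-1] - end(p)[-length(p)] >= 5000))
  }
})

test_that("motif hit density in TSS windows tracks the planted enrichment", {
  base <- list(seed = 13, nChroms = 2L, chromLength = 1e6, nGenes = 400L,
               motifBackgroundRate = 1e-3, tssWindow = 500L)
  genomeRate <- function(cfg, tg) {
    gm <- makeGenome(cfg)
    genes <- makeGenes(gm, cfg)
    targets <- genes$gene_id[seq(1, 400, by = 2)]
    mo <- plantMotifs(gm, genes, if (tg) targets else character(0), cfg)
    tgGenes <- genes[genes$gene_id %in% targets]
    ntGenes <- genes[!genes$gene_id %in% targets]
    win <- function(g) {
      plus <- as.character(strand(g)) == "+"
      GRanges(seqnames(g),
              IRanges(start = ifelse(plus, g$tss - 500L, g$tss + 1L),
                      width = 500L))
    }
    c(target = sum(countOverlaps(win(tgGenes), mo$hits) > 0) /
        length(tgGenes),
      nontarget = sum(countOverlaps(win(ntGenes), mo$hits) > 0) /
        length(ntGenes),
      nHits = length(mo$hits))
  }
  cfg1 <- do.call(simConfig, c(base, motifTssEnrichment = 1))
  r1 <- genomeRate(cfg1, tg = TRUE)
  expect_lt(abs(r1["target"] / r1["nontarget"] - 1), 0.35)
  # 10x planted fold: compare hit counts in target vs non-target windows on
  # a sparse gene layout, so neighbouring windows cannot catch planted hits
  cfg10 <- simConfig(seed = 13, nChroms = 3L, chromLength = 1e6,
                     nGenes = 150L, motifBackgroundRate = 1e-3,
                     motifTssEnrichment = 10, tssWindow = 500L)
  gm <- makeGenome(cfg10); genes <- makeGenes(gm, cfg10)
  targets <- genes$gene_id[seq(1, 150, by = 2)]
  mo <- plantMotifs(gm, genes, targets, cfg10)
  win <- function(g) {
    plus <- as.character(strand(g)) == "+"
    GRanges(seqnames(g), IRanges(start = ifelse(plus, g$tss - 500L,
                                                g$tss + 1L), width = 500L))
  }
  tgN <- sum(countOverlaps(win(genes[genes$gene_id %in% targets]), mo$hits))
  ntN <- sum(countOverlaps(win(genes[!genes$gene_id %in% targets]), mo$hits))
  expect_gt(tgN / ntN, 6)
  expect_lt(tgN / ntN, 14)
})

test_that("DE truth labels partition the planted DE genes", {
  cfg <- simConfig(seed = 21)
  de <- simulateDeTable(cfg)
  tr <- de$truth
  expect_equal(nrow(tr), cfg@nDeGenes)
  expect_equal(sum(tr$label != "unchanged"), cfg@nDe)
  expect_equal(sum(tr$label == "reverted"), round(0.3 * cfg@nDe))
  expect_equal(sum(tr$label == "restored"), round(0.3 * cfg@nDe))
  # treatment truth follows the labels
  expect_true(all(tr$treatment_l2fc[tr$label == "restored"] == 0))
  expect_true(all(tr$treatment_l2fc[tr$label == "reverted"] ==
                    -tr$baseline_l2fc[tr$label == "reverted"]))
  expect_true(all(tr$treatment_l2fc[tr$label == "still_changed"] ==
                    tr$baseline_l2fc[tr$label == "still_changed"]))
  expect_true(all(abs(tr$baseline_l2fc[tr$label != "unchanged"]) >= 1.5))
  # observed l2fc of restored genes is centred at zero
  obs <- de$treatment$l2fc[tr$label == "restored"]
  expect_lt(abs(mean(obs)), 3 * 0.15 / sqrt(length(obs)))
})

test_that("in the noise-free limit observed l2fc equals the truth", {
  cfg <- simConfig(seed = 22, seRange = c(1e-9, 1e-9))
  de <- simulateDeTable(cfg)
  expect_equal(de$baseline$l2fc, de$truth$baseline_l2fc, tolerance = 1e-6)
  expect_equal(de$treatment$l2fc, de$truth$treatment_l2fc, tolerance = 1e-6)
})

test_that("writeSimulation emits a complete, re-loadable file tree", {
  dir <- withr::local_tempdir()
  cfg <- simConfig(seed = 31, chromLength = 1e5, nGenes = 20L,
                   sequencingDepth = 2e5, nDeGenes = 100L, nDe = 20L)
  sim <- writeSimulation(cfg, dir)
  expect_true(all(file.exists(file.path(dir,
    c("chrom.sizes", "gatc.bed", "genes.gff3", "domains.bed",
      "planted_peaks.bed", "motifs.bed", "baseline_de.tsv",
      "treatment_de.tsv", "truth.json", "fusion_rep1.counts.bedgraph",
      "dam_rep3.counts.bedgraph")))))
  gm <- readGenome(file.path(dir, "chrom.sizes"), file.path(dir, "gatc.bed"))
  expect_equal(chromLengths(gm), chromLengths(sim$genome))
  expect_identical(gatcSites(gm), gatcSites(sim$genome))
  genes <- readGenes(file.path(dir, "genes.gff3"), gm)
  expect_equal(genes$gene_id, sim$genes$gene_id)
  tr <- readBedgraph(file.path(dir, "fusion_rep1.counts.bedgraph"), gm,
                     kind = "count")
  expect_equal(trackValues(tr), trackValues(sim$counts$fusion[[1]]))
  de <- readDeTable(file.path(dir, "baseline_de.tsv"))
  expect_equal(de$l2fc, sim$de$baseline$l2fc, tolerance = 1e-6)
})
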