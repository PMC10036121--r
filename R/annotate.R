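#' Genes targeted by a peak set
#'
#' A gene is a target of the profiled factor iff some peak overlaps its
#' span by at least 1 bp — anywhere on the gene's length, introns
#' included. Strand is ignored.
#'
#' @param peaks a \code{GRanges} of peaks.
#' @param genes gene models with a \code{gene_id} column.
#' @return sorted character vector of target gene_ids.
#' @export
assignTargets <- function(peaks, genes) {
  hit <- countOverlaps(genes, peaks, ignore.strand = TRUE) > 0
  sort(unique(genes$gene_id[hit]))
}

#' Classify peaks by genomic feature
#'
#' Each peak is classified by its midpoint with priority promoter-TSS >
#' gene body > TTS window > intergenic. The promoter window is
#' strand-aware around the TSS (default 1000 bp upstream to 100 bp
#' downstream, the usual annotation default); the TTS window runs from
#' 100 bp inside to 1000 bp past the gene end. Without an exon model the
#' gene body is reported as \code{"intron"}.
#'
#' @param peaks a \code{GRanges}.
#' @param genes stranded gene models.
#' @param promoterWindow \code{c(upstream, downstream)} bp around the TSS.
#' @param ttsWindow \code{c(inside, past)} bp around the gene end.
#' @return a list with \code{categories} (one per peak) and
#'   \code{fractions} (over all peaks; sums to 1).
#' @export
annotatePeakFeatures <- function(peaks, genes,
                                 promoterWindow = c(1000, 100),
                                 ttsWindow = c(100, 1000)) {
  if (length(peaks) == 0L)
    return(list(categories = character(0), fractions = numeric(0)))
  mids <- GRanges(seqnames(peaks),
                  IRanges(start = (start(peaks) + end(peaks)) %/% 2L, width = 1L))
  plus <- as.character(strand(genes)) == "+"
  tss <- tssOf(genes)
  prom <- GRanges(seqnames(genes),
                  IRanges(start = ifelse(plus, tss - promoterWindow[1],
                                         tss - promoterWindow[2]),
                          end = ifelse(plus, tss + promoterWindow[2],
                                       tss + promoterWindow[1])))
  tts <- ifelse(plus, end(genes), start(genes))
  ttsW <- GRanges(seqnames(genes),
                  IRanges(start = ifelse(plus, tts - ttsWindow[1],
                                         tts - ttsWindow[2]),
                          end = ifelse(plus, tts + ttsWindow[2],
                                       tts + ttsWindow[1])))
  inProm <- countOverlaps(mids, prom) > 0
  inBody <- countOverlaps(mids, granges(genes), ignore.strand = TRUE) > 0
  inTts <- countOverlaps(mids, ttsW) > 0
  cat <- rep("intergenic", length(mids))
  cat[inTts] <- "tts"
  cat[inBody] <- "intron"
  cat[inProm] <- "promoter-TSS"
  fr <- table(factor(cat, levels = c("promoter-TSS", "intron", "tts",
                                     "intergenic")))
  list(categories = cat,
       fractions = setNames(as.vector(fr) / length(mids), names(fr)))
}

#' Chromatin-colour allocation of target genes with a permutation test
#'
#' Each gene is assigned the single colour covering the largest share of
#' its span (ties broken by the domain set's colour order). The expected
#' proportion per colour comes from all genes; the observed counts are
#' compared to resamples of \code{length(targetGenes)} genes drawn
#' uniformly without replacement from all genes. The per-colour
#' permutation p-value uses the add-one estimator
#' \eqn{(1 + \#\{\mathrm{resample\ count} \ge \mathrm{observed}\}) /
#' (n_{\mathrm{resamples}} + 1)} (one-sided, enrichment).
#'
#' @param targetGenes character vector of target gene_ids (non-empty).
#' @param allGenes gene models with a \code{gene_id} column; every gene
#'   must overlap at least one domain.
#' @param domains a \code{GRanges} with a \code{label} colour column.
#' @param nResamples number of resamples (default 1000).
#' @param seed RNG seed.
#' @return a \code{data.frame} with one row per colour: observed_count,
#'   observed_proportion, expected_proportion, ratio, permutation_p.
#' @export
domainAllocation <- function(targetGenes, allGenes, domains,
                             nResamples = 1000, seed = 1) {
  if (length(targetGenes) == 0L) stop("empty target gene set")
  if (!all(targetGenes %in% allGenes$gene_id))
    stop("targetGenes must be a subset of allGenes$gene_id")
  colors <- unique(domains$label)
  fo <- findOverlaps(allGenes, domains, ignore.strand = TRUE)
  if (length(setdiff(seq_along(allGenes), queryHits(fo))) > 0L)
    stop("some genes overlap no chromatin domain")
  w <- width(pintersect(granges(allGenes)[queryHits(fo)],
                        granges(domains)[subjectHits(fo)]))
  colIdx <- match(domains$label[subjectHits(fo)], colors)
  cov <- matrix(0, nrow = length(allGenes), ncol = length(colors))
  for (k in seq_along(colors)) {
    sel <- colIdx == k
    if (any(sel)) {
      s <- rowsum(w[sel], queryHits(fo)[sel])
      cov[as.integer(rownames(s)), k] <- as.vector(s)
    }
  }
  geneColor <- colors[max.col(cov, ties.method = "first")]
  expectedCount <- tabulate(match(geneColor, colors), nbins = length(colors))
  expectedProp <- expectedCount / length(allGenes)
  isTarget <- allGenes$gene_id %in% targetGenes
  m <- sum(isTarget)
  obsCount <- tabulate(match(geneColor[isTarget], colors),
                       nbins = length(colors))
  geneColorIdx <- match(geneColor, colors)
  permGE <- integer(length(colors))
  withSeed(stageSeed(seed, "domain_allocation"), {
    for (r in seq_len(nResamples)) {
      idx <- sample.int(length(allGenes), m)
      cnt <- tabulate(geneColorIdx[idx], nbins = length(colors))
      permGE <- permGE + as.integer(cnt >= obsCount)
    }
  })
  obsProp <- obsCount / m
  data.frame(color = colors,
             observed_count = obsCount,
             observed_proportion = obsProp,
             expected_proportion = expectedProp,
             ratio = obsProp / expectedProp,
             permutation_p = (1 + permGE) / (nResamples + 1))
}
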