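#' Pool motif-hit sets at a q-value threshold
#'
#' Filters each motif variant's hits at \code{q <= qThreshold} (the
#' per-hit match q-value must be in a \code{q} metadata column when
#' filtering is requested), pools the survivors across variants, and
#' unions overlapping hits into single intervals (gap 0).
#'
#' @param hitSets a list of \code{GRanges}, one per motif variant.
#' @param qThreshold q-value cutoff (default 0.1); \code{NULL} skips
#'   filtering.
#' @return a sorted, unioned \code{GRanges}.
#' @export
mergeMotifHits <- function(hitSets, qThreshold = 0.1) {
  if (!is.list(hitSets)) hitSets <- list(hitSets)
  kept <- lapply(hitSets, function(g) {
    if (!is.null(qThreshold)) {
      if (is.null(g$q)) stop("hit set lacks a 'q' column; cannot filter")
      g <- g[g$q <= qThreshold]
    }
    granges(g)
  })
  reduce(do.call(c, kept), ignore.strand = TRUE)
}

#' Randomly re-place intervals on the genome
#'
#' Each interval is re-placed uniformly at random with its length
#' preserved — on its own chromosome when \code{preserveChromosome} — and,
#' when \code{forbidOverlap}, subject to pairwise non-overlap of the
#' placed set. Non-overlapping placement is sampled exactly (uniformly
#' over all non-overlapping configurations) rather than by rejection.
#' Metadata columns travel with their intervals. Deterministic given
#' \code{seed}.
#'
#' @param set a \code{GRanges}.
#' @param genome a [GenomeModel].
#' @param preserveChromosome keep each interval on its chromosome
#'   (default \code{TRUE}).
#' @param forbidOverlap require the placed intervals to be pairwise
#'   non-overlapping (default \code{TRUE}).
#' @param seed RNG seed.
#' @return a \code{GRanges} in the original element order.
#' @export
shuffleIntervals <- function(set, genome, preserveChromosome = TRUE,
                             forbidOverlap = TRUE, seed = 1) {
  checkWithinGenome(set, genome, what = "interval")
  cl <- chromLengths(genome)
  withSeed(stageSeed(seed, "shuffle"), {
    chrom <- as.character(seqnames(set))
    if (!preserveChromosome)
      chrom <- sample(names(cl), length(set), replace = TRUE,
                      prob = as.numeric(cl))
    lens <- width(set)
    newStart <- integer(length(set))
    for (ch in unique(chrom)) {
      idx <- which(chrom == ch)
      L <- cl[[ch]]
      if (forbidOverlap) {
        newStart[idx] <- placeNonOverlapping(lens[idx], L, "interval", ch)
      } else {
        newStart[idx] <- 1L + as.integer(floor(runif(length(idx)) *
                                                 (L - lens[idx] + 1)))
      }
    }
    out <- GRanges(chrom, IRanges(start = newStart, width = lens))
    out <- setGenomeSeqinfo(out, genome)
    mcols(out) <- mcols(set)
    out
  })
}

#' Permutation test for motif-overlap enrichment
#'
#' The observed statistic is the number of feature intervals overlapping
#' at least one motif hit by at least 1 bp. Under the null, the set named
#' by \code{mode} is re-placed with [shuffleIntervals()] (chromosome
#' preserved, non-overlapping) \code{nResamples} times and the statistic
#' recounted. Reported are the mean permuted overlap, the log2 fold
#' enrichment \eqn{\log_2((\mathrm{obs}+\epsilon)/(\mathrm{mean}+\epsilon))}
#' with \eqn{\epsilon = 0.5}, and the one-sided add-one empirical p-value
#' \eqn{(1 + \#\{\mathrm{perm} \ge \mathrm{obs}\})/(n+1)}, which can never
#' report 0 and has floor \eqn{1/(n+1)}.
#'
#' @param features a non-empty \code{GRanges} (e.g. factor-occupancy
#'   peaks).
#' @param hits motif-hit \code{GRanges}.
#' @param genome a [GenomeModel].
#' @param nResamples number of shuffles (default 100).
#' @param mode which set to shuffle: \code{"shuffle_motifs"} (default) or
#'   \code{"shuffle_features"}.
#' @param seed RNG seed.
#' @param eps pseudo-count in the fold change (default 0.5).
#' @return a list of class \code{EnrichmentResult}: observed_overlap,
#'   permuted_overlaps, expected_mean, l2fc, p_emp, n_resamples, mode,
#'   seed.
#' @export
overlapEnrichment <- function(features, hits, genome, nResamples = 100,
                              mode = c("shuffle_motifs", "shuffle_features"),
                              seed = 1, eps = 0.5) {
  mode <- match.arg(mode)
  if (length(features) == 0L) stop("empty feature set")
  checkWithinGenome(features, genome, "feature")
  checkWithinGenome(hits, genome, "motif hit")
  countFn <- function(f, h) sum(countOverlaps(f, h, ignore.strand = TRUE) > 0)
  observed <- countFn(features, hits)
  perm <- vapply(seq_len(nResamples), function(r) {
    if (mode == "shuffle_motifs")
      countFn(features, shuffleIntervals(hits, genome, seed = seed * 1000 + r))
    else
      countFn(shuffleIntervals(features, genome, seed = seed * 1000 + r), hits)
  }, numeric(1))
  expectedMean <- mean(perm)
  structure(list(observed_overlap = observed,
                 permuted_overlaps = perm,
                 expected_mean = expectedMean,
                 l2fc = log2((observed + eps) / (expectedMean + eps)),
                 p_emp = (1 + sum(perm >= observed)) / (nResamples + 1),
                 n_resamples = nResamples,
                 mode = mode,
                 seed = seed),
            class = "EnrichmentResult")
}

#' @export
print.EnrichmentResult <- function(x, ...) {
  cat(sprintf(paste0("Permutation overlap enrichment (%s, %d resamples, ",
                     "seed %s)\n  observed %d, expected %.2f, ",
                     "l2fc %.3f, p_emp %.4g\n"),
              x$mode, x$n_resamples, format(x$seed), x$observed_overlap,
              x$expected_mean, x$l2fc, x$p_emp))
  invisible(x)
}

#' TSS-relative motif density, normalized to the genome-wide expectation
#'
#' For each gene, motif-hit-covered bp are counted in strand-aware bins
#' spanning \code{[-flank, +flank)} around the TSS (negative = upstream;
#' bins of minus-strand genes are mirrored) and summed over genes. The
#' expected count per bin is the bin's total genomic width across genes
#' (bins truncated at chromosome ends contribute only their retained
#' width) times the fraction of the genome covered by hits, so a
#' normalized density of 1.0 means exactly the genome-average overlap.
#' Overlapping hits are unioned before counting.
#'
#' @param genes a non-empty stranded gene \code{GRanges} (the subset of
#'   interest).
#' @param hits motif-hit \code{GRanges}.
#' @param genome a [GenomeModel].
#' @param flank half-width in bp (default 2500).
#' @param binsize bin width in bp (default 100); must divide \code{flank}.
#' @return a \code{data.frame} of class \code{TssDensityProfile} with
#'   columns offset (bin centre), observed_bp, expected_bp,
#'   normalized_density; attributes n_genes, genome_motif_fraction,
#'   flank, binsize.
#' @export
tssDensityProfile <- function(genes, hits, genome, flank = 2500,
                              binsize = 100) {
  if (length(genes) == 0L) stop("empty gene set")
  if (flank %% binsize != 0) stop("flank must be a multiple of binsize")
  checkWithinGenome(genes, genome, "gene")
  hits <- reduce(granges(hits), ignore.strand = TRUE)
  motifFraction <- sum(as.numeric(width(hits))) / genomeLength(genome)
  nb <- as.integer(2 * flank / binsize)
  off <- -flank + (seq_len(nb) - 1L) * binsize
  tss <- tssOf(genes)
  plus <- as.character(strand(genes)) == "+"
  chrom <- rep(as.character(seqnames(genes)), each = nb)
  gtss <- rep(tss, each = nb)
  gplus <- rep(plus, each = nb)
  o <- rep(off, length(genes))
  # + strand: bin [o, o+binsize) right of tss; - strand mirrored
  bs <- ifelse(gplus, gtss + o, gtss - o - binsize + 1L)
  binIdx <- rep(seq_len(nb), length(genes))
  L <- chromLengths(genome)[chrom]
  s <- pmax(bs, 1)
  e <- pmin(bs + binsize - 1, L)
  keep <- s <= e
  bins <- GRanges(chrom[keep], IRanges(start = s[keep], end = e[keep]))
  bi <- binIdx[keep]
  expected <- numeric(nb)
  s1 <- rowsum(width(bins), bi)
  expected[as.integer(rownames(s1))] <- as.vector(s1) * motifFraction
  fo <- findOverlaps(bins, hits, ignore.strand = TRUE)
  wcov <- width(pintersect(bins[queryHits(fo)], hits[subjectHits(fo)]))
  observed <- numeric(nb)
  if (length(fo) > 0L) {
    s2 <- rowsum(wcov, bi[queryHits(fo)])
    observed[as.integer(rownames(s2))] <- as.vector(s2)
  }
  out <- data.frame(offset = off + binsize / 2,
                    observed_bp = observed,
                    expected_bp = expected,
                    normalized_density = observed / expected)
  attr(out, "n_genes") <- length(genes)
  attr(out, "genome_motif_fraction") <- motifFraction
  attr(out, "flank") <- flank
  attr(out, "binsize") <- binsize
  class(out) <- c("TssDensityProfile", "data.frame")
  out
}

#' Mean normalized motif density over a TSS-relative window
#'
#' @param profile a [tssDensityProfile()] result.
#' @param window \code{c(from, to)} in bp relative to the TSS; must be
#'   aligned to bin boundaries and lie inside the profiled flank.
#' @return mean normalized density over the bins inside
#'   \code{[from, to)}.
#' @export
summarizeWindow <- function(profile, window) {
  stopifnot(inherits(profile, "TssDensityProfile"), length(window) == 2L,
            window[1] < window[2])
  b <- attr(profile, "binsize")
  fl <- attr(profile, "flank")
  if (window[1] < -fl || window[2] > fl)
    stop("window outside the profiled flank")
  if (window[1] %% b != 0 || window[2] %% b != 0)
    stop("window must be aligned to bin boundaries")
  lo <- profile$offset - b / 2
  hi <- profile$offset + b / 2
  sel <- lo >= window[1] & hi <= window[2]
  mean(profile$normalized_density[sel])
}
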