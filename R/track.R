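#' Construct a FragmentTrack
#'
#' @param genome a [GenomeModel].
#' @param values numeric, one value per GATC fragment in genome order.
#' @param kind \code{"count"}, \code{"coverage"} or \code{"log2ratio"}.
#' @return a validated [FragmentTrack].
#' @export
fragmentTrack <- function(genome, values, kind = "count") {
  new("FragmentTrack", genome = genome, values = as.numeric(values),
      kind = kind)
}

#' @rdname FragmentTrack-class
#' @export
setMethod("trackValues", "FragmentTrack", function(x) x@values)

#' @rdname FragmentTrack-class
#' @export
setMethod("trackKind", "FragmentTrack", function(x) x@kind)

#' @rdname FragmentTrack-class
#' @export
setMethod("trackGenome", "FragmentTrack", function(x) x@genome)

#' @describeIn FragmentTrack-class the track as a \code{GRanges} with a
#'   \code{score} column, one range per fragment.
#' @export
setMethod("fragments", "FragmentTrack", function(x) {
  gr <- fragments(x@genome)
  gr$score <- x@values
  gr
})

setMethod("show", "FragmentTrack", function(object) {
  v <- object@values
  cat(sprintf("FragmentTrack (%s): %d fragments, range [%.4g, %.4g], mean %.4g\n",
              object@kind, length(v),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA,
              if (length(v)) mean(v) else NA))
  invisible(NULL)
})

#' Parameters for the log2 ratio transform
#'
#' @param pseudocount value \eqn{\psi \ge 0} added to both numerator and
#'   denominator counts so zero-count fragments stay finite and unbiased in
#'   sign (default 0.5).
#' @param normalization \code{"library_size"} scales the Dam-only counts by
#'   total(fusion)/total(Dam) before taking the ratio; \code{"none"} uses
#'   raw counts.
#' @return a list of class \code{RatioParams}.
#' @export
ratioParams <- function(pseudocount = 0.5,
                        normalization = c("library_size", "none")) {
  stopifnot(is.numeric(pseudocount), length(pseudocount) == 1L,
            pseudocount >= 0)
  structure(list(pseudocount = pseudocount,
                 normalization = match.arg(normalization)),
            class = "RatioParams")
}

sameLattice <- function(a, b) {
  identical(chromLengths(a), chromLengths(b)) &&
    identical(gatcSites(a), gatcSites(b))
}

#' Log2 Dam-fusion / Dam ratio at GATC resolution
#'
#' The core DamID signal transform: per fragment \eqn{i},
#' \deqn{r_i = \log_2\left(\frac{f_i + \psi}{d'_i + \psi}\right)}
#' where \eqn{f_i} are Dam-fusion counts and \eqn{d'_i} Dam-only counts
#' after library-size scaling (so swapping the two tracks exactly negates
#' every value).
#'
#' @param fusion,dam count [FragmentTrack]s on the same genome.
#' @param params a [ratioParams()] object.
#' @return a [FragmentTrack] of kind \code{"log2ratio"}.
#' @export
computeLog2Ratio <- function(fusion, dam, params = ratioParams()) {
  stopifnot(is(fusion, "FragmentTrack"), is(dam, "FragmentTrack"))
  if (trackKind(fusion) != "count" || trackKind(dam) != "count")
    stop("computeLog2Ratio expects count tracks")
  if (!sameLattice(trackGenome(fusion), trackGenome(dam)))
    stop("fusion and dam tracks are on different genomes")
  f <- trackValues(fusion)
  d <- trackValues(dam)
  if (params$normalization == "library_size") {
    # scale both to the geometric mean of the totals: identical ratios to
    # scaling Dam by total(fusion)/total(Dam) when psi = 0, but exactly
    # antisymmetric under a fusion/dam swap for any psi
    if (sum(d) == 0) stop("total Dam count is zero")
    if (sum(f) == 0) stop("total fusion count is zero")
    tot <- sqrt(sum(f) * sum(d))
    f <- f * (tot / sum(f))
    d <- d * (tot / sum(d))
  }
  psi <- params$pseudocount
  fragmentTrack(trackGenome(fusion), log2((f + psi) / (d + psi)),
                kind = "log2ratio")
}

#' Normalize counts to 1x genome coverage
#'
#' Converts fragment counts to reads-per-genome-coverage: each fragment's
#' count is turned into a coverage density \eqn{c_i = n_i \cdot
#' \mathrm{readLen} / w_i} and the track is rescaled so its length-weighted
#' genome mean is exactly 1. A value of 1 therefore means genome-average
#' coverage. Used for accessibility (Dam-only, CATaDa) tracks, which are
#' not expressed as ratios.
#'
#' @param counts a count [FragmentTrack].
#' @param readLen the (extended) read length in bp used as the coverage
#'   constant; default 300.
#' @return a [FragmentTrack] of kind \code{"coverage"}.
#' @export
normalizeCoverage1x <- function(counts, readLen = 300) {
  stopifnot(is(counts, "FragmentTrack"))
  if (trackKind(counts) != "count")
    stop("normalizeCoverage1x expects a count track")
  v <- trackValues(counts)
  if (sum(v) == 0) stop("all-zero count track cannot be normalized")
  genome <- trackGenome(counts)
  w <- width(fragments(genome))
  cdens <- v * readLen / w
  scale <- genomeLength(genome) / sum(cdens * w)
  fragmentTrack(genome, cdens * scale, kind = "coverage")
}

#' Average signal metaprofile around anchor points
#'
#' For every anchor interval the signal is sampled in fixed-width bins
#' centred on the anchor midpoint; the per-bin value is the length-weighted
#' mean of the fragment values overlapping that bin, and the profile is the
#' unweighted mean over anchors. Bins extending past a chromosome end are
#' excluded for that anchor (the \code{n_anchors} column records how many
#' anchors contributed to each bin).
#'
#' @param track a [FragmentTrack].
#' @param anchors a non-empty \code{GRanges}; the anchor point is the
#'   interval midpoint.
#' @param flank half-width of the profile in bp (default 2500).
#' @param binsize bin width in bp (default 50); must divide \code{flank}.
#' @return a \code{data.frame} with columns \code{offset} (bin centre
#'   relative to the anchor, negative = left), \code{mean_signal} and
#'   \code{n_anchors} (\code{mean_signal} is \code{NaN} where no anchor
#'   contributes).
#' @export
metaprofile <- function(track, anchors, flank = 2500, binsize = 50) {
  stopifnot(is(track, "FragmentTrack"), is(anchors, "GRanges"))
  if (length(anchors) == 0L) stop("anchors must be non-empty")
  if (flank %% binsize != 0) stop("flank must be a multiple of binsize")
  genome <- trackGenome(track)
  checkWithinGenome(anchors, genome, what = "anchor")
  nb <- as.integer(2 * flank / binsize)
  off <- -flank + (seq_len(nb) - 1L) * binsize          # bin left edges
  mids <- (start(anchors) + end(anchors)) %/% 2L
  chrom <- rep(as.character(seqnames(anchors)), each = nb)
  bs <- rep(mids, each = nb) + rep(off, length(anchors))
  binIdx <- rep(seq_len(nb), length(anchors))
  L <- chromLengths(genome)[chrom]
  keep <- bs >= 1L & (bs + binsize - 1L) <= L
  if (!any(keep)) stop("no bin lies inside the genome for any anchor")
  bins <- setGenomeSeqinfo(
    GRanges(chrom[keep], IRanges(start = bs[keep], width = binsize)), genome)
  fr <- fragments(genome)
  v <- trackValues(track)
  fo <- findOverlaps(bins, fr)
  w <- width(pintersect(bins[queryHits(fo)], fr[subjectHits(fo)]))
  num <- rowsum(v[subjectHits(fo)] * w, queryHits(fo))
  den <- rowsum(w, queryHits(fo))
  binMean <- as.vector(num / den)
  bi <- binIdx[keep][as.integer(rownames(num))]
  meanSignal <- rep(NaN, nb)
  agg <- rowsum(binMean, bi)
  cnt <- tabulate(bi, nbins = nb)
  meanSignal[as.integer(rownames(agg))] <- as.vector(agg) / cnt[as.integer(rownames(agg))]
  data.frame(offset = off + binsize / 2,
             mean_signal = meanSignal,
             n_anchors = cnt)
}
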