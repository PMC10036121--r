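#' Parameters for shuffle-FDR peak calling
#'
#' @param fdrThreshold retain peaks with estimated FDR strictly below this
#'   (default 0.01).
#' @param quantileThreshold fragment-value quantile used as the run
#'   threshold (default 0.95); fragments exactly at the threshold are
#'   included.
#' @param minFragments minimum run length in fragments (default 2).
#' @param nShuffles number of value permutations used to build the null
#'   (default 100; more gives a finer-grained FDR estimate).
#' @param perChromosome permute values within each chromosome (default
#'   \code{TRUE}) rather than genome-wide.
#' @param seed RNG seed for the permutations.
#' @return a list of class \code{PeakCallParams}.
#' @export
peakCallParams <- function(fdrThreshold = 0.01, quantileThreshold = 0.95,
                           minFragments = 2L, nShuffles = 100L,
                           perChromosome = TRUE, seed = 1L) {
  stopifnot(fdrThreshold > 0, fdrThreshold < 1,
            quantileThreshold > 0, quantileThreshold < 1,
            minFragments >= 1L, nShuffles >= 1L)
  structure(list(fdrThreshold = fdrThreshold,
                 quantileThreshold = quantileThreshold,
                 minFragments = as.integer(minFragments),
                 nShuffles = as.integer(nShuffles),
                 perChromosome = isTRUE(perChromosome),
                 seed = as.integer(seed)),
            class = "PeakCallParams")
}

# Maximal same-chromosome runs of >= minFrag consecutive fragments with
# value >= threshold. Returns first/last fragment index, run length, and
# the mean value (the run score).
runsAboveThreshold <- function(vals, chromIdx, threshold, minFrag) {
  n <- length(vals)
  if (n == 0L) return(data.frame(first = integer(0), last = integer(0),
                                 n = integer(0), score = numeric(0)))
  above <- vals >= threshold
  brk <- c(TRUE, chromIdx[-1L] != chromIdx[-n] | above[-1L] != above[-n])
  id <- cumsum(brk)
  first <- which(brk)
  len <- diff(c(first, n + 1L))
  keep <- above[first] & len >= minFrag
  if (!any(keep)) return(data.frame(first = integer(0), last = integer(0),
                                    n = integer(0), score = numeric(0)))
  sums <- as.vector(rowsum(vals, id, reorder = FALSE))
  data.frame(first = first[keep], last = (first + len - 1L)[keep],
             n = len[keep], score = (sums / len)[keep])
}

permuteWithinChrom <- function(vals, chromIdx, perChromosome) {
  if (!perChromosome || length(unique(chromIdx)) == 1L) return(sample(vals))
  out <- vals
  for (ci in unique(chromIdx)) {
    idx <- which(chromIdx == ci)
    out[idx] <- vals[idx][sample.int(length(idx))]
  }
  out
}

#' Call FDR-controlled peaks from a log2 ratio track
#'
#' Candidate peaks are maximal runs of at least \code{minFragments}
#' consecutive same-chromosome fragments whose value meets or exceeds the
#' \code{quantileThreshold} quantile of all fragment values; the run score
#' is the mean fragment value. The null is built by permuting the fragment
#' values (within each chromosome by default) \code{nShuffles} times and
#' re-extracting candidates. For each observed score \eqn{s},
#' \deqn{\mathrm{FDR}(s) = \frac{\mathrm{mean\ null\ candidates\ scoring}
#' \ge s}{\#\{\mathrm{observed\ candidates\ scoring} \ge s\}}}
#' capped at 1 and made monotone non-increasing in \eqn{s}; peaks with
#' \eqn{\mathrm{FDR} <} \code{fdrThreshold} are retained. Peak extent runs
#' from the first fragment's start to the last fragment's end.
#'
#' @param track a log2-ratio [FragmentTrack].
#' @param params a [peakCallParams()] object.
#' @return a list with \code{peaks} (retained, as a \code{GRanges} with
#'   \code{score}, \code{n_fragments}, \code{fdr}) and \code{candidates}
#'   (all candidates with their FDRs, same form), plus the threshold used.
#' @export
callPeaks <- function(track, params = peakCallParams()) {
  stopifnot(is(track, "FragmentTrack"))
  genome <- trackGenome(track)
  fr <- fragments(genome)
  vals <- trackValues(track)
  empty <- GRanges(score = numeric(0), n_fragments = integer(0),
                   fdr = numeric(0))
  if (length(vals) < params$minFragments)
    return(list(peaks = empty, candidates = empty, threshold = NA_real_))
  chromIdx <- as.integer(match(as.character(seqnames(fr)), seqlevels(fr)))
  threshold <- quantile(vals, params$quantileThreshold, names = FALSE)
  obs <- runsAboveThreshold(vals, chromIdx, threshold, params$minFragments)
  if (nrow(obs) == 0L)
    return(list(peaks = empty, candidates = empty, threshold = threshold))
  nullScores <- withSeed(params$seed, {
    unlist(lapply(seq_len(params$nShuffles), function(i) {
      pv <- permuteWithinChrom(vals, chromIdx, params$perChromosome)
      runsAboveThreshold(pv, chromIdx, threshold, params$minFragments)$score
    }), use.names = FALSE)
  })
  sortedNull <- sort(nullScores)
  sortedObs <- sort(obs$score)
  nullGE <- (length(sortedNull) -
               findInterval(obs$score, sortedNull, left.open = TRUE)) /
    params$nShuffles
  obsGE <- nrow(obs) - findInterval(obs$score, sortedObs, left.open = TRUE)
  raw <- pmin(1, nullGE / obsGE)
  ord <- order(obs$score)
  fdr <- numeric(nrow(obs))
  fdr[ord] <- cummin(raw[ord])
  cand <- GRanges(seqnames(fr)[obs$first],
                  IRanges(start = start(fr)[obs$first], end = end(fr)[obs$last]),
                  score = obs$score, n_fragments = obs$n, fdr = fdr)
  seqinfo(cand) <- seqinfo(fr)
  keep <- fdr < params$fdrThreshold
  list(peaks = cand[keep], candidates = cand, threshold = threshold)
}

#' Merge overlapping or nearby intervals
#'
#' Same-chromosome intervals whose gap is at most \code{maxGap} bp are
#' transitively unioned (strand is ignored); a gap of exactly
#' \code{maxGap + 1} is left unmerged.
#'
#' @param set a \code{GRanges}.
#' @param maxGap maximum gap in bp (default 50).
#' @return a sorted, merged \code{GRanges}.
#' @export
mergeIntervals <- function(set, maxGap = 50) {
  reduce(set, min.gapwidth = maxGap + 1L, ignore.strand = TRUE)
}

#' Consensus peaks across replicates
#'
#' The genome is segmented at every replicate interval boundary; segments
#' covered by at least \code{minSupport} replicates are kept and then
#' merged with [mergeIntervals()] (multi-intersect semantics, since
#' replicate peak boundaries never match exactly).
#'
#' @param replicates a list of \code{GRanges}, one per replicate.
#' @param minSupport minimum number of supporting replicates (default 2).
#' @param maxGap gap for the final merge (default 50 bp).
#' @return a sorted \code{GRanges} of consensus intervals.
#' @export
consensusPeaks <- function(replicates, minSupport = 2L, maxGap = 50) {
  if (minSupport > length(replicates))
    stop(sprintf("minSupport (%d) exceeds the number of replicates (%d)",
                 minSupport, length(replicates)))
  lvls <- unique(unlist(lapply(replicates, seqlevels)))
  # common seqlengths so per-replicate coverage vectors line up
  sl <- setNames(rep(0L, length(lvls)), lvls)
  for (g in replicates) {
    if (length(g) == 0L) next
    m <- vapply(split(end(g), as.character(seqnames(g))), max, numeric(1))
    sl[names(m)] <- pmax(sl[names(m)], m)
  }
  for (g in replicates) {
    gsl <- seqlengths(g)
    known <- !is.na(gsl)
    if (any(known)) sl[names(gsl)[known]] <- pmax(sl[names(gsl)[known]],
                                                  gsl[known])
  }
  si <- Seqinfo(seqnames = lvls, seqlengths = unname(sl))
  covs <- lapply(replicates, function(g) {
    g <- reduce(g, ignore.strand = TRUE)
    g <- GRanges(factor(as.character(seqnames(g)), levels = lvls),
                 ranges(g), seqinfo = si)
    coverage(g)
  })
  total <- Reduce(`+`, covs)
  kept <- as(IRanges::slice(total, lower = minSupport, rangesOnly = TRUE),
             "GRanges")
  mergeIntervals(kept, maxGap = maxGap)
}

#' Overlap two interval sets (Venn-style)
#'
#' An interval of \code{a} is shared iff it overlaps at least 1 bp of some
#' interval of \code{b}, and symmetrically. Strand is ignored.
#'
#' @param a,b \code{GRanges}.
#' @return a list with \code{shared_a}, \code{shared_b}, \code{a_only},
#'   \code{b_only} and a \code{counts} vector
#'   (\code{a_shared}, \code{a_only}, \code{b_shared}, \code{b_only}).
#' @export
intersectSets <- function(a, b) {
  inB <- countOverlaps(a, b, ignore.strand = TRUE) > 0
  inA <- countOverlaps(b, a, ignore.strand = TRUE) > 0
  list(shared_a = a[inB], shared_b = b[inA],
       a_only = a[!inB], b_only = b[!inA],
       counts = c(a_shared = sum(inB), a_only = sum(!inB),
                  b_shared = sum(inA), b_only = sum(!inA)))
}
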