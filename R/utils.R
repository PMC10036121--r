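# Derive a stage-specific RNG seed from a master seed and a stable label.
# Each simulator stage draws from its own stream so adding a stage never
# perturbs the draws of earlier stages. Result stays below 2^31 - 1.
stageSeed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((abs(as.numeric(seed)) * 131 + h) %% 2147483629)
}

# Run expr under a fixed seed without disturbing the caller's RNG state.
withSeed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# Uniform random placement of k non-overlapping intervals of the given
# lengths on a chromosome of length L (1-based starts). The intervals are
# laid out in random order with iid-uniform gap offsets: subtract the total
# occupied length, drop k sorted uniform draws into the remaining free
# space, and re-inflate. Equivalent in distribution to rejection-sampling
# non-overlapping placements, but O(k log k).
placeNonOverlapping <- function(lens, L, what = "interval", chrom = "?") {
  k <- length(lens)
  if (k == 0L) return(integer(0))
  free <- L - sum(lens)
  if (free < 0)
    stop(sprintf("cannot place %d non-overlapping %ss (%.0f bp) on chromosome '%s' (%.0f bp)",
                 k, what, sum(lens), chrom, L))
  ord <- sample.int(k)
  g <- sort(sample.int(free + 1, k, replace = TRUE) - 1L)
  starts <- integer(k)
  starts[ord] <- g + cumsum(c(0, lens[ord][-k])) + 1L
  starts
}

# Sort a GRanges by (chrom, start, end) with chromosome order taken from
# its seqlevels; strand is ignored for ordering.
sortIntervals <- function(gr) {
  gr[order(match(as.character(seqnames(gr)), seqlevels(gr)), start(gr), end(gr))]
}

# Rebuild a GRanges onto the genome's Seqinfo (full level set, genome
# order), regardless of the seqlevels the object arrived with.
setGenomeSeqinfo <- function(gr, genome) {
  si <- seqinfoOf(genome)
  out <- GRanges(factor(as.character(seqnames(gr)), levels = seqlevels(si)),
                 ranges(gr), strand = strand(gr), seqinfo = si)
  mcols(out) <- mcols(gr)
  out
}

# Concatenate GRanges built per chromosome; silences the benign Seqinfo
# merge chatter for parts with disjoint seqlevels.
bindGRanges <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && is.list(parts[[1]])) parts <- parts[[1]]
  suppressWarnings(do.call(c, parts))
}
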