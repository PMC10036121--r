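suppressPackageStartupMessages(library(GenomicRanges))

# --- tiny fixture builders -------------------------------------------------

# Genome with one chromosome and evenly spaced GATC sites.
uniformGenome <- function(L = 10000L, spacing = 100L, chrom = "chr1") {
  genomeModel(setNames(L, chrom),
              setNames(list(seq(spacing + 1L, L - 3L, by = spacing)), chrom))
}

gr1 <- function(starts, ends, chrom = "chr1", strand = NULL, ...) {
  g <- GRanges(chrom, IRanges(start = starts, end = ends), ...)
  if (!is.null(strand)) BiocGenerics::strand(g) <- strand
  g
}

randomIntervals <- function(seed, n = 10, L = 1000, maxW = 40, chrom = "chr1") {
  set.seed(seed)
  s <- sample.int(L - maxW, n, replace = TRUE)
  gr1(s, s + sample.int(maxW, n, replace = TRUE) - 1L, chrom = chrom)
}

# --- brute-force per-bp oracles --------------------------------------------

bpCover <- function(gr, L) {
  v <- logical(L)
  for (i in seq_along(gr)) v[start(gr)[i]:end(gr)[i]] <- TRUE
  v
}

runsOf <- function(v) {
  r <- rle(v)
  e <- cumsum(r$lengths)
  s <- c(1L, head(e, -1) + 1L)
  keep <- r$values
  data.frame(start = s[keep], end = e[keep])
}

# Transitive union of intervals with gaps <= maxGap, by bp scanning.
bruteMerge <- function(gr, L, maxGap = 50) {
  v <- bpCover(gr, L)
  r <- runsOf(v)
  if (nrow(r) <= 1) return(r)
  out <- r[1, ]
  for (i in 2:nrow(r)) {
    if (r$start[i] - out$end[nrow(out)] - 1 <= maxGap)
      out$end[nrow(out)] <- r$end[i]
    else out <- rbind(out, r[i, ])
  }
  out
}

bruteConsensus <- function(reps, L, minSupport = 2, maxGap = 50) {
  tot <- Reduce(`+`, lapply(reps, function(g) as.integer(bpCover(g, L))))
  r <- runsOf(tot >= minSupport)
  if (nrow(r) == 0) return(r)
  gr <- gr1(r$start, r$end)
  bruteMerge(gr, L, maxGap)
}

bruteShared <- function(a, b, L) {
  cb <- bpCover(b, L)
  vapply(seq_along(a), function(i) any(cb[start(a)[i]:end(a)[i]]), logical(1))
}

asDf <- function(gr) data.frame(start = start(gr), end = end(gr))

# Step-up BH, written straight from the definition.
bhStepUp <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in m:1) {
    prev <- min(prev, p[o[i]] * m / i)
    q[o[i]] <- prev
  }
  q
}
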