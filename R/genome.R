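#' Construct a GenomeModel
#'
#' @param chromLengths named numeric/integer vector of chromosome lengths
#'   in bp.
#' @param gatcSites named list of sorted 1-based GATC motif start positions,
#'   one integer vector per chromosome, in the same order as
#'   \code{chromLengths}. Chromosomes without sites may be omitted.
#' @return a validated [GenomeModel].
#' @examples
#' gm <- genomeModel(c(chr1 = 100L), list(chr1 = c(21L, 61L)))
#' fragments(gm)
#' @export
genomeModel <- function(chromLengths, gatcSites = list()) {
  if (is.null(names(chromLengths)))
    stop("chromLengths must be named")
  cl <- setNames(as.integer(chromLengths), names(chromLengths))
  gs <- lapply(names(cl), function(ch) {
    s <- gatcSites[[ch]]
    if (is.null(s)) integer(0) else as.integer(s)
  })
  names(gs) <- names(cl)
  new("GenomeModel", chromLengths = cl, gatcSites = gs)
}

#' @rdname GenomeModel-class
#' @export
setMethod("chromLengths", "GenomeModel", function(x) x@chromLengths)

#' @rdname GenomeModel-class
#' @export
setMethod("gatcSites", "GenomeModel", function(x) x@gatcSites)

#' @rdname GenomeModel-class
#' @export
setMethod("genomeLength", "GenomeModel", function(x) sum(as.numeric(x@chromLengths)))

#' @rdname GenomeModel-class
#' @export
setMethod("nFragments", "GenomeModel", function(x) {
  sum(vapply(names(x@chromLengths), function(ch) {
    s <- x@gatcSites[[ch]]
    length(s[s > 1L]) + 1L
  }, integer(1)))
})

#' @describeIn GenomeModel-class the GATC fragments as a \code{GRanges}
#'   tiling every chromosome exactly: boundaries at the chromosome start,
#'   every motif start, and the chromosome end.
#' @export
setMethod("fragments", "GenomeModel", function(x) {
  cl <- x@chromLengths
  parts <- lapply(names(cl), function(ch) {
    L <- cl[[ch]]
    s <- x@gatcSites[[ch]]
    b <- c(1L, s[s > 1L], L + 1L)
    GRanges(ch, IRanges(start = b[-length(b)], end = b[-1L] - 1L))
  })
  gr <- bindGRanges(parts)
  seqinfo(gr) <- seqinfoOf(x)
  gr
})

# Seqinfo matching the model, for coverage()/trimming operations.
seqinfoOf <- function(genome) {
  Seqinfo(seqnames = names(chromLengths(genome)),
          seqlengths = unname(chromLengths(genome)))
}

setMethod("show", "GenomeModel", function(object) {
  cl <- chromLengths(object)
  cat(sprintf("GenomeModel: %d chromosome(s), %.3g bp, %d GATC sites, %d fragments\n",
              length(cl), sum(as.numeric(cl)),
              sum(lengths(gatcSites(object))), nFragments(object)))
  show(head(data.frame(chrom = names(cl), length = unname(cl),
                       gatcSites = unname(lengths(gatcSites(object)))), 10))
  invisible(NULL)
})

#' Read a UCSC-style chrom.sizes file
#'
#' Two-column TSV: chromosome name, length in bp.
#'
#' @param path file path.
#' @return named integer vector of chromosome lengths.
#' @export
readChromSizes <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chrom", "length"),
                   colClasses = c("character", "integer"))
  setNames(df$length, df$chrom)
}

#' Assemble a GenomeModel from chrom.sizes and a GATC-site BED file
#'
#' @param chromSizesPath path to a two-column chrom.sizes TSV.
#' @param gatcBedPath optional BED file of GATC motif locations (4-bp
#'   intervals); only the starts are used. \code{NULL} gives a model with
#'   no internal cut sites (one fragment per chromosome).
#' @return a [GenomeModel].
#' @export
readGenome <- function(chromSizesPath, gatcBedPath = NULL) {
  cl <- readChromSizes(chromSizesPath)
  gs <- list()
  if (!is.null(gatcBedPath)) {
    gr <- rtracklayer::import(gatcBedPath, format = "BED")
    gs <- split(start(gr), as.character(seqnames(gr)))
    gs <- lapply(gs, function(s) sort(unique(as.integer(s))))
  }
  genomeModel(cl, gs)
}

#' Write chromosome sizes and GATC sites of a GenomeModel
#'
#' @param genome a [GenomeModel].
#' @param chromSizesPath,gatcBedPath output paths (either may be
#'   \code{NULL} to skip).
#' @return invisibly, the genome.
#' @export
writeGenome <- function(genome, chromSizesPath = NULL, gatcBedPath = NULL) {
  if (!is.null(chromSizesPath)) {
    cl <- chromLengths(genome)
    write.table(data.frame(names(cl), unname(cl)), chromSizesPath,
                sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(gatcBedPath)) {
    gs <- gatcSites(genome)
    gr <- GRanges(rep(names(gs), lengths(gs)),
                  IRanges(start = unlist(gs, use.names = FALSE), width = 4L))
    gr <- setGenomeSeqinfo(gr, genome)
    rtracklayer::export(gr, gatcBedPath, format = "BED")
  }
  invisible(genome)
}

# Validate that a GRanges fits inside the genome; used by every reader.
checkWithinGenome <- function(gr, genome, what = "interval") {
  cl <- chromLengths(genome)
  bad <- !(as.character(seqnames(gr)) %in% names(cl))
  if (any(bad))
    stop(sprintf("%s on unknown chromosome '%s'", what,
                 as.character(seqnames(gr))[which(bad)[1]]))
  L <- cl[as.character(seqnames(gr))]
  out <- start(gr) < 1L | end(gr) > L
  if (any(out)) {
    i <- which(out)[1]
    stop(sprintf("%s %s:%d-%d extends beyond chromosome length %d",
                 what, as.character(seqnames(gr))[i], start(gr)[i],
                 end(gr)[i], L[i]))
  }
  invisible(gr)
}
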