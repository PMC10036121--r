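#' Read a BED file of intervals against a genome
#'
#' Accepts BED3 or BED6 (0-based half-open on disk; returned as the usual
#' 1-based closed \code{GRanges}). Name, score and strand columns are kept
#' when present. Every interval is validated against the genome: unknown
#' chromosomes or intervals extending beyond the chromosome end are
#' errors.
#'
#' @param path BED file path.
#' @param genome a [GenomeModel] used for validation.
#' @return a sorted \code{GRanges}.
#' @export
readBed <- function(path, genome) {
  lines <- readLines(path)
  body <- !grepl("^(track|browser|#)", lines) & nzchar(lines)
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nf < 3L)) {
    bad <- which(body)[which(nf < 3L)[1]]
    stop(sprintf("malformed BED line %d in '%s': fewer than 3 fields", bad, path))
  }
  gr <- rtracklayer::import(path, format = "BED")
  checkWithinGenome(gr, genome, what = "BED interval")
  gr <- setGenomeSeqinfo(gr, genome)
  sortIntervals(gr)
}

#' Write intervals to BED
#'
#' @param gr a \code{GRanges} (name/score/strand metadata written when
#'   present).
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeBed <- function(gr, path) {
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read gene models with strand-aware TSS
#'
#' Reads \code{gene} features from GFF3 (1-based closed on disk) or genes
#' from BED6 (0-based half-open). Strand must be \code{+} or \code{-} for
#' every gene, otherwise the TSS is undefined and an error is raised. The
#' TSS of a \code{+} gene is its start; of a \code{-} gene its end (the
#' last transcribed-from base).
#'
#' @param path file path.
#' @param genome a [GenomeModel] used for validation.
#' @param dialect \code{"gff3"} or \code{"bed6"}.
#' @return a sorted \code{GRanges} with metadata columns \code{gene_id} and
#'   \code{tss}.
#' @export
readGenes <- function(path, genome, dialect = c("gff3", "bed6")) {
  dialect <- match.arg(dialect)
  if (dialect == "gff3") {
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[!is.na(gr$type) & as.character(gr$type) == "gene"]
    ids <- as.character(gr$ID)
    if (all(is.na(ids)) && !is.null(gr$Name)) ids <- as.character(gr$Name)
    mcols(gr) <- NULL
    gr$gene_id <- ids
  } else {
    gr <- rtracklayer::import(path, format = "BED")
    ids <- if (!is.null(gr$name)) as.character(gr$name) else
      paste0("gene", seq_along(gr))
    mcols(gr) <- NULL
    gr$gene_id <- ids
  }
  if (any(!as.character(strand(gr)) %in% c("+", "-")))
    stop("gene without strand: TSS undefined")
  checkWithinGenome(gr, genome, what = "gene")
  gr <- setGenomeSeqinfo(gr, genome)
  gr <- sortIntervals(gr)
  gr$tss <- tssOf(gr)
  gr
}

#' Strand-aware transcription start sites
#'
#' @param genes a stranded \code{GRanges} of gene spans.
#' @return integer vector of TSS positions (1-based): start on \code{+},
#'   end on \code{-}.
#' @export
tssOf <- function(genes) {
  if (any(!as.character(strand(genes)) %in% c("+", "-")))
    stop("gene without strand: TSS undefined")
  ifelse(as.character(strand(genes)) == "+", start(genes), end(genes))
}

#' Write gene models to GFF3
#'
#' @param genes a \code{GRanges} with a \code{gene_id} column.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeGenes <- function(genes, path) {
  out <- genes
  mcols(out) <- DataFrame(source = "nutrichrom", type = "gene",
                          ID = genes$gene_id, Name = genes$gene_id)
  rtracklayer::export(out, path, format = "gff3")
  invisible(path)
}

#' Write a FragmentTrack as bedGraph
#'
#' One record per fragment by default, so a read/write round trip is exact
#' to the printed precision (6 significant digits). With
#' \code{mergeRuns = TRUE} adjacent equal-valued fragments are run-length
#' merged into single records, as browser tracks usually are.
#'
#' @param track a [FragmentTrack].
#' @param path output path.
#' @param mergeRuns merge adjacent equal-valued fragments (default
#'   \code{FALSE}).
#' @return invisibly, \code{path}.
#' @export
writeBedgraph <- function(track, path, mergeRuns = FALSE) {
  fr <- fragments(trackGenome(track))
  v <- trackValues(track)
  chrom <- as.character(seqnames(fr))
  s0 <- start(fr) - 1L
  e0 <- end(fr)
  if (mergeRuns && length(v) > 0L) {
    newRun <- c(TRUE, v[-1] != v[-length(v)] | chrom[-1] != chrom[-length(v)])
    first <- which(newRun)
    last <- c(first[-1] - 1L, length(v))
    chrom <- chrom[first]; s0 <- s0[first]; e0 <- e0[last]; v <- v[first]
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("track type=bedGraph", con)
  if (length(v) > 0L)
    writeLines(sprintf("%s\t%d\t%d\t%.6g", chrom, s0, e0, v), con)
  invisible(path)
}

#' Read a bedGraph into a FragmentTrack
#'
#' Every fragment of the genome must be covered by exactly one bedGraph
#' record (run-length merged records are fine); uncovered fragments get 0.
#'
#' @param path bedGraph file path.
#' @param genome the [GenomeModel] whose fragment lattice the file is on.
#' @param kind the value kind to stamp on the track (\code{"count"},
#'   \code{"coverage"} or \code{"log2ratio"}).
#' @return a [FragmentTrack].
#' @export
readBedgraph <- function(path, genome, kind = "log2ratio") {
  gr <- rtracklayer::import(path, format = "bedGraph")
  checkWithinGenome(gr, genome, what = "bedGraph record")
  fr <- fragments(genome)
  fo <- findOverlaps(fr, gr)
  if (anyDuplicated(queryHits(fo))) {
    d <- queryHits(fo)[duplicated(queryHits(fo))][1]
    stop(sprintf("fragment %s:%d-%d overlaps multiple bedGraph records",
                 as.character(seqnames(fr))[d], start(fr)[d], end(fr)[d]))
  }
  v <- numeric(length(fr))
  v[queryHits(fo)] <- gr$score[subjectHits(fo)]
  fragmentTrack(genome, v, kind = kind)
}
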