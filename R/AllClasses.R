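#' GenomeModel: chromosome lengths plus the GATC fragment lattice
#'
#' A \code{GenomeModel} holds the chromosome lengths of a genome together
#' with the per-chromosome positions of GATC motif starts. Consecutive GATC
#' starts define the fragments on which all DamID signal is expressed: each
#' chromosome is tiled exactly by the spans between its start, the
#' successive motif starts, and its end. The 4-bp motif belongs to the
#' fragment it opens (fragments are cut at motif \emph{starts}).
#'
#' Coordinates are 1-based closed throughout the package (the
#' GenomicRanges convention); BED input/output converts at the boundary.
#'
#' @slot chromLengths named integer vector of chromosome lengths (bp).
#' @slot gatcSites named list, one sorted integer vector of 1-based GATC
#'   motif start positions per chromosome. A start \eqn{p} must satisfy
#'   \eqn{1 \le p \le L - 3} so the motif fits on the chromosome.
#'
#' @seealso [genomeModel()], [fragments()], [makeGenome()]
#' @export
setClass("GenomeModel",
  slots = c(chromLengths = "integer", gatcSites = "list"))

setValidity("GenomeModel", function(object) {
  cl <- object@chromLengths
  gs <- object@gatcSites
  if (length(cl) == 0L) return("no chromosomes")
  if (is.null(names(cl)) || anyDuplicated(names(cl)) || any(!nzchar(names(cl))))
    return("chromLengths must have unique non-empty names")
  if (any(is.na(cl)) || any(cl < 1L)) return("chromosome lengths must be >= 1")
  if (!identical(names(gs), names(cl)))
    return("gatcSites must have the same names, in the same order, as chromLengths")
  for (ch in names(cl)) {
    s <- gs[[ch]]
    if (length(s) == 0L) next
    if (!is.integer(s)) return(sprintf("gatcSites[['%s']] must be integer", ch))
    if (any(s < 1L) || any(s > cl[[ch]] - 3L))
      return(sprintf("GATC position outside [1, length-3] on '%s'", ch))
    if (is.unsorted(s, strictly = TRUE))
      return(sprintf("GATC positions must be strictly increasing on '%s'", ch))
  }
  TRUE
})

#' FragmentTrack: one value per GATC fragment
#'
#' A signal track at GATC-fragment resolution: a numeric vector with one
#' entry per fragment of its [GenomeModel], in genome fragment order
#' (chromosomes in genome order, fragments left to right). The \code{kind}
#' records what the values are: raw counts, 1x-normalized coverage, or a
#' log2 Dam-fusion/Dam ratio.
#'
#' @slot genome the [GenomeModel] the track lives on.
#' @slot values numeric, one value per fragment.
#' @slot kind one of \code{"count"}, \code{"coverage"}, \code{"log2ratio"}.
#'
#' @seealso [fragmentTrack()], [computeLog2Ratio()], [normalizeCoverage1x()]
#' @export
setClass("FragmentTrack",
  slots = c(genome = "GenomeModel", values = "numeric", kind = "character"))

setValidity("FragmentTrack", function(object) {
  kinds <- c("count", "coverage", "log2ratio")
  if (length(object@kind) != 1L || !object@kind %in% kinds)
    return(sprintf("kind must be one of %s", paste(kinds, collapse = ", ")))
  n <- nFragments(object@genome)
  if (length(object@values) != n)
    return(sprintf("track has %d values but genome has %d fragments",
                   length(object@values), n))
  if (object@kind == "count") {
    v <- object@values
    if (any(is.na(v)) || any(v < 0) || any(v != round(v)))
      return("count tracks must hold non-negative integers")
  }
  TRUE
})

#' SimConfig: parameters of the synthetic-data generators
#'
#' One object collects every knob of the simulator. The defaults define the
#' study conditions used throughout the package's tests: a 1 Mbp
#' chromosome cut at GATC rate 1/256 (fly-like density), three replicates
#' of 2e6 reads (2 reads/bp, about 500 counts on an average fragment, so
#' that even the shortest fragments are well covered), negative-binomial count
#' noise with dispersion 0.01, three planted enriched regions of 2
#' consecutive GATC fragments each (the natural unit of DamID signal) at
#' 4-fold Dam-fusion enrichment, motif hits of 10 bp at background rate
#' 5e-4 per bp with 10-fold extra density in the 500 bp window upstream of
#' target-gene TSSs, and a 2000-gene differential-expression table with
#' 400 true changes of |l2fc| in [1.5, 3] and per-gene standard errors in
#' [0.05, 0.15], of which 30\% revert and 30\% are restored under
#' treatment. See the methods vignette for why each value was chosen.
#'
#' @seealso [simConfig()]
#' @export
setClass("SimConfig",
  slots = c(
    seed = "numeric",
    nChroms = "integer",
    chromLength = "numeric",
    gatcRate = "numeric",
    nGenes = "integer",
    geneMeanLog = "numeric",
    geneSdLog = "numeric",
    nReplicates = "integer",
    sequencingDepth = "numeric",
    peakEnrichment = "numeric",
    nbDispersion = "numeric",
    nPeaks = "integer",
    peakFragments = "integer",
    domainMeanLength = "numeric",
    motifBackgroundRate = "numeric",
    motifTssEnrichment = "numeric",
    motifWidth = "integer",
    tssWindow = "integer",
    nDeGenes = "integer",
    nDe = "integer",
    effectRange = "numeric",
    seRange = "numeric",
    fracReverted = "numeric",
    fracRestored = "numeric"),
  prototype = list(
    seed = 1,
    nChroms = 1L,
    chromLength = 1e6,
    gatcRate = 1 / 256,
    nGenes = 200L,
    geneMeanLog = log(2000),
    geneSdLog = 0.4,
    nReplicates = 3L,
    sequencingDepth = 2e6,
    peakEnrichment = 4,
    nbDispersion = 0.01,
    nPeaks = 3L,
    peakFragments = 2L,
    domainMeanLength = 25000,
    motifBackgroundRate = 5e-4,
    motifTssEnrichment = 10,
    motifWidth = 10L,
    tssWindow = 500L,
    nDeGenes = 2000L,
    nDe = 400L,
    effectRange = c(1.5, 3),
    seRange = c(0.05, 0.15),
    fracReverted = 0.3,
    fracRestored = 0.3))

setValidity("SimConfig", function(object) {
  pos <- c("chromLength", "gatcRate", "sequencingDepth", "peakEnrichment",
           "domainMeanLength", "motifBackgroundRate",
           "motifTssEnrichment")
  for (s in pos)
    if (slot(object, s) <= 0) return(sprintf("%s must be > 0", s))
  if (object@nbDispersion < 0) return("nbDispersion must be >= 0")
  if (object@fracReverted < 0 || object@fracRestored < 0 ||
      object@fracReverted + object@fracRestored > 1)
    return("fracReverted + fracRestored must lie in [0, 1]")
  if (length(object@effectRange) != 2L || diff(object@effectRange) < 0 ||
      object@effectRange[1] <= 0)
    return("effectRange must be an increasing positive pair")
  if (length(object@seRange) != 2L || diff(object@seRange) < 0 ||
      object@seRange[1] <= 0)
    return("seRange must be an increasing positive pair")
  if (object@nDe > object@nDeGenes) return("nDe cannot exceed nDeGenes")
  if (object@tssWindow < 1L) return("tssWindow must be >= 1")
  if (object@motifWidth < 1L) return("motifWidth must be >= 1")
  TRUE
})
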