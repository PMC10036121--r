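#' Recovery of planted regions by called peaks
#'
#' A planted region is recovered if some called peak overlaps it with
#' reciprocal overlap at least \code{minFrac} (the overlap covers that
#' fraction of both intervals); a called peak is a true positive if it
#' recovers some planted region by the same rule.
#'
#' @param called \code{GRanges} of called peaks.
#' @param truth \code{GRanges} of planted regions.
#' @param minFrac minimum reciprocal overlap fraction (default 0.5).
#' @return a list with \code{recall}, \code{precision}, \code{nCalled},
#'   \code{nTruth}.
#' @export
peakRecovery <- function(called, truth, minFrac = 0.5) {
  if (length(truth) == 0L)
    return(list(recall = NA_real_, precision = NA_real_,
                nCalled = length(called), nTruth = 0L))
  fo <- findOverlaps(called, truth, ignore.strand = TRUE)
  w <- width(pintersect(granges(called)[queryHits(fo)],
                        granges(truth)[subjectHits(fo)]))
  good <- w >= minFrac * width(called)[queryHits(fo)] &
    w >= minFrac * width(truth)[subjectHits(fo)]
  list(recall = length(unique(subjectHits(fo)[good])) / length(truth),
       precision = if (length(called) == 0L) NA_real_ else
         length(unique(queryHits(fo)[good])) / length(called),
       nCalled = length(called), nTruth = length(truth))
}

# Per-replicate ratio -> peaks -> consensus, for one factor.
callFactorPeaks <- function(counts, nShuffles, seed) {
  reps <- lapply(seq_along(counts$fusion), function(i) {
    ratio <- computeLog2Ratio(counts$fusion[[i]], counts$dam[[i]])
    callPeaks(ratio, peakCallParams(nShuffles = nShuffles,
                                    seed = seed + i))$peaks
  })
  list(replicates = reps,
       consensus = consensusPeaks(lapply(reps, granges), minSupport = 2L))
}

#' Run the full synthetic demonstration pipeline
#'
#' Exercises every stage end to end on simulated data with known ground
#' truth: genome/genes/domains simulation; two profiled factors (sharing
#' part of their planted occupancy, as a nutrient sensor and a Polycomb
#' recruiter would) with three replicates each; log2 ratio tracks; peak
#' calling, replicate consensus and factor intersection; target-gene
#' assignment and chromatin-colour allocation; an accessibility
#' metaprofile at shared peaks; planted TSS-proximal motif hits with
#' permutation overlap enrichment and the TSS density profile; and the
#' paired DE tables with rescue classification. Writes the simulated
#' inputs, all stage outputs, a \code{summary.json} of
#' planted-vs-recovered metrics and a \code{run_manifest.json}; the result
#' tree is a pure function of \code{(cfg, seed)}.
#'
#' @param outdir writable output directory.
#' @param seed master seed (overrides \code{cfg@seed}).
#' @param cfg a [SimConfig] (defaults to [simConfig()]).
#' @param nShuffles permutations for the peak-caller null (default 1000).
#' @param nResamples resamples for the enrichment tests (default 100).
#' @return invisibly, the summary list.
#' @export
runDemo <- function(outdir, seed = 1, cfg = simConfig(),
                    nShuffles = 1000, nResamples = 100) {
  cfg@seed <- seed
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("demo stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  genome <- stage("simulate", makeGenome(cfg))
  genes <- stage("simulate", makeGenes(genome, cfg))
  domains <- stage("simulate", makeDomains(genome, seed = seed))
  plantedA <- stage("simulate", plantPeaks(genome, cfg))
  cfgB <- cfg; cfgB@seed <- seed + 7919
  plantedBnew <- stage("simulate", plantPeaks(genome, cfgB))
  # factor B shares all but one of A's regions and adds one of its own
  plantedB <- sortIntervals(c(plantedA[-1], plantedBnew[1]))
  plantedShared <- plantedA[-1]
  countsA <- stage("simulate", simulateDamidCounts(genome, plantedA, cfg))
  countsB <- stage("simulate", simulateDamidCounts(genome, plantedB, cfgB))
  facA <- stage("callpeaks", callFactorPeaks(countsA, nShuffles, seed))
  facB <- stage("callpeaks", callFactorPeaks(countsB, nShuffles,
                                             seed + 5000))
  ix <- stage("intersect", intersectSets(facA$consensus, facB$consensus))
  sharedPeaks <- mergeIntervals(c(ix$shared_a, ix$shared_b))
  targets <- stage("targets", assignTargets(sharedPeaks, genes))
  alloc <- if (length(targets) > 0L)
    stage("domains", domainAllocation(targets, genes, domains, seed = seed))
  else NULL
  cov1x <- stage("coverage1x", normalizeCoverage1x(countsA$dam[[1]]))
  meta <- if (length(sharedPeaks) > 0L)
    stage("metaprofile", metaprofile(cov1x, sharedPeaks)) else NULL
  truthTargets <- assignTargets(plantedShared, genes)
  motifs <- stage("simulate", plantMotifs(genome, genes, truthTargets, cfg))
  enr <- if (length(sharedPeaks) > 0L)
    stage("motif-enrich", overlapEnrichment(sharedPeaks, motifs$hits,
                                            genome, nResamples, seed = seed))
  else NULL
  targetGenes <- genes[genes$gene_id %in% truthTargets]
  prof <- if (length(targetGenes) > 0L)
    stage("tss-profile", tssDensityProfile(targetGenes, motifs$hits, genome))
  else NULL
  de <- stage("simulate", simulateDeTable(cfg))
  rescue <- stage("rescue", classifyRescue(de$baseline, de$treatment))
  truthDe <- de$truth[match(rescue$table$gene_id, de$truth$gene_id), ]
  recA <- peakRecovery(facA$consensus, plantedA)
  recB <- peakRecovery(facB$consensus, plantedB)
  summary <- list(
    seed = seed,
    planted = list(factorA = length(plantedA), factorB = length(plantedB),
                   shared = length(plantedShared)),
    peak_recovery = list(
      factorA = recA[c("recall", "precision", "nCalled")],
      factorB = recB[c("recall", "precision", "nCalled")]),
    shared_peaks = length(sharedPeaks),
    target_genes = list(called = length(targets),
                        truth = length(truthTargets)),
    motif_enrichment = if (is.null(enr)) NULL else
      enr[c("observed_overlap", "expected_mean", "l2fc", "p_emp")],
    tss_upstream_density = if (is.null(prof)) NULL else
      summarizeWindow(prof, c(-500, 0)),
    rescue = list(
      rescued_fraction = rescue$rescued_fraction,
      truth_rescued_fraction =
        mean(truthDe$label %in% c("reverted", "restored"))))
  p <- function(f) file.path(outdir, f)
  writeSimulation(cfg, p("sim"))
  writeBed(facA$consensus, p("consensus_A.bed"))
  writeBed(facB$consensus, p("consensus_B.bed"))
  if (length(sharedPeaks) > 0L) writeBed(sharedPeaks, p("shared_peaks.bed"))
  writeLines(targets, p("target_genes.txt"))
  if (!is.null(alloc))
    write.table(alloc, p("domain_allocation.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  if (!is.null(meta))
    write.table(meta, p("metaprofile.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  if (!is.null(prof))
    write.table(as.data.frame(prof), p("tss_profile.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  write.table(rescue$table, p("rescue.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(summary, p("summary.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  manifest <- list(command = "runDemo", seed = seed,
                   nShuffles = nShuffles, nResamples = nResamples,
                   config = setNames(
                     lapply(slotNames("SimConfig"), function(s) slot(cfg, s)),
                     slotNames("SimConfig")),
                   version = as.character(packageVersion("nutrichrom")))
  jsonlite::write_json(manifest, p("run_manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(summary)
}
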