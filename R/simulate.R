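#' Configure the synthetic-data generators
#'
#' Returns a validated [SimConfig]; any argument overrides its default.
#' The defaults are the study conditions the package's tests are run
#' under — see the class documentation and the methods vignette.
#'
#' @param ... slot values to override, by name (e.g. \code{seed = 7},
#'   \code{nChroms = 5L}).
#' @return a [SimConfig].
#' @examples
#' cfg <- simConfig(seed = 7, chromLength = 2e5, nGenes = 40L)
#' @export
simConfig <- function(...) {
  args <- list(...)
  proto <- new("SimConfig")
  for (nm in names(args)) {
    if (!nm %in% slotNames("SimConfig"))
      stop(sprintf("unknown SimConfig field '%s'", nm))
    value <- args[[nm]]
    if (is(slot(proto, nm), "integer")) value <- as.integer(value)
    slot(proto, nm) <- value
  }
  validObject(proto)
  proto
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:\n")
  for (nm in slotNames("SimConfig"))
    cat(sprintf("  %-20s %s\n", nm,
                paste(format(slot(object, nm)), collapse = ", ")))
  invisible(NULL)
})

#' Simulate a genome with GATC cut sites
#'
#' Chromosomes \code{chrS1..chrSn} of equal length; GATC motif starts are a
#' homogeneous point process at rate \code{gatcRate} thinned to a minimum
#' spacing of 4 bp (successive gaps are 4 bp plus an exponential draw), so
#' motifs never overlap. Deterministic given \code{cfg@seed}.
#'
#' @param cfg a [SimConfig].
#' @return a [GenomeModel].
#' @export
makeGenome <- function(cfg) {
  stopifnot(is(cfg, "SimConfig"))
  L <- cfg@chromLength
  if (L < 8) stop("chromosome too short to host any GATC site")
  withSeed(stageSeed(cfg@seed, "genome"), {
    gs <- lapply(seq_len(cfg@nChroms), function(i) {
      m <- ceiling(L * cfg@gatcRate * 1.3) + 50L
      pos <- cumsum(4 + rexp(m, cfg@gatcRate))
      while (pos[length(pos)] <= L - 3) {
        pos <- c(pos, pos[length(pos)] + cumsum(4 + rexp(m, cfg@gatcRate)))
      }
      as.integer(floor(pos[pos <= L - 3]))
    })
    names(gs) <- paste0("chrS", seq_len(cfg@nChroms))
    genomeModel(setNames(rep(L, cfg@nChroms), names(gs)), gs)
  })
}

#' Simulate non-overlapping stranded gene models
#'
#' Gene lengths are log-normal (\code{geneMeanLog}, \code{geneSdLog}),
#' floored at 200 bp; genes are assigned to chromosomes proportionally to
#' chromosome length and placed uniformly at random without overlap;
#' strands are Bernoulli(1/2). Errors if the genes cannot fit.
#'
#' @param genome a [GenomeModel].
#' @param cfg a [SimConfig].
#' @return a sorted \code{GRanges} with \code{gene_id} and \code{tss}
#'   metadata columns.
#' @export
makeGenes <- function(genome, cfg) {
  withSeed(stageSeed(cfg@seed, "genes"), {
    n <- cfg@nGenes
    lens <- pmax(200L, as.integer(round(rlnorm(n, cfg@geneMeanLog, cfg@geneSdLog))))
    cl <- chromLengths(genome)
    chrom <- sample(names(cl), n, replace = TRUE, prob = as.numeric(cl))
    parts <- lapply(names(cl), function(ch) {
      idx <- which(chrom == ch)
      if (length(idx) == 0L) return(NULL)
      starts <- placeNonOverlapping(lens[idx], cl[[ch]], "gene", ch)
      GRanges(ch, IRanges(start = starts, width = lens[idx]))
    })
    gr <- bindGRanges(parts[!vapply(parts, is.null, logical(1))])
    gr <- setGenomeSeqinfo(gr, genome)
    strand(gr) <- sample(c("+", "-"), length(gr), replace = TRUE)
    gr <- sortIntervals(gr)
    gr$gene_id <- sprintf("g%05d", seq_along(gr))
    gr$tss <- tssOf(gr)
    gr
  })
}

#' Five-colour chromatin domain labels
#' @export
DOMAIN_COLORS <- c("BLACK", "GREEN", "BLUE", "YELLOW", "RED")

#' Simulate a five-colour chromatin-domain tiling
#'
#' Alternating blocks of exponentially distributed length tile every
#' chromosome exactly (no gaps, no overlaps); each block carries a colour
#' label drawn uniformly, never repeating the previous block's colour, so
#' the marginal colour frequencies are uniform.
#'
#' @param genome a [GenomeModel].
#' @param colors character vector of labels (default the five-colour
#'   chromatin classification [DOMAIN_COLORS]).
#' @param meanLen mean block length in bp (default 25000).
#' @param seed integer seed.
#' @return a sorted \code{GRanges} with a \code{label} column.
#' @export
makeDomains <- function(genome, colors = DOMAIN_COLORS, meanLen = 25000,
                        seed = 1) {
  stopifnot(length(colors) >= 2L, meanLen > 0)
  withSeed(stageSeed(seed, "domains"), {
    cl <- chromLengths(genome)
    parts <- lapply(names(cl), function(ch) {
      L <- cl[[ch]]
      lens <- integer(0)
      while (sum(lens) < L) {
        more <- pmax(1L, as.integer(round(rexp(ceiling(L / meanLen) + 10L,
                                               1 / meanLen))))
        lens <- c(lens, more)
      }
      ends <- pmin(cumsum(as.numeric(lens)), L)
      lens <- as.integer(diff(c(0, ends[!duplicated(ends)])))
      k <- length(lens)
      lab <- character(k)
      lab[1] <- sample(colors, 1L)
      for (i in seq_len(k - 1L))
        lab[i + 1L] <- sample(setdiff(colors, lab[i]), 1L)
      GRanges(ch, IRanges(start = cumsum(c(1L, lens[-k])), width = lens),
              label = lab)
    })
    gr <- setGenomeSeqinfo(bindGRanges(parts), genome)
    gr
  })
}

#' Plant true enriched regions for the DamID simulation
#'
#' Places \code{cfg@nPeaks} enriched regions per chromosome, each the
#' exact span of \code{cfg@peakFragments} consecutive GATC fragments
#' (DamID methylation has fragment resolution, so true enrichment lives
#' on the fragment lattice). Regions are drawn uniformly at random among
#' fragment runs, separated by at least \code{minGap} bp so that
#' downstream peak merging cannot fuse two distinct truths.
#'
#' @param genome a [GenomeModel].
#' @param cfg a [SimConfig].
#' @param minGap minimum separation between planted regions (default
#'   5000 bp).
#' @return a sorted \code{GRanges} of true enriched regions.
#' @export
plantPeaks <- function(genome, cfg, minGap = 5000) {
  withSeed(stageSeed(cfg@seed, "planted_peaks"), {
    fr <- fragments(genome)
    chroms <- as.character(seqnames(fr))
    f <- cfg@peakFragments
    parts <- lapply(names(chromLengths(genome)), function(ch) {
      idx <- which(chroms == ch)
      if (length(idx) < f * cfg@nPeaks)
        stop(sprintf("chromosome '%s' has too few fragments for %d planted regions",
                     ch, cfg@nPeaks))
      valid <- idx[seq_len(length(idx) - f + 1L)]
      for (try in seq_len(1000L)) {
        first <- sort(sample(valid, cfg@nPeaks))
        s <- start(fr)[first]
        e <- end(fr)[first + f - 1L]
        if (cfg@nPeaks == 1L ||
            all(s[-1] - e[-length(e)] >= minGap) && all(e >= s))
          return(GRanges(ch, IRanges(start = s, end = e)))
      }
      stop(sprintf("could not place %d separated planted regions on '%s'",
                   cfg@nPeaks, ch))
    })
    gr <- bindGRanges(parts)
    gr <- setGenomeSeqinfo(gr, genome)
    sortIntervals(gr)
  })
}

#' Simulate replicate Dam-fusion and Dam-only fragment counts
#'
#' Counts per fragment are negative binomial with mean proportional to
#' fragment length times sequencing depth; inside planted regions the
#' Dam-fusion mean is multiplied by \code{cfg@peakEnrichment} (a fragment
#' counts as inside when it overlaps a planted region by at least 1 bp).
#' Replicates are independent. \code{cfg@nbDispersion = 0} gives Poisson
#' counts.
#'
#' @param genome a [GenomeModel].
#' @param planted \code{GRanges} of true enriched regions (may be empty).
#' @param cfg a [SimConfig].
#' @return a list with elements \code{fusion} and \code{dam} (lists of
#'   count [FragmentTrack]s, one per replicate) and \code{truth} (a list
#'   recording the planted regions).
#' @export
simulateDamidCounts <- function(genome, planted, cfg) {
  if (cfg@sequencingDepth <= 0) stop("sequencing depth must be positive")
  checkWithinGenome(planted, genome, what = "planted region")
  fr <- fragments(genome)
  w <- width(fr)
  mu <- cfg@sequencingDepth * w / genomeLength(genome)
  mult <- ifelse(countOverlaps(fr, planted, ignore.strand = TRUE) > 0,
                 cfg@peakEnrichment, 1)
  rcounts <- function(m) {
    if (cfg@nbDispersion <= 1e-12) rpois(length(m), m)
    else rnbinom(length(m), mu = m, size = 1 / cfg@nbDispersion)
  }
  withSeed(stageSeed(cfg@seed, "damid_counts"), {
    fusion <- lapply(seq_len(cfg@nReplicates), function(i)
      fragmentTrack(genome, rcounts(mu * mult), kind = "count"))
    dam <- lapply(seq_len(cfg@nReplicates), function(i)
      fragmentTrack(genome, rcounts(mu), kind = "count"))
    list(fusion = fusion, dam = dam,
         truth = list(plantedPeaks = planted))
  })
}

#' Simulate motif-hit intervals with TSS-proximal enrichment
#'
#' Background hits of width \code{cfg@motifWidth} fall as a Poisson process
#' at \code{cfg@motifBackgroundRate} hits per bp genome-wide. In the
#' strand-aware window of \code{cfg@tssWindow} bp immediately upstream of
#' each target gene's TSS, extra hits are added at
#' \code{(motifTssEnrichment - 1)} times the background rate, so the total
#' hit density there is \code{motifTssEnrichment}-fold background (and
#' enrichment 1 leaves the windows at exactly background density). Hits are
#' clipped to chromosome bounds.
#'
#' @param genome a [GenomeModel].
#' @param genes gene models from [makeGenes()] / [readGenes()].
#' @param targetGenes character vector of gene_ids receiving the planted
#'   enrichment (must be a subset of \code{genes$gene_id}).
#' @param cfg a [SimConfig].
#' @return a list with \code{hits} (sorted \code{GRanges}) and
#'   \code{truth} (target gene set and the planted fold).
#' @export
plantMotifs <- function(genome, genes, targetGenes, cfg) {
  if (!all(targetGenes %in% genes$gene_id))
    stop("targetGenes must be a subset of genes$gene_id")
  cl <- chromLengths(genome)
  wm <- cfg@motifWidth
  withSeed(stageSeed(cfg@seed, "motifs"), {
    nBg <- rpois(1, cfg@motifBackgroundRate * genomeLength(genome))
    chrom <- sample(names(cl), nBg, replace = TRUE, prob = as.numeric(cl))
    starts <- floor(runif(nBg, 1, cl[chrom] + 1))
    bg <- GRanges(chrom, IRanges(start = starts, width = wm))
    extra <- GRanges()
    tg <- genes[genes$gene_id %in% targetGenes]
    if (length(tg) > 0L && cfg@motifTssEnrichment > 1) {
      rate <- (cfg@motifTssEnrichment - 1) * cfg@motifBackgroundRate
      nEx <- rpois(length(tg), rate * cfg@tssWindow)
      gchrom <- rep(as.character(seqnames(tg)), nEx)
      gtss <- rep(tg$tss, nEx)
      gplus <- rep(as.character(strand(tg)) == "+", nEx)
      offs <- floor(runif(sum(nEx), 1, cfg@tssWindow + 1))  # 1..window bp upstream
      starts <- ifelse(gplus, gtss - offs, gtss + offs - wm + 1L)
      extra <- GRanges(gchrom, IRanges(start = starts, width = wm))
    }
    hits <- bindGRanges(bg, extra)
    # clip to chromosome bounds
    hitsL <- cl[as.character(seqnames(hits))]
    start(hits) <- pmax(start(hits), 1L)
    end(hits) <- pmin(end(hits), hitsL)
    hits <- setGenomeSeqinfo(hits[width(hits) > 0L], genome)
    list(hits = sortIntervals(hits),
         truth = list(targetGenes = sort(targetGenes),
                      tssEnrichment = cfg@motifTssEnrichment))
  })
}

#' Simulate paired baseline/treatment differential-expression tables
#'
#' Baseline true log2 fold changes are 0 for non-DE genes and drawn from
#' \code{cfg@effectRange} (uniform magnitude, random sign) for
#' \code{cfg@nDe} genes. Each DE gene gets a rescue label: under treatment
#' a \emph{restored} gene's true l2fc returns to 0, a \emph{reverted}
#' gene's flips sign, and a \emph{still_changed} gene keeps its baseline
#' effect; non-DE genes are \emph{unchanged}. Observed l2fc = true +
#' Normal(0, SE) with per-gene SE from \code{cfg@seRange}; Wald p and BH q
#' are attached (see [makeDeTable()]).
#'
#' @param cfg a [SimConfig].
#' @return a list with \code{baseline} and \code{treatment} DE tables
#'   (data.frames with gene_id, l2fc, lfcSE, p_wald, q_wald) and
#'   \code{truth} (per-gene true l2fcs and rescue label).
#' @export
simulateDeTable <- function(cfg) {
  withSeed(stageSeed(cfg@seed, "de_table"), {
    n <- cfg@nDeGenes
    ids <- sprintf("gene%05d", seq_len(n))
    de <- sample.int(n, cfg@nDe)
    eff <- numeric(n)
    eff[de] <- runif(cfg@nDe, cfg@effectRange[1], cfg@effectRange[2]) *
      sample(c(-1, 1), cfg@nDe, replace = TRUE)
    label <- rep("unchanged", n)
    nRev <- round(cfg@fracReverted * cfg@nDe)
    nRes <- round(cfg@fracRestored * cfg@nDe)
    lab <- sample(c(rep("reverted", nRev), rep("restored", nRes),
                    rep("still_changed", cfg@nDe - nRev - nRes)))
    label[de] <- lab
    trtEff <- numeric(n)
    trtEff[label == "reverted"] <- -eff[label == "reverted"]
    trtEff[label == "still_changed"] <- eff[label == "still_changed"]
    obs <- function(true) {
      se <- runif(n, cfg@seRange[1], cfg@seRange[2])
      makeDeTable(data.frame(gene_id = ids, l2fc = true + rnorm(n, 0, se),
                             lfcSE = se))
    }
    list(baseline = obs(eff), treatment = obs(trtEff),
         truth = data.frame(gene_id = ids, baseline_l2fc = eff,
                            treatment_l2fc = trtEff, label = label))
  })
}

#' Write a complete simulated data set to a directory
#'
#' Runs every generator under one [SimConfig] and writes the standard file
#' tree: \code{chrom.sizes}, \code{gatc.bed}, \code{genes.gff3},
#' \code{domains.bed}, \code{planted_peaks.bed}, per-replicate
#' \code{fusion_rep<i>.counts.bedgraph} / \code{dam_rep<i>.counts.bedgraph},
#' \code{motifs.bed}, \code{baseline_de.tsv}, \code{treatment_de.tsv} and
#' \code{truth.json}. Target genes for the motif planting are the genes
#' overlapped by planted regions.
#'
#' @param cfg a [SimConfig].
#' @param outdir output directory (created if needed).
#' @return invisibly, a list with all in-memory objects.
#' @export
writeSimulation <- function(cfg, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  genome <- makeGenome(cfg)
  genes <- makeGenes(genome, cfg)
  domains <- makeDomains(genome, seed = cfg@seed)
  planted <- plantPeaks(genome, cfg)
  counts <- simulateDamidCounts(genome, planted, cfg)
  targets <- assignTargets(planted, genes)
  motifs <- plantMotifs(genome, genes, targets, cfg)
  de <- simulateDeTable(cfg)
  p <- function(f) file.path(outdir, f)
  writeGenome(genome, p("chrom.sizes"), p("gatc.bed"))
  writeGenes(genes, p("genes.gff3"))
  dm <- domains; dm$name <- dm$label; dm$label <- NULL
  writeBed(dm, p("domains.bed"))
  writeBed(planted, p("planted_peaks.bed"))
  for (i in seq_len(cfg@nReplicates)) {
    writeBedgraph(counts$fusion[[i]], p(sprintf("fusion_rep%d.counts.bedgraph", i)))
    writeBedgraph(counts$dam[[i]], p(sprintf("dam_rep%d.counts.bedgraph", i)))
  }
  writeBed(motifs$hits, p("motifs.bed"))
  write.table(de$baseline, p("baseline_de.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(de$treatment, p("treatment_de.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  truth <- list(seed = cfg@seed,
                planted_peaks = sprintf("%s:%d-%d",
                                        as.character(seqnames(planted)),
                                        start(planted), end(planted)),
                target_genes = motifs$truth$targetGenes,
                de_labels = setNames(as.list(de$truth$label), de$truth$gene_id))
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(list(genome = genome, genes = genes, domains = domains,
                 planted = planted, counts = counts, motifs = motifs, de = de))
}
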