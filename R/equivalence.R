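#' Two-sided Wald p-value for a log2 fold change
#'
#' \eqn{z = \mathrm{l2fc}/\mathrm{lfcSE}}, \eqn{p = 2(1 - \Phi(|z|))}.
#' Vectorized.
#'
#' @param l2fc observed log2 fold change(s).
#' @param lfcSE standard error(s), strictly positive.
#' @return p-value(s) in \code{[0, 1]}.
#' @export
waldP <- function(l2fc, lfcSE) {
  if (any(lfcSE <= 0)) stop("lfcSE must be > 0")
  2 * pnorm(-abs(l2fc / lfcSE))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up BH: \eqn{q_{(i)} = \min_{j \ge i} p_{(j)} m / j}, returned in
#' input order.
#'
#' @param pvals numeric vector of p-values in \code{[0, 1]}.
#' @return vector of q-values in input order.
#' @export
bhAdjust <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0) || any(pvals > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(pvals, method = "BH")
}

#' Practical-equivalence (TOST) p-value for a log2 fold change
#'
#' Tests the null hypothesis that the true change is \emph{larger} than
#' the equivalence region \eqn{\pm\delta} on the log2 scale, assuming the
#' true l2fc estimate is normal with the gene-wise standard error: the two
#' one-sided tests are
#' \eqn{p_{\mathrm{lower}} = 1 - \Phi((\mathrm{l2fc}+\delta)/\mathrm{SE})}
#' (against \eqn{\mu \le -\delta}) and
#' \eqn{p_{\mathrm{upper}} = \Phi((\mathrm{l2fc}-\delta)/\mathrm{SE})}
#' (against \eqn{\mu \ge +\delta}); the TOST p is their maximum. Small
#' values are evidence that expression is \emph{equivalent} — changed by
#' less than \eqn{2^\delta}-fold. Vectorized.
#'
#' @param l2fc observed log2 fold change(s).
#' @param lfcSE standard error(s), strictly positive.
#' @param delta half-width of the region of practical equivalence on the
#'   log2 scale; default \code{log2(1.5)}, i.e. a 1.5-fold change.
#' @return TOST p-value(s).
#' @export
equivalenceP <- function(l2fc, lfcSE, delta = log2(1.5)) {
  if (any(lfcSE <= 0)) stop("lfcSE must be > 0")
  if (any(delta <= 0)) stop("delta must be > 0")
  pLower <- 1 - pnorm((l2fc + delta) / lfcSE)
  pUpper <- pnorm((l2fc - delta) / lfcSE)
  pmax(pLower, pUpper)
}

#' Configuration of the rescue classification
#'
#' @param delta equivalence half-width on the log2 scale (default
#'   \code{log2(1.5)}).
#' @param qDe BH q cutoff calling differential expression, both for the
#'   baseline DEG set and the treatment "reverted" call (default 0.1).
#' @param qEquiv BH q cutoff on the equivalence test for "restored"
#'   (default 0.05).
#' @param revertedRequiresSignificance require treatment
#'   \code{q_wald < qDe} (not just a sign flip) for "reverted"
#'   (default \code{TRUE}).
#' @param equivScope compute the equivalence BH correction within the
#'   baseline-DEG set (\code{"degs"}, default — that is the population
#'   being classified) or over the whole table (\code{"all"}).
#' @return a list of class \code{EquivalenceConfig}.
#' @export
equivalenceConfig <- function(delta = log2(1.5), qDe = 0.1, qEquiv = 0.05,
                              revertedRequiresSignificance = TRUE,
                              equivScope = c("degs", "all")) {
  stopifnot(delta > 0, qDe > 0, qDe < 1, qEquiv > 0, qEquiv < 1)
  structure(list(delta = delta, qDe = qDe, qEquiv = qEquiv,
                 revertedRequiresSignificance =
                   isTRUE(revertedRequiresSignificance),
                 equivScope = match.arg(equivScope)),
            class = "EquivalenceConfig")
}

#' Build a differential-expression table with Wald and BH columns
#'
#' Takes the de-facto standard results layout (columns \code{gene_id},
#' \code{l2fc} or \code{log2FoldChange}, \code{lfcSE}, optionally
#' \code{pvalue}; extra columns ignored) and attaches \code{p_wald}
#' (computed from l2fc/lfcSE when no \code{pvalue} is supplied) and
#' \code{q_wald} (BH).
#'
#' @param df a data.frame.
#' @return a data.frame with columns gene_id, l2fc, lfcSE, p_wald, q_wald.
#' @export
makeDeTable <- function(df) {
  if (!is.null(df$log2FoldChange) && is.null(df$l2fc))
    df$l2fc <- df$log2FoldChange
  need <- c("gene_id", "l2fc", "lfcSE")
  if (!all(need %in% names(df)))
    stop(sprintf("missing column(s): %s",
                 paste(setdiff(need, names(df)), collapse = ", ")))
  if (anyDuplicated(df$gene_id)) stop("duplicated gene_id")
  p <- if (!is.null(df$pvalue)) df$pvalue else waldP(df$l2fc, df$lfcSE)
  data.frame(gene_id = as.character(df$gene_id), l2fc = df$l2fc,
              lfcSE = df$lfcSE, p_wald = p, q_wald = bhAdjust(p))
}

#' Read a DE results TSV into a DE table
#'
#' @param path TSV with columns gene_id, log2FoldChange (or l2fc), lfcSE
#'   and optionally pvalue.
#' @return see [makeDeTable()].
#' @export
readDeTable <- function(path) {
  makeDeTable(read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE))
}

#' Classify rescue of baseline DEGs under a treatment
#'
#' Baseline DEGs are the genes with baseline \code{q_wald < qDe}. For each
#' of them, against the treatment contrast:
#' \itemize{
#'   \item \strong{reverted} — the treatment change is significant
#'     (\code{q_wald < qDe}) \emph{and} in the opposite direction to the
#'     baseline change;
#'   \item \strong{restored} — the treatment change is practically
#'     equivalent to zero: BH-adjusted [equivalenceP()] \code{< qEquiv},
#'     the correction computed within the baseline-DEG set;
#'   \item \strong{not_rescued} — neither.
#' }
#' When both flags fire, reverted takes precedence (a sign-flipped
#' significant change is the stronger statement); both flags are always
#' reported.
#'
#' @param baseline,treatment DE tables from [makeDeTable()] /
#'   [readDeTable()]; every baseline DEG must appear in \code{treatment}.
#' @param cfg an [equivalenceConfig()].
#' @return a list with \code{table} (one row per baseline DEG: gene_id,
#'   baseline/treatment l2fc, flags, p/q columns, label) and
#'   \code{rescued_fraction} = |reverted or restored| / |baseline DEGs|.
#' @export
classifyRescue <- function(baseline, treatment, cfg = equivalenceConfig()) {
  degs <- baseline[baseline$q_wald < cfg$qDe, , drop = FALSE]
  if (nrow(degs) == 0L)
    return(list(table = data.frame(), rescued_fraction = NA_real_))
  missing <- setdiff(degs$gene_id, treatment$gene_id)
  if (length(missing) > 0L)
    stop(sprintf("baseline DEG(s) missing from treatment table: %s",
                 paste(head(missing, 5), collapse = ", ")))
  trt <- treatment[match(degs$gene_id, treatment$gene_id), , drop = FALSE]
  pEq <- equivalenceP(trt$l2fc, trt$lfcSE, cfg$delta)
  qEq <- if (cfg$equivScope == "degs") {
    bhAdjust(pEq)
  } else {
    pAll <- equivalenceP(treatment$l2fc, treatment$lfcSE, cfg$delta)
    bhAdjust(pAll)[match(degs$gene_id, treatment$gene_id)]
  }
  signFlip <- sign(trt$l2fc) == -sign(degs$l2fc) & trt$l2fc != 0
  revertedFlag <- if (cfg$revertedRequiresSignificance)
    trt$q_wald < cfg$qDe & signFlip else signFlip
  restoredFlag <- qEq < cfg$qEquiv
  label <- ifelse(revertedFlag, "reverted",
                  ifelse(restoredFlag, "restored", "not_rescued"))
  tab <- data.frame(gene_id = degs$gene_id,
                    baseline_l2fc = degs$l2fc, baseline_q = degs$q_wald,
                    treatment_l2fc = trt$l2fc, treatment_q = trt$q_wald,
                    p_equiv = pEq, q_equiv = qEq,
                    reverted_flag = revertedFlag,
                    restored_flag = restoredFlag,
                    label = label)
  list(table = tab,
       rescued_fraction = mean(revertedFlag | restoredFlag))
}
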