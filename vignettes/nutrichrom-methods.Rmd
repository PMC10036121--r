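---
title: "Methods: GATC-resolution DamID analysis with verifiable synthetic data"
author: "nutrichrom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: GATC-resolution DamID analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

nutrichrom re-implements, as reusable and testable components, the
downstream computational analysis of a Targeted DamID (TaDa) / chromatin
accessibility (CATaDa) study design: a Dam-methyltransferase fusion
deposits adenine methylation at GATC sites near the chromatin locations of
its fusion partner (a nutrient-sensing enzyme such as OGT, or a Polycomb
recruiter such as Pcl), restricted to a cell population of interest; an
untethered Dam control reports accessibility. The native resolution unit
is the **GATC fragment** — the span between consecutive GATC motifs — and
every signal in this package is a vector with one value per fragment
(`FragmentTrack` on a `GenomeModel`).

The package starts from fragment **counts**; read alignment, read
extension and the upstream ratio pipeline are out of scope. Downstream it
covers: log2 fusion/Dam ratio tracks, 1x-normalized coverage, shuffle-FDR
peak calling with replicate consensus, peak-to-gene target assignment,
chromatin-colour domain allocation with a permutation test, motif-overlap
permutation enrichment with chromosome-preserving shuffles, TSS-relative
motif density normalized to the genome-wide expectation, and a
practical-equivalence (TOST) classification of expression rescue. A
seeded simulator generates all of these inputs with known ground truth.

# Coordinate conventions

Internally every interval is a `GRanges` (1-based, closed — the
Bioconductor convention). BED and bedGraph are 0-based half-open on disk
and converted at the I/O boundary by rtracklayer; GFF3 is natively
1-based. Fragments are cut at GATC motif *starts*: the 4-bp motif belongs
to the fragment it opens, fragments are contiguous, and their widths sum
exactly to the chromosome length (an invariant asserted in the tests).
bedGraph is written with 6 significant digits, one record per fragment by
default so that a write/read round trip is exact at the printed
precision.

# Signal transforms

**Log2 ratio.** Per fragment, \(r_i = \log_2\!\big((f_i + \psi)/(d_i +
\psi)\big)\) with pseudocount \(\psi = 0.5\) applied after library-size
scaling. Both tracks are scaled to the *geometric mean* of their totals
rather than scaling Dam alone: the two formulations give identical ratios
when \(\psi = 0\), but only the symmetric form is exactly antisymmetric
under a fusion/Dam swap for every \(\psi\), which we treat as the defining
invariant of the transform. \(\psi\) keeps zero-count fragments finite and
unbiased in sign. The upstream pipeline this emulates uses a kernel-based
ratio matching; library-size scaling is a deliberate, documented
simplification — deterministic and adequate on synthetic data; parity
with the original tool is not claimed.

**1x coverage.** Accessibility (Dam-only) tracks are not ratios: counts
become densities \(c_i = n_i \cdot \mathrm{readLen} / w_i\)
(readLen = 300 bp, echoing the typical extension length, used only as a
constant) and are rescaled so the length-weighted genome mean is exactly
1. The transform is scale invariant in the input counts.

**Metaprofiles.** Signal around anchor midpoints is sampled in fixed bins
(default ±2500 bp, 50-bp bins) as the length-weighted mean of overlapping
fragment values; the profile is the unweighted mean over anchors; bins
crossing a chromosome end are dropped for that anchor and the per-bin
anchor count is reported. The estimator is linear in the track, which the
tests assert exactly.

# Peak calling

The upstream peak caller for this kind of data is published only as
"FDR < 0.01"; our concrete reconstruction is: threshold \(T\) at the 0.95
quantile of all fragment values (ties included); candidates are maximal
runs of ≥ 2 consecutive same-chromosome fragments with value ≥ \(T\),
scored by their mean value; the null permutes fragment values within each
chromosome (genome-wide permutation is exposed as a flag) and re-extracts
candidates; for each observed score \(s\),
\[
\mathrm{FDR}(s) = \frac{\text{mean null candidates scoring} \ge s}
                       {\#\{\text{observed candidates scoring} \ge s\}},
\]
capped at 1 and made monotone non-increasing in \(s\) by a cumulative
minimum; peaks with FDR < 0.01 are retained. Parity with the original
script is not claimed. Replicate consensus follows multi-intersect
semantics: the genome is segmented at all replicate peak boundaries,
segments covered by ≥ 2 replicates are kept, and nearby intervals
(≤ 50 bp) are merged — replicate boundaries never match exactly, so
whole-interval identity would be wrong.

**A property of the mean-score null worth knowing.** The permutation
null scatters *all* values, including genuinely enriched fragments. Any
two enriched-level values that land adjacently form a null run whose mean
score equals that of a true peak, so the FDR at true-peak scores has a
floor of roughly \(k(k-1)/N\) null runs per shuffle for \(k\)
enriched-level values among \(N\) fragments. Concentrated true signal
(small \(k\)) is therefore recoverable at FDR < 0.01 while diffuse signal
of the same strength is not — a property of the estimator, not a bug. The
simulator's default conditions (below) were chosen by this power analysis
so that planted signal is comfortably inside the recoverable regime, and
the acceptance checks run the caller with 1000 shuffles, where the
null-count estimate at stringent FDRs has adequate granularity.

# Permutation enrichment and TSS density

Motif-hit sets (upstream, per-motif PWM scans) are consumed as intervals
with per-hit q-values, filtered at q ≤ 0.1 per variant and unioned.
Overlap enrichment counts *features overlapping ≥ 1 hit* (binary per
feature); the null re-places the chosen set (motif hits by default)
uniformly at random, preserving each interval's chromosome and length and
forbidding overlap. Placement is sampled exactly — lay the lengths in
random order and distribute the free space as sorted uniform gaps —
rather than by bedtools-style rejection, which is equivalent in
distribution and O(k log k). Reported are the mean permuted overlap, the
fold change \(\log_2((\mathrm{obs}+0.5)/(\mathrm{mean}+0.5))\), and the
one-sided add-one p-value \((1 + \#\{\mathrm{perm} \ge
\mathrm{obs}\})/(n+1)\), which never reports 0; at 100 resamples its floor
is \(1/101 \approx 0.0099\), the smallest p such an analysis can print.

TSS-relative motif density counts hit-covered bp (hits unioned first, so
nothing is double-counted) in strand-aware 100-bp bins over ±2500 bp
around each gene's TSS, summed over genes, and divides by the genome-wide
expectation: bin width available after chromosome-end truncation times
the fraction of the genome covered by hits. A value of 1.0 is exactly the
genome-average overlap; normalization is per bin, which reduces to a
single constant when bins have equal width. The 500-bp window immediately
upstream of the TSS is summarized by `summarizeWindow(profile, c(-500, 0))`.

# Practical equivalence and rescue

Differential-expression tables carry per-gene log2 fold change and its
standard error. "Significantly not different" is operationalized as a
TOST against the region of practical equivalence ±log2(1.5), assuming
normality with the gene-wise SE: \(p = \max\{1 - \Phi((\hat\beta +
\delta)/\mathrm{SE}),\ \Phi((\hat\beta - \delta)/\mathrm{SE})\}\). At the
boundary \(|\hat\beta| = \delta\) the p-value is exactly 0.5, and the
boundary type-I error is ≤ α (asserted over 10,000 simulated genes).

Baseline DEGs (BH q < 0.1, Wald) are classified against the treatment
contrast: **reverted** = significant (q < 0.1) opposite-direction change;
**restored** = equivalence BH q < 0.05, with the BH correction computed
*within the baseline-DEG set* — that is the population being classified
(a genome-wide scope is exposed as a flag). Reverted takes precedence
when both fire (a sign-flipped significant change is the stronger
statement); both flags are always reported. "Reverted" requires treatment
significance, not just a sign flip, with a flag to relax it. Note that a
BH cutoff of q < 0.1 admits ~10% false DEGs by construction; their
expression truly is equivalent to zero, so classifying them "restored" is
correct behaviour, and the rescued fraction estimated on the DEG set is
accordingly a couple of points above the planted fraction.

# The simulator and its study conditions

Every generator is a pure function of a `SimConfig` and its seed; each
stage draws from its own stream derived from the master seed by a stable
label, so adding a stage never perturbs earlier stages. Defaults (the
conditions all tests run under, chosen once from the power analysis
above):

* **Genome**: 1 chromosome × 1 Mbp; GATC sites as a 4-bp-minimum-spacing
  exponential-gap process at rate 1/256 — the density of a random 4-mer,
  matching fly-like genomes (~3900 fragments/Mbp).
* **Genes**: 200 non-overlapping spans, log-normal lengths (median
  2 kb), Bernoulli(1/2) strands, placed uniformly.
* **Domains**: exponential blocks (mean 25 kb) tiling the genome,
  five-colour labels drawn uniformly without immediate repeats.
* **DamID counts**: negative binomial, mean ∝ fragment length ×
  depth; 3 replicates; depth 2e6 reads (2 reads/bp), dispersion 0.01;
  3 planted regions of 2 consecutive GATC fragments at 4× fusion
  enrichment. Planted truth lives on the fragment lattice because that is
  the resolution of the assay. Depth is set so that even the shortest
  fragments are well covered: at low coverage the ratio variance of short
  fragments dominates the run threshold and contaminates the permutation
  null (see above). Dispersion has no published estimate for this assay;
  the default is chosen for testability, with overdispersion still
  present, and is configurable.
* **Motifs**: 10-bp hits (a typical zinc-finger footprint) at 5e-4/bp
  background; target genes get extra hits at (fold − 1) × background in
  the 500-bp strand-aware window upstream of the TSS, so fold 1 means
  exactly background and fold 10 means 10× — planted only upstream,
  matching the observed bias window the analysis is meant to detect.
* **DE tables**: 2000 genes, 400 true changes with |l2fc| ~ U(1.5, 3)
  and SE ~ U(0.05, 0.15); 30% revert, 30% restore, the rest stay
  changed. Observed l2fc = truth + N(0, SE).

What the simulator does **not** emulate: sequence composition and
mappability, the kernel ratio normalization of the upstream pipeline,
spatially autocorrelated accessibility, per-motif PWM widths and
q-values, count-model shrinkage of l2fc estimates, or any wet-lab
covariates. Passing tests therefore demonstrate the correctness and
calibration of the algorithms under their stated assumptions — not
performance on real fly data, whose headline numbers derive from
deposited sequencing experiments and are outside desk scale.

# Numerical choices and degenerate inputs

* Fragments at exactly the run threshold are included (≥).
* An all-equal track yields FDR = 1 everywhere and no peaks; a track
  shorter than one run returns an empty result, not an error.
* Merging uses strict gap arithmetic: gap ≤ 50 merges, 51 does not.
* Gene-to-colour assignment is by plurality of span coverage (ties by
  domain colour order); TSS-based assignment was the alternative and is
  noted as such.
* Empirical p-values always use the add-one estimator; permutation
  p-values can never be 0.
* Pseudocounts: ψ = 0.5 in the ratio, ε = 0.5 in the enrichment fold
  change; both configurable.
* `simConfig(seRange = c(x, x))` with tiny x gives the noise-free DE
  limit (observed = truth), used by the tests.
* Problem sizes in the test-suite property checks — 20-seed recovery runs
  at 1 Mbp, 200 null enrichment data sets, 10,000 boundary genes, 1000
  brute-force interval fixtures — were sized to give stable Monte-Carlo
  margins at the package's own tolerances.

# Known limitations

* The peak caller reconstruction is one concrete reading of an
  under-specified published method; exact parity with the original
  `find_peaks` script is explicitly not claimed.
* The FDR estimator's null-contamination floor (above) means diffuse,
  genome-wide weak enrichment is not recoverable at stringent FDRs.
* `annotatePeakFeatures` is a simplified annotator (promoter/body/TTS/
  intergenic by midpoint, promoter −1000/+100 around the TSS); it does
  not reproduce the full HOMER taxonomy.
* Equivalence testing assumes normal l2fc estimates with known SE; with
  very small counts both assumptions degrade together.
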