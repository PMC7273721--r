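---
title: "Methods: simulating and scoring photoactivation-encoded visual cell sorting screens"
author: "vcsort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and scoring visual cell sorting screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vcsort)
```

## The screen this package models

Visual cell sorting couples automated microscopy to FACS through an
irreversibly photoconvertible fluorescent protein (Dendra2). A microscope
images each field, computes a per-cell phenotype — here the
nucleus-to-cytoplasm (N:C) ratio of a miRFP reporter fused to a nuclear
localization signal (NLS), or the nuclear shape factor — and marks each
cell with a 405 nm pulse of 0, 50, 200 or 800 ms. The pulse duration sets
the cell's activated:unactivated Dendra2 ratio, and FACS recovers the four
encoded populations as four sort bins. Downstream, deep sequencing of an
NLS variant library per bin yields quantitative localization scores, and
single-cell RNA-seq of morphology-sorted cells links nuclear lobulation to
a transcriptional program.

`vcsort` implements the analysis arms of such a screen together with
seeded simulators that produce every input with ground truth attached, so
each stage can be tested end to end.

## Bin-sort localization scores

Per replicate, the scoring pipeline (`scoreVariants()`) proceeds:

1. **Filtering.** A nucleotide variant must reach `min_count = 5` reads in
   every bin of every replicate, and its mutant codon must be reachable by
   NNK mutagenesis (third base G or T). Both filters mirror how saturation
   mutagenesis data are cleaned before scoring; the NNK filter removes
   sequencing artifacts that cannot exist in the library.
2. **Collapse.** Nucleotide variants encoding the same amino-acid change
   are summed per bin.
3. **Raw score.** With within-bin frequencies $f_{b1} \dots f_{b4}$,
   $$S_{raw} = \frac{0.25 f_{b1} + 0.50 f_{b2} + 0.75 f_{b3} + 1.00 f_{b4}}
   {f_{b1}+f_{b2}+f_{b3}+f_{b4}} \in [0.25, 1].$$
   The score is invariant to per-bin sequencing depth and monotone under
   moving read mass to higher bins.
4. **Normalization.** $S_{norm} = (S_{raw} - S_{P10}) / (S_{WT} -
   S_{P10})$, the unique linear map sending the wild-type raw score to 1
   and the median raw score of the bottom decile of missense variants to
   0. The bottom-decile set is missense-only by default
   (`include_syn_in_bottom` switches this); the choice is recorded in the
   output config. When the wild-type sequence itself is filtered out, the
   mean raw score of synonymous variants anchors $S_{WT}$ instead, since
   synonymous variants score indistinguishably from wild type.
5. **Frequency re-filter.** Variants below `frequency_floor = 3e-5`
   (0.003% of reads) in *all four bins* of a replicate are dropped from
   that replicate, and frequencies, raw and normalized scores are
   recomputed. The re-filter is applied per replicate, matching the
   per-replicate symmetry of the count filter and the fact that scores are
   recalculated within each replicate.
6. **Aggregation.** Mean and standard error of $S_{norm}$ over the
   replicates in which the variant scored; variants scored in fewer than
   `min_replicates = 2` are flagged unreliable rather than dropped.

## The amino-acid-preference NLS model

Position-wise preferences are computed from **raw** scores (not
normalized), $x_{r,a} = (s_{r,a} - \min s_r)/(\max s_r - \min s_r)$, with
missing (position, residue) pairs imputed by the position's median raw
score and flagged. The wild-type residue at each position takes the
WT/synonymous raw score. An 11-mer peptide scores
$\sum_{r=1}^{11} x_{r,a_r}$.

Training labels come from annotated NLS spans: among all 11-mers sharing
at least one residue with a span, the maximum-preference window is the
"likely NLS" (ties go leftmost, a documented convention); every other
window of every training protein is a negative. The model is ordinary
least squares of the 0/1 label on the 11 positional preferences — a linear
probability model fit exactly as specified rather than logistic
regression, despite the class imbalance — with 8-fold cross-validation
(seeded fold assignment) reporting the out-of-fold AUC and the final
coefficients fit on all data.

Two call cutoffs are calibrated on a held-out test set: the smallest
cutoff achieving precision ≥ 0.9 ("high-confidence") and the largest
achieving recall ≥ 0.9 ("candidate"). A window counts as a true positive
when it overlaps a test annotation by at least 6 of 11 residues (majority
overlap); the matching rule is configurable because published evaluations
rarely state theirs. Unreachable targets fall back to the nearest
achievable cutoff with a warning. `scanProteome()` scores every in-bounds
window, records per-protein maxima, and `compareCompartments()` contrasts
nuclear versus cytoplasmic proteins' top scores with a two-sided Wilcoxon
rank-sum test plus equal-count score-bin proportions.

## Imaging: N:C ratio and shape factor

Nuclear segmentation is Gaussian smoothing (`smooth_sigma = 1.5` px), Otsu
thresholding, hole filling, a distance-transform watershed
(`watershed_tolerance = 3`, which separates nuclei touching at a thin neck
while keeping the lobes of one nucleus together) and an area filter. The
screen's own vendor pipeline is proprietary; any external label mask can
be supplied directly to the measurement functions.

Cytoplasm masks follow the dilate-and-subtract construction: every pixel
within `ring_radius = 8` px (Euclidean distance transform) of a nucleus,
minus all nuclei, with pixels contested by neighboring rings dropped from
both. N:C is the mean reporter intensity in the nuclear mask over the mean
in the ring; cells with either mean below `intensity_floor` (0 for
synthetic fixtures; 11,000 for real 12–16-bit acquisitions) are flagged
excluded, not scored. Optional background subtraction (median non-cell
intensity) precedes the means for real images and is off for noise-free
fixtures.

The shape factor is $4\pi A / P^2$ with the perimeter from a
four-direction Crofton estimator (the standard 2×2-configuration
look-up table). Unlike a boundary-pixel count, this is nearly unbiased for
smooth shapes — a digitized circle of radius 30 px scores ≈ 0.98 — which
matters because the classification cutoff (lobulated iff shape factor
< 0.65) presumes round nuclei score near 1. `polygonShapeFactor()`
computes the same quantity analytically on a generating outline and is
used for simulator ground truth.

## Single-cell stage: the lobulation score and differential expression

Counts are size-scaled to the median library size, log1p-transformed, and
the top `n_hvg = 2000` variable genes feed a centered PCA (`n_pcs = 30`;
both are configuration, not claims about any particular dataset).
Component signs follow a deterministic convention. Cell-cycle scores are
mean log-expression of a phase gene set minus an expression-matched
control (per-bin means over 25 expression bins, set genes excluded), with
the phase call the top-scoring program and a G1 fallback when none is
positive.

The lobulation model is maximum-likelihood logistic regression of the
morphology label on PCs 1–4; under complete separation it refits with a
small ridge penalty (`ridge_lambda = 1e-3`) and says so. The per-cell
lobulation *score* is the linear predictor (log-odds), not the
probability — the screen's score is only required to be high in lobulated
cells, and the log-odds preserves resolution in the tails. Batch
alignment between experiments is out of scope here: the simulator is
single-batch, so the train-on-labeled / score-on-held-out split within one
batch stands in for the original two-experiment transfer.

The DE test fits, per gene expressed in ≥ 10 cells, a negative-binomial
GLM of counts on the lobulation score with G1 and G2M scores as covariates
(the S score is computed but not used, mirroring the covariate list of the
original analysis; a cell-cycle-stratified alternative was deliberately
not implemented) and log total UMIs as offset. Dispersion is a per-gene
method-of-moments estimate from Poisson residuals
($\hat\alpha = \sum[(y-\hat\mu)^2 - \hat\mu]/\sum \hat\mu^2$) with a
Poisson fallback when $\hat\alpha \le 0$. The Wald p-value of the
lobulation coefficient is BH-adjusted across converged genes, and the
effect size is the coefficient divided by $\ln 2$: the expected log2 fold
change per unit lobulation score. Over-representation of gene sets in the
significant genes (effect < −0.1, q < 0.01 by default in the pipeline) is
a one-sided hypergeometric test, BH across sets — a deliberately simple
stand-in for consensus enrichment machinery.

## What the simulators emulate — and what they do not

* `generateNNKLibrary()` enumerates all single-codon NNK substitutions of
  a 33 nt region. The default `svNLSRegion()` is a documented stand-in
  encoding the 11 residues around the classic SV40 monopartite NLS from
  common human codons; every function takes `wt_dna` as input. Ground
  truth N:C: wild type and synonymous variants share `wt_nc = 1.40`
  (above the top gate, as for a strong NLS); nonsense variants sit at the
  bottom of `nc_range = c(0.85, 1.55)`; missense truth is uniform on that
  range, spanning no-NLS to slightly-better-than-WT phenotypes. The
  library a specific construct yields (e.g. 346 nucleotide variants)
  depends on its wild-type codons; the count is not an invariant.
* `simulateSortExperiment()` jitters each cell's log N:C (SD 0.10,
  matching the broad per-cell N:C distributions single-cell imaging of
  reporter lines shows), applies a marking miss rate of 0.2 (recall ≈
  80%), a 1% false-mark rate, 2% adjacent-bin FACS spillover and a 2%
  stray rate (doublets/impurity), then draws per-bin reads multinomially
  at `depth_per_bin = 2e5`. Deep sequencing is what lets sorter-impurity
  frequencies clear the count filter, exactly as in real screens. There
  is no PCR-bias model — the frequency-based score is depth-invariant in
  expectation — and no optics model.
* `renderNucleiImage()` paints ellipses and lobulated nuclei (a core disc
  plus four overlapping lobe discs, giving analytic shape factors around
  0.4–0.5 versus ≈ 0.95 for ellipses) with configured channel means,
  Gaussian noise and 12–16-bit clipping. No PSF, illumination field, or
  3-D structure.
* `simulateScRNA()` draws NB counts with mean `library × rate ×
  2^(effect × lobulation score) × cycle multiplier`; defaults: 30%
  lobulated cells, median 9,249 UMIs (a downsampled 10x depth), NB
  dispersion 0.4, three 25-gene cycle programs, and a 40-gene planted
  program at ±0.5 log2 per unit score. No doublets, ambient RNA, or
  batch structure — so passing tests demonstrate correct recovery under
  the generative model, not robustness to those artifacts.

All generators are pure functions of (spec, seed); pipeline stages derive
child seeds from the global seed by a fixed hash, so a config plus seed
determines every artifact byte-for-byte.

## Numerical conventions and edge cases

* Gate intervals are half-open and lower-inclusive, `[lo, hi)`; the
  published boundary values do not state membership, so the convention is
  fixed here and used everywhere (a value exactly at a boundary joins the
  upper bin).
* "Distinguishable" activation levels are operationalized as the largest
  consecutive run of encoded levels for which optimal 1-D thresholds
  achieve ≥ 95% per-level assignment accuracy; the original judgment was
  visual.
* Ties in likely-NLS extraction go to the leftmost window; ranking ties
  in the bottom decile are kept (nearest-rank decile).
* Degenerate inputs error loudly: non-increasing gates, empty nucleus
  masks, zero-read bins, constant preference positions,
  $S_{WT} \le S_{P10}$, single-label training sets.
* Genes whose NB fit does not converge are reported NA and excluded from
  the BH denominator.
* All sequence coordinates in user-facing files are 1-based inclusive;
  image coordinates are 0-based pixel indices with origin top-left.

## Problem sizes used by the test suite

The suite exercises parameter recovery at roughly the scales a desk run
affords: the full 11-codon library (227 amino-acid changes) at 500 cells
per variant over 2 replicates for score recovery; 2,000 cells × 300–500
genes for DE effect recovery and lobulation-score AUC; 800 cells × 500
genes for the null type-I check; 200 rendered nuclei across eight fields
for morphology classification. Oracle-equivalence checks (brute-force
rescoring, confusion-matrix and rank-sum oracles, closed-form
hypergeometric) run on inputs small enough to enumerate.

## Known limitations

* The segmentation is a generic pipeline, not the bleb-optimized vendor
  pipeline the original screen used; heavily fragmented nuclei may
  segment differently.
* The linear probability model can emit scores outside [0, 1]; cutoff
  calibration works on the raw score scale, so this is cosmetic.
* The stray/spillover noise model reproduces the qualitative
  imperfection of optical marking; realized precision and recall depend
  on the bin mix and are not fixed parameters.
* Method-of-moments NB dispersion is less efficient than likelihood
  estimation for very low counts; for such genes the Poisson fallback
  keeps tests conservative.
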