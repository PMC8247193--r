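---
title: "Methods: single-step GWAS, genetic parameters, tissue specificity and enrichment in sswool"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-step GWAS, genetic parameters, tissue specificity and enrichment in sswool}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`sswool` implements the statistical machinery of a weighted single-step
genome-wide association study (WssGWAS) for quantitative traits in a
partially genotyped pedigreed population — the design typical of livestock
breeding programmes, where thousands of animals carry phenotypes and
pedigree records but only a fraction are genotyped — together with the two
downstream analyses that interpret its output: tissue-specificity scoring of
genes from a multi-tissue expression atlas, and a sum-based enrichment test
of GWAS signal in tissue-specific gene sets. Because the motivating data
(wool and weight records from commercial Merino flocks) are private, the
package ships a synthetic-data generator with known ground truth; every
claim the test suite makes is a recovery-of-truth statement about that
generator, not about any real population.

## The animal model and variance components

All prediction and estimation rests on the Gaussian animal model

$$ y = X\beta + Za + e, \qquad a \sim N(0,\, K\sigma^2_a), \quad
   e \sim N(0,\, I\sigma^2_e), $$

where $\beta$ holds the environmental fixed effects — flock, birth year and
season, modelled as unordered factors with treatment coding — and $K$ is a
relationship matrix: the pedigree numerator matrix $A$ for classical
estimation, or the combined pedigree–genomic matrix $H$ for single-step
prediction. Heritability is $h^2 = \sigma^2_a/(\sigma^2_a + \sigma^2_e)$;
for a pair of traits the genetic correlation is
$r_g = \mathrm{cov}_a/\sqrt{\sigma^2_{a1}\sigma^2_{a2}}$.

`reml_fit()` maximises the restricted likelihood by average-information (AI)
updates. The implementation first rotates the model by the eigenvectors of
the observed-animal block of $K$; in the rotated basis the covariance is
diagonal (single trait) or block-diagonal in 2×2 blocks (bivariate), so each
likelihood, gradient and AI evaluation costs $O(np^2)$ after one $O(n^3)$
eigendecomposition per dataset. An AI step that leaves the parameter space
or decreases the likelihood is step-halved; if positivity still fails, a
damped multiplicative update (the fixed point of the REML equations, which
preserves positivity) or — in the bivariate case — a projection of the 2×2
covariance blocks onto the positive-definite cone is used instead.
Convergence is declared when the largest relative parameter change falls
below `tol` (default `1e-8`). Standard errors come from the inverse of the
final AI matrix; heritability and correlation SEs are delta-method
propagations of that sampling covariance, and are labelled as such — no
claim is made that they match any particular software's internal SE
formula. `reml_loglik()` evaluates the same restricted likelihood
(`-0.5 [log|V| + log|X'V^{-1}X| + y'Py]`) by direct dense linear algebra; it
exists so that optimiser output can be checked against an independent grid.

Bivariate fits use the animals observed for both traits: the eigen-rotation
mixes animal indices, so a common phenotyped set is required. Single-trait
fits simply drop missing records. The package fits trait pairs rather than a
joint six-trait model; every reported quantity (heritabilities, pairwise
genetic and phenotypic correlations) is defined pairwise, and pairwise fits
are far better conditioned at the problem sizes used here.

## Single-step machinery

* `numerator_relationship()` builds $A$ by the recursive tabular method with
  inbreeding ($a_{ii} = 1 + a_{sd}/2$).
* `a_inverse()` assembles the sparse $A^{-1}$ directly from Henderson's
  rules with inbreeding-adjusted Mendelian-sampling variances
  $d_i = 0.5 - 0.25(F_s + F_d)$ (terms for unknown parents dropped).
* `genomic_relationship()` forms the allele-frequency-scaled genomic matrix
  $G = Z D Z' \lambda$ with $Z$ the dosage matrix centred columnwise by
  $2p_i$, $D$ a diagonal SNP-weight matrix and
  $\lambda = 1/\sum_i 2p_i(1-p_i)$. Missing dosages are mean-imputed to
  $2p_i$ — a zero contribution after centring — and markers fixed in the
  genotyped sample are excluded. Centring by allele frequencies is adopted
  because $\lambda$ is exactly the scale that gives a mean diagonal near 1
  under Hardy–Weinberg proportions; the dosage coding (aa = 0, Aa = 1,
  AA = 2) counts the declared A1 allele.
* `tune_and_blend()` makes $G$ compatible with the pedigree expectation: it
  solves the two-moment system so that the mean diagonal *and* mean
  off-diagonal of $\alpha + \beta G$ match those of $A_{22}$, then blends
  $G_w = 0.95(\alpha + \beta G) + 0.05 A_{22}$. Matching only the mean
  diagonal (a single weighting factor) is a special case; the two-moment
  version additionally aligns the base-population reference and guarantees
  a sensible $\beta$, which is reported. The 0.95/0.05 blend is the standard
  device that makes $G_w$ invertible — necessary because a frequency-centred
  $G$ is always singular when the frequencies are estimated from the
  genotyped sample itself.
* `h_inverse()` assembles
  $H^{-1} = A^{-1} + \begin{bmatrix} 0 & 0 \\ 0 & G_w^{-1} - A_{22}^{-1}
  \end{bmatrix}$, keeping $A^{-1}$ sparse and adding the dense correction on
  the genotyped block. Dense factorisations throughout use symmetric
  Cholesky with a logged `1e-8` diagonal jitter fallback.

`solve_mme()` solves Henderson's mixed-model equations with the variance
ratio $\sigma^2_e/\sigma^2_a$ on the additive block via a sparse Cholesky
factorisation, so animals without phenotypes receive breeding values
through their relationships. With no genotyped animals the system reduces
exactly to pedigree BLUP, which the tests verify against a dense
generalised-least-squares oracle.

## The weighted single-step GWAS loop

`run_wssgwas()` executes the published iteration: start with $D = I$; build
$G_{(t)} = Z D_{(t)} Z' \lambda$, tune/blend, assemble $H^{-1}$, solve the
mixed-model equations for GEBV; backsolve SNP effects
$\hat u_{(t)} = \lambda D_{(t)} Z' G_{(t)}^{-1} \hat a_g$ from the genotyped
animals' GEBV; reweight $d_{i(t+1)} = \hat u_{i(t)}^2\, 2p_i(1-p_i)$;
normalise $D_{(t+1)}$ to constant trace ($\sum_i d_i = m$); rebuild $G$.
`n_reweight = 1` is the default, matching the published procedure, with the
loop exposed for monotonicity studies. Two implementation decisions:

* The backsolve uses the same tuned/blended $G_w$ that enters $H^{-1}$: the
  raw $G$ is singular (see above), and using one matrix throughout keeps
  $Z\hat u$ consistent with the GEBV it decomposes. On full-rank toy
  matrices with externally supplied frequencies the identity
  $Z\hat u = \hat a_g$ holds to machine precision, which the tests assert.
* Weights lag one iteration behind effects exactly as the printed steps
  order them: the GEBV solved with $D_{(t)}$ produce $\hat u_{(t)}$, which
  produce $D_{(t+1)}$.

### Window variances and QTL regions

`window_variances()` slides a 20-SNP window (step one SNP, never spanning a
chromosome boundary) and reports
$\mathrm{var}(a_i)/\sigma^2_a \times 100$, where
$a_i = \sum_{j \in \text{window}} z_j \hat u_j$ is the window genomic value
over the genotyped individuals and the variance is the empirical $1/(n-1)$
variance — the denominator convention is declared here because the source
formula leaves it open. Chromosome tails shorter than the window yield a
single truncated window, flagged and excluded from ranking.

`top_windows(k)` reports the top `k` *QTL regions*: windows are visited in
rank order, and a window overlapping (or bookended to) an already-selected
region extends that region instead of consuming a selection slot. Counting
regions rather than raw windows is deliberate: with step-1 sliding windows,
the ~19 windows covering one strong locus would otherwise monopolise every
top rank, and a "top 10" would describe one locus. Region counting matches
how QTL are reported in practice (distinct merged bp intervals, of which
several dozen across traits). Each region records its best single window's
variance percentage (`best_pct_variance`) and the sum over member windows
(`sum_pct_variance`); the former is the honest per-locus summary, because
overlapping windows share SNPs and their percentages are not additive.
`top_percent_snps()` takes the best `ceiling(fraction × n)` windows
(default 1%) and returns the genes whose annotated span overlaps them, the
input for functional enrichment done elsewhere.

## Quality control

`qc_filter()` applies the array-data rules in a declared order — unmapped
markers, sex chromosomes, individuals below 90% call rate, markers below
90% call rate, MAF below 1%, exact Hardy–Weinberg test $p < 10^{-6}$ — with
allele frequencies recomputed after individual removal. The order
(individuals before marker call rate) is a convention, made explicit
because published pipelines rarely state it; the filter is idempotent.
`hwe_exact_test()` is the two-sided exact conditional test that sums the
probabilities of all heterozygote counts no more probable than the observed
one; it is verified against a full-enumeration oracle for every count
triple with total ≤ 50. LD is the squared Pearson correlation of dosage
vectors (composite/genotypic $r^2$; genotypes are unphased), with pairwise
deletion of missing calls. The phenotype outlier rule sets records more
than 3 SD from the trait mean to missing in a single pass — deliberately
not iterated, for reproducibility.

## Tissue specificity

Expression input is a genes × samples TPM matrix
(`tpm_normalize()`: rate = counts per kb, scaled to one million per
sample). `scale_expression()` takes $y = \log_2(\mathrm{TPM} + 0.25)$ and
standardises each gene to mean 0, SD 1 across samples. The pseudo-count
0.25 is used consistently on the log2 scale; "scaled" is interpreted as
per-gene z-scaling (the alternatives — per-sample or global scaling — would
let highly expressed genes dominate every tissue contrast). For each gene
and each target, `fit_tissue_model()` regresses $y$ on an intercept, a
tissue code ($+1$ for target samples, $-1$ for the rest) and age-stage and
sex factors by least squares; $t = \beta/\mathrm{SE}$ with the SE floored
at $10^{-12}$ so perfect separation yields a large finite statistic. When
the target is a single tissue, other samples of the same organ system are
excluded from the $-1$ group (they are neither the target nor clean
background); organ-system targets use all samples. The top decile of genes
by $t$ (ties broken by gene id) is the tissue-specific set.

## Enrichment with a cyclical-permutation null

For a gene set, `map_markers_to_genes()` marks every SNP within a symmetric
20-kb extension of any member gene (inclusive bounds, clamped at position 1,
strand ignored), and the statistic is $T_{\text{sum}} = \sum b_i^2$ over the
$m_g$ masked SNPs, with $b$ the WssGWAS SNP effects. The null rotates the
genome-ordered effect vector by a uniform random offset — the genome
treated as a single circle in (chromosome, position) order — and recomputes
$T_{\text{sum}}$ against the fixed mask. Rotation preserves the effect
multiset, the set size $m_g$, and all local (LD) adjacencies except at the
single seam, which is why it is the appropriate null for sets of clustered,
correlated markers. Whole-genome rotation (rather than per-chromosome
circles) is a declared choice: it preserves the mask exactly and needs no
per-chromosome bookkeeping. One-tailed empirical p-values use the
add-one convention $p = (1 + \#\{T_{\text{perm}} \ge T_{\text{obs}}\}) /
(1 + n_{\text{perm}})$ — never zero, ties counted conservatively — with
10000 rotations by default and offsets sampled with replacement.
`fdr_bh()` (a thin wrapper over `stats::p.adjust`) corrects within trait
across gene sets.

## The synthetic-data generator

`sim_config()` defaults encode the emulated study design: six traits with
the published heritabilities (0.36, 0.05, 0.07, 0.27, 0.28, 0.33) and the
published genetic-correlation matrix as targets; flock/year/season with
50/8/2 levels; females phenotyped; 17% of phenotyped animals genotyped; 26
autosomes; founder allele frequencies uniform on (0.05, 0.5). Phenotypic
variance is 1 per trait, so $\sigma^2_a = h^2$ — the published raw variances
are trait-unit-specific and carry no extra information once $h^2$ is fixed.

* **Pedigree** — non-overlapping generations from an even founder sex
  split; random monogamous matings, so no selfing by construction.
* **Genotypes** — gene dropping: founder haplotypes in Hardy–Weinberg
  proportions, descendants receive one recombinant gamete per parent under
  a Haldane map at 1 cM/Mb (Poisson crossovers, uniform positions); a
  missing parent's gamete is drawn from the founder frequencies. Mendelian
  consistency is exhaustively checkable and tested.
* **Traits** — true breeding values are the sum of explicit QTL effects on
  centred dosages and an infinitesimal polygenic term bred down the
  pedigree (parent average plus Mendelian sampling with variance
  $1 - 0.25 \times$ number of known parents, scaled by the polygenic
  covariance). Each planted QTL is scaled to contribute an **equal share**
  `qtl_variance_fraction / n_qtl` of the additive variance among founders:
  with raw Gaussian effects one or two loci dominate the QTL variance and
  "n planted QTL" would not mean n detectable loci. Cross-trait effect
  correlations are drawn from the target matrix before this per-locus
  rescaling, so the QTL part carries correlation mainly through effect
  signs; recovery studies of genetic correlations therefore use the pure
  polygenic architecture (`qtl_variance_fraction = 0`), where the target is
  exact. Fixed-effect level values are drawn once from
  $N(0, (0.5\,\mathrm{SD}_p)^2)$ — large enough to matter, small enough to
  estimate. If the requested correlation matrix is not positive
  semi-definite (printed estimates need not be), it is projected to the
  nearest PSD matrix.
* **Expression atlas** — 87 tissues in 13 organ systems, 6 samples per
  tissue by default (~522 samples); baseline $\log_2$ expression per gene
  from $N(3, 2^2)$, i.i.d. per-sample noise (SD 1 on the log2 scale),
  planted tissue-specific genes raised by $\log_2(\text{fold change})$ in
  their target tissue, columns rescaled to TPM. Planted sets are disjoint
  across target tissues. The rescaling makes the data honestly
  compositional: a strong planted signal depresses every other gene in that
  tissue, which the tissue-specificity model must overcome.

What the generator does **not** emulate: selection and assortative mating,
overlapping generations, flock–family confounding (flocks are assigned at
random), dominance and epistasis, genotyping-array ascertainment, and — in
the atlas — system-wide co-expression beyond the planted genes, sample-level
library-size artefacts, or multi-role cell types. Passing tests therefore
demonstrate that the estimators recover truth under a clean additive
design, not that they are robust to confounding found in real data.

## Problem sizes and numerical conventions

The test suite and the acceptance script run at desk scale, chosen so the
full suite completes in minutes on one CPU: heritability recovery uses 50
replicates of ~1000 phenotyped animals; correlation recovery 20 replicates
of ~2000; QTL localisation 10 replicates of ~2850 animals (~2000 genotyped)
with 5000 SNPs on five 50-Mb chromosomes — an array-like density at which a
20-SNP window spans about 1 Mb; enrichment calibration estimates the null
rejection rate from 600 random gene sets. The analysis scripts under
`analysis/` run one larger narrative instance (~3800 animals, ~1900
phenotyped females, ~17% genotyped). Internal genomic coordinates are
1-based inclusive everywhere; BED input is converted on import. Unknown
parents default to code `"0"`. All stochastic stages derive independent
sub-seeds from one global seed via a labelled hash, so any stage can be
re-run alone and byte-identical outputs are reproduced.

## Known limitations

Dense $A$ and eigendecompositions bound practical problem sizes to a few
thousand animals — appropriate for a reference implementation, not for
national evaluations. The bivariate REML requires complete cases for the
trait pair. SE formulas are delta-method approximations from the AI matrix.
The enrichment null treats the genome as one circle; sets covering a large
fraction of the genome leave little room for rotation and lose power. The
tissue model assumes balanced-enough covariates within each contrast;
degenerate designs drop covariates with a warning rather than refusing to
fit.
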