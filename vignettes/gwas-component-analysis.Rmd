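---
title: "Methods: hierarchical GWAS component analysis"
author: "gwascomp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hierarchical GWAS component analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`gwascomp` stacks two linear propagation steps to move disease
association from the genome to transcriptional programs.

**Stage 1 — SNP to gene.** A pre-trained sparse model
$T_g = \sum_{i \in Model_g} W_{gi} X_i + \epsilon$ predicts the
expression of gene $g$ from allelic dosages $X_i$. When only GWAS
summary statistics $Z_i$ are available, the gene-level association is
approximated by
$$Z_g \approx \sum_{i \in Model_g} W_{gi}\,\frac{\sigma_i}{\sigma_g}\,Z_i,
\qquad \sigma_i = \sqrt{\Gamma_{ii}},\quad
\sigma_g^2 = \sum_{ij} W_{gi}\,\Gamma_{ij}\,W_{gj},$$
where $\Gamma$ is the dosage covariance of the model SNPs taken from an
LD reference panel. The approximation assumes the trait regression and
the reference panel share the same LD structure, and that per-SNP
effects are small (the usual summary-based TWAS regime).

**Stage 2 — gene to component.** A co-expression module's eigengene is
the first principal component of its member genes' standardized
profiles, $L_l = \sum_g R_{lg} \tilde T_g$ — again a linear map, so the
same relation applies once more:
$$Z_l \approx \sum_{g \in Module_l} R_{lg}\,\frac{\sigma_g}{\sigma_l}\,Z_g,
\qquad \sigma_l^2 = \sum_{gh} R_{lg}\,\Gamma^G[g,h]\,R_{lh},
\quad \Gamma^G = W\,\Gamma\,W^\top.$$
Under the null hypothesis $Z_l$ is standard normal; after Holm–Sidak
adjustment across all components tested together, significant ones are
called *GWAS components*. Because both stages are linear in the SNP
z-scores, composing them is algebraically identical to a single-step
propagation with combined weights $W\,(R/s)$ — a property the test suite
checks to $10^{-8}$.

**Which standard deviations enter the ratio.** The eigengene is fitted
on *standardized* gene profiles, so the loading applied to raw predicted
expression is $R_{lg}/s_g$ with $s_g$ the per-gene standard deviation
recorded at fit time; `computeComponentZ()` performs that division by
default. The $\sigma_g$ in the ratio is taken from the
genotype-propagated covariance $W\Gamma W^\top$, not from measured
expression: this keeps both stages internally consistent with the same
reference panel, and in the simulation harness the two coincide up to
sampling error. Externally supplied per-gene SDs can be injected through
the model table's `gene_sd` column (or bypassed with
`useGeneSd = FALSE`) for workflows that prefer measured-expression
scaling; which variant is preferable on real data is genuinely open, and
the package treats it as a user choice.

**Variance bookkeeping across genes.** $\Gamma^G$ requires SNP
covariances across genes. Standard LD references are stored per gene, so
`predictedGeneCovariance()` pools SNP pairs over all blocks and fills
pairs never observed together with 0 — the only assumption-free
completion. When a full-panel SNP covariance is available (as in the
simulation harness, where it is computed in-sample) it can be passed via
`fullCov` and overrides the pooled lookup.

# Module detection

`detectModules()` implements the classic unsigned weighted-correlation
pipeline: standardize rows, Pearson correlation, adjacency
$a_{ij} = |cor_{ij}|^\beta$, topological overlap similarity,
average-linkage clustering of the TOM dissimilarity, and a *static* cut
at a fixed height. Defaults:

| parameter | default | rationale |
|---|---|---|
| `softPower` | 6 | the customary unsigned soft-threshold exponent |
| `minModuleSize` | 5 | permits small modules while excluding pairs/triplets |
| `cutHeight` | 0.98 | static cut near the top of the TOM dendrogram |

The dynamic hybrid tree cut common in WGCNA workflows is deliberately
not implemented: the static cut keeps the stage fully deterministic and
dependency-free, and externally fitted module tables can always be
supplied through `readEigengeneModel()`. Detection is
permutation-equivariant, and module labels (size-descending, ties by
smallest member id) do not depend on gene order.

Eigengene loadings are the leading singular direction of the
standardized module matrix, so $var(L_l)$ equals the leading eigenvalue
of the module correlation matrix (checked to $10^{-8}$). PCA signs are
arbitrary; loadings are flipped so the eigengene correlates
non-negatively with the module's mean standardized profile, with the
first nonzero loading forced positive on exact ties. This makes outputs
reproducible across platforms.

# Allele harmonization

GWAS effect alleles are aligned to the prediction model's coding before
stage 1: matching pairs keep their z-score, swapped pairs negate it, and
strand-ambiguous (A/T, C/G) or irreconcilable pairs are dropped with
logged counts. No strand-flip rescue is attempted — for ambiguous pairs
a flip cannot be distinguished from a swap without allele frequencies,
which the package deliberately does not consume.

# Enrichment and driver ranking

The overrepresentation engine is shared by driver ranking, phenotype
(mouse-model-style) validation and edge-overlap analyses. It evaluates
the hypergeometric point probability of a 2×2 table in factorial form
$$p = \frac{(a+b)!\,(c+d)!\,(a+c)!\,(b+d)!}{n!\,a!\,b!\,c!\,d!}$$
and reports the one-sided upper tail (sum over overlaps $\ge a$ at fixed
margins), since the scientific hypothesis is an odds ratio *greater*
than 1; the tail is verified against brute-force enumeration for every
table with $n \le 12$. When $b = 0$ or $c = 0$ the odds ratio is
reported as `Inf` and flagged rather than continuity-corrected: the
exact test needs no correction, and a corrected OR would be an invented
number.

Driver candidates are *all* network nodes with at least one descendant
in the background — drivers need not belong to the component. "Downstream"
is the full descendant set by default; `directChildrenOnly = TRUE`
restricts to immediate children for users who prefer the narrower
reading. Adjustment is across all candidates tested in a run; analyses
spanning several tissues or diseases should adjust within whatever
family matches their inferential claim.

# Characteristic directions

`characteristicDirection()` computes
$v \propto \hat\Sigma^{-1}(\mu_1-\mu_0)$ with
$\hat\Sigma = (1-s)\,\Sigma_{pool} + s\,(tr(\Sigma_{pool})/p)\,I$. The
shrinkage default $s = 0.5$ exists because expression data almost always
have $p \gg n$, making the pooled covariance singular; the full
PCA-subspace construction used elsewhere in the literature is not
re-derived — this is a documented simplification, exact when the true
shared covariance is well-conditioned and estimable.

The empirical null for cosine matching can be built two ways, because
the provenance of a "random signature" is genuinely ambiguous: resample
a user-supplied signature pool (closer to real empirical nulls, which
are bell-shaped but skewed), or draw isotropic random unit vectors
(closed-form moments: mean 0, sd $\approx 1/\sqrt{p}$, used by the
calibration tests). Both are seeded. Hit calling applies the
|normalized score| > 1.96 idea through adjusted two-sided normal
p-values (Holm–Sidak over all pairs involving a perturbation, hit at
adjusted p < 0.05); `adjust = FALSE` reproduces the bare 1.96 threshold.

# The synthetic-data harness

The generator emulates the artifacts the pipeline consumes, not any
particular cohort:

* **Genotypes** — two haplotypes per individual from a latent Gaussian
  AR(1) process (`ldRho`, default 0.3) thresholded at per-SNP MAFs drawn
  from (0.05, 0.5), giving Hardy–Weinberg dosages with tunable local LD.
* **Weight models** — each gene draws `snpsPerGene = 5` SNPs; genes of
  the same module share 80% of them (`shareFrac = 0.8`) with common
  weights, which plants within-module predicted-expression correlation
  above 0.5 while keeping modules mutually independent.
* **Traits** — $Y = L_1 + \alpha\,\epsilon$ with
  $\alpha = sd(L_1)(1-SNR)/SNR$, so
  $SNR = sd(L_1)/(sd(L_1)+\alpha)$ — broad-sense heritability — holds
  exactly by construction. SNR settings 0.10/0.05/0.02 are the
  validation grid; `nullTrait()` provides the genotype-independent
  counterpart.

The default validation scale is 2,000 individuals, 300 SNPs, 60 genes,
12 modules and 10 replicates — large enough that the causal component
separates cleanly at 10% SNR (z ≈ 5–7 against a null of |z| ≲ 2.5)
while a full 30-run consistency experiment completes in well under a
minute; the reference-cohort scale of a few thousand samples is
reachable by configuration. Per-gene LD covariance handed to the
association stage is computed from the same simulated dosages
(in-sample), so the consistency check isolates the propagation
approximation itself rather than reference-panel mismatch.

What the harness does **not** emulate: realistic (coalescent) LD decay
and allele-frequency spectra, binary traits, covariate structure or
batch effects in expression, cross-module genetic correlation, and
weight-model estimation error (planted weights are exact). Passing the
simulation suite therefore demonstrates the statistical machinery is
correct under its own assumptions — not that any particular real-data
result will replicate.

# Numerical choices

* Degenerate variances ($\sigma^2 \le 10^{-12}$) omit the entity with a
  logged reason; `NaN` never propagates.
* Covariance blocks must be positive semidefinite within $10^{-8}$
  (scaled by the largest variance) at assembly.
* Two-sided normal p-values are floored at the smallest positive double
  before Holm–Sidak adjustment, which requires $p \in (0,1]$.
* Writers emit 17 significant digits so every reader/writer pair
  round-trips numerics bitwise.
* All stochastic utilities take an explicit integer seed; replicate
  seeds are derived by fixed affine maps kept below $2^{31}$.

# Known limitations

* The static tree cut is cruder than dynamic hybrid cutting on real
  expression data with nested module structure; for production
  co-expression analyses, import externally fitted module tables.
* Cross-gene covariance zero-fill underestimates $\sigma_l$ when module
  genes have correlated SNPs that never co-occur in a reference block;
  supply a full-panel covariance when available.
* The shrunk pooled covariance is a pragmatic stand-in for the full
  characteristic-direction construction; directions for $p \gg n$ data
  depend on the shrinkage intensity.
* Driver ranking inherits the directed network it is given; edge
  orientation errors propagate directly into descendant sets.
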