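---
title: "Multi-resolution group knockoffs for GWAS: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-resolution group knockoffs for GWAS: models, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Genome-wide association studies test whether genetic variants influence a
trait. Marginal tests (single-SNP regressions, linear mixed models) cannot
separate causal variants from their neighbors in linkage disequilibrium
(LD): both are marginally associated. `mrknockoff` instead tests
*conditional* hypotheses on groups of variants: a group $G$ is null when the
trait $Y$ is independent of $X_G$ given all remaining variants $X_{-G}$.
Rejections therefore localize distinct signals. Because tightly linked
variants are individually unresolvable, the hypotheses are formed at several
nested resolutions — from wide LD blocks down to single variants — and the
false discovery rate (FDR) is controlled separately at each resolution with
the knockoff filter.

# The model stack

## Genotype distribution: haplotype-cluster HMM

Inference relies on a model for the genotype distribution only; nothing is
assumed about how the trait depends on the genotypes. Haplotypes are modeled
with the classical fastPHASE-style hidden Markov model: latent states are
$K$ ancestral haplotype clusters, the chain jumps at site $j$ with
probability $r_j$ (recombination), a jump redraws the cluster from weights
$\alpha_{j\cdot}$, and the allele at site $j$ is emitted with cluster
frequency $\theta_{jk}$. Diploid genotypes are two independent chains; with
phased input each haplotype is handled on its own, which avoids any implicit
re-phasing. Parameters are fitted by Baum–Welch EM on the haplotypes
(log-space scaled recursions; random restarts with
$\theta \sim \mathrm{Uniform}(0.1, 0.9)$, uniform $\alpha$, constant
$r = 0.1$; the restart with the best final log-likelihood wins). The EM
trace is exposed so monotonicity is testable. The closed-form $K = 1$ fit
(empirical frequencies) is special-cased.

## Group knockoffs

A group knockoff $\tilde X$ of $X$ for a partition $\mathcal G$ satisfies
(1) $Y \perp \tilde X \mid X$ — guaranteed here because knockoff generation
never receives the phenotype — and (2) swapping $\{X_j : j \in G\}$ with
$\{\tilde X_j : j \in G\}$ for any $G \in \mathcal G$ leaves the joint law
of $(X, \tilde X)$ unchanged. Generation proceeds per haplotype in three
steps: draw a latent path from the exact posterior $P(Z \mid H)$ by backward
sampling; copy the path group by group with a sequential
conditional-independent-pairs (SCIP) sampler; re-emit alleles at the
knockoff states.

The SCIP step is the technical core. Processing groups left to right, the
knockoff segment for group $g$ (sites $a..b$) is drawn jointly from its
conditional law given the original path and the knockoffs of earlier
groups. For a Markov chain this conditional factorizes over the group: the
weight at site $a$ is
$Q_a(z_{a-1}, k)\, Q_a(\tilde z_{a-1}, k) / n_{g-1}(k)$, interior sites use
the chain transitions, and the right boundary contributes
$Q_{b+1}(\cdot, z_{b+1})$; $n_{g-1}(k)$ is the normalizing function of the
previous group evaluated at $k$, carried forward recursively. Sampling is a
forward pass restricted to the group followed by backward sampling, giving
$O(pK^2)$ per path. Exchangeability is not taken on faith: for every
contiguous partition of up to four sites the test suite enumerates the
sampler's conditionals exactly and verifies that the joint law of
$(h, \tilde h)$ is invariant under group swaps to $10^{-10}$, and that the
knockoff marginal equals the original law. Larger instances are checked
statistically (moments, LD profile, independence in the whole-chromosome
and independent-sites limits).

The genomic processing order keeps the dynamic program banded; any order
would be valid. Randomness is drawn from R's RNG under a single master
seed; stages derive fixed offsets from it, so the whole pipeline is
deterministic and single-threaded (no per-individual counter streams are
needed).

## Partitions

Variants are grouped by adjacency-constrained agglomerative clustering of
the dissimilarity $1 - r^2$, where $r^2$ is the squared Pearson correlation
of allele counts (computed on haplotypes when available, within a window of
1000 variants by default). Complete linkage is used because it bounds the
within-group dissimilarity — groups exist precisely because their members
are too similar to distinguish — and because complete linkage is reducible,
so merge heights are non-decreasing and dendrogram cuts are well defined.
Ties are broken by the leftmost pair; cutting applies the merge prefix with
height at or below the threshold, so partitions from decreasing cut heights
are nested by construction. Partitions are computed before the phenotype is
read. At desk scale the default ladder targets mean group sizes of about
10, 3 and 1 variants (roughly 20 kb, 6 kb, and single-variant resolution on
the simulator's 2-kb grid). This is deliberately finer than a ladder for a
biobank-sized study: with six causal clusters, coarser blocks would leave
fewer than $1/q$ discoverable groups, and the filter would then have no
power at all (see below).

## Importance statistics

A lasso (linear or logistic, via `glmnet`) is fitted to
$[\mathbf Z, X, \tilde X]$ with covariates $\mathbf Z$ unpenalized
(penalty factor 0) and genotype/knockoff columns standardized. Within each
original/knockoff pair the column order is randomized (seeded) so a solver
cannot break ties in favor of originals; the permutation is recorded and
undone when the coefficients are read. The regularization level is chosen
by 10-fold cross-validation at the minimum of the CV deviance, with a
50-point log-spaced path down to $10^{-2}\lambda_{\max}$ (a shorter path
than the solver's default: with hundreds to thousands of candidate
predictors the CV minimum sits well above $10^{-4}\lambda_{\max}$, and the
shorter path halves the fit time without moving the selected model).
Group importances are $T_g = \sum_{j \in G_g} |\hat\beta_j|$ and
$\tilde T_g$ over the knockoff copies; the statistic is the antisymmetric
contrast $W_g = T_g - \tilde T_g$, so for null groups the sign of $W_g$ is
a fair coin flip.

## The knockoff filter

The threshold is
$\tau = \min\{t : (1 + \#\{W_g \le -t\}) / \max(1, \#\{W_g \ge t\}) \le q\}$,
and groups with $W_g \ge \tau$ are reported. The $+1$ offset gives provable
FDR control; `offset = 0` is available but warns that the guarantee is
lost. One practical consequence of the offset is a power floor: no
discovery can be made unless at least $1/q$ findings clear the threshold
together, so sparse-signal configurations can yield empty discovery sets at
coarse resolutions while finer resolutions (with more non-null groups)
succeed.

Per-finding significance is summarized by a local FDR estimate exploiting
the same sign symmetry: the reflected negative statistics estimate the
positive half of the null, and
$\widehat{\mathrm{fdr}}(w) = n_- \hat f_-(w) / (n_+ \hat f_+(w))$ with a
shared Gaussian kernel bandwidth, clipped to $[0,1]$ and made monotone
non-increasing by isotonic adjustment. With fewer than 200 groups the
estimate is refused (NA with a flag) rather than returned as noise.

Across resolutions, each level is filtered independently — that is the
guarantee the method offers — and a *simplified count* summarizes the
ladder: a finer discovery supported by a selected group at the immediately
coarser level supersedes it; unsupported fine discoveries are flagged
"floating" and excluded from the summary (only the immediately coarser
level is consulted; tolerating deeper gaps would silently change what
"supported" means). Floating blocks are flagged, never suppressed, because
suppression would require coordinating the filters across resolutions,
which costs power.

# The simulator

The generator draws the study conditions used throughout the tests: a
ground-truth HMM on a 2-kb variant grid (uniform cluster weights, emission
frequencies from Uniform(0.05, 0.95), jump probabilities from
Uniform(0.02, 0.08), so LD decays over a few tens of kb and variants stay
polymorphic), phased haplotypes, and traits. Causal variants sit in evenly
spaced 0.1-Mb windows, five per window; each cluster gets one relative
effect magnitude, uniform draws rescaled so the smallest-to-largest ratio
is exactly 1/19, with random signs, attached to standardized genotypes.
Gaussian traits fix the realized heritability exactly (the noise is
residualized against the genetic score and rescaled), which makes
acceptance bands tighter than an in-expectation construction. Binary traits
threshold a latent Gaussian liability (probit), and the realized case
fraction is reported.

What the simulator does *not* emulate: population structure and
relatedness, rare variants (the emission range keeps frequencies common),
genotyping error and missingness, and non-additive trait architectures.
Passing tests therefore demonstrate correctness of the machinery and FDR
control when the genotype model is well specified at desk scale; they do
not certify robustness to the model misspecification present in real
cohorts.

# Default parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `K` | 5 (desk scale); 50 suggested for real data | clusters | matches the generating model at test scale; real-data fits need more clusters |
| EM | 20 iterations, 2 restarts (pipeline) | — | recovery is within 0.05 MAE at this budget; the trace is exposed |
| `q` | 0.1 | — | conventional FDR target for complex traits |
| ladder | mean group sizes 10 / 3 / 1 | variants | keeps ≥ 1/q non-null groups per level under the 6×5 causal design |
| LD window | 1000 | variants | beyond this, r² is treated as 0 |
| lasso | 10 folds, 50 λ's, min ratio 0.01, CV-min rule | — | deviance-minimizing λ; path shortened for speed (see above) |
| causal design | 6 clusters × 5 variants, 0.1 Mb wide, ratio 1/19 | — | clustered architecture with heterogeneous effects |
| local FDR | ≥ 200 groups required | groups | kernel two-group estimate is meaningless below this |

Desk-scale problem sizes used by the acceptance machinery: n = 2000
samples, p = 600 variants, 25 replicates for the FDR study; smaller
configurations (n = 1000–1500, p = 300–400, 3–4 replicates per condition)
for the power-trend and case-control checks. These sizes keep the full
statistical suite to tens of minutes while leaving Monte-Carlo error small
relative to the tested margins; they scale the original design down in n
and p without changing its structure.

# Numerical choices and degenerate inputs

* All HMM recursions are scaled per site; log-likelihoods accumulate in log
  space, so chromosomes of arbitrary length do not underflow. A haplotype
  with probability zero under the model raises an explicit
  impossible-observation error.
* EM clamps $\theta$ to $[10^{-6}, 1-10^{-6}]$ and $r$ to
  $[10^{-6}, 1-10^{-6}]$ to keep every observation reachable; user-supplied
  models may use exact 0/1 parameters.
* Monomorphic variants get off-diagonal $r^2 = 0$ with a warning;
  zero-variance columns are dropped from the regression design (warning)
  and contribute zero importance.
* Ties at the filter threshold are selected (`>=`); ties in merge heights
  are applied together at a cut, so a requested group count may be
  undershot when duplicates collapse.
* Missing genotypes are mean-imputed per variant before fitting and
  regression — the simplest deterministic choice.

# Known limitations

* The HMM describes homogeneous, unrelated samples; no long-range
  background (population structure) or family structure.
* One knockoff draw per analysis: re-sampling knockoffs yields another
  valid analysis, but combining several into one inference is not
  implemented.
* The simplified count is a summary, not a guarantee; FDR control holds per
  resolution.
* Partition quality depends on the LD estimate; with very few samples the
  dendrogram is noisy and group boundaries arbitrary.
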