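---
title: "Methods: multi-condition co-expression networks and cross-species comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-condition co-expression networks and cross-species comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stressnet)
```

## The model

stressnet reconstructs condition-specific gene co-expression networks under
a Gaussian graphical model (GGM).  Standardized log-expression profiles of
p genes are modeled as multivariate normal; two genes are connected under
condition k exactly when the corresponding off-diagonal entry of the
precision matrix $\Theta_k = \Sigma_k^{-1}$ is nonzero.  Edge strength is
reported as the partial correlation
$r_{ij} = -\theta_{ij} / \sqrt{\theta_{ii}\theta_{jj}}$, the conditional
association of genes $i$ and $j$ given all others.

Because $p$ typically exceeds the per-condition sample count, estimation is
penalized.  With per-condition correlation matrices $S_k$, the joint
estimator maximizes

$$\sum_{k=1}^{K}\Big[\log\det\Theta_k - \mathrm{tr}(S_k\Theta_k)\Big]
 - \lambda_1 \sum_k \sum_{i\neq j}\lvert\theta^k_{ij}\rvert
 - \lambda_2 \sum_{k=1}^{K-1}\sum_{i\neq j} W^{k,k+1}_{ij}
   \lvert\theta^k_{ij}-\theta^{k+1}_{ij}\rvert ,$$

i.e. a graphical lasso per condition plus a *sequential* fused penalty that
shrinks differences between conditions adjacent in an ordered chain.  The
binary weights $W$ make the fusion condition-adaptive: gene pairs whose
correlations demonstrably differ between two adjacent conditions are
released from fusion and may stay condition-specific.

Three deliberate conventions:

* **Likelihood scale.**  Every condition contributes its likelihood on the
  per-sample (correlation-matrix) scale rather than multiplied by $n_k$.
  This keeps the penalty grid $\{0.01, 0.03, 0.05\}$ on a scale where it
  actually induces sparsity in correlation-scale problems, and it makes
  $\lambda_2 = 0$ decouple *exactly* into K independent single-condition
  graphical lassos — a property the test suite verifies.  Sample sizes
  still enter where they carry information: the Fisher-z screening and the
  AIC.
* **Diagonal.**  Diagonal precision entries are never penalized and never
  fused, which keeps positive definiteness attainable.
* **Edges.**  An estimated entry only becomes a network edge if its partial
  correlation survives the truncation $\tau = 0.05$ (default).  All
  support-recovery statements in the tests use this network definition,
  because it is the definition of an edge everywhere downstream.

## Condition chain and adaptive weights

The fusion chain is obtained by average-linkage hierarchical clustering of
Euclidean distances between per-condition mean expression profiles;
conditions are name-sorted before clustering so ties and the two-condition
reflection resolve deterministically.

For each chain-adjacent pair of conditions the package screens every gene
pair with the Fisher z statistic
$z = (\operatorname{atanh} r_k - \operatorname{atanh} r_{k+1}) /
\sqrt{1/(n_k-3) + 1/(n_{k+1}-3)}$, adjusts the two-sided p-values with
Benjamini–Hochberg across all gene pairs of that condition pair, and sets
$W_{ij} = 0$ (no fusion) where $q < \alpha$ (default $\alpha = 0.05$).
Correlations are clamped to $\pm(1 - 10^{-12})$ before `atanh`.  The exact
screening statistic behind condition-adaptive fusion is a genuinely open
design point; the Fisher-z/BH rule is one defensible instantiation, and its
type-I behaviour under the null is regression-tested
(mean fraction of released pairs stays at the nominal level).

## ADMM solver

The joint problem is solved by consensus ADMM with fixed step
$\rho = 1$, no adaptive scaling:

1. $\Theta_k$-update: eigen-decomposition of
   $Z_k - U_k - S_k/\rho$ followed by the usual spectral expansion
   $d \mapsto (d + \sqrt{d^2 + 4/\rho})/2$, which is exactly the
   unconstrained penalized-likelihood minimizer and always positive
   definite.
2. $Z$-update: per gene-pair coordinate, the chain of K values is split at
   released weights ($W = 0$); each fused segment is solved by an exact 1-D
   total-variation proximal operator (dual coordinate descent on the
   tridiagonal box QP, iterated to a $10^{-14}$ sweep change), then
   soft-thresholded by $\lambda_1/\rho$.  Soft-thresholding after the TV
   prox is exact for the fused-lasso signal approximator.  The compiled
   implementation is validated in the tests against an independent
   projected-gradient oracle.
3. Dual update and residuals: iteration stops when the Frobenius norms of
   the primal ($\Theta - Z$) and dual ($\rho\,\Delta Z$) residuals, each
   scaled by $\sqrt{K p^2}$, fall below the tolerance (default $10^{-3}$,
   iteration cap 100 — both the conventional solver defaults for this
   model family).  Non-convergent fits are flagged, kept, and remain
   eligible in the model search; they are not discarded.

The returned matrices are the sparse consensus copies $Z_k$ (so reported
supports contain exact zeros), symmetrized and checked for positive
definiteness; a non-PD result raises an error since it indicates a solver
defect, not a data property.

Penalty selection searches the $3\times3$ grid
$\{0.01, 0.03, 0.05\}^2$ and picks the fit minimizing

$$\mathrm{AIC} = \sum_k\Big[n_k\,\mathrm{tr}(S_k\Theta_k)
  - n_k \log\det\Theta_k + 2E_k\Big],$$

with $E_k$ the number of nonzero upper-triangle entries
($|\theta| > 10^{-10}$).  Ties break toward smaller $\lambda_1$, then
smaller $\lambda_2$.  Whether the AIC log-likelihood should be
$n_k$-weighted is not uniquely determined by the model-selection
literature for this family; weighting by $n_k$ is the package's fixed
choice and documented here.

## Preprocessing chain

`preprocess_counts()` replays the standard RNA-seq chain in fixed stage
order (`counts → cpm → log → normalized → adjusted → standardized`, a
forward-only contract enforced by the `ExpressionMatrix` class):

1. **CPM** — each sample rescaled to one million.
2. **Filtering** — a gene is removed when its CPM is below 10 in at least
   $\lceil 0.30\,S\rceil$ of the $S$ samples ("at least 30 percent" is read
   as $\geq$ at the exact ceiling boundary and tested there), or when it
   carries no biological-process GO term (when a GO map is supplied).  The
   filter is applied per species, across all of its conditions.
3. **log2** with a pseudo-value of 0.5 (so CPM 0 maps to $-1$); the
   pseudo-value is a package default, exposed as `log_prior`.
4. **Smoothed group-aware quantile normalization** — per sample, sorted
   values are replaced by $w\,\bar q + (1-w)\,\bar q_{g}$, where $\bar q$
   is the overall mean quantile profile, $\bar q_g$ the sample's group
   (treatment) profile, and the per-quantile weight $w = 1 -
   \mathrm{SSB}/\mathrm{SST}$ is the within-group share of total variance
   across samples at that quantile, smoothed with a running median
   spanning 5% of the quantiles (the window fraction is the package's
   choice).  When groups agree, $w \to 1$ and the procedure collapses to
   plain quantile normalization; when a group genuinely differs, $w \to 0$
   and its profile — e.g. a +5 global shift — is preserved.  Ties within a
   sample receive averaged reference values.
5. **Empirical-Bayes covariate adjustment** — per gene, a linear model on
   retained (e.g. treatment) plus unwanted (e.g. batch, instrument)
   covariates; each unwanted coefficient is shrunk toward its across-gene
   mean with weight $\tau^2/(\tau^2 + \sigma_g^2 c_{jj})$ and only the
   unwanted component is subtracted.  Covariates are centered first, so
   removal never shifts a gene's mean, and the retained contribution is
   untouched by construction.
6. **Standardization** — zero-variance genes are dropped (ids recorded on
   the result), remaining genes centered and scaled to unit *population*
   (1/n) variance.  The GGM consumes correlation-scale input, so unit
   variance is applied even though centering alone would suffice for the
   linear algebra; this is a deliberate strengthening.

Mean–variance precision weights (voom-style) are intentionally *not*
computed: the joint estimator consumes the unweighted log-scale matrix.

## The synthetic generator

`make_precision_set()` plants a shared backbone of $\pm$`magnitude`
off-diagonal entries present in every condition plus disjoint
condition-specific entries, then repairs positive definiteness by adding
$|\lambda_{\min}| + 0.1$ to the diagonal when needed — the standard GGM
simulation recipe.  Defaults (shared density 0.10, specific density 0.05,
magnitude 0.3) are fixed once as the package's study conditions.

`simulate_expression()` draws latent profiles
$z \sim \mathrm{MVN}(0, \Theta_k^{-1})$, adds per-gene baselines and
additive batch offsets on the latent scale (matching the linear-model
removal contract of the adjustment step), maps through softplus, rescales
to a library size drawn uniformly from 0.5–2 million, and draws
negative-binomial counts with dispersion 0.1 to emulate RNA-seq
overdispersion (any overdispersed count model is a stand-in here; real
studies use real counts).  Realized counts are then rescaled to the drawn
library size, so each sample's total matches its library size up to
rounding — which makes "column sums equal library sizes" a checkable
contract rather than an asymptotic statement.

What the generator does *not* emulate: realistic library-size or GC-bias
distributions, read-level error, gene-length effects, count zero-inflation
beyond what the NB produces, or annotation noise.  Passing tests therefore
demonstrate correctness of the algorithms under the stated generative
model, not performance on any particular organism's data.

Support-recovery checks run on the standardized latent Gaussian draws,
where the planted precision matrices define the ground truth; the full
count → preprocess → infer chain is exercised end-to-end separately by the
pipeline tests.  Problem sizes used throughout the checks — p = 30 genes,
K = 3 conditions, 200 samples per condition for recovery; p ≤ 20 for the
penalty limit laws; 50 replicates for the screening null — are the
package's fixed desk-scale conditions.

`make_species_panel()` plants a cross-species fixture for the comparison
stage: each species carries one or two genes per HOG (hierarchical
orthogroup), a chosen fraction of HOG pairs is realized in at least one
tracheophyte, one bryophyte and one zygnematophyte (ancestral-conserved
under the clade rule), and all remaining pairs deliberately violate that
rule (land-plant-only or single-clade).  The round-trip — build networks,
project to HOG space, merge, classify — must recover exactly the planted
conserved set.

## Cross-species comparison

Gene networks are projected into HOG space using OrthoFinder N0.tsv maps:
an edge becomes a HOG edge when both genes map to *different* HOGs;
paralog edges within one HOG are dropped (they cannot be compared as a
pair across species) and counted, as are edges with unmapped genes.
Provenance — the set of (species, condition) pairs supporting each HOG
edge — accumulates through unions and intersections.

The conservation rule operates on species sets only (an edge present in
any condition counts, consistent with feeding union networks into the
comparison): ancestral-conserved requires at least one tracheophyte, one
bryophyte and one zygnematophyte; land-plant requires tracheophyte and
bryophyte only; everything else is "other".  Edges are unordered and
sign-agnostic — conservation requires presence, not same-signed partial
correlation.  Hub ranking breaks degree ties lexicographically by gene id.

## Overrepresentation analysis

`ora()` tests annotation terms by the exact hypergeometric upper tail
$P[X \ge k]$ against the background of genes that entered network
construction, restricts terms to background-projected sizes in [10, 500],
adjusts with Benjamini–Hochberg, and filters at $p \le 0.05$ and
$q \le 0.05$ — the conventional ORA settings.  Two documented
simplifications: q-values are BH FDR (not the slightly different
empirical-null q-value method some tools default to), and GO terms are
used exactly as annotated, with no DAG ancestor propagation.

## Numerical choices and degenerate inputs

* ADMM $\rho = 1$ fixed; tolerance on scaled residual norms; results are
  bit-for-bit reproducible given identical inputs (the solver is
  deterministic and seed-free).
* Correlations at $\pm1$ are clamped before `atanh`; per-condition
  standard deviations below $10^{-12}$ are floored before correlation
  rescaling; zero-variance genes are removed before estimation, with ids
  logged.
* Zero-count samples, empty filters, rank-deficient covariate designs,
  duplicate gene→HOG assignments, query genes outside the ORA background,
  and unknown clade species all raise errors naming the offender;
  unknown neighborhood seeds merely warn unless all seeds are unknown.
* All generator randomness flows through explicit integer seeds; the
  pipeline derives per-stage seeds from the global seed and the stage
  name, so stages are individually reproducible and reruns are
  byte-identical.

## Limitations

* The sequential fused penalty fuses only chain-adjacent conditions; a
  full pairwise fusion is out of scope (it coincides with the sequential
  form for K ≤ 2 and $\lambda_2 = 0$).
* λ selection is AIC on a small fixed grid, not cross-validation.
* The conservation classifier is a set-cover rule over clades; it does not
  weight by how many species support an edge, nor require matched
  conditions.
* Desk-scale defaults (tens of genes) are for verification; the solver's
  cost grows roughly linearly in K and cubically in p per iteration
  (eigen-decompositions), so genome-scale runs are a matter of patience,
  not correctness.
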