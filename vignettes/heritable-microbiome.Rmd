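---
title: "Quantitative genetics of host-associated microbiomes in clonal pedigreed trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative genetics of host-associated microbiomes in clonal pedigreed trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microherit)
```

## The problem

Host genotype can shape the composition of the root microbiome, but
detecting that influence in a field trial is hard: spatial heterogeneity,
sequencing batches and soil chemistry all imprint on amplicon count tables,
and genetic effects on individual taxa are usually small. microherit
implements the full analysis chain for a clonal, pedigreed forest-tree trial
in which each host genotype is replicated as vegetatively propagated ramets
and genotypes are grouped into control-pollinated full-sib families:

1. pedigree validation and the additive (numerator) relationship matrix
   **A**;
2. a seeded generator of complete synthetic studies with known genetic
   architecture;
3. rarefaction, singleton removal, core-microbiome identification, and a
   soil-covariate principal component;
4. per-ASV thin-plate-spline correction of spatial field trends;
5. community-level tests (Bray-Curtis, PERMDISP, nested PERMANOVA with
   Type I sums of squares and permutation of residuals under a reduced
   model);
6. per-ASV REML variance components and broad-/narrow-sense heritability.

The design the package targets is 28 full-sib families contributing 132
genotypes (3–6 each) with 4 ramets per genotype — 528 trees in a
single-tree incomplete block layout — but every dimension is a parameter.

## The genetic model

For each ASV, the response is the vector of spatially corrected residuals
of square-root transformed, rarefied counts. The linear mixed model is

$$y = Xb + Z_a u_a + Z_f u_f + Z_c u_c + e$$

with fixed effects $b$ (intercept, sequencing batch, soil PC1) and three
random genetic terms: $u_a \sim N(0, A\sigma^2_a)$ (additive, structured by
the pedigree relationship matrix), $u_f \sim N(0, I\sigma^2_f)$ (full-sib
family), and $u_c \sim N(0, I\sigma^2_c)$ (genotype non-additive, identified
by the clonal replication), plus residual $e \sim N(0, I\sigma^2_e)$.

Why this decomposition works: with clonal ramets, the genotype term
captures the *total* non-additive genotypic value, while full-sib family
membership captures the part of dominance shared by sibs. Classical
covariance theory gives $\mathrm{Cov(FS)} = \tfrac12 V_A + \tfrac14 V_D$,
so with the additive part modelled through **A**, the family term absorbs
25% of dominance variance and the clone term the remaining 75% plus all
epistasis. This 25/75 split is a design-derived property that the package's
gene-dropping simulator reproduces and its tests verify.

Heritabilities:

$$H^2 = \frac{\sigma^2_a + \sigma^2_f + \sigma^2_c}
            {\sigma^2_a + \sigma^2_f + \sigma^2_c + \sigma^2_e},
\qquad
h^2 = \frac{\sigma^2_a}
           {\sigma^2_a + \sigma^2_f + \sigma^2_c + \sigma^2_e}$$

Standard errors come from the first-order delta method on the inverse
average-information matrix; an estimate is called significant when its
z-score (estimate/SE) exceeds 1.65, the one-sided 5% normal critical value
(1.645, conventionally rounded to 1.65). No multiple-testing correction is
applied to the headline counts — the per-ASV $\alpha$ is the reported
convention — but a Benjamini-Hochberg column is emitted for reference.

### REML implementation

The solver is average-information (AI) REML: at each iterate the score and
AI matrix are assembled from $P = V^{-1} - V^{-1}X(X'V^{-1}X)^{-1}X'V^{-1}$
and the proposed Newton-like step is step-halved whenever it would decrease
the REML log-likelihood; if no AI step is acceptable, a multiplicative
EM-style update $\sigma^2_i \leftarrow \sigma^2_i \cdot
(y'PV_iPy)/\mathrm{tr}(PV_i)$ is taken instead. The log-likelihood is
therefore non-decreasing across accepted iterations (asserted in tests).
Components are floored at $10^{-8}\,\mathrm{var}(y)$; convergence is a
relative log-likelihood change below $10^{-8}$. Components pinned at the
floor are flagged and held fixed in the covariance of the estimates (the
projected-information convention), which keeps the delta-method covariance
positive semi-definite. Validation is by independent oracles: on a balanced
clonal design with $A = I$ the REML genotype variance equals the
closed-form ANOVA estimator $(MS_B - MS_W)/k$ whenever that is positive,
and parameter-recovery simulations at the full design size recover
$(\sigma^2_a, \sigma^2_f, \sigma^2_c, \sigma^2_e) = (0.3, 0.1, 0.2, 0.4)$
within Monte-Carlo error over 200 replicate ASVs.

## Spatial correction

Field position imprints smooth trends on abundances. Each ASV's transformed
counts are regressed on a penalised thin-plate smooth of the planting
coordinates (`mgcv::gam`, `s(x, y, bs = "tp")`), with smoothness chosen by
generalised cross-validation — the default behaviour of standard thin-plate
routines, overridable via a fixed smoothing parameter. The basis dimension
defaults to 60, well above the complexity of the low-frequency field trends
the generator produces and those plausible in a 4–5 ha trial; the low-rank
eigen-basis of mgcv at this dimension is indistinguishable from a full-rank
solve for such smooth targets while being far better conditioned. Residuals
(surface included the affine terms, so they sum to zero) are kept in two
forms, matching their two downstream uses:

* **unadjusted residuals** (negative values retained) feed the REML scan;
* **adjusted residuals** — shifted per ASV by the absolute value of the
  minimum residual so the minimum is exactly zero — feed Bray-Curtis, which
  requires non-negative input. "Adjusted to be non-zero" is implemented as
  non-negative-with-minimum-zero: residuals from a model with an intercept
  almost surely have a negative minimum, and the purpose of the shift is
  valid dissimilarity input, which a rigid shift achieves while preserving
  all pairwise differences.

One spline is fitted per ASV (the per-ASV shift rule presumes per-ASV
fits). Duplicate coordinates enter as replicate observations — numerically
equivalent to averaging them — with a warning; collinear coordinate sets
are an error.

## Community tests

Bray-Curtis dissimilarities are computed on the adjusted residuals. Before
testing composition, PERMDISP (principal-coordinate embedding, distances to
group centroids, permutation F-test) checks dispersion homogeneity for each
factor, since location tests are confounded by heterogeneous dispersion.

The composition test is a nested PERMANOVA on the Gower-centred
inner-product matrix $G$: terms are fitted sequentially (Type I) in the
order batch, soil PC1, family, genotype-within-family, each term's sum of
squares being $\mathrm{tr}(H_{\mathrm{inc}} G)$ for its incremental
projection. Expected mean squares for the random terms are computed by the
general quadratic-form rules ($c_{ij} = \mathrm{tr}(H_{\mathrm{inc},i}
Z_jZ_j')/\mathrm{df}_i$), valid for unbalanced family sizes; the pseudo-F
denominator for each term is the linear combination of later mean squares
whose expectation matches the term's null expectation (for the family term
this is essentially the genotype-within-family mean square; for terms with
no random terms below them, the residual). P-values use permutation of
residuals under the reduced model containing all prior terms
(Freedman-Lane on $G$), with $p = (\#\{F^\pi \ge F\} + 1)/(n_{perm}+1)$;
when the number of distinct orderings is below the requested permutation
count the engine switches to complete enumeration and the p-value is exact.
Components of variation are solved from the EMS equations and reported as
sign-preserving square roots, so negative components — a recognised
by-product of these estimators — print as negative. The continuous soil
covariate contributes one regression degree of freedom. Batch is fitted
first and tested like any sequential term. An ancestry variant (ancestry
fixed, family nested in it) is available simply by passing a different term
list; it is exercised on synthetic data only.

## The synthetic-data generator

The generator is the package's test bed and defines the conditions under
which every downstream claim is checked. Its defaults mirror the target
study design: a three-generation pedigree (founders, a parent pool of 40,
and 28 full-sib crosses yielding 132 genotypes in families of 3–6, with
parents shared across crosses so half-sib links exist), 4 ramets per
genotype randomised over contiguous 36-tree blocks with each genotype at
most once per block, and two sequencing batches assigned by contiguous
layout regions — batch structure in real studies follows plates and runs,
which correlate with collection order and hence space.

Soil covariates are multivariate Gaussian with means and SDs set to the
field summaries the generator is calibrated against (pH 4.63 ± 0.18;
moisture 43.9 ± 6.0%; total C 9.79 ± 2.46%; total N 0.45 ± 0.10%) and
correlations pH–C $-0.78$, pH–N $-0.70$, C–N $0.89$. The three
moisture correlations are not pinned down by those summaries; they default
to $-0.3$ (with pH) and $+0.3$ (with C and N), an explicitly arbitrary
completion that happens to be positive definite as given (smallest
eigenvalue 0.099), so no nearest-PD repair is triggered at the defaults.

Genetic values come from gene dropping: founders receive Hardy-Weinberg
genotypes at independent biallelic loci, alleles segregate by Mendelian
sampling, and per-locus contributions are additive ($a(\mathrm{dose}-2p)$),
dominance ($d(\mathrm{het}-2pq)$), and optional additive-by-additive
epistasis on random locus pairs. ASV counts are negative-binomial around
$\exp(\mathrm{latent})$ times a lognormal library-size factor, the latent
scale being baseline + genetic + smooth spatial surface (2–4 random
low-frequency sinusoids, smooth enough for a thin-plate spline to capture)
+ batch + soil effect + Gaussian noise; a truth object records each ASV's
realised variance shares. No generative model for the counts is claimed by
the field data themselves; the log-latent negative-binomial with
library-size factors is the standard amplicon abundance model and is the
package's own choice.

What the generator does *not* emulate: taxonomy (labels are arbitrary),
phylogenetic correlation among ASVs, compositional coupling beyond the
shared library size, zero-inflation beyond what the negative binomial
produces, and temporal or within-tree sampling variation. Passing tests
demonstrate correctness of the estimators under this model, not that real
data satisfy it.

## Numerical choices and degenerate inputs

* Rarefaction is a single without-replacement draw with a recorded seed
  (the analysis chain consumes one rarefied table, not an average over
  draws); samples below depth are dropped and reported. Core membership is
  computed after that filtering.
* Unknown parents are unique, unrelated, non-inbred founders (the standard
  tabular-method base-population convention); **A** is built over the whole
  pedigree densely — hundreds of genotypes never require sparse inverse-A
  machinery — then subset to the sampled genotypes.
* Soil PC1's sign is fixed by requiring a positive pH loading; loading
  magnitudes are data-dependent and not anchored to anything.
* A constant response gives a flagged degenerate REML result with all
  genetic components zero, never an exception; scan-level failures are
  recorded per ASV and skipped.
* The p-value convention everywhere is $(\text{count} \ge \text{observed} +
  1)/(n_{perm} + 1)$; exhaustive enumeration replaces sampling when
  feasible.
* Master seeds spawn per-component child seeds (`spawn_seeds()`), so each
  pipeline stage is independently reproducible and the whole run is
  bit-identical under a fixed seed.

## Problem sizes used in the test-suite simulations

Simulation-based checks run at sizes chosen to make Monte-Carlo error small
relative to the asserted tolerances while keeping the suite quick: the
dominance-partition experiment gene-drops 2,000 loci through 200 families
of 50 progeny (the between/within shares are pooled per locus, a
Rao-Blackwellised estimator with the same 25/75 expectation and much
smaller Monte-Carlo error than the variance of summed values); parameter
recovery uses 200 replicate ASVs at the full 528-sample design; spline
recovery uses 100 ASVs with a spatial variance share of 0.3; the PERMANOVA
type-I error check uses 200 null datasets of 90 samples; unit tests use
miniature studies of 20–40 genotypes.

## Known limitations

* The AI-REML solver is validated against closed-form and simulation
  oracles, not against any commercial mixed-model package; boundary SEs use
  the projected-information convention and are approximate.
* PERMANOVA EMS denominators are synthesised from later mean squares; in
  severely unbalanced designs the Satterthwaite-style denominator is
  approximate, as in all distance-based implementations of this test.
* The thin-plate basis dimension caps the spatial complexity that can be
  removed; pathological high-frequency spatial structure would leak into
  residuals (and into apparent heritability) under any smoother.
* Two-stage correct-then-model analysis is not free: the GCV-selected
  surface absorbs a few percent of the genetic variance along with the
  spatial trend, which the package's own recovery simulations show as a
  small (about $-0.02$ at a spatial share of 0.3) downward bias in mean
  $H^2$. Joint spatial-genetic modelling would avoid this but is outside
  the implemented pipeline's two-stage design.
* Heritability z-scores use asymptotic SEs; profile-likelihood intervals
  are not implemented.
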