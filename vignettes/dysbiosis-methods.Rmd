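---
title: "Models and methods in icudysbiosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in icudysbiosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its statistical machinery:
the models, the assumptions they lean on, the tunable parameters and their
defaults, the numerical choices, and what the synthetic cohorts do and do
not establish about real data.

## The analysis problem

Longitudinal ICU microbiome cohorts sample three body compartments (oral,
lung, gut) at up to three intervals (baseline within 72 h of intubation,
middle at days 3–6, late at days 7–12), producing genus-level 16S count
tables with very uneven sequencing depth, plus subject outcomes (60-day
survival) and host-response biomarkers. The scientific questions the
package serves: do communities fall into reproducible diversity types; can
a sample be classified into those types from its composition alone; and do
the types, or longitudinal trends in dysbiosis features, predict survival
once informative censoring is taken seriously?

## Ecology layer

**QC.** Samples need at least `min_reads` (default 1000) reads; the bound
is inclusive. Gut tables additionally drop samples flagged as "unsoiled"
rectal swabs, which under-represent gut communities. An empty surviving
table is an explicit error, never an empty result.

**Rarefied Shannon.** Diversity is the Shannon entropy (natural log; the
base is an argument) of counts subsampled *without replacement* to
`depth = 1000` reads — multivariate hypergeometric sampling, implemented by
sequential conditional `rhyper` draws vectorised over the `reps = 100`
repetitions — and averaged over repetitions. Sampling without replacement
matters: resampling proportions (multinomial) would overstate the diversity
of shallow samples. When a sample's total equals the depth the subsample is
the sample itself and the estimate is exact. Monte-Carlo error shrinks as
1/sqrt(reps).

**CLR.** `clr_transform()` maps counts x to log(x + c) centered by the
sample's mean log, with pseudocount c = 0.5 added to every cell. The
pseudocount is a documented, configurable choice (the additive-smoothing
default); exact invariance of CLR to depth holds only as counts grow large
relative to c, and a property test checks that limit rather than asserting
exact invariance.

**Bray-Curtis on CLR values is ill-defined** (the classical index assumes
non-negative abundances). The default mode therefore computes Bray-Curtis
on relative abundances; a `clr_shifted` mode subtracts the global minimum
of the CLR matrix first, following the literal "Bray-Curtis on CLR" recipe.
The shifted variant depends on the shift and is not a true Bray-Curtis
fraction; both are exposed so users can see the difference rather than have
it hidden.

**PCoA** is classical scaling: Gower double-centering of −d²/2 and an
eigen-decomposition; coordinates are returned for positive eigenvalues and
negative eigenvalues are reported untouched — no Lingoes/Cailliez
correction, because a corrected embedding silently changes the geometry
being tested.

**PERMANOVA** delegates the sums-of-squares decomposition and permutation
loop to `vegan::adonis2`, with the add-one p-value convention
p = (1 + #{F* ≥ F}) / (1 + n_perm), which keeps p in (0, 1]. Bonferroni
correction is `min(1, m p)`.

## Dirichlet-multinomial mixtures

A sample with depth n has likelihood under component k

DirMult(x | α_k) = [Γ(A_k)/Γ(A_k+n)] · ∏_t Γ(x_t+α_kt)/Γ(α_kt),  A_k = Σ_t α_kt,

mixed over K components with weights π. The multinomial coefficient is
omitted throughout — it is constant in the parameters, so responsibilities
and evidence *comparisons* are unaffected.

**EM.** The E-step is the usual softmax of log π_k + log DirMult; the
M-step sets π to mean responsibilities and updates each α_k by three
responsibility-weighted fixed-point iterations of the bound-based update
(which cannot decrease the weighted objective), floored at 1e-10.
Initialisation: k-means on CLR values for the first restart, random
assignments for the rest (`n_init = 5` by default; the pipeline uses 3).
The EM objective is checked to be non-decreasing at every iteration and a
decrease beyond numerical slack warns loudly.

**Convergence** is declared when the *mean per-sample* log-likelihood
changes by less than `tol = 1e-6` between iterations. A criterion relative
to the total log-likelihood would loosen as depths and cohort sizes grow
(at |logLik| ~ 10^6 a "relative 1e-6" is a whole nat) and demonstrably
under-converges α; the per-sample form is scale-stable.

**Laplace evidence.** The number of components is chosen by a Laplace
approximation to the log marginal likelihood at the fitted mode, in an
unconstrained parameterisation (log α; mixing-weight logits), with weakly
informative normal priors: log α_kt ~ N(0, 3²) and weight logits
~ N(0, 1.5²). The priors matter: with an improper flat prior the
"evidence" has no Occam factor and model selection drifts upward; a prior
whose 3σ range spans α from e⁻⁹ to e⁹ is diffuse enough to be harmless for
estimation yet makes superfluous components pay their rent. The α-blocks
of the Hessian are analytic (responsibility-weighted; exact at K = 1,
verified against numerical differentiation); cross-component curvature is
neglected (block-diagonal approximation) and the small weight block is
finite-differenced. Indefinite or singular blocks raise an error advising
a smaller K — at desk scale that is nearly always what a singular Hessian
means. A BIC-style fallback (`method = "bic"`) exists for degenerate
cases.

**Prevalence rule.** Following the clinical-relevance criterion, any K
whose smallest *hard-assigned* cluster holds < 10% of samples is discarded
before evidence comparison; hard assignment (argmax responsibility, ties
to the lowest index) reads "a cluster contains a sample" as membership
counts. If every K is discarded, K = 1 is returned with a warning.

**Labeling.** Components are ranked by the mean rarefied Shannon index of
their members, descending: High, Intermediate(-i), Low. Ties are broken by
component index with a warning. Sample labels are invariant to permuting
component indices.

## The Dysbiosis Index

The classifier is a three-class multinomial logit with the High-Diversity
cluster as reference:

ln P(I)/P(H) = b₁·[1, f],  ln P(L)/P(H) = b₂·[1, f],

solved in closed form as P(H) = 1/(1+X+Y), P(I) = X/(1+X+Y),
P(L) = Y/(1+X+Y) with X = exp(b₁·[1, f]), Y = exp(b₂·[1, f]). Prediction
is computed on the log scale with log-sum-exp, so extreme logits give
probabilities of 0/1 rather than overflow, and the three probabilities sum
to one to machine precision by construction. Argmax ties break
conservatively Low > Intermediate > High — in a clinical screen the costly
mistake is missing dysbiosis. Features are matched strictly by name;
missing features are an error unless `fill_missing = TRUE` explicitly
declares "at the geometric mean" (CLR 0) semantics.

**Derivation.** Candidate features are the top-50 taxa by mean relative
abundance (CLR-transformed) plus the Shannon index; ranking by mean
relative abundance is the order-stable default and `rank_by = "clr"` is
available. The 80/20 split is stratified by cluster label and
seed-reproducible — with three imbalanced classes an unstratified 20%
test set is too easily missing a class. Feature selection approximates a
Markov-blanket search around the cluster variable by stability selection:
an L1-penalised multinomial fit (penalty fixed once by cross-validation on
the training data), refitted on 50 stratified half-subsamples; a feature
is kept when it is active in ≥ 70% of fits. A constraint-based screen
(likelihood-ratio association tests at level α = 0.1) is available as
`method = "ci_screen"`. The final model is an unpenalised multinomial
logit; quasi-separation (any |coefficient| > 15) triggers a refit with
weight decay 1e-4 and flags the model. Accuracy is reported with an exact
Clopper-Pearson interval.

The packaged published models record their feature-space assumptions
(CLR pseudocount, Shannon variant) in a `feature_space` descriptor, so a
serialized model states how its prediction-time features must be built
instead of leaving it implicit.

## Moderated differential abundance

Two-group comparisons of CLR values use an empirical-Bayes moderated t:
per-taxon pooled variances s_g² (d_g = n₁+n₂−2 df) are shrunk to
s̃² = (d₀s₀² + d_g s_g²)/(d₀+d_g), with (d₀, s₀²) estimated by
moment-matching the distribution of log s_g² — the closed-form trigamma
inversion with Newton refinement. The statistic logFC/(s̃·√(1/n₁+1/n₂)) is
referred to t on d₀+d_g df. Setting the prior df to zero reproduces the
ordinary two-sample t exactly, and the whole construction is cross-checked
against an independent reference implementation in the test suite. "logFC"
is the difference of mean CLR values in natural-log units (a base-2
display option exists); significance is |logFC| > 1.5 with BH-adjusted
p < 0.05. Zero-variance taxa are reported NA and excluded from the BH
family. Optional observation weights are accepted (default 1).

## Survival and joint modeling

Kaplan-Meier, log-rank, and Cox regression go through the survival
package (Efron ties by default; Breslow behind a flag); monotone
likelihood triggers a ridge-penalised refit that is flagged rather than
silently reported. The 2×2 association test returns the sample
cross-product odds ratio with the Haldane-Anscombe 0.5 correction when a
cell is zero and a Woolf log-odds CI; the p-value is the exact
hypergeometric test. The point estimate deliberately differs from the
conditional-MLE odds ratio some environments print.

The joint model couples y_ij = x_ij'β + b_i + ε_ij (b_i ~ N(0, σ_b²))
with hazard λ₀·exp(z_i'γ + ν·b_i). Because the longitudinal part is
conjugate, each subject's likelihood factorises exactly into the marginal
compound-symmetry normal density times E[survival factor | y_i] under the
closed-form posterior b_i | y_i; that expectation is evaluated by 15-node
Gauss-Hermite quadrature centered on the posterior (adaptive centering in
the exact sense). The baseline hazard is constant (exponential): at
desk-scale cohort sizes a nonparametric baseline inside the integrated
likelihood is fragile, the exponential form keeps the likelihood smooth
for the bootstrap, and ν — the parameter of interest — measures the
transfer of persistent subject-level deviation to risk either way. At
ν = 0 the likelihood separates exactly into LMM + exponential survival
(a property test verifies this within quadrature error). CIs for ν come
from a subject-level nonparametric bootstrap (default 100 resamples;
failed refits are counted and reported). A two-stage variant (empirical
Bayes intercepts plugged into Cox) exists behind a flag; it attenuates ν
and is not the default.

## The synthetic cohort generator

The generator is the package's study-conditions statement, not a tuning
dial. Defaults: 3 community types per compartment built from
block-structured Dirichlet parameters (each component concentrates its
mass on a disjoint block of 5 taxa; the well-separated test fixture uses
block mass 0.7, the graded cohort 0.5/0.7/0.9 so Shannon decreases across
components and the last block is the respiratory-pathogen block); mixing
weights 0.40/0.35/0.25; read depths uniform on 2000–10000; visits at days
1/5/9; within-subject cluster persistence 0.8 across visits; baseline
hazard 0.0052/day (≈ 27% mortality by day 60) with relative hazards
0.6/1/2.2 across High/Intermediate/Low; administrative censoring at day
60; follow-up dropout logistic in cluster and latent event time (so
censoring is informative, the situation joint models exist for); oral and
lung baseline membership coupled through a shared latent cluster
(probability 0.75); 5% of oral/lung samples redrawn with gut-origin taxa
boosted to an expected ~45% share (translocation events); biomarkers =
loading × pathogen-class CLR abundance + N(0, 1) noise. All randomness
flows from one root seed through a documented splitting scheme
(`split_seed()`), so a cohort is a pure function of its configuration.

What the generator does *not* emulate: taxonomic correlation structure
beyond the mixture (real genera co-occur), depth-composition coupling,
measurement/contamination noise, fungal communities (dominance is
taxon-generic), age/comorbidity covariates, and competing risks. Passing
tests on these cohorts therefore establish that the estimators recover
the structure they assume — correctness, identifiability, calibration —
not that real ICU data satisfy those assumptions.

## Problem sizes in the test suite

The suite favours a few deep, parameterised checks per operation and
scales simulation oracles to desk size: 500 replicates for the PERMANOVA
type-I property (199 permutations each), 200 for the differential-
abundance false-discovery and log-rank null properties, 100 for the
outcome-generator null, 10–40 replicates for the heavier mixed-model and
joint-model coverage checks, and 4 seeded replicates per K for DMM model-
selection recovery. The acceptance script derives indices at n = 400
(lung-like) and n = 250 (gut-like). These sizes are the package's own
choice of where Monte-Carlo error is small enough for the stated bounds.

## Known limitations

Compartment count tables share one taxa universe in simulation; the
block-diagonal Hessian approximation can refuse (singular block) rather
than report evidence for heavily over-parameterised K; the Laplace
evidence is a mode approximation and near-flat evidence differences of a
few nats between adjacent K should not be over-read — the prevalence rule
and the three-class convention exist precisely because evidence alone is
a weak arbiter there; the joint model assumes a shared random *intercept*
(no random slopes) and an exponential baseline; and the Dysbiosis Index
is only as good as the DMM labels it is trained on.
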