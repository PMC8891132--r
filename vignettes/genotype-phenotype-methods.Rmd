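---
title: "Methods: Bayesian genotype-phenotype models for Cockayne syndrome B"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Bayesian genotype-phenotype models for Cockayne syndrome B}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its statistical machinery:
the models, the priors and their elicitation, the sampler, the synthetic
cohort generator, and the numerical and design choices that were
genuinely open. It states no empirical result beyond what the test suite
and `scripts/acceptance.R` compute.

## Scientific setting

Cockayne syndrome severity is analysed as an ordered outcome,
III < I < II, where "type II" pools classical type II with COFS — the
two most severe presentations, merged before any analysis. The genotype
of interest is the position of the two *CSB/ERCC6* alleles relative to
the PGBD3 transposon insertion in intron 5 (c.1397+6912): both upstream
(2U), one on each side (1U1D), or both downstream (2D). The biological
hypothesis is that downstream mutations leave a deleterious CSB–PGBD3
fusion protein intact, so severity should increase with the number of
downstream alleles. 2U is therefore the reference level everywhere.

### Classification rules

Coding positions classify by the exon-5 boundary: c. ≤ 1397 is UPSTREAM,
c. ≥ 1398 DOWNSTREAM. Intron-5 variants (c.1397+N, c.1398−N) are
genuinely between the exon-based groups; the package splits them at the
insertion offset itself (N ≤ 6912 upstream, N > 6912 downstream) because
the insertion coordinate is the stated breakpoint, and *always* attaches
an `intron5_flag` so such records can be reviewed — classification
guidance for them was never published, and we flag rather than guess.

Variant classes are taken from the input (PTV: protein-truncating, PAV:
protein-altering); the package deliberately does not infer consequences
from HGVS strings, because no operational PTV/PAV rule was published. An
opt-in keyword helper (`consequence_to_class()`) maps nonsense /
frameshift / splice to PTV and missense / in-frame to PAV. A PTV+PAV
pair is analysed in the PAV group (the more permissive allele wins);
pairs with an unknown class are excluded from complete-case variant
analyses.

Patients with ambiguous subtype labels ("I or II", "I/II") or no
classification are excluded from ordinal modelling, with a per-record
exclusion log. Records from the clinical database and from literature
case reports are treated identically after ingest.

## The models

### Dirichlet-multinomial contingency analysis

The 3×3 table of counts `n[g,k]` is modelled as multinomial with a
conjugate Dirichlet prior on the joint cell probabilities — Jeffreys
(0.5 per cell, the default and the prior behind the reported table) or
uniform (1 per cell). The posterior is `Dir(n + α)` and is sampled by
normalized Gamma variates; odds ratios between (possibly pooled) rows
and a column pair are computed per draw and summarized by the posterior
median, the equal-tailed 95% credible interval, and Pr(OR > 1). Zero
cells need no continuity correction: α > 0 handles them.

Two properties justify implementation choices here:

- *Aggregation*: sums of Dirichlet components are Dirichlet with summed
  concentrations, so pooling rows before or after the prior is applied
  is immaterial; the pooled 2D-versus-(2U ∪ 1U1D) contrast simply sums
  cell probabilities per draw.
- *The digamma identity*: under `p ~ Dir(α)`,
  `E[log p_i] = ψ(α_i) − ψ(α_0)`, and the normalizer cancels in any log
  odds ratio, so `E[log OR]` is an exact four-term digamma sum with
  variance given by the matching trigamma sum. The test suite uses this
  as an independent oracle for the sampler. The *median* is the reported
  point estimate (the posterior of an OR is right-skewed, and the
  median, unlike the mean, is transform-equivariant and reproduces the
  reported table at one-decimal rounding); note that for the sparse
  type-III column (cells with concentration 1.5) the skew is strong
  enough that the median of log OR sits up to ~0.1 away from the
  digamma mean — a property of the distribution, not a sampler error.

### Proportional-odds severity regression

The central model is a cumulative-logit (proportional-odds) regression
computed from sufficient-statistic counts:

    logit P(Y <= k | x) = theta_k - x' beta,   k = 1, ..., K-1

with severity ordered III < I < II. Under this sign convention β > 0
means higher odds of a *more severe* subtype, so `exp(β)` is directly
the quantity of clinical interest. Covariates are categorical: mutation
position (ref 2U), variant class (ref PAV), or both additively (no
interaction) for the multivariate model. The likelihood is linear in
the counts, so fitting from the 3×3 table and from 136 expanded
individual records is exactly the same computation — a tested identity.

Cutpoint ordering is enforced by construction: the sampler works on
`(θ₁, δ, …)` with `θ₂ = θ₁ + exp(δ)`, removing any need for rejection
or sorting tie-breaks. Priors: independent Normals on each β
(see below) and N(0, 1000) on θ₁ and on δ — essentially flat, and
dominated by n = 136; this choice is a package decision, as the original
cutpoint prior was not published.

### Prior elicitation and sensitivity

A Normal prior on a log odds ratio is elicited from a central 95% prior
odds-ratio range `[L, H]`:

    mu = (ln L + ln H) / 2,    sigma = (ln H - ln L) / (2 * 1.95996)

`cs_priors` packages the study's elicited set: vague N(0, 1000), precise
N(0, 0.674) (OR 0.2–5), optimistic N(1.099, 0.377) (OR 0.9–10), and
N(0.661, 0.234) (OR 0.75–5) for the variant-class model.
`prior_or_interval()` inverts the elicitation (a tested inverse pair).
`sensitivity_suite()` fits one model per prior with all settings and
seeds aligned, so differences between blocks are attributable to the
prior alone.

### Onset-age group means

Age at first symptoms (months) is modelled as `y ~ N(μ_g, σ²)` with a
cell-means parametrization — one N(0, 100) prior per group mean, applied
symmetrically, rather than reference-plus-offset coding (the original
parametrization was not published; cell means make the stated prior
meaningful for every group). The residual SD gets a half-Normal(50)
prior, weak relative to the observed SD of ~13 months, and is sampled on
the log scale with the Jacobian included. Missing ages are dropped
(complete-case); an empty group is still reported, prior-dominated, with
a warning. `contrast_prob()` reports Pr(μ_g1 − μ_g2 > 0) from joint
draws.

## The sampler

`run_chains()` implements component-wise random-walk Metropolis with
per-parameter proposal scales adapted by Robbins–Monro (gain t^−0.6)
toward 0.44 acceptance — the one-dimensional optimum — *during burn-in
only*; scales are frozen afterwards, so the retained chain is a genuine
Markov chain. The default schedule is the study's: 3 chains, 5000
burn-in, 150,000 iterations, thinning 3 (50,000 stored draws per chain).
The original engine was a general-purpose Gibbs sampler; samplers agree
in distribution, and the test suite cross-checks this fit against JAGS
on the identical posterior.

Determinism: per-chain sub-seeds are drawn deterministically from the
master seed, and all proposal innovations are pre-generated, so runs are
bit-reproducible. (The synthetic-cohort generator likewise uses a single
stream seeded by its master seed rather than per-patient sub-streams;
the reproducibility contract — identical spec, identical cohort — is
what matters and is tested.)

Diagnostics: split-chain R-hat (each chain halved before the
between/within variance ratio) and Geyer initial-positive-sequence
effective sample size. The original convergence assessment was graphical
only; the package quantifies it and attaches a warning to any fit with
R-hat > 1.05. Summaries use equal-tailed intervals (the standard output
of the original toolchain, rather than HPD) and type-7 linear
interpolation between order statistics for all quantiles.

Initialization: cutpoints at the empirical cumulative marginal logits,
coefficients at 0, jittered per chain (SD 0.1); overridable via
`run_chains()` directly. A non-finite log-posterior at an initial point
is an immediate classed error, and (including +Inf, which arises only
from degenerate likelihoods) non-finite proposals are rejected.

## The synthetic cohort generator

Because the per-patient study data is available only on request, the
generator emulates the published structure: 147 patients, group mix
24/18/105 (2U/1U1D/2D), severity from the cumulative-logit model with
coefficients defaulting to the vague-prior posterior medians, onset age
from a Gamma matched by moments to mean 8 / SD 13.4 months (a Gamma
because the distribution is non-negative with SD well above the mean —
no symmetric family fits; the printed "standard error = 13.4" is read
as the standard deviation, since an SE of 13.4 at n ≈ 123 would imply an
impossible spread), truncated at 72 months by resampling, ~16% missing
ages, and ~7% of type I/II patients relabelled with an ambiguous label
(ambiguity only ever afflicts the I/II boundary, mirroring the clinical
reality). Group-specific onset means are supported for recovery studies.

Two caveats the tests make explicit:

- Truncation at 72 months lowers the realized mean below the Gamma's
  nominal mean (by roughly half a month at mean 11.8); recovery tests
  therefore simulate uncapped ages, and moment checks are stated for the
  pre-truncation distribution.
- What passing tests show is that the *inference machinery* recovers the
  *generator's* truth. Real cohorts differ in ways the generator does
  not emulate: classification error in severity, correlation between
  variant class and position beyond "upstream is always truncating",
  literature-ascertainment bias, and non-Gamma onset tails.

Problem sizes used in the checks (package choices): moment and
frequency convergence at n = 100,000; ordinal parameter recovery at
n = 20,000 (the posterior SD of a coefficient at a few thousand records
is still ~0.07, so a within-0.1 recovery check needs the larger size to
be a test of correctness rather than of luck); onset-age recovery at
n = 2,000; credible-interval coverage over 100 cohorts of n = 136 — the
study's own size — checked against a 90–99/100 band.

## Known limitations

- Recomputing the proportional-odds regression from the published 3×3
  table does not reproduce the originally reported 2D point estimates:
  the package obtains a vague-prior posterior median OR(2D) of 2.3
  (Pr(OR>1) 96.4%) where 2.0 (94.1%) was reported, and 3.0 under the
  optimistic prior where 2.6 was reported. This is not a sampler issue:
  the maximum-likelihood estimate on the same counts is 2.26, and an
  independent JAGS fit of the identical model (run in the test suite)
  agrees with the package to two decimals, across several cutpoint
  priors. The 1U1D coefficient, its credible interval, and every
  Dirichlet contingency result match the reported values at print
  precision. The likeliest explanations are a difference between the
  printed table and the data freeze behind the regression, or an
  unpublished finer severity coding; with per-patient data unavailable,
  the package reports what the published table implies.
- The multivariate (position + variant class) model is implemented and
  tested structurally, but no published numbers exist to check it
  against.
- Intron-5 variants are classified by the insertion offset and flagged;
  users with such records should review them rather than trust the flag
  silently.
- No survival modelling of age at death, no imputation of missing onset
  ages, and no HGVS grammar parsing — all out of scope by design.
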