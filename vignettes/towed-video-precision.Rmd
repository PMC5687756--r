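---
title: "Validating towed-video oyster surveys and planning their precision"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating towed-video oyster surveys and planning their precision}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Towed video is an attractive way to survey epibenthic organisms such as the
European flat oyster (*Ostrea edulis*): a camera sled is pulled along fixed
transects and the footage is scored later in the lab. Compared with
destructive or diver-based sampling it is cheap and repeatable — but it
introduces its own errors. Oysters can be missed (imperfect detection),
live and dead individuals can be confused (misclassification), and two
people scoring the same footage — or the same person scoring it twice —
will not produce identical counts (observer error). Before the method can
anchor a monitoring programme, those errors have to be quantified and
propagated into the precision of the abundance estimates a programme would
produce.

`towvid` packages that whole chain: simulation of surveys with realistic
error processes, confusion-matrix validation of live/dead scoring,
variance-component estimation for the nested survey design, and an
error-propagation model that predicts the standard error of mean abundance
for any candidate design.

## The survey model

The reference layout is hierarchical: sites hold transects (20 m × 0.8 m
strips), each transect is divided into five contiguous 4-m sections of
3.2 m² — the observation unit — and each section's video is scored twice
by each of two observers. A per-section count `y` is modelled as

```
y = mu + Site + Tr(Si) + Se(Tr,Si) + Ob + Ob:Si + Ob:Tr(Si) + Ob:Se(Tr,Si) + e
```

with Site fixed (sites are chosen deliberately, not sampled) and
everything else random. The residual `e` is the variability between
replicate readings by the same observer. The seven random variances —
`s_ob2`, `s_tr2`, `s_se2`, the three interactions, and `s_e2` — are the
package's central currency, held in a `variance_components` object in
units of (counts per section)².

### ANOVA, expected mean squares, and the two conventions

`build_anova()` decomposes the total sum of squares from cell and marginal
means. The only imbalance the layout permits is in transects-per-site; as
that is a *nested* factor fully crossed with Observer, the decomposition
stays orthogonal and term sums of squares add to the total (the test suite
checks this against `anova(lm(...))` term by term).

F-test denominators are not obvious in a mixed nested model, so
`derive_ems()` derives each term's expected mean square with the
Cornfield–Tukey rules. Two conventions exist for mixed models and the
package implements both:

* **restricted** (default): interactions between a random factor and the
  fixed Site factor carry sum-to-zero constraints, so they drop out of the
  random main effect's EMS. This is the convention of the classical
  ecological ANOVA literature, and it is the one that reproduces the
  significance pattern of published tables of this design (e.g. the
  observer effect tested over the observer-by-transect mean square).
* **unrestricted**: all random effects independent — exactly the model
  REML software fits. The method-of-moments/REML equivalence checks use
  this convention for that reason.

Where a single mean square cannot serve as denominator, `f_tests()` builds
a quasi-F from a linear combination of mean squares (solved exactly
against the EMS matrix) with Satterthwaite denominator degrees of freedom.
With unequal transects-per-site the EMS coefficients that involve the
per-site transect count use its harmonic mean; the table is flagged
approximate and a warning points users to REML.

### Method-of-moments and REML

`estimate_vc_mom()` inverts the EMS system — the classical ANOVA
estimator, exactly unbiased, but free to go negative; negative values are
truncated to zero with the raw solution preserved (the raw values are what
the unbiasedness and equivalence tests look at). `estimate_vc_reml()`
delegates the restricted-likelihood fit to `lme4::lmer()` with a tight
`bobyqa` tolerance (`rhoend = 1e-12`), so that on balanced designs with
interior solutions the two estimators agree to well below `1e-3` — a
strong cross-check, since they travel completely different code paths.
REML is the authoritative estimator for the unbalanced case.

A caveat worth stating plainly: REML constrains components to be
non-negative, so for components that are small relative to their sampling
noise the *mean* REML estimate over replicate surveys is biased upward
(E[max(0, X)] > E[X]). At the reference design the transect component has
only 10 degrees of freedom and its mean square is dominated by the much
larger section component, so its truncated estimate has a standard
deviation near 3 around a truth of ~1; replication cannot average that
bias away. The untruncated method-of-moments estimates are the right
object for unbiasedness checks, and the package keeps them available for
exactly that reason.

## The precision model

Given the variance components, the variance of a survey's mean count per
section under a design with `a` transects, `b` sections per transect, `c`
observers and `n` readings per observer is

```
V[ybar] = s_tr2/a + s_se2/(a*b) + s_ob2/c + s_e2/(a*b*c*n)
```

implemented in `mean_variance()`. Site-level variance is deliberately
outside the formula: it predicts precision *within* a site-sized spatial
unit, and extrapolation across sites needs a between-site component the
within-site survey cannot supply. The two observer-by-spatial interaction
components are omitted by default to keep the formula in its standard
four-term form; `include_interactions = TRUE` adds `s_trob2/(a*c) +
s_seob2/(a*b*c)` (the full balanced-design variance) for users who want
it. Per-square-metre reporting divides the SE by the section area at the
boundary (`se_per_m2()`), never inside the formula, so all components stay
in per-section units.

`se_vs_area()` enumerates every factorisation of a section budget into
`a × b` and reports the SE envelope — when the transect component is small
the envelope collapses and precision is a function of total area only,
which is the main design insight the model yields. `required_area()`
inverts the curve; because only the transect term depends on the split,
the best split for a fixed section budget is always many short transects
(`a = k, b = 1`), and the observer term sets a floor
`sqrt(s_ob2/c)/section_area` that no amount of area can beat — infeasible
targets are refused with that floor named.

## The synthetic-data generator

Two deliberately different generating processes cover the two kinds of
question:

* **gaussian-vc** (`generate_vc_dataset()`) draws reading-level values
  directly from the Gaussian mixed model above. It is the exact
  data-generating process the estimators assume, so it is what parameter
  recovery, F-test calibration and Monte-Carlo validation of the
  propagation formula use. Its values are non-integer by construction —
  a Gaussian model on counts cannot produce counts, which is precisely
  why the second mode exists.
* **mechanistic** (`generate_field_truth()` +
  `generate_video_observations()`) builds an integer field census — a
  latent hierarchical mean (grand mean + fixed site effect + Normal
  transect and section effects, floored at zero) feeding a Poisson draw
  per section, individuals materialised — and then simulates video
  reading per oyster, observer and pass: Bernoulli detection with
  status-dependent probability, misclassification of detected oysters,
  and a confidence split of detected living oysters into "probably" and
  "possibly living". Matched oyster records take the video status from
  observer 1, reading 1 — an individually relocatable oyster is scored
  once, as in a field validation.

The Poisson stage gives overdispersed integer counts whose between-section
variance is the configured `s_se2` plus the Poisson mean; a
`count_model = "deterministic"` switch rounds the latent mean instead,
which makes zero-variance configurations produce exactly constant data —
useful for degeneracy tests, and the honest way to reconcile integer
counts with an exactly-assertable degenerate limit.

Default parameters are chosen to emulate the validation study the package
grew from, and are fixed rather than tuned: detection 0.8 for living and
0.5 for dead oysters, misclassification 0.18 (live scored dead) and 0.20
(dead scored living) matching the validation matrix's off-diagonals, and
a 0.55 "probably" split so the high-confidence category alone recovers
about 40% of living oysters while the merged category recovers 70–80%.
The living-count field process defaults to a grand mean of 4 per section
(≈ 1.3 m⁻²) with site offsets (−1.5, 0, +1.5) and the fitted variance
components; the dead process is independently parameterised with a
slightly lower mean, since only living-oyster variability was ever
analysed in the source surveys. Cluster (18%) and cover (14%) flags are
carried per oyster with optional detection-factor hooks, defaulting to
no effect.

What the generator does *not* emulate: spatial autocorrelation beyond the
nested hierarchy, substrate- or vegetation-driven detection gradients
(vegetation cover is carried as an inert covariate column), size-dependent
detectability, and any dependence between the passes of one observer
beyond the shared truth. Passing tests therefore demonstrate that the
estimators and the propagation formula are correct *under the stated
model*, not that real seabeds are that tidy.

### Seeds

A config carries one root seed; every generator call derives its draws
deterministically from it (video observation offsets the root by one so
that truth and observation use distinct streams). Same config + same seed
is byte-identical; `seed = NULL` leaves the caller's RNG state in charge,
which is what the Monte-Carlo loops use under one outer `set.seed`.

## Numerical choices

* SS are accumulated from per-observation group means (`ave`); the
  orthogonality identity is asserted at `1e-8` on unbalanced layouts.
* The EMS denominator search solves the 7-component linear system by QR;
  coefficients below `1e-10` are zeroed and a residual above `1e-8` marks
  the term untestable rather than inventing an approximate denominator.
* Quasi-F denominators may combine mean squares with negative weights;
  a non-positive realised denominator is reported untestable (`NA`)
  rather than producing a negative F.
* `lmer` runs with `bobyqa`, `rhoend = 1e-12`, singular fits tolerated
  (boundary estimates are legitimate zeros), derivative checks off for
  speed.
* Method-of-moments truncation happens after the exact solve, never
  inside it.

## Problem sizes used in the checks

The simulation-based checks run at sizes chosen to keep Monte-Carlo error
comfortably inside the asserted tolerances: 10,000 replicate surveys per
design for validating the propagation formula (relative SE of an SD
estimate ≈ 0.7%), 500 replicate surveys for REML recovery at the reference
design, 1,000 simulated null datasets for F-test size (binomial SE
≈ 0.7 points at α = 0.05), and 3,000-replicate smoke versions inside the
unit tests.

## Known limitations

* Only the survey's model shape is supported: one fixed crossed factor,
  one random crossed factor, a two-level nested random chain. This is a
  feature — the EMS algebra is verified for exactly this lattice — but it
  is not a general mixed-model engine.
* With unequal transects-per-site the ANOVA path is approximate by
  construction; REML is the estimator of record there, and the published
  mean squares of such designs are not promised bit-exact.
* The precision formula is within-site; programme design across many
  sites needs a between-site component from elsewhere.
* Mean REML estimates of weakly identified components are
  truncation-biased upward (see above); judge recovery of such components
  by the raw method-of-moments estimates or by medians.
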