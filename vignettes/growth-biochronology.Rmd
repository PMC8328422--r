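---
title: "Sea-trout growth biochronologies: model, priors and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sea-trout growth biochronologies: model, priors and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

scalechron analyses annual growth-zone (increment) widths measured on the
scales of anadromous brown trout (sea trout, *Salmo trutta* L.). Because a
scale grows in proportion to the fish, the width of the zone laid down
between two winter annuli proxies that year's somatic growth, in freshwater
before smolting and at sea afterwards. The package covers the full chain:
data validation and filtering, a Bayesian mixed model of log increment
width, growth chronologies and variance partitioning, a wild-versus-hatchery
plasticity test, and temperature-correlation tests that propagate posterior
uncertainty. A synthetic-cohort generator with known parameters makes every
stage testable without field data.

This vignette records the model, its assumptions, and the design decisions
taken where more than one reasonable convention existed.

## Data model and filtering

An analysis dataset pairs a fish table (id, group, sex, capture year, age
code, fork length, scale radius, circulus count, repeat-spawner flag) with
an increment table (one row per annual growth zone: 1-based index from the
scale focus, age class FW1/FW2/SW1/SW2/SW3, width in micrometres, flags for
the marginal plus-growth zone and spawning-eroded zones). Age codes follow
the standard `fw.sw+` nomenclature: freshwater winters, completed sea
winters, and a trailing `+` for incomplete marginal growth at the scale
edge.

Three filters run before modelling, in this order, each logged to a
provenance table so that rows in always equal rows retained plus rows
removed per rule:

1. **Rare life histories.** Fish whose age code is in a configurable
   exclusion list (default `2.0+`, `2.3+`, `3.1+`) are removed with all
   their zones; with so few fish, group-by-age cells for these histories
   are unestimable.
2. **Calendar anchoring.** With `m` completed (non-marginal) zones, zone
   `k` is assigned growth year `capture_year - 1 - (m - k)`; the marginal
   zone gets the capture year. The anchoring convention is that the last
   completed annulus closed the year before capture: fish are caught in
   autumn on their spawning run, after the season's plus growth has begun.
   For captures 2007–2016 and retained life histories up to `2.2+` this
   places every completed zone in 2003–2015. The same convention is applied
   uniformly to FW2 smolts regardless of capture year; no special case is
   made for fish caught the calendar year they smolted.
3. **Zone exclusion.** Marginal zones (incomplete by definition) and zones
   formed in a spawning year (eroded by the spawning mark, so they
   under-represent growth) are dropped. Filtering is idempotent.

## The growth model

For increment \(i\) of fish \(f\) in stratum-year cell \(c\) (a
group-by-environment-by-year combination),

\[
\log w_i = \mathbf{x}_i^\top \boldsymbol\beta + u_{f(i)} + v_{c(i)} +
\varepsilon_i, \qquad
u_f \sim N(0, \sigma_{\mathrm{fish}}^2),\;
v_c \sim N(0, \sigma_{\mathrm{year}}^2),\;
\varepsilon_i \sim N(0, \sigma_{\mathrm{obs}}^2),
\]

with fixed effects for age class (FW1 reference), group (hatchery
reference), their interaction, and optionally sex. The two random intercepts
are crossed: each increment belongs to one fish and one stratum-year cell.

**The response is natural-log width.** This is the single most consequential
convention in the package. It is forced by internal consistency of the
field's reported effect sizes: an intercept near 6.70 on the log scale
corresponds to a hatchery FW1 median of \(e^{6.70} \approx 812\) μm, and
adding an SW1 effect of 0.61 gives \(e^{7.31} \approx 1{,}492\) μm — both
on the scale of observed micrometre means, which no other transform
reproduces. All defaults of the synthetic generator
(`generative_params()`) live on this scale.

**Priors.** Each SD gets a penalized-complexity (PC) prior by default: an
exponential density on \(\sigma\) with rate \(\lambda = -\log(\alpha)/U\),
so \(P(\sigma > U) = \alpha\). Defaults are \(U = 1\) (log scale),
\(\alpha = 0.01\) — one unit on the log scale is a ±170% growth swing, so
this is deliberately weak while still shrinking toward the simpler model.
Half-Cauchy and inverse-gamma-on-the-variance (Gamma(1, 5e-5) on the
precision) families are available for sensitivity sweeps
(`prior_sensitivity()`); with datasets of the size this package targets the
fixed-effect posteriors are insensitive to the family, while on very small
datasets the SD posteriors legitimately differ — the prior dominates.
Fixed effects get independent \(N(0, 100^2)\) priors. A `prior_fixed()`
family freezes a component, which makes the coefficient posterior exactly
normal and gives the test suite its analytic oracle.

**Inference** is by blocked Gibbs sampling. Given the variances, the full
conditional of the stacked coefficient vector \((\boldsymbol\beta, u, v)\)
is multivariate normal — the mixed-model normal equations — and is sampled
in one block via a sparse Cholesky factorization whose symbolic analysis is
reused across sweeps. Given the coefficients, each SD is updated by its
conjugate Gamma step (inverse-gamma family) or a stepping-out slice sampler
on \(\log\sigma\) (PC, half-Cauchy). Convergence is summarized by
split-chain potential scale reduction on the SDs, with a warning above
1.01. The weakly identified fish-level SD (many fish, ~2–3 increments each)
mixes slowest and occasionally trips the warning at default draw counts;
the warning carries the diagnostics rather than failing the fit. Runs are
bit-reproducible under a fixed seed, and a single master seed derives all
stage seeds (`derive_seed()`).

**Model comparison** uses DIC with the likelihood conditional on the latent
effects (the convention of the nested-Laplace software that popularized
this model class; the focus matters because it changes what pD counts —
here, effective numbers of latent parameters). A term is supported when
dropping it raises DIC by more than 2. Sex enters only through this test
and is excluded from the default specification, since growth data of this
kind typically show no sex effect.

Degenerate inputs are handled explicitly: empty interaction cells (e.g. no
wild SW3 fish) leave all-zero design columns whose coefficients are
identified by the prior alone (warned, not an error); a random term with
zero levels collapses to prior-only SD draws; true collinearity among
populated columns is an error.

## Chronologies, variance partition, plasticity

The posterior of the stratum-year intercepts \(v_c\) *is* the growth
biochronology: per group and environment, a time series of systematic
growth deviations from the stratum average. `extract_chronology()` keeps
the full draw matrix attached to the summary table because downstream
inference needs it (below).

`variance_partition()` reports each component as
\(100\,\sigma_k^2 / (\sigma_{\mathrm{obs}}^2 + \sigma_{\mathrm{fish}}^2 +
\sigma_{\mathrm{year}}^2)\) with the posterior-mean SDs plugged in. This
definition — shares of the three-way total — is the one under which SDs of
0.155/0.058/0.065 give the familiar 11% (fish) and 13% (year) shares, and
the shares are invariant to rescaling the response.

`fish_plasticity_test()` compares the dispersion of individual average
growth between groups: the variance of per-fish posterior-mean intercepts
in the hatchery group over that in the wild group, referred to an F
distribution with (n_hatchery − 1, n_wild − 1) degrees of freedom,
two-sided by default (a one-sided flag exists; two-sided is the
conservative default when the direction is not prespecified). This test
deliberately uses point summaries of the fish intercepts — the standard
two-step practice — and is therefore mildly anticonservative; the package
propagates posterior uncertainty only where the year effects feed
secondary tests, which is where the problem bites hardest (13 years versus
1,600 fish).

## Temperature coupling

Sea conditions are summarized as July–December surface means (smolts enter
the sea in spring; the second half of the year covers the main marine
growing season), freshwater conditions as annual means;
`aggregate_monthly()` builds either from a monthly table and flags years
with missing months. Gridded-reanalysis retrieval is out of scope: the
interface is a CSV.

`monte_carlo_correlation()` computes, for each posterior draw of a
stratum's year-effect vector, the Pearson correlation (Spearman by flag;
Pearson is the default since the relationship of interest is linear) with
temperature over the overlapping years, plus the per-draw least-squares
line for plotting. The summary is the mean correlation and the 2.5/97.5%
quantiles across draws; a stratum is flagged *important* when that interval
excludes zero. Two properties pin the procedure down:

- **Reduction.** With a degenerate posterior (all draws equal) every draw's
  correlation equals the plain Pearson correlation of the point chronology:
  the naive two-step test is exactly the zero-uncertainty special case.
- **Conservatism.** Under a null coupling, with per-year posterior
  uncertainty comparable to or larger than the between-year spread — the
  regime short biochronologies actually live in — the propagated test's
  rejection rate stays below the naive test's nominal 5%. The test suite
  demonstrates this with a conjugate normal–normal mini-model rather than
  full refits, which isolates the phenomenon from sampler noise. When the
  posterior is much tighter than the between-year spread the two tests
  agree, and the credible-interval criterion is not a frequentist
  error-rate guarantee.

## The synthetic cohort generator

`generate_cohort()` is first-class, tested code, not a fixture. Its
defaults are the study conditions the rest of the package assumes: 1,596
fish captured 2007–2016; 89.9% FW1 smolts; sea ages 63.0/35.1/1.9%
(SW1/SW2/SW3); 10.7% repeat spawners (only possible with ≥2 sea winters, so
the conditional rate is rescaled); 1,249:347 female:male; 1,147:449
hatchery:wild. Widths are log-normal from the fixed effects above
(defaults: intercept 6.70; FW2 −0.23; SW1 0.61; SW2 0.58; SW3 0.23; wild
−0.39; interactions 0.32/0.53/0.35/0.24) with SDs 0.155/0.058/0.065.
Temperature series are normal draws (optionally AR(1)) with sea mean 12.0,
SD 0.7 °C and freshwater mean 9.1, SD 0.5 °C; year effects are built as
\(\sigma_{\mathrm{year}}(\rho z_{\mathrm{temp}} + \sqrt{1-\rho^2}
z_{\mathrm{noise}})\) so their population correlation with standardized
temperature is exactly \(\rho\) (defaults 0.41/0.29 sea wild/hatchery,
0.21/0.05 freshwater — sea coupling stronger than freshwater, wild stronger
than hatchery). Year effects are independent across strata beyond their
shared temperature driver.

Plumbing the generator does *not* attempt: survival or density dependence;
realistic marginal-zone growth (a uniform 0.2–0.8 fraction of a full year's
median growth — these zones are discarded by the pipeline, so only
plausibility matters); spawning erosion beyond a uniform 0.5–0.9 width
retention on one post-first-spawning sea zone. Scale radius is the sum of
all zone widths — physically, the focus-to-edge distance — and fork length
follows the calibration line \(FL = 17.128 + 0.013\,r\) (cm, with 3.66 cm
residual SD); circulus counts are a noisier linear function of radius.
Because the synthetic radius is exactly the width sum, the simulated
radius–length calibration is cleaner (R² ≈ 0.9) than real scale data would
be. Printed group means of raw widths are arithmetic means pooled over
years, which under a log-normal model sit slightly above
\(\exp(\text{linear predictor})\); generator checks therefore compare
medians, and cross-checks against published means are treated as
approximate.

## What the tests do and do not show

Passing tests show that the pipeline recovers known generative structure:
frozen-variance posteriors match the mixed-model-equations solution to
Monte Carlo precision; credible intervals cover generative fixed effects at
near-nominal rates over ≥20 replicates; a study-scale simulation-and-refit
run returns the generative parameters within simulation error; filter
arithmetic, growth-year spans, F ratios and least squares match
hand-computed oracles. They do not show that real scale data satisfy the
model: real increments carry measurement error correlated along the
reading axis, age-reading error, within-year environmental structure, and
selection effects (only survivors returning to spawn are sampled), none of
which the generator emulates.

Problem sizes used by the checked-in analyses and tests were chosen to
keep full runs in the minutes range on a single core: the analysis scripts
and the acceptance script fit 2,500 post-burn-in draws after 600 burn-in at
the full cohort size (about 15 s per fit here); module tests use cohorts of
60–400 fish with 150–4,000 draws. One chain is the default since the
blocked sampler's draws are nearly independent; multi-chain runs are one
argument away.

## Known limitations

- DIC from short chains carries Monte Carlo noise of a few units; term
  decisions near the ΔDIC = 2 boundary need longer chains.
- The fish-level plasticity F test ignores posterior uncertainty in the
  fish intercepts (documented above).
- The group main effect and the stratum-year intercepts are only
  prior-separated: the realized mean of a group's year effects is absorbed
  into the group coefficient, which adds simulation-level wobble of a few
  hundredths (log scale) to group-contrast recovery at 13-year spans.
- Chronology endpoints with few contributing fish shrink strongly toward
  zero; the draw matrix, not the posterior means, carries that information
  downstream.
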