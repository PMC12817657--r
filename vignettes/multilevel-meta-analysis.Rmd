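---
title: "Multilevel phylogenetic meta-analysis of parental-age effects on offspring telomere length"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilevel phylogenetic meta-analysis of parental-age effects on offspring telomere length}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(telometa)
```

## The scientific problem

Does the age of a parent at conception predict the telomere length of its
offspring?  Primary studies answer this with very different statistics — some
report regression slopes with standard errors or confidence intervals, some
report t statistics, some raw correlation coefficients — on samples ranging
from a few dozen birds to tens of thousands of humans, measured with
different laboratory methods (qPCR, TRF Southern blot, TRF in-gel, WGS) in
different cell types.  `telometa` implements the full analysis chain needed
to synthesise such a literature: standardisation to a common effect-size
scale, multilevel random-effects meta-regression with phylogenetic
correlation, heterogeneity decomposition, moderator inference, and
publication-bias diagnostics, together with a synthetic-data generator that
reproduces the assumed data-generating process so every stage can be
validated by simulation.

## Effect-size standardisation

Every extracted statistic is mapped to a correlation, then to Fisher's z:

* slopes with a t statistic (or a standard error, whence $t = b/\mathrm{SE}$;
  when only a 95% CI is reported, $\mathrm{SE} = (\mathrm{upper} -
  \mathrm{estimate})/1.96$) are converted with
  $r = t/\sqrt{t^2 + \mathrm{df}}$;
* observed correlations are used directly;
* $r$ is adjusted for the skew of its sampling distribution,
  $\rho = r + \frac{r(1-r^2)}{2(N-4)}$;
* $Z_r = \tfrac12 \log\frac{1+\rho}{1-\rho}$ with known sampling variance
  $V_Z = 1/(N-3)$.

Two points here were genuinely open and are worth recording.  First, the
adjustment's denominator admits two algebraic readings, $2(N-4)$ and
$2N-4$; we adopt $2(N-4)$, the standard Olkin–Pratt-style approximation of
the source methodology, and expose the literal alternative through
`r_to_rho(reading = "2n-4")`.  Under the adopted reading $N = 4$ annihilates
the denominator, so $N \le 4$ is an error by default (with an explicit
pass-through option).  Second, for integer $N \ge 5$ the adjustment can be
shown never to leave $(-1, 1)$, but fractional "effective" sample sizes
below 5 can overshoot; such values are clamped to $\pm(1 - 10^{-10})$ with a
warning rather than failing.  All intermediates ($t$, $r$, $\rho$, $Z_r$,
$V_Z$) are retained in the output so each row's conversion is auditable.

## The model

For effect $i$ in study $s(i)$ on species $p(i)$,

$$ Z_{r,i} = \mathbf{x}_i^\top \boldsymbol\beta + u_{s(i)} + a_{p(i)} + e_i + m_i $$

with $u \sim N(0, \sigma^2_u)$ (between-study), $e \sim N(0, \sigma^2_e)$
(between-estimate within study; with one row per estimate this is the
residual-heterogeneity term), $m_i \sim N(0, V_{Z,i})$ with **known**
sampling variance, and species effects $\mathbf a \sim N(0, \sigma^2_a
\mathbf C)$ where $\mathbf C$ is the phylogenetic correlation matrix:
$C_{jk}$ is the shared root-to-MRCA branch length of species $j,k$ divided
by $\sqrt{d_j d_k}$ (root-to-tip depths), i.e. the Brownian-motion
covariance normalised to a correlation.  Non-ultrametric trees are admitted
through exactly this normalisation; polytomies are accepted as-is, and
topologies without branch lengths can be used with a unit-length fallback.

The marginal covariance is
$\mathbf V = \sigma^2_u \mathbf S + \sigma^2_e \mathbf I + \sigma^2_a
\mathbf R + \mathrm{diag}(V_Z)$, with $\mathbf S$ the same-study indicator
and $\mathbf R$ the row-expanded species correlation.  An exchangeable
species term $\sigma^2_s$ is available but off by default: in the motivating
data it is either meaningless (single-species subset) or aliased with study
(each non-human species appears in one study), so it is carried at zero
unless explicitly requested.

## Estimation and numerical choices

Fixed effects are profiled out by generalised least squares through a
Cholesky factorisation of $\mathbf V$ (no explicit inverse); variance
components maximise the ML or REML log-likelihood on the $\log \sigma^2$
scale, bounded in $[\log 10^{-12}, \log 100]$, using `nlminb` from five
deterministic starts perturbed around a DerSimonian–Laird method-of-moments
initialiser, followed by a tighter polish from the best candidate
(`rel.tol` $10^{-12}$).  Convergence is declared when the optimiser reports
success and the projected numerical gradient on the log-variance scale is
small; components pressed against the lower bound are treated by their KKT
condition (an outward gradient at the bound is not a failure).  The REML
objective includes the $\tfrac12\log|\mathbf X^\top \mathbf X|$ constant, so
it is invariant under full-rank reparameterisations of the design and
directly comparable with the common mixed-model convention.

Intercept-only models default to REML (less biased variance components);
moderated models default to ML, the convention for meta-regressions whose
moderator tests are the target.  Coefficient intervals are Wald normal
($\pm 1.96\,\mathrm{SE}$) with no small-sample correction — a deliberate
match to standard multilevel meta-analytic practice, with a limitation noted
below.  Variance-component intervals are profile-likelihood, computed on
demand (`vc_profile_ci()`) rather than inside every fit, because the
simulation studies refit thousands of models.  The likelihood-ratio test
for a component uses the plain $\chi^2_1$ reference by default (mirroring
common reporting practice); the boundary-corrected 50:50 mixture — the
statistically preferable reference, since the null value lies on the edge
of the parameter space — is available via `lrt_vc(boundary = TRUE)`.

Design matrices are treatment-coded against declared reference levels; rows
with missing moderators are dropped with a count, constant moderators and
aliased columns are dropped deterministically in column order with named
warnings.  Post-hoc contrasts compare predicted marginal means averaged with
equal weight over the levels of all other categorical moderators; p-values
are unadjusted by default with a Tukey (studentised-range) option, since
the field reports both and the motivating analysis does not state its
adjustment.

## Heterogeneity and variance explained

The typical sampling-error variance is
$\sigma^2_m = \frac{(k-1)\sum w_j}{(\sum w_j)^2 - \sum w_j^2}$ with
$w_j = 1/V_{Z,j}$.  Here $k$ counts **effect sizes**, not studies: the
weights are indexed per effect, and only this reading collapses to the
common variance when all $V_Z$ are equal — that collapse is tested exactly.
Total variance is $\sigma^2_t = \sigma^2_u + \sigma^2_e + \sigma^2_s +
\sigma^2_a + \sigma^2_m$; $I^2_{\text{total}} = (\sigma^2_t -
\sigma^2_m)/\sigma^2_t$, and each component's share is $\sigma^2/\sigma^2_t$
(the residual share $\sigma^2_m/\sigma^2_t$ completes the identity).

Per-moderator marginal $R^2$ refits a model containing only that moderator
(same random structure, ML) and reports
$\mathrm{Var}(\mathbf X\hat{\boldsymbol\beta}) /
(\mathrm{Var}(\mathbf X\hat{\boldsymbol\beta}) + \sum \hat\sigma^2 +
\sigma^2_m)$.  Single-moderator refits are the primary definition because
marginal $R^2$ is defined per model, not per term; a full-model
leave-one-term-out $\Delta R^2$ is available (`strategy = "leave_one_out"`),
and a companion value without $\sigma^2_m$ in the denominator is always
returned because published tools differ on whether sampling variance belongs
there.

## Publication-bias diagnostics

Funnel data plot precision ($1/\sqrt{V_Z}$) against **fixed-effect
residuals** of the full meta-regression — residuals, because moderator and
phylogenetic structure would otherwise masquerade as asymmetry.  BLUP-
conditional residuals are available as an option.  The modified Egger test
fits the multilevel model with the sampling variance $V_Z$ itself as the
only moderator (an SE variant exists for sensitivity analysis); the time-lag
test uses mean-centred publication year.  Both inherit the random structure
of the corresponding main model; centring only moves the intercept, never
the slope, and the Egger slope is invariant to shifting all effects by a
constant — both invariances are tested.

## What the generator emulates — and what it does not

`simulate_dataset()` draws data from exactly the model above: fixed
moderator effects, study effects, phylogenetically correlated species
effects over a pure-birth tree rescaled to unit depth, estimate-level
noise, and sampling error $N(0, 1/(N-3))$ with $N$ log-uniform between 10
and 1000 (the heavy right tail of real sample sizes).  Defaults mirror the
motivating study's scale: 42 studies contributing 1–6 estimates (~148
effects), 13 species with one species per study, $\sigma^2_u = 0.004$,
$\sigma^2_e = 0.002$, $\sigma^2_a = 0.022$, intercept 0.06, publication
years 2004–2023 drawn **per study** (a study has one publication year).
`apply_selection()` injects publication bias by suppressing non-significant
negative effects with configurable probability.

The generator does **not** emulate: non-Gaussian random effects, correlation
between moderators and study size, missing or misreported statistics,
rounding of published values, or dependence among sampling errors from
shared control groups.  Passing simulation-based tests therefore validates
the estimation machinery under the model's own assumptions — it cannot
certify robustness to violations real literatures exhibit.

## Simulation scale and known limitations

The package's validation suite uses 200 replicate datasets for parameter
recovery and 500 for test calibration — sizes chosen to make Monte-Carlo
error small relative to the quantities checked (binomial SE ≈ 0.01 for a
rejection rate at 500 replicates).

Two limitations surface clearly in those simulations and are worth stating
plainly.  First, with a dominant phylogenetic component spread over only ~13
species, Wald-normal intervals for the pooled effect undercover (about 0.88
rather than 0.95 in the package's own recovery simulations); the effective
number of independent clusters is closer to the number of deep lineages than
to the number of effects, and the same behaviour is reproduced by
independent multilevel meta-analysis software on identical data.  Second,
Wald/chi-square moderator tests under ML are mildly anticonservative at ~42
study clusters (null rejection around 0.07–0.09 at nominal 0.05 in the
calibration simulations); REML reduces this for the omnibus test, and users
wanting stricter type-I control should prefer `method = "REML"` and the
boundary-corrected LRT.  Neither issue is specific to this implementation;
both are properties of the standard methodology at this data scale.

Other non-goals: no Hedges' g or log-response-ratio conversions, no
trim-and-fill or selection-model estimation, no tree inference, no robust
sandwich variances, and no Bayesian fitting.
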