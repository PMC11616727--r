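---
title: "Designing randomized basket trials with commensurate borrowing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing randomized basket trials with commensurate borrowing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(basketssd)
```

## The design problem

A randomized basket trial runs $K$ parallel two-arm comparisons of one
treatment in $K$ disease-defined subgroups. Outcomes in subtrial $k$ are
normal with known variance $\sigma_k^2$; patients are allocated to the
experimental arm with probability $R_k$; the estimand is the per-subtrial
effect $\theta_k = \mu_{Ek} - \mu_{Ck}$. The design goal is a decisive
conclusion in *every* subtrial: declare efficacy when
$P(\theta_k \text{ beneficial side of } 0 \mid \text{data}) \ge \eta$, or
futility when
$P(\theta_k \text{ not better than } \delta \mid \text{data}) \ge \zeta_k$,
where $\delta$ is the clinically relevant difference. Both rules can be
guaranteed satisfiable exactly when the posterior precision of $\theta_k$
reaches $\left((z_\eta + z_{\zeta_k})/\delta\right)^2$ — the design target.

Analyzed in isolation, each subtrial needs
$n_k^0 = \frac{\sigma_k^2}{R_k(1-R_k)}\left[\left(\frac{z_\eta+z_{\zeta_k}}{\delta}\right)^2 - \frac{1}{s_{0k}^2}\right]$
patients (`sample_size_no_borrowing()`). The package's purpose is the
alternative: let each subtrial's analysis borrow from the others through a
collective commensurate prior, so that the same precision target is met with
fewer patients.

## The borrowing prior, piece by piece

1. **Operational posterior** (`operational_posterior()`): subtrial $q$'s own
   data update a vague $N(m_{0q}, s_{0q}^2)$ prior through the difference in
   arm means, whose sampling variance is $\sigma_q^2/(n_q R_q(1-R_q))$. This
   is exact conjugate normal arithmetic.
2. **Discounting** (`commensurate_prior()`): subtrial $q$'s posterior is
   recentered as a prior for $\theta_k$ with variance inflated by the
   moment-matched mixture term $\frac{w_{qk}b_1}{a_1-1} +
   \frac{(1-w_{qk})b_2}{a_2-1}$, where the precision $\nu_{qk}$ of the
   conditional commensurate prior carries the two-component Gamma mixture
   prior. $w_{qk} = 0$ means fully commensurate (borrow strongly),
   $w_{qk} = 1$ maximal skepticism.
3. **Synthesis** (`synthesis_weights()`, `collective_prior()`): the $K-1$
   sources are convolved with weights
   $p_{qk} \propto \exp(-w_{qk}^2/c_0)$ into
   $N\!\left(\sum_q p_{qk}\lambda_q,\; \sum_q p_{qk}^2 \xi_{qk}^2\right)$.
4. **Update and decide** (`posterior_with_borrowing()`, `decide()`): the
   collective prior is updated by the subtrial's own data; tail
   probabilities are exact normal integrals, no sampling anywhere.

At the design stage only variances matter — the constraint system couples
the $K$ sizes through the $\xi_{qk}^2(n_q)$ terms, and
`solve_sample_sizes()` finds the minimal $n_1,\dots,n_K$ meeting all $K$
precision targets simultaneously. The prior means $\lambda_q$ play no role
until analysis, where they are computed from the *observed* complementary
data.

## Tunable parameters

* `delta` (outcome units, no default): the effect the trial must
  discriminate from zero. Negative when smaller outcomes indicate benefit
  (e.g. tumor shrinkage); all decision rules mirror automatically. A
  per-subtrial vector is accepted.
* `eta`, `zeta` (probabilities in (0.5, 1)): efficacy and futility
  thresholds. $\eta = 0.95$, $\zeta = 0.80$ make the no-borrowing sizes
  comparable to a frequentist design with one-sided $\alpha = 0.05$ and 80%
  power, which is why the examples use them; `zeta` may vary by subtrial.
* `s02`, `m0` (outcome units², outcome units; defaults 100 and 0): the
  operational prior. `s02 = 100` is effectively flat for outcomes on
  single-digit scales; on other scales pick `s02` large relative to
  plausible $\theta^2$.
* `w` ($K\times K$, entries in [0, 1]): prespecified pairwise
  incommensurability. Elicit from subject-matter experts, or derive from
  assumed outcome distributions with `hellinger_matrix()`. The matrix must
  be symmetric with zero diagonal; asymmetric input is an error, never
  repaired silently, because silent symmetrization would hide elicitation
  mistakes.
* `c0` (> 0, default 0.05): concentration of the synthesis-weight
  transform. Values much smaller than typical $w_{qk}$ concentrate the
  collective prior on the most commensurate source; values much larger give
  uniform weights. The constructor warns when `c0` is not below the
  smallest positive $w_{qk}$.
* `mixture` (default `gamma_mixture_prior(1.1, 1.1, 54, 3)`): shape/rate
  Gamma components for the precision $\nu_{qk}$. The defaults give a
  discounting component with mean 1 (marginal variance contribution
  $b_1/(a_1-1) = 11$) and a borrowing component with mean 18 (contribution
  $3/53 \approx 0.057$). Both shapes must exceed 1 or the moment matching
  in step 2 is undefined; the constructor enforces this. If the first
  component implies *less* discounting than the second, the roles are
  reported as inverted (a warning), not swapped.

## Numerical choices

* The design constraints are inequalities ("at least this precision"); the
  solver treats them as equalities because the minimal sizes are the design
  answer. Residuals at the returned solution are required to be below
  `tol = 1e-8`; the solver iterates well past that when it can.
* Newton's method uses the analytic Jacobian (each constraint is smooth,
  with $\partial F_k/\partial n_k = R_k(1-R_k)/\sigma_k^2$ and cross terms
  $p_{qk}^2 A_q v_q^2 / S_k^2$), started at the no-borrowing solution —
  always a feasible upper start since borrowing only adds precision. Steps
  are halved when an iterate turns negative or fails to reduce the residual
  norm; if Newton stalls, a damped fixed-point sweep
  ($n_k \leftarrow$ its own closed-form given the others) takes over, and
  failure after 500 iterations is reported with diagnostics rather than
  hidden. Tests cross-check the solution against an independent
  coordinate-bisection oracle to $10^{-6}$.
* A subtrial whose target is met by prior (or complementary) information
  alone is clamped at $n_k = 0$ with a prominent warning: a subtrial
  enrolling nobody cannot practically or ethically be run, so this is a
  design smell, not a convenience.
* `synthesis_weights()` subtracts the largest exponent before
  exponentiating, so $c_0 \to 0^+$ degrades gracefully to a point mass on
  the smallest $w$ instead of 0/0.
* $K = 2$ is allowed but degenerate: the "collective" prior is the single
  complementary source. Genuine collective borrowing needs $K \ge 3$.
* Solved sizes are reported real-valued (`n_real`, displayed to 1 decimal)
  with ceilings (`n_int`) alongside; the constraints are continuous in $n$
  and the rounding policy is the user's decision.

## What the simulator emulates — and what it does not

`scenario_spec()` + `operating_characteristics()` generate replicate trials
with per-patient normal outcomes at true means $(\mu_{Ek}, \mu_{Ck})$ and
variances $\sigma_k^2$, analyze each replicate with the borrowing and/or
stand-alone model, and tabulate per-subtrial efficacy/futility/inconclusive
rates plus the familywise false-positive rate over the null subtrials.

Two bookkeeping choices matter:

* **Enrollment**: whole patients are simulated — $\lfloor n_k R_k \rfloor$
  on E and $\lfloor n_k(1-R_k) \rfloor$ on C — while the analysis model
  evaluates posterior precisions at the *nominal* design size $n_k$, which
  the constraint system was solved for and which is generally fractional.
  This matches how the design's operating characteristics are defined (the
  plan is the fractional size; the realized trial quantizes it) and
  reproduces the published behavior of such designs: per-subtrial true
  positive rates near $\zeta$ under the borderline alternative
  $\theta_k = \delta$, per-subtrial false positives below $1-\eta$, and a
  familywise false-positive rate around 5–6% for seven null subtrials under
  borrowing. Passing an even integer `n` with $R = 0.5$ makes the nominal
  and realized allocations coincide exactly.
* **Analysis-stage weights**: $p_{qk}$ and the mixture variances are fixed
  at their *design* values; only the $\lambda_q$ are recomputed from the
  observed complementary data (with the design's operational priors,
  $m_0 = 0$ by default). Re-deriving $w$ from observed data would be a
  sample-size-reassessment procedure, which this package deliberately does
  not implement.

The simulator draws i.i.d. normal outcomes with *known, correctly specified*
variances and no missingness, dropout, accrual dynamics, or interim looks.
Passing simulations therefore validate the probability calculus and the
design's frequentist calibration under the assumed model — not robustness to
variance misspecification, non-normality, or misspecified $w_{qk}$ (the
latter is a known sensitivity: too-small analysis-stage $w$ sharpens
posteriors at the price of occasional ambiguous conclusions).

The test suite runs its Monte Carlo checks at 20 000 replicates and the
reproduction script at 100 000, the scale at which the published rates were
tabulated; the closed-form analysis makes either take only seconds.

## Design choices where the ground was open

* **Gamma parameterization** is shape/rate, pinned down by the borrowing
  component's stated mean 18 for Gamma(54, 3) and confirmed by every solved
  sample size. (The equal-tailed 95% interval of the Gamma(1.1, 1.1)
  component under this parameterization is [0.034, 3.542].)
* **$w = 1$ is not "no borrowing"**: even at maximal discounting the
  collective prior has finite variance (the discounting component's 11), so
  a borrowing analysis with $w = 1$ still differs from the stand-alone
  model. The true no-borrowing analysis is `posterior_standalone()` /
  `sample_size_no_borrowing()`; the package keeps the two modes explicit
  rather than treating one as a limit of the other. Consequently the
  dominance property $n_k \le n_k^0$ is guaranteed for $w_{qk} < 1$ and can
  fail only in the degenerate $K=2$, $w=1$ corner where the single inflated
  source is weaker than the operational prior.
* **Futility thresholds** apply per subtrial; the efficacy threshold $\eta$
  is global, with an optional Bonferroni sharpening
  ($\eta \to 1 - (1-\eta)/K$) for strong familywise control, off by default
  because the design targets subtrial-level error control.

## Limitations

* Known variances only. Unknown-$\sigma^2$ designs require integrating the
  nuisance parameters out of the posterior and are out of scope.
* Normal outcomes only; binary and time-to-event endpoints need different
  likelihood and constraint algebra.
* No interim analyses, early stopping, or sample-size reassessment; the
  design assumes all subtrials complete and are analyzed together.
* $w_{qk}$ are inputs, not estimates. They should encode a priori pairwise
  incommensurability — never be tuned to shrink the sample size.
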