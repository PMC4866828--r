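---
title: "RPE-boosted anticipation: model, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{RPE-boosted anticipation: model, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(savouR)
library(dplyr)
```

## The model

savouR implements a valuation model for outcome-predictive cues built on the
*utility of anticipation*: while waiting a delay $T$ for an outcome of
magnitude $R$, the subject accrues anticipatory utility
$a(t) = R\,e^{-\nu (T - t)}$ — savouring when $R > 0$, dread when $R < 0$ —
growing at rate $\nu$ (1/s) towards delivery. With exponential discounting at
rate $\gamma$ (1/s), the value of the cue signalling the outcome is

$$Q \;=\; \eta\,A + B, \qquad
A = \frac{R}{\nu - \gamma}\left(e^{-\gamma T} - e^{-\nu T}\right), \qquad
B = R\,e^{-\gamma T},$$

where $A$ is the discounted anticipation integrated over the wait, $B$ the
discounted outcome, and $\eta$ the relative weight of anticipation. $Q(T)$
equals $R$ at $T = 0$, rises above it whenever anticipation outweighs
discounting, and decays to zero — the inverted-U delay profile.

The central hypothesis is that $\eta$ is not constant but *boosted by the
absolute reward prediction error (RPE)* evoked by the cue:

$$\eta = \eta_0 + c\,|\delta_{pe}| \quad\text{(linear)}, \qquad
\eta = \eta_0 + c_1 \tanh(c_2 |\delta_{pe}|) \quad\text{(tanh)}, \qquad
\eta = \eta_0 + c\,\theta(|\delta_{pe}|) \quad\text{(step)}.$$

The linear rule is the small-RPE expansion of the tanh rule and the step rule
its saturated limit. Because the boosted value of the cue feeds back into the
RPE the cue evokes, the equilibrium RPE solves a self-consistency equation
$\delta_{pe} = \alpha\,g(|\delta_{pe}|) + \beta$; under the linear rule a
finite positive solution exists only while
$(1-q)\,c\,A < 1$ (with $q$ the probability the rewarded cue appears), and
`solve_selfconsistent()` / `boosted_cue_value()` report the stability margin
rather than just a flag, so parameter sweeps can mask the unstable region.
The tanh rule is bounded and always has a solution.

Boosting by the *absolute* RPE matters: unexpected bad news boosts dread just
as unexpected good news boosts savouring. This is what lets one model couple
a preference for advance information at long delays with indifference at
short ones, where boosted savouring and boosted dread still cancel.

## Task applications

`monkey_values()` solves the coupled equilibrium for the three-target
information-choice task (targets differing only in the probability of an
uncertainty-resolving cue). Target values are probability-weighted means of
cue values; cue values carry anticipation weighted by an RPE-boosted $\eta$;
and each RPE is the cue value minus the preceding target's value. The system
is solved by damped fixed-point iteration on the per-(cue, target) RPEs
(damping 0.5, tolerance 1e-10, cap 1e4 iterations) because only the
equilibrium conditions, not a solver, are implied by the theory. Without
boosting the three targets are exactly equally valued; with it the
more-informative targets are worth more across a wide parameter region. One
caveat found while implementing: at the published task magnitudes the linear
ansatz diverges for gains $c \gtrsim 2$ (the coupled analogue of the
stability condition), so strong-gain illustrations use the bounded step or
tanh rules.

`pigeon_delta_q()` and `phase_diagram()` cover the two-target observing
paradigm: an informative target whose rewarded cue appears with probability
$p_I$ against an uninformative target rewarded with probability $p_N$. The
linear ansatz gives the closed form

$$\Delta Q = (\eta_0 a + b)\left(\frac{p_I R_I}{1 - (1-p_I)\,c\,A_I} -
p_N R_N\right),$$

with $a, b$ the unit-reward anticipation and discount factors. At
$p_N = 1$ the model reproduces the classic delay-dependent preference for
the poorer 50%-rewarded-but-informative target, including the predicted
second reversal at very long delays; at $p_N = 0.5$ information is always
preferred; and the $p_I = 0.2$ vs $p_N = 0.5$ variant is preferred only with
boosting. The phase diagram uses the dimensionless delay axis $\gamma T$,
matching the printed parameter ratios ($\nu/\gamma = 0.5$, $\eta_0/\gamma =
3$, $c/\gamma = 3$, $R = 1$).

A limitation worth stating: with the bounded tanh rule at small amplitude
($c_1/\gamma = 1$) the boosted value can never exceed a sure reward's value
at $p_N = 1$ (the bound $\max\eta\,A + B < \eta_0 A + B$ fails only for
larger amplitudes), so the two ansatzes agree qualitatively — same
matched-odds behaviour, same existence of an information-preferred region,
same double reversal once amplitudes are matched — but not cell-by-cell at
every printed parameter set.

## The trial-by-trial human model

For the human advance-information experiments the model becomes generative:
on each trial the chosen target's value moves toward the experienced outcome
value by a learning rate $\alpha$ (delta rule), and choices are a softmax of
the learned value difference. The outcome value is $V = \eta_{S_i} A_i +
B_i$ with $i = +$ (reward, parameters $R_+, \nu_+$) or $i = -$ (no reward,
$R_-, \nu_-$), a shared discount rate $\gamma$, and $\eta = \eta_0 + c$ after
an informative cue versus $\eta = \eta_0$ on the uninformative path. Since
only $cR_\pm/\sigma$ is identifiable, $c = \sigma = 1$ is fixed for fitting,
and $\eta_0$ is fixed at 0 in the boosted variants (it cancels from the
value difference). The sign of $R_-$ is deliberately unconstrained — its
negativity (dread of the no-reward outcome) is an empirical finding.

The comparison zoo (`model_zoo()`) spans plain Q-learning (3 parameters),
Q-learning with outcome-specific discounting (5), anticipation with a free
constant weight but no boosting (7), and boosted variants without $R_-$ (4),
without discounting (5), and full (6). `boosted_asymmetric` — separate gains
for positive and negative RPEs — is exposed as a named variant; with
$\eta_0 = 0$ the gains are absorbed into $R_\pm$, so its likelihood
coincides with `boosted_full` and the asymmetry is read off the fitted
$R_+/|R_-|$ ratio.

Two conventions the theory leaves open were fixed here:

* **Value initialization.** Both targets start at 0 and are not reset
  between blocks (target colors persist across blocks in the blocked
  design).
* **Randomized designs learn per delay condition.** With a single learned
  value pair, an interleaved-delay session could express no delay-dependent
  preference at all — the choice would depend only on past trials, not the
  announced delay. Because the randomized design announces the delay before
  each choice, `simulate_subject()` and `session_loglik(per_delay = TRUE)`
  keep a separate value pair per delay condition there; the blocked design
  keeps the single shared pair.

## Synthetic cohorts

`builtin_design()` encodes the three experimental schedules: the blocked
design (delays 2.5/7.5/20/40 s with 90/36/18/18 trials — roughly equal
*time* per condition), its control variant with reordered blocks and a
repeated first condition, and the randomized design (25 trials, 5 per delay
in 1/5/10/20/40 s). Reward probability is 0.5 throughout. Subjects are drawn
from a diagonal Gaussian on the transformed parameter scale
(`population_spec()`), matching the random-effects assumption of the
fitting model; a single seeded generator drives the choice draw then the
outcome draw on each trial, so fixtures are bit-reproducible.

What the generator emulates is the *model's own* choice process under the
published designs with known ground truth. It does not emulate features of
real data the theory itself sets aside: delay adaptation across blocks (seen
in the control experiment), reaction times, key errors, or cross-trial
anticipation. Passing recovery tests therefore certify the estimation
machinery, not the model's adequacy for any particular real dataset.

Recovery cohorts use `center = TRUE`, which moment-matches the realized
transformed draws to the group means. This removes the sampling noise of a
small (14-subject) cohort from the recovery error so that what is measured
is estimation error; it was fixed as part of the recovery design, not tuned.

## Hierarchical fitting and model comparison

`em_fit()` implements random-effects estimation by Laplace-approximate EM:
the E-step computes each subject's MAP on the transformed scale (logit for
$\alpha$; log for $\nu_\pm$, $\gamma$, $\eta_0$; identity for the
sign-free $R_\pm$) with covariance from the numerically differentiated
Hessian; the M-step updates the diagonal group Gaussian by moments,
$\mu = \tfrac1N\sum_i m_i$,
$\Sigma = \mathrm{diag}(\tfrac1N\sum_i (m_i m_i^T + \Sigma_i) - \mu\mu^T)$.
Numerical choices: BFGS with relative tolerance 1e-12 and a Nelder-Mead
fallback; five prior-drawn restarts on the first E-step and warm starts
thereafter; central-difference Hessians with covariance repaired by
eigenvalue flooring at 1e-8; group variances floored at 1e-6; convergence
when the group mean moves less than 1e-4 (cap 200 iterations, smaller caps
in the test suite where only rankings or coarse recovery are at stake). The
per-iteration sum of Laplace log-evidences is stored as a convergence
surrogate. Because the plain EM map approaches its fixed point slowly on
this model (the group mean creeps for hundreds of iterations along the
$\gamma$–$\nu_+$ ridge), `em_settings(accel = )` offers standard
over-relaxation of the EM step (stable for factors below 2); recovery runs
use a factor of 1.8 with a 250-iteration cap.

Two honest-uncertainty caveats at small cohort sizes. First, when
per-subject measurement noise exceeds the between-subject spread, the
maximum-likelihood group variance legitimately collapses towards zero, and
the Laplace posterior covariances then mirror the collapsed prior rather
than the data. `tidy()` therefore reports the group-mean standard error as
$\sqrt{(\hat\Sigma_b + \overline{\sigma^2_w})/N}$, where the per-subject
measurement variance $\sigma^2_w$ is recovered by subtracting the prior
precision from the Laplace posterior precision (directions the data leave
unconstrained are capped). Second, the recovered group mean of a weakly
subject-identified parameter such as the discount rate carries a
cohort-to-cohort scatter of order 10–15% at 14 subjects — visible directly
by re-running the recovery at different seeds — which is exactly what this
standard error predicts.

`ibic()` scores a fitted prior by Monte-Carlo integration of each subject's
likelihood over $K$ prior draws (default $10^4$; 3000 in the comparison
tests) and penalizes $|M|\log|D|$, with $|M|$ equal to twice the free
parameter count — a mean and a variance per parameter — and $|D|$ the number
of choices actually fitted (recorded alongside, since raw and balanced
counts differ). `balance_trials()` implements per-condition sub-sampling to
the minimum count; recovery fits in this package use all trials, because at
the 14-subject scale the balanced fit measurably biases the recovered
discount rate upward while the full-data fit recovers it to within a few
percent.

### What model comparison can and cannot resolve at desk scale

On cohorts simulated from the full boosted model at the fitted group means
(14 subjects, blocked-design counts), the full model's data-evidence
advantage over its no-discount restriction is about 9–12 points on the
$-2\log$ scale — smaller than the $2\log|D| \approx 15.5$ iBIC penalty for
the two extra prior parameters, so iBIC prefers the simpler nested model at
exactly this size; with three sessions' worth of trials the generating model
separates cleanly (gap ≈ 74). The corresponding test is therefore expected
to flag this at the single-session size: it is a property of the criterion
at that data size, not of the estimator. Recovery of *structure* is robust
at desk scale: the recovered $R_-$ is negative and $\nu_- > \nu_+$
(dread faster than savouring), and plain Q-learning data are correctly
attributed to Q-learning.

## A worked example

```{r example-values}
params <- anticipation_params(R = 1, nu = 0.5, gamma = 1, eta0 = 3,
                              boost = boost_spec("linear", c = 3))
pigeon_delta_q(pigeon_task(p_noinfo = 1, T = c(0.1, 1, 5)), params)
```

```{r example-phase, fig.alt = "Observing-preference phase diagram"}
autoplot(phase_diagram(params, p_noinfo = seq(0.5, 1, by = 0.025),
                       gamma_T = seq(0.05, 5, length.out = 80)))
```

```{r example-recovery, eval = FALSE}
# a small end-to-end recovery run (a few minutes)
spec <- population_spec(make_model("boosted_full"), fitted_group_means(),
                        sd = 0.1, n_subjects = 14)
trials <- simulate_cohort(spec, builtin_design("exp1"), seed = 1,
                          center = TRUE)
fit <- em_fit(trials, make_model("boosted_full"),
              settings = em_settings(max_iter = 250, tol = 1e-4,
                                     n_restarts = 3, accel = 1.8), seed = 2)
tidy(fit)
```

## Known limitations

* Exponential discounting only; hyperbolic or double-exponential forms are
  out of scope, as are anticipation of the cues themselves and cross-trial
  anticipation.
* The equilibrium treatment of the boosted RPE assumes the loop has settled;
  no learning dynamics toward the fixed point are modelled.
* The monkey application predicts forward only (no fitting of the animal
  data), and the exact gain/baseline pair behind the published preference
  bars is not identifiable from what is printed — orderings, not bar
  heights, are the testable content.
* iBIC comparisons at single-session size cannot resolve a discount rate of
  0.041/s against its no-discount restriction (see above).
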