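---
title: "Exact inference for F-beta classification scores: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact inference for F-beta classification scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fbinfer)
```

## The model

A binary classifier evaluated on a test set of `N` instances, `S` of them
actual positives, produces a confusion matrix with `d` true positives and
`b` false positives. `fbinfer` treats the classifier's per-instance
decisions as independent, so

$$d \sim \mathrm{Bin}(S, p_s), \qquad b \sim \mathrm{Bin}(N-S, p_\alpha),$$

independently, where $p_s$ is the sensitivity and $p_\alpha$ the
per-negative false-positive rate. The estimated F-beta score is the
plug-in

$$f_\beta = \frac{(1+\beta^2)\,d}{b + d + \beta^2 S},$$

which estimates $F_\beta(p_s, p_p) = (1+\beta^2) p_p p_s / (\beta^2 p_p +
p_s)$, the $\beta$-weighted harmonic mean of precision $p_p$ and
sensitivity $p_s$ ($\beta = 1$ is the F1 score; $\beta > 1$ up-weights
sensitivity). Everything in the package conditions on `S` and `N - S`
only — there is no conditioning on the number of predicted positives, so
both the false-positive *and* true-positive counts contribute their full
binomial variability.

A target operating point $(p_s, p_p)$ pins down $p_\alpha$ through the
calibration equation

$$\mathbb{E}\!\left[f_\beta \mid S, N-S, p_s, p_\alpha\right] = F_\beta(p_s, p_p),$$

whose left side is a finite double sum over the $(b, d)$ lattice and is
strictly decreasing in $p_\alpha$. `solve_p_alpha()` finds the unique root
by bisection to an absolute tolerance of `1e-10` on the expectation
(derivative-free, unconditionally convergent). In the large-sample limit
the equation inverts in closed form, $p_\alpha \approx S p_s (1-p_p) /
((N-S) p_p)$ for every $\beta$ (`p_alpha_approx()`); the exact root
converges to it as `N` grows, which the test suite checks at relative
error below 1%.

When `S` is very small the calibration can be infeasible — even
$p_\alpha = 0$ leaves the expected score below the target. This is raised
as an explicit, typed error rather than a clamped answer, because a design
whose target score is unreachable on average needs more positives, not a
silently adjusted rate.

## The exact distribution and its truncation

`score_pmf()` enumerates the lattice, groups cells by their exact score
value, and returns the sorted support with probabilities. Two numerical
choices matter:

* **Rational grouping.** Distinct cells can share a score exactly (with
  `S = 3`, `d = 1, b = 0` and `d = 2, b = 3` both give 1/2). Tail sums are
  wrong if such ties fail to merge, so support values are keyed by the
  reduced integer fraction $(1+\beta^2)d \,/\, (b+d+\beta^2 S)$ whenever
  $\beta$ is a ratio of small integers (covering the usual 0.5, 1, 2);
  otherwise grouping falls back to 12-decimal rounding. Differences of two
  scores are grouped at 12 decimals: genuinely distinct rational
  differences closer than $10^{-12}$ merge, costing at most $10^{-12}$ in
  any tail sum.
* **Tail truncation.** At `N` in the tens of thousands the full lattice is
  infeasible, but almost all of its mass sits in a small central window.
  Enumeration is restricted to binomial windows holding all but `1e-12` of
  the joint mass; the discarded mass is recorded in the distribution's
  `trunc_mass` and checked against the tail sizes actually used (interval
  construction re-enumerates with a tighter window in the — practically
  unreachable — case where a requested tail is not at least 100 times the
  truncated mass). This makes the 15,841-instance worked example exact at
  desk scale: its two score distributions have 534 and 11,496 mass points.

`brute_force_pmf()` recomputes the same distribution by the naive
untruncated scalar loop with string-keyed rational grouping, sharing no
code with the fast path; the suite requires the two to agree to `1e-12`
for every `S, M <= 12` and each supported $\beta$.

## Intervals

`ci_fbeta_one()` calibrates the distribution at the Jeffreys-style
corrected plug-ins $\tilde p_s = (d+0.5)/(S+1)$ and $\tilde p_p =
(d+0.5)/(b+d+1)$, with `b` replaced by 0.5 when `b = 0` — the posterior
means under Jeffreys priors, which stabilize small-sample coverage — and
reads an equal-tail interval off the support. The endpoint rule is driven
by one cdf vector: `L` is the largest support value with $F(L) \le
\alpha/2$ and `U` the smallest with $F(U) \ge 1-\alpha/2$. The
alternative reading, "smallest `u` whose upper tail mass is at most
$\alpha/2$", differs by at most one support point; the one-cdf rule is the
one that reproduces the published worked application on both of its arms,
and is what the package uses everywhere (including for differences). The
correction is applied to interval plug-ins only; tests and power use the
raw estimates or the user-specified design rates.

## Tests

The two-sided exact p-value uses the *minimum-tail* ordering of
extremeness: with null pmf $g$,

$$C(u) = \min\{P(f \le u),\, P(f \ge u)\}, \qquad
\mathrm{pv}(f_{obs}) = \sum_{f:\,C(f) \le C(f_{obs})} g(f).$$

Because the grouped rational support makes exact ties common, the
comparison carries an absolute tolerance of `1e-12` (configurable as
`tie_tol`). One-sided p-values are the plain tail sums. This p-value is
superuniform by construction, and the suite verifies size control by full
enumeration for every design up to `N = 20` on a grid of nulls.

For a benchmark null `H0: F_beta = F0` with no committed operating point,
the p-value is the supremum of the point-null p-value over the iso-F-beta
curve $\Theta(F_0)$. Solving the harmonic-mean identity for sensitivity
gives $p_s = \beta^2 F_0 p_p / ((1+\beta^2)p_p - F_0)$, and $p_s \le 1$
bounds the precision below by $F_0 / ((1+\beta^2) - \beta^2 F_0)$ (at
$\beta = 1$: $F_0/(2-F_0)$). The supremum is located on a precision grid
of step `grid_step` (default `1e-3`) with a local fine pass at
`refine_step` (default `1e-5`). A bracketing optimizer is deliberately
*not* used: the p-value is piecewise constant in $(p_s, p_p)$, so
golden-section-style reduction has no validity guarantee, while a fine
grid has a transparent resolution. Curve members whose target is
infeasible at the observed counts are skipped. By construction the
benchmark p-value dominates the point-null p-value at any curve member,
so rejecting the benchmark null is the harder task.

### Two classifiers

Both classifiers share one test set (`N`, `S` equal) and are assumed to
predict independently — correlated classifiers (e.g. one a refinement of
the other) violate the model and are out of scope; the convolution has no
covariance term. The difference distribution is the exact convolution of
one score distribution with the negation of the other. The pooled-null
test averages the raw per-arm plug-ins, places *both* margins of the null
difference distribution at the pooled rates (making it exactly symmetric
about zero), and applies the same minimum-tail machinery to the observed
difference. If neither arm has a true positive the pooled score is zero
and the test degenerates; it returns p-value 1 with a warning rather than
an undefined quantity.

The conservative two-classifier test takes a further supremum over
benchmark values. Searching all of $(0,1)$ is needlessly conservative, so
the benchmark range is restricted to the 2.5th–97.5th percentile window of
the pooled single-score distribution; candidates are that distribution's
support points inside the window plus a uniform grid. Each candidate runs
an inner curve supremum as above. The cost is quadratic in grid
resolution, which is why this test is intended for the small test sets
where conservatism actually matters.

## Power and sample size

Analytic power needs no simulation: the rejection region is the set of
null support points with p-value below $\alpha$ (computed for all points
in one pass from prefix sums of the ordered $C$ values), and power is the
alternative distribution's mass on that region. Alternative support points
absent from the (truncated) null support are assessed through the null cdf
directly, so truncation cannot misclassify extreme points.

Sample-size search sets `S = round(N * pI)` (half-up, at least 1) for a
user-supplied positive fraction `pI` and increases `N`. Discrete-test
power is a sawtooth in `N`, so the target must hold for `lookahead`
(default 3) consecutive increments; the search brackets by doubling,
bisects to the smallest guarded `N`, and then walks downward while the
guarded target still holds. Strict global minimality under an arbitrary
sawtooth is not guaranteed by any finite rule; the guarded local minimum
is reported together with its achieved power.

## Normal approximation and mode selection

Writing the score as $w(x, y) = (1+\beta^2)y/(x+y+\beta^2)$ with $x =
b/S$, $y = d/S$, the delta method gives mean $(1+\beta^2)p_s /
((N-S)p_\alpha/S + p_s + \beta^2)$ and a first-order variance from the
gradient of $w$ and the two binomial variances; difference surrogates
subtract means and add variances. In normal mode the whole procedure is
replaced by its continuous analogue — equal-tail quantiles for intervals,
$2\min(\Phi(z), 1-\Phi(z))$ for two-sided p-values — rather than
substituting the surrogate density into the discrete formulas; this is
the cleaner of the two readings and is recorded in every result's
`method` field.

Mode selection is automatic by mass-point count: `auto` stays exact up to
20,000 projected mass points for a single score (inclusive at the
boundary), and up to `conv_cap = 5e7` projected support pairs for a
difference convolution. The single-score threshold keeps every simulation
scenario in this package exact while letting truly large problems switch;
the convolution cap was chosen so that the reference two-classifier power
grid (support products around $10^7$) stays exact within about 1 GB of
transient memory, with the normal surrogate taking over beyond. Support
points carrying jointly less than `1e-13` of mass are pruned before
convolving (the pruned mass is added to `trunc_mass`). Forcing
`mode = "normal"` on a coarse discrete problem triggers a warning.

## The synthetic-data generator

`simulate_tables()` draws `d ~ Bin(S, ps)` and `b ~ Bin(N-S, p_alpha)`
with `p_alpha` calibrated exactly as the inference routines assume — the
generator states the model, it does not approximate data. A
`rate = "precision"` variant draws `b` at the closed-form large-sample
rate instead; the two coincide asymptotically, and both are exposed
because the reference simulation designs do not pin down which was used.
Scenario seeds are single integers; each named grid assigns consecutive
sub-seeds so any scenario can be reproduced in isolation. Replicates come
from one seeded stream per scenario.

What a green Monte-Carlo test establishes, therefore, is internal
consistency: that the interval/test machinery achieves its nominal
operating characteristics *under the stated binomial model*. It says
nothing about correlated predictions, instance clustering, or
distribution shift — data features the generator deliberately does not
emulate.

The coverage harness caches intervals by observed `(tp, fp)` (the
corrected plug-ins depend on nothing else), which makes 1000-replicate
runs interactive. The two-classifier power harness fixes the pooled null
at the scenario's generating averages instead of re-pooling the noisy
per-replicate estimates; this keeps per-replicate work to a vectorized
p-value lookup where re-estimation would cost a fresh multi-million-pair
convolution per table. The analytic-versus-empirical agreement checks in
the test suite are run under that convention.

## Degenerate and edge inputs

* `ps * pp = 0` gives score 0 by the limit convention; `ps = 0` yields a
  point mass at 0, `ps = 1, p_alpha = 0` a point mass at 1.
* A precision target of 0 with positive sensitivity cannot be calibrated
  and errors out.
* Intervals on a point-mass distribution collapse to that point; if no
  support point has lower-tail mass within $\alpha/2$, the interval is
  closed at the extreme support value.
* Counts are validated on construction (`0 < S < N`, `0 <= tp <= S`,
  `0 <= fp <= N - S`); violations raise typed validation errors, which the
  CLI maps to exit status 2 (infeasibility: 3).

## Known limitations

* Independence of the two classifiers' predictions is assumed; no
  paired-design covariance adjustment is provided.
* The benchmark-null supremum is grid-based; its resolution is the
  documented grid step, not machine precision.
* One-sided benchmark tests and benchmark-based power ("reject any
  operating point with this F-beta") are defined by the natural tail-sum
  and rejection-mass constructions and should be considered experimental;
  the two-sided point-null path is the validated core.
* No mid-p variants, no continuity corrections, and no multi-class
  (micro/macro-averaged) scores.
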