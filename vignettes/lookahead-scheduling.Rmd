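---
title: "Look-ahead scheduling for ABC-SMC: model, weighting, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Look-ahead scheduling for ABC-SMC: model, weighting, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The inference problem

Approximate Bayesian computation (ABC) targets models whose likelihood is
intractable but which can be simulated: draw parameters $\theta \sim \pi(\theta)$,
simulate data $y \sim \pi(y\mid\theta)$, and accept $\theta$ when
$d(y, y_{\mathrm{obs}}) \le \varepsilon$ for a distance $d$ and threshold
$\varepsilon > 0$. The accepted particles are a sample from

$$
\pi_{\mathrm{ABC},\varepsilon}(\theta \mid y_{\mathrm{obs}}) \propto
\int \mathbb{1}\!\left[d(y, y_{\mathrm{obs}}) \le \varepsilon\right]
\pi(y \mid \theta)\, \mathrm{d}y \cdot \pi(\theta),
$$

which converges to the true posterior as $\varepsilon \to 0$. The sequential
Monte Carlo variant (ABC-SMC) runs generations $t = 1, \dots, n_t$ with
strictly decreasing thresholds $\varepsilon_t$. Generation 1 samples from
the prior ($g_1 = \pi$); generation $t > 1$ samples from a proposal $g_t$
built from the previous weighted population — here a Gaussian kernel
mixture centered at the accepted particles. Each accepted particle carries
the importance weight $w_t(\theta) = \pi(\theta)/g_t(\theta)$, and posterior
expectations use the self-normalized estimator
$\hat f = \sum_i W_t^i f(\theta_t^i)$ with $W_t^i = w_t^i / \sum_j w_t^j$.
Weight imbalance is summarized by the effective sample size
$\mathrm{ESS}(w) = (\sum_i w_i)^2 / \sum_i w_i^2$.

Data are assumed to already be (or incorporate) summary statistics; summary
selection is out of scope.

## Scheduling strategies on a simulated worker pool

The computational cost of ABC is dominated by model simulations, which are
independent and therefore parallelize over $W$ workers. The package
implements three strategies against a *simulated* worker pool: every model
evaluation declares how many seconds it takes, and a discrete-event loop
advances a simulated clock. This makes wall-time and idle-time accounting
exact and runs bit-reproducible, so scheduling semantics are testable at
desk scale.

**Static scheduling (STAT).** Exactly $N$ tasks per generation, each
sampling until one acceptance; tasks queue when $N > W$, and at most $N$
workers are ever busy. Minimal compute, but workers idle increasingly
toward the end of a generation.

**Dynamic scheduling (DYN).** All workers sample continuously until $N$
particles are accepted, then in-flight simulations run to completion.
Taking the first $N$ *accepted* particles would favor parameters with fast
simulations; DYN therefore keeps, of all $\tilde N_{\mathrm{all}} \ge N$
accepted particles, the $N$ that *started* earliest. A particle's
acceptance then cannot depend on events after its launch, hence not on its
run-time. Ties on start time break deterministically by launch sequence
number.

**Look-ahead scheduling (LA).** DYN still leaves workers idle while
stragglers finish. LA fills that window: as soon as $N$ acceptances are
reached in generation $t-1$, a *preliminary* proposal $\tilde g_t$ is
built and freed workers immediately start sampling generation $t$ from it.
When the last generation-$(t-1)$ simulation finishes, the actual population
$P_{t-1}$ is finalized, the proper proposal $g_t$ is built, and all workers
switch to it. The generation-$t$ population is selected by the same
first-started rule over the union of both streams, giving

$$
P_t = \{(\tilde\theta_t^i, \tilde w_t^i)\}_{i \le \tilde N}
\cup \{(\theta_t^i, w_t^i)\}_{\tilde N < i \le N},
$$

with $\tilde w_t = \pi/\tilde g_t$ and $w_t = \pi/g_t$ — each subpopulation
is weighted by the Radon-Nikodym derivative with respect to the proposal it
was actually drawn from, so each is asymptotically unbiased on its own as
long as $\tilde g_t \gg \pi$ (automatic for Gaussian kernel mixtures, whose
density is positive everywhere).

Two variants differ in how $\tilde g_t$ is built:

* **LA Prel** uses the preliminary population $\hat P_{t-1}$ of the first
  $N$ acceptances (in finish order). Efficient, but when simulation time is
  parameter-dependent the early finishers over-represent fast-simulating
  regions, and the proposal can practically (in finite samples) miss slow
  modes entirely.
* **LA Past** reuses the previous proposal, $\tilde g_t = g_{t-1}$ (for
  $t = 2$, the prior). By induction it carries no run-time bias; it is the
  safe default.

Preliminary launches are capped at `prelim_cap_factor * N` per generation
(default 10), and preliminary sampling is suppressed when the run is
predicted to terminate after the current generation (last generation, or a
threshold floor already reached by the running distance quantile).

### Combining the two subpopulations

The weight functions $\tilde w_t$ and $w_t$ have different, unknown
normalization constants, so raw weights are not comparable across
subpopulations. Each subpopulation is therefore self-normalized separately
and the estimates mixed:

$$
\hat f = \beta \sum_{i \le \tilde N} \tilde W_t^i f(\tilde\theta_t^i)
+ (1 - \beta) \sum_{\tilde N < i \le N} W_t^i f(\theta_t^i),
\qquad \beta \in [0, 1].
$$

Choosing $\beta$ to maximize the ESS of the combined weight vector gives
the closed form

$$
\beta = \frac{\mathrm{ESS}(\tilde W)}{\mathrm{ESS}(\tilde W) + \mathrm{ESS}(W)},
$$

i.e. each subpopulation contributes in proportion to its effective sample
size; the package cross-checks this against a brute-force grid search in
its tests. $\beta = \tilde N / N$ (contribution proportional to counts) is
available as a config option. With $K$ subpopulations the rule generalizes
to $\beta_k \propto \mathrm{ESS}_k$; the package implements and documents
this proportional rule as its $K$-proposal extension. An empty
subpopulation has $\mathrm{ESS} = 0$ by convention, so the estimator
degrades exactly to the ordinary single-proposal case.

### Acceptance evaluation for preliminary samples

If the distance and $\varepsilon_t$ are pre-defined (fixed schedule),
preliminary samples are evaluated directly as they finish. If any component
is adaptive — e.g. $\varepsilon_t$ a quantile of the previous generation's
accepted distances — evaluation is *delayed* until $P_{t-1}$ is finalized,
so one common criterion applies to every particle of a generation. For
fixed schedules both modes give identical populations (asserted in the
tests); launch decisions never consult preliminary acceptance states, which
is what makes the two modes equivalent.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `population_size` $N$ | — | accepted particles per generation |
| `n_workers` $W$ | — | simulated parallel workers |
| `scale_factor` | 2 | kernel covariance = 2 × weighted sample covariance |
| `jitter` | 1e-10 | relative diagonal jitter on the kernel covariance |
| `prelim_cap_factor` | 10 | cap on preliminary launches per generation |
| `beta_rule` | `"ess"` | ESS-optimal vs count-proportional mixing |
| `selection` | `"first_started"` | `"first_finished"` kept only as a bias diagnostic |
| `q` | 0.5 | quantile for adaptive thresholds |
| `post_process_time` | 0 | simulated seconds of serial work between generations |

The kernel covariance is the previous generation's *weighted sample
covariance* (plain weighted second moment about the weighted mean, no
small-sample correction) scaled by 2 — the classic adaptive choice; the
exact kernel used in reference experiments is not printed anywhere, so this
is a documented package default. Perturbed draws falling outside the prior
support keep the proposal density exact: they are recorded with infinite
distance (prior mass zero, so they can never contribute), rather than
truncating or re-drawing.

## Built-in problems and what the generator does (not) emulate

**`t1` — bimodal, run-time-skewed.** $y = \theta^2 + \mathcal N(0, 0.1^2)$,
prior $\mathcal U(-2, 2)$, $y_{\mathrm{obs}} = 1$: modes at $\theta \approx \pm 1$.
Durations: log-normal with $(\mu, \sigma^2) = (1, 2)$ on the log scale for
$\theta > 0$, constant 0.1 s for $\theta \le 0$. The published description
of this duration law prints three arguments whose roles are ambiguous, so
both log-normal parameters are exposed as configuration. The duration
depends only on $\mathrm{sign}(\theta)$, making mode masses a sharp
diagnostic for run-time bias.

**`t2` — conversion reaction.** $x_1 \leftrightarrow x_2$ with rates
$(k_1, k_2)$, solved in closed form; both species observed at 10 time
points on $(0, 30]$ under multiplicative log-normal noise (log-sd 0.02);
Euclidean distance; uniform prior on $[0, 0.5]^2$; true rates
$(0.06, 0.08)$; observed data generated once at construction from the true
rates. Durations are parameter-independent log-normal sleep times; the
heterogeneity scenarios use $\sigma^2 \in \{1, 2, 4\}$ for the log-scale
variance (the package's reading of the published "variance" of the sleep
time). Time grid, noise level, prior bounds and true rates are documented
package choices, as the corresponding experimental values are not printed
in the main text of the literature this follows.

**`gauss` — exactly solvable toy.** Prior $\mathcal N(0, \tau^2)$, model
$y \sim \mathcal N(\theta, 1)$: the uniform-kernel ABC posterior at any
$\varepsilon$ is known up to quadrature, giving an independent oracle
(cross-checked in the tests against brute-force rejection sampling with
$2 \times 10^6$ draws).

The simulated backend reproduces scheduling semantics exactly, but
idealizes away everything a real cluster adds: network latency and task
serialization, heterogeneous or failing workers, and garbage-collection or
I/O jitter. Durations are *declared*, not measured, and the cost of
proposal construction and weighting is modeled only through the optional
`post_process_time` constant. Passing tests therefore validate the
algorithms (selection rules, weighting, unbiasedness, relative wall-time
ordering) — not absolute speed-ups on any particular hardware, which are
known to vary substantially.

## Threshold schedules

Fixed schedules are used for all strategy comparisons (identical
$\varepsilon_t$ across strategies makes wall-times and populations directly
comparable). The frozen per-problem defaults in
`default_epsilon_schedule()` were chosen once from each problem's
prior-predictive distance quantiles (roughly successive 30% reductions
starting near the median), giving practical acceptance rates across all
generations. The adaptive schedule takes $\varepsilon_t$ as the
median (type-7 linear interpolation, configurable $q$) of the previous
generation's accepted distances, calibrates $\varepsilon_1$ on a pilot
prior sample of size $N$, and guards strict decrease by shrinking to
$0.99\,\varepsilon_{t-1}$ if the quantile fails to decrease (degenerate
distance distributions).

## Numerical and design notes

* **Determinism.** All randomness flows through named substreams (prior,
  perturbation, simulator, durations, scheduler), so scheduler interleaving
  cannot perturb statistical draws; identical seed and config give
  byte-identical serialized output. Event processing and launch decisions
  are ordered by worker index and launch sequence number.
* **Lazy proposal construction.** $g_t$ is built on first use; a generation
  fully covered by preliminary samples never constructs its final mixture.
  This also keeps degenerate cases (e.g. $N = 1$ populations, whose kernel
  covariance is singular) runnable whenever the degenerate object is never
  actually needed.
* **Degenerate inputs.** Singular kernel covariance after jitter is an
  error; an all-zero weight vector has ESS 0; a subpopulation with no
  usable particles receives $\beta = 0$; non-finite distances from a
  simulation are rejected with a warning.
* **Discarded surplus.** Accepted particles beyond the first-started $N$
  are dropped, not recycled — no recycling rule is published, and recycling
  across proposals would complicate the weighting.
* **Problem sizes in the tests.** The test suite exercises the study
  conditions at desk scale: the Gaussian-toy correctness check uses
  $N = 500$, $W = 50$, 10 replicates per strategy; the run-time-bias checks
  use $N = W = 100$ (bias) and $N = 20$, $W = 200$ (preliminary-proposal
  bias) with 10 replicates; wall-time ordering uses $N = 32$,
  $W \in \{32, 128, 256\}$ with 20 matched-seed replicates; the
  preliminary-fraction trend uses $N \in \{64, 256, 1024\}$ at $W = 256$
  with 13 replicates, the replicate count used for scenario statistics in
  the literature this package follows.

## Known limitations

* The simulated backend is the only execution backend; the scheduler
  contract is written so a real multi-process backend could implement it,
  but none is shipped.
* Only shared-covariance Gaussian kernels are provided (no local or
  heavy-tailed kernels), and only the proportional $K$-proposal mixing
  rule.
* Adaptive distance functions and summary-statistic selection are not
  implemented; the delayed-evaluation hook is where they would attach.
* The preliminary-fraction trend across population sizes saturates in the
  regime $W \gg N$ (nearly all final-population particles originate from
  the preliminary proposal for both variants), so monotone decrease in $N$
  only emerges once $N$ is comparable to the number of preliminary
  acceptances a straggler window can produce.
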