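---
title: "The vectorized non-parametric bootstrap: model, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The vectorized non-parametric bootstrap: model, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vecboot)
```

## The multinomial-sampling formulation

The non-parametric bootstrap estimates the sampling distribution of a
statistic $\hat\theta = s(\mathbf{x})$ by drawing $B$ resamples of size $N$
with replacement from the observed data
$\mathbf{x} = (x_1, \dots, x_N)^t$ and re-evaluating $s$ on each. In a
matrix-oriented language the resampling loop is the expensive part, and it
can be eliminated for every statistic that is a function of sample moments.

Let $n_i^*$ count how often observation $i$ appears in a bootstrap sample.
The count vector is multinomial,
$$\mathbf{n}^* \sim \mathrm{Multinomial}(N,\; N^{-1}\mathbf{1}_N),$$
and for any transformation $f$ of the data,
$$\sum_{i=1}^N f(x_i^*) \;=\; \sum_{i=1}^N n_i^* f(x_i).$$
Dividing by $N$ and writing $w_i^* = n_i^*/N$, a bootstrap replication of a
weighted first moment is $\sum_i w_i^* f(x_i)$. Stacking the weight vectors
of all $B$ replications into an $N \times B$ matrix $W^*$ gives the whole
replication vector of the mean as a single product,
$$\hat\theta^* = \mathbf{x}^t W^*,$$
and any statistic built from several moments needs only one such product
per moment. `vecboot` implements exactly this: `draw_multinomial_weights()`
generates $W^*$, and `boot_first_moment()`, `boot_statistic()` and
`boot_correlation()` turn it into replication vectors.

For the Pearson correlation of $\mathbf{z}$ and $\mathbf{y}$ the five
moments are $\bar z, \bar y, \overline{z^2}, \overline{y^2},
\overline{zy}$, and the replication vector is evaluated in moment form,
$$\hat\theta^* = \frac{(\mathbf{z}\bullet\mathbf{y})^t W^* -
  (\mathbf{z}^t W^*)\bullet(\mathbf{y}^t W^*)}
 {\sqrt{[(\mathbf{z}^2)^t W^* - (\mathbf{z}^t W^*)^2] \bullet
        [(\mathbf{y}^2)^t W^* - (\mathbf{y}^t W^*)^2]}},$$
with $\bullet$ the elementwise (Hadamard) product. The centered two-pass
formula is *not* used on this path; it serves instead as the independent
cross-check in the test suite (see below).

A general statistic is declared with `statistic_spec()`: an ordered list of
transforms $f_1, \dots, f_m$ plus a combiner mapping the $m \times B$
moment matrix to the $B$ replications. The registered statistics are the
mean, the plug-in variance and standard deviation (denominator $N$,
matching the empirical distribution $\hat F$), and the Pearson correlation.
Statistics not expressible through weighted moments — medians, quantiles —
are out of scope by construction.

```{r example}
s <- simulate_paired_additive(15, seed = 1)
w <- draw_multinomial_weights(15, 10000, seed = 2)
boot_correlation(s$x, s$y, w)
```

## Weight schemes

Three sampling schemes share the `weight_matrix` container:

* **multinomial** — $w_i^* = n_i^*/N$; columns sum to exactly 1 and recover
  integer counts via `round(w * N)`. This is the classical bootstrap.
* **dirichlet** — columns drawn from $\mathrm{Dirichlet}(\mathbf{1}_N)$,
  the Bayesian bootstrap. Marginally each weight is
  $\mathrm{Beta}(1, N-1)$, with mean $1/N$ and variance
  $\tfrac{1}{N}(1-\tfrac1N)/(N+1)$ — slightly smoother than the multinomial
  weights, same first moment.
* **poisson** — i.i.d. Poisson(1) frequencies $p_i^*$, the approximate
  frequency bootstrap. Column totals are $\mathrm{Poisson}(N)$ rather than
  fixed at $N$, so frequencies are stored raw and the mean becomes the
  ratio estimator $\bar y^* = \sum_i p_i^* y_i / \sum_i p_i^*$
  (`poisson_boot_mean()`). A column can be entirely zero with probability
  $e^{-N}$; that replication is an empty bootstrap sample, and the ratio
  $0/0$ is reported as `NaN` rather than an error — at $N = 2$ roughly
  13.5% of columns are empty, and aborting a long run over an expected
  event would be wrong. Only the mean is implemented for this scheme; other
  ratio-form statistics would need their own estimators.

## Reproducibility and chunking

Every generator takes an explicit integer seed, recorded in the returned
object; the caller's RNG state is saved and restored. Generation proceeds
in column blocks of at most `chunk_size` matrix entries ($10^8$ by
default, about 0.8 GB of doubles) so that very large $N \times B$ problems
can stream through `vec_boot()` without materializing $W^*$.

Two implementation details make results *bitwise* invariant to the block
size. First, all blocks are drawn consecutively from a single seeded RNG
stream, and R's `rmultinom`, `rgamma` and `rpois` consume the stream
column-wise, so concatenated blocks equal a single draw. Second, the
moment products are computed as `colSums(W * v)` instead of a BLAS
matrix product: BLAS accumulates with width-dependent blocking, so the
same column can round differently inside matrices of different widths,
whereas `colSums` accumulates each column independently. The price is a
modest constant factor; the benefit is that `vec_boot(..., chunk_size =
anything)` is exactly reproducible.

## Numerical choices

* **Degenerate correlation replications.** A resample concentrated on a
  single point has zero weighted variance and no defined correlation. Both
  variables are scaled to unit maximum absolute value, and any replication
  with a weighted variance at or below $10^{-12}$ (absolute, on that
  scale) is set to `NaN`, counted in `nan_count`, and excluded from the
  standard error and interval. At small $N$ such columns occur with
  probability $\approx N^{1-N}$ per replication, which is far from
  negligible at $N \le 5$; erroring mid-run is therefore never acceptable.
  The threshold guards the moment-form denominator, a difference of
  products that loses precision near zero.
* **Variance clamping.** The moment form $M_2 - M_1^2$ can round to a tiny
  negative number for constant data; values in $(-10^{-12}, 0)$ are
  clamped to zero, anything more negative becomes `NaN`.
* **Percentile intervals.** Linear interpolation of order statistics
  (`quantile(type = 7)`), computed over finite replications only, at a
  user-chosen level in $(0,1)$. The bootstrap standard error uses
  denominator $B_{\text{finite}} - 1$. These summaries are conveniences of
  this package, not part of the vectorization itself; BCa or studentized
  intervals are deliberately out of scope.
* **Everything in double precision**; the moment parameterization is used
  exactly as written above, with the centered form reserved for oracles.

## Verification strategy

The test suite verifies the implementation against three independent
routes rather than against itself:

1. **Count-expansion identity.** For random instances
   ($N \in [2,30]$, $B \in [1,200]$), each vectorized replication is
   compared with the statistic evaluated classically (two-pass formulas,
   `stats::cor`) on the dataset expanded from the same counts by
   `counts_to_resample()`. Agreement is required to $10^{-10}$ relative.
2. **Exact enumeration.** `exhaustive_bootstrap()` enumerates all
   $\binom{2N-1}{N-1}$ count vectors with their multinomial probabilities
   (guarded at $N \le 8$; compositions in a fixed recursive order) and
   yields the exact bootstrap distribution. Monte-Carlo estimates at
   $B = 10^5$ must fall within 3 Monte-Carlo standard errors of the exact
   mean and SE. A subtlety worth recording: for $N = 2$ the bootstrap
   distribution of the mean is symmetric around its center with equal-size
   deviations, the leading term of the usual delta-method variance of a
   sample SD vanishes, and the exact finite-$B$ expression
   $m_4/B - m_2^2 (B-3)/(B(B-1))$ must be used to set the tolerance.
3. **The loop bootstrap.** `loop_bootstrap()` re-implements the classical
   resampling loop; the two-sample Kolmogorov–Smirnov distance between its
   correlation replications and the vectorized ones (independent seeds,
   $B = 10^5$) must stay below the 0.1%-level critical value.

Monte-Carlo tolerances are always computed from the relevant sampling
variance ($3$ MC SEs), never hard-coded.

## The synthetic data model

`simulate_paired_additive()` draws
$x_{1i} = \epsilon_{1i}$, $x_{2i} = x_{1i} + \epsilon_{2i}$ with
$\epsilon_{ji} \sim N(0,1)$, giving population correlation
$1/\sqrt{2} \approx 0.7071$; `simulate_custom_correlation()` generalizes
it to any $|\rho| < 1$ via the standard linear construction. These
generators emulate clean, complete, bivariate-normal data. They do not
emulate heavy tails, outliers, ties, missingness, or dependence between
observations — so a passing suite demonstrates the *algebraic* correctness
of the vectorization and the distributional equivalence of the routes, not
robustness of the bootstrap itself on messy real data. (The bootstrap's own
statistical limitations at small $N$ are inherited unchanged.)

## The timing harness

`run_method_grid()` compares the loop and vectorized implementations over
grids of $N$ and $B$ (default $N$ grid: 15 to 915 in steps of 100, ten
points), simulating fresh data per $N$ and timing with a monotonic clock;
each cell is repeated (default 3) after a discarded warm-up, and medians
are taken at report time. `run_component_split()` separates the time spent
drawing $W^*$ from the time spent on the matrix operations; weight
generation dominates as $N$ grows, which is why a plain loop eventually
catches up with the vectorized route at large $N$ while the vectorized
route wins decisively at small and moderate $N$. `write_bench_report()`
emits the raw CSV, a log-time-ratio figure with a reference line at zero
(below it the resampling method is faster), and the mapping from log
ratios to speed-up factors ($e^4 \approx 54.60$, $e^3 \approx 20.09$,
…). Timings are machine-dependent facts about the host: the package
reports them and asserts nothing about their values.

The test suite exercises the harness on reduced grids
($N \in \{15, 215\}$, $B \le 10^5$) chosen so the full suite runs in a few
minutes on one core; the harness itself accepts the full grids.

## Known limitations

* Statistics outside the weighted-moment form (quantiles, the median) are
  not expressible and not supported.
* The Poisson scheme implements only the mean; its approximation error at
  very small $N$ is visible (random sample size), though its finite-column
  mean agrees with the multinomial bootstrap within Monte-Carlo error.
* Exhaustive enumeration is combinatorial and capped at $N = 8$.
* Weight generation is the memory and time bottleneck for large $N$;
  parallel generation is out of scope here.
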