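---
title: "Distribution models for thresholded connectivity networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distribution models for thresholded connectivity networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rplnet)
```

## The problem

A functional connectome is summarised by a symmetric matrix of correlation
weights $w_{ij} \in [-1, 1]$ between brain regions. The topological network
at threshold $r_c$ keeps an edge wherever $|w_{ij}| > r_c$ (strictly), and
the per-node statistics of interest are the degree $k_i$ (edge count) and
the node strength $s_i = \sum_{j \ne i,\, |w_{ij}| > r_c} |w_{ij}|$.

Two competing ideas shape the expected distribution of these statistics.
Criticality predicts scale-free (power-law) behaviour; metabolic and
wiring constraints predict a finite upper limit on how connected a region
can be. `rplnet` implements the three candidate models this tension
suggests and the machinery to compare them on data:

* **plain power law** $P(x) = \frac{\alpha-1}{x_{min}}(x/x_{min})^{-\alpha}$
  on $[x_{min}, \infty)$, $\alpha > 1$ — pure scale-free behaviour;
* **exponentially truncated power law** $P(x) \propto x^{\alpha-1}
  e^{-x/x_c}$ on $[x_{min}, \infty)$ — a soft cut-off at scale $x_c$;
* **restricted power law** $P(x) = \frac{\gamma+1}{x_{max}-x_{min}}
  \left(\frac{x_{max}-x}{x_{max}-x_{min}}\right)^{\gamma}$ on
  $[x_{min}, x_{max}]$ — a power law in the distance to a *hard* upper
  bound, the model of scale-free statistics under an energy constraint.

A note on conventions: the truncated model is sometimes written with a
growing exponential $e^{x/x_c}$, which has no finite normalisation on an
unbounded support; `rplnet` implements the decaying form $e^{-x/x_c}$
throughout, the standard exponentially truncated power law.

## Fitting and model selection

All three models are fitted by maximum likelihood with the likelihood
handled entirely in log space — the raw product of densities underflows
double precision already around $N \approx 170$, the size of one
thresholded connectome sample.

* `fit_powerlaw()` uses the closed-form continuous MLE
  $\hat\alpha = 1 + N / \sum_i \ln(x_i / x_{min})$.
* `fit_truncated()` maximises over $(\alpha, \log x_c)$ with bounded
  quasi-Newton (`L-BFGS-B`) from five deterministic moment-based starts.
  The $\alpha$ box is wide ($[-5, 1000]$): noise-dominated degree samples
  are bump-shaped with $\alpha \approx \text{mean}^2/\text{var}$, which can
  exceed 50, and a tight box would handicap the model exactly where it
  should win. The normalising constant is the upper incomplete gamma
  $x_c^{\alpha} \Gamma(\alpha, x_{min}/x_c)$, evaluated through `pgamma`
  for $\alpha > 0$ and through the downward recurrence
  $\Gamma(s, a) = (\Gamma(s+1, a) - a^s e^{-a})/s$ in log space for
  $\alpha \le 0$.
* `fit_restricted()` maximises over $(\gamma, x_{max})$ subject to
  $x_{max} > \max(x)$ (lower box bound $\max(x)(1 + 10^{-6})$) and the
  upper box bound $100 \max(x)$; hitting the upper bound is reported as a
  flat-likelihood condition (the sample carries no information about a
  bound far beyond its maximum). Starting $\gamma$ values are
  moment-matched to each trial $x_{max}$ through the analytic mean.

In every model $x_{min}$ is plugged in as the sample minimum and not
counted as a free parameter, so $K = 1$ for the power law and $K = 2$ for
the other two — a symmetric treatment that keeps the comparison about
shape, not about support estimation. Zero values (unconnected nodes) are
removed before fitting, and fewer than 5 positive values is treated as
insufficient data. Degrees are fitted with the same continuous likelihood
as strengths.

Selection uses the small-sample-corrected AIC,
$AICc = -2\log L(\hat\theta) + 2K + 2K(K+1)/(N - K - 1)$; exact ties go to
the smaller $K$, then to the fixed order (powerlaw, truncated,
restricted). Across a collection, per-matrix statistics are computed
first and aggregated second (selection ratios; per-model mean AICc minus
the minimum of the three means), mirroring how heterogeneous multi-subject
collections are normally summarised.

## Graph metrics

`binarize()` applies the strict $|w_{ij}| > r_c$ rule (ties excluded), and
the summaries follow the standard definitions: global transitivity
$C = 3 \times \text{triangles} / \text{connected triples}$;
characteristic path length $\langle L \rangle$ over ordered pairs with
unreachable pairs substituted by $L_{ij} = N$, so fragmentation inflates
the average rather than disappearing from it; global efficiency
$E = \text{mean}(1/L_{ij})$ with the standard convention $1/L = 0$ for
unreachable pairs (the $1/N$ substitution variant is exposed through the
`unreachable` flag, since either convention is defensible and they differ
on fragmented networks); cost as the edge count, normalised per network by
$N(N-1)/2$ and per sweep by the maximum per-threshold mean cost. These are
computed with `igraph`; the test suite checks them against brute-force
triple enumeration and Floyd–Warshall oracles to $10^{-12}$.

## Quantile subsampling

To reduce noise before fitting, the sample is sorted by absolute value and
$n$ points are taken at the mid-quantile ranks
$i' = \mathrm{round}(d \cdot (2i-1)/2)$, $d = N/n$, i.e. at cumulative
positions $(2i-1)/(2n)$ — for $n = 10$: $0.05, 0.15, \dots, 0.95$.
Rounding is half-up and ranks are clamped to $[1, N]$, which makes
$n = N$ the exact identity selection. (An alternative step convention,
$d = N/(n+1)$, yields positions $\approx 0.14 \dots 0.95$ and is
inconsistent with the mid-quantile positions above; the mid-quantile form
is the one implemented.) Mid-quantile fitting discards the noise-dominated
extremes of the empirical CDF while preserving its shape, which is what
raises the bounded model's selection frequency on noisy collections.

## Cost-stability simulation

`simulate_strength_means()` draws strength collections by inverse-CDF
sampling (uniform sequence through the model's quantile function; the
restricted and plain power laws have closed-form inverses, the truncated
model inverts through its truncated-gamma representation) and records
replicate means; `delta_mean_strength()` compares the mean of means with a
reference. Because the mean strength is a proxy for network cost, the
spread of this difference measures how stably a fitted model predicts the
cost: the restricted model's hard bound caps every draw at $x_{max}$,
while the truncated model's unbounded tail admits occasional large
excursions. Both MLE fits track the sample mean on average (for the
truncated/gamma family the fitted mean matches the sample mean almost
exactly), so the stability difference is a variance effect, not a bias
effect — the package's paired test asserts the majority direction, not a
gap in means.

## The synthetic generator

`synthetic_config()` / `generate_connectivity()` emulate the statistical
structure the analysis assumes, not any particular acquisition pipeline:
each node gets a latent connectedness propensity $f_i$ (by default drawn
from the restricted law with $\gamma = 2.22$, $x_{min} = 0.546$,
$x_{max} = 33.5$, rescaled to $[0,1]$), raw pair weights are
$u_{ij} = f_i f_j + \varepsilon_{ij}$ with Gaussian noise of scale
`noise_sd` (default 0.05), a random 20% of pairs have their sign flipped
(so the absolute-value thresholding rule is exercised), and weights are
mapped through the saturating odd function
$w = \text{clip} \cdot \tanh(g \cdot u)$ with gain $g = 4$. The gain
positions the signal structure on the threshold scale: with $g = 4$ the
intermediate thresholds ($r_c \approx 0.2$–$0.45$) carry bounded
heavy-tailed degree/strength distributions, while heavy noise
(`noise_sd` $\approx 0.15$) dominates the low-threshold band — matching
the qualitative regimes a real sweep crosses. Matrices are exactly
symmetric with zero diagonal and entries strictly inside
$(-\text{clip}, \text{clip})$; per-matrix random streams are derived from
`(seed, index)`, so collections are reproducible and order-independent.

Defaults are desk-scale study stand-ins: 177 regions per matrix as in the
multi-subject resting-state corpus this kind of analysis targets, and 20
matrices per collection rather than a full near-thousand-subject corpus.

What the generator does *not* emulate: empirical weight marginals (the
marginal law of real correlation matrices is not part of the model and
was chosen only for its downstream behaviour), spatial/anatomical
structure, and modular fragmentation. The multiplicative propensity
construction produces a *nested* (core–periphery) graph whose
high-threshold remnant is a dense hub core with a soft degree cutoff —
real connectomes fragment into small modules instead. For this reason the
default family alone cannot produce a high-threshold band where the plain
power law wins, and the package ships a designed composite,
`generate_three_regime_collection()`: a restricted-propensity signal layer
capped at weight 0.6, a sparse Pareto-propensity layer occupying
$(0.6, 1)$, and noise of scale 0.1. On that family a degree sweep crosses
the full three-phase pattern — truncated wins the noise band
($r_c \approx 0.1$), restricted the signal band ($r_c \approx 0.35$), and
the plain power law the sparse band ($r_c \approx 0.7$). Consequently,
passing tests demonstrate the *machinery* (fitting, selection, sweeps,
noise reduction) under controlled conditions; they do not certify which
model real data select.

```{r three-regime, eval = FALSE}
coll <- generate_three_regime_collection(seed = 1)
comparison_sweep(coll, c(0.1, 0.35, 0.7), "degree")
```

## Numerical choices and degenerate inputs

* Matrices are validated once at ingestion (symmetry within $10^{-9}$,
  averaged symmetrisation, diagonal zeroed); file reading accepts
  whitespace- or comma-delimited square text with an optional label
  header, warns when it symmetrises, and raises classed parse errors
  otherwise.
* All-equal samples make the power-law MLE divergent and the restricted
  fit degenerate; both raise classed errors, and `compare_models()`
  excludes a failing model rather than failing the comparison.
* The truncated quantile function uses the truncated-gamma representation
  for $\alpha > 0$ and bracketed root-finding (absolute tolerance
  $10^{-10}$) otherwise.
* An empty network has zero cost; efficiency per cost returns `NaN` with
  a warning rather than dividing by zero.
* Test problem sizes are chosen to exercise the estimators at the scales
  the analysis actually meets: single-matrix samples of about 100–180
  values, recovery checks at $N = 5000$, selection-consistency checks at
  $N = 150$ with 200 replicates, and collections of 20 matrices of
  177 regions.

## Known limitations

* The restricted fit treats $x_{max}$ as an interior optimum of a smooth
  likelihood; for samples carrying no bound information the reported
  $x_{max}$ sits at the search bound and should be read as "unbounded",
  as flagged by the flat-likelihood note.
* Degrees are treated as continuous; at very small or heavily tied
  samples a discrete likelihood would differ.
* Selection ratios on synthetic collections depend on the generator's
  design (gain, noise scale, propensity law); they are qualitative
  regime indicators, not predictions of real-data percentages.
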