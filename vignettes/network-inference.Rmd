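---
title: "Causal network inference by subspace pursuit and Granger elimination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Causal network inference by subspace pursuit and Granger elimination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(caspian)
```

## The inference problem

Given expression time courses for $N$ genes measured in $E$ experiments
(experiment $j$ contributing $M_j$ ordered time-points), we want the directed
graph of regulatory influences: which genes' past expression predicts a target
gene's present expression, beyond what the other candidates already explain.
The package assumes first-order linear dynamics as its working model: the
target's expression at time $t$ is approximately a sparse linear combination
of other genes' expressions at times $t-1, \dots, t-D$. Sparsity is the
biological prior — a gene is regulated by few transcription factors — and is
what makes the problem solvable when time-points are scarcer than genes.

Inference proceeds per target gene $v$ in three stages.

**1. Lagged design construction** (`build_lagged_design`). For each retained
experiment (those with at least $D+1$ time-points) the target profile
$y$ stacks $x_v(t)$ for $t = D+1, \dots, M_j$, giving $M = \sum_j (M_j - D)$
rows. For every other gene $g$ and lag $d \in 1..D$, one column of the
sensing matrix $\Phi$ stacks $x_g(t-d)$ over the same rows, so
$\Phi$ has $(N-1)D + 1$ columns including an all-ones intercept. Rows never
mix experiments. Each stacked profile — every column and $y$ itself — is
centered and scaled to unit Euclidean norm, which removes per-gene offset and
scale (inference is invariant to positively rescaling any gene) and makes the
correlation ranking inside the sparse solver meaningful. The intercept column
is appended unnormalized to absorb any steady-state offset. The target's own
lagged profiles are excluded: autocorrelation would otherwise mask true
regulators, and selecting them would not evidence self-regulation — self-loops
are outside the edge universe of this method. Columns with zero variance
cannot be normalized; they are dropped with a warning, and a target whose own
stacked profile is constant is skipped (a constant profile carries no
information about its regulators).

**2. Sparse support recovery** (`subspace_pursuit`, `list_sp`). Subspace
Pursuit (SP) recovers an $s$-column support for $y$ in $\Phi$: initialize
with the $s$ columns of largest $|\Phi^\top y|$; each iteration adds the $s$
columns most correlated with the current residual, solves least squares on
the enlarged set ($\le 2s$ columns), keeps the $s$ columns of largest
coefficient magnitude, and re-solves. Iteration stops when the retained
residual norm fails to strictly decrease, or after 100 iterations — the cap
and the strict-decrease rule are implementation choices; in practice
convergence takes a handful of iterations. Correlation and magnitude ties
break toward the lowest column index so identical inputs always give
identical supports. Because the true in-degree is unknown, `list_sp` runs SP
at every sparsity level $s = 1..k$ and returns the union of the supports:
low-level supports are not always nested in high-level ones, and the union
trades extra false positives (removed in stage 3) for fewer false negatives.

**3. Granger elimination** (`granger_prune`). Let $S$ be the List-SP support.
The unrestricted model regresses $y$ on $\Phi_S$; for each candidate gene $g$
in $S$ the restricted model removes *all* of $g$'s lag-columns jointly (the
per-gene joint test; $\mathrm{df}_1$ = number of columns removed). With
$\mathrm{RSS}_r$, $\mathrm{RSS}_u$ the residual sums of squares, $p_u = |S|$,
$p_r = p_u - \mathrm{df}_1$ and $n = M$ rows,

$$F = \frac{(\mathrm{RSS}_r - \mathrm{RSS}_u) / (p_u - p_r)}
           {\mathrm{RSS}_u / (n - p_u)}$$

is compared with the upper-$\alpha$ quantile of $F(p_u - p_r,\; n - p_u)$;
genes exceeding it become in-edges of the target, signed by the sign of the
sum of their lag coefficients in the unrestricted fit. The intercept sits in
both models and is never tested. All least-squares solves use the SVD
pseudo-inverse with singular values below $10^{-10}$ of the largest treated
as zero, so duplicated or collinear profiles yield minimum-norm coefficients
rather than failures — and a candidate duplicated elsewhere in the support is
correctly found non-significant (its removal changes nothing).

*Degenerate perfect fit.* On noiseless data $\mathrm{RSS}_u$ can be zero to
machine precision and $F$ is undefined. The decision rule then becomes:
accept a candidate iff removing its columns raises the RSS above $10^{-10}$
(on unit-norm $y$). This preserves the test's intent — does the candidate
carry irreplaceable information? — where the F distribution does not apply.

## Parameters

* **`k`** (sparsity bound, default 5): a proxy upper bound on the maximum
  in-degree. A somewhat loose bound is safe because stage 3 prunes excess
  candidates; `k` must not exceed $\min(M, P)$, and violations are an error
  rather than a silent truncation so that under-determined configurations
  surface. The whole-network drivers report per-target failures in a
  `skipped` attribute instead of aborting.
* **`D`** (`lags`, default 1): maximum time-lag in sampling steps. Raising
  `D` multiplies the column count by $D$ and shortens profiles, so it should
  track the real regulatory delay relative to the sampling period.
* **`alpha`** (default 0.05): F-test significance level, the
  sensitivity/precision dial. Edge sets are nested in `alpha`: lowering it
  only removes edges. 0.001–0.05 is the useful range; precision-critical
  applications should sit at the low end. An off-by-default `bonferroni`
  flag divides `alpha` by the number of candidates tested per target.

## Scaffold priors

`caspian_with_scaffold` accepts a set of trusted directed edges. For a target
with known parents $K$, the known parents' lag-columns $\Phi_K$ are
partialled out of the problem: $y' = y - \Phi_K \Phi_K^{+} y$, and every
remaining column is likewise projected off the span of $\Phi_K$ and
re-normalized (columns falling entirely inside that span are dropped for
that target). Projecting both sides — not just $y$ — is deliberate: by the
standard partialling-out identity the reduced regression then equals the
full regression with the known parents' coefficients concentrated out.
Residualizing $y$ alone leaves components along the removed directions that
the remaining columns cannot represent; in development this inflated
residuals and produced spurious edges precisely when the prior was correct.
Scaffold edges are always emitted (provenance `"scaffold"`, signed by their
least-squares coefficients on the original $y$; sign 0 if the target's
design cannot be built), inferred additions carry provenance `"inferred"`.
A prior that shrinks the candidate set below `k` lowers the bound with it.
An empty scaffold reproduces `caspian_network` exactly. Note the contract:
wrong scaffold edges are trusted too, and appear in the output by
construction.

## The synthetic benchmark generator

`generate_network` draws degree-controlled random topologies: each gene's
parents arise from independent Bernoulli(`edge_prob`) trials, subsampled
uniformly when they exceed `max_in_degree`; weights are uniform in
$\pm[\text{low}, \text{high}]$; the matrix is rescaled so the spectral
radius of $|A|$ is 0.9, guaranteeing stable dynamics with geometric
convergence (0.9 is fast enough to converge yet slow enough to leave
informative transients). A hub-skewed preset adds a high-out-degree master
regulator. `simulate_expression` runs the deterministic recursion
$x(t) = A\,x(t-1) + b$ from independent uniform $[0,1]$ initial states per
experiment, with $b$ set so the fixed point is the drawn steady state
(uniform $[0.5, 1.5]$, a typical normalized expression scale), then adds
white Gaussian measurement noise with variance `noise_power_ratio` times the
mean squared clean signal. `subsample_timepoints` emulates coarser uniform
sampling (every $\mathrm{round}(1/f)$-th point) or irregular sampling (a
random subset, later treated as consecutive steps — exactly the distortion
irregular designs inflict on lag-based methods).

What this emulates: linear lagged dependence, steady-state convergence,
controlled in-degree, measurement (not process) noise, multi-experiment
concatenation. What it does not: nonlinear Hill kinetics, mRNA/protein
two-layer dynamics, process noise, cell-cycle periodicity, or realistic
microarray error models. Passing the simulation benchmarks therefore
demonstrates correctness of the pipeline under its own working model, not
performance on real biology.

Two consequences of the *deterministic* dynamics are worth knowing. First,
in the under-sampled regime ($M < N$), when List-SP misses one true parent
the unexplained residual is tiny but genuine, so every surviving support
gene tests as overwhelmingly significant and precision drops for that
target; measured over 20 seeds at $N=50$, $M=30$, mean precision sits near
0.7 (versus ~0.26 for unpruned List-SP). Second, uniformly keeping every
2nd time-point of a deterministic lag-1 process yields data exactly linear
in $A^2$ — whose support, the 2-step paths, is nearly disjoint from the
direct edges since $A$ has a zero diagonal — so uniform subsampling scores
*worse* against the 1-step truth than irregular subsampling, which at least
leaves 1-step transitions in the data. Both behaviors are properties of the
noise-free linear test-bed, and both would soften under process noise or
slower (self-decaying) dynamics.

## Evaluation

`confusion` counts edges over the ordered-pair universe excluding self-loops
(sign-blind, with sign agreement reported separately over signed true
positives), `network_metrics` derives sensitivity, precision, accuracy and
F-measure with explicit `NA` markers for zero denominators.
`multiplicity_ratio` scores confidence over repeated randomized runs
(`random_panel_runs`: core genes plus a fresh random panel per run, edges
reported among core genes); the denominator is always the total number of
runs, including runs that lacked an edge's endpoints, so MR = 1 means
recovered by every single run.

## Problem sizes used by the test suite

The packaged checks run 20-seed batches per regime: a well-sampled regime
($N=20$ genes, 3 experiments x 21 time-points, so $M=60$ rows, noiseless,
$\alpha=0.01$), an under-sampled regime ($N=50$, 3 x 11, $M=30$), a noisy
regime (noise power ratio 0.1 at $\alpha \in \{0.001, 0.05\}$), subsampled
variants (keep fraction 0.5), and scaffold-assisted runs with up to 3 true
prior edges. Mean in-degree is set to 2 (`edge_prob = 2/(N-1)`, cap 3) —
typical of the sparse regulatory networks this method targets. Sparse
recovery is verified against exhaustive subset search on 12 x 16 instances,
and F-test calibration against 5000 null regressions at $n = 60$. These
sizes keep the full suite under a few minutes while leaving Monte-Carlo
error well below the asserted margins.

## Known limitations

* Lag structure must be meaningful: the method treats consecutive columns as
  one sampling period apart, so irregularly sampled data violate the model
  (see above) and missing values are rejected rather than imputed.
* No multiple-testing correction across targets by default; the per-target
  Bonferroni flag is the only built-in adjustment.
* Granger significance on near-perfectly predictable (noise-free) data
  converts any support-recovery miss into multiple confident false
  positives; interpret edge F-statistics with that in mind when residuals
  are tiny.
* Self-loops are unidentifiable by construction and excluded everywhere.
* The stationarity-style assumption that one network generates all
  experiments is the user's responsibility; concatenating experiments that
  engage different regulatory programs will blur both.
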