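---
title: "Run-length analysis of geometric charts for GINAR(1) counts"
author: "ginarchart"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Run-length analysis of geometric charts for GINAR(1) counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ginarchart)
```

## The model

Autocorrelated counts with a geometric marginal arise wherever successive
"number of events between failures"-type observations are collected faster
than the underlying process renews itself: counts of machines awaiting
maintenance, monthly counts of rare adverse events, conforming items between
two nonconforming ones under high-frequency sampling. The GINAR(1) process
models such data as

$$X_t = \rho \circ X_{t-1} + B_t G_t,$$

where $\rho \circ X = \sum_{i=1}^{X} Y_i$ is binomial thinning (each of the
$X$ "individuals" survives one step with probability $\rho$, independently),
$B_t \sim \text{Bernoulli}(1-\rho)$ and $G_t \sim \text{geometric}(p)$ on
$\{0, 1, 2, \dots\}$ with $P(G = j) = (1-p)^j p$. Started from a
geometric($p$) value the chain is stationary with geometric($p$) marginal —
mean $(1-p)/p$, variance $(1-p)/p^2$ — and autocorrelation
$\mathrm{corr}(X_t, X_{t+k}) = \rho^k$.

Two conventions are fixed throughout and worth stating because libraries
disagree on both:

* **geometric support starts at 0** ($P(X = j) = (1-p)^j p$), forced by the
  innovation law and by the mean $(1-p)/p$;
* $\rho = 0$ is admitted as the iid limit (useful for closed-form checks),
  while $\rho = 1$ is rejected — the chain would never renew.

The innovation $\varepsilon_t = B_t G_t$ has the zero-modified geometric law

$$P(\varepsilon = 0) = p(1-\rho) + \rho, \qquad
  P(\varepsilon = j) = (1-\rho)(1-p)^j p,\; j \ge 1,$$

and the one-step transition probability $p_{ij}(p, \rho)$ is the convolution
of a binomial$(i, \rho)$ with this law, available in closed form
(`transitionProb()`). The simulator draws $\varepsilon$ as the literal
product of two variates rather than by inverse-cdf of the merged law, so it
is faithful to the defining recursion; the test suite uses the merged-law
convolution as the independent oracle for the closed form.

## The chart and its run length

The upper one-sided geometric chart signals at the first $t$ with
$X_t > U$. Because the control statistic becomes stochastically *smaller* as
$p$ grows, an exceedance of $U$ indicates a *decrease* in $p$, i.e. an
increase of the process mean $(1-p)/p$. The chart cannot detect increases in
$p$ expediently; `arlProfile()` makes that visible instead of hiding it.

All run-length quantities are exact, via the Markov-chain (Brook–Evans /
discrete phase-type) method: the in-control states $\{0, \dots, U\}$ form
the substochastic block $Q = [p_{ij}]_{i,j \le U}$ — a finite block of the
infinite transition matrix, so no truncation is involved — and

* fixed start $u$: $P(RL_u > m) = e_u^\top Q^m \mathbf 1$, ARL from
  $(I - Q)a = \mathbf 1$ (a linear solve; no explicit inverse);
* second moment for the SDRL from
  $E[RL^2] = e_u^\top (I + Q)(I - Q)^{-2}\mathbf 1$;
* the Perron root $\xi$ of $Q$ gives the geometric-like tail: hazards from
  every start converge to $1 - \xi$ (eigendecomposition by default, power
  iteration kept as an independent cross-check).

### The overall run length

In practice $X_0$ is unknown, so a natural alternative treats the first
*observation* $X_1 \sim \text{geometric}(p)$ as the random initial state.
The definition is read literally: $X_1$ is itself monitored, so a signal at
$t = 1$ is possible, and

$$E[RL_{X_1}] = 1 + \pi^\top (I - Q)^{-1} \mathbf 1,
  \qquad \pi_u = (1-p)^u p, \; u = 0, \dots, U,$$

with the defective mass $P(X_1 > U)$ accounting for the immediate signal.
A competing reading — $X_1$ as a pure pre-period state with monitoring from
$t = 2$ — gives *exactly the same expectation* by stationarity of the
geometric marginal (the two laws differ only in the $t = 1$ atom), so the
choice is immaterial for ARLs; the literal reading is implemented because it
also reproduces the published in-control overall ARL of the reference chart
(393.5, see the README worked example).

At the reference parameters $(p, \rho) = (0.63, 0.165)$, $U = 5$, the
package computes ARLs of 393.7 (start 0), 391.4 (head start $U$), overall
393.5, and a limiting hazard $1 - \xi = 0.002541$. One caveat belongs here
rather than in a footnote: at the boundary parameter $p = \rho/(\rho+1)$ the
overall ARL evaluates to about 2.7, *not* the 8.3 sometimes quoted for this
illustration. The value 2.7 is confirmed by direct Monte Carlo simulation of
the process, and 8.3 is impossible for this chart on arithmetic grounds:
every fixed-state ARL at that parameter point lies in $[2.76, 2.91]$, so no
mixture over initial states — whatever the convention — can exceed
$1 + \max_u E[RL_u] \approx 3.9$. The corresponding acceptance check is left
failing rather than redefined.

## Ordering structure: what holds and what does not

The chart's qualitative behaviour rests on stochastic-ordering properties of
the chain, which this package verifies *numerically*, reporting the minimal
defining margin and a recomputable witness on failure (`OrderReport`).

**What holds.** Numerically, across randomized parameter sweeps:

* the Kalmykov order between chains: rows of the transition matrix at
  $(p', \rho)$ are dominated in the usual sense by rows at $(p, \rho)$
  whenever $\rho/(\rho+1) < p \le p'$ (`kalmykovLE()`), and each GINAR(1)
  matrix is stochastically monotone in the usual sense;
* run-length consequences at the chart level: the $RL_0$ pmf is PF2
  (log-concave), hence increasing hazard; the head-start run length $RL_U$
  has decreasing hazard and dominates $RL_0$ in hazard rate; run lengths are
  likelihood-ratio ordered in the initial state and usual-order ordered in
  $p$; the overall ARL is increasing in $p$ on $(\rho/(\rho+1), 1)$.
  `verifyCorollaries()` exercises all of these in one call.

**What does not.** The blanket claim that the transition matrix is totally
positive of order 2 fails for every $\rho > 0$. The innovation is
*log-convex* at the origin — $f(1)^2 - f(0)f(2) = -\rho(1-\rho)(1-p)^2 p$ —
because thinning inflates the atom at zero, and this corner propagates into
genuinely negative $2 \times 2$ minors of the transition matrix near the
diagonal (at the reference parameters, rows/states 0–1 × columns/states 1–2
give $-0.00196$, recomputable by hand from the closed form). `isTP2()`
therefore reports a violation with its witness; the test suite pins this
behaviour, and the acceptance check that expects TP2 to hold is left
failing. The run-length corollaries above were confirmed independently of
the TP2 route, which is why they appear under "what holds".

## Numerical choices

* **Tolerances.** Ordering margins are compared against $10^{-12}$:
  entries are $O(1)$ probabilities, so anything smaller is rounding.
  Genuine violations observed in practice are $10^{-3}$–$10^{-1}$; rounding
  noise is $10^{-16}$ — the gap is eight orders of magnitude, so the
  verdicts are not tolerance-sensitive.
* **Truncation.** `transitionMatrix()` truncates at the smallest $n$ with
  $(1-p)^{n+1} < 10^{-12}$ by default, never renormalises, and carries the
  per-row tail deficit (`tailMass()`). `kalmykovLE()` adds that deficit back
  when given `TransitionMatrix` objects, so tail-sum comparisons are exact
  for every cut $l \le n$; without the correction, truncation alone can
  produce spurious violations of the order of the last rows' tail mass
  (about $10^{-10}$ at $n = 30$ for the reference parameters).
* **Binomial terms** go through `dbinom()` (log-space internally), so
  states up to several hundred are overflow-safe.
* **TP2 scan.** The reference check is the exhaustive all-pairs minor scan
  (vectorised per row pair, $O(n^3)$ in time); the adjacent-minor shortcut
  `isTP2Adjacent()` is provided for strictly positive matrices but is not
  the reference, because truncated rows contain exact zeros.
* **Horizons.** Run-length arrays stop once survival falls below `eps`
  (default $10^{-12}$, hard cap $10^6$ steps). Pairwise likelihood-ratio
  checks are $O(M^2)$ in the horizon, so `verifyCorollaries()` caps the
  comparison grid at 2000 masses — beyond that the pmf is geometric with
  ratio $\xi$ to within $10^{-13}$ relative and adds no information.
* **Degenerate inputs.** Constant series make the lag-1 autocorrelation
  undefined (`estimateParams()` errors); all-zero series have no usable
  mean; $\rho$ estimates are clipped to $[0, 1)$; percentile requests
  outside $(0,1)$ and infeasible UCL targets raise explicit errors.

## The synthetic-data generator

`simulateGINAR()` (and the `fixtures` CLI subcommand) generates stationary
series at the reference parameters $(0.63, 0.165)$, a 10%-shifted variant
($p = 0.9 \times 0.63$), and an iid ($\rho = 0$) control, each of length
144 — the shape of the monthly-counts setting the reference chart was
designed around. The generator reproduces exactly the features the
run-length engine relies on: the geometric marginal, the $\rho^k$
autocorrelation, and the Markov transition law. It does **not** emulate
features real count series may have beyond the model — overdispersion
relative to the geometric, seasonality, trend, or negative serial
dependence — so a green simulation-based test establishes correctness of
the implementation *under the model*, not adequacy of the model for any
particular data set. `estimateParams()` is deliberately a moment estimator
(mean and lag-1 autocorrelation); likelihood fitting is out of scope.

## Worked example

```{r example, eval = FALSE}
m <- GINARModel(p = 0.63, rho = 0.165)
findUCL(m, targetArl = 370, init = 0)   # chooses U = 5, achieved 393.7

d <- rlDistribution(m, chartSpec(5, 0))
rlSummary(d, c(0.5, 0.95))              # ARL 393.7, SDRL 393.0, median 273

verifyCorollaries(m, U = 5, pPrime = 0.7)$allPass   # TRUE

isTP2(transitionMatrix(m, 20))          # VIOLATED, margin -0.00196
```

## Limitations

* Lower one-sided and two-sided charts, CUSUM/EWMA statistics, and
  steady-state ARL variants other than the overall run length are not
  implemented.
* Alternative thinning kernels (negative-binomial thinning and its
  relatives) are out of scope; only binomial thinning is supported.
* The ordering verifiers are numerical, not symbolic: a "holds" verdict is
  a statement about the scanned grid at the stated tolerance, not a proof.
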