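---
title: "Expected allele frequency spectra by coalescent time rescaling"
author: "coalafs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Expected allele frequency spectra by coalescent time rescaling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coalafs)
```

## The model

The allele frequency spectrum (AFS) of a sample of $n$ haplotypes is the
vector $S_j$, $j = 1, \dots, n-1$, counting segregating sites with $j$ copies
of the derived allele.  Under the infinitely-many-sites model the expected
spectrum is a linear functional of the genealogy's expected intercoalescence
times $E[W_k]$ (the duration during which exactly $k$ ancestral lineages
exist):

$$
E[S_j] \;=\; \sum_{k=2}^{n}
\frac{\binom{n-j-1}{k-2}}{\binom{n-1}{k-1}} \,\mu\, k\, E[W_k],
$$

where $\mu$ is the per-generation, **per-locus** mutation rate (multiply a
per-site rate by the locus length).  Everything therefore reduces to the
expected coalescence times $E[T_m]$, $T_m$ being the backward time at which
$m+1$ lineages merge into $m$, with $W_k = T_{k-1} - T_k$ and $T_n \equiv 0$.

For a haploid population size $N(t)$ varying in backward time $t$, the
coalescent is an inhomogeneous Markov process that becomes the standard
Kingman coalescent after rescaling time by

$$
g(t) = \int_0^t \frac{du}{N(u)},
$$

so the scaled times $\tau_m = g(T_m)$ have the classical expectations
$\mu_m = 2(1/m - 1/n)$ and variances
$\sigma_m^2 = \sum_{k=m+1}^{n} 4/k^2(k-1)^2$.  A first-order Taylor
expansion of $g^{-1}$ about $\mu_m$ gives the point approximations used
throughout:

$$
E[T_m] \approx g^{-1}(\mu_m), \qquad
\operatorname{Var}[T_m] \approx \sigma_m^2 \, N\!\big(g^{-1}(\mu_m)\big)^2 .
$$

Computing an AFS under an arbitrary $N(t)$ is thus the problem of inverting
the monotone function $g$ at $n-1$ points.

## Demographic families

All sizes are **haploid** (numbers of sequences); the CLI's `--diploid` flag
doubles user-supplied census sizes on input.  Backward time is measured in
generations with $t = 0$ the present.

* **constant** — $N(t) = N_0$.
* **exponential** — $N(t) = N_0 e^{-\gamma t}$, growth rate $\gamma$ per
  generation.
* **logistic** — growth from a founding size of one sequence, `onset`
  generations ago, towards carrying capacity $N_k$ with intrinsic rate
  $\gamma$; backward form
  $N(t) = N_k e^{\gamma T} / \big(e^{\gamma T} + (N_k - 1) e^{\gamma t}\big)$
  with $T$ = `onset`.  Evaluation uses the algebraically identical
  $N_k / \big(1 + (N_k-1)e^{\gamma (t-T)}\big)$, which does not overflow for
  large $\gamma T$.
* **gompertz** — per-capita growth rate decaying exponentially from $\gamma$
  at rate $\alpha$; the backward form is obtained by substituting forward
  time $T - t$ into the forward solution:
  $N(t) = N_0 \exp\!\big(\tfrac{\gamma}{\alpha}(1 - e^{-\alpha (T - t)})\big)$.
* **piecewise** — right-continuous step function; the last size extends
  indefinitely.

Beyond the onset the logistic and Gompertz formulas keep decaying below one
sequence.  This is deliberate: it follows the analytic forms verbatim and
guarantees that $g$ diverges, i.e. that every lineage pair eventually
coalesces.  Users who prefer a constant ancestral size can set `size_floor`,
which clamps $N(t)$ from below and is documented as a departure from the
analytic treatment (closed-form paths refuse floored models and the code
falls back to quadrature).

The logistic time scale and its inverse are not taken from any printed
transcription: both were re-derived here.  Integrating $1/N$ gives

$$
g(t) = \frac{(N_k - 1)e^{-\gamma T}\big(e^{\gamma t} - 1\big) + \gamma t}
            {N_k \gamma},
$$

verified in the tests against adaptive quadrature to $10^{-9}$ relative.
Solving $\gamma t + A e^{\gamma t} = B$ with $A = (N_k-1)e^{-\gamma T}$ and
$B = A + N_k \gamma \tau$ yields the principal-branch Lambert-W inverse

$$
g^{-1}(\tau) = \frac{B - W_0\!\big(A e^{B}\big)}{\gamma},
$$

validated against bracketed root-finding to $10^{-8}$ relative over a
parameter grid.  Because $B$ can exceed 700 (where $e^B$ overflows), $W_0$
is evaluated from the log of its argument by solving $w + \log w = z$ with
safeguarded Newton iterations.

## Inversion schemes

Three interchangeable schemes invert $g$:

1. **finite_sum** — a single-pass generation-stepping scan.  The integral is
   replaced by the left-endpoint sum $\sum_{u=0}^{t} \text{step}/N(u)$
   (initialised at $\text{step}/N(0)$), and the scan advances once, consuming
   the targets $\mu_{n-1} < \dots < \mu_1$ in ascending order.  When the
   accumulator $G$ first reaches a target, the classic boundary rule returns
   the current step $t$ whenever $G - \mu$ is smaller than the last increment
   — which is always true with exact arithmetic, since the final increment is
   exactly $\text{step}/N(t)$; the `t - step` branch is retained purely as
   floating-point protection, and an alternative `nearest` rule is offered.
   Because the scan never rewinds, its cost is governed by the largest target
   alone, not by $n$: this is what makes large-sample spectra cheap, and the
   property is asserted by counting $N(t)$ evaluations.
2. **root** — bracketed root-finding on $g$ ($g$ analytic where available,
   otherwise quadrature): geometric bracket expansion doubling from the
   initial guess $N(0)\mu$ (capped at `max_time`), Brent's hybrid
   bisection/interpolation step, then Newton polish using $g'(t) = 1/N(t)$
   until $|g(t) - \mu| \le \text{tol} \cdot \max(1, \mu)$ (default
   $10^{-10}$).
3. **analytic** — closed forms: $N_0\mu$ (constant),
   $\log(1 + N_0\gamma\mu)/\gamma$ (exponential, via `log1p` so the
   small-$\gamma$ limit degrades gracefully to $N_0\mu$), and the Lambert-W
   form above (logistic).

Where no closed form exists (Gompertz, floored or piecewise histories used by
the root scheme and the Monte-Carlo sampler), $g$ is evaluated by a cached
cumulative composite 5-point Gauss–Legendre rule on unit-generation panels —
effectively exact for the smooth reciprocals that occur here — extended
lazily into the past.  Reciprocal sizes that overflow (a collapsing history
whose size underflows to zero deep in the past) are clamped to $10^{12}$ per
generation; any realistic target ($\mu < 2\log n$) is reached long before the
clamp could bias a result.  For piecewise histories both $g$ and $g^{-1}$ are
computed exactly from the epoch sums.

### Numerical choices and degenerate inputs

* Default `step` is one generation, the natural unit of the discrete
  derivation.  When the scan meets sizes below 100 with `step >= 1`, a
  warning recommends a sub-generation step, because one step's mass
  $\text{step}/N$ then resolves the target only coarsely.
* The scan (and bracket expansion) abort with a *non-coalescing-history*
  error when `max_time` (default $10^8$ generations) passes without reaching
  the target — the signature of a history too large into the past.
* Adjacent levels can land on the same generation grid point at large $n$
  (e.g. $\mu_{499} \approx 8\times 10^{-6}$ is under one generation for
  $N_0 = 10^5$).  Intercoalescence times therefore tolerate ties (giving
  $E[W_k] = 0$) and reject only increases, which would indicate a broken
  inversion.
* Spectrum combinatorics use log-gamma differences everywhere; structurally
  zero probabilities short-circuit to exact zeros before exponentiation.
  The algebraically equivalent front-factor rearrangement of the spectrum
  sum overflows double precision already near $n \approx 180$ and is used
  only as a small-$n$ test oracle.  The implemented path is validated to be
  finite and within $10^{-8}$ relative of the exact $\theta/j$ law at
  $n = 2000$.

## The Monte-Carlo oracle

`estimate_afs_mc()` draws the scaled epochs of the standard coalescent
(exponentials with rates $k(k-1)/2$), maps each accumulated $\tau_m$ to
generations through the numerical inverse of $g$ (tolerance $10^{-8}$
relative), and summarises means and standard errors across replicates.
Spectrum entries are Rao-Blackwellised: the mutation mixture is evaluated
analytically on each replicate's $W_k$, so no mutation-placement noise
enters and the standard errors reflect genealogical noise only.  The
generator is R's Mersenne-Twister with an explicit seed recorded in the
result; the caller's RNG state is restored afterwards.

The oracle deliberately measures a different quantity than the point
approximation: the MC mean estimates $E[g^{-1}(\tau_m)]$, whereas the
first-order value is $g^{-1}(E[\tau_m])$.  The test suite validates each
against its own target and never mixes tolerances: the sampler is checked
against an exact computation of $E[g^{-1}(\tau_m)]$ (quadrature over the
hypoexponential density of $\tau_m$, expanded in partial fractions), and the
gap between the two quantities is characterised separately.  On steep
sigmoid histories that gap is real and not small everywhere: for the
logistic setting ($N_k = 10^4$, onset 5000, $\gamma = 0.003$) at $n = 10$
the first-order times sit above the MC mean by up to $\approx 9\%$ at
intermediate levels (where $g^{-1}$ is most convex across the growth ramp),
while the tree depth $E[T_1]$ is within $\approx 2.5\%$ and constant-size
histories are exact.  Spectra built from the first-order times inherit a
correspondingly modest distortion; the package's accuracy claims about the
*finite-sum scan* (below) are unaffected, since both spectra being compared
use the same estimator.

## What the tests do and do not show

The synthetic settings exercised by the test-suite and the acceptance script
are the published study conditions: logistic histories with carrying
capacity $10^4$, onset 5000 generations and rates
$\gamma \in \{0.003, 0.006, 0.015\}$ (sampled at $n = 51$ for a 50-entry
AFS); exponential growth with $N_0 = 10^5$, $\gamma = 0.003$ at
$n \in \{10, 50, 100, 500\}$; a Gompertz history with $N_0 = 1$,
$\gamma = 0.01$, $\alpha = 0.001$, onset 5000; and constant sizes up to
$n = 2000$.  Monte-Carlo checks use $10{,}000$ seeded replicates at
$n = 10$ — enough to resolve 1% effects in per-level means at these
variances while keeping the default suite fast.

These are single-locus, neutral, panmictic, infinite-sites expectations.
Passing tests demonstrate that the numerical machinery reproduces the
analytic theory under those assumptions; they say nothing about
recombination, selection, population structure, finite-sites saturation, or
sampling noise in real SNP counts (the expected spectrum is a vector of
Poisson means, not a simulated data set).

## Design notes

* Targets are always consumed in ascending scaled-time order internally,
  whatever order the caller supplies levels in; outputs are reported for
  $m = 1, \dots, n-1$ and $k = 2, \dots, n$ with explicit labels.
* $\sigma_m^2$ is assembled from the standard epoch variances; its
  correctness is pinned by the constant-size case, where the first-order
  machinery is exact and $\operatorname{Var}[T_1] = N^2$ for $n = 2$.
* The variance composition evaluates $g'$ at the first-order mean, not at
  any MC mean.
* The CLI is a thin wrapper (`exec/coalafs`) over `run_cli()`; every output
  is a headered TSV with 12-significant-digit numbers, making reruns with
  identical configuration byte-identical.
* Config files may be YAML or JSON with one schema.  YAML 1.1 would resolve
  the bare key `n` to a boolean; the reader installs identity handlers so
  the documented keys always arrive literally.

## A worked check

```{r}
m <- logistic_growth(Nk = 1e4, gamma = 0.003, onset = 5000)
analytic <- expected_afs(m, n = 51, mutation_rate = 1e-3, method = "analytic")
approx1  <- expected_afs(m, n = 51, mutation_rate = 1e-3, method = "finite_sum")
max(abs(log(approx1$counts / analytic$counts)))
```

The worst log-ratio between the generation-stepping scan and the Lambert-W
closed form stays near $10^{-3}$, an order of magnitude inside the
$\pm 0.02$ band the method is expected to hold.

## Known limitations

* Single population only: no migration, splits, or joint spectra.
* First-order point times only; no higher Taylor terms, no marginal
  densities of $T_m$, no covariances between levels.
* Folded spectra and inference (likelihoods over the Poisson field) are out
  of scope; the output is the expectation itself.
* The finite-sum scan's accuracy is bounded by one step's mass $1/N$ near
  small sizes; use a finer `step` (at a linear cost in scan length) when a
  history spends many of the targeted generations below $N \approx 100$.
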