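---
title: "Testing for crossover and gene conversion from population haplotypes"
author: "meiotest"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing for crossover and gene conversion from population haplotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meiotest)
```

## The scientific problem

Meiotic recombination leaves two distinct footprints in population SNP data:
*crossovers*, which exchange whole chromosome arms and decouple distant
markers, and *gene conversions*, which copy short tracts (typically
50 bp - 2 kb) between homologues and therefore only perturb tightly linked
markers. Coalescent-based estimators of the population-scaled crossover rate
$\rho$ (per kb), the conversion initiation rate $\gamma$ (per kb) and the
mean tract length $\lambda$ (kb) are well developed, but they behave badly
when one of the two processes is absent: because $\gamma = 0$ (or
$\rho = 0$) lies on the *boundary* of the parameter space, the maximum a
posteriori estimate of the missing rate is systematically inflated above
zero. Before interpreting a fitted $\hat\gamma > 0$ as evidence of gene
conversion one therefore needs a calibrated hypothesis test. `meiotest`
provides that test: a likelihood-ratio statistic under a copying-model
likelihood, calibrated by a parametric bootstrap because the usual
$\chi^2$ asymptotics are invalid at the boundary (and doubly so here, since
$\gamma = 0$ and $\lambda = 0$ describe the same model, breaking
identifiability).

## The PAC copying likelihood

The exact coalescent likelihood
$\ell(\rho,\gamma,\lambda) = P(h_1,\dots,h_n \mid \rho,\gamma,\lambda)$
requires an intractable integral over genealogies. The
product-of-approximate-conditionals (PAC) surrogate replaces each factor of
the exact decomposition
$P(h_1)\,P(h_2 \mid h_1)\cdots P(h_n \mid h_1,\dots,h_{n-1})$
with a computable copying approximation $\hat\pi$: haplotype $h_{k+1}$ is
modelled as an imperfect mosaic copy of the $k$ haplotypes already seen.
`meiotest` uses the classic mosaic emission: at each SNP the allele is
copied faithfully with probability $k/(k+\hat\theta)$ and otherwise
repainted uniformly, with $\hat\theta = (\sum_{i=1}^{n-1} 1/i)^{-1}$, and a
uniform allele model $2^{-S}$ for the first haplotype (a constant that
cancels from every likelihood ratio; the tests assert this cancellation).

The hidden copying process is an *interleaved* HMM over joint states
$(X_j, G_j)$ at SNP $j$:

* the **crossover chain** $X_j \in \{1,\dots,k\}$ names the background
  donor; between SNPs at distance $d$ kb it jumps as a Poisson process with
  rate $\rho/k$, i.e. with probability $p = e^{-\rho d/k}$ it keeps its
  donor and otherwise re-draws uniformly;
* the **conversion chain** $G_j \in \{\varnothing, 1,\dots,k\}$ says
  whether the site sits inside a conversion tract and from whom the tract
  is copied. Tracts initiate as a Poisson process with rate $\gamma/k$ and
  terminate with rate $1/\lambda$. With
  $c = 1 - e^{-\gamma d/k}$ (a new tract has captured the next site) and
  $e = 1 - e^{-d/\lambda}$ (the ongoing tract has ended), the chain moves
  $\varnothing\!\to\!\varnothing$ with $1-c$, enters any given donor with
  $c/k$ (also from inside a tract - this donor *renewal* is how
  overlapping and nested conversions are represented within a single
  current-donor state), continues its tract with an extra $(1-c)(1-e)$ and
  drops back to $\varnothing$ with $(1-c)\,e$;
* coupling: whenever the next site is inside a tract
  ($G_{j+1} \neq \varnothing$) the crossover chain is frozen,
  $P(X_{j+1}\mid X_j, G_{j+1}\neq\varnothing) = \mathbf 1(X_{j+1}=X_j)$,
  which reproduces the prefix-tract-suffix pattern a conversion stamps on a
  descendant sequence.

The chain starts from the stationary balance of initiation and termination:
$X_1$ uniform, $P(G_1 = \varnothing) = 1/(1+\gamma\lambda/k)$ with the
remaining mass uniform over donors. Each conditional $\hat\pi$ is computed
by the forward algorithm over the $k(k+1)$ joint states with per-site
renormalisation (log-space accumulation of the scaling factors), so no
probability is truncated to zero; the recursion is implemented in C++ and
is checked in the test suite against exhaustive path enumeration on small
instances and an independent dense matrix-product forward pass at moderate
size, to $10^{-10}$.

Because the tract length typically ranges over 0.05-2 kb, a prior
$\log_{10}\lambda \sim N(-0.5, 0.4^2)$ - placing 95% of its mass on that
interval - regularises $\lambda$, and fitting maximises the posterior
objective $\log f(\lambda) + \log\ell(\rho,\gamma,\lambda)$. When
$\gamma = 0$ the model has no tract length and the prior term is dropped.

### Conditioning order

A PAC likelihood depends on the order in which haplotypes are conditioned.
`meiotest` exposes both policies and uses them as follows:

* `order = "fixed"` (package default): the input row order; fully
  deterministic, cheapest, appropriate wherever only internally consistent
  comparisons matter. The parametric bootstrap is policy-invariant in this
  sense: as long as observed and replicate statistics use the same policy,
  the p-value is calibrated, which the uniformity test verifies under the
  fixed policy.
* `order = "averaged"`: the mean log-likelihood over `n_orders` random
  permutations drawn from a fixed seed. Averaging over orders is the
  standard remedy for order dependence in PAC inference, and it matters
  scientifically here: with a single fixed order the three-parameter model
  can exploit order-specific mosaic noise, inflating the null
  likelihood-ratio statistic's tail roughly twofold, whereas averaging
  (5 permutations is enough in our experiments) yields the stable null
  distribution the simulation-study checks reproduce. The simulation-study
  configuration therefore fits with `order = "averaged", n_orders = 5`.

## Estimation

`recfit()` maximises the objective by Nelder-Mead in $\log_{10}$
coordinates inside finite boxes ($\rho,\gamma \in [10^{-4},10^{3}]$ per kb,
$\lambda \in [10^{-3},10^{2}]$ kb; hitting a bound is reported, not an
error). Three deterministic starts - $(1, 1, 10^{-0.5})$,
$(0.1, 1, 10^{-0.5})$, $(1, 0.1, 10^{-0.5})$, the tract length starting at
the prior median - guard against local optima (the conversion-only null
model, whose surface is often bimodal between a moderate-rate/long-tract
and a high-rate/short-tract mode, swaps in a high-rate start
$(\gamma, \lambda) = (10, 10^{-0.5})$); per start the simplex runs
at most 500 evaluations with absolute objective tolerance $10^{-5}$, and a
grid-search oracle in the tests confirms the returned optimum is never
below any grid point by more than $10^{-3}$ log units. The crossover-only
null model is a smooth one-dimensional problem, so it is maximised by
Brent search over $\log_{10}\rho$ rather than a one-dimensional simplex.
A fitted $\gamma$ pinned at the lower search bound is reported as 0 by
`coef()` (no measurable conversion signal); the raw value stays in the fit
object.

## The boundary LRT and its bootstrap calibration

For $H_0\!: \gamma = 0$ the statistic is
$$\Lambda(H) = -2\log\frac{\sup_\rho \ell_{\text{PAC}}(\rho,0,0 \mid H)}
{\sup_{\rho,\gamma,\lambda} f(\lambda)\,\ell(\rho,\gamma,\lambda\mid H)},$$
with the numerator the crossover-only PAC likelihood (no prior: $\lambda$
is not a parameter of that model). $\Lambda$ may come out slightly negative
(prior factor, finite optimiser tolerance) and is returned unclamped. The
swapped null $H_0\!:\rho = 0$ uses the conversion-only supremum (prior
active) in the numerator. Because the null lies on the boundary and
$(\gamma,\lambda)$ are not jointly identifiable there, $\Lambda$ is *not*
$\chi^2_2$; the acceptance checks recompute its null distribution and
verify both the departure from $\chi^2_2$ and the level of its 95%
quantile.

`rectest()` calibrates $\Lambda$ by parametric bootstrap: fit the nuisance
parameters under the null ($\hat\rho$; or $(\hat\gamma,\hat\lambda)$ for
the swapped test), simulate $B$ coalescent datasets of the same sample size
and region length from the fitted null - with the mutation rate set to the
data's Watterson estimate $S/(L\sum 1/i)$, since the generating $\theta$ is
unknown in practice - recompute $\Lambda$ on each, and report the
proportion reaching the observed value. Choices worth knowing:

* the estimator is $\#\{\Lambda_b \ge \Lambda_{\text{obs}}\}/B$, so
  $p = 0$ is a possible outcome; ties count toward the null
  (conservative); an add-one variant $(\#+1)/(B+1)$ is available;
* replicate fits use a single Nelder-Mead start (the first default start)
  to keep $B$ affordable; observed-data fits keep the multi-start default;
* all replicate streams derive from one integer seed, making the p-value
  bit-reproducible;
* $B = 200$ is the simulation-study default, $B = 500$ typical for data
  analysis;
* replicate datasets with fewer than 2 SNPs (possible under tiny fitted
  rates) are redrawn from the replicate's own stream; non-converged
  replicate fits are retained at their attained objectives and counted.

For locus scans, `segment_haplotypes()` divides a locus into overlapping
windows (default 20 SNPs with 15 shared between neighbours, the final
window absorbing up to 4 trailing SNPs, e.g. sizes 20, 20, 20, 20, 21 for
41 SNPs) and `rectest_segments()` tabulates per-window p-values; each
window's physical length is the distance between its first and last SNP.

## The coalescent simulator

`sim_genealogy()`/`sim_haplotypes()` implement the back-in-time coalescent
with both recombination processes, which doubles as the fixture generator
and the bootstrap engine. For $k$ active lineages: pairwise coalescence at
rate $k(k-1)/2$; per-lineage crossover at rate $\rho L/2$ with a uniform
breakpoint; per-lineage conversion at rate $\gamma L/2$ with a uniform
tract start and an exponential tract length of mean $\lambda$ kb (truncated
at the region ends). Ancestral material is tracked as half-open intervals
mapped into a growing node forest; an interval retires when a merge brings
its leaf count to $n$ (its grand MRCA), and the simulation ends when no
tracked material remains. Mutations then fall on each breakpoint interval's
marginal tree as a Poisson process of rate $\theta/2$ per kb per unit
branch length, one biallelic SNP per mutation (infinite sites). Tests
check the closed-form moments ($E[S] = \theta L \sum_{i<n} 1/i$,
$E[\pi] = \theta L$, mean pair coalescence time 1, tree height
$2(1-1/n)$), the exponentiality of tract lengths, and agreement of $E[S]$
and $E[\pi]$ with an independent coalescent simulator (msprime) under
conversion-only histories.

Deliberate simplifications: tract lengths are continuous-exponential in kb
where discrete simulators use geometric lengths in bp (negligible at 20 kb
scale, and consistent with the HMM's continuous termination); events may
fall on non-ancestral material, with empty lineages pruned (MS-like; the
sampled distribution is unchanged, at a modest cost in no-op events); no
demography, no variable recombination maps, no finite-sites mutation. The
generator emulates neutral, panmictic, constant-size histories - passing
tests say nothing about robustness to population structure, growth,
selection, genotyping error or phasing error in real data.

## Problem sizes and numerical choices in the checks

The simulation-study checks run at desk scale: 100 replicates per setting
in the acceptance script (the scale at which the reference quantities are
defined), 30-100 in the test suite with tolerances widened to the
Monte-Carlo error at those counts; the bootstrap-uniformity check uses 50
null datasets at $B = 100$ under the fixed-order policy, and the power
comparison uses 8 datasets per setting at $B = 30$. Simulator moments are
checked at 500 replicates against 3-standard-error bands. Event counts in
the simulator are capped (default $10^6$) to fail fast on absurd rate
inputs rather than hang.

## Known limitations

* The PAC surrogate is an approximation, not the coalescent likelihood:
  rate estimates inherit its known biases (the crossover MLE drifts low at
  large $\rho$; the test suite reproduces this rather than hiding it).
* A fixed-order likelihood makes the test statistic itself
  order-dependent; use the averaged policy when the statistic's absolute
  level matters.
* The bootstrap assumes the null simulator family (neutral coalescent,
  constant $\theta$ from Watterson's estimate) is adequate for the data;
  strong demographic departures shift the null distribution of $\Lambda$.
* Estimates at the search-box boundary mean the data carry no information
  on that side of the parameter; they are flagged, and should be read as
  censored, not as point estimates.
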