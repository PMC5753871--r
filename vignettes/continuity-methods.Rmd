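---
title: "Testing population continuity from low-coverage ancient DNA: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing population continuity from low-coverage ancient DNA: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(continuitest)
```

## The question and the model

Given a panel of ancient individuals sequenced to (possibly very) low
coverage and a modern population whose allele frequencies are known, we ask
whether the ancient panel belonged to a population *directly ancestral* to
the modern one. The demographic model is a clean split: the ancient
population branches off the modern lineage and the two branches accumulate
drift `t1` (modern side) and `t2` (ancient side), measured in diffusion
units `t = generations / (2 Ne)` of the branch's own effective size.
Continuity is the boundary hypothesis `t2 = 0`: the sampled individuals sit
on the lineage leading to the modern population, with no private drift.

Per site, the data are the counts of reads carrying the ancestral and the
derived allele in each ancient individual, plus the modern derived-allele
frequency `x`. All inference conditions on `x`, which makes the likelihood
insensitive to how the SNPs were discovered — the practical prerequisite
for using capture-array data.

## Binomial moments by matrix exponentiation

The sampling probability of `k` derived alleles among `n` ancient
chromosomes needs only the binomial moments
`p_{n,k} = E[Y^k (1-Y)^(n-k) | x]` of the unknown ancient frequency `Y`.
Under pure drift these moment vectors satisfy linear ODEs, so

`p_n(t1, t2) = exp(Q t2) exp(Q↓ t1) h_n(x)`,

with seed vector `h_n(x)_k = x^k (1-x)^(n-k)` and tridiagonal generators
(rows/columns indexed by `k = 0..n`; the vector index equals the
derived-allele count):

* forward `Q`: sub-diagonal `i(i-1)/2`, diagonal `-i(n-i)`, super-diagonal
  `(n-i)(n-i-1)/2` — evolves moments from the common ancestor to the
  ancient population;
* backward `Q↓`: sub-diagonal `i(i-1)/2`, diagonal `-i(n-i+1)`,
  super-diagonal `(n-i+1)(n-i)/2` — evolves the modern observation back to
  the common ancestor.

The backward operator corresponds to time-reversing the neutral diffusion
with the ancestral frequency weighted by the neutral frequency spectrum
(density proportional to `1/z`). We verified this identification
numerically against exact posterior computations on a discrete
Wright–Fisher chain before adopting it for the simulation engine; the unit
suite retains a scaled-down version of that check (`wf_grid_moments`).

Numerical choices:

* Exponentials use dense scaling-and-squaring (`Matrix::expm`). `Q↓` is
  non-normal, so eigendecomposition routes were avoided deliberately.
* Round-off can leave tiny negative moment entries; these are clamped to
  zero and the vector renormalized **only** when the pre-clamp departure of
  `sum(choose(n,k) p_k)` from 1 is below 1e-6. A larger departure raises an
  error instead of silently repairing a broken result.
* Drift times are bounded above by 10 diffusion units in the optimizer;
  beyond that the moments are numerically at fixation and the exponentials
  add no information.
* One pair of exponentials is shared by all sites of a given order, and an
  optional cache (`moment_cache()`) shares them across repeated
  evaluations. Cached and uncached results are bit-identical, which is
  under test.

## From reads to the likelihood

Genotype likelihoods use binomial read sampling with a symmetric per-read
error `ε` (sequencing error and postmortem damage folded into one
parameter): per-read derived probabilities `ε`, `1/2`, `1-ε` for genotypes
0, 1, 2. A site's contribution is `log Σ_k W_k p_{2m,k}` where `W_k` sums,
over genotype configurations with derived-allele total `k`, the products of
`choose(2, g_i)` and each individual's genotype likelihood. Two identities
keep this both correct and fast:

* **Vandermonde**: `Σ_{g: Σg=k} Π choose(2, g_i) = choose(2m, k)`, so the
  `W_k` already carry all combinatorics and pair with the raw moments
  `p_{n,k}` (no extra binomial coefficient) — the likelihood of a fully
  uncovered site is exactly 1.
* **Marginalization**: an individual with no reads contributes the exact
  triplet `(1, 2, 1)`, and convolving it in changes nothing after pairing
  with the order-incremented moments. We therefore evaluate every site at
  the fixed panel order `n = 2m` instead of reducing the order per site:
  this costs a few extra convolution steps but lets all sites share one
  pair of matrix exponentials and vectorizes cleanly. The identity is
  tested to 1e-10.

`W_k` is built by sequential convolution of per-individual triplets in
O(m²) — never by 3^m enumeration, which serves only as the test oracle.
Triplets are rescaled by the heterozygote likelihood `0.5^(a+d)` (an
`ε`-free constant restored on the log scale at the end), which keeps the
convolution well-scaled at arbitrary coverage. The inner loop is compiled
(Rcpp); a plain-R reference implementation stays in the package and the
suite asserts exact agreement between the two.

A useful corollary, which the suite checks as an invariant: a site covered
by a single read in a single individual has likelihood
`ε + (1-2ε) x e^{-t1}` for a derived read — independent of `t2`. Datasets
in which no individual ever has two reads at a site are exactly flat in
`t2`; information about ancient drift comes from within-individual evidence
of heterozygosity.

## Maximization, the continuity test, bootstrap

The log-likelihood is maximized over `t1, t2 ∈ [0, 10]` and
`ε ∈ [1e-6, 0.5-1e-6]` with bounded L-BFGS-B using analytic gradients
(`d/dt2` via `Q exp(Q t2) exp(Q↓ t1)`, `d/dt1` via the middle-factor
derivative, `d/dε` by carrying the product rule through the convolution).
We chose bounded quasi-Newton from a deterministic multi-start grid over a
simplex-first scheme: the box constraint lets `t2` rest exactly on the
continuity boundary, where a simplex cannot live, and the analytic gradient
makes refinement from every start cheap. The default grid crosses
`t1, t2 ∈ {0.005, 0.05, 0.5}` with `ε ∈ {0.001, 0.01}` (18 starts; 6 for
the null). Convergence is tolerated at 1e-6 in log-likelihood; ties are
broken toward the smallest `t1 + t2`, then smallest `ε` (parsimony). The
fit records how many starts agree within 1e-4 of the optimum. An L-BFGS-B
line-search abort at the optimum counts as converged only when a cleanly
converged start reaches the same log-likelihood.

`ε` is coestimated and shared across the panel by default; per-individual
estimation and a fixed value are available (`fit_options(eps_mode = ...)`).
Shared is the lower-variance default for low-coverage panels.

The continuity test compares the full fit with the `t2 = 0` fit. Because
the null pins a parameter to the boundary, the likelihood-ratio statistic
is asymptotically a 50:50 mixture of a point mass at zero and χ²₁; we
report both the mixture p-value (the default decision value) and the plain
χ²₁ p-value. The null solution is injected as an extra start of the full
fit, so the nesting inequality holds by construction. Confidence intervals
come from a nonparametric bootstrap over sites (optionally over blocks of
consecutive sites for linked data), with percentile intervals and a seeded,
reproducible resampling stream.

## What the simulators emulate — and what they do not

`simulate_dataset()` provides two generators:

* **model_exact** draws modern frequencies from a truncated neutral `1/x`
  spectrum (panel size 100 diploids fixes the truncation), ancient allele
  counts from the model's own sampling distribution `P_{2m,k}`, assigns
  them to chromosomes at random, and pairs chromosomes into diploids. It is
  exact but circular by construction — good for calibration, not
  validation.
* **wright_fisher** simulates discrete binomial resampling forward in time
  from an ancestral frequency drawn from the truncated `1/z` spectrum,
  computes the modern frequency from the simulated modern population, and
  is therefore an independent check on the moment engine. It is the only
  engine supporting the admixture scenarios: a secondary-contact pulse from
  the (still-living) ancient population into the modern one after the
  sample's death, and a ghost pulse from an unsampled outgroup into the
  modern population under true continuity. Pulses are one-generation
  mixtures of allele frequencies, the simplest faithful discretization of a
  pulse.

Reads are Poisson in depth (mean = coverage), each read contaminant with
probability `c` (carrying the derived allele with probability `x`),
otherwise drawn from the individual's genotype, and finally flipped with
probability `ε`. The default simulated error is `ε = 0.01` — a
realistic order of magnitude for trimmed, quality-filtered ancient reads
once damage is included.

The default demography — split 400 generations ago, modern Ne 10,000,
ancient Ne 1,000, sample age 300 generations, hence `t1 = 0.02`,
`t2 = 0.05` — is the reference design used across the replicate studies in
the test suite.

Deliberate non-goals of the generators: no linkage (sites are independent,
matching the likelihood's own assumption), no sequence-level artifacts
(mapping, fragment length, position-dependent damage), no finite-panel
noise in `x` (the modern frequency is treated as known, as one does with a
large reference panel). Passing tests therefore demonstrate correctness of
the inference machinery under the model's assumptions plus the studied
violations (admixture, contamination) — they do not certify robustness to
linked sites or to mis-estimated modern frequencies.

## Problem sizes used in the checks

Replicate studies in the test suite use scaled-down designs chosen to keep
the full suite comfortably reproducible on a laptop: parameter-recovery and
RMSE-ordering studies use 20 replicates of ~20,000 sites; the size of the
continuity test uses 200 null replicates of 5,000 sites; power, admixture
and contamination studies use 12–40 replicates of 5,000–20,000 sites.
Replicate studies use a reduced 2×2×1 start grid after the full 18-start
grid's agreement has been established in the unit tests. One deliberate
departure from a naively scaled design: at 5,000 sites the continuity test
cannot have near-perfect power for 5 diploids at 0.5× (the expected
likelihood-ratio statistic is ~6), so the power study uses 20,000 sites,
where the noncentrality (~24) makes rejection essentially certain — the
qualitative claim being tested is about sampling design, not site count.

## Known limitations

* The model ignores new mutations on the ancient branch and linked
  selection; it is a pure-drift split model.
* A single shared `ε` cannot capture strongly individual-specific damage;
  use `eps_mode = "per_individual"` for heterogeneous panels (at some cost
  in variance).
* Contamination is simulated but not estimated: contaminated panels bias
  `t2` toward zero, i.e. toward spurious continuity — interpret
  non-rejection cautiously for poorly decontaminated samples.
* Ghost admixture into the modern population makes truly ancestral panels
  reject continuity at moderate admixture fractions; rejection is evidence
  against the clean split model, not necessarily against ancestry.
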