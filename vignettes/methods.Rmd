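---
title: "Pedigree-based Y-STR match probabilities: model, estimators and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pedigree-based Y-STR match probabilities: model, estimators and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ystrmatch)
```

## The quantity being computed

A patrilineal pedigree is a rooted tree of `n` males; father–son edges carry
one meiosis each. `k` members, always including the suspect, have typed
Y-STR haplotypes (`h^v`); the remaining `n - k` are untyped. Writing
`m(H^u)` for the number of untyped members whose haplotype equals the
suspect's, the package computes

* `P(h^v)`: the probability of the typed observations given the suspect's
  haplotype, and
* `p_x = P(m(H^u) = x | h^v)` for `x = 0 .. n-k`.

`p_x` for `x >= 1` is the forensic object of interest: the probability that
an untyped relative — a plausible alternative trace donor — carries exactly
the haplotype that matched the trace.

## Mutation model and its assumptions

Each marker mutates independently per meiosis by −1, 0 or +1 repeat with
probabilities `mu/2`, `1 − mu`, `mu/2` (`step_probs()`); `z = mu/2` is the
unidirectional rate. Larger jumps, multi-copy markers and fractional
(intermediate) alleles have probability zero and are rejected at the input
layer, because the single-step state space is what both the estimators and
the exact oracles enumerate. Rates must lie in (0, 1); values above 0.2
trigger a warning as outside the regime exercised by the validation
catalogue (whose rates are 0.1, 0.02 and 0.005 — the first is high even for
rapidly mutating Y-STRs and is included because it makes match probabilities
large enough to exercise every code path).

Two consequences of the model matter structurally:

* **Symmetry** (`mu(A,B) = mu(B,A)`): allows re-rooting (below).
* **Shift invariance**: only allele differences enter transition
  probabilities, so all internal computation shifts alleles to put the
  suspect at the origin per marker. Inputs are absolute repeat counts; the
  shift is invisible to the user.

## Re-rooting and processing order

The suspect's position in the pedigree varies from case to case, which
complicates a generic simulation scheme. Because transitions are symmetric,
the tree may instead be re-rooted at the suspect: exactly the edges on the
lineage between suspect and original root are inverted
(`reroot_at_suspect()`), the undirected edge set is unchanged, and all
probabilities are preserved. `renumber()` then assigns 1 to the suspect,
2..k to the other typed members and k+1..n to the untyped members, each
group ordered by generation; untyped members are simulated in level order,
so every member's father is known (typed, or already simulated) when his
haplotype is drawn.

Ties within a generation are broken lexicographically on the original member
id. The choice is arbitrary but deterministic; every probability computed by
the package is invariant to it, because a simulation's weight depends only
on the set of simulated members and their father–son relations, never on
the order in which a generation was traversed.

## The estimators

**`estimate_pv()`.** Each simulation draws all untyped haplotypes top-down
and multiplies the transition probabilities over the father–son edges whose
son is *typed*; the mean of this product over simulations is an unbiased
estimate of `P(h^v)`. (This is the importance-sampling identity with the
proposal equal to the generative law of the untyped members: the simulated
edges cancel from the weight.) Two cases are exact and skip simulation:
`k = 1` gives the empty product 1, and `n = k` gives the full edge product.

**`estimate_px()`.** For fixed `x`, each simulation pins a uniformly random
size-`x` subset of untyped members to the suspect haplotype (probability
`1/bin(n-k, x)` per subset), simulates the rest, and accumulates

```
w = bin(n-k, x) * prod(transition probs of non-simulated edges) / P(h^v)
```

over simulations whose *total* match count — pinned plus coincidental —
equals exactly `x`. Coincidental matches among simulated members count
toward `m(H^u)`, since `m` is defined over all untyped members; a simulation
whose coincidental matches push the total past `x` contributes zero. The
transition factors of simulated edges are identical in the target numerator
and the proposal denominator and cancel algebraically, so the implementation
never evaluates them — numerically preferable and exactly equivalent.

`P(h^v)` enters every weight but depends only on the typed data, so it is
computed once per pedigree (exactly when feasible, otherwise by
`estimate_pv()`) and passed in.

**`estimate_distribution()`.** Runs `estimate_pv()` once and
`estimate_px()` for each `x` on independent substreams (seed + x), then sets
`p_0 = 1 − sum(p_x)`. Estimates can sum marginally above one; `p_0` is then
clamped to zero with a warning rather than renormalizing, leaving the per-x
estimates untouched.

A pinned member whose father's haplotype is more than one step away yields a
zero-probability edge and hence weight zero; such proposals waste
simulations but do not bias the estimate. `n_nonzero` in every result
surfaces this efficiency loss (e.g. scenarios where a match requires an
improbable mutation path show small `n_nonzero`).

## Exact oracles

Two independent exact routes serve as ground truth:

* `exact_distribution_enum()` enumerates every untyped-haplotype assignment.
  The support bound is per member: at depth `d` below the suspect an allele
  cannot differ from the suspect's by more than `d` per marker, so the box
  `[-d, d]` per marker is exhaustive. Enumeration refuses above a state cap
  (default 2e6) with a pointer to the estimator.
* `exact_distribution_dp()` runs a sum-product pass over the suspect-rooted
  tree: each node carries a table over (own haplotype, match count in its
  subtree); children are absorbed by a transition-weighted matrix product
  and a convolution over counts. It scales with tree size rather than the
  joint state space and agrees with enumeration to double precision.

Both report `pv` and the full distribution, which sums to one exactly; a
typed configuration that is impossible under the single-step model
(`P(h^v) = 0`, e.g. a typed father–son pair two repeats apart) raises a
classed error, and `validate_case()` flags such pairs up front.

## The validation catalogue

`build_scenario()` encodes nine elementary pedigrees (A–I, two to five
members) with every sensible allele assignment to their typed members — 33
scenarios in all, each with closed-form `P(h^v)` and `p_x * P(h^v)` stored
as explicit polynomials in `z`. These pedigrees are small enough for exact
arithmetic yet cover the structurally distinct situations: untyped chains,
typed members above and below untyped ones, fans of brothers, and mixed
branches. The catalogue's polynomials were derived per structure and are
locked to the enumeration oracle by `validate_all_fixtures()` at a relative
tolerance of 1e-10 across all three rates, so a mistranscribed structure or
coefficient cannot survive the test suite. (`p_0` is excluded from that
strict check: it is defined by subtraction from unity and loses relative
precision by cancellation when it is within a few 1e-11 of zero.)

What the catalogue does *not* emulate: multi-marker panels (the fixtures are
single-marker; multi-marker code paths are tested separately with small
two-marker cases), realistic pedigree sizes, empirical per-marker rate
vectors, mutation asymmetry or length dependence, and population-level
haplotype frequencies. Passing the catalogue shows the estimator and oracles
are correct under the stated model, not that the model captures every
feature of real Y-STR data.

## Numerical choices

* Weights are accumulated in log space and exponentiated per simulation;
  impossible edges contribute `-Inf` and exponentiate to exact zeros, so
  deep pedigrees or many markers cannot underflow an edge product.
* The Monte-Carlo standard error is the sample SD of the (indicator-masked)
  per-simulation weights divided by `sqrt(n_sims)`.
* Subset pinning enumerates the `bin(n-k, x)` combinations and samples a
  column index when the count is at most 2e5, and falls back to per-sim
  `sample()` calls beyond that.
* Seeding: every public estimator takes an optional integer seed, restores
  the caller's RNG state afterwards, and derives substreams additively
  (distribution: seed + x; accuracy experiment: seed + 1009·repeat). A fixed
  seed makes CLI output byte-identical.
* `run_accuracy_experiment()` reports, per quantity, the mean and SD over
  repeats of `100 * (estimate − exact) / exact`; quantities whose exact
  value is zero are instead checked to estimate exactly zero (their
  estimator is structurally zero for every seed, not merely small).

## Problem sizes in the shipped tests

The test suite validates all 33 scenarios against the closed forms at all
three rates (exact, sub-second); runs the full stochastic sweep — every
scenario at `mu = 0.1`, 10 repeats × 100,000 simulations — asserting mean
and SD percentage differences below 10%; and checks every scenario's
estimates against the oracle at 100,000 simulations within five standard
errors. The whole suite completes in about a minute on one core, which is
why the full sweep is run rather than a spot-check subset.

## Limitations

* The suspect must be typed and must be a pedigree member; pedigrees are
  strictly patrilineal (no female links, no `PED`/kinship formats).
* Single-step symmetric mutation only; markers with frequent multi-step or
  asymmetric mutations should not be analysed with this model.
* The exact oracles are for small pedigrees by design; large pedigrees are
  exactly the importance sampler's job.
* Prior weighting of competing hypotheses (pedigree member vs. outsider) and
  likelihood-ratio reporting are out of scope; `meiosis_match_prob()`
  provides the per-lineage exact bound for outsiders of bounded relatedness,
  nothing more.
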