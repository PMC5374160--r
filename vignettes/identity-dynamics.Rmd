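---
title: "Modeling bicultural identification dynamics on ego networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling bicultural identification dynamics on ego networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(egoident)
```

## The model

`egoident` implements a deliberately minimal agent-based model of how one
bicultural person's identifications with two cultures respond to the
composition and structure of their personal network. The entities are one
ego and a fixed roster of alters (eight by default, matching the
four-friends-plus-four-colleagues elicitation common in egocentric survey
designs). Each alter carries a culture label, A or B (display aliases
"Latino" and "European-American"); undirected ties connect alters to each
other; ego is implicitly tied to all of them. The network is static: no tie
formation or dissolution, no alter turnover, and no selection — the model
isolates *influence*.

Ego's state is a pair of identification scores `(ID_A, ID_B)`, each on a
1–6 Likert-type scale and initialized at the 3.5 midpoint. Time is discrete;
at each of 50 steps ego interacts with one alter drawn uniformly at random,
independently across steps (the same alter may recur). An interaction with
an alter of culture A changes the state by `delta = 0.1 * (1 + d_a)`, where
`d_a` is that alter's *same-culture degree*: its count of ties to other
culture-A alters (0–7). The `0.1` is the basic unit of change — small enough
that full identification is not reached in a handful of steps — and the
degree multiplier encodes complex-contagion-style reinforcement: alters
embedded among same-culture contacts push harder.

Three mechanisms decide where `delta` goes (culture B symmetric):

* **positive** — `ID_A += delta`; identification with the partner's culture
  grows, the other is untouched (identities coexist independently).
* **negative** — `ID_B -= delta`; contact with one culture suppresses the
  other (identities are oppositional).
* **mixed(α)** — `ID_A += α·delta`, `ID_B -= (1−α)·delta`, both from the
  pre-update state. `α ∈ [0, 1]` regulates the balance; only `α = 0.5`
  weighs the effects equally, and the endpoints reproduce the pure
  mechanisms *bit-identically* (the implementation routes all three kinds
  through one weighted update, so this is true by construction, and the test
  suite asserts it).

After every interaction both coordinates are clamped into `[1, 6]`,
immediately and independently, with no banking of overshoot.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `n_steps` | 50 | interactions | the model's stated horizon; long enough for saturation regimes to emerge |
| `initial_identification` | 3.5 | scale points | scale midpoint: maximal room to move either way |
| `base_increment` | 0.1 | scale points | basic unit of change between 0 and 1 |
| `lower_bound`, `upper_bound` | 1, 6 | scale points | the identification scale's ends |
| `alpha` | — | unitless | positive-vs-negative mixing weight of the mixed mechanism |
| `replicates` | 50 | runs/cell | one run shows one of many possible developments; 50 stabilizes cell means |

## The factorial design and the generator

`grid_spec()` defaults encode the full design: culture-A counts 0–8, tie
counts 0, 4, …, 28 placed uniformly at random among the 28 alter pairs,
mechanisms positive + negative + mixed at α = 0, 0.1, …, 1, and 50
replicates — 936 cells, 46,800 outcome pairs. The alpha grid keeps both
endpoints even though they duplicate the pure mechanisms, preserving the
design arithmetic `9 · 8 · (1 + 1 + 11) · 50`.

Design choices where the stated world was genuinely open:

* **Tie placement per replicate.** Whether a cell's network is drawn once or
  redrawn every replicate was unstated; we redraw per replicate, which makes
  the per-cell SD reflect both interaction noise and structural variability
  — the interpretation consistent with reading the SD surfaces as variation
  across simulation runs of a *design cell*, not of one frozen graph.
* **Uniform interaction sampling.** "Interacts randomly" is read minimally:
  uniform, with replacement, independent across steps; no recency or
  homophily preference.
* **Label placement.** The sweep assigns culture A to the first
  `n_culture_a` roster slots: the dynamics depend only on counts and tie
  placement, so shuffling labels (available as `random_labels = TRUE`) is
  cosmetic.
* **Seeding.** Every run's stream derives from
  `derive_seed(base_seed, mechanism kind, 100·alpha, ratio, ties,
  replicate)` — an FNV/murmur-style 32-bit hash — so per-run streams are
  independent of cell execution order and unchanged when other cells are
  added. Cells are executed sequentially; because seeds are
  order-independent, a parallel backend could be added without changing any
  number.
* **Sample SD.** The n−1 denominator; a single-replicate cell reports its SD
  as undefined (empty field) rather than 0.

## Numerical choices

Identifications are accumulated in doubles. On the default 0.1 grid the
exact values are multiples of 0.05, but 25 accumulated additions of 0.1 land
at `5.999999999999998`, so saturation is reached one step "late" at the bit
level. All behavioral comparisons in the tests therefore use an absolute
tolerance of 1e-9; exact (`==`) assertions are reserved for regimes where a
coordinate is provably never touched (e.g. `ID_A` under the positive
mechanism with zero culture-A alters stays at 3.5 bit-exactly). Clamping is
`min`/`max` per coordinate after each step; ties in the mixed rule are
immaterial because the two increments touch different coordinates, but the
contract fixes both to be computed from the pre-update state.

## Verification oracles

Two independent references check the simulator:

* `exact_expectation()` enumerates all `n_alters^n_steps` equally likely
  interaction sequences (capped at 10^6) and applies the exact clamped
  update to each — an exact oracle for Monte-Carlo means on toy horizons.
  At 2000 replicates the simulator agrees within 3 standard errors on
  ≤3-step cases.
* `no_clamp_mean()` gives the linear closed form, e.g. for the positive
  mechanism `E[ID_A] = 3.5 + n_steps · (1/n) · Σ_A 0.1·(1 + d_i)`, valid
  when *no* interaction sequence can reach a bound. Its strict reachability
  precondition is checked against the worst-case path; designs where a bound
  is reachable only with negligible probability (the classic example: one
  culture-A alter would have to be drawn 26+ times in 50 steps,
  `P ≈ 10^-10`) can opt out via `on_clamp_risk = "warn"`/`"ignore"` and use
  the linear value as an approximate oracle — that is exactly how the
  4.125 reference for the single-alter regime arises. The closed form and
  the enumeration agree to 1e-9 whenever both preconditions hold; absorbing-
  boundary arithmetic is deliberately out of scope (enumeration covers it).

## The network metrics

For observational description the package computes per-culture group sizes
(0–8 on the default roster) and the inter-class tie weight
`ω(F, C) = e(F, C) / (|F|·|C|)` between two disjoint alter groups, typically
same-culture friends vs. same-culture colleagues. Under this normalization
`ω ∈ [0, 1]`, 0 iff there is no cross-group tie and 1 iff the cross-group
bipartite graph is complete. Empty groups return `NA` (undefined) rather
than 0, so "no members" is distinguishable from "members but no ties".
Survey reports of similarly named interconnection measures sometimes quote
observed values above 1, which implies a different denominator; this package
implements the product-of-group-sizes form only and makes no guess at
alternatives. Relational domains exist solely for these metrics; the
dynamics ignore them.

## What the synthetic design does and does not establish

The generator *is* the stated world of the model: equal-size rosters, a
controlled culture ratio, exactly `n_ties` uniformly placed ties, and a
static network. Real personal networks differ in ways the model abstracts
away: rosters vary in size, more than two cultural categories occur, ties
are clustered rather than uniform, networks evolve, and people choose whom
to interact with. A green test therefore establishes that the simulator
reproduces the *model's* regimes — saturation at 6 with ≥6 same-culture
alters under the positive effect, the floor at 1 under the negative effect,
exact stability at 3.5 for absent (positive) or exclusive (negative)
cultures, the 4.1–4.2 single-alter band, the ≈2.9 seven-alter negative mean,
and the α ↔ 1−α mirror — not that real biculturals behave this way.
The mirror symmetry is exact pathwise: under one draw sequence, `ID_B` at
mixing weight α is the reflection about 3.5 of `ID_A` at 1−α, because the
bounds 1 and 6 are themselves symmetric about the midpoint; the tests check
both this strong form and its Monte-Carlo surface form.

## Known limitations

* Two cultures only; no third-culture or hyphenated-identity states.
* No selection dynamics, network evolution, or per-alter identification
  states — influence on a static graph is the entire process.
* Closed-form expectations are unavailable once clamping binds; only the
  enumeration oracle covers that territory, and only at toy horizons.
* The sweep configuration file is JSON (mirroring `grid_spec()` field
  names): the target environment ships no YAML/TOML reader for R, and
  adding a hand-rolled parser for a config file was judged worse than using
  the JSON infrastructure already required for manifests.
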