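---
title: "Methods: evaluating and accelerating PSSM-based secondary structure prediction"
author: "ssptools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evaluating and accelerating PSSM-based secondary structure prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssptools)
```

# The problem

Modern secondary structure predictors take as their feature set a PSSM built
by iterative PSI-BLAST search against a large *target dataset* of protein
sequences. Two properties of that dataset drive the whole pipeline: its
**size** `n_t` (search time is essentially linear in it, because PSSM
generation dominates the pipeline) and its **sequence redundancy** (a more
redundant dataset yields a more homogeneous homolog set, hence a flatter,
less informative profile). `ssptools` implements the measurement and
manipulation machinery for studying this trade-off: rigorous accuracy
scoring, profile-quality measurement by Shannon entropy, dataset reduction
by sampling and by non-redundant (NR) set construction, and parametric
speed/accuracy models.

# Accuracy measures

**Q accuracy.** The fraction of residues whose predicted state equals the
observed state, over the 3-state alphabet `{H, E, C}` or the 8-state DSSP
alphabet `{H, G, I, E, B, T, S, C}`. Aggregation is *micro-average* by
default: total correct residues over all query proteins divided by total
residues. The unweighted per-protein (macro) mean is available for
comparison, but it over-weights short proteins and is not the reported
measure. The 8→3 reduction is the standard one (`H,G,I→H`, `E,B→E`,
`T,S,C→C`); because it collapses within-class substitutions, 3-state Q is
never below 8-state Q on the same pairs — a property the test suite checks.

**SOV.** The segment-overlap score rewards correctly placed secondary
structure elements rather than individual residues. We fix the 1999
revision of the definition: for each observed segment $s_1$ of a state and
each predicted segment $s_2$ of the same state overlapping it, the score
accumulates $\frac{minov + \delta}{maxov}\,len(s_1)$ with
$\delta = \min(maxov - minov,\ minov,\ \lfloor len(s_1)/2\rfloor,\
\lfloor len(s_2)/2\rfloor)$, and the normalizer counts $len(s_1)$ once per
overlapping pair (once in total for unmatched observed segments). Two
deliberate consequences: SOV is exactly 1 iff the segment structures
coincide, and it lies in $[0,1]$. The 8-state SOV8 is the identical formula
summed over the eight states. Earlier (1994) variants of the formula exist;
the package deliberately fixes one definition rather than dispatching on
predictor provenance. Per-protein SOV values are aggregated with protein
size as the weight, $\overline{SOV} = \sum_i size_i\,SOV_i / \sum_i
size_i$, which degenerates to the plain mean for equal sizes.

**Statistics.** Repeated measurements of two experimental groups are
compared by a fixed cascade: Shapiro–Wilk normality on each group at level
$\alpha$ (default 0.05), then an F test for variance equality, then
Student's *t* (equal variances) or Welch's *t* (unequal). The cascade as
described covers only the both-groups-normal path; we resolve the open case
by falling back to Welch's *t* when normality fails, and the returned
object always names the branch taken so the decision is auditable.

# PSSM entropy

A PSSM row is by construction a probability distribution over a 20-state
variable, so its complexity is measured by Shannon entropy
$S = -\sum_c p_c \log_2 p_c$ (bits, $0\log 0 = 0$), bounded by
$[0, \log_2 20 \approx 4.32]$. The observed-probability block of the
PSI-BLAST ASCII PSSM is used — *not* the log-odds block and *not*
PSI-BLAST's own "information per position" column, which is a different
(relative-entropy) quantity; both are parsed but only the probabilities
enter $S$. Two parser conventions matter: percentages are integers, so rows
are renormalized by their sum; and PSI-BLAST emits all-zero rows where no
homolog aligns, which we replace by the one-hot distribution on the query
residue (zero entropy — the profile carries no information beyond the query
there). Dataset-level entropy defaults to the residue-weighted mean (all
positions of all proteins pooled), consistent with the micro-average
philosophy of Q; a protein-weighted mode is provided because published
dataset-level values do not state their weighting.

# Dataset reduction

**Random sampling.** Subsets of size `round-half-up(n / 2^k)` emulate the
halving series used in size-reduction experiments. Each repeat `r` draws
without replacement using seed `seed + r`; different repeats may share
entries ("inter-subset replacement"), which is unavoidable once
`repeats × size > n` and empirically harmless, and a strict mode forbids
overlap when feasible.

**NR construction.** The divide-and-conquer algorithm sorts sequences by
length (descending; ties broken by id so runs are reproducible), partitions
into subsets of capacity `m`, applies a greedy incremental clustering pass
within each subset, and then iterates: the current head subset is held
invariable while every body subset is purged of sequences with identity
≥ *h* to any head member; the head then joins the output. The original
procedure's merge–screen–requery dance (screening a merged head+body set,
then re-purging the body with the head's removed members as queries) exists
only because its external clustering engine cannot hold the head fixed; we
implement the equivalent postcondition directly — the body is purged
against the *invariable* head — which yields the same final contract: no
output pair reaches *h*. Because both passes enforce the same longest-first
dominance order, the result coincides, as a set, with a single global
greedy pass for **any** `m`; the test suite verifies this
partition-independence and brute-forces the all-pairs postcondition on
every instance. The default `m = 100000` reflects memory-bounded production
engines; tests use single-digit `m` to exercise many partitions.

**Identity.** No single convention for "percent identity" exists; we fix:
global affine-gap alignment (match +1, mismatch −1, gap open 2, gap
extend 1 — a documented constant of the built-in engine), identity =
identical aligned positions / length of the shorter sequence, capped
at 100. This is the convention of greedy-clustering tools, and the
shorter-length denominator makes a perfect substring score 100%, the
conservative choice for redundancy removal. Ambiguity letters
(X, B, Z, U, O, J) are accepted in sequences but never count as identical
positions. The engine is compiled (Gotoh dynamic programming with
deterministic tie-breaks, canonicalized argument order so the measure is
exactly symmetric) and validated against an independent aligner's optimal
scores in the tests; the `identity_fun` argument lets production runs
substitute an external engine without touching the algorithm.

# Performance models

The size-dependent reference models are
$TC(n_t) = 2.8658\times10^{-5} n_t + 5.8248$ seconds,
$Q3(n_t) = 0.1363\,(1+e^{(17.0963-\log_2 n_t)/2.1447})^{-0.6205} + 0.6716$
and
$Q8(n_t) = 0.1281\,(1+e^{(15.6095-\log_2 n_t)/2.5405})^{-1} + 0.5621$.
The printed form of the Q3 curve is typographically ambiguous about where
the asymmetry exponent binds; we adopt the reading above, the only one
consistent with its published prediction of 0.807 at $n_t = 87.3$ million.
The homology-series models are a quadratic in $n_t$ for time and cubics in
the identity cutoff $c_t$ for Q3/Q8, evaluated exactly as printed.
Accuracy curves are monotone in $n_t$ and bounded in
(baseline, baseline+amplitude); time-cost constants are hardware-specific
and the fitted objects carry a note saying so — use them for relative
comparisons, not absolute runtimes. Inputs outside the fitted ranges
($c_t \in [20,100]$, $n_t \ge 1$) are evaluated but flagged as
extrapolation.

**Refitting.** The linear and polynomial forms use ordinary least squares
(`lm`). The logistic forms use bounded Levenberg–Marquardt
(`minpack.lm::nlsLM`, ftol/ptol $10^{-10}$) with data-derived starts:
baseline = min(y), amplitude = range(y), midpoint = $\log_2 n$ at the half
rise, scale = 2, asymmetry = 1. No fitting protocol is published for these
curves; this initialization makes refits deterministic, and noiseless
samples of every reference curve are recovered to well within 1% relative
parameter error in the acceptance tests. The generalized-logistic
asymmetry parameter is weakly identified near flat data, hence the bounds
($10^{-3}$ to 20) and the requirement of at least as many points as
parameters.

# Synthetic data

The generators define the study conditions for every test:

- `gen_family` emulates UniRef-style redundancy: uniform-composition
  random roots with members at an exact substitution count
  `round((1 − identity/100)·length)`, so realized member–root identity
  hits the target to within one position. Cross-family identity sits at the
  random background (~5–10% for typical lengths), far below any threshold
  of interest.
- `gen_ss_pair` draws observed strings as alternating segments with
  geometric lengths (minimum 1, mean 7 residues — the scale of typical
  secondary structure elements) and corrupts an exact count of positions,
  so realized Q equals the target within `1/length`. Corruptions are
  independent single residues; real predictor errors cluster at segment
  boundaries, so synthetic SOV values are lower at a given Q than on real
  predictions — tests built on this generator exercise the measures'
  arithmetic, not realistic SOV levels.
- `gen_pssm` draws rows from a symmetric Dirichlet; concentration sweeps
  entropy continuously from ~0 (near one-hot) to $\log_2 20$
  (near uniform). It emulates profile *entropy structure*, not
  evolutionary substitution patterns.

All generators are seed-deterministic (`withr::with_seed`), and their
contracts (exact substitution counts, Q within `1/length`, entropy
monotone in concentration) are themselves tested.

What passing tests on these fixtures establishes is that the measures,
reductions and fits implement their definitions exactly; they do not
establish accuracy levels on real predictor output, which depends on
error clustering and composition the generators deliberately idealize.

# Numerical and design choices

- $0\log_2 0 = 0$ throughout entropy computation.
- SOV interval arithmetic is integer; the score itself is reported on the
  $[0,1]$ scale (×100 only at display layers).
- Sample-size rounding is round-half-up; with very deep halvings the
  published series' smallest counts cannot be reproduced exactly from the
  rounded headline sizes, so the rounding rule is fixed and documented
  rather than tuned.
- The greedy tie-break (length, then id) is arbitrary but frozen;
  different tie-breaks give different—equally valid—NR sets.
- Problem sizes in the test suite (families of ≤ 20 sequences of ≤ 60
  residues, 1000 random SOV pairs of length ≤ 30, $10^4$ entropy rows)
  are chosen so the whole oracle-verified property suite runs in well
  under a minute while still exercising hundreds of random instances.

# Known limitations

- The time-cost models predict one specific hardware/software setup;
  only their functional form transfers.
- The NR engine is quadratic in dataset size and meant for method study
  and moderate datasets; production-scale runs (> 10⁵ sequences) should
  plug an external clustering engine into `identity_fun`.
- Predicted SOV-versus-size curves are not modelled: their fitted forms
  were never published, and refitting them requires the raw measurements.
- 3-state Q/SOV on 3-state input is supported, but `evaluate_set`'s
  coupled 8-and-3-state report requires 8-state input, as produced by
  8-state predictors.
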