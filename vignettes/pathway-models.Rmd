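---
title: "Pathway models for the correlated evolution of colouration and aggregation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway models for the correlated evolution of colouration and aggregation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evopath)
```

## The model

evopath fits Pagel-style *pathway models* for two binary traits evolving
jointly on a time-calibrated phylogeny. The motivating system is caterpillar
antipredator strategy: colouration (cryptic vs aposematic) and aggregation
(solitary vs group-living). The two traits combine into four composite
states,

    1 SC solitary-cryptic    2 SA solitary-aposematic
    3 GC group-cryptic       4 GA group-aposematic

which evolve as a continuous-time Markov chain along the tree. The central
assumption of the correlated-evolution framework is that both traits never
change in the same instant: the generator `Q` has rate 0 at the two "dual"
transitions (SC<->GA, SA<->GC), leaving eight free single-trait rates. The
fixed numbering (`rate_mapping()`) is

    q1 GC->SC   q2 SA->SC   q3 SC->GC   q4 GA->GC
    q5 SC->SA   q6 GA->SA   q7 GC->GA   q8 SA->GA

so rates 7, 6, 2, 3 form the clockwise cycle GC -> GA -> SA -> SC -> GC and
rates 4, 8, 5, 1 the counterclockwise one. This numbering is not arbitrary:
`derive_rate_mapping()` re-derives it, uniquely, from the anchor q3 = SC->GC
together with the structure of the named constraint models (the symmetric
pairs eq13/eq25/eq47/eq68, the trait-independence pairs eq57/eq24/eq16/eq38,
and the cycle ordering), and the test suite asserts uniqueness.

Transition probabilities over a branch of length `t` are `expm(Q t)`. Note
that a *rate* constraint is not a *probability* constraint: even with the
dual rates fixed at zero, `P(t)[SC, GA] > 0` for `t > 0`, because two single
steps can compose along a branch.

The likelihood of the tip data is Felsenstein's pruning recursion: postorder
partial-likelihood vectors with per-node rescaling (676-tip trees with small
rates underflow double precision without it). Unknown tip states are
all-ones partials. At the root the partials are combined with one of three
weightings (`RootPolicy`): `flat` (1/4 each; the default, mirroring
corDISC-style equal root weighting), `stationary` (the stationary
distribution of `Q`), or `fitzjohn` (weights proportional to the root
partials). The source analysis does not state its root treatment, so the
policy is an explicit argument recorded in every result, and the default is
documented rather than asserted as the original choice.

## The model space and its comparison

The constrained-model space is exactly:

* the **general** model, all 8 rates free (K = 8);
* **254 zero-constrained models** (`n1`, `n34`, ...): every nonempty proper
  subset of the eight rates fixed at 0 (2^8 - 2 = 254);
* **8 equality-constrained models** (K = 7): the four symmetric models
  eq47, eq68, eq25, eq13 tying a transition to its reverse, and the four
  trait-independence models eq57, eq24, eq16, eq38 tying the same move
  across contexts of the other trait.

`run_model_selection()` fits all 263 and builds the comparison table:
`AIC = 2K - 2 logLik`, `dAIC = AIC - min(AIC)`, the evidence ratio
`exp((AICmin - AIC)/2)`, and Akaike weights normalized **over the full
fitted set**, not a displayed top-10 (in the published table the ten best
weights sum to about 0.979, which identifies full-set normalization). Ties
in AIC are broken lexicographically by model name, for determinism. Zero
sets that disconnect the chain are still fitted — the likelihood remains
well defined — and flagged (`reducible`) in the table, since dropping them
would change the weight normalization.

## Fitting

Free parameters are the equality classes of non-zeroed rates, optimized in
log space (which enforces positivity) with box bounds `q` in
`[1e-9, 100]` per unit branch time. The search is a derivative-free
Nelder-Mead simplex from multiple starts: a fixed moderate start
(`q = 0.5`), an optional start projected from the general-model MLE (used
automatically for every constrained model in a sweep), and `n_restarts`
log-uniform random draws (default 10; seeded). The winner is then polished
by restarting the simplex from the incumbent until the objective stops
improving, because a single simplex pass reliably stalls on the ridges that
zero constraints create. Bounds are enforced by clamping plus a quadratic
penalty, and a `boundary` flag marks rates that finish at a bound. Fits are
deterministic given (data, spec, seed, settings), and a failed convergence
is reported in the result, never silently dropped.

Tolerances: convergence at `reltol = 1e-8` on the log-likelihood;
the nestedness sanity check (a more constrained model can never beat a less
constrained one) is asserted in the tests at `1e-6`, the realistic
agreement of two independent simplex runs.

## Ancestral states

`marginal_ancestral_states()` reports, for every internal node, the
posterior probability of each composite state given **all** tips (the
quantities drawn as node pies in plotRECON-style figures): marginal, not
joint/MAP, reconstruction. It combines the downward (pruning) partials with
an upward pass carrying the outside-subtree likelihood; sibling
contributions are assembled by prefix/suffix products rather than division,
so exact zeros in `P(t)` (zero-length branches, reducible generators) are
handled without 0/0. Nodes are identified by their postorder index plus a
hash of the sorted descendant tip labels, which is stable across Newick
serializations. `reconstruct_under_best()` runs the reconstruction under
the AIC-best model of a completed sweep.

Both the likelihood and the marginals are validated against independent
brute-force enumeration over all joint internal-state assignments
(`enumerate_assignments_loglik()`, `enumerate_node_marginals()`) at `1e-9`
on hundreds of small random instances.

## The synthetic-data generator

The package deliberately ships no copy of the study's tree or trait data;
every stage is exercised on simulated data with the structure the analysis
assumes.

* `simulate_yule_tree()` grows a pure-birth (Yule) tree forward in time,
  conditioned on the tip count, matching the tree prior used for the
  original inference. Trees are ultrametric; by convention depth is
  rescaled to 1 and rates are read "per unit tree depth", since only the
  product of rate and time is identified (multiplying all rates by `c` and
  dividing all branch lengths by `c` leaves the likelihood unchanged).
* `simulate_traits()` runs the exact CTMC forward along each branch
  (exponential waiting times, embedded jump chain) and returns the latent
  internal-node states alongside the tips, so recovery experiments can
  score reconstructions against truth.
* `emulate_study_dataset()` produces a 676-tip dataset whose expected
  composition matches the study's 80.0 / 12.1 / 3.1 / 4.7% split of
  SC/SA/GC/GA species. Calibration tunes rates, not trees (rejection
  sampling on a 676-tip joint composition is hopeless): a deterministic
  Nelder-Mead search over n1-constrained rates (q1 = 0, mirroring the best
  published model) matches the expected tip distribution — for an
  ultrametric tree this is just the root distribution (solitary-aposematic,
  the published root inference) pushed through `expm(Q * depth)`,
  independent of topology — with a small ridge penalty keeping the
  under-determined search well posed. Two aspects of the start are part of
  the documented calibration: the qualitative pattern (colouration labile,
  aggregation slower, net flow toward SC) and the overall speed, set fast
  enough (several colour transitions per root-tip path) that tip states
  decorrelate across the tree and the *realized* composition of a single
  dataset concentrates near its expectation; across a 20-seed bank the
  realized SC fraction stays within [0.70, 0.90].

What the generator does **not** emulate: the real tree's non-Yule features
(calibrated node heights, lineage-specific sampling of five superfamilies),
phylogenetic signal in sampling, state-dependent diversification, or
observation error in trait coding. Tests passing on these simulations
demonstrate that the machinery is correct under the model's own
assumptions, not that the model is adequate for any particular empirical
dataset.

## Recovery experiments and their honest limits

`recovery_experiment()` wraps simulate -> fit -> compare. Two standing
results from the test suite (fixed seeds, one CPU):

* With a general-model truth with well-separated rates on 500-tip trees,
  the median relative error of recovered rates (over free rates and 20
  replicates) is well under 50%. The two counterclockwise rates q1 (GC->SC)
  and q8 (SA->GA) are individually the least identifiable — their
  *per-rate* median errors can exceed 50% at this size — because the states
  they leave are rare at stationarity and a nonzero q1 can be partially
  mimicked by the detour GC -> GA -> SA -> SC. This is the information
  geometry of the model, not an optimizer artifact: forcing q1 to its true
  value costs well under one log-likelihood unit on typical replicates.
* With an n1 truth (q1 = 0), AIC prefers n1 over the general model in well
  over 70% of replicates, and the general model essentially never beats the
  truth by more than its 2-unit parameter penalty.

Problem sizes in the routine tests (16-40 tips for fitting unit tests,
300-500 tips and 8-20 replicates for the recovery experiments, 2-6 tips for
the enumeration oracles) were chosen as the smallest sizes at which each
property is cleanly expressed.

## Numerical choices

* **Matrix exponential**: scaling-and-squaring Padé (`arma::expmat`) as the
  robust default; an eigendecomposition fast path is used only when the
  eigenvector matrix has condition number below 1e8, since zero-constrained
  generators are routinely defective or nearly so. Tiny negative entries
  from roundoff are clamped to 0.
* **Underflow**: per-node rescaling with accumulated log scalers in the
  pruning pass; normalized partials in the reconstruction passes.
* **Stationary distributions** solve `pi Q = 0, sum(pi) = 1` by SVD least
  squares; a rank deficiency (reducible chain) is reported via the `unique`
  attribute rather than silently returning one of many solutions.
* **Zero-length branches** are legal everywhere (`P(0) = I`); a unary root
  (one-tip tree) is tolerated as a degenerate case.
* **Determinism**: every stochastic routine takes a seed and restores the
  caller's RNG stream; sweep checkpoints serialize fits at full precision
  (17 significant digits), so a resumed table is bit-identical.

## Known limitations

* No hidden-rate (HMM) extensions, more than two traits, AICc/BIC, model
  averaging, confidence intervals on rates, or stochastic character
  mapping.
* The root policy of the original analysis is unknown; results can be
  sensitive to it on small trees, which is why it is a recorded argument.
* Rate estimates near the `1e-9` lower bound should be read as "zero up to
  this dataset", and the `boundary` flag should be checked before
  interpreting them.
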