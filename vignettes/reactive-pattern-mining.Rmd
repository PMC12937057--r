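---
title: "Mining and testing reactive patterns in simulated reaction networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining and testing reactive patterns in simulated reaction networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crnminer)
```

This vignette is the package's account of its model and the choices made
where the design was genuinely open. It states no empirical result that the
test suite or `scripts/acceptance.R` does not itself compute.

## The hypergraph model of a reaction network

A simulation's chemical reaction network is a directed hypergraph
$G = (V, E)$: one vertex per chemical species, labelled with its SMILES
string, and one hyperedge $e = (T, H)$ per reaction, connecting the set of
reactant species to the set of product species and labelled with the
stoichiometric coefficients. Ordinary graphs with pairwise edges are
ambiguous the moment a species takes part in several reactions or acts as a
catalyst; the hyperedge keeps each reaction a single, faithful object.
Catalysts (the same species in tail and head) are permitted and never
cancelled.

Two consequences of building one vertex per species ("node injectivity")
do all the algorithmic work:

* each hyperedge has an injective, deterministic text encoding
  (`canonical_item()`): coefficient–label pairs sorted bytewise by label
  within tail and head, joined as `tail >> head` with the delimiter
  characters `\ * + >` backslash-escaped inside labels. Two reactions share
  a key exactly when tail, head, and all coefficients agree, and the key
  parses back to the reaction (`parse_item()`);
* a hypergraph is determined by the *set* of its edge keys, and the
  subhypergraph relation between node-injective hypergraphs reduces to
  edge-key containment, because the only candidate label-preserving vertex
  map is the one forced by the labels. The test suite verifies this
  reduction against an exhaustive injective-mapping search.

The core treats species labels as opaque text. SMILES canonicalization is
a one-pass ingest concern (`read_event_log(canonicalize = TRUE)`, via Open
Babel through ChemmineOB) so that the same molecule written two ways
collapses to one vertex; records whose SMILES fail to parse are rejected
with their line numbers. Reactions whose two sides are the identical
species multiset (pure proton transfers, for example) are retained in the
model — they are real events — but flagged, and network export drops them
by default, which mirrors the usual reporting convention.

## Frequent pattern mining by reduction to itemsets

Collections of hypergraphs become collections of itemsets (one transaction
per simulation), and mining frequent directed subhypergraphs becomes
frequent itemset mining. Support is the number of *simulations* containing
the pattern — within-simulation multiplicity is discarded at construction,
so a pattern firing fifty times in one trajectory counts once. This is the
right notion when trajectories differ by starting configuration: recurrence
across independent runs, not abundance within one, is the evidence of
interest.

`mine_frequent()` enumerates, for a frequency threshold $\sigma \in (0,1]$,
the itemsets occurring in at least $\lceil \sigma N \rceil$ of $N$
transactions ("at least" semantics, hence the ceiling; a tolerance of
$10^{-9}$ absorbs binary representation of products like $0.3 \times 10$).
Two modes:

* `mode = "closed"` (default) returns the closed frequent itemsets — no
  strict superset with equal support — via an LCM-style prefix-preserving
  closure extension. Each closed set is generated exactly once, without
  materializing the full frequent family, which is what makes the default
  safe on denser collections.
* `mode = "all"` is a tid-set depth-first search (Eclat-style) over every
  frequent itemset, provided because sub-patterns of a closed pattern are
  sometimes wanted explicitly.

Correctness, not any specific engine's internals, is the contract: both
modes are tested for exact agreement with brute-force $2^{|U|}$ enumeration
on small universes, and mined supports are cross-checked against the
subhypergraph oracle. Output order is fixed (support desc, size desc,
lexicographic key) so every downstream artifact is reproducible
byte-for-byte. An optional `max_pattern_edges` cap bounds the worst case —
the underlying problem is NP-hard and adversarial inputs can blow up the
closed family; the cap simply truncates pattern size and is off by default.
Common thresholds in reactor studies are $\sigma = 0.10$ and
$\sigma = 0.25$; 0.10 is the package default.

## Enrichment testing

For a binary condition $Y$ (two temperatures, two water fractions), pattern
presence per simulation is a Bernoulli variable, and independence of
presence and condition is tested per pattern on the 2×2 table with
Fisher's exact test. Choices that the literature leaves open, fixed here:

* **Two-sidedness.** The point-probability convention: the p-value sums the
  hypergeometric probabilities of all tables with the observed margins
  whose point probability does not exceed the observed one (with a
  $1+10^{-7}$ relative guard for floating-point ties). This matches the
  mainstream implementations, including `stats::fisher.test`, against
  which the implementation is verified exhaustively for all margins with
  $n \le 30$ — but through an independent enumeration built directly from
  binomial coefficients. All hypergeometric arithmetic is done in log
  space, so a few hundred simulations per arm cannot underflow.
* **Degenerate margins** (support 0 or $n$, or an empty arm) return exactly
  1: no evidence is obtainable.
* **Testability.** The minimum attainable p-value $\psi(n_1, n_2, x)$ is
  the minimum of the two-sided p-value over all feasible allocations of the
  support $x$ at fixed arm sizes — computed exactly by enumeration and
  memoized on $(n_1, n_2, x)$, which makes testing thousands of patterns
  cheap since $x$ takes at most $n+1$ values.
* **Tarone's correction** finds the smallest integer $K$ such that at most
  $K$ hypotheses have $\psi \le \alpha/K$; patterns above the corrected
  level $\alpha/K$ are untestable and discarded before the Bonferroni-style
  comparison $p \le \alpha/K$. This controls the FWER at $\alpha$ and is
  never more stringent than plain Bonferroni over all $m$ patterns. The
  package verifies the FWER empirically under the conditional
  (hypergeometric) null.
* **FDR variant.** The cited FDR procedure for discrete tests is not fully
  specified by its users; here `method = "tarone_fdr"` is implemented as
  Benjamini–Hochberg step-up restricted to the Tarone-testable set. This is
  an interpretation, and is labelled as such in the documentation; the FWER
  method is the default.
* **Effect size.** The unconditional sample odds ratio $(ad)/(bc)$, with
  the Haldane–Anscombe +0.5 on all cells when any cell is zero, and the
  Woolf log-normal 95% CI. Deterministic and closed-form; the direction is
  set by `condition_a` (first label lexicographically, by default).
* Patterns are mined from the pooled transactions of both arms before
  testing, so the testable count is well defined prior to correction. If a
  per-arm threshold union is wanted instead, mine each arm and take the
  union of pattern keys before `significant_patterns()`.

## Kinetics

`eyring_rate()` is transition-state theory,
$k = \kappa\,(k_B T/h)\,e^{-\Delta G^\ddagger/RT}$, with
$k_B/h = 2.083661912\times10^{10}\,\mathrm{s^{-1}K^{-1}}$ and
$R = 1.987204259\times10^{-3}\,\mathrm{kcal\,mol^{-1}K^{-1}}$. Units are
fixed — kcal/mol and kelvin — with no auto-detection, because silent unit
errors dominate the failure modes of this one-liner. The transmission
coefficient defaults to 1 (plain Eyring estimates); no tunneling or
recrossing corrections are attempted.

## The hyperdynamics bias on model surfaces

The boost potential is the lower-bound Gaussian-accelerated form: below a
boost level $E$, $\Delta V = \tfrac{k}{2}(E - V)^2$; at and above $E$ the
surface is untouched. The join at $V = E$ is $C^1$, $\Delta V \ge 0$
everywhere, and for $k \le 1/(E - V_{\min})$ the biased surface is monotone
in $V$ on the filled region — `validate_bias()` warns when the standard
bounds ($E \ge V_{\max}$ sampled, $k \le 1/(E - V_{\min})$) are violated
rather than failing, since exploratory use legitimately probes them.

The printed compact form of the spherical confinement term,
$m_n k_{\mathrm{conf}}/2\, r^2_{\mathrm{conf}}(t)$, carries no positional
dependence; the only physically sensible reading of "spherical confinement
on atom $n$" is a harmonic wall on the excursion, and that is what is
implemented: $\tfrac{m\,k_{\mathrm{conf}}}{2}\max(0, |x - c| -
r_{\mathrm{conf}}(t))^2$, exactly zero inside the sphere. This
interpretation is deliberate and documented rather than silent. The radius
schedule is user-supplied; the shipped default is a $C^1$ smoothstep
periodic contraction–expansion, standing in for schedule details that are
not part of this package's scope.

The Langevin demonstration uses the BAOAB splitting (reduced units,
$k_B = 1$) with fixed-seed noise streams. Well-to-well transitions are
counted with a hysteresis band around the barrier (default half of the well
half-width) so barrier-top recrossings do not inflate the count. The demo
exists to show rate enhancement and thermostat sanity on 1-D/2-D toy
surfaces — it is not an MD engine, makes no claim about many-atom systems,
and no reweighting of boosted statistics is provided.

## The synthetic generator: what it emulates, and what it does not

`generator_spec()` encodes the statistical assumptions the testing model
makes about real campaigns: independent simulations; per-simulation binary
presence; a condition that changes presence probabilities of planted
patterns while the background is condition-independent. Defaults define
the study conditions and are not tuning knobs:

* two arms labelled 39 K and 62 K, 100 simulations each — the scale at
  which binary presence frequencies stabilize in reactor studies;
* 20 background reactions over small NH3/CO2/H2O-system SMILES, each
  included independently with probability 0.3 — busy enough that closed
  mining is non-trivial, sparse enough that background pairs sit near the
  default support threshold;
* one planted two-step carbamic-acid pattern at presence probabilities
  (0.8, 0.1), an implied odds ratio of 36 — a strong association of the
  kind the method is meant to flag.

What the generator does *not* emulate: kinetics (no time ordering, no
within-simulation multiplicity), mechanistic coupling between background
reactions, encounter rates, or any chemistry beyond the species strings.
Passing the end-to-end tests therefore shows that mining and testing
recover planted statistical structure under the model's own assumptions —
it says nothing about bond perception, trajectory processing, or whether a
real campaign's simulations are truly independent.

## Numerical and testing choices

* Sorting everywhere is bytewise (`method = "radix"`), so canonical keys,
  mining output and CSVs are platform- and locale-independent; the
  determinism test reruns `synth → mine → test` and compares bytes.
* Support thresholds round up with a $10^{-9}$ slack;
  Fisher tie comparison uses a $1+10^{-7}$ relative guard (the same
  convention as `stats::fisher.test`); $\psi$ memoization is keyed on
  `(n1, n2, x)`.
* Exhaustive verification sizes: itemset mining against $2^{|U|}$
  enumeration up to 12 transactions × 10 items; Fisher and $\psi$ against
  enumeration for all margins with $n \le 30$; the null FWER simulation
  uses 1000 replicates of 200 patterns at 50 + 50 simulations; power and
  recovery use 200 generator seeds at 100 + 100. These sizes make the
  checks exact or tight while keeping the default test run comfortably
  inside a routine CI budget.
* The Langevin thermostat check compares the kinetic temperature across
  independent seeds to the set point within three standard errors plus a
  small discretization allowance, acknowledging both Monte-Carlo error and
  the $O(\Delta t^2)$ bias of the splitting.

## Known limitations

* Only node-injective hypergraphs are mined; general subhypergraph
  isomorphism (duplicate labels) is out of scope, as are weighted or
  encounter-normalized supports.
* The condition is strictly binary; multi-level designs need repeated
  pairwise runs with their own corrections.
* `mode = "all"` can be exponential on dense collections; use the closed
  default or `max_pattern_edges`.
* The FDR method is an interpretation (BH on the testable set), not a
  reproduction of any specific published discrete-FDR procedure.
* Odds ratios from the Haldane-corrected estimator are biased toward the
  null for small arms; the CIs, not the point estimates, should carry the
  inferential weight.
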