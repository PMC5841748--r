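---
title: "Temporal Boolean modelling of the IBD cytokine network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal Boolean modelling of the IBD cytokine network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ibdlogic)
```

## The modelling problem

Inflammatory bowel disease is driven by a densely cross-regulated cytokine
and immune-cell network in the gut mucosa. Most of what is known about the
wiring is qualitative — activations and inhibitions reported across many
heterogeneous experimental settings — which rules out a fully parameterised
dynamical model but fits Boolean logic modelling well. Each node holds a
binary state (active / not active) and updates through a logic rule over
its regulators; long-run node activity is read off once the dynamics reach
their attractor regime.

Plain Boolean rules cannot express *sustained* regulation: a cytokine that
needs several iterations of exposure before it shuts a cell type down, or
an antimicrobial response that must persist before it clears an antigen.
The engine therefore extends the rule language with two temporal window
operators over a node's recent history:

* `ALL(X, w)` — 1 iff `X` was active at **every** one of the `w` most
  recent completed iterations;
* `ANY(X, w)` — 1 iff `X` was active at **at least one** of them.

History that does not exist yet (the start of a run) counts as 0, so
threshold effects cannot fire before enough iterations have elapsed.

## Update semantics

`simulate_network()` implements three disciplines:

* **synchronous** — all nodes update simultaneously from the previous
  state; deterministic, used for exact attractor detection and for
  cross-checks against brute-force state-transition enumeration;
* **asynchronous** (default) — each iteration draws a fresh uniformly
  random permutation of the nodes and updates them one at a time, each
  update seeing the freshest current values. Every node updates exactly
  once per iteration, which keeps "iteration" well defined for the
  lag-`i` window terms;
* **asynchronous_single** — one random node per iteration, exposed for
  sensitivity checks only (it rescales time and therefore reinterprets
  window widths).

Two choices deserve emphasis because they pin down the temporal
semantics. First, window terms always read *completed-iteration* history,
never the partially updated sweep; this makes the lagged terms independent
of the within-iteration update order and keeps asynchronous runs
reproducible in distribution. Second, knockout/overexpression clamps are
enforced in the initial state, after every individual update, and in all
recorded history, so a clamped node is constant everywhere the dynamics
can observe it.

Randomness is deterministic: each repetition derives its own counter-based
stream from the master seed, so a (model, config, seed) triple yields a
bit-identical ensemble on any platform.

## Readouts

The long-run readout is the per-node ON-fraction over the trailing half of
the run, averaged across repetitions (`summarize_activation()`). The
trailing-50% window is a package default: the transient of the bundled
model dies out within a few hundred iterations at the reference protocol
(25 repetitions × 5000 iterations), and `stationarity_gap()` — the maximum
per-node difference between the two halves of the summary window — is
reported so non-convergence is visible rather than silent. Under
synchronous updating `detect_attractor()` instead hashes the extended
state (current bits plus the trailing `W − 1` history columns, `W` the
maximum window width) and returns the exact fixed point or minimal cycle
period; non-recurrence within the configured iterations is reported, not
raised.

## The bundled disease network

`build_ibd_model()` loads a 43-node model: three bacterial antigen inputs
(PGN, LPS, MDP — peptidoglycan, lipopolysaccharide, muramyl dipeptide)
that stay ON unless an antimicrobial effector (perforin, granzyme B,
defensins) has been active for `Ag_elim` consecutive iterations; 39
internal nodes covering the TLR/NOD–NFkB axis, the main interleukins, T
helper subsets and their memory pools, NK and NKG2D-bearing cells,
macrophages, dendritic cells and fibroblasts; and the matrix
metalloproteinases output `MMPs`, a surrogate for tissue damage. The named
window widths are part of the model file: `Ag_elim = 6` (disease),
`downreg_cyt = 4`, `upreg_cyt = 3`, `upreg_cell = downreg_cell =
upreg_rec = 2`, and activation thresholds of 3 for Th0 priming, Treg
induction, defensin induction and NKG2D-ligand feedback.

Condition presets differ only in parameters, never in rules. The disease
preset keeps `Ag_elim = 6` (impaired clearance); the healthy preset sets
`Ag_elim = 1`, i.e. a single iteration of effector activity clears
antigen. The exact healthy parameterisation is a genuinely open design
point — effective clearance is the defining difference of the disease
condition, and `Ag_elim` is the knob that encodes it, so the package
models health as the minimal threshold and exposes `ag_elim` as an
argument for sensitivity analyses. Both conditions start with the three
antigens ON and everything else OFF (chronic exposure).

Two transcription notes on the bundled rule file. The IFNg rule adopts the
reading "NK AND (antigen OR-block) AND (cytokine block)" of an ambiguous
source fragment; the alternative reading (antigen block OR cytokine
block) was implemented and compared — it changes no interaction and moves
no downstream readout materially, and the conjunctive reading is kept as
canonical. Parameter-name spelling variants were canonicalised to one
underscore form per parameter (documented at the top of
`inst/extdata/ibd_model.dsl`).

## Interaction extraction

`extract_interactions()` defines the network's edge list: one interaction
per distinct (regulator, target, sign) triple, where a regulator is any
node occurring in the target's rule (atom or window term) and the sign is
the parity of enclosing NOT operators — activating for even, inhibitory
for odd. A node occurring under both parities contributes both edges;
self-references count. Under this convention the bundled model has 299
signed interactions (280 distinct regulator–target pairs, 19 of them with
both signs). Counting conventions genuinely matter here: occurrence
counts, unsigned pairs and windowness-aware variants give different
totals, so the package fixes and documents this one.

## Perturbation screen

`knockout_matrix()` clamps each node to 0 in turn (reference protocol: 24
repetitions × 999 iterations, asynchronous) and reports the Perturbation
Index PI(k, j): the ratio of node *j*'s mean attractor activation under
knockout of *k* to the matched unperturbed baseline. Both means are
shifted by ε = 1/(iterations × repetitions) — one ON state in the whole
ensemble — which keeps the ratio defined and equal to 1 when both means
are 0, at the cost that a fully silenced node scores ε/(baseline + ε)
rather than exactly 0. Classification bands follow the heatmap
convention: PI ≤ 0.8 downregulated, PI ≥ 1.25 overexpressed, strictly
between unchanged; the boundaries are closed on the altered side.
Clustering of knockout and response profiles uses average linkage on
Euclidean distance (`stats::hclust`); with tied distances the merge order
follows the matrix's row order — deterministic, but not permutation
invariant, which is why the screen fixes the node order of the model file.

## Therapy simulation

`simulate_therapy()` compares a preset's clamped run against an untreated
run under the identical configuration and master seed, reporting the
percent change of mean MMPs activation; `compare_therapies()` computes the
untreated ensemble once and shares it across presets. The seven presets
map antibody therapies to knockout of their target (anti-TNFa, anti-IL17,
anti-IFNg, anti-IL2, and the dual knockout anti-IL12-IL23),
granulocyte/monocyte apheresis to knockout of the macrophage node, and
recombinant IL10 to clamping IL10 ON for the whole run — the simplest
reading of exogenous supplementation. Perturbations act from iteration 0;
percent changes are always reported against the untreated *disease* run,
not against health.

## Validation against the literature survey

`validate_ibd_model()` simulates both condition presets with one
configuration, computes per-node directions with a tolerance band
(default 0.02 absolute activation, sized to the Monte-Carlo noise of the
reference protocol), and scores them against the bundled annotation table:
31 nodes reported upregulated in patients, 9 altered (conflicting
reports), 3 unknown. The two nodes reported downregulated in blood but
upregulated in mucosa (Treg, DC) are scored as upregulated, since the
model represents the mucosal compartment.

A structural caveat: the two memory pools Th0_M and Th17_M are absorbing
(`... | SELF` with no decay term), so in *any* chronic-exposure condition
they eventually saturate at 1; in the healthy condition the absorption
merely starts later. Their disease-minus-healthy difference at the
reference protocol is therefore a small, heavy-tailed positive quantity
that straddles the 0.02 tolerance, and the matched-upregulated count
fluctuates between 29 and 31 across master seeds. This is a property of
the published rule set, not of the engine; a decay term on the memory
pools would remove it, but the package ships the rules as printed.

## Fixtures and test oracles

`named_fixtures()` provides hand-checkable toys (constant, negation
oscillator, two-node feedback, feed-forward chain, a width-3 temporal toy,
a clamp toy); `random_model()` draws validated random networks whose rules
are shallow OR-of-AND forms, keeping truth tables cheap to enumerate. The
test-suite uses them for the properties that define the engine: language
round-trip identity, agreement of the compiled engine with a naive
brute-force enumerator over **all** initial states of temporal-free
models, window-width-1 reduction to the lagged atom, clamp invariants, and
the all-zero fixed point of the bundled model when antigens are clamped
off. The random fixtures emulate structure, not biology: they do not
reproduce the long feedback cycles, the absorbing memory pools or the
input-driven regime of the disease network, so passing them validates the
simulator's semantics, not the disease model itself — that is what the
condition-comparison and therapy analyses are for.

## Problem sizes and limitations

The analyses default to the reference protocols (25 × 5000 for condition
and therapy runs, 24 × 999 for the 43-knockout screen); unit tests run
reduced sizes (hundreds of iterations, a handful of repetitions) chosen so
that every qualitative conclusion they assert is already stable, and the
full protocols are exercised by the acceptance checks. Known limitations:
no partial (graded) inhibition — clamps are all-or-nothing; no
combinatorial knockout screen beyond user-supplied perturbation lists; the
asynchronous attractor is characterised statistically (stationarity gap),
not enumerated; and SBML-qual export of temporal models is necessarily
approximate (window terms have no counterpart in the format and are
replaced by their plain atoms, with the document annotated accordingly).
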