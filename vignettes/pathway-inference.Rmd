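---
title: "Predicting biosynthetic pathways from paired omics data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting biosynthetic pathways from paired omics data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`pathomics` turns a paired untargeted metabolomics / transcriptomics
experiment into ranked, enzyme-supported biosynthetic pathway hypotheses.
This vignette explains the model behind each stage, the parameters that
matter, what the synthetic data generator does and does not emulate, and
the numerical choices made where the design was genuinely open.

## The integration model

The biological premise is that genes and metabolites of one biosynthetic
pathway respond coherently to the conditions sampled (treatments, tissues,
time points), while the chemistry connecting consecutive metabolites is
constrained: an enzymatic step changes a substrate's monoisotopic mass by
the mass transition of its reaction class (+15.994915 Da for a
hydroxylation, −2.015650 Da for a desaturation, and so on). The workflow
therefore demands two independent kinds of evidence for every proposed
reaction: *statistical* (the two metabolites and a candidate enzyme
transcript co-vary) and *chemical* (their mass difference is explained by
a reaction rule that the transcript's protein family can catalyze).

### Correlation and mutual ranks

Rows are first rescaled robustly: `x -> (x - median(x)) / MAD(x)` with the
raw median absolute deviation `MAD = median(|x_i - median(x)|)` (no
consistency constant). MAD rescaling resists the single-sample spikes
common in induction experiments; rows with zero MAD carry no rankable
signal and are dropped with a log message. Rescaling is on by default
(`mad_rescaling` in the run configuration) and is the only normalization
the package applies — inputs are expected to be library-size/batch
normalized already.

Pearson coefficients are computed for all transcript x feature pairs and
kept when `|r| >= min_abs_r` (default 0.1, deliberately permissive — the
mutual-rank transform does the real pruning). The two-sided p-value tests
a true correlation of zero via `t = r sqrt((n-2)/(1-r^2))` on `n - 2`
degrees of freedom and is reported unadjusted; downstream thresholds, not
multiple-testing control, gate the predictions.

Raw correlation magnitudes are incomparable across transcripts with
different dynamic ranges, so each edge is re-expressed through its mutual
rank: `MR = sqrt(rank_t(f) * rank_f(t))`, the geometric mean of where f
falls among t's partners and where t falls among f's partners. Ranks are
computed within cross-omics partner lists only, by descending `|r|`
(sign-agnostic, since edges are admitted by absolute correlation), with
average ranks on ties — the tie policy is our choice; it makes the
statistic permutation-invariant. `MR = 1` means mutual top partners.

Mutual ranks become edge weights through an exponential decay,
`w = exp(-(MR - 1) / DR)`, at four decay rates `DR ∈ {5, 10, 25, 50}`
(one network per decay rate; small DR keeps only mutual near-top
partners). Edges with `w < 0.01` are excluded. We interpret the decay
transform with the decay-rate division: a rate-free transform could not
produce the different-size networks the four rates are meant to give, and
the division matches the mutual-rank coexpression methodology this stage
is modelled on. This is the package's central formula interpretation.

### Functional clusters

Each decay-rate network is clustered with a self-contained
reimplementation of cohesiveness-based overlapping clustering
(ClusterONE): grow a candidate from each uncovered seed (descending
weighted degree, ties by node id — determinism is our addition) by the
single add/remove move that most improves
`f(C) = w_in / (w_in + w_bound + penalty |C|)`; merge candidates with
overlap `omega = |A∩B|^2 / (|A||B|) >= 0.8`; discard clusters smaller
than 3. Penalty 2 and threshold 0.8 are the original method's defaults;
all three are configurable because the upstream tool's exact settings are
not published. A reported functional cluster must contain at least one
transcript and one mass feature; pure-transcript clusters are kept
internally so coexpression edges can merge clusters later.

Each cluster's p-value compares internal against boundary edge weights
with a one-sided rank-sum test. The published description names only "a
comparison" — we compute `P(W >= w_obs)` from the exact tie-aware null
distribution of the rank sum (a dynamic program over doubled average
ranks, equivalent to enumerating all assignments), so an all-tied
configuration gives p = 1 naturally. A cluster with no boundary edges has
no outside comparison; it is assigned the smallest representable double
and flagged, rather than an arbitrary zero.

### Adduct annotation

An LC-MS feature is an ion; its neutral mass depends on the adduct
hypothesis: `M = (mz |z| - shift) / n` for an [nM+X] adduct of charge z
and mass shift `shift`. The shipped table has 48 adducts (protonation,
alkali attachment, ammonium, solvent clusters, water losses, multimers,
multiply charged forms; both polarities); a user CSV overrides it.
Candidates are structures whose database mass agrees within `ppm`
(default 20; tighten to ~5 for Orbitrap-class data). The ppm error is
taken relative to the database mass — the lookup direction — which is the
conventional choice. Annotation is restricted to the acquisition's
ionization mode (`ionization_mode`, default positive): mixing polarities
creates systematically aliased neutral-mass hypotheses (e.g. protonated
vs deprotonated interpretations differ by two proton masses, 2.0146 Da —
within tolerance of a desaturation transition). Features with several
surviving hypotheses contribute one node per hypothesis; unannotated
features fall back to a default [M+H]+ hypothesis so they can still
anchor reactions, and manual annotations bypass matching entirely.

### Reaction rules and mass transitions

Rules are single-substrate reaction SMARTS with a signed transition
`Δm = m_product - m_substrate` (recomputed on load and checked to 1e-6 Da)
and tiered enzyme associations: `strict` (experimentally validated) ⊆
`medium` (+ domain-mining predictions) ⊆ `loose` (+ orthology-propagated
links). Stereochemical templates (`@`, `/`, `\`) and multi-substrate
templates are filtered on load — mass spectrometry cannot distinguish
stereoisomers, and the rule formalism is single-substrate. Individually
malformed rules are skipped with a warning rather than aborting a batch,
because large public rule dumps always contain unparsable entries. The
"Pfam cutoff" (default 6) drops associations whose Pfam is linked to more
than that many distinct rules: such generic domains (transferases,
short-chain reductases) would support almost any transition. We apply the
cutoff at the association level; taxonomy filtering is association-level
too.

A transition index holds every rule under its signed transition —
bidirectional rules under both signs — and is queried with the absolute
tolerance implied by the global ppm setting at the dataset's mass scale.

### Network assembly, ghosts, and enzyme support

All ordered node pairs whose mass difference matches an indexed transition
become candidate reactions (a pair may carry several rules; parallel edges
are kept). Ghost mass signatures — virtual intermediates between two
measured nodes two rule steps apart — are inserted at `mass(A) + Δm_1`
when `Δm_1 + Δm_2` explains the gap; in the default `auto` mode this
happens only for features that received no substrate/product assignment,
and at most one ghost sits between two measured nodes per round (depth is
capped at one by choice; the published behaviour is silent on depth).

A candidate pair survives only with enzyme support: a transcript that (i)
is correlated with the substrate or product feature in the active
decay-rate network (DR = 10 by default) and — in the default
cluster-restricted mode — shares a functional cluster with it, and (ii)
carries a Pfam associated with the rule at the active tier. The edge
records every supporting transcript and its correlation; `edge_support`
is the maximum supporting weight.

### DAGs and pathway extraction

For a chosen root metabolite, reaction distance is breadth-first edge
count from the root on the undirected skeleton (edge counts, not weighted
distance — a deliberate simplification). Edges that retreat toward the
root are removed; edges between equidistant nodes may form cycles, which
are broken by repeatedly deleting the cycle edge with the weakest
`edge_support`, ties resolved by the lexicographically smallest
(substrate, product, rule) triple. Tie-breaking is lexicographic
everywhere after the stated support criteria, so the whole workflow is
deterministic: two runs on identical inputs produce byte-identical
outputs. The longest root-originating path (dynamic programming in
topological order; ties by summed support, then lexicographic node
sequence) is the prediction, computed twice — from the root forward, and
from the terminal node of that path on the reversed network — giving the
two directional hypotheses for each input metabolite.

In-silico iteration (`rounds > 1`) applies admissible rules to the
structures attached to nodes, maps product masses back onto the network,
and extends it; products must reproduce the rule's mass transition to
0.005 Da or they are discarded. A divide-and-conquer substructure
prescreen keeps this affordable: structures are tested against a
hierarchy of keys (element presence first, then rule reactant templates
gated on their required elements). The element gates are *necessary*
conditions extracted conservatively from the template text, so
prescreening provably never loses an applicable rule — an equivalence the
test suite checks against brute force on a 20-structure × 30-rule panel.

### Reaction likelihoods

Per-atom site-of-metabolism scores are a pluggable input: a CSV exported
from any external predictor, or a built-in heuristic baseline (uniform or
degree-weighted) intended only for exercising the pipeline — the package
deliberately ships no trained model. Scores are heavy-atom indexed from 0
(hydrogens are not scored). The reaction center — substrate atoms whose
bonding changes — comes from the rule's own atom-mapped template, located
on the substrate by the template match that reproduces the product; when
no template is available, the fallback is the maximum-common-substructure
difference plus attachment atoms. The reaction likelihood is the maximum
score within the center, so raising any center atom's score can never
lower it. Score populations are compared with a two-sided, tie-corrected
Mann–Whitney U (exact by dynamic programming for `n1*n2 <= 400`, normal
approximation with continuity correction beyond).

## The synthetic data generator

`generate_pathway_chain()` plants a chain on an octylbenzene scaffold:
terminal hydroxylation (+15.994915), chain desaturation (−2.015650), then
O-methylation (+14.015650); further steps are hydroxylations. The default
"mixed" ladder exists because a pure hydroxylation ladder makes the
per-step *rule* assignment inherently ambiguous — every step has the same
transition, so any same-transition rule with a correlated carrier
transcript is an equally valid explanation; with three pairwise distinct
transitions the planted rule sequence is uniquely identifiable from
masses. A uniform `kind = "hydroxylation"` ladder is still available.

`generate_paired_omics()` drives the pathway's transcripts (one per step,
annotated with their rule's Pfam) and features with a latent step-response
induction profile — emulating an elicitor-treatment time course — plus
Gaussian noise (`noise_sd = 0.2` of the unit profile by default), with 24
samples, 27 decoy transcripts (unrelated Pfams, independent variation)
and 16 decoy features. Decoy masses are resampled until no
decoy-involving pair difference mimics a rule transition or two-rule sum
and no adduct hypothesis of a decoy aliases a planted structure mass;
without this constraint the planted truth would not be a well-defined
answer key. Feature m/z values are the planted neutral masses observed as
[M+H]+ ions. One integer seed controls all randomness; regeneration is
bit-identical.

What the generator does **not** emulate: chromatography (retention times
are uniform noise), isotope patterns, in-source fragmentation, missing
values, heteroscedastic intensity noise, correlated decoy structure, or
multiple latent factors. Passing the end-to-end recovery test therefore
shows that the machinery is correct and internally consistent under its
own assumptions — not that real data of this size would yield a unique
answer.

## Problem sizes and runtime choices

The shipped test surface runs at toy scale by design: 30 transcripts ×
20 features × 24 samples for the end-to-end recovery, a 20 × 30
structure/rule panel for the prescreen equivalence, ≤ 10-node networks
for exhaustive cohesiveness comparison, and ≤ 40 pooled observations for
exact Mann–Whitney enumeration — sizes at which brute-force oracles are
feasible and the whole suite completes in about a minute. The staged
commands persist every intermediate in a single-file SQLite store
(numeric values travel as shortest round-trip decimals, so reload is
bit-identical), and structure-aware operations batch all SMILES through
one external RDKit process per call.

## Known limitations

- Enzyme support is guilt-by-association: a correlated Pfam match is
  evidence, not proof, and promiscuous domains surviving the Pfam cutoff
  inflate the loose tier.
- Mass transitions cannot distinguish isomeric transformations, and
  stereochemistry is invisible throughout.
- Cluster p-values are descriptive; no FDR control is applied across
  clusters.
- The adduct fallback assigns [M+H]+ to unannotated features; in negative
  mode set `ionization_mode` accordingly so the fallback and annotation
  stay consistent.
- Two-substrate reactions are out of scope of the rule formalism, so
  pathways through condensations cannot be recovered.
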