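---
title: "Organizing the LarA superfamily: models, defaults, and what the tests establish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Organizing the LarA superfamily}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(larasig)
```

## Scope and model

`larasig` organizes a protein superfamily — modeled on the lactate racemase
(LarA) family of NPN-dependent alpha-hydroxyacid racemases/epimerases —
through five linked analyses: multiple sequence alignment, clustering into
phylogenetic groups, gene-neighborhood association, structure-anchored
signature profiles with activity classification, and enzyme kinetics
fitting. The package deliberately does **not** attempt to reproduce any
particular database snapshot: the original family census (hundreds of
sequences retrieved with their genomic contexts from a context-analysis
database) is not archived anywhere we can reach, so all quantitative
validation runs against synthetic families with planted ground truth.

## The synthetic world

`simulate_family()` emulates the features the downstream stages consume:

* a reference of 400 residues carrying the 20 anchor positions
  (catalytic D72/H108/H174/K298, NPN-binding R75/K184/H200, the four
  substrate-recognition anchors 175/176/297/358, and nine further conserved
  positions, in LarA-style 1-based numbering);
* per group, a **signature** at the substrate anchors (defaults: LAR
  FF/V/W, SAR LM/V/W, MAR QK/Q/K, HGR NQ/T/Y, GntE ES/G/N) and conserved
  residues everywhere else among the anchors;
* a two-level substitution process: a group ancestor drawn from the
  reference at `group_divergence_rate = 0.30` per non-anchor site, then
  members drawn from their ancestor at `background_mutation_rate = 0.05`
  (within-group identity about 90%, between-group just under 50%, values typical
  of family-versus-superfamily divergence);
* indels starting at `indel_rate = 0.01` per non-anchor site with geometric
  length (mean 2), never deleting an anchor, so the planted coordinate map
  from reference anchors to member positions stays defined.

The group-ancestor level is an extension of the flat
"members-from-reference" picture: without it, within- and between-group
distances would coincide (groups would differ at only 4 of 400 sites) and
no clustering method could recover the planted partition. The defaults
above are the package's single fixed choice of "realistic"; they are all
exposed in `family_sim_config()`.

What a green test does **not** establish: real families have
phylogenetic correlation structure (the simulator's members are
conditionally independent given their ancestor), composition bias,
heterotachy, and domain-level events; neighborhood tables from real genomes
have operon structure and strand correlation that the independent-inclusion
model ignores. Green tests establish that the pipeline's inference is
correct when its own model assumptions hold — not that the model describes
any particular genome database.

`simulate_neighborhoods()` gives every member exactly `2 * window` flanking
genes; each group-partner COG enters independently with its planted
probability, remaining slots are filled from a background pool.
`simulate_kinetics()` inverts the (competitively inhibited)
Michaelis–Menten model with multiplicative Gaussian noise
(`v_obs = v (1 + eps)`, `eps ~ N(0, cv)`): multiplicative because
enzymological error scales with signal, and it keeps rates positive at
realistic CVs.

## Alignment

The aligner is a progressive profile–profile method: a WPGMA guide tree
over a 3-mer distance, then affine-gap Gotoh alignment of frequency
profiles (BLOSUM62, gap open 10, extend 0.5; a gap of length k costs
`open + k * extend`). Three numerical choices matter:

* **Position-specific gap costs.** The penalty for a gap consuming a
  profile column is scaled by that column's non-gap fraction, so new gaps
  co-locate with existing ones.
* **Residue-vs-gap charge.** Diagonal moves are charged
  `(open/2 + extend) ×` the cross gap fraction of the two columns;
  without this, residues thread through sparsely occupied insert columns
  for free and isolated conserved residues can slip by one column.
* **Duplicate down-weighting and WPGMA.** Rows are weighted by one over
  the multiplicity of their sequence, and the guide tree uses the weighted
  average update. Together these make the alignment of the original rows
  exactly invariant to adding a duplicate sequence — a property the test
  suite checks — which size-weighted UPGMA plus unweighted profiles does
  not satisfy.

Tie-breaking in the DP traceback is fixed (diagonal, then gap in the first
profile, then gap in the second) so results are identical across
platforms. The aligner does no iterative refinement; on simulated
families at default divergence, all anchors of all members land in the
reference anchor's column in most runs, with occasional single-anchor,
whole-group shifts when a member inserts residues immediately adjacent to
an anchor (about 1–2% of anchor placements at the default indel rate;
refinement, which would repair these, is out of scope). Externally
computed alignments can be supplied as aligned FASTA and bypass the
internal aligner entirely.

## Grouping

`cluster_family()` is deterministic agglomerative clustering (average,
single or complete linkage) of the p-distance matrix, merging while the
linkage distance is at most the cutoff. Ties are broken by the
lexicographically smallest pair of cluster representatives. The default
cutoff 0.3 sits between the simulated within-group (~0.09) and
between-group (~0.54) p-distances; on real data it is a free
parameter, which is why the pipeline also accepts a user-supplied grouping
table. Group labels are dense integers ordered by decreasing size;
`split_group()` re-clusters one group at a tighter cutoff and labels the
parts `Na`, `Nb`, ... as done when a group's signature logos are divergent.

## Neighborhood association

Association is presence/absence per member: a COG occurring twice in one
flank counts once, because the "percent association" reading is a fraction
of genomes and presence semantics is robust to tandem duplication. Members
without a neighborhood record stay in the denominator. The partner filter
is strictly greater than 0.30 — the printed rule is "more than 30%" — and
the core NPN-biosynthesis partners (larB/larC/larE labels by default) are
excluded as uninformative. Strand is carried through but ignored.

## Signature profiles and classification

Anchor columns come from the reference row's coordinate map, so every
group's logo is computed over the same columns. Column frequencies are
over non-gap residues only (a gap is never a 21st symbol; gap fraction is
tracked separately, and an all-gap column is reported as missing rather
than zero information). Information content is the WebLogo statistic
`R = log2 20 − (H + e_n)` with `e_n = 19/(2 ln 2 · n)` and clamping at 0.

The five-color rule is: catalytic anchors green, NPN-binding anchors blue
(regardless of conservation — a separate flag records failures), and for
the rest: conserved with the reference residue dominant, yellow; conserved
with a different dominant residue, red; not conserved, black. "Conserved"
means dominant-residue frequency at least `conservation_threshold`,
default 0.7. The source material never quantifies its "conserved within
the group", so 0.7 is a package choice, exposed everywhere it is used, and
never asserted as the original value.

Classification is two rules. First, a group is accepted as a LarA homolog
only when every catalytic and every NPN-binding anchor is conserved with
the reference residue dominant; failing groups (like those excluded from
the original logo analysis) are `is_larah = FALSE`, activity `unknown`.
Second, the three substrate-recognition regions are derived from the
anchor configuration itself — loop = the two positions after the second
catalytic His, helix-11 = the position before the catalytic Lys, helix-14
= the remaining substrate anchor — and matched against an activity table
of allowed residue strings. A definite call requires a unique activity
matching all of its constrained regions; anything less returns `unknown`
with ranked candidates. The built-in table encodes LAR (`FF`, `V`, `W`),
SAR (`LM` or `FM`), MAR (`QK` or `HK`: Gln/His then Lys at the loop — the
"GHK" shorthand's letters do not map one-to-one onto the two loop
positions, so the package encodes the residues, not the shorthand), HGR
(`NQ` with `T`, the NQT motif), and GntE. For GntE the described logo
features (loop EV/S, helix-11 W, helix-14 A/V) and the structurally
observed residues of a characterized member (E/S, G, N) disagree; the
allowed sets are their union, so both variants classify as GntE. Users
can replace the table via JSON.

## Kinetics

`fit_mm()` fits `v = kcat·[E]·S/(K_M + S)` by nonlinear least squares
(`nls`, port algorithm, positivity bounds), initialized from the
Hanes–Woolf linearization — deterministic and derivative-free, so the fit
has no seed sensitivity. Confidence intervals are Wald: `t`-quantile at
the residual degrees of freedom times the linearized standard error;
profile likelihood is out of scope. Rates at or below zero are retained in
the loss (clipping would bias low-substrate fits). `fit_ki_competitive()`
fits `K_i` with `K_M`/`k_cat` either fixed (from a prior fit or given) or
co-fitted; both designs are supported because the original fitting design
is unstated. At the simulation defaults (CV 0.05, 8 substrate levels
spanning K_M geometrically, 3 replicates) the estimators are unbiased
within a few percent and the 95% intervals cover at close to nominal rate
— the acceptance suite measures both over 500 simulations.

`catalytic_efficiency()` always reports the self-consistent quotient
`k_cat/K_M`. Display rounding mirrors kinetics-table precision: two
significant figures below 100, nearest integer above (printed tables mix
the two). Note that some published table rows are *not* the quotient of
their own printed parameters; the package never reproduces such
inconsistencies. `optimum_range()` returns the smallest and largest
measured pH/temperature with activity strictly above 90% of the maximum;
endpoints are measured values, no interpolation.

## Determinism and degenerate inputs

All generators are pure functions of (config, seed) and restore the
caller's RNG state; the analysis stages use no randomness at all, so a
pipeline rerun is byte-identical (manifest timestamps are simply not
written). Degenerate cases follow the contracts: a single sequence aligns
to itself without error; a single-member group cannot be split; an all-gap
anchor column is "missing", not zero bits; empty neighborhood files yield
empty tables; all readers fail loudly on malformed input rather than
truncating.

## Known limitations

* No iterative alignment refinement, HMMs, or bit-compatibility with any
  external aligner; anchor columns can be off by one for a whole group in
  rare indel configurations (see above).
* Clustering cutoffs are behavioral choices validated on synthetic data
  only; nothing calibrates them to any published group count.
* Neighborhood analysis does not model operons, intergenic distances, or
  COG enrichment statistics.
* Kinetics fitting covers initial rates only — no progress curves, no
  enzyme inactivation, no substrate inhibition.
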