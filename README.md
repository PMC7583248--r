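# larasig

Signature-based functional organization of the lactate racemase (LarA)
superfamily — and of protein superfamilies with the same shape of evidence.

## The problem

LarA homologs (LarAHs) form a superfamily of nickel-pincer-nucleotide
(NPN) dependent enzymes that racemize or epimerize alpha-hydroxyacids
(lactate, malate, alpha-hydroxyglutarate, phenyllactate, hexonates, ...).
Members share a catalytic machinery — the catalytic tetrad (D72, H108,
H174, K298 in LarA numbering) and the NPN-binding triad (R75, K184, H200) —
while their substrate specificity is written in a handful of
substrate-recognition residues: the "loop" (the two residues after the
second catalytic histidine, F175/F176 in LarA), the residue before the
catalytic lysine in helix 11 (V297) and a helix-14 residue pointing at the
substrate side chain (W358). Given family sequences, gene neighborhoods and
a few characterized members, the question is: which phylogenetic groups
exist, which genomic partners do they travel with, and what does each group
most likely do?

`larasig` implements that workflow as a tested pipeline:

1. **Alignment** — progressive multiple sequence alignment (affine-gap
   profile–profile Gotoh DP in C++, WPGMA guide tree from a 3-mer distance)
   with exact column/residue coordinate maps; external alignments are
   first-class input.
2. **Grouping** — deterministic agglomerative clustering of the p-distance
   matrix (`d = 1 -` fractional identity over both-ungapped columns) with a
   distance cutoff; groups may be re-split at a tighter cutoff (7 → 7a/7b).
3. **Gene-neighborhood association** — per group, the fraction of members
   whose ±3-gene flank contains each COG; partners are flagged by the
   strict "more than 30% association" rule, with larB/larC/larE excluded.
4. **Signature profiles** — anchor residues mapped through the alignment,
   per-group residue frequencies, WebLogo-style information content
   `R = log2(20) − (H + e_n)` with small-sample correction
   `e_n = 19 / (2 ln 2 · n)`, and the five-color rule (catalytic green,
   NPN-binding blue, conserved-as-reference yellow, conserved-but-different
   red, non-conserved black).
5. **Classification** — a group is accepted as a LarA homolog only if all
   catalytic and NPN-binding anchors are conserved; accepted groups are
   matched against activity signatures (LAR `FF/V/W`, SAR `LM|FM`, MAR
   `QK|HK`, HGR `NQ`+`T`, GntE `EV|ES` / `W|G` / `A|V|N`).
6. **Kinetics** — Michaelis–Menten fits (`v = kcat·[E]·S / (K_M + S)`) by
   nonlinear least squares with Hanes–Woolf initialization and Wald 95%
   confidence intervals; competitive inhibition
   (`v = kcat·[E]·S / (K_M(1 + I/K_i) + S)`) with fixed or co-fitted
   K_M/k_cat; catalytic efficiency `k_cat/K_M`; pH/temperature optima as
   the range where activity exceeds 90% of the maximum.
7. **Synthetic data** — generators that plant group signatures, partner-COG
   probabilities and kinetic parameters, so every stage is validated
   against known ground truth without any database access.

## Worked example

```r
library(larasig)

b <- demo_bundle("demo/in", seed = 1)       # synthetic family, 5 groups x 10
res <- run_pipeline(pipeline_config(
  fasta = b$fasta, neighborhoods = b$neighborhoods,
  anchor_config = b$anchors, out_dir = "demo/out"))

res$grouping
#> family_grouping: 50 members in 5 groups
vapply(res$classifications, function(x) x$predicted_activity, character(1))
#>      1      2      3      4      5
#>  "LAR"  "SAR"  "MAR"  "HGR" "GntE"
res$partners[["3"]]                          # planted 0.8-probability partner
#>       cog fraction count
#> 1 COG1003      0.9     9
head(res$profiles[["1"]][, c("position", "ref_residue", "dominant",
                             "dominant_freq", "information_bits", "color")], 4)
#>   position ref_residue dominant dominant_freq information_bits color
#> 1       72           D        D             1             2.95 green
#> 2       75           R        R             1             2.95  blue
#> 3      108           H        H             1             2.95 green
#> 4      174           H        H             1             2.95 green
```

All five planted activities are recovered; the recovered partner fraction
(0.9 of 10 members) is the planted 0.8 probability plus sampling noise, and
the anchors carry the full single-residue information content
(`log2(20)` minus the n = 10 small-sample correction, 2.95 bits).

Kinetics, planted at the Mar2-like values K_M = 0.38 mM, k_cat = 66 1/s:

```r
d <- simulate_kinetics(kinetics_sim_config(true_km = 0.38, true_kcat = 66,
                                           enzyme_conc = 0.1, noise_cv = 0.05,
                                           seed = 42))
fit_mm(d)
#> Michaelis-Menten fit: K_M = 0.3422 +/- 0.06 mM, k_cat = 63.06 +/- 3.9 1/s,
#>   k_cat/K_M = 184 1/(s mM)
```

Both planted parameters lie inside their 95% confidence intervals.

A command-line front end mirrors the pipeline:

```sh
Rscript -e 'larasig::larasig_cli()' demo --out demo/in --seed 1
Rscript -e 'larasig::larasig_cli()' run --fasta demo/in/family.fasta \
  --neighborhoods demo/in/neighborhoods.tsv --anchors demo/in/anchors.json \
  --out demo/out
```

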