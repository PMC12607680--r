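---
title: "From differential tables to druggable upstream regulators: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From differential tables to druggable upstream regulators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(transomic)
```

# The problem

Paired transcriptome and proteome differential-expression experiments often
disagree feature by feature, yet both layers are downstream shadows of the
same regulatory events. `transomic` implements the in-silico chain that
walks from those shadows back to candidate causes: which transcription
factors (TFs) plausibly drive the observed expression changes, which
signaling molecules sit upstream of those TFs, and which of those upstream
molecules are tractable drug targets. The chain is:

1. **Differential integration** — call significant features per layer,
   classify transcript–protein concordance, select the top input genes.
2. **Motif enrichment** — scan fixed promoter windows (1100 bp, TSS-relative
   \[-1000, +100\]) with position weight matrices (PWMs) and test binding-site
   excess in the study ("Yes") promoters against background ("No") promoters.
3. **Composite modules** — search for a weighted cluster of up to 10 motifs
   co-occurring in a 200–300 bp sliding window that best separates Yes from
   No promoter scores (minimizing a one-sided Wilcoxon rank-sum p-value).
4. **Master regulators** — walk a directed signaling network up to 12 steps
   upstream of the module's TFs, score key nodes, and control error with an
   empirical resampling null over random TF sets.
5. **Druggability** — rank candidate targets by curated drug counts and by
   probability-of-activity (Pa) weighted predicted scores.

Because the real inputs of such studies (expression matrices, commercial
motif/pathway/drug databases) are typically unavailable, the package ships a
first-class synthetic-data module that generates every input with planted,
recoverable truth. All validation rests on it; the limits of that validation
are spelled out below.

# Models and statistics

## PWM scoring and enrichment

Counts (or frequencies — rows are renormalized either way) are
pseudocount-smoothed (`c = 0.01`), converted to log-odds against a uniform
0.25 background, and min–max normalized per matrix, so the consensus window
scores exactly 1 and the anti-consensus 0 (the Match-style convention). `N`
bases contribute the position's background-expected weight. Both strands are
scanned; reverse-strand matches are reported at the leftmost forward-strand
base (BED-like, 0-based half-open). The default score cutoff is 0.85,
overridable per matrix — synthetic matrices carry 0.95 (a high-stringency
profile).

Enrichment contrasts, per matrix, matched windows out of scanned windows in
Yes versus No on a 2×2 table, with a one-sided Fisher exact test (exact
hypergeometric tail; a binomial approximation is available). P-values are
Benjamini–Hochberg (BH) adjusted across matrices; `enriched` means adjusted
p < 0.01 (strict, configurable). Overlapping matches of one matrix are all
counted — no greedy pruning — and an optional caller-supplied third sequence
set (e.g. random genomic regions) can replace the No set in the test while
densities still contrast Yes vs No.

## Composite modules

A module is 1–10 slots `(matrix, weight ≥ 0, cutoff, max_sites)` plus a
window length in \[200, 300\] bp. A promoter's score is the maximum over
window placements (stride 10 bp) of the weighted sum, over slots, of the top
`max_sites` match scores fully inside the window. Fitness of a module is
`-log10 p - λ·|slots|` where `p` is the one-sided Wilcoxon rank-sum p-value
(Yes > No; mid-ranks; exact enumeration for pooled n ≤ 20, otherwise normal
approximation with tie and continuity correction) and `λ = 0.1` is a
parsimony penalty that stops the slot ceiling from saturating.

The genetic algorithm uses tournament selection (size 3), per-field mutation
(probability 0.2), slot-level uniform crossover (probability 0.4), random
immigration (probability 0.1) and elitism of 1, over discrete grids for
cutoffs (0.75–0.95), window lengths (200/250/300) and site caps (1–3).
Crossover matters: it is the operator that merges two good single-motif
individuals into a composite. The initial population contains one
deterministic single-slot individual per library matrix at the default slot
parameters, which guarantees — via elitism and the penalty arithmetic — that
the returned module's Wilcoxon p never exceeds the best single matrix's.

Because a statistic optimized on the data and then tested on the same data
is inflated, `cma_permutation_null()` refits the GA on label-permuted
promoter sets and returns the null of the optimized statistic with a
smoothed empirical p.

**Per-TF regulatory scores.** The source platform defines its regulatory
score via positive-feedback-loop involvement, which needs network context a
motif-only stage does not have. We operationalize it as the *drop-one
contribution*: the loss in `-log10 p` when all slots of a TF are removed
from the fitted module, floored at zero. TFs outside the module score 0.
This is our own definition, isolated behind `regulatory_score()`.

## Master regulators

`upstream_reach()` computes, for every node, shortest directed path lengths
node → TF for each input TF within a radius (default 12; cycles are handled
by shortest-path semantics). The key-node score is
`Σ_reached 1/(1 + distance)` — covering many input TFs at short range scores
highest. The platform's exact formula is unpublished; ours is deliberately
simple and isolated behind `keynode_score()` so alternates can be swapped.

Input TFs themselves are excluded as candidates (each trivially reaches
itself at distance 0; the search is strictly upstream).

The null resamples TF sets of the observed size from the network's
TF-annotated nodes (default 10,000 draws; scalable). The smoothed empirical
p is `(1 + #{null ≥ obs}) / (1 + n_runs)`. Because that p is floor-limited
at `1/(n_runs + 1)`, BH across hundreds of nodes cannot fall below the
floor times the node count at scaled run counts; the FDR is therefore
computed by BH on the normal-tail p of the per-node Z-score
`(obs − null mean)/null sd`, which follows the Z-score basis the platform
describes. Nodes with a degenerate null (sd = 0) fall back to the empirical
p and are flagged.

**Total rank** fuses four descending rankings — key-node score, best
regulatory score among reached TFs, |transcriptome logFC| and |proteome
logFC| of the node's mapped gene symbols (best symbol by |logFC| when a node
maps to several) — with the midpoint rank `(N+1)/2` substituted for missing
components (a protein not detected still carries a total rank, as in
published master-regulator tables with blank cells). The sum orders the
report ascending; ties break by key-node rank, then node name.

## Druggability

Curated mode: a compound's *target activity score* is
`-(|T| / (|T| + w(|AT| − |T|))) · Σ_{t∈T} log10(rank(t)/(1 + maxRank(T)))`
(`T` = compound targets ∩ input list, `AT` = all its targets, ranks from the
master-regulator stage; every log term is negative so the score is positive
whenever `T` is non-empty). The printed form of this formula in the source
material is typographically corrupted; this reconstruction parses the
printed token stream and is rank-monotone — it is isolated behind
`t_score_psd()` and flagged as a reconstruction. The *disease activity
score* sums the distinct observed trial phases per selected disease; the
*clinical validity score* is the highest phase ever reached. Drug rank is
the sum of the three descending component ranks. A gene's curated
druggability is its count of distinct known compounds.

Predicted mode: compounds pass when toxicity Pa < threshold, all
disease-matched effect Pa > threshold, and ≥ 2 target genes have mechanism
Pa > threshold (all inequalities strict, as printed; a compound with no
disease-matched effect rows passes clause two vacuously). Passing compounds
contribute `IAP(g) · Σ_s Σ_m pa(m)` to gene `g`'s predicted druggability.
`w` (off-target weight) defaults to 1; no value is published.

# The synthetic world

Defaults state one fixed scenario; they are not tuned per run.

* **Differential tables**: 1000 genes, 10% up / 10% down, signal
  |log2FC| ~ N(1.2, 0.3) with p ~ 10^U(−8,−4), nulls N(0, 0.15) with
  uniform p; 80% proteome coverage; 5% of proteome-measured signal genes
  sign-flipped (the discordance the trans-omic comparison is meant to
  expose).
* **Promoters**: 50 Yes / 50 No, 1100 bp i.i.d. background at GC 0.45. With
  probability 0.9 a Yes promoter receives one max-scoring site per planted
  TF (consensus or its reverse complement), non-overlapping, inside one
  uniformly placed 250 bp window.
* **Motifs**: 6 bp cores with mixed per-position conservation
  (dominant-base counts 45/60/75/90 of 100), per-matrix cutoff 0.95, three
  planted TFs plus five decoys. Short, partially degenerate cores are the
  realistic regime: each consensus also occurs in background (~0.5 times
  per promoter), so no single matrix can separate Yes from No perfectly and
  motif *co-occurrence* carries the signal — the premise of composite-module
  analysis. With long near-digital motifs the optimal module provably
  collapses to one slot and multi-TF recovery would be meaningless.
* **Network**: 200 nodes (40 TF-annotated), Poisson out-degree (mean 2),
  cycles allowed; the planted regulator has a direct edge to every planted
  TF (`max_path_len = 1` by default — curated master-regulator hits are
  typically direct effectors of their TFs; with longer planted chains,
  random hub nodes legitimately attain shorter TF distances than the
  planted node and the planted truth stops being the right answer).
  `planted_regulator = NA` generates a null network.
* **Drug tables**: requested compounds per target exactly realize the
  intended curated druggability; each compound gets two mechanism rows, a
  toxicity row and a disease-effect row with Pa drawn in stated ranges.

What a green test establishes — and what it does not: generators use i.i.d.
backgrounds (no dinucleotide structure, no CpG islands), implant perfect
consensus sites, and use symbol-identical gene/node namespaces. Recovery
under these conditions demonstrates the machinery is correct and calibrated,
not that real promoters, real TRANSFAC-scale motif redundancy, or real
pathway topologies would yield the same power.

# Numerical and interface choices

* Duplicate feature IDs collapse to the min-p row (deterministic,
  conservative), with a warning.
* The significance criterion of the original analysis is unstated; the
  default is BH at α = 0.05 with no fold-change floor, both configurable —
  documented as our convention, not asserted as the source's.
* Features significant in neither layer get no concordance class but are
  counted (`n_not_significant`); "detected" for the class-count invariant
  means carrying a significant call in ≥ 1 layer.
* Top-N selection (default 300) sorts by p ascending, then |logFC|
  descending, then ID — fully deterministic under row permutation.
* Promoters shorter than 1100 bp are rejected by default; opt-in 5' N
  padding.
* Gene-ID mapping between species/databases is the caller's problem by
  design: the package never guesses orthology.
* All stage outputs are TSVs with one comment header line (package version,
  seed, config hash — no timestamps), so identical config + seed give
  byte-identical reports; `run_pipeline(..., from_stage =)` resumes from
  on-disk intermediates.
* Configs are JSON (YAML accepted when the `yaml` package is present);
  unknown keys are an error listing them.

# Known limitations

* The CMA fitness ceiling is set by the Yes promoters that never received a
  module (site_prob < 1); no module can rank them above background.
* The empirical-null Z assumes approximate normality of resampled key-node
  scores; for very sparse networks the degenerate-null fallback (empirical
  p) is the honest answer and is flagged.
* `total_rank`'s CMA component uses the best regulatory score among
  *reached* TFs — a proxy; how the source platform computed a master
  molecule's CMA score is unpublished.
* The pipeline consumes per-feature p-values; it never recomputes
  replicate-level differential statistics.
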