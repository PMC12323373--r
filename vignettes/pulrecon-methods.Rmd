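---
title: "Methods: PUL prediction, degradative-capacity statistics, and DTL reconciliation"
author: "pulrecon developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PUL prediction, degradative-capacity statistics, and DTL reconciliation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

# Scope and model

`pulrecon` re-implements, as a tested and reusable pipeline, a genome-mining
workflow for polysaccharide-degrading marine Bacteroidota (built around the
genus *Flagellimonas* but not specific to it): consensus CAZyme annotation
from multi-tool domain hits, rule-based prediction of polysaccharide
utilization loci (PULs) with substrate classification — notably alginate
utilization loci (AULs) — genome-level degradative-capacity statistics, and
event-cost parsimony reconciliation of CAZyme gene trees against a species
tree to separate vertical inheritance from duplication, horizontal transfer
and loss.

The package consumes the *outputs* of annotation services (dbCAN-style CAZyme
hit tables, Pfam/TIGRFAM marker hits, MEROPS/SulfAtlas BLASTP hits) together
with ordered gene tables; it does not run HMMER/DIAMOND/eCAMI/BLASTP itself.

# Annotation rules

**CAZyme consensus.** Each search tool (HMMER, DIAMOND, eCAMI) casts one vote
per gene: its best hit by e-value, ties broken lexicographically by
accession. Votes are cast at family level after stripping subfamily suffixes
("GH16_3" votes for "GH16"), because tools disagree at subfamily level far
more often than at family level and all downstream logic is family-based. A
gene is a CAZyme of family F when at least `consensus_min_tools` (default 2
of 3) tools vote for F. No additional e-value filter is applied here — the
upstream tools apply their own significance thresholds.

**SusC/SusD markers.** SusC-like TonB-dependent transporters are called from
TIGR04056/TIGR04057 hits, SusD-like lipoproteins from
PF07980/PF12741/PF12771, each requiring `evalue < 1e-15`. The strict cutoff
is stated for peptidase/sulfatase searches in the source methodology; we
apply it to the marker searches as well because no separate threshold is
given — it is configurable via `marker_config()`. A gene matching both
marker sets is called SusC only (the receptor models are the more specific
evidence); the conflict is reported as a warning.

**Peptidases and sulfatases** are flagged when the best MEROPS (resp.
SulfAtlas) e-value is *strictly* below `1e-15`; a hit at exactly `1e-15` is
excluded.

# PUL prediction

Gene order is the 0-based rank by start coordinate within each replicon
(ties by end, then gene id); strand is ignored. Two seed rules fire:

1. **Pair rule** — a SusC/D pair (rank gap ≤ `pair_max_gap`, default 2) with
   at least one gene holding a GH or PL family within `window` (default 10)
   ranks of either pair gene.
2. **Lone-SusC rule** — an unpaired SusC with at least `min_gh_rule2`
   (default 5) distinct GH genes within `window` ranks.

A window of 10 includes a rank difference of exactly 10; windows never cross
replicon boundaries unless `circular = TRUE`, in which case they wrap around
the origin (locus spans are still reported linearly). Each accepted seed
expands to the minimal rank interval covering the seed genes and every
CAZyme/SusC/SusD gene in its window; overlapping loci on a replicon merge
(union of members, rule category = min), which is what collapses multi-seed
alginate systems into the single locus per strain that cohort reports count.

**Pair matching** is greedy by increasing rank gap; at equal gap the
downstream partner wins, and each gene joins at most one pair. "Nearby" has
no published definition; a gap of 2 (one intervening gene) is the package's
stated default.

**Substrates.** A locus's substrates are the union of map labels over its
CAZyme families (`default_substrate_map()`): alginate ← the 15 PL families
with known alginate lyase activity (PL5, 6, 7, 8, 14, 15, 17, 18, 31, 32,
34, 36, 38, 39, 41); fucoidan ← GH29/GH95; laminarin ← GH16/GH17/GH30;
β-mannan ← GH130/GH26; xylan ← GH43/GH30/GH10; α-mannan ← GH92; rhamnose ←
GH78; agar ← GH117/GH16/GH50/GH86; ulvan ← PL24/PL25/PL40. A locus may carry
several labels; the only privileged flag is `is_AUL`, which requires an
alginate label **and** at least one SusC/D pair — a category-2 locus with an
alginate lyase but no pair is labelled alginate yet is not an AUL.

# Genome statistics

G+C content excludes ambiguity codes from numerator and denominator; genome
length includes them. Densities are counts per Mb of sequence; the P/C ratio
(peptidases / CAZymes) is `NA` for CAZyme-free genomes. All rounding happens
at the reporting layer.

**ANI** follows the fragment-based reciprocal best-hit algorithm: both
genomes are cut into consecutive non-overlapping 1020 bp fragments
(trailing remainders discarded per replicon), every fragment's best local
alignment against the other genome's fragment set is found in both
directions, and the ANI is the mean identity over reciprocal best-hit pairs
— symmetric by construction. The local-alignment backend is pluggable
behind a (fragment, candidate set) → (score, identity) contract:

* `blastn` — shells out to NCBI BLAST+ (`-task blastn`, dust off,
  single-threaded), which is what the published tool wraps; roughly 15 s per
  1 Mb genome pair.
* `biostrings` — in-process Smith-Waterman (`Biostrings::pairwiseAlignment`)
  restricted to candidate fragments that share exact 13-mers (subject seeds
  sampled every 2 bp, query seeds every 4 bp; candidates with fewer than
  `max(3, 0.25 × top)` shared seeds are discarded). No external binaries;
  roughly 10× slower.

Both backends agree to < 0.01 ANI points on mutated-copy benchmarks. Ties
between equally scoring best hits resolve by identity, then lowest fragment
index. Identity is matches / aligned columns of the local alignment
(PID1-style); published tools differ at exactly this point, which is why the
16S identity below states its denominator explicitly.

**16S identity** uses a global (Needleman–Wunsch) alignment (match +1,
mismatch −1, gap open 2, gap extend 0.5); identity = matches / aligned
columns where terminal overhangs are excluded and internal gap columns count
in the denominator. Reference web services use slightly different
conventions, so a few tenths of a percent of disagreement with their values
is expected.

dDDH is deliberately not implemented; ANI (with the < 95% species threshold)
is the only delineation statistic computed.

# DTL reconciliation

`reconcile()` embeds a rooted binary gene tree into a rooted binary species
tree under the undated duplication–transfer–loss parsimony model, with
default costs loss = 1, duplication = 2, transfer (HGT) = 3 and free
speciations. Dynamic programming over (gene node × species node) evaluates
at each gene node the cheapest of speciation, duplication, or transfer, with
one loss charged per species branch skipped on a descent path; transfer
recipients are any branch not in an ancestor–descendant relation with the
donor. Global time-consistency across multiple transfers is **not**
enforced — a known limitation of undated parsimony models relative to
branch-length-aware reconciliation engines.

Numerical choices: costs are doubles compared with a `1e-9` tolerance; ties
between co-optimal events resolve speciation > duplication > transfer, then
lowest canonical species-branch id (ids are assigned in preorder with
children ordered by smallest descendant leaf, so they are invariant to input
rotation). The preference is applied per node, top-down — when a history
with a root speciation and a deeper transfer ties a history with a root
duplication, the root speciation is preferred and the transfer is reported.
One optimal history is returned; `count_optima = TRUE` additionally counts
co-optimal histories. `root_search()` evaluates all `2n − 3` rootings of an
unrooted gene tree and breaks cost ties by the smallest canonical Newick
string.

Two independent oracles guard the implementation: `reconcile_brute()`
enumerates every assignment of gene nodes to species nodes explicitly
(event choice is provably independent per node given the assignment), and
`dl_cost_lca()` is the closed-form duplication–loss cost of the classical
LCA mapping, which the DP must reproduce when transfers are disabled
(`transfer = Inf`).

`classify_family_history()` renders the verdicts used in cohort reports:
*vertical* (no transfers), *HGT-dominated* (transfer cost > half the total),
otherwise *mixed*.

# Synthetic data: what it emulates and what it does not

`simulate_genome()` generates the stated world for locus-recovery testing:
gene tables with uniform random gene lengths (600–1800 bp) and intergenic
gaps (20–200 bp), planted loci that satisfy exactly one of the two seed
rules, and enumerated decoys each violating exactly one rule condition
(pair gap too large; only 4 GH genes; a CAZyme supported by a single tool;
a SusC with an empty window). Planted blocks are separated by 12 filler
genes — more than the window — so rules cannot interact across blocks, and
filler genes carry no hits so the annotation layer must actively ignore
them. A green recovery test therefore establishes that the rule logic and
its boundary conditions are implemented correctly; it does **not**
establish performance on real genomes, where SusC/D homologs, fragmented
assemblies and atypical locus architectures blur the rules.

`mutate_genome()` applies uniform independent substitutions — no indels, no
rate heterogeneity — so `orthoani` on an (original, mutated) pair has
expectation ≈ 100(1 − r), the basis of the ANI calibration tests.

`simulate_family()` evolves a gene family top-down along the species tree:
each copy entering a branch draws at most one event (loss, duplication, or
transfer to a uniformly chosen non-comparable branch) with the configured
per-branch probabilities, then passes through the speciation at the branch's
end; lost lineages are pruned and extinct families are resampled from
derived seeds. One event per copy per branch keeps the low-rate regime
(≤ 1 event per family) clean for event-recovery tests. In that regime the
reconciliation recovers the planted event type in well over 95% of
replicates; the known residual error is a transfer whose recipient is the
donor's sibling, which ties a duplication-plus-loss explanation at equal
cost and is then reported as the preferred duplication.

# Orchestration

`run_cohort()` chains annotate → predict-puls → stats → reconcile over a
cohort, writing per-genome PUL tables, a genome-statistics table, the
cohort substrate-count matrix, reconciliation summaries and a manifest
holding every threshold and seed. Outputs contain no timestamps, so reruns
with identical inputs are byte-identical. The config file is JSON rather
than YAML because the supported R stack has no YAML parser; the flat-key
schema is otherwise as described in `read_pipeline_config()`.

# Known limitations

* The undated transfer model can produce globally time-inconsistent
  multi-transfer histories.
* PUL prediction has no notion of transcriptional units; strand and
  intergenic distance are ignored by design, trading specificity for
  reproducibility of the published gene-count window.
* Substrate labels are evidence of *potential*, not activity; subfamily
  information, which sometimes separates substrate specificities within a
  family, is discarded by the consensus rule.
* The accession-based spot checks (genome lengths, G+C, inter-strain ANI,
  16S identity of the two type strains) require two GenBank downloads and
  cannot run offline; the corresponding acceptance test documents the
  expected cache layout and fails cleanly when the cache is absent.
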