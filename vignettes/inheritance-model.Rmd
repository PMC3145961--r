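---
title: "A nucleosome-lattice model of histone-mark inheritance, and a G-quadruplex motif scanner"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A nucleosome-lattice model of histone-mark inheritance, and a G-quadruplex motif scanner}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quadmark)
```

## The question the model addresses

Repressive histone marks such as H3K9me2 must survive DNA replication.
Each division displaces parental histones ahead of the replicative
helicase and redeposits them, mixed with newly synthesized (unmarked)
histones, on the two daughter strands; marks are then copied from
parental to new histones by reader–writer enzymes acting locally along
the fiber. Replication-fork stalling breaks this choreography: when
synthesis restarts downstream of a block, the intervening stretch is
filled in later, uncoupled from the fork, and is chromatinized almost
entirely with new histones. The model in this package asks a
quantitative question: given realistic stall frequencies and
postreplicative gap lengths, when does local mark copying keep up, and
when does a domain lose its repressive marks?

Two regimes matter. Sporadic, genome-random stalling (spontaneous DNA
damage) versus recurrent stalling at one fixed position, as expected at
a replication impediment such as a G-quadruplex (G4). The second half of
the package supports the G4 side of that argument: a consensus motif
scanner and a gene-set enrichment test for G4 motifs near transcription
start sites.

## The lattice model

The simulation substrate is a 1-dimensional lattice of `n_nucleosomes`
nucleosomes at a fixed spacing (`spacing_bp`, default 200 bp, so the
default 500-nucleosome fiber spans 100 kb). Each nucleosome is in one of
two states, marked or unmarked, and the fiber starts fully marked — the
modelled domain is repressed at time zero, and the reported statistic
"fraction of marks lost" is `1 - fraction_marked()`. One generation is
the composition of four steps, in order:

1. **Segregation** (`segregate`). Each position independently keeps its
   parental histone with probability `p_retain` (default 0.5, random
   distribution of parental histones between the daughters, with one
   daughter lineage tracked); otherwise the position is occupied by a
   new, unmarked histone.
2. **Stall drawing** (`draw_stalls`). Every position stalls
   independently with probability `p_stall_random` per division, and a
   designated `fixed_site` additionally stalls with probability
   `p_stall_fixed`. A per-nucleosome probability p corresponds to one
   stall per `spacing_bp / p / 1000` kb (`stall_interval_kb`).
3. **Gap filling** (`apply_gaps`). Each stall spawns a postreplicative
   gap whose length in nucleosomes is a rounded normal draw
   (`gap_spec(mean_len, variance)`, clamped to ≥ 1; variance 0 makes the
   length deterministic). All positions under a gap become unmarked
   regardless of retention: gap-filling synthesis is uncoupled from
   histone recycling. Overlapping gaps are unioned, and gaps are
   truncated at the fiber ends.
4. **Restoration** (`restore_marks`). One synchronous pass: every
   unmarked nucleosome acquires the mark with probability `p_copy1`
   (default 1.0) if the template has a marked neighbour at distance 1,
   otherwise with probability `p_copy2` (default 0.25, the "two-place
   copy") if there is a marked neighbour at distance 2. Marked
   nucleosomes never lose marks in this pass, and marks gained within a
   pass do not cascade. Fiber ends do not wrap; the boundaries act as
   insulators limiting spread.

`run_trajectory` repeats this for `generations` divisions (default 30)
over `replicates` independent lineages (default 30), recording the
fraction marked and, when a fixed site is set, the length of the
unmarked tract containing it (`max_unmarked_run`).

### What templates the restore pass: a genuinely open choice

The copying step admits two readings, and the package exposes both via
`copy_source`:

* `"parental"` (the default): the pass is templated by the
  start-of-generation fiber with this division's gap intervals masked
  out. This is copying *at the fork*: new histones acquire marks while
  the locus still carries its parental chromatin in register, but
  postreplicative gaps offer no parental template, because there the
  parental histones were never redeposited.
* `"daughter"`: the pass is templated by the post-segregation daughter
  state, i.e. only parental histones retained on the tracked daughter
  can donate marks.

The two differ sharply in their no-stall behaviour. Under `"parental"`
with `p_copy1 = 1`, a fiber without stalls returns to fully marked every
generation: random segregation alone never erodes the domain, and all
loss is gap-driven. Under `"daughter"` the chain is subcritical at the
default copy probabilities — about a third of all marks are lost within
30 generations *with no stalling at all*, because segregation losses
cluster faster than a single synchronous pass can heal them. A model in
which ordinary replication destroys epigenetic memory cannot speak to
the question posed above, so `"parental"` is the default; `"daughter"`
is one configuration flag away for sensitivity analyses.

### Gap placement

A stall site marks where the fork was blocked; where the resulting
tract of new histones sits relative to it depends on fork direction and
restart geometry, neither of which the model resolves. `gap_anchor`
offers `"center"` (default), `"downstream"` and `"upstream"`. The
center anchor is the default because the edge anchors make the
fixed-site tract statistic degenerate: the stall site then sits at the
gap's healing edge, is re-marked by the first restore pass, and the
tract containing the site reads 0 at every stall probability. Centering
keeps the impediment inside the tract it creates, which is the regime
the fixed-site statistic is meant to probe.

### What the healing arithmetic implies

With `p_copy1 = 1` and `p_copy2 = 0.25`, an unmarked tract heals from
each flank by one nucleosome surely plus a second with probability 0.25
— at most ~1.25 nucleosomes per flank per generation. Two consequences
follow, and the package's acceptance script measures both.

First, for random stalling at rate r per fiber per division with mean
gap G, the standing unmarked mass balances creation against healing at
roughly r·G²/(4·1.25) nucleosomes, so the minimal G sustaining 40% loss
of a 500-nucleosome fiber at one stall per 60 kb comes out near
20–25 nucleosomes (the sweep in `scripts/acceptance.R` reports 23).
One- and two-nucleosome gaps heal fully within their own generation —
every cleared position still has a marked distance-1 template across a
flank — so sporadic short gaps cost nothing at all.

Second, because trajectories are recorded *after* the restore pass, a
fresh deterministic gap of 5 has already lost an expected ~2.5
nucleosomes to its flanks when measured. The mean fixed-site tract
therefore saturates near half the gap length even at stall probability
1.0, and `fixed_stall_threshold`'s criterion (mean tract ≥ the full gap
length, stable thereafter) is never met at the default copy
probabilities: the function returns `NA` rather than a number, and the
acceptance script omits the quantity rather than inventing one. A
threshold in between would require healing slow enough to let tracts
accumulate but fast enough to protect the bulk — the two figure-level
behaviours jointly over-constrain a single front-healing rule, which is
the main caveat attached to this reconstruction.

### Randomness and reproducibility

One root seed (`sim_params(seed = )`) drives everything. Replicate r
runs under a seed drawn from a `sample.int` stream initialized with the
root seed, so any replicate is reproducible in isolation; sweep cells
derive per-cell seeds by a fixed affine-mod scheme. Identical parameter
sets give bit-identical `trajectory_result`s. Within one generation the
draw order is fixed: segregation uniforms, stall uniforms, fixed-site
uniform, gap lengths (in stall order), restore uniforms.

## The G4 scanner

`find_g4` matches the quadruplex consensus
G₃₋₅ L₁₋₇ G₃₋₅ L₁₋₇ G₃₋₅ L₁₋₇ G₃₋₅ (L any base) on the forward strand,
and on the reverse complement for the minus strand, reporting both on
forward 0-based half-open coordinates. Three policy decisions are
explicit, because the consensus alone does not determine a unique motif
set:

* **Leftmost, non-overlapping per strand.** Scanning resumes at the end
  of each match. Gene-level statistics (`has_motif`) are insensitive to
  this choice; motif counts are not, so the policy is pinned down and
  oracle-tested against an exhaustive enumerator.
* **Greedy G-runs, lazy loops.** A run of more than five Gs contributes
  its first five; the trailing Gs fall into the following loop. Loops
  are as short as the rest of the match allows. Motif widths are
  therefore bounded by 4·3 + 3·1 = 15 and 4·5 + 3·7 = 41 bp.
* **N breaks everything.** N matches neither runs nor loops
  (conservative: no motif is reported across ambiguous sequence).

`scan_windows` restricts counting to windows of `halfwidth` (default
1500 bp) either side of each gene's TSS, clamped to the sequence. A
motif counts if ≥ 1 bp overlaps the window — "in the vicinity of the
promoter" rather than "strictly inside" — with `full_containment` as the
stricter alternative. `prevalence_enrichment` compares the fraction of
genes with at least one motif between a test and a control set with a
two-sided Fisher's exact test (p-value from `stats::fisher.test`, whose
tie handling the exhaustive-sum oracle in the test suite reproduces to
< 1e-10 for all tables with N ≤ 40; the odds ratio reported is the
sample (a·d)/(b·c)).

## Synthetic data

`make_sequence` plants consensus-conforming motifs at known coordinates
on either strand in an i.i.d. background of chosen GC content, then
rejection-scrubs the background: while the scanner's output differs
from the planted truth, offending background positions (never plant
positions) are resampled. The returned truth table is therefore exact
by construction, which is what makes set-equality tests between scanner
and truth meaningful. `make_gene_sets` builds per-gene windows
(default 71% of "test" genes and 38% of controls carrying exactly one
planted motif at a random in-window position and strand) for
enrichment-recovery tests.

What the generator deliberately does not emulate: real base
composition (isochores, CpG islands), motif clustering, overlapping or
bulged quadruplexes, and any relationship between G4 position and gene
orientation. Passing the recovery tests shows the scanner and the
enrichment arithmetic are correct, not that any particular biological
gene set is enriched.

## Assay arithmetic

The `assays` functions encode the small qPCR identities used around
such experiments, all at amplification efficiency 1 unless overridden:
ChIP enrichment `2^-(Ct_ab - Ct_h3)`; renormalization to a reference
site by division; ΔΔCt expression fold change; and the methylated
fraction `2^-(Ct_HpaII - Ct_BamHI)`, clamped to 1 with a warning since a
fraction above 1 can only be noise. `hpaii_mspi_qc` checks the
isoschizomer control (HpaII vs MspI at an unmethylated site) as a
boolean flag. Duplicate wells are averaged before any ratio
(`read_ct_table`).

## Problem sizes and limitations

The shipped tests run the simulator at fiber lengths 100–500 and 5–45
generations with 5–200 replicates, the scanner oracle on fifty 10 kb
sequences, and the Fisher oracle on all 135,746 tables with N ≤ 40;
the full suite completes in well under five minutes on one core.
Known limitations: marks are binary (no me1/me2/me3 levels), nucleosomes
do not reposition, stalling is sequence-blind inside the simulator (G4
positions enter only as stall probabilities), there is no transcription
feedback or collective domain bistability beyond what insulating
boundaries provide, and the restore rule is a reconstruction whose
figure-level consequences — discussed above — should be read with that
uncertainty in mind.
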