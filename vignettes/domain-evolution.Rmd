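---
title: "Detecting and tracing clustered-acidic C-terminal domains across a protein family"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and tracing clustered-acidic C-terminal domains across a protein family}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acidtrace)
```

## The problem

Dbx1 and Dbx2 are homeodomain transcription factors that pattern the ventral
spinal cord; Dbx1 defines the p0 progenitor domain. Beyond the DNA-binding
homeodomain and the eh1-like repressor domains (RD1, shared by both paralogs,
and RD2, specific to Dbx1), Dbx1 proteins of tetrapods — and scattered
invertebrate lineages — carry a C-terminal cluster of acidic residues
(Asp/Glu), here called the Cter domain. Three computational questions follow:

1. **Detection.** When does a sequence "carry" a Cter? The operational
   criterion is a stretch of ten amino acids containing at least 80 % D or E
   within the C-terminal region.
2. **Comparative mapping.** Which taxa carry RD1/RD2/Cter, judged from a
   family alignment anchored on reference coordinates?
3. **History.** Is the patchy distribution of the Cter across the species
   tree better explained by one ancestral gain followed by secondary losses,
   or by convergent gains in independent lineages?

This package implements each step as a tested function, plus a simulator
that generates families with known gain/loss ground truth so the whole chain
can be validated end to end. The numbered scripts under `analysis/` run the
workflow; `run_pipeline()` does the same from one configuration.

## The window statistic

`scan_acidic_windows()` slides a window of `window` residues (default 10)
across the search region and reports every window whose acidic fraction is
at least `min_fraction` (default 0.8). Choices that matter:

* **Inclusive threshold.** "At least 80 %" with a 10-residue window means 8
  or more D/E residues qualify; the comparison is `>=`, not `>`.
* **Search region.** The criterion restricts the search to "the C-terminus"
  without fixing its extent, so the region length is an explicit parameter
  `tail_len` (default 50 residues, which comfortably covers a 25-residue
  terminal domain such as the mouse Cter at reference positions 311–335 of a
  335-residue protein). `tail_len = "all"` scans everything. The default is
  a documented package choice, not a claim about any published procedure.
* **Alphabet.** `X` (ambiguity) never counts as acidic. All coordinates are
  1-based inclusive.
* **Overlaps.** All qualifying windows are reported; the per-sequence call
  (`call_cter()`) needs only existence, and its best hit maximizes the
  fraction with ties broken by the rightmost start.

```{r}
scan_acidic_windows("DEDEEGEEDEE", acidic_scan_params(tail_len = "all"))
```

Both 10-mers of this 11-residue motif carry 9/10 acidic residues, so a
protein ending in it is Cter-positive at the default threshold.

## Domain projection and conservation

`project_domain()` walks the reference row of the alignment counting non-gap
residues to locate the alignment columns carrying reference residues
`start..end`, then extracts every taxon's slice at those columns. Presence
calls (`call_domain_presence()`) require

* coverage `>= min_coverage` (default 0.6): non-gap residues over domain
  length, and
* similarity `>= min_similarity` (default 0.4): the fraction of mutually
  ungapped positions that are identical to the reference **or share a
  ClustalX strong group** with it.

Counting strong-group matches is deliberate: a repressor domain can be
"conserved" across highly diverged species where strict identity would fail.
The thresholds are package defaults, validated only on synthetic data, and
are echoed in every output row; published presence/absence judgments are
typically qualitative readings of an alignment figure, so no claim is made
that any specific threshold pair reproduces them.

`conservation_symbols()` renders per-column ClustalX-style marks: `*` for a
single residue type without gaps, `:` for columns contained in one ClustalX
strong group, `.` for one weak group, blank otherwise. A gap anywhere in the
column suppresses all marks. The strong/weak group tables are hard-coded
from the ClustalX definition and unit-tested; note that under these tables
some intuitively dissimilar pairs do share a weak group (D and K both sit in
SNDEQK, for example).

## Construct editing

`delete_interval()`, `truncate_cterm()` and `append_cterm()` perform the
deletion/transfer arithmetic of in-silico construct design with exact length
accounting (removing `start..end` shortens by `end - start + 1`; appending
the last `n` donor residues lengthens by `n`), mirroring deletion constructs
such as removing residues 36–50 (ΔRD1), 105–127 (ΔRD2) or 311–335 (ΔCter)
from a 335-residue protein, truncating a 21-residue terminus, or grafting a
25-residue terminus onto another family member.

## Parsimony: losses versus convergent gains

Three event counts are computed per binary character on a rooted tree
(branch lengths ignored):

* `fitch_cost()` — the unconstrained minimum number of state changes
  (generalized to polytomies by the multi-child counting rule, verified
  against exhaustive labeling enumeration in the tests).
* `dollo_scenario()` — the best single-gain history: the gain sits above the
  MRCA of all carrier leaves, and the losses are the roots of the maximal
  all-absent subtrees inside that clade; `event_count = 1 + losses`.
* `gains_only_cost()` — the minimum number of gains when losses are
  forbidden: the number of maximal all-carrier clades.

`compare_scenarios()` renders a verdict per character:
`convergence_scenario` when independent gains need strictly fewer events
than the single-gain history, `losses_scenario` when more, `tie` otherwise.
A tie is reported as such rather than forcing a winner, mirroring how an
even balance leaves both hypotheses open. This is an explicit
operationalization of a qualitative argument — "an unparsimonious number of
losses" — as an event-count comparison; reports should say so. On the
canonical illustration (carriers scattered across four distant cherries of a
16-leaf tree), four convergent gains beat one gain plus four losses, and the
verdict is `convergence_scenario`.

## RSA summaries

`domain_rsa_summary()` consumes per-residue relative solvent accessibility
profiles produced by an external predictor (a minimal NetSurfP-like
tab-separated layout: `pos`, `res`, `rsa` columns; the exact predictor
output format is not standardized, so the dialect is documented rather than
inferred). Summaries report the mean and **sample** (n−1) standard deviation
per domain — published "±" dispersions on modest-n domains rarely state the
convention, so `n` is printed alongside for conversion — plus the
whole-protein mean. `compare_domains()` is a two-sided Mann–Whitney U test:
exact null when the smaller group has ≤ 8 values and no ties, normal
approximation with tie correction otherwise, at alpha 0.01. The test choice
follows the nonparametric toolkit used elsewhere in the same study; RSA
prediction itself is out of scope, so the published mouse RSA means are not
regression targets (reproducing them requires running the predictor on the
exact accessions; `scripts/fetch_dbx_pair.R` documents the analogous
download-gated path for sequences).

## Pairwise identity

`global_align()` is Needleman–Wunsch with affine gaps via
`Biostrings::pairwiseAlignment` (BLOSUM62, gap open 10, gap extend 0.5 — the
conventional protein defaults; no alignment parameters are published for the
~40 % paralog identity figure, which is dominated by the homeodomain and
therefore robust to them). Percent identity defaults to the mutually
ungapped-column denominator, with the shorter-sequence denominator exposed
as an option since either may underlie a published round number. Two
numerical choices worth noting:

* the alignment is computed in a canonical orientation of the pair so that
  co-optimal tracebacks cannot make score or identity depend on argument
  order (symmetry is a tested invariant);
* the optimum is verified in the tests against exhaustive enumeration of
  every global alignment for short pairs, with the same gap-cost convention
  (`open + length × extend` per maximal gap run).

## The simulator and what it does (not) emulate

`simulate_family()` generates a rooted binary tree by uniform random
joining, draws a root protein with fixed consensus motifs inside the
configured domain blocks (the RD1 block is seeded from the published
endecapeptide LKFGVNAILSS, RD2 from KSFLIENLLRA), and substitutes each site
along each branch with probability `background_rate × relative_rate(site)`
to a uniformly chosen different residue. The Cter character evolves by
explicit events: gained at the configured branches, lost with per-branch
probability `loss_rate` where carried. At the leaves the terminal
`cter_len` residues are overwritten — carriers get a cluster with exactly
`ceiling(fraction × len)` acidic residues (12 residues at 90 % by default,
which guarantees a qualifying 10-mer at the 80 % scan threshold),
non-carriers get non-acidic residues (a degraded tail).

Defaults are the study conditions used across the tests: 12 taxa, 240
residues, background rate 0.05 substitutions/site/branch, RD blocks at 0.2×
and an HD-like block at 0.1× the background rate, a single root gain, loss
rate 0.1.

Two deliberate design points:

* **Identifiable losses.** A sampled loss is only realized where the parent
  node keeps at least one other carrying child (two for the gain node
  itself). This makes the simulated history exactly the unique most
  parsimonious single-gain explanation of the leaf states, so
  `dollo_scenario()` must recover the true gain node and loss set — an
  exact-recovery test rather than a statistical one. Without the
  constraint, a loss on a child branch of the gain node silently relocates
  the parsimony gain below the truth and exact recovery is ill-posed.
* **No indels, uniform replacement.** Sequences stay positionally
  homologous (the "alignment" of a simulated family is the sequences
  themselves) and substitution is uniform rather than WAG-like. The
  simulator's job is ground truth for detector/parsimony recovery, not
  phylogenetic realism: passing these tests says the machinery is correct,
  not that real alignments, alignment error, rate heterogeneity or
  convergent sequence similarity are handled — those enter only through
  real data.

A background residue drawn uniformly from 20 amino acids is D/E with
probability 0.1, so a spurious qualifying window in a non-carrier tail is
possible in principle but has probability around 10⁻⁵ per sequence —
negligible at the replicate counts used here.

## Problem sizes and runtime choices

The validation suites run at: 1000 random sequences against the brute-force
window enumerator; every global alignment enumerated for pairs up to 6
residues; 500 random trees of up to 8 leaves against exhaustive ancestral
labelings (plus fixed polytomy topologies); exact Mann–Whitney enumeration
for all group-size pairs up to 6; and 50 simulated 12-taxon families for
exact gain/loss recovery. These sizes keep the whole suite under a minute
on one CPU while leaving every oracle genuinely exhaustive at its scale.

## Known limitations

* Domain presence thresholds (0.6/0.4) are sensible defaults, not fitted
  quantities; on real alignments they should be examined per family.
* The scenario comparison counts events only; it ignores branch lengths and
  rate asymmetries between gain and loss, and a `tie` verdict carries no
  strength-of-evidence measure.
* The scanner is a windowed composition statistic; it does not model
  unclustered acidity ("acid blob" net charge) or nucleotide-level signals.
* `read_rsa_table()` parses a minimal predictor-like dialect, not the exact
  column layout of any specific NetSurfP release.
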