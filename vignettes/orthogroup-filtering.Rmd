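---
title: "Selecting orthologous loci from de novo transcriptomes: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting orthologous loci from de novo transcriptomes: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(ohdlf)
```

## The problem

Phylogenies for species without reference genomes are usually built from de
novo assembled transcriptomes: assemble reads into transcripts, predict and
translate ORFs, cluster the proteins of all species into orthogroups (for
example with OrthoFinder), and select loci suitable for tree building. The
selection step is where highly heterozygous plant genomes break the standard
recipe. A de novo assembler reports both haplotypes of a divergent locus —
and recent tandem duplicates, and some splice variants — as separate
"genes", so a locus that is biologically single-copy looks multi-copy, and a
strict one-to-one orthogroup filter discards nearly everything. In genera
with this profile, only a few dozen strictly single-copy orthogroups may
survive out of a hundred thousand, far too few informative sites for a
well-supported tree.

The copy-number inflation has a diagnostic signature: apparent copies born
from heterozygosity or very recent duplication are *nearly identical*
(roughly 99% amino-acid identity), while paralogs retained from ancient
whole-genome duplications are *deeply diverged* (tens of percent). A
similarity threshold between those two regimes separates collapsible copies
from true paralogs. This package implements that idea as a three-stage
orthogroup filter with consensus merging.

## The selection model

For an orthogroup $g$ over a species roster $S$:

1. **Missing-rate filter.** The missing rate is
   $m(g) = |\{s \in S : c_s(g) = 0\}| / |S|$, where $c_s(g)$ is the copy
   count of $g$ in species $s$. Keep $g$ iff
   $m(g) \le$ `max_missing_rate` (default 0.05). The rate is always
   computed against the roster declared by the input table's header.

2. **Duplication filter.** Keep $g$ iff $\max_s c_s(g) \le$
   `max_duplication_num` (default 6). This is the *per-species* maximum
   copy number, not the orthogroup's total gene count: it is the quantity
   that heterozygosity and recent duplication inflate, and the quantity a
   per-species consensus can deflate again.

3. **Similarity gate and consensus merging.** For every species with
   $c_s(g) \ge 2$, compute all pairwise global-alignment identities among
   its copies. The copies are mergeable iff **all** pairs reach
   `min_similarity` (default 0.97) — complete linkage, so a single deep
   paralog in the set blocks the merge no matter how similar the other
   copies are. Mergeable copies are collapsed to a consensus (below);
   non-mergeable ones either discard the orthogroup
   (`reject_policy = "drop_orthogroup"`, default) or just that species'
   copies (`"drop_species"`).

Both comparisons are inclusive ($\le$); `strict = TRUE` switches to strict
inequalities for users who read thresholds exclusively. Thresholds are
deliberately run-time parameters: a genus with rampant recent duplication
wants `(0.10, 10, 0.95)` for supermatrix building, while cleaner genomes
can afford the stricter default `(0.05, 6, 0.97)`. Relaxing any one
threshold can only grow the pass set (monotonicity), which the tests check.

Stage order matters for reporting: the missing rate is computed on the
*original* membership, before any similarity-based species removal, so that
outcomes do not depend on evaluation order.

### Pairwise identity

The identity computation needs a concrete alignment model, which we fix as
Needleman–Wunsch global alignment with affine gaps (match +1, mismatch −1,
gap open −5, gap extend −1; a gap run of length $k$ scores
$\mathrm{open} + k \cdot \mathrm{extend}$). The alignment itself is standard
machinery and is delegated to `Biostrings::pairwiseAlignment()`; the test
suite certifies its optimality against an independent exhaustive-enumeration
oracle on short sequences.

Identity is the number of identical aligned columns divided by, per default,
the number of alignment columns between the first and last column where
*both* sequences carry a residue. Excluding terminal overhangs is the right
default for de novo transcripts, which are often fragmentary: a 5′-truncated
allele should not be rejected for being short. The CD-HIT-style
`shorter_sequence_length` denominator is available as an option. Because tied
optimal alignments can differ in match count, identity is computed on the
lexicographically ordered pair, which makes `pairwise_identity(a, b)`
exactly symmetric by construction.

### Consensus merging

Mergeable copies are star-aligned against the longest copy (ties broken by
the smallest gene ID — any copy would do at ≥97% identity, but the choice
must be deterministic). Insertions private to non-reference copies are
dropped; each reference column is then decided by voting over the non-gap
residues:

* unanimous → residue kept (unanimous site);
* strict majority (> half of non-gap votes) → majority residue kept;
* otherwise → column removed (divergent site trimmed).

Gaps do not vote, so a fragmentary copy abstains where it has no data
instead of vetoing it. For a heterozygous pair this reduces to: homozygous
sites pass through, heterozygous sites are trimmed — the consensus is the
sequence of sites where the haplotypes agree. Voting is per-column and
therefore independent of copy order; a column whose non-gap vote set is
empty is trimmed. Merging identical copies is a fixed point, and
`length(consensus) + n_trimmed` always equals the reference length.

We use star alignment rather than a full progressive MSA because the gate
guarantees the copies are ≥ `min_similarity` identical, a regime where star
alignment against a fixed reference is effectively exact and, unlike
general-purpose MSA heuristics, exactly reproducible.

## Outputs for tree building

Retained loci (≥ 2 species after merging) feed two standard routes:

* **Concatenation:** per-locus alignments are concatenated into a
  supermatrix written as relaxed PHYLIP (`final_OrthologsAlign_GDL.phy`)
  with a RAxML-style partition file. Species absent from a locus are padded
  with `-` (configurable); relaxed PHYLIP is used because real species
  names exceed strict PHYLIP's 10 characters. Typical downstream command:
  `raxmlHPC -f a -# 1000 -m PROTGAMMAAUTO -s final_OrthologsAlign_GDL.phy ...`.
* **Coalescent:** per-locus alignment FASTAs (for e.g.
  `iqtree2 -m MFP`) and, once per-locus trees exist, an aggregated
  multi-newick `all.trees` for ASTRAL-family methods.
  `aggregate_gene_trees()` validates every newick with ape but writes the
  input strings verbatim, so aggregation is byte-deterministic.

Tree inference itself is out of scope: RAxML/IQ-TREE/ASTRAL are external
programs with their own stochastic search, and this package's job ends at
preparing exact, reproducible inputs for them. Per-locus alignment defaults
to the builtin star aligner for reproducibility; `aligner =
"external_mafft"` shells out to MAFFT when a general-purpose aligner is
preferred. The supermatrix is emitted as amino acids (the merging operates
on proteins throughout); users who want nucleotide matrices must
back-translate externally.

## The synthetic-data generator

`generate_dataset()` creates OrthoFinder-dialect datasets with the exact
failure modes the filter targets, plus analytic ground truth. Per
orthogroup: a random ancestral protein (uniform over the 20 residues,
default length 300); per species, a base copy mutated at
`species_divergence` (default 0.05) unless lost (`loss_prob`, default
0.02); with probability `het_prob` (0.15) a second allele mutated from the
base at `het_divergence` (0.01 — the ~99% identity heterozygosity regime);
with probability `dup_prob` (0.05) a recent duplicate at the same
divergence; with probability `paralog_prob` (0.02) a deep paralog at
`paralog_divergence` (0.40 — the ancient-WGD regime, safely below any
sensible merge threshold).

Substitutions are uniform over the 19 alternative residues — no empirical
amino-acid exchange matrix, no rate heterogeneity — because what is under
test is identity-threshold behaviour, not phylogenetic realism. Mutation is
applied on one branch of each allele pair (allele 2 is mutated *from*
allele 1), so the unanimous sites of the merged consensus provably equal
the ancestral allele; a two-branch model would allow rare coincident
substitutions to break that identity. No indels are generated by default,
which makes every pairwise identity an exact Hamming identity and hence
analytically known from the realized draws; `indel_prob` adds short
deletions to exercise gap handling, at the price that similarity ground
truth for affected orthogroups becomes `NA`. Loss, heterozygosity,
duplication and contamination are drawn independently per species — real
gene loss is phylogenetically correlated, and real orthogroup membership
errors are not independent of divergence, so passing these tests shows the
bookkeeping and thresholds are exact, not that the method is validated on
real transcriptomes.

Ground-truth labels (`ground_truth_labels()`) are derived from the realized
draws — realized absences, realized copy counts, exact Hamming identities —
with the same precedence as the filter, never by running the filter itself.
The default rates give a 24-species, 1000-orthogroup study a realistic
mixture: most orthogroups pass, a few percent fail each criterion, and
boundary cases (exactly one missing species out of 24, exactly 6 or 7
copies) occur naturally.

Unstated-by-construction choices fixed here once: `het_prob` 0.15 (high
heterozygosity without dominating), `dup_prob` 0.05, `paralog_prob` 0.02,
`loss_prob` 0.02 (expected missing rate 2%, putting the 5% threshold in
play for a 24-species roster), `species_divergence` 0.05 (well inside the
mergeable regime between species, irrelevant to within-species identity).

## Numerical and degenerate-input choices

* Comparisons with thresholds are exact floating-point comparisons on
  ratios; both the filter and the ground-truth labels compute the same
  ratios, so concordance checks are exact, not tolerance-based.
* Empty cells in the orthogroup table are absences (data, not errors); an
  orthogroup row with no genes at all is a hard error.
* Sequences are upper-cased and trailing stop codons stripped on read;
  a gene ID listed without a sequence, duplicate gene IDs, duplicate
  orthogroup IDs and empty sequences are hard errors naming the offender.
* A consensus that trims to zero length drops that species with a warning.
* Loci with fewer than two species after merging are skipped with a
  warning; a run whose concatenation has zero loci is a hard error.
* `run_pipeline()` removes a partially written output directory it created
  before re-raising any error, and serializes its full configuration to
  `run_manifest.json`.

## Scale of the shipped checks

The package's own test suite and acceptance script run the generator at the
study scale the method targets — 24 species × 1000 orthogroups at sequence
length 300 for the filter-concordance checks, with smaller rosters for
pipeline-level round trips — sizes chosen to exercise every code path and
boundary while keeping a full run in minutes on one core.

## Known limitations

* Allopolyploids violate the model: homoeologous copies sit between the
  heterozygosity and deep-paralog regimes and no single identity threshold
  separates them; the method is not designed for hybrid polyploid species.
* Merging is amino-acid only; codon-aware merging and haplotype phasing are
  out of scope.
* Complete-linkage mergeability is conservative by design: one contaminant
  copy rejects the species (or orthogroup) even if five others are clean
  alleles.
* The star alignment is exact only in the high-identity regime the gate
  enforces; it is not a general MSA.
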