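---
title: "linckit: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{linckit: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains what linckit computes, why its defaults are what
they are, what the synthetic-data generator does and does not emulate,
and where the design was genuinely open.

# The identification model

A long intergenic non-coding RNA (lincRNA) is operationally defined by
exclusion: a transcript longer than 200 nt, with no evidence of
protein-coding capacity, no strong similarity to transposable elements,
and no overlap with annotated genes. linckit applies these filters as a
fixed cascade — length, coding potential, TE similarity, genomic overlap
— so that every transcript receives exactly one class and the counts
across classes always sum to the input. The cascade order matters for
interpretation: a TE copy that also carries a long ORF is reported as
coding, not TE-derived, because the coding filter runs first.

Boundary conventions are deliberate and covered by tests: "longer than
200 nt" and "more than 100 aa" are strict inequalities (a 200-nt
transcript is rejected, a 100-aa ORF is still non-coding), while the
protein-hit E-value rule (≤ 1e-5) and the TSS window (≤ 100 bp) are
inclusive. ORF length counts codons from the initiator ATG (inclusive)
to the stop (exclusive), over all six frames; ORFs without an in-frame
stop do not count, which is exactly why truncated assemblies of real
coding genes can slip through the filter — the package reproduces that
failure mode on purpose in its validation.

The TE rule is a conjunction (bit score ≥ 200 **and** E ≤ 1e-20). The
alternative reading — either threshold alone — would discard transcripts
with only weak, possibly exapted TE ancestry; the conjunction keeps
them, which matches the stated motivation of separating only
high-confidence TE derivatives. Simple tandem di-/tri-nucleotide repeats
are not filtered at all: there is no biological reason to exclude them,
and repeat-bearing transcripts can be of particular interest.

Overlap classification uses the transcript's genomic **span** against
gene loci (optionally widened by a 500 bp flank to stand in for missing
UTR annotation), not exon-level intersection. Span overlap matches the
intergenic-space framing of the definition — a transcript inside an
intron of a gene is not "intergenic" — and is the more conservative
choice. Direction calls need a strand: stranded assemblies provide it
directly, and unstranded multi-exon transcripts are oriented by their
splice junctions (GT..AG on the transcribed strand, each intron voting).
Single-exon unstranded transcripts over a gene cannot be oriented and go
to `AMBIGUOUS_OVERLAP`, excluded from the lincRNA output rather than
guessed.

# The homology engine

The conservation stage needs a local similarity search with
BLAST-comparable significance. The built-in engine seeds exact 11-mers
(both strands, numeric 2-bit codes, N-containing words skipped),
clusters seeds by subject position and diagonal, and computes one
optimal local alignment per clustered window with
`Biostrings::pairwiseAlignment` (match +2, mismatch −3, gap open 5, gap
extend 2 — the classic nucleotide-search scheme). Raw scores are
converted with the ungapped Karlin–Altschul parameters of the
match/mismatch scheme: λ solves `Σ pₛ e^(λs) = 1` by bisection to 1e-9,
and K comes from the standard lattice renewal computation (convolution
powers of the score distribution). For uniform composition these
reproduce the published ungapped constants to four digits — (+1,−2):
λ = 1.3327, K = 0.621; (+2,−3): λ = 0.6337, K = 0.408 — so E-values are
on the familiar scale. Using ungapped statistics with affine-gap scores
slightly overstates significance of gapped alignments; at the stringent
default cutoff (1e-20) this has no practical effect on which loci pass.

Hits of one query on one subject strand merge into a locus when their
gap is at most `merge_gap` = 10,000 nt (single linkage). The value is a
default, not a finding: it spans typical plant and mammalian introns
without bridging neighbouring genes at the scales the package targets,
and it is configurable. A merged locus scores the **sum** of its member
bit scores, which rewards multi-exon queries whose exons hit separately
— the very situation merging exists for. Top-hit selection breaks ties
by lower minimum E-value, then leftmost coordinate, so runs are
deterministic.

Queries with no passing full-length hit are re-searched as 200-nt
segments; segment hits are mapped back to parent-query coordinates and
merged as usual, so segments of one homolog reassemble into one locus.
A trailing remainder shorter than 100 nt is discarded: sub-100-nt
queries produce unstable E-values against genome-scale search spaces.
(A 250-nt query therefore yields a single 200-nt segment.)

The reciprocity test extracts the candidate locus, searches it back
against the query genome, and requires the reciprocal top hit to overlap
the original query locus — by at least 1 bp by default. Any-overlap is
the weakest faithful reading of the mutual-top-hit requirement; a
minimum-fraction knob (`reciprocal_min_overlap`) is provided for users
who want a stricter criterion.

# Families, trees and events

Reciprocal top hits are collected per query into a family, at most one
call per species, ordered by the panel (a species list ranked by
relatedness to the query species, which is the first entry).
Conservation depth is reported as the farthest panel rank with a
reciprocal homolog — panel rank as a proxy for phylogenetic depth; no
binning into named clades is imposed, that is left to the user's panel
design. Families are aligned by an internal star alignment (global
pairwise alignment of every member to the longest sequence, gap
propagation into a shared profile); a MAFFT adapter
(`align_family(..., method = "mafft")`, run with `--maxiterate 1000`) is
available when the executable is on the PATH. Gene trees come from
neighbour joining on p-distances (gaps treated as missing, pairwise
deletion) with a nonparametric bootstrap over columns; 100 replicates by
default, which is enough to separate supported from unsupported edges at
family sizes of a handful of sequences.

Reconciliation is classical LCA mapping: each gene-tree node maps to the
LCA of its leaves' species; a node is a duplication when it maps where
one of its children maps; a child edge spanning k species-tree edges
implies k−1 losses after a speciation and k after a duplication. Before
mapping, internal edges with bootstrap support below 70 are collapsed
and the polytomies re-resolved greedily (repeatedly joining the pair of
children whose species mappings have the deepest LCA). This
collapse-and-re-resolve is an approximation to full rearrangement-mode
reconciliation: it guarantees that weakly supported conflict with the
species tree costs nothing (the greedy join reproduces the species
topology for concordant leaf sets) but does not search all resolutions.
Unrooted gene trees are reconciled under every possible rooting and the
minimum-event rooting is kept. The exhaustive-minimum property of LCA
mapping is verified in the test suite against a brute-force oracle over
all 432 distinct gene trees with up to 5 species-labelled leaves on a
3-taxon species tree.

# The synthetic-data generator

The generator is the package's study design. `make_identify_fixture`
plants, on one random chromosome: coding transcripts that are complete
ORFs of 120–300 codons (safely past the 100-aa limit); lincRNAs of
300–800 nt with 1–3 exons, verified ORF-free above 100 aa and kept more
than the flank margin away from any annotated gene; TE transcripts
copied from a generated TE database at ≤ 3% divergence (re-mutated if a
long ORF arises by chance, since a coding TE copy would truthfully be
coding); sense/antisense transcripts planted inside annotated gene
spans; single-exon unstranded gene-overlapping transcripts; and sub-200-nt
transcripts. TSSs are placed at the exact 5′ ends of half the lincRNAs.
Every file is a deterministic function of the seed.

`make_panel_fixture` evolves an ancestral genome with planted lincRNA
loci along a ladder species tree: per-branch uniform substitutions at a
stated rate (0.03/site by default — within-family divergence where
homologs remain confidently alignable), and indel events of geometric
length placed *between* planted loci so truth coordinates stay exact.
Losses and duplications are explicit per-branch events; duplicate copies
are placed farther than the hit-merging gap from existing copies so they
register as distinct loci. On a ladder tree a "loss in the two deepest
species" is two single-branch events, and the generator keeps that
explicit rather than inventing a clade.

What the fixtures do **not** emulate: real base composition and
repetitive landscapes (sequences are uniform i.i.d. DNA), splice-site
realism beyond GT..AG, transcript-abundance effects, assembly artefacts
other than the deliberate truncation experiment, genome rearrangement,
and selection (all sites evolve at one rate). Passing the suite
therefore demonstrates that the algorithms implement their definitions
exactly and recover planted signal under idealised noise — not that the
thresholds are optimal for any particular real genome.

Problem sizes were chosen so the whole suite exercises every path in a
few minutes on one core: identification fixtures of ~50–210 transcripts
(3 seeds at the larger size), a 500-transcript coding set for the
false-discovery check, panels of 4–5 species with 30–50 kb genomes and
8–20 queries, 100-replicate bootstraps, and the full 432-tree
reconciliation enumeration.

# Numerical and degenerate-input choices

* Internal coordinates are Bioconductor-native (1-based, closed,
  `GRanges`); BED converts to 0-based half-open at the boundary, GFF/GTF
  stay 1-based. Strand `"*"` is a first-class "unknown" consumed
  explicitly by the classification rules.
* FASTA ids are the header token before the first whitespace; pipe
  characters are stripped with a warning rather than an error, and
  duplicate ids abort. Empty FASTA/GTF files yield empty, valid
  containers; an empty assembly produces a zero-row summary.
* λ bisection tolerance 1e-9; the K renewal series stops when a term
  falls below 1e-12 (at most 60 convolutions).
* Queries shorter than the seed word (11 nt) return an empty result with
  a warning. Transcripts referencing chromosomes absent from the genome
  abort with the offending ids listed.
* TSS distance is a direct base-pair count between the 5′ point and the
  TSS interval (0 inside), keeping "within 100 bp" inclusive and
  independent of interval-algebra gap conventions.
* When several known lincRNAs overlap one candidate, the nearest by
  midpoint is reported as *the* overlapping locus and all are retained
  in the summary table. Homolog calls overlapping several annotation
  features keep every feature id, ordered by coordinate.
* A query lincRNA with no locatable locus in the query genome skips the
  reciprocity test with a recorded warning and is never called a
  homolog.

# Limitations

The engine's sensitivity floor is the exact 11-mer seed: homologs below
roughly 75% identity over their best-conserved stretch can be missed
regardless of the E-value cutoff, which is the expected regime for
deeply diverged lincRNAs. Ungapped significance statistics are applied
to gapped alignments (see above). The reconciliation heuristic does not
explore all polytomy resolutions, and transfer events are out of scope.
The identification stage trusts the supplied annotation: genes missing
from it will not demote overlapping transcripts, exactly as annotation
quality limits any intergenicity call.
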