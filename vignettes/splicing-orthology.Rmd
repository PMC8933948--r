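---
title: "Splicing-structure orthology: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Splicing-structure orthology: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spliceortho)
```

## The problem

Alternative splicing lets one eukaryotic gene encode several CDSs, but most
orthology resources stop at the gene or exon level: they do not say which
*isoforms* of two orthologous genes correspond. This package implements a
structural notion of transcript orthology. Two transcripts of orthologous
genes are *spliced CDS orthologs* when their CDSs use pairwise-orthologous
start/stop codons, splice sites and coding blocks — syntactically equal
structure models. Because the test is structural, a CDS known in one
species can be *predicted* in another whenever all of its building blocks
are present there, even if no transcript was ever annotated.

## The token grammar

A gene's coding structure is a string over `[` (start codon), `]` (stop
codon), `<` (splice donor), `>` (splice acceptor) and letters (coding
blocks). Blocks are maximal coding segments between functional sites; an
exon is a chain of directly adjacent blocks, so an alternative 5' extension
B of exon C appears as `B>C` — block B flush against C with a second
acceptor at the B/C boundary. Every token is anchored to genomic
coordinates, held internally as 0-based half-open intervals in
transcription orientation; sites are zero-width boundaries with an attached
motif window. Minus-strand loci are reverse-complemented at load, so the
grammar is orientation-free and a gene serialized on either genomic strand
yields the identical model (this is asserted by a test).

The gene model is built from the known transcripts: the token union, with
blocks re-segmented so that every site position of any transcript is a
block boundary. Stop codons are modelled inside the stop token's
trinucleotide; whether a GTF dialect includes the stop codon in its CDS
features is a configuration flag (`stop_in_cds`, default off, the stop is
read from the genome). Start codons default to ATG; known transcripts with
another start are accepted with a warning, predictions always require a
configured start codon.

## Pairwise comparison

For two orthologous genes, known coding blocks are anchored in the other
gene by local alignment, longest block first, each search window bounded by
the previously accepted anchors — this enforces colinearity and avoids
paralogous exon matches. Known functional sites are then mapped through the
resulting boundary correspondence (every site used by a transcript sits on
a block boundary); a site whose flanking blocks did not anchor falls back
to aligning its motif with 12 nt of context on each side. A mapped position
carrying a known token of the same kind records a token orthology; a mapped
position in unannotated sequence with an exact motif (GT donor, AG
acceptor, configured start/stop codon) becomes a predicted token. All
boundary pairs are merged into one strictly monotone map; crossing pairs
are dropped and reported.

The alignment backend is `Biostrings::pairwiseAlignment` with match +2,
mismatch −3, gap open −5, gap extend −2. A block hit must reach identity
≥ 0.70 (matches over query length) and, by default, a length offset
divisible by three (`frame_check`; turning it off defers frame problems to
the executability test, where they are still caught). The site-context
fallback uses a laxer 0.50 identity because half of the context may be
intron, plus the exact-motif requirement. All thresholds live in
`orthology_config()` and were fixed once as reproducible defaults; the
alignment literature this step builds on does not pin published values.

Only known tokens seed alignments. Predicted tokens never seed further
predictions across pairs, so there is no transitive prediction chaining; a
consequence is that a site known in only one species yields a 2-edge path
across three species, which the site-graph classification treats as
irregular.

## Triplet analysis

Three pairwise comparisons are run per triplet (pairs (1,2), (1,3), (2,3)
of the configured species order, which also sets prediction-source
precedence). Predicted tokens are merged into final per-gene models, and a
segmentation-closure pass carries block boundaries discovered by one pair
across the others (by exact map lookup, or offset within a gapless anchored
block pair) so orthologous regions share one segmentation. Orthology edges
are recomputed on the final segmentation, and orthologous blocks are
unified to one letter per connected set (union–find; a merge that would put
two blocks of one gene under one letter is dropped and reported).

Prediction then tests every known transcript model of every gene in both
other genes: expressible (all tokens have orthologs) and executable (the
assembled candidate is a valid CDS). Deduplication is by unified-label
model string, so a CDS predictable from two species appears once with the
full source set. Predicted IDs are `<gene>.pred<N>` in lexicographic
model-string order, purely for determinism.

The *functional-site graph* takes all sites involved in known and predicted
transcripts — predicted sites participate exactly as known ones, since the
classification concerns structure, not annotation provenance. Component
classes are singleton / couple / triplet / irregular, where a triplet must
be a 3-clique (all three pairwise orthologies), the stricter reading of a
three-species site. A triplet of genes is *retained* when no component is
irregular and *structurally orthologous* when all components are triplets.
The *transcript graph* links equal model strings across genes; connected
components spanning the three species are the CDS orthology groups, and
per-gene verdicts `all_conserved` / `single_copy` follow. Same-species
known transcripts sharing a model string are redundancy sets; transcripts
lacking a 5' or 3' UTR in their annotation are excluded from that
enumeration (without UTRs, "same CDS, different transcript" cannot be
established) and reported separately.

Evidence tags are assigned with strict precedence: `confirmed` (exact
ordered coding-exon chain in a supplied annotation collection — a 3 nt
boundary shift already fails), else `possible` (no specific exon junction:
every junction of the prediction occurs in some known transcript of the
input set), else `achievable` when all specific junctions have read support
≥ `min_reads` (default 1; no published threshold exists for this step),
else `not_achievable`. Read alignment itself is out of scope; junction
support enters as a summary table (STAR-style tab or BED).

## The synthetic generator

`fixture_spec()`/`realize_fixture()` generate tri-species gene loci that
realize declared grammars: homologous blocks descend from one ancestral
sequence mutated to the requested identity (default 0.95, a realistic
mammalian coding-exon level), introns and flanks diverge at 0.25
(indistinguishable from independent sequence), and every declared site gets
its exact motif. Mutations never touch site motifs, start/stop codons, or
create in-frame stops in declared transcripts (codon-aware substitution
with per-position rejection). Default geometry — blocks 24–36 nt, introns
80 nt, flanks 60 nt — keeps loci around 1 kb so a full triplet analysis
runs in about a second; these sizes are stated here as the package's chosen
study conditions. Equal seeds give byte-identical files.

What the generator does **not** emulate: indels between orthologs (the
default is substitution-only, so boundary mapping is exact by
construction), repeats and paralogy, non-canonical splice sites, GC/AT
isochore structure, and annotation errors. Passing tests therefore
demonstrate correctness of the method's logic under clean homology, not
robustness to genome-scale noise; on real data the alignment thresholds do
the filtering and recovery will degrade with divergence, as the
identity-titration property test shows monotonically.

The bundled figure fixtures encode the package's three reference
scenarios. The alternative-exon gene (`fig1`) is defined by its counts —
seven known transcripts as 4 mouse + 2 human + 1 dog over four CDS
structures, five predictions, four orthology groups; those counts do not
fully determine which two structures human knows, and the fixture fixes
human to the two BC-containing forms, the unique choice consistent with
all of them. The predictions this implies are the acceptor of C in human,
and block B, its acceptor and the acceptor of H in dog. The redundant-UTR
gene (`fig4`) uses the grammar `[A<>B<>C]` with structures `[A<>B<>C]`
(encoded redundantly in human and mouse) and `[A<>C]`. The deleted-block
gene (`fig5`) declares its five transcripts as 2+1+1 known structures with
block C genuinely deleted from the third locus; only the per-gene
properties (the prediction appears where C exists, not where it is
deleted) are load-bearing.

## Numerical and degenerate-input choices

* Ties between equal-scoring alignment hits resolve to the smallest target
  coordinate (the alignment backend's deterministic choice).
* Conflicting boundary pairs are resolved by score, then position; the
  merged map is strictly monotone.
* An empty search window is a no-hit, not an error.
* Overlapping transcripts implying inconsistent reading frames raise a
  model-conflict error naming the transcripts (`strict_frames`; set to
  FALSE to downgrade to a warning).
* Block labels are single uppercase letters; more than 26 orthologous block
  sets in one triplet is a hard error (far beyond the intended desk scale).
* Per-triplet failures in `run_pipeline()` are recorded and do not stop the
  run.

## Known limitations

Classification rules are specified for exactly three species (the data
model is N-ary, the verdicts are not). UTR structure is not modelled as
tokens and UTR-bearing transcripts are not predicted — predictions are CDS
only. Trans-splicing, selenocysteine recoding and polycistronic CDSs are
out of scope. The simplified tabular export replaces a relational-database
export; no SQL schema is produced.
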