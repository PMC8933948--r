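# spliceortho

Comparative genomics of splicing structure: identify orthologous genes that
share their complete splicing structure across three species, and predict
spliced CDS orthologs — coding transcripts whose exon/intron structure is
conserved — from annotation plus genome sequence alone.

## Who this is for

Genome annotators and comparative-genomics researchers who have, for each of
three species (the reference use case is human, mouse and dog): gene-locus
sequences (FASTA), CDS/UTR annotations (GTF), and a one-to-one ortholog gene
map (TSV). The package tells you, per gene triplet, which splice sites,
start/stop codons and coding exons are shared, which known CDS structures
can be expressed in the other species, and how much support each predicted
CDS has in external annotation and splice-junction read data.

## The model

The coding structure of a gene *i* is an ordered token string, the *gene
structure model* `M^G_i`: functional sites — start codon `[`, stop codon
`]`, splice donor `<`, splice acceptor `>` — and lettered *coding blocks*
(maximal coding segments between sites; an exon is one or more adjacent
blocks). A transcript's spliced CDS is a token subsequence, its *transcript
structure model* `M^T_iu`. For example a gene with two alternative terminal
exons is

```
M^G_i = [A<>B<>C]>D]        M^T_i1 = [A<>B<>C]     M^T_i2 = [A<>B<>D]
```

Between two orthologous genes, each known block and site is aligned against
the other gene's sequence (colinear local alignment; block hits need
identity >= 0.70 and a frame-compatible length offset; predicted sites need
an exact GT/AG/ATG/stop motif at the mapped position). Aligned same-kind
tokens form the symmetric *token orthology* relation `A(K_im, K_jn)`; hits
in unannotated sequence become *predicted* tokens. A transcript model is

* **expressible** in gene *j* if every one of its tokens has an orthologous
  token in `M^G_j`;
* **executable** if additionally the concatenation `S(M^T_iu, M^G_j)` of
  the orthologous blocks of *j* forms a valid CDS (start codon, length
  divisible by three, no internal in-frame stop).

An executable model not matching any known transcript of *j* is emitted
once as a *predicted transcript* — a spliced CDS ortholog of its source.
Per triplet, a *functional-site graph* (nodes = sites, edges = orthologies)
classifies each site as species-specific (singleton), two-species (couple)
or three-species (triplet = 3-clique); a gene triplet whose graph contains
only triplets of sites is *structurally orthologous*. A *transcript graph*
(edges = equal model strings across genes) yields *CDS orthology groups*,
and same-species transcripts with equal CDS but different UTRs are reported
as redundancy sets. Each predicted CDS is tagged `confirmed` (exact
coding-exon chain in a supplied annotation), `possible` (no specific exon
junction), `achievable` (all specific junctions read-supported) or
`not_achievable`.

## Worked example

The package bundles deterministic tri-species fixtures. `fig1` realizes a
gene with alternative exon variants C/BC and G/GH-H and four CDS
structures; mouse knows all four, human two, dog one:

```r
library(spliceortho)
spec  <- figure_fixtures()$fig1
files <- realize_fixture(spec, "fix/")             # FASTA + GTF + junctions
genes <- sapply(spec$species, function(sp)
  load_species(files$species[[sp]]$gtf, files$species[[sp]]$fasta, sp),
  simplify = FALSE)
genes <- sapply(genes, `[[`, 1, simplify = FALSE)
jx    <- sapply(spec$species, function(sp)
  read_junctions(files$species[[sp]]$junctions), simplify = FALSE)
report <- run_triplet(genes, junctions = jx)
report
#> <triplet_report> humanG1~mouseG1~dogG1
#>   known transcripts: 7   predicted CDSs: 5
#>   retained: TRUE   structurally orthologous: TRUE
#>   CDS orthology groups: 4   all conserved: TRUE   single copy: TRUE
#>   redundant-CDS sets: human=0 mouse=0 dog=0
```

The seven known transcripts represent four CDS structures; five predictions
(two in human, three in dog) complete the transcript graph into four
three-species CDS orthology groups, and every functional site is shared by
all three species, so the triplet is structurally orthologous. Each
prediction carries its source species and an evidence tag:

```r
report$predictions$dog[[1]][c("transcript_id", "model_string", "source")]
#> $transcript_id  "dogG1.pred1"
#> $model_string   "[A<>BC<>DE<>F]"
#> $source         "human,mouse"
report$evidence[1, ]
#>   species transcript_id        tag                         detail
#> 1   human humanG1.pred1 achievable 1/1 specific junctions covered
```

`write_predictions_gtf()`, `write_groups_tsv()` and `write_verdicts_tsv()`
export the results; `inst/scripts/spliceortho` wraps `simulate` and `run`
as shell subcommands.

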