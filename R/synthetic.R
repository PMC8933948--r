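## Deterministic tri-species fixture generator.
##
## A FixtureSpec declares, per species, the true gene grammar present in the
## locus sequence (including elements no known transcript uses), the known
## transcript structures, and UTR variants. realize_fixture() turns it into
## FASTA + GTF + junction files with exact splice motifs: homologous coding
## blocks descend from one ancestral sequence mutated to the requested
## identity, introns diverge independently of coding constraints.

.SAFE_CODONS <- setdiff(apply(expand.grid(c("A","C","G","T"),
                                          c("A","C","G","T"),
                                          c("A","C","G","T")), 1, paste,
                              collapse = ""),
                        c("TAG", "TGA", "TAA"))

#' Declare a synthetic tri-species gene fixture
#'
#' @param name fixture name.
#' @param species species names in precedence order.
#' @param gene_ids named character vector of gene identifiers per species.
#' @param grammars named character vector: the true structure grammar of each
#'   species' locus (see [parse_model_string()]); a block absent from a
#'   species' grammar is genuinely deleted from its sequence.
#' @param transcripts named list (per species) of lists; each transcript is
#'   `list(id =, model =, utr5 =, utr3 =)` with UTR lengths in nt (0 = the
#'   annotation lacks that UTR).
#' @param block_lengths named integer vector of block lengths per label;
#'   lengths must keep every declared transcript's coding length a multiple
#'   of three (the default enforces per-block multiples of three).
#' @param intron_length,flank intron/flanking lengths in nt.
#' @param block_identity cross-species identity of coding blocks (fraction;
#'   homologous blocks are mutated copies of one ancestral sequence).
#' @param intron_identity cross-species identity of introns and flanks
#'   (0.25 is indistinguishable from independent random sequence).
#' @param strands named character vector giving the genomic strand on which
#'   each species' locus is serialized.
#' @param junction_reads read count attached to every realized splice
#'   junction in the junction files (0 drops the junction line).
#' @param seed RNG seed; equal seeds give byte-identical outputs.
#' @return A list of class `"fixture_spec"` (validated).
#' @export
fixture_spec <- function(name, species = c("human", "mouse", "dog"),
                         gene_ids = setNames(paste0(species, "G1"), species),
                         grammars, transcripts,
                         block_lengths = NULL,
                         intron_length = 80L, flank = 60L,
                         block_identity = 0.95, intron_identity = 0.25,
                         strands = setNames(c("+", "+", "-"), species),
                         junction_reads = 5L, seed = 1L) {
  stopifnot(all(species %in% names(grammars)),
            all(species %in% names(transcripts)))
  labels <- sort(unique(unlist(lapply(grammars, function(g) {
    tk <- parse_model_string(g)
    tk$label[tk$kind == "block"]
  }))))
  if (is.null(block_lengths)) {
    block_lengths <- setNames(c(30L, 24L, 36L, 30L, 27L, 24L, 30L, 33L, 36L,
                                30L, 27L, 24L)[seq_along(labels)], labels)
  }
  if (!all(labels %in% names(block_lengths))) {
    stop("validation error: missing block length for some labels")
  }
  spec <- structure(list(name = name, species = species, gene_ids = gene_ids,
                         grammars = grammars, transcripts = transcripts,
                         block_lengths = block_lengths,
                         intron_length = as.integer(intron_length),
                         flank = as.integer(flank),
                         block_identity = block_identity,
                         intron_identity = intron_identity,
                         strands = strands,
                         junction_reads = as.integer(junction_reads),
                         seed = as.integer(seed)),
                    class = "fixture_spec")
  .validate_fixture_spec(spec)
  spec
}

.validate_fixture_spec <- function(spec) {
  for (sp in spec$species) {
    gtok <- parse_model_string(spec$grammars[[sp]])
    gsyms <- .symbol_of_token(gtok$kind, gtok$label)
    for (tr in spec$transcripts[[sp]]) {
      ttok <- parse_model_string(tr$model)
      if (!.is_token_subsequence(ttok, gtok)) {
        stop(sprintf("validation error: transcript %s is not a subsequence of the %s grammar",
                     tr$model, sp))
      }
      blk <- ttok$label[ttok$kind == "block"]
      if (sum(spec$block_lengths[blk]) %% 3L != 0L) {
        stop(sprintf("validation error: transcript %s coding length not a multiple of three",
                     tr$model))
      }
    }
  }
  invisible(TRUE)
}

## Can transcript tokens be embedded in gene tokens (in order, with
## adjacency of consecutive transcript blocks meaning no gene block between)?
.is_token_subsequence <- function(ttok, gtok) {
  gi <- 0L
  n <- nrow(gtok)
  positions <- integer(nrow(ttok))
  for (i in seq_len(nrow(ttok))) {
    found <- FALSE
    while (gi < n) {
      gi <- gi + 1L
      if (gtok$kind[gi] == ttok$kind[i] &&
          (ttok$kind[i] != "block" || gtok$label[gi] == ttok$label[i])) {
        positions[i] <- gi
        found <- TRUE
        break
      }
    }
    if (!found) return(FALSE)
  }
  ## adjacency: consecutive transcript blocks may not skip a gene block
  bl <- which(ttok$kind == "block")
  for (j in seq_along(bl)[-1]) {
    if (bl[j] == bl[j - 1] + 1L) {
      between <- gtok$kind[seq(positions[bl[j - 1]] + 1L,
                               length.out = positions[bl[j]] -
                                 positions[bl[j - 1]] - 1L)]
      if (any(between == "block")) return(FALSE)
    }
  }
  TRUE
}

## ---- layout -------------------------------------------------------------

## Assign internal coordinates (transcription orientation, 0-based
## half-open) to every token of a grammar.
.layout_grammar <- function(tokens, block_lengths, intron_length, flank) {
  pos <- flank
  n <- nrow(tokens)
  tokens$start <- NA_integer_
  tokens$end <- NA_integer_
  tokens$gap_before <- FALSE
  prev_kind <- ""
  for (i in seq_len(n)) {
    k <- tokens$kind[i]
    if (k == "block") {
      len <- block_lengths[[tokens$label[i]]]
      tokens$start[i] <- pos
      tokens$end[i] <- pos + len
      pos <- pos + len
    } else if (k == "acceptor") {
      if (prev_kind != "block") {
        pos <- pos + intron_length
        tokens$gap_before[i] <- TRUE
      }
      tokens$start[i] <- tokens$end[i] <- pos
    } else if (k == "donor") {
      if (prev_kind != "block") {
        stop("layout error: donor must directly follow a block")
      }
      tokens$start[i] <- tokens$end[i] <- pos
    } else { # start / stop
      if (k == "stop" && i < n && tokens$kind[i + 1L] == "block") {
        stop("layout error: stop codon would overlap the next coding block")
      }
      tokens$start[i] <- tokens$end[i] <- pos
    }
    prev_kind <- k
  }
  attr(tokens, "locus_length") <- pos + flank
  tokens
}

## Constraints a label's ancestral block must satisfy, across all species
## grammars: ATG at start when a start codon sits at its 5' end, terminal
## CAG when an acceptor boundary is flush at its 3' end, leading GT when a
## donor is flush at its 5' end.
.block_constraints <- function(spec) {
  cons <- list()
  for (sp in spec$species) {
    tk <- parse_model_string(spec$grammars[[sp]])
    for (i in seq_len(nrow(tk))) {
      if (tk$kind[i] != "block") next
      lab <- tk$label[i]
      entry <- cons[[lab]]
      if (is.null(entry)) entry <- list(atg = FALSE, cag = FALSE, gt = FALSE)
      if (i > 1L && tk$kind[i - 1L] == "start") entry$atg <- TRUE
      if (i > 1L && tk$kind[i - 1L] == "donor" &&
          i > 2L && tk$kind[i - 2L] == "block") entry$gt <- TRUE
      if (i < nrow(tk) && tk$kind[i + 1L] == "acceptor" &&
          i + 1L < nrow(tk) && tk$kind[i + 2L] == "block") entry$cag <- TRUE
      cons[[lab]] <- entry
    }
  }
  cons
}

.random_block <- function(len, atg = FALSE, cag = FALSE, gt = FALSE) {
  if (len %% 3L == 0L) {
    codons <- sample(.SAFE_CODONS, len %/% 3L, replace = TRUE)
    if (atg) codons[1] <- "ATG"
    if (gt && !atg) codons[1] <- sample(c("GTA", "GTC", "GTG", "GTT"), 1L)
    if (cag) codons[length(codons)] <- "CAG"
    paste(codons, collapse = "")
  } else {
    seq <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                 collapse = "")
    if (atg) substr(seq, 1, 3) <- "ATG"
    if (gt && !atg) substr(seq, 1, 2) <- "GT"
    if (cag) substr(seq, len - 2L, len) <- "CAG"
    seq
  }
}

## Positions (1-based, within block) that must not be mutated.
.frozen_positions <- function(len, cons) {
  fr <- integer()
  if (isTRUE(cons$atg)) fr <- c(fr, 1:3)
  if (isTRUE(cons$gt)) fr <- c(fr, 1:2)
  if (isTRUE(cons$cag)) fr <- c(fr, (len - 2L):len)
  unique(fr)
}

## Mutate a coding block to the requested identity without creating an
## in-frame stop codon (frame 0) or touching frozen positions.
.mutate_block <- function(seq, identity, frozen) {
  len <- nchar(seq)
  n_mut <- round((1 - identity) * len)
  if (n_mut == 0L) return(seq)
  cand <- setdiff(seq_len(len), frozen)
  n_mut <- min(n_mut, length(cand))
  pos <- sort(sample(cand, n_mut))
  chars <- strsplit(seq, "")[[1]]
  for (p in pos) {
    alt <- sample(setdiff(c("A", "C", "G", "T"), chars[p]))
    for (b in alt) {
      old <- chars[p]
      chars[p] <- b
      cd0 <- ((p - 1L) %/% 3L) * 3L + 1L
      codon <- paste(chars[cd0:min(cd0 + 2L, len)], collapse = "")
      if (!(codon %in% c("TAG", "TGA", "TAA"))) break
      chars[p] <- old
    }
  }
  paste(chars, collapse = "")
}

.mutate_plain <- function(seq, identity) {
  len <- nchar(seq)
  n_mut <- round((1 - identity) * len)
  if (n_mut == 0L || len == 0L) return(seq)
  pos <- sort(sample(seq_len(len), min(n_mut, len)))
  chars <- strsplit(seq, "")[[1]]
  for (p in pos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
  }
  paste(chars, collapse = "")
}

.random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

## ---- realization --------------------------------------------------------

#' Realize a fixture: FASTA, GTF, junctions, ortholog map
#'
#' Deterministically generates per-species locus sequences and annotation
#' files for a [fixture_spec()]. Splice motifs (GT/AG), start (ATG) and stop
#' codons are exact at every declared site; homologous blocks are mutated
#' copies of one ancestral sequence; introns diverge at `intron_identity`.
#' Equal seeds give byte-identical files.
#'
#' @param spec a [fixture_spec()].
#' @param dir output directory (created if needed).
#' @param seed overrides `spec$seed` when given.
#' @return (invisibly) a list with per-species file paths (`fasta`, `gtf`,
#'   `junctions`), the ortholog `map` path, and `truth`: per-species token
#'   tables with ancestral labels and internal coordinates, for
#'   planted-orthology evaluation.
#' @export
realize_fixture <- function(spec, dir, seed = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  .validate_fixture_spec(spec)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  seed <- if (is.null(seed)) spec$seed else as.integer(seed)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  cons <- .block_constraints(spec)
  labels <- names(spec$block_lengths)
  ancestral <- setNames(vapply(labels, function(lab) {
    cc <- if (is.null(cons[[lab]])) list() else cons[[lab]]
    .random_block(spec$block_lengths[[lab]],
                  atg = isTRUE(cc$atg), cag = isTRUE(cc$cag),
                  gt = isTRUE(cc$gt))
  }, character(1)), labels)

  ## ancestral introns/flanks keyed by the next block label (or flank5/3)
  max_gap <- spec$intron_length
  anc_intron <- list(flank5 = .random_dna(spec$flank),
                     flank3 = .random_dna(spec$flank))
  for (lab in labels) anc_intron[[lab]] <- .random_dna(max_gap)

  out <- list(species = list(), truth = list())
  map_row <- list()
  for (sp in spec$species) {
    tk <- parse_model_string(spec$grammars[[sp]])
    tk <- .layout_grammar(tk, spec$block_lengths, spec$intron_length,
                          spec$flank)
    L <- attr(tk, "locus_length")
    seq_chars <- strsplit(.random_dna(L), "")[[1]]
    ## flanks
    f5 <- .mutate_plain(anc_intron$flank5, spec$intron_identity)
    seq_chars[1:spec$flank] <- strsplit(f5, "")[[1]]
    f3 <- .mutate_plain(anc_intron$flank3, spec$intron_identity)
    seq_chars[(L - spec$flank + 1L):L] <- strsplit(f3, "")[[1]]
    ## introns (gaps before acceptors)
    for (i in which(tk$gap_before)) {
      nxt_blk <- which(tk$kind == "block" & seq_len(nrow(tk)) > i)
      key <- if (length(nxt_blk)) tk$label[nxt_blk[1]] else "flank3"
      gseq <- .mutate_plain(anc_intron[[key]], spec$intron_identity)
      g0 <- tk$start[i] - spec$intron_length
      seq_chars[(g0 + 1L):tk$start[i]] <- strsplit(gseq, "")[[1]]
    }
    ## blocks
    for (i in which(tk$kind == "block")) {
      lab <- tk$label[i]
      cc <- if (is.null(cons[[lab]])) list() else cons[[lab]]
      bs <- .mutate_block(ancestral[[lab]], spec$block_identity,
                          .frozen_positions(spec$block_lengths[[lab]], cc))
      seq_chars[(tk$start[i] + 1L):tk$end[i]] <- strsplit(bs, "")[[1]]
    }
    ## stamp site motifs
    for (i in seq_len(nrow(tk))) {
      p <- tk$start[i]
      switch(tk$kind[i],
             start = { seq_chars[(p + 1L):(p + 3L)] <- c("A", "T", "G") },
             stop = { seq_chars[(p + 1L):(p + 3L)] <- c("T", "A", "A") },
             donor = { seq_chars[(p + 1L):(p + 2L)] <- c("G", "T") },
             acceptor = { seq_chars[(p - 1L):p] <- c("A", "G") },
             NULL)
    }
    locus <- paste(seq_chars, collapse = "")

    gene_id <- spec$gene_ids[[sp]]
    strand <- spec$strands[[sp]]
    files <- .write_species_files(spec, sp, gene_id, strand, locus, tk, dir)
    out$species[[sp]] <- files
    tk$species <- sp
    out$truth[[sp]] <- tk
    map_row[[sp]] <- gene_id
  }
  map_path <- file.path(dir, paste0(spec$name, "_orthologs.tsv"))
  map_df <- as.data.frame(map_row, stringsAsFactors = FALSE)
  write.table(map_df, map_path, sep = "\t", quote = FALSE, row.names = FALSE)
  out$map <- map_path
  out$name <- spec$name
  invisible(out)
}

## exon chain (internal coords) of a transcript model string laid out on tk
.exons_of_model <- function(model, tk) {
  tt <- parse_model_string(model)
  stopifnot(.is_token_subsequence(tt, tk))
  blocks <- tt[tt$kind == "block", , drop = FALSE]
  coords <- tk[match(blocks$label, tk$label), , drop = FALSE]
  ## split into exons at donor/acceptor pairs of the transcript
  exon_id <- cumsum(c(1L, vapply(seq_len(nrow(blocks))[-1], function(j) {
    bi <- which(tt$label == blocks$label[j])
    prev <- which(tt$label == blocks$label[j - 1L])
    between <- tt$kind[seq(prev + 1L, length.out = bi - prev - 1L)]
    as.integer("donor" %in% between)
  }, integer(1))))
  ex <- do.call(rbind, lapply(split(seq_len(nrow(coords)), exon_id),
                              function(ii) {
    data.frame(start = min(coords$start[ii]), end = max(coords$end[ii]))
  }))
  rownames(ex) <- NULL
  ex
}

.internal_to_genomic <- function(start, end, L, strand) {
  if (strand == "+") {
    data.frame(start = start + 1L, end = end)
  } else {
    data.frame(start = L - end + 1L, end = L - start)
  }
}

.write_species_files <- function(spec, sp, gene_id, strand, locus, tk, dir) {
  L <- nchar(locus)
  out_seq <- if (strand == "+") locus else {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(locus)))
  }
  fasta <- file.path(dir, sprintf("%s_%s.fa", spec$name, sp))
  Biostrings::writeXStringSet(
    setNames(Biostrings::DNAStringSet(out_seq), gene_id), fasta)

  rows <- list()
  for (tr in spec$transcripts[[sp]]) {
    ex <- .exons_of_model(tr$model, tk)
    cds_start <- min(ex$start)
    cds_end <- max(ex$end)
    cum <- cumsum(c(0L, ex$end - ex$start))
    for (i in seq_len(nrow(ex))) {
      g <- .internal_to_genomic(ex$start[i], ex$end[i], L, strand)
      rows[[length(rows) + 1L]] <- data.frame(
        type = "CDS", start = g$start, end = g$end,
        phase = (3L - cum[i] %% 3L) %% 3L,
        transcript_id = tr$id, stringsAsFactors = FALSE)
    }
    if (!is.null(tr$utr5) && tr$utr5 > 0L) {
      g <- .internal_to_genomic(cds_start - tr$utr5, cds_start, L, strand)
      rows[[length(rows) + 1L]] <- data.frame(
        type = "five_prime_utr", start = g$start, end = g$end,
        phase = NA_integer_, transcript_id = tr$id, stringsAsFactors = FALSE)
    }
    if (!is.null(tr$utr3) && tr$utr3 > 0L) {
      g <- .internal_to_genomic(cds_end + 3L, cds_end + 3L + tr$utr3, L,
                                strand)
      rows[[length(rows) + 1L]] <- data.frame(
        type = "three_prime_utr", start = g$start, end = g$end,
        phase = NA_integer_, transcript_id = tr$id, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = gene_id,
    ranges = IRanges::IRanges(tab$start, tab$end),
    strand = strand)
  S4Vectors::mcols(gr)$type <- tab$type
  S4Vectors::mcols(gr)$source <- "spliceortho_fixture"
  S4Vectors::mcols(gr)$phase <- tab$phase
  S4Vectors::mcols(gr)$gene_id <- gene_id
  S4Vectors::mcols(gr)$transcript_id <- tab$transcript_id
  gtf <- file.path(dir, sprintf("%s_%s.gtf", spec$name, sp))
  rtracklayer::export(gr, gtf, format = "gtf")

  ## junction support: every intron of every structure realizable on this
  ## locus (union of all species' declared structures), with read counts
  jx <- list()
  models <- unique(unlist(lapply(spec$transcripts, function(x) {
    vapply(x, `[[`, character(1), "model")
  })))
  for (m in models) {
    tt <- parse_model_string(m)
    if (!.is_token_subsequence(tt, tk)) next
    ex <- .exons_of_model(m, tk)
    if (nrow(ex) < 2L) next
    for (i in seq_len(nrow(ex) - 1L)) {
      g <- .internal_to_genomic(ex$end[i], ex$start[i + 1L], L, strand)
      jx[[length(jx) + 1L]] <- data.frame(
        seqname = gene_id, start = g$start, end = g$end, strand = strand,
        reads = spec$junction_reads)
    }
  }
  jpath <- file.path(dir, sprintf("%s_%s_junctions.tab", spec$name, sp))
  jdf <- unique(do.call(rbind, jx))
  if (is.null(jdf) || spec$junction_reads <= 0L) {
    jdf <- data.frame(seqname = character(), start = integer(),
                      end = integer(), strand = character(),
                      reads = integer())
  }
  jdf <- jdf[order(jdf$start, jdf$end), , drop = FALSE]
  write.table(jdf, jpath, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  list(fasta = fasta, gtf = gtf, junctions = jpath, gene_id = gene_id,
       strand = strand)
}

#' Worked-example fixtures
#'
#' Named [fixture_spec()]s reproducing the package's three reference
#' scenarios:
#' \describe{
#'   \item{fig1}{One gene with alternative exon variants C/BC and G/GH-H and
#'     four CDS structures; mouse knows all four, human the two BC-containing
#'     forms, dog one. The pipeline predicts the five missing CDSs and the
#'     triplet is structurally orthologous with four CDS orthology groups.}
#'   \item{fig4}{Two CDS structures; one is encoded redundantly (two human
#'     and two mouse known transcripts with distinct UTRs plus one dog
#'     transcript), the other once per species.}
#'   \item{fig5}{Two alternative terminal exons C and D; the dog locus has
#'     block C genuinely deleted, so the C-containing structure cannot be
#'     predicted there.}
#' }
#'
#' @return A named list of `"fixture_spec"` objects.
#' @export
figure_fixtures <- function() {
  tr <- function(id, model, utr5 = 40L, utr3 = 30L) {
    list(id = id, model = model, utr5 = utr5, utr3 = utr3)
  }
  fig1 <- fixture_spec(
    name = "fig1",
    grammars = c(human = "[A<>B>C<>G>H<>Z]",
                 mouse = "[A<>B>C<>G>H<>Z]",
                 dog = "[A<>B>C<>G>H<>Z]"),
    transcripts = list(
      mouse = list(tr("MUST001", "[A<>BC<>GH<>Z]"),
                   tr("MUST002", "[A<>C<>GH<>Z]", utr5 = 48L),
                   tr("MUST003", "[A<>BC<>H<>Z]", utr3 = 36L),
                   tr("MUST004", "[A<>C<>H<>Z]")),
      human = list(tr("HST001", "[A<>BC<>GH<>Z]"),
                   tr("HST002", "[A<>BC<>H<>Z]", utr5 = 52L)),
      dog = list(tr("CFT001", "[A<>C<>GH<>Z]"))),
    block_lengths = c(A = 30L, B = 24L, C = 36L, G = 24L, H = 30L, Z = 36L),
    seed = 101L)
  fig4 <- fixture_spec(
    name = "fig4",
    grammars = c(human = "[A<>B<>C]", mouse = "[A<>B<>C]", dog = "[A<>B<>C]"),
    transcripts = list(
      human = list(tr("HST101", "[A<>B<>C]", utr5 = 40L, utr3 = 30L),
                   tr("HST102", "[A<>B<>C]", utr5 = 55L, utr3 = 45L),
                   tr("HST103", "[A<>C]")),
      mouse = list(tr("MUST101", "[A<>B<>C]", utr5 = 40L, utr3 = 30L),
                   tr("MUST102", "[A<>B<>C]", utr5 = 55L, utr3 = 45L),
                   tr("MUST103", "[A<>C]")),
      dog = list(tr("CFT101", "[A<>B<>C]"),
                 tr("CFT102", "[A<>C]"))),
    block_lengths = c(A = 30L, B = 24L, C = 36L),
    seed = 104L)
  fig5 <- fixture_spec(
    name = "fig5",
    grammars = c(human = "[A<>B<>C]>D]", mouse = "[A<>B<>C]>D]",
                 dog = "[A<>B<>D]"),
    transcripts = list(
      human = list(tr("HST201", "[A<>B<>C]", utr5 = 0L, utr3 = 0L),
                   tr("HST202", "[A<>B<>D]", utr3 = 36L)),
      mouse = list(tr("MUST201", "[A<>B<>D]")),
      dog = list(tr("CFT201", "[A<>B<>D]"))),
    block_lengths = c(A = 30L, B = 24L, C = 36L, D = 30L),
    seed = 105L)
  list(fig1 = fig1, fig4 = fig4, fig5 = fig5)
}

#' Random single-gene tri-species fixture
#'
#' Draws a random gene grammar (shared by the three species) and declares a
#' random subset of its grammar-valid CDS structures as known in every
#' species. Used for self-comparison and planted-orthology property checks.
#'
#' @param seed RNG seed (also the fixture seed).
#' @param block_identity,intron_identity passed to [fixture_spec()].
#' @return A `"fixture_spec"`.
#' @export
random_fixture <- function(seed, block_identity = 1.0,
                           intron_identity = 0.25) {
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  grammar <- random_model_string(1L, max_exons = 4L)
  gtok <- parse_model_string(grammar)
  labels <- gtok$label[gtok$kind == "block"]
  lens <- setNames(3L * sample(8:14, length(labels), replace = TRUE), labels)
  models <- .enumerate_grammar_models(gtok)
  keep <- sort(unique(c(1L, sample(seq_along(models),
                                   min(length(models),
                                       sample(1:3, 1L))))))
  trs <- lapply(seq_along(keep), function(i) {
    list(id = sprintf("T%03d", i), model = models[keep[i]],
         utr5 = 30L, utr3 = 30L)
  })
  fixture_spec(
    name = sprintf("rand%d", seed),
    grammars = c(human = grammar, mouse = grammar, dog = grammar),
    transcripts = list(human = trs, mouse = trs, dog = trs),
    block_lengths = lens,
    block_identity = block_identity, intron_identity = intron_identity,
    seed = seed)
}

## All grammar-valid transcript token subsequences of a gene grammar
## (structure level, no sequence test). Transition rules encode the token
## positions: a donor/stop attaches at the end of the directly preceding
## block; an acceptor not directly preceded by a block implies an intron
## gap, so blocks straddling it are not adjacent; a donor may splice to any
## later acceptor (exon skipping).
.enumerate_grammar_models <- function(gtok) {
  n <- nrow(gtok)
  kinds <- gtok$kind
  results <- character()
  between_kinds <- function(a, b) {
    if (b <= a + 1L) character(0) else kinds[(a + 1L):(b - 1L)]
  }
  ok_step <- function(last, nxt) {
    lk <- kinds[last]
    nk <- kinds[nxt]
    btw <- between_kinds(last, nxt)
    switch(lk,
      start = nk == "block" && nxt == last + 1L,
      block = switch(nk,
        donor = nxt == last + 1L,
        stop = !any(btw %in% c("block", "acceptor")),
        block = {
          accs <- which(btw == "acceptor")
          !any(btw == "block") && all(accs + last == last + 1L)
        },
        FALSE),
      donor = nk == "acceptor",
      acceptor = nk == "block" && !any(btw %in% c("block", "acceptor")),
      FALSE)
  }
  recurse <- function(chain) {
    last <- chain[length(chain)]
    if (kinds[last] == "stop") {
      results[[length(results) + 1L]] <<-
        paste(.symbol_of_token(gtok$kind[chain], gtok$label[chain]),
              collapse = "")
      return(invisible(NULL))
    }
    if (last < n) {
      for (nxt in (last + 1L):n) {
        if (ok_step(last, nxt)) recurse(c(chain, nxt))
      }
    }
    invisible(NULL)
  }
  for (st in which(kinds == "start")) recurse(st)
  unique(results)
}
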