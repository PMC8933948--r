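## Readers/writers: GTF + FASTA species loading, ortholog maps, junction
## support files, result tables.
##
## Internal coordinates are 0-based half-open in transcription orientation;
## GTF I/O converts from/to 1-based inclusive genomic coordinates.
## Minus-strand genes are normalized at load: the locus is stored
## reverse-complemented so every model reads 5'->3'.

.genomic_to_internal <- function(start, end, L, strand) {
  if (strand == "+") {
    data.frame(start = start - 1L, end = end)
  } else {
    data.frame(start = L - end, end = L - start + 1L)
  }
}

#' Load one species' gene set from GTF + FASTA
#'
#' Reads gene-locus sequences (one FASTA record per locus) and a GTF with
#' `CDS` and UTR features carrying `gene_id`/`transcript_id` attributes, and
#' builds a [build_gene_model()] per gene. Coordinates are converted to the
#' internal convention and minus-strand loci are reverse-complemented, so
#' downstream code never sees strand.
#'
#' @param gtf,fasta file paths.
#' @param species species name attached to every gene.
#' @param config an [orthology_config()]; `stop_in_cds` controls whether the
#'   final 3 nt of each CDS feature chain are trimmed as the stop codon.
#' @return A named list of `"gene_model"` objects, with a `validity`
#'   attribute (per-transcript CDS validity report across genes).
#' @export
load_species <- function(gtf, fasta, species,
                         config = orthology_config()) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  gr <- rtracklayer::import(gtf, format = "gtf")
  df <- as.data.frame(gr)
  if (is.null(df$transcript_id)) {
    stop("input error: GTF features lack transcript_id attributes")
  }
  df <- df[df$type %in% c("CDS", "five_prime_utr", "three_prime_utr",
                          "UTR"), , drop = FALSE]
  if (is.null(df$gene_id) || any(is.na(df$gene_id[df$type == "CDS"]))) {
    stop("input error: CDS feature without gene_id")
  }
  if (any(is.na(df$transcript_id[df$type == "CDS"]))) {
    stop("input error: CDS feature without transcript_id")
  }
  genes <- list()
  for (gid in unique(df$gene_id)) {
    sub <- df[df$gene_id == gid, , drop = FALSE]
    seqname <- as.character(unique(sub$seqnames))
    if (length(seqname) != 1L) {
      stop(sprintf("input error: gene %s spans several sequences", gid))
    }
    if (!seqname %in% names(seqs)) {
      stop(sprintf("input error: missing sequence for region %s", seqname))
    }
    strand <- as.character(unique(sub$strand))
    if (length(strand) != 1L || !strand %in% c("+", "-")) {
      stop(sprintf("input error: unknown or mixed strand for gene %s", gid))
    }
    locus <- as.character(seqs[[seqname]])
    L <- nchar(locus)
    if (any(sub$end > L) || any(sub$start < 1L)) {
      stop(sprintf("input error: feature outside locus for gene %s", gid))
    }
    if (strand == "-") {
      locus <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(locus)))
    }
    records <- lapply(split(sub, sub$transcript_id), function(tr) {
      conv <- function(rows) {
        if (nrow(rows) == 0L) return(NULL)
        iv <- .genomic_to_internal(rows$start, rows$end, L, strand)
        iv[order(iv$start), , drop = FALSE]
      }
      cds <- conv(tr[tr$type == "CDS", , drop = FALSE])
      if (is.null(cds)) return(NULL)
      if (isTRUE(config$stop_in_cds)) {
        cds$end[nrow(cds)] <- cds$end[nrow(cds)] - 3L
        cds <- cds[cds$end > cds$start, , drop = FALSE]
      }
      cds_start <- min(cds$start)
      cds_end <- max(cds$end)
      explicit5 <- conv(tr[tr$type == "five_prime_utr", , drop = FALSE])
      explicit3 <- conv(tr[tr$type == "three_prime_utr", , drop = FALSE])
      plain <- conv(tr[tr$type == "UTR", , drop = FALSE])
      utr5 <- rbind(explicit5,
                    if (!is.null(plain)) plain[plain$end <= cds_start, ])
      utr3 <- rbind(explicit3,
                    if (!is.null(plain)) plain[plain$start >= cds_end, ])
      transcript_record(unique(tr$transcript_id), gid, cds,
                        utr5_exons = utr5, utr3_exons = utr3)
    })
    records <- Filter(Negate(is.null), records)
    genes[[gid]] <- build_gene_model(records, gid, species = species,
                                     locus = locus, seqname = seqname,
                                     genomic_strand = strand,
                                     config = config)
  }
  validity <- do.call(rbind, lapply(genes, function(g) {
    cbind(gene_id = g$gene_id, g$validity)
  }))
  rownames(validity) <- NULL
  attr(genes, "validity") <- validity
  genes
}

#' Read a gene-triplet ortholog map
#'
#' TSV with a header row; each column is a species, each row a tuple of
#' one-to-one orthologous gene IDs. Duplicate IDs across rows are rejected.
#'
#' @param path TSV path.
#' @return Data frame of gene-ID tuples (one row per triplet).
#' @export
read_ortholog_map <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(df) < 2L) stop("input error: ortholog map needs >= 2 columns")
  for (cn in names(df)) {
    if (anyDuplicated(df[[cn]])) {
      stop(sprintf("input error: duplicate gene ID in column %s (one-to-one map)",
                   cn))
    }
  }
  df
}

#' Read a splice-junction support file
#'
#' Accepts the 5-column tab format (seqname, intron start, intron end,
#' strand, read count; 1-based inclusive intron coordinates) or 6-column BED
#' (0-based half-open; `score` holds the read count).
#'
#' @param path file path.
#' @return Data frame with columns `seqname`, `start`, `end`, `strand`,
#'   `reads` (1-based inclusive intron coordinates).
#' @export
read_junctions <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    return(data.frame(seqname = character(), start = integer(),
                      end = integer(), strand = character(),
                      reads = integer()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- unique(lengths(fields))
  if (length(ncols) != 1L || !ncols %in% c(5L, 6L)) {
    bad <- which(lengths(fields) != lengths(fields)[1])[1]
    stop(sprintf("parse error at line %d: expected 5 (tab) or 6 (BED) columns",
                 if (is.na(bad)) 1L else bad))
  }
  parse_int <- function(x, col) {
    v <- suppressWarnings(as.integer(x))
    if (anyNA(v)) {
      stop(sprintf("parse error at line %d: non-integer %s",
                   which(is.na(v))[1], col))
    }
    v
  }
  m <- do.call(rbind, fields)
  if (ncols == 5L) {
    data.frame(seqname = m[, 1], start = parse_int(m[, 2], "intron start"),
               end = parse_int(m[, 3], "intron end"), strand = m[, 4],
               reads = parse_int(m[, 5], "read count"),
               stringsAsFactors = FALSE)
  } else {
    data.frame(seqname = m[, 1],
               start = parse_int(m[, 2], "intron start") + 1L,
               end = parse_int(m[, 3], "intron end"),
               strand = m[, 6],
               reads = parse_int(m[, 5], "read count"),
               stringsAsFactors = FALSE)
  }
}

#' Write predicted transcripts as GTF
#'
#' One transcript per prediction, CDS features only, with attributes
#' `status` (`"predicted"`), `source_species` and optionally the evidence
#' tag. Coordinates are converted back to genomic (the strand the locus was
#' loaded from).
#'
#' @param predictions list of predicted `"transcript_model"`s.
#' @param genes named list of `"gene_model"`s (by gene_id).
#' @param path output GTF path.
#' @param evidence optional data frame with columns `transcript_id`, `tag`.
#' @export
write_predictions_gtf <- function(predictions, genes, path,
                                  evidence = NULL) {
  genes <- setNames(genes, vapply(genes, `[[`, character(1), "gene_id"))
  rows <- list()
  for (pm in predictions) {
    gene <- genes[[pm$gene_id]]
    L <- nchar(gene$locus)
    exons <- .exons_of_tokens(pm$tokens)
    tag <- NA_character_
    if (!is.null(evidence)) {
      hit <- match(pm$transcript_id, evidence$transcript_id)
      if (!is.na(hit)) tag <- evidence$tag[hit]
    }
    cum <- cumsum(c(0L, exons$end - exons$start))
    for (i in seq_len(nrow(exons))) {
      g <- .internal_to_genomic(exons$start[i], exons$end[i], L,
                                gene$genomic_strand)
      rows[[length(rows) + 1L]] <- data.frame(
        seqname = gene$seqname, start = g$start, end = g$end,
        strand = gene$genomic_strand, phase = (3L - cum[i] %% 3L) %% 3L,
        gene_id = pm$gene_id,
        transcript_id = pm$transcript_id, source_species = pm$source,
        evidence = tag, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    writeLines("##gff-version 2", path)
    return(invisible(path))
  }
  tab <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(seqnames = tab$seqname,
                               ranges = IRanges::IRanges(tab$start, tab$end),
                               strand = tab$strand)
  S4Vectors::mcols(gr)$type <- "CDS"
  S4Vectors::mcols(gr)$source <- "spliceortho"
  S4Vectors::mcols(gr)$phase <- tab$phase
  S4Vectors::mcols(gr)$gene_id <- tab$gene_id
  S4Vectors::mcols(gr)$transcript_id <- tab$transcript_id
  S4Vectors::mcols(gr)$status <- "predicted"
  S4Vectors::mcols(gr)$source_species <- tab$source_species
  if (!all(is.na(tab$evidence))) {
    S4Vectors::mcols(gr)$evidence <- tab$evidence
  }
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

## merge a model's adjacent blocks into exon intervals
.exons_of_tokens <- function(tokens) {
  tokens <- .order_tokens(tokens)
  blk <- tokens[tokens$kind == "block", , drop = FALSE]
  if (nrow(blk) == 0L) return(data.frame(start = integer(), end = integer()))
  new_exon <- c(TRUE, blk$start[-1] != blk$end[-nrow(blk)])
  exon_id <- cumsum(new_exon)
  out <- do.call(rbind, lapply(split(seq_len(nrow(blk)), exon_id),
                               function(ii) {
    data.frame(start = blk$start[ii[1]], end = blk$end[ii[length(ii)]])
  }))
  rownames(out) <- NULL
  out
}

#' Write CDS orthology groups to TSV
#'
#' @param groups result of [extract_groups()].
#' @param path output path.
#' @export
write_groups_tsv <- function(groups, path) {
  rows <- do.call(rbind, lapply(groups$groups, function(g) {
    data.frame(group_id = g$group_id, model_string = g$model_string,
               species = g$members$species,
               transcript_id = g$members$transcript_id,
               status = g$members$status,
               redundancy_size = g$members$redundancy_size,
               stringsAsFactors = FALSE)
  }))
  if (is.null(rows)) {
    rows <- data.frame(group_id = character(), model_string = character(),
                       species = character(), transcript_id = character(),
                       status = character(), redundancy_size = integer())
  }
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write per-triplet verdicts to TSV
#'
#' @param reports list of `"triplet_report"`s (or one report).
#' @param path output path.
#' @export
write_verdicts_tsv <- function(reports, path) {
  if (inherits(reports, "triplet_report")) reports <- list(reports)
  rows <- do.call(rbind, lapply(reports, function(r) {
    data.frame(triplet_id = r$triplet_id, retained = r$verdicts$retained,
               structurally_orthologous = r$verdicts$structurally_orthologous,
               all_conserved = r$verdicts$all_conserved,
               single_copy = r$verdicts$single_copy,
               stringsAsFactors = FALSE)
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
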