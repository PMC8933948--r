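## Four-level evidence tagging of predicted transcripts.
##
## confirmed  — the prediction's ordered coding-exon chain occurs verbatim
##              in a supplied annotation collection;
## possible   — no specific exon junction (every junction of the prediction
##              is already used by a known transcript of the input set);
## achievable — all specific junctions are covered by aligned reads
##              (support >= min_reads);
## not_achievable — at least one specific junction lacks read support.

## genomic (1-based inclusive) intron coordinates of a model's junctions
.junctions_of_model <- function(tokens, gene) {
  exons <- .exons_of_tokens(tokens)
  n <- nrow(exons)
  if (n < 2L) {
    return(data.frame(seqname = character(), start = integer(),
                      end = integer(), strand = character()))
  }
  L <- nchar(gene$locus)
  out <- lapply(seq_len(n - 1L), function(i) {
    g <- .internal_to_genomic(exons$end[i], exons$start[i + 1L], L,
                              gene$genomic_strand)
    data.frame(seqname = gene$seqname, start = g$start, end = g$end,
               strand = gene$genomic_strand, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

.junction_keys <- function(df) {
  if (nrow(df) == 0L) return(character())
  paste(df$seqname, df$start, df$end, sep = ":")
}

## all junctions used by known transcripts across a set of genes
.known_junction_keys <- function(genes) {
  keys <- character()
  for (g in genes) {
    for (tm in g$transcripts) {
      if (tm$status != "known") next
      keys <- c(keys, .junction_keys(.junctions_of_model(tm$tokens, g)))
    }
  }
  unique(keys)
}

#' Look for a predicted CDS in external annotation collections
#'
#' A prediction is confirmed iff some annotated transcript's ordered
#' coding-exon chain (genomic CDS intervals on the same sequence and strand)
#' equals the prediction's exactly; UTRs are ignored. Features outside the
#' gene locus indicate a coordinate-system mismatch and raise an error.
#'
#' @param pred a predicted `"transcript_model"`.
#' @param gene the owning `"gene_model"`.
#' @param annotations named list of annotation sets; each element is a GTF
#'   path or a data frame with columns `seqname`, `start`, `end`, `strand`,
#'   `type`, `transcript_id`.
#' @return List with `confirmed` (logical) and `source` (name of the first
#'   matching collection, or `NA`).
#' @export
confirm_in_annotations <- function(pred, gene, annotations) {
  if (length(annotations) == 0L) {
    return(list(confirmed = FALSE, source = NA_character_))
  }
  L <- nchar(gene$locus)
  exons <- .exons_of_tokens(pred$tokens)
  chain <- do.call(rbind, lapply(seq_len(nrow(exons)), function(i) {
    .internal_to_genomic(exons$start[i], exons$end[i], L,
                         gene$genomic_strand)
  }))
  chain <- chain[order(chain$start), , drop = FALSE]
  key <- paste(paste(chain$start, chain$end, sep = "-"), collapse = ",")
  for (nm in names(annotations)) {
    ann <- annotations[[nm]]
    if (is.character(ann)) {
      ann <- as.data.frame(rtracklayer::import(ann, format = "gtf"))
      names(ann)[names(ann) == "seqnames"] <- "seqname"
    }
    ann <- ann[ann$type == "CDS" & ann$seqname == gene$seqname &
                 as.character(ann$strand) == gene$genomic_strand, ,
               drop = FALSE]
    if (nrow(ann) == 0L) next
    if (any(ann$end > L | ann$start < 1L)) {
      stop(sprintf("input error: annotation '%s' has features outside locus %s (coordinate-system mismatch?)",
                   nm, gene$seqname))
    }
    for (tid in unique(ann$transcript_id)) {
      sub <- ann[ann$transcript_id == tid, , drop = FALSE]
      sub <- sub[order(sub$start), , drop = FALSE]
      akey <- paste(paste(sub$start, sub$end, sep = "-"), collapse = ",")
      if (identical(akey, key)) {
        return(list(confirmed = TRUE, source = nm))
      }
    }
  }
  list(confirmed = FALSE, source = NA_character_)
}

#' Exon junctions specific to a prediction
#'
#' The prediction's exon junctions minus every junction occurring in any
#' known transcript of the whole input set. An intron-retention-style
#' prediction (junctions a subset of a known transcript's) has an empty
#' specific set.
#'
#' @param pred a predicted `"transcript_model"`.
#' @param gene the owning `"gene_model"`.
#' @param known_keys precomputed junction keys of the input set's known
#'   transcripts (or a list of `"gene_model"`s to derive them from).
#' @return Data frame of specific junctions (seqname, start, end, strand).
#' @export
specific_junctions <- function(pred, gene, known_keys) {
  if (is.list(known_keys) && !is.data.frame(known_keys) &&
      length(known_keys) && inherits(known_keys[[1]], "gene_model")) {
    known_keys <- .known_junction_keys(known_keys)
  }
  jx <- .junctions_of_model(pred$tokens, gene)
  jx[!(.junction_keys(jx) %in% known_keys), , drop = FALSE]
}

#' Tag a predicted transcript with its evidence level
#'
#' Precedence: annotation confirmation beats everything; otherwise an empty
#' specific-junction set gives `possible`; otherwise `achievable` iff every
#' specific junction has read support of at least `min_reads`, else
#' `not_achievable`.
#'
#' @param pred a predicted `"transcript_model"`.
#' @param confirmed result of [confirm_in_annotations()] (or logical).
#' @param specific data frame from [specific_junctions()].
#' @param support junction support data frame (see [read_junctions()]),
#'   or NULL for no read data.
#' @param min_reads minimum read count for a supported junction.
#' @return One-row data frame: `transcript_id`, `tag`, `detail`.
#' @export
tag_evidence <- function(pred, confirmed, specific, support = NULL,
                         min_reads = 1L) {
  if (is.list(confirmed) && isTRUE(confirmed$confirmed)) {
    return(data.frame(transcript_id = pred$transcript_id, tag = "confirmed",
                      detail = confirmed$source, stringsAsFactors = FALSE))
  }
  if (isTRUE(confirmed) && !is.list(confirmed)) {
    return(data.frame(transcript_id = pred$transcript_id, tag = "confirmed",
                      detail = "annotation", stringsAsFactors = FALSE))
  }
  if (nrow(specific) == 0L) {
    return(data.frame(transcript_id = pred$transcript_id, tag = "possible",
                      detail = "no specific junction",
                      stringsAsFactors = FALSE))
  }
  if (is.null(support)) support <- data.frame(seqname = character(),
                                              start = integer(),
                                              end = integer(),
                                              strand = character(),
                                              reads = integer())
  supported <- vapply(seq_len(nrow(specific)), function(i) {
    hit <- support$seqname == specific$seqname[i] &
      support$start == specific$start[i] & support$end == specific$end[i]
    any(hit & support$reads >= min_reads)
  }, logical(1))
  if (all(supported)) {
    data.frame(transcript_id = pred$transcript_id, tag = "achievable",
               detail = sprintf("%d/%d specific junctions covered",
                                sum(supported), length(supported)),
               stringsAsFactors = FALSE)
  } else {
    data.frame(transcript_id = pred$transcript_id, tag = "not_achievable",
               detail = sprintf("%d/%d specific junctions covered",
                                sum(supported), length(supported)),
               stringsAsFactors = FALSE)
  }
}
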