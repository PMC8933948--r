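#' Analysis configuration
#'
#' Bundles the tunable parameters of the comparison pipeline. Defaults follow
#' the package's reference settings: local alignment with match +2 /
#' mismatch -3 / gap open -5 / gap extend -2, a 0.70 identity threshold for
#' coding-block hits, a 12 nt flanking context on each side of a site motif,
#' canonical GT/AG splice motifs, ATG start codons and the three standard
#' stop codons.
#'
#' @param block_identity minimum fraction of matching positions (relative to
#'   the query block length) for a coding-block alignment hit.
#' @param site_identity minimum identity for a site context alignment used as
#'   fallback evidence when no flanking block anchors the site.
#' @param site_context width (nt) of flanking sequence on each side of a site
#'   motif used for site alignment.
#' @param frame_check require the length offset of a block hit to be 0 mod 3.
#' @param match,mismatch,gap_open,gap_ext local alignment scores (penalties
#'   are given as positive numbers for `gap_open`/`gap_ext`).
#' @param start_codons allowed start codons for predicted CDSs; known
#'   transcripts with other starts are accepted with a warning.
#' @param stop_codons recognized stop codons.
#' @param donor_motifs,acceptor_motifs motifs accepted for predicted splice
#'   sites; non-canonical motifs in known annotations are always accepted.
#' @param min_reads minimum read count for a supported splice junction.
#' @param stop_in_cds whether annotation CDS features include the stop codon.
#' @param strict_frames error (rather than warn) when overlapping transcripts
#'   of one gene imply inconsistent reading frames.
#' @return A list of class `"ortho_config"`.
#' @export
orthology_config <- function(block_identity = 0.70,
                             site_identity = 0.50,
                             site_context = 12L,
                             frame_check = TRUE,
                             match = 2, mismatch = -3,
                             gap_open = 5, gap_ext = 2,
                             start_codons = "ATG",
                             stop_codons = c("TAG", "TGA", "TAA"),
                             donor_motifs = "GT",
                             acceptor_motifs = "AG",
                             min_reads = 1L,
                             stop_in_cds = FALSE,
                             strict_frames = TRUE) {
  structure(list(block_identity = block_identity,
                 site_identity = site_identity,
                 site_context = as.integer(site_context),
                 frame_check = frame_check,
                 match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_ext = gap_ext,
                 start_codons = toupper(start_codons),
                 stop_codons = toupper(stop_codons),
                 donor_motifs = toupper(donor_motifs),
                 acceptor_motifs = toupper(acceptor_motifs),
                 min_reads = as.integer(min_reads),
                 stop_in_cds = stop_in_cds,
                 strict_frames = strict_frames),
            class = "ortho_config")
}

## 0-based half-open substring of a locus character string
.subseq <- function(locus, start, end) {
  if (is.na(start) || is.na(end)) return(NA_character_)
  substr(locus, start + 1L, end)
}

.site_motif <- function(locus, kind, pos) {
  switch(kind,
         start = .subseq(locus, pos, pos + 3L),
         stop = .subseq(locus, pos, pos + 3L),
         donor = .subseq(locus, pos, pos + 2L),
         acceptor = .subseq(locus, pos - 2L, pos),
         NA_character_)
}

.make_token <- function(kind, label, start, end, motif,
                        status = "known", source = "") {
  data.frame(kind = kind, label = label, start = as.integer(start),
             end = as.integer(end), motif = motif, status = status,
             source = source, stringsAsFactors = FALSE)
}

## token identity key (position + kind; blocks also by end)
.token_key <- function(tokens) {
  paste(tokens$kind, tokens$start,
        ifelse(tokens$kind == "block", tokens$end, tokens$start), sep = ":")
}

#' Validate a candidate CDS nucleotide sequence
#'
#' A valid CDS is at least two codons long, has length divisible by three,
#' begins with a configured start codon, ends with a stop codon, and contains
#' no internal in-frame stop codon.
#'
#' @param seq nucleotide string over A/C/G/T.
#' @param start_codons accepted start codons (default ATG).
#' @param stop_codons accepted stop codons.
#' @return A list with elements `valid` (logical) and `reason`
#'   (`NA` when valid; otherwise one of `"length"`, `"frame"`, `"start"`,
#'   `"stop"`, `"internal_stop"`).
#' @examples
#' is_valid_cds("ATGTAA")$valid
#' is_valid_cds("ATGTAATGA")$reason
#' @export
is_valid_cds <- function(seq, start_codons = "ATG",
                         stop_codons = c("TAG", "TGA", "TAA")) {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  if (grepl("[^ACGT]", seq)) {
    stop("alphabet error: CDS sequence contains non-ACGT characters")
  }
  n <- nchar(seq)
  if (n < 6L) return(list(valid = FALSE, reason = "length"))
  if (n %% 3L != 0L) return(list(valid = FALSE, reason = "frame"))
  codons <- substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
  if (!(codons[1] %in% toupper(start_codons))) {
    return(list(valid = FALSE, reason = "start"))
  }
  stops <- toupper(stop_codons)
  if (!(codons[length(codons)] %in% stops)) {
    return(list(valid = FALSE, reason = "stop"))
  }
  if (any(codons[-length(codons)] %in% stops)) {
    return(list(valid = FALSE, reason = "internal_stop"))
  }
  list(valid = TRUE, reason = NA_character_)
}

#' Assemble the CDS sequence encoded by a transcript model
#'
#' Concatenates the coding-block sequences of the model in transcription
#' order and appends the stop-codon trinucleotide carried by (or read at) the
#' stop token. Loci are stored in transcription orientation, so the result is
#' the coding strand 5'->3'; a gene loaded from the genomic minus strand
#' yields the identical string.
#'
#' @param model a transcript model (list with a `tokens` data frame) or a
#'   token data frame.
#' @param locus locus nucleotide string in transcription orientation.
#' @return CDS nucleotide string (stop codon included).
#' @export
assemble_cds_sequence <- function(model, locus) {
  tokens <- if (is.data.frame(model)) model else model$tokens
  if (any(is.na(tokens$start) | is.na(tokens$end))) {
    stop("unresolved-token error: token without coordinates")
  }
  tokens <- .order_tokens(tokens)
  blocks <- tokens[tokens$kind == "block", , drop = FALSE]
  if (nrow(blocks) == 0L) stop("unresolved-token error: model has no blocks")
  body <- paste(mapply(.subseq, blocks$start, blocks$end,
                       MoreArgs = list(locus = locus)), collapse = "")
  stop_row <- tokens[tokens$kind == "stop", , drop = FALSE]
  stop_row <- stop_row[nrow(stop_row), , drop = FALSE]
  stop_motif <- stop_row$motif
  if (is.na(stop_motif) || !nzchar(stop_motif)) {
    stop_motif <- .subseq(locus, stop_row$start, stop_row$start + 3L)
  }
  paste0(body, stop_motif)
}

## ---- transcript records -------------------------------------------------

#' Create a transcript record
#'
#' A transcript record holds the CDS and UTR exon intervals of one annotated
#' transcript in internal coordinates (0-based half-open, transcription
#' orientation).
#'
#' @param transcript_id,gene_id identifiers.
#' @param cds_exons two-column matrix/data.frame of CDS exon intervals.
#' @param utr5_exons,utr3_exons optional UTR exon intervals.
#' @return A list of class `"transcript_record"` with `has_utr5`/`has_utr3`
#'   flags set from the UTR exon lists.
#' @export
transcript_record <- function(transcript_id, gene_id, cds_exons,
                              utr5_exons = NULL, utr3_exons = NULL) {
  cds_exons <- .as_intervals(cds_exons)
  if (nrow(cds_exons) == 0L) stop("input error: transcript has no CDS exons")
  cds_exons <- cds_exons[order(cds_exons$start), , drop = FALSE]
  if (any(cds_exons$end[-nrow(cds_exons)] > cds_exons$start[-1])) {
    stop("input error: overlapping CDS exons in one transcript")
  }
  utr5 <- .as_intervals(utr5_exons)
  utr3 <- .as_intervals(utr3_exons)
  structure(list(transcript_id = transcript_id, gene_id = gene_id,
                 cds_exons = cds_exons, utr5_exons = utr5, utr3_exons = utr3,
                 has_utr5 = nrow(utr5) > 0L, has_utr3 = nrow(utr3) > 0L),
            class = "transcript_record")
}

.as_intervals <- function(x) {
  if (is.null(x)) {
    return(data.frame(start = integer(), end = integer()))
  }
  x <- as.data.frame(x)
  names(x)[1:2] <- c("start", "end")
  data.frame(start = as.integer(x$start), end = as.integer(x$end))
}

## ---- model construction -------------------------------------------------

## Site positions implied by an exon chain.
.sites_of_exons <- function(exons) {
  n <- nrow(exons)
  rbind(
    data.frame(kind = "start", pos = exons$start[1]),
    if (n > 1L) data.frame(kind = "donor", pos = exons$end[-n]),
    if (n > 1L) data.frame(kind = "acceptor", pos = exons$start[-1]),
    data.frame(kind = "stop", pos = exons$end[n])
  )
}

#' Build the structure model of one transcript
#'
#' Derives the token string of a transcript's spliced CDS: one start token at
#' the CDS 5' end, one coding block per exon segment, a donor/acceptor pair
#' per intron, and one stop token. UTR exons contribute no tokens, so
#' transcripts differing only in UTRs have identical models.
#'
#' When a gene model is supplied, blocks follow the gene's segmentation and
#' labels (each exon may span several adjacent blocks); otherwise blocks are
#' labeled A, B, C, ... per exon.
#'
#' @param rec a [transcript_record()].
#' @param gene optional owning gene model (a `"gene_model"`).
#' @param status `"known"` or `"predicted"`.
#' @param source predicting species for predicted transcripts.
#' @return A list of class `"transcript_model"` with fields `transcript_id`,
#'   `gene_id`, `tokens`, `status`, `model_string` (labels valid relative to
#'   the gene model when one is given).
#' @export
build_transcript_model <- function(rec, gene = NULL, status = "known",
                                   source = "") {
  exons <- rec$cds_exons
  if (nrow(exons) == 0L) stop("input error: zero CDS exons")
  if (!is.null(gene)) {
    L <- nchar(gene$locus)
    if (any(exons$start < 0L) || any(exons$end > L)) {
      stop("input error: CDS exon outside gene locus")
    }
    tokens <- .transcript_tokens_from_gene(gene, exons)
  } else {
    sites <- .sites_of_exons(exons)
    blocks <- .make_token("block", LETTERS[seq_len(nrow(exons))],
                          exons$start, exons$end, NA_character_,
                          status, source)
    site_tok <- .make_token(sites$kind, NA_character_, sites$pos, sites$pos,
                            NA_character_, status, source)
    tokens <- .order_tokens(rbind(blocks, site_tok))
  }
  model <- structure(list(transcript_id = rec$transcript_id,
                          gene_id = rec$gene_id,
                          tokens = tokens, status = status, source = source),
                     class = "transcript_model")
  model$model_string <- format_model(tokens)
  model
}

## Select the gene-model tokens realizing an exon chain.
.transcript_tokens_from_gene <- function(gene, exons) {
  gt <- gene$tokens
  sites <- .sites_of_exons(exons)
  picked <- list()
  for (i in seq_len(nrow(sites))) {
    hit <- which(gt$kind == sites$kind[i] & gt$start == sites$pos[i])
    if (length(hit) != 1L) {
      stop(sprintf("structural error: %s site at %d not in gene model of %s",
                   sites$kind[i], sites$pos[i], gene$gene_id))
    }
    picked[[length(picked) + 1L]] <- gt[hit, , drop = FALSE]
  }
  for (i in seq_len(nrow(exons))) {
    blk <- gt[gt$kind == "block" & gt$start >= exons$start[i] &
                gt$end <= exons$end[i], , drop = FALSE]
    blk <- blk[order(blk$start), , drop = FALSE]
    if (nrow(blk) == 0L ||
        blk$start[1] != exons$start[i] || blk$end[nrow(blk)] != exons$end[i] ||
        (nrow(blk) > 1L && any(blk$start[-1] != blk$end[-nrow(blk)]))) {
      stop(sprintf("structural error: exon [%d,%d) not tiled by gene blocks",
                   exons$start[i], exons$end[i]))
    }
    picked[[length(picked) + 1L]] <- blk
  }
  .order_tokens(do.call(rbind, picked))
}

#' Build a gene structure model from its transcripts
#'
#' Merges the CDS structures of a gene's transcripts into one ordered token
#' string: the token union of all transcripts, with coding blocks
#' re-segmented so that every functional-site position of any transcript is a
#' block boundary (an alternative 5'/3' exon extension becomes a separate
#' block directly adjacent to its neighbour). Each input transcript remains
#' expressible as a token subsequence of the result.
#'
#' @param records list of [transcript_record()] (all of one gene).
#' @param gene_id,species,seqname,genomic_strand gene identity. The locus
#'   must already be in transcription orientation (minus-strand genes are
#'   normalized at load time).
#' @param locus locus nucleotide string in transcription orientation.
#' @param config an [orthology_config()].
#' @return A list of class `"gene_model"`: `gene_id`, `species`, `seqname`,
#'   `genomic_strand`, `locus`, `tokens` (ordered data frame), `transcripts`
#'   (list of `"transcript_model"`), `records`, `validity` (per-transcript
#'   CDS validity report).
#' @export
build_gene_model <- function(records, gene_id, species = "", locus,
                             seqname = gene_id, genomic_strand = "+",
                             config = orthology_config()) {
  if (inherits(records, "transcript_record")) records <- list(records)
  if (length(records) == 0L) stop("input error: gene has no transcripts")
  L <- nchar(locus)
  for (r in records) {
    if (any(r$cds_exons$start < 0L) || any(r$cds_exons$end > L)) {
      stop(sprintf("input error: CDS exon of %s outside locus",
                   r$transcript_id))
    }
  }
  exon_list <- lapply(records, `[[`, "cds_exons")
  all_bounds <- sort(unique(unlist(lapply(exon_list,
                                          function(e) c(e$start, e$end)))))
  ## union of covered regions
  cov <- .merge_intervals(do.call(rbind, exon_list))
  blocks <- .cut_regions(cov, all_bounds)
  ## unique functional sites
  site_list <- unique(do.call(rbind, lapply(exon_list, .sites_of_exons)))
  site_tok <- .make_token(site_list$kind, NA_character_,
                          site_list$pos, site_list$pos,
                          vapply(seq_len(nrow(site_list)), function(i) {
                            .site_motif(locus, site_list$kind[i],
                                        site_list$pos[i])
                          }, character(1)),
                          "known", "")
  block_tok <- .make_token("block", NA_character_, blocks$start, blocks$end,
                           NA_character_, "known", "")
  tokens <- .order_tokens(rbind(block_tok, site_tok))
  tokens <- .assign_labels(tokens)
  gene <- structure(list(gene_id = gene_id, species = species,
                         seqname = seqname, genomic_strand = genomic_strand,
                         locus = locus, tokens = tokens,
                         transcripts = list(), records = records),
                    class = "gene_model")
  .check_frames(gene, records, config)
  gene$transcripts <- lapply(records, build_transcript_model, gene = gene)
  names(gene$transcripts) <-
    vapply(gene$transcripts, `[[`, character(1), "transcript_id")
  gene$validity <- .validate_transcripts(gene, config)
  gene
}

.merge_intervals <- function(iv) {
  iv <- iv[order(iv$start, iv$end), , drop = FALSE]
  out <- iv[0, ]
  for (i in seq_len(nrow(iv))) {
    if (nrow(out) > 0L && iv$start[i] <= out$end[nrow(out)]) {
      out$end[nrow(out)] <- max(out$end[nrow(out)], iv$end[i])
    } else {
      out <- rbind(out, iv[i, ])
    }
  }
  out
}

.cut_regions <- function(regions, bounds) {
  pieces <- list()
  for (i in seq_len(nrow(regions))) {
    cuts <- sort(unique(c(regions$start[i], regions$end[i],
                          bounds[bounds > regions$start[i] &
                                   bounds < regions$end[i]])))
    pieces[[i]] <- data.frame(start = cuts[-length(cuts)], end = cuts[-1])
  }
  do.call(rbind, pieces)
}

## Per-gene block labels, A..Z in coordinate order.
.assign_labels <- function(tokens) {
  idx <- which(tokens$kind == "block")
  if (length(idx) > 26L) {
    stop("structural error: more than 26 coding blocks in one gene")
  }
  tokens$label[idx] <- LETTERS[seq_along(idx)]
  tokens
}

## Reading-frame consistency across overlapping transcripts: each final
## block must sit at one frame offset in every transcript using it.
.check_frames <- function(gene, records, config) {
  frames <- list()
  offenders <- character()
  for (r in records) {
    tt <- tryCatch(.transcript_tokens_from_gene(gene, r$cds_exons),
                   error = function(e) NULL)
    if (is.null(tt)) next
    blk <- tt[tt$kind == "block", , drop = FALSE]
    cum <- cumsum(c(0L, blk$end - blk$start))
    for (i in seq_len(nrow(blk))) {
      key <- paste(blk$start[i], blk$end[i], sep = ":")
      f <- cum[i] %% 3L
      if (!is.null(frames[[key]]) && frames[[key]] != f) {
        offenders <- c(offenders, r$transcript_id)
      }
      frames[[key]] <- f
    }
  }
  if (length(offenders)) {
    msg <- sprintf("model-conflict error: inconsistent CDS frames (%s)",
                   paste(unique(offenders), collapse = ", "))
    if (isTRUE(config$strict_frames)) stop(msg) else warning(msg)
  }
  invisible(NULL)
}

.validate_transcripts <- function(gene, config) {
  res <- lapply(gene$transcripts, function(tm) {
    seq <- assemble_cds_sequence(tm, gene$locus)
    v <- is_valid_cds(seq, start_codons = config$start_codons,
                      stop_codons = config$stop_codons)
    if (!v$valid && identical(v$reason, "start")) {
      ## known transcripts may use a non-configured start codon
      v2 <- is_valid_cds(seq, start_codons = substr(seq, 1, 3),
                         stop_codons = config$stop_codons)
      if (v2$valid) {
        warning(sprintf("transcript %s of %s uses non-configured start codon %s",
                        tm$transcript_id, gene$gene_id, substr(seq, 1, 3)),
                call. = FALSE)
        v <- list(valid = TRUE, reason = "noncanonical_start")
      }
    }
    data.frame(transcript_id = tm$transcript_id, valid = v$valid,
               reason = if (is.na(v$reason)) "" else v$reason,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(res, list(make.row.names = FALSE)))
}

#' Grammar string of a model
#'
#' @param x a `"gene_model"` or `"transcript_model"`.
#' @return The model's grammar string (see [parse_model_string()]).
#' @export
model_string <- function(x) {
  if (is.data.frame(x)) return(format_model(x))
  format_model(x$tokens)
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s (%s, %s strand genomic)\n  model: %s\n  %d tokens, %d transcripts\n",
              x$gene_id, x$species, x$genomic_strand, model_string(x),
              nrow(x$tokens), length(x$transcripts)))
  invisible(x)
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s (%s, %s): %s\n",
              x$transcript_id, x$gene_id, x$status, x$model_string))
  invisible(x)
}

#' Serialize a gene model's tokens to TSV
#'
#' Writes one row per token: gene_id, token_index, kind, label, start, end,
#' motif, status, source_species.
#'
#' @param gene a `"gene_model"`.
#' @param path output file.
#' @export
write_model_tsv <- function(gene, path) {
  tk <- gene$tokens
  out <- data.frame(gene_id = gene$gene_id,
                    token_index = seq_len(nrow(tk)) - 1L,
                    kind = tk$kind, label = ifelse(is.na(tk$label), "", tk$label),
                    start = tk$start, end = tk$end,
                    motif = ifelse(is.na(tk$motif), "", tk$motif),
                    status = tk$status, source_species = tk$source)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
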