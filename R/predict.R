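## Expressibility / executability tests and predicted-transcript creation.
##
## A transcript model of gene i is expressible in gene j iff every one of
## its tokens has an orthologous token (known or predicted) in j; it is
## executable iff, additionally, the concatenation of the orthologous block
## sequences of j forms a valid CDS. An executable model with no equal known
## transcript in j becomes a predicted transcript.

## Map a transcript's tokens through pair orthology edges into the target
## gene; NULL when some token has no ortholog.
.map_transcript_tokens <- function(model, target, edges) {
  tokens <- model$tokens
  out <- list()
  for (i in seq_len(nrow(tokens))) {
    tk <- tokens[i, ]
    if (tk$kind == "block") {
      j <- which(edges$blocks$start_a == tk$start &
                   edges$blocks$end_a == tk$end)
      if (length(j) != 1L) return(NULL)
      ti <- which(target$tokens$kind == "block" &
                    target$tokens$start == edges$blocks$start_b[j] &
                    target$tokens$end == edges$blocks$end_b[j])
    } else {
      j <- which(edges$sites$kind == tk$kind & edges$sites$pos_a == tk$start)
      if (length(j) != 1L) return(NULL)
      ti <- which(target$tokens$kind == tk$kind &
                    target$tokens$start == edges$sites$pos_b[j])
    }
    if (length(ti) != 1L) return(NULL)
    out[[length(out) + 1L]] <- target$tokens[ti, , drop = FALSE]
  }
  .order_tokens(do.call(rbind, out))
}

#' Is a transcript model expressible in another gene?
#'
#' TRUE iff every token of the model has an orthologous token (known or
#' predicted) in the target gene model, under the pairwise orthologies
#' between the two genes.
#'
#' @param model a `"transcript_model"` of the source gene.
#' @param target the target `"gene_model"`.
#' @param edges pair orthology edges (`$edges` of a
#'   `"pairwise_comparison"`, oriented source -> target).
#' @return Logical.
#' @export
is_expressible <- function(model, target, edges) {
  !is.null(.map_transcript_tokens(model, target, edges))
}

#' Is a transcript model executable in another gene?
#'
#' Expressibility plus the sequence test: the candidate CDS assembled from
#' the target's orthologous blocks (stop codon appended from the stop token)
#' must be a valid CDS — start codon, frame, no internal in-frame stop.
#'
#' @inheritParams is_expressible
#' @param config an [orthology_config()] (predictions require a configured
#'   start codon).
#' @return List with `executable`, `sequence` (candidate CDS or `NA`),
#'   `reason` (failure class) and `tokens` (mapped target tokens or `NULL`).
#' @export
is_executable <- function(model, target, edges,
                          config = orthology_config()) {
  mapped <- .map_transcript_tokens(model, target, edges)
  if (is.null(mapped)) {
    return(list(executable = FALSE, sequence = NA_character_,
                reason = "not_expressible", tokens = NULL))
  }
  seq <- assemble_cds_sequence(mapped, target$locus)
  v <- is_valid_cds(seq, start_codons = config$start_codons,
                    stop_codons = config$stop_codons)
  list(executable = v$valid, sequence = seq, reason = v$reason,
       tokens = mapped)
}

#' Predict spliced CDS orthologs across a gene triplet
#'
#' For every known transcript model of every gene and every other gene of
#' the triplet: if the model is executable there and no known transcript of
#' that gene has an equal model, exactly one predicted transcript is
#' emitted (deduplicated by unified-label model string, so a CDS predictable
#' from several source species appears once, attributed to the full source
#' set with the primary source chosen by species order). Predicted IDs are
#' `<gene_id>.pred<N>` with N in model-string lexicographic order.
#'
#' @param genes named list (species order) of the triplet's final
#'   `"gene_model"`s (labels unified).
#' @param pair_edges named list of orthology edge sets, one per ordered
#'   species pair, names `"i|j"` by index, oriented i -> j (see
#'   [run_triplet()] internals); accepted in either orientation.
#' @param config an [orthology_config()].
#' @return Named list (per species) of lists of predicted
#'   `"transcript_model"`s, each with `source` (comma-joined source species,
#'   primary first) and `cds_sequence` attached.
#' @export
predict_transcripts <- function(genes, pair_edges,
                                config = orthology_config()) {
  species <- names(genes)
  known_strings <- lapply(genes, function(g) {
    vapply(g$transcripts, `[[`, character(1), "model_string")
  })
  cand <- list()  # key: tgt_species | model_string
  for (si in seq_along(species)) {
    for (sj in seq_along(species)) {
      if (si == sj) next
      edges <- .oriented_edges(pair_edges, si, sj)
      if (is.null(edges)) next
      src <- genes[[si]]
      tgt <- genes[[sj]]
      for (tm in src$transcripts) {
        if (tm$status != "known") next
        ex <- is_executable(tm, tgt, edges, config)
        if (!isTRUE(ex$executable)) next
        ms <- format_model(ex$tokens)
        if (ms %in% known_strings[[sj]]) next
        key <- paste(species[sj], ms, sep = "|")
        if (is.null(cand[[key]])) {
          cand[[key]] <- list(species = species[sj], model_string = ms,
                              tokens = ex$tokens, sequence = ex$sequence,
                              sources = character())
        }
        cand[[key]]$sources <- union(cand[[key]]$sources, species[si])
      }
    }
  }
  out <- setNames(vector("list", length(species)), species)
  for (sp in species) {
    mine <- Filter(function(x) x$species == sp, cand)
    if (length(mine) == 0L) {
      out[[sp]] <- list()
      next
    }
    ord <- order(vapply(mine, `[[`, character(1), "model_string"))
    mine <- mine[ord]
    out[[sp]] <- lapply(seq_along(mine), function(i) {
      x <- mine[[i]]
      srcs <- species[sort(match(x$sources, species))]
      m <- structure(list(
        transcript_id = sprintf("%s.pred%d", genes[[sp]]$gene_id, i),
        gene_id = genes[[sp]]$gene_id,
        tokens = x$tokens, status = "predicted",
        source = paste(srcs, collapse = ","),
        model_string = x$model_string,
        cds_sequence = x$sequence), class = "transcript_model")
      m
    })
  }
  out
}

## fetch edges for ordered pair (i, j), flipping a stored (j, i) set
.oriented_edges <- function(pair_edges, i, j) {
  key <- paste(i, j, sep = "|")
  if (!is.null(pair_edges[[key]])) return(pair_edges[[key]])
  rkey <- paste(j, i, sep = "|")
  e <- pair_edges[[rkey]]
  if (is.null(e)) return(NULL)
  blocks <- e$blocks
  names(blocks)[match(c("start_a", "end_a", "start_b", "end_b"),
                      names(blocks))] <-
    c("start_b", "end_b", "start_a", "end_a")
  sites <- e$sites
  names(sites)[match(c("pos_a", "pos_b"), names(sites))] <-
    c("pos_b", "pos_a")
  list(blocks = blocks, sites = sites)
}
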