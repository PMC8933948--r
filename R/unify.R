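## Cross-gene block label unification.
##
## Block orthologies (within pairs) connect blocks across genes; connected
## sets share one letter, assigned by scanning genes in input order and
## blocks in coordinate order. A merge that would put two distinct blocks of
## one gene in one set is a conflict: the offending orthology is dropped and
## reported.

## genes: list of gene_model; edge_sets: list of block-edge data frames
## (start_a/end_a/start_b/end_b) where edge set k relates genes
## pair_index[[k]] = c(i, j) (defaults to c(1, 2) for a single pair).
.unify_block_labels <- function(genes, edge_sets,
                                pair_index = list(c(1L, 2L))) {
  nodes <- list()
  for (gi in seq_along(genes)) {
    blk <- genes[[gi]]$tokens[genes[[gi]]$tokens$kind == "block", ,
                              drop = FALSE]
    blk <- blk[order(blk$start), , drop = FALSE]
    for (i in seq_len(nrow(blk))) {
      nodes[[paste(gi, blk$start[i], blk$end[i], sep = "|")]] <-
        list(gene = gi, start = blk$start[i], end = blk$end[i])
    }
  }
  parent <- setNames(names(nodes), names(nodes))
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  members <- lapply(names(nodes), function(x) x)
  names(members) <- names(nodes)
  conflicts <- list()
  for (k in seq_along(edge_sets)) {
    es <- edge_sets[[k]]
    gi <- pair_index[[k]][1]
    gj <- pair_index[[k]][2]
    for (i in seq_len(nrow(es))) {
      ka <- paste(gi, es$start_a[i], es$end_a[i], sep = "|")
      kb <- paste(gj, es$start_b[i], es$end_b[i], sep = "|")
      if (!ka %in% names(parent) || !kb %in% names(parent)) next
      ra <- find(ka)
      rb <- find(kb)
      if (ra == rb) next
      genes_a <- vapply(members[[ra]], function(x) nodes[[x]]$gene,
                        integer(1))
      genes_b <- vapply(members[[rb]], function(x) nodes[[x]]$gene,
                        integer(1))
      if (length(intersect(genes_a, genes_b))) {
        conflicts[[length(conflicts) + 1L]] <-
          data.frame(gene_a = genes[[gi]]$gene_id, start_a = es$start_a[i],
                     end_a = es$end_a[i], gene_b = genes[[gj]]$gene_id,
                     start_b = es$start_b[i], end_b = es$end_b[i])
        next
      }
      parent[[rb]] <- ra
      members[[ra]] <- c(members[[ra]], members[[rb]])
      members[[rb]] <- NULL
    }
  }
  ## letters by first occurrence, scanning genes in order, blocks by coord
  comp_letter <- list()
  next_letter <- 0L
  for (gi in seq_along(genes)) {
    blk <- genes[[gi]]$tokens[genes[[gi]]$tokens$kind == "block", ,
                              drop = FALSE]
    blk <- blk[order(blk$start), , drop = FALSE]
    for (i in seq_len(nrow(blk))) {
      root <- find(paste(gi, blk$start[i], blk$end[i], sep = "|"))
      if (is.null(comp_letter[[root]])) {
        next_letter <- next_letter + 1L
        if (next_letter > 26L) {
          stop("structural error: label alphabet exhausted (more than 26 orthologous block sets)")
        }
        comp_letter[[root]] <- LETTERS[next_letter]
      }
    }
  }
  for (gi in seq_along(genes)) {
    tk <- genes[[gi]]$tokens
    bi <- which(tk$kind == "block")
    for (i in bi) {
      root <- find(paste(gi, tk$start[i], tk$end[i], sep = "|"))
      tk$label[i] <- comp_letter[[root]]
    }
    genes[[gi]]$tokens <- tk
    genes[[gi]]$transcripts <- lapply(genes[[gi]]$records,
                                      build_transcript_model,
                                      gene = genes[[gi]])
    names(genes[[gi]]$transcripts) <-
      vapply(genes[[gi]]$transcripts, `[[`, character(1), "transcript_id")
  }
  list(genes = genes,
       conflicts = if (length(conflicts)) do.call(rbind, conflicts) else
         NULL)
}

#' Unify block labels across a gene triplet
#'
#' Propagates block orthology through the three pairwise comparisons so that
#' orthologous coding blocks carry one letter in every gene in which they
#' occur (labeling is per connected set of the orthology relation);
#' within-gene coordinate order is preserved. Label merges that would force
#' two distinct blocks of one gene onto one letter are dropped and reported
#' in the `conflicts` element.
#'
#' @param comparisons list of three `"pairwise_comparison"`s over one
#'   triplet, in the order (1,2), (1,3), (2,3).
#' @param genes named list of the three `"gene_model"`s (final segmentation,
#'   predictions merged), in species order.
#' @return List with relabeled `genes` and `conflicts`.
#' @export
unify_labels <- function(comparisons, genes) {
  edge_sets <- lapply(comparisons, function(cmp) cmp$edges$blocks)
  .unify_block_labels(genes, edge_sets,
                      pair_index = list(c(1L, 2L), c(1L, 3L), c(2L, 3L)))
}
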