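## Orchestration of the full triplet analysis.
##
## Per triplet: gene models (from known transcripts) -> three pairwise
## comparisons (only known tokens seed alignments) -> predicted tokens
## merged into final per-gene models with a common re-segmentation ->
## orthology edges recomputed on the final segmentation -> label
## unification -> transcript prediction -> site graph classification ->
## transcript graph, CDS orthology groups, redundancy -> evidence tags.

## Extend a pair's boundary map with segmentation boundaries introduced by
## the third comparison: a boundary x of gene i lying strictly inside a
## block-to-block anchored interval of the map is carried to gene j by
## offset (valid for the substitution-dominated alignments used here).
.extend_map <- function(map, bounds_i, gene_i, gene_j) {
  if (nrow(map) < 2L) return(map)
  blocks_i <- gene_i$tokens[gene_i$tokens$kind == "block", , drop = FALSE]
  blocks_j <- gene_j$tokens[gene_j$tokens$kind == "block", , drop = FALSE]
  inside_block <- function(blocks, lo, hi) {
    any(blocks$start <= lo & blocks$end >= hi)
  }
  add <- list()
  for (x in setdiff(bounds_i, map$pa)) {
    below <- map[map$pa < x, , drop = FALSE]
    above <- map[map$pa > x, , drop = FALSE]
    if (nrow(below) == 0L || nrow(above) == 0L) next
    la <- max(below$pa); lb <- below$pb[which.max(below$pa)]
    ra <- min(above$pa); rb <- above$pb[which.min(above$pa)]
    if ((ra - la) != (rb - lb)) next
    if (!inside_block(blocks_i, la, ra) || !inside_block(blocks_j, lb, rb)) next
    add[[length(add) + 1L]] <- data.frame(pa = x, pb = lb + (x - la),
                                          score = 0)
  }
  if (length(add)) {
    map <- rbind(map, do.call(rbind, add))
    map <- map[order(map$pa), , drop = FALSE]
  }
  map
}

#' Run the full analysis on one gene triplet
#'
#' @param genes named list of three `"gene_model"`s; names are the species
#'   in precedence order (the first species named is the primary prediction
#'   source when several species predict the same CDS).
#' @param config an [orthology_config()].
#' @param junctions optional named list (per species) of junction support
#'   data frames (see [read_junctions()]).
#' @param annotations optional named list (per species) of annotation
#'   collections for confirmation (see [confirm_in_annotations()]).
#' @param known_junction_keys optional precomputed set of known-transcript
#'   junction keys of the whole input set (defaults to this triplet's).
#' @return A list of class `"triplet_report"`: final `genes`, `comparisons`,
#'   `pair_edges`, `predictions`, `site_graph`, `site_classes`,
#'   `transcript_graph`, `groups`, `redundancy`, `evidence`, `verdicts`
#'   (retained / structurally_orthologous / all_conserved / single_copy)
#'   and `counts`.
#' @export
run_triplet <- function(genes, config = orthology_config(),
                        junctions = NULL, annotations = NULL,
                        known_junction_keys = NULL) {
  stopifnot(length(genes) == 3L, !is.null(names(genes)))
  species <- names(genes)
  pairs <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))
  cmp <- lapply(pairs, function(ij) {
    compare_genes(genes[[ij[1]]], genes[[ij[2]]], config)
  })
  names(cmp) <- vapply(pairs, paste, character(1), collapse = "|")

  ## merge predicted tokens (sites and blocks) per gene across its pairs
  pred_sites <- setNames(vector("list", 3L), as.character(1:3))
  pred_blocks <- setNames(vector("list", 3L), as.character(1:3))
  for (k in seq_along(pairs)) {
    ij <- pairs[[k]]
    pred_sites[[ij[1]]] <- rbind(pred_sites[[ij[1]]], cmp[[k]]$predicted_a)
    pred_sites[[ij[2]]] <- rbind(pred_sites[[ij[2]]], cmp[[k]]$predicted_b)
    pred_blocks[[ij[1]]] <- rbind(pred_blocks[[ij[1]]],
                                  cmp[[k]]$predicted_blocks_a)
    pred_blocks[[ij[2]]] <- rbind(pred_blocks[[ij[2]]],
                                  cmp[[k]]$predicted_blocks_b)
  }
  final <- lapply(1:3, function(i) {
    ps <- pred_sites[[i]]
    pb <- pred_blocks[[i]]
    if (is.null(ps)) ps <- data.frame(kind = character(), pos = integer(),
                                      motif = character(),
                                      source = character())
    if (is.null(pb)) pb <- data.frame(start = integer(), end = integer(),
                                      source = character())
    ## merge duplicated predictions from different pairs (sources joined)
    if (nrow(ps)) {
      ps <- do.call(rbind, lapply(split(ps, paste(ps$kind, ps$pos)),
                                  function(g) {
        g$source[1] <- paste(unique(unlist(strsplit(g$source, ","))),
                             collapse = ",")
        g[1, , drop = FALSE]
      }))
    }
    if (nrow(pb)) {
      pb <- do.call(rbind, lapply(split(pb, paste(pb$start, pb$end)),
                                  function(g) {
        g$source[1] <- paste(unique(unlist(strsplit(g$source, ","))),
                             collapse = ",")
        g[1, , drop = FALSE]
      }))
    }
    g <- genes[[i]]
    attr(g, "needs_reseg") <- TRUE
    .augment_gene(g, ps, pb, config)
  })
  names(final) <- species

  ## segmentation closure: carry boundaries across pairs so orthologous
  ## regions share one segmentation, then re-segment where needed
  maps <- lapply(cmp, `[[`, "map")
  for (pass in 1:2) {
    changed <- FALSE
    for (k in seq_along(pairs)) {
      ij <- pairs[[k]]
      bi <- sort(unique(c(final[[ij[1]]]$tokens$start,
                          final[[ij[1]]]$tokens$end)))
      bj <- sort(unique(c(final[[ij[2]]]$tokens$start,
                          final[[ij[2]]]$tokens$end)))
      maps[[k]] <- .extend_map(maps[[k]], bi, final[[ij[1]]],
                               final[[ij[2]]])
      maps[[k]] <- .extend_map(.flip_pairs(maps[[k]]), bj, final[[ij[2]]],
                               final[[ij[1]]])
      maps[[k]] <- .flip_pairs(maps[[k]])
      ## boundaries implied on each side that the gene lacks
      for (side in 1:2) {
        gidx <- ij[side]
        m <- if (side == 1L) maps[[k]] else .flip_pairs(maps[[k]])
        other <- ij[c(2L, 1L)][side]
        obounds <- sort(unique(c(final[[other]]$tokens$start,
                                 final[[other]]$tokens$end)))
        need <- m$pa[m$pb %in% obounds]
        tk <- final[[gidx]]$tokens
        blocks <- tk[tk$kind == "block", , drop = FALSE]
        inner <- need[vapply(need, function(x) {
          any(blocks$start < x & blocks$end > x)
        }, logical(1))]
        if (length(inner)) {
          g <- final[[gidx]]
          attr(g, "extra_bounds") <- unique(c(attr(g, "extra_bounds"),
                                              inner))
          attr(g, "needs_reseg") <- TRUE
          final[[gidx]] <- .augment_gene(
            g,
            data.frame(kind = character(), pos = integer(),
                       motif = character(), source = character()),
            data.frame(start = integer(), end = integer(),
                       source = character()),
            config)
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }

  ## orthology edges on the final segmentation
  pair_edges <- list()
  for (k in seq_along(pairs)) {
    ij <- pairs[[k]]
    pair_edges[[paste(ij, collapse = "|")]] <-
      .pair_edges(final[[ij[1]]], final[[ij[2]]], maps[[k]],
                  cmp[[k]]$site_pairs)
  }

  ## unified labels across the triplet
  lab <- .unify_block_labels(final,
                             lapply(pair_edges, `[[`, "blocks"),
                             pair_index = pairs)
  final <- setNames(lab$genes, species)

  predictions <- predict_transcripts(final, pair_edges, config)

  sg <- build_site_graph(final, pair_edges, predictions)
  site_classes <- classify_components(sg)
  tg <- build_transcript_graph(final, predictions)
  groups <- extract_groups(tg)
  redundancy <- lapply(final, find_redundant_sets)

  ## evidence tagging
  if (is.null(known_junction_keys)) {
    known_junction_keys <- .known_junction_keys(final)
  }
  evidence <- list()
  for (sp in species) {
    for (pm in predictions[[sp]]) {
      conf <- confirm_in_annotations(pm, final[[sp]],
                                     if (is.null(annotations)) list()
                                     else annotations[[sp]])
      spec_jx <- specific_junctions(pm, final[[sp]], known_junction_keys)
      supp <- if (is.null(junctions)) NULL else junctions[[sp]]
      evidence[[length(evidence) + 1L]] <-
        cbind(species = sp,
              tag_evidence(pm, conf, spec_jx, supp,
                           min_reads = config$min_reads))
    }
  }
  evidence <- if (length(evidence)) do.call(rbind, evidence) else
    data.frame(species = character(), transcript_id = character(),
               tag = character(), detail = character())

  n_pred <- sum(lengths(predictions))
  verdicts <- list(retained = site_classes$retained,
                   structurally_orthologous =
                     site_classes$structurally_orthologous,
                   all_conserved = groups$all_conserved,
                   single_copy = groups$single_copy)
  counts <- list(
    known = sum(vapply(final, function(g) {
      sum(vapply(g$transcripts, function(t) t$status == "known",
                 logical(1)))
    }, numeric(1))),
    predicted = n_pred,
    groups = length(groups$groups),
    redundant_sets = vapply(redundancy, function(r) length(r$sets),
                            integer(1)))

  structure(list(triplet_id = paste(vapply(final, `[[`, character(1),
                                           "gene_id"), collapse = "~"),
                 species = species, genes = final, comparisons = cmp,
                 pair_edges = pair_edges, predictions = predictions,
                 site_graph = sg, site_classes = site_classes,
                 transcript_graph = tg, groups = groups,
                 redundancy = redundancy, evidence = evidence,
                 verdicts = verdicts, counts = counts,
                 label_conflicts = lab$conflicts),
            class = "triplet_report")
}

#' @export
print.triplet_report <- function(x, ...) {
  cat(sprintf("<triplet_report> %s\n", x$triplet_id))
  cat(sprintf("  known transcripts: %d   predicted CDSs: %d\n",
              x$counts$known, x$counts$predicted))
  cat(sprintf("  retained: %s   structurally orthologous: %s\n",
              x$verdicts$retained, x$verdicts$structurally_orthologous))
  cat(sprintf("  CDS orthology groups: %d   all conserved: %s   single copy: %s\n",
              x$counts$groups, x$verdicts$all_conserved,
              x$verdicts$single_copy))
  cat(sprintf("  redundant-CDS sets: %s\n",
              paste(sprintf("%s=%d", names(x$counts$redundant_sets),
                            x$counts$redundant_sets), collapse = " ")))
  invisible(x)
}

#' Run the pipeline over an ortholog map
#'
#' Loads nothing itself: takes per-species gene sets (from [load_species()])
#' and a triplet map (from [read_ortholog_map()]), runs [run_triplet()] per
#' row, and summarizes. Errors in one triplet are recorded and do not stop
#' the run.
#'
#' @param species_data named list (species order = column order of the map)
#'   of gene sets.
#' @param map data frame of gene-ID tuples.
#' @param ... passed to [run_triplet()].
#' @return A list of class `"ortho_run"`: `reports`, `errors`, `summary`.
#' @export
run_pipeline <- function(species_data, map, ...) {
  species <- names(species_data)
  stopifnot(all(species %in% names(map)))
  reports <- list()
  errors <- list()
  for (r in seq_len(nrow(map))) {
    ids <- as.character(map[r, species])
    key <- paste(ids, collapse = "~")
    res <- tryCatch({
      genes <- setNames(lapply(seq_along(species), function(i) {
        g <- species_data[[i]][[ids[i]]]
        if (is.null(g)) stop(sprintf("input error: unknown gene ID %s",
                                     ids[i]))
        g
      }), species)
      run_triplet(genes, ...)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[key]] <- conditionMessage(res)
    } else {
      reports[[key]] <- res
    }
  }
  summary_df <- data.frame(
    triplets = length(reports) + length(errors),
    analyzed = length(reports),
    retained = sum(vapply(reports, function(x) x$verdicts$retained,
                          logical(1))),
    structurally_orthologous =
      sum(vapply(reports,
                 function(x) x$verdicts$structurally_orthologous,
                 logical(1))),
    all_conserved = sum(vapply(reports,
                               function(x) x$verdicts$all_conserved &
                                 x$verdicts$structurally_orthologous,
                               logical(1))),
    single_copy = sum(vapply(reports,
                             function(x) x$verdicts$single_copy &
                               x$verdicts$structurally_orthologous,
                             logical(1))),
    predicted = sum(vapply(reports, function(x) x$counts$predicted,
                           numeric(1))),
    groups = sum(vapply(reports, function(x) x$counts$groups, numeric(1))))
  structure(list(reports = reports, errors = errors, summary = summary_df),
            class = "ortho_run")
}

#' @export
print.ortho_run <- function(x, ...) {
  cat("<ortho_run>\n")
  print(x$summary, row.names = FALSE)
  if (length(x$errors)) {
    cat(sprintf("  %d triplet(s) failed:\n", length(x$errors)))
    for (nm in names(x$errors)) cat(sprintf("   %s: %s\n", nm,
                                            x$errors[[nm]]))
  }
  invisible(x)
}

#' @exportS3Method summary ortho_run
summary.ortho_run <- function(object, ...) object$summary
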