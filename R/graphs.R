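## Per-triplet functional-site graph and transcript graph; component
## classification; CDS orthology groups; same-CDS redundancy analysis.

## functional-site tokens used by a set of transcript models
.used_sites <- function(transcripts) {
  rows <- lapply(transcripts, function(tm) {
    tk <- tm$tokens
    tk[tk$kind != "block", c("kind", "start", "status"), drop = FALSE]
  })
  out <- unique(do.call(rbind, rows))
  if (is.null(out)) {
    out <- data.frame(kind = character(), start = integer(),
                      status = character())
  }
  out
}

#' Build the functional-site graph of a gene triplet
#'
#' Nodes are the functional sites (start/stop codons, splice donors and
#' acceptors) of the three genes that are involved in known or predicted
#' transcripts; edges are the pairwise site orthologies. Edges never connect
#' two sites of one species.
#'
#' @param genes named list (species order) of the triplet's `"gene_model"`s.
#' @param pair_edges named list of pair orthology edge sets (`"i|j"` keys).
#' @param predictions per-species predicted transcripts
#'   (from [predict_transcripts()]).
#' @return A list of class `"site_graph"`: `graph` (igraph), `nodes`
#'   (data frame with species, kind, pos, status).
#' @export
build_site_graph <- function(genes, pair_edges, predictions = NULL) {
  species <- names(genes)
  nodes <- do.call(rbind, lapply(seq_along(species), function(si) {
    g <- genes[[si]]
    tms <- c(Filter(function(t) t$status == "known", g$transcripts),
             if (!is.null(predictions)) predictions[[species[si]]])
    us <- .used_sites(tms)
    if (nrow(us) == 0L) return(NULL)
    data.frame(species = species[si], kind = us$kind, pos = us$start,
               status = us$status, stringsAsFactors = FALSE)
  }))
  if (is.null(nodes)) {
    nodes <- data.frame(species = character(), kind = character(),
                        pos = integer(), status = character())
  }
  nodes$id <- paste(nodes$species, nodes$kind, nodes$pos, sep = ":")
  edges <- list()
  for (key in names(pair_edges)) {
    ij <- as.integer(strsplit(key, "|", fixed = TRUE)[[1]])
    es <- pair_edges[[key]]$sites
    for (i in seq_len(nrow(es))) {
      ida <- paste(species[ij[1]], es$kind[i], es$pos_a[i], sep = ":")
      idb <- paste(species[ij[2]], es$kind[i], es$pos_b[i], sep = ":")
      if (ida %in% nodes$id && idb %in% nodes$id) {
        edges[[length(edges) + 1L]] <- c(ida, idb)
      }
    }
  }
  gr <- igraph::make_empty_graph(n = 0, directed = FALSE)
  gr <- igraph::add_vertices(gr, nrow(nodes), name = nodes$id,
                             species = nodes$species, kind = nodes$kind,
                             status = nodes$status)
  if (length(edges)) {
    gr <- igraph::add_edges(gr, t(do.call(rbind, edges)))
    gr <- igraph::simplify(gr)
  }
  structure(list(graph = gr, nodes = nodes), class = "site_graph")
}

#' Classify site-graph components and derive the triplet verdict
#'
#' Component classes: `singleton` (one node: a site present in a single
#' species), `couple` (two nodes of two species joined by an edge: a site
#' shared by two species), `triplet` (three nodes of three species joined by
#' all three pairwise edges: a site shared by the whole triplet), and
#' `irregular` (anything else — including a 3-node path missing one edge or
#' two same-species nodes in one component).
#'
#' The gene triplet is `retained` iff no component is irregular, and
#' `structurally_orthologous` iff every component is a triplet.
#'
#' @param sg a `"site_graph"`.
#' @return List with `components` (data frame: component id, size, n_species,
#'   n_edges, class), `retained`, `structurally_orthologous`.
#' @export
classify_components <- function(sg) {
  gr <- sg$graph
  if (igraph::vcount(gr) == 0L) {
    return(list(components = data.frame(component = integer(),
                                        size = integer(),
                                        n_species = integer(),
                                        n_edges = integer(),
                                        class = character()),
                retained = TRUE, structurally_orthologous = TRUE))
  }
  comp <- igraph::components(gr)
  rows <- lapply(seq_len(comp$no), function(ci) {
    vids <- which(comp$membership == ci)
    sub <- igraph::induced_subgraph(gr, vids)
    n <- length(vids)
    nsp <- length(unique(igraph::V(sub)$species))
    ne <- igraph::ecount(sub)
    cls <- if (n == 1L) "singleton"
    else if (n == 2L && nsp == 2L && ne == 1L) "couple"
    else if (n == 3L && nsp == 3L && ne == 3L) "triplet"
    else "irregular"
    data.frame(component = ci, size = n, n_species = nsp, n_edges = ne,
               class = cls, stringsAsFactors = FALSE)
  })
  components <- do.call(rbind, rows)
  list(components = components,
       retained = !any(components$class == "irregular"),
       structurally_orthologous = all(components$class == "triplet"))
}

#' Build the transcript graph of a gene triplet
#'
#' Nodes are the known and predicted transcripts of the three genes; an edge
#' joins two transcripts of different genes iff they are spliced CDS
#' orthologs, i.e. their unified-label model strings are equal. Same-species
#' redundancy shows up through shared neighbours, never as a same-species
#' edge.
#'
#' @inheritParams build_site_graph
#' @return A list of class `"transcript_graph"`: `graph` (igraph), `nodes`
#'   (data frame: species, transcript_id, status, model_string).
#' @export
build_transcript_graph <- function(genes, predictions = NULL) {
  species <- names(genes)
  nodes <- do.call(rbind, lapply(seq_along(species), function(si) {
    g <- genes[[si]]
    tms <- c(Filter(function(t) t$status == "known", g$transcripts),
             if (!is.null(predictions)) predictions[[species[si]]])
    if (length(tms) == 0L) return(NULL)
    data.frame(species = species[si],
               transcript_id = vapply(tms, `[[`, character(1),
                                      "transcript_id"),
               status = vapply(tms, `[[`, character(1), "status"),
               model_string = vapply(tms, `[[`, character(1),
                                     "model_string"),
               stringsAsFactors = FALSE)
  }))
  if (is.null(nodes)) {
    nodes <- data.frame(species = character(), transcript_id = character(),
                        status = character(), model_string = character())
  }
  nodes$id <- paste(nodes$species, nodes$transcript_id, sep = ":")
  gr <- igraph::make_empty_graph(n = 0, directed = FALSE)
  gr <- igraph::add_vertices(gr, nrow(nodes), name = nodes$id,
                             species = nodes$species,
                             status = nodes$status,
                             model_string = nodes$model_string)
  edges <- list()
  for (i in seq_len(nrow(nodes))) {
    for (j in seq_len(nrow(nodes))) {
      if (j <= i) next
      if (nodes$species[i] != nodes$species[j] &&
          nodes$model_string[i] == nodes$model_string[j]) {
        edges[[length(edges) + 1L]] <- c(nodes$id[i], nodes$id[j])
      }
    }
  }
  if (length(edges)) gr <- igraph::add_edges(gr, t(do.call(rbind, edges)))
  structure(list(graph = gr, nodes = nodes), class = "transcript_graph")
}

#' Extract CDS orthology groups and per-gene conservation verdicts
#'
#' A CDS orthology group is a connected component of the transcript graph
#' that spans all three species: a cross-species set of transcripts sharing
#' one CDS splicing structure. Verdicts: `all_conserved` iff every component
#' spans the three species (no species-specific or two-species CDS);
#' `single_copy` iff additionally every species contributes exactly one
#' transcript per component.
#'
#' @param tg a `"transcript_graph"`.
#' @param n_species number of species expected per group.
#' @return List of class `"cds_groups"`: `groups` (list; each with
#'   `group_id`, `model_string`, `members` data frame and per-species
#'   `redundancy`), `components` (summary data frame), `all_conserved`,
#'   `single_copy`.
#' @export
extract_groups <- function(tg, n_species = 3L) {
  nodes <- tg$nodes
  if (nrow(nodes) == 0L) {
    return(structure(list(groups = list(),
                          components = data.frame(),
                          all_conserved = TRUE, single_copy = TRUE),
                     class = "cds_groups"))
  }
  comp <- igraph::components(tg$graph)
  groups <- list()
  comp_rows <- list()
  for (ci in seq_len(comp$no)) {
    vids <- which(comp$membership == ci)
    mem <- nodes[match(igraph::V(tg$graph)$name[vids], nodes$id), ,
                 drop = FALSE]
    spp <- unique(mem$species)
    per_species <- table(mem$species)
    spans <- length(spp) == n_species
    comp_rows[[ci]] <- data.frame(
      component = ci, size = nrow(mem), n_species = length(spp),
      spans_all = spans,
      single_copy = spans && all(per_species == 1L),
      model_string = mem$model_string[1])
    if (spans) {
      gid <- sprintf("G%03d", length(groups) + 1L)
      mem$redundancy_size <- as.integer(per_species[mem$species])
      groups[[length(groups) + 1L]] <- list(
        group_id = gid, model_string = mem$model_string[1],
        members = mem[, c("species", "transcript_id", "status",
                          "model_string", "redundancy_size")],
        redundancy = setNames(as.integer(per_species), names(per_species)))
    }
  }
  components <- do.call(rbind, comp_rows)
  structure(list(groups = groups, components = components,
                 all_conserved = all(components$spans_all),
                 single_copy = all(components$spans_all) &&
                   all(components$single_copy)),
            class = "cds_groups")
}

#' Find same-CDS redundancy sets among one gene's known transcripts
#'
#' Maximal sets (size >= 2) of known transcripts encoding the same CDS
#' (equal model strings). Transcripts whose annotation lacks a 5' or 3' UTR
#' are excluded from the enumeration and reported separately, since missing
#' UTRs make "same CDS, different transcript" undecidable.
#'
#' @param gene a `"gene_model"`.
#' @return List with `sets` (list of character vectors of transcript IDs)
#'   and `excluded` (data frame of transcripts left out, with the missing
#'   UTR side).
#' @export
find_redundant_sets <- function(gene) {
  recs <- gene$records
  has_utr <- vapply(recs, function(r) r$has_utr5 && r$has_utr3, logical(1))
  ids <- vapply(recs, `[[`, character(1), "transcript_id")
  excluded <- data.frame(
    transcript_id = ids[!has_utr],
    missing = vapply(recs[!has_utr], function(r) {
      paste(c(if (!r$has_utr5) "5'UTR", if (!r$has_utr3) "3'UTR"),
            collapse = "+")
    }, character(1)),
    stringsAsFactors = FALSE)
  eligible <- ids[has_utr]
  strings <- vapply(eligible, function(id) {
    gene$transcripts[[id]]$model_string
  }, character(1))
  sets <- split(eligible, strings)
  sets <- unname(Filter(function(s) length(s) >= 2L, sets))
  list(sets = sets, excluded = excluded)
}
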