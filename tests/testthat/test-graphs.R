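test_that("site graphs classify singletons, couples, triplets and irregulars", {
  ## fig1: every functional site shared by all three species
  rep1 <- fig_report("fig1")$report
  cls1 <- rep1$site_classes
  expect_true(all(cls1$components$class == "triplet"))
  expect_true(cls1$retained)
  expect_true(cls1$structurally_orthologous)

  ## fig5: the C-specific acceptor and stop are couples (human + mouse)
  rep5 <- fig_report("fig5")$report
  cls5 <- rep5$site_classes
  expect_setequal(unique(cls5$components$class), c("triplet", "couple"))
  expect_equal(sum(cls5$components$class == "couple"), 2L)
  expect_true(cls5$retained)
  expect_false(cls5$structurally_orthologous)

  ## disconnected structures: all singletons, retained but not structural
  sg0 <- build_site_graph(rep1$genes,
                          pair_edges = list(`1|2` = list(sites = data.frame(
                            kind = character(), pos_a = integer(),
                            pos_b = integer(), identity = numeric()))),
                          predictions = rep1$predictions)
  cls0 <- classify_components(sg0)
  expect_true(all(cls0$components$class == "singleton"))
  expect_true(cls0$retained)
  expect_false(cls0$structurally_orthologous)
})

test_that("a 3-node path missing one edge is irregular and excludes the triplet", {
  nodes <- data.frame(species = c("human", "mouse", "dog"),
                      kind = "donor", pos = c(10L, 10L, 10L),
                      status = "known")
  nodes$id <- paste(nodes$species, nodes$kind, nodes$pos, sep = ":")
  gr <- igraph::make_empty_graph(n = 0, directed = FALSE)
  gr <- igraph::add_vertices(gr, 3, name = nodes$id,
                             species = nodes$species, kind = nodes$kind,
                             status = nodes$status)
  gr <- igraph::add_edges(gr, c(nodes$id[1], nodes$id[2],
                                nodes$id[2], nodes$id[3]))
  cls <- classify_components(structure(list(graph = gr, nodes = nodes),
                                       class = "site_graph"))
  expect_identical(cls$components$class, "irregular")
  expect_false(cls$retained)

  ## two same-species nodes in one component are irregular as well
  nodes2 <- nodes
  nodes2$species[3] <- "human"
  nodes2$pos[3] <- 99L
  nodes2$id <- paste(nodes2$species, nodes2$kind, nodes2$pos, sep = ":")
  gr2 <- igraph::make_empty_graph(n = 0, directed = FALSE)
  gr2 <- igraph::add_vertices(gr2, 3, name = nodes2$id,
                              species = nodes2$species, kind = nodes2$kind,
                              status = nodes2$status)
  gr2 <- igraph::add_edges(gr2, c(nodes2$id[1], nodes2$id[2],
                                  nodes2$id[2], nodes2$id[3],
                                  nodes2$id[1], nodes2$id[3]))
  cls2 <- classify_components(structure(list(graph = gr2, nodes = nodes2),
                                        class = "site_graph"))
  expect_identical(cls2$components$class, "irregular")
})

test_that("transcript graphs connect equal models across genes only", {
  rep1 <- fig_report("fig1")$report
  tg1 <- rep1$transcript_graph
  comp <- igraph::components(tg1$graph)
  expect_equal(comp$no, 4L)
  for (ci in seq_len(comp$no)) {
    vs <- igraph::V(tg1$graph)[comp$membership == ci]
    expect_length(vs, 3L)
    expect_setequal(vs$species, c("human", "mouse", "dog"))
    expect_length(unique(vs$model_string), 1L)
  }
  ## edges never join two transcripts of one species, and components are
  ## dense across genes (every cross-gene pair connected)
  el <- igraph::as_edgelist(tg1$graph)
  sp_of <- setNames(tg1$nodes$species, tg1$nodes$id)
  expect_true(all(sp_of[el[, 1]] != sp_of[el[, 2]]))

  rep4 <- fig_report("fig4")$report
  tg4 <- rep4$transcript_graph
  comp4 <- igraph::components(tg4$graph)
  expect_equal(comp4$no, 2L)
  expect_setequal(comp4$csize, c(5L, 3L))
  big <- which(comp4$membership == which.max(comp4$csize))
  vs <- igraph::V(tg4$graph)[big]
  expect_equal(sum(vs$species == "human"), 2L)
  expect_equal(sum(vs$species == "mouse"), 2L)
  expect_equal(sum(vs$species == "dog"), 1L)
  ## dense across genes: all cross-gene pairs inside the component joined
  sub <- igraph::induced_subgraph(tg4$graph, big)
  expected_edges <- sum(outer(igraph::V(sub)$species,
                              igraph::V(sub)$species, "!=")) / 2
  expect_equal(igraph::ecount(sub), expected_edges)

  ## node count equals known + predicted transcripts
  expect_equal(igraph::vcount(tg1$graph),
               rep1$counts$known + rep1$counts$predicted)
})

test_that("transcript graphs with no shared models are edgeless", {
  g1 <- fig_report("fig1")$report$genes$human
  g4 <- fig_report("fig4")$report$genes$mouse
  g5 <- fig_report("fig5")$report$genes$dog
  tg <- build_transcript_graph(list(human = g1, mouse = g4, dog = g5))
  expect_equal(igraph::ecount(tg$graph), 0L)
})

test_that("CDS orthology groups span three species with correct verdicts", {
  rep1 <- fig_report("fig1")$report
  gr1 <- rep1$groups
  expect_length(gr1$groups, 4L)
  expect_true(gr1$all_conserved)
  expect_true(gr1$single_copy)
  ## each distinct model string maps to at most one group
  ms <- vapply(gr1$groups, `[[`, character(1), "model_string")
  expect_false(any(duplicated(ms)))

  rep4 <- fig_report("fig4")$report
  gr4 <- rep4$groups
  expect_length(gr4$groups, 2L)
  expect_true(gr4$all_conserved)
  expect_false(gr4$single_copy)
  sizes <- vapply(gr4$groups, function(g) nrow(g$members), integer(1))
  expect_setequal(sizes, c(5L, 3L))

  ## fig5: the human/mouse-only C-structure component is not a group
  rep5 <- fig_report("fig5")$report
  expect_length(rep5$groups$groups, 1L)
  expect_false(rep5$groups$all_conserved)
})

test_that("structural orthology implies full CDS conservation (S253 >= S135)", {
  for (nm in c("fig1", "fig4", "fig5")) {
    rep <- fig_report(nm)$report
    if (rep$verdicts$structurally_orthologous) {
      expect_true(rep$verdicts$all_conserved, label = nm)
    }
  }
})

test_that("redundant-CDS sets respect the UTR-completeness rule", {
  rep4 <- fig_report("fig4")$report
  red <- rep4$redundancy
  expect_length(red$human$sets, 1L)
  expect_length(red$human$sets[[1]], 2L)
  expect_length(red$mouse$sets, 1L)
  expect_length(red$dog$sets, 0L)

  ## all models distinct -> no sets
  expect_length(fig_report("fig1")$report$redundancy$mouse$sets, 0L)

  ## a duplicate pair where one member lacks its 3'UTR is not enumerated
  spec <- figure_fixtures()$fig4
  spec$transcripts$human[[2]]$utr3 <- 0L
  d <- file.path(tempdir(), "fig4_noutr")
  r <- realize_fixture(spec, d)
  g <- load_species(r$species$human$gtf, r$species$human$fasta,
                    "human")[[1]]
  red2 <- find_redundant_sets(g)
  expect_length(red2$sets, 0L)
  expect_equal(red2$excluded$transcript_id, "HST102")
  expect_match(red2$excluded$missing, "3'UTR")
})
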