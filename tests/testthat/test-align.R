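test_that("a token aligned against its own gene hits its own position", {
  g <- simple_gene()
  blk <- g$tokens[g$tokens$kind == "block", ][2, ]
  hit <- align_token(blk, g, g)
  expect_true(hit$hit)
  expect_equal(hit$start, blk$start)
  expect_equal(hit$end, blk$end)
  expect_equal(hit$identity, 1.0)

  acc <- g$tokens[g$tokens$kind == "acceptor", ][1, ]
  shit <- align_token(acc, g, g)
  expect_true(shit$hit)
  expect_equal(shit$pos, acc$start)
  expect_true(shit$motif_ok)

  ## empty window is a no-hit, not an error
  nohit <- align_token(blk, g, g, window = c(10L, 12L))
  expect_false(nohit$hit)
  expect_identical(nohit$reason, "empty_window")
})

test_that("self-comparison yields a full token bijection and no predictions", {
  for (seed in c(11L, 12L, 13L)) {
    g <- random_report(seed)$genes$human
    cmp <- compare_genes(g, g)
    expect_equal(nrow(cmp$predicted_a), 0L)
    expect_equal(nrow(cmp$predicted_b), 0L)
    expect_equal(nrow(cmp$predicted_blocks_a), 0L)
    n_blocks <- sum(g$tokens$kind == "block")
    n_sites <- sum(g$tokens$kind != "block")
    expect_equal(nrow(cmp$edges$blocks), n_blocks)
    expect_equal(nrow(cmp$edges$sites), n_sites)
    expect_equal(cmp$edges$blocks$start_a, cmp$edges$blocks$start_b)
    expect_equal(cmp$edges$sites$pos_a, cmp$edges$sites$pos_b)
  }
})

test_that("pairwise comparison predicts hidden sites and blocks (worked example)", {
  fr <- fig_report("fig1")
  ## mouse vs human: human lacks only the acceptor splitting its BC exon
  cmp_mh <- compare_genes(fr$genes$mouse, fr$genes$human)
  expect_equal(nrow(cmp_mh$predicted_b), 1L)
  expect_identical(cmp_mh$predicted_b$kind, "acceptor")
  expect_identical(cmp_mh$predicted_b$motif, "AG")
  expect_identical(cmp_mh$predicted_b$source, "mouse")
  ## the predicted acceptor splits human's BC block into adjacent B and C
  hb <- cmp_mh$gene_b$tokens
  expect_true(any(hb$kind == "acceptor" & hb$status == "predicted"))

  ## mouse vs dog: dog gains block B plus two acceptors
  cmp_md <- compare_genes(fr$genes$mouse, fr$genes$dog)
  expect_equal(nrow(cmp_md$predicted_blocks_b), 1L)
  expect_setequal(cmp_md$predicted_b$kind, "acceptor")
  expect_equal(nrow(cmp_md$predicted_b), 2L)
  expect_equal(nrow(cmp_md$predicted_a), 0L)  # mouse gains nothing
})

test_that("orthologies are symmetric and colinear", {
  for (fr in list(fig_report("fig1"), fig_report("fig5"))) {
    rep <- fr$report
    for (key in names(rep$pair_edges)) {
      e <- rep$pair_edges[[key]]
      ## colinearity: same relative order in both genes
      blocks <- e$blocks[order(e$blocks$start_a), ]
      expect_true(!is.unsorted(blocks$start_b, strictly = TRUE))
      sites <- e$sites[order(e$sites$pos_a, e$sites$kind), ]
      expect_true(!is.unsorted(sites$pos_b))
      ## symmetry: querying the flipped orientation gives the same pairs
      ij <- as.integer(strsplit(key, "|", fixed = TRUE)[[1]])
      flipped <- spliceortho:::.oriented_edges(rep$pair_edges, ij[2], ij[1])
      expect_setequal(paste(flipped$blocks$start_a, flipped$blocks$start_b),
                      paste(e$blocks$start_b, e$blocks$start_a))
      expect_setequal(paste(flipped$sites$pos_a, flipped$sites$pos_b),
                      paste(e$sites$pos_b, e$sites$pos_a))
    }
  }
})

test_that("predicted site motifs match their consensus exactly", {
  for (nm in c("fig1", "fig5")) {
    rep <- fig_report(nm)$report
    for (g in rep$genes) {
      tk <- g$tokens
      pred <- tk[tk$status == "predicted" & tk$kind != "block", ]
      for (i in seq_len(nrow(pred))) {
        expected <- switch(pred$kind[i], donor = "GT", acceptor = "AG",
                           start = "ATG", stop = c("TAA", "TAG", "TGA"))
        expect_true(pred$motif[i] %in% expected)
      }
    }
  }
})

test_that("planted orthologies are recovered exactly at full block identity", {
  for (seed in c(21L, 22L)) {
    rr <- random_report(seed, block_identity = 1.0)
    rep <- rr$report
    ## all species share one grammar, annotation and layout, so the planted
    ## orthology is the identity mapping over every annotated token
    tk <- rep$genes[[1]]$tokens
    planted_sites <- tk[tk$kind != "block", ]
    planted_blocks <- tk[tk$kind == "block", ]
    for (key in names(rep$pair_edges)) {
      e <- rep$pair_edges[[key]]
      ## recall 1.0: every planted token pair recovered ...
      expect_setequal(e$sites$pos_a, planted_sites$start)
      expect_setequal(e$blocks$start_a, planted_blocks$start)
      ## ... and precision 1.0: nothing else, all position-identical
      expect_equal(nrow(e$sites), nrow(planted_sites))
      expect_equal(nrow(e$blocks), nrow(planted_blocks))
      expect_equal(e$sites$pos_a, e$sites$pos_b)
      expect_equal(e$blocks$start_a, e$blocks$start_b)
      expect_equal(e$blocks$end_a, e$blocks$end_b)
    }
    expect_equal(sum(lengths(rep$predictions)), 0L)
    expect_true(rep$verdicts$structurally_orthologous)
  }
})

test_that("orthology recovery degrades monotonically as block identity falls", {
  idents <- c(1.0, 0.9, 0.75, 0.55, 0.4)
  recov <- vapply(idents, function(bi) {
    rr <- random_report(31L, block_identity = bi)
    sum(vapply(rr$report$pair_edges, function(e) nrow(e$blocks),
               integer(1)))
  }, numeric(1))
  expect_true(all(diff(recov) <= 0))
  expect_true(recov[length(recov)] < recov[1])
})

test_that("label unification follows connected sets and reports conflicts", {
  ## chained i<->j, j<->k orthologies without an i<->k edge: one letter
  fr <- fig_report("fig1")
  genes <- fr$report$genes
  e12 <- fr$report$pair_edges[["1|2"]]$blocks
  e23 <- fr$report$pair_edges[["2|3"]]$blocks
  lab <- spliceortho:::.unify_block_labels(
    genes, list(e12, e23), pair_index = list(c(1L, 2L), c(2L, 3L)))
  ## oracle: components of the same relation built with igraph
  nodes <- unlist(lapply(seq_along(genes), function(gi) {
    b <- genes[[gi]]$tokens
    paste(gi, b$start[b$kind == "block"], b$end[b$kind == "block"],
          sep = "|")
  }))
  edges <- rbind(
    cbind(paste(1, e12$start_a, e12$end_a, sep = "|"),
          paste(2, e12$start_b, e12$end_b, sep = "|")),
    cbind(paste(2, e23$start_a, e23$end_a, sep = "|"),
          paste(3, e23$start_b, e23$end_b, sep = "|")))
  gr <- igraph::graph_from_data_frame(as.data.frame(edges),
                                      directed = FALSE,
                                      vertices = nodes)
  comp <- igraph::components(gr)$membership
  letter_of <- function(gi, gene) {
    tk <- gene$tokens
    setNames(tk$label[tk$kind == "block"],
             paste(gi, tk$start[tk$kind == "block"],
                   tk$end[tk$kind == "block"], sep = "|"))
  }
  letters_all <- c(letter_of(1, lab$genes[[1]]), letter_of(2, lab$genes[[2]]),
                   letter_of(3, lab$genes[[3]]))
  for (ci in unique(comp)) {
    members <- names(comp)[comp == ci]
    expect_length(unique(letters_all[members]), 1L)
  }

  ## conflict: an edge forcing two blocks of one gene onto one letter
  g <- genes[[1]]
  blk <- g$tokens[g$tokens$kind == "block", ]
  bad <- data.frame(start_a = blk$start[1:2], end_a = blk$end[1:2],
                    start_b = rep(blk$start[1], 2),
                    end_b = rep(blk$end[1], 2))
  lab2 <- spliceortho:::.unify_block_labels(list(g, g), list(bad))
  expect_false(is.null(lab2$conflicts))
  expect_equal(nrow(lab2$conflicts), 1L)
})
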