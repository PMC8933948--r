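test_that("annotation confirmation requires an exact coding-exon chain", {
  fr <- fig_report("fig1")
  rep <- fr$report
  pred <- rep$predictions$dog[[1]]
  gene <- rep$genes$dog

  ## write the predictions out and use the file as an annotation collection
  ann_path <- file.path(tempdir(), "later_release.gtf")
  write_predictions_gtf(rep$predictions$dog, rep$genes, ann_path)
  conf <- confirm_in_annotations(pred, gene, list(ens96 = ann_path))
  expect_true(conf$confirmed)
  expect_identical(conf$source, "ens96")

  ## empty annotation set
  expect_false(confirm_in_annotations(pred, gene, list())$confirmed)

  ## same exons with one boundary shifted by 3 nt: no match
  ann <- as.data.frame(rtracklayer::import(ann_path, format = "gtf"))
  names(ann)[names(ann) == "seqnames"] <- "seqname"
  shifted <- ann
  shifted$start[1] <- shifted$start[1] + 3L
  expect_false(confirm_in_annotations(pred, gene,
                                      list(x = shifted))$confirmed)

  ## out-of-locus features flag a coordinate-system mismatch
  bad <- ann
  bad$end[1] <- nchar(gene$locus) + 500L
  expect_error(confirm_in_annotations(pred, gene, list(x = bad)),
               "input error")
})

test_that("specific junctions exclude everything seen in known transcripts", {
  fr <- fig_report("fig1")
  rep <- fr$report
  known_keys <- spliceortho:::.known_junction_keys(rep$genes)

  ## a known transcript re-presented as a prediction has no specific junction
  km <- rep$genes$mouse$transcripts[[1]]
  expect_equal(nrow(specific_junctions(km, rep$genes$mouse, known_keys)),
               0L)

  ## predictions reuse known junctions except their novel intron(s)
  for (sp in c("human", "dog")) {
    for (p in rep$predictions[[sp]]) {
      spec <- specific_junctions(p, rep$genes[[sp]], known_keys)
      expect_true(nrow(spec) >= 1L)
    }
  }

  ## single-exon model: no junctions at all, so none specific
  g <- simple_gene(blens = c(A = 30L, B = 24L, C = 36L))
  tk <- g$tokens
  one_exon <- tk[tk$kind %in% c("start", "stop") |
                   (tk$kind == "block" & tk$start == tk$start[
                     tk$kind == "block"][1]), ][1:3, ]
  fake <- structure(list(transcript_id = "x", gene_id = g$gene_id,
                         tokens = one_exon, status = "predicted",
                         model_string = "[A]"),
                    class = "transcript_model")
  expect_equal(nrow(specific_junctions(fake, g, known_keys)), 0L)
})

test_that("evidence tags follow the confirmed/possible/achievable precedence", {
  fr <- fig_report("fig1")
  rep <- fr$report
  p <- rep$predictions$human[[1]]
  gene <- rep$genes$human
  known_keys <- spliceortho:::.known_junction_keys(rep$genes)
  spec <- specific_junctions(p, gene, known_keys)
  support_all <- read_junctions(fr$files$species$human$junctions)

  ## all specific junctions supported -> achievable
  t1 <- tag_evidence(p, FALSE, spec, support_all)
  expect_identical(t1$tag, "achievable")

  ## one of two junctions supported -> not achievable
  two <- rbind(spec, data.frame(seqname = spec$seqname[1],
                                start = 9999L, end = 10500L,
                                strand = spec$strand[1]))
  t2 <- tag_evidence(p, FALSE, two, support_all)
  expect_identical(t2$tag, "not_achievable")

  ## empty specific set -> possible, regardless of support
  t3 <- tag_evidence(p, FALSE, spec[0, ], NULL)
  expect_identical(t3$tag, "possible")

  ## annotation match takes precedence over unsupported junctions
  t4 <- tag_evidence(p, list(confirmed = TRUE, source = "db"), two, NULL)
  expect_identical(t4$tag, "confirmed")
  expect_identical(t4$detail, "db")

  ## min_reads threshold
  weak <- support_all
  weak$reads <- 0L
  t5 <- tag_evidence(p, FALSE, spec, weak, min_reads = 1L)
  expect_identical(t5$tag, "not_achievable")
})

test_that("tags partition predictions and respond monotonically to support", {
  fr <- fig_report("fig1")
  rep <- fr$report
  ev <- rep$evidence
  expect_equal(nrow(ev), rep$counts$predicted)
  expect_false(any(duplicated(ev$transcript_id)))
  expect_true(all(ev$tag %in% c("confirmed", "possible", "achievable",
                                "not_achievable")))

  ## adding junction support never demotes achievable to not_achievable
  jx_full <- setNames(lapply(c("human", "mouse", "dog"), function(sp) {
    read_junctions(fr$files$species[[sp]]$junctions)
  }), c("human", "mouse", "dog"))
  jx_none <- lapply(jx_full, function(df) df[0, , drop = FALSE])
  rep_none <- run_triplet(fr$genes, junctions = jx_none)
  rep_full <- run_triplet(fr$genes, junctions = jx_full)
  ev0 <- setNames(rep_none$evidence$tag, rep_none$evidence$transcript_id)
  ev1 <- setNames(rep_full$evidence$tag, rep_full$evidence$transcript_id)
  expect_setequal(names(ev0), names(ev1))
  for (id in names(ev0)) {
    if (ev0[[id]] == "achievable") expect_identical(ev1[[id]], "achievable")
    if (ev0[[id]] == "possible") expect_identical(ev1[[id]], "possible")
  }
  ## with no read support, junction-bearing predictions are not achievable
  expect_true(all(ev0 %in% c("possible", "not_achievable")))
  expect_true(all(ev1 %in% c("possible", "achievable")))

  ## adding annotations never removes confirmed
  ann_path <- file.path(tempdir(), "conf_all.gtf")
  write_predictions_gtf(unlist(rep$predictions, recursive = FALSE),
                        rep$genes, ann_path)
  ann <- setNames(rep(list(list(db = ann_path)), 3),
                  c("human", "mouse", "dog"))
  rep_conf <- run_triplet(fr$genes, junctions = jx_none,
                          annotations = ann)
  expect_true(all(rep_conf$evidence$tag == "confirmed"))
})
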