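test_that("transcript models have the expected shape and ignore UTRs", {
  g <- simple_gene()
  tm <- g$transcripts[["t1"]]
  expect_identical(tm$model_string, "[A<>B<>C]")

  ## same CDS exons, different UTRs -> identical models
  rec2 <- transcript_record("t2", "g1", g$records[[1]]$cds_exons,
                            utr5_exons = data.frame(start = 5L, end = 30L))
  tm2 <- build_transcript_model(rec2, g)
  expect_identical(tm2$model_string, tm$model_string)
  expect_equal(`rownames<-`(tm2$tokens, NULL),
               `rownames<-`(tm$tokens, NULL))

  ## single-exon CDS
  rec1 <- transcript_record("t3", "g1",
                            data.frame(start = 30L, end = 60L))
  expect_identical(build_transcript_model(rec1)$model_string, "[A]")

  expect_error(transcript_record("bad", "g1",
                                 data.frame(start = integer(),
                                            end = integer())),
               "input error")
})

test_that("gene models merge transcripts and re-segment alternative extensions", {
  ## alternative terminal exons: {[A<>B<>C], [A<>B<>D]} -> "[A<>B<>C]>D]"
  h <- fig_report("fig5")$genes$human
  expect_identical(model_string(h), "[A<>B<>C]>D]")
  expect_true(all(vapply(h$transcripts, function(t) {
    t$model_string %in% c("[A<>B<>C]", "[A<>B<>D]")
  }, logical(1))))

  ## single transcript: gene model == transcript model
  g <- simple_gene()
  expect_identical(model_string(g), g$transcripts[["t1"]]$model_string)

  ## exon BC vs exon C -> adjacent blocks B, C with two acceptor tokens
  m <- fig_report("fig1")$genes$mouse
  tk <- m$tokens
  blocks <- tk[tk$kind == "block", ]
  b <- blocks[2, ]
  c_ <- blocks[3, ]
  expect_identical(b$end, c_$start)  # B directly adjacent to C
  expect_setequal(tk$start[tk$kind == "acceptor" &
                             tk$start %in% c(b$start, c_$start)],
                  c(b$start, c_$start))
})

test_that("gene model construction is idempotent", {
  for (fr in list(fig_report("fig1"), fig_report("fig5"))) {
    for (g in fr$genes) {
      rebuilt <- build_gene_model(g$records, g$gene_id,
                                  species = g$species, locus = g$locus)
      expect_identical(model_string(rebuilt), model_string(g))
    }
  }
})

test_that("inconsistent reading frames across transcripts are a model conflict", {
  g <- simple_gene()
  ex <- g$records[[1]]$cds_exons
  ex2 <- ex
  ex2$end[1] <- ex2$end[1] + 1L  # 5' exon one base longer: frame shift
  recs <- list(g$records[[1]],
               transcript_record("t_bad", "g1", ex2))
  expect_error(
    suppressWarnings(build_gene_model(recs, "g1", species = "sp",
                                      locus = g$locus)),
    "model-conflict")
})

test_that("CDS assembly concatenates blocks and appends the stop codon", {
  g <- simple_gene(blens = c(A = 3L, B = 3L, C = 3L))
  tm <- g$transcripts[["t1"]]
  seq <- assemble_cds_sequence(tm, g$locus)
  expect_equal(nchar(seq), 12L)  # 3 blocks + stop codon
  expect_identical(substr(seq, 1, 3), "ATG")
  expect_true(substr(seq, 10, 12) %in% c("TAA", "TAG", "TGA"))

  bad <- tm$tokens
  bad$start[2] <- NA_integer_
  expect_error(assemble_cds_sequence(bad, g$locus), "unresolved-token")
})

test_that("models are invariant under genomic-strand representation", {
  fx <- figure_fixtures()$fig1
  fx_plus <- fx
  fx_plus$strands[] <- "+"
  fx_minus <- fx
  fx_minus$strands[] <- "-"
  d1 <- file.path(tempdir(), "strand_plus")
  d2 <- file.path(tempdir(), "strand_minus")
  r1 <- realize_fixture(fx_plus, d1)
  r2 <- realize_fixture(fx_minus, d2)
  g1 <- load_species(r1$species$mouse$gtf, r1$species$mouse$fasta,
                     "mouse")[[1]]
  g2 <- load_species(r2$species$mouse$gtf, r2$species$mouse$fasta,
                     "mouse")[[1]]
  expect_identical(model_string(g1), model_string(g2))
  expect_equal(`rownames<-`(g1$tokens, NULL),
               `rownames<-`(g2$tokens, NULL))
  s1 <- assemble_cds_sequence(g1$transcripts[[1]], g1$locus)
  s2 <- assemble_cds_sequence(g2$transcripts[[1]], g2$locus)
  expect_identical(s1, s2)
  ## the minus-strand FASTA record is the reverse complement of the plus one
  f1 <- as.character(Biostrings::readDNAStringSet(r1$species$mouse$fasta)[[1]])
  f2 <- as.character(Biostrings::readDNAStringSet(r2$species$mouse$fasta)[[1]])
  expect_identical(f2, revcomp_oracle(f1))
})

test_that("is_valid_cds applies length, frame, start, stop and internal-stop rules", {
  expect_true(is_valid_cds("ATGTAA")$valid)
  expect_false(is_valid_cds("ATGTAATGA")$valid)
  expect_identical(is_valid_cds("ATGTAATGA")$reason, "internal_stop")
  expect_identical(is_valid_cds("ATGAATAA")$reason, "frame")   # length 8
  expect_identical(is_valid_cds("ATG")$reason, "length")
  expect_identical(is_valid_cds("CTGAAATAA")$reason, "start")
  expect_true(is_valid_cds("CTGAAATAA", start_codons = "CTG")$valid)
  expect_identical(is_valid_cds("ATGAAAAAC")$reason, "stop")
  expect_error(is_valid_cds("ATGNNNTAA"), "alphabet error")
})

test_that("known annotated transcripts assemble to valid CDSs at load", {
  for (nm in c("fig1", "fig4", "fig5")) {
    fr <- fig_report(nm)
    for (g in fr$genes) {
      for (tm in g$transcripts) {
        seq <- assemble_cds_sequence(tm, g$locus)
        expect_true(is_valid_cds(seq)$valid,
                    label = sprintf("%s/%s valid", nm, tm$transcript_id))
      }
    }
  }
})
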