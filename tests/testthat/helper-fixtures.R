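# Shared fixture plumbing: figure fixtures are realized and analyzed once
# per session and cached.

.fixture_cache <- new.env(parent = emptyenv())

fig_report <- function(name, junctions = TRUE) {
  key <- paste0(name, if (junctions) "_jx" else "")
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  spec <- figure_fixtures()[[name]]
  d <- file.path(tempdir(), paste0("fx_", name))
  r <- realize_fixture(spec, d)
  species <- spec$species
  sets <- setNames(lapply(species, function(sp) {
    load_species(r$species[[sp]]$gtf, r$species[[sp]]$fasta, sp)
  }), species)
  genes <- setNames(lapply(sets, function(s) s[[1]]), species)
  jx <- if (junctions) {
    setNames(lapply(species, function(sp) {
      read_junctions(r$species[[sp]]$junctions)
    }), species)
  }
  rep <- run_triplet(genes, junctions = jx)
  res <- list(spec = spec, files = r, genes = genes, report = rep)
  .fixture_cache[[key]] <- res
  res
}

# Run a random single-gene tri-species fixture end to end.
random_report <- function(seed, block_identity = 1.0) {
  spec <- random_fixture(seed, block_identity = block_identity)
  d <- file.path(tempdir(), paste0("rand_", seed, "_", block_identity * 100))
  r <- realize_fixture(spec, d)
  species <- spec$species
  genes <- setNames(lapply(species, function(sp) {
    load_species(r$species[[sp]]$gtf, r$species[[sp]]$fasta, sp)[[1]]
  }), species)
  list(spec = spec, files = r, genes = genes,
       report = run_triplet(genes), truth = r$truth)
}

# Hand-built single gene: "[A<>B<>C]" structure with given block lengths
# (multiples of 3), deterministic sequence; optionally insert one extra
# base into block B (shifts downstream frame).
simple_gene <- function(blens = c(A = 30L, B = 24L, C = 36L),
                        insert_in_B = FALSE, gene_id = "g1",
                        species = "sp", seed = 42L) {
  set.seed(seed)
  safe <- spliceortho:::.SAFE_CODONS
  blk <- lapply(blens, function(n) {
    paste(sample(safe, n / 3L, replace = TRUE), collapse = "")
  })
  substr(blk$A, 1, 3) <- "ATG"
  if (insert_in_B) {
    blk$B <- paste0(substr(blk$B, 1, 12), "A", substr(blk$B, 13, nchar(blk$B)))
  }
  intron <- function() {
    paste0("GT", paste(sample(c("A", "C", "G", "T"), 56, replace = TRUE),
                       collapse = ""), "AG")
  }
  flank <- paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE),
                 collapse = "")
  locus <- paste0(flank, blk$A, intron(), blk$B, intron(), blk$C, "TAA",
                  flank)
  a0 <- nchar(flank)
  aE <- a0 + nchar(blk$A)
  b0 <- aE + 60L
  bE <- b0 + nchar(blk$B)
  c0 <- bE + 60L
  cE <- c0 + nchar(blk$C)
  rec <- transcript_record("t1", gene_id,
                           data.frame(start = c(a0, b0, c0),
                                      end = c(aE, bE, cE)),
                           utr5_exons = data.frame(start = a0 - 10L,
                                                   end = a0),
                           utr3_exons = data.frame(start = cE + 3L,
                                                   end = cE + 13L))
  build_gene_model(list(rec), gene_id, species = species, locus = locus)
}
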