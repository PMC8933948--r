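# Independent oracles used by property tests.

# reverse complement, independent of Biostrings
revcomp_oracle <- function(seq) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", seq), "")[[1]]), collapse = "")
}

# Brute-force enumeration of every token subset of a gene model that forms
# a grammar-valid transcript chain (checked on coordinates) and assembles
# to a valid CDS. Independent of the prediction path.
brute_force_models <- function(gene, start_codons = "ATG") {
  tk <- gene$tokens
  tk <- tk[order(tk$start, c(acceptor = 0, start = 1, donor = 2, stop = 3,
                             block = 4)[tk$kind]), ]
  n <- nrow(tk)
  stopifnot(n <= 14L)
  valid_chain <- function(rows) {
    if (rows$kind[1] != "start" || rows$kind[nrow(rows)] != "stop") {
      return(FALSE)
    }
    if (!any(rows$kind == "block")) return(FALSE)
    state <- "start"
    pos <- rows$start[1]
    for (i in seq_len(nrow(rows))[-1]) {
      k <- rows$kind[i]
      ok <- switch(state,
        start = k == "block" && rows$start[i] == pos,
        block = (k == "donor" && rows$start[i] == pos) ||
          (k == "stop" && rows$start[i] == pos) ||
          (k == "block" && rows$start[i] == pos),
        donor = k == "acceptor" && rows$start[i] > pos,
        acceptor = k == "block" && rows$start[i] == pos,
        stop = FALSE)
      if (!isTRUE(ok)) return(FALSE)
      pos <- if (k == "block") rows$end[i] else rows$start[i]
      state <- k
    }
    state == "stop"
  }
  out <- character()
  for (mask in seq_len(2^n - 1L)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L)
    if (length(idx) < 3L) next
    rows <- tk[idx, , drop = FALSE]
    if (!valid_chain(rows)) next
    seq <- assemble_cds_sequence(rows, gene$locus)
    if (!is_valid_cds(seq, start_codons = start_codons)$valid) next
    out <- c(out, format_model(rows))
  }
  unique(out)
}
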