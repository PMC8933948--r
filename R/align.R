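## Pairwise comparison of two orthologous genes.
##
## Known coding blocks are anchored by local alignment in decreasing length
## order inside colinear windows; known functional sites are mapped through
## the resulting boundary correspondence (sites sit on block boundaries) or,
## when no flanking block anchors them, by aligning the site motif with
## flanking context. A mapped position in unannotated sequence with an exact
## splice/codon motif becomes a predicted token; a mapped position on a
## known token records a token orthology. The merged boundary map is forced
## to be strictly monotone (colinearity), crossing pairs are dropped.

.nucleotide_submat <- local({
  cache <- NULL
  function(match, mismatch) {
    key <- paste(match, mismatch)
    if (is.null(cache) || attr(cache, "key") != key) {
      m <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                    mismatch = mismatch,
                                                    baseOnly = TRUE)
      attr(m, "key") <- key
      cache <<- m
    }
    cache
  }
})

.align_local <- function(pattern, subject, config) {
  Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(pattern),
    subject = Biostrings::DNAString(subject),
    type = "local",
    substitutionMatrix = .nucleotide_submat(config$match, config$mismatch),
    gapOpening = config$gap_open, gapExtension = config$gap_ext)
}

## Map a pattern boundary (0-based, 0..plen) to a subject boundary (0-based
## within the subject string), extrapolating beyond the locally aligned
## region. Assumes substitutions dominate (gaps are handled but boundaries
## inside gap runs are approximated by the left flank).
.aln_boundary_map <- function(aln, plen) {
  pg <- strsplit(as.character(Biostrings::pattern(aln)), "")[[1]]
  sg <- strsplit(as.character(Biostrings::subject(aln)), "")[[1]]
  p0 <- IRanges::start(Biostrings::pattern(aln))
  s0 <- IRanges::start(Biostrings::subject(aln))
  ## subject boundary (0-based) to the left of each aligned pattern base
  map <- rep(NA_integer_, plen + 1L)
  pi <- p0 - 1L
  si <- s0 - 1L
  for (j in seq_along(pg)) {
    if (pg[j] != "-" && sg[j] != "-") {
      pi <- pi + 1L
      si <- si + 1L
      map[pi] <- si - 1L        # boundary before base pi
      map[pi + 1L] <- si        # boundary after base pi
    } else if (pg[j] != "-") {
      pi <- pi + 1L
      map[pi + 1L] <- si
    } else {
      si <- si + 1L
    }
  }
  known <- which(!is.na(map))
  if (length(known) == 0L) return(map)
  first <- known[1]
  last <- known[length(known)]
  if (first > 1L) {
    map[seq_len(first - 1L)] <- map[first] - (first - seq_len(first - 1L))
  }
  if (last < length(map)) {
    idx <- (last + 1L):length(map)
    map[idx] <- map[last] + (idx - last)
  }
  for (i in which(is.na(map))) map[i] <- map[i - 1L] + 1L
  map
}

#' Align one token against a target gene
#'
#' Local alignment of a coding block's sequence, or of a functional-site
#' motif with flanking context, inside a window of the target locus.
#'
#' @param token one-row token data frame of `source`.
#' @param source the `"gene_model"` owning the token.
#' @param target target `"gene_model"`.
#' @param window optional `c(lo, hi)` internal interval of the target locus
#'   to search (default: whole locus).
#' @param config an [orthology_config()].
#' @return For a block: list with `hit`, `start`, `end` (internal target
#'   coordinates), `identity`, `score`, `reason`. For a site: list with
#'   `hit`, `pos`, `identity`, `motif`, `motif_ok`, `reason`. `hit` is FALSE
#'   with a reason when the window is empty, identity is below threshold,
#'   the frame offset is incompatible, or the mapped motif does not match.
#' @export
align_token <- function(token, source, target, window = NULL,
                        config = orthology_config()) {
  Lt <- nchar(target$locus)
  if (is.null(window)) window <- c(0L, Lt)
  lo <- max(0L, window[1])
  hi <- min(Lt, window[2])
  if (token$kind == "block") {
    plen <- token$end - token$start
    if (hi - lo < 4L || plen < 1L) {
      return(list(hit = FALSE, reason = "empty_window"))
    }
    pat <- .subseq(source$locus, token$start, token$end)
    aln <- .align_local(pat, .subseq(target$locus, lo, hi), config)
    identity <- Biostrings::nmatch(aln) / plen
    if (identity < config$block_identity) {
      return(list(hit = FALSE, reason = "identity", identity = identity))
    }
    bmap <- .aln_boundary_map(aln, plen)
    s <- max(0L, lo + bmap[1])
    e <- min(Lt, lo + bmap[plen + 1L])
    if (e <= s) return(list(hit = FALSE, reason = "degenerate"))
    if (config$frame_check && ((e - s) - plen) %% 3L != 0L) {
      return(list(hit = FALSE, reason = "frame", identity = identity))
    }
    list(hit = TRUE, start = s, end = e, identity = identity,
         score = Biostrings::score(aln), reason = NA_character_)
  } else {
    ctx <- config$site_context
    span <- switch(token$kind,
                   start = c(token$start, token$start + 3L),
                   stop = c(token$start, token$start + 3L),
                   donor = c(token$start, token$start + 2L),
                   acceptor = c(token$start - 2L, token$start))
    Ls <- nchar(source$locus)
    c0 <- max(0L, span[1] - ctx)
    c1 <- min(Ls, span[2] + ctx)
    if (hi - lo < 4L) return(list(hit = FALSE, reason = "empty_window"))
    pat <- .subseq(source$locus, c0, c1)
    plen <- c1 - c0
    aln <- .align_local(pat, .subseq(target$locus, lo, hi), config)
    identity <- Biostrings::nmatch(aln) / plen
    if (identity < config$site_identity) {
      return(list(hit = FALSE, reason = "identity", identity = identity))
    }
    bmap <- .aln_boundary_map(aln, plen)
    boundary <- if (token$kind == "acceptor") span[2] - c0 else span[1] - c0
    pos <- lo + bmap[boundary + 1L]
    if (pos < 0L || pos > Lt) return(list(hit = FALSE, reason = "range"))
    motif <- .site_motif(target$locus, token$kind, pos)
    motif_ok <- .motif_allowed(token$kind, motif, config)
    list(hit = TRUE, pos = pos, identity = identity, motif = motif,
         motif_ok = motif_ok, reason = NA_character_)
  }
}

.motif_allowed <- function(kind, motif, config) {
  if (is.na(motif)) return(FALSE)
  switch(kind,
         donor = motif %in% config$donor_motifs,
         acceptor = motif %in% config$acceptor_motifs,
         start = motif %in% config$start_codons,
         stop = motif %in% config$stop_codons,
         FALSE)
}

## Anchor the known blocks of src inside tgt, longest first, windows bounded
## by already-accepted anchors (colinearity by construction).
.block_anchor_pass <- function(src, tgt, config) {
  blocks <- src$tokens[src$tokens$kind == "block" &
                         src$tokens$status == "known", , drop = FALSE]
  if (nrow(blocks) == 0L) {
    return(list(anchors = data.frame(), unaligned = data.frame()))
  }
  blocks <- blocks[order(-(blocks$end - blocks$start), blocks$start), ,
                   drop = FALSE]
  Lt <- nchar(tgt$locus)
  anchors <- data.frame(sa = integer(), ea = integer(),
                        sb = integer(), eb = integer(), identity = numeric())
  unaligned <- data.frame(kind = character(), start = integer(),
                          end = integer(), reason = character())
  for (i in seq_len(nrow(blocks))) {
    x <- blocks[i, ]
    lo <- c(0L, anchors$eb[anchors$ea <= x$start])
    hi <- c(Lt, anchors$sb[anchors$sa >= x$end])
    win <- c(max(lo), min(hi))
    hit <- align_token(x, src, tgt, window = win, config = config)
    if (!isTRUE(hit$hit)) {
      unaligned <- rbind(unaligned,
                         data.frame(kind = "block", start = x$start,
                                    end = x$end, reason = hit$reason))
      next
    }
    anchors <- rbind(anchors,
                     data.frame(sa = x$start, ea = x$end,
                                sb = hit$start, eb = hit$end,
                                identity = hit$identity))
  }
  list(anchors = anchors, unaligned = unaligned)
}

## Merge candidate boundary pairs into one strictly monotone map.
.monotone_merge <- function(pairs) {
  if (nrow(pairs) == 0L) {
    return(list(map = pairs, dropped = pairs[0, , drop = FALSE]))
  }
  pairs <- pairs[order(-pairs$score, pairs$pa, pairs$pb), , drop = FALSE]
  pairs <- pairs[!duplicated(pairs[, c("pa", "pb")]), , drop = FALSE]
  acc <- pairs[0, , drop = FALSE]
  dropped <- pairs[0, , drop = FALSE]
  for (i in seq_len(nrow(pairs))) {
    pa <- pairs$pa[i]
    pb <- pairs$pb[i]
    ok <- all(sign(pa - acc$pa) == sign(pb - acc$pb)) &&
      !any(pa == acc$pa | pb == acc$pb)
    if (isTRUE(ok) || nrow(acc) == 0L) {
      acc <- rbind(acc, pairs[i, ])
    } else {
      dropped <- rbind(dropped, pairs[i, ])
    }
  }
  acc <- acc[order(acc$pa), , drop = FALSE]
  rownames(acc) <- NULL
  list(map = acc, dropped = dropped)
}

.lookup_map <- function(map, pa) {
  hit <- match(pa, map$pa)
  if (is.na(hit)) NA_integer_ else map$pb[hit]
}

## Map the known sites of src into tgt: through the boundary map when the
## site position is anchored, by context alignment otherwise. Returns
## accepted site pairs and failures.
.site_map_pass <- function(src, tgt, map, config) {
  sites <- src$tokens[src$tokens$kind != "block" &
                        src$tokens$status == "known", , drop = FALSE]
  Lt <- nchar(tgt$locus)
  out <- list()
  failed <- list()
  for (i in seq_len(nrow(sites))) {
    s <- sites[i, ]
    p <- s$start
    pb <- .lookup_map(map, p)
    identity <- NA_real_
    if (is.na(pb)) {
      lo <- c(0L, map$pb[map$pa <= p])
      hi <- c(Lt, map$pb[map$pa >= p])
      pad <- config$site_context + 8L
      win <- c(max(0L, max(lo) - pad), min(Lt, min(hi) + pad))
      hit <- align_token(s, src, tgt, window = win, config = config)
      if (!isTRUE(hit$hit)) {
        failed[[length(failed) + 1L]] <-
          data.frame(kind = s$kind, start = p, end = p, reason = hit$reason)
        next
      }
      pb <- hit$pos
      identity <- hit$identity
    }
    known_b <- any(tgt$tokens$kind == s$kind & tgt$tokens$start == pb)
    if (!known_b) {
      motif <- .site_motif(tgt$locus, s$kind, pb)
      if (!.motif_allowed(s$kind, motif, config)) {
        failed[[length(failed) + 1L]] <-
          data.frame(kind = s$kind, start = p, end = p, reason = "motif")
        next
      }
    }
    out[[length(out) + 1L]] <-
      data.frame(kind = s$kind, pa = p, pb = pb, identity = identity,
                 known_target = known_b)
  }
  list(pairs = if (length(out)) do.call(rbind, out) else
         data.frame(kind = character(), pa = integer(), pb = integer(),
                    identity = numeric(), known_target = logical()),
       failed = if (length(failed)) do.call(rbind, failed) else NULL)
}

.flip_pairs <- function(df, cols = c("pa", "pb")) {
  if (nrow(df) == 0L) return(df)
  tmp <- df[[cols[1]]]
  df[[cols[1]]] <- df[[cols[2]]]
  df[[cols[2]]] <- tmp
  df
}

#' Compare two orthologous gene models
#'
#' Anchors the known coding blocks of each gene in the other by colinear
#' local alignment, maps the known functional sites through the resulting
#' boundary correspondence, records token orthologies where a hit lands on a
#' known token of matching kind, and predicted tokens (with the predicting
#' species as source) where it lands in unannotated sequence with an exact
#' splice/codon motif. Orthologous blocks receive a unified label across the
#' two returned gene models.
#'
#' @param gene_a,gene_b `"gene_model"` objects built from known transcripts.
#' @param config an [orthology_config()].
#' @return A list of class `"pairwise_comparison"`: updated `gene_a`,
#'   `gene_b` (with predicted tokens and re-segmented blocks), `orthologies`
#'   (one row per token pair, stored once and symmetric), `predicted_a`,
#'   `predicted_b`, `unaligned`, `dropped` (crossing/conflicting boundary
#'   pairs), and the merged boundary `map`.
#' @export
compare_genes <- function(gene_a, gene_b, config = orthology_config()) {
  ab <- .block_anchor_pass(gene_a, gene_b, config)
  ba <- .block_anchor_pass(gene_b, gene_a, config)
  bp <- rbind(
    if (nrow(ab$anchors)) {
      with(ab$anchors, data.frame(pa = c(sa, ea), pb = c(sb, eb),
                                  score = rep(identity, 2)))
    },
    if (nrow(ba$anchors)) {
      with(ba$anchors, data.frame(pa = c(sb, eb), pb = c(sa, ea),
                                  score = rep(identity, 2)))
    })
  if (is.null(bp)) {
    bp <- data.frame(pa = integer(), pb = integer(), score = numeric())
  }
  m1 <- .monotone_merge(bp)
  s_ab <- .site_map_pass(gene_a, gene_b, m1$map, config)
  s_ba <- .site_map_pass(gene_b, gene_a, .flip_pairs(m1$map), config)
  site_pairs <- unique(rbind(
    s_ab$pairs[, c("kind", "pa", "pb", "identity")],
    .flip_pairs(s_ba$pairs)[, c("kind", "pa", "pb", "identity")]))
  sp_scored <- data.frame(pa = site_pairs$pa, pb = site_pairs$pb,
                          score = ifelse(is.na(site_pairs$identity), 1,
                                         site_pairs$identity))
  m2 <- .monotone_merge(rbind(m1$map, sp_scored))
  map <- m2$map
  in_map <- function(pa, pb) {
    !is.na(pa) & !is.na(pb) & vapply(seq_along(pa), function(i) {
      any(map$pa == pa[i] & map$pb == pb[i])
    }, logical(1))
  }
  site_pairs <- site_pairs[in_map(site_pairs$pa, site_pairs$pb), ,
                           drop = FALSE]

  ## predicted sites in each gene
  pred_site_b <- .predicted_sites(site_pairs, gene_b, "pb", gene_a$species)
  pred_site_a <- .predicted_sites(.flip_pairs(site_pairs), gene_a, "pb",
                                  gene_b$species)
  ## predicted blocks: known src blocks mapped into unannotated tgt regions
  pred_blk_b <- .predicted_blocks(gene_a, gene_b, map)
  pred_blk_a <- .predicted_blocks(gene_b, gene_a, .flip_pairs(map))

  new_a <- .augment_gene(gene_a, pred_site_a, pred_blk_a, config)
  new_b <- .augment_gene(gene_b, pred_site_b, pred_blk_b, config)

  edges <- .pair_edges(new_a, new_b, map, site_pairs)
  lab <- .unify_block_labels(list(new_a, new_b), list(edges$blocks))
  new_a <- lab$genes[[1]]
  new_b <- lab$genes[[2]]
  orth <- .orthology_table(new_a, new_b, edges)

  structure(list(gene_a = new_a, gene_b = new_b,
                 orthologies = orth, map = map,
                 site_pairs = site_pairs,
                 predicted_a = pred_site_a, predicted_b = pred_site_b,
                 predicted_blocks_a = pred_blk_a,
                 predicted_blocks_b = pred_blk_b,
                 edges = edges,
                 unaligned = list(a = rbind(ab$unaligned, s_ab$failed),
                                  b = rbind(ba$unaligned, s_ba$failed)),
                 dropped = rbind(m1$dropped, m2$dropped),
                 label_conflicts = lab$conflicts),
            class = "pairwise_comparison")
}

.predicted_sites <- function(site_pairs, tgt, col, src_species) {
  if (nrow(site_pairs) == 0L) {
    return(data.frame(kind = character(), pos = integer(),
                      motif = character(), source = character()))
  }
  rows <- lapply(seq_len(nrow(site_pairs)), function(i) {
    kind <- site_pairs$kind[i]
    pos <- site_pairs[[col]][i]
    if (any(tgt$tokens$kind == kind & tgt$tokens$start == pos)) return(NULL)
    data.frame(kind = kind, pos = pos,
               motif = .site_motif(tgt$locus, kind, pos),
               source = src_species)
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  if (is.null(out)) {
    out <- data.frame(kind = character(), pos = integer(),
                      motif = character(), source = character())
  }
  unique(out)
}

.predicted_blocks <- function(src, tgt, map) {
  blocks <- src$tokens[src$tokens$kind == "block" &
                         src$tokens$status == "known", , drop = FALSE]
  tblk <- tgt$tokens[tgt$tokens$kind == "block", , drop = FALSE]
  rows <- lapply(seq_len(nrow(blocks)), function(i) {
    s <- .lookup_map(map, blocks$start[i])
    e <- .lookup_map(map, blocks$end[i])
    if (is.na(s) || is.na(e) || e <= s) return(NULL)
    overlaps <- any(tblk$start < e & tblk$end > s)
    if (overlaps) return(NULL)
    data.frame(start = s, end = e, source = src$species)
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  if (is.null(out)) {
    out <- data.frame(start = integer(), end = integer(),
                      source = character())
  }
  unique(out)
}

## Rebuild a gene model with extra (predicted) sites and blocks; blocks are
## re-segmented at every site position and block endpoint.
.augment_gene <- function(gene, pred_sites, pred_blocks, config) {
  if (nrow(pred_sites) == 0L && nrow(pred_blocks) == 0L &&
      !isTRUE(attr(gene, "needs_reseg"))) {
    return(gene)
  }
  tk <- gene$tokens
  regions <- rbind(
    data.frame(start = tk$start[tk$kind == "block"],
               end = tk$end[tk$kind == "block"],
               status = tk$status[tk$kind == "block"],
               source = tk$source[tk$kind == "block"]),
    if (nrow(pred_blocks)) {
      data.frame(start = pred_blocks$start, end = pred_blocks$end,
                 status = "predicted", source = pred_blocks$source)
    })
  sites <- rbind(
    data.frame(kind = tk$kind[tk$kind != "block"],
               pos = tk$start[tk$kind != "block"],
               motif = tk$motif[tk$kind != "block"],
               status = tk$status[tk$kind != "block"],
               source = tk$source[tk$kind != "block"]),
    if (nrow(pred_sites)) {
      data.frame(kind = pred_sites$kind, pos = pred_sites$pos,
                 motif = pred_sites$motif, status = "predicted",
                 source = pred_sites$source)
    })
  ## dedupe sites by kind+pos (known wins; sources merged)
  key <- paste(sites$kind, sites$pos)
  sites <- do.call(rbind, lapply(split(sites, key), function(g) {
    g <- g[order(g$status != "known"), , drop = FALSE]
    g$source[1] <- paste(unique(setdiff(unlist(strsplit(g$source, ",")),
                                        "")), collapse = ",")
    g[1, , drop = FALSE]
  }))
  extra_bounds <- attr(gene, "extra_bounds")
  bounds <- sort(unique(c(sites$pos, regions$start, regions$end,
                          extra_bounds)))
  merged <- .merge_intervals(regions[, c("start", "end")])
  pieces <- .cut_regions(merged, bounds)
  piece_status <- vapply(seq_len(nrow(pieces)), function(i) {
    cover <- regions$status[regions$start < pieces$end[i] &
                              regions$end > pieces$start[i]]
    if (any(cover == "known")) "known" else "predicted"
  }, character(1))
  piece_source <- vapply(seq_len(nrow(pieces)), function(i) {
    src <- regions$source[regions$start < pieces$end[i] &
                            regions$end > pieces$start[i]]
    paste(unique(setdiff(unlist(strsplit(src, ",")), "")), collapse = ",")
  }, character(1))
  block_tok <- .make_token("block", NA_character_, pieces$start, pieces$end,
                           NA_character_, piece_status, piece_source)
  site_tok <- .make_token(sites$kind, NA_character_, sites$pos, sites$pos,
                          sites$motif, sites$status, sites$source)
  gene$tokens <- .assign_labels(.order_tokens(rbind(block_tok, site_tok)))
  attr(gene, "needs_reseg") <- NULL
  gene$transcripts <- lapply(gene$records, build_transcript_model,
                             gene = gene)
  names(gene$transcripts) <-
    vapply(gene$transcripts, `[[`, character(1), "transcript_id")
  gene
}

## Token-level edges between the two augmented genes, derived from the
## boundary map: block edge iff both endpoints correspond; site edge per
## accepted site pair.
.pair_edges <- function(a, b, map, site_pairs) {
  ab <- a$tokens[a$tokens$kind == "block", , drop = FALSE]
  bb <- b$tokens[b$tokens$kind == "block", , drop = FALSE]
  blocks <- do.call(rbind, Filter(Negate(is.null),
    lapply(seq_len(nrow(ab)), function(i) {
      s <- .lookup_map(map, ab$start[i])
      e <- .lookup_map(map, ab$end[i])
      if (is.na(s) || is.na(e)) return(NULL)
      j <- which(bb$start == s & bb$end == e)
      if (length(j) != 1L) return(NULL)
      data.frame(start_a = ab$start[i], end_a = ab$end[i],
                 start_b = s, end_b = e)
    })))
  if (is.null(blocks)) {
    blocks <- data.frame(start_a = integer(), end_a = integer(),
                         start_b = integer(), end_b = integer())
  }
  sites <- do.call(rbind, Filter(Negate(is.null),
    lapply(seq_len(nrow(site_pairs)), function(i) {
      kind <- site_pairs$kind[i]
      pa <- site_pairs$pa[i]
      pb <- site_pairs$pb[i]
      if (!any(a$tokens$kind == kind & a$tokens$start == pa)) return(NULL)
      if (!any(b$tokens$kind == kind & b$tokens$start == pb)) return(NULL)
      data.frame(kind = kind, pos_a = pa, pos_b = pb,
                 identity = site_pairs$identity[i])
    })))
  if (is.null(sites)) {
    sites <- data.frame(kind = character(), pos_a = integer(),
                        pos_b = integer(), identity = numeric())
  }
  list(blocks = blocks, sites = sites)
}

.orthology_table <- function(a, b, edges) {
  tok <- function(g, kind, start, end = start) {
    i <- which(g$tokens$kind == kind & g$tokens$start == start &
                 (kind != "block" | g$tokens$end == end))
    g$tokens[i[1], , drop = FALSE]
  }
  rows <- list()
  for (i in seq_len(nrow(edges$blocks))) {
    e <- edges$blocks[i, ]
    ta <- tok(a, "block", e$start_a, e$end_a)
    tb <- tok(b, "block", e$start_b, e$end_b)
    rows[[length(rows) + 1L]] <- data.frame(
      kind = "block", label_a = ta$label, label_b = tb$label,
      start_a = e$start_a, end_a = e$end_a,
      start_b = e$start_b, end_b = e$end_b,
      status_a = ta$status, status_b = tb$status, identity = NA_real_)
  }
  for (i in seq_len(nrow(edges$sites))) {
    e <- edges$sites[i, ]
    ta <- tok(a, e$kind, e$pos_a)
    tb <- tok(b, e$kind, e$pos_b)
    rows[[length(rows) + 1L]] <- data.frame(
      kind = e$kind, label_a = NA_character_, label_b = NA_character_,
      start_a = e$pos_a, end_a = e$pos_a,
      start_b = e$pos_b, end_b = e$pos_b,
      status_a = ta$status, status_b = tb$status, identity = e$identity)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(kind = character(), label_a = character(),
                      label_b = character(), start_a = integer(),
                      end_a = integer(), start_b = integer(),
                      end_b = integer(), status_a = character(),
                      status_b = character(), identity = numeric())
  }
  out
}
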