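#' @importFrom stats setNames runif
#' @importFrom utils write.table read.table
NULL

## Token grammar
##
## A gene or transcript structure is written as a one-line string over the
## alphabet {[, ], <, >, A-Z}:
##   '['  start codon        ']'  stop codon
##   '<'  splice donor       '>'  splice acceptor
##   A-Z  coding blocks (maximal coding segments between functional sites)
## e.g. "[A<>B<>C]" is a three-exon CDS; "[A<>B<>C]>D]" a gene with two
## alternative terminal exons C and D.

.token_kinds <- c(start = "[", donor = "<", acceptor = ">", stop = "]")

.kind_of_symbol <- function(ch) {
  if (ch %in% c("[", "<", ">", "]")) {
    names(.token_kinds)[match(ch, .token_kinds)]
  } else if (grepl("^[A-Z]$", ch)) {
    "block"
  } else {
    NA_character_
  }
}

.symbol_of_token <- function(kind, label) {
  ifelse(kind == "block", label, unname(.token_kinds[kind]))
}

## Sort rank of tokens sharing a boundary coordinate: zero-width sites
## attached at position p precede a block starting at p and follow a block
## ending at p (blocks sort by their own start).
.kind_rank <- c(acceptor = 0L, start = 1L, donor = 2L, stop = 3L, block = 4L)

.empty_tokens <- function() {
  data.frame(kind = character(), label = character(),
             start = integer(), end = integer(), motif = character(),
             status = character(), source = character(),
             stringsAsFactors = FALSE)
}

.order_tokens <- function(tokens) {
  tokens[order(tokens$start, .kind_rank[tokens$kind], tokens$end), ,
         drop = FALSE]
}

.grammar_error <- function(msg, offset) {
  stop(structure(class = c("grammar_error", "error", "condition"),
                 list(message = sprintf("grammar error at offset %d: %s",
                                        offset, msg),
                      call = NULL, offset = offset)))
}

#' Parse a structure-model grammar string
#'
#' Converts a one-line grammar string such as \code{"[A<>B<>C]"} into an
#' ordered token table. Symbols: \code{[} start codon, \code{]} stop codon,
#' \code{<} splice donor, \code{>} splice acceptor, uppercase letters coding
#' blocks. The parse is the inverse of [format_model()].
#'
#' Validity rules: non-empty; alphabet as above; the first token is a start
#' and the last a stop; at least one coding block; block labels are unique;
#' every donor is followed by a later acceptor and every acceptor preceded by
#' an earlier donor (an acceptor directly after a block with no intervening
#' donor marks an alternative 5' extension boundary, which is legal because a
#' donor occurs earlier in the gene).
#'
#' @param text grammar string.
#' @return A token `data.frame` with columns `kind`, `label`, `start`, `end`,
#'   `motif`, `status`, `source`; coordinates are `NA` (a parsed string
#'   carries structure only).
#' @examples
#' parse_model_string("[A<>B<>C]")$kind
#' format_model(parse_model_string("[A<>B<>C]>D]"))
#' @export
parse_model_string <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) ||
      !nzchar(text)) {
    .grammar_error("empty or non-scalar input", 0L)
  }
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  kinds <- vapply(chars, .kind_of_symbol, character(1), USE.NAMES = FALSE)
  bad <- which(is.na(kinds))
  if (length(bad)) {
    .grammar_error(sprintf("unknown symbol '%s'", chars[bad[1]]),
                   bad[1] - 1L)
  }
  if (kinds[1] != "start") .grammar_error("missing start codon '['", 0L)
  if (kinds[length(kinds)] != "stop") {
    .grammar_error("missing terminal stop codon ']'", length(kinds) - 1L)
  }
  if (!any(kinds == "block")) .grammar_error("no coding block", 0L)
  labels <- ifelse(kinds == "block", chars, NA_character_)
  if (anyDuplicated(labels[!is.na(labels)])) {
    dup <- which(duplicated(labels) & !is.na(labels))[1]
    .grammar_error(sprintf("duplicate block label '%s'", labels[dup]),
                   dup - 1L)
  }
  for (i in which(kinds == "donor")) {
    later <- kinds[seq_along(kinds) > i]
    if (!any(later == "acceptor")) {
      .grammar_error("donor without a later acceptor", i - 1L)
    }
  }
  for (i in which(kinds == "acceptor")) {
    earlier <- kinds[seq_along(kinds) < i]
    if (!any(earlier == "donor")) {
      .grammar_error("acceptor without an earlier donor", i - 1L)
    }
  }
  data.frame(kind = kinds, label = labels,
             start = NA_integer_, end = NA_integer_,
             motif = NA_character_, status = "known", source = "",
             stringsAsFactors = FALSE)
}

#' Format tokens as a grammar string
#'
#' Canonical inverse of [parse_model_string()]: renders an ordered token
#' table as its one-line grammar string. Tokens carrying coordinates are
#' ordered by coordinate first; coordinate-free tokens keep their row order.
#'
#' @param tokens token `data.frame` (see [parse_model_string()]).
#' @return A single grammar string.
#' @export
format_model <- function(tokens) {
  stopifnot(is.data.frame(tokens))
  if (nrow(tokens) == 0L) stop("structural error: empty token list")
  if (!all(tokens$kind %in% names(.kind_rank))) {
    stop("structural error: unknown token kind")
  }
  if (all(!is.na(tokens$start))) tokens <- .order_tokens(tokens)
  if (tokens$kind[1] != "start" || tokens$kind[nrow(tokens)] != "stop") {
    stop("structural error: model must begin with a start and end with a stop")
  }
  if (any(tokens$kind == "block" & is.na(tokens$label))) {
    stop("structural error: unlabeled coding block")
  }
  paste(.symbol_of_token(tokens$kind, tokens$label), collapse = "")
}

#' Generate random valid structure-model strings
#'
#' Draws random gene-style grammar strings (alternative terminal exons,
#' alternative 5' extensions and internal exons) that satisfy the validity
#' rules of [parse_model_string()]. Used for property checks (parse/format
#' round trips, random fixture grammars).
#'
#' @param n number of strings.
#' @param max_exons maximum number of exon slots per model.
#' @return Character vector of `n` grammar strings.
#' @export
random_model_string <- function(n = 1L, max_exons = 5L) {
  out <- character(n)
  for (i in seq_len(n)) {
    n_exons <- sample.int(max_exons, 1L)
    letters_pool <- LETTERS
    used <- 0L
    parts <- "["
    for (e in seq_len(n_exons)) {
      n_blocks <- sample(1:2, 1L, prob = c(0.8, 0.2))
      for (b in seq_len(n_blocks)) {
        used <- used + 1L
        if (b > 1L && runif(1) < 0.5 && e > 1L) parts <- c(parts, ">")
        parts <- c(parts, letters_pool[used])
      }
      if (e < n_exons) parts <- c(parts, "<", ">")
    }
    parts <- c(parts, "]")
    ## optionally an alternative terminal exon ">X]" (needs an earlier donor)
    if (n_exons > 1L && runif(1) < 0.3 && used < 26L) {
      used <- used + 1L
      parts <- c(parts, ">", letters_pool[used], "]")
    }
    out[i] <- paste(parts, collapse = "")
  }
  out
}
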