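#' Text objects over a dense integer alphabet
#'
#' A `lem_text` is the indexable text: one or more sequences mapped
#' case-insensitively onto dense integer ranks, each sequence terminated by its
#' own sentinel symbol. Sentinels are ranked `1..s` in sequence order and are
#' strictly smaller than every regular symbol, so the last symbol of the
#' concatenation is a sentinel and no match can ever span a sequence boundary.
#'
#' @param seqs character vector of sequences (one element per sequence record);
#'   characters are case-folded to lower case before rank assignment.
#' @param names optional per-sequence identifiers; defaults to `seq1`, `seq2`, ...
#' @return an object of class `lem_text` with fields `symbols` (integer ranks,
#'   length n), `n`, `sentinel_count`, `alphabet` (regular characters in rank
#'   order), `names`, and `seq_ends` (sentinel positions in the concatenation).
#' @examples
#' tx <- text_from_strings("abaab")
#' tx$symbols   # sentinel is rank 1, 'a' rank 2, 'b' rank 3
#' @export
text_from_strings <- function(seqs, names = NULL) {
  if (!is.character(seqs) || length(seqs) == 0L)
    stop("`seqs` must be a non-empty character vector")
  if (any(!nzchar(seqs))) stop("empty sequence record")
  seqs <- tolower(seqs)
  if (is.null(names)) names <- paste0("seq", seq_along(seqs))
  if (length(names) != length(seqs)) stop("`names` length mismatch")
  chars <- sort(unique(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE)))
  s <- length(seqs)
  sym_list <- vector("list", 2L * s)
  for (i in seq_len(s)) {
    v <- match(strsplit(seqs[[i]], "", fixed = TRUE)[[1L]], chars)
    sym_list[[2L * i - 1L]] <- v + s        # regular symbols rank above sentinels
    sym_list[[2L * i]] <- i                 # sentinel of sequence i
  }
  symbols <- as.integer(unlist(sym_list, use.names = FALSE))
  structure(
    list(symbols = symbols, n = length(symbols), sentinel_count = s,
         alphabet = chars, names = as.character(names),
         seq_ends = cumsum(nchar(seqs) + 1L)),
    class = "lem_text")
}

#' @export
print.lem_text <- function(x, ...) {
  cat(sprintf("lem_text: %d sequence(s), n = %d, alphabet size = %d (+%d sentinel(s))\n",
              x$sentinel_count, x$n, length(x$alphabet), x$sentinel_count))
  invisible(x)
}

#' Validate the invariants of a text object
#'
#' Checks that the last symbol is a sentinel, each sentinel rank occurs exactly
#' once, and all ranks are at least 1.
#' @param text a `lem_text`.
#' @return `text`, invisibly; errors if an invariant is violated.
#' @export
validate_text <- function(text) {
  stopifnot(inherits(text, "lem_text"))
  sym <- text$symbols
  s <- text$sentinel_count
  if (length(sym) < 1L || any(sym < 1L)) stop("invalid symbol ranks")
  if (sym[length(sym)] > s) stop("text does not end in a sentinel")
  if (!identical(sort(sym[sym <= s]), seq_len(s))) stop("sentinel ranks must each occur exactly once")
  invisible(text)
}

#' Map a pattern string onto a text's alphabet
#'
#' Characters absent from the text's alphabet are mapped to rank 0: they are
#' legal in patterns but can never match any text symbol (and are reported via
#' the `unknown` attribute so callers may warn).
#' @param text a `lem_text`.
#' @param pattern a single pattern string (case-folded).
#' @return integer vector of ranks (0 for unknown characters).
#' @export
map_pattern <- function(text, pattern) {
  stopifnot(is.character(pattern), length(pattern) == 1L)
  ch <- strsplit(tolower(pattern), "", fixed = TRUE)[[1L]]
  r <- match(ch, text$alphabet)
  unknown <- which(is.na(r))
  r[is.na(r)] <- -text$sentinel_count   # becomes 0 after shift
  out <- as.integer(r + text$sentinel_count)
  out[out < 0L] <- 0L
  attr(out, "unknown") <- unknown
  out
}

#' Decode a slice of the text back to characters
#'
#' Sentinels decode to `$`. Used for verification and display only.
#' @param text a `lem_text`.
#' @param from,to 1-based inclusive bounds.
#' @return a character scalar.
#' @export
text_slice <- function(text, from, to) {
  sym <- text$symbols[from:to]
  s <- text$sentinel_count
  paste(ifelse(sym <= s, "$", text$alphabet[sym - s]), collapse = "")
}

#' Resolve a concatenated-text position to (sequence, offset)
#'
#' @param text a `lem_text`.
#' @param pos positions in the concatenation (1-based).
#' @return data.frame with `seq_id` (sequence name) and `offset` (1-based within
#'   the sequence).
#' @export
resolve_position <- function(text, pos) {
  starts <- c(1L, text$seq_ends[-length(text$seq_ends)] + 1L)
  k <- findInterval(pos, starts)
  data.frame(seq_id = text$names[k], offset = as.integer(pos - starts[k] + 1L),
             stringsAsFactors = FALSE)
}

#' Read a (multi-record) FASTA file into a text object
#'
#' @param path FASTA file.
#' @return a `lem_text` with one sentinel per record.
#' @export
read_fasta_text <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA: ", path)
  nm <- sub("\\s.*$", "", names(ss))
  text_from_strings(as.character(ss), names = nm)
}

#' Read FASTA records as plain strings
#' @param path FASTA file.
#' @return named character vector.
#' @export
read_fasta_strings <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA: ", path)
  out <- as.character(ss)
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Write named sequences to a FASTA file
#' @param seqs named character vector.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::BStringSet(seqs)
  names(ss) <- names(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
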