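#' Circular nucleotide sequence
#'
#' A light container for a (possibly circular) nucleotide sequence. Residues
#' are uppercased on construction and restricted to `A`, `C`, `G`, `T`, `N`
#' (masked); `U` is converted to `T`. Other IUPAC ambiguity codes are
#' rejected: in this toolkit `N` is the only admitted ambiguity, marking
#' masked or missing stretches.
#'
#' @param residues Single character string of nucleotides.
#' @param id Sequence identifier.
#' @param circular Is the molecule circular (e.g. a mitochondrial genome)?
#' @return An object of class `circ_seq`.
#' @examples
#' g <- circ_seq("acgtACGT", id = "toy")
#' seq_length(g)
#' @export
circ_seq <- function(residues, id = "seq", circular = TRUE) {
  stopifnot(is.character(residues), length(residues) == 1L)
  residues <- chartr("uU", "tT", residues)
  residues <- toupper(residues)
  names(residues) <- id
  assert_bases(residues, sprintf("record '%s'", id))
  structure(
    list(id = id, residues = unname(residues), circular = isTRUE(circular)),
    class = "circ_seq"
  )
}

#' @export
print.circ_seq <- function(x, ...) {
  cat(sprintf(
    "<circ_seq> %s: %s bp, %s\n", x$id,
    format(seq_length(x), big.mark = ","),
    if (x$circular) "circular" else "linear"
  ))
  invisible(x)
}

#' @export
as.character.circ_seq <- function(x, ...) x$residues

#' Sequence length in base pairs
#' @param x A `circ_seq`.
#' @export
seq_length <- function(x) {
  if (inherits(x, "circ_seq")) nchar(x$residues) else nchar(x)
}

#' Rotate a circular sequence
#'
#' Cuts the first `offset` bases and appends them at the end, the classic
#' trick for recovering alignment coverage across the origin of a circular
#' genome: position `offset + 1` of the input becomes position 1 of the
#' output.
#'
#' @param seq A circular `circ_seq`.
#' @param offset Integer number of bases to rotate by, `0 <= offset < length`.
#' @return A rotated `circ_seq` of identical length.
#' @examples
#' rotate(circ_seq("ACGT"), 1) # "CGTA"
#' @export
rotate <- function(seq, offset) {
  stopifnot(inherits(seq, "circ_seq"))
  if (!seq$circular) abort("cannot rotate a non-circular sequence")
  L <- seq_length(seq)
  offset <- as.integer(offset)
  if (offset < 0L || offset >= L) abort("offset must satisfy 0 <= offset < length")
  if (offset == 0L) return(seq)
  out <- seq
  out$residues <- paste0(
    substr(seq$residues, offset + 1L, L),
    substr(seq$residues, 1L, offset)
  )
  out
}

# Substring with wrap-around on circular sequences (1-based, inclusive).
circ_substr <- function(seq, start, len) {
  L <- seq_length(seq)
  s <- as.character(seq)
  start <- wrap1(start, L)
  if (start + len - 1L <= L) return(substr(s, start, start + len - 1L))
  if (!seq$circular) abort("interval exceeds length of a non-circular sequence")
  paste0(substr(s, start, L), substr(s, 1L, start + len - 1L - L))
}

#' Extract the coding-strand sequence of a feature
#'
#' Returns the nucleotide sequence of a feature in coding orientation:
#' genome orientation for `+` strand features, reverse complement for `-`
#' strand features. The feature `phase` (0-2) drops that many leading bases
#' so that position 1 of the result is the first base of a complete codon.
#'
#' @param seq A `circ_seq` (the reference genome).
#' @param feature One-row tibble or list with `start`, `end`, `strand`,
#'   `phase` (see [read_feature_table()]).
#' @return Character string, coding orientation.
#' @export
extract_coding <- function(seq, feature) {
  L <- seq_length(seq)
  start <- as.integer(feature$start); end <- as.integer(feature$end)
  if (start < 1L || end < start) abort("feature coordinates must satisfy 1 <= start <= end")
  if (end > L) abort(sprintf("feature end %d beyond sequence length %d", end, L))
  s <- substr(as.character(seq), start, end)
  if (identical(feature$strand, "-")) s <- revcomp(s)
  phase <- as.integer(feature$phase %||% 0L)
  if (is.na(phase)) phase <- 0L
  if (phase > 0L) s <- substr(s, phase + 1L, nchar(s))
  s
}
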