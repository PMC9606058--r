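#' Read nucleotide FASTA into circular sequences
#'
#' Residues are uppercased, `U` is converted to `T`, and characters outside
#' `{A,C,G,T,N}` raise a parse error naming the offending record.
#'
#' @param path FASTA file.
#' @param circular Mark sequences as circular (default `TRUE`; mitogenomes).
#' @return List of [circ_seq()] objects, one per record.
#' @export
read_fasta <- function(path, circular = TRUE) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) abort(sprintf("no FASTA records in '%s'", path))
  ids <- sub("\\s.*$", "", names(set))
  purrr::map2(as.character(set), ids, circ_seq, circular = circular)
}

#' Write sequences to FASTA
#'
#' @param seqs A `circ_seq`, a list of them, or a named character vector.
#' @param path Output file.
#' @param width Line width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (inherits(seqs, "circ_seq")) seqs <- list(seqs)
  if (is.character(seqs)) {
    ids <- names(seqs) %||% paste0("seq", seq_along(seqs))
    vals <- unname(seqs)
  } else {
    ids <- purrr::map_chr(seqs, "id")
    vals <- purrr::map_chr(seqs, as.character)
  }
  set <- Biostrings::BStringSet(setNames(vals, ids))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

FEATURE_TYPES <- c("protein_coding", "rRNA", "tRNA", "control_region")

#' Read a gene feature table
#'
#' Accepts a simple TSV with a header containing at least `name`, `start`,
#' `end` (optional `ftype`, `strand`, `phase`), or a GFF3 file
#' (`.gff`/`.gff3` suffix). Coordinates are 1-based inclusive on the
#' reference heavy strand. Origin-spanning features are represented as two
#' parts sharing a `name`.
#'
#' @param path Feature file.
#' @return Tibble with columns `name`, `ftype`, `start`, `end`, `strand`,
#'   `phase`.
#' @export
read_feature_table <- function(path) {
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    ft <- read_gff3_features(path)
  } else {
    ft <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
    if (!all(c("name", "start", "end") %in% names(ft))) {
      abort("feature TSV needs at least columns: name, start, end")
    }
  }
  ft <- as_tibble(ft)
  if (is.null(ft$ftype)) ft$ftype <- "protein_coding"
  if (is.null(ft$strand)) ft$strand <- "+"
  if (is.null(ft$phase)) ft$phase <- 0L
  ft$phase[is.na(ft$phase)] <- 0L
  ft <- mutate(ft,
    start = as.integer(.data$start), end = as.integer(.data$end),
    phase = as.integer(.data$phase)
  )
  bad <- !ft$ftype %in% FEATURE_TYPES
  if (any(bad)) abort(sprintf("unknown feature type(s): %s",
                              paste(unique(ft$ftype[bad]), collapse = ", ")))
  if (any(ft$start < 1L | ft$end < ft$start)) {
    abort("feature coordinates must satisfy 1 <= start <= end")
  }
  select(ft, "name", "ftype", "start", "end", "strand", "phase")
}

# Minimal GFF3 column reader for gene annotations (types mapped onto the
# four feature classes used here).
read_gff3_features <- function(path) {
  gff <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         col_names = c("seqid", "source", "type", "start",
                                       "end", "score", "strand", "phase",
                                       "attributes"))
  type_map <- c(gene = "protein_coding", CDS = "protein_coding",
                mRNA = "protein_coding", rRNA = "rRNA", tRNA = "tRNA",
                D_loop = "control_region", region = "control_region")
  gff <- filter(gff, .data$type %in% names(type_map))
  nm <- stringr::str_match(gff$attributes, "(?:Name|gene|ID)=([^;]+)")[, 2]
  tibble(
    name = ifelse(is.na(nm), gff$type, nm),
    ftype = unname(type_map[gff$type]),
    start = gff$start, end = gff$end,
    strand = ifelse(gff$strand == "-", "-", "+"),
    phase = suppressWarnings(as.integer(gff$phase))
  )
}

#' Read an aligned FASTA file
#'
#' All records must have identical (gapped) length; gaps are `-`, missing
#' data is `N` (distinct from gaps).
#'
#' @param path Aligned FASTA.
#' @return A `seq_alignment`: named character vector of gapped rows with
#'   attribute `columns`.
#' @export
read_alignment <- function(path) {
  set <- Biostrings::readBStringSet(path)
  rows <- toupper(as.character(set))
  names(rows) <- sub("\\s.*$", "", names(set))
  new_alignment(rows)
}

#' Construct an alignment from gapped rows
#' @param rows Named character vector of equal-length gapped sequences.
#' @export
new_alignment <- function(rows) {
  w <- unique(nchar(rows))
  if (length(w) != 1L) {
    abort(sprintf("alignment rows have unequal lengths: %s",
                  paste(w, collapse = ", ")))
  }
  assert_bases(rows, "alignment", allow = "ACGTN-")
  structure(rows, columns = w, class = "seq_alignment")
}

#' @export
print.seq_alignment <- function(x, ...) {
  cat(sprintf("<seq_alignment> %d sequences x %d columns\n",
              length(x), attr(x, "columns")))
  invisible(x)
}

#' Read a phylogenetic tree (newick)
#'
#' @param path Newick file.
#' @param alignment Optional `seq_alignment`; tip labels are cross-checked
#'   against alignment ids and a mismatch raises an error.
#' @return An `ape::phylo` tree.
#' @export
read_tree <- function(path, alignment = NULL) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) abort(sprintf("could not parse newick in '%s'", path))
  if (!is.null(alignment)) {
    missing_ids <- setdiff(tr$tip.label, names(alignment))
    extra_ids <- setdiff(names(alignment), tr$tip.label)
    if (length(missing_ids) || length(extra_ids)) {
      abort(sprintf(
        "tree/alignment id mismatch (tips not in alignment: %s; rows not in tree: %s)",
        paste(missing_ids, collapse = ",") %||% "-",
        paste(extra_ids, collapse = ",") %||% "-"
      ))
    }
  }
  tr
}
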