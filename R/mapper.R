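#' Build an exact k-mer seed index over a circular reference
#'
#' The reference is extended by its first `max_read_len` bases so that reads
#' spanning the origin seed normally; indexed positions are reported in the
#' unrotated 1..L frame.
#'
#' @param ref A [circ_seq()].
#' @param k Seed k-mer size. The default (12) balances the 20-bp minimum
#'   read length against the random-hit rate on a ~17-kb genome.
#' @param max_read_len Longest read the index must accommodate.
#' @return A `read_index` object.
#' @export
build_index <- function(ref, k = 12L, max_read_len = 75L) {
  L <- seq_length(ref)
  if (k > L) abort("k-mer size exceeds reference length")
  refext <- if (ref$circular) {
    paste0(as.character(ref), substr(as.character(ref), 1L, max_read_len - 1L))
  } else {
    as.character(ref)
  }
  n_start <- if (ref$circular) L else L - k + 1L
  starts <- seq_len(n_start)
  kmers <- substring(refext, starts, starts + k - 1L)
  env <- new.env(hash = TRUE, size = as.integer(2L * n_start), parent = emptyenv())
  list2env(split(starts, kmers), envir = env)
  structure(list(env = env, k = as.integer(k), L = L, ref_id = ref$id,
                 circular = ref$circular, refext = refext,
                 refraw = charToRaw(refext),
                 max_read_len = as.integer(max_read_len)),
            class = "read_index")
}

#' Look up the reference positions of a k-mer
#' @param index A `read_index`.
#' @param kmer Character string of length `index$k`.
#' @return Integer vector of 1-based start positions (possibly empty).
#' @export
index_hits <- function(index, kmer) {
  stopifnot(nchar(kmer) == index$k)
  get0(toupper(kmer), envir = index$env, ifnotfound = integer(0))
}

RAW_C <- charToRaw("C"); RAW_G <- charToRaw("G")
RAW_T <- charToRaw("T"); RAW_A <- charToRaw("A")

#' Map reads onto a circular reference
#'
#' Ungapped seed-and-extend placement: exact k-mer seeds at three offsets
#' per orientation propose candidate diagonals, every candidate is scored
#' over the full read length, and the best placement is kept. A read is
#' dropped as unmapped when its best placement has more than
#' `ceil(max_mismatch_frac * length)` mismatches (the fractional-mismatch
#' rule of classical short-read aligners). A placement is flagged unique
#' when its score exceeds the runner-up by at least `uniqueness_margin`
#' (the stand-in for a Phred-scaled mapping-quality cutoff).
#' `damage_tolerant` halves the penalty of C(ref)->T(read) and
#' G(ref)->A(read) mismatches, the signatures of cytosine deamination.
#'
#' @param reads Character vector of read sequences (named by read id) or a
#'   tibble with `read_id` and `seq`.
#' @param index A [build_index()] object.
#' @param max_mismatch_frac Maximum mismatch fraction of read length.
#' @param damage_tolerant Halve deamination-type mismatch penalties?
#' @param min_read_len Reads shorter than this are not mapped.
#' @param uniqueness_margin Minimum best-minus-second-best score difference.
#' @param mismatch_penalty Score penalty per (non-damage) mismatch; score =
#'   matches - penalty * mismatches.
#' @return Tibble of alignments: `read_id`, `ref_start` (1-based, unrotated
#'   frame), `strand`, `length`, `read_seq`, `score`, `mismatches`,
#'   `unique`, `duplicate`. Attributes `n_input`, `n_short`, `n_unmapped`
#'   carry the bookkeeping.
#' @export
map_reads <- function(reads, index, max_mismatch_frac = 0.05,
                      damage_tolerant = FALSE, min_read_len = 20L,
                      uniqueness_margin = 5, mismatch_penalty = 4) {
  if (is.data.frame(reads)) {
    ids <- reads$read_id
    reads <- reads$seq
  } else {
    ids <- names(reads) %||% sprintf("read%06d", seq_along(reads))
    reads <- unname(reads)
  }
  n_input <- length(reads)
  lens <- nchar(reads)
  short <- lens < min_read_len | lens > index$max_read_len
  ids <- ids[!short]; reads <- toupper(reads[!short]); lens <- lens[!short]
  n <- length(reads)
  k <- index$k; L <- index$L
  empty <- tibble(read_id = character(), ref_start = integer(),
                  strand = character(), length = integer(),
                  read_seq = character(), score = double(),
                  mismatches = integer(), unique = logical(),
                  duplicate = logical())
  if (n == 0L) {
    return(structure(empty, n_input = n_input, n_short = sum(short),
                     n_unmapped = 0L))
  }
  revs <- revcomp(reads)
  max_start <- nchar(index$refext) - lens + 1L

  # Candidate diagonals from seeds at three offsets per orientation;
  # encoded as +start for forward, -start for reverse placements.
  cand <- vector("list", n)
  for (ori in 1:2) {
    rs <- if (ori == 1L) reads else revs
    offs <- list(rep(1L, n), pmax(1L, (lens - k) %/% 2L + 1L), lens - k + 1L)
    for (off in offs) {
      km <- substring(rs, off, off + k - 1L)
      hits <- mget(km, envir = index$env, ifnotfound = list(integer(0)))
      for (i in seq_len(n)) {
        h <- hits[[i]]
        if (length(h)) {
          s <- h - off[i] + 1L
          if (index$circular) s <- wrap1(s, L)
          s <- s[s >= 1L & s <= max_start[i]]
          if (length(s)) cand[[i]] <- c(cand[[i]], if (ori == 2L) -s else s)
        }
      }
    }
  }

  raw_f <- lapply(reads, charToRaw)
  raw_r <- lapply(revs, charToRaw)
  refraw <- index$refraw
  half <- mismatch_penalty / 2

  out_start <- integer(n); out_strand <- character(n)
  out_score <- double(n); out_mm <- integer(n); out_uni <- logical(n)
  mapped <- logical(n)
  for (i in seq_len(n)) {
    cc <- unique(cand[[i]])
    if (!length(cc)) next
    l <- lens[i]
    scores <- double(length(cc)); mms <- integer(length(cc))
    for (j in seq_along(cc)) {
      s <- abs(cc[j])
      q <- if (cc[j] < 0L) raw_r[[i]] else raw_f[[i]]
      r <- refraw[s:(s + l - 1L)]
      mm <- r != q
      n_mm <- sum(mm)
      if (damage_tolerant && n_mm) {
        n_dmg <- sum((r[mm] == RAW_C & q[mm] == RAW_T) |
                       (r[mm] == RAW_G & q[mm] == RAW_A))
        scores[j] <- (l - n_mm) - mismatch_penalty * (n_mm - n_dmg) - half * n_dmg
      } else {
        scores[j] <- (l - n_mm) - mismatch_penalty * n_mm
      }
      mms[j] <- n_mm
    }
    ord <- order(-scores, abs(cc), cc < 0L)  # deterministic tie-break
    best <- ord[1L]
    if (mms[best] > ceiling(max_mismatch_frac * l)) next
    mapped[i] <- TRUE
    out_start[i] <- abs(cc[best])
    out_strand[i] <- if (cc[best] < 0L) "-" else "+"
    out_score[i] <- scores[best]
    out_mm[i] <- mms[best]
    out_uni[i] <- length(cc) == 1L ||
      (scores[best] - scores[ord[2L]]) >= uniqueness_margin
  }

  res <- tibble(
    read_id = ids[mapped],
    ref_start = if (index$circular) wrap1(out_start[mapped], L) else out_start[mapped],
    strand = out_strand[mapped],
    length = lens[mapped],
    read_seq = reads[mapped],
    score = out_score[mapped],
    mismatches = out_mm[mapped],
    unique = out_uni[mapped],
    duplicate = FALSE
  )
  structure(res, n_input = n_input, n_short = sum(short),
            n_unmapped = sum(!mapped))
}

#' Map a single read
#' @inheritParams map_reads
#' @param read One read sequence.
#' @return One-row alignment tibble, or a zero-row tibble if unmapped.
#' @export
map_read <- function(read, index, ...) {
  map_reads(setNames(read, "read1"), index, ...)
}

#' Flag PCR-duplicate alignments
#'
#' Among alignments sharing (`ref_start`, `length`, `strand`) — the
#' single-end analogue of the classical duplicate criterion — all but the
#' highest-scoring one are flagged, with deterministic tie-breaking by read
#' id. The last representative of a placement class is never flagged.
#'
#' @param alignments Alignment tibble from [map_reads()].
#' @return Same tibble with the `duplicate` flag set.
#' @export
mark_duplicates <- function(alignments) {
  if (nrow(alignments) == 0L) return(alignments)
  alignments |>
    group_by(.data$ref_start, .data$length, .data$strand) |>
    mutate(duplicate = row_number(order(-.data$score, .data$read_id)) > 1L) |>
    ungroup()
}

#' Filter alignments on uniqueness and duplicate flags
#'
#' @param alignments Alignment tibble.
#' @param require_unique Drop non-unique placements?
#' @param drop_duplicates Drop flagged duplicates?
#' @return Filtered tibble; attributes `n_retained` and `n_dropped` report
#'   the counts.
#' @export
filter_alignments <- function(alignments, require_unique = TRUE,
                              drop_duplicates = TRUE) {
  keep <- rep(TRUE, nrow(alignments))
  if (require_unique) keep <- keep & alignments$unique
  if (drop_duplicates) keep <- keep & !alignments$duplicate
  out <- alignments[keep, ]
  structure(out, n_retained = sum(keep), n_dropped = sum(!keep))
}

# Read bases in reference orientation (reverse complement for - strand).
aln_ref_oriented <- function(alignments) {
  s <- alignments$read_seq
  neg <- alignments$strand == "-"
  s[neg] <- revcomp(s[neg])
  s
}

#' Write alignments as minimal SAM
#'
#' Emits `@HD`/`@SQ` headers, ungapped CIGAR (`<L>M`), FLAG bits for strand
#' (16) and duplicate (1024), and MAPQ 37/0 by uniqueness. Positions of
#' origin-spanning alignments are written in the extended frame (POS may
#' exceed LN by up to a read length).
#'
#' @param alignments Alignment tibble.
#' @param index The [build_index()] used for mapping (reference name/length).
#' @param path Output SAM path.
#' @export
write_sam <- function(alignments, index, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unknown",
               sprintf("@SQ\tSN:%s\tLN:%d", index$ref_id, index$L)), con)
  if (nrow(alignments)) {
    flag <- ifelse(alignments$strand == "-", 16L, 0L) +
      ifelse(alignments$duplicate, 1024L, 0L)
    writeLines(sprintf(
      "%s\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t*",
      alignments$read_id, flag, index$ref_id, alignments$ref_start,
      ifelse(alignments$unique, 37L, 0L), alignments$length,
      aln_ref_oriented(alignments)), con)
  }
  invisible(path)
}

#' Read ungapped alignments from a SAM file
#'
#' Accepts externally produced single-end ungapped alignments (CIGAR
#' `<L>M`); others are skipped with a warning.
#'
#' @param path SAM path.
#' @return Alignment tibble in the [map_reads()] layout (scores are
#'   recomputed as `length`; mismatches `NA`).
#' @export
read_sam <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0L) {
    return(map_reads(character(0), build_index(circ_seq("ACGTACGTACGTACGT"), k = 4)))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  ok <- vapply(f, function(x) grepl("^[0-9]+M$", x[6]), TRUE)
  if (any(!ok)) warn(sprintf("skipping %d non-ungapped SAM records", sum(!ok)))
  f <- f[ok]
  flag <- as.integer(vapply(f, `[`, "", 2))
  seq_aln <- vapply(f, `[`, "", 10)
  neg <- bitwAnd(flag, 16L) > 0L
  read_seq <- seq_aln
  read_seq[neg] <- revcomp(read_seq[neg])
  tibble(
    read_id = vapply(f, `[`, "", 1),
    ref_start = as.integer(vapply(f, `[`, "", 4)),
    strand = ifelse(neg, "-", "+"),
    length = nchar(seq_aln),
    read_seq = read_seq,
    score = as.double(nchar(seq_aln)),
    mismatches = NA_integer_,
    unique = as.integer(vapply(f, `[`, "", 5)) > 0L,
    duplicate = bitwAnd(flag, 1024L) > 0L
  )
}
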