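#' Per-site base counts over a reference
#'
#' Builds the per-site pileup of filtered, duplicate-free ungapped
#' alignments on the reference frame. Origin-spanning alignments contribute
#' to both arcs of a circular reference. Reference homopolymer runs are
#' scanned at build time: every alignment fully spanning a run (covering
#' one flanking base on each side) votes on the observed run length in its
#' read bases, the evidence consumed by [call_homopolymer_indels()].
#'
#' @param alignments Alignment tibble ([map_reads()] layout).
#' @param ref Reference [circ_seq()].
#' @param min_run Minimum reference homopolymer length to collect indel
#'   evidence for.
#' @return A `pileup` object: base-count matrix, depth vector, and
#'   homopolymer vote table.
#' @export
pileup <- function(alignments, ref, min_run = 4L) {
  L <- seq_length(ref)
  counts <- matrix(0L, nrow = L, ncol = 4L,
                   dimnames = list(NULL, DNA_BASES))
  if (nrow(alignments)) {
    ends <- alignments$ref_start + alignments$length - 1L
    if (!ref$circular && any(ends > L)) {
      abort("alignment extends beyond the end of a non-circular reference")
    }
    lens <- alignments$length
    sites <- wrap1(sequence(lens, from = alignments$ref_start), L)
    bases <- strsplit(paste(aln_ref_oriented(alignments), collapse = ""),
                      NULL)[[1]]
    bi <- match(bases, DNA_BASES)
    ok <- !is.na(bi)
    tabs <- tabulate(sites[ok] + L * (bi[ok] - 1L), nbins = 4L * L)
    counts[] <- tabs
  }
  votes <- hp_votes(alignments, ref, min_run)
  structure(list(counts = counts, depth = as.integer(rowSums(counts)),
                 L = L, ref_id = ref$id, circular = ref$circular,
                 hp_votes = votes, n_alignments = nrow(alignments)),
            class = "pileup")
}

#' @export
print.pileup <- function(x, ...) {
  cat(sprintf("<pileup> %s: %s sites, %d alignments, mean depth %.1f\n",
              x$ref_id, format(x$L, big.mark = ","), x$n_alignments,
              mean(x$depth)))
  invisible(x)
}

#' @rdname pileup
#' @param x A `pileup`.
#' @param ... Unused.
#' @export
tidy.pileup <- function(x, ...) {
  as_tibble(x$counts) |>
    mutate(site = dplyr::row_number(), depth = x$depth) |>
    select("site", dplyr::all_of(DNA_BASES), "depth")
}

# Homopolymer-run votes from fully spanning alignments.
hp_votes <- function(alignments, ref, min_run = 4L) {
  empty <- tibble(run_id = integer(), start = integer(), end = integer(),
                  base = character(), ref_len = integer(),
                  read_id = character(), observed = integer())
  L <- seq_length(ref)
  r <- rle(strsplit(as.character(ref), NULL)[[1]])
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  sel <- r$lengths >= min_run & r$values %in% DNA_BASES &
    run_start > 1L & run_end < L  # origin-adjacent runs not scanned
  if (!any(sel) || nrow(alignments) == 0L) return(empty)
  runs <- tibble(start = run_start[sel], end = run_end[sel],
                 base = r$values[sel], ref_len = r$lengths[sel])
  runs$run_id <- seq_len(nrow(runs))
  aln_start <- alignments$ref_start
  aln_end <- aln_start + alignments$length - 1L
  oriented <- aln_ref_oriented(alignments)
  out <- vector("list", nrow(runs))
  for (i in seq_len(nrow(runs))) {
    rs <- runs$start[i]; re <- runs$end[i]; b <- runs$base[i]
    ref_next <- substr(as.character(ref), re + 1L, re + 1L)
    for (shift in if (ref$circular) c(0L, L) else 0L) {
      span <- which(aln_start <= rs + shift - 1L & aln_end >= re + shift + 1L)
      if (!length(span)) next
      o <- rs + shift - aln_start[span] + 1L
      tails <- substring(oriented[span], o)
      obs <- nchar(sub(sprintf("^(%s*).*$", b), "\\1", tails))
      # a non-reference run length is only believable when the read
      # continues with the base that follows the run in the reference
      # (the shift signature of a true length change); run-edge
      # substitutions fail this and are left to the consensus caller
      after <- substr(tails, obs + 1L, obs + 1L)
      keep <- obs > 0L &
        (obs == runs$ref_len[i] | (nzchar(after) & after == ref_next))
      if (any(keep)) {
        out[[i]] <- tibble(run_id = runs$run_id[i], start = rs, end = re,
                           base = b, ref_len = runs$ref_len[i],
                           read_id = alignments$read_id[span][keep],
                           observed = as.integer(obs[keep]))
      }
    }
  }
  bind_rows(empty, out)
}

#' Call a majority-rule consensus from a pileup
#'
#' A site is called as the strict-majority base when its depth is at least
#' `min_depth` (default 3); it is `N` when depth is below the threshold or
#' the top two base counts tie.
#'
#' @param p A [pileup()].
#' @param min_depth Minimum read depth for a call.
#' @return A `consensus_result` with elements `sequence`,
#'   `called_fraction`, `coverage_fraction` (depth > 0), `mask_intervals`,
#'   `indel_candidates`.
#' @export
call_consensus <- function(p, min_depth = 3L) {
  m <- p$counts
  L <- p$L
  top <- max.col(m, ties.method = "first")
  mx <- m[cbind(seq_len(L), top)]
  m2 <- m
  m2[cbind(seq_len(L), top)] <- -1L
  second <- m2[cbind(seq_len(L), max.col(m2, ties.method = "first"))]
  base <- DNA_BASES[top]
  base[p$depth < min_depth | second == mx] <- "N"
  new_consensus(paste(base, collapse = ""), p$ref_id, min_depth,
                coverage_fraction = mean(p$depth > 0))
}

new_consensus <- function(sequence, ref_id, min_depth, coverage_fraction = NA,
                          mask_intervals = NULL, indel_candidates = NULL) {
  structure(list(
    sequence = sequence, ref_id = ref_id, min_depth = min_depth,
    called_fraction = 1 - stringr::str_count(sequence, "N") / nchar(sequence),
    coverage_fraction = coverage_fraction,
    mask_intervals = mask_intervals %||%
      tibble(start = integer(), end = integer(), reason = character()),
    indel_candidates = indel_candidates %||% empty_indel_candidates()
  ), class = "consensus_result")
}

empty_indel_candidates <- function() {
  tibble(site = integer(), base = character(), ref_len = integer(),
         alt_len = integer(), ref_allele = character(),
         alt_allele = character(), support = integer(),
         spanning = integer(), flag = character())
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf(
    "<consensus_result> %s: %s bp, %.2f%% called (min depth %d), %d mask interval(s), %d indel candidate(s)\n",
    x$ref_id, format(nchar(x$sequence), big.mark = ","),
    100 * x$called_fraction, x$min_depth, nrow(x$mask_intervals),
    nrow(x$indel_candidates)))
  invisible(x)
}

#' @rdname call_consensus
#' @param x A `consensus_result`.
#' @param ... Unused.
#' @export
glance.consensus_result <- function(x, ...) {
  tibble(length = nchar(x$sequence), called_fraction = x$called_fraction,
         coverage_fraction = x$coverage_fraction, min_depth = x$min_depth,
         n_mask_intervals = nrow(x$mask_intervals),
         n_indel_candidates = nrow(x$indel_candidates))
}

#' Two-pass consensus with rotation-based recovery of terminal positions
#'
#' Maps the reads twice — once against the reference, once against the
#' reference rotated by `rotation_bp` (its first `rotation_bp` bases cut
#' and appended) — and merges the consensus calls: sites within
#' `rotation_bp` of the origin junction are taken from the rotated pass,
#' where reads spanning the origin align contiguously. Sites where the two
#' passes make conflicting non-N calls are set to `N` with a warning.
#'
#' @param reads Read tibble (`read_id`, `seq`) or character vector.
#' @param ref Circular reference [circ_seq()].
#' @param rotation_bp Rotation amount (default 200; 0 reduces to a single
#'   pass).
#' @param min_depth Consensus depth threshold.
#' @param k Seed size for [build_index()].
#' @param min_run Homopolymer scan threshold for [pileup()].
#' @param ... Further arguments to [map_reads()].
#' @return A `consensus_result`; the pass-1 filtered alignments and pileup
#'   are attached as attributes `alignments` and `pileup`.
#' @export
recover_terminal <- function(reads, ref, rotation_bp = 200L, min_depth = 3L,
                             k = 12L, min_run = 4L, ...) {
  if (!ref$circular) abort("terminal recovery requires a circular reference")
  L <- seq_length(ref)
  one_pass <- function(r) {
    idx <- build_index(r, k = k)
    aln <- filter_alignments(mark_duplicates(map_reads(reads, idx, ...)))
    p <- pileup(aln, r, min_run = min_run)
    list(aln = aln, p = p, cons = call_consensus(p, min_depth))
  }
  pass1 <- one_pass(ref)
  if (rotation_bp == 0L) {
    out <- pass1$cons
    attr(out, "alignments") <- pass1$aln
    attr(out, "pileup") <- pass1$p
    return(out)
  }
  pass2 <- one_pass(rotate(ref, rotation_bp))
  seq2 <- rotate(circ_seq(pass2$cons$sequence, id = ref$id), L - rotation_bp)
  b1 <- strsplit(pass1$cons$sequence, NULL)[[1]]
  b2 <- strsplit(as.character(seq2), NULL)[[1]]
  junction <- c(seq_len(min(rotation_bp, L)),
                seq.int(max(L - rotation_bp + 1L, 1L), L))
  merged <- b1
  merged[junction] <- b2[junction]
  conflict <- b1 != "N" & b2 != "N" & b1 != b2
  if (any(conflict)) {
    warn(sprintf("%d site(s) conflict between rotation passes; set to N",
                 sum(conflict)))
    merged[conflict] <- "N"
  }
  out <- new_consensus(paste(merged, collapse = ""), ref$id, min_depth,
                       coverage_fraction = mean(pass1$p$depth > 0 |
                                                  b2 != "N"))
  attr(out, "alignments") <- pass1$aln
  attr(out, "pileup") <- pass1$p
  out
}

#' Mask repeat regions and manual intervals in a consensus
#'
#' Automatically masks any perfect tandem repeat (unit length 1-10,
#' homopolymers included) whose total span is at least `read_len_max` —
#' such repeats cannot be bridged by any single read and their consensus is
#' unreliable — plus any manually specified intervals (overlapping manual
#' intervals are merged, not rejected). Masked sites become `N`.
#'
#' @param result A `consensus_result`.
#' @param ref Reference [circ_seq()] (repeat detection runs on the
#'   reference).
#' @param read_len_max Maximum read length (default 75).
#' @param manual_intervals Tibble/data frame with `start`, `end` (1-based
#'   inclusive), or `NULL`.
#' @param max_unit Largest tandem repeat unit scanned.
#' @return The updated `consensus_result`.
#' @export
mask_regions <- function(result, ref, read_len_max = 75L,
                         manual_intervals = NULL, max_unit = 10L) {
  L <- nchar(result$sequence)
  auto <- find_long_repeats(ref, read_len_max, max_unit)
  man <- if (!is.null(manual_intervals) && nrow(manual_intervals)) {
    merge_intervals(tibble(start = pmax(1L, as.integer(manual_intervals$start)),
                           end = pmin(L, as.integer(manual_intervals$end)))) |>
      mutate(reason = "manual")
  } else {
    tibble(start = integer(), end = integer(), reason = character())
  }
  intervals <- bind_rows(auto, man)
  if (nrow(intervals)) {
    chars <- strsplit(result$sequence, NULL)[[1]]
    for (i in seq_len(nrow(intervals))) {
      chars[intervals$start[i]:intervals$end[i]] <- "N"
    }
    result <- new_consensus(paste(chars, collapse = ""), result$ref_id,
                            result$min_depth, result$coverage_fraction,
                            mask_intervals = bind_rows(result$mask_intervals,
                                                       intervals),
                            indel_candidates = result$indel_candidates)
  }
  result
}

# Perfect tandem repeats (unit 1..max_unit) with span >= read_len_max.
find_long_repeats <- function(ref, read_len_max, max_unit = 10L) {
  chars <- strsplit(as.character(ref), NULL)[[1]]
  L <- length(chars)
  out <- list()
  for (u in seq_len(min(max_unit, L - 1L))) {
    eq <- chars[seq_len(L - u)] == chars[(u + 1L):L]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    hit <- r$values & (r$lengths + u) >= read_len_max
    if (any(hit)) {
      out[[length(out) + 1L]] <- tibble(start = starts[hit],
                                        end = ends[hit] + u)
    }
  }
  if (!length(out)) {
    return(tibble(start = integer(), end = integer(), reason = character()))
  }
  merge_intervals(bind_rows(out)) |> mutate(reason = "repeat")
}

# Merge overlapping/adjacent 1-based inclusive intervals.
merge_intervals <- function(iv) {
  if (nrow(iv) <= 1L) return(iv)
  iv <- arrange(iv, .data$start, .data$end)
  out_start <- iv$start[1]; out_end <- iv$end[1]
  res <- list()
  for (i in 2:nrow(iv)) {
    if (iv$start[i] <= out_end + 1L) {
      out_end <- max(out_end, iv$end[i])
    } else {
      res[[length(res) + 1L]] <- c(out_start, out_end)
      out_start <- iv$start[i]; out_end <- iv$end[i]
    }
  }
  res[[length(res) + 1L]] <- c(out_start, out_end)
  m <- do.call(rbind, res)
  tibble(start = m[, 1], end = m[, 2])
}

#' Call homopolymer length-change candidates from spanning reads
#'
#' For each reference homopolymer with vote evidence in the pileup, an
#' indel candidate is emitted when at least `min_support` spanning reads
#' agree on the same non-reference run length and *no* spanning read
#' supports the reference length. Candidates are flagged
#' `"manual-confirmation"` and never applied automatically (see
#' [apply_indels()]), mirroring how such calls are made by eye in practice.
#'
#' @param p A [pileup()] (carries the homopolymer votes).
#' @param ref Reference [circ_seq()] (unused beyond id checks; kept for a
#'   stable signature).
#' @param min_support Minimum agreeing spanning reads (default 2).
#' @return Tibble of candidates (`site` = run start, `ref_len`, `alt_len`,
#'   alleles, `support`, `spanning`, `flag`).
#' @export
call_homopolymer_indels <- function(p, ref = NULL, min_support = 2L) {
  v <- p$hp_votes
  if (nrow(v) == 0L) return(empty_indel_candidates())
  v |>
    group_by(.data$run_id, .data$start, .data$base, .data$ref_len) |>
    summarise(
      spanning = dplyr::n(),
      ref_support = sum(.data$observed == .data$ref_len[1]),
      alt_len = {
        alt <- .data$observed[.data$observed != .data$ref_len[1]]
        if (length(alt)) as.integer(names(sort(-table(alt)))[1]) else NA_integer_
      },
      support = sum(.data$observed == alt_len),
      .groups = "drop"
    ) |>
    filter(!is.na(.data$alt_len), .data$ref_support == 0L,
           .data$support >= min_support) |>
    mutate(site = .data$start,
           ref_allele = strrep(.data$base, .data$ref_len),
           alt_allele = strrep(.data$base, .data$alt_len),
           flag = "manual-confirmation") |>
    select("site", "base", "ref_len", "alt_len", "ref_allele",
           "alt_allele", "support", "spanning", "flag")
}

#' Apply homopolymer indel candidates to a consensus sequence
#'
#' Rewrites each candidate run to its alternate length and returns the
#' edited sequence with a coordinate map shifting downstream positions.
#'
#' @param result A `consensus_result` (or a bare sequence string).
#' @param candidates Candidate tibble from [call_homopolymer_indels()].
#' @return List with `sequence` (character) and `map` (tibble `original`,
#'   `mutated`, NA for removed positions).
#' @export
apply_indels <- function(result, candidates) {
  s <- if (inherits(result, "consensus_result")) result$sequence else result
  L <- nchar(s)
  keep_rep <- rep(list(NULL), L)
  chars <- strsplit(s, NULL)[[1]]
  out <- as.list(chars)
  for (i in seq_len(nrow(candidates))) {
    cd <- candidates[i, ]
    run <- cd$site:(cd$site + cd$ref_len - 1L)
    d <- cd$alt_len - cd$ref_len
    if (d < 0L) {
      out[run[(cd$ref_len + d + 1L):cd$ref_len]] <- list("")
    } else if (d > 0L) {
      out[[run[cd$ref_len]]] <- strrep(cd$base, 1L + d)
    }
  }
  lens <- vapply(out, nchar, 1L)
  map <- tibble(original = seq_len(L),
                mutated = ifelse(lens == 0L, NA_integer_,
                                 as.integer(cumsum(lens) - lens + 1L)))
  list(sequence = paste(unlist(out), collapse = ""), map = map)
}

#' Write mask intervals as BED
#'
#' Internal coordinates are 1-based inclusive; on disk BED is 0-based
#' half-open.
#'
#' @param result A `consensus_result` (or an interval tibble).
#' @param path Output path.
#' @param chrom Chromosome/sequence name.
#' @export
write_mask_bed <- function(result, path, chrom = NULL) {
  iv <- if (inherits(result, "consensus_result")) result$mask_intervals else result
  chrom <- chrom %||%
    (if (inherits(result, "consensus_result")) result$ref_id else "seq")
  df <- tibble(chrom = chrom, start = iv$start - 1L, end = iv$end,
               name = iv$reason %||% "mask")
  readr::write_tsv(df, path, col_names = FALSE)
  invisible(path)
}

#' Read mask intervals from BED (back to 1-based inclusive)
#' @param path BED path.
#' @export
read_mask_bed <- function(path) {
  df <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "name"),
                        show_col_types = FALSE)
  tibble(start = df$start + 1L, end = df$end,
         reason = df$name %||% "mask")
}
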