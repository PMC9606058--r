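#' Classify a substitution as transition or transversion
#'
#' Purine<->purine (A/G) or pyrimidine<->pyrimidine (C/T) changes are
#' transitions; all others are transversions. Vectorised.
#'
#' @param ref_base,alt_base Nucleotides in `{A,C,G,T}` (case-insensitive),
#'   pairwise different.
#' @return Character vector of `"transition"`/`"transversion"`.
#' @export
classify_ts_tv <- function(ref_base, alt_base) {
  ref_base <- toupper(ref_base); alt_base <- toupper(alt_base)
  stopifnot(all(ref_base %in% DNA_BASES), all(alt_base %in% DNA_BASES))
  if (any(ref_base == alt_base)) abort("bases must differ for ts/tv classification")
  purine <- c("A", "G")
  same_class <- (ref_base %in% purine) == (alt_base %in% purine)
  ifelse(same_class, "transition", "transversion")
}

#' Translate codons under a selectable genetic code
#'
#' The default is the vertebrate mitochondrial code (NCBI translation
#' table 2: `TGA` = Trp, `ATA` = Met, `AGA`/`AGG` = Stop); the standard
#' code (`"1"`) is selectable for non-mitochondrial use. Codons containing
#' characters outside `{A,C,G,T}` translate to `NA`.
#'
#' @param codons Character vector of triplets.
#' @param code NCBI genetic code id (`"2"` vertebrate mitochondrial,
#'   `"1"` standard).
#' @return Single-letter amino acids (`*` = stop).
#' @export
mt_translate <- function(codons, code = "2") {
  tab <- Biostrings::getGeneticCode(code)
  out <- unname(tab[toupper(codons)])
  out[is.na(out)] <- NA_character_
  out
}

# Coding-orientation CDS of a (possibly multi-part) feature; parts share a
# name and are concatenated in coding order. Returns the CDS string plus a
# vector mapping CDS position -> genomic site.
cds_with_map <- function(ref, parts) {
  parts <- arrange(parts, .data$start)
  strand <- parts$strand[1]
  segs <- purrr::map(seq_len(nrow(parts)), function(i) {
    parts$start[i]:parts$end[i]
  })
  sites <- unlist(segs)
  s <- paste(substring(as.character(ref), parts$start, parts$end),
             collapse = "")
  if (strand == "-") {
    s <- revcomp(s)
    sites <- rev(sites)
  }
  phase <- parts$phase[1] %||% 0L
  if (is.na(phase)) phase <- 0L
  if (phase > 0L) {
    s <- substr(s, phase + 1L, nchar(s))
    sites <- sites[-seq_len(phase)]
  }
  list(cds = s, sites = sites, strand = strand)
}

#' Annotate a substitution with codon and amino-acid change
#'
#' Looks up the protein-coding feature containing `site`, extracts the
#' codon in coding orientation (strand- and phase-aware; reported codons
#' are coding-strand even when the reported bases are reference-strand,
#' as for light-strand genes such as *ND6*), substitutes the alternate
#' base, and translates both codons.
#'
#' @param site 1-based reference coordinate.
#' @param ref_seq Reference [circ_seq()].
#' @param alt_base Alternate base on the reference strand.
#' @param features Feature tibble ([read_feature_table()] layout).
#' @param code Genetic code id (default vertebrate mitochondrial).
#' @return One-row tibble: `feature`, `codon_position` (1-3), `ref_codon`,
#'   `alt_codon`, `ref_aa`, `alt_aa`, `synonymous`. All fields `NA` (with
#'   `feature` set to the overlapping non-coding feature or
#'   `"intergenic/control"`) outside protein-coding features.
#' @export
annotate_codon <- function(site, ref_seq, alt_base, features, code = "2") {
  non_coding <- function(name) {
    tibble(feature = name, codon_position = NA_integer_,
           ref_codon = NA_character_, alt_codon = NA_character_,
           ref_aa = NA_character_, alt_aa = NA_character_,
           synonymous = NA)
  }
  hit <- filter(features, .data$start <= site, .data$end >= site)
  if (nrow(hit) == 0L) return(non_coding("intergenic/control"))
  coding <- filter(hit, .data$ftype == "protein_coding")
  if (nrow(coding) == 0L) return(non_coding(hit$name[1]))
  parts <- filter(features, .data$name == coding$name[1],
                  .data$ftype == "protein_coding")
  cm <- cds_with_map(ref_seq, parts)
  p <- match(site, cm$sites)
  if (is.na(p)) return(non_coding(coding$name[1]))  # inside trimmed phase
  codon_position <- ((p - 1L) %% 3L) + 1L
  c0 <- p - codon_position + 1L
  if (c0 + 2L > nchar(cm$cds)) return(non_coding(coding$name[1]))  # partial codon
  ref_codon <- substr(cm$cds, c0, c0 + 2L)
  alt <- toupper(alt_base)
  if (cm$strand == "-") alt <- chartr("ACGT", "TGCA", alt)
  alt_codon <- ref_codon
  substr(alt_codon, codon_position, codon_position) <- alt
  ref_aa <- mt_translate(ref_codon, code)
  alt_aa <- mt_translate(alt_codon, code)
  tibble(feature = coding$name[1], codon_position = codon_position,
         ref_codon = ref_codon, alt_codon = alt_codon,
         ref_aa = ref_aa, alt_aa = alt_aa,
         synonymous = identical(ref_aa, alt_aa))
}

#' Tabulate differences between two aligned mitogenome sequences
#'
#' One record per differing alignment column (substitution) or per maximal
#' gap run (indel, counted once however long). Columns where either row is
#' `N` are skipped — missing data is ignored, not called as difference.
#' Coordinates are reported in the first (reference) row's ungapped frame.
#' With a feature table, substitutions are annotated with the containing
#' feature and, inside protein-coding genes, the codon and amino-acid
#' change under `code`.
#'
#' @param alignment A 2-row `seq_alignment` (see [read_alignment()]), the
#'   reference first.
#' @param features Optional feature tibble.
#' @param code Genetic code id.
#' @return Tibble of difference records: `site`, `ref_base`, `alt_base`,
#'   `kind`, `ts_tv`, plus annotation columns.
#' @export
pairwise_differences <- function(alignment, features = NULL, code = "2") {
  if (length(alignment) != 2L) {
    abort("pairwise_differences needs a 2-row alignment; extract the pair first")
  }
  a <- strsplit(unname(alignment[[1]]), NULL)[[1]]
  b <- strsplit(unname(alignment[[2]]), NULL)[[1]]
  ref_pos <- cumsum(a != "-")
  usable <- a != "N" & b != "N"
  is_base_a <- a %in% DNA_BASES
  is_base_b <- b %in% DNA_BASES

  empty <- tibble(site = integer(), ref_base = character(),
                  alt_base = character(), kind = character(),
                  ts_tv = character())
  recs <- list()

  sub_cols <- which(usable & is_base_a & is_base_b & a != b)
  if (length(sub_cols)) {
    recs$subs <- tibble(site = ref_pos[sub_cols], ref_base = a[sub_cols],
                        alt_base = b[sub_cols], kind = "substitution",
                        ts_tv = classify_ts_tv(a[sub_cols], b[sub_cols]))
  }
  gap <- usable & ((a == "-") != (b == "-"))
  if (any(gap)) {
    r <- rle(gap)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    gi <- which(r$values)
    recs$indels <- purrr::map_dfr(gi, function(g) {
      cols <- starts[g]:ends[g]
      if (all(b[cols] == "-")) {           # deletion relative to reference
        tibble(site = ref_pos[cols[1]],
               ref_base = paste(a[cols], collapse = ""),
               alt_base = "-", kind = "indel", ts_tv = "not_applicable")
      } else {                              # insertion relative to reference
        tibble(site = max(ref_pos[cols[1]] - 1L, 0L) + 1L,
               ref_base = "-",
               alt_base = paste(b[cols], collapse = ""),
               kind = "indel", ts_tv = "not_applicable")
      }
    })
  }
  out <- bind_rows(empty, recs$subs, recs$indels) |> arrange(.data$site)
  if (!is.null(features) && nrow(out)) {
    ref_seq <- circ_seq(paste(a[a != "-"], collapse = ""), id = "ref")
    ann <- purrr::map_dfr(seq_len(nrow(out)), function(i) {
      if (out$kind[i] != "substitution") {
        hit <- filter(features, .data$start <= out$site[i],
                      .data$end >= out$site[i])
        return(tibble(feature = if (nrow(hit)) hit$name[1] else "intergenic/control",
                      codon_position = NA_integer_, ref_codon = NA_character_,
                      alt_codon = NA_character_, ref_aa = NA_character_,
                      alt_aa = NA_character_, synonymous = NA))
      }
      annotate_codon(out$site[i], ref_seq, out$alt_base[i], features, code)
    })
    out <- dplyr::bind_cols(out, ann)
  }
  out
}

#' Summarise a pairwise difference set, with a region excluded
#'
#' Reports substitution and indel counts overall and outside an excluded
#' region (e.g. the hypervariable *ND6*/D-loop block), per-bp substitution
#' rates inside and outside the region, and the headline percent
#' divergence, whose denominator is the full reference length (both
#' conventions are reported: `rate_*` use compared lengths).
#'
#' @param differences Difference tibble ([pairwise_differences()] layout).
#' @param excluded_region Tibble with `start`, `end` (1-based inclusive,
#'   reference frame) or `NULL`.
#' @param covered_length Reference length (bp) used as rate/percent
#'   denominator.
#' @return One-row tibble of counts and rates.
#' @export
summarize_pair <- function(differences, excluded_region = NULL,
                           covered_length) {
  subs <- filter(differences, .data$kind == "substitution")
  inds <- filter(differences, .data$kind == "indel")
  in_region <- function(site) {
    if (is.null(excluded_region) || nrow(excluded_region) == 0L) {
      return(rep(FALSE, length(site)))
    }
    if (any(excluded_region$end > covered_length |
              excluded_region$start < 1L)) {
      abort("excluded region outside reference bounds")
    }
    purrr::map_lgl(site, function(s) {
      any(excluded_region$start <= s & excluded_region$end >= s)
    })
  }
  region_len <- if (is.null(excluded_region) || nrow(excluded_region) == 0L) {
    0L
  } else {
    sum(merge_intervals(excluded_region[, c("start", "end")])$end -
          merge_intervals(excluded_region[, c("start", "end")])$start + 1L)
  }
  s_in <- sum(in_region(subs$site))
  i_in <- sum(in_region(inds$site))
  n_sub <- nrow(subs); n_ind <- nrow(inds)
  tibble(
    substitutions = n_sub,
    indels = n_ind,
    substitutions_excl = n_sub - s_in,
    indels_excl = n_ind - i_in,
    region_length = region_len,
    rate_overall = n_sub / covered_length,
    rate_in_region = if (region_len > 0) s_in / region_len else NA_real_,
    rate_outside_region = if (region_len > 0) {
      (n_sub - s_in) / (covered_length - region_len)
    } else {
      n_sub / covered_length
    },
    percent_divergence = round(100 * nrow(differences) / covered_length, 2)
  )
}

#' Pairwise-deletion distance matrix
#'
#' Entry (i, j) is the number of differing columns divided by the number of
#' columns where both rows carry an unambiguous base (`A/C/G/T`) — sites
#' with missing data (`N`) or gaps are ignored per pair. A pair with zero
#' comparable columns gets `NA`.
#'
#' @param alignment A `seq_alignment` of n >= 2 rows.
#' @return Symmetric n x n numeric matrix with zero diagonal.
#' @export
distance_matrix <- function(alignment) {
  n <- length(alignment)
  stopifnot(n >= 2L)
  m <- do.call(rbind, strsplit(unname(unclass(alignment)), NULL))
  valid <- matrix(m %in% DNA_BASES, nrow = n)
  d <- matrix(0, n, n, dimnames = list(names(alignment), names(alignment)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      comp <- valid[i, ] & valid[j, ]
      nc <- sum(comp)
      d[i, j] <- d[j, i] <- if (nc == 0L) NA_real_ else {
        sum(m[i, comp] != m[j, comp]) / nc
      }
    }
  }
  d
}

#' Write a distance matrix in PHYLIP format
#' @param d Square matrix with dimnames.
#' @param path Output path.
#' @export
write_phylip_dist <- function(d, path) {
  lines <- c(sprintf("%5d", nrow(d)),
             vapply(seq_len(nrow(d)), function(i) {
               paste0(formatC(rownames(d)[i], width = -10),
                      paste(sprintf("%.6f", d[i, ]), collapse = "  "))
             }, ""))
  writeLines(lines, path)
  invisible(path)
}

#' Globally align two near-identical sequences
#'
#' Needleman-Wunsch global alignment (via Biostrings) with gap penalties
#' suited to near-identical mitogenomes, returned as a 2-row
#' `seq_alignment` ready for [pairwise_differences()].
#'
#' @param a,b `circ_seq` objects or character strings (reference first).
#' @param gap_opening,gap_extension Gap penalties.
#' @return A `seq_alignment` of 2 rows.
#' @export
align_pair <- function(a, b, gap_opening = 10, gap_extension = 0.5) {
  ida <- if (inherits(a, "circ_seq")) a$id else "ref"
  idb <- if (inherits(b, "circ_seq")) b$id else "alt"
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(as.character(b)),
    Biostrings::DNAString(as.character(a)),
    type = "global", gapOpening = gap_opening, gapExtension = gap_extension
  )
  rows <- c(as.character(Biostrings::alignedSubject(pa)),
            as.character(Biostrings::alignedPattern(pa)))
  names(rows) <- c(ida, idb)
  new_alignment(rows)
}

#' Read a Table-2-style difference table
#'
#' A TSV with columns `site`, `ref_base`, `alt_base` (`-` marks the deleted
#' allele), and optional `codon_position`, `ref_codon`, `alt_codon`,
#' `ref_aa`, `alt_aa`. Bases and codons are case-normalised.
#'
#' @param path TSV path. The package ships the published 27-row
#'   *Channichthys* difference set at
#'   `system.file("extdata", "channichthys_mt_differences.tsv",
#'   package = "museomt")`.
#' @return Difference tibble with `kind` derived from the alleles.
#' @export
read_difference_table <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(all(c("site", "ref_base", "alt_base") %in% names(tbl)))
  tbl |>
    mutate(
      ref_base = toupper(.data$ref_base),
      alt_base = toupper(.data$alt_base),
      kind = ifelse(.data$ref_base == "-" | .data$alt_base == "-",
                    "indel", "substitution"),
      across(dplyr::any_of(c("ref_codon", "alt_codon")), toupper)
    )
}

#' Reclassify a difference table from first principles
#'
#' Recomputes, rather than trusting, the derived columns of a difference
#' table: transition/transversion status from the bases and amino acids
#' (and synonymy) from the codon pairs under the chosen genetic code.
#'
#' @param tbl Difference tibble (needs `site`, `ref_base`, `alt_base`;
#'   codon columns optional).
#' @param code Genetic code id (default vertebrate mitochondrial).
#' @return The tibble with recomputed `ts_tv`, `ref_aa`, `alt_aa`,
#'   `synonymous`.
#' @export
classify_differences <- function(tbl, code = "2") {
  if (is.null(tbl$kind)) {
    tbl$kind <- ifelse(tbl$ref_base == "-" | tbl$alt_base == "-",
                       "indel", "substitution")
  }
  is_sub <- tbl$kind == "substitution"
  ts_tv <- rep("not_applicable", nrow(tbl))
  ts_tv[is_sub] <- classify_ts_tv(tbl$ref_base[is_sub], tbl$alt_base[is_sub])
  tbl$ts_tv <- ts_tv
  if (!is.null(tbl$ref_codon)) {
    tbl$ref_aa <- mt_translate(tbl$ref_codon, code)
    tbl$alt_aa <- mt_translate(tbl$alt_codon, code)
    tbl$synonymous <- ifelse(is.na(tbl$ref_aa) | is.na(tbl$alt_aa), NA,
                             tbl$ref_aa == tbl$alt_aa)
  }
  tbl
}

#' Count summary of a classified difference table
#'
#' @param tbl Difference tibble; derived columns are recomputed via
#'   [classify_differences()] first.
#' @param code Genetic code id.
#' @return One-row tibble: record, substitution, indel, transition,
#'   transversion and amino-acid-substitution counts.
#' @export
summarize_differences <- function(tbl, code = "2") {
  tbl <- classify_differences(tbl, code)
  tibble(
    n_records = nrow(tbl),
    substitutions = sum(tbl$kind == "substitution"),
    indels = sum(tbl$kind == "indel"),
    transitions = sum(tbl$ts_tv == "transition"),
    transversions = sum(tbl$ts_tv == "transversion"),
    aa_substitutions = if (is.null(tbl$synonymous)) NA_integer_ else {
      sum(!tbl$synonymous, na.rm = TRUE)
    },
    synonymous_coding = if (is.null(tbl$synonymous)) NA_integer_ else {
      sum(tbl$synonymous, na.rm = TRUE)
    }
  )
}
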