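#' Fragment-length model
#'
#' Fragment lengths of degraded museum DNA are modelled as a lognormal
#' truncated to `[min_len, max_len]` and rounded to integers. The defaults
#' reproduce the scale of formalin-fixed specimen libraries: analytic
#' truncated mean 32.98 bp, with reads shorter than 20 bp discarded by the
#' sequencing pipeline and 75 bp the single-end read length of the
#' instrument.
#'
#' @param mean_log,sd_log Lognormal parameters (log-bp).
#' @param min_len,max_len Truncation bounds (bp).
#' @export
fragment_model <- function(mean_log = log(29), sd_log = 0.35,
                           min_len = 20L, max_len = 75L) {
  stopifnot(min_len >= 1L, max_len >= min_len, sd_log > 0)
  structure(list(mean_log = mean_log, sd_log = sd_log,
                 min_len = as.integer(min_len), max_len = as.integer(max_len)),
            class = "fragment_model")
}

#' Analytic mean of the truncated fragment-length distribution
#' @param fm A [fragment_model()].
#' @export
fragment_mean <- function(fm) {
  Z <- plnorm(fm$max_len, fm$mean_log, fm$sd_log) -
    plnorm(fm$min_len, fm$mean_log, fm$sd_log)
  integrate(function(x) x * dlnorm(x, fm$mean_log, fm$sd_log),
            fm$min_len, fm$max_len)$value / Z
}

#' Post-mortem damage model
#'
#' Cytosine deamination converts C to U, read as T. The per-position flip
#' probability decays exponentially with the 0-based distance `i` from the
#' relevant read end: `p(i) = p_base + (p_max - p_base) * exp(-decay * i)`.
#' Under single-stranded library preparation the signal is C->T at *both*
#' read ends (distance to the nearer end); under double-stranded
#' preparation it is C->T from the 5' end and G->A from the 3' end.
#' Independent per-base sequencing error is applied afterwards, uniformly
#' over the three alternative bases.
#'
#' @param library `"single_stranded"` or `"double_stranded"`.
#' @param p_max Deamination probability at the terminal base.
#' @param p_base Background deamination probability in the read interior.
#' @param decay Per-position exponential decay rate (dimensionless, >= 0).
#' @param seq_error Per-base random sequencing error probability.
#' @export
damage_model <- function(library = c("single_stranded", "double_stranded"),
                         p_max = 0.25, p_base = 0.01, decay = 0.4,
                         seq_error = 0.002) {
  library <- match.arg(library)
  stopifnot(p_base >= 0, p_base <= p_max, p_max <= 1, decay >= 0,
            seq_error >= 0, seq_error < 1)
  structure(list(library = library, p_max = p_max, p_base = p_base,
                 decay = decay, seq_error = seq_error),
            class = "damage_model")
}

#' Read-set simulation configuration
#'
#' @param target_depth Expected fold-coverage of the genome (the specimen
#'   analysed in the motivating study reached 35.4x).
#' @param seed RNG seed; fixed seeds give byte-identical output.
#' @param contamination_fraction Proportion of reads drawn from an unrelated
#'   seeded random decoy genome (GC 50%).
#' @param duplication_fraction Proportion of extra PCR-duplicate reads added
#'   on top of the unique fragments.
#' @export
sim_config <- function(target_depth = 35, seed = 1L,
                       contamination_fraction = 0,
                       duplication_fraction = 0) {
  stopifnot(target_depth > 0, contamination_fraction >= 0,
            contamination_fraction < 1, duplication_fraction >= 0,
            duplication_fraction < 1)
  structure(list(target_depth = target_depth, seed = as.integer(seed),
                 contamination_fraction = contamination_fraction,
                 duplication_fraction = duplication_fraction),
            class = "sim_config")
}

#' Plant a truth set of variants into a genome
#'
#' Applies substitutions, single-base deletions and insertions to a
#' reference genome, returning the mutated genome together with a
#' bidirectional coordinate map. `ref_base` of every substitution/deletion
#' must match the reference; a mismatch raises an error naming the site.
#'
#' @param genome A [circ_seq()].
#' @param variants Tibble with columns `site` (1-based), `ref_base`, `alt`
#'   (`-` for deletion; for insertions the string inserted *after* `site`),
#'   `kind` (`substitution`, `deletion`, `insertion`). Sites must be unique.
#' @return List with elements `genome` (mutated `circ_seq`) and `map`
#'   (tibble `original`, `mutated`; `NA` for deleted sites).
#' @export
plant_variants <- function(genome, variants) {
  L <- seq_length(genome)
  chars <- strsplit(as.character(genome), NULL)[[1]]
  if (nrow(variants) == 0L) {
    return(list(genome = genome,
                map = tibble(original = seq_len(L), mutated = seq_len(L))))
  }
  stopifnot(all(c("site", "ref_base", "alt", "kind") %in% names(variants)))
  if (anyDuplicated(variants$site)) abort("variant sites must be unique")
  variants <- arrange(variants, .data$site)
  chk <- variants$kind %in% c("substitution", "deletion")
  bad <- chk & toupper(variants$ref_base) != chars[variants$site]
  if (any(bad)) {
    abort(sprintf("ref_base mismatch at site(s): %s",
                  paste(variants$site[bad], collapse = ", ")))
  }
  out <- as.list(chars)          # per original position: replacement string
  keep <- rep(TRUE, L)
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    if (v$kind == "substitution") {
      out[[v$site]] <- toupper(v$alt)
    } else if (v$kind == "deletion") {
      out[[v$site]] <- ""
      keep[v$site] <- FALSE
    } else if (v$kind == "insertion") {
      out[[v$site]] <- paste0(chars[v$site], toupper(v$alt))
    } else {
      abort(sprintf("unknown variant kind '%s'", v$kind))
    }
  }
  lens <- vapply(out, nchar, 1L)
  mutated_pos <- ifelse(keep, cumsum(lens) - lens + 1L, NA_integer_)
  mut <- circ_seq(paste(unlist(out), collapse = ""), id = genome$id,
                  circular = genome$circular)
  list(genome = mut, map = tibble(original = seq_len(L),
                                  mutated = as.integer(mutated_pos)))
}

#' Draw random fragments from a circular genome
#'
#' Start positions are uniform on the circle (fragments may span the
#' origin), lengths are truncated-lognormal, strands uniform.
#'
#' @param genome A [circ_seq()].
#' @param fm A [fragment_model()].
#' @param n Number of fragments.
#' @param seed Optional seed for deterministic output.
#' @return Tibble with `start` (1-based), `length`, `strand`.
#' @export
simulate_fragments <- function(genome, fm, n, seed = NULL) {
  stopifnot(n >= 0)
  draw <- function() {
    L <- seq_length(genome)
    lo <- plnorm(fm$min_len, fm$mean_log, fm$sd_log)
    hi <- plnorm(fm$max_len, fm$mean_log, fm$sd_log)
    len <- as.integer(pmin(pmax(
      round(qlnorm(runif(n, lo, hi), fm$mean_log, fm$sd_log)),
      fm$min_len), fm$max_len))
    tibble(
      start = sample.int(L, n, replace = TRUE),
      length = len,
      strand = sample(c("+", "-"), n, replace = TRUE)
    )
  }
  if (is.null(seed)) draw() else with_seed_(seed, draw())
}

# Extract fragment sequences (read orientation) from a genome.
fragment_sequences <- function(genome, frags) {
  L <- seq_length(genome)
  ext <- if (genome$circular) {
    paste0(as.character(genome), substr(as.character(genome), 1L, max(frags$length)))
  } else {
    as.character(genome)
  }
  s <- substring(ext, frags$start, frags$start + frags$length - 1L)
  neg <- frags$strand == "-"
  s[neg] <- revcomp(s[neg])
  s
}

#' Apply post-mortem damage and sequencing error to fragments
#'
#' Vectorised over fragments. Damage never changes read length; it only
#' flips C->T (and G->A for double-stranded libraries) before uniform
#' sequencing error is added.
#'
#' @param fragments Character vector of fragment sequences (read
#'   orientation).
#' @param dm A [damage_model()].
#' @param seed Optional seed.
#' @return Character vector of damaged read sequences.
#' @export
apply_damage <- function(fragments, dm, seed = NULL) {
  run <- function() {
    if (length(fragments) == 0L) return(character(0))
    assert_bases(fragments, "fragment", allow = "ACGT")
    lens <- nchar(fragments)
    chars <- strsplit(paste(fragments, collapse = ""), NULL)[[1]]
    pos <- sequence(lens)                # 1-based position within read
    len_at <- rep(lens, lens)
    i5 <- pos - 1L
    i3 <- len_at - pos
    pfun <- function(i) dm$p_base + (dm$p_max - dm$p_base) * exp(-dm$decay * i)
    if (dm$library == "single_stranded") {
      p_ct <- pfun(pmin(i5, i3))
      flip <- chars == "C" & runif(length(chars)) < p_ct
      chars[flip] <- "T"
    } else {
      flip_c <- chars == "C" & runif(length(chars)) < pfun(i5)
      flip_g <- chars == "G" & runif(length(chars)) < pfun(i3)
      chars[flip_c] <- "T"
      chars[flip_g] <- "A"
    }
    if (dm$seq_error > 0) {
      err <- runif(length(chars)) < dm$seq_error
      if (any(err)) {
        cur <- match(chars[err], DNA_BASES)
        shift <- sample.int(3L, sum(err), replace = TRUE)
        chars[err] <- DNA_BASES[((cur - 1L + shift) %% 4L) + 1L]
      }
    }
    vapply(split(chars, rep(seq_along(lens), lens)), paste, "",
           collapse = "", USE.NAMES = FALSE)
  }
  if (is.null(seed)) run() else with_seed_(seed, run())
}

#' Simulate a full degraded read set with ground truth
#'
#' The number of unique fragments is chosen so the expected depth matches
#' `cfg$target_depth` (`round(L * depth / mean_fragment_length)`).
#' Contaminant reads are drawn from a seeded i.i.d. random decoy genome and
#' flagged in the truth table; optional PCR duplicates are resampled
#' fragments re-damaged independently. FASTQ qualities are a constant
#' placeholder (`I`): the degradation lives in the bases.
#'
#' @param genome Sample genome (a [circ_seq()], e.g. the output of
#'   [plant_variants()]).
#' @param fm A [fragment_model()].
#' @param dm A [damage_model()].
#' @param cfg A [sim_config()].
#' @param fastq,truth Optional output paths (FASTQ; truth TSV). With a fixed
#'   seed the FASTQ is byte-identical across reruns.
#' @return Invisibly, a list with `reads` (tibble `read_id`, `seq`) and
#'   `truth` (tibble `read_id`, `origin`, `start`, `length`, `strand`,
#'   `duplicate_of`).
#' @export
simulate_readset <- function(genome, fm, dm, cfg, fastq = NULL, truth = NULL) {
  L <- seq_length(genome)
  res <- with_seed_(cfg$seed, {
    n_unique <- max(1L, round(L * cfg$target_depth / fragment_mean(fm)))
    n_cont <- round(cfg$contamination_fraction * n_unique)
    n_endo <- n_unique - n_cont
    frags <- simulate_fragments(genome, fm, n_endo)
    frags$origin <- rep("endogenous", n_endo)
    if (n_cont > 0L) {
      decoy <- circ_seq(paste(sample(DNA_BASES, L, replace = TRUE),
                              collapse = ""), id = "decoy")
      cfr <- simulate_fragments(decoy, fm, n_cont)
      cfr$origin <- "contaminant"
      frag_seqs <- c(fragment_sequences(genome, frags[, 1:3]),
                     fragment_sequences(decoy, cfr[, 1:3]))
      frags <- bind_rows(frags, cfr)
    } else {
      frag_seqs <- fragment_sequences(genome, frags[, 1:3])
    }
    frags$duplicate_of <- NA_character_
    n_dup <- round(cfg$duplication_fraction * nrow(frags))
    if (n_dup > 0L) {
      src <- sample.int(nrow(frags), n_dup, replace = TRUE)
      dups <- frags[src, ]
      dups$duplicate_of <- sprintf("read%06d", src)
      frags <- bind_rows(frags, dups)
      frag_seqs <- c(frag_seqs, frag_seqs[src])
    }
    frags$read_id <- sprintf("read%06d", seq_len(nrow(frags)))
    reads <- apply_damage(frag_seqs, dm)
    list(reads = tibble(read_id = frags$read_id, seq = reads),
         truth = select(frags, "read_id", "origin", "start", "length",
                        "strand", "duplicate_of"))
  })
  if (!is.null(fastq)) write_fastq(res$reads, fastq)
  if (!is.null(truth)) readr::write_tsv(res$truth, truth)
  invisible(res)
}

#' Write reads as FASTQ (Phred+33, constant quality)
#' @param reads Tibble with `read_id`, `seq`.
#' @param path Output FASTQ path.
#' @export
write_fastq <- function(reads, path) {
  qual <- strrep("I", nchar(reads$seq))
  con <- file(path, "wb")  # binary mode: byte-identical across platforms
  on.exit(close(con))
  writeLines(as.vector(rbind(paste0("@", reads$read_id), reads$seq,
                             "+", qual)), con, sep = "\n")
  invisible(path)
}

#' Read a FASTQ file into a read tibble
#' @param path FASTQ path.
#' @export
read_fastq <- function(path) {
  set <- Biostrings::readDNAStringSet(path, format = "fastq")
  tibble(read_id = sub("\\s.*$", "", names(set)),
         seq = unname(as.character(set)))
}
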