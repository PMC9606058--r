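RUN_CONFIG_DEFAULTS <- list(
  seed = 1L,
  out_dir = NULL,
  genome_fasta = NULL,        # reference FASTA; NULL -> seeded random genome
  genome_length = 17408L,
  variants = NULL,            # tibble or TSV path of variants to plant
  target_depth = 35,
  contamination_fraction = 0,
  duplication_fraction = 0,
  fragment_mean_log = log(29),
  fragment_sd_log = 0.35,
  min_read_len = 20L,
  max_read_len = 75L,
  library = "single_stranded",
  p_max = 0.25,
  p_base = 0.01,
  decay = 0.4,
  seq_error = 0.002,
  k = 12L,
  max_mismatch_frac = 0.05,
  damage_tolerant = TRUE,
  uniqueness_margin = 5,
  min_depth = 3L,
  rotation_bp = 200L,
  window = 25L,
  mask_intervals = NULL,      # tibble or "start-end,start-end" string
  apply_indels = FALSE,
  genetic_code = "2",
  excluded_region = NULL
)

#' Build a pipeline run configuration
#'
#' Unset parameters fall back to the defaults of the motivating study
#' (minimum depth 3, rotation 200 bp, minimum read length 20 bp, depth 35).
#' Unknown keys raise a validation error listing them. A configuration can
#' also be read from a flat `key = value` text file.
#'
#' @param ... Named parameters overriding the defaults (see
#'   `museomt:::RUN_CONFIG_DEFAULTS`).
#' @param file Optional flat key-value config file.
#' @return A `run_config` list.
#' @export
run_config <- function(..., file = NULL) {
  over <- list(...)
  if (!is.null(file)) {
    lines <- readr::read_lines(file)
    lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
    kv <- stringr::str_match(lines, "^\\s*([A-Za-z0-9_.]+)\\s*[=:]\\s*(.*?)\\s*$")
    if (anyNA(kv[, 1])) abort("config file lines must be 'key = value'")
    parsed <- setNames(as.list(kv[, 3]), kv[, 2])
    parsed <- purrr::map(parsed, function(v) {
      num <- suppressWarnings(as.numeric(v))
      if (!is.na(num)) num
      else if (v %in% c("TRUE", "FALSE", "true", "false")) as.logical(toupper(v))
      else v
    })
    over <- utils::modifyList(parsed, over)
  }
  unknown <- setdiff(names(over), names(RUN_CONFIG_DEFAULTS))
  if (length(unknown)) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(RUN_CONFIG_DEFAULTS, over)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

# Default truth set shaped like the published difference table: 26
# substitutions and one single-base deletion inside a 14-mer C repeat.
default_variant_set <- function() {
  tbl <- shipped_difference_table()
  tbl |>
    mutate(kind = ifelse(.data$alt_base == "-", "deletion", "substitution"),
           alt = .data$alt_base) |>
    select("site", "ref_base", "alt", "kind")
}

#' Path to (and contents of) the shipped mitogenome difference table
#'
#' The published 27-row set of differences between the *C. rhinoceratus*
#' and *C. rugosus* mitochondrial genomes (26 substitutions and one
#' single-base deletion in a 14-mer C homopolymer), used as fixture and as
#' the default planted truth set.
#'
#' @return Difference tibble (see [read_difference_table()]).
#' @export
shipped_difference_table <- function() {
  read_difference_table(system.file("extdata",
                                    "channichthys_mt_differences.tsv",
                                    package = "museomt"))
}

# A seeded random reference carrying the sequence context the default
# truth set needs: printed reference bases at the variant sites and the
# 14-mer C homopolymer at 15986-15999.
synthetic_reference <- function(length = 17408L, seed = 1L,
                                variants = NULL) {
  with_seed_(seed, {
    chars <- sample(DNA_BASES, length, replace = TRUE)
    if (!is.null(variants)) {
      sub <- variants[variants$kind != "insertion" & variants$ref_base != "-", ]
      chars[sub$site] <- toupper(sub$ref_base)
      if (any(variants$site == 15999L) && length >= 16000L) {
        chars[15986:15999] <- "C"
        chars[15985] <- "A"; chars[16000] <- "G"  # firm run boundaries
      }
    }
    # avoid accidental long repeats elsewhere is unnecessary: random i.i.d.
    circ_seq(paste(chars, collapse = ""), id = "reference")
  })
}

#' Run the full simulate-map-profile-consensus-compare pipeline
#'
#' Executes the stages with per-stage child seeds derived from the global
#' seed (so stages are independently rerunnable and identical seeds give
#' identical outputs), and returns a machine-readable run report with the
#' stage bookkeeping: reads simulated, mapped, unique, duplicate-filtered,
#' consensus called fraction, differences found, and truth-set recovery
#' when variants were planted. With `out_dir` set, FASTQ, SAM, consensus
#' FASTA, profiles, difference tables, the resolved configuration and the
#' JSON report are written to disk.
#'
#' @param config A [run_config()].
#' @return The run report (list), invisibly when writing to disk.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  # --- reference and truth -------------------------------------------------
  variants <- config$variants
  if (is.character(variants)) {
    variants <- readr::read_tsv(variants, show_col_types = FALSE)
  }
  if (is.null(variants)) {
    variants <- default_variant_set()
    # trim the default truth set to genomes smaller than the full scale
    variants <- filter(variants, .data$site <= config$genome_length)
    if (config$genome_length < 16000L) {
      variants <- filter(variants, .data$kind != "deletion")
    }
  }
  if (!is.null(config$genome_fasta)) {
    ref <- read_fasta(config$genome_fasta)[[1]]
  } else {
    ref <- synthetic_reference(config$genome_length,
                               child_seed(config$seed, "genome"), variants)
  }
  planted <- plant_variants(ref, variants)

  # --- simulate ------------------------------------------------------------
  fm <- fragment_model(config$fragment_mean_log, config$fragment_sd_log,
                       config$min_read_len, config$max_read_len)
  dm <- damage_model(config$library, config$p_max, config$p_base,
                     config$decay, config$seq_error)
  sc <- sim_config(config$target_depth, child_seed(config$seed, "simulate"),
                   config$contamination_fraction, config$duplication_fraction)
  sim <- simulate_readset(planted$genome, fm, dm, sc)

  # --- map (two rotation passes inside recover_terminal) -------------------
  cons <- recover_terminal(
    sim$reads, ref, rotation_bp = config$rotation_bp,
    min_depth = config$min_depth, k = config$k,
    max_mismatch_frac = config$max_mismatch_frac,
    damage_tolerant = config$damage_tolerant,
    min_read_len = config$min_read_len,
    uniqueness_margin = config$uniqueness_margin
  )
  aln_filtered <- attr(cons, "alignments")
  p <- attr(cons, "pileup")
  idx <- build_index(ref, k = config$k)
  aln_all <- map_reads(sim$reads, idx,
                       max_mismatch_frac = config$max_mismatch_frac,
                       damage_tolerant = config$damage_tolerant,
                       min_read_len = config$min_read_len,
                       uniqueness_margin = config$uniqueness_margin)
  aln_dedup <- mark_duplicates(aln_all)

  # --- damage --------------------------------------------------------------
  prof <- damage_profile(aln_filtered, ref, window = config$window)
  hist <- read_length_histogram(aln_filtered)

  # --- consensus extras ----------------------------------------------------
  mask_iv <- config$mask_intervals
  if (is.character(mask_iv)) {
    mm <- stringr::str_match_all(mask_iv, "(\\d+)-(\\d+)")[[1]]
    mask_iv <- tibble(start = as.integer(mm[, 2]), end = as.integer(mm[, 3]))
  }
  if (!is.null(mask_iv) && nrow(mask_iv)) {
    cons <- mask_regions(cons, ref, config$max_read_len, mask_iv)
  }
  indels <- call_homopolymer_indels(p, ref)
  cons$indel_candidates <- indels
  cons_seq <- cons$sequence
  if (isTRUE(config$apply_indels) && nrow(indels)) {
    cons_seq <- apply_indels(cons, indels)$sequence
  }

  # --- compare -------------------------------------------------------------
  aln2 <- new_alignment(c(reference = as.character(ref),
                          consensus = cons$sequence))
  diffs <- pairwise_differences(aln2)
  excl <- config$excluded_region
  summ <- summarize_pair(diffs, excl, covered_length = seq_length(ref))
  recovery <- recovered_variants(variants, diffs, indels)

  report <- list(
    tool = "museomt",
    version = as.character(utils::packageVersion("museomt")),
    seed = config$seed,
    counts = list(
      reads_simulated = nrow(sim$reads),
      reads_mapped = nrow(aln_all),
      reads_unique = sum(aln_all$unique),
      reads_after_duplicate_filter = nrow(filter_alignments(aln_dedup)),
      mean_read_length = attr(hist, "mean_length"),
      mean_depth = mean(p$depth),
      consensus_called_fraction = cons$called_fraction,
      coverage_fraction = cons$coverage_fraction,
      differences_found = nrow(diffs),
      indel_candidates = nrow(indels),
      variants_planted = nrow(variants),
      variants_recovered = recovery$recovered
    ),
    summary = as.list(summ),
    damage_fit = tryCatch(as.list(glance(fit_deamination(prof, "5p"))),
                          error = function(e) NULL),
    config = unclass(config)[!vapply(unclass(config), is.null, TRUE) &
                               !names(unclass(config)) %in%
                               c("variants", "mask_intervals")],
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    pth <- function(f) file.path(config$out_dir, f)
    write_fastq(sim$reads, pth("reads.fastq"))
    readr::write_tsv(sim$truth, pth("read_truth.tsv"))
    readr::write_tsv(variants, pth("variant_truth.tsv"))
    write_fasta(ref, pth("reference.fasta"))
    write_sam(filter_alignments(aln_dedup), idx, pth("alignments.sam"))
    write_fasta(setNames(cons_seq, "consensus"), pth("consensus.fasta"))
    write_damage_profile(prof, pth("damage_profile.tsv"))
    readr::write_tsv(diffs, pth("differences.tsv"))
    readr::write_tsv(indels, pth("indel_candidates.tsv"))
    if (nrow(cons$mask_intervals)) write_mask_bed(cons, pth("mask.bed"))
    jsonlite::write_json(report, pth("report.json"), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    writeLines(paste(names(report$config),
                     vapply(report$config, function(v) paste(format(v), collapse = ","), ""),
                     sep = " = "),
               pth("resolved_config.txt"))
    return(invisible(report))
  }
  report
}

# How many planted variants are recovered by the consensus difference set
# (substitutions by site + alternate base) and the homopolymer indel
# candidates (deletions inside a run, matched by run overlap and length
# change).
recovered_variants <- function(variants, diffs, indel_candidates) {
  subs <- variants[variants$kind == "substitution", ]
  dsub <- diffs[diffs$kind == "substitution", ]
  hit_sub <- sum(paste(subs$site, toupper(subs$alt)) %in%
                   paste(dsub$site, dsub$alt_base))
  dels <- variants[variants$kind == "deletion", ]
  hit_del <- 0L
  if (nrow(dels) && nrow(indel_candidates)) {
    hit_del <- sum(vapply(dels$site, function(s) {
      any(indel_candidates$site <= s &
            indel_candidates$site + indel_candidates$ref_len - 1L >= s &
            indel_candidates$alt_len < indel_candidates$ref_len)
    }, TRUE))
  }
  list(recovered = hit_sub + hit_del, substitutions = hit_sub,
       indels = hit_del, planted = nrow(variants))
}
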