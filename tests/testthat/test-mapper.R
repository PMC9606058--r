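test_that("k-mer index reports all occurrences, including across the origin", {
  ref <- circ_seq("ACGTACGT", id = "toy")
  idx <- build_index(ref, k = 4)
  expect_equal(sort(index_hits(idx, "ACGT")), c(1L, 5L))
  expect_equal(index_hits(idx, "AAAA"), integer(0))
  # every rotation of the circle is seedable: brute-force all-rotations check
  g <- random_genome(200, seed = 1)
  idx2 <- build_index(g, k = 12)
  s <- as.character(g)
  doubled <- paste0(s, s)
  for (pos in c(1, 100, 195, 199, 200)) {   # incl. origin-spanning k-mers
    km <- substr(doubled, pos, pos + 11)
    expect_true(pos %in% index_hits(idx2, km))
  }
})

test_that("exact reads and their reverse complements map to the same locus", {
  g <- random_genome(2000, seed = 2)
  idx <- build_index(g)
  read <- substr(as.character(g), 101, 130)
  hit <- map_read(read, idx)
  expect_equal(hit$ref_start, 101L)
  expect_equal(hit$strand, "+")
  expect_equal(hit$mismatches, 0L)
  hit_rc <- map_read(rc(read), idx)
  expect_equal(hit_rc$ref_start, 101L)
  expect_equal(hit_rc$strand, "-")
})

test_that("origin-straddling reads place identically to an exhaustive scan", {
  g <- random_genome(2000, seed = 3)
  idx <- build_index(g)
  doubled <- paste0(as.character(g), as.character(g))
  read <- substr(doubled, 1990, 2020)  # spans position 2000/1
  hit <- map_read(read, idx)
  oracle <- brute_best_placement(read, g)
  expect_equal(hit$ref_start, oracle$start)
  expect_equal(hit$mismatches, oracle$mm)
})

test_that("seeded mapping agrees with the exhaustive aligner on a toy read set", {
  g <- random_genome(2000, seed = 4)
  idx <- build_index(g)
  withr::with_seed(5, {
    n <- 100
    starts <- sample.int(2000, n, replace = TRUE)
    lens <- sample(25:60, n, replace = TRUE)
    doubled <- paste0(as.character(g), as.character(g))
    reads <- substring(doubled, starts, starts + lens - 1)
    neg <- sample(c(TRUE, FALSE), n, replace = TRUE)
    reads[neg] <- rc(reads[neg])
    # plant up to one mismatch per read
    mutate_one <- function(s) {
      p <- sample.int(nchar(s), 1)
      substr(s, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                        substr(s, p, p)), 1)
      s
    }
    mut <- sample(c(TRUE, FALSE), n, replace = TRUE)
    reads[mut] <- vapply(reads[mut], mutate_one, "", USE.NAMES = FALSE)
    aln <- map_reads(setNames(reads, sprintf("r%03d", 1:n)), idx)
    expect_equal(nrow(aln), n)
    for (i in seq_len(n)) {
      row <- aln[aln$read_id == sprintf("r%03d", i), ]
      oracle <- brute_best_placement(reads[i], g)
      expect_equal(row$mismatches, oracle$mm)
    }
  })
})

test_that("error-free simulated reads map back to their true origin", {
  g <- random_genome(3000, seed = 6)
  fr <- simulate_fragments(g, fragment_model(min_len = 25), 1500, seed = 7)
  reads <- museomt:::fragment_sequences(g, fr)
  aln <- map_reads(setNames(reads, sprintf("r%04d", 1:1500)),
                   build_index(g))
  joined <- dplyr::left_join(
    tibble(read_id = sprintf("r%04d", 1:1500), true_start = fr$start,
           true_strand = fr$strand),
    aln, by = "read_id")
  ok <- !is.na(joined$ref_start) & joined$ref_start == joined$true_start &
    joined$strand == joined$true_strand
  expect_gte(mean(ok), 0.99)
})

test_that("short reads are excluded and mismatch budget enforces unmapping", {
  g <- random_genome(2000, seed = 8)
  idx <- build_index(g)
  short <- substr(as.character(g), 10, 24)  # 15 bp < 20
  expect_equal(nrow(map_read(short, idx)), 0)
  read <- substr(as.character(g), 300, 339)  # 40 bp, budget ceil(2) = 2
  for (p in c(5, 15, 25)) {
    substr(read, p, p) <- setdiff(c("A", "C", "G", "T"),
                                  substr(read, p, p))[1]
  }
  expect_equal(nrow(map_read(read, idx)), 0)  # 3 mismatches > budget
})

test_that("duplicate marking keeps exactly one best representative per placement", {
  g <- random_genome(2000, seed = 9)
  idx <- build_index(g)
  read <- substr(as.character(g), 501, 535)
  aln <- map_reads(c(a = read, b = read), idx)
  marked <- mark_duplicates(aln)
  expect_equal(sum(marked$duplicate), 1)
  expect_equal(marked$read_id[!marked$duplicate], "a")  # id tie-break

  distinct <- map_reads(c(x = substr(as.character(g), 101, 135),
                          y = substr(as.character(g), 901, 935)), idx)
  expect_equal(sum(mark_duplicates(distinct)$duplicate), 0)

  # a placement class never loses its last representative
  sim <- simulate_readset(g, fragment_model(), damage_model(),
                          sim_config(10, seed = 10,
                                     duplication_fraction = 0.4))
  a2 <- mark_duplicates(map_reads(sim$reads, build_index(g)))
  survivors <- a2 |> filter(!duplicate) |>
    dplyr::distinct(ref_start, length, strand)
  classes <- a2 |> dplyr::distinct(ref_start, length, strand)
  expect_equal(nrow(survivors), nrow(classes))
})

test_that("deduplication recovers the planted unique read count", {
  g <- random_genome(17408, seed = 11)
  sim <- simulate_readset(g, fragment_model(),
                          damage_model(p_max = 0, p_base = 0, seq_error = 0),
                          sim_config(2, seed = 12,
                                     duplication_fraction = 0.3))
  aln <- mark_duplicates(map_reads(sim$reads, build_index(g)))
  mapped_truth <- sim$truth[sim$truth$read_id %in% aln$read_id, ]
  planted_classes <- nrow(dplyr::distinct(mapped_truth, start, length, strand))
  expect_equal(sum(!aln$duplicate), planted_classes)
})

test_that("filtering respects flags and is reproducible under a fixed seed", {
  g <- circ_seq(strrep("ACGTACGTAC", 40), id = "rep")  # exact 10-mer repeat
  idx <- build_index(g)
  ambiguous <- substr(as.character(g), 1, 30)  # placeable every 10 bp
  aln <- map_read(ambiguous, idx)
  expect_false(aln$unique[1])
  expect_equal(nrow(filter_alignments(aln, require_unique = TRUE)), 0)

  g2 <- random_genome(2000, seed = 13)
  u <- map_reads(c(p = substr(as.character(g2), 50, 90),
                   q = substr(as.character(g2), 700, 745)),
                 build_index(g2))
  expect_equal(filter_alignments(u), u, ignore_attr = TRUE)

  sim <- simulate_readset(g2, fragment_model(), damage_model(),
                          sim_config(5, seed = 14))
  n1 <- nrow(filter_alignments(mark_duplicates(
    map_reads(sim$reads, build_index(g2)))))
  sim2 <- simulate_readset(g2, fragment_model(), damage_model(),
                           sim_config(5, seed = 14))
  n2 <- nrow(filter_alignments(mark_duplicates(
    map_reads(sim2$reads, build_index(g2)))))
  expect_identical(n1, n2)
})

test_that("SAM round trip preserves placements, strands and flags", {
  g <- random_genome(2000, seed = 15)
  idx <- build_index(g)
  reads <- c(a = substr(as.character(g), 101, 140),
             b = rc(substr(as.character(g), 501, 540)),
             c = substr(as.character(g), 501, 540))
  aln <- mark_duplicates(map_reads(reads, idx))
  f <- withr::local_tempfile(fileext = ".sam")
  write_sam(aln, idx, f)
  back <- read_sam(f)
  expect_equal(nrow(back), nrow(aln))
  ord <- match(aln$read_id, back$read_id)
  expect_equal(back$ref_start[ord], aln$ref_start)
  expect_equal(back$strand[ord], aln$strand)
  expect_equal(back$duplicate[ord], aln$duplicate)
  expect_equal(back$read_seq[ord], aln$read_seq)
})
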