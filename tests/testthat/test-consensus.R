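test_that("pileup accumulates per-site base counts on the reference frame", {
  ref <- circ_seq("ACGTTACG", id = "r")
  p <- pileup(manual_alignment(1, "ACG"), ref)
  expect_equal(p$depth, c(1L, 1L, 1L, 0L, 0L, 0L, 0L, 0L))
  expect_equal(p$counts[1, "A"], c(A = 1L))

  p2 <- pileup(manual_alignment(c(1, 2), c("ACG", "CGT")), ref)
  expect_equal(p2$depth[2], 2L)
  expect_equal(tidy(p2)$depth, p2$depth)

  # origin-wrapping alignment contributes to both arcs
  p3 <- pileup(manual_alignment(7, "CGAC"), ref)
  expect_equal(p3$depth, c(1L, 1L, 0L, 0L, 0L, 0L, 1L, 1L))

  lin <- circ_seq("ACGTTACG", circular = FALSE)
  expect_error(pileup(manual_alignment(7, "CGAC"), lin), "beyond")
})

test_that("pileup is equivariant under reference rotation", {
  g <- random_genome(1500, seed = 1)
  fr <- simulate_fragments(g, fragment_model(), 800, seed = 2)
  reads <- setNames(museomt:::fragment_sequences(g, fr),
                    sprintf("r%04d", seq_len(nrow(fr))))
  rot <- 200L
  a1 <- map_reads(reads, build_index(g))
  a2 <- map_reads(reads, build_index(rotate(g, rot)))
  p1 <- pileup(a1, g)
  p2 <- pileup(a2, rotate(g, rot))
  # back-transform rotated-frame counts to the unrotated frame
  back <- rbind(p2$counts[(1500 - rot + 1):1500, ], p2$counts[1:(1500 - rot), ])
  expect_equal(unname(back), unname(p1$counts))
})

test_that("consensus calls need depth 3 and a strict majority", {
  ref <- circ_seq("ACGTA", circular = FALSE)
  aln <- manual_alignment(c(1, 1), c("ACGTA", "ACGTA"))
  cons <- call_consensus(pileup(aln, ref))
  expect_equal(cons$sequence, "NNNNN")     # depth 2 < 3 everywhere

  aln3 <- manual_alignment(c(1, 1, 1), c("ACGTA", "ACGTA", "ACGTA"))
  expect_equal(call_consensus(pileup(aln3, ref))$sequence, "ACGTA")

  tie <- manual_alignment(c(1, 1, 1, 1), c("A", "A", "G", "G"))
  expect_equal(substr(call_consensus(pileup(tie, ref))$sequence, 1, 1), "N")

  mix <- manual_alignment(c(1, 1, 1), c("A", "A", "G"))
  expect_equal(substr(call_consensus(pileup(mix, ref))$sequence, 1, 1), "A")
})

test_that("error-free simulation at depth 35 reproduces the planted genome", {
  g <- random_genome(2500, seed = 3)
  vars <- withr::with_seed(4, {
    sites <- sort(sample.int(2500, 8))
    chars <- strsplit(as.character(g), NULL)[[1]]
    tibble(site = sites, ref_base = chars[sites],
           alt = vapply(chars[sites],
                        function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                        ""),
           kind = "substitution")
  })
  mut <- plant_variants(g, vars)$genome
  sim <- simulate_readset(mut, fragment_model(),
                          damage_model(p_max = 0, p_base = 0, seq_error = 0),
                          sim_config(35, seed = 5))
  aln <- filter_alignments(mark_duplicates(map_reads(sim$reads,
                                                     build_index(g))))
  cons <- call_consensus(pileup(aln, g))
  called <- strsplit(cons$sequence, NULL)[[1]]
  truth <- strsplit(as.character(mut), NULL)[[1]]
  idx <- which(called != "N")
  expect_equal(called[idx], truth[idx])
  expect_gt(cons$called_fraction, 0.99)
})

test_that("rotation passes recover terminal sites a linear mapping leaves uncalled", {
  g <- random_genome(2000, seed = 6)
  sim <- simulate_readset(g, fragment_model(),
                          damage_model(p_max = 0, p_base = 0, seq_error = 0),
                          sim_config(30, seed = 7))
  # linear single pass: origin-spanning reads cannot map, terminal depth
  # collapses and the first/last sites are N
  lin <- circ_seq(as.character(g), id = g$id, circular = FALSE)
  aln_lin <- filter_alignments(mark_duplicates(
    map_reads(sim$reads, build_index(lin))))
  cons_lin <- call_consensus(pileup(aln_lin, lin))
  term <- c(1:2, 1999:2000)
  expect_true(any(strsplit(cons_lin$sequence, NULL)[[1]][term] == "N"))

  merged <- recover_terminal(sim$reads, g, rotation_bp = 200)
  expect_equal(strsplit(merged$sequence, NULL)[[1]][term],
               strsplit(as.character(g), NULL)[[1]][term])
  expect_gt(merged$called_fraction, 0.999)

  # rotation 0 reduces to the single circular pass
  single <- recover_terminal(sim$reads, g, rotation_bp = 0)
  aln_circ <- filter_alignments(mark_duplicates(
    map_reads(sim$reads, build_index(g))))
  expect_equal(single$sequence,
               call_consensus(pileup(aln_circ, g))$sequence)

  # deep error-free data: both passes agree everywhere
  expect_equal(merged$sequence, single$sequence)
  expect_error(recover_terminal(sim$reads, lin), "circular")
})

test_that("mask arithmetic reproduces the two-interval 510-bp example", {
  g <- random_genome(17408, seed = 8)
  cons <- museomt:::new_consensus(as.character(g), "r", 3L)
  masked <- mask_regions(cons, g, read_len_max = 75,
                         manual_intervals = tibble(
                           start = c(15192L, 16856L),
                           end = c(15294L, 17262L)))
  expect_equal(stringr::str_count(masked$sequence, "N"), 510)
  expect_equal(masked$called_fraction, (17408 - 510) / 17408)
  expect_equal(nrow(masked$mask_intervals), 2)
})

test_that("repeats longer than the read length are masked automatically", {
  left <- random_genome(300, seed = 9)
  right <- random_genome(300, seed = 10)
  s <- paste0(as.character(left), strrep("A", 80), as.character(right))
  g <- circ_seq(s, id = "hp")
  cons <- museomt:::new_consensus(s, "hp", 3L)
  masked <- mask_regions(cons, g, read_len_max = 75)
  expect_equal(masked$mask_intervals$reason, "repeat")
  expect_true(all(strsplit(masked$sequence, NULL)[[1]][301:380] == "N"))

  # an 80-bp span of a 10-mer tandem repeat also qualifies
  s2 <- paste0(as.character(left), strrep("ACGTTGCAAT", 8),
               as.character(right))
  m2 <- mask_regions(museomt:::new_consensus(s2, "tr", 3L),
                     circ_seq(s2, id = "tr"), read_len_max = 75)
  expect_equal(nrow(m2$mask_intervals), 1)

  # no qualifying repeat, no manual interval: untouched
  clean <- mask_regions(cons, random_genome(681, seed = 11),
                        read_len_max = 75)
  expect_equal(clean$sequence, s)
  # overlapping manual intervals merge
  m3 <- mask_regions(cons, g, manual_intervals = tibble(
    start = c(10L, 20L), end = c(30L, 40L)))
  man <- m3$mask_intervals[m3$mask_intervals$reason == "manual", ]
  expect_equal(nrow(man), 1)
  expect_equal(c(man$start, man$end), c(10L, 40L))
})

test_that("homopolymer indel candidates need agreeing spanning reads and no reference support", {
  # reference with a 14-mer C run; reads show 13 Cs then the correct
  # downstream flank (the shift signature of a single-base deletion)
  s <- paste0("ATGAAGTCAGGTTCAGATAA", strrep("C", 14), "GGTCAGTAGACTTGACTGAC")
  ref <- circ_seq(s, id = "hp", circular = FALSE)
  mut <- paste0(substr(s, 1, 20), strrep("C", 13), substr(s, 35, 54))
  two <- manual_alignment(c(15, 17), c(substr(mut, 15, 44), substr(mut, 17, 48)))
  cand <- call_homopolymer_indels(pileup(two, ref), ref)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$site, 21L)
  expect_equal(cand$ref_len, 14L)
  expect_equal(cand$alt_len, 13L)
  expect_equal(cand$support, 2L)
  expect_equal(cand$flag, "manual-confirmation")

  one <- call_homopolymer_indels(pileup(two[1, ], ref), ref)
  expect_equal(nrow(one), 0)   # support 1 < 2

  # a read supporting the reference length vetoes the candidate
  refread <- manual_alignment(15, substr(s, 15, 44), read_id = "ok")
  veto <- call_homopolymer_indels(pileup(bind_rows(two, refread), ref), ref)
  expect_equal(nrow(veto), 0)
})

test_that("a planted homopolymer deletion is recovered from simulated reads", {
  chars <- strsplit(as.character(random_genome(2000, seed = 12)), NULL)[[1]]
  chars[1000:1013] <- "C"; chars[999] <- "A"; chars[1014] <- "G"
  ref <- circ_seq(paste(chars, collapse = ""), id = "toy")
  mut <- plant_variants(ref, tibble(site = 1013L, ref_base = "C",
                                    alt = "-", kind = "deletion"))$genome
  sim <- simulate_readset(mut, fragment_model(),
                          damage_model(p_max = 0, p_base = 0, seq_error = 0),
                          sim_config(300, seed = 13))
  aln <- filter_alignments(mark_duplicates(map_reads(sim$reads,
                                                     build_index(ref))))
  cand <- call_homopolymer_indels(pileup(aln, ref), ref)
  expect_true(any(cand$site == 1000L & cand$ref_len == 14L &
                    cand$alt_len == 13L))
})

test_that("applying an indel candidate shifts downstream coordinates", {
  cand <- tibble(site = 5L, base = "C", ref_len = 4L, alt_len = 3L,
                 ref_allele = "CCCC", alt_allele = "CCC", support = 2L,
                 spanning = 2L, flag = "manual-confirmation")
  out <- apply_indels("ATGACCCCGTA", cand)
  expect_equal(out$sequence, "ATGACCCGTA")
  expect_equal(out$map$mutated[9:11], 8:10)   # downstream shifted by -1
  expect_true(is.na(out$map$mutated[8]))
})

test_that("consensus is invariant to read input order", {
  g <- random_genome(1200, seed = 14)
  sim <- simulate_readset(g, fragment_model(), damage_model(),
                          sim_config(15, seed = 15))
  shuffled <- sim$reads[withr::with_seed(16, sample.int(nrow(sim$reads))), ]
  c1 <- recover_terminal(sim$reads, g)
  c2 <- recover_terminal(shuffled, g)
  expect_equal(c1$sequence, c2$sequence)
})
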