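test_that("transition/transversion classification follows base chemistry", {
  expect_equal(classify_ts_tv("A", "G"), "transition")
  expect_equal(classify_ts_tv("T", "G"), "transversion")
  expect_equal(classify_ts_tv(c("C", "A", "G"), c("T", "C", "T")),
               c("transition", "transversion", "transversion"))
  expect_error(classify_ts_tv("A", "A"), "differ")
})

test_that("the vertebrate mitochondrial code drives translation", {
  expect_equal(mt_translate(c("TGA", "ATA", "AGA", "AGG")),
               c("W", "M", "*", "*"))
  expect_equal(mt_translate("TGA", code = "1"), "*")  # standard code differs
  expect_equal(mt_translate(c("GGC", "GAC", "GAG", "GCG")),
               c("G", "D", "E", "A"))
  expect_true(is.na(mt_translate("GN-")))
})

test_that("codon annotation is strand- and phase-aware", {
  # + strand gene at 4..15 (ATG GGC GAG TAA), - strand gene at 31..42
  # whose coding sequence is also ATG GGC GAG TAA (genomic revcomp)
  plus_cds <- "ATGGGCGAGTAA"
  g <- circ_seq(paste0("AAA", plus_cds, "TTTTTTTTTTTTTTT",
                       rc(plus_cds), "AAA"),
                id = "toy", circular = FALSE)
  feats <- tibble(name = c("geneP", "geneM"), ftype = "protein_coding",
                  start = c(4L, 31L), end = c(15L, 42L),
                  strand = c("+", "-"), phase = c(0L, 0L))
  # ggc -> gac at codon position 2 is G/D, non-synonymous
  ann <- annotate_codon(8, g, "A", feats)
  expect_equal(ann$codon_position, 2L)
  expect_equal(c(ann$ref_codon, ann$alt_codon), c("GGC", "GAC"))
  expect_equal(c(ann$ref_aa, ann$alt_aa), c("G", "D"))
  expect_false(ann$synonymous)

  # gag -> gcg at position 2 is E/A
  ann2 <- annotate_codon(11, g, "C", feats)
  expect_equal(c(ann2$ref_codon, ann2$alt_codon), c("GAG", "GCG"))
  expect_equal(c(ann2$ref_aa, ann2$alt_aa), c("E", "A"))

  # minus-strand gene: genomic site 38 is codon position 2 of GGC, and the
  # genomic C->T change reads as coding-strand G->A (gac), i.e. G/D again
  ann3 <- annotate_codon(38, g, "T", feats)
  expect_equal(ann3$codon_position, 2L)
  expect_equal(c(ann3$ref_codon, ann3$alt_codon), c("GGC", "GAC"))
  expect_equal(c(ann3$ref_aa, ann3$alt_aa), c("G", "D"))

  # tgg -> tga at position 3 is synonymous only under the mitochondrial code
  g2 <- circ_seq("TGGAAA", circular = FALSE)
  f2 <- tibble(name = "w", ftype = "protein_coding", start = 1L, end = 6L,
               strand = "+", phase = 0L)
  a4 <- annotate_codon(3, g2, "A", f2)
  expect_true(a4$synonymous)
  expect_false(annotate_codon(3, g2, "A", f2, code = "1")$synonymous)

  # phase shifts the codon frame
  g3 <- circ_seq("GATGGGC", circular = FALSE)
  f3 <- tibble(name = "p", ftype = "protein_coding", start = 1L, end = 7L,
               strand = "+", phase = 1L)
  a5 <- annotate_codon(5, g3, "A", f3)
  expect_equal(a5$codon_position, 1L)
  expect_equal(a5$ref_codon, "GGC")

  # outside coding features the codon fields are absent
  a6 <- annotate_codon(20, g, "A", feats)
  expect_equal(a6$feature, "intergenic/control")
  expect_true(is.na(a6$codon_position))
})

test_that("pairwise differences recover a planted variant set exactly", {
  expect_equal(nrow(pairwise_differences(new_alignment(
    c(a = "ACGT", b = "ACGT")))), 0)

  g <- random_genome(2000, seed = 1, circular = FALSE)
  chars <- strsplit(as.character(g), NULL)[[1]]
  vars <- withr::with_seed(2, {
    sites <- sort(sample.int(1990, 10))
    tibble(site = sites, ref_base = chars[sites],
           alt = vapply(chars[sites],
                        function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                        ""),
           kind = "substitution")
  })
  alt_chars <- chars
  alt_chars[vars$site] <- vars$alt
  alt_chars[1995] <- "-"   # single-base deletion as a gap column
  aln <- new_alignment(c(ref = paste(chars, collapse = ""),
                         alt = paste(alt_chars, collapse = "")))
  d <- pairwise_differences(aln)
  expect_equal(sum(d$kind == "substitution"), 10)
  expect_equal(sum(d$kind == "indel"), 1)
  subs <- d[d$kind == "substitution", ]
  expect_equal(subs$site, vars$site)
  expect_equal(subs$alt_base, unname(vars$alt))
  expect_equal(subs$ts_tv, classify_ts_tv(vars$ref_base, vars$alt))
})

test_that("a gap run inside a homopolymer yields one indel record", {
  ref <- paste0(strrep("A", 5), strrep("C", 14), strrep("G", 5))
  alt <- paste0(strrep("A", 5), strrep("C", 13), "-", strrep("G", 5))
  d <- pairwise_differences(new_alignment(c(r = ref, q = alt)))
  expect_equal(nrow(d), 1)
  expect_equal(d$kind, "indel")
  expect_equal(d$ts_tv, "not_applicable")
  expect_equal(d$alt_base, "-")

  # a multi-column gap run still counts once
  alt2 <- paste0(strrep("A", 5), strrep("C", 11), "---", strrep("G", 5))
  d2 <- pairwise_differences(new_alignment(c(r = ref, q = alt2)))
  expect_equal(nrow(d2), 1)
  expect_equal(nchar(d2$ref_base), 3)
})

test_that("columns with missing data are skipped", {
  d <- pairwise_differences(new_alignment(c(r = "ACGTAC", q = "ANGTNC")))
  expect_equal(nrow(d), 0)
  d2 <- pairwise_differences(new_alignment(c(r = "ACGTAC", q = "TNGTNC")))
  expect_equal(d2$site, 1L)
})

test_that("pair summaries split counts by region and report headline divergence", {
  diffs <- tibble(site = c(100L, 500L, 900L, 950L),
                  ref_base = c("A", "C", "G", "C"),
                  alt_base = c("G", "T", "A", "-"),
                  kind = c("substitution", "substitution", "substitution",
                           "indel"))
  s <- summarize_pair(diffs, tibble(start = 800L, end = 1000L),
                      covered_length = 1000L)
  expect_equal(s$substitutions, 3)
  expect_equal(s$indels, 1)
  expect_equal(s$substitutions_excl, 2)
  expect_equal(s$indels_excl, 0)
  expect_equal(s$rate_in_region, 1 / 201)
  expect_equal(s$rate_outside_region, 2 / 799)
  expect_equal(s$percent_divergence, 0.4)

  s0 <- summarize_pair(diffs[0, ], NULL, covered_length = 1000L)
  expect_equal(s0$substitutions, 0)
  expect_equal(s0$percent_divergence, 0)
  expect_error(summarize_pair(diffs, tibble(start = 900L, end = 1200L),
                              covered_length = 1000L), "bounds")
})

test_that("pairwise-deletion distances ignore missing columns per pair", {
  expect_equal(distance_matrix(new_alignment(c(a = "ACGT", b = "ACGT")))[1, 2], 0)
  expect_equal(distance_matrix(new_alignment(c(a = "ACGT", b = "ACGA")))[1, 2], 0.25)
  expect_equal(distance_matrix(new_alignment(c(a = "ACNT", b = "ACGA")))[1, 2], 1 / 3)

  aln <- random_alignment(5, 300, seed = 3)
  d <- distance_matrix(aln)
  expect_equal(d, t(d))
  expect_equal(diag(d), setNames(rep(0, 5), names(aln)))
  # adding an all-N column changes nothing
  aln2 <- new_alignment(setNames(paste0(unclass(aln), "N"), names(aln)))
  expect_equal(distance_matrix(aln2), d)
  # independent cross-check against the classical raw-distance routine
  bin <- ape::as.DNAbin(do.call(rbind, strsplit(tolower(unclass(aln)), NULL)))
  ref_d <- as.matrix(ape::dist.dna(bin, model = "raw",
                                   pairwise.deletion = TRUE))
  expect_equal(unname(d), unname(ref_d[names(aln), names(aln)]),
               tolerance = 1e-12)
})

test_that("global alignment of near-identical genomes feeds the difference table", {
  g <- random_genome(600, seed = 4, circular = FALSE)
  chars <- strsplit(as.character(g), NULL)[[1]]
  chars[100] <- setdiff(c("A", "C", "G", "T"), chars[100])[1]
  alt <- paste(chars[-300], collapse = "")   # one substitution + one deletion
  aln <- align_pair(g, circ_seq(alt, id = "alt", circular = FALSE))
  expect_equal(attr(aln, "columns"), 600L)
  d <- pairwise_differences(aln)
  expect_equal(sum(d$kind == "substitution"), 1)
  expect_equal(sum(d$kind == "indel"), 1)
  expect_equal(d$site[d$kind == "substitution"], 100L)
})

test_that("the shipped difference set reclassifies to the published counts", {
  tbl <- shipped_difference_table()
  s <- summarize_differences(tbl)
  expect_equal(s$n_records, 27L)
  expect_equal(s$substitutions, 26L)
  expect_equal(s$indels, 1L)
  expect_equal(s$transitions, 21L)
  expect_equal(s$transversions, 5L)
  expect_equal(s$aa_substitutions, 6L)
  # recomputed amino acids agree with the printed ones where printed
  cl <- classify_differences(tbl)
  printed <- !is.na(tbl$ref_aa)
  expect_equal(cl$ref_aa[printed], toupper(tbl$ref_aa[printed]))
  expect_equal(cl$alt_aa[printed], toupper(tbl$alt_aa[printed]))
})
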