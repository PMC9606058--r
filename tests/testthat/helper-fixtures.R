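library(tibble)
library(dplyr)

random_genome <- function(n, seed = 1, id = "ref", circular = TRUE) {
  withr::with_seed(seed, {
    circ_seq(paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                   collapse = ""), id = id, circular = circular)
  })
}

# Alignment tibble straight from simulation truth (no mapper involved):
# lets damage/consensus modules be tested independently of mapping.
truth_alignments <- function(frags, reads) {
  tibble(
    read_id = sprintf("r%06d", seq_len(nrow(frags))),
    ref_start = frags$start,
    strand = frags$strand,
    length = frags$length,
    read_seq = reads,
    score = as.double(frags$length),
    mismatches = 0L,
    unique = TRUE,
    duplicate = FALSE
  )
}

manual_alignment <- function(ref_start, read_seq, strand = "+",
                             read_id = NULL) {
  n <- length(ref_start)
  tibble(
    read_id = read_id %||% sprintf("m%03d", seq_len(n)),
    ref_start = as.integer(ref_start),
    strand = strand,
    length = nchar(read_seq),
    read_seq = toupper(read_seq),
    score = as.double(nchar(read_seq)),
    mismatches = 0L,
    unique = TRUE,
    duplicate = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

rc <- function(x) museomt:::revcomp(x)

# Exhaustive best ungapped placement of a read over all rotations and both
# strands of a circular reference; independent oracle for the seeded mapper.
brute_best_placement <- function(read, ref) {
  L <- seq_length(ref)
  l <- nchar(read)
  ext <- paste0(as.character(ref), substr(as.character(ref), 1, l - 1))
  extraw <- charToRaw(ext)
  best <- list(mm = Inf)
  for (strand in c("+", "-")) {
    q <- charToRaw(if (strand == "+") read else rc(read))
    for (s in seq_len(L)) {
      mm <- sum(extraw[s:(s + l - 1)] != q)
      if (mm < best$mm) best <- list(mm = mm, start = s, strand = strand)
    }
  }
  best
}

# Exhaustive minimum-parsimony score: enumerate all assignments of internal
# nodes over the observed states, per site. Independent oracle for the
# Fitch reconstruction (small trees only).
oracle_parsimony <- function(tree, alignment) {
  if (!ape::is.rooted(tree)) {
    tree <- ape::root(tree, outgroup = tree$tip.label[1], resolve.root = TRUE)
  }
  if (!ape::is.binary(tree)) tree <- ape::multi2di(tree, random = FALSE)
  ntip <- length(tree$tip.label)
  nint <- tree$Nnode
  edge <- tree$edge
  tipmat <- do.call(rbind,
                    strsplit(unname(unclass(alignment[tree$tip.label])), NULL))
  total_score <- 0L
  for (s in seq_len(ncol(tipmat))) {
    obs <- tipmat[, s]
    states <- sort(unique(obs[obs %in% c("A", "C", "G", "T")]))
    if (length(states) <= 1L) next
    combos <- as.matrix(expand.grid(rep(list(states), nint),
                                    stringsAsFactors = FALSE))
    G <- nrow(combos)
    M <- matrix("", nrow = ntip + nint, ncol = G)
    M[seq_len(ntip), ] <- obs
    M[(ntip + 1):(ntip + nint), ] <- t(combos)
    changes <- integer(G)
    for (e in seq_len(nrow(edge))) {
      a <- M[edge[e, 1], ]; b <- M[edge[e, 2], ]
      ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
      changes <- changes + (ok & a != b)
    }
    total_score <- total_score + min(changes)
  }
  total_score
}

random_alignment <- function(ntip, nsites, seed, labels = NULL) {
  withr::with_seed(seed, {
    rows <- vapply(seq_len(ntip), function(i) {
      paste(sample(c("A", "C", "G", "T"), nsites, replace = TRUE),
            collapse = "")
    }, "")
    names(rows) <- labels %||% paste0("t", seq_len(ntip))
    new_alignment(rows)
  })
}

# 14-sequence fixture shaped like a published CO1 haplotype genealogy:
# 11 individuals share the majority haplotype, three more carry private
# haplotypes one substitution away.
hapgraph_fixture <- function(nsites = 60, seed = 3) {
  withr::with_seed(seed, {
    base <- paste(sample(c("A", "C", "G", "T"), nsites, replace = TRUE),
                  collapse = "")
    mut_at <- function(s, pos) {
      ch <- substr(s, pos, pos)
      alt <- setdiff(c("A", "C", "G", "T"), ch)[1]
      substr(s, pos, pos) <- alt
      s
    }
    rows <- c(setNames(rep(base, 11), sprintf("maj%02d", 1:11)),
              priv1 = mut_at(base, 5),
              priv2 = mut_at(base, 20),
              priv3 = mut_at(base, 40))
    aln <- new_alignment(rows)
    tree <- ape::read.tree(text = paste0(
      "((priv1,(maj01,maj02)),((priv2,(maj03,maj04)),",
      "((maj05,maj06),((priv3,(maj07,maj08)),(maj09,(maj10,maj11))))));"
    ))
    list(alignment = aln, tree = tree)
  })
}
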