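#' Fitch-parsimony ancestral sequence reconstruction
#'
#' Classic two-pass Fitch parsimony on a rooted binary tree, fully
#' deterministic: the bottom-up pass computes per-site state sets and the
#' parsimony score; the top-down pass resolves them — the root takes the
#' lexicographically smallest state in its set, children inherit the parent
#' state when it is in their set and otherwise take their own
#' lexicographically smallest state. Alignment sites with gaps or `N`
#' contribute no state (missing data) and are reconstructed as `N` where no
#' information exists. Unrooted trees are rooted at the first tip's pendant
#' edge and polytomies resolved deterministically, neither changing the
#' collapsed graph.
#'
#' @param tree An `ape::phylo`; tips must be bijective with alignment rows.
#' @param alignment A `seq_alignment` (see [read_alignment()]).
#' @return A `fitch_reconstruction`: `tree` (as used), `states` (character
#'   matrix, rows = tips then internal nodes in `phylo` numbering),
#'   `score` (total parsimony changes).
#' @export
fitch_ancestral <- function(tree, alignment) {
  if (is.null(tree$tip.label) || any(!nzchar(tree$tip.label))) {
    abort("tree has unlabelled tips")
  }
  miss <- setdiff(tree$tip.label, names(alignment))
  extra <- setdiff(names(alignment), tree$tip.label)
  if (length(miss) || length(extra)) {
    abort(sprintf("tip/alignment id mismatch: missing [%s], extra [%s]",
                  paste(miss, collapse = ","), paste(extra, collapse = ",")))
  }
  if (!ape::is.rooted(tree)) {
    tree <- ape::root(tree, outgroup = tree$tip.label[1], resolve.root = TRUE)
  }
  if (!ape::is.binary(tree)) tree <- ape::multi2di(tree, random = FALSE)
  tree <- ape::reorder.phylo(tree, "postorder")

  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  total <- ntip + nnode
  ncol_aln <- attr(alignment, "columns")
  tipmat <- do.call(rbind,
                    strsplit(unname(unclass(alignment[tree$tip.label])), NULL))
  bit <- c(A = 1L, C = 2L, G = 4L, T = 8L)
  # state-set masks: rows nodes, cols sites; 0 = missing
  mask <- matrix(0L, nrow = total, ncol = ncol_aln)
  mask[seq_len(ntip), ] <- matrix(
    ifelse(tipmat %in% DNA_BASES, bit[tipmat], 0L), nrow = ntip)

  edge <- tree$edge
  score <- 0L
  # bottom-up: postorder edge list groups children before parents
  for (nd in unique(edge[, 1])) {
    ch <- edge[edge[, 1] == nd, 2]
    m <- mask[ch[1], ]
    for (c2 in ch[-1]) {
      m2 <- mask[c2, ]
      inter <- bitwAnd(m, m2)
      uni <- bitwOr(m, m2)
      use_union <- inter == 0L & m != 0L & m2 != 0L
      score <- score + sum(use_union)
      m <- ifelse(m == 0L, m2, ifelse(m2 == 0L, m,
                                      ifelse(inter != 0L, inter, uni)))
    }
    mask[nd, ] <- m
  }

  lex_first <- function(msk) {
    # lexicographically smallest base in a bitmask (A<C<G<T = bit order)
    out <- rep(NA_integer_, length(msk))
    for (b in 1:4) {
      hit <- is.na(out) & bitwAnd(msk, bit[b]) != 0L
      out[hit] <- bit[b]
    }
    out
  }
  assigned <- matrix(0L, nrow = total, ncol = ncol_aln)
  root <- ntip + 1L
  rl <- lex_first(mask[root, ])
  assigned[root, ] <- ifelse(is.na(rl), 0L, rl)
  # top-down in reverse postorder (parents before children)
  for (e in rev(seq_len(nrow(edge)))) {
    par <- edge[e, 1]; ch <- edge[e, 2]
    pm <- assigned[par, ]
    cm <- mask[ch, ]
    inherit <- bitwAnd(pm, cm) != 0L
    cl <- lex_first(cm)
    assigned[ch, ] <- ifelse(cm == 0L, 0L, ifelse(inherit, pm,
                                                  ifelse(is.na(cl), 0L, cl)))
  }
  base_of <- setNames(c("A", "C", "G", "T", "N"), c(1L, 2L, 4L, 8L, 0L))
  states <- matrix(base_of[as.character(assigned)], nrow = total)
  rownames(states) <- c(tree$tip.label, paste0("node", seq_len(nnode) + ntip))
  structure(list(tree = tree, states = states, score = score),
            class = "fitch_reconstruction")
}

#' @export
print.fitch_reconstruction <- function(x, ...) {
  cat(sprintf("<fitch_reconstruction> %d tips, %d sites, parsimony score %d\n",
              length(x$tree$tip.label), ncol(x$states), x$score))
  invisible(x)
}

# Substitution count between two sequences on comparable (non-N) sites.
hap_dist <- function(a, b) {
  comp <- a != "N" & b != "N"
  sum(a[comp] != b[comp])
}

#' Collapse a reconstructed tree into a haplotype genealogy graph
#'
#' Contracts every branch whose endpoint sequences are identical on
#' comparable sites, merges the resulting nodes accumulating tip
#' multiplicities, and weights the remaining edges by pairwise substitution
#' counts. Internal nodes matching no sampled sequence are retained as
#' inferred haplotypes of multiplicity zero. Node radii in the classic
#' drawing are proportional to multiplicity.
#'
#' @param fr A [fitch_ancestral()] reconstruction.
#' @return A `haplotype_graph`: `nodes` tibble (`id`, `sequence`,
#'   `multiplicity`, `members` list-column), `edges` tibble (`from`, `to`,
#'   `weight`), attribute `score`.
#' @export
build_graph <- function(fr) {
  tree <- fr$tree
  states <- fr$states
  ntip <- length(tree$tip.label)
  total <- nrow(states)
  edge <- tree$edge
  w <- vapply(seq_len(nrow(edge)), function(e) {
    hap_dist(states[edge[e, 1], ], states[edge[e, 2], ])
  }, 0L)

  parent <- seq_len(total)                    # union-find over zero edges
  for (e in which(w == 0L)) {
    a <- edge[e, 1]; b <- edge[e, 2]
    while (parent[a] != a) a <- parent[a]
    while (parent[b] != b) b <- parent[b]
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  comp <- vapply(seq_len(total), function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }, 0L)

  groups <- split(seq_len(total), comp)
  node_tbl <- purrr::map_dfr(groups, function(members) {
    tips <- members[members <= ntip]
    # representative sequence: per site, first non-N across members
    sm <- states[members, , drop = FALSE]
    rep_seq <- apply(sm, 2, function(col) {
      nz <- col[col != "N"]
      if (length(nz)) nz[1] else "N"
    })
    tibble(comp = members[1],
           sequence = paste(rep_seq, collapse = ""),
           multiplicity = length(tips),
           members = list(sort(tree$tip.label[tips])))
  })
  node_tbl <- arrange(node_tbl, desc(.data$multiplicity),
                      purrr::map_chr(.data$members,
                                     ~ if (length(.x)) .x[1] else "~"))
  sampled <- node_tbl$multiplicity > 0L
  node_tbl$id <- NA_character_
  node_tbl$id[sampled] <- paste0("H", seq_len(sum(sampled)))
  node_tbl$id[!sampled] <- paste0("I", seq_len(sum(!sampled)))

  comp_id <- setNames(node_tbl$id, node_tbl$comp)
  keep <- which(w > 0L)
  edges <- tibble(
    from = comp_id[as.character(comp[edge[keep, 1]])],
    to = comp_id[as.character(comp[edge[keep, 2]])],
    weight = as.integer(w[keep])
  )

  # An inferred (unsampled) haplotype that merely sits on the path between
  # two other haplotypes carries no information: splice its two edges into
  # one, summing the substitution counts; prune dangling inferred nodes.
  # Inferred nodes are kept only where the genealogy branches (degree >= 3).
  repeat {
    deg <- table(c(edges$from, edges$to))
    inferred <- node_tbl$id[node_tbl$multiplicity == 0L]
    chain <- inferred[inferred %in% names(deg)[deg == 2L]]
    dangling <- inferred[!inferred %in% names(deg)[deg >= 2L]]
    if (length(chain)) {
      nd <- chain[1]
      hit <- edges$from == nd | edges$to == nd
      pair <- edges[hit, ]
      other <- ifelse(pair$from == nd, pair$to, pair$from)
      edges <- bind_rows(edges[!hit, ],
                         tibble(from = other[1], to = other[2],
                                weight = sum(pair$weight)))
      node_tbl <- node_tbl[node_tbl$id != nd, ]
    } else if (length(dangling)) {
      nd <- dangling[1]
      edges <- edges[edges$from != nd & edges$to != nd, ]
      node_tbl <- node_tbl[node_tbl$id != nd, ]
    } else {
      break
    }
  }
  edges <- if (nrow(edges)) {
    edges |>
      mutate(a = pmin(.data$from, .data$to),
             b = pmax(.data$from, .data$to)) |>
      group_by(.data$a, .data$b) |>
      summarise(weight = as.integer(min(.data$weight)), .groups = "drop") |>
      select(from = "a", to = "b", "weight") |>
      arrange(.data$from, .data$to)
  } else {
    tibble(from = character(), to = character(), weight = integer())
  }

  structure(list(nodes = select(node_tbl, "id", "sequence", "multiplicity",
                                "members"),
                 edges = edges),
            score = fr$score, class = "haplotype_graph")
}

#' @export
print.haplotype_graph <- function(x, ...) {
  cat(sprintf("<haplotype_graph> %d haplotypes (%d inferred), %d edges, total weight %d\n",
              nrow(x$nodes), sum(x$nodes$multiplicity == 0L),
              nrow(x$edges), sum(x$edges$weight)))
  invisible(x)
}

#' @rdname build_graph
#' @param x A `haplotype_graph`.
#' @param ... Unused.
#' @export
tidy.haplotype_graph <- function(x, ...) x$nodes

#' @rdname build_graph
#' @export
glance.haplotype_graph <- function(x, ...) {
  tibble(n_nodes = nrow(x$nodes),
         n_inferred = sum(x$nodes$multiplicity == 0L),
         n_edges = nrow(x$edges),
         total_weight = sum(x$edges$weight),
         n_sequences = sum(x$nodes$multiplicity))
}

#' Export a haplotype graph
#'
#' DOT output sizes nodes proportionally to multiplicity; JSON output
#' round-trips through [read_graph_json()]. Node ordering is deterministic.
#'
#' @param g A `haplotype_graph`.
#' @param path Output file.
#' @param format `"dot"` or `"json"`.
#' @export
export_graph <- function(g, path, format = c("dot", "json")) {
  format <- match.arg(format)
  if (format == "dot") {
    n <- g$nodes
    lines <- c(
      "graph haplotypes {",
      "  node [shape=circle];",
      sprintf('  %s [label="%s (%d)", width=%.2f];', n$id, n$id,
              n$multiplicity, 0.3 + 0.2 * sqrt(n$multiplicity)),
      sprintf('  %s -- %s [label="%d"];', g$edges$from, g$edges$to,
              g$edges$weight),
      "}")
    writeLines(lines, path)
  } else {
    jsonlite::write_json(
      list(nodes = mutate(g$nodes, members = purrr::map(.data$members,
                                                        as.list)),
           edges = g$edges,
           score = attr(g, "score")),
      path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

#' Read a haplotype graph from its JSON serialisation
#' @param path JSON file written by [export_graph()].
#' @export
read_graph_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
  nodes <- as_tibble(j$nodes)
  nodes$members <- purrr::map(nodes$members, as.character)
  nodes$multiplicity <- as.integer(nodes$multiplicity)
  edges <- as_tibble(j$edges)
  if (nrow(edges)) edges$weight <- as.integer(edges$weight)
  else edges <- tibble(from = character(), to = character(), weight = integer())
  structure(list(nodes = nodes, edges = edges),
            score = j$score, class = "haplotype_graph")
}
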