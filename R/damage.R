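#' Per-position mismatch spectrum from both read ends
#'
#' The classical post-mortem damage plot: for each position within the
#' first `window` bases from the 5' and 3' read ends and each ordered base
#' pair (reference -> read), the mismatch frequency conditioned on the
#' reference base at risk (mismatches / opportunities, not / all bases).
#' Positions are counted in read orientation; for minus-strand alignments
#' both read and reference slice are reverse-complemented first. Reads
#' shorter than `2 * window` contribute each base to its nearer end only
#' (ties to the 5' end), so no base is double counted.
#'
#' @param alignments Alignment tibble (ungapped, from [map_reads()]).
#' @param ref The reference [circ_seq()].
#' @param window Positions per end (default 25).
#' @return A `damage_profile`: tibble with `end` ("5p"/"3p"), `position`
#'   (0-based distance from the end), `ref`, `read`, `count`,
#'   `opportunities`, `frequency`.
#' @export
damage_profile <- function(alignments, ref, window = 25L) {
  grid <- tidyr::expand_grid(
    end = c("5p", "3p"), position = 0:(window - 1L),
    ref = DNA_BASES, read = DNA_BASES
  ) |> filter(TRUE)
  if (nrow(alignments) == 0L) {
    out <- mutate(grid, count = 0L, opportunities = 0L, frequency = NA_real_) |>
      filter(.data$ref != .data$read)
    return(structure(out, window = window, class = c("damage_profile",
                                                     class(out))))
  }
  L <- seq_length(ref)
  refstr <- if (ref$circular) {
    paste0(as.character(ref), substr(as.character(ref), 1L,
                                     max(alignments$length)))
  } else {
    as.character(ref)
  }
  lens <- alignments$length
  ref_slice <- substring(refstr, alignments$ref_start,
                         alignments$ref_start + lens - 1L)
  read_seq <- alignments$read_seq
  neg <- alignments$strand == "-"
  ref_slice[neg] <- revcomp(ref_slice[neg])  # read orientation

  rchar <- strsplit(paste(ref_slice, collapse = ""), NULL)[[1]]
  qchar <- strsplit(paste(read_seq, collapse = ""), NULL)[[1]]
  pos <- sequence(lens)
  len_at <- rep(lens, lens)
  i5 <- pos - 1L
  i3 <- len_at - pos
  short <- len_at < 2L * window
  use5 <- (i5 < window) & (!short | i5 <= i3)
  use3 <- (i3 < window) & (!short | i3 < i5)

  tab <- function(sel, idx, end_label) {
    keep <- sel & rchar %in% DNA_BASES & qchar %in% DNA_BASES
    tibble(end = end_label, position = idx[keep],
           ref = rchar[keep], read = qchar[keep]) |>
      dplyr::count(.data$end, .data$position, .data$ref, .data$read,
                   name = "count")
  }
  counts <- bind_rows(tab(use5, i5, "5p"), tab(use3, i3, "3p"))
  out <- grid |>
    left_join(counts, by = c("end", "position", "ref", "read")) |>
    mutate(count = dplyr::coalesce(.data$count, 0L)) |>
    group_by(.data$end, .data$position, .data$ref) |>
    mutate(opportunities = sum(.data$count)) |>
    ungroup() |>
    filter(.data$ref != .data$read) |>
    mutate(frequency = ifelse(.data$opportunities > 0,
                              .data$count / .data$opportunities, NA_real_))
  structure(out, window = window, class = c("damage_profile", class(out)))
}

#' Read-length histogram of an alignment set
#'
#' @param alignments Alignment tibble (or any tibble with a `length`
#'   column).
#' @param long_threshold Report the fraction of reads at or above this
#'   length (default 70 bp).
#' @return Tibble `length`, `reads`, `bases` with attributes `mean_length`
#'   and `fraction_long`.
#' @export
read_length_histogram <- function(alignments, long_threshold = 70L) {
  h <- alignments |>
    dplyr::count(.data$length, name = "reads") |>
    mutate(bases = .data$length * .data$reads) |>
    arrange(.data$length)
  mean_len <- if (nrow(alignments)) mean(alignments$length) else NA_real_
  frac_long <- if (nrow(alignments)) {
    mean(alignments$length >= long_threshold)
  } else {
    NA_real_
  }
  structure(h, mean_length = mean_len, fraction_long = frac_long,
            long_threshold = long_threshold,
            class = c("length_histogram", class(h)))
}

#' Fit the exponential deamination curve to a damage profile
#'
#' Least-squares fit of `p(i) = p_base + (p_max - p_base) * exp(-decay * i)`
#' to the C->T frequency series of one read end, with box constraints
#' `0 <= p_base, p_max <= 1`, `decay >= 0`. A flat or all-zero series is
#' returned with `decay = NA` (undefined) and `p_max = p_base`.
#'
#' @param profile A [damage_profile()].
#' @param end Which end's series to fit ("5p" or "3p").
#' @return A `deamination_fit` with elements `p_max`, `p_base`, `decay`,
#'   `residual` (RSS), `converged`, `n_positions`.
#' @export
fit_deamination <- function(profile, end = c("5p", "3p")) {
  end <- match.arg(end)
  ser <- profile |>
    filter(.data$end == !!end, .data$ref == "C", .data$read == "T",
           .data$opportunities > 0) |>
    arrange(.data$position)
  if (nrow(ser) < 5L) abort("need >= 5 positions with nonzero denominators")
  i <- ser$position
  y <- ser$frequency
  new_fit <- function(p_max, p_base, decay, residual, converged) {
    structure(list(p_max = p_max, p_base = p_base, decay = decay,
                   residual = residual, converged = converged,
                   n_positions = length(i), end = end),
              class = "deamination_fit")
  }
  if (all(y == 0)) return(new_fit(0, 0, NA_real_, 0, TRUE))
  if (diff(range(y)) < 1e-12) {
    return(new_fit(y[1], y[1], NA_real_, 0, TRUE))
  }
  start <- list(p_max = max(y), p_base = max(min(y), 1e-6),
                decay = 0.5)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ p_base + (p_max - p_base) * exp(-decay * i),
      start = start,
      lower = c(p_max = 0, p_base = 0, decay = 0),
      upper = c(p_max = 1, p_base = 1, decay = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    # fall back to direct box-constrained least squares
    obj <- function(par) {
      sum((y - (par[2] + (par[1] - par[2]) * exp(-par[3] * i)))^2)
    }
    o <- stats::optim(unlist(start), obj, method = "L-BFGS-B",
                      lower = c(0, 0, 0), upper = c(1, 1, 50))
    return(new_fit(o$par[1], o$par[2], o$par[3], o$value,
                   o$convergence == 0))
  }
  cf <- stats::coef(fit)
  new_fit(unname(cf["p_max"]), unname(cf["p_base"]), unname(cf["decay"]),
          sum(stats::resid(fit)^2), fit$convInfo$isConv %||% TRUE)
}

#' @export
print.deamination_fit <- function(x, ...) {
  cat(sprintf(
    "<deamination_fit> %s end: p_max=%.4f p_base=%.4f decay=%s (RSS %.3g)\n",
    x$end, x$p_max, x$p_base,
    if (is.na(x$decay)) "NA" else sprintf("%.3f", x$decay), x$residual))
  invisible(x)
}

#' @rdname fit_deamination
#' @param x A `deamination_fit`.
#' @param ... Unused.
#' @export
tidy.deamination_fit <- function(x, ...) {
  tibble(term = c("p_max", "p_base", "decay"),
         estimate = c(x$p_max, x$p_base, x$decay))
}

#' @rdname fit_deamination
#' @export
glance.deamination_fit <- function(x, ...) {
  tibble(p_max = x$p_max, p_base = x$p_base, decay = x$decay,
         residual = x$residual, converged = x$converged,
         n_positions = x$n_positions, end = x$end)
}

#' Export a damage profile as TSV
#' @param profile A [damage_profile()].
#' @param path Output path.
#' @export
write_damage_profile <- function(profile, path) {
  readr::write_tsv(as_tibble(profile), path)
  invisible(path)
}
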