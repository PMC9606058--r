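#' @importFrom ggplot2 ggplot aes geom_line geom_col geom_point geom_segment
#'   facet_wrap labs scale_colour_manual theme_minimal autoplot sec_axis
#'   scale_y_continuous geom_text
NULL

#' @export
ggplot2::autoplot

#' Plot a damage profile
#'
#' The classic deamination plot: C->T in red, G->A in blue, all other
#' substitution types in grey, one panel per read end.
#'
#' @param object A [damage_profile()].
#' @param ... Unused.
#' @export
autoplot.damage_profile <- function(object, ...) {
  df <- as_tibble(object) |>
    mutate(type = paste0(.data$ref, ">", .data$read),
           cls = dplyr::case_when(.data$ref == "C" & .data$read == "T" ~ "C>T",
                                  .data$ref == "G" & .data$read == "A" ~ "G>A",
                                  TRUE ~ "other"),
           end = factor(.data$end, levels = c("5p", "3p"),
                        labels = c("from 5' end", "from 3' end")))
  ggplot(df, aes(x = .data$position, y = .data$frequency,
                 group = .data$type, colour = .data$cls)) +
    geom_line(na.rm = TRUE) +
    scale_colour_manual(values = c("C>T" = "#c0392b", "G>A" = "#2c5aa0",
                                   "other" = "grey70"), name = NULL) +
    facet_wrap(~end) +
    labs(x = "position in read (0-based from end)",
         y = "mismatch frequency (per reference-base opportunity)") +
    theme_minimal()
}

#' Plot a read-length histogram
#'
#' Bars show reads per length; the dotted line shows the total bases
#' gathered from reads of that length (right axis).
#'
#' @param object A [read_length_histogram()].
#' @param ... Unused.
#' @export
autoplot.length_histogram <- function(object, ...) {
  df <- as_tibble(object)
  scale <- max(df$bases) / max(df$reads)
  ggplot(df, aes(x = .data$length)) +
    geom_col(aes(y = .data$reads), fill = "grey40") +
    geom_line(aes(y = .data$bases / scale), linetype = "dotted") +
    scale_y_continuous(
      name = "reads",
      sec.axis = sec_axis(~ . * scale, name = "bases")
    ) +
    labs(x = "read length (bp)") +
    theme_minimal()
}

#' Plot a haplotype genealogy graph
#'
#' Deterministic circular layout; circle areas are proportional to
#' haplotype multiplicity (inferred haplotypes drawn as points), edges
#' labelled with their substitution counts.
#'
#' @param object A [build_graph()] result.
#' @param ... Unused.
#' @export
autoplot.haplotype_graph <- function(object, ...) {
  n <- nrow(object$nodes)
  ang <- 2 * pi * (seq_len(n) - 1L) / max(n, 1L)
  lay <- mutate(object$nodes, x = cos(ang), y = sin(ang))
  ed <- object$edges |>
    left_join(select(lay, "id", xf = "x", yf = "y"), by = c(from = "id")) |>
    left_join(select(lay, "id", xt = "x", yt = "y"), by = c(to = "id"))
  ggplot() +
    geom_segment(data = ed, aes(x = .data$xf, y = .data$yf,
                                xend = .data$xt, yend = .data$yt),
                 colour = "grey50") +
    geom_text(data = ed, aes(x = (.data$xf + .data$xt) / 2,
                             y = (.data$yf + .data$yt) / 2,
                             label = .data$weight), size = 3) +
    geom_point(data = lay, aes(x = .data$x, y = .data$y,
                               size = .data$multiplicity),
               colour = "#2c5aa0", alpha = 0.8) +
    geom_text(data = lay, aes(x = .data$x, y = .data$y,
                              label = paste0(.data$id, " (",
                                             .data$multiplicity, ")")),
              vjust = -1.5, size = 3) +
    ggplot2::scale_size_area(max_size = 18, guide = "none") +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}
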