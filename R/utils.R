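#' @importFrom rlang abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter arrange group_by ungroup summarise select
#'   bind_rows left_join n row_number desc across
#' @importFrom stats runif rbinom setNames integrate qlnorm plnorm dlnorm
NULL

DNA_BASES <- c("A", "C", "G", "T")

revcomp <- function(x) {
  stringi::stri_reverse(chartr("ACGTNacgtn-", "TGCANtgcan-", x))
}

#' @export
generics::tidy

#' @export
generics::glance

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed_ <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Deterministic per-stage child seeds below 2^31.
child_seed <- function(seed, stage) {
  (as.double(seed) * 1009 + match(stage, PIPELINE_STAGES) * 9973) %% 2147483647
}

PIPELINE_STAGES <- c(
  "genome", "variants", "simulate", "map", "damage",
  "consensus", "compare", "hapgraph"
)

# Wrap 1-based positions onto a circle of length L.
wrap1 <- function(pos, L) ((pos - 1L) %% L) + 1L

assert_bases <- function(x, what = "sequence", allow = "ACGTN") {
  bad <- grepl(sprintf("[^%s]", allow), x)
  if (any(bad)) {
    abort(sprintf(
      "%s contains characters outside {%s}: %s",
      what, paste(strsplit(allow, "")[[1]], collapse = ","),
      paste(utils::head(names(x)[bad] %||% which(bad), 3), collapse = ", ")
    ))
  }
  invisible(x)
}
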