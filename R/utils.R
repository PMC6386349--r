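#' @keywords internal
"_PACKAGE"

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Derive a named child random stream from a root seed
#'
#' All stochastic draws in the package flow from named child streams so that,
#' e.g., drawing more reads never perturbs the taxonomy generated from the
#' same root seed. The child seed is a deterministic 31-bit hash of the root
#' seed and the stream name.
#'
#' @param seed integer root seed.
#' @param stream character scalar naming the stream (e.g. "taxonomy", "db").
#' @return an integer seed in [0, 2^31 - 1].
#' @export
child_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 131 + ch) %% 2147483647
  as.integer((abs(seed) %% 2147483647 * 48271 + h) %% 2147483647)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

stop_invalid <- function(...) {
  stop(..., call. = FALSE)
}

# TSV helpers: machine outputs carry the seed in a comment header so every
# file records its provenance; readers skip '#' lines.
write_tsv_seeded <- function(df, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(seed)) writeLines(sprintf("# seed=%d", as.integer(seed)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_plain <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE)
}
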