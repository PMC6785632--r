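# Internal helpers shared across modules.

#' Evaluate an expression under a local RNG state
#'
#' Runs `expr` with the global RNG seeded to `seed`, then restores whatever
#' RNG state existed before the call.  All stochastic operations in the
#' package route their randomness through this helper so that no function
#' leaves a trace in the caller's RNG stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

# Canonical key for an unordered gene pair: lexicographically sorted,
# tab-separated (gene IDs never contain tabs; readers enforce this).
pair_key <- function(a, b) {
  ifelse(a <= b, paste(a, b, sep = "\t"), paste(b, a, sep = "\t"))
}

# Split pair keys back into a two-column character matrix.
split_pair_key <- function(key) {
  parts <- strsplit(key, "\t", fixed = TRUE)
  matrix(unlist(parts), ncol = 2L, byrow = TRUE,
         dimnames = list(NULL, c("gene_a", "gene_b")))
}

# Timestamped log line on stderr; results never go to stdout.
ns_log <- function(..., level = "INFO") {
  msg <- paste0("[", format(Sys.time(), "%Y-%m-%d %H:%M:%S"), "] ",
                level, " ", paste0(..., collapse = ""))
  message(msg)
  invisible(msg)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
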