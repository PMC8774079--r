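# Internal helpers shared across modules.

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores `.Random.seed` so callers' RNG streams are untouched.
#' All stochastic operations in the package route through this helper, which
#' is what makes every generator a pure function of (config, seed).
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Child seeds derived from one parent seed by fixed offsets, so each
# generated dataset is independently reproducible. Kept below 2^31.
child_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(offset) %% 1000L
}

#' Canonical diploid genotype label
#'
#' Orders the two allele names (lexicographically) and joins them with "/",
#' so that e.g. `("S3L", "S3")` and `("S3", "S3L")` map to the same label.
#'
#' @param a,b Allele names.
#' @return Character label such as `"S3/S3L"`.
#' @export
genotype_label <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "/")
}

stop_input <- function(...) {
  stop(..., call. = FALSE)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
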