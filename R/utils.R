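#' @importFrom stats rbinom rmultinom rlnorm rgamma rnorm runif sd median
#'   fisher.test wilcox.test ks.test hclust as.dist cor cutree quantile
#' @importFrom utils write.table packageVersion
#' @import data.table
NULL

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded package functions do not
#' perturb the caller's random number stream. A `NULL` seed evaluates the
#' expression in the current stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# polynomial rolling hash of a character scalar, kept below 2^31 so it can
# seed R's RNG (doubles stay exact: intermediate values < 2^53)
fnv1a <- function(x) {
  bytes <- utf8ToInt(x)
  h <- 5381
  for (b in bytes) h <- (h * 127 + b) %% 2147483647
  h
}

#' Derive a stage-specific seed from a global seed
#'
#' Each pipeline stage draws from its own deterministic stream so that
#' enabling or disabling one stage does not perturb the others.
#'
#' @param seed Integer global seed.
#' @param stage Character stage name.
#' @return Integer seed below 2^31.
#' @keywords internal
derive_seed <- function(seed, stage) {
  as.integer((fnv1a(paste0(stage, ":", format(seed))) + as.numeric(seed)) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# strand-aware comparison helpers: "3'-most" position w.r.t. transcription
most_3prime <- function(positions, strand) {
  if (strand == "+") max(positions) else min(positions)
}
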