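# Shared helpers: seeded substreams, gene-keyed RNG, logging.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG state
#'
#' Sets the RNG seed, evaluates `expr`, and restores the caller's random
#' state, so library code never perturbs a user's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# FNV-1a style 31-bit string hash; used to derive gene-intrinsic random
# substreams so a gene's planted chromatin state does not depend on the
# run seed (conditions sharing a gene set share its base architecture).
str_hash <- function(s) {
  vapply(s, function(x) {
    h <- 2166136261 %% 2147483647
    for (b in utf8ToInt(x)) {
      h <- bitwXor(h, b)
      h <- (h * 16777619) %% 2147483647
    }
    as.integer(h)
  }, integer(1), USE.NAMES = FALSE)
}

# Substream seed for a named stage under a global seed (stays < 2^31;
# arithmetic in doubles to avoid integer overflow).
substream <- function(seed, stage) {
  (as.numeric(seed) * 7919 + str_hash(stage)) %% 2147483647
}

# Draw from a gene-keyed stream: deterministic in (gene_id, context),
# independent of the run seed.
gene_draw <- function(gene_id, context, fn) {
  with_seed(str_hash(paste0(gene_id, "::", context)), fn())
}

ns_log <- function(..., verbose = getOption("nucleoscope.verbose", FALSE)) {
  if (isTRUE(verbose)) message("[nucleoscope] ", ...)
  invisible(NULL)
}
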