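## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the random number generator seeded to `seed`, then
#' restores the previous RNG state so callers are unaffected.
#'
#' @param seed Integer seed, or `NULL` to leave the RNG untouched.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Derive a stage seed from a root seed
#'
#' Maps a root seed and a stage index to a reproducible, distinct
#' 32-bit seed so that every pipeline stage draws from its own stream.
#'
#' @param root Integer root seed.
#' @param stage Integer stage index (1-based) or stage name.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(root, stage) {
  if (is.character(stage)) stage <- sum(utf8ToInt(stage))
  stopifnot(is.numeric(root), length(root) == 1L)
  as.integer((as.double(root) * 48271 + as.double(stage) * 1000003) %% 2147483629)
}

## Stop with a consistent message prefix for structural errors.
check_aligned <- function(a, b, what_a = "intensity", what_b = "snr") {
  if (!identical(dim(a), dim(b)) ||
      !identical(rownames(a), rownames(b)) ||
      !identical(colnames(a), colnames(b))) {
    stop(sprintf("'%s' and '%s' matrices must share identical gene and sample indices",
                 what_a, what_b), call. = FALSE)
  }
  invisible(TRUE)
}

as_prob <- function(x, name) {
  if (any(x < 0 | x > 1)) stop(sprintf("'%s' must lie in [0, 1]", name), call. = FALSE)
  x
}
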