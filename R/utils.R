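#' Round half away from zero
#'
#' Plain decimal rounding where .5 always moves away from zero, matching how
#' clinical tables print percentages (base `round()` rounds half to even).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector; `NA` passes through.
#' @export
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  # tiny nudge guards against values like 83.15 stored as 83.14999...
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

# Deterministic child seeds below 2^31, so nested draws are reproducible from
# one master seed without the subdraws sharing a stream.
derive_seeds <- function(seed, n) {
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(restore_rng(old))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# Evaluate expr under a fixed seed, restoring the caller's RNG state after.
with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(restore_rng(old))
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
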