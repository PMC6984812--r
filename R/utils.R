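#' @keywords internal
"_PACKAGE"

## Condition labels of the 3 (stimulus) x 2 (attended modality) design.
CONDITIONS <- c("A_AttA", "A_AttV", "V_AttA", "V_AttV", "AV_AttA", "AV_AttV")

condition_modality <- function(cond) sub("_Att[AV]$", "", cond)
condition_attention <- function(cond) sub("^.*_", "", cond)

#' Evaluate code with a fixed RNG seed, restoring the caller's RNG state
#'
#' All stochastic generators in the package funnel their randomness through
#' this helper so that a given seed yields bit-identical output regardless of
#' the surrounding RNG state.
#'
#' @param seed integer seed (kept below 2^31).
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_rng_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

#' Derive a stage sub-seed from a master seed
#'
#' Counter-based expansion so pipeline stages can be re-run in isolation with
#' the same randomness they received in the end-to-end run.
#'
#' @param seed master integer seed.
#' @param stage integer stage counter (>= 0).
#' @return an integer seed below 2^31.
#' @export
stage_seed <- function(seed, stage) {
  as.integer((as.double(seed) * 48271 + as.double(stage) * 10007) %% 2147483647)
}

stopifnot_positive <- function(...) {
  vals <- list(...)
  nms <- names(vals)
  for (i in seq_along(vals)) {
    v <- vals[[i]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v <= 0)) {
      stop(sprintf("`%s` must be strictly positive and finite", nms[i]),
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

## Centered depth regressor for an n-point laminar grid (unit step per depth).
depth_regressor <- function(n = 6L) seq_len(n) - (n + 1) / 2
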