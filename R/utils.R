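#' Derive a reproducible child seed from a master seed
#'
#' Each stochastic stage of the pipeline draws from its own stream, keyed by a
#' stage label, so that adding replicates to one stage never perturbs another.
#'
#' @param seed master integer seed.
#' @param stage character label of the stage (e.g. "cohort", "predictions").
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @keywords internal
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  # multiplicative string hash modulo a prime below 2^31
  s <- as.double(seed) %% 2147483629
  for (code in utf8ToInt(stage)) {
    s <- (s * 31 + code) %% 2147483629
  }
  as.integer(s + 1)
}

#' Brain-predicted age difference (brain-PAD)
#'
#' The brain age gap: predicted brain age minus chronological age. Always
#' derived on demand so it can never be stored inconsistently.
#'
#' @param records a cohort data frame with `predicted_brain_age` and `age`.
#' @return Numeric vector of brain-PAD values in years.
#' @export
brain_pad <- function(records) {
  stopifnot(all(c("predicted_brain_age", "age") %in% names(records)))
  records$predicted_brain_age - records$age
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate expr with the RNG seeded, restoring the caller's RNG state after.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
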