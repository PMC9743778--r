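`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` after `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so library functions do not disturb a user's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a per-unit seed from a master seed
#'
#' Deterministic seed for taxon (or repetition) `index`, kept below 2^31 so it
#' is a valid R integer. Used so that multi-worker runs are worker-count
#' invariant: every taxon carries its own pre-assigned seed.
#'
#' @param seed master integer seed.
#' @param index positive integer index.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) %% 2147483647 + as.numeric(index) * 99991) %%
               2147483647)
}

# pairwise log(exp(a) + exp(b)), numerically stable
logspace_add <- function(a, b) {
  m <- pmax(a, b)
  r <- m + log1p(exp(pmin(a, b) - m))
  # if both are -Inf, pmin - m is NaN; the sum is -Inf
  r[is.infinite(a) & is.infinite(b) & a < 0 & b < 0] <- -Inf
  r
}

is_wholenumber <- function(x, tol = 1e-8) {
  is.numeric(x) && all(is.finite(x)) && all(abs(x - round(x)) < tol)
}
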