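stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Derive a stage- or task-specific seed from a run seed
#'
#' All randomness in the package flows from one user-supplied integer seed.
#' Sub-tasks (pipeline stages, base learners, repeats) use seeds derived
#' deterministically from that seed and a text label, so that re-running any
#' component with the same run seed reproduces its output bit for bit while
#' distinct components draw from distinct streams.
#'
#' @param seed integer run seed.
#' @param label character label of the consuming component.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(length(seed) == 1L, is.finite(seed), length(label) == 1L)
  h <- 0
  for (k in utf8ToInt(as.character(label))) h <- (h * 131 + k) %% 1048573
  as.integer(((as.numeric(seed) %% 2147480000) * 389 + h * 7919 + 1) %% 2147483646 + 1)
}

# evaluate `expr` under a local RNG state seeded with `seed`; restores the
# caller's RNG so library code does not perturb user-level streams
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
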