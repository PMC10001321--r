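# Internal helpers shared across modules.

#' Run code under a temporary RNG seed
#'
#' Saves and restores the caller's RNG state so seeded generators do not
#' clobber the global random stream.
#' @noRd
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Derive a per-stream child seed from a master seed
#'
#' Deterministic, collision-poor mapping kept inside 32-bit integer range.
#' @noRd
derive_seed <- function(master, stream) {
  (as.double(master) * 7919 + as.double(stream) * 104729) %% 2147483647
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) && x == round(x)
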