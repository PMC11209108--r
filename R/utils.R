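# Internal helpers shared across modules.

#' Evaluate code under a fixed RNG seed, restoring the caller's RNG state
#'
#' All stochastic operations in the package route their randomness through
#' this helper so that a user-supplied seed makes a run bit-reproducible
#' without clobbering the session RNG.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  genv <- globalenv()
  if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    old <- get(".Random.seed", envir = genv, inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = genv), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
        rm(".Random.seed", envir = genv)
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

# Classed error so callers can condition on failure modes.
coral_stop <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "coral_error")))
}

# FNV-1a 32-bit hash of a character scalar; used to stamp run configs into
# reports without an external digest dependency.
fnv1a32 <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    # xor touches only the low byte; keep h as a double (it exceeds .Machine's int)
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), b)
    # multiply by the FNV prime mod 2^32 in two halves to stay inside
    # double precision
    h <- (h %% 65536 * p + ((h %/% 65536 * p) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# Format a double so that read-back with as.numeric() is bit-exact.
fmt_num <- function(x) sprintf("%.17g", x)
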