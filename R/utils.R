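# internal helpers shared across modules

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded schedule/simulation code
#' never leaks RNG state into (or depends on) the caller's session.
#'
#' @param seed non-negative integer seed
#' @param expr expression to evaluate
#' @return value of `expr`
#' @keywords internal
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, seed >= 0, seed == floor(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Deterministic per-subject seed derived from a session/cohort seed and a
# subject index, kept below 2^31 (exact in double arithmetic: both terms are
# far below 2^53 before the modulus).
subject_seed <- function(seed, subject_id) {
  as.integer((seed + subject_id * 1299709 + 15485863) %% (2^31 - 1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(class, msg, ...) {
  stop(structure(class = c(class, "loudreg_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}
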