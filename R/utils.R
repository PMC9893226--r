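# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves any existing `.Random.seed`, seeds the generator, evaluates `expr`,
#' and restores the previous RNG state so that generators are deterministic
#' without clobbering the caller's random stream.
#'
#' @param seed single integer seed (must be < 2^31).
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Derive a deterministic substream seed from a root seed and a stream label,
# keeping the result strictly below 2^31.
substream_seed <- function(seed, stream) {
  offsets <- c(
    cohort = 101L, word_report = 211L, coherence = 307L, association = 401L,
    audio = 503L, volumes = 601L, vocoder = 701L, items = 809L
  )
  if (!stream %in% names(offsets)) stop("unknown RNG stream: ", stream)
  (as.numeric(seed) * 1000 + offsets[[stream]]) %% 2147483647
}

stop_if_not_scalar_finite <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop("'", name, "' must be a single finite number", call. = FALSE)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
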