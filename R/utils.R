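# Internal helpers: error classes, seed management, small utilities.

abort <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "tractsa_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run code with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded package functions do not
#' disturb the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

#' Derive a stage seed from a global seed
#'
#' Deterministic mixing of a global integer seed with a stage name, so that
#' every stochastic pipeline stage consumes an independent, reproducible
#' stream.  The result is always in `[1, 2^31 - 2]`.
#'
#' @param seed global integer seed.
#' @param stage character stage label.
#' @return integer seed.
#' @export
derive_seed <- function(seed, stage) {
  h <- 2166136261
  for (b in utf8ToInt(paste0(stage, ":", seed))) {
    h <- ((h %% 65536) * 16777619 + (h %/% 65536 * 16777619 %% 65536) * 65536 + b) %% 2147483647
  }
  as.integer(h %% 2147483645 + 1)
}

# FNV-1a style hash of a character string, returned as hex; used for
# provenance blocks (no cryptographic intent).
content_hash <- function(x) {
  h <- 2166136261
  for (b in utf8ToInt(paste(x, collapse = "\n"))) {
    h <- (bitwXor(as.integer(h %% 2147483647), b) * 16777619) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}

is_count <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 0 && x == round(x)

stopifnot_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1)
    abort(sprintf("'%s' must be a single value in [0, 1]", name), "tractsa_config_error")
}

clamp01 <- function(x) {
  # preserves dim attributes, unlike pmin(1, pmax(0, x))
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}
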