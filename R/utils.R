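# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Logging goes to stderr so stdout stays clean for piped output.
# Levels: 0 = silent, 1 = info (default), 2 = debug.
log_msg <- function(..., level = 1L) {
  opt <- getOption("strokeage.verbose", 1L)
  if (opt >= level) message("[strokeage] ", sprintf(...))
  invisible(NULL)
}

# Deterministic sub-seed derivation so each pipeline component consumes an
# independent stream from one master seed. Kept inside 2^31 - 1.
sub_seed <- function(seed, offset) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((abs(seed) * 7919 + offset * 104729) %% 2147483647)
}

# Run an expression under a locally-set RNG state and restore it afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_strokeage <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
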