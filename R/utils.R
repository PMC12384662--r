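# Internal helpers shared across modules.

#' Derive a reproducible sub-seed from a master seed and a stage tag
#'
#' A single master seed fans out to named sub-seeds (data generation, split,
#' weight initialisation, batch order, per-fold training) so that individual
#' pipeline stages can be varied independently while the whole run stays
#' reproducible. The derivation is a small deterministic hash kept below
#' 2^31 so it is always a valid R integer seed.
#'
#' @param seed master seed (integer).
#' @param tag character stage tag, e.g. "split" or "fold1".
#' @return an integer seed.
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  h <- 0
  for (k in utf8ToInt(tag)) h <- (h * 131 + k) %% 2147480009
  as.integer((abs(as.numeric(seed)) %% 2147480009 * 7919 + h) %% 2147483647)
}

# Stop with a message composed via sprintf.
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Structured one-line log message, silenced via option(capseeg.verbose = FALSE).
log_msg <- function(stage, fmt, ...) {
  if (isFALSE(getOption("capseeg.verbose", TRUE))) return(invisible(NULL))
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
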