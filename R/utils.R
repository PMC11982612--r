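#' @keywords internal
#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @noRd
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Structured one-line log message
#'
#' Every filtering/realignment step reports what it did and how many records
#' were affected through this single channel, so pipelines can be audited
#' from their logs. Suppress with `suppressMessages()`.
#' @noRd
logf <- function(step, fmt, ...) {
  message(sprintf("[meiodiv:%s] %s", step, sprintf(fmt, ...)))
}

#' Derive a named substream seed from a master seed
#'
#' Each randomized stage of the pipeline draws from its own stream, derived
#' deterministically from the master seed and the stage name, so changing one
#' stage's resampling depth never perturbs another stage's draws.
#'
#' @param seed master integer seed.
#' @param stream character stage name.
#' @return an integer seed < 2^31.
#' @export
#' @examples
#' substream_seed(1L, "landscape")
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  h <- 0
  for (k in utf8ToInt(stream)) h <- (h * 131 + k) %% 2147483629
  as.integer((abs(as.numeric(seed)) + h) %% 2147483629 + 1)
}

#' Set the RNG locally if a seed is supplied
#'
#' Restores the caller's RNG state on exit so seeded calls do not disturb
#' the global stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}
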