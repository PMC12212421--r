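# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a stage-specific seed from a global seed
#'
#' All randomness in the pipeline flows from one global seed. Stage seeds are
#' derived by hashing the stage name into the global seed so that individual
#' stages can be re-run in isolation with identical results.
#'
#' @param seed Integer global seed.
#' @param stage Character stage tag (e.g. `"train_cohort"`).
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- 0
  for (k in utf8ToInt(stage)) h <- (h * 31 + k) %% 2147483647
  out <- (abs(seed) * 48271 + h) %% 2147483646 + 1
  as.integer(out)
}

# round-half-up to integer (base round() is banker's rounding)
round_half_up <- function(x) floor(x + 0.5)

assert_prob <- function(p, name) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1)
    stop(sprintf("'%s' must be a probability in [0, 1]", name), call. = FALSE)
  invisible(p)
}

assert_pos <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x <= 0))
    stop(sprintf("'%s' must be positive", name), call. = FALSE)
  invisible(x)
}

# mode of a vector, NA-removed; ties broken by sorted order (deterministic)
stat_mode <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) stop("cannot take the mode of an all-missing vector", call. = FALSE)
  tab <- sort(table(x), decreasing = TRUE)
  nm <- names(tab)[tab == max(tab)]
  nm <- sort(nm)[1L]
  if (is.numeric(x)) as.numeric(nm) else nm
}
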