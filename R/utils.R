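#' Derive a child RNG seed from a master seed and a stage label
#'
#' A single pipeline seed fans out to per-stage (and per-location-week) seeds
#' through a small polynomial string hash, so any stage can be re-run in
#' isolation and still reproduce its part of a full run. All derived seeds are
#' kept below 2^31 - 1.
#'
#' @param seed master integer seed.
#' @param ... labels (coerced to character) identifying the stage and unit.
#' @return an integer seed.
#' @export
child_seed <- function(seed, ...) {
  key <- paste(vapply(list(...), as.character, character(1)), collapse = "/")
  m <- 2147483647
  h <- as.double(seed %% m)
  for (code in utf8ToInt(key)) {
    h <- (h * 31 + code) %% m
  }
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_scalar_num <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    stop(sprintf("'%s' must be a single number in [%s, %s]", name, lower, upper),
         call. = FALSE)
  }
  invisible(x)
}

#' Zero-truncated Poisson draws
#'
#' Inverse-CDF sampler conditioned on values >= 1; used for weekly local
#' population sizes, which are only defined where at least one bird was
#' recorded.
#' @param n number of draws.
#' @param lambda rate(s) of the untruncated Poisson.
#' @keywords internal
rztpois <- function(n, lambda) {
  p0 <- stats::dpois(0, lambda)
  u <- stats::runif(n, min = p0, max = 1)
  stats::qpois(u, lambda)
}
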