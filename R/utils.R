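#' Geometric mean
#'
#' @param x positive numeric vector.
#' @return `exp(mean(log(x)))`.
#' @export
geomean <- function(x) {
  stopifnot(is.numeric(x), length(x) >= 1L)
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop("geomean() requires strictly positive finite values", call. = FALSE)
  }
  exp(mean(log(x)))
}

# Internal: derive a stage-specific RNG seed from the master seed so that the
# pipeline stages are independently reproducible. Kept below 2^31 - 1.
derive_seed <- function(seed, stage) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  h <- 0
  for (k in utf8ToInt(stage)) h <- (h * 131 + k) %% 999983
  as.integer((abs(as.numeric(seed)) %% 1e6 * 1009 + h * 1013) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_mp <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "mpsoilrisk_error")))
}
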