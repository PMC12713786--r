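#' Distribution families for SSD/EED fitting
#'
#' The package fits five positive continuous families by maximum likelihood.
#' Parameterizations are pinned as follows (all scale parameters are true
#' scale parameters, so dividing the scale by a factor d divides every
#' quantile by d):
#'
#' * `lognormal`: params `(meanlog, sdlog)`; the distribution of `exp(Z)`,
#'   `Z ~ N(meanlog, sdlog)`.
#' * `loglogistic`: params `(shape, scale)`; CDF `1 / (1 + (x/scale)^-shape)`.
#' * `burr` (Burr type XII): params `(shape1, shape2, scale)` = (k, c, s);
#'   CDF `1 - (1 + (x/s)^c)^(-k)`. The log-logistic is the k = 1 special case.
#' * `weibull`: params `(shape, scale)` as in [stats::pweibull()].
#' * `gamma`: params `(shape, scale)` (scale, not rate).
#'
#' @param family one of `"lognormal"`, `"loglogistic"`, `"burr"`,
#'   `"weibull"`, `"gamma"`.
#' @return `family_spec()` returns a list with the family name, parameter
#'   names, density/CDF/quantile/sampler closures (vectorized over both the
#'   probability/quantile argument and the parameters), and a `start()`
#'   function producing moment-informed starting values from data.
#' @export
family_spec <- function(family) {
  family <- match.arg(family, mp_families())
  switch(family,
    lognormal = list(
      name = "lognormal", par_names = c("meanlog", "sdlog"),
      dfun = function(x, par, log = FALSE)
        stats::dlnorm(x, par[[1L]], par[[2L]], log = log),
      pfun = function(q, par) stats::plnorm(q, par[[1L]], par[[2L]]),
      qfun = function(p, par) stats::qlnorm(p, par[[1L]], par[[2L]]),
      rfun = function(n, par) stats::rlnorm(n, par[[1L]], par[[2L]]),
      # meanlog unconstrained, sdlog > 0
      positive = c(FALSE, TRUE),
      start = function(x) c(meanlog = mean(log(x)), sdlog = stats::sd(log(x)))
    ),
    loglogistic = list(
      name = "loglogistic", par_names = c("shape", "scale"),
      dfun = function(x, par, log = FALSE) dllogis(x, par[[1L]], par[[2L]], log),
      pfun = function(q, par) pllogis(q, par[[1L]], par[[2L]]),
      qfun = function(p, par) qllogis(p, par[[1L]], par[[2L]]),
      rfun = function(n, par) qllogis(stats::runif(n), par[[1L]], par[[2L]]),
      positive = c(TRUE, TRUE),
      start = function(x) {
        lx <- log(x)
        c(shape = pi / (stats::sd(lx) * sqrt(3)), scale = exp(mean(lx)))
      }
    ),
    burr = list(
      name = "burr", par_names = c("shape1", "shape2", "scale"),
      dfun = function(x, par, log = FALSE)
        dburr(x, par[[1L]], par[[2L]], par[[3L]], log),
      pfun = function(q, par) pburr(q, par[[1L]], par[[2L]], par[[3L]]),
      qfun = function(p, par) qburr(p, par[[1L]], par[[2L]], par[[3L]]),
      rfun = function(n, par)
        qburr(stats::runif(n), par[[1L]], par[[2L]], par[[3L]]),
      positive = c(TRUE, TRUE, TRUE),
      start = function(x) {
        lx <- log(x)
        c(shape1 = 1, shape2 = pi / (stats::sd(lx) * sqrt(3)),
          scale = exp(mean(lx)))
      }
    ),
    weibull = list(
      name = "weibull", par_names = c("shape", "scale"),
      dfun = function(x, par, log = FALSE)
        stats::dweibull(x, par[[1L]], par[[2L]], log = log),
      pfun = function(q, par) stats::pweibull(q, par[[1L]], par[[2L]]),
      qfun = function(p, par) stats::qweibull(p, par[[1L]], par[[2L]]),
      rfun = function(n, par) stats::rweibull(n, par[[1L]], par[[2L]]),
      positive = c(TRUE, TRUE),
      start = function(x) {
        # Menon-style moment start from log data
        c(shape = 1.2 / stats::sd(log(x)), scale = exp(mean(log(x)) + 0.5772 *
            stats::sd(log(x))))
      }
    ),
    gamma = list(
      name = "gamma", par_names = c("shape", "scale"),
      dfun = function(x, par, log = FALSE)
        stats::dgamma(x, shape = par[[1L]], scale = par[[2L]], log = log),
      pfun = function(q, par) stats::pgamma(q, shape = par[[1L]], scale = par[[2L]]),
      qfun = function(p, par) stats::qgamma(p, shape = par[[1L]], scale = par[[2L]]),
      rfun = function(n, par) stats::rgamma(n, shape = par[[1L]], scale = par[[2L]]),
      positive = c(TRUE, TRUE),
      start = function(x) {
        m <- mean(x); v <- stats::var(x)
        c(shape = max(m^2 / v, 1e-3), scale = max(v / m, 1e-12))
      }
    )
  )
}

#' @rdname family_spec
#' @export
mp_families <- function() {
  c("lognormal", "loglogistic", "burr", "weibull", "gamma")
}

#' Log-logistic distribution
#'
#' Density, CDF and quantile function of the log-logistic distribution with
#' CDF `1 / (1 + (x/scale)^-shape)`.
#'
#' @param x,q quantiles (non-negative).
#' @param p probabilities.
#' @param shape,scale positive parameters, recycled against `x`/`q`/`p`.
#' @param log return the log density.
#' @export
dllogis <- function(x, shape, scale, log = FALSE) {
  lr <- suppressWarnings(base::log(x) - base::log(scale))
  ld <- ifelse(x > 0,
    base::log(shape) - base::log(scale) + (shape - 1) * lr -
      2 * log1pexp(shape * lr),
    -Inf)
  if (log) ld else exp(ld)
}

#' @rdname dllogis
#' @export
pllogis <- function(q, shape, scale) {
  ifelse(q > 0,
         stats::plogis(shape * (suppressWarnings(base::log(q)) - base::log(scale))),
         0)
}

#' @rdname dllogis
#' @export
qllogis <- function(p, shape, scale) {
  stopifnot(all(p >= 0 & p <= 1))
  scale * (p / (1 - p))^(1 / shape)
}

#' Burr type XII distribution
#'
#' Density, CDF and quantile function of the Burr XII distribution with
#' CDF `1 - (1 + (x/scale)^shape2)^(-shape1)`. Heavy-tailed for small
#' `shape1 * shape2`; reduces to the log-logistic when `shape1 = 1`.
#'
#' @param x,q quantiles (non-negative).
#' @param p probabilities.
#' @param shape1,shape2,scale positive parameters (k, c, s), recycled.
#' @param log return the log density.
#' @export
dburr <- function(x, shape1, shape2, scale, log = FALSE) {
  lr <- suppressWarnings(base::log(x) - base::log(scale))
  ld <- ifelse(x > 0,
    base::log(shape1) + base::log(shape2) - base::log(scale) +
      (shape2 - 1) * lr - (shape1 + 1) * log1pexp(shape2 * lr),
    -Inf)
  if (log) ld else exp(ld)
}

#' @rdname dburr
#' @export
pburr <- function(q, shape1, shape2, scale) {
  lr <- suppressWarnings(base::log(q) - base::log(scale))
  ifelse(q > 0, -expm1(-shape1 * log1pexp(shape2 * lr)), 0)
}

#' @rdname dburr
#' @export
qburr <- function(p, shape1, shape2, scale) {
  stopifnot(all(p >= 0 & p <= 1))
  # computed in log space: the intermediate (1-p)^(-1/shape1) overflows for
  # small shape1 long before the quantile itself does
  t <- -log1p(-p) / shape1
  scale * exp(logexpm1(t) / shape2)
}

# log(1 + exp(t)) without overflow
log1pexp <- function(t) ifelse(t > 33, t, log1p(exp(pmin(t, 33))))

# log(exp(t) - 1) without overflow (t >= 0)
logexpm1 <- function(t) ifelse(t > 33, t, base::log(expm1(pmin(t, 33))))
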