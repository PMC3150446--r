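# Generalized extreme value distribution: density, CDF, quantile and a
# maximum-likelihood fit. Parameterisation: location mu, scale sigma > 0,
# shape xi (xi = 0 is the Gumbel limit). No GEV package is assumed.

#' GEV density
#' @param x Quantiles.
#' @param loc,scale,shape GEV parameters (scale > 0).
#' @param log Return log-density?
#' @export
dgev <- function(x, loc = 0, scale = 1, shape = 0, log = FALSE) {
  stopifnot(scale > 0)
  z <- (x - loc) / scale
  if (abs(shape) < 1e-8) {
    ld <- -log(scale) - z - exp(-z)
  } else {
    t <- 1 + shape * z
    ld <- ifelse(t > 0,
                 -log(scale) - (1 / shape + 1) * log(pmax(t, .Machine$double.xmin)) -
                   pmax(t, .Machine$double.xmin)^(-1 / shape),
                 -Inf)
  }
  if (log) ld else exp(ld)
}

#' GEV cumulative distribution function
#' @inheritParams dgev
#' @param lower.tail If `FALSE`, the survival function is returned.
#' @export
pgev <- function(x, loc = 0, scale = 1, shape = 0, lower.tail = TRUE) {
  stopifnot(scale > 0)
  z <- (x - loc) / scale
  if (abs(shape) < 1e-8) {
    p <- exp(-exp(-z))
  } else {
    t <- 1 + shape * z
    p <- ifelse(t > 0, exp(-t^(-1 / shape)),
                if (shape > 0) 0 else 1)
    # outside the support: left of it for xi>0 (p=0), right of it for xi<0 (p=1)
    p[t <= 0] <- if (shape > 0) 0 else 1
  }
  if (lower.tail) p else 1 - p
}

#' GEV quantile function
#' @param p Probabilities.
#' @inheritParams dgev
#' @export
qgev <- function(p, loc = 0, scale = 1, shape = 0) {
  stopifnot(scale > 0, all(p > 0 & p < 1))
  if (abs(shape) < 1e-8) {
    loc - scale * log(-log(p))
  } else {
    loc + scale * ((-log(p))^(-shape) - 1) / shape
  }
}

#' Maximum-likelihood GEV fit
#'
#' Nelder-Mead optimisation of the negative log-likelihood with
#' Gumbel-moment initialisation (shape unconstrained).
#'
#' @param x Numeric sample (length >= 5, non-degenerate).
#' @return List `loc`, `scale`, `shape`, `convergence` (0 = success),
#'   `loglik`; or `NULL` when the sample is degenerate or the fit fails.
#' @export
fit_gev <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 5L || stats::sd(x) == 0) return(NULL)
  s0 <- stats::sd(x) * sqrt(6) / pi
  m0 <- mean(x) - 0.5772157 * s0
  nll <- function(par) {
    sc <- exp(par[2L])
    -sum(dgev(x, loc = par[1L], scale = sc, shape = par[3L], log = TRUE))
  }
  fit <- tryCatch(
    stats::optim(c(m0, log(s0), 0.1), nll, method = "Nelder-Mead",
                 control = list(maxit = 2000)),
    error = function(e) NULL)
  if (is.null(fit) || !is.finite(fit$value)) return(NULL)
  list(loc = fit$par[1L], scale = exp(fit$par[2L]), shape = fit$par[3L],
       convergence = fit$convergence, loglik = -fit$value)
}
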