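# The three candidate node-statistic distribution models.
#
# * restricted power law: P(x) = ((g+1)/(x_max-x_min)) ((x_max-x)/(x_max-x_min))^g
#   on [x_min, x_max] -- a power law in the distance to a hard upper bound,
#   motivated by an energy constraint on the number/strength of connections.
# * exponentially truncated power law: P(x) ~ x^(alpha-1) exp(-x/x_c)
#   on [x_min, Inf) -- power law with an exponential cut-off at scale x_c.
# * plain power law: P(x) = ((alpha-1)/x_min) (x/x_min)^(-alpha) on [x_min, Inf).
#
# All variables are treated as continuous, including integer degrees, so the
# same likelihood machinery applies to degree and strength samples alike.

check_rpl_params <- function(gamma, x_min, x_max) {
  check_scalar_number(gamma, "gamma")
  check_scalar_number(x_min, "x_min")
  check_scalar_number(x_max, "x_max")
  if (gamma <= -1) {
    rpl_stop("rplnet_param_error", "restricted power law requires gamma > -1 (got %g)", gamma)
  }
  if (x_min >= x_max) {
    rpl_stop("rplnet_param_error", "restricted power law requires x_min < x_max")
  }
  invisible(NULL)
}

check_tpl_params <- function(alpha, x_c, x_min) {
  check_scalar_number(alpha, "alpha")
  check_scalar_number(x_c, "x_c")
  check_scalar_number(x_min, "x_min")
  if (x_c <= 0) rpl_stop("rplnet_param_error", "truncated power law requires x_c > 0")
  if (x_min <= 0) rpl_stop("rplnet_param_error", "truncated power law requires x_min > 0")
  invisible(NULL)
}

check_plaw_params <- function(alpha, x_min) {
  check_scalar_number(alpha, "alpha")
  check_scalar_number(x_min, "x_min")
  if (alpha <= 1) {
    rpl_stop("rplnet_param_error", "power law requires alpha > 1 for normalizability (got %g)", alpha)
  }
  if (x_min <= 0) rpl_stop("rplnet_param_error", "power law requires x_min > 0")
  invisible(NULL)
}

#' Restricted (bounded-support) power law
#'
#' Density, distribution function, quantile function, random generation and
#' analytic mean for the bounded-support power law
#' \deqn{P(x) = \frac{\gamma+1}{x_{max}-x_{min}}
#'   \left(\frac{x_{max}-x}{x_{max}-x_{min}}\right)^{\gamma},
#'   \quad x \in [x_{min}, x_{max}],}
#' a power law in the distance to a hard upper bound \eqn{x_{max}}. The model
#' encodes scale-free behaviour under a finite resource (energy) constraint:
#' the bound suppresses the divergence of the tail and concentrates mass near
#' \eqn{x_{max}} when \eqn{\gamma < 0}, or decays to zero at the bound when
#' \eqn{\gamma > 0}.
#'
#' Closed forms: \eqn{F(x) = 1 - ((x_{max}-x)/(x_{max}-x_{min}))^{\gamma+1}},
#' \eqn{F^{-1}(u) = x_{max} - (x_{max}-x_{min})(1-u)^{1/(\gamma+1)}}, and
#' \eqn{E[X] = x_{max} - (x_{max}-x_{min})(\gamma+1)/(\gamma+2)}.
#'
#' @param x,q Vector of quantiles.
#' @param p Vector of probabilities in \[0, 1\].
#' @param n Number of draws.
#' @param gamma Exponent \eqn{\gamma > -1}.
#' @param x_min,x_max Support bounds, `x_min < x_max`.
#' @param log Logical; return log density.
#' @return `drpl` the density, `prpl` the CDF, `qrpl` the inverse CDF,
#'   `rrpl` random draws (inverse-CDF transform of uniforms), `rpl_mean`
#'   the analytic first moment.
#' @examples
#' drpl(1, gamma = 1, x_min = 0, x_max = 2)  # 0.5
#' qrpl(prpl(1.3, 2.22, 0.546, 33.5), 2.22, 0.546, 33.5)
#' rpl_mean(2.22, 0.546, 33.5)
#' @export
drpl <- function(x, gamma, x_min, x_max, log = FALSE) {
  check_rpl_params(gamma, x_min, x_max)
  span <- x_max - x_min
  tail <- pmax(x_max - x, 0)
  ld <- if (gamma == 0) {
    rep(log1p(gamma) - log(span), length(x))
  } else {
    log1p(gamma) - log(span) + gamma * (log(tail) - log(span))
  }
  ld[x < x_min | x > x_max] <- -Inf
  if (log) ld else exp(ld)
}

#' @rdname drpl
#' @export
prpl <- function(q, gamma, x_min, x_max) {
  check_rpl_params(gamma, x_min, x_max)
  span <- x_max - x_min
  p <- 1 - ((x_max - q) / span)^(gamma + 1)
  p[q <= x_min] <- 0
  p[q >= x_max] <- 1
  p
}

#' @rdname drpl
#' @export
qrpl <- function(p, gamma, x_min, x_max) {
  check_rpl_params(gamma, x_min, x_max)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    rpl_stop("rplnet_prob_error", "probabilities must lie in [0, 1]")
  }
  x_max - (x_max - x_min) * (1 - p)^(1 / (gamma + 1))
}

#' @rdname drpl
#' @export
rrpl <- function(n, gamma, x_min, x_max) {
  qrpl(stats::runif(n), gamma, x_min, x_max)
}

#' @rdname drpl
#' @export
rpl_mean <- function(gamma, x_min, x_max) {
  check_rpl_params(gamma, x_min, x_max)
  x_max - (x_max - x_min) * (gamma + 1) / (gamma + 2)
}

# log of the upper incomplete gamma function Gamma(shape, a), a > 0.
# For shape > 0 via pgamma; for shape <= 0 through the downward recurrence
# Gamma(s, a) = (Gamma(s + 1, a) - a^s e^(-a)) / s, applied until the shape
# is positive (stable in log space: for s < 0 the subtraction flips sign).
log_upper_inc_gamma <- function(shape, a) {
  if (shape > 1e-8) {
    return(lgamma(shape) +
             stats::pgamma(a, shape = shape, lower.tail = FALSE, log.p = TRUE))
  }
  lg1 <- log_upper_inc_gamma(shape + 1, a)
  lt <- shape * log(a) - a
  # Gamma(s, a) = (a^s e^(-a) - Gamma(s+1, a)) / (-s) for s < 0; when the
  # difference underflows the tail mass is numerically zero
  d <- -expm1(lg1 - lt)
  if (!is.finite(d) || d <= 0) return(-Inf)
  lt + log(d) - log(-shape)
}

# log normalizing constant of the truncated power law on [x_min, Inf):
# Z = integral_{x_min}^Inf t^(alpha-1) exp(-t/x_c) dt = x_c^alpha Gamma(alpha, x_min/x_c)
tpl_log_norm <- function(alpha, x_c, x_min) {
  alpha * log(x_c) + log_upper_inc_gamma(alpha, x_min / x_c)
}

#' Exponentially truncated power law
#'
#' Density, distribution, quantile function and random generation for the
#' exponentially truncated power law
#' \deqn{P(x) \propto x^{\alpha-1} e^{-x/x_c}, \quad x \ge x_{min} > 0,}
#' with cut-off scale \eqn{x_c}. The normalizing constant is
#' \eqn{x_c^{\alpha}\,\Gamma(\alpha, x_{min}/x_c)} (upper incomplete gamma),
#' evaluated through stable special functions for \eqn{\alpha > 0} and
#' through a downward log-space recurrence otherwise, so exponents
#' \eqn{\alpha \le 0} (pure-power-law-like shapes with an exponential tail)
#' are supported.
#'
#' The decaying exponential convention is used throughout: the density has a
#' finite integral on \eqn{[x_{min}, \infty)} and reduces pointwise to a pure
#' power-law shape \eqn{x^{\alpha-1}} on any compact window as
#' \eqn{x_c \to \infty}.
#'
#' @inheritParams drpl
#' @param alpha Shape exponent (any real).
#' @param x_c Positive exponential cut-off scale.
#' @param x_min Positive lower support bound.
#' @return `dtpl` the density, `ptpl` the CDF, `qtpl` the inverse CDF
#'   (through the truncated-gamma representation for `alpha > 0`; monotone
#'   bracketed root-finding, absolute tolerance 1e-10, otherwise), `rtpl`
#'   random draws.
#' @examples
#' dtpl(1, alpha = 2.17, x_c = 5.67, x_min = 0.5)
#' ptpl(c(1, 5, 20), 2.17, 5.67, 0.5)
#' @export
dtpl <- function(x, alpha, x_c, x_min, log = FALSE) {
  check_tpl_params(alpha, x_c, x_min)
  lz <- tpl_log_norm(alpha, x_c, x_min)
  ld <- (alpha - 1) * log(x) - x / x_c - lz
  ld[x < x_min] <- -Inf
  if (log) ld else exp(ld)
}

#' @rdname dtpl
#' @export
ptpl <- function(q, alpha, x_c, x_min) {
  check_tpl_params(alpha, x_c, x_min)
  a <- x_min / x_c
  if (alpha > 1e-8) {
    lden <- stats::pgamma(a, shape = alpha, lower.tail = FALSE, log.p = TRUE)
    lnum <- stats::pgamma(pmax(q, x_min) / x_c, shape = alpha,
                          lower.tail = FALSE, log.p = TRUE)
    p <- 1 - exp(lnum - lden)
  } else {
    lden <- log_upper_inc_gamma(alpha, a)
    lnum <- vapply(pmax(q, x_min) / x_c, function(b) log_upper_inc_gamma(alpha, b),
                   numeric(1))
    p <- 1 - exp(lnum - lden)
  }
  p[q <= x_min] <- 0
  pmin(pmax(p, 0), 1)
}

#' @rdname dtpl
#' @export
qtpl <- function(p, alpha, x_c, x_min) {
  check_tpl_params(alpha, x_c, x_min)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    rpl_stop("rplnet_prob_error", "probabilities must lie in [0, 1]")
  }
  if (alpha > 1e-8) {
    # left-truncated gamma: S(x) = Q(alpha, x/x_c) / Q(alpha, a), inverted
    # through qgamma on the (log) upper tail for numerical stability
    a <- x_min / x_c
    lsa <- stats::pgamma(a, shape = alpha, lower.tail = FALSE, log.p = TRUE)
    out <- x_c * stats::qgamma(log1p(-p) + lsa, shape = alpha,
                               lower.tail = FALSE, log.p = TRUE)
    out[p >= 1] <- Inf
    return(pmax(out, x_min))
  }
  # monotone bracketed inversion for alpha <= 0
  vapply(p, function(u) {
    if (u <= 0) return(x_min)
    if (u >= 1) return(Inf)
    upper <- x_min + x_c
    while (ptpl(upper, alpha, x_c, x_min) < u) upper <- x_min + 2 * (upper - x_min)
    stats::uniroot(function(x) ptpl(x, alpha, x_c, x_min) - u,
                   lower = x_min, upper = upper, tol = 1e-10)$root
  }, numeric(1))
}

#' @rdname dtpl
#' @export
rtpl <- function(n, alpha, x_c, x_min) {
  qtpl(stats::runif(n), alpha, x_c, x_min)
}

#' Plain power law
#'
#' Density, distribution, quantile function and random generation for the
#' Pareto-type power law
#' \deqn{P(x) = \frac{\alpha-1}{x_{min}} \left(\frac{x}{x_{min}}\right)^{-\alpha},
#'   \quad x \ge x_{min} > 0, \; \alpha > 1,}
#' the scale-free reference model. \eqn{x_{min}} rescales the support when the
#' minimum of the variable is not 1.
#'
#' @inheritParams drpl
#' @param alpha Exponent, must exceed 1 for normalizability on
#'   \eqn{[x_{min}, \infty)}.
#' @param x_min Positive lower support bound.
#' @return `dplaw` the density, `pplaw` the CDF, `qplaw` the closed-form
#'   inverse CDF, `rplaw` random draws.
#' @examples
#' dplaw(2, alpha = 2, x_min = 1)  # 0.25
#' @export
dplaw <- function(x, alpha, x_min, log = FALSE) {
  check_plaw_params(alpha, x_min)
  ld <- log(alpha - 1) - log(x_min) - alpha * (log(x) - log(x_min))
  ld[x < x_min] <- -Inf
  if (log) ld else exp(ld)
}

#' @rdname dplaw
#' @export
pplaw <- function(q, alpha, x_min) {
  check_plaw_params(alpha, x_min)
  p <- 1 - (q / x_min)^(1 - alpha)
  p[q <= x_min] <- 0
  p
}

#' @rdname dplaw
#' @export
qplaw <- function(p, alpha, x_min) {
  check_plaw_params(alpha, x_min)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    rpl_stop("rplnet_prob_error", "probabilities must lie in [0, 1]")
  }
  x_min * (1 - p)^(-1 / (alpha - 1))
}

#' @rdname dplaw
#' @export
rplaw <- function(n, alpha, x_min) {
  qplaw(stats::runif(n), alpha, x_min)
}

model_ids <- function() c("powerlaw", "truncated", "restricted")

#' Draw a sample from one of the three candidate models
#'
#' Inverse-CDF sampling dispatcher: a uniform sequence \eqn{r_1, \dots, r_n}
#' is mapped through the model's inverse cumulative distribution. The
#' restricted and plain power laws use their closed-form inverses; the
#' truncated power law inverts its CDF by bracketed root-finding.
#'
#' @param model_id One of `"restricted"`, `"truncated"`, `"powerlaw"`.
#' @param params Named list of model parameters: `gamma`, `x_min`, `x_max`
#'   (restricted); `alpha`, `x_c`, `x_min` (truncated); `alpha`, `x_min`
#'   (powerlaw).
#' @param n Number of draws.
#' @param seed Optional integer seed; when supplied the caller's RNG state is
#'   left untouched.
#' @return Numeric vector of `n` draws.
#' @examples
#' sample_model("restricted", list(gamma = 2.22, x_min = 0.546, x_max = 33.5), 5, seed = 1)
#' @export
sample_model <- function(model_id, params, n, seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    rpl_stop("rplnet_param_error", "`n` must be a positive count")
  }
  with_seed(seed, {
    switch(model_id,
      restricted = rrpl(n, params$gamma, params$x_min, params$x_max),
      truncated  = rtpl(n, params$alpha, params$x_c, params$x_min),
      powerlaw   = rplaw(n, params$alpha, params$x_min),
      rpl_stop("rplnet_model_error", "unknown model id '%s'", model_id)
    )
  })
}
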