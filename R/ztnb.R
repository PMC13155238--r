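#' Zero-truncated negative binomial distribution
#'
#' Density, random generation and log-likelihood for the zero-truncated
#' negative binomial (ZTNB) distribution in the NB2 parameterisation
#' (mean `mu`, size `k`, variance `mu + mu^2 / k` before truncation).
#' Truncation conditions on `y >= 1`: the NB log pmf is adjusted by
#' `-log(1 - p0)` with `p0 = (k / (k + mu))^k`, the NB probability of a zero.
#'
#' The analysis frame behind this family contains only observed
#' country x substrate x species combinations -- absences are never imputed
#' as zeros -- so the zero class is structurally missing and a truncated
#' count family is the natural likelihood.
#'
#' @param y Vector of positive integer counts (`y >= 1`).
#' @param mu Positive mean of the untruncated NB distribution.
#' @param k Positive NB size (dispersion) parameter; `k -> Inf` recovers the
#'   zero-truncated Poisson.
#' @param log Logical; return log density?
#' @param n Number of random draws.
#' @return `dztnb()` returns (log) densities; `rztnb()` returns positive
#'   integer draws; `ztnb_loglik()` returns the summed log-likelihood.
#' @export
#' @examples
#' sum(dztnb(1:500, mu = 3, k = 0.8)) # ~1: normalises on y >= 1
dztnb <- function(y, mu, k, log = FALSE) {
  if (any(y < 1) || any(y != floor(y))) {
    stop("dztnb() is defined on positive integers only (zeros are structurally absent)")
  }
  assert_that(all(mu > 0) && all(k > 0), "mu and k must be positive")
  # log(1 - p0) computed stably: log1p(-exp(k * log(k / (k + mu))))
  log_p0 <- k * (log(k) - log(k + mu))
  ll <- stats::dnbinom(y, size = k, mu = mu, log = TRUE) - log1p(-exp(log_p0))
  if (log) ll else exp(ll)
}

#' @rdname dztnb
#' @export
ztnb_loglik <- function(y, mu, k) {
  sum(dztnb(y, mu, k, log = TRUE))
}

#' @rdname dztnb
#' @export
rztnb <- function(n, mu, k) {
  # inverse-CDF on the untruncated NB restricted to (p0, 1]: exact and cheap
  p0 <- exp(k * (log(k) - log(k + mu)))
  u <- stats::runif(n, min = p0, max = 1)
  stats::qnbinom(pmin(u, 1 - 1e-15), size = k, mu = mu)
}

#' Fixed-effects zero-truncated negative binomial regression
#'
#' Maximum-likelihood ZTNB regression with a log link and an offset, fitted by
#' direct optimisation of the truncated log-likelihood. This is the
#' fixed-effects-only counterpart of [fit_substrate_model()]: when random-effect
#' variances are zero the two agree, and it is the fast engine used inside
#' cross-validation and simulation studies.
#'
#' @param formula Model formula for the fixed effects (response on the left).
#' @param data Data frame containing the variables and the offset.
#' @param offset Optional numeric vector of log-exposure offsets (length
#'   `nrow(data)`); defaults to 0.
#' @param start Optional starting values for the coefficients; defaults to a
#'   Poisson GLM fit.
#' @return An object of class `ztnb_glm` with elements `coefficients`, `k`
#'   (NB size), `vcov` (fixed-effect covariance from the observed information),
#'   `logLik`, `fitted` (conditional ZTNB means are *not* returned; `fitted`
#'   holds the untruncated `mu`), `converged`, and the model frame pieces
#'   needed for prediction.
#' @export
ztnb_glm <- function(formula, data, offset = NULL, start = NULL) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  off <- offset %||% rep(0, nrow(X))
  assert_that(all(y >= 1), "ztnb_glm() requires strictly positive counts")
  assert_that(all(is.finite(off)), "offsets must be finite")

  if (is.null(start)) {
    start <- stats::glm.fit(X, y, offset = off, family = stats::poisson())$coefficients
  }
  negll <- function(par) {
    beta <- par[-length(par)]
    k <- exp(max(min(par[length(par)], 30), -30))
    mu <- exp(drop(X %*% beta) + off)
    if (!all(is.finite(mu)) || any(mu <= 0)) return(1e10)
    ll <- ztnb_loglik(y, mu, k)
    if (!is.finite(ll)) 1e10 else -ll
  }
  grad <- function(par) {
    beta <- par[-length(par)]
    k <- exp(max(min(par[length(par)], 30), -30))
    eta <- drop(X %*% beta) + off
    mu <- exp(eta)
    if (!all(is.finite(mu))) return(rep(0, length(par)))
    log_p0 <- k * (log(k) - log(k + mu))
    p0 <- exp(log_p0)
    dll_dmu <- y / mu - (y + k) / (k + mu) - p0 * k / ((1 - p0) * (k + mu))
    g_beta <- -drop(crossprod(X, dll_dmu * mu))
    dll_dk <- digamma(y + k) - digamma(k) + log(k / (k + mu)) +
      (mu - y) / (k + mu) +
      p0 * (log(k / (k + mu)) + mu / (k + mu)) / (1 - p0)
    c(g_beta, -sum(dll_dk) * k)
  }
  opt <- stats::optim(c(start, log_k = 0), negll, gr = grad, method = "BFGS",
                      control = list(maxit = 500), hessian = TRUE)
  par <- opt$par
  beta <- par[-length(par)]
  names(beta) <- colnames(X)
  vcov_all <- tryCatch(solve(opt$hessian), error = function(e) {
    matrix(NA_real_, length(par), length(par))
  })
  vc <- vcov_all[seq_along(beta), seq_along(beta), drop = FALSE]
  dimnames(vc) <- list(names(beta), names(beta))
  structure(
    list(coefficients = beta, k = unname(exp(par[length(par)])), vcov = vc,
         logLik = -opt$value, converged = opt$convergence == 0,
         mu = exp(drop(X %*% beta) + off), y = y, formula = formula,
         xlevels = stats::.getXlevels(stats::terms(formula, data = data), mf)),
    class = "ztnb_glm"
  )
}

#' @export
coef.ztnb_glm <- function(object, ...) object$coefficients

#' @export
vcov.ztnb_glm <- function(object, ...) object$vcov

#' @export
logLik.ztnb_glm <- function(object, ...) {
  structure(object$logLik, df = length(object$coefficients) + 1, class = "logLik")
}

#' Predict untruncated means from a ztnb_glm fit
#'
#' @param object A `ztnb_glm` fit.
#' @param newdata Data frame of new observations.
#' @param offset Log-exposure offsets for `newdata` (default 0).
#' @param ... Unused.
#' @return Vector of untruncated NB means `mu` on the response scale.
#' @export
predict.ztnb_glm <- function(object, newdata, offset = NULL, ...) {
  tt <- stats::delete.response(stats::terms(object$formula))
  X <- stats::model.matrix(tt, stats::model.frame(tt, newdata,
                                                 xlev = object$xlevels))
  off <- offset %||% rep(0, nrow(X))
  exp(drop(X %*% object$coefficients) + off)
}

#' @export
print.ztnb_glm <- function(x, ...) {
  cat("Zero-truncated negative binomial regression\n")
  cat("  log-likelihood:", format(x$logLik), "  k:", format(x$k), "\n")
  print(x$coefficients)
  invisible(x)
}

#' @export
tidy.ztnb_glm <- function(x, conf.int = TRUE, conf.level = 0.95,
                          exponentiate = FALSE, ...) {
  se <- sqrt(diag(x$vcov))
  z <- x$coefficients / se
  out <- tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = unname(se),
    statistic = unname(z),
    p.value = unname(2 * stats::pnorm(-abs(z)))
  )
  if (conf.int) {
    q <- stats::qnorm(1 - (1 - conf.level) / 2)
    out$conf.low <- out$estimate - q * out$std.error
    out$conf.high <- out$estimate + q * out$std.error
  }
  if (exponentiate) {
    out <- dplyr::mutate(out, dplyr::across(
      dplyr::any_of(c("estimate", "conf.low", "conf.high")), exp))
  }
  out
}

#' @export
glance.ztnb_glm <- function(x, ...) {
  tibble::tibble(
    logLik = x$logLik, k = x$k,
    nobs = length(x$mu),
    converged = x$converged
  )
}
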