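# Negative-binomial GLM with log link, fitted by IRLS for the regression
# coefficients alternated with maximum-likelihood estimation of the
# dispersion theta (moment start, Newton polish on the profile score).
# Variance model: Var(y) = mu + mu^2 / theta, so larger theta approaches
# Poisson.

#' Fit a negative-binomial GLM (log link)
#'
#' Models non-negative counts (or intensity measurements treated as counts)
#' whose variance grows with the mean as `mu + mu^2 / theta`. Coefficients
#' are estimated by iteratively reweighted least squares at the current
#' `theta`; `theta` is then updated by Newton steps on its profile score
#' equation, starting from a moment estimate. The two updates alternate
#' until the relative change in both falls below `tol`.
#'
#' @param counts Non-negative integer response vector.
#' @param design Numeric design matrix (rows = observations); include an
#'   intercept column if wanted. Must have full column rank.
#' @param tol Convergence tolerance on the relative change of `beta` and
#'   `theta` (default 1e-8).
#' @param max_iter Cap on outer iterations (default 100). Non-convergence is
#'   flagged in the result, not raised.
#' @return An object of class `nb_glm_fit`: list with `beta`, `se_beta`
#'   (from the inverse Fisher information at the optimum), `theta`,
#'   `loglik`, `converged`, `iterations`, `fitted` (the mean vector) and
#'   `vcov_beta`.
#' @export
fit_nb_glm <- function(counts, design, tol = 1e-8, max_iter = 100L) {
  y <- counts
  if (!is.numeric(y) || any(!is.finite(y)) || any(y < 0) ||
    any(y != floor(y))) {
    stop("`counts` must be non-negative integers", call. = FALSE)
  }
  x <- as.matrix(design)
  if (nrow(x) != length(y)) {
    stop("`design` rows must match `counts` length", call. = FALSE)
  }
  if (qr(x)$rank < ncol(x)) {
    stop("`design` must have full column rank", call. = FALSE)
  }

  # initial mean and coefficients from a Poisson-like weighted fit
  mu <- pmax(y, 1 / 6) + mean(y) / 10
  eta <- log(mu)
  beta <- qr.solve(x, eta)
  mu <- exp(drop(x %*% beta))
  theta <- nb_theta_moment(y, mu, ncol(x))

  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    beta_new <- nb_irls_beta(y, x, theta, beta)
    mu <- exp(drop(x %*% beta_new))
    theta_new <- nb_theta_ml(y, mu, theta)
    d_beta <- max(abs(beta_new - beta)) / max(1, max(abs(beta_new)))
    d_theta <- abs(theta_new - theta) / max(1, theta_new)
    beta <- beta_new
    theta <- theta_new
    if (d_beta < tol && d_theta < tol) {
      converged <- TRUE
      break
    }
  }

  w <- mu / (1 + mu / theta)
  info <- crossprod(x, x * w)
  vcov <- solve(info)
  ll <- sum(stats::dnbinom(y, size = theta, mu = mu, log = TRUE))
  structure(
    list(
      beta = stats::setNames(drop(beta), colnames(x)),
      se_beta = stats::setNames(sqrt(diag(vcov)), colnames(x)),
      theta = theta,
      loglik = ll,
      converged = converged,
      iterations = iter,
      fitted = mu,
      vcov_beta = vcov
    ),
    class = "nb_glm_fit"
  )
}

#' @export
print.nb_glm_fit <- function(x, ...) {
  cat("Negative-binomial GLM (log link)\n")
  cat(
    "theta:", format(x$theta, digits = 5),
    if (x$converged) "(converged" else "(NOT converged",
    "in", x$iterations, "iterations)\n\n"
  )
  tab <- data.frame(
    estimate = x$beta, se = x$se_beta,
    z = x$beta / x$se_beta,
    p = 2 * stats::pnorm(-abs(x$beta / x$se_beta))
  )
  print(tab, digits = 4)
  invisible(x)
}

# IRLS for beta at fixed theta; weights w = mu/(1 + mu/theta), working
# response z = eta + (y - mu)/mu
nb_irls_beta <- function(y, x, theta, beta, tol = 1e-10, max_iter = 50L) {
  for (i in seq_len(max_iter)) {
    eta <- drop(x %*% beta)
    mu <- exp(eta)
    w <- mu / (1 + mu / theta)
    z <- eta + (y - mu) / mu
    xtw <- crossprod(x, x * w)
    beta_new <- solve(xtw, crossprod(x, w * z))
    if (max(abs(beta_new - beta)) < tol * max(1, max(abs(beta_new)))) {
      return(drop(beta_new))
    }
    beta <- drop(beta_new)
  }
  beta
}

# moment estimate of theta from Pearson-type residuals
nb_theta_moment <- function(y, mu, p) {
  num <- sum((y - mu)^2 - mu)
  den <- sum(mu^2)
  if (num <= 0) {
    return(1e6) # under-dispersed sample: effectively Poisson
  }
  max(den / num * max(1, (length(y) - p) / length(y)), 1e-3)
}

# Newton iteration on the profile score in theta:
#   S(theta) = sum[ digamma(theta+y) - digamma(theta) + log(theta) + 1
#                   - log(theta+mu) - (theta+y)/(theta+mu) ]
nb_theta_ml <- function(y, mu, theta, tol = 1e-10, max_iter = 50L) {
  for (i in seq_len(max_iter)) {
    tm <- theta + mu
    ty <- theta + y
    score <- sum(
      digamma(ty) - digamma(theta) + log(theta) + 1 - log(tm) - ty / tm
    )
    dscore <- sum(
      trigamma(ty) - trigamma(theta) + 1 / theta - 2 / tm + ty / tm^2
    )
    if (!is.finite(score) || !is.finite(dscore) || dscore == 0) break
    step <- score / dscore
    theta_new <- theta - step
    # keep theta positive; damp overshooting steps
    while (theta_new <= 0) {
      step <- step / 2
      theta_new <- theta - step
    }
    if (theta_new > 1e8) theta_new <- 1e8
    if (abs(theta_new - theta) < tol * max(1, theta_new)) {
      return(theta_new)
    }
    theta <- theta_new
  }
  theta
}
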