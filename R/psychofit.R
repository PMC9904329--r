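# Psychometric (cumulative Gaussian) and confidence (inverted Gaussian PDF)
# curve fitting by nonlinear least squares on per-level response proportions.

#' Cumulative Gaussian psychometric function
#'
#' \deqn{\Psi(x) = \gamma + \frac{1-\gamma-\lambda}{2}\left(1 +
#'   \mathrm{erf}\frac{x-\alpha}{\beta\sqrt 2}\right)}
#' where `alpha` is the mean (the point of subjective equality), `beta` the
#' standard deviation, `gamma` the guess rate and `lambda` the lapse rate.
#' Equivalent to `gamma + (1 - gamma - lambda) * pnorm(x, alpha, beta)`.
#'
#' @param x stimulus axis (here the numerosity difference in pieces).
#' @param alpha,beta location and spread; `beta > 0`.
#' @param gamma,lambda guess and lapse rates.
#' @return probabilities in `[gamma, 1 - lambda]`.
#' @examples
#' psi(1, alpha = 0, beta = 1)  # 0.8413
#' @export
psi <- function(x, alpha, beta, gamma = 0, lambda = 0) {
  if (beta <= 0) stop("`beta` must be positive", call. = FALSE)
  gamma + (1 - gamma - lambda) * stats::pnorm(x, mean = alpha, sd = beta)
}

#' Confidence curve: inverted Gaussian PDF
#'
#' \deqn{C(x) = 1 - a\,e^{-\frac12\left(\frac{x-\mu}{\sigma}\right)^2}}
#' The curve dips to its global minimum `1 - a` at `x = mu` (the point of
#' minimum confidence) and rises to 1 far from it; `a` is the amplitude of
#' the confidence modulation.
#'
#' @param x stimulus axis.
#' @param mu,sigma location and width of the dip; `sigma > 0`.
#' @param a amplitude in [0, 1].
#' @return probabilities of a high-confidence response.
#' @examples
#' confidence_curve(0, mu = 0, sigma = 4, a = 0.73)  # 0.27
#' @export
confidence_curve <- function(x, mu, sigma, a) {
  if (sigma <= 0) stop("`sigma` must be positive", call. = FALSE)
  1 - a * exp(-0.5 * ((x - mu) / sigma)^2)
}

# Shared multi-start bounded least-squares driver.
ls_multistart <- function(objective, starts, lower, upper) {
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(as.numeric(starts[i, ]), objective, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 500, factr = 4.5e6)),  # ~1e-9 on the RSS
      error = function(e) NULL
    )
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value - 1e-12 ||
        (abs(fit$value - best$value) <= 1e-12 && abs(fit$par[1]) < abs(best$par[1]))) {
      best <- fit
    }
  }
  if (is.null(best)) stop("optimization failed from every start", call. = FALSE)
  # polish the winning start at high precision
  polished <- tryCatch(
    stats::optim(best$par, objective, method = "L-BFGS-B",
                 lower = lower, upper = upper,
                 control = list(maxit = 500, factr = 10)),
    error = function(e) NULL
  )
  if (!is.null(polished) && polished$value <= best$value) best <- polished
  best
}

check_fit_input <- function(x, prop) {
  if (length(x) != length(prop)) stop("`x` and `prop` lengths differ", call. = FALSE)
  if (length(unique(x)) < 4L) stop("need at least 4 distinct stimulus levels", call. = FALSE)
  if (any(prop < 0 | prop > 1)) stop("`prop` must be proportions in [0, 1]", call. = FALSE)
}

#' Fit the psychometric function to per-level choice proportions
#'
#' Unweighted nonlinear least squares of the cumulative Gaussian `psi()` to
#' the proportion of one choice per stimulus level, with free parameters
#' (alpha, beta, lambda) and the guess rate constrained to the lapse rate
#' (gamma = lambda). The point of subjective equality (PSE) is the fitted
#' alpha. Optimization uses bounded L-BFGS-B from a 3 x 3 x 3 multi-start
#' grid; ties are broken by the smaller |alpha|. Degenerate data (constant
#' proportions, where alpha is unidentifiable) are flagged as not converged.
#'
#' @param x stimulus levels (numerosity differences).
#' @param prop observed proportion at each level.
#' @param n_trials trials per level (metadata; the objective is unweighted).
#' @return an object of class `psychometric_fit`: list with `alpha`, `beta`,
#'   `gamma`, `lambda`, `pse`, `rss`, `fitted`, `converged`, `n_levels`,
#'   `n_trials`.
#' @export
fit_psychometric <- function(x, prop, n_trials = NULL) {
  check_fit_input(x, prop)
  objective <- function(par) {
    sum((psi(x, par[1], par[2], gamma = par[3], lambda = par[3]) - prop)^2)
  }
  xr <- range(x)
  span <- max(diff(xr), 1e-6)
  starts <- expand.grid(
    alpha = stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE),
    beta = pmax(span * c(0.1, 0.3, 0.8), 0.2),
    lambda = c(0, 0.05, 0.15)
  )
  lower <- c(xr[1] - span, 0.1, 0)
  upper <- c(xr[2] + span, 50, 0.25)
  best <- ls_multistart(objective, starts, lower, upper)
  degenerate <- stats::sd(prop) < 1e-9
  par <- best$par
  structure(list(
    alpha = par[1], beta = par[2], gamma = par[3], lambda = par[3],
    pse = par[1],
    rss = best$value,
    fitted = psi(x, par[1], par[2], gamma = par[3], lambda = par[3]),
    x = x, prop = prop,
    converged = best$convergence == 0 && !degenerate,
    n_levels = length(unique(x)),
    n_trials = n_trials
  ), class = "psychometric_fit")
}

#' Fit the confidence curve to per-level high-confidence proportions
#'
#' Least-squares fit of `confidence_curve()` with free (mu, sigma, a); the
#' point of minimum confidence is the fitted mu and the minimum confidence
#' level is 1 - a. Same optimizer and convergence conventions as
#' `fit_psychometric()`; flat data (including all-high-confidence responses,
#' where mu is unidentifiable) are flagged as not converged.
#'
#' @inheritParams fit_psychometric
#' @return an object of class `confidence_fit`: list with `mu`, `sigma`, `a`,
#'   `min_confidence_point`, `rss`, `fitted`, `converged`, `n_levels`,
#'   `n_trials`.
#' @export
fit_confidence <- function(x, prop, n_trials = NULL) {
  check_fit_input(x, prop)
  objective <- function(par) {
    sum((confidence_curve(x, par[1], par[2], par[3]) - prop)^2)
  }
  xr <- range(x)
  span <- max(diff(xr), 1e-6)
  starts <- expand.grid(
    mu = stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE),
    sigma = pmax(span * c(0.1, 0.3, 0.8), 0.2),
    a = c(0.3, 0.6, 0.9)
  )
  lower <- c(xr[1] - span, 0.1, 0)
  upper <- c(xr[2] + span, 50, 1)
  best <- ls_multistart(objective, starts, lower, upper)
  degenerate <- stats::sd(prop) < 1e-9
  par <- best$par
  structure(list(
    mu = par[1], sigma = par[2], a = par[3],
    min_confidence_point = par[1],
    rss = best$value,
    fitted = confidence_curve(x, par[1], par[2], par[3]),
    x = x, prop = prop,
    converged = best$convergence == 0 && !degenerate,
    n_levels = length(unique(x)),
    n_trials = n_trials
  ), class = "confidence_fit")
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf("<psychometric_fit> PSE = %.3f, beta = %.3f, lambda = %.4f, RSS = %.4g%s\n",
              x$pse, x$beta, x$lambda, x$rss,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' @export
print.confidence_fit <- function(x, ...) {
  cat(sprintf("<confidence_fit> mu = %.3f, sigma = %.3f, a = %.3f, RSS = %.4g%s\n",
              x$mu, x$sigma, x$a, x$rss,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}
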