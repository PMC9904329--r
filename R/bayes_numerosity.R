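# Bayesian observer for hidden-object numerosity: hypergeometric urn
# likelihood over board cells, Gaussian priors over the total or hidden
# count, posterior over the total, and BIC model comparison.

#' Urn specification for the cell-occupancy model
#'
#' The board's cells form an urn with two categories of balls: `N_v` visible
#' cells and `N_h` completely hidden cells. Placing `n_total` objects on
#' distinct cells is a draw of `n_total` balls without replacement, so the
#' visible count is hypergeometric.
#'
#' @param N_v,N_h visible and hidden cell counts.
#' @return an object of class `urn_spec` with `N_v`, `N_h`, `N_total`.
#' @export
urn_spec <- function(N_v, N_h) {
  stopifnot_scalar_count(N_v, "N_v")
  stopifnot_scalar_count(N_h, "N_h")
  structure(list(N_v = as.integer(N_v), N_h = as.integer(N_h),
                 N_total = as.integer(N_v + N_h)), class = "urn_spec")
}

#' Integer urns for the two estimation-experiment occluders
#'
#' The published hidden-to-visible area ratios for the small and large mesh
#' occluders are 0.27 and 1.05. With `ratio_source = "paper"` these ratios
#' are converted to the nearest integer split of the 117 board cells
#' (N_h = 25/92 and 60/57); with `ratio_source = "geometry"` the urns are
#' computed from this package's rasterized occluder geometry, whose hole
#' layout is a reconstruction and therefore yields its own ratios.
#'
#' @param ratio_source `"paper"` or `"geometry"`.
#' @return named list of `urn_spec` objects (`small_occluder`, `large_occluder`).
#' @export
exp2_urns <- function(ratio_source = c("paper", "geometry")) {
  ratio_source <- match.arg(ratio_source)
  if (ratio_source == "paper") {
    total <- 117L
    ratios <- c(small_occluder = 0.27, large_occluder = 1.05)
    out <- lapply(ratios, function(r) {
      n_h <- as.integer(round_half_up(total * r / (1 + r)))
      urn_spec(total - n_h, n_h)
    })
  } else {
    board <- make_board()
    out <- list(
      small_occluder = local({
        g <- occlusion_geometry(board, make_mesh_occluder(40, 60))
        urn_spec(g$N_v, g$N_h)
      }),
      large_occluder = local({
        g <- occlusion_geometry(board, make_mesh_occluder(30, 45))
        urn_spec(g$N_v, g$N_h)
      })
    )
  }
  out
}

#' Hypergeometric likelihood of the visible count
#'
#' Probability of observing `n_v` visible objects when `n_total` objects are
#' placed on distinct cells of an urn with `N_v` visible and `N_h` hidden
#' cells:
#' \deqn{P(n_v \mid n_{v+h}) = \binom{N_v}{n_v}\binom{N_h}{n_{v+h}-n_v}
#'   \Big/ \binom{N_v+N_h}{n_{v+h}}}
#'
#' @param n_v observed visible count (vectorised).
#' @param n_total total object count (vectorised; recycled against `n_v`).
#' @param urn an `urn_spec`.
#' @param lenient if TRUE (default), out-of-support combinations return 0
#'   instead of raising an error.
#' @return probabilities.
#' @examples
#' hypergeom_likelihood(1, 2, urn_spec(3, 2))  # 0.6
#' @export
hypergeom_likelihood <- function(n_v, n_total, urn, lenient = TRUE) {
  stopifnot(inherits(urn, "urn_spec"))
  if (any(n_v < 0) || any(n_total < 0)) stop("counts must be non-negative", call. = FALSE)
  k <- pmax(length(n_v), length(n_total))
  n_v <- rep_len(n_v, k); n_total <- rep_len(n_total, k)
  ok <- n_v <= urn$N_v & (n_total - n_v) >= 0 & (n_total - n_v) <= urn$N_h &
        n_total <= urn$N_total
  if (!lenient && any(!ok)) {
    stop("visible/total counts outside the urn's support", call. = FALSE)
  }
  out <- numeric(k)
  out[ok] <- exp(lchoose(urn$N_v, n_v[ok]) + lchoose(urn$N_h, n_total[ok] - n_v[ok]) -
                 lchoose(urn$N_total, n_total[ok]))
  out
}

#' Gaussian prior over the total or the hidden object count
#'
#' `constant_total` places a Gaussian directly on the total count
#' n_{v+h}; `constant_hidden` places it on the hidden count n_h, which maps
#' to n_{v+h} = n_v + n_h per trial (the only reading under which "a
#' constant number of hidden objects" does not depend on the visible count).
#' The density is discretized by evaluation at the integers of the truncated
#' support and renormalized.
#'
#' @param kind `"constant_total"` or `"constant_hidden"`.
#' @param mean,sd prior centre and spread in pieces; `sd > 0`.
#' @return an object of class `prior_model`.
#' @export
prior_model <- function(kind = c("constant_total", "constant_hidden"), mean, sd) {
  kind <- match.arg(kind)
  if (!is.numeric(sd) || sd <= 0) stop("`sd` must be positive", call. = FALSE)
  structure(list(kind = kind, mean = mean, sd = sd), class = "prior_model")
}

#' Posterior over the total object count
#'
#' Combines the hypergeometric likelihood with the discretized Gaussian
#' prior by Bayes' rule:
#' \deqn{P(n_{v+h} \mid n_v) = P(n_v \mid n_{v+h})\,P(n_{v+h}) / P(n_v)}
#' on the integer support n_{v+h} in [n_v, n_v + N_h].
#'
#' @param n_v observed visible count.
#' @param urn an `urn_spec`.
#' @param prior a `prior_model`.
#' @return an object of class `posterior_total`: list with `support`,
#'   `prob`, `n_v`, `urn`, `prior`.
#' @export
posterior_total <- function(n_v, urn, prior) {
  stopifnot_scalar_count(n_v, "n_v")
  stopifnot(inherits(urn, "urn_spec"), inherits(prior, "prior_model"))
  if (n_v > urn$N_v) stop("n_v exceeds the number of visible cells", call. = FALSE)
  support <- n_v:(n_v + urn$N_h)
  prior_prob <- switch(prior$kind,
    constant_total = stats::dnorm(support, prior$mean, prior$sd),
    constant_hidden = stats::dnorm(support - n_v, prior$mean, prior$sd)
  )
  if (sum(prior_prob) <= 0) stop("prior support empty after truncation", call. = FALSE)
  lik <- hypergeom_likelihood(n_v, support, urn)
  post <- lik * prior_prob
  z <- sum(post)
  if (z <= 0) stop("empty posterior: likelihood and prior do not overlap", call. = FALSE)
  structure(list(support = support, prob = post / z, n_v = n_v,
                 urn = urn, prior = prior), class = "posterior_total")
}

#' Predicted number of hidden objects
#'
#' Posterior readout of the hidden count n_h = n_{v+h} - n_v. The default
#' readout is the posterior mean; the mode is available as an alternative.
#' Because the hypergeometric likelihood is much broader than typical
#' priors, the prediction tracks the prior: a constant-hidden prior yields
#' near-constant predictions across visible counts, a constant-total prior
#' yields predictions decreasing in the visible count.
#'
#' @param n_v visible count(s); vectorised.
#' @param urn an `urn_spec`.
#' @param prior a `prior_model`.
#' @param readout `"mean"` or `"mode"`.
#' @return expected hidden count(s), real-valued.
#' @export
predict_hidden <- function(n_v, urn, prior, readout = c("mean", "mode")) {
  readout <- match.arg(readout)
  vapply(n_v, function(nv) {
    post <- posterior_total(nv, urn, prior)
    hidden <- post$support - nv
    switch(readout,
      mean = sum(post$prob * hidden),
      mode = hidden[which.max(post$prob)]
    )
  }, numeric(1))
}

#' Fit a prior model to condition-mean hidden estimates
#'
#' Least-squares fit of the Bayesian observer's predicted hidden count to
#' observed condition means over the (visible count, occluder) design cells,
#' with the prior's mean and standard deviation as the two free parameters.
#' Multi-start bounded optimization (mean starts 1..20, sd starts 0.5-8;
#' bounds mean in (0, 117], sd in (0.1, 50]).
#'
#' @param data data.frame with columns `n_v`, `occluder` and
#'   `mean_estimate` (one row per design cell).
#' @param urns named list of `urn_spec`, indexed by the `occluder` values.
#' @param kind prior kind to fit.
#' @param readout posterior readout passed to `predict_hidden()`.
#' @return list with `prior` (fitted `prior_model`), `rss`, `converged`,
#'   `n_points`, of class `prior_fit`.
#' @export
fit_prior <- function(data, urns, kind = c("constant_total", "constant_hidden"),
                      readout = "mean") {
  kind <- match.arg(kind)
  stopifnot(all(c("n_v", "occluder", "mean_estimate") %in% names(data)))
  if (nrow(data) < 3L) stop("need at least 3 design cells", call. = FALSE)
  if (!all(data$occluder %in% names(urns))) {
    stop("every `occluder` level needs an urn in `urns`", call. = FALSE)
  }
  # The likelihood depends only on (urn, n_v), not on the prior parameters:
  # precompute it per design cell and flatten all supports into single
  # vectors so each objective evaluation is a handful of vectorized ops.
  cell_parts <- lapply(seq_len(nrow(data)), function(i) {
    urn <- urns[[data$occluder[i]]]
    support <- data$n_v[i]:(data$n_v[i] + urn$N_h)
    list(support = support, hidden = support - data$n_v[i],
         lik = hypergeom_likelihood(data$n_v[i], support, urn))
  })
  support_all <- unlist(lapply(cell_parts, `[[`, "support"))
  hidden_all <- unlist(lapply(cell_parts, `[[`, "hidden"))
  lik_all <- unlist(lapply(cell_parts, `[[`, "lik"))
  cell_id <- rep(seq_len(nrow(data)), vapply(cell_parts, function(p) length(p$lik), 0L))
  prior_axis <- if (kind == "constant_hidden") hidden_all else support_all
  mode_readout <- identical(readout, "mode")

  predict_cells <- function(mean, sd) {
    p <- lik_all * stats::dnorm(prior_axis, mean, sd)
    if (mode_readout) {
      vapply(split(seq_along(p), cell_id), function(idx) {
        hidden_all[idx][which.max(p[idx])]
      }, numeric(1))
    } else {
      as.numeric(rowsum(p * hidden_all, cell_id) / rowsum(p, cell_id))
    }
  }
  obs <- data$mean_estimate
  objective <- function(par) {
    pred <- predict_cells(par[1], par[2])
    if (any(!is.finite(pred))) return(1e12)  # prior misses every support point
    sum((pred - obs)^2)
  }
  starts <- expand.grid(mean = seq(1, 20, by = 1), sd = c(0.5, 1, 2, 4, 8))
  best <- ls_multistart(objective, starts, lower = c(1e-2, 0.1), upper = c(117, 50))
  structure(list(
    prior = prior_model(kind, best$par[1], best$par[2]),
    rss = best$value,
    converged = best$convergence == 0,
    n_points = nrow(data)
  ), class = "prior_fit")
}

#' @export
print.prior_fit <- function(x, ...) {
  cat(sprintf("<prior_fit> %s prior: mean = %.3f, sd = %.3f, RSS = %.4g (n = %d)%s\n",
              x$prior$kind, x$prior$mean, x$prior$sd, x$rss, x$n_points,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Compare two model fits by BIC and relative model weights
#'
#' For least-squares fits with Gaussian errors, BIC = n ln(RSS/n) + k ln(n)
#' with k = 2 free parameters per prior model. Relative weights are
#' w_i = exp(-Delta_i / 2) / sum_j exp(-Delta_j / 2) with
#' Delta_i = BIC_i - min(BIC).
#'
#' @param fit_a,fit_b `prior_fit` objects (or any lists with `rss`) fitted
#'   to the same data.
#' @param n_points number of fitted data points.
#' @param k free parameters per model (2: prior mean and sd).
#' @return an object of class `model_comparison`: list with `bic` (named
#'   vector), `weights`, `winner`.
#' @export
compare_models <- function(fit_a, fit_b, n_points, k = 2) {
  if (n_points < k + 1) stop("`n_points` must exceed the parameter count", call. = FALSE)
  rss <- c(a = fit_a$rss, b = fit_b$rss)
  if (any(rss <= 0)) {
    warning("zero RSS floored at 1e-12 for BIC")
    rss <- pmax(rss, 1e-12)
  }
  labels <- c(
    if (!is.null(fit_a$prior)) fit_a$prior$kind else "model_a",
    if (!is.null(fit_b$prior)) fit_b$prior$kind else "model_b"
  )
  bic <- n_points * log(rss / n_points) + k * log(n_points)
  names(bic) <- labels
  delta <- bic - min(bic)
  w <- exp(-delta / 2)
  w <- w / sum(w)
  structure(list(bic = bic, weights = w, winner = labels[which.min(bic)]),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("<model_comparison>\n")
  for (i in seq_along(x$bic)) {
    cat(sprintf("  %s: BIC = %.3f, weight = %.3f\n",
                names(x$bic)[i], x$bic[i], x$weights[i]))
  }
  cat("  winner:", x$winner, "\n")
  invisible(x)
}
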