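# Synthetic observers: generate trial-level responses for every task so the
# fitting stages can be exercised and validated without human data.

response_table <- function(trials, n_visible, delta_n, response_type, response, seed) {
  data.frame(
    experiment = trials$experiment,
    trial = trials$trial,
    condition = trials$condition,
    n_visible = n_visible,
    delta_n = delta_n,
    occluder = trials$occluder,
    response_type = response_type,
    response = response,
    seed = if (is.null(seed)) NA_integer_ else seed,
    stringsAsFactors = FALSE
  )
}

#' Simulate two-alternative forced-choice selections
#'
#' For each analyzed trial with a standard/comparison numerosity pair, draws
#' a Bernoulli choice with success probability given by the cumulative
#' Gaussian `psi()` evaluated at the numerosity difference
#' `delta_n = n_visible_std - n_visible_cmp`.
#'
#' @param trials a trial table from `enumerate_trials()` (experiment 1
#'   layout); only rows with `analyzed = TRUE` are simulated.
#' @param params list with `alpha`, `beta`, `gamma`, `lambda`.
#' @param rng_seed integer seed.
#' @return a response table with `response_type = "choice"` and binary
#'   `response` (1 = standard judged more numerous).
#' @export
simulate_selection <- function(trials, params, rng_seed = NULL) {
  tr <- trials[trials$analyzed & !is.na(trials$n_visible_cmp), , drop = FALSE]
  delta <- tr$n_visible_std - tr$n_visible_cmp
  p <- psi(delta, params$alpha, params$beta, gamma = params$gamma, lambda = params$lambda)
  resp <- with_seed(rng_seed, stats::rbinom(nrow(tr), 1L, p))
  response_table(tr, tr$n_visible_std, delta, "choice", resp, rng_seed)
}

#' Simulate high/low confidence responses
#'
#' Bernoulli high-confidence responses with probability given by
#' `confidence_curve()` at the numerosity difference.
#'
#' @inheritParams simulate_selection
#' @param params list with `mu`, `sigma`, `a`.
#' @return a response table with `response_type = "confidence"` and binary
#'   `response` (1 = high confidence).
#' @export
simulate_confidence <- function(trials, params, rng_seed = NULL) {
  tr <- trials[trials$analyzed & !is.na(trials$n_visible_cmp), , drop = FALSE]
  delta <- tr$n_visible_std - tr$n_visible_cmp
  p <- confidence_curve(delta, params$mu, params$sigma, params$a)
  resp <- with_seed(rng_seed, stats::rbinom(nrow(tr), 1L, p))
  response_table(tr, tr$n_visible_std, delta, "confidence", resp, rng_seed)
}

#' Simulate direct numerosity estimates from a noisy linear observer
#'
#' Estimates are `round(p1 * n_true + p2 + e)` with Gaussian noise `e`,
#' rounded half-up and clamped to the response menu [0, response_max]
#' (drop-down menus force integers).
#'
#' @param trials a trial table; `n_visible_std` is the true count.
#' @param estimator list with slope `p1`, intercept `p2` and noise `sd`.
#' @param rng_seed integer seed.
#' @param response_max top of the response menu.
#' @return a response table with `response_type = "estimate"`.
#' @export
simulate_linear_estimates <- function(trials, estimator, rng_seed = NULL,
                                      response_max = 40L) {
  if (estimator$sd < 0) stop("noise `sd` must be non-negative", call. = FALSE)
  tr <- trials[trials$analyzed & !is.na(trials$n_visible_std), , drop = FALSE]
  eps <- with_seed(rng_seed, stats::rnorm(nrow(tr), 0, estimator$sd))
  est <- clamp(round_half_up(estimator$p1 * tr$n_visible_std + estimator$p2 + eps),
               0, response_max)
  response_table(tr, tr$n_visible_std, NA_real_, "estimate", est, rng_seed)
}

#' Simulate hidden-count estimates from a Bayesian observer
#'
#' For each trial the observer reads out the posterior over the total count
#' (hypergeometric likelihood for the trial's occluder urn combined with the
#' prior) and reports the hidden count `n_total - n_v`. Optional Gaussian
#' response noise and integer rounding map the readout onto the response
#' menu; the default is the noiseless posterior mean so that model fits to
#' the simulated data are exact.
#'
#' @param trials a trial table; each row's urn is looked up first by its
#'   `occluder` label and then by its `condition` label, so urn lists may be
#'   keyed either way. Rows with no matching urn (e.g. the non-occluded
#'   condition) receive estimate 0.
#' @param urns named list of `urn_spec` objects.
#' @param prior a `prior_model`.
#' @param rng_seed integer seed (used only when `noise_sd > 0`).
#' @param noise_sd response noise standard deviation (default 0).
#' @param round_estimates round half-up and clamp to [0, response_max].
#' @param readout posterior readout, `"mean"` or `"mode"`.
#' @param response_max top of the response menu.
#' @return a response table with `response_type = "estimate"` (hidden count).
#' @export
simulate_bayesian_estimates <- function(trials, urns, prior, rng_seed = NULL,
                                        noise_sd = 0, round_estimates = TRUE,
                                        readout = "mean", response_max = 40L) {
  tr <- trials[trials$analyzed & !is.na(trials$n_visible_std), , drop = FALSE]
  urn_key <- ifelse(tr$occluder %in% names(urns), tr$occluder,
                    ifelse(tr$condition %in% names(urns), tr$condition, NA))
  est <- numeric(nrow(tr))
  for (key in unique(urn_key)) {
    idx <- which(if (is.na(key)) is.na(urn_key) else !is.na(urn_key) & urn_key == key)
    if (is.na(key)) {
      est[idx] <- 0
      next
    }
    nv_vals <- sort(unique(tr$n_visible_std[idx]))
    pred <- predict_hidden(nv_vals, urns[[key]], prior, readout)
    est[idx] <- pred[match(tr$n_visible_std[idx], nv_vals)]
  }
  if (noise_sd > 0) {
    est <- est + with_seed(rng_seed, stats::rnorm(length(est), 0, noise_sd))
  }
  if (round_estimates) est <- clamp(round_half_up(est), 0, response_max)
  response_table(tr, tr$n_visible_std, NA_real_, "estimate", est, rng_seed)
}

#' Per-level response proportions from a binary response table
#'
#' Aggregates a choice or confidence response table into the proportion of
#' positive responses per `delta_n` level, the input format of the curve
#' fitters.
#'
#' @param responses a response table with binary `response` and `delta_n`.
#' @return data.frame with `delta_n`, `prop`, `n_trials`.
#' @export
prop_by_level <- function(responses) {
  agg <- stats::aggregate(response ~ delta_n, data = responses, FUN = mean)
  cnt <- stats::aggregate(response ~ delta_n, data = responses, FUN = length)
  data.frame(delta_n = agg$delta_n, prop = agg$response, n_trials = cnt$response)
}
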