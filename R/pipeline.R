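# Descriptive-statistics layer and end-to-end orchestration.

#' Ordinary least-squares linear fit
#'
#' Fits `f(x) = p1 * x + p2` (slope and intercept) by ordinary least
#' squares, the summary model applied to all direct-estimation tasks.
#'
#' @param x,y numeric vectors of equal length, `n >= 2`, `x` not constant.
#' @return an object of class `linear_fit`: list with `p1` (slope), `p2`
#'   (intercept), `r_squared` (clamped at 0, with `r_squared_clamped` flag)
#'   and `n`.
#' @examples
#' fit_linear(1:5, 2 * (1:5) + 1)  # slope 2, intercept 1
#' @export
fit_linear <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L) {
    stop("`x` and `y` must have equal length >= 2", call. = FALSE)
  }
  if (stats::sd(x) == 0) stop("degenerate fit: `x` is constant", call. = FALSE)
  fit <- stats::lm(y ~ x)
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - rss / tss else 0
  structure(list(
    p1 = unname(stats::coef(fit)[2]),
    p2 = unname(stats::coef(fit)[1]),
    r_squared = max(r2, 0),
    r_squared_clamped = r2 < 0,
    n = length(x)
  ), class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("<linear_fit> slope = %.4f, intercept = %.4f, R^2 = %.4f (n = %d)\n",
              x$p1, x$p2, x$r_squared, x$n))
  invisible(x)
}

#' Coefficient of variation
#'
#' Ratio of the sample standard deviation (n - 1 denominator) over the mean;
#' the precision measure for direct numerosity estimates.
#'
#' @param values numeric vector, `n >= 2`, nonzero mean.
#' @return sd / mean.
#' @export
coefficient_of_variation <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values", call. = FALSE)
  m <- mean(values)
  if (abs(m) < .Machine$double.eps) stop("coefficient of variation undefined for zero mean",
                                         call. = FALSE)
  stats::sd(values) / m
}

#' Convert a maximum-piece-count response to an occluded-area proportion
#'
#' The area-estimation task asks for the maximum number of pieces that might
#' fit behind the occluder on a 0-117 slider (117 being the total cell
#' count); dividing by the cell count converts the response to a proportion
#' of occluded area.
#'
#' @param max_count slider response(s), between 0 and the board's cell count.
#' @param board a `board_spec` supplying the cell count (default 13 x 9).
#' @return proportion(s) in [0, 1].
#' @export
exp3_proportion <- function(max_count, board = make_board()) {
  total <- board$rows * board$cols
  if (any(max_count < 0 | max_count > total)) {
    stop(sprintf("`max_count` must lie in [0, %d]", total), call. = FALSE)
  }
  max_count / total
}

#' Subjectively expected hidden count
#'
#' Density extrapolation applied to perceived rather than true quantities:
#' given a perceived visible count and a perceived cover proportion `p`
#' (interpreted as hidden area over total area, S_h / (S_v + S_h)), the
#' expected hidden count is `est_visible * p / (1 - p)`.
#'
#' @param est_visible perceived visible count(s).
#' @param est_proportion perceived cover proportion(s), in [0, 1).
#' @return expected hidden count(s).
#' @examples
#' subjective_expectation(10, 0.5)  # 10
#' @export
subjective_expectation <- function(est_visible, est_proportion) {
  if (any(est_proportion < 0 | est_proportion >= 1)) {
    stop("`est_proportion` must lie in [0, 1)", call. = FALSE)
  }
  est_visible * est_proportion / (1 - est_proportion)
}

#' Per-condition summary of direct estimates
#'
#' Aggregates an estimate response table into per-condition, per-numerosity
#' means and standard deviations, the coefficient of variation over each
#' condition's estimates, and a linear fit of the mean estimate on the true
#' visible count.
#'
#' @param responses a response table with `response_type = "estimate"`.
#' @return list with `cells` (data.frame: condition, n_visible, mean, sd, n)
#'   and `by_condition` (data.frame: condition, cv, slope, intercept,
#'   r_squared).
#' @export
condition_summary <- function(responses) {
  est <- responses[responses$response_type == "estimate", , drop = FALSE]
  if (nrow(est) == 0L) stop("no estimate rows to summarize", call. = FALSE)
  cells <- do.call(rbind, lapply(split(est, list(est$condition, est$n_visible), drop = TRUE),
    function(d) data.frame(condition = d$condition[1], n_visible = d$n_visible[1],
                           mean = mean(d$response), sd = stats::sd(d$response),
                           n = nrow(d), stringsAsFactors = FALSE)))
  cells <- cells[order(cells$condition, cells$n_visible), ]
  rownames(cells) <- NULL
  by_condition <- do.call(rbind, lapply(split(cells, cells$condition), function(d) {
    lf <- if (nrow(d) >= 2L && stats::sd(d$n_visible) > 0) fit_linear(d$n_visible, d$mean)
          else list(p1 = NA_real_, p2 = NA_real_, r_squared = NA_real_)
    all_resp <- est$response[est$condition == d$condition[1]]
    cv <- if (abs(mean(all_resp)) > .Machine$double.eps && length(all_resp) >= 2L) {
      coefficient_of_variation(all_resp)
    } else NA_real_
    data.frame(condition = d$condition[1], cv = cv, slope = lf$p1,
               intercept = lf$p2, r_squared = lf$r_squared,
               stringsAsFactors = FALSE)
  }))
  rownames(by_condition) <- NULL
  list(cells = cells, by_condition = by_condition)
}

#' Run a full simulate-and-fit pipeline
#'
#' Orchestrates one experiment end to end: trial-design enumeration,
#' synthetic-observer simulation, curve or model fitting, condition
#' summaries, and (optionally) CSV/manifest output. Supported experiments:
#' 1 (selection + confidence tasks, psychometric and confidence fits per
#' condition) and 2 (Bayesian hidden-count estimates, both prior fits and
#' their BIC comparison).
#'
#' @param config list. For experiment 1: `experiment = 1`, `psychometric`
#'   (alpha, beta, gamma, lambda) and `confidence` (mu, sigma, a) generator
#'   parameters. For experiment 2: `experiment = 2`, `prior` (a
#'   `prior_model`), optional `urns` (default `exp2_urns("paper")`),
#'   optional `noise_sd`.
#' @param seed integer seed controlling every random draw.
#' @param out_dir optional directory; when given, writes `trials.csv`,
#'   `responses.csv`, `fits.csv`, `manifest.txt` and `report.txt`.
#' @return list with `trials`, `responses`, `fits`, `report` (character
#'   vector of headline numbers) and `seed`.
#' @export
run_pipeline <- function(config, seed = 1L, out_dir = NULL) {
  exp_id <- config$experiment
  if (is.null(exp_id)) stop("pipeline stage `config`: missing `experiment`", call. = FALSE)
  trials <- enumerate_trials(exp_id)
  report <- character(0)

  if (exp_id == 1) {
    sel <- simulate_selection(trials, config$psychometric, rng_seed = seed)
    conf <- simulate_confidence(trials, config$confidence, rng_seed = seed + 1L)
    responses <- rbind(sel, conf)
    fits <- do.call(rbind, lapply(unique(sel$condition), function(cond) {
      ps <- prop_by_level(sel[sel$condition == cond, ])
      pc <- prop_by_level(conf[conf$condition == cond, ])
      fs <- fit_psychometric(ps$delta_n, ps$prop, ps$n_trials)
      fc <- fit_confidence(pc$delta_n, pc$prop, pc$n_trials)
      rbind(
        data.frame(condition = cond, task = "selection", location = fs$pse,
                   spread = fs$beta, extra = fs$lambda, rss = fs$rss,
                   converged = fs$converged, stringsAsFactors = FALSE),
        data.frame(condition = cond, task = "confidence", location = fc$mu,
                   spread = fc$sigma, extra = fc$a, rss = fc$rss,
                   converged = fc$converged, stringsAsFactors = FALSE)
      )
    }))
    for (i in seq_len(nrow(fits))) {
      report <- c(report, sprintf("%s %s: location = %.3f, spread = %.3f, extra = %.3f",
                                  fits$condition[i], fits$task[i], fits$location[i],
                                  fits$spread[i], fits$extra[i]))
    }
  } else if (exp_id == 2) {
    urns <- if (!is.null(config$urns)) config$urns else exp2_urns("paper")
    noise_sd <- if (!is.null(config$noise_sd)) config$noise_sd else 0
    responses <- simulate_bayesian_estimates(
      trials, urns, config$prior, rng_seed = seed,
      noise_sd = noise_sd, round_estimates = noise_sd > 0
    )
    responses$urn_key <- ifelse(responses$occluder %in% names(urns), responses$occluder,
                                ifelse(responses$condition %in% names(urns),
                                       responses$condition, NA))
    occl <- responses[!is.na(responses$urn_key), ]
    cell_means <- do.call(rbind, lapply(
      split(occl, list(occl$urn_key, occl$n_visible), drop = TRUE),
      function(d) data.frame(n_v = d$n_visible[1], occluder = d$urn_key[1],
                             mean_estimate = mean(d$response), stringsAsFactors = FALSE)))
    fit_h <- fit_prior(cell_means, urns, "constant_hidden")
    fit_t <- fit_prior(cell_means, urns, "constant_total")
    cmp <- compare_models(fit_t, fit_h, n_points = nrow(cell_means))
    fits <- data.frame(
      kind = c(fit_t$prior$kind, fit_h$prior$kind),
      mean = c(fit_t$prior$mean, fit_h$prior$mean),
      sd = c(fit_t$prior$sd, fit_h$prior$sd),
      rss = c(fit_t$rss, fit_h$rss),
      bic = as.numeric(cmp$bic),
      weight = as.numeric(cmp$weights),
      stringsAsFactors = FALSE
    )
    report <- c(
      sprintf("constant_total prior: mean = %.3f, sd = %.3f, BIC = %.2f, weight = %.3f",
              fit_t$prior$mean, fit_t$prior$sd, cmp$bic[1], cmp$weights[1]),
      sprintf("constant_hidden prior: mean = %.3f, sd = %.3f, BIC = %.2f, weight = %.3f",
              fit_h$prior$mean, fit_h$prior$sd, cmp$bic[2], cmp$weights[2]),
      sprintf("winning model: %s", cmp$winner)
    )
  } else {
    stop(sprintf("pipeline stage `simulate`: experiment %s not supported by run_pipeline",
                 exp_id), call. = FALSE)
  }

  result <- list(trials = trials, responses = responses, fits = fits,
                 report = report, seed = seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(trials, file.path(out_dir, "trials.csv"), row.names = FALSE)
    utils::write.csv(responses, file.path(out_dir, "responses.csv"), row.names = FALSE)
    utils::write.csv(fits, file.path(out_dir, "fits.csv"), row.names = FALSE)
    writeLines(c(
      sprintf("experiment: %s", exp_id),
      sprintf("seed: %d", seed),
      sprintf("package: hidenum %s", as.character(utils::packageVersion("hidenum"))),
      sprintf("r_version: %s", R.version.string)
    ), file.path(out_dir, "manifest.txt"))
    writeLines(report, file.path(out_dir, "report.txt"))
  }
  result
}
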