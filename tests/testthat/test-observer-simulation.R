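test_that("simulated responses are seed-deterministic", {
  trials <- enumerate_trials(1)
  params <- list(alpha = -1.45, beta = 3, gamma = 0.02, lambda = 0.02)
  expect_identical(simulate_selection(trials, params, rng_seed = 5),
                   simulate_selection(trials, params, rng_seed = 5))
  expect_false(identical(simulate_selection(trials, params, rng_seed = 5)$response,
                         simulate_selection(trials, params, rng_seed = 6)$response))

  t2 <- enumerate_trials(2)
  est <- list(p1 = 0.81, p2 = 1.31, sd = 1.5)
  expect_identical(simulate_linear_estimates(t2, est, rng_seed = 9),
                   simulate_linear_estimates(t2, est, rng_seed = 9))
})

test_that("empirical choice and confidence rates converge to the generating curves", {
  # one trial row replicated many times per level; frequencies must match the
  # curve within 3 Monte-Carlo standard errors
  n_rep <- 10000L
  levels <- c(-4, 0, 2)
  trials <- data.frame(experiment = 1L, trial = seq_len(n_rep * length(levels)),
                       condition = "mixed",
                       n_visible_std = 10L,
                       n_visible_cmp = rep(10L - levels, each = n_rep),
                       proportion = NA_real_, occluder = "mesh_40_60",
                       scale = 1, rep = 1L, analyzed = TRUE,
                       stringsAsFactors = FALSE)
  params <- list(alpha = -1.45, beta = 3, gamma = 0.02, lambda = 0.02)
  sel <- simulate_selection(trials, params, rng_seed = 77)
  pl <- prop_by_level(sel)
  expected <- psi(pl$delta_n, params$alpha, params$beta, params$gamma, params$lambda)
  se <- sqrt(expected * (1 - expected) / n_rep)
  expect_true(all(abs(pl$prop - expected) <= 3 * se))

  cparams <- list(mu = -1.99, sigma = 4, a = 0.73)
  conf <- simulate_confidence(trials, cparams, rng_seed = 78)
  plc <- prop_by_level(conf)
  expectedc <- confidence_curve(plc$delta_n, cparams$mu, cparams$sigma, cparams$a)
  sec <- sqrt(expectedc * (1 - expectedc) / n_rep)
  expect_true(all(abs(plc$prop - expectedc) <= 3 * sec))
})

test_that("confidence generator hits its analytic limits", {
  tr <- enumerate_trials(1)
  tr <- tr[tr$analyzed & tr$n_visible_cmp == 10, ]  # delta_n = 0 rows
  # a = 1 and mu at the tested level: high confidence never occurs
  conf <- simulate_confidence(tr, list(mu = 0, sigma = 4, a = 1), rng_seed = 3)
  expect_true(all(conf$response == 0))
  # a = 0: always high confidence
  conf1 <- simulate_confidence(tr, list(mu = 0, sigma = 4, a = 0), rng_seed = 3)
  expect_true(all(conf1$response == 1))
})

test_that("linear estimation observer rounds, clamps and recovers its slope", {
  t2 <- enumerate_trials(2)
  # identity observer: estimates equal the true counts
  ident <- simulate_linear_estimates(t2, list(p1 = 1, p2 = 0, sd = 0), rng_seed = 1)
  expect_equal(ident$response, ident$n_visible)

  # estimates never leave the menu even under huge noise
  wild <- simulate_linear_estimates(t2, list(p1 = 1, p2 = 0, sd = 100), rng_seed = 2)
  expect_true(all(wild$response >= 0 & wild$response <= 40))

  # slope recovery through the condition-mean linear fit
  noisy <- simulate_linear_estimates(t2, list(p1 = 0.81, p2 = 1.31, sd = 1.5),
                                     rng_seed = 11)
  summ <- condition_summary(noisy)
  slopes <- summ$by_condition$slope
  expect_true(all(abs(slopes - 0.81) < 0.15))
})

test_that("Bayesian estimation observers follow their priors", {
  t2 <- enumerate_trials(2)
  urns <- exp2_urns("paper")

  # near-point-mass constant-hidden prior: everyone reports ~2 hidden
  ph <- prior_model("constant_hidden", mean = 2, sd = 1e-4)
  resp <- simulate_bayesian_estimates(t2, urns, ph, round_estimates = FALSE)
  occl <- resp[resp$condition != "non_occluded", ]
  expect_equal(occl$response, rep(2, nrow(occl)), tolerance = 1e-6)
  # unoccluded rows have no urn and produce zero hidden estimates
  expect_true(all(resp$response[resp$condition == "non_occluded"] == 0))

  # constant-total prior (tight, centred above the tested counts): hidden
  # estimates decrease with the visible count; with a broad prior centred
  # below the range, support truncation at n_v flattens this trend
  pt <- prior_model("constant_total", mean = 20, sd = 1)
  respt <- simulate_bayesian_estimates(t2, urns, pt, round_estimates = FALSE)
  small <- respt[respt$condition == "small_occluder", ]
  means <- tapply(small$response, small$n_visible, mean)
  expect_true(all(diff(means[order(as.numeric(names(means)))]) < 0))

  # rounding maps onto the integer response menu
  respr <- simulate_bayesian_estimates(t2, urns, pt, rng_seed = 4, noise_sd = 1)
  expect_true(all(respr$response == round(respr$response)))
  expect_true(all(respr$response >= 0 & respr$response <= 40))
})
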