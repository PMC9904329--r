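test_that("hypergeometric likelihood matches brute-force urn enumeration", {
  # exhaustive check over small urns, against both the combinatorial
  # enumeration oracle and the reference distribution in stats
  for (urn_dims in list(c(3, 2), c(4, 4), c(7, 5), c(2, 9))) {
    urn <- urn_spec(urn_dims[1], urn_dims[2])
    for (n_total in 0:urn$N_total) {
      pmf_enum <- enum_visible_pmf(urn$N_v, urn$N_h, n_total)
      pmf_pkg <- hypergeom_likelihood(0:n_total, n_total, urn)
      expect_equal(unname(pmf_pkg), as.vector(pmf_enum), tolerance = 1e-12)
      expect_equal(sum(pmf_pkg), 1, tolerance = 1e-12)  # normalization
      expect_equal(pmf_pkg, stats::dhyper(0:n_total, urn$N_v, urn$N_h, n_total),
                   tolerance = 1e-12)
    }
  }
})

test_that("hypergeometric likelihood handles edge cases and bad input", {
  urn <- urn_spec(3, 2)
  expect_equal(hypergeom_likelihood(0, 0, urn), 1)   # empty draw
  expect_equal(hypergeom_likelihood(1, 2, urn), 0.6) # 3*2 / C(5,2)=10
  all_vis <- urn_spec(5, 0)
  expect_equal(hypergeom_likelihood(3, 3, all_vis), 1)  # no hidden cells
  expect_equal(hypergeom_likelihood(4, 2, urn), 0)      # lenient out-of-support
  expect_error(hypergeom_likelihood(4, 2, urn, lenient = FALSE), "support")
  expect_error(hypergeom_likelihood(-1, 2, urn), "non-negative")
})

test_that("posterior over the total is normalized with correct support", {
  urn <- urn_spec(3, 2)
  flat <- prior_model("constant_total", mean = 2.5, sd = 100)  # near-flat
  post <- posterior_total(1, urn, flat)
  expect_equal(sum(post$prob), 1)
  expect_true(all(post$prob >= 0))
  expect_true(all(post$support >= 1 & post$support <= urn$N_total))

  # flat-prior posterior is proportional to the likelihood alone
  lik <- hypergeom_likelihood(1, post$support, urn)
  prior_wts <- dnorm(post$support, 2.5, 100)
  expect_equal(post$prob, lik * prior_wts / sum(lik * prior_wts), tolerance = 1e-12)

  # no hidden cells: posterior collapses onto n_v
  post0 <- posterior_total(4, urn_spec(6, 0), flat)
  expect_equal(post0$support, 4)
  expect_equal(post0$prob, 1)

  # a near-point-mass prior dominates when the likelihood allows it
  point <- prior_model("constant_total", mean = 3, sd = 1e-4)
  postp <- posterior_total(1, urn, point)
  expect_equal(postp$support[which.max(postp$prob)], 3)
  expect_gt(max(postp$prob), 1 - 1e-9)

  expect_error(posterior_total(10, urn, flat), "exceeds")
  empty <- prior_model("constant_total", mean = -50, sd = 1e-6)
  expect_error(posterior_total(1, urn, empty), "empty|overlap")
})

test_that("predicted hidden counts follow the prior structure", {
  urns <- exp2_urns("paper")
  # constant-hidden point mass: prediction pins at the prior mean everywhere
  ph <- prior_model("constant_hidden", mean = 2, sd = 1e-4)
  preds <- predict_hidden(6:14, urns$small_occluder, ph)
  expect_equal(preds, rep(2, 9), tolerance = 1e-6)

  # constant-total point mass at T: prediction is T - n_v, decreasing
  pt <- prior_model("constant_total", mean = 20, sd = 1e-4)
  predt <- predict_hidden(6:14, urns$small_occluder, pt)
  expect_equal(predt, 20 - (6:14), tolerance = 1e-6)

  # small-urn posterior mean against a hand-enumerable oracle
  urn <- urn_spec(3, 2)
  flat <- prior_model("constant_total", mean = 0, sd = 1e6)
  lik <- hypergeom_likelihood(1, 1:5, urn)
  expect_equal(predict_hidden(1, urn, flat),
               sum((1:5 - 1) * lik) / sum(lik), tolerance = 1e-6)

  # mode readout returns an integer from the support
  expect_equal(predict_hidden(8, urns$small_occluder, ph, readout = "mode"), 2)
})

test_that("prior parameters are recovered from noiseless design-cell means", {
  urns <- exp2_urns("paper")

  gen_h <- prior_model("constant_hidden", 2.48, 1.45)
  cells_h <- exp2_cell_means(gen_h, urns)
  fit_h <- fit_prior(cells_h, urns, "constant_hidden")
  expect_lt(fit_h$rss, 1e-8)
  expect_equal(fit_h$prior$mean, 2.48, tolerance = 0.2 / 2.48)
  expect_equal(fit_h$prior$sd, 1.45, tolerance = 0.2)

  gen_t <- prior_model("constant_total", 7.21, 4.07)
  cells_t <- exp2_cell_means(gen_t, urns)
  fit_t <- fit_prior(cells_t, urns, "constant_total")
  expect_lt(fit_t$rss, 1e-8)
  expect_equal(fit_t$prior$mean, 7.21, tolerance = 0.2 / 7.21)
  expect_equal(fit_t$prior$sd, 4.07, tolerance = 0.2)

  expect_error(fit_prior(cells_h[1:2, ], urns, "constant_hidden"), "3 design cells")
})

test_that("model comparison identifies the generating prior under noise", {
  urns <- exp2_urns("paper")
  gen_h <- prior_model("constant_hidden", 2.48, 1.45)
  gen_t <- prior_model("constant_total", 7.21, 4.07)
  hits <- 0L
  n_rep <- 10L
  for (i in seq_len(n_rep)) {
    for (gen in list(gen_h, gen_t)) {
      cells <- exp2_cell_means(gen, urns)
      set.seed(7000 + i)
      cells$mean_estimate <- cells$mean_estimate + rnorm(nrow(cells), 0, 0.5)
      fh <- fit_prior(cells, urns, "constant_hidden")
      ft <- fit_prior(cells, urns, "constant_total")
      cmp <- compare_models(ft, fh, n_points = nrow(cells))
      if (cmp$winner == gen$kind) hits <- hits + 1L
    }
  }
  expect_gte(hits / (2 * n_rep), 0.9)
})

test_that("BIC and relative weights follow the penalized-RSS formula", {
  fa <- list(rss = 1.0, prior = prior_model("constant_total", 5, 1))
  fb <- list(rss = 2.0, prior = prior_model("constant_hidden", 2, 1))
  cmp <- compare_models(fa, fb, n_points = 18)
  expect_equal(unname(diff(cmp$bic)), 18 * log(2), tolerance = 1e-12)
  w_b <- exp(-18 * log(2) / 2) / (1 + exp(-18 * log(2) / 2))
  expect_equal(unname(cmp$weights[2]), w_b, tolerance = 1e-12)
  expect_equal(sum(cmp$weights), 1)
  expect_equal(cmp$winner, "constant_total")

  # identical RSS: even split
  cmp_eq <- compare_models(fa, list(rss = 1.0, prior = fb$prior), n_points = 18)
  expect_equal(unname(cmp_eq$weights), c(0.5, 0.5))

  expect_warning(compare_models(list(rss = 0, prior = fa$prior), fb, 18), "floored")
  expect_error(compare_models(fa, fb, n_points = 2), "exceed")
})
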