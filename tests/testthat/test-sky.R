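test_that("Brownian noise is normalized, reproducible and 1/f^2 in spectrum", {
  f <- brownian_noise(256, rng_seed = 7)
  expect_equal(min(f), 0)
  expect_equal(max(f), 1)
  expect_identical(brownian_noise(256, rng_seed = 7), f)
  expect_false(identical(brownian_noise(256, rng_seed = 8), f))

  # radially averaged log-log periodogram regression (independent of the
  # synthesis path, which shapes amplitudes before the inverse transform)
  n <- 256
  ps <- Mod(stats::fft(f - mean(f)))^2
  k <- seq_len(n) - 1
  k <- ifelse(k > n %/% 2, k - n, k) / n
  fr <- sqrt(outer(k^2, k^2, "+"))
  sel <- fr > 0.01 & fr < 0.4
  slope <- unname(coef(stats::lm(log(ps[sel]) ~ log(fr[sel])))[2])
  expect_lt(abs(slope + 2), 0.3)

  expect_error(brownian_noise(1), "size")
})

test_that("cloud weight subtraction clamps at zero", {
  noise <- matrix(c(0, 0.3, 0.6, 0.9), 2, 2)
  w <- make_cloud_weight(noise, 0.6)
  expect_equal(as.vector(w), c(0, 0, 0, 0.3))
  expect_equal(make_cloud_weight(noise, 0), noise)  # offset 0 is the identity
  expect_error(make_cloud_weight(noise - 5), "0, 1")
})

test_that("cover calibration hits every target on the menu within 0.005", {
  noise <- brownian_noise(500, rng_seed = 21)
  targets <- seq(0.30, 0.70, by = 0.02)
  achieved <- vapply(targets, function(tgt) calibrate_cover(noise, tgt)$achieved,
                     numeric(1))
  expect_true(all(abs(achieved - targets) <= 0.005))

  # cover proportion is monotone non-increasing in the offset
  offsets <- seq(0, 0.9, by = 0.1)
  covers <- vapply(offsets, function(o) mean(make_cloud_weight(noise, o) > 0.05),
                   numeric(1))
  expect_true(all(diff(covers) <= 0))

  expect_error(calibrate_cover(noise, 1.5), "target")
})

test_that("stars are balanced, visible, and absent when none requested", {
  noise <- brownian_noise(300, rng_seed = 5)
  cal <- calibrate_cover(noise, 0.5)
  wc <- make_cloud_weight(noise, cal$offset)

  st <- make_star_layer(10, wc, rng_seed = 11)
  expect_equal(sort(as.vector(table(st$star_positions$class))), c(5, 5))
  # visibility guarantee: brute-force scan of every star footprint
  for (i in seq_len(nrow(st$star_positions))) {
    sz <- if (st$star_positions$class[i] == "small") 2 else 3
    ys <- st$star_positions$y[i] + 0:(sz - 1)
    xs <- st$star_positions$x[i] + 0:(sz - 1)
    expect_true(all(wc[ys, xs] <= 0.05))
  }

  st9 <- make_star_layer(9, wc, rng_seed = 12)
  expect_equal(sort(as.vector(table(st9$star_positions$class))), c(4, 5))

  st0 <- make_star_layer(0, wc, rng_seed = 13)
  expect_equal(nrow(st0$star_positions), 0)
  expect_true(all(st0$w_star == 0))

  expect_true(all(st$w_star >= 0 & st$w_star <= 1))
})

test_that("compositing respects the weighted-average limits and convexity", {
  # scalar checks of the combination rule
  expect_equal(compose_sky(100, 0, w_cloud = 0.5, w_star = 0), 177.5)
  expect_equal(compose_sky(100, 200, w_cloud = 1, w_star = 0.3), 255)  # all cloud
  expect_equal(compose_sky(100, 200, w_cloud = 0, w_star = 0), 100)   # plain sky

  scene <- make_sky_scene(8, cover = 0.4, rng_seed = 31, size = 150)
  expect_equal(dim(scene$composite), c(150, 150, 3))
  expect_equal(scene$cover_proportion, 0.4, tolerance = 0.005 / 0.4)
  expect_equal(sort(as.vector(table(scene$star_positions$class))), c(4, 4))

  # full cloud weight reproduces the cloud layer everywhere
  all_cloud <- compose_sky(scene$I_sky, scene$I_star,
                           w_cloud = matrix(1, 150, 150), w_star = scene$w_star)
  expect_true(all(all_cloud == 255))
  # zero weights reproduce the background sky
  plain <- compose_sky(scene$I_sky, scene$I_star,
                       w_cloud = matrix(0, 150, 150), w_star = matrix(0, 150, 150))
  expect_equal(plain, scene$I_sky)

  # convexity: each composite pixel lies within the per-channel extremes of
  # the three source layers
  for (ch in 1:3) {
    lo <- pmin(scene$I_sky[, , ch], scene$I_star[, , ch], 255)
    hi <- pmax(scene$I_sky[, , ch], scene$I_star[, , ch], 255)
    expect_true(all(scene$composite[, , ch] >= lo - 1e-9))
    expect_true(all(scene$composite[, , ch] <= hi + 1e-9))
  }

  expect_error(compose_sky(scene$I_sky, scene$I_star,
                           w_cloud = matrix(0.5, 10, 10), w_star = matrix(0, 10, 10)),
               "shape")
  expect_error(compose_sky(100, 0, w_cloud = 1.2, w_star = 0), "0, 1")
})

test_that("scene determinism and PNG round trip", {
  a <- make_sky_scene(6, 0.35, rng_seed = 2, size = 100)
  b <- make_sky_scene(6, 0.35, rng_seed = 2, size = 100)
  expect_identical(a$composite, b$composite)
  expect_identical(a$star_positions, b$star_positions)

  path <- tempfile(fileext = ".png")
  write_scene_png(a, path)
  img <- png::readPNG(path) * 255
  expect_equal(dim(img), c(100, 100, 3))
  expect_equal(max(abs(img - a$composite)), 0, tolerance = 0.51)  # 8-bit quantization
  unlink(path)
})
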