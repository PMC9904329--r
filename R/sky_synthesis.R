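# Night-sky stimulus synthesis: Brownian-noise cloud weights, Gaussian-
# smoothed star weights, and the weighted composite
#   I = (1 - w_cloud) * ((1 - w_star) * I_sky + w_star * I_star) + w_cloud * I_cloud.

#' Brownian (1/f^2) noise field
#'
#' Synthesizes a square random field whose power spectral density falls as
#' 1/f^2 (Brownian noise) by spectral shaping: Gaussian white noise is
#' Fourier transformed, each coefficient is scaled by 1/f (so power scales
#' as 1/f^2), the DC term is zeroed, and the real part of the inverse
#' transform is min-max normalized to [0, 1].
#'
#' @param size field edge in pixels (>= 2).
#' @param rng_seed integer seed for reproducibility.
#' @return a `size` x `size` matrix with values in [0, 1].
#' @examples
#' f <- brownian_noise(64, rng_seed = 1)
#' range(f)  # 0 and 1
#' @export
brownian_noise <- function(size, rng_seed = NULL) {
  if (!is.numeric(size) || size < 2 || size != round(size)) {
    stop("`size` must be an integer >= 2", call. = FALSE)
  }
  size <- as.integer(size)
  white <- with_seed(rng_seed, matrix(stats::rnorm(size * size), size, size))
  k <- seq_len(size) - 1L
  k <- ifelse(k > size %/% 2, k - size, k) / size  # two-sided frequency axis
  f <- sqrt(outer(k^2, k^2, "+"))
  amp <- ifelse(f > 0, 1 / f, 0)  # amplitude 1/f => power 1/f^2; DC zeroed
  shaped <- stats::fft(stats::fft(white) * amp, inverse = TRUE)
  field <- Re(shaped)
  rng <- range(field)
  (field - rng[1]) / (rng[2] - rng[1])
}

#' Cloud weight field from a noise map
#'
#' Shifts a normalized noise field downward by `offset` and clamps negative
#' values at zero, leaving cloud weight only where the noise exceeds the
#' offset. The default offset of 0.6 reproduces the standard cloud texture;
#' `calibrate_cover()` finds the offset for a requested cover proportion.
#'
#' @param noise matrix with values in [0, 1].
#' @param offset subtraction constant.
#' @return matrix `pmax(noise - offset, 0)`.
#' @export
make_cloud_weight <- function(noise, offset = 0.6) {
  if (any(noise < -1e-12) || any(noise > 1 + 1e-12)) {
    stop("`noise` must lie in [0, 1]", call. = FALSE)
  }
  pmax(noise - offset, 0)
}

#' Calibrate the cloud offset to a target cover proportion
#'
#' A pixel counts as cloud-covered when its cloud weight exceeds `tau`. The
#' cover proportion is monotone non-increasing in the offset, so the offset
#' achieving a target cover is found by inverting the empirical distribution
#' of the noise field (equivalent to a monotone search, but exact).
#'
#' @param noise normalized noise field in [0, 1].
#' @param target requested covered fraction, strictly between 0 and 1.
#' @param tau cover/visibility threshold on the cloud weight.
#' @return list with `offset` and `achieved` (pixel fraction with weight > tau).
#' @export
calibrate_cover <- function(noise, target, tau = 0.05) {
  if (!(is.numeric(target) && length(target) == 1L && target > 0 && target < 1)) {
    stop("`target` must be in (0, 1)", call. = FALSE)
  }
  n <- length(noise)
  s <- sort(as.vector(noise))
  k <- round_half_up(target * n)  # pixels that should exceed offset + tau
  if (k < 1 || k >= n) stop("calibration error: target cover unattainable", call. = FALSE)
  thresh <- s[n - k]  # exactly k sorted values are strictly above (no ties in continuous noise)
  offset <- thresh - tau
  achieved <- mean(noise - offset > tau)
  if (abs(achieved - target) > 0.005) {
    stop(sprintf("calibration error: achieved cover %.4f vs target %.4f", achieved, target),
         call. = FALSE)
  }
  list(offset = offset, achieved = achieved)
}

# Separable Gaussian smoothing with zero padding; sigma in pixels.
gaussian_smooth <- function(mat, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  kern <- stats::dnorm(-r:r, sd = sigma)
  kern <- kern / sum(kern)
  smooth1 <- function(m) { # along rows (dimension 1)
    out <- matrix(0, nrow(m), ncol(m))
    for (j in seq_along(kern)) {
      off <- j - r - 1L
      src <- seq_len(nrow(m)) + off
      keep <- src >= 1L & src <= nrow(m)
      out[keep, ] <- out[keep, ] + kern[j] * m[src[keep], ]
    }
    out
  }
  t(smooth1(t(smooth1(mat))))
}

#' Place stars and build the star layer
#'
#' Places `n_visible` stars at uncovered locations (cloud weight at or below
#' `tau` over the whole star footprint), balancing the two star classes:
#' small stars are 2x2 pixels at luminance 213 (RGB 220, 220, 160), large
#' stars 3x3 pixels at luminance 171 (RGB 176, 176, 128). The star weight
#' field is built by stamping each star's footprint and smoothing with a
#' Gaussian kernel of variance 0.9 (small) or 1.2 (large) pixels^2, then
#' clipping to [0, 1].
#'
#' @param n_visible number of stars to place.
#' @param w_cloud cloud weight field.
#' @param rng_seed integer seed.
#' @param tau visibility threshold on the cloud weight.
#' @return list with `I_star` (H x W x 3 array, 0-255), `w_star` (matrix in
#'   [0, 1]) and `star_positions` (data.frame x, y, class; x/y are the
#'   top-left pixel of the star footprint).
#' @export
make_star_layer <- function(n_visible, w_cloud, rng_seed = NULL, tau = 0.05) {
  stopifnot_scalar_count(n_visible, "n_visible")
  h <- nrow(w_cloud); w <- ncol(w_cloud)
  star_px <- c(small = 2L, large = 3L)
  star_rgb <- list(small = c(220, 220, 160), large = c(176, 176, 128))
  star_var <- c(small = 0.9, large = 1.2)

  n_per <- c(n_visible %/% 2L, n_visible %/% 2L)
  if (n_visible %% 2L == 1L) {
    extra <- with_seed(if (is.null(rng_seed)) NULL else rng_seed + 2L, sample(2L, 1L))
    n_per[extra] <- n_per[extra] + 1L
  }
  names(n_per) <- c("small", "large")

  i_star <- array(0, dim = c(h, w, 3))
  stamp <- list(small = matrix(FALSE, h, w), large = matrix(FALSE, h, w))
  occupied <- matrix(FALSE, h, w)
  positions <- NULL
  with_seed(rng_seed, {
    for (cls in c("small", "large")) {
      sz <- star_px[[cls]]
      # top-left positions whose whole footprint is uncovered and in bounds
      ok <- matrix(FALSE, h, w)
      ok[seq_len(h - sz + 1L), seq_len(w - sz + 1L)] <- TRUE
      clear <- w_cloud <= tau
      for (dy in 0:(sz - 1L)) for (dx in 0:(sz - 1L)) {
        shifted <- matrix(FALSE, h, w)
        shifted[seq_len(h - dy), seq_len(w - dx)] <- clear[(1L + dy):h, (1L + dx):w]
        ok <- ok & shifted
      }
      cand <- which(ok)
      for (i in seq_len(n_per[[cls]])) {
        free <- cand[!occupied[cand]]
        if (length(free) == 0L) {
          stop("placement error: not enough uncovered sky for the requested stars",
               call. = FALSE)
        }
        pos <- free[sample.int(length(free), 1L)]
        y <- (pos - 1L) %% h + 1L
        x <- (pos - 1L) %/% h + 1L
        ys <- y:(y + sz - 1L); xs <- x:(x + sz - 1L)
        stamp[[cls]][ys, xs] <- TRUE
        # block a margin around the star so footprints never overlap
        my <- max(1L, y - 3L):min(h, y + sz + 2L)
        mx <- max(1L, x - 3L):min(w, x + sz + 2L)
        occupied[my, mx] <- TRUE
        for (ch in 1:3) i_star[ys, xs, ch] <- star_rgb[[cls]][ch]
        positions <- rbind(positions,
                           data.frame(x = x, y = y, class = cls, stringsAsFactors = FALSE))
      }
    }
  })
  w_star <- matrix(0, h, w)
  for (cls in c("small", "large")) {
    if (any(stamp[[cls]])) {
      w_star <- w_star + gaussian_smooth(stamp[[cls]] * 1.0, sqrt(star_var[[cls]]))
    }
  }
  w_star <- clamp(w_star, 0, 1)
  if (is.null(positions)) positions <- data.frame(x = integer(0), y = integer(0),
                                                  class = character(0))
  list(I_star = i_star, w_star = w_star, star_positions = positions)
}

#' Background sky gradient
#'
#' Linear gradient from light blue (49, 87, 133) at the upper-left corner to
#' dark blue (10, 25, 44) at the lower-right corner.
#'
#' @param size image edge in pixels.
#' @return `size` x `size` x 3 array, values 0-255.
#' @export
make_sky_background <- function(size = 500L) {
  from <- c(49, 87, 133); to <- c(10, 25, 44)
  xy <- outer(seq_len(size) - 1L, seq_len(size) - 1L, "+")
  t01 <- xy / max(xy)
  out <- array(0, dim = c(size, size, 3))
  for (ch in 1:3) out[, , ch] <- from[ch] + t01 * (to[ch] - from[ch])
  out
}

#' Composite the night-sky image
#'
#' Per pixel and channel the composite is
#' `(1 - w_cloud) * ((1 - w_star) * I_sky + w_star * I_star) + w_cloud * I_cloud`,
#' clipped to [0, 255]. With full cloud weight the composite equals the cloud
#' layer; with zero cloud and star weight it equals the background sky.
#'
#' @param i_sky background image (H x W x 3 array or scalar).
#' @param i_star star layer (same shape convention).
#' @param w_cloud,w_star weight fields in [0, 1] (H x W matrices or scalars).
#' @param i_cloud cloud layer value, default a constant 255 (white).
#' @return composited H x W x 3 array (or scalar arithmetic result when all
#'   inputs are scalars).
#' @export
compose_sky <- function(i_sky, i_star, w_cloud, w_star, i_cloud = 255) {
  if (any(w_cloud < 0 | w_cloud > 1) || any(w_star < 0 | w_star > 1)) {
    stop("weights must lie in [0, 1]", call. = FALSE)
  }
  if (is.array(i_sky) && length(dim(i_sky)) == 3L) {
    dm <- dim(i_sky)
    if (is.matrix(w_cloud) && !all(dim(w_cloud) == dm[1:2])) {
      stop("shape mismatch between weights and images", call. = FALSE)
    }
    out <- array(0, dim = dm)
    for (ch in seq_len(dm[3])) {
      sky <- i_sky[, , ch]
      star <- if (is.array(i_star)) i_star[, , ch] else i_star
      cloud <- if (is.array(i_cloud)) i_cloud[, , ch] else i_cloud
      out[, , ch] <- (1 - w_cloud) * ((1 - w_star) * sky + w_star * star) + w_cloud * cloud
    }
    clamp(out, 0, 255)
  } else {
    clamp((1 - w_cloud) * ((1 - w_star) * i_sky + w_star * i_star) + w_cloud * i_cloud,
          0, 255)
  }
}

#' Generate a complete night-sky scene
#'
#' Runs the full stimulus chain: Brownian noise, offset calibration to the
#' requested cloud cover, star placement on uncovered sky, and the weighted
#' composite.
#'
#' @param n_visible number of visible stars.
#' @param cover target cloud-cover proportion (the published menu spans
#'   0.30 to 0.70).
#' @param rng_seed integer seed.
#' @param size image edge in pixels.
#' @param tau cover/visibility threshold.
#' @return an object of class `sky_scene`: list with `composite`, `I_sky`,
#'   `I_star`, `w_cloud`, `w_star`, `star_positions`, `cover_proportion`,
#'   `offset` and `seed`.
#' @export
make_sky_scene <- function(n_visible, cover, rng_seed = NULL, size = 500L, tau = 0.05) {
  noise <- brownian_noise(size, rng_seed)
  cal <- calibrate_cover(noise, cover, tau)
  w_cloud <- make_cloud_weight(noise, cal$offset)
  stars <- make_star_layer(n_visible, w_cloud,
                           rng_seed = if (is.null(rng_seed)) NULL else rng_seed + 1L,
                           tau = tau)
  i_sky <- make_sky_background(size)
  composite <- compose_sky(i_sky, stars$I_star, w_cloud, stars$w_star)
  structure(list(
    composite = composite, I_sky = i_sky, I_star = stars$I_star,
    w_cloud = w_cloud, w_star = stars$w_star,
    star_positions = stars$star_positions,
    cover_proportion = cal$achieved, offset = cal$offset, seed = rng_seed
  ), class = "sky_scene")
}

#' Write a scene (or any 0-255 RGB array) to a PNG file
#'
#' @param image H x W x 3 array with values in 0-255, or a `sky_scene`.
#' @param path output file path.
#' @export
write_scene_png <- function(image, path) {
  if (inherits(image, "sky_scene")) image <- image$composite
  png::writePNG(image / 255, path)
}
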