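# Shared fixtures and independent oracles for the test suite.

# A centred uniform-coat two-channel vesicle on a square image.
make_uniform_vesicle <- function(radius = 20, sigma = 2, shape = c(64L, 64L),
                                 noise_sd = 0, seed = 1L,
                                 center = c((shape[2] - 1) / 2,
                                            (shape[1] - 1) / 2)) {
  spec <- vesicle_spec(center_xy = center,
                       peak_radius_px = c(radius, radius),
                       ring_sigma_px = sigma,
                       angular = list(angular_uniform()),
                       noise_sd = noise_sd)
  render_vesicle_image(spec, shape, seed = seed)
}

default_band <- function(truth, pad = 7) {
  annulus_band(truth$center_xy,
               max(0, min(truth$true_peak_radius_px) - pad),
               max(truth$true_peak_radius_px) + pad)
}

# Exhaustive per-pixel sector oracle: plain double loop over pixels,
# membership by centre distance in [r_in, r_out), sector by atan2 angle.
brute_force_sectors <- function(band, n_sectors, image_shape,
                                angle_origin_deg = 0) {
  h <- image_shape[1]; w <- image_shape[2]
  out <- matrix(NA_integer_, h, w)
  width <- 360 / n_sectors
  for (yy in 0:(h - 1)) {
    for (xx in 0:(w - 1)) {
      dx <- xx - band$center_xy[1]
      dy <- yy - band$center_xy[2]
      r <- sqrt(dx * dx + dy * dy)
      if (r >= band$r_inner_px && r < band$r_outer_px) {
        ang <- (atan2(-dy, dx) * 180 / pi) %% 360
        k <- floor(((ang - angle_origin_deg) %% 360) / width)
        if (k >= n_sectors) k <- 0
        out[yy + 1, xx + 1] <- as.integer(k)
      }
    }
  }
  out
}

# Random annulus band guaranteed to fit a square image.
random_band <- function(shape, rng_seed) {
  set.seed(rng_seed)
  h <- shape[1]; w <- shape[2]
  cx <- runif(1, w * 0.3, w * 0.7)
  cy <- runif(1, h * 0.3, h * 0.7)
  rmax_fit <- min(cx, cy, w - 1 - cx, h - 1 - cy) - 0.6
  r_out <- runif(1, rmax_fit * 0.5, rmax_fit)
  r_in <- runif(1, 0, r_out * 0.8)
  annulus_band(c(cx, cy), r_in, r_out)
}
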