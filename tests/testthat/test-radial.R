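test_that("sector masks partition the annulus with 15-degree sectors at n=24", {
  band <- annulus_band(c(31.5, 31.5), 10, 25)
  sectors <- build_sector_masks(band, 24, c(64L, 64L))
  pol <- vesicoat:::pixel_polar(band$center_xy, c(64L, 64L))
  annulus <- pol$r >= 10 & pol$r < 25
  # membership: sector index defined exactly on annulus pixels, NA elsewhere
  expect_identical(!is.na(sectors), annulus)
  # each pixel's sector matches its centre angle within a 15-degree bin
  idx <- which(annulus)
  expect_true(all(sectors[idx] == floor(pol$angle_deg[idx] / 15)))
  expect_setequal(unique(sectors[idx]), 0:23)
})

test_that("sector masks equal the exhaustive per-pixel oracle", {
  shape <- c(64L, 64L)
  for (n_sectors in c(12L, 24L)) {
    for (s in 1:6) {
      band <- random_band(shape, rng_seed = 1000 * n_sectors + s)
      got <- build_sector_masks(band, n_sectors, shape)
      want <- brute_force_sectors(band, n_sectors, shape)
      expect_identical(got, want)
    }
  }
})

test_that("bands outside the image raise a geometry error naming the clip", {
  band <- annulus_band(c(10, 31.5), 5, 20)
  expect_error(build_sector_masks(band, 24, c(64L, 64L)), "left")
})

test_that("sector signal is conserved and homogeneous images scale by count", {
  band <- annulus_band(c(30.2, 33.7), 8, 22)
  # uniform image: each sector's signal is v * pixel_count
  v <- 0.37
  img <- matrix(v, 64, 64)
  prof <- sector_profile(img, band, 24)
  expect_equal(prof$signal[, 1], v * prof$pixel_count, tolerance = 1e-12)

  # conservation for random images, exactly
  pol <- vesicoat:::pixel_polar(band$center_xy, c(64L, 64L))
  mask <- pol$r >= 8 & pol$r < 22
  for (s in 1:10) {
    set.seed(s)
    img <- matrix(runif(64 * 64), 64, 64)
    prof <- sector_profile(img, band, 24)
    expect_identical(sum(prof$signal[, 1]), sum(img[mask]))
    expect_identical(sum(prof$pixel_count), sum(mask))
  }
})

test_that("focal vesicles put their maximum in the ground-truth sector", {
  for (ang in c(7, 100, 222, 340)) {
    spec <- vesicle_spec(peak_radius_px = c(20, 20),
                         angular = list(angular_focal(ang, 25)))
    ves <- render_vesicle_image(spec, c(64L, 64L), seed = 1)
    prof <- sector_profile(ves$stack, default_band(ves$truth), 24)
    expect_identical(which.max(prof$signal[, 1]),
                     which.max(ves$truth$sector_fractions[[1]]))
  }
})

test_that("uniform rings give flat sector sums in the fine-sampling limit", {
  # wedge discretization error scales like 1/R; at R = 300 px the sums are
  # flat to better than 1%
  R <- 300
  W <- 636L
  ctr <- c((W - 1) / 2 + 0.3, (W - 1) / 2 - 0.2)
  spec <- vesicle_spec(center_xy = ctr, peak_radius_px = c(R, R),
                       ring_sigma_px = 2,
                       angular = list(angular_uniform()),
                       cytosol_level = 0, lumen_level = 0)
  ves <- render_vesicle_image(spec, c(W, W), seed = 1)
  prof <- sector_profile(ves$stack, annulus_band(ctr, R - 7, R + 7), 24)
  s <- prof$signal[, 1]
  expect_lt(max(s) / min(s), 1.01)

  # at the realistic 20 px vesicle scale the same sums carry a
  # discretization ripple of order 15%
  ves20 <- make_uniform_vesicle(radius = 20)
  s20 <- sector_profile(ves20$stack, default_band(ves20$truth), 24)$signal[, 1]
  expect_lt(max(s20) / min(s20), 1.15)
})

test_that("alignment rotates maxima to the target and is shift-invariant", {
  set.seed(5)
  sig <- matrix(runif(48), 24, 2)
  base <- structure(list(n_sectors = 24L, angle_origin_deg = 0,
                         signal = sig, pixel_count = rep(10L, 24),
                         channel_names = c("a", "b")),
                    class = "sector_profile")
  target <- 5L
  aligned <- align_profile(base, target)
  expect_identical(which.max(aligned$signal[, 1]) - 1L, target)

  # already at target: unchanged
  again <- align_profile(aligned, target)
  expect_equal(again$signal, aligned$signal)

  # alignment is invariant to any prior rotation of the profile
  for (k in 0:23) {
    perm <- ((seq_len(24) - 1L + k) %% 24) + 1L
    rot <- base
    rot$signal <- base$signal[perm, , drop = FALSE]
    rot$pixel_count <- base$pixel_count[perm]
    expect_equal(align_profile(rot, target)$signal, aligned$signal)
  }

  # constant profile: tie-break picks original index 0 deterministically
  flat <- base
  flat$signal[] <- 1
  out <- align_profile(flat, target)
  expect_identical(attr(out, "rotation"), target %% 24L)
})

test_that("mean_profile averages aligned profiles and checks shapes", {
  ves <- make_uniform_vesicle()
  p <- sector_profile(ves$stack, default_band(ves$truth), 24)
  expect_equal(mean_profile(list(p))$signal, p$signal)

  p2 <- p
  p2$signal <- p$signal * 3
  m <- mean_profile(list(p, p2))
  expect_equal(m$signal, 2 * p$signal)

  p12 <- sector_profile(ves$stack, default_band(ves$truth), 12)
  expect_error(mean_profile(list(p, p12)), "2")

  # averaging aligned noisy focal profiles keeps the peak at the target
  spec <- vesicle_spec(peak_radius_px = c(20, 20),
                       angular = list(angular_focal(57, 10)),
                       noise_sd = 0.05)
  target <- 0L
  profs <- lapply(1:10, function(s) {
    ves <- render_vesicle_image(spec, c(64L, 64L), seed = s)
    align_profile(sector_profile(ves$stack, default_band(ves$truth), 24),
                  target)
  })
  m <- mean_profile(profs)
  expect_identical(which.max(m$signal[, 1]) - 1L, target)
})

test_that("polarization index spans 0 (uniform) to 1 (single sector)", {
  mk <- function(sig) {
    structure(list(n_sectors = length(sig), angle_origin_deg = 0,
                   signal = matrix(sig, ncol = 1),
                   pixel_count = rep(1L, length(sig)),
                   channel_names = "a"),
              class = "sector_profile")
  }
  expect_lt(polarization_index(mk(rep(3, 24))), 1e-12)
  one <- rep(0, 24); one[4] <- 5
  expect_equal(polarization_index(mk(one)), 1, tolerance = 1e-12)
  two <- rep(0, 24); two[1] <- 2; two[13] <- 2 # opposite sectors cancel
  expect_lt(polarization_index(mk(two)), 1e-12)
  expect_error(polarization_index(mk(rep(0, 24))), "zero total")
})

test_that("polarization rises monotonically with focal concentration", {
  kappas <- c(0, 0.5, 1, 2, 4, 8, 16)
  pis <- vapply(kappas, function(k) {
    ang <- if (k == 0) angular_uniform() else angular_focal(45, k)
    spec <- vesicle_spec(peak_radius_px = c(20, 20), angular = list(ang))
    ves <- render_vesicle_image(spec, c(64L, 64L), seed = 1)
    polarization_index(
      sector_profile(ves$stack, default_band(ves$truth), 24))
  }, numeric(1))
  expect_true(all(diff(pis) > 0))
})

test_that("rotating the coat by one sector width permutes the profile", {
  w <- 360 / 24
  spec0 <- vesicle_spec(peak_radius_px = c(20, 20),
                        angular = list(angular_focal(40, 6)))
  spec1 <- vesicle_spec(peak_radius_px = c(20, 20),
                        angular = list(angular_focal(40 + w, 6)))
  band <- annulus_band(c(31.5, 31.5), 13, 27)
  p0 <- sector_profile(render_vesicle_image(spec0, c(64L, 64L))$stack,
                       band, 24)$signal[, 1]
  p1 <- sector_profile(render_vesicle_image(spec1, c(64L, 64L))$stack,
                       band, 24)$signal[, 1]
  shifted <- p0[((seq_len(24) - 2L) %% 24) + 1L] # permute by one sector
  # tolerance set by pixel resampling of the rotated coat
  expect_equal(p1, shifted, tolerance = 0.1)
})

test_that("vesicle-to-cytosol ratio behaves like a contrast measure", {
  band <- annulus_band(c(31.5, 31.5), 17, 23)
  cyto <- matrix(FALSE, 64, 64)
  cyto[1:8, 1:8] <- TRUE
  # uniform image: ratio 1
  expect_equal(vesicle_to_cytosol_ratio(matrix(0.2, 64, 64), band, cyto), 1)
  # ratio grows with coat amplitude
  ratios <- vapply(c(0.1, 0.2, 0.4), function(a) {
    spec <- vesicle_spec(peak_radius_px = c(20, 20),
                         angular = list(angular_uniform()),
                         coat_amplitude = a, cytosol_level = 0.05,
                         lumen_level = 0.05)
    ves <- render_vesicle_image(spec, c(64L, 64L), seed = 1)
    vesicle_to_cytosol_ratio(ves$stack, band, cyto)
  }, numeric(1))
  expect_gt(ratios[1], 1)
  expect_true(all(diff(ratios) > 0))
  # errors: empty mask, overlapping mask
  expect_error(vesicle_to_cytosol_ratio(matrix(1, 64, 64), band,
                                        matrix(FALSE, 64, 64)), "empty")
  overlap <- matrix(FALSE, 64, 64); overlap[32, 52] <- TRUE # inside band
  expect_error(vesicle_to_cytosol_ratio(matrix(1, 64, 64), band, overlap),
               "overlaps")
})

test_that("masked Pearson matches the brute-force formula", {
  set.seed(8)
  a <- matrix(runif(400), 20, 20)
  b <- 0.6 * a + matrix(rnorm(400, 0, 0.1), 20, 20)
  b <- b - min(b)
  mask <- matrix(runif(400) < 0.4, 20, 20)
  got <- masked_pearson(a, b, mask)
  # explicit covariance / sd computation over the masked pixels
  av <- a[mask]; bv <- b[mask]
  n <- length(av)
  cov_ab <- sum((av - mean(av)) * (bv - mean(bv))) / (n - 1)
  want <- cov_ab / (sqrt(sum((av - mean(av))^2 / (n - 1))) *
                      sqrt(sum((bv - mean(bv))^2 / (n - 1))))
  expect_equal(got, want, tolerance = 1e-12)

  expect_equal(masked_pearson(a, a, mask), 1)
  expect_equal(masked_pearson(a, max(a) - a, mask), -1)
  tiny <- matrix(FALSE, 20, 20); tiny[1, 1:2] <- TRUE
  expect_error(masked_pearson(a, b, tiny), "3 pixels")
  expect_error(masked_pearson(a, matrix(1, 20, 20), mask), "constant")
})
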