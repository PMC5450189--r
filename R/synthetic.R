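# Synthetic ground-truth generators: ring-shaped vesicle images with patchy
# or focal angular coats, single-exponential FRAP traces, and replicate
# retention curves. Every generator returns the full generating spec plus the
# seed, sufficient to regenerate the object bit-exactly.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = .GlobalEnv)
    } else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
      rm(".Random.seed", envir = .GlobalEnv)
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Angular coat profiles
#'
#' The angular distribution of coat protein around the vesicle circumference
#' is modelled as a mixture of von Mises bumps (or a uniform coat). The
#' concentration parameter controls the phenotype: several moderate bumps
#' give a "patchy" coat, a single high-concentration bump a "focal"
#' aggregate.
#'
#' @param mean_angle_deg,concentration,weight mixture component parameters;
#'   vectors of equal length. Weights are the angular integrals of each bump
#'   (the von Mises densities integrate to 1).
#' @return an angular component table, or the string `"uniform"`.
#' @export
angular_components <- function(mean_angle_deg, concentration, weight = 1) {
  df <- data.frame(mean_angle_deg = mean_angle_deg,
                   concentration = concentration,
                   weight = rep_len(weight, length(mean_angle_deg)))
  if (nrow(df) < 1L) stop("at least one angular component is required")
  if (any(df$weight < 0)) stop("component weights must be >= 0")
  if (any(df$concentration < 0)) stop("concentrations must be >= 0")
  df
}

#' @rdname angular_components
#' @export
angular_uniform <- function() "uniform"

#' @rdname angular_components
#' @export
angular_patchy <- function() {
  angular_components(mean_angle_deg = c(20, 110, 205, 300),
                     concentration = c(4, 4, 4, 4),
                     weight = c(1, 0.7, 1.2, 0.6))
}

#' @rdname angular_components
#' @param focus_angle_deg direction of the focal aggregate.
#' @export
angular_focal <- function(focus_angle_deg = 0, concentration = 12) {
  angular_components(mean_angle_deg = focus_angle_deg,
                     concentration = concentration, weight = 1)
}

# Evaluate the angular profile a(theta) for one channel.
# For mixtures, a(theta) = sum_j w_j * vonMises(theta; mu_j, kappa_j) with
# densities normalized over the circle; for "uniform", a(theta) = 1.
eval_angular <- function(theta_rad, comps) {
  if (identical(comps, "uniform")) {
    return(rep(1, length(theta_rad)))
  }
  out <- numeric(length(theta_rad))
  for (j in seq_len(nrow(comps))) {
    mu <- comps$mean_angle_deg[j] * pi / 180
    k <- comps$concentration[j]
    w <- comps$weight[j]
    # exp-scaled Bessel keeps large concentrations finite
    out <- out + w * exp(k * (cos(theta_rad - mu) - 1)) /
      (2 * pi * besselI(k, 0, expon.scaled = TRUE))
  }
  out
}

# Mean of a(theta) over the circle (the "mean angular weight").
mean_angular_weight <- function(comps) {
  if (identical(comps, "uniform")) return(1)
  sum(comps$weight) / (2 * pi)
}

#' Specification of a synthetic two-channel vesicle image
#'
#' Describes a ring-shaped fluorescent coat: a radial Gaussian of width
#' `ring_sigma_px` centred at `peak_radius_px` (per channel, so a channel
#' pair can encode a radial displacement), modulated by an angular profile,
#' on top of cytosolic background and luminal fill, with optional additive
#' Gaussian noise.
#'
#' @param center_xy subpixel vesicle centre `(x, y)`, 0-based pixel
#'   coordinates.
#' @param peak_radius_px per-channel ring radius in pixels.
#' @param ring_sigma_px radial Gaussian width of the coat, pixels.
#' @param angular list of per-channel angular profiles (see
#'   [angular_components()]); recycled if shorter than the channel count.
#' @param coat_amplitude per-channel peak coat intensity (normalized units).
#' @param cytosol_level background intensity outside the ring.
#' @param lumen_level interior fill intensity inside the ring.
#' @param noise_sd additive Gaussian noise standard deviation.
#' @return a `vesicle_spec` list.
#' @export
vesicle_spec <- function(center_xy = NULL, peak_radius_px = c(20, 20),
                         ring_sigma_px = 2,
                         angular = list(angular_patchy()),
                         coat_amplitude = 0.6, cytosol_level = 0.05,
                         lumen_level = 0.05, noise_sd = 0) {
  nch <- length(peak_radius_px)
  stopifnot(nch >= 1L, ring_sigma_px >= 0, noise_sd >= 0)
  if (any(peak_radius_px <= 3 * ring_sigma_px)) {
    stop("peak_radius_px must exceed 3 * ring_sigma_px ",
         "(ring must be separable from the centre)")
  }
  angular <- rep_len(angular, nch)
  for (a in angular) {
    if (!identical(a, "uniform") && !is.data.frame(a)) {
      stop("each angular profile must be \"uniform\" or an ",
           "angular_components() table")
    }
  }
  structure(
    list(center_xy = center_xy,
         peak_radius_px = peak_radius_px,
         ring_sigma_px = ring_sigma_px,
         angular = angular,
         coat_amplitude = rep_len(coat_amplitude, nch),
         cytosol_level = cytosol_level,
         lumen_level = lumen_level,
         noise_sd = noise_sd),
    class = "vesicle_spec"
  )
}

#' True per-sector angular signal fractions for a vesicle spec
#'
#' Integrates the angular profile over each sector's half-open interval
#' (fine trapezoidal quadrature) and normalizes, giving the ground-truth
#' fraction of coat signal expected in each sector.
#'
#' @param spec a [vesicle_spec()].
#' @param n_sectors number of sectors.
#' @param channel 1-based channel index.
#' @param angle_origin_deg start edge of sector 0.
#' @return numeric vector of length `n_sectors` summing to 1.
#' @export
true_sector_fractions <- function(spec, n_sectors = 24L, channel = 1L,
                                  angle_origin_deg = 0) {
  comps <- spec$angular[[channel]]
  w <- 2 * pi / n_sectors
  origin <- angle_origin_deg * pi / 180
  fr <- vapply(seq_len(n_sectors) - 1L, function(k) {
    th <- seq(origin + k * w, origin + (k + 1) * w, length.out = 2001L)
    y <- eval_angular(th, comps)
    sum((y[-1] + y[-length(y)]) / 2) * (th[2] - th[1])
  }, numeric(1))
  fr / sum(fr)
}

#' Render a synthetic two-channel vesicle image
#'
#' Evaluates, per channel, the analytic intensity
#' `baseline(r) + coat_amplitude * exp(-(r - peak_radius)^2 / (2 sigma^2)) *
#' a(theta)` at each pixel centre, where `baseline` is `lumen_level` inside
#' the ring radius and `cytosol_level` outside, then adds Gaussian noise.
#' Evaluating at pixel centres (no area integration) keeps the exact
#' analytic form available as a test oracle.
#'
#' @param spec a [vesicle_spec()].
#' @param shape image dimensions `c(height, width)` in pixels.
#' @param seed integer seed for the noise.
#' @param n_sectors sector count used for the ground-truth sector fractions.
#' @return list with elements `stack` (an [image_stack()], one frame) and
#'   `truth` (a `synthetic_truth` list recording the spec, seed, shape,
#'   analytic total coat signal, per-sector fractions, true peak radii and
#'   the true cross-channel diameter difference).
#' @export
render_vesicle_image <- function(spec, shape = c(64L, 64L), seed = 1L,
                                 n_sectors = 24L) {
  stopifnot(inherits(spec, "vesicle_spec"), length(shape) == 2L)
  h <- shape[1]; w <- shape[2]
  ctr <- spec$center_xy
  if (is.null(ctr)) ctr <- c((w - 1) / 2, (h - 1) / 2)
  nch <- length(spec$peak_radius_px)
  margin <- max(spec$peak_radius_px) + 3 * spec$ring_sigma_px
  if (ctr[1] - margin < 0 || ctr[1] + margin > w - 1 ||
      ctr[2] - margin < 0 || ctr[2] + margin > h - 1) {
    stop("ring (radius + 3 sigma = ", round(margin, 2),
         " px) does not fit inside a ", h, " x ", w,
         " image at centre (", ctr[1], ", ", ctr[2], ")")
  }
  x <- matrix(rep(0:(w - 1), each = h), h, w)
  y <- matrix(rep(0:(h - 1), times = w), h, w)
  dx <- x - ctr[1]; dy <- y - ctr[2]
  r <- sqrt(dx^2 + dy^2)
  theta <- atan2(-dy, dx) # y flipped: angles counter-clockwise on screen
  px <- array(0, c(1L, nch, h, w))
  for (c in seq_len(nch)) {
    base <- ifelse(r < spec$peak_radius_px[c], spec$lumen_level,
                   spec$cytosol_level)
    ring <- exp(-(r - spec$peak_radius_px[c])^2 / (2 * spec$ring_sigma_px^2))
    ang <- matrix(eval_angular(as.vector(theta), spec$angular[[c]]), h, w)
    px[1, c, , ] <- base + spec$coat_amplitude[c] * ring * ang
  }
  if (spec$noise_sd > 0) {
    noise <- with_seed(seed, stats::rnorm(length(px), 0, spec$noise_sd))
    px <- px + array(noise, dim(px))
  }
  px[px < 0] <- 0
  stack <- image_stack(px)
  total <- vapply(seq_len(nch), function(c) {
    spec$coat_amplitude[c] * 2 * pi * spec$peak_radius_px[c] *
      spec$ring_sigma_px * sqrt(2 * pi) *
      mean_angular_weight(spec$angular[[c]])
  }, numeric(1))
  fractions <- lapply(seq_len(nch), function(c) {
    true_sector_fractions(spec, n_sectors, c)
  })
  truth <- structure(
    list(kind = "vesicle_image", spec = spec, center_xy = ctr,
         shape = shape, seed = as.integer(seed),
         total_coat_signal = total,
         n_sectors = as.integer(n_sectors),
         sector_fractions = fractions,
         true_peak_radius_px = spec$peak_radius_px,
         true_diameter_difference_px =
           if (nch >= 2L) 2 * (spec$peak_radius_px[1] - spec$peak_radius_px[2])
           else NA_real_),
    class = "synthetic_truth"
  )
  list(stack = stack, truth = truth)
}

#' Specification of a synthetic FRAP trace
#'
#' Post-bleach recovery follows the single-exponential model
#' `Intensity(t) = A + B * exp(-C * t)` with `t` measured from the bleach
#' instant; pre-bleach samples sit at `pre_bleach_level`.
#'
#' @param A plateau intensity.
#' @param B recovery amplitude (negative for recovery from below toward `A`).
#' @param C rate constant per second, > 0.
#' @param pre_bleach_level intensity before the bleach.
#' @param bleach_time_s bleach instant; samples at `t >= bleach_time_s` are
#'   post-bleach.
#' @param times_s strictly increasing sample times spanning the bleach.
#' @param noise_sd additive Gaussian noise standard deviation.
#' @return a `frap_sim_spec` list.
#' @export
frap_sim_spec <- function(A = 100, B = -80, C = 0.2, pre_bleach_level = 100,
                          bleach_time_s = 0,
                          times_s = seq(-4, 30, by = 0.2), noise_sd = 0) {
  stopifnot(C > 0, noise_sd >= 0, all(diff(times_s) > 0))
  if (!any(times_s < bleach_time_s) || !any(times_s >= bleach_time_s)) {
    stop("times_s must contain samples both before and after bleach_time_s")
  }
  structure(list(A = A, B = B, C = C, pre_bleach_level = pre_bleach_level,
                 bleach_time_s = bleach_time_s, times_s = times_s,
                 noise_sd = noise_sd),
            class = "frap_sim_spec")
}

#' Simulate a FRAP recovery trace
#'
#' @param spec a [frap_sim_spec()].
#' @param seed integer noise seed.
#' @param trace_id identifier attached to the trace.
#' @return list with `trace` (a [frap_trace()]) and `truth`
#'   (spec, seed, and the true half-time `ln(2)/C`).
#' @export
simulate_frap_trace <- function(spec, seed = 1L, trace_id = "sim") {
  stopifnot(inherits(spec, "frap_sim_spec"))
  t <- spec$times_s
  post <- t >= spec$bleach_time_s
  ideal <- ifelse(post,
                  spec$A + spec$B * exp(-spec$C * (t - spec$bleach_time_s)),
                  spec$pre_bleach_level)
  intensity <- if (spec$noise_sd > 0) {
    ideal + with_seed(seed, stats::rnorm(length(t), 0, spec$noise_sd))
  } else {
    ideal
  }
  trace <- frap_trace(trace_id, t, intensity,
                      phase = ifelse(post, "post", "pre"))
  truth <- structure(
    list(kind = "frap_trace", spec = spec, seed = as.integer(seed),
         A = spec$A, B = spec$B, C = spec$C,
         half_time_s = log(2) / spec$C),
    class = "synthetic_truth"
  )
  list(trace = trace, truth = truth)
}

#' Specification of a synthetic retention assay
#'
#' Emulates a bulk fluorimetry exocytosis assay: cells loaded with a
#' fluorescent tracer release it over time, and the remaining fluorescence
#' of replicate samples is measured on a fixed time grid.
#'
#' @param half_time_min target time to 50% retention, minutes.
#' @param form decay family: `"exponential"`
#'   (`fraction(t) = exp(-t ln 2 / half_time)`) or `"linear"`
#'   (`max(0, 1 - t / (2 half_time))`).
#' @param n_replicates number of replicate curves.
#' @param times_min sample grid in minutes, starting at 0.
#' @param noise_cv multiplicative lognormal noise coefficient of variation
#'   applied independently per measurement.
#' @param initial_fluorescence raw fluorescence at t = 0 before noise.
#' @return a `retention_sim_spec` list.
#' @export
retention_sim_spec <- function(half_time_min = 60,
                               form = c("exponential", "linear"),
                               n_replicates = 11L,
                               times_min = seq(0, 360, by = 30),
                               noise_cv = 0.1,
                               initial_fluorescence = 1000) {
  form <- match.arg(form)
  stopifnot(half_time_min > 0, n_replicates >= 1L, noise_cv >= 0,
            times_min[1] == 0, all(diff(times_min) > 0))
  structure(list(half_time_min = half_time_min, form = form,
                 n_replicates = as.integer(n_replicates),
                 times_min = times_min, noise_cv = noise_cv,
                 initial_fluorescence = initial_fluorescence),
            class = "retention_sim_spec")
}

retention_fraction <- function(spec, t) {
  switch(spec$form,
         exponential = exp(-t * log(2) / spec$half_time_min),
         linear = pmax(0, 1 - t / (2 * spec$half_time_min)))
}

#' Simulate replicate retention curves
#'
#' Raw fluorescence per replicate is the ideal decay scaled by
#' `initial_fluorescence` with independent multiplicative lognormal noise
#' (unit mean, stated CV) at every time point, then normalized to the t = 0
#' measurement via [normalize_retention()].
#'
#' @param spec a [retention_sim_spec()].
#' @param seed integer noise seed.
#' @param strain_label label attached to each curve.
#' @return list with `curves` (list of normalized retention curves) and
#'   `truth` (spec, seed, true half-time, and a `censored` flag set when the
#'   noise-free curve never reaches 50% within the grid).
#' @export
simulate_retention <- function(spec, seed = 1L, strain_label = "sim") {
  stopifnot(inherits(spec, "retention_sim_spec"))
  t <- spec$times_min
  ideal <- retention_fraction(spec, t)
  censored <- ideal[length(ideal)] > 0.5
  if (censored) {
    warning("time grid does not reach 50% decay; true t50 is censored")
  }
  sdlog <- sqrt(log(1 + spec$noise_cv^2))
  curves <- with_seed(seed, {
    lapply(seq_len(spec$n_replicates), function(i) {
      eps <- if (spec$noise_cv > 0) {
        stats::rlnorm(length(t), meanlog = -sdlog^2 / 2, sdlog = sdlog)
      } else {
        rep(1, length(t))
      }
      raw <- spec$initial_fluorescence * ideal * eps
      normalize_retention(t, raw, replicate_id = i, strain = strain_label)
    })
  })
  truth <- structure(
    list(kind = "retention", spec = spec, seed = as.integer(seed),
         strain_label = strain_label,
         half_time_min = spec$half_time_min, censored = censored),
    class = "synthetic_truth"
  )
  list(curves = curves, truth = truth)
}

#' Sample vesicle cross-sectional areas
#'
#' Lognormal draws parameterized so that the arithmetic mean and standard
#' deviation match the requested moments; all draws are positive, as areas
#' must be.
#'
#' @param mean_um2 target arithmetic mean, square micrometres.
#' @param sd_um2 target arithmetic standard deviation (0 gives constant
#'   draws).
#' @param n number of draws.
#' @param seed integer seed.
#' @return numeric vector of `n` positive areas.
#' @export
sample_vesicle_areas <- function(mean_um2, sd_um2, n, seed = 1L) {
  stopifnot(mean_um2 > 0, sd_um2 >= 0, n >= 1)
  if (sd_um2 == 0) return(rep(mean_um2, n))
  sdlog2 <- log(1 + (sd_um2 / mean_um2)^2)
  meanlog <- log(mean_um2) - sdlog2 / 2
  with_seed(seed, stats::rlnorm(n, meanlog = meanlog, sdlog = sqrt(sdlog2)))
}

#' Regenerate a synthetic object from its recorded truth
#'
#' Every generator records its full spec and seed; this reruns the matching
#' generator, which must reproduce the object bit-exactly.
#'
#' @param truth a `synthetic_truth` object.
#' @return the regenerated object (same structure as the original
#'   generator's return value).
#' @export
regenerate <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  switch(truth$kind,
         vesicle_image = render_vesicle_image(truth$spec, truth$shape,
                                              truth$seed, truth$n_sectors),
         frap_trace = simulate_frap_trace(truth$spec, truth$seed),
         retention = suppressWarnings(
           simulate_retention(truth$spec, truth$seed,
                              truth$strain_label %||% "sim")),
         stop("unknown truth kind: ", truth$kind))
}
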