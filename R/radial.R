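# Radial sector profiling: annulus bands around vesicles, sector
# decomposition, profile alignment/averaging, polarization scoring,
# vesicle-to-cytosol ratios and masked colocalization.

#' Circumferential band around a vesicle
#'
#' @param center_xy subpixel centre `(x, y)` in 0-based pixel coordinates.
#' @param r_inner_px inner radius, pixels (>= 0).
#' @param r_outer_px outer radius, pixels (> `r_inner_px`). A pixel belongs
#'   to the band when its centre distance lies in `[r_inner_px, r_outer_px)`.
#' @return an `annulus_band` list.
#' @export
annulus_band <- function(center_xy, r_inner_px, r_outer_px) {
  stopifnot(length(center_xy) == 2L, is.numeric(center_xy))
  if (!(r_inner_px >= 0 && r_inner_px < r_outer_px)) {
    stop("radii must satisfy 0 <= r_inner_px < r_outer_px")
  }
  structure(list(center_xy = as.numeric(center_xy),
                 r_inner_px = r_inner_px, r_outer_px = r_outer_px),
            class = "annulus_band")
}

check_band_fits <- function(band, image_shape) {
  h <- image_shape[1]; w <- image_shape[2]
  cx <- band$center_xy[1]; cy <- band$center_xy[2]
  r <- band$r_outer_px
  clip <- character(0)
  if (cx - r < -0.5) clip <- c(clip, sprintf("left by %.2f px", -0.5 - (cx - r)))
  if (cx + r > w - 0.5) clip <- c(clip, sprintf("right by %.2f px", cx + r - (w - 0.5)))
  if (cy - r < -0.5) clip <- c(clip, sprintf("top by %.2f px", -0.5 - (cy - r)))
  if (cy + r > h - 0.5) clip <- c(clip, sprintf("bottom by %.2f px", cy + r - (h - 0.5)))
  if (length(clip)) {
    stop("annulus band extends outside the image: clipped ",
         paste(clip, collapse = ", "))
  }
  invisible(band)
}

# Pixel-centre polar coordinates relative to a band centre, for an
# image_shape grid. Returns matrices r (px) and angle (degrees in [0, 360),
# measured from +x, counter-clockwise on screen i.e. on (x, -y)).
pixel_polar <- function(center_xy, image_shape) {
  h <- image_shape[1]; w <- image_shape[2]
  x <- matrix(rep(0:(w - 1), each = h), h, w)
  y <- matrix(rep(0:(h - 1), times = w), h, w)
  dx <- x - center_xy[1]; dy <- y - center_xy[2]
  list(r = sqrt(dx^2 + dy^2),
       angle_deg = (atan2(-dy, dx) * 180 / pi) %% 360)
}

#' Build sector membership masks for an annulus band
#'
#' Every pixel whose centre distance lies in `[r_inner, r_outer)` is
#' assigned to exactly one sector by its centre angle; sectors are
#' half-open angular intervals `[k w, (k+1) w)` of width `w = 360 /
#' n_sectors` measured from `angle_origin_deg`. The masks therefore tile
#' the annulus with no overlap and no gap.
#'
#' @param band an [annulus_band()].
#' @param n_sectors number of sectors (>= 2).
#' @param image_shape image dimensions `c(height, width)`.
#' @param angle_origin_deg start edge of sector 0, degrees.
#' @return integer matrix of `image_shape` dimensions: 0-based sector index
#'   for annulus pixels, `NA` elsewhere.
#' @export
build_sector_masks <- function(band, n_sectors, image_shape,
                               angle_origin_deg = 0) {
  stopifnot(inherits(band, "annulus_band"), n_sectors >= 2L)
  check_band_fits(band, image_shape)
  pol <- pixel_polar(band$center_xy, image_shape)
  inside <- pol$r >= band$r_inner_px & pol$r < band$r_outer_px
  w <- 360 / n_sectors
  k <- floor(((pol$angle_deg - angle_origin_deg) %% 360) / w)
  k[k >= n_sectors] <- 0L # guard the 360-degree wrap at floating-point edge
  sectors <- matrix(NA_integer_, image_shape[1], image_shape[2])
  sectors[inside] <- as.integer(k[inside])
  sectors
}

#' Per-sector, per-channel signal of an annulus band
#'
#' Sums (not averages) each channel's intensity over every sector's pixels,
#' so that summing over sectors reproduces the total band signal exactly
#' (conservation). Empty sectors are reported with zero pixel count and
#' zero signal.
#'
#' @param frame an [image_stack()] (first frame used), a `(channel, y, x)`
#'   array, or a `(y, x)` matrix.
#' @param band an [annulus_band()].
#' @param n_sectors number of sectors.
#' @param angle_origin_deg start edge of sector 0, degrees.
#' @param channel_names optional channel labels.
#' @return a `sector_profile`: list with `n_sectors`, `angle_origin_deg`,
#'   `signal` (`n_sectors` x channels matrix), `pixel_count`, and
#'   `channel_names`.
#' @export
sector_profile <- function(frame, band, n_sectors = 24L,
                           angle_origin_deg = 0, channel_names = NULL) {
  if (inherits(frame, "image_stack") && is.null(channel_names)) {
    channel_names <- frame$channel_names
  }
  fr <- as_frame(frame)
  nch <- dim(fr)[1L]
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nch) - 1L)
  sectors <- build_sector_masks(band, n_sectors, dim(fr)[2:3],
                                angle_origin_deg)
  idx <- which(!is.na(sectors))
  sec <- sectors[idx]
  signal <- matrix(0, n_sectors, nch)
  for (c in seq_len(nch)) {
    img <- fr[c, , ]
    sums <- vapply(split(img[idx], factor(sec, levels = 0:(n_sectors - 1))),
                   sum, numeric(1))
    signal[, c] <- sums
  }
  pixel_count <- as.integer(table(factor(sec, levels = 0:(n_sectors - 1))))
  structure(
    list(n_sectors = as.integer(n_sectors),
         angle_origin_deg = angle_origin_deg,
         signal = signal, pixel_count = pixel_count,
         channel_names = channel_names),
    class = "sector_profile"
  )
}

#' @export
print.sector_profile <- function(x, ...) {
  cat(sprintf("<sector_profile> %d sectors x %d channel(s), %d px total\n",
              x$n_sectors, ncol(x$signal), sum(x$pixel_count)))
  invisible(x)
}

#' Rotate a profile so its maximum lands at a target sector
#'
#' Mirrors the orientation step used when averaging profiles across
#' vesicles: each vesicle is rotated so any focus sits at a common sector
#' (conventionally the one facing image right). Ties for the maximum break
#' toward the lowest original index, so alignment of a constant profile is
#' deterministic. All channels rotate jointly by the shift determined on
#' the reference channel.
#'
#' @param profile a [sector_profile()].
#' @param target_sector 0-based destination sector index.
#' @param ref_channel 1-based channel used to locate the maximum.
#' @return the rotated `sector_profile`, with the applied shift in
#'   attribute `"rotation"`.
#' @export
align_profile <- function(profile, target_sector = 0L, ref_channel = 1L) {
  stopifnot(inherits(profile, "sector_profile"), profile$n_sectors >= 2L)
  n <- profile$n_sectors
  target_sector <- as.integer(target_sector) %% n
  peak <- which.max(profile$signal[, ref_channel]) - 1L # ties -> lowest index
  shift <- (target_sector - peak) %% n
  perm <- ((seq_len(n) - 1L - shift) %% n) + 1L
  out <- profile
  out$signal <- profile$signal[perm, , drop = FALSE]
  out$pixel_count <- profile$pixel_count[perm]
  attr(out, "rotation") <- shift
  out
}

#' Average aligned sector profiles
#'
#' @param profiles list of [sector_profile()]s sharing sector and channel
#'   counts, typically after [align_profile()].
#' @return a `sector_profile` holding the per-sector, per-channel
#'   arithmetic mean signal and mean pixel count.
#' @export
mean_profile <- function(profiles) {
  stopifnot(length(profiles) >= 1L)
  n <- profiles[[1]]$n_sectors
  nch <- ncol(profiles[[1]]$signal)
  bad <- which(vapply(profiles, function(p) {
    p$n_sectors != n || ncol(p$signal) != nch
  }, logical(1)))
  if (length(bad)) {
    stop("profiles ", paste(bad, collapse = ", "),
         " do not match the first profile's sector/channel counts")
  }
  out <- profiles[[1]]
  out$signal <- Reduce(`+`, lapply(profiles, `[[`, "signal")) / length(profiles)
  out$pixel_count <- Reduce(`+`, lapply(profiles, `[[`, "pixel_count")) /
    length(profiles)
  attr(out, "rotation") <- NULL
  out
}

#' Polarization index of a sector profile
#'
#' Length of the circular resultant vector of the per-sector signal,
#' `|sum_k s_k exp(i theta_k)| / sum_k s_k`, with `theta_k` the sector
#' mid-angle. 0 for a perfectly even coat, 1 when all signal points in one
#' direction — a scalar summary of the patchy-versus-focal phenotype.
#'
#' @param profile a [sector_profile()].
#' @param channel 1-based channel index.
#' @return a number in `[0, 1]`.
#' @export
polarization_index <- function(profile, channel = 1L) {
  stopifnot(inherits(profile, "sector_profile"))
  s <- profile$signal[, channel]
  total <- sum(s)
  if (total <= 0) {
    stop("polarization index undefined: channel has zero total signal")
  }
  n <- profile$n_sectors
  mid <- (profile$angle_origin_deg + (seq_len(n) - 0.5) * 360 / n) * pi / 180
  sqrt(sum(s * cos(mid))^2 + sum(s * sin(mid))^2) / total
}

#' Vesicle-to-cytosol signal ratio
#'
#' Ratio of the mean intensity over the vesicle band to the mean intensity
#' over a user-supplied cytosolic region, per channel.
#'
#' @param frame image frame (see [as_frame()]).
#' @param band an [annulus_band()].
#' @param cytosol_mask logical matrix marking cytosol pixels; must be
#'   non-empty and disjoint from the band.
#' @param channel 1-based channel index.
#' @return positive ratio.
#' @export
vesicle_to_cytosol_ratio <- function(frame, band, cytosol_mask,
                                     channel = 1L) {
  fr <- as_frame(frame)
  shape <- dim(fr)[2:3]
  stopifnot(identical(dim(cytosol_mask), as.integer(shape)) ||
              identical(dim(cytosol_mask), shape))
  if (!any(cytosol_mask)) stop("cytosol mask is empty")
  pol <- pixel_polar(band$center_xy, shape)
  band_mask <- pol$r >= band$r_inner_px & pol$r < band$r_outer_px
  if (any(band_mask & cytosol_mask)) {
    stop("cytosol mask overlaps the vesicle band")
  }
  img <- fr[channel, , ]
  cyt <- mean(img[cytosol_mask])
  if (cyt == 0) stop("undefined ratio: cytosol mean intensity is zero")
  mean(img[band_mask]) / cyt
}

#' Pearson correlation of two channels within a mask
#'
#' The standard masked colocalization coefficient: per-pixel Pearson
#' correlation restricted to the region of interest.
#'
#' @param channel_a,channel_b `(y, x)` intensity matrices of equal size.
#' @param mask logical matrix; at least 3 pixels must be selected.
#' @return correlation in `[-1, 1]`.
#' @export
masked_pearson <- function(channel_a, channel_b, mask) {
  stopifnot(identical(dim(channel_a), dim(channel_b)),
            identical(dim(channel_a), dim(mask)))
  a <- channel_a[mask]; b <- channel_b[mask]
  if (length(a) < 3L) stop("mask must select at least 3 pixels")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("undefined correlation: a channel is constant within the mask")
  }
  stats::cor(a, b)
}

#' Radar plot of a sector profile
#'
#' Draws each channel's per-sector signal as a closed polygon in polar
#' coordinates, the visualization conventionally used for vesicle coat
#' profiles.
#'
#' @param profile a [sector_profile()].
#' @param main plot title.
#' @param cols line colours, one per channel.
#' @return invisibly, `NULL`.
#' @export
plot_radar <- function(profile, main = "sector profile",
                       cols = c("#D62728", "#2CA02C", "#1F77B4")) {
  stopifnot(inherits(profile, "sector_profile"))
  n <- profile$n_sectors
  mid <- (profile$angle_origin_deg + (seq_len(n) - 0.5) * 360 / n) * pi / 180
  smax <- max(profile$signal)
  if (smax <= 0) smax <- 1
  graphics::plot(NA, xlim = c(-1.1, 1.1), ylim = c(-1.1, 1.1), asp = 1,
                 axes = FALSE, xlab = "", ylab = "", main = main)
  graphics::symbols(0, 0, circles = 1, inches = FALSE, add = TRUE,
                    fg = "grey70")
  for (c in seq_len(ncol(profile$signal))) {
    s <- profile$signal[, c] / smax
    graphics::polygon(c(s * cos(mid), s[1] * cos(mid[1])),
                      c(s * sin(mid), s[1] * sin(mid[1])),
                      border = cols[((c - 1) %% length(cols)) + 1])
  }
  invisible(NULL)
}
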