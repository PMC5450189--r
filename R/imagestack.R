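#' Multi-channel image stack
#'
#' Container for fluorescence microscopy pixel data with axes ordered
#' `(time, channel, y, x)`. Coordinates are 0-based with a pixel's centre at
#' integer coordinates; `y` increases downward and `x` rightward (raster
#' order). Intensities are in normalized detector units and must be finite
#' and non-negative; on-disk TIFF storage uses the `[0, 1]` range.
#'
#' @param pixels numeric array. Either 4-d `(time, channel, y, x)`, 3-d
#'   `(channel, y, x)` (promoted to one frame) or a 2-d `(y, x)` matrix
#'   (promoted to one frame, one channel).
#' @param pixel_size_nm optional physical edge length of one pixel in
#'   nanometres; required downstream for displacement outputs in nm.
#' @param channel_names optional character vector of channel labels.
#' @param frame_interval_s optional time between frames in seconds.
#'
#' @return An object of class `image_stack`: a list with elements `pixels`
#'   (4-d array), `pixel_size_nm`, `channel_names`, `frame_interval_s`.
#' @export
image_stack <- function(pixels, pixel_size_nm = NULL, channel_names = NULL,
                        frame_interval_s = NULL) {
  if (!is.numeric(pixels)) {
    stop("`pixels` must be numeric")
  }
  d <- dim(pixels)
  if (is.null(d) || length(d) == 2L) {
    pixels <- array(pixels, c(1L, 1L, dim(as.matrix(pixels))))
  } else if (length(d) == 3L) {
    pixels <- array(pixels, c(1L, d))
  } else if (length(d) != 4L) {
    stop("`pixels` must have 2, 3 or 4 dimensions, got ", length(d))
  }
  if (any(!is.finite(pixels))) {
    stop("all intensities must be finite")
  }
  if (any(pixels < 0)) {
    stop("all intensities must be >= 0")
  }
  if (!is.null(pixel_size_nm)) {
    stopifnot(is.numeric(pixel_size_nm), length(pixel_size_nm) == 1L)
    if (!is.finite(pixel_size_nm) || pixel_size_nm <= 0) {
      stop("`pixel_size_nm` must be a positive number")
    }
  }
  nc <- dim(pixels)[2L]
  if (is.null(channel_names)) {
    channel_names <- paste0("ch", seq_len(nc) - 1L)
  } else if (length(channel_names) != nc) {
    stop("`channel_names` has length ", length(channel_names),
         " but the stack has ", nc, " channels")
  }
  structure(
    list(pixels = pixels, pixel_size_nm = pixel_size_nm,
         channel_names = as.character(channel_names),
         frame_interval_s = frame_interval_s),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<image_stack> %d frame(s), %d channel(s), %d x %d px\n",
              d[1], d[2], d[3], d[4]))
  if (!is.null(x$pixel_size_nm)) {
    cat(sprintf("  pixel size: %g nm\n", x$pixel_size_nm))
  }
  cat("  channels:", paste(x$channel_names, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$pixels)

n_frames <- function(stack) dim(stack$pixels)[1L]
n_channels <- function(stack) dim(stack$pixels)[2L]

#' Extract one time point as a (channel, y, x) array
#'
#' Operations on single images accept a frame in this layout; a plain `(y, x)`
#' matrix is treated as one channel.
#'
#' @param x an `image_stack`, a `(channel, y, x)` array or a `(y, x)` matrix.
#' @param time 1-based frame index when `x` is a stack.
#' @return numeric array with dimensions `(channel, y, x)`.
#' @export
as_frame <- function(x, time = 1L) {
  if (inherits(x, "image_stack")) {
    d <- dim(x$pixels)
    if (time < 1L || time > d[1L]) {
      stop("frame ", time, " out of range (stack has ", d[1L], " frames)")
    }
    return(array(x$pixels[time, , , , drop = FALSE], d[2:4]))
  }
  if (is.matrix(x)) {
    return(array(x, c(1L, dim(x))))
  }
  if (is.array(x) && length(dim(x)) == 3L) {
    return(x)
  }
  stop("cannot interpret object of class ", paste(class(x), collapse = "/"),
       " as an image frame")
}

require_two_channels <- function(frame, what = "this operation") {
  if (dim(frame)[1L] < 2L) {
    stop(what, " requires a two-channel image; got ", dim(frame)[1L],
         " channel(s)")
  }
  invisible(frame)
}

#' Read a TIFF file into an image stack
#'
#' Plain multi-page TIFF files are supported. Pages with a samples-per-pixel
#' dimension are read as channels within a frame; for single-sample files the
#' page axis is interpreted according to `axes`.
#'
#' @param path path to a TIFF file.
#' @param pixel_size_nm optional pixel size override in nanometres.
#' @param axes how to interpret the page axis of single-sample files:
#'   `"tyx"` (pages are time points, the default) or `"cyx"` (pages are
#'   channels of a single frame).
#' @return an [image_stack()].
#' @export
read_image_stack <- function(path, pixel_size_nm = NULL,
                             axes = c("tyx", "cyx")) {
  axes <- match.arg(axes)
  if (!file.exists(path)) {
    stop("cannot read image: file does not exist: ", path)
  }
  pages <- tryCatch(
    suppressWarnings(tiff::readTIFF(path, all = TRUE, info = TRUE)),
    error = function(e) stop("cannot read image '", path, "': ",
                             conditionMessage(e))
  )
  if (!is.list(pages)) pages <- list(pages)
  nd <- vapply(pages, function(p) length(dim(p)), integer(1))
  if (length(unique(nd)) != 1L) {
    stop("ambiguous axis layout in '", path,
         "': pages differ in dimensionality; pass an explicit `axes`")
  }
  if (nd[1] == 3L) {
    # pages are frames, third dim is channels
    nc <- dim(pages[[1]])[3L]
    h <- dim(pages[[1]])[1L]; w <- dim(pages[[1]])[2L]
    px <- array(0, c(length(pages), nc, h, w))
    for (t in seq_along(pages)) {
      for (c in seq_len(nc)) px[t, c, , ] <- pages[[t]][, , c]
    }
  } else {
    h <- dim(pages[[1]])[1L]; w <- dim(pages[[1]])[2L]
    if (axes == "cyx") {
      px <- array(0, c(1L, length(pages), h, w))
      for (c in seq_along(pages)) px[1, c, , ] <- pages[[c]]
    } else {
      px <- array(0, c(length(pages), 1L, h, w))
      for (t in seq_along(pages)) px[t, 1, , ] <- pages[[t]]
    }
  }
  image_stack(px, pixel_size_nm = pixel_size_nm)
}

#' Write an image stack to a multi-page TIFF
#'
#' Each time point is written as one page carrying all channels as samples.
#' Intensities must lie in `[0, 1]` (the package's normalized unit
#' convention); storage is 32-bit float, so values round-trip to single
#' precision.
#'
#' @param stack an [image_stack()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  if (max(stack$pixels) > 1) {
    stop("TIFF storage requires intensities in [0, 1]; rescale before writing")
  }
  d <- dim(stack$pixels)
  pages <- lapply(seq_len(d[1L]), function(t) {
    page <- array(0, c(d[3L], d[4L], d[2L]))
    for (c in seq_len(d[2L])) page[, , c] <- stack$pixels[t, c, , ]
    if (d[2L] == 1L) page <- page[, , 1L] # single-sample page
    page
  })
  suppressWarnings(tiff::writeTIFF(pages, path, bits.per.sample = 32L))
  invisible(path)
}
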