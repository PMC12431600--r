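# Frame-sequence rendering: a vibrating fruit as an anti-aliased ellipse
# with a central marker, translated along a vibration axis.

#' Rendering configuration
#'
#' @param frame_size `c(width, height)` in px (default 64 x 64).
#' @param fruit_axes Ellipse semi-axes `c(ax, ay)` in px.
#' @param marker_radius Radius of the central marker disc in px (0 disables).
#' @param vibration_axis Unit 2-vector for the displacement direction
#'   (x rightward, y downward); normalised internally.
#' @param supersampling_factor Subpixel samples per axis for anti-aliasing
#'   (at least 1; use 8 or more when rendering sub-pixel amplitudes).
#' @param pixel_noise_sd Additive Gaussian pixel noise SD, in intensity
#'   units on the 0 to 1 scale.
#' @param background,foreground,marker_intensity Grayscale levels.
#' @param seed Integer seed for the pixel noise.
#' @return An object of class `render_config`.
#' @export
render_config <- function(frame_size = c(64, 64), fruit_axes = c(20, 16),
                          marker_radius = 3, vibration_axis = c(1, 0),
                          supersampling_factor = 8, pixel_noise_sd = 0,
                          background = 0, foreground = 0.9,
                          marker_intensity = 0.4, seed = 1) {
  stopifnot(length(frame_size) == 2, all(frame_size >= 8),
            length(fruit_axes) == 2, all(fruit_axes > 0),
            marker_radius >= 0, length(vibration_axis) == 2,
            supersampling_factor >= 1, pixel_noise_sd >= 0)
  nrm <- sqrt(sum(vibration_axis^2))
  if (nrm == 0) stop("vibration_axis must be non-zero")
  structure(list(frame_size = as.integer(frame_size),
                 fruit_axes = fruit_axes,
                 marker_radius = marker_radius,
                 vibration_axis = vibration_axis / nrm,
                 supersampling_factor = as.integer(supersampling_factor),
                 pixel_noise_sd = pixel_noise_sd,
                 background = background, foreground = foreground,
                 marker_intensity = marker_intensity, seed = seed),
            class = "render_config")
}

#' Construct a frame sequence
#'
#' @param frames A `height x width x n` numeric array of grayscale frames
#'   in `[0, 1]`; rows are y (downward), columns x (rightward).
#' @param frame_rate Frames per second.
#' @param pixel_scale Optional mm per px.
#' @param ground_truth Optional generating metadata.
#' @return An object of class `frame_sequence`.
#' @export
frame_sequence <- function(frames, frame_rate, pixel_scale = NULL,
                           ground_truth = NULL) {
  stopifnot(length(dim(frames)) == 3, frame_rate > 0)
  structure(list(frames = frames, frame_rate = frame_rate,
                 pixel_scale = pixel_scale, ground_truth = ground_truth),
            class = "frame_sequence")
}

#' @export
print.frame_sequence <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<frame_sequence> %d frames of %d x %d px at %g fps\n",
              d[3], d[2], d[1], x$frame_rate))
  invisible(x)
}

#' Render a displacement trace as a frame sequence
#'
#' One grayscale frame per sample: an anti-aliased ellipse (the fruit) with
#' a central marker disc, translated along the vibration axis by the trace
#' value in px. Rendering is deterministic given the config seed.
#'
#' @param trace A [displacement_trace()] in px.
#' @param cfg A [render_config()].
#' @return A [frame_sequence()] at `frame_rate = trace$sampling_rate`.
#' @export
render_frames <- function(trace, cfg = render_config()) {
  stopifnot(inherits(trace, "displacement_trace"),
            inherits(cfg, "render_config"))
  w <- cfg$frame_size[1]; h <- cfg$frame_size[2]
  cx <- (w - 1) / 2; cy <- (h - 1) / 2
  amax <- max(abs(trace$value))
  reach_x <- cfg$fruit_axes[1] + amax * abs(cfg$vibration_axis[1])
  reach_y <- cfg$fruit_axes[2] + amax * abs(cfg$vibration_axis[2])
  if (cx - reach_x < 0.5 || cx + reach_x > w - 1.5 ||
      cy - reach_y < 0.5 || cy + reach_y > h - 1.5) {
    stop("fruit leaves the frame: reduce amplitude or fruit_axes, ",
         "or enlarge frame_size")
  }
  frames <- .render_frames_cpp(
    trace$value * cfg$vibration_axis[1],
    trace$value * cfg$vibration_axis[2],
    w, h, cx, cy, cfg$fruit_axes[1], cfg$fruit_axes[2],
    cfg$marker_radius, cfg$background, cfg$foreground,
    cfg$marker_intensity, cfg$supersampling_factor)
  if (cfg$pixel_noise_sd > 0) {
    noise <- withr::with_seed(cfg$seed,
                              rnorm(length(frames), 0, cfg$pixel_noise_sd))
    frames <- frames + array(noise, dim = dim(frames))
    frames[frames < 0] <- 0
    frames[frames > 1] <- 1
  }
  frame_sequence(frames, frame_rate = trace$sampling_rate,
                 ground_truth = trace$ground_truth)
}

#' Write a frame sequence to numbered image files
#'
#' Writes zero-padded numbered PNG (or TIFF) files plus a JSON sidecar
#' (`sequence.json`) holding the frame rate, pixel scale and any ground
#' truth.
#'
#' @param seq A [frame_sequence()].
#' @param dir Output directory (created if needed).
#' @param format `"png"` (default) or `"tiff"`.
#' @return `dir`, invisibly.
#' @export
write_frames <- function(seq, dir, format = c("png", "tiff")) {
  format <- match.arg(format)
  stopifnot(inherits(seq, "frame_sequence"))
  if (format == "tiff" && !requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required for TIFF output")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- dim(seq$frames)[3]
  digits <- max(6L, nchar(as.character(n)))
  for (i in seq_len(n)) {
    fr <- seq$frames[, , i]
    fr[fr < 0] <- 0; fr[fr > 1] <- 1
    path <- file.path(dir, sprintf("frame_%0*d.%s", digits, i,
                                   if (format == "png") "png" else "tif"))
    if (format == "png") png::writePNG(fr, path) else tiff::writeTIFF(fr, path)
  }
  jsonlite::write_json(
    list(frame_rate = seq$frame_rate,
         pixel_scale = seq$pixel_scale,
         n_frames = n, format = format,
         coordinate_convention = "pixel-centre origin (0,0), x right, y down",
         ground_truth = seq$ground_truth),
    file.path(dir, "sequence.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  invisible(dir)
}

#' Read a frame sequence from a directory of numbered images
#'
#' Reads the numbered PNG/TIFF files written by [write_frames()] (or any
#' numbered single-channel image sequence) and the JSON sidecar when
#' present.
#'
#' @param dir Directory containing the frames.
#' @param frame_rate Frames per second; overrides the sidecar value.
#' @return A [frame_sequence()].
#' @export
read_frames <- function(dir, frame_rate = NULL) {
  side <- file.path(dir, "sequence.json")
  meta <- if (file.exists(side)) jsonlite::read_json(side) else list()
  fr <- frame_rate %||% meta$frame_rate
  if (is.null(fr)) stop("frame_rate not given and no sidecar found")
  files <- sort(list.files(dir, pattern = "\\.(png|tif|tiff)$",
                           full.names = TRUE))
  if (length(files) == 0) stop("no image files found in ", dir)
  read1 <- function(f) {
    img <- if (grepl("\\.png$", f)) png::readPNG(f) else tiff::readTIFF(f)
    if (length(dim(img)) == 3) img <- img[, , 1]
    img
  }
  first <- read1(files[1])
  frames <- array(0, dim = c(nrow(first), ncol(first), length(files)))
  frames[, , 1] <- first
  for (i in seq_along(files)[-1]) frames[, , i] <- read1(files[i])
  frame_sequence(frames, frame_rate = as.numeric(fr),
                 pixel_scale = meta$pixel_scale %||% NULL)
}
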