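# Fruit segmentation and sub-pixel centre tracking across a frame sequence.

#' Segment the fruit in a grayscale frame
#'
#' Global thresholding (Otsu by default, or a fixed numeric threshold)
#' followed by hole filling; the largest connected foreground component is
#' returned.
#'
#' @param frame A `height x width` numeric matrix in `[0, 1]`.
#' @param threshold `"otsu"` (default) or a numeric threshold in `(0, 1)`.
#' @return A logical mask matrix of the same dimensions.
#' @export
segment_fruit <- function(frame, threshold = "otsu") {
  stopifnot(is.matrix(frame))
  if (max(frame) - min(frame) < .Machine$double.eps) {
    stop("segmentation failure: constant frame, no foreground found")
  }
  img <- EBImage::Image(t(frame))   # EBImage stores x (columns) first
  th <- if (identical(threshold, "otsu")) {
    EBImage::otsu(img, range = range(frame), levels = 256)
  } else {
    as.numeric(threshold)
  }
  mask <- img > th
  if (!any(mask)) stop("segmentation failure: empty foreground")
  mask <- EBImage::fillHull(mask)
  lab <- EBImage::bwlabel(mask)
  counts <- tabulate(as.integer(lab))
  biggest <- which.max(counts)
  t(as.matrix(lab == biggest))
}

#' Sub-pixel centroid of a frame or mask
#'
#' Intensity-weighted centre of mass. Coordinates are continuous with the
#' origin at the centre of pixel (0, 0), x rightward (columns) and y
#' downward (rows). A logical matrix gives the unweighted (binary) centroid;
#' a numeric frame with a mask restricts the weights to the masked region.
#'
#' @param frame Numeric intensity matrix, or a logical mask.
#' @param mask Optional logical matrix restricting the weighted region.
#' @return Named numeric vector `c(x = , y = )` in px.
#' @export
centroid <- function(frame, mask = NULL) {
  if (is.logical(frame)) {
    w <- frame * 1
  } else {
    w <- frame
    if (!is.null(mask)) w <- w * mask
  }
  s <- sum(w)
  if (s <= 0) stop("empty mask: centroid undefined")
  xs <- col(w) - 1
  ys <- row(w) - 1
  c(x = sum(w * xs) / s, y = sum(w * ys) / s)
}

#' Track fruit displacement across a frame sequence
#'
#' Segments each frame ([segment_fruit()]), computes the intensity-weighted
#' centroid of the fruit region ([centroid()]), projects it onto the
#' vibration axis and subtracts the first-frame projection, so the trace
#' starts at 0 by construction. `mode = "marker"` tracks the dark central
#' marker disc inside the fruit region instead, weighting by intensity
#' deficit.
#'
#' @param seq A [frame_sequence()].
#' @param axis Projection axis 2-vector (x rightward, y downward);
#'   normalised internally. Default horizontal.
#' @param mode `"fruit"` (default) or `"marker"`.
#' @param magnitude If `TRUE`, return the 2-D displacement magnitude from
#'   the first-frame centre instead of the signed projection.
#' @param mask_dilate Pixels of mask dilation before intensity weighting
#'   (default 1). The binary mask cuts off faint anti-aliased edge pixels
#'   whose intensities carry the sub-pixel information; growing the mask by
#'   one pixel restores them (on a dark background they contribute their
#'   correct, small weight).
#' @return A [displacement_trace()] in px at the sequence frame rate.
#' @export
track_displacement <- function(seq, axis = c(1, 0), mode = c("fruit", "marker"),
                               magnitude = FALSE, mask_dilate = 1) {
  mode <- match.arg(mode)
  stopifnot(inherits(seq, "frame_sequence"))
  n <- dim(seq$frames)[3]
  if (n < 2) stop("need at least 2 frames")
  nrm <- sqrt(sum(axis^2))
  if (nrm == 0) stop("axis must be non-zero")
  axis <- axis / nrm
  brush <- if (mask_dilate > 0) {
    EBImage::makeBrush(2 * mask_dilate + 1, shape = "box")
  } else NULL
  cents <- matrix(0, n, 2)
  for (i in seq_len(n)) {
    fr <- seq$frames[, , i]
    m <- tryCatch(segment_fruit(fr),
                  error = function(e) stop("frame ", i, ": ",
                                           conditionMessage(e)))
    if (mode == "fruit") {
      if (!is.null(brush)) {
        m <- t(EBImage::dilate(t(m * 1), brush)) > 0
      }
      cents[i, ] <- centroid(fr, m)
    } else {
      # marker: intensity deficit relative to the fruit's bright surface
      inten <- fr[m]
      deficit <- (max(inten) - fr) * m
      cents[i, ] <- centroid(deficit)
    }
  }
  if (magnitude) {
    val <- sqrt((cents[, 1] - cents[1, 1])^2 + (cents[, 2] - cents[1, 2])^2)
  } else {
    proj <- cents %*% axis
    val <- proj - proj[1]
  }
  tm <- (seq_len(n) - 1) / seq$frame_rate
  displacement_trace(tm, as.numeric(val), seq$frame_rate,
                     ground_truth = seq$ground_truth)
}
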