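# helpers ---------------------------------------------------------------------

fov_channel <- function(fov, channel) {
  if (is.matrix(fov)) return(fov)
  if (inherits(fov, "phox_fov") || is.list(fov)) {
    ch <- fov$channels[[channel]]
    if (is.null(ch)) {
      abort(sprintf("Channel `%s` not present in the field of view.", channel))
    }
    return(ch)
  }
  abort("`fov` must be a `phox_fov` object or a numeric matrix.")
}

# fill holes (background components not touching the border) smaller than
# `max_area` pixels
fill_small_holes <- function(mask, max_area) {
  holes <- EBImage::bwlabel(!mask)
  border_labels <- unique(c(holes[1, ], holes[nrow(holes), ],
                            holes[, 1], holes[, ncol(holes)]))
  tab <- tabulate(holes)
  fill <- which(tab <= max_area)
  fill <- setdiff(fill, border_labels)
  if (length(fill) > 0) mask[holes %in% fill] <- TRUE
  mask
}

#' Demarcate cell-occupied regions from background fluorescence
#'
#' Gaussian-smooths the chosen channel and thresholds it at an absolute
#' background level: pixels whose smoothed intensity reaches the threshold
#' are considered cell-occupied cytoplasm. Holes smaller than
#' `min_hole_area` are filled.
#'
#' @param fov A `phox_fov` or a numeric matrix.
#' @param channel Channel carrying diffuse cytoplasmic background (default
#'   the lysosomal channel; pass `"nuclear"` to use UV background).
#' @param gaussian_sigma Smoothing sigma (px).
#' @param background_threshold Absolute intensity threshold (fraction of
#'   saturation).
#' @param min_hole_area Holes up to this many pixels are filled.
#' @return Logical matrix (`TRUE` = cell-occupied).
#' @export
demarcate_cell_regions <- function(fov, channel = "lysosomal",
                                   gaussian_sigma = 3,
                                   background_threshold = 0.04,
                                   min_hole_area = 400) {
  img <- fov_channel(fov, channel)
  smoothed <- matrix(EBImage::imageData(EBImage::gblur(img, sigma = gaussian_sigma)), nrow(img), ncol(img))
  if (background_threshold > max(smoothed)) {
    warn("Background threshold exceeds the channel maximum; mask is empty.")
    return(matrix(FALSE, nrow(img), ncol(img)))
  }
  mask <- smoothed >= background_threshold
  fill_small_holes(mask, min_hole_area)
}

#' Segment nuclei by thresholding and distance-transform watershed
#'
#' Thresholds the nuclear channel (Otsu by default), fills holes, and splits
#' touching nuclei with a watershed on the Euclidean distance transform of
#' the binary mask (distance maxima act as seeds). Objects smaller than
#' `min_area` pixels are removed and labels are renumbered consecutively.
#'
#' @param fov A `phox_fov` or a numeric matrix (nuclear channel).
#' @param threshold `"otsu"` or a numeric absolute threshold.
#' @param min_area Minimum object area (px^2).
#' @param gaussian_sigma Pre-smoothing sigma (px).
#' @param watershed_tolerance Minimum depth between distance-transform maxima
#'   for them to seed distinct objects (px).
#' @return Integer label matrix; 0 is background. An image with no
#'   foreground returns an all-zero map (not an error).
#' @export
segment_nuclei <- function(fov, threshold = "otsu", min_area = 60,
                           gaussian_sigma = 1.5, watershed_tolerance = 1) {
  img <- fov_channel(fov, "nuclear")
  smoothed <- matrix(EBImage::imageData(EBImage::gblur(img, sigma = gaussian_sigma)), nrow(img), ncol(img))
  thr <- if (identical(threshold, "otsu")) {
    EBImage::otsu(EBImage::Image(smoothed), range = c(0, 1))
  } else {
    check_number(threshold, "threshold")
    threshold
  }
  mask <- smoothed >= thr
  if (!any(mask)) return(matrix(0L, nrow(img), ncol(img)))
  mask <- fill_small_holes(mask, max_area = 500)
  dm <- EBImage::distmap(EBImage::Image(mask * 1))
  labels <- EBImage::watershed(dm, tolerance = watershed_tolerance)
  labels <- matrix(as.integer(EBImage::imageData(labels)), nrow(labels), ncol(labels))
  # drop undersized objects and renumber
  tab <- tabulate(labels)
  keep <- which(tab >= min_area)
  out <- matrix(0L, nrow(labels), ncol(labels))
  for (k in seq_along(keep)) out[labels == keep[k]] <- k
  out
}

#' Count nuclei in a label map
#'
#' @param nucleus_labels Integer label matrix from [segment_nuclei()].
#' @return Number of distinct nonzero labels.
#' @export
count_nuclei <- function(nucleus_labels) {
  length(setdiff(unique(as.integer(nucleus_labels)), 0L))
}

#' Euclidean distance to the nearest nucleus
#'
#' Per-pixel Euclidean distance transform of the complement of the nuclear
#' mask: pixels inside nuclei map to 0, all others to the distance to the
#' nearest nucleus pixel.
#'
#' @param nucleus_labels Integer label matrix (or logical mask).
#' @return Numeric matrix of distances (px).
#' @export
nucleus_distance_map <- function(nucleus_labels) {
  mask <- nucleus_labels > 0
  if (!any(mask)) abort("Distance map needs at least one nucleus pixel.")
  matrix(EBImage::imageData(EBImage::distmap(EBImage::Image((!mask) * 1))), nrow(mask), ncol(mask))
}
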