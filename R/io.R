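# readers/writers for the plain-text interchange formats used around the
# package; all are thin wrappers that validate the expected columns

#' Read a pH-gradient growth plate CSV
#'
#' Expects columns `replicate`, `ph`, `absorbance`.
#'
#' @param path File path.
#' @return A tibble suitable for [normalize_growth()].
#' @export
read_plate_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  check_columns(df, c("replicate", "ph", "absorbance"), "plate CSV")
  as_tibble(df)
}

#' Read raw plate-reader traces CSV
#'
#' Expects columns `well`, `time_h`, `ratio`, `o2_intensity` and optionally
#' `live_cell_signal`.
#'
#' @param path File path.
#' @return A tibble suitable for [calibrate_traces()].
#' @export
read_traces_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  check_columns(df, c("well", "time_h", "ratio", "o2_intensity"),
                "traces CSV")
  as_tibble(df)
}

#' Read a proteins-by-samples abundance TSV
#'
#' First column must hold protein identifiers; remaining columns are
#' samples. Empty cells and `NA` are treated as missing.
#'
#' @param path File path.
#' @return A numeric matrix with protein row names.
#' @export
read_abundance_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  proteins <- df[[1]]
  if (anyDuplicated(proteins)) abort("Protein identifiers must be unique.")
  mat <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- proteins
  mat
}

#' Read a sample design CSV
#'
#' Expects columns `sample`, `ph`, `o2`, `batch`.
#'
#' @param path File path.
#' @return A design tibble for [fit_factorial_anova()].
#' @export
read_design_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  check_columns(df, c("sample", "ph", "o2", "batch"), "design CSV")
  as_tibble(df)
}

#' Write / read a field of view as multi-page TIFF with a truth CSV
#'
#' One 32-bit float page per channel, page order alphabetical by channel
#' name; the particle ground truth goes to `<stem>_truth.csv` and the
#' nucleus label map to `<stem>_nuclei.tif` (16-bit).
#'
#' @param fov A `phox_fov`.
#' @param stem Output path stem (no extension).
#' @return `write_fov_tiff()` returns the paths invisibly; `read_fov_tiff()`
#'   returns a `phox_fov` (without a generating spec).
#' @export
write_fov_tiff <- function(fov, stem) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    abort("Writing TIFF requires the tiff package.")
  }
  chn <- sort(names(fov$channels))
  img_path <- paste0(stem, ".tif")
  tiff::writeTIFF(unname(fov$channels[chn]), img_path, bits.per.sample = 32)
  truth_path <- paste0(stem, "_truth.csv")
  utils::write.csv(fov$truth, truth_path, row.names = FALSE)
  lbl_path <- paste0(stem, "_nuclei.tif")
  tiff::writeTIFF(fov$nucleus_labels / 65535, lbl_path, bits.per.sample = 16)
  invisible(c(image = img_path, truth = truth_path, labels = lbl_path))
}

#' @rdname write_fov_tiff
#' @param channel_names Channel names for the pages of the image TIFF, in
#'   page order.
#' @export
read_fov_tiff <- function(stem, channel_names = c("lysosomal", "nuclear")) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    abort("Reading TIFF requires the tiff package.")
  }
  pages <- tiff::readTIFF(paste0(stem, ".tif"), all = TRUE)
  stopifnot(length(pages) == length(channel_names))
  channels <- setNames(lapply(pages, function(p) matrix(p, nrow(p), ncol(p))),
                       channel_names)
  truth <- as_tibble(utils::read.csv(paste0(stem, "_truth.csv")))
  labels <- round(tiff::readTIFF(paste0(stem, "_nuclei.tif")) * 65535)
  structure(
    list(channels = channels, truth = truth,
         nucleus_labels = matrix(as.integer(labels), nrow(labels),
                                 ncol(labels)),
         cell_mask = NULL, saturation_value = 1, spec = NULL),
    class = "phox_fov"
  )
}

#' Export / import a trained radius-intensity classifier as JSON
#'
#' @param classifier An `ri_classifier`.
#' @param path Output path.
#' @return `read_classifier_json()` returns an `ri_classifier`.
#' @export
write_classifier_json <- function(classifier, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    abort("Classifier export requires the jsonlite package.")
  }
  payload <- list(
    radius_grid = classifier$radius_grid,
    intensity_grid = classifier$intensity_grid,
    posterior = classifier$posterior,
    threshold = classifier$threshold,
    n_training = classifier$n_training,
    prior = classifier$prior,
    bandwidth = classifier$bandwidth
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_classifier_json
#' @export
read_classifier_json <- function(path) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    abort("Classifier import requires the jsonlite package.")
  }
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$posterior <- as.matrix(x$posterior)
  structure(x[c("radius_grid", "intensity_grid", "posterior", "threshold",
                "n_training", "prior", "bandwidth")],
            class = "ri_classifier")
}
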