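#' Lysosomes per cell for a field of view
#'
#' Counts accepted particles whose centers fall inside the cell-occupied
#' mask and normalizes by the number of segmented nuclei (the per-field-of-
#' view cell count). Fields with no nuclei are flagged and their statistic
#' set to `NA` so that hierarchical summaries can exclude them.
#'
#' @param particles Classified particle tibble (needs `row`, `col`,
#'   `accepted`).
#' @param cell_mask Logical matrix from [demarcate_cell_regions()].
#' @param nucleus_labels Integer label matrix from [segment_nuclei()].
#' @param fov_id Optional identifier carried into the output.
#' @return A one-row tibble: `fov`, `n_nuclei`, `n_lysosomes`,
#'   `lysosomes_per_cell`, `flagged`.
#' @export
lysosomes_per_cell <- function(particles, cell_mask, nucleus_labels,
                               fov_id = NA_character_) {
  particles <- as_tibble(particles)
  n_nuclei <- count_nuclei(nucleus_labels)
  inside <- rep(FALSE, nrow(particles))
  if (nrow(particles) > 0) {
    pr <- pmin(pmax(round(particles$row), 1), nrow(cell_mask))
    pc <- pmin(pmax(round(particles$col), 1), ncol(cell_mask))
    inside <- cell_mask[cbind(pr, pc)]
  }
  n_lyso <- sum(particles$accepted & inside, na.rm = TRUE)
  tibble(
    fov = fov_id, n_nuclei = n_nuclei, n_lysosomes = n_lyso,
    lysosomes_per_cell = if (n_nuclei > 0) n_lyso / n_nuclei else NA_real_,
    flagged = n_nuclei == 0
  )
}

#' Histogram of lysosome-to-nucleus distances
#'
#' Each accepted particle is assigned the Euclidean distance-transform value
#' at its center (0 inside a nucleus, otherwise the distance to the nearest
#' nucleus pixel). Distances are binned and the position at half-maximal
#' abundance is located on the decreasing flank to the right of the modal
#' bin, by linear interpolation between bin centers: a right-shift of this
#' marker indicates peripheral redistribution of lysosomes.
#'
#' @param particles Classified particle tibble.
#' @param nucleus_labels Integer label matrix.
#' @param binwidth Histogram bin width (px).
#' @param accepted_only Use only accepted particles (default).
#' @return A list with `histogram` (tibble `bin_mid`, `count`), `distances`
#'   (per-particle, px) and `half_max_distance` (px, `NA` when undefined).
#' @export
nucleus_distance_histogram <- function(particles, nucleus_labels,
                                       binwidth = 2, accepted_only = TRUE) {
  particles <- as_tibble(particles)
  if (accepted_only && "accepted" %in% names(particles)) {
    particles <- particles[which(particles$accepted), ]
  }
  if (nrow(particles) == 0) {
    return(list(histogram = tibble(bin_mid = numeric(0), count = integer(0)),
                distances = numeric(0), half_max_distance = NA_real_))
  }
  dm <- nucleus_distance_map(nucleus_labels)
  pr <- pmin(pmax(round(particles$row), 1), nrow(dm))
  pc <- pmin(pmax(round(particles$col), 1), ncol(dm))
  distances <- dm[cbind(pr, pc)]
  breaks <- seq(0, max(distances) + binwidth, by = binwidth)
  bin <- findInterval(distances, breaks, rightmost.closed = TRUE)
  counts <- tabulate(bin, nbins = length(breaks) - 1)
  hist <- tibble(bin_mid = breaks[-length(breaks)] + binwidth / 2,
                 count = counts)
  list(histogram = hist, distances = distances,
       half_max_distance = half_max_position(hist$bin_mid, hist$count))
}

# largest distance on the right (decreasing) flank of the mode where the
# frequency first falls to half the modal frequency, linearly interpolated
half_max_position <- function(bin_mid, count) {
  if (length(count) < 2 || max(count) == 0) return(NA_real_)
  mode_i <- which.max(count)
  half <- count[mode_i] / 2
  if (mode_i == length(count)) return(bin_mid[mode_i])
  for (j in seq(mode_i + 1, length(count))) {
    if (count[j] <= half) {
      if (count[j - 1] == count[j]) return(bin_mid[j])
      return(bin_mid[j - 1] + (count[j - 1] - half) /
               (count[j - 1] - count[j]) * (bin_mid[j] - bin_mid[j - 1]))
    }
  }
  bin_mid[length(bin_mid)]
}

#' Prune particles by mean fluorescence
#'
#' Removes particles whose mean fluorescence is strictly lower than a given
#' fraction of the saturating signal. A particle at exactly the cutoff is
#' kept.
#'
#' @param particles Particle tibble with `mean_intensity` as a fraction of
#'   saturation.
#' @param prune_fraction Fraction of saturation below which particles are
#'   discarded.
#' @param saturation_value Saturating signal that `mean_intensity` is
#'   expressed against, when intensities are not already fractions.
#' @return The filtered tibble.
#' @export
prune_particles <- function(particles, prune_fraction = 0.15,
                            saturation_value = 1) {
  if (is.null(saturation_value) || !is.finite(saturation_value)) {
    abort("`saturation_value` is required to prune on fractional intensity.")
  }
  particles <- as_tibble(particles)
  particles[particles$mean_intensity / saturation_value >= prune_fraction, ]
}

#' Cathepsin-activity particle count per cell
#'
#' Detects circular particles in a fluorogenic-substrate activity channel
#' using the lysosome radius window, prunes particles whose mean
#' fluorescence is lower than `prune_fraction` of the saturating signal, and
#' reports the count per segmented cell.
#'
#' @param fov A `phox_fov` (must carry `saturation_value`) or numeric matrix.
#' @param cell_mask,nucleus_labels Segmentation inputs as in
#'   [lysosomes_per_cell()].
#' @param channel Name of the activity channel.
#' @param radius_range Lysosome radius window (px).
#' @param prune_fraction Pruning cutoff as a fraction of saturation.
#' @param ... Further arguments passed to [detect_candidates()].
#' @return A one-row tibble: `fov`, `n_nuclei`, `n_particles`,
#'   `particles_per_cell`, `flagged`.
#' @export
magic_red_count <- function(fov, cell_mask, nucleus_labels,
                            channel = "activity", radius_range = c(2, 10),
                            prune_fraction = 0.15, ...) {
  saturation <- if (is.matrix(fov)) 1 else fov$saturation_value
  if (is.null(saturation)) {
    abort("`saturation_value` missing from the field of view.")
  }
  cand <- detect_candidates(fov, channel = channel,
                            radius_range = radius_range, ...)
  kept <- prune_particles(cand, prune_fraction, saturation)
  kept$accepted <- TRUE
  stats <- lysosomes_per_cell(kept, cell_mask, nucleus_labels)
  tibble(fov = stats$fov, n_nuclei = stats$n_nuclei,
         n_particles = stats$n_lysosomes,
         particles_per_cell = stats$lysosomes_per_cell,
         flagged = stats$flagged)
}

#' Run the full lysosome pipeline on one field of view
#'
#' Convenience wrapper: demarcate cell regions, segment nuclei, detect and
#' classify particles, and compute per-field statistics.
#'
#' @param fov A `phox_fov`.
#' @param classifier A trained `ri_classifier`.
#' @param fov_id Identifier for the output rows.
#' @param ... Passed to [detect_candidates()].
#' @return A list with `particles`, `summary` (from [lysosomes_per_cell()]),
#'   `distance` (from [nucleus_distance_histogram()]), `cell_mask`,
#'   `nucleus_labels`.
#' @export
analyze_fov <- function(fov, classifier, fov_id = "fov1", ...) {
  cell_mask <- demarcate_cell_regions(fov)
  labels <- segment_nuclei(fov)
  particles <- detect_candidates(fov, ...)
  particles <- classify_particles(particles, classifier)
  summary <- lysosomes_per_cell(particles, cell_mask, labels, fov_id)
  distance <- if (count_nuclei(labels) > 0 && any(particles$accepted)) {
    nucleus_distance_histogram(particles, labels)
  } else {
    list(histogram = tibble(bin_mid = numeric(0), count = integer(0)),
         distances = numeric(0), half_max_distance = NA_real_)
  }
  list(particles = particles, summary = summary, distance = distance,
       cell_mask = cell_mask, nucleus_labels = labels)
}
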