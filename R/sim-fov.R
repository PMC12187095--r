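#' Specification for a synthetic fluorescence field of view
#'
#' Renders a two-channel field of view emulating live-cell lysosome imaging:
#' a nuclear channel with soft-edged nuclear blobs, and a lysosomal channel
#' with a cytoplasmic background plus punctate particles rendered as radially
#' decaying (Gaussian-profile) disks with `sigma = radius / 2`, so the
#' nominal truth radius is the distance at which a punctum falls to
#' `exp(-2)` (about 13.5%) of its peak. Decoy particles (dim artefacts) can
#' be added for classifier training. All intensities are fractions of
#' saturation in `[0, 1]`.
#'
#' @param image_shape Image size, `c(rows, cols)` in pixels.
#' @param n_nuclei Number of nuclei to place.
#' @param nucleus_radius_px `c(mean, sd)` of nucleus radii (px).
#' @param cell_radius_factor Cell (cytoplasm) radius as a multiple of the
#'   nucleus radius; puncta are placed in the annulus between nucleus edge
#'   and cell edge.
#' @param puncta_per_cell Mean of the Poisson count of lysosomes per cell.
#' @param lysosome_radius_px Radius distribution,
#'   `list(min, max, shape1, shape2)` for a scaled Beta; support must lie in
#'   strictly positive territory (default 2-10 px).
#' @param lysosome_intensity Peak-intensity distribution `list(min, max)`
#'   (uniform, as a fraction of saturation).
#' @param decoy_particle_spec Same fields for decoys plus `n_mean` (Poisson
#'   mean per field of view); `NULL` for no decoys.
#' @param peripheral_bias In `[0, 1]`: puncta are placed at a radial fraction
#'   of the nucleus-to-cell-edge annulus drawn from a Beta distribution whose
#'   mean shifts outward as the bias rises (mean `0.25 + 0.5 * bias`).
#' @param background_level Cytoplasmic background on the lysosomal channel.
#' @param noise_sd Additive Gaussian noise SD (intensity fraction), applied
#'   to both channels.
#' @param nucleus_centers Optional matrix of `(row, col)` centers overriding
#'   random placement (used to construct touching-nuclei test cases).
#' @param seed Integer seed; fully determines the output.
#' @return A `fov_spec` object.
#' @export
fov_spec <- function(image_shape = c(256, 256),
                     n_nuclei = 8,
                     nucleus_radius_px = c(12, 1.5),
                     cell_radius_factor = 2.8,
                     puncta_per_cell = 12,
                     lysosome_radius_px = list(min = 2, max = 10,
                                               shape1 = 1.5, shape2 = 6),
                     lysosome_intensity = list(min = 0.4, max = 0.9),
                     decoy_particle_spec = list(n_mean = 10, min = 2, max = 10,
                                                shape1 = 1.5, shape2 = 6,
                                                int_min = 0.06, int_max = 0.25),
                     peripheral_bias = 0.3,
                     background_level = 0.08,
                     noise_sd = 0.02,
                     nucleus_centers = NULL,
                     seed = 1) {
  stopifnot(length(image_shape) == 2, all(image_shape >= 32))
  check_number(n_nuclei, "n_nuclei", lower = 0)
  stopifnot(length(nucleus_radius_px) == 2, nucleus_radius_px[1] > 0)
  check_number(cell_radius_factor, "cell_radius_factor", lower = 1)
  check_number(puncta_per_cell, "puncta_per_cell", lower = 0)
  if (lysosome_radius_px$min <= 0) {
    abort("Lysosome radius distribution must have strictly positive support.")
  }
  if (lysosome_radius_px$min >= lysosome_radius_px$max) {
    abort("Lysosome radius support must satisfy min < max.")
  }
  check_number(peripheral_bias, "peripheral_bias", lower = 0, upper = 1)
  check_number(background_level, "background_level", lower = 0, upper = 1)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(seed, "seed")
  structure(
    list(image_shape = as.integer(image_shape), n_nuclei = as.integer(n_nuclei),
         nucleus_radius_px = nucleus_radius_px,
         cell_radius_factor = cell_radius_factor,
         puncta_per_cell = puncta_per_cell,
         lysosome_radius_px = lysosome_radius_px,
         lysosome_intensity = lysosome_intensity,
         decoy_particle_spec = decoy_particle_spec,
         peripheral_bias = peripheral_bias,
         background_level = background_level, noise_sd = noise_sd,
         nucleus_centers = nucleus_centers, seed = seed),
    class = "fov_spec"
  )
}

# add a Gaussian-profile disk to `img` in place; returns the image
render_punctum <- function(img, row, col, radius, peak) {
  sigma <- radius / 2
  ext <- ceiling(radius * 1.8)
  nr <- nrow(img); nc <- ncol(img)
  r0 <- max(1, floor(row - ext)); r1 <- min(nr, ceiling(row + ext))
  c0 <- max(1, floor(col - ext)); c1 <- min(nc, ceiling(col + ext))
  rr <- r0:r1; cc <- c0:c1
  d2 <- outer((rr - row)^2, (cc - col)^2, `+`)
  img[rr, cc] <- img[rr, cc] + peak * exp(-d2 / (2 * sigma^2))
  img
}

# soft-edged disk (logistic edge, ~1 px wide)
render_blob <- function(img, row, col, radius, level) {
  ext <- ceiling(radius + 4)
  nr <- nrow(img); nc <- ncol(img)
  r0 <- max(1, floor(row - ext)); r1 <- min(nr, ceiling(row + ext))
  c0 <- max(1, floor(col - ext)); c1 <- min(nc, ceiling(col + ext))
  rr <- r0:r1; cc <- c0:c1
  d <- sqrt(outer((rr - row)^2, (cc - col)^2, `+`))
  img[rr, cc] <- pmin(1, img[rr, cc] + level / (1 + exp(2 * (d - radius))))
  img
}

place_nuclei <- function(spec) {
  if (!is.null(spec$nucleus_centers)) {
    stopifnot(nrow(spec$nucleus_centers) == spec$n_nuclei)
    return(spec$nucleus_centers)
  }
  sh <- spec$image_shape
  r_mean <- spec$nucleus_radius_px[1]
  margin <- r_mean * spec$cell_radius_factor * 0.7
  min_sep <- 2.6 * r_mean
  centers <- matrix(numeric(0), ncol = 2)
  tries <- 0
  while (nrow(centers) < spec$n_nuclei) {
    tries <- tries + 1
    if (tries > 4000) {
      abort(sprintf(
        "Could not place %d nuclei of mean radius %.1f px in a %d x %d image (minimum separation %.1f px).",
        spec$n_nuclei, r_mean, sh[1], sh[2], min_sep))
    }
    cand <- c(runif(1, margin, sh[1] - margin), runif(1, margin, sh[2] - margin))
    if (nrow(centers) == 0 ||
        min(sqrt(rowSums((centers - rep(cand, each = nrow(centers)))^2))) >
        min_sep) {
      centers <- rbind(centers, cand)
    }
  }
  centers
}

#' Simulate a synthetic field of view with ground truth
#'
#' @param spec A [fov_spec()].
#' @return A `phox_fov` object: list with `channels` (named list of numeric
#'   matrices `nuclear`, `lysosomal`), `truth` (tibble: `row`, `col`,
#'   `radius`, `peak_intensity`, `class` = `"lysosome"`/`"decoy"`,
#'   `cell_id`), `nucleus_labels` (integer matrix), `cell_mask` (logical
#'   matrix of the rendered cell footprint), `saturation_value` (1) and
#'   `spec`.
#' @examples
#' fov <- sim_fov(fov_spec(n_nuclei = 3, seed = 11))
#' nrow(fov$truth)
#' @export
sim_fov <- function(spec) {
  stopifnot(inherits(spec, "fov_spec"))
  sh <- spec$image_shape
  with_seed(spec$seed, {
    centers <- place_nuclei(spec)
    n_nuc <- nrow(centers)
    nuc_r <- pmax(3, rnorm(n_nuc, spec$nucleus_radius_px[1],
                           spec$nucleus_radius_px[2]))
    nuclear <- matrix(0, sh[1], sh[2])
    labels <- matrix(0L, sh[1], sh[2])
    cell_mask <- matrix(FALSE, sh[1], sh[2])
    row_idx <- matrix(seq_len(sh[1]), sh[1], sh[2])
    col_idx <- matrix(seq_len(sh[2]), sh[1], sh[2], byrow = TRUE)
    for (i in seq_len(n_nuc)) {
      nuclear <- render_blob(nuclear, centers[i, 1], centers[i, 2],
                             nuc_r[i], 0.85)
      d <- sqrt((row_idx - centers[i, 1])^2 + (col_idx - centers[i, 2])^2)
      labels[d <= nuc_r[i] & labels == 0L] <- i
      cell_mask <- cell_mask | (d <= nuc_r[i] * spec$cell_radius_factor)
    }
    lysosomal <- matrix(0, sh[1], sh[2])
    lysosomal[cell_mask] <- spec$background_level
    truth <- list()
    for (i in seq_len(n_nuc)) {
      n_p <- rpois(1, spec$puncta_per_cell)
      if (n_p == 0) next
      rd <- spec$lysosome_radius_px
      radius <- rbeta_scaled(n_p, rd$min, rd$max, rd$shape1, rd$shape2)
      peak <- runif(n_p, spec$lysosome_intensity$min,
                    spec$lysosome_intensity$max)
      mu <- 0.25 + 0.5 * spec$peripheral_bias
      # sequential placement with a minimum separation: lysosomes are solid
      # organelles and cannot interpenetrate; puncta that cannot be placed
      # after several tries are skipped (truth records rendered puncta only)
      placed <- dplyr::bind_rows(truth)
      prow <- pcol <- numeric(0)
      kept <- integer(0)
      for (j in seq_len(n_p)) {
        for (try in 1:40) {
          frac <- rbeta(1, mu * 4, (1 - mu) * 4)
          ang <- runif(1, 0, 2 * pi)
          rad_pos <- nuc_r[i] + 2 + frac *
            (nuc_r[i] * spec$cell_radius_factor - nuc_r[i] - 4 - radius[j])
          cr <- min(max(centers[i, 1] + rad_pos * sin(ang), 2), sh[1] - 1)
          cc <- min(max(centers[i, 2] + rad_pos * cos(ang), 2), sh[2] - 1)
          ok <- nrow(placed) == 0 ||
            all(sqrt((placed$row - cr)^2 + (placed$col - cc)^2) >
                  0.7 * (placed$radius + radius[j]))
          if (ok) {
            prow <- c(prow, cr); pcol <- c(pcol, cc); kept <- c(kept, j)
            placed <- dplyr::bind_rows(placed,
                                       tibble(row = cr, col = cc,
                                              radius = radius[j]))
            break
          }
        }
      }
      if (length(kept) == 0) next
      for (j in seq_along(kept)) {
        lysosomal <- render_punctum(lysosomal, prow[j], pcol[j],
                                    radius[kept[j]], peak[kept[j]])
      }
      truth[[length(truth) + 1]] <- tibble(
        row = prow, col = pcol, radius = radius[kept],
        peak_intensity = peak[kept], class = "lysosome", cell_id = i
      )
    }
    dspec <- spec$decoy_particle_spec
    if (!is.null(dspec) && n_nuc > 0) {
      n_d <- rpois(1, dspec$n_mean)
      if (n_d > 0) {
        in_cell <- which(cell_mask)
        pick <- sample(in_cell, n_d, replace = TRUE)
        drow <- row_idx[pick]; dcol <- col_idx[pick]
        dradius <- rbeta_scaled(n_d, dspec$min, dspec$max,
                                dspec$shape1, dspec$shape2)
        dpeak <- runif(n_d, dspec$int_min, dspec$int_max)
        for (j in seq_len(n_d)) {
          lysosomal <- render_punctum(lysosomal, drow[j], dcol[j],
                                      dradius[j], dpeak[j])
        }
        truth[[length(truth) + 1]] <- tibble(
          row = drow, col = dcol, radius = dradius, peak_intensity = dpeak,
          class = "decoy", cell_id = NA_integer_
        )
      }
    }
    truth <- if (length(truth) > 0) dplyr::bind_rows(truth) else
      tibble(row = numeric(0), col = numeric(0), radius = numeric(0),
             peak_intensity = numeric(0), class = character(0),
             cell_id = integer(0))
    nuclear <- pmin(1, pmax(0, nuclear + rnorm(length(nuclear),
                                               sd = spec$noise_sd)))
    lysosomal <- pmin(1, pmax(0, lysosomal + rnorm(length(lysosomal),
                                                   sd = spec$noise_sd)))
    structure(
      list(channels = list(nuclear = matrix(nuclear, sh[1], sh[2]),
                           lysosomal = matrix(lysosomal, sh[1], sh[2])),
           truth = truth, nucleus_labels = labels, cell_mask = cell_mask,
           saturation_value = 1, spec = spec),
      class = "phox_fov"
    )
  })
}

#' @export
print.phox_fov <- function(x, ...) {
  cat(sprintf("Synthetic field of view %d x %d: %d nuclei, %d particles (%d lysosomes, %d decoys)\n",
              nrow(x$channels$nuclear), ncol(x$channels$nuclear),
              x$spec$n_nuclei, nrow(x$truth),
              sum(x$truth$class == "lysosome"),
              sum(x$truth$class == "decoy")))
  invisible(x)
}
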