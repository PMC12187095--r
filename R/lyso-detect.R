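# central-difference gradients of a matrix image (returns list gx, gy, mag);
# gx is the derivative along rows, gy along columns, so the gradient vector
# points uphill (into bright particles)
image_gradient <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  gx <- matrix(0, nr, nc)
  gy <- matrix(0, nr, nc)
  gx[2:(nr - 1), ] <- (img[3:nr, ] - img[1:(nr - 2), ]) / 2
  gy[, 2:(nc - 1)] <- (img[, 3:nc] - img[, 1:(nc - 2)]) / 2
  list(gx = gx, gy = gy, mag = sqrt(gx^2 + gy^2))
}

# circularly averaged intensity profile around (row, col)
radial_profile <- function(img, row, col, max_d) {
  nr <- nrow(img); nc <- ncol(img)
  ext <- ceiling(max_d)
  r0 <- max(1, floor(row - ext)); r1 <- min(nr, ceiling(row + ext))
  c0 <- max(1, floor(col - ext)); c1 <- min(nc, ceiling(col + ext))
  rr <- r0:r1; cc <- c0:c1
  d <- sqrt(outer((rr - row)^2, (cc - col)^2, `+`))
  bin <- floor(d) + 1L
  ok <- bin <= ext
  prof <- tapply(img[rr, cc][ok], bin[ok], mean)
  out <- rep(NA_real_, ext)
  out[as.integer(names(prof))] <- prof
  out   # out[k] = mean intensity at distances [k-1, k)
}

# radius at which the profile decays to exp(-2) of its peak above local
# background -- consistent with the Gaussian-profile radius convention
refine_radius <- function(img, row, col, rough_r) {
  prof <- radial_profile(img, row, col, max_d = rough_r * 2.2 + 2)
  prof <- prof[!is.na(prof)]
  if (length(prof) < 3) return(rough_r)
  peak <- prof[1]
  bg <- min(prof)
  level <- bg + (peak - bg) * exp(-2)
  d <- seq_along(prof) - 0.5
  below <- which(prof <= level)
  below <- below[below > 1]
  if (length(below) == 0) return(rough_r)
  j <- below[1]
  if (prof[j - 1] == prof[j]) return(d[j])
  d[j - 1] + (prof[j - 1] - level) / (prof[j - 1] - prof[j]) *
    (d[j] - d[j - 1])
}

#' Detect circular particles with a two-stage circular Hough transform
#'
#' Stage one: edge pixels (Sobel gradient magnitude above `min_gradient`)
#' vote along their gradient direction into an accumulator indexed by center
#' and radius; because puncta have a radially decaying Gaussian profile with
#' `sigma = radius / 2`, the gradient-maximum ring of a particle of nominal
#' radius `r` sits at `edge_scale * r` (default 0.5), and votes are cast at
#' that offset. Stage two: accumulator peaks above `sensitivity` become
#' candidates; their centers are refined to the local intensity centroid,
#' radii re-estimated from the circularly averaged intensity profile (the
#' distance at which it decays to `exp(-2)` of its peak, matching the same
#' convention), mean disk intensity measured, and a circularity score
#' computed as the fraction of perimeter directions with supra-threshold
#' gradient support. Duplicates within one radius of a stronger peak are
#' merged; candidates with circularity below `1 - circularity_tolerance` or
#' refined radius outside `radius_range` are dropped.
#'
#' @param fov A `phox_fov` or numeric matrix; intensities as fractions of
#'   saturation.
#' @param channel Channel to detect in.
#' @param radius_range Nominal radius acceptance window (px), default 2-10.
#' @param circularity_tolerance Allowed departure from perfect circularity
#'   (target score 1.0).
#' @param sensitivity Minimum normalized accumulator support (votes per unit
#'   circumference) for a peak to be kept; lower is more permissive.
#' @param edge_scale Ratio of the gradient-maximum ring radius to the nominal
#'   particle radius (0.5 for Gaussian-profile particles; 1 for hard disks).
#' @param min_gradient Absolute gradient-magnitude threshold defining edge
#'   pixels (intensity fraction per px).
#' @return A tibble of candidates: `row`, `col`, `radius`, `mean_intensity`,
#'   `circularity`, `score`, `accepted` (`NA` until classified).
#' @examples
#' fov <- sim_fov(fov_spec(n_nuclei = 2, puncta_per_cell = 5, seed = 5))
#' detect_candidates(fov)
#' @export
detect_candidates <- function(fov, channel = "lysosomal",
                              radius_range = c(2, 10),
                              circularity_tolerance = 0.35,
                              sensitivity = 1.6,
                              edge_scale = 0.5,
                              min_gradient = 0.02) {
  img <- fov_channel(fov, channel)
  nr <- nrow(img); nc <- ncol(img)
  if (radius_range[1] < 1 || radius_range[2] > min(nr, nc) / 2) {
    abort("`radius_range` is outside the scale of the image.")
  }
  smoothed <- matrix(EBImage::imageData(EBImage::gblur(img, sigma = 1)), nrow(img), ncol(img))
  g <- image_gradient(smoothed)
  edge <- which(g$mag >= min_gradient)
  empty <- tibble(row = numeric(0), col = numeric(0), radius = numeric(0),
                  mean_intensity = numeric(0), circularity = numeric(0),
                  score = numeric(0), accepted = logical(0))
  if (length(edge) == 0) return(empty)
  er <- (edge - 1L) %% nr + 1L
  ec <- (edge - 1L) %/% nr + 1L
  ux <- g$gx[edge] / g$mag[edge]
  uy <- g$gy[edge] / g$mag[edge]

  radii <- seq(radius_range[1], radius_range[2], by = 1)
  offsets <- radii * edge_scale
  box3_sum <- function(m) {
    out <- matrix(0, nr, nc)
    for (dr in -1:1) for (dc in -1:1) {
      rs <- max(1, 1 + dr):min(nr, nr + dr)
      cs <- max(1, 1 + dc):min(nc, nc + dc)
      out[rs, cs] <- out[rs, cs] + m[rs - dr, cs - dc]
    }
    out
  }
  best_score <- matrix(0, nr, nc)
  best_r <- matrix(0, nr, nc)
  for (k in seq_along(offsets)) {
    rho <- offsets[k]
    vr <- round(er + rho * ux)
    vc <- round(ec + rho * uy)
    ok <- vr >= 1 & vr <= nr & vc >= 1 & vc <= nc
    acc <- matrix(0, nr, nc)
    idx <- (vc[ok] - 1L) * nr + vr[ok]
    tab <- tabulate(idx, nbins = nr * nc)
    acc[] <- tab
    score <- box3_sum(acc) / (2 * pi * rho)
    better <- score > best_score
    best_score[better] <- score[better]
    best_r[better] <- radii[k]
  }

  # local maxima of the collapsed score map
  shift_max <- matrix(-Inf, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    shifted <- matrix(-Inf, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    shifted[rs, cs] <- best_score[rs - dr, cs - dc]
    shift_max <- pmax(shift_max, shifted)
  }
  peaks <- which(best_score >= sensitivity & best_score >= shift_max)
  if (length(peaks) == 0) return(empty)
  pr <- (peaks - 1L) %% nr + 1L
  pc <- (peaks - 1L) %/% nr + 1L
  cand <- tibble(row = as.numeric(pr), col = as.numeric(pc),
                 rough_r = best_r[peaks], score = best_score[peaks])
  cand <- dplyr::arrange(cand, dplyr::desc(.data$score))

  # greedy merge: drop peaks within one radius of a stronger kept peak
  keep <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!keep[i]) next
    if (i < nrow(cand)) {
      later <- (i + 1):nrow(cand)
      d <- sqrt((cand$row[later] - cand$row[i])^2 +
                  (cand$col[later] - cand$col[i])^2)
      tooclose <- d < pmax(cand$rough_r[later], cand$rough_r[i])
      keep[later[tooclose]] <- FALSE
    }
  }
  cand <- cand[keep, ]

  grad_thr <- min_gradient
  out <- purrr::pmap(cand, function(row, col, rough_r, score) {
    # centroid refinement over the core of the particle
    rad0 <- max(1.5, rough_r * edge_scale)
    rr <- max(1, floor(row - rad0)):min(nr, ceiling(row + rad0))
    cc <- max(1, floor(col - rad0)):min(nc, ceiling(col + rad0))
    d2 <- outer((rr - row)^2, (cc - col)^2, `+`)
    wpatch <- pmax(0, smoothed[rr, cc] - min(smoothed[rr, cc]))
    wpatch[d2 > rad0^2] <- 0
    if (sum(wpatch) > 0) {
      row <- sum(outer(rr, rep(1, length(cc))) * wpatch) / sum(wpatch)
      col <- sum(outer(rep(1, length(rr)), cc) * wpatch) / sum(wpatch)
    }
    radius <- refine_radius(smoothed, row, col, rough_r)
    # perimeter gradient support at the gradient-maximum ring
    rho <- radius * edge_scale
    ang <- seq(0, 2 * pi, length.out = 25)[-25]
    support <- vapply(ang, function(a) {
      # supra-threshold gradient pointing back at the center counts as
      # perimeter evidence for this circle
      hit <- FALSE
      for (drho in c(-1, 0, 1)) {
        sr <- round(row + (rho + drho) * cos(a))
        sc <- round(col + (rho + drho) * sin(a))
        if (sr >= 1 && sr <= nr && sc >= 1 && sc <= nc &&
            g$mag[sr, sc] >= grad_thr) {
          inward <- -(g$gx[sr, sc] * cos(a) + g$gy[sr, sc] * sin(a)) /
            g$mag[sr, sc]
          if (inward >= 0.5) hit <- TRUE
        }
      }
      hit
    }, logical(1))
    circ <- mean(support)
    # mean intensity over the nominal disk, as a fraction of saturation
    rr2 <- max(1, floor(row - radius)):min(nr, ceiling(row + radius))
    cc2 <- max(1, floor(col - radius)):min(nc, ceiling(col + radius))
    dd <- outer((rr2 - row)^2, (cc2 - col)^2, `+`) <= radius^2
    mi <- mean(img[rr2, cc2][dd])
    tibble(row = row, col = col, radius = radius, mean_intensity = mi,
           circularity = circ, score = score)
  }) |> dplyr::bind_rows()

  out <- dplyr::filter(
    out,
    .data$radius >= radius_range[1], .data$radius <= radius_range[2],
    .data$circularity >= 1 - circularity_tolerance
  )
  out$accepted <- NA
  out
}
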