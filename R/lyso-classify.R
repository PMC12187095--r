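#' Train the radius-intensity lysosome classifier
#'
#' Builds a posterior-probability surface over (radius, mean intensity) from
#' annotated particles: each class's 2-D distribution is estimated by a
#' kernel-smoothed density (normal kernels, plug-in bandwidth) on a common
#' grid, combined with class priors taken from the training frequencies. A
#' particle is later accepted as a bona fide lysosome where the posterior
#' probability of the lysosome class reaches `threshold` (default the 50%
#' probability level).
#'
#' @param annotated A data frame with columns `radius`, `mean_intensity` and
#'   logical `is_lysosome`. Both classes must be present; a training set
#'   below `min_training` rows triggers a warning (training to convergence
#'   typically needs thousands of inspected particles).
#' @param threshold Posterior level defining acceptance.
#' @param grid_n Grid resolution per axis.
#' @param bandwidth Optional `c(radius, intensity)` kernel bandwidths;
#'   defaults to the normal-reference plug-in rule per class, averaged.
#' @param min_training Advisory floor on the number of annotations.
#' @return An `ri_classifier`: list with `radius_grid`, `intensity_grid`,
#'   `posterior` (matrix, probability of lysosome), `threshold`,
#'   `n_training`, `prior`. Supports `predict()` and [autoplot()].
#' @examples
#' ann <- tibble::tibble(
#'   radius = c(rnorm(50, 4), rnorm(50, 4)),
#'   mean_intensity = c(rnorm(50, 0.4, 0.05), rnorm(50, 0.1, 0.05)),
#'   is_lysosome = rep(c(TRUE, FALSE), each = 50)
#' )
#' clf <- train_radius_intensity_classifier(ann)
#' @export
train_radius_intensity_classifier <- function(annotated, threshold = 0.5,
                                              grid_n = 96, bandwidth = NULL,
                                              min_training = 200) {
  annotated <- as_tibble(annotated)
  check_columns(annotated, c("radius", "mean_intensity", "is_lysosome"),
                "annotated")
  pos <- annotated[annotated$is_lysosome, ]
  neg <- annotated[!annotated$is_lysosome, ]
  if (nrow(pos) == 0 || nrow(neg) == 0) {
    abort("Training requires annotated examples of both classes.")
  }
  if (nrow(annotated) < min_training) {
    warn(sprintf("Only %d annotated particles; the probability map may be unstable (recommend >= %d).",
                 nrow(annotated), min_training))
  }
  check_number(threshold, "threshold", lower = 0, upper = 1)
  rx <- range(annotated$radius)
  ry <- range(annotated$mean_intensity)
  pad_x <- 0.15 * diff(rx) + 1e-6
  pad_y <- 0.15 * diff(ry) + 1e-6
  lims <- c(rx[1] - pad_x, rx[2] + pad_x, ry[1] - pad_y, ry[2] + pad_y)
  bw <- bandwidth %||% c(
    mean(c(MASS::bandwidth.nrd(pos$radius), MASS::bandwidth.nrd(neg$radius))),
    mean(c(MASS::bandwidth.nrd(pos$mean_intensity),
           MASS::bandwidth.nrd(neg$mean_intensity)))
  )
  bw[bw <= 0] <- c(diff(rx), diff(ry))[bw <= 0] / 10 + 1e-6
  d_pos <- MASS::kde2d(pos$radius, pos$mean_intensity, h = bw, n = grid_n,
                       lims = lims)
  d_neg <- MASS::kde2d(neg$radius, neg$mean_intensity, h = bw, n = grid_n,
                       lims = lims)
  prior <- nrow(pos) / nrow(annotated)
  post <- prior * d_pos$z / (prior * d_pos$z + (1 - prior) * d_neg$z)
  post[!is.finite(post)] <- 0
  structure(
    list(radius_grid = d_pos$x, intensity_grid = d_pos$y, posterior = post,
         threshold = threshold, n_training = nrow(annotated), prior = prior,
         bandwidth = bw),
    class = "ri_classifier"
  )
}

# bilinear interpolation of the posterior surface; points outside the grid
# clamp to the nearest edge
posterior_at <- function(clf, radius, intensity) {
  gx <- clf$radius_grid; gy <- clf$intensity_grid
  x <- pmin(pmax(radius, gx[1]), gx[length(gx)])
  y <- pmin(pmax(intensity, gy[1]), gy[length(gy)])
  ix <- pmin(findInterval(x, gx), length(gx) - 1)
  iy <- pmin(findInterval(y, gy), length(gy) - 1)
  tx <- (x - gx[ix]) / (gx[ix + 1] - gx[ix])
  ty <- (y - gy[iy]) / (gy[iy + 1] - gy[iy])
  z <- clf$posterior
  z[cbind(ix, iy)] * (1 - tx) * (1 - ty) +
    z[cbind(ix + 1, iy)] * tx * (1 - ty) +
    z[cbind(ix, iy + 1)] * (1 - tx) * ty +
    z[cbind(ix + 1, iy + 1)] * tx * ty
}

#' @export
print.ri_classifier <- function(x, ...) {
  cat(sprintf("Radius-intensity classifier: %d training particles (%.0f%% lysosome), acceptance at posterior >= %.2f\n",
              x$n_training, 100 * x$prior, x$threshold))
  invisible(x)
}

#' @export
predict.ri_classifier <- function(object, newdata, ...) {
  check_columns(newdata, c("radius", "mean_intensity"), "newdata")
  posterior_at(object, newdata$radius, newdata$mean_intensity)
}

#' @rdname train_radius_intensity_classifier
#' @param object An `ri_classifier`.
#' @param ... Unused.
#' @export
autoplot.ri_classifier <- function(object, ...) {
  df <- tidyr::expand_grid(i = seq_along(object$radius_grid),
                           j = seq_along(object$intensity_grid))
  df$radius <- object$radius_grid[df$i]
  df$mean_intensity <- object$intensity_grid[df$j]
  df$posterior <- object$posterior[cbind(df$i, df$j)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$radius,
                                   y = .data$mean_intensity)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$posterior)) +
    ggplot2::geom_contour(ggplot2::aes(z = .data$posterior),
                          breaks = object$threshold, colour = "green") +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "radius (px)", y = "mean intensity (fraction)",
                  fill = "P(lysosome)") +
    ggplot2::theme_minimal()
}

#' Classify detected particles with a trained classifier
#'
#' Sets `accepted` to `TRUE` where the posterior probability of the lysosome
#' class at (radius, mean intensity) reaches the classifier threshold.
#'
#' @param candidates Tibble from [detect_candidates()].
#' @param classifier An `ri_classifier`.
#' @return The candidates tibble with `posterior` and `accepted` filled in.
#' @export
classify_particles <- function(candidates, classifier) {
  stopifnot(inherits(classifier, "ri_classifier"))
  candidates <- as_tibble(candidates)
  if (nrow(candidates) == 0) {
    candidates$posterior <- numeric(0)
    candidates$accepted <- logical(0)
    return(candidates)
  }
  candidates$posterior <- posterior_at(classifier, candidates$radius,
                                       candidates$mean_intensity)
  candidates$accepted <- candidates$posterior >= classifier$threshold
  candidates
}
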