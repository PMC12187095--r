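test_that("cell demarcation thresholds the smoothed background", {
  # blank image -> empty mask, with a warning when threshold is unreachable
  blank <- matrix(0.005, 128, 128)
  expect_warning(m <- demarcate_cell_regions(blank,
                                             background_threshold = 0.5),
                 "empty")
  expect_false(any(m))

  # pixels strictly below threshold (after smoothing) are never in the mask
  fov <- sim_fov(fov_spec(seed = 3))
  mask <- demarcate_cell_regions(fov)
  smoothed <- as.matrix(EBImage::gblur(fov$channels$lysosomal, 3))
  outside_holes <- phoxcell:::fill_small_holes(smoothed >= 0.04, 400)
  expect_true(all(mask == outside_holes))

  # and the mask overlaps the generator's cell footprint well
  iou <- sum(mask & fov$cell_mask) / sum(mask | fov$cell_mask)
  expect_gte(iou, 0.8)
})

test_that("nuclear segmentation counts and splits nuclei", {
  # single blob -> one label
  one <- matrix(0, 96, 96)
  one <- phoxcell:::render_blob(one, 48, 48, 12, 0.85)
  expect_equal(count_nuclei(segment_nuclei(one)), 1)

  # no foreground -> zero labels, not an error
  expect_equal(count_nuclei(segment_nuclei(matrix(0, 64, 64),
                                           threshold = 0.5)), 0)

  # two overlapping nuclei (centers 1.5 radii apart) are split by watershed
  sp <- fov_spec(n_nuclei = 2,
                 nucleus_centers = matrix(c(120, 120, 120, 138), 2, 2,
                                          byrow = TRUE),
                 puncta_per_cell = 0, decoy_particle_spec = NULL, seed = 1)
  expect_equal(count_nuclei(segment_nuclei(sim_fov(sp))), 2)

  # over 20 synthetic fields the mean relative count error is <= 5%
  errs <- sapply(1:20, function(s) {
    fov <- sim_fov(fov_spec(seed = 100 + s))
    abs(count_nuclei(segment_nuclei(fov)) - fov$spec$n_nuclei) /
      fov$spec$n_nuclei
  })
  expect_lte(mean(errs), 0.05)
})

test_that("Hough detection finds isolated disks with px-level accuracy", {
  # zero-puncta image -> no candidates
  expect_equal(nrow(detect_candidates(matrix(0, 64, 64))), 0)

  # one rendered disk: one candidate, center within 1 px, radius within 1 px
  img <- matrix(0, 64, 64)
  img <- phoxcell:::render_punctum(img, 32, 30, 4, 0.8)
  cand <- detect_candidates(img)
  expect_equal(nrow(cand), 1)
  expect_lt(abs(cand$row - 32), 1)
  expect_lt(abs(cand$col - 30), 1)
  expect_lt(abs(cand$radius - 4), 1)

  # radii outside the acceptance window are not returned
  img2 <- matrix(0, 96, 96)
  img2 <- phoxcell:::render_punctum(img2, 25, 25, 1, 0.8)
  img2 <- phoxcell:::render_punctum(img2, 60, 60, 15, 0.8)
  cand2 <- detect_candidates(img2, radius_range = c(2, 10))
  expect_true(all(cand2$radius >= 2 & cand2$radius <= 10))
  if (nrow(cand2) > 0) {
    # nothing may be reported at the true out-of-range locations/radii
    d1 <- sqrt((cand2$row - 25)^2 + (cand2$col - 25)^2)
    expect_true(all(d1 > 2 | abs(cand2$radius - 1) > 0.9))
  }

  expect_error(detect_candidates(matrix(0, 32, 32),
                                 radius_range = c(2, 40)),
               "radius_range")
})

test_that("detection is translation-equivariant away from borders", {
  base <- matrix(0, 96, 96)
  base <- phoxcell:::render_punctum(base, 40, 36, 4, 0.7)
  base <- phoxcell:::render_punctum(base, 60, 62, 3, 0.6)
  shifted <- matrix(0, 96, 96)
  shifted <- phoxcell:::render_punctum(shifted, 40 + 7, 36 + 5, 4, 0.7)
  shifted <- phoxcell:::render_punctum(shifted, 60 + 7, 62 + 5, 3, 0.6)
  c1 <- detect_candidates(base)
  c2 <- detect_candidates(shifted)
  expect_equal(nrow(c1), 2)
  expect_equal(nrow(c2), 2)
  ord1 <- order(c1$row); ord2 <- order(c2$row)
  expect_equal(c2$row[ord2], c1$row[ord1] + 7, tolerance = 0.51)
  expect_equal(c2$col[ord2], c1$col[ord1] + 5, tolerance = 0.51)
})

test_that("detection on synthetic fields reaches F1 >= 0.9", {
  scores <- purrr::map_dfr(31:36, function(s) {
    fov <- sim_fov(fov_spec(seed = s, decoy_particle_spec = NULL))
    detection_scores(detect_candidates(fov), fov$truth)
  })
  expect_gte(mean(scores$f1), 0.9)
})

test_that("the distance transform matches brute force on small images", {
  set.seed(42)
  for (trial in 1:3) {
    mask <- matrix(FALSE, 48, 48)
    centers <- cbind(sample(8:40, 2), sample(8:40, 2))
    rr <- matrix(seq_len(48), 48, 48)
    cc <- t(rr)
    for (i in 1:2) {
      mask <- mask | (sqrt((rr - centers[i, 1])^2 +
                             (cc - centers[i, 2])^2) <= 5)
    }
    dm <- nucleus_distance_map(mask * 1L)
    probe <- cbind(sample(1:48, 12), sample(1:48, 12))
    for (k in seq_len(nrow(probe))) {
      bf <- brute_force_distance(mask, probe[k, 1], probe[k, 2])
      if (mask[probe[k, 1], probe[k, 2]]) bf <- 0
      expect_equal(dm[probe[k, 1], probe[k, 2]], bf, tolerance = 1e-6)
    }
  }
})

test_that("radius-intensity classifier recovers the Bayes boundary", {
  # perfectly separated classes -> 100% training accuracy
  set.seed(1)
  sep <- tibble::tibble(
    radius = c(rnorm(300, 4, 0.5), rnorm(300, 4, 0.5)),
    mean_intensity = c(rnorm(300, 0.6, 0.03), rnorm(300, 0.1, 0.03)),
    is_lysosome = rep(c(TRUE, FALSE), each = 300)
  )
  clf <- train_radius_intensity_classifier(sep)
  acc <- mean((predict(clf, sep) >= 0.5) == sep$is_lysosome)
  expect_equal(acc, 1)

  # two overlapping isotropic Gaussians with equal priors: the fitted 0.5
  # contour approximates the analytic equal-posterior locus (the
  # perpendicular bisector of the class means)
  set.seed(2)
  n <- 4000
  ov <- tibble::tibble(
    radius = c(rnorm(n, 3.5, 0.8), rnorm(n, 6.5, 0.8)),
    mean_intensity = c(rnorm(n, 0.5, 0.08), rnorm(n, 0.5, 0.08)),
    is_lysosome = rep(c(TRUE, FALSE), each = n)
  )
  clf2 <- train_radius_intensity_classifier(ov, grid_n = 128)
  # along the intensity slice at the common mean, posterior crosses 0.5
  # near the midpoint radius 5
  rads <- seq(4, 6, by = 0.01)
  post <- predict(clf2, tibble::tibble(radius = rads, mean_intensity = 0.5))
  crossing <- rads[which.min(abs(post - 0.5))]
  expect_lt(abs(crossing - 5), 0.25)

  # default acceptance threshold is the 50% probability level
  expect_equal(train_radius_intensity_classifier(sep)$threshold, 0.5)
  expect_error(train_radius_intensity_classifier(sep[sep$is_lysosome, ]),
               "both classes")
})

test_that("classification accepts true lysosomes and rejects dim particles", {
  clf <- trained_classifier()

  # empty candidate list passes through
  empty <- detect_candidates(matrix(0, 64, 64))
  expect_equal(nrow(classify_particles(empty, clf)), 0)

  # candidates drawn from the lysosome training distribution: >= 90% accepted
  fovs <- lapply(41:43, function(s) sim_fov(fov_spec(seed = s)))
  ann <- annotate_from_truth(fovs)
  lyso <- classify_particles(ann[ann$is_lysosome, ], clf)
  expect_gte(mean(lyso$accepted), 0.9)

  # a near-zero intensity particle is rejected
  dim_particle <- tibble::tibble(row = 1, col = 1, radius = 4,
                                 mean_intensity = 0.01, circularity = 1,
                                 score = 2, accepted = NA)
  expect_false(classify_particles(dim_particle, clf)$accepted)

  # acceptance is monotone in the threshold
  cand <- classify_particles(ann, clf)
  stricter <- clf
  stricter$threshold <- 0.8
  cand2 <- classify_particles(ann, stricter)
  expect_true(all(!cand2$accepted | cand$accepted))
})

test_that("per-cell statistics follow the arithmetic and the truth", {
  clf <- trained_classifier()

  none <- tibble::tibble(row = numeric(0), col = numeric(0),
                         radius = numeric(0), mean_intensity = numeric(0),
                         accepted = logical(0))
  labels <- matrix(0L, 32, 32); labels[5:8, 5:8] <- 1L; labels[20:23, 20:23] <- 2L
  mask <- matrix(TRUE, 32, 32)
  expect_equal(lysosomes_per_cell(none, mask, labels)$lysosomes_per_cell, 0)

  thirty <- tibble::tibble(row = rep(16, 30), col = rep(16, 30),
                           accepted = TRUE)
  labels10 <- matrix(0L, 32, 32)
  for (i in 1:10) labels10[i * 3, 2:4] <- i
  expect_equal(lysosomes_per_cell(thirty, mask, labels10)$lysosomes_per_cell,
               3)

  # no nuclei -> flagged, statistic NA
  res <- lysosomes_per_cell(thirty, mask, matrix(0L, 32, 32))
  expect_true(res$flagged)
  expect_true(is.na(res$lysosomes_per_cell))

  # pipeline mean within 10% of the generator truth mean
  res <- purrr::map_dfr(31:36, function(s) {
    fov <- sim_fov(fov_spec(seed = s))
    out <- analyze_fov(fov, clf)
    tibble::tibble(est = out$summary$lysosomes_per_cell,
                   truth = sum(fov$truth$class == "lysosome") /
                     fov$spec$n_nuclei)
  })
  expect_lt(abs(mean(res$est) / mean(res$truth) - 1), 0.1)
})

test_that("nucleus distances and the histogram half-max behave correctly", {
  labels <- matrix(0L, 64, 64)
  rr <- matrix(seq_len(64), 64, 64); cc <- t(rr)
  labels[sqrt((rr - 32)^2 + (cc - 32)^2) <= 10] <- 1L

  # particle inside the nucleus -> distance 0
  inside <- tibble::tibble(row = 32, col = 35, accepted = TRUE)
  d0 <- nucleus_distance_histogram(inside, labels)
  expect_equal(d0$distances, 0)

  # particle d px beyond the edge -> distance d (within 1 px)
  for (d in c(4, 9)) {
    p <- tibble::tibble(row = 32, col = 32 + 10 + d, accepted = TRUE)
    got <- nucleus_distance_histogram(p, labels)$distances
    bf <- brute_force_distance(labels > 0, 32, 32 + 10 + d)
    expect_lt(abs(got - d), 1)
    expect_equal(got, bf, tolerance = 1e-6)
  }

  # no particles -> empty histogram, not an error
  none <- tibble::tibble(row = numeric(0), col = numeric(0),
                         accepted = logical(0))
  expect_equal(nrow(nucleus_distance_histogram(none, labels)$histogram), 0)

  # a peripheral-bias increase right-shifts the distance distribution
  half_max <- sapply(c(0.05, 0.95), function(bias) {
    hm <- sapply(1:4, function(s) {
      fov <- sim_fov(fov_spec(peripheral_bias = bias, puncta_per_cell = 20,
                              decoy_particle_spec = NULL, seed = 200 + s))
      truth <- fov$truth
      truth$accepted <- TRUE
      nucleus_distance_histogram(truth, fov$nucleus_labels)$half_max_distance
    })
    mean(hm)
  })
  expect_gt(half_max[2], half_max[1])
})

test_that("activity-particle counting prunes at 15% of saturation", {
  # the pruning rule: strictly below the cutoff is discarded
  parts <- tibble::tibble(row = c(10, 20), col = c(10, 20),
                          radius = c(4, 4),
                          mean_intensity = c(0.14, 0.16))
  kept <- prune_particles(parts, prune_fraction = 0.15)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$mean_intensity, 0.16)
  expect_equal(nrow(prune_particles(parts, prune_fraction = 0.15,
                                    saturation_value = 1)), 1)
  # a particle exactly at the cutoff is kept
  at <- tibble::tibble(mean_intensity = 0.15)
  expect_equal(nrow(prune_particles(at)), 1)

  # all-dim particles -> count 0
  dim_parts <- tibble::tibble(row = 10, col = 10, radius = 4,
                              mean_intensity = 0.10)
  labels <- matrix(0L, 32, 32); labels[14:18, 14:18] <- 1L
  dimmed <- prune_particles(dim_parts)
  expect_equal(nrow(dimmed), 0)

  # end-to-end count equals a brute-force filter over the truth list
  fov <- sim_fov(fov_spec(seed = 55, puncta_per_cell = 10,
                          lysosome_intensity = list(min = 0.15, max = 0.9),
                          decoy_particle_spec = NULL))
  mask <- demarcate_cell_regions(fov)
  nlab <- segment_nuclei(fov)
  got <- magic_red_count(fov, mask, nlab, channel = "lysosomal")
  cand <- detect_candidates(fov, channel = "lysosomal")
  oracle <- cand[cand$mean_intensity >= 0.15, ]
  expect_equal(got$n_particles, nrow(oracle))
  expect_equal(got$particles_per_cell, nrow(oracle) / count_nuclei(nlab))
})
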