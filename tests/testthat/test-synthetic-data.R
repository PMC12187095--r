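test_that("generators are deterministic under a fixed seed", {
  f1 <- sim_fov(fov_spec(seed = 3))
  f2 <- sim_fov(fov_spec(seed = 3))
  expect_identical(f1$channels, f2$channels)
  expect_identical(f1$truth, f2$truth)

  s1 <- sim_flux_timecourse(flux_sim_spec(seed = 5))
  s2 <- sim_flux_timecourse(flux_sim_spec(seed = 5))
  expect_identical(s1$traces, s2$traces)

  p1 <- sim_survival_plate(survival_sim_spec(seed = 9))
  p2 <- sim_survival_plate(survival_sim_spec(seed = 9))
  expect_identical(p1$absorbance, p2$absorbance)

  m1 <- sim_abundance_matrix(proteomics_sim_spec(n_proteins = 60, seed = 2))
  m2 <- sim_abundance_matrix(proteomics_sim_spec(n_proteins = 60, seed = 2))
  expect_identical(m1$values, m2$values)
})

test_that("field-of-view truth respects the radius window and zero-count case", {
  # zero puncta and no decoys -> empty truth
  fov0 <- sim_fov(fov_spec(puncta_per_cell = 0, decoy_particle_spec = NULL,
                           seed = 1))
  expect_equal(nrow(fov0$truth), 0)

  # all generated radii stay within the distribution's support
  fov <- sim_fov(fov_spec(puncta_per_cell = 25, n_nuclei = 4, seed = 8))
  lys <- fov$truth[fov$truth$class == "lysosome", ]
  expect_gt(nrow(lys), 30)
  expect_true(all(lys$radius >= 2 & lys$radius <= 10))

  # the default radius support is the 2-10 px acceptance window
  spec <- fov_spec()
  expect_equal(spec$lysosome_radius_px$min, 2)
  expect_equal(spec$lysosome_radius_px$max, 10)
})

test_that("nuclei render as the requested number of connected components", {
  for (s in 1:3) {
    fov <- sim_fov(fov_spec(seed = s, noise_sd = 0))
    comps <- EBImage::bwlabel(fov$channels$nuclear > 0.4)
    expect_equal(max(comps), fov$spec$n_nuclei)
  }
})

test_that("impossible nucleus placement raises an informative error", {
  expect_error(sim_fov(fov_spec(image_shape = c(64, 64), n_nuclei = 30,
                                seed = 1)),
               "Could not place")
})

test_that("flux generator matches closed forms and stays monotone", {
  # no metabolism, no noise -> flat pH and pO2
  still <- sim_flux_timecourse(flux_sim_spec(
    fermentative_rate = 0, respiratory_rate = 0, oil_ingress_rate = 0,
    noise_sd = 0, seed = 1))
  expect_equal(still$truth$ph, rep(7.4, nrow(still$truth)))
  expect_equal(still$truth$po2, rep(160, nrow(still$truth)))

  # constant fermentative rate, no ingress: pH(t) = pH0 - J t / (beta V)
  spec <- flux_sim_spec(fermentative_rate = 2e-8, respiratory_rate = 0,
                        oil_ingress_rate = 0, noise_sd = 0, seed = 1)
  sim <- sim_flux_timecourse(spec)
  expected <- 7.4 - 2e-8 * sim$truth$time_h / (2e-3 * 2e-4)
  expect_equal(sim$truth$ph, expected, tolerance = 1e-10)

  # fermentation + respiration: both traces monotone non-increasing
  both <- sim_flux_timecourse(flux_sim_spec(noise_sd = 0,
                                            oil_ingress_rate = 0, seed = 1))
  expect_true(all(diff(both$truth$ph) <= 1e-12))
  expect_true(all(diff(both$truth$po2) <= 1e-12))
})

test_that("halving the integration step changes the trajectory by < 0.1%", {
  spec <- flux_sim_spec(noise_sd = 0, co2_acid_fraction = 0.3,
                        glycolysis_ph_block = list(pk = 6.6, n = 2),
                        oil_ingress_rate = 0.05, seed = 1)
  full <- sim_flux_timecourse(spec)
  halved <- sim_flux_timecourse(spec, step = spec$sampling_interval / 2)
  expect_equal(halved$truth$ph, full$truth$ph, tolerance = 1e-3)
  expect_equal(halved$truth$po2, full$truth$po2, tolerance = 1e-3)
  expect_equal(halved$truth$cum_h, full$truth$cum_h, tolerance = 1e-3)
})

test_that("without volatile acid, cumulative H+ equals cumulative lactate", {
  sim <- sim_flux_timecourse(flux_sim_spec(co2_acid_fraction = 0,
                                           noise_sd = 0, seed = 2))
  expect_equal(sim$truth$cum_h, sim$truth$cum_lactate, tolerance = 1e-12)

  # with a volatile share f, lactate accounts for (1 - f) of total acid
  simf <- sim_flux_timecourse(flux_sim_spec(co2_acid_fraction = 0.4,
                                            noise_sd = 0, seed = 2))
  late <- nrow(simf$truth)
  expect_equal(simf$truth$cum_lactate[late] / simf$truth$cum_h[late], 0.6,
               tolerance = 1e-9)
})

test_that("flux spec rejects inconsistent parameters", {
  expect_error(flux_sim_spec(buffering_capacity = 0), "non-finite")
  expect_error(flux_sim_spec(co2_acid_fraction = 1), "inconsistent")
  expect_error(flux_sim_spec(co2_acid_fraction = 1.2), "must be in")
})

test_that("survival plate draws from the model with stored truth", {
  # zero noise reproduces the model exactly
  spec0 <- survival_sim_spec(noise_sd = 0, seed = 1)
  plate0 <- sim_survival_plate(spec0)
  expect_equal(plate0$absorbance,
               spec0$scale * predict_growth(spec0$params, plate0$ph),
               tolerance = 1e-12)

  # replicate means stay within 3 noise-SEs of the model value
  spec <- survival_sim_spec(n_replicates = 8, noise_sd = 2, seed = 3)
  plate <- sim_survival_plate(spec)
  means <- tapply(plate$absorbance / spec$scale, plate$ph, mean)
  mu <- predict_growth(spec$params, as.numeric(names(means)))
  se <- spec$noise_sd / sqrt(spec$n_replicates)
  expect_true(all(abs(means - mu) < 3 * se))

  # the default grid spans the 6.2-7.7 assay window
  expect_equal(range(survival_sim_spec()$ph_grid), c(6.2, 7.7))
  expect_error(survival_sim_spec(ph_grid = c(6.5, 7, 7.5)), "at least 5")
})

test_that("proteomics generator produces the 2x2x3 design and left-censoring", {
  spec <- proteomics_sim_spec(n_proteins = 400, seed = 6)
  sim <- sim_abundance_matrix(spec)
  expect_equal(ncol(sim$values), 12)
  expect_equal(nrow(sim$design), 12)
  expect_equal(dplyr::n_distinct(sim$design$batch), 3)

  # every batch spans all four conditions
  per_batch <- table(sim$design$batch, paste(sim$design$ph, sim$design$o2))
  expect_true(all(per_batch == 1))

  # missingness concentrates at low abundance: negative rank correlation
  miss_frac <- rowMeans(is.na(sim$values))
  keep <- miss_frac > 0 | TRUE
  rho <- suppressWarnings(cor(miss_frac, rowMeans(sim$complete),
                              method = "spearman"))
  expect_lt(rho, -0.3)

  # observed marginal is left-truncated: observed mean above complete mean
  expect_gt(mean(sim$values, na.rm = TRUE), mean(sim$complete))

  # global null: per-protein group means differ only by sampling noise
  null_sim <- sim_abundance_matrix(proteomics_sim_spec(
    n_proteins = 300,
    effect_classes = default_effect_classes(0, 0, 0, 0),
    censoring = NULL, batch_sd = 0, seed = 7))
  cond <- paste(null_sim$design$ph, null_sim$design$o2)
  f <- apply(null_sim$values, 1, function(y) {
    anova(lm(y ~ cond))[["Pr(>F)"]][1]
  })
  expect_gt(mean(f < 0.05), 0.01)
  expect_lt(mean(f < 0.05), 0.12)

  expect_error(proteomics_sim_spec(
    effect_classes = default_effect_classes(0.5, 0.3, 0.3, 0.2)),
    "at most 1")
})
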