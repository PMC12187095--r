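# shared test utilities

# adjusted Rand index between two labelings
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(n, 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}

# brute-force Euclidean distance to the nearest TRUE pixel
brute_force_distance <- function(mask, row, col) {
  fg <- which(mask, arr.ind = TRUE)
  if (nrow(fg) == 0) return(Inf)
  min(sqrt((fg[, 1] - row)^2 + (fg[, 2] - col)^2))
}

# simulate the standard lactate-coupling batch: `n` fermentation-only wells
# spanning 0.5-2x the reference fermentative rate, sampled at 8 h and 17 h
simulate_lactate_pairs <- function(n_wells = 12, seeds = seq_len(n_wells),
                                   co2_acid_fraction = 0, noise_sd = 0.005,
                                   rate_range = c(0.5, 2)) {
  purrr::map2_dfr(seq_len(n_wells), seeds, function(i, s) {
    rate <- 2e-8 * (rate_range[1] + diff(rate_range) * (i - 1) /
                      (n_wells - 1))
    spec <- flux_sim_spec(fermentative_rate = rate,
                          co2_acid_fraction = co2_acid_fraction,
                          noise_sd = noise_sd, seed = s)
    sim <- sim_flux_timecourse(spec, well = paste0("w", i))
    fx <- calibrate_traces(sim$traces, sim$calibration)
    sample_times <- c(8, 17)
    idx <- match(sample_times, fx$time_h)
    tix <- match(sample_times, sim$truth$time_h)
    tibble::tibble(cumulative_acid = fx$cumulative_acid[idx],
                   lactate = sim$truth$cum_lactate[tix])
  })
}

# train the lysosome classifier once per session from synthetic fields
trained_classifier <- local({
  clf <- NULL
  function() {
    if (is.null(clf)) {
      fovs <- lapply(21:26, function(s) sim_fov(fov_spec(seed = s)))
      ann <- annotate_from_truth(fovs)
      clf <<- suppressWarnings(train_radius_intensity_classifier(ann))
    }
    clf
  }
})
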