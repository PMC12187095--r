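#' Specification for a simulated pH-gradient growth plate
#'
#' Draws SRB-type absorbances from the biphasic Hill survival model across a
#' grid of starting medium pH. The default grid spans pH 6.2-7.7, the window
#' over which acid sensitivity of growth is typically assayed.
#'
#' @param params True [biphasic_hill_params()].
#' @param ph_grid Medium pH values (at least 5 distinct points, within a
#'   physiological window of pH 5-9).
#' @param n_replicates Number of biological replicates.
#' @param noise_sd Additive Gaussian noise, in percent-growth units.
#' @param scale Absorbance per 100% growth (converts model percent to raw
#'   absorbance units).
#' @param seed Integer seed.
#' @return A `survival_sim_spec` object.
#' @export
survival_sim_spec <- function(params = biphasic_hill_params(),
                              ph_grid = seq(6.2, 7.7, by = 0.15),
                              n_replicates = 3,
                              noise_sd = 2,
                              scale = 0.01,
                              seed = 1) {
  stopifnot(inherits(params, "biphasic_hill_params"))
  if (length(unique(ph_grid)) < 5) {
    abort("`ph_grid` must contain at least 5 distinct pH points (the model has 5 parameters).")
  }
  if (any(ph_grid < 5) || any(ph_grid > 9)) {
    abort("`ph_grid` must lie within the physiological window pH 5-9.")
  }
  check_number(n_replicates, "n_replicates", lower = 1)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(scale, "scale", lower = 1e-12)
  check_number(seed, "seed")
  structure(
    list(params = params, ph_grid = sort(unique(ph_grid)),
         n_replicates = as.integer(n_replicates), noise_sd = noise_sd,
         scale = scale, seed = seed),
    class = "survival_sim_spec"
  )
}

#' Simulate an SRB-type absorbance plate across a pH gradient
#'
#' Absorbance = model prediction x scale + Gaussian noise. The generating
#' parameters are attached as the `"truth"` attribute for recovery testing.
#'
#' @param spec A [survival_sim_spec()].
#' @return A tibble with columns `replicate`, `ph`, `absorbance` and a
#'   `"truth"` attribute holding the generating parameters.
#' @examples
#' plate <- sim_survival_plate(survival_sim_spec(seed = 2))
#' head(plate)
#' @export
sim_survival_plate <- function(spec) {
  stopifnot(inherits(spec, "survival_sim_spec"))
  grid <- tidyr::expand_grid(replicate = seq_len(spec$n_replicates),
                             ph = spec$ph_grid)
  mu <- predict_growth(spec$params, grid$ph)
  plate <- with_seed(spec$seed, {
    grid$absorbance <- spec$scale *
      (mu + rnorm(nrow(grid), sd = spec$noise_sd))
    grid
  })
  attr(plate, "truth") <- spec$params
  plate
}
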