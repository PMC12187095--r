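#' Specification for a simulated metabolic-profiling time course
#'
#' Forward model for a single plate-reader well: cells ferment (releasing
#' lactic acid, one H+ per lactate) and respire (consuming O2) in a small
#' volume of weakly buffered medium under an oil barrier. Medium pH follows
#' the acid load through the buffering capacity, pO2 follows respiration
#' through the oxygen solubility, and atmospheric oxygen leaks in through the
#' oil at a first-order rate. Optionally, fermentation is attenuated at low pH
#' by a Hill-type block (glycolysis is acutely inhibited by acidity).
#'
#' @param fermentative_rate Lactic-acid production rate (mol H+ per hour).
#' @param respiratory_rate Oxygen consumption rate (mol O2 per hour).
#' @param co2_acid_fraction Fraction of total released acid carried by
#'   volatile/respiratory acid (CO2) rather than lactic acid, in `[0, 1)`
#'   when `fermentative_rate > 0`. With fraction `f`, CO2-derived acid is
#'   released at `f / (1 - f)` times the lactic rate so that lactate accounts
#'   for a share `1 - f` of cumulative H+.
#' @param buffering_capacity,o2_solubility,volume,oil_ingress_rate,atmospheric_po2
#'   Medium constants as in [flux_calibration()].
#' @param ph0,po2_0 Initial medium pH and pO2 (mmHg).
#' @param glycolysis_ph_block Optional `list(pk =, n =)`: fermentative rate is
#'   multiplied by `1 / (1 + 10^(n * (pk - pH)))`, shutting glycolysis down
#'   below `pk`.
#' @param noise_sd Relative (fractional) Gaussian noise applied to the raw
#'   probe signals.
#' @param duration,sampling_interval Total simulated time and sample spacing
#'   (hours).
#' @param seed Integer seed; fully determines the output.
#' @return A `flux_sim_spec` object.
#' @export
flux_sim_spec <- function(fermentative_rate = 2e-8,
                          respiratory_rate = 4e-9,
                          co2_acid_fraction = 0,
                          buffering_capacity = 2e-3,
                          o2_solubility = 1.3e-6,
                          volume = 2e-4,
                          oil_ingress_rate = 0.01,
                          atmospheric_po2 = 160,
                          ph0 = 7.4, po2_0 = 160,
                          glycolysis_ph_block = NULL,
                          noise_sd = 0.005,
                          duration = 17, sampling_interval = 0.25,
                          seed = 1) {
  check_number(fermentative_rate, "fermentative_rate", lower = 0)
  check_number(respiratory_rate, "respiratory_rate", lower = 0)
  check_number(co2_acid_fraction, "co2_acid_fraction", lower = 0, upper = 1)
  if (co2_acid_fraction >= 1 && fermentative_rate > 0) {
    abort("`co2_acid_fraction` = 1 is inconsistent with a nonzero lactic rate.")
  }
  check_number(buffering_capacity, "buffering_capacity", lower = 0)
  if (buffering_capacity == 0 &&
      (fermentative_rate > 0 || co2_acid_fraction > 0)) {
    abort("Zero buffering capacity with a nonzero acid rate gives a non-finite pH trajectory.")
  }
  check_number(o2_solubility, "o2_solubility", lower = 1e-15)
  check_number(volume, "volume", lower = 1e-15)
  check_number(oil_ingress_rate, "oil_ingress_rate", lower = 0)
  check_number(atmospheric_po2, "atmospheric_po2", lower = 0)
  check_number(ph0, "ph0", lower = 5, upper = 9)
  check_number(po2_0, "po2_0", lower = 0)
  if (!is.null(glycolysis_ph_block)) {
    check_number(glycolysis_ph_block$pk, "glycolysis_ph_block$pk")
    check_number(glycolysis_ph_block$n, "glycolysis_ph_block$n", lower = 1e-9)
  }
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(duration, "duration", lower = 1e-9)
  check_number(sampling_interval, "sampling_interval", lower = 1e-9)
  check_number(seed, "seed")
  structure(
    list(fermentative_rate = fermentative_rate,
         respiratory_rate = respiratory_rate,
         co2_acid_fraction = co2_acid_fraction,
         buffering_capacity = buffering_capacity,
         o2_solubility = o2_solubility, volume = volume,
         oil_ingress_rate = oil_ingress_rate,
         atmospheric_po2 = atmospheric_po2,
         ph0 = ph0, po2_0 = po2_0,
         glycolysis_ph_block = glycolysis_ph_block,
         noise_sd = noise_sd, duration = duration,
         sampling_interval = sampling_interval, seed = seed),
    class = "flux_sim_spec"
  )
}

# derivative of the well state c(ph, po2) plus the flux integrands;
# respiration tapers smoothly to zero near anoxia (half-saturation 1 mmHg)
flux_derivs <- function(state, spec) {
  ph <- state[1]; po2 <- state[2]
  block <- spec$glycolysis_ph_block
  f_act <- if (is.null(block)) 1 else {
    1 / (1 + 10^(block$n * (block$pk - ph)))
  }
  j_lac <- spec$fermentative_rate * f_act
  f <- spec$co2_acid_fraction
  j_co2 <- if (f > 0 && f < 1) j_lac * f / (1 - f) else 0
  j_h <- j_lac + j_co2
  o2_avail <- max(po2, 0) / (max(po2, 0) + 1)
  j_o2 <- spec$respiratory_rate * o2_avail
  bv <- spec$buffering_capacity * spec$volume
  dph <- if (j_h == 0) 0 else -j_h / bv
  dpo2 <- -j_o2 / (spec$o2_solubility * spec$volume) +
    spec$oil_ingress_rate * (spec$atmospheric_po2 - po2)
  c(dph = dph, dpo2 = dpo2, j_h = j_h, j_lac = j_lac, j_o2 = j_o2)
}

# explicit midpoint (RK2) integration at a fixed step
integrate_flux <- function(spec, step = spec$sampling_interval) {
  n_steps <- ceiling(spec$duration / step)
  times <- seq(0, by = step, length.out = n_steps + 1)
  out <- matrix(0, nrow = n_steps + 1, ncol = 5,
                dimnames = list(NULL, c("ph", "po2", "cum_h", "cum_lactate",
                                        "cum_o2")))
  state <- c(spec$ph0, spec$po2_0)
  cum <- c(0, 0, 0)
  out[1, ] <- c(state, cum)
  for (i in seq_len(n_steps)) {
    k1 <- flux_derivs(state, spec)
    mid <- state + step / 2 * k1[1:2]
    k2 <- flux_derivs(mid, spec)
    state <- state + step * k2[1:2]
    state[2] <- max(state[2], 0)
    cum <- cum + step * k2[3:5]
    out[i + 1, ] <- c(state, cum)
    if (!all(is.finite(state))) {
      abort("Flux integration produced non-finite values; check spec parameters.")
    }
  }
  cbind(time_h = times, as.data.frame(out))
}

#' Simulate a fluorometric metabolic-profiling well
#'
#' Integrates the forward model of [flux_sim_spec()] with a fixed-step
#' explicit midpoint scheme at the sampling interval, then renders the raw
#' probe signals through the same calibration model that [calibrate_traces()]
#' inverts, adding relative Gaussian noise. Ground-truth pH, pO2 and
#' cumulative H+/lactate/O2 series are returned alongside.
#'
#' @param spec A [flux_sim_spec()].
#' @param well Label for the simulated well.
#' @param step Integration step (hours); defaults to the sampling interval.
#' @return A list with elements `traces` (tibble: `well`, `time_h`, `ratio`,
#'   `o2_intensity`, `live_cell_signal`), `truth` (tibble: `time_h`, `ph`,
#'   `po2`, `cum_h`, `cum_lactate`, `cum_o2`), `calibration` (the matching
#'   [flux_calibration()]) and `spec`.
#' @examples
#' sim <- sim_flux_timecourse(flux_sim_spec(noise_sd = 0, seed = 3))
#' head(sim$truth)
#' @export
sim_flux_timecourse <- function(spec, well = "w1",
                                step = spec$sampling_interval) {
  stopifnot(inherits(spec, "flux_sim_spec"))
  every <- spec$sampling_interval / step
  if (abs(every - round(every)) > 1e-8) {
    abort("`step` must divide the sampling interval.")
  }
  truth <- as_tibble(integrate_flux(spec, step))
  truth <- truth[seq(1, nrow(truth), by = round(every)), ]
  cal <- flux_calibration(
    buffering_capacity = spec$buffering_capacity,
    o2_solubility = spec$o2_solubility, volume = spec$volume,
    oil_ingress_rate = spec$oil_ingress_rate,
    atmospheric_po2 = spec$atmospheric_po2
  )
  n <- nrow(truth)
  traces <- with_seed(spec$seed, {
    ratio <- ph_to_ratio(truth$ph, cal)
    intensity <- po2_to_intensity(truth$po2, cal)
    live0 <- 1000 * (1 + rnorm(1, sd = spec$noise_sd))
    tibble(
      well = well, time_h = truth$time_h,
      ratio = ratio * (1 + rnorm(n, sd = spec$noise_sd)),
      o2_intensity = intensity * (1 + rnorm(n, sd = spec$noise_sd)),
      live_cell_signal = live0 * (1 + rnorm(n, sd = spec$noise_sd / 4))
    )
  })
  list(traces = traces, truth = truth, calibration = cal, spec = spec)
}
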