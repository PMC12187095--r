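#' Calibration constants for fluorometric metabolic profiling
#'
#' Bundles the probe and medium constants needed to convert raw plate-reader
#' signals into pH, oxygen partial pressure and cumulative metabolic fluxes.
#' The pH probe (an HPTS-type ratiometric dye) follows a standard ratiometric
#' calibration with acid dissociation constant `ph_pka` and asymptotic ratios
#' `ph_ratio_min`/`ph_ratio_max`; the oxygen probe (a RuBPY-type collisionally
#' quenched dye) follows Stern-Volmer quenching with unquenched intensity
#' `o2_i0` and quenching constant `o2_ksv`. Probe constants are instrument- and
#' batch-specific and must be measured by the user; the defaults here are the
#' ones used by the package's forward simulator.
#'
#' @param ph_pka Apparent pKa of the pH probe (pH units).
#' @param ph_ratio_min,ph_ratio_max Ratiometric signal at the fully acidic /
#'   fully basic limits; `ph_ratio_min < ph_ratio_max`.
#' @param o2_i0 Probe intensity at zero oxygen (arbitrary units).
#' @param o2_ksv Stern-Volmer constant (per mmHg), > 0.
#' @param buffering_capacity Medium buffering capacity beta
#'   (mol L^-1 pH-unit^-1), > 0. Converts a pH change to moles of acid.
#' @param o2_solubility Oxygen solubility alpha (mol L^-1 mmHg^-1).
#' @param volume Medium volume per well (L).
#' @param oil_ingress_rate Optional first-order rate constant (h^-1) for
#'   atmospheric oxygen ingress through the oil barrier; 0 disables the
#'   ingress correction.
#' @param atmospheric_po2 Atmospheric oxygen partial pressure (mmHg).
#' @return A `flux_calibration` object (named list).
#' @examples
#' cal <- flux_calibration()
#' ratio_to_ph(1.2, cal)
#' @export
flux_calibration <- function(ph_pka = 7.2, ph_ratio_min = 0.2,
                             ph_ratio_max = 2.2, o2_i0 = 1000,
                             o2_ksv = 0.025,
                             buffering_capacity = 2e-3,
                             o2_solubility = 1.3e-6,
                             volume = 2e-4,
                             oil_ingress_rate = 0,
                             atmospheric_po2 = 160) {
  check_number(ph_pka, "ph_pka")
  check_number(ph_ratio_min, "ph_ratio_min")
  check_number(ph_ratio_max, "ph_ratio_max")
  if (ph_ratio_min >= ph_ratio_max) {
    abort("`ph_ratio_min` must be below `ph_ratio_max`.")
  }
  check_number(o2_i0, "o2_i0", lower = 1e-12)
  check_number(o2_ksv, "o2_ksv", lower = 1e-12)
  check_number(buffering_capacity, "buffering_capacity", lower = 1e-15)
  check_number(o2_solubility, "o2_solubility", lower = 1e-15)
  check_number(volume, "volume", lower = 1e-15)
  check_number(oil_ingress_rate, "oil_ingress_rate", lower = 0)
  check_number(atmospheric_po2, "atmospheric_po2", lower = 0)
  structure(
    list(ph_pka = ph_pka, ph_ratio_min = ph_ratio_min,
         ph_ratio_max = ph_ratio_max, o2_i0 = o2_i0, o2_ksv = o2_ksv,
         buffering_capacity = buffering_capacity,
         o2_solubility = o2_solubility, volume = volume,
         oil_ingress_rate = oil_ingress_rate,
         atmospheric_po2 = atmospheric_po2),
    class = "flux_calibration"
  )
}

# forward models (used by the simulator; exact inverses of the two
# calibration functions below)
ph_to_ratio <- function(ph, cal) {
  x <- 10^(ph - cal$ph_pka)
  cal$ph_ratio_min + (cal$ph_ratio_max - cal$ph_ratio_min) * x / (1 + x)
}

po2_to_intensity <- function(po2, cal) {
  cal$o2_i0 / (1 + cal$o2_ksv * po2)
}

#' Convert ratiometric probe signal to pH
#'
#' Inverts the ratiometric calibration
#' `pH = pKa + log10((ratio - ratio_min) / (ratio_max - ratio))`, which is
#' strictly increasing in the ratio. Ratios at or beyond the calibration
#' limits indicate probe saturation: they are clipped just inside the open
#' interval and flagged via the `"clipped"` attribute, with a warning.
#'
#' @param ratio Numeric vector of ratiometric signals.
#' @param cal A [flux_calibration()].
#' @return Numeric vector of pH values with a logical `"clipped"` attribute.
#' @export
ratio_to_ph <- function(ratio, cal) {
  stopifnot(inherits(cal, "flux_calibration"))
  eps <- 1e-6 * (cal$ph_ratio_max - cal$ph_ratio_min)
  clipped <- ratio <= cal$ph_ratio_min | ratio >= cal$ph_ratio_max
  if (any(clipped)) {
    warn(sprintf("%d ratio value(s) outside the calibration range were clipped (probe saturation).",
                 sum(clipped)))
    ratio <- pmin(pmax(ratio, cal$ph_ratio_min + eps), cal$ph_ratio_max - eps)
  }
  ph <- cal$ph_pka +
    log10((ratio - cal$ph_ratio_min) / (cal$ph_ratio_max - ratio))
  attr(ph, "clipped") <- clipped
  ph
}

#' Convert oxygen-probe intensity to oxygen partial pressure
#'
#' Inverts Stern-Volmer quenching: `pO2 = (I0 / I - 1) / K_SV`, strictly
#' decreasing in intensity. Intensities above `I0` (probe noise at anoxia)
#' are clipped to `pO2 = 0` with a warning; non-positive intensities are a
#' data error.
#'
#' @param intensity Numeric vector of probe intensities (same units as `o2_i0`).
#' @param cal A [flux_calibration()].
#' @return Numeric vector of pO2 (mmHg) with a logical `"clipped"` attribute.
#' @export
intensity_to_po2 <- function(intensity, cal) {
  stopifnot(inherits(cal, "flux_calibration"))
  if (any(intensity <= 0)) {
    abort("Oxygen-probe intensities must be positive.")
  }
  clipped <- intensity > cal$o2_i0
  if (any(clipped)) {
    warn(sprintf("%d intensity value(s) above I0 were clipped to pO2 = 0.",
                 sum(clipped)))
  }
  po2 <- pmax(0, (cal$o2_i0 / intensity - 1) / cal$o2_ksv)
  attr(po2, "clipped") <- clipped
  po2
}

#' Cumulative acid production from a calibrated pH series
#'
#' Converts a pH time series into cumulative H+ release into the medium,
#' `H+(t) = beta * V * (pH(0) - pH(t))`, optionally normalized to a live-cell
#' signal. Negative values from probe noise are retained (clipping would bias
#' downstream slope estimates).
#'
#' @param ph Numeric vector of calibrated pH values, ordered in time.
#' @param cal A [flux_calibration()] (supplies `buffering_capacity`, `volume`).
#' @param live_cell_signal Optional scalar cell-density marker value for the
#'   well; when given, output is mol per signal unit.
#' @return Numeric vector of cumulative H+ (mol), starting at 0.
#' @export
cumulative_acid <- function(ph, cal, live_cell_signal = NULL) {
  stopifnot(inherits(cal, "flux_calibration"))
  if (is.null(cal$buffering_capacity)) {
    abort("`buffering_capacity` missing from calibration.")
  }
  out <- cal$buffering_capacity * cal$volume * (ph[1] - ph)
  if (!is.null(live_cell_signal)) {
    check_number(live_cell_signal, "live_cell_signal", lower = 1e-12)
    out <- out / live_cell_signal
  }
  out
}

#' Cumulative oxygen consumption from a calibrated pO2 series
#'
#' Converts a pO2 time series into cumulative O2 consumed:
#' `O2(t) = alpha * V * (pO2(0) - pO2(t))` plus, when the calibration sets a
#' non-zero `oil_ingress_rate`, the oxygen that leaked in through the oil
#' barrier, `integral of k_in * (pO2_atm - pO2) * alpha * V dt` (trapezoidal
#' rule). The corrected estimate is therefore at least the naive depletion
#' estimate whenever the well is below atmospheric pO2.
#'
#' @param po2 Numeric vector of calibrated pO2 (mmHg), ordered in time.
#' @param time_h Time of each sample (hours); required when the ingress
#'   correction is active.
#' @param cal A [flux_calibration()].
#' @param live_cell_signal Optional normalizer as in [cumulative_acid()].
#' @return Numeric vector of cumulative O2 (mol), starting at 0.
#' @export
cumulative_o2 <- function(po2, cal, time_h = NULL, live_cell_signal = NULL) {
  stopifnot(inherits(cal, "flux_calibration"))
  out <- cal$o2_solubility * cal$volume * (po2[1] - po2)
  if (cal$oil_ingress_rate > 0) {
    if (is.null(time_h)) {
      abort("`time_h` is required when `oil_ingress_rate` > 0.")
    }
    influx <- cal$oil_ingress_rate * (cal$atmospheric_po2 - po2) *
      cal$o2_solubility * cal$volume
    dt <- diff(time_h)
    added <- cumsum(c(0, dt * (head(influx, -1) + tail(influx, -1)) / 2))
    out <- out + added
  }
  if (!is.null(live_cell_signal)) {
    check_number(live_cell_signal, "live_cell_signal", lower = 1e-12)
    out <- out / live_cell_signal
  }
  out
}

#' Calibrate raw plate-reader traces into a flux time course
#'
#' Applies [ratio_to_ph()], [intensity_to_po2()], [cumulative_acid()] and
#' [cumulative_o2()] per well to a tidy table of raw traces.
#'
#' @param traces Data frame with columns `well`, `time_h`, `ratio`,
#'   `o2_intensity` and optionally `live_cell_signal`.
#' @param cal A [flux_calibration()].
#' @param normalize Divide cumulative fluxes by the per-well pre-assay
#'   live-cell signal (first time point)?
#' @return A tibble with columns `well`, `time_h`, `ph`, `po2`,
#'   `cumulative_acid`, `cumulative_o2` (a `FluxTimeCourse`).
#' @export
calibrate_traces <- function(traces, cal, normalize = FALSE) {
  traces <- as_tibble(traces)
  check_columns(traces, c("well", "time_h", "ratio", "o2_intensity"), "traces")
  if (normalize) check_columns(traces, "live_cell_signal", "traces")
  dplyr::group_by(traces, .data$well) |>
    dplyr::group_modify(function(df, key) {
      df <- dplyr::arrange(df, .data$time_h)
      ph <- as.numeric(ratio_to_ph(df$ratio, cal))
      po2 <- as.numeric(intensity_to_po2(df$o2_intensity, cal))
      norm <- if (normalize) df$live_cell_signal[1] else NULL
      tibble(time_h = df$time_h, ph = ph, po2 = po2,
             cumulative_acid = cumulative_acid(ph, cal, norm),
             cumulative_o2 = cumulative_o2(po2, cal, df$time_h, norm))
    }) |>
    dplyr::ungroup()
}

#' Lactate versus cumulative acid coupling
#'
#' Relates end-point lactate to cumulative fluorometric H+ production across
#' wells. The headline statistic is the least-squares slope constrained
#' through the origin (fermentation releases one H+ per lactate, so 1:1
#' coupling means a slope of 1); an unconstrained slope and intercept and the
#' Pearson correlation are reported as diagnostics.
#'
#' @param pairs Data frame with columns `cumulative_acid` and `lactate`
#'   (matching units, e.g. mol per well).
#' @return A `lactate_fit` object with [tidy()] and [glance()] methods.
#' @examples
#' pairs <- tibble::tibble(cumulative_acid = 1:5, lactate = (1:5) * 1.02)
#' glance(lactate_slope(pairs))
#' @export
lactate_slope <- function(pairs) {
  pairs <- as_tibble(pairs)
  check_columns(pairs, c("cumulative_acid", "lactate"), "pairs")
  x <- pairs$cumulative_acid
  y <- pairs$lactate
  if (length(x) < 3) abort("Need at least 3 paired points.")
  if (var(x) == 0 || var(y) == 0) {
    abort("Zero-variance inputs; slope is undefined.")
  }
  slope0 <- sum(x * y) / sum(x^2)
  free <- lm(y ~ x)
  structure(
    list(slope_origin = slope0,
         slope_free = unname(coef(free)[2]),
         intercept_free = unname(coef(free)[1]),
         correlation = cor(x, y),
         n = length(x), data = pairs),
    class = "lactate_fit"
  )
}

#' @export
print.lactate_fit <- function(x, ...) {
  cat(sprintf("Lactate vs cumulative H+ coupling (n = %d wells)\n", x$n))
  cat(sprintf("  through-origin slope %.3f; free slope %.3f (intercept %.3g); r = %.3f\n",
              x$slope_origin, x$slope_free, x$intercept_free, x$correlation))
  invisible(x)
}

#' @export
tidy.lactate_fit <- function(x, ...) {
  tibble(term = c("slope_origin", "slope_free", "intercept_free"),
         estimate = c(x$slope_origin, x$slope_free, x$intercept_free))
}

#' @export
glance.lactate_fit <- function(x, ...) {
  tibble(slope_origin = x$slope_origin, slope_free = x$slope_free,
         intercept_free = x$intercept_free, correlation = x$correlation,
         nobs = x$n)
}

#' @rdname lactate_slope
#' @param object A `lactate_fit`.
#' @param ... Unused.
#' @export
autoplot.lactate_fit <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$cumulative_acid, y = .data$lactate)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_abline(slope = object$slope_origin, intercept = 0,
                         colour = "black") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "cumulative H+ (mol)", y = "end-point lactate (mol)") +
    ggplot2::theme_minimal()
}
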