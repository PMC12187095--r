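#' Normalize a pH-gradient growth plate to percent of maximal growth
#'
#' Converts raw SRB-type absorbances measured across a gradient of starting
#' medium pH into percentage of maximal growth, per replicate. The maximum is
#' taken from a monotone (shape-preserving) piecewise-cubic interpolant of the
#' per-replicate absorbance versus pH, evaluated on a fine grid, so a peak
#' falling between measured pH points is honoured; raw points may therefore
#' slightly exceed 100 only if the interpolant underestimates the peak (it
#' cannot overshoot measured values).
#'
#' @param plate A data frame with columns `replicate`, `ph` and `absorbance`.
#' @param grid_n Number of points of the interpolation grid per replicate.
#' @return A tibble with columns `replicate`, `ph`, `growth_pct` (a
#'   `SurvivalCurve` in the package's vocabulary).
#' @examples
#' plate <- tibble::tibble(replicate = 1, ph = c(6.4, 6.8, 7.2, 7.6),
#'                         absorbance = c(0.2, 0.4, 0.8, 0.4))
#' normalize_growth(plate)
#' @export
normalize_growth <- function(plate, grid_n = 201) {
  plate <- as_tibble(plate)
  if (!"replicate" %in% names(plate)) plate$replicate <- 1L
  check_columns(plate, c("replicate", "ph", "absorbance"), "plate")
  if (all(plate$absorbance == 0)) {
    abort("All absorbances are zero; growth cannot be normalized.")
  }
  dplyr::group_by(plate, .data$replicate) |>
    dplyr::group_modify(function(df, key) {
      if (dplyr::n_distinct(df$ph) < 3) {
        abort("Each replicate needs at least 3 distinct pH points.")
      }
      means <- dplyr::summarise(dplyr::group_by(df, .data$ph),
                                absorbance = mean(.data$absorbance))
      f <- splinefun(means$ph, means$absorbance, method = "monoH.FC")
      grid <- sort(unique(c(means$ph,
                            seq(min(means$ph), max(means$ph),
                                length.out = grid_n))))
      peak <- max(f(grid))
      if (peak <= 0) abort("Interpolated maximum absorbance is not positive.")
      tibble(ph = df$ph, growth_pct = 100 * df$absorbance / peak)
    }) |>
    dplyr::ungroup()
}

# candidate starts: midpoints at the pH of half-max on each flank,
# Hill coefficients {1, 2, 4} -- the surface has flat ridges in n
hill_starts <- function(ph, growth, bounds) {
  means <- tapply(growth, ph, mean)
  phs <- as.numeric(names(means))
  g <- as.numeric(means)
  i_max <- which.max(g)
  half <- max(g) / 2
  half_cross <- function(idx) {
    # first crossing of the half-max level along idx ordering
    for (j in seq_along(idx)[-1]) {
      a <- idx[j - 1]; b <- idx[j]
      if ((g[a] - half) * (g[b] - half) <= 0 && g[a] != g[b]) {
        return(phs[a] + (half - g[a]) * (phs[b] - phs[a]) / (g[b] - g[a]))
      }
    }
    NA_real_
  }
  pk_up0 <- half_cross(seq_len(i_max))
  pk_down0 <- half_cross(seq(length(g), i_max))
  if (!is.finite(pk_up0)) pk_up0 <- min(phs) + 0.25 * diff(range(phs))
  if (!is.finite(pk_down0)) pk_down0 <- max(phs) - 0.15 * diff(range(phs))
  pk_up0 <- min(max(pk_up0, bounds$pk[1]), bounds$pk[2])
  pk_down0 <- min(max(pk_down0, bounds$pk[1]), bounds$pk[2])
  if (pk_down0 <= pk_up0) pk_down0 <- min(pk_up0 + 0.5, bounds$pk[2])
  expand.grid(n_up = c(1, 2, 4), n_down = c(1, 2, 4)) |>
    purrr::pmap(function(n_up, n_down) {
      list(g_max = max(g), pk_up = pk_up0, n_up = n_up,
           pk_down = pk_down0, n_down = n_down)
    })
}

monotone_direction <- function(ph, growth) {
  means <- tapply(growth, ph, mean)
  d <- diff(as.numeric(means))
  if (all(d > 0)) "increasing" else if (all(d < 0)) "decreasing" else "none"
}

#' Fit the biphasic Hill survival model to a pH-survival curve
#'
#' Weighted least-squares fit of the five-parameter biphasic Hill model (see
#' [biphasic_hill_params()]) by Levenberg-Marquardt with multi-start
#' initialization. Midpoint starts are placed at the pH of half-maximal growth
#' on each flank and Hill-coefficient starts at 1, 2 and 4; among converged
#' starts the fit with the lowest residual sum of squares wins, ties broken by
#' the smallest `n_up + n_down`. Midpoints are bounded to pH 5.5-8.5 and Hill
#' coefficients to (0, 10].
#'
#' Strictly monotone data cannot constrain both limbs; in that case the
#' unidentifiable limb is dropped (its parameters returned as `NA`) and
#' `reduced_model` is flagged instead of failing silently.
#'
#' @param curve A data frame with columns `ph` and `growth_pct` (e.g. from
#'   [normalize_growth()]); a `replicate` column is allowed and pooled.
#' @param fix_g_max Fix `g_max` instead of estimating it. Default `NULL`
#'   estimates `g_max`; pass `100` to pin normalized curves to their scale.
#' @param weights Optional per-point weights for the least squares.
#' @param bounds List with elements `pk` and `n`, each a length-2 numeric
#'   giving box constraints.
#' @return A `biphasic_hill_fit` object with elements `params`
#'   ([biphasic_hill_params()] or reduced version), `se` (per-parameter
#'   standard errors), `rss`, `sigma`, `df_residual`, `convergence`,
#'   `reduced_model`, `data`. Supports [tidy()], [glance()], `predict()` and
#'   [autoplot()].
#' @examples
#' spec <- survival_sim_spec(noise_sd = 2, seed = 7)
#' plate <- sim_survival_plate(spec)
#' fit <- fit_biphasic_hill(normalize_growth(plate))
#' tidy(fit)
#' @export
fit_biphasic_hill <- function(curve, fix_g_max = NULL, weights = NULL,
                              bounds = list(pk = c(5.5, 8.5), n = c(1e-3, 10))) {
  curve <- as_tibble(curve)
  check_columns(curve, c("ph", "growth_pct"), "curve")
  ph <- curve$ph
  growth <- curve$growth_pct
  if (!all(is.finite(growth))) abort("Growth values must be finite.")
  if (dplyr::n_distinct(ph) < 5) {
    abort("Need at least 5 distinct pH points to fit 5 parameters.")
  }
  w <- weights %||% rep(1, length(ph))
  direction <- monotone_direction(ph, growth)
  reduced <- direction != "none"

  if (!reduced) {
    fit <- fit_hill_full(ph, growth, w, fix_g_max, bounds)
  } else {
    fit <- fit_hill_reduced(ph, growth, w, fix_g_max, bounds, direction)
  }
  fit$reduced_model <- reduced
  fit$data <- curve
  class(fit) <- "biphasic_hill_fit"
  fit
}

fit_hill_full <- function(ph, growth, w, fix_g_max, bounds) {
  starts <- hill_starts(ph, growth, bounds)
  free_g <- is.null(fix_g_max)
  lower <- c(if (free_g) 1e-6, bounds$pk[1], bounds$n[1], bounds$pk[1], bounds$n[1])
  upper <- c(if (free_g) Inf, bounds$pk[2], bounds$n[2], bounds$pk[2], bounds$n[2])
  results <- purrr::map(starts, function(s) {
    par0 <- unlist(s)
    if (!free_g) par0 <- par0[-1]
    resid_fn <- function(p) {
      pr <- as.list(p)
      if (!free_g) pr$g_max <- fix_g_max
      sqrt(w) * (growth - predict_growth(pr, ph))
    }
    out <- try(minpack.lm::nls.lm(
      par = par0, lower = lower, upper = upper, fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ), silent = TRUE)
    if (inherits(out, "try-error")) return(NULL)
    out
  })
  results <- purrr::compact(results)
  converged <- purrr::keep(results, ~ .x$info %in% 1:4)
  if (length(converged) == 0) {
    best <- results[[which.min(purrr::map_dbl(results, ~ .x$deviance))]]
    abort(c("Biphasic Hill fit failed to converge from any start.",
            i = sprintf("Best residual sum of squares so far: %.4g",
                        best$deviance)))
  }
  rss <- purrr::map_dbl(converged, ~ .x$deviance)
  nsum <- purrr::map_dbl(converged, function(f) {
    p <- coef_list(f, free_g, fix_g_max)
    p$n_up + p$n_down
  })
  # lowest RSS wins; ties (to 8 significant digits) broken by the least
  # cooperative solution, i.e. the smallest n_up + n_down
  ord <- order(signif(rss, 8), nsum)
  best <- converged[[ord[1]]]
  p <- coef_list(best, free_g, fix_g_max)
  params <- biphasic_hill_params(p$g_max, p$pk_up, p$n_up, p$pk_down, p$n_down)
  se <- fit_se(best, free_g)
  list(params = params, se = se, rss = best$deviance,
       df_residual = length(ph) - length(best$par),
       sigma = sqrt(best$deviance / (length(ph) - length(best$par))),
       convergence = TRUE, n_obs = length(ph))
}

coef_list <- function(fit, free_g, fix_g_max) {
  p <- as.list(fit$par)
  if (!free_g) p$g_max <- fix_g_max
  p[c("g_max", "pk_up", "n_up", "pk_down", "n_down")]
}

fit_se <- function(fit, free_g) {
  se <- rep(NA_real_, length(fit$par))
  vc <- try(suppressWarnings(
    fit$deviance / max(1, length(fit$fvec) - length(fit$par)) *
      solve(fit$hessian)
  ), silent = TRUE)
  if (!inherits(vc, "try-error")) {
    d <- diag(vc)
    se <- ifelse(d >= 0, sqrt(d), NA_real_)
  }
  out <- setNames(se, names(fit$par))
  full <- c(g_max = NA_real_, pk_up = NA_real_, n_up = NA_real_,
            pk_down = NA_real_, n_down = NA_real_)
  full[names(out)] <- out
  full
}

# one limb only: monotone data leave the other limb unidentifiable
fit_hill_reduced <- function(ph, growth, w, fix_g_max, bounds, direction) {
  free_g <- is.null(fix_g_max)
  rising <- direction == "increasing"
  limb <- if (rising) {
    function(p, ph) hill_up(ph, p[["pk"]], p[["n"]])
  } else {
    function(p, ph) hill_down(ph, p[["pk"]], p[["n"]])
  }
  par0 <- c(if (free_g) c(g_max = max(growth) * 1.05),
            pk = mean(range(ph)), n = 2)
  lower <- c(if (free_g) 1e-6, bounds$pk[1], bounds$n[1])
  upper <- c(if (free_g) Inf, bounds$pk[2], bounds$n[2])
  fit <- minpack.lm::nls.lm(
    par = par0, lower = lower, upper = upper,
    fn = function(p) {
      g <- if (free_g) p[["g_max"]] else fix_g_max
      sqrt(w) * (growth - g * limb(p, ph))
    },
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  p <- as.list(fit$par)
  g <- if (free_g) p$g_max else fix_g_max
  params <- list(g_max = g,
                 pk_up = if (rising) p$pk else NA_real_,
                 n_up = if (rising) p$n else NA_real_,
                 pk_down = if (rising) NA_real_ else p$pk,
                 n_down = if (rising) NA_real_ else p$n)
  class(params) <- "biphasic_hill_params"
  se0 <- fit_se(fit, free_g)
  se <- c(g_max = unname(se0["g_max"]),
          pk_up = if (rising) unname(se0["pk"]) else NA_real_,
          n_up = if (rising) unname(se0["n"]) else NA_real_,
          pk_down = if (rising) NA_real_ else unname(se0["pk"]),
          n_down = if (rising) NA_real_ else unname(se0["n"]))
  list(params = params, se = se, rss = fit$deviance,
       df_residual = length(ph) - length(fit$par),
       sigma = sqrt(fit$deviance / max(1, length(ph) - length(fit$par))),
       convergence = fit$info %in% 1:4, n_obs = length(ph))
}

#' @export
print.biphasic_hill_fit <- function(x, ...) {
  cat("Biphasic Hill survival fit",
      if (x$reduced_model) "(reduced: one limb unidentifiable)", "\n")
  print(x$params)
  cat(sprintf("  RSS %.4g on %d residual df; converged: %s\n",
              x$rss, x$df_residual, x$convergence))
  invisible(x)
}

#' @export
predict.biphasic_hill_fit <- function(object, ph = NULL, ...) {
  ph <- ph %||% object$data$ph
  p <- object$params
  if (object$reduced_model) {
    if (is.na(p$pk_down)) {
      return(p$g_max * hill_up(ph, p$pk_up, p$n_up))
    }
    return(p$g_max * hill_down(ph, p$pk_down, p$n_down))
  }
  predict_growth(p, ph)
}

#' @export
tidy.biphasic_hill_fit <- function(x, ...) {
  tibble(
    term = c("g_max", "pk_up", "n_up", "pk_down", "n_down"),
    estimate = unlist(x$params[c("g_max", "pk_up", "n_up",
                                 "pk_down", "n_down")]),
    std.error = unname(x$se[c("g_max", "pk_up", "n_up",
                              "pk_down", "n_down")])
  )
}

#' @export
glance.biphasic_hill_fit <- function(x, ...) {
  tibble(rss = x$rss, sigma = x$sigma, df.residual = x$df_residual,
         nobs = x$n_obs, converged = x$convergence,
         reduced.model = x$reduced_model)
}

#' @rdname fit_biphasic_hill
#' @param object A `biphasic_hill_fit`.
#' @param ... Unused.
#' @export
autoplot.biphasic_hill_fit <- function(object, ...) {
  grid <- tibble(ph = seq(min(object$data$ph), max(object$data$ph),
                          length.out = 200))
  grid$growth_pct <- predict(object, grid$ph)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$ph,
                                            y = .data$growth_pct)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(data = grid, colour = "black", linewidth = 0.8) +
    ggplot2::labs(x = "medium pH", y = "growth (% of maximum)") +
    ggplot2::theme_minimal()
}
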