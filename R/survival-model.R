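#' Biphasic Hill survival-model parameters
#'
#' Container for the five parameters of the biphasic Hill-type pH-survival
#' model used to describe growth of cultured cells across a gradient of medium
#' pH. Growth is modelled as the product of two cooperative proton-binding
#' interactions: an activatory limb that rises with pH (growth is lost below
#' `pk_up`, the acid-limiting midpoint) and an inhibitory limb that falls with
#' pH (growth is lost above `pk_down`, the alkaline-limiting midpoint):
#'
#' \deqn{G(pH) = g_{max} \cdot \frac{1}{1 + 10^{n_{up}(pk_{up} - pH)}} \cdot
#'       \frac{1}{1 + 10^{n_{down}(pH - pk_{down})}}}
#'
#' Each limb is a Hill function of proton concentration with binding constant
#' \eqn{10^{-pk}} and Hill coefficient \eqn{n}; working on the pH scale turns
#' them into the logistic sigmoids above.
#'
#' @param g_max Maximal growth, in the units of the fitted data (100 for
#'   curves normalized to percent of maximal growth). Must be positive.
#' @param pk_up Midpoint pH of the rising, acid-limiting limb.
#' @param n_up Hill coefficient of the rising limb (> 0).
#' @param pk_down Midpoint pH of the falling, alkaline-limiting limb.
#' @param n_down Hill coefficient of the falling limb (> 0).
#'
#' @return An object of class `biphasic_hill_params` (a named list).
#' @examples
#' p <- biphasic_hill_params(100, 6.6, 2, 7.9, 3)
#' predict_growth(p, c(6.2, 7.0, 7.7))
#' @export
biphasic_hill_params <- function(g_max = 100, pk_up = 6.6, n_up = 2,
                                 pk_down = 7.9, n_down = 3) {
  check_number(g_max, "g_max", lower = 1e-12)
  check_number(pk_up, "pk_up")
  check_number(pk_down, "pk_down")
  check_number(n_up, "n_up", lower = 1e-12)
  check_number(n_down, "n_down", lower = 1e-12)
  if (pk_up >= pk_down) {
    abort("`pk_up` must be below `pk_down` for a biphasic growth optimum.")
  }
  structure(
    list(g_max = g_max, pk_up = pk_up, n_up = n_up,
         pk_down = pk_down, n_down = n_down),
    class = "biphasic_hill_params"
  )
}

#' @export
print.biphasic_hill_params <- function(x, ...) {
  cat("Biphasic Hill survival parameters\n")
  cat(sprintf("  g_max   %8.3f\n", x$g_max))
  cat(sprintf("  pk_up   %8.3f   n_up   %6.3f\n", x$pk_up, x$n_up))
  cat(sprintf("  pk_down %8.3f   n_down %6.3f\n", x$pk_down, x$n_down))
  invisible(x)
}

# the two sigmoid limbs, kept separate so invariants can be tested
hill_up <- function(ph, pk_up, n_up) 1 / (1 + 10^(n_up * (pk_up - ph)))
hill_down <- function(ph, pk_down, n_down) 1 / (1 + 10^(n_down * (ph - pk_down)))

#' Evaluate the biphasic Hill survival model
#'
#' @param params A [biphasic_hill_params()] object (or a named list with the
#'   same fields).
#' @param ph Numeric vector of medium pH values.
#' @return Numeric vector of predicted growth, same length as `ph`.
#' @export
predict_growth <- function(params, ph) {
  stopifnot(is.numeric(ph))
  params$g_max * hill_up(ph, params$pk_up, params$n_up) *
    hill_down(ph, params$pk_down, params$n_down)
}
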