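#' Stationary ATP concentration at a given lactate level
#'
#' Setting `dATP/dt = 0` in the ATP balance gives
#' \deqn{ATP = \nu/k + (\gamma/k)\,L/(K_L + L),}
#' a monotone nondecreasing, saturating function of extracellular lactate.
#'
#' @param params an [atp_model_params()] object.
#' @param l extracellular lactate, mM (vectorised, nonnegative).
#' @return Stationary ATP, mM.
#' @export
atp_steady_state <- function(params, l) {
  stopifnot(inherits(params, "atp_model_params"))
  if (any(l < 0)) stop("lactate must be nonnegative")
  params$nu / params$k + (params$gamma / params$k) * l / (params$k_l + l)
}

#' Lactate-driven pump saturation
#'
#' The ATP Michaelis saturation of the calcium pumps, expressed through the
#' composite parameters of the ATP balance:
#' \deqn{h(L) = \frac{\phi + \omega L/(K_L+L)}{1 + \phi + \omega L/(K_L+L)}}
#' with `phi = nu/(k Km)` and `omega = gamma/(k Km)`. Equals
#' `ATP/(Km + ATP)` at the stationary ATP of [atp_steady_state()]; strictly
#' inside (0, 1) whenever `phi + omega > 0`.
#'
#' @param phi,omega dimensionless saturation parameters, nonnegative.
#' @param k_l lactate affinity, mM; positive.
#' @param l extracellular lactate, mM (vectorised, nonnegative).
#' @return Saturation in `[0, 1)`, dimensionless.
#' @export
lactate_saturation <- function(phi, omega, k_l, l) {
  if (any(l < 0)) stop("lactate must be nonnegative")
  s <- phi + omega * l / (k_l + l)
  s / (1 + s)
}

#' Stationary cytosolic calcium at a given lactate level
#'
#' Solves the steady-state quadratic
#' \deqn{\delta\,h(L)\,x^2 + B\,x - 1 = 0}
#' for its unique positive root
#' \deqn{x = \frac{-B + \sqrt{B^2 + 4\,\delta h(L)}}{2\,\delta h(L)}.}
#' The constant term -1 forces roots of opposite sign, so positivity and
#' uniqueness are structural. With `omega > 0` the root decreases strictly
#' with lactate: more lactate means more ATP, stronger pumping, lower
#' stationary cytosolic calcium.
#'
#' @param params a [steady_state_params()] object.
#' @param l extracellular lactate, mM (scalar; see [predict_curve()] for the
#'   vectorised form).
#' @return Stationary cytosolic calcium, nM.
#' @examples
#' tg <- steady_state_params(0.0013, 0.011, 1.8251, 52.4576, 3.6864e-6,
#'                           with_thapsigargin = TRUE)
#' ca_steady_state(tg, 0.08)   # ~238 nM, cf. the observed 240 +/- 39 nM
#' @export
ca_steady_state <- function(params, l) {
  stopifnot(inherits(params, "steady_state_params"),
            is.numeric(l), length(l) == 1L)
  a <- params$delta * lactate_saturation(params$phi, params$omega,
                                         params$k_l, l)
  if (a <= 0)
    stop("delta * h(L) must be positive: no bounded positive steady state")
  (-params$b + sqrt(params$b^2 + 4 * a)) / (2 * a)
}

#' Lactate dose-response curve of stationary calcium
#'
#' Vectorised [ca_steady_state()]; strictly decreasing in lactate whenever
#' `omega > 0`.
#'
#' @param params a [steady_state_params()] object.
#' @param l_values extracellular lactate values, mM.
#' @return Numeric vector of stationary cytosolic calcium, nM.
#' @export
predict_curve <- function(params, l_values) {
  vapply(l_values, function(l) ca_steady_state(params, l), numeric(1))
}

#' Compare pre- and post-thapsigargin steady-state parameters
#'
#' Derives the two headline pump-physiology quantities from a fitted pair of
#' parameter sets: the ER-to-vesicular pump activity ratio
#' `(delta' - delta)/delta` and the fractional drop in the constitutive ATP
#' parameter `(phi_pre - phi_post)/phi_pre`.
#'
#' @param pre a [steady_state_params()] object with
#'   `with_thapsigargin = FALSE` (its delta is delta prime).
#' @param post a [steady_state_params()] object with
#'   `with_thapsigargin = TRUE`.
#' @return A list with elements `pump_ratio` and `phi_change_fraction`.
#' @export
compare_conditions <- function(pre, post) {
  stopifnot(inherits(pre, "steady_state_params"),
            inherits(post, "steady_state_params"))
  if (pre$with_thapsigargin || !post$with_thapsigargin)
    stop("expected pre without thapsigargin and post with thapsigargin")
  if (post$delta <= 0) stop("delta must be positive")
  list(pump_ratio = (pre$delta - post$delta) / post$delta,
       phi_change_fraction = (pre$phi - post$phi) / pre$phi)
}
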