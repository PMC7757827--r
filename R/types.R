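#' Reduced dynamic-model parameters
#'
#' The five phenomenological rate constants of the post-thapsigargin
#' two-variable calcium system
#' \deqn{d[Ca]_{cyt}/dt = p - q[Ca]_{cyt} + r[Ca]_{ret} - d[Ca]_{cyt}^2}
#' \deqn{d[Ca]_{ret}/dt = g([Ca]_{cyt} - [Ca]_{ret}).}
#' Concentrations are in nM and time in s throughout, so `p` is in nM/s,
#' `q`, `r`, `g` in 1/s and `d` in 1/(nM s).
#'
#' @param p constant cytosolic source term, nM/s.
#' @param q first-order cytosolic removal constant, 1/s.
#' @param r ER-leak feed constant, 1/s.
#' @param d quadratic (pump-driven) removal constant, 1/(nM s); must be
#'   strictly positive for a finite positive steady state to exist.
#' @param g ER equilibration constant, 1/s.
#' @return An object of class `reduced_params` (named numeric list).
#' @examples
#' reduced_params(p = 0.247, q = 1.77e-8, r = 6.27e-5, d = 2.31e-5, g = 3.38e-3)
#' @export
reduced_params <- function(p, q, r, d, g) {
  v <- c(p, q, r, d, g)
  names(v) <- c("p", "q", "r", "d", "g")
  stopifnot(is.numeric(v), length(v) == 5L, all(is.finite(v)))
  if (any(v < 0)) stop("reduced parameters must be nonnegative")
  structure(as.list(v), class = "reduced_params")
}

#' @export
print.reduced_params <- function(x, ...) {
  cat("Reduced calcium-model parameters:\n")
  print(unlist(x))
  invisible(x)
}

#' @export
as.numeric.reduced_params <- function(x, ...) unlist(x)

#' Cell compartment geometry
#'
#' Volumes, membrane areas and free-to-total calcium fractions of the three
#' compartments (cytosol, endoplasmic reticulum, acidic vesicles). The free
#' fraction f converts a free concentration to total compartment calcium:
#' total = free * Vol / f.
#'
#' @param vol_cyt,vol_ret,vol_ves compartment volumes, dm^3.
#' @param a_ret,a_ves ER and vesicular membrane areas, dm^2.
#' @param f_cyt,f_ret,f_ves free-to-total calcium fractions in (0, 1].
#' @return An object of class `cell_geometry`.
#' @export
cell_geometry <- function(vol_cyt, vol_ret, vol_ves, a_ret, a_ves,
                          f_cyt, f_ret, f_ves) {
  g <- list(vol_cyt = vol_cyt, vol_ret = vol_ret, vol_ves = vol_ves,
            a_ret = a_ret, a_ves = a_ves,
            f_cyt = f_cyt, f_ret = f_ret, f_ves = f_ves)
  num <- unlist(g)
  stopifnot(all(is.finite(num)))
  if (any(num[1:5] <= 0)) stop("volumes and areas must be positive")
  fr <- num[6:8]
  if (any(fr <= 0 | fr > 1)) stop("free fractions must lie in (0, 1]")
  structure(g, class = "cell_geometry")
}

#' Physical (flux-level) constants of the closed model
#'
#' Leak permeabilities, pump composite rates and the opaque composite
#' constants that enter the reduction to [reduced_params()]. `alpha`, `beta`
#' and the pump composites are treated as opaque positive inputs; they group
#' pump densities and rate constants that the printed material does not
#' resolve individually.
#'
#' @param p_leak1 ER leak permeability, dm/s.
#' @param p_leak2 vesicular leak permeability, dm/s.
#' @param alpha,beta opaque composite constants of the vesicular leak.
#' @param k3_prime vesicular pump rate constant.
#' @param k2_atpase_ret composite ER (SERCA) pump rate.
#' @param k2p_k1p_atpase_ves composite vesicular pump rate.
#' @param km_atp pump ATP affinity, mM.
#' @return An object of class `physical_params`.
#' @export
physical_params <- function(p_leak1, p_leak2, alpha = 1, beta = 1,
                            k3_prime = 1, k2_atpase_ret = 1,
                            k2p_k1p_atpase_ves = 1, km_atp = 2e-3) {
  if (p_leak1 < 0 || p_leak2 < 0)
    stop("permeabilities must be nonnegative")
  if (km_atp <= 0) stop("km_atp must be positive")
  structure(list(p_leak1 = p_leak1, p_leak2 = p_leak2, alpha = alpha,
                 beta = beta, k3_prime = k3_prime,
                 k2_atpase_ret = k2_atpase_ret,
                 k2p_k1p_atpase_ves = k2p_k1p_atpase_ves, km_atp = km_atp),
            class = "physical_params")
}

#' Free calcium concentrations of the three compartments
#'
#' @param ca_cyt,ca_ret,ca_ves free concentrations, nM; all nonnegative.
#' @return An object of class `cell_state`.
#' @export
cell_state <- function(ca_cyt, ca_ret, ca_ves) {
  v <- c(ca_cyt, ca_ret, ca_ves)
  stopifnot(all(is.finite(v)))
  if (any(v < 0)) stop("concentrations must be nonnegative")
  structure(list(ca_cyt = ca_cyt, ca_ret = ca_ret, ca_ves = ca_ves),
            class = "cell_state")
}

#' Timestamped cytosolic calcium record
#'
#' A fura-2-style record of cytosolic free calcium versus time, optionally
#' annotated with the time at which thapsigargin was added.
#'
#' @param t observation times, s; strictly increasing, length >= 2.
#' @param ca_cyt cytosolic free calcium, nM; same length as `t`, nonnegative.
#' @param thapsigargin_time optional time of thapsigargin addition, s.
#' @return An object of class `calcium_trace`.
#' @export
calcium_trace <- function(t, ca_cyt, thapsigargin_time = NULL) {
  stopifnot(is.numeric(t), is.numeric(ca_cyt))
  if (length(t) != length(ca_cyt))
    stop("t and ca_cyt must have the same length")
  if (length(t) < 2L) stop("a trace needs at least two observations")
  if (anyNA(t) || anyNA(ca_cyt)) stop("NA values are not allowed in a trace")
  if (any(diff(t) <= 0)) stop("times must be strictly increasing")
  if (any(ca_cyt < 0)) stop("ca_cyt must be nonnegative")
  if (!is.null(thapsigargin_time))
    stopifnot(is.numeric(thapsigargin_time), length(thapsigargin_time) == 1L)
  structure(list(t = as.numeric(t), ca_cyt = as.numeric(ca_cyt),
                 thapsigargin_time = thapsigargin_time),
            class = "calcium_trace")
}

#' @export
print.calcium_trace <- function(x, ...) {
  cat(sprintf("Calcium trace: %d points, t in [%g, %g] s, [Ca2+]cyt in [%g, %g] nM\n",
              length(x$t), min(x$t), max(x$t), min(x$ca_cyt), max(x$ca_cyt)))
  if (!is.null(x$thapsigargin_time))
    cat(sprintf("  thapsigargin added at t = %g s\n", x$thapsigargin_time))
  invisible(x)
}

#' ATP balance parameters
#'
#' Parameters of the cytosolic ATP balance
#' \deqn{dATP/dt = \nu + \gamma L/(K_L + L) - k\,ATP,}
#' i.e. constitutive synthesis plus a lactate-transport-limited synthesis
#' term (rectangular hyperbola in extracellular lactate L) minus first-order
#' hydrolysis.
#'
#' @param nu constitutive ATP synthesis rate, mM/s.
#' @param gamma maximal lactate-driven synthesis rate, mM/s.
#' @param k first-order ATP hydrolysis constant, 1/s; positive.
#' @param k_l lactate transporter affinity, mM; positive.
#' @param km_atp pump ATP affinity, mM.
#' @return An object of class `atp_model_params`.
#' @export
atp_model_params <- function(nu, gamma, k, k_l, km_atp = 2e-3) {
  if (k <= 0) stop("k must be positive")
  if (k_l <= 0) stop("k_l must be positive")
  if (nu < 0 || gamma < 0) stop("nu and gamma must be nonnegative")
  structure(list(nu = nu, gamma = gamma, k = k, k_l = k_l, km_atp = km_atp),
            class = "atp_model_params")
}

#' Steady-state model parameters
#'
#' Composite parameters of the lactate-modulated steady-state quadratic
#' \deqn{\delta\,h(L)\,x^2 + B\,x - 1 = 0,}
#' where `x` is the stationary cytosolic calcium in nM and
#' `h(L) = (phi + omega L/(k_l + L)) / (1 + phi + omega L/(k_l + L))` is the
#' ATP Michaelis saturation of the pumps expressed through lactate-driven ATP
#' synthesis. With thapsigargin only the vesicular pump contributes (delta);
#' without it the ER pump adds in (delta prime), so the same class holds
#' either condition and a flag records which.
#'
#' @param delta pump-strength composite, 1/nM^2; delta with thapsigargin,
#'   delta prime without. Strictly positive.
#' @param phi dimensionless constitutive ATP saturation parameter
#'   (nu / (k Km)); nonnegative.
#' @param omega dimensionless lactate-driven saturation parameter
#'   (gamma / (k Km)); nonnegative.
#' @param k_l lactate transporter affinity, mM; positive.
#' @param b linear coefficient (q - r)/p of the underlying dynamics, 1/nM.
#' @param with_thapsigargin logical; `TRUE` selects the thapsigargin
#'   (vesicular-pump-only) interpretation of `delta`.
#' @return An object of class `steady_state_params`.
#' @examples
#' steady_state_params(delta = 0.0013, phi = 0.011, omega = 1.8251,
#'                     k_l = 52.4576, b = 3.6864e-6, with_thapsigargin = TRUE)
#' @export
steady_state_params <- function(delta, phi, omega, k_l, b,
                                with_thapsigargin = FALSE) {
  if (delta <= 0) stop("delta must be positive")
  if (k_l <= 0) stop("k_l must be positive")
  if (phi < 0 || omega < 0) stop("phi and omega must be nonnegative")
  stopifnot(is.logical(with_thapsigargin), length(with_thapsigargin) == 1L)
  structure(list(delta = delta, phi = phi, omega = omega, k_l = k_l, b = b,
                 with_thapsigargin = with_thapsigargin),
            class = "steady_state_params")
}

#' @export
print.steady_state_params <- function(x, ...) {
  cat(sprintf("Steady-state parameters (%s thapsigargin):\n",
              if (x$with_thapsigargin) "with" else "without"))
  print(unlist(x[c("delta", "phi", "omega", "k_l", "b")]))
  invisible(x)
}

#' Lactate dose-response records
#'
#' @param l extracellular lactate, mM; unique nonnegative values.
#' @param ca_ss stationary cytosolic calcium, nM; positive.
#' @param sem optional standard errors, nM.
#' @return An object of class `lactate_response` (a data.frame).
#' @export
lactate_response <- function(l, ca_ss, sem = NULL) {
  stopifnot(length(l) == length(ca_ss))
  if (any(l < 0)) stop("lactate concentrations must be nonnegative")
  if (any(ca_ss <= 0)) stop("steady-state calcium must be positive")
  if (anyDuplicated(l)) stop("lactate concentrations must be unique")
  df <- data.frame(l = as.numeric(l), ca_ss = as.numeric(ca_ss))
  df$sem <- if (is.null(sem)) NA_real_ else as.numeric(sem)
  class(df) <- c("lactate_response", "data.frame")
  df
}
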