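#' Right-hand side of the reduced post-thapsigargin system
#'
#' Evaluates the vector field of the two-variable reduced model at a state
#' `(ca_cyt, ca_ret)`:
#' \deqn{d[Ca]_{cyt}/dt = p - q[Ca]_{cyt} + r[Ca]_{ret} - d[Ca]_{cyt}^2}
#' \deqn{d[Ca]_{ret}/dt = g([Ca]_{cyt} - [Ca]_{ret}).}
#'
#' @param state numeric length-2 vector `(ca_cyt, ca_ret)`, nM; nonnegative.
#' @param params a [reduced_params()] object.
#' @return Numeric length-2 vector of time derivatives, nM/s.
#' @export
reduced_rhs <- function(state, params) {
  stopifnot(inherits(params, "reduced_params"),
            is.numeric(state), length(state) == 2L)
  if (any(state < 0)) stop("state components must be nonnegative")
  cyt <- state[[1]]; ret <- state[[2]]
  c(params$p - params$q * cyt + params$r * ret - params$d * cyt^2,
    params$g * (cyt - ret))
}

#' Integrate the reduced dynamic model
#'
#' Solves the reduced two-variable system with an adaptive Dormand-Prince
#' Runge-Kutta 4(5) pair (the same family as MATLAB's `ode45`) and returns
#' the solution evaluated on a user grid. The first row of the result is the
#' initial condition, exactly.
#'
#' @param params a [reduced_params()] object.
#' @param ic numeric length-2 initial condition `(ca_cyt0, ca_ret0)`, nM.
#' @param t_grid strictly increasing times, s, including the initial time as
#'   its first element.
#' @param rel_tol,abs_tol integrator tolerances; defaults 1e-8 relative,
#'   1e-3 nM absolute.
#' @return A data.frame with columns `t`, `ca_cyt`, `ca_ret`.
#' @examples
#' th <- reduced_params(0.247, 1.77e-8, 6.27e-5, 2.31e-5, 3.38e-3)
#' sol <- simulate_reduced(th, c(30, 60000), seq(0, 1800, by = 3))
#' max(sol$ca_cyt)   # thapsigargin-style transient peak
#' @export
simulate_reduced <- function(params, ic, t_grid,
                             rel_tol = 1e-8, abs_tol = 1e-3) {
  stopifnot(inherits(params, "reduced_params"),
            is.numeric(ic), length(ic) == 2L, all(is.finite(ic)),
            is.numeric(t_grid), length(t_grid) >= 2L)
  if (any(diff(t_grid) <= 0)) stop("t_grid must be strictly increasing")
  if (rel_tol <= 0 || abs_tol <= 0) stop("tolerances must be positive")
  m <- cpp_simulate_reduced(params$p, params$q, params$r, params$d, params$g,
                            as.numeric(ic), as.numeric(t_grid),
                            rel_tol, abs_tol)
  data.frame(t = as.numeric(t_grid), ca_cyt = m[, 1], ca_ret = m[, 2])
}

#' Analytic steady state of the reduced model
#'
#' At the fixed point both derivatives vanish, which forces
#' `ca_ret = ca_cyt` and leaves the quadratic
#' `d x^2 - (r - q) x - p = 0`. Because the root product is `-p/d < 0`
#' whenever `p > 0`, exactly one root is nonnegative; that root is returned:
#' \deqn{x = \frac{(r-q) + \sqrt{(r-q)^2 + 4dp}}{2d}.}
#'
#' @param params a [reduced_params()] object with `d > 0`.
#' @return Stationary cytosolic calcium, nM.
#' @export
reduced_steady_state <- function(params) {
  stopifnot(inherits(params, "reduced_params"))
  if (params$d <= 0) {
    if (params$p > 0)
      stop("d <= 0 with p > 0: no finite positive steady state")
    # p = 0, linear system: origin if q >= r
    return(0)
  }
  a <- params$r - params$q
  (a + sqrt(a^2 + 4 * params$d * params$p)) / (2 * params$d)
}

#' Total cell calcium of a compartment state
#'
#' Converts the free concentrations to total compartment calcium and sums:
#' `sum(ca_X * vol_X / f_X)` over cytosol, ER and acidic vesicles. Division
#' by the free fraction converts a free concentration to total calcium; with
#' concentrations in nM and volumes in dm^3 the result has units of
#' nmol (nM * dm^3 = 1e-9 mol/L * L).
#'
#' @param state a [cell_state()] object.
#' @param geom a [cell_geometry()] object.
#' @return Total calcium amount, nmol.
#' @export
total_calcium <- function(state, geom) {
  stopifnot(inherits(state, "cell_state"), inherits(geom, "cell_geometry"))
  state$ca_cyt * geom$vol_cyt / geom$f_cyt +
    state$ca_ret * geom$vol_ret / geom$f_ret +
    state$ca_ves * geom$vol_ves / geom$f_ves
}

#' Vesicular concentration from conservation
#'
#' Inverts [total_calcium()] for the vesicular compartment of a closed cell:
#' given the conserved total and the cytosolic and ER free concentrations,
#' returns the implied vesicular free concentration.
#'
#' @param total conserved total calcium, nmol.
#' @param ca_cyt,ca_ret free concentrations, nM.
#' @param geom a [cell_geometry()] object.
#' @return Vesicular free calcium, nM.
#' @export
ves_from_conservation <- function(total, ca_cyt, ca_ret, geom) {
  stopifnot(inherits(geom, "cell_geometry"))
  rest <- ca_cyt * geom$vol_cyt / geom$f_cyt +
    ca_ret * geom$vol_ret / geom$f_ret
  ves <- (total - rest) * geom$f_ves / geom$vol_ves
  if (ves < 0)
    stop("inconsistent inputs: implied vesicular calcium is negative")
  ves
}

#' Map physical constants to reduced parameters
#'
#' Composes the reduced rate constants from compartment geometry and
#' flux-level constants. The ER equilibration constant is fully determined:
#' `g = p_leak1 * a_ret * f_ret / vol_ret`. The remaining groupings carry
#' opaque composite factors (`alpha`, `beta`, `a_total`) that stand in for
#' unresolved pump/leak algebra; they default to values that keep every
#' output finite and nonnegative:
#' \itemize{
#'   \item `p = alpha * a_total * p_leak2 * a_ves * f_cyt / (vol_cyt * f_ves * vol_ves)`
#'   \item `q = alpha * p_leak2 * a_ves * (beta * f_ves / vol_ves + f_cyt / vol_cyt) + p_leak1 * a_ret * f_cyt / vol_cyt`
#'   \item `r = p_leak1 * a_ret * f_cyt / vol_cyt`
#'   \item `d = f_cyt / vol_cyt * k3_prime`
#' }
#' Only `g` is quantitatively trustworthy (its inputs are direct geometric
#' measurements); `p`, `q`, `r`, `d` serve as order-of-magnitude initial
#' values for fitting and are refit in practice.
#'
#' @param geom a [cell_geometry()] object.
#' @param phys a [physical_params()] object.
#' @param a_total opaque composite amplitude entering `p` (default 1).
#' @return A [reduced_params()] object.
#' @examples
#' g4 <- cell_geometry(8.6e-13, 1.3e-13, 1.8e-15, 3.6e-7, 2.1e-9,
#'                     0.01, 0.01, 0.01)
#' ph <- physical_params(p_leak1 = 1e-7, p_leak2 = 1e-7)
#' map_physical_to_reduced(g4, ph)$g   # ~2.77e-3 1/s
#' @export
map_physical_to_reduced <- function(geom, phys, a_total = 1) {
  stopifnot(inherits(geom, "cell_geometry"), inherits(phys, "physical_params"))
  fc_vc <- geom$f_cyt / geom$vol_cyt
  p <- phys$alpha * a_total * phys$p_leak2 * geom$a_ves * fc_vc /
    (geom$f_ves * geom$vol_ves)
  q <- phys$alpha * phys$p_leak2 * geom$a_ves *
    (phys$beta * geom$f_ves / geom$vol_ves + fc_vc) +
    phys$p_leak1 * geom$a_ret * fc_vc
  r <- phys$p_leak1 * geom$a_ret * fc_vc
  d <- fc_vc * phys$k3_prime
  g <- phys$p_leak1 * geom$a_ret * geom$f_ret / geom$vol_ret
  reduced_params(p = p, q = q, r = r, d = d, g = g)
}

#' Integrate the full closed three-compartment model
#'
#' Simulates free calcium in cytosol, ER and acidic vesicles with leak
#' fluxes proportional to concentration differences and pump fluxes
#' proportional to `ca_cyt^2 * [ATP]/(Km + [ATP])`. Thapsigargin sets the
#' SERCA (ER pump) flux to zero. The cell is closed: the three net fluxes
#' sum to zero by construction, so [total_calcium()] is a conserved quantity
#' of the continuous system and is preserved by the integration up to the
#' integrator tolerance.
#'
#' @param geom a [cell_geometry()] object.
#' @param phys a [physical_params()] object.
#' @param state0 a [cell_state()] initial condition.
#' @param t_grid strictly increasing times, s.
#' @param atp cytosolic ATP held constant during the run, mM (default
#'   1.33 mM, the measured resting value).
#' @param thapsigargin logical; `TRUE` blocks the SERCA flux.
#' @param rel_tol,abs_tol integrator tolerances.
#' @return A data.frame with columns `t`, `ca_cyt`, `ca_ret`, `ca_ves`.
#' @export
simulate_full <- function(geom, phys, state0, t_grid, atp = 1.33,
                          thapsigargin = TRUE,
                          rel_tol = 1e-8, abs_tol = 1e-3) {
  stopifnot(inherits(geom, "cell_geometry"), inherits(phys, "physical_params"),
            inherits(state0, "cell_state"),
            is.numeric(t_grid), length(t_grid) >= 2L)
  if (any(diff(t_grid) <= 0)) stop("t_grid must be strictly increasing")
  pars <- list(p_leak1 = phys$p_leak1, p_leak2 = phys$p_leak2,
               a_ret = geom$a_ret, a_ves = geom$a_ves,
               k_serca = phys$k2_atpase_ret, k_av = phys$k2p_k1p_atpase_ves,
               atp_sat = atp / (phys$km_atp + atp),
               fc_vc = geom$f_cyt / geom$vol_cyt,
               fr_vr = geom$f_ret / geom$vol_ret,
               fv_vv = geom$f_ves / geom$vol_ves)
  m <- cpp_simulate_full(pars, c(state0$ca_cyt, state0$ca_ret, state0$ca_ves),
                         as.numeric(t_grid), rel_tol, abs_tol,
                         isTRUE(thapsigargin))
  data.frame(t = as.numeric(t_grid),
             ca_cyt = m[, 1], ca_ret = m[, 2], ca_ves = m[, 3])
}
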