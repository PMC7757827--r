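#' Coefficient of determination
#'
#' `1 - SS_res / SS_tot` with the total sum of squares taken about the mean
#' of the observations.
#'
#' @param observed,predicted numeric vectors of equal length >= 2.
#' @return R-squared (at most 1; can be negative for a fit worse than the
#'   mean).
#' @export
r_squared <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 2L)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) stop("observed values have zero variance")
  1 - sum((observed - predicted)^2) / ss_tot
}

# objective value returned when the integrator fails inside a simplex step,
# large enough to repel the simplex but finite so it can recover
.MSE_PENALTY <- 1e12

# post-thapsigargin portion of a trace (the whole trace when no event time)
.post_thapsigargin <- function(trace) {
  if (is.null(trace$thapsigargin_time)) return(trace)
  keep <- trace$t >= trace$thapsigargin_time
  if (sum(keep) < 2L) stop("fewer than two post-thapsigargin observations")
  calcium_trace(trace$t[keep], trace$ca_cyt[keep],
                thapsigargin_time = trace$thapsigargin_time)
}

.predict_trace <- function(params, trace, ic_ret, rel_tol, abs_tol) {
  cpp_simulate_reduced(params$p, params$q, params$r, params$d, params$g,
                       c(trace$ca_cyt[1], ic_ret), trace$t,
                       rel_tol, abs_tol)[, 1]
}

#' Mean squared error of the reduced model against a trace
#'
#' Integrates the reduced model from the first observed cytosolic value and
#' a supplied ER load, over the post-thapsigargin observation times, and
#' returns the mean of squared residuals. An integrator failure (possible
#' for pathological parameter combinations visited by the simplex) returns a
#' large finite penalty rather than an error, so that an optimiser can move
#' away from the failing region.
#'
#' @param params a [reduced_params()] object.
#' @param trace a [calcium_trace()]; only observations at or after
#'   `thapsigargin_time` (when set) are used.
#' @param ic_ret initial ER free calcium, nM.
#' @param rel_tol,abs_tol integrator tolerances.
#' @return Mean squared error, nM^2.
#' @export
mse_objective <- function(params, trace, ic_ret,
                          rel_tol = 1e-8, abs_tol = 1e-3) {
  stopifnot(inherits(params, "reduced_params"),
            inherits(trace, "calcium_trace"))
  tr <- .post_thapsigargin(trace)
  pred <- tryCatch(.predict_trace(params, tr, ic_ret, rel_tol, abs_tol),
                   error = function(e) NULL)
  if (is.null(pred) || anyNA(pred)) return(.MSE_PENALTY)
  mean((tr$ca_cyt - pred)^2)
}

# Nelder-Mead over log-parameters with restarts: rebuild the simplex at the
# previous optimum until the objective stops improving. Returns the running
# best objective after the initial point and each optim() run in $history.
.fit_nm <- function(theta0, fn, maxit, reltol, restarts) {
  best <- list(par = theta0, value = fn(theta0))
  history <- best$value
  n_iter <- 0L
  converged <- FALSE
  for (i in seq_len(restarts + 1L)) {
    opt <- stats::optim(best$par, fn, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = reltol))
    n_iter <- n_iter + opt$counts[["function"]]
    if (opt$value <= best$value) best <- opt[c("par", "value")]
    history <- c(history, best$value)
    if (opt$convergence == 0L) converged <- TRUE
    improv <- history[length(history) - 1L] - best$value
    if (improv <= reltol * (abs(best$value) + reltol)) break
  }
  list(par = best$par, value = best$value, n_iter = n_iter,
       converged = converged, history = history)
}

.new_fit_result <- function(params, mse, r2, n_iter, converged, fixed_names,
                            ...) {
  structure(c(list(params = params, mse = mse, r2 = r2, n_iter = n_iter,
                   converged = converged, fixed_names = fixed_names),
              list(...)),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Fit result: mse = %.6g, R^2 = %.4f, %d evaluations%s\n",
              x$mse, x$r2, x$n_iter,
              if (x$converged) "" else " (not converged)"))
  print(x$params)
  if (length(x$fixed_names))
    cat("Held fixed:", paste(x$fixed_names, collapse = ", "), "\n")
  invisible(x)
}

#' Fit the reduced dynamic model to a calcium trace
#'
#' Nelder-Mead simplex minimisation of [mse_objective()] over the five rate
#' constants and (by default) the initial ER load. All quantities are
#' strictly positive, so the simplex runs over log-parameters, which both
#' enforces positivity and equalises scales across constants spanning eight
#' orders of magnitude. The simplex can optionally be restarted at its own
#' optimum (`restarts`), which refines toward the exact minimum; the default
#' is a single run, because with realistic measurement noise the refinement
#' chases a sloppy (p, q) ridge of the objective — it lowers the MSE by a
#' few percent while degrading the identifiable parameters (see the package
#' vignette).
#'
#' @param trace a [calcium_trace()] with at least 10 post-thapsigargin
#'   observations.
#' @param init a [reduced_params()] object of strictly positive starting
#'   values (the same starting set can be reused across an experiment
#'   cohort).
#' @param init_ca_ret starting ER free calcium, nM; default 60000 nM
#'   (60 uM), a typical loaded-ER value.
#' @param options list overriding any of `fit_ca_ret0` (logical, default
#'   `TRUE`: treat the ER load as a sixth adjustable), `maxit` (per simplex
#'   run, default 5000), `reltol` (default 1e-10), `restarts` (default 0),
#'   `rel_tol`/`abs_tol` (integrator tolerances).
#' @return A `fit_result` with elements `params` ([reduced_params()]),
#'   `ca_ret0`, `mse`, `r2`, `n_iter`, `converged`, `fixed_names`,
#'   `history` (best objective after the initial point and each simplex
#'   run, nonincreasing) and `fitted` (data.frame of `t`, `observed`,
#'   `predicted`).
#' @export
fit_trace <- function(trace, init, init_ca_ret = 6e4, options = list()) {
  stopifnot(inherits(trace, "calcium_trace"), inherits(init, "reduced_params"))
  opt <- modifyList(list(fit_ca_ret0 = TRUE, maxit = 5000, reltol = 1e-10,
                         restarts = 0, rel_tol = 1e-8, abs_tol = 1e-3),
                    options)
  tr <- .post_thapsigargin(trace)
  if (length(tr$t) < 10L)
    stop("need at least 10 post-thapsigargin observations")
  start <- unlist(init)
  if (opt$fit_ca_ret0) start <- c(start, ca_ret0 = init_ca_ret)
  if (any(start <= 0))
    stop("all starting values must be strictly positive (log scale)")

  obj <- function(theta) {
    v <- exp(theta)
    ret0 <- if (opt$fit_ca_ret0) v[[6]] else init_ca_ret
    pred <- tryCatch(
      cpp_simulate_reduced(v[[1]], v[[2]], v[[3]], v[[4]], v[[5]],
                           c(tr$ca_cyt[1], ret0), tr$t,
                           opt$rel_tol, opt$abs_tol)[, 1],
      error = function(e) NULL)
    if (is.null(pred) || anyNA(pred)) return(.MSE_PENALTY)
    mean((tr$ca_cyt - pred)^2)
  }
  fit <- .fit_nm(log(start), obj, opt$maxit, opt$reltol, opt$restarts)
  v <- exp(fit$par)
  params <- reduced_params(v[[1]], v[[2]], v[[3]], v[[4]], v[[5]])
  ca_ret0 <- if (opt$fit_ca_ret0) v[[6]] else init_ca_ret
  pred <- .predict_trace(params, tr, ca_ret0, opt$rel_tol, opt$abs_tol)
  .new_fit_result(params, mse = fit$value, r2 = r_squared(tr$ca_cyt, pred),
                  n_iter = fit$n_iter, converged = fit$converged,
                  fixed_names = if (opt$fit_ca_ret0) character(0) else "ca_ret0",
                  ca_ret0 = ca_ret0, history = fit$history,
                  fitted = data.frame(t = tr$t, observed = tr$ca_cyt,
                                      predicted = pred))
}

#' Extrapolate a steady state by exponential decay
#'
#' Least-squares fit of `y(t) = ca_ss + amplitude * exp(-rate * (t -
#' t_start))` to the trace tail at/after `t_start`; the asymptote `ca_ss` is
#' the extrapolated stationary cytosolic calcium. This is how stationary
#' values are estimated from recordings that end before the decay completes.
#'
#' @param trace a [calcium_trace()].
#' @param t_start start of the fitted tail, s; defaults to the thapsigargin
#'   time (or the first observation when neither is available).
#' @return An `exp_decay_fit` list with `ca_ss`, `amplitude`, `rate`, `r2`
#'   and `decaying` (`FALSE` flags a non-decaying record).
#' @export
fit_exponential_decay <- function(trace, t_start = NULL) {
  stopifnot(inherits(trace, "calcium_trace"))
  if (is.null(t_start))
    t_start <- if (!is.null(trace$thapsigargin_time))
      trace$thapsigargin_time else trace$t[1]
  keep <- trace$t >= t_start
  if (sum(keep) < 4L)
    stop("need at least 4 observations at/after t_start")
  tt <- trace$t[keep] - t_start
  y <- trace$ca_cyt[keep]

  if (sd(y) < 1e-12) {            # degenerate constant record
    return(structure(list(ca_ss = mean(y), amplitude = 0, rate = NA_real_,
                          r2 = 1, decaying = FALSE),
                     class = "exp_decay_fit"))
  }
  fit <- tryCatch(
    # scaleOffset makes the convergence test valid for zero-residual
    # (noise-free) records
    nls(y ~ SSasymp(tt, Asym, R0, lrc),
        control = stats::nls.control(maxiter = 200, scaleOffset = 1)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    cf <- coef(fit)
    ca_ss <- cf[["Asym"]]; rate <- exp(cf[["lrc"]])
    amplitude <- cf[["R0"]] - ca_ss
    pred <- ca_ss + amplitude * exp(-rate * tt)
  } else {
    # direct SSE minimisation as fallback when the self-start model fails
    obj <- function(th) {
      p <- th[1] + th[2] * exp(-exp(th[3]) * tt)
      sum((y - p)^2)
    }
    th0 <- c(min(y), y[1] - min(y) + 1e-6, log(1 / max(tt)))
    o <- stats::optim(th0, obj, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-12))
    ca_ss <- o$par[1]; amplitude <- o$par[2]; rate <- exp(o$par[3])
    pred <- ca_ss + amplitude * exp(-rate * tt)
  }
  structure(list(ca_ss = ca_ss, amplitude = amplitude, rate = rate,
                 r2 = r_squared(y, pred),
                 decaying = is.finite(rate) && rate > 0 && amplitude > 0),
            class = "exp_decay_fit")
}

#' @export
print.exp_decay_fit <- function(x, ...) {
  cat(sprintf(
    "Exponential-decay extrapolation: ca_ss = %.4g nM, amplitude = %.4g nM, rate = %.4g 1/s, R^2 = %.4f\n",
    x$ca_ss, x$amplitude, x$rate, x$r2))
  invisible(x)
}

.SS_PAR_NAMES <- c("delta", "phi", "omega", "k_l", "b")

#' Fit the steady-state model to a lactate dose-response
#'
#' Minimises the squared residuals of [predict_curve()] against observed
#' (lactate, stationary calcium) pairs, over any subset of the five
#' composite parameters; the rest are held at their values in `init`.
#' Optimisation runs over log-parameters via Nelder-Mead with restarts.
#' The canonical two-stage protocol of [fit_lactate_two_stage()] builds on
#' this with `fixed_names = c("omega", "k_l", "b")` in its second stage.
#'
#' @param data a [lactate_response()].
#' @param init a [steady_state_params()] object; starting values for the
#'   free parameters and held values for the fixed ones.
#' @param fixed_names character subset of
#'   `c("delta", "phi", "omega", "k_l", "b")` held fixed. Fixing all five
#'   evaluates the model as-is (no iterations).
#' @param options list overriding `maxit`, `reltol`, `restarts` as in
#'   [fit_trace()].
#' @return A `fit_result`; `params` is a [steady_state_params()] carrying
#'   `init`'s thapsigargin flag.
#' @export
fit_lactate_curve <- function(data, init, fixed_names = character(),
                              options = list()) {
  stopifnot(inherits(data, "lactate_response"),
            inherits(init, "steady_state_params"))
  if (!all(fixed_names %in% .SS_PAR_NAMES))
    stop("fixed_names must be among: ", paste(.SS_PAR_NAMES, collapse = ", "))
  opt <- modifyList(list(maxit = 5000, reltol = 1e-10, restarts = 3),
                    options)
  free <- setdiff(.SS_PAR_NAMES, fixed_names)
  full <- unlist(init[.SS_PAR_NAMES])

  make_params <- function(vals) {
    full[free] <- vals
    steady_state_params(full[["delta"]], full[["phi"]], full[["omega"]],
                        full[["k_l"]], full[["b"]],
                        with_thapsigargin = init$with_thapsigargin)
  }
  sse <- function(p) sum((data$ca_ss - predict_curve(p, data$l))^2)

  if (length(free) == 0L) {
    p <- make_params(numeric(0))
    return(.new_fit_result(p, mse = sse(p) / nrow(data),
                           r2 = r_squared(data$ca_ss, predict_curve(p, data$l)),
                           n_iter = 0L, converged = TRUE,
                           fixed_names = fixed_names))
  }
  if (nrow(data) < length(free))
    stop("under-determined: fewer data points than free parameters")
  if (any(full[free] <= 0))
    stop("starting values of free parameters must be strictly positive")

  obj <- function(theta) {
    p <- tryCatch(make_params(exp(theta)), error = function(e) NULL)
    if (is.null(p)) return(.MSE_PENALTY)
    sse(p)
  }
  fit <- .fit_nm(log(full[free]), obj, opt$maxit, opt$reltol, opt$restarts)
  params <- make_params(exp(fit$par))
  pred <- predict_curve(params, data$l)
  .new_fit_result(params, mse = fit$value / nrow(data),
                  r2 = r_squared(data$ca_ss, pred),
                  n_iter = fit$n_iter, converged = fit$converged,
                  fixed_names = fixed_names, history = fit$history,
                  fitted = data.frame(l = data$l, observed = data$ca_ss,
                                      predicted = pred))
}

#' Two-stage fit of both lactate dose-response conditions
#'
#' Stage 1 fits all five parameters to the with-thapsigargin data. Stage 2
#' fits only (`delta`, `phi`) to the without-thapsigargin data, holding
#' (`omega`, `k_l`, `b`) at their stage-1 values — lactate transport and
#' the underlying calcium dynamics are condition-independent, while pump
#' strength (SERCA active or not) and the constitutive ATP parameter may
#' differ.
#'
#' @param post with-thapsigargin [lactate_response()].
#' @param pre without-thapsigargin [lactate_response()].
#' @param init a [steady_state_params()] of starting values (flag ignored);
#'   stage 2 starts from the same `delta` and `phi`.
#' @param options passed to [fit_lactate_curve()].
#' @return List with `post` and `pre` fit results and the derived
#'   `comparison` of [compare_conditions()].
#' @export
fit_lactate_two_stage <- function(post, pre, init, options = list()) {
  init_post <- steady_state_params(init$delta, init$phi, init$omega,
                                   init$k_l, init$b, with_thapsigargin = TRUE)
  fit_post <- fit_lactate_curve(post, init_post, options = options)
  p1 <- fit_post$params
  init_pre <- steady_state_params(init$delta, init$phi, p1$omega, p1$k_l,
                                  p1$b, with_thapsigargin = FALSE)
  fit_pre <- fit_lactate_curve(pre, init_pre,
                               fixed_names = c("omega", "k_l", "b"),
                               options = options)
  list(post = fit_post, pre = fit_pre,
       comparison = compare_conditions(fit_pre$params, fit_post$params))
}

#' Summary statistics of a cohort of fitted parameter sets
#'
#' Per-parameter arithmetic mean, coefficient of variation
#' (`100 * sd / mean`, sample standard deviation with n-1 denominator) and
#' ratio of the mean to the shared starting value.
#'
#' @param results list of [reduced_params()] (or `fit_result`) objects,
#'   length >= 2.
#' @param initial the [reduced_params()] starting set shared by the fits.
#' @return A `summary_table` data.frame with one row per parameter and
#'   columns `mean`, `cv_percent`, `ratio_to_initial`.
#' @export
summarize_fits <- function(results, initial) {
  stopifnot(is.list(results), length(results) >= 2L,
            inherits(initial, "reduced_params"))
  mat <- t(vapply(results, function(x) {
    if (inherits(x, "fit_result")) x <- x$params
    stopifnot(inherits(x, "reduced_params"))
    unlist(x)
  }, numeric(5)))
  means <- colMeans(mat)
  if (any(means == 0))
    warning("parameter mean of zero: CV% undefined for that parameter")
  tab <- data.frame(
    mean = means,
    cv_percent = ifelse(means == 0, NA_real_,
                        100 * apply(mat, 2, sd) / means),
    ratio_to_initial = means / unlist(initial),
    row.names = names(means))
  class(tab) <- c("summary_table", "data.frame")
  tab
}
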