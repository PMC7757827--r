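test_that("r_squared behaves and reproduces the dose-response fit quality", {
  obs <- c(3, 1, 4, 1, 5)
  expect_equal(r_squared(obs, obs), 1)
  expect_equal(r_squared(obs, rep(mean(obs), 5)), 0)
  expect_error(r_squared(rep(2, 5), obs), "zero variance")

  t1 <- fixture_table1()
  post <- fixture_table5("post")
  expect_equal(round(r_squared(t1$post$ca_ss, predict_curve(post, t1$post$l)),
                     2), 0.98)
})

test_that("mse_objective measures model-trace discrepancy", {
  th <- mean_dynamic_params()

  # self-consistency on a noiseless trace
  tr <- generate_trace(trace_gen_spec(th, ca_cyt0 = 30, ca_ret0 = 6e4,
                                      noise_sd = 0))
  expect_lt(mse_objective(th, tr, 6e4), 1e-8)

  # constant trace against the matching null vector field
  null <- reduced_params(0, 0, 0, 0, 0)
  flat <- calcium_trace(seq(0, 100, by = 10), rep(55, 11))
  expect_equal(mse_objective(null, flat, 70), 0)

  # with Gaussian noise of sd sigma the mse at the true parameters
  # approaches sigma^2 (law of large numbers at n = 2001)
  trn <- generate_trace(trace_gen_spec(th, ca_cyt0 = 30, ca_ret0 = 6e4,
                                       duration = 2000, dt = 1,
                                       noise_sd = 10, seed = 99))
  expect_lt(abs(mse_objective(th, trn, 6e4) - 100) / 100, 0.10)
})

test_that("fit_trace recovers the generating parameters from clean data", {
  th <- mean_dynamic_params()
  tr <- generate_trace(trace_gen_spec(th, ca_cyt0 = 30, ca_ret0 = 6e4,
                                      noise_sd = 0))

  # perturbed start, restarts to polish the exact optimum
  fit <- fit_trace(tr, scale_params(th, 2), init_ca_ret = 1.2e5,
                   options = list(restarts = 2))
  rel <- abs(unlist(fit$params) - unlist(th)) / unlist(th)
  expect_lt(max(rel[c("p", "r", "d", "g")]), 0.05)  # q weakly identifiable
  expect_gt(fit$r2, 0.999)
  expect_lt(fit$mse, 1e-6)
  expect_equal(fit$ca_ret0, 6e4, tolerance = 0.01)

  # starting at the optimum terminates immediately with a tiny objective
  fit0 <- fit_trace(tr, th, init_ca_ret = 6e4)
  expect_lt(fit0$mse, 1e-6)
  expect_true(fit0$converged)

  # the running best objective never increases across simplex runs
  expect_true(all(diff(fit$history) <= 0))

  expect_error(fit_trace(calcium_trace(1:5, rep(30, 5)), th),
               "at least 10")
})

test_that("noisy synthetic traces fit with the familiar R^2 band", {
  th <- mean_dynamic_params()
  for (s in 1:3) {
    tr <- generate_trace(trace_gen_spec(th, ca_cyt0 = 30, ca_ret0 = 6e4,
                                        noise_sd = 10, seed = s))
    fit <- fit_trace(tr, scale_params(th, 2), init_ca_ret = 6e4,
                     options = list(fit_ca_ret0 = FALSE))
    expect_gte(fit$r2, 0.97)
    expect_lte(fit$r2, 0.999)
  }
})

test_that("parameter recovery holds for the identifiable constants", {
  # 20 seeded noisy traces (sd 10 nM, 600 samples over 1800 s); medians of
  # the relative errors of p, r, d, g stay under 15%. q is excluded: its
  # contribution q*[Ca] sits orders of magnitude below the quadratic term,
  # so it is unidentifiable by design. The ER load is pinned at the
  # generator's value because the cytosol observes only r*[Ca]ret(t),
  # making (r, ca_ret0) structurally confounded.
  th <- mean_dynamic_params()
  errs <- vapply(1:20, function(s) {
    tr <- generate_trace(trace_gen_spec(th, ca_cyt0 = 30, ca_ret0 = 6e4,
                                        noise_sd = 10, seed = s))
    fit <- fit_trace(tr, scale_params(th, 2), init_ca_ret = 6e4,
                     options = list(fit_ca_ret0 = FALSE))
    abs(unlist(fit$params) - unlist(th)) / unlist(th)
  }, numeric(5))
  med <- apply(errs, 1, median)
  expect_lt(med[["p"]], 0.15)
  expect_lt(med[["r"]], 0.15)
  expect_lt(med[["d"]], 0.15)
  expect_lt(med[["g"]], 0.15)
})

test_that("fit_exponential_decay extrapolates the stationary level", {
  # exact exponential round trip
  t <- seq(0, 300, by = 5)
  tr <- calcium_trace(t, 100 + 200 * exp(-0.01 * t))
  fit <- fit_exponential_decay(tr, t_start = 0)
  expect_equal(fit$ca_ss, 100, tolerance = 1e-6)
  expect_equal(fit$amplitude, 200, tolerance = 1e-6)
  expect_equal(fit$rate, 0.01, tolerance = 1e-6)
  expect_true(fit$decaying)

  # constant record
  flat <- calcium_trace(seq(0, 30, by = 5), rep(42, 7))
  ffit <- fit_exponential_decay(flat)
  expect_equal(ffit$ca_ss, 42)
  expect_equal(ffit$amplitude, 0)
  expect_false(ffit$decaying)

  # under-determined tail
  expect_error(fit_exponential_decay(calcium_trace(1:3, c(3, 2, 1)),
                                     t_start = 0), "at least 4")

  # the extrapolation rationale: the tail of a reduced-model transient
  # lands within 10% of the analytic steady state
  th <- mean_dynamic_params()
  sol <- simulate_reduced(th, c(30, 6e4), seq(0, 1800, by = 3))
  tail_fit <- fit_exponential_decay(calcium_trace(sol$t, pmax(sol$ca_cyt, 0)),
                                    t_start = 300)
  expect_lt(abs(tail_fit$ca_ss - reduced_steady_state(th)) /
              reduced_steady_state(th), 0.10)
})

test_that("fit_lactate_curve honours fixed subsets and recovers exact data", {
  post_true <- fixture_table5("post")
  l <- c(0.08, 0.4, 0.8, 1.5, 10)
  exact <- lactate_response(l, predict_curve(post_true, l))

  # all fixed: straight evaluation, no iterations
  fixed_all <- fit_lactate_curve(exact, post_true,
                                 fixed_names = c("delta", "phi", "omega",
                                                 "k_l", "b"))
  expect_identical(fixed_all$n_iter, 0L)
  expect_equal(fixed_all$r2, 1, tolerance = 1e-12)

  # recovery of (delta, phi, b) from a perturbed start along the
  # identifiable directions, omega and K_L pinned
  init <- steady_state_params(post_true$delta * 3, post_true$phi * 3,
                              post_true$omega, post_true$k_l,
                              post_true$b * 3, TRUE)
  fit <- fit_lactate_curve(exact, init, fixed_names = c("omega", "k_l"))
  expect_lt(fit$mse, 1e-10)
  expect_equal(fit$params$delta, post_true$delta, tolerance = 1e-3)
  expect_equal(fit$params$phi, post_true$phi, tolerance = 1e-3)

  # under-determined configuration rejected
  three <- lactate_response(c(0.1, 1, 10), c(200, 150, 60))
  expect_error(fit_lactate_curve(three, init), "under-determined")
})

test_that("the two-stage dose-response protocol matches the printed quality", {
  t1 <- fixture_table1()
  init <- fixture_table5("init")
  ts <- fit_lactate_two_stage(t1$post, t1$pre, init)
  # the printed fit quality for both conditions
  expect_gte(round(ts$post$r2, 2), 0.98)
  expect_gte(round(ts$pre$r2, 2), 0.98)
  # stage 2 holds the transport/dynamics parameters at stage-1 values
  expect_setequal(ts$pre$fixed_names, c("omega", "k_l", "b"))
  expect_equal(ts$pre$params$omega, ts$post$params$omega)
  # ER + vesicular pumping beats vesicular alone
  expect_gt(ts$comparison$pump_ratio, 0)
})

test_that("summarize_fits reproduces the cohort aggregates", {
  t2 <- fixture_table2()
  init <- fixture_table3_initial()
  tab <- summarize_fits(attr(t2, "params"), init)

  expect_equal(signif(tab["p", "mean"], 3), 2.47e-1)
  expect_equal(signif(tab["r", "mean"], 3), 6.27e-5)
  expect_equal(signif(tab["d", "mean"], 3), 2.31e-5)
  expect_equal(signif(tab["g", "mean"], 3), 3.38e-3)
  expect_equal(round(tab["p", "cv_percent"]), 82)
  expect_equal(round(tab["g", "ratio_to_initial"], 2), 1.21)

  # permutation invariance
  perm <- summarize_fits(attr(t2, "params")[c(8:15, 1:7)], init)
  expect_equal(perm, tab)

  # identical inputs: zero dispersion
  th <- mean_dynamic_params()
  same <- summarize_fits(list(th, th, th), init)
  expect_equal(same$cv_percent, rep(0, 5))
  expect_equal(same$mean, unlist(th), ignore_attr = TRUE)
})
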