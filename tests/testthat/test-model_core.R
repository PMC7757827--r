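test_that("reduced_rhs matches its defining algebra and rejects bad states", {
  th <- mean_dynamic_params()

  # the analytic fixed point annihilates the vector field
  ss <- reduced_steady_state(th)
  expect_lt(max(abs(reduced_rhs(c(ss, ss), th))) / max(abs(unlist(th))), 1e-9)

  # state-dependent terms vanish at the origin
  expect_equal(reduced_rhs(c(0, 0), th), c(th$p, 0))

  # null vector field
  zero <- reduced_params(0, 0, 0, 0, 0)
  expect_equal(reduced_rhs(c(123, 456), zero), c(0, 0))

  expect_error(reduced_rhs(c(-1, 10), th), "nonnegative")
})

test_that("simulate_reduced agrees with an independent RK4 oracle", {
  th <- mean_dynamic_params()
  tgrid <- seq(0, 1800, by = 60)
  sol <- simulate_reduced(th, c(30, 6e4), tgrid,
                          rel_tol = 1e-10, abs_tol = 1e-8)
  ref <- rk4_oracle(reduced_rhs_oracle(th), c(30, 6e4), tgrid,
                    substeps = 1200)
  expect_lt(max(abs(sol$ca_cyt - ref[, 1])), 1e-5)
  expect_lt(max(abs(sol$ca_ret - ref[, 2])), 1e-5)
})

test_that("simulate_reduced honours its contract", {
  th <- mean_dynamic_params()
  ss <- reduced_steady_state(th)
  tgrid <- seq(0, 1800, by = 30)

  # first row is the initial condition, exactly
  sol <- simulate_reduced(th, c(30, 6e4), tgrid)
  expect_identical(sol$ca_cyt[1], 30)
  expect_identical(sol$ca_ret[1], 6e4)

  # fixed point stays put
  flat <- simulate_reduced(th, c(ss, ss), tgrid)
  expect_lt(max(abs(flat$ca_cyt - ss)), 1e-4)

  # transient peaks between the baseline and the ER load, then relaxes
  # toward the analytic steady state
  expect_gt(max(sol$ca_cyt), 30)
  expect_lt(max(sol$ca_cyt), 6e4)
  expect_lt(abs(sol$ca_cyt[length(tgrid)] - ss) / ss, 0.10)
  expect_lt(sol$ca_cyt[length(tgrid)], max(sol$ca_cyt))

  # g = 0 decouples the ER
  th0 <- reduced_params(th$p, th$q, th$r, th$d, 0)
  sol0 <- simulate_reduced(th0, c(30, 6e4), tgrid)
  expect_equal(sol0$ca_ret, rep(6e4, length(tgrid)))

  expect_error(simulate_reduced(th, c(30, 6e4), c(0, 10, 5)),
               "strictly increasing")
})

test_that("tightening the tolerance changes the trajectory below the bound", {
  th <- mean_dynamic_params()
  tgrid <- seq(0, 1800, by = 30)
  loose <- simulate_reduced(th, c(30, 6e4), tgrid, rel_tol = 1e-6)
  tight <- simulate_reduced(th, c(30, 6e4), tgrid, rel_tol = 1e-9)
  expect_lt(max(abs(loose$ca_cyt - tight$ca_cyt)),
            1e-6 * max(tight$ca_ret))
})

test_that("reduced_steady_state is the unique nonnegative quadratic root", {
  th <- mean_dynamic_params()

  # frozen from the long-horizon integration and the polyroot oracle;
  # inside the observed 100-200 nM asymptotic band
  expect_equal(reduced_steady_state(th), 104.7709, tolerance = 1e-6)
  roots <- positive_roots_oracle(th$d, -(th$r - th$q), -th$p)
  expect_length(roots, 1)
  expect_equal(reduced_steady_state(th), roots, tolerance = 1e-9)

  # degenerate cases
  expect_equal(reduced_steady_state(reduced_params(0, 2e-5, 1e-5, 1e-5, 0)), 0)
  th_qr <- reduced_params(0.25, 3e-5, 3e-5, 2e-5, 1e-3)
  expect_equal(reduced_steady_state(th_qr), sqrt(0.25 / 2e-5))
  expect_error(reduced_steady_state(reduced_params(1, 0, 0, 0, 0)),
               "no finite")

  # uniqueness and consistency with the t -> infinity limit over random draws
  set.seed(7)
  for (i in 1:100) {
    th_i <- reduced_params(p = runif(1, 0.01, 1), q = 10^runif(1, -9, -3),
                           r = 10^runif(1, -6, -3), d = 10^runif(1, -6, -4),
                           g = 10^runif(1, -3, -2))
    expect_length(positive_roots_oracle(th_i$d, -(th_i$r - th_i$q), -th_i$p),
                  1)
    ss_i <- reduced_steady_state(th_i)
    # 30x the slowest relaxation timescale (ER equilibration or the
    # linearised cytosolic rate at the fixed point)
    horizon <- 30 / min(th_i$g, th_i$q + 2 * th_i$d * ss_i)
    sim <- simulate_reduced(th_i, c(ss_i * 0.5, ss_i * 2),
                            c(0, horizon / 2, horizon))
    expect_lt(abs(sim$ca_cyt[3] - ss_i), 0.1)
  }
})

test_that("total_calcium sums free/f-weighted compartment contents", {
  geom <- table4_geometry()
  expect_equal(total_calcium(cell_state(0, 0, 0), geom), 0)

  # hand-arithmetic oracle at the characteristic concentrations
  st <- cell_state(77, 6e4, 4e4)
  by_hand <- 77 * 8.6e-13 / 0.01 + 6e4 * 1.3e-13 / 0.01 + 4e4 * 1.8e-15 / 0.01
  expect_equal(total_calcium(st, geom), by_hand)

  # linear in concentrations
  st2 <- cell_state(154, 12e4, 8e4)
  expect_equal(total_calcium(st2, geom), 2 * total_calcium(st, geom))
})

test_that("ves_from_conservation inverts total_calcium", {
  geom <- table4_geometry()
  set.seed(11)
  for (i in 1:1000) {
    st <- cell_state(runif(1, 0, 500), runif(1, 0, 1e5), runif(1, 0, 1e5))
    tot <- total_calcium(st, geom)
    ves <- ves_from_conservation(tot, st$ca_cyt, st$ca_ret, geom)
    # ca_ves itself is reconstructed through a cancelling subtraction whose
    # condition number is total/(vesicular share), so allow 1e-9; the
    # conserved-total round trip below carries the 1e-12 contract
    expect_equal(ves, st$ca_ves, tolerance = 1e-9)
    expect_equal(total_calcium(cell_state(st$ca_cyt, st$ca_ret, ves), geom),
                 tot, tolerance = 1e-12)
  }

  # cytosol + ER already hold the whole budget
  st <- cell_state(100, 5e4, 0)
  expect_equal(ves_from_conservation(total_calcium(st, geom), 100, 5e4, geom),
               0)
  expect_error(ves_from_conservation(0, 100, 5e4, geom), "negative")
})

test_that("map_physical_to_reduced composes g from ER geometry", {
  geom <- table4_geometry()
  phys <- physical_params(p_leak1 = 1e-7, p_leak2 = 1e-7, k3_prime = 288)

  red <- map_physical_to_reduced(geom, phys)
  # P_leak * A_ret * f_ret / Vol_ret, within 2% of the rounded reference
  # initial value 2.80e-3 1/s
  expect_equal(red$g, 1e-7 * 3.6e-7 * 0.01 / 1.3e-13, tolerance = 1e-12)
  expect_lt(abs(red$g - 2.80e-3) / 2.80e-3, 0.02)

  # no leaks, no exchange rates
  none <- map_physical_to_reduced(geom, physical_params(0, 0, k3_prime = 288))
  expect_equal(unlist(none)[c("p", "q", "r", "g")],
               c(p = 0, q = 0, r = 0, g = 0))

  # g is linear in ER area
  geom2 <- cell_geometry(8.6e-13, 1.3e-13, 1.8e-15, 2 * 3.6e-7, 2.1e-9,
                         0.01, 0.01, 0.01)
  expect_equal(map_physical_to_reduced(geom2, phys)$g, 2 * red$g)
})

test_that("the closed three-compartment model conserves total calcium", {
  geom <- table4_geometry()
  # pump composites scaled so the vesicular flux matches the magnitude of
  # the reduced model's quadratic removal term
  phys <- physical_params(p_leak1 = 1e-7, p_leak2 = 1e-7,
                          k2_atpase_ret = 2e-15, k2p_k1p_atpase_ves = 2e-15)
  st0 <- cell_state(30, 6e4, 4e4)
  tot0 <- total_calcium(st0, geom)
  for (thaps in c(TRUE, FALSE)) {
    sol <- simulate_full(geom, phys, st0, seq(0, 1800, by = 60),
                         thapsigargin = thaps, rel_tol = 1e-9)
    tots <- vapply(seq_len(nrow(sol)), function(i)
      total_calcium(cell_state(sol$ca_cyt[i], sol$ca_ret[i], sol$ca_ves[i]),
                    geom), numeric(1))
    expect_lt(max(abs(tots - tot0)) / tot0, 1e-6)
    # something actually moved between compartments
    expect_gt(max(sol$ca_cyt) - min(sol$ca_cyt), 1)
  }
  # thapsigargin kills ER uptake: the ER can only drain
  sol_tg <- simulate_full(geom, phys, st0, seq(0, 1800, by = 60),
                          thapsigargin = TRUE)
  expect_true(all(diff(sol_tg$ca_ret) <= 0))
})
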