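# Shared fixtures built in code.

# cohort-mean dynamic constants (the canonical working point)
mean_dynamic_params <- function() {
  reduced_params(p = 2.47e-1, q = 1.77e-8, r = 6.27e-5, d = 2.31e-5,
                 g = 3.38e-3)
}

scale_params <- function(params, factor) {
  v <- unlist(params) * factor
  reduced_params(v[["p"]], v[["q"]], v[["r"]], v[["d"]], v[["g"]])
}

table4_geometry <- function() {
  cell_geometry(vol_cyt = 8.6e-13, vol_ret = 1.3e-13, vol_ves = 1.8e-15,
                a_ret = 3.6e-7, a_ves = 2.1e-9,
                f_cyt = 0.01, f_ret = 0.01, f_ves = 0.01)
}

# independent fixed-step classical RK4 oracle, pure R, no shared code with
# the package integrator
rk4_oracle <- function(rhs, y0, t_grid, substeps = 20) {
  out <- matrix(NA_real_, length(t_grid), length(y0))
  out[1, ] <- y <- y0
  for (i in 2:length(t_grid)) {
    h <- (t_grid[i] - t_grid[i - 1]) / substeps
    for (s in seq_len(substeps)) {
      k1 <- rhs(y)
      k2 <- rhs(y + h / 2 * k1)
      k3 <- rhs(y + h / 2 * k2)
      k4 <- rhs(y + h * k3)
      y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    out[i, ] <- y
  }
  out
}

reduced_rhs_oracle <- function(params) {
  function(y) c(params$p - params$q * y[1] + params$r * y[2] -
                  params$d * y[1]^2,
                params$g * (y[1] - y[2]))
}

# positive root of a*x^2 + b*x + c = 0 via polyroot (independent of the
# closed forms used in the package)
positive_roots_oracle <- function(a, b, c) {
  z <- polyroot(c(c, b, a))
  re <- Re(z)[abs(Im(z)) < 1e-9]
  re[re >= 0]
}
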