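# Shared fixtures, built in code.

# symmetric reference cell (uniform adhesion, centred convergence zone)
sym_params <- function(n_grid = 801L, xi = 1000, mu = 1000, L = 20,
                       sigma = 1, amplitude = 10) {
  cell_params(L = L, x_cz = L / 2, sigma = sigma, amplitude = amplitude,
              mu = mu, xi_left = xi, n_grid = n_grid)
}

# observed profile traced from an analytic function on a uniform grid
fun_profile <- function(f, from = 0, to = 20, n = 101L) {
  x <- seq(from, to, length.out = n)
  observed_profile(x, f(x))
}

expect_rel <- function(actual, expected, tol) {
  expect_lt(abs(actual / expected - 1), tol)
}
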