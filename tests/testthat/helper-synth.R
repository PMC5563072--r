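# Shared fixtures and independent oracles for the test suite.

noiseless_truth <- function(...) {
  ground_truth(noise_gaussian_sd = 0, poisson_scale = 0, ...)
}

# Independent brute-force oracle for the single-boundary erf fit: grid over
# (c, m) with the linear parameters (a, b) solved analytically by least
# squares at each grid point. Returns the best rss found.
grid_oracle_single <- function(x, y, n_grid = 50) {
  cs <- seq(min(x), max(x), length.out = n_grid)
  ms <- exp(seq(log(2), log(500), length.out = n_grid))
  best <- Inf
  for (cc in cs) {
    for (mm in ms) {
      f <- pracma::erf(mm * (x - cc)) / 2
      fit <- stats::lm.fit(cbind(1, f), y)
      rss <- sum(fit$residuals^2)
      if (rss < best) best <- rss
    }
  }
  best
}

# Same idea for the double-boundary model: grid over (c1, c2) at a fixed
# boundary slope m, analytic (a, b).
grid_oracle_double <- function(x, y, m, n_grid = 50) {
  cs <- seq(0, 1, length.out = n_grid)
  best <- Inf
  for (i in seq_len(n_grid - 1L)) {
    for (j in (i + 1L):n_grid) {
      f <- (pracma::erf(m * (x - cs[i])) - pracma::erf(m * (x - cs[j]))) / 2
      fit <- stats::lm.fit(cbind(1, f), y)
      rss <- sum(fit$residuals^2)
      if (rss < best) best <- rss
    }
  }
  best
}

# circular shift of a plain numeric vector by k samples (value at index 1
# moves to index 1 + k)
rotate_vec <- function(v, k) {
  n <- length(v)
  k <- ((k %% n) + n) %% n
  if (k == 0) v else c(v[(n - k + 1L):n], v[1L:(n - k)])
}
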