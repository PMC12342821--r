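# Independent brute-force oracles for the forward model.  These deliberately
# re-derive everything from the defining formulas with plain dense
# quadrature, sharing no code with the package internals.

# truncated-Gaussian mixture density on a vector of distances
oracle_density <- function(r, means, sds, fracs) {
  out <- numeric(length(r))
  for (j in seq_along(means)) {
    z <- 1 - pnorm(0, means[j], sds[j])
    out <- out + fracs[j] * dnorm(r, means[j], sds[j]) / z
  }
  out
}

# single-acceptor unconvolved intensity by dense trapezoid quadrature
oracle_intensity_single <- function(tc, f_D, alphas, taus, R0,
                                    means, sds, fracs, A0 = 1,
                                    r_grid = seq(0.5, 150, length.out = 15001)) {
  h <- r_grid[2] - r_grid[1]
  w <- rep(h, length(r_grid)); w[c(1, length(r_grid))] <- h / 2
  dens <- oracle_density(r_grid, means, sds, fracs)
  dens <- dens / sum(w * dens)          # renormalize on the grid support
  donor <- rowSums(sapply(seq_along(alphas), function(i)
    alphas[i] * exp(-tc / taus[i])))
  fret <- vapply(tc, function(t) {
    sum(w * dens * rowSums(sapply(seq_along(alphas), function(i)
      alphas[i] * exp(-t / taus[i] - (t / taus[i]) * (R0 / r_grid)^6))))
  }, numeric(1))
  A0 * (f_D * donor + (1 - f_D) * fret)
}

# two-acceptor unconvolved intensity by direct 2-D quadrature of the double
# integral (no factorization)
oracle_intensity_double <- function(tc, alphas, taus, R0,
                                    means1, sds1, means2, sds2, fracs,
                                    n_r = 351L) {
  span <- function(means, sds)
    seq(max(0.5, min(means - 7 * sds)), max(means + 7 * sds),
        length.out = n_r)
  r1 <- span(means1, sds1); r2 <- span(means2, sds2)
  w1 <- rep(r1[2] - r1[1], n_r); w1[c(1, n_r)] <- w1[1] / 2
  w2 <- rep(r2[2] - r2[1], n_r); w2[c(1, n_r)] <- w2[1] / 2
  p1 <- oracle_density(r1, means1, sds1, fracs); p1 <- p1 / sum(w1 * p1)
  p2 <- oracle_density(r2, means2, sds2, fracs); p2 <- p2 / sum(w2 * p2)
  P <- outer(w1 * p1, w2 * p2)
  out <- numeric(length(tc))
  for (i in seq_along(alphas)) {
    Rate <- outer((R0 / r1)^6, (R0 / r2)^6, "+") + 1      # x (t / tau_i)
    for (k in seq_along(tc))
      out[k] <- out[k] + alphas[i] * sum(P * exp(-tc[k] * Rate / taus[i]))
  }
  out
}

# direct O(n^2) linear convolution truncated to length n
oracle_convolve <- function(a, b) {
  n <- length(a)
  out <- numeric(n)
  for (k in seq_len(n))
    out[k] <- sum(a[seq_len(k)] * b[k - seq_len(k) + 1])
  out
}

# small shared fixtures -------------------------------------------------------

small_grid <- function(n = 512L, bw = 0.2) time_grid(bw, n)

test_irf <- function(grid = small_grid(), seed = 42L)
  make_irf(grid, center = 2, fwhm = 0.4, total_counts = 5e5,
           background_rate = 0.01, seed = seed)

test_buffer <- function() buffer_model(c(5, 5), c(1, 6),
                                       acquisition_duration = 300)
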