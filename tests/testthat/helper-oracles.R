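# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: densities are written out from their formulas,
# integrals use stats::integrate, and the Bayes rule is applied brute-force.

# Closed-form inverse-Gaussian CDF (mean mu, shape lam), via the standard
# normal CDF.
pinvgauss_oracle <- function(q, mu, lam) {
  s <- sqrt(lam / q)
  stats::pnorm(s * (q / mu - 1)) +
    exp(2 * lam / mu) * stats::pnorm(-s * (q / mu + 1))
}

# Gamma prior on the precision sigma = 1/h^2 (the un-transformed form).
dprec_gamma <- function(sigma, alpha, beta) {
  stats::dgamma(sigma, shape = alpha, scale = beta)
}

# Mixture-of-Gaussians likelihood of the spike train at time t, bandwidth h.
likelihood_oracle <- function(h, t, ts) {
  vapply(h, function(hh) mean(stats::dnorm(t - ts, sd = hh)), numeric(1))
}

# Integrate f(h) over h in (0, Inf) via the substitution h = exp(u), which
# keeps sharply peaked posteriors (small-bandwidth regimes) well resolved.
# A coarse scan first brackets the support so the adaptive rule cannot lock
# onto a negligible secondary bump and miss the main mass.
integrate_logh <- function(f) {
  g <- function(u) f(exp(u)) * exp(u)
  us <- seq(-30, 10, length.out = 3001)
  gv <- g(us)
  keep <- which(gv > max(gv) * 1e-18)
  lo <- us[max(1L, min(keep) - 10L)]
  hi <- us[min(length(us), max(keep) + 10L)]
  stats::integrate(g, lo, hi, rel.tol = 1e-11, subdivisions = 600L)$value
}

# Brute-force Bayes posterior density: likelihood x prior / numeric marginal.
posterior_oracle <- function(h, t, ts, alpha, beta) {
  unnorm <- function(hh) {
    likelihood_oracle(hh, t, ts) * baks::prior_density(hh, alpha, beta)
  }
  Z <- integrate_logh(unnorm)
  unnorm(h) / Z
}

# Posterior-mean bandwidth by quadrature of h * posterior(h).
posterior_mean_oracle <- function(t, ts, alpha, beta) {
  unnorm <- function(hh) {
    likelihood_oracle(hh, t, ts) * baks::prior_density(hh, alpha, beta)
  }
  integrate_logh(function(hh) hh * unnorm(hh)) / integrate_logh(unnorm)
}

# Naive (linear-domain) evaluation of the closed-form bandwidth, for the
# log-domain equivalence check.
bandwidth_naive <- function(t, ts, alpha, beta) {
  q <- (t - ts)^2 / 2 + 1 / beta
  gamma(alpha) * sum(q^(-alpha)) /
    (gamma(alpha + 0.5) * sum(q^(-alpha - 0.5)))
}

# Rescale a spike train through a high-resolution cumulative intensity
# (independent of the simulator's coarser inversion grid) and return the
# rescaled ISIs, which should follow the renewal model's ISI law.
rescaled_isis <- function(st, rate, multiplier, dt = 2.5e-4) {
  grid <- seq(0, st$duration, by = dt)
  ci <- baks::cumulative_intensity(rate, grid, multiplier = multiplier)
  lam_at <- stats::approx(ci$time, ci$Lambda, xout = st$times)$y
  diff(c(0, lam_at))
}

# Shared fixture: the medium sine rate of the benchmark scenarios.
medium_sine <- function() {
  baks::rate_params("sine", eta = 50, amp = 25, freq = 1, phase = -pi / 2)
}
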