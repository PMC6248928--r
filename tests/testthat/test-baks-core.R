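test_that("default prior scale follows the n^(4/5) rule", {
  expect_equal(default_beta(1), 1)
  expect_equal(default_beta(32), 16)
  expect_equal(default_beta(100), 100^0.8)
  expect_error(default_beta(0), "n = 0")
})

test_that("the bandwidth prior is a proper density with the stated moments", {
  expect_equal(integrate(prior_density, 0, Inf, alpha = 4, beta = 1,
                         rel.tol = 1e-10)$value, 1, tolerance = 1e-8)
  expect_equal(integrate(prior_density, 0, Inf, alpha = 2.5, beta = 7,
                         rel.tol = 1e-10)$value, 1, tolerance = 1e-8)

  # change of variables against the Gamma density on the precision
  set.seed(12)
  h <- exp(runif(100, -2, 1))
  for (ab in list(c(4, 1), c(2, 0.5), c(7, 3))) {
    sigma <- 1 / h^2
    jac <- 2 / h^3                     # |d sigma / d h|
    expect_equal(prior_density(h, ab[1], ab[2]),
                 dprec_gamma(sigma, ab[1], ab[2]) * jac, tolerance = 1e-12)
  }

  # tails vanish
  expect_equal(prior_density(1e-4, 4, 1), 0, tolerance = 1e-10)
  expect_lt(prior_density(1e4, 4, 1), 1e-10)

  # moments: closed form vs quadrature and vs Monte Carlo through the
  # precision representation
  pm <- prior_moments(4, 1)
  expect_equal(pm$mean, gamma(3.5) / gamma(4), tolerance = 1e-12)
  m_quad <- integrate(function(h) h * prior_density(h, 4, 1), 0, Inf,
                      rel.tol = 1e-11)$value
  v_quad <- integrate(function(h) (h - m_quad)^2 * prior_density(h, 4, 1),
                      0, Inf, rel.tol = 1e-11)$value
  expect_equal(pm$mean, m_quad, tolerance = 1e-8)
  expect_equal(pm$variance, v_quad, tolerance = 1e-8)

  set.seed(13)
  hs <- 1 / sqrt(rgamma(1e6, shape = 4, scale = 1))
  expect_lt(abs(mean(hs) - pm$mean), 3 * sd(hs) / sqrt(1e6))

  # beta scaling: E[h] ~ beta^(-1/2)
  expect_equal(prior_moments(4, 4)$mean, prior_moments(4, 1)$mean / 2)

  expect_error(prior_moments(1, 1), "alpha > 1")
})

test_that("the bandwidth posterior is proper and matches the Bayes-rule oracle", {
  st1 <- spike_train(0.7, 2)
  expect_equal(integrate(posterior_density, 0, Inf, t = 0.5, spikes = st1,
                         alpha = 4, beta = 1, rel.tol = 1e-10)$value,
               1, tolerance = 1e-8)

  # mass shifts to larger h as the evaluation point leaves the lone spike
  m_near <- integrate(function(h) h * posterior_density(h, 0.7, st1, 4, 1),
                      0, Inf)$value
  m_far <- integrate(function(h) h * posterior_density(h, 1.9, st1, 4, 1),
                     0, Inf)$value
  expect_gt(m_far, m_near)

  # 50-spike train: closed form vs likelihood x prior / numeric marginal
  set.seed(14)
  ts <- sort(runif(50, 0, 2))
  st <- spike_train(ts, 2)
  hh <- exp(seq(log(0.02), log(2), length.out = 20))
  for (par in list(c(4, 1), c(2.5, 50^0.8))) {
    got <- posterior_density(hh, 0.8, st, par[1], par[2])
    want <- posterior_oracle(hh, 0.8, ts, par[1], par[2])
    expect_equal(got, want, tolerance = 1e-6)
  }

  expect_error(posterior_density(0.5, 1, spike_train(numeric(0), 2), 4, 1),
               "at least one spike")
})

test_that("closed-form adaptive bandwidth equals the posterior-mean quadrature", {
  # the central correctness oracle: 50 random (spikes, t, alpha, beta) cases
  set.seed(15)
  for (i in 1:50) {
    n <- sample(c(1, 3, 10, 50, 120), 1)
    ts <- sort(runif(n, 0, 2))
    t_eval <- runif(1, 0, 2)
    alpha <- runif(1, 1.2, 9)
    beta <- exp(runif(1, log(0.5), log(60)))
    closed <- adaptive_bandwidth(spike_train(ts, 2), alpha, beta,
                                 times = t_eval)$bandwidth
    quad <- posterior_mean_oracle(t_eval, ts, alpha, beta)
    expect_equal(closed, quad, tolerance = 1e-6)
  }
})

test_that("single-spike bandwidth and rate have their closed forms", {
  st <- spike_train(1, 2)
  h0 <- gamma(4) / gamma(4.5)
  expect_equal(adaptive_bandwidth(st, 4, 1, times = 1)$bandwidth, h0,
               tolerance = 1e-10)
  # one grid point at |t - t1| = sqrt(2): single-term ratio gives
  # h0 * sqrt((t-t1)^2/2 + 1)
  expect_equal(adaptive_bandwidth(st, 4, 1, times = 1 + sqrt(2))$bandwidth,
               h0 * sqrt(2), tolerance = 1e-10)
  fit <- estimate_rate(st, alpha = 4, beta = 1, times = 1)
  expect_equal(fit$rate, 1 / (sqrt(2 * pi) * h0), tolerance = 1e-10)
})

test_that("log-domain evaluation matches the naive form where it is finite", {
  set.seed(16)
  for (i in 1:20) {
    ts <- sort(runif(30, 0, 2))
    t_eval <- runif(1, 0, 2)
    alpha <- runif(1, 1.5, 8)
    beta <- exp(runif(1, log(1), log(30)))
    naive <- bandwidth_naive(t_eval, ts, alpha, beta)
    if (is.finite(naive) && naive > 0) {
      got <- adaptive_bandwidth(spike_train(ts, 2), alpha, beta,
                                times = t_eval)$bandwidth
      expect_equal(got, naive, tolerance = 1e-10)
    }
  }
  # a regime where the naive form would overflow: large alpha, tiny beta
  ts <- c(0.01, 1.99)
  h <- adaptive_bandwidth(spike_train(ts, 2), alpha = 50, beta = 1e-4,
                          times = seq(0, 2, by = 0.5))$bandwidth
  expect_true(all(is.finite(h) & h > 0))
})

test_that("estimates are translation invariant and mass-conserving", {
  set.seed(17)
  ts <- sort(runif(40, 0, 2))
  grid <- seq(0, 2, by = 0.01)
  f1 <- estimate_rate(spike_train(ts, 2), alpha = 4, times = grid)
  f2 <- estimate_rate(spike_train(ts + 5, 7.5), alpha = 4, times = grid + 5)
  expect_equal(f1$bandwidth, f2$bandwidth, tolerance = 1e-12)
  expect_equal(f1$rate, f2$rate, tolerance = 1e-12)

  # homogeneous Poisson train: integral of the estimate over an extended
  # grid approximately recovers the spike count
  const <- rate_params("sine", eta = 50, amp = 0, freq = 1)
  set.seed(18)
  st <- generate_spike_train(const, renewal_model("IG", 1, scale = 1), 2)
  ext <- seq(-1, 3, by = 1e-3)
  fit <- estimate_rate(st, alpha = 4, times = ext)
  mass <- sum(fit$rate) * 1e-3
  expect_equal(mass, length(st$times), tolerance = 0.05 * length(st$times))
})

test_that("bandwidth adapts to local spike density", {
  set.seed(19)
  ts <- sort(c(runif(50, 0, 1), runif(5, 1, 2)))
  ab <- adaptive_bandwidth(spike_train(ts, 2), alpha = 4,
                           times = seq(0, 2, by = 1e-3))
  dense <- mean(ab$bandwidth[ab$time >= 0.2 & ab$time <= 0.8])
  sparse <- mean(ab$bandwidth[ab$time >= 1.2 & ab$time <= 1.8])
  expect_lt(dense, sparse)
})

test_that("estimation error shrinks as the homogeneous rate grows tenfold", {
  md <- renewal_model("IG", 4, scale = 1)
  grid <- seq(0, 2, by = 1e-3)
  ise_at <- function(eta, seeds) {
    const <- rate_params("sine", eta = eta, amp = 0, freq = 1)
    truth <- evaluate_rate(const, grid)
    vapply(seeds, function(s) {
      set.seed(s)
      st <- generate_spike_train(const, md, 2)
      integrated_squared_error(estimate_rate(st, alpha = 4, times = grid),
                               truth)
    }, numeric(1))
  }
  lo <- ise_at(10, 1:30)
  hi <- ise_at(100, 1:30)
  expect_lt(median(hi) / 100^2, median(lo) / 10^2)  # relative error shrinks
})

test_that("empty and malformed inputs are rejected with guidance", {
  empty <- spike_train(numeric(0), 2)
  expect_error(estimate_rate(empty), "allow_empty")
  z <- estimate_rate(empty, allow_empty = TRUE)
  expect_true(all(z$rate == 0))
  expect_error(adaptive_bandwidth(empty, 4), "at least one spike")
  expect_error(estimate_rate(spike_train(1, 2), alpha = 4, beta = -1),
               "positive")
  expect_error(estimate_rate(spike_train(1, 2), alpha = 4, beta = "n^2"),
               "n\\^4/5")
})

test_that("tidy and glance summarise a fit", {
  set.seed(20)
  st <- generate_spike_train(medium_sine(), renewal_model("IG", 4, scale = 1), 2)
  fit <- estimate_rate(st, alpha = 4)
  td <- tidy(fit)
  expect_named(td, c("time", "bandwidth", "rate"))
  expect_equal(nrow(td), 2001)
  gl <- glance(fit)
  expect_equal(gl$n, length(st$times))
  expect_equal(gl$alpha, 4)
  expect_equal(gl$beta, length(st$times)^0.8)
  expect_s3_class(autoplot(fit), "ggplot")
})
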