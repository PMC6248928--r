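#' Default prior scale from the spike count
#'
#' The prior scale \eqn{\beta} is tied to the number of observed spikes as
#' \eqn{\beta = n^{4/5}}, matching the MISE convergence rate of a Gaussian
#' kernel so that the bandwidth shrinks appropriately as data accumulate.
#'
#' @param n Spike count (>= 1).
#' @return \eqn{n^{4/5}}.
#' @examples
#' default_beta(32)  # 16
#' @export
default_beta <- function(n) {
  if (length(n) != 1L || !is.numeric(n) || n < 1) {
    rlang::abort("`n` must be a positive spike count (beta is undefined at n = 0).")
  }
  n^(4 / 5)
}

# Resolve the beta argument: a positive number, or the rule token
# "n^4/5" / "auto" evaluated against the observed spike count.
resolve_beta <- function(beta, n) {
  if (is.character(beta)) {
    if (!beta %in% c("n^4/5", "auto")) {
      rlang::abort('`beta` must be a positive number or the rule "n^4/5".')
    }
    return(default_beta(n))
  }
  if (!is.numeric(beta) || length(beta) != 1L || beta <= 0) {
    rlang::abort("`beta` must be positive once resolved.")
  }
  as.numeric(beta)
}

#' Prior density of the kernel bandwidth
#'
#' The adaptive kernel places a Gamma(\eqn{\alpha}, scale \eqn{\beta}) prior
#' on the kernel precision \eqn{\sigma = 1/h^2}; the change of variables
#' gives the bandwidth prior
#' \deqn{\pi(h) = \frac{2\, h^{-2\alpha - 1}}{\Gamma(\alpha)\beta^\alpha}
#'   \exp\{-1/(\beta h^2)\}.}
#'
#' @param h Bandwidth value(s), s; must be positive.
#' @param alpha Prior shape \eqn{\alpha > 0}.
#' @param beta Prior scale \eqn{\beta > 0}.
#' @return Density value(s).
#' @examples
#' integrate(prior_density, 0, Inf, alpha = 4, beta = 1)  # 1
#' @export
prior_density <- function(h, alpha, beta) {
  stopifnot(alpha > 0, beta > 0)
  if (any(h <= 0)) rlang::abort("`h` must be positive.")
  exp(log(2) + (-2 * alpha - 1) * log(h) - lgamma(alpha) -
        alpha * log(beta) - 1 / (beta * h^2))
}

#' Prior mean and variance of the bandwidth
#'
#' Closed-form first two moments of the bandwidth prior:
#' \deqn{E[h] = \frac{\Gamma(\alpha - 1/2)}{\Gamma(\alpha)\,\beta^{1/2}},
#'   \qquad
#'   V[h] = \frac{\Gamma(\alpha)\Gamma(\alpha - 1) -
#'   \Gamma(\alpha - 1/2)^2}{\Gamma(\alpha)^2\,\beta}.}
#' Both require \eqn{\alpha > 1}.
#'
#' @inheritParams prior_density
#' @return A tibble with columns `mean` and `variance` (units s and s^2).
#' @examples
#' prior_moments(alpha = 4, beta = 1)
#' @export
prior_moments <- function(alpha, beta) {
  stopifnot(beta > 0)
  if (alpha <= 1) {
    rlang::abort("prior moments require alpha > 1 (they diverge otherwise).")
  }
  m <- exp(lgamma(alpha - 0.5) - lgamma(alpha)) / sqrt(beta)
  v <- (exp(lgamma(alpha) + lgamma(alpha - 1)) - exp(2 * lgamma(alpha - 0.5))) /
    (exp(2 * lgamma(alpha)) * beta)
  tibble::tibble(mean = m, variance = v)
}

#' Posterior density of the bandwidth at an evaluation time
#'
#' Combining the Gaussian-mixture likelihood of the spike train with the
#' bandwidth prior yields the closed-form posterior
#' \deqn{\pi(h \mid \rho) = \frac{\sum_i h^{-2\alpha - 2}
#'   \exp\{-[\,(t - t_i)^2/2 + 1/\beta\,]/h^2\}}
#'   {\tfrac12 \Gamma(\alpha + \tfrac12) \sum_i
#'   [\,(t - t_i)^2/2 + 1/\beta\,]^{-\alpha - 1/2}}.}
#'
#' @param h Bandwidth value(s), s; positive.
#' @param t Evaluation time, s.
#' @param spikes A [spike_train], numeric spike-time vector, or data frame
#'   with a `time` column; must contain at least one spike.
#' @inheritParams prior_density
#' @return Density value(s).
#' @examples
#' st <- spike_train(c(0.4, 0.6, 1.1), 2)
#' integrate(posterior_density, 0, Inf, t = 0.5, spikes = st,
#'           alpha = 4, beta = 1)  # 1
#' @export
posterior_density <- function(h, t, spikes, alpha, beta) {
  ts <- spike_times_of(spikes)
  if (!length(ts)) rlang::abort("`spikes` must contain at least one spike.")
  stopifnot(alpha > 0, beta > 0, length(t) == 1L)
  if (any(h <= 0)) rlang::abort("`h` must be positive.")
  q <- (t - ts)^2 / 2 + 1 / beta                    # one value per spike
  log_den <- log(0.5) + lgamma(alpha + 0.5) +
    logsumexp_rows(matrix((-alpha - 0.5) * log(q), nrow = 1L))
  vapply(h, function(hh) {
    log_num <- logsumexp_rows(matrix((-2 * alpha - 2) * log(hh) - q / hh^2,
                                     nrow = 1L))
    exp(log_num - log_den)
  }, numeric(1))
}

# Core bandwidth computation on precomputed log-terms.
# Lq: matrix [grid x n] of log((t - t_i)^2/2 + 1/beta).
bandwidth_from_logq <- function(Lq, alpha) {
  log_num <- logsumexp_rows(-alpha * Lq)
  log_den <- logsumexp_rows((-alpha - 0.5) * Lq)
  exp(lgamma(alpha) - lgamma(alpha + 0.5) + log_num - log_den)
}

#' Posterior-mean adaptive bandwidth
#'
#' Evaluates the closed-form posterior mean of the bandwidth at every grid
#' time,
#' \deqn{\hat h(t) = \frac{\Gamma(\alpha) \sum_i
#'   [\,(t - t_i)^2/2 + 1/\beta\,]^{-\alpha}}
#'   {\Gamma(\alpha + \tfrac12) \sum_i
#'   [\,(t - t_i)^2/2 + 1/\beta\,]^{-\alpha - 1/2}},}
#' working in the log domain (log-gamma and log-sum-exp over spikes) so the
#' spike sums cannot under- or overflow for large \eqn{\alpha} or distant
#' spikes.  The bandwidth is small where the local spike density is high.
#'
#' @inheritParams posterior_density
#' @param times Evaluation grid, s.
#' @return A tibble with columns `time` (s) and `bandwidth` (s), classed
#'   `bandwidth_curve`.
#' @examples
#' st <- spike_train(1, 2)
#' adaptive_bandwidth(st, alpha = 4, beta = 1, times = 1)
#' # gamma(4)/gamma(4.5) = 0.51583
#' @export
adaptive_bandwidth <- function(spikes, alpha, beta = "n^4/5",
                               times = NULL) {
  ts <- spike_times_of(spikes)
  if (!length(ts)) rlang::abort("`spikes` must contain at least one spike.")
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0)
  beta <- resolve_beta(beta, length(ts))
  if (is.null(times)) {
    dur <- if (inherits(spikes, "spike_train")) spikes$duration
           else max(ts)
    times <- default_grid(dur)
  }
  Lq <- log(outer(times, ts, `-`)^2 / 2 + 1 / beta)
  h <- bandwidth_from_logq(Lq, alpha)
  out <- tibble::tibble(time = as.numeric(times), bandwidth = h)
  class(out) <- c("bandwidth_curve", class(out))
  out
}

#' Estimate a firing rate with the Bayesian adaptive kernel smoother
#'
#' The rate estimate is the sum of Gaussian kernels centred on the spike
#' times with the posterior-mean adaptive bandwidth at each evaluation time:
#' \deqn{\hat\lambda(t) = \sum_{i=1}^n \frac{1}{\sqrt{2\pi}\,\hat h(t)}
#'   \exp\left\{-\frac{(t - t_i)^2}{2 \hat h(t)^2}\right\}.}
#'
#' @inheritParams adaptive_bandwidth
#' @param duration Recording duration \eqn{T}, s; taken from the
#'   `spike_train` when available.  Used to build the default 1 ms grid.
#' @param dt Grid step of the default evaluation grid, s.
#' @param allow_empty If `TRUE`, an empty train yields an all-zero curve
#'   instead of an error.
#'
#' @return A tibble of class `baks_fit` with columns `time` (s),
#'   `bandwidth` (s) and `rate` (spikes/s), carrying the fit parameters as
#'   attributes (`alpha`, `beta`, `n`, `duration`).
#'
#' @examples
#' set.seed(2)
#' rp <- rate_params("sine", eta = 50, amp = 25, freq = 1, phase = -pi / 2)
#' st <- generate_spike_train(rp, renewal_model("IG", 4, scale = 1), 2)
#' fit <- estimate_rate(st, alpha = 4)
#' fit
#' glance(fit)
#' @export
estimate_rate <- function(spikes, alpha = 4, beta = "n^4/5",
                          times = NULL, duration = NULL, dt = 1e-3,
                          allow_empty = FALSE) {
  ts <- spike_times_of(spikes)
  if (is.null(duration)) {
    duration <- if (inherits(spikes, "spike_train")) spikes$duration
                else if (length(ts)) max(ts) else
                  rlang::abort("`duration` required when spikes carry none.")
  }
  if (is.null(times)) times <- default_grid(duration, dt)
  if (!length(ts)) {
    if (!allow_empty) {
      rlang::abort(paste0(
        "cannot estimate a rate from an empty spike train ",
        "(beta = n^(4/5) and the bandwidth are undefined at n = 0); ",
        "pass allow_empty = TRUE for an all-zero curve."))
    }
    out <- tibble::tibble(time = as.numeric(times),
                          bandwidth = NA_real_, rate = 0)
    return(new_baks_fit(out, alpha, NA_real_, 0L, duration))
  }
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0)
  beta <- resolve_beta(beta, length(ts))
  D2 <- outer(times, ts, `-`)^2
  h <- bandwidth_from_logq(log(D2 / 2 + 1 / beta), alpha)
  # h recycles down rows of the [grid x n] matrix
  rate <- rowSums(exp(-D2 / (2 * h^2))) / (sqrt(2 * pi) * h)
  out <- tibble::tibble(time = as.numeric(times), bandwidth = h, rate = rate)
  new_baks_fit(out, alpha, beta, length(ts), duration)
}

new_baks_fit <- function(tbl, alpha, beta, n, duration) {
  structure(tbl,
            alpha = alpha, beta = beta, n = n, duration = duration,
            class = c("baks_fit", class(tbl)))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a BAKS fit
#'
#' @param x A `baks_fit`.
#' @param ... Unused.
#' @return A plain tibble with columns `time`, `bandwidth`, `rate`.
#' @export
tidy.baks_fit <- function(x, ...) {
  tibble::tibble(time = x$time, bandwidth = x$bandwidth, rate = x$rate)
}

#' One-row summary of a BAKS fit
#'
#' @param x A `baks_fit`.
#' @param ... Unused.
#' @return A one-row tibble: spike count `n`, prior parameters `alpha` and
#'   `beta`, `duration`, mean and range of the adaptive bandwidth, and the
#'   peak estimated rate.
#' @export
glance.baks_fit <- function(x, ...) {
  tibble::tibble(
    n = attr(x, "n"),
    alpha = attr(x, "alpha"),
    beta = attr(x, "beta"),
    duration = attr(x, "duration"),
    mean_bandwidth = mean(x$bandwidth),
    min_bandwidth = min(x$bandwidth),
    max_bandwidth = max(x$bandwidth),
    peak_rate = max(x$rate)
  )
}

#' Plot a BAKS fit
#'
#' Draws the estimated firing rate with a rug of the (implied) kernel
#' centres, and optionally the adaptive bandwidth in a lower panel.
#'
#' @param object A `baks_fit`.
#' @param truth Optional `rate_curve` tibble of the ground truth to overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.baks_fit <- function(object, truth = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$rate), colour = "#2166ac") +
    ggplot2::labs(x = "time (s)", y = "firing rate (spikes/s)") +
    ggplot2::theme_minimal()
  if (!is.null(truth)) {
    p <- p + ggplot2::geom_line(
      data = truth, ggplot2::aes(y = .data$rate),
      colour = "grey40", linetype = "dashed")
  }
  p
}

#' @rdname autoplot.baks_fit
#' @param x A `baks_fit`.
#' @export
plot_baks_fit <- function(x, truth = NULL, ...) autoplot.baks_fit(x, truth, ...)
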