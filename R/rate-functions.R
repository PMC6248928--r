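#' Parametric ground-truth firing-rate functions
#'
#' Constructs the description of a time-varying firing rate \eqn{\lambda(t)}
#' from one of five parametric families commonly used to benchmark
#' single-trial rate estimators:
#'
#' * `chirp`: \eqn{\lambda(t) = \eta + A \sin(2\pi f t^2 + \phi)} — an
#'   oscillation whose instantaneous frequency grows with time
#'   (heterogeneous dynamics).
#' * `sine`: \eqn{\lambda(t) = \eta + A \sin(2\pi f t + \phi)} — a
#'   stationary oscillation.
#' * `sawtooth`: \eqn{\lambda(t) = \eta + \frac{2A}{\pi}
#'   \arctan(\cot(\pi f t + \phi))} — a discontinuous ramp with sudden
#'   resets.
#' * `square`: \eqn{\lambda(t) = \eta + A\,\mathrm{sign}(\sin(2\pi f t +
#'   \phi))} — a discontinuous two-level rate (at the switching instants the
#'   upper level is returned, i.e. right-continuous sampling).
#' * `gds` (Gaussian-damped sinusoid): \eqn{\lambda(t) = \eta + \eta A
#'   \exp\{-(t - t_0)^2 / 2\sigma^2\} \sin(2\pi f t + \phi)} — an
#'   oscillation inside a Gaussian envelope centred at `t0` with width
#'   `sigma_env`.
#'
#' @param kind One of `"chirp"`, `"sine"`, `"sawtooth"`, `"square"`, `"gds"`.
#' @param eta Base (average) rate \eqn{\eta}, spikes/s; must be positive.
#' @param amp Amplitude \eqn{A}: spikes/s for chirp/sine/sawtooth/square, a
#'   dimensionless multiplier of `eta` for `gds`.
#' @param freq Frequency \eqn{f} in Hz; must be positive.
#' @param phase Phase \eqn{\phi} in radians.
#' @param t0 Centre of the Gaussian envelope, s (`gds` only).
#' @param sigma_env Width of the Gaussian envelope, s (`gds` only); must be
#'   positive.
#' @param duration Interval \eqn{[0, T]} on which the configuration is
#'   validated to be non-negative, s.
#'
#' @return An object of class `rate_params`.
#'
#' @details The parameter set is validated at construction: the rate is
#'   evaluated on a fine grid over `[0, duration]` and any configuration that
#'   dips below zero is rejected, naming the offending time.
#'
#' @examples
#' rp <- rate_params("sine", eta = 50, amp = 25, freq = 1, phase = -pi / 2)
#' evaluate_rate(rp, seq(0, 2, by = 0.25))
#' @export
rate_params <- function(kind = c("chirp", "sine", "sawtooth", "square", "gds"),
                        eta, amp, freq, phase = 0,
                        t0 = NULL, sigma_env = NULL, duration = 2) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(eta), length(eta) == 1L,
            is.numeric(amp), length(amp) == 1L,
            is.numeric(freq), length(freq) == 1L,
            is.numeric(phase), length(phase) == 1L)
  if (eta <= 0) rlang::abort("`eta` must be positive (spikes/s).")
  if (freq <= 0) rlang::abort("`freq` must be positive (Hz).")
  if (kind == "gds") {
    if (is.null(t0) || is.null(sigma_env)) {
      rlang::abort("`gds` rates require `t0` and `sigma_env`.")
    }
    if (sigma_env <= 0) rlang::abort("`sigma_env` must be positive (s).")
  } else {
    t0 <- NA_real_
    sigma_env <- NA_real_
  }
  rp <- structure(
    list(kind = kind, eta = eta, amp = amp, freq = freq, phase = phase,
         t0 = t0, sigma_env = sigma_env),
    class = "rate_params"
  )
  # reject configurations that go negative anywhere on the working interval
  chk <- seq(0, duration, length.out = 4001L)
  v <- rate_values(rp, chk)
  if (any(v < 0)) {
    bad <- chk[which.min(v)]
    rlang::abort(sprintf(
      "rate is negative (%.3f spikes/s) at t = %.4f s; adjust eta/amp.",
      min(v), bad))
  }
  rp
}

#' @export
print.rate_params <- function(x, ...) {
  cat(sprintf("<rate_params: %s>  eta = %g spikes/s, A = %g, f = %g Hz, phi = %.4g rad",
              x$kind, x$eta, x$amp, x$freq, x$phase))
  if (x$kind == "gds") {
    cat(sprintf(", t0 = %g s, sigma_env = %g s", x$t0, x$sigma_env))
  }
  cat("\n")
  invisible(x)
}

# Raw vectorised evaluation (no validation); the single source of truth for
# every lambda(t) formula.
rate_values <- function(params, times) {
  eta <- params$eta; A <- params$amp; f <- params$freq; phi <- params$phase
  switch(params$kind,
    chirp = eta + A * sin(2 * pi * f * times^2 + phi),
    sine = eta + A * sin(2 * pi * f * times + phi),
    sawtooth = {
      # arctan(cot(x)) == pi/2 - (x mod pi) for x not a multiple of pi;
      # the piecewise form is exact and has no cot() poles.  At multiples of
      # pi the mod is 0 and the upper value eta + A is returned
      # (right-continuous).
      x <- pi * f * times + phi
      eta + (2 * A / pi) * (pi / 2 - (x %% pi))
    },
    square = {
      s <- sign(sin(2 * pi * f * times + phi))
      s[s == 0] <- 1   # right limit at the switching instant
      eta + A * s
    },
    gds = eta + eta * A * exp(-(times - params$t0)^2 / (2 * params$sigma_env^2)) *
      sin(2 * pi * f * times + phi)
  )
}

#' Evaluate a rate function on a time grid
#'
#' @param params A [rate_params] object.
#' @param times Increasing numeric vector of evaluation times, s.
#'
#' @return A tibble with columns `time` (s) and `rate` (spikes/s), classed
#'   `rate_curve`, carrying the grid step as attribute `dt` when the grid is
#'   uniform.
#'
#' @examples
#' rp <- rate_params("chirp", eta = 50, amp = 25, freq = 0.5)
#' evaluate_rate(rp, seq(0, 2, by = 0.5))
#' @export
evaluate_rate <- function(params, times) {
  stopifnot(inherits(params, "rate_params"))
  if (length(times) == 0L) rlang::abort("`times` must be nonempty.")
  if (is.unsorted(times, strictly = TRUE)) {
    rlang::abort("`times` must be strictly increasing.")
  }
  v <- rate_values(params, times)
  if (any(v < 0)) {
    bad <- times[which.min(v)]
    rlang::abort(sprintf("rate is negative at t = %.4f s.", bad))
  }
  out <- tibble::tibble(time = as.numeric(times), rate = v)
  d <- diff(times)
  if (length(d) && diff(range(d)) <= 1e-9 * max(d)) {
    attr(out, "dt") <- mean(d)
  }
  class(out) <- c("rate_curve", class(out))
  out
}

#' Cumulative (integrated) intensity of a rate function
#'
#' Computes \eqn{\Lambda(t) = m \int_0^t \lambda(u)\,du} by cumulative
#' trapezoidal quadrature on the supplied grid.  The multiplier `m` is the
#' renewal-model scaling of the time-rescaling transform: the shape
#' \eqn{\gamma} for the inhomogeneous Gamma model, 1 for the inhomogeneous
#' inverse-Gaussian model.
#'
#' @param params A [rate_params] object.
#' @param times Increasing grid starting at 0, s.  Should resolve the rate
#'   (at least ~20 samples per oscillation period).
#' @param multiplier Positive scalar \eqn{m}.
#'
#' @return A tibble with columns `time` and `Lambda` (nondecreasing,
#'   `Lambda[1] == 0`).
#'
#' @examples
#' rp <- rate_params("sine", eta = 50, amp = 25, freq = 1, phase = -pi / 2)
#' ci <- cumulative_intensity(rp, seq(0, 2, by = 1e-3), multiplier = 4)
#' tail(ci, 1)  # gamma * eta * T = 400 over full periods
#' @export
cumulative_intensity <- function(params, times, multiplier = 1) {
  stopifnot(inherits(params, "rate_params"))
  if (length(times) == 0L || times[1] != 0) {
    rlang::abort("`times` must be a grid starting at 0.")
  }
  if (is.unsorted(times, strictly = TRUE)) {
    rlang::abort("`times` must be strictly increasing.")
  }
  if (!is.numeric(multiplier) || multiplier <= 0) {
    rlang::abort("`multiplier` must be a positive scalar.")
  }
  v <- rate_values(params, times)
  tibble::tibble(time = as.numeric(times),
                 Lambda = multiplier * cumtrapz_vec(times, v))
}

#' @rdname plot_rate_curve
#' @param object,x A `rate_curve` tibble from [evaluate_rate()].
#' @param ... Unused.
#' @export
autoplot.rate_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$rate)) +
    ggplot2::geom_line(colour = "grey25") +
    ggplot2::labs(x = "time (s)", y = "firing rate (spikes/s)") +
    ggplot2::theme_minimal()
}

#' Plot a ground-truth rate curve
#'
#' @return A ggplot object.
#' @export
plot_rate_curve <- function(x, ...) autoplot.rate_curve(x, ...)
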