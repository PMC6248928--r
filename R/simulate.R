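#' Spike trains
#'
#' A spike train is a strictly increasing sequence of event times in the
#' half-open recording interval \eqn{(0, T]}.  An empty train is a valid
#' object (downstream estimators reject it explicitly).
#'
#' @param times Numeric vector of event times, s.
#' @param duration Recording duration \eqn{T}, s.
#'
#' @return An object of class `spike_train` with fields `times` and
#'   `duration`.
#' @examples
#' st <- spike_train(c(0.2, 0.8, 1.5), duration = 2)
#' st
#' tibble::as_tibble(st)
#' @export
spike_train <- function(times, duration) {
  stopifnot(is.numeric(times), is.numeric(duration), length(duration) == 1L,
            duration > 0)
  times <- as.numeric(times)
  if (length(times)) {
    if (is.unsorted(times, strictly = TRUE)) {
      rlang::abort("spike `times` must be strictly increasing.")
    }
    if (times[1] <= 0 || times[length(times)] > duration) {
      rlang::abort("spike times must lie in (0, duration].")
    }
  }
  structure(list(times = times, duration = as.numeric(duration)),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train: %d spikes over %g s>\n", length(x$times),
              x$duration))
  invisible(x)
}

#' @export
as_tibble.spike_train <- function(x, ...) {
  tibble::tibble(time = x$times)
}

#' Renewal interspike-interval models
#'
#' Describes the stationary interspike-interval (ISI) law of a renewal spike
#' model in the rescaled-time domain:
#'
#' * `"IG"` (inhomogeneous Gamma): ISIs are Gamma(shape \eqn{\gamma}, scale
#'   \eqn{\theta}).  \eqn{\gamma = 1} recovers the Poisson process;
#'   \eqn{\gamma > 1} expresses refractoriness, \eqn{\gamma < 1} bursting.
#' * `"IIG"` (inhomogeneous inverse Gaussian): ISIs are inverse-Gaussian
#'   with location (mean) \eqn{\mu} and shape \eqn{\gamma} — the
#'   first-passage-time law of a drifting integrate-and-fire neuron.
#'
#' @param family `"IG"` or `"IIG"`.
#' @param shape Shape \eqn{\gamma > 0}.
#' @param scale Scale \eqn{\theta > 0} (IG only).
#' @param location Location \eqn{\mu > 0} (IIG only).
#'
#' @return An object of class `renewal_model`.
#' @examples
#' renewal_model("IG", shape = 4, scale = 1)
#' renewal_model("IIG", shape = 4, location = 1)
#' @export
renewal_model <- function(family = c("IG", "IIG"), shape,
                          scale = NULL, location = NULL) {
  family <- match.arg(family)
  stopifnot(is.numeric(shape), length(shape) == 1L, shape > 0)
  if (family == "IG") {
    if (is.null(scale) || scale <= 0) {
      rlang::abort("IG models require a positive `scale` (theta).")
    }
    location <- NA_real_
  } else {
    if (is.null(location) || location <= 0) {
      rlang::abort("IIG models require a positive `location` (mu).")
    }
    scale <- NA_real_
  }
  structure(list(family = family, shape = as.numeric(shape),
                 scale = as.numeric(scale %||% NA_real_),
                 location = as.numeric(location %||% NA_real_)),
            class = "renewal_model")
}

#' @export
print.renewal_model <- function(x, ...) {
  if (x$family == "IG") {
    cat(sprintf("<renewal_model: IG>  gamma = %g, theta = %g\n",
                x$shape, x$scale))
  } else {
    cat(sprintf("<renewal_model: IIG>  gamma = %g, mu = %g\n",
                x$shape, x$location))
  }
  invisible(x)
}

# Mean rescaled ISI of a renewal model (used to size sampling blocks).
mean_isi <- function(model) {
  switch(model$family, IG = model$shape * model$scale, IIG = model$location)
}

#' Sample inverse-Gaussian variates
#'
#' Draws from the inverse-Gaussian distribution with mean `mu` and shape
#' `lam` by the Michael–Schucany–Haas transformation method: a chi-squared
#' variate is mapped through the root of the quadratic relating the
#' first-passage time to its reciprocal, and one of the two roots is chosen
#' with the appropriate probability.
#'
#' @param n Number of draws.
#' @param mu Mean \eqn{\mu > 0}.
#' @param lam Shape \eqn{\lambda > 0}.
#'
#' @return Numeric vector of `n` positive draws.
#' @examples
#' set.seed(1)
#' mean(rinv_gaussian(1e4, mu = 1, lam = 4))  # ~ 1
#' @export
rinv_gaussian <- function(n, mu, lam) {
  stopifnot(is.numeric(mu), mu > 0, is.numeric(lam), lam > 0, n >= 0)
  if (n == 0L) return(numeric(0))
  y <- stats::rnorm(n)^2
  x1 <- mu + mu^2 * y / (2 * lam) -
    mu / (2 * lam) * sqrt(4 * mu * lam * y + mu^2 * y^2)
  u <- stats::runif(n)
  smaller <- u <= mu / (mu + x1)
  ifelse(smaller, x1, mu^2 / x1)
}

#' Sample rescaled interspike intervals
#'
#' Draws i.i.d. ISIs from the renewal model's rescaled-domain law:
#' Gamma(\eqn{\gamma}, \eqn{\theta}) for `"IG"`, inverse-Gaussian(\eqn{\mu},
#' shape \eqn{\gamma}) for `"IIG"`.
#'
#' @param model A [renewal_model].
#' @param count Number of draws (>= 1).
#'
#' @return Numeric vector of positive ISIs.
#' @examples
#' set.seed(1)
#' mean(sample_renewal_isis(renewal_model("IG", 4, scale = 1), 1e4))  # ~ 4
#' @export
sample_renewal_isis <- function(model, count) {
  stopifnot(inherits(model, "renewal_model"), count >= 1)
  switch(model$family,
    IG = stats::rgamma(count, shape = model$shape, scale = model$scale),
    IIG = rinv_gaussian(count, mu = model$location, lam = model$shape)
  )
}

#' Invert a cumulative intensity at target values
#'
#' Maps rescaled-time values back to real time through the inverse of the
#' time-rescaling transform, \eqn{t = \Lambda^{-1}(\tau)}, by monotone
#' piecewise-linear interpolation on the tabulated intensity.  Targets
#' beyond \eqn{\Lambda(T)} fall outside the recording window and are
#' dropped.
#'
#' @param intensity_times Grid of times, s.
#' @param intensity_values Nondecreasing \eqn{\Lambda} values with
#'   `intensity_values[1] == 0`.
#' @param targets Nondecreasing positive rescaled times.
#'
#' @return Numeric vector of event times (possibly shorter than `targets`).
#' @examples
#' invert_intensity(c(0, 2), c(0, 20), c(5, 15))  # 0.5, 1.5
#' @export
invert_intensity <- function(intensity_times, intensity_values, targets) {
  stopifnot(length(intensity_times) == length(intensity_values))
  if (is.unsorted(intensity_values)) {
    rlang::abort("`intensity_values` must be nondecreasing.")
  }
  if (length(intensity_values) == 0L || intensity_values[1] != 0) {
    rlang::abort("`intensity_values` must start at 0.")
  }
  keep <- targets <= intensity_values[length(intensity_values)]
  targets <- targets[keep]
  if (!length(targets)) return(numeric(0))
  # approx() requires distinct x; collapse flat stretches of Lambda (zero-rate
  # intervals), keeping the first grid time of each flat — events cannot fall
  # inside a zero-rate stretch anyway.
  dup <- duplicated(intensity_values)
  stats::approx(x = intensity_values[!dup], y = intensity_times[!dup],
                xout = targets, ties = "ordered")$y
}

#' Generate a spike train from an inhomogeneous renewal model
#'
#' Simulates one trial via the time-rescaling theorem: i.i.d. ISIs are drawn
#' from the model's rescaled-domain law, cumulatively summed, and mapped
#' through the inverse cumulative intensity \eqn{\Lambda^{-1}}.  For the IG
#' model \eqn{\Lambda(t) = \gamma \int_0^t \lambda}, for the IIG model
#' \eqn{\Lambda(t) = \int_0^t \lambda}.  The renewal process starts fresh at
#' \eqn{t = 0}; simulation stops at the first rescaled time beyond
#' \eqn{\Lambda(T)}.
#'
#' @param rate A [rate_params] ground-truth intensity.
#' @param model A [renewal_model].
#' @param duration Recording duration \eqn{T}, s.
#' @param dt Quadrature/inversion grid step, s.
#'
#' @return A [spike_train].
#' @examples
#' set.seed(7)
#' rp <- rate_params("sine", eta = 50, amp = 25, freq = 1, phase = -pi / 2)
#' generate_spike_train(rp, renewal_model("IG", 4, scale = 1), duration = 2)
#' @export
generate_spike_train <- function(rate, model, duration = 2, dt = 1e-3) {
  stopifnot(inherits(rate, "rate_params"), inherits(model, "renewal_model"),
            duration > 0)
  mult <- if (model$family == "IG") model$shape else 1
  grid <- default_grid(duration, dt)
  Lam <- cumulative_intensity(rate, grid, multiplier = mult)
  Lam_T <- Lam$Lambda[nrow(Lam)]
  m_isi <- mean_isi(model)

  # draw rescaled ISIs in blocks sized to overshoot Lambda(T), extending if a
  # block falls short
  block <- max(16L, ceiling(1.5 * Lam_T / m_isi))
  taus <- cumsum(sample_renewal_isis(model, block))
  while (taus[length(taus)] <= Lam_T) {
    taus <- c(taus, taus[length(taus)] +
                cumsum(sample_renewal_isis(model, block)))
  }
  taus <- taus[taus <= Lam_T]
  times <- invert_intensity(Lam$time, Lam$Lambda, taus)
  # interpolation at float resolution can tie consecutive times; nudge the
  # later one by a grid epsilon to keep strict ordering
  if (length(times) > 1L) {
    eps <- dt * 1e-6
    for (i in seq(2, length(times))) {
      if (times[i] <= times[i - 1]) times[i] <- times[i - 1] + eps
    }
  }
  times <- times[times > 0 & times <= duration]
  spike_train(times, duration)
}

#' Superimpose spike trains from several trials
#'
#' Pools trials recorded over the same interval into one compact spike
#' train, as done when estimating a rate from superimposed multi-trial
#' data.
#'
#' @param trains List of [spike_train] objects sharing one duration.
#'
#' @return A [spike_train] containing all events, sorted.
#' @examples
#' a <- spike_train(0.5, 2); b <- spike_train(1.0, 2)
#' pool_trials(list(a, b))
#' @export
pool_trials <- function(trains) {
  stopifnot(is.list(trains), length(trains) >= 1L,
            all(vapply(trains, inherits, logical(1), "spike_train")))
  durs <- vapply(trains, function(x) x$duration, numeric(1))
  if (diff(range(durs)) > 0) {
    rlang::abort("all trains must share the same duration.")
  }
  times <- sort(unlist(lapply(trains, function(x) x$times)))
  if (length(times) > 1L) {
    eps <- 1e-9
    for (i in seq(2, length(times))) {
      if (times[i] <= times[i - 1]) times[i] <- times[i - 1] + eps
    }
  }
  spike_train(times, durs[1])
}
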