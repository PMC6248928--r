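#' Integrated squared error between two rate curves
#'
#' Riemann approximation of \eqn{\int (\hat\lambda(t) - \lambda(t))^2 dt}
#' over the shared grid: \eqn{\Delta t \sum_t (\hat\lambda - \lambda)^2}.
#'
#' @param estimate,truth Data frames with `time` and `rate` columns on
#'   identical grids (e.g. a `baks_fit` and an [evaluate_rate()] curve).
#' @return Scalar ISE in (spikes/s)^2 * s.
#' @examples
#' g <- seq(0, 2, by = 1e-3)
#' a <- tibble::tibble(time = g, rate = 5)
#' b <- tibble::tibble(time = g, rate = 7)
#' integrated_squared_error(a, b)  # 2^2 * 2 = 8
#' @export
integrated_squared_error <- function(estimate, truth) {
  stopifnot(is.data.frame(estimate), is.data.frame(truth))
  if (nrow(estimate) != nrow(truth) ||
      max(abs(estimate$time - truth$time)) > 1e-9) {
    rlang::abort("`estimate` and `truth` must share an identical time grid.")
  }
  dt <- grid_dt(estimate$time)
  dt * sum((estimate$rate - truth$rate)^2)
}

#' Credible-interval-weighted integrated squared error
#'
#' As [integrated_squared_error()], but each pointwise error is first
#' divided by an asymmetric normaliser \eqn{C(t)}: the `upper` interval
#' value where the estimate is at or above the reference, the `lower` value
#' where it is below.  Used when the reference rate is itself an estimate
#' with a credible band, so errors are discounted where the reference is
#' uncertain.
#'
#' @param estimate,reference Data frames with `time` and `rate` on one grid.
#' @param upper,lower Data frames with `time` and `value` columns (strictly
#'   positive) on the same grid, or numeric vectors of the grid length.
#' @return Scalar weighted ISE.
#' @examples
#' g <- seq(0, 1, by = 0.25)
#' est <- tibble::tibble(time = g, rate = c(1, 2, 3, 2, 1))
#' ref <- tibble::tibble(time = g, rate = 2)
#' weighted_mise(est, ref, upper = rep(2, 5), lower = rep(1, 5))
#' @export
weighted_mise <- function(estimate, reference, upper, lower) {
  stopifnot(is.data.frame(estimate), is.data.frame(reference))
  if (nrow(estimate) != nrow(reference) ||
      max(abs(estimate$time - reference$time)) > 1e-9) {
    rlang::abort("curves must share an identical time grid.")
  }
  as_vals <- function(x, nm) {
    v <- if (is.data.frame(x)) {
      col <- intersect(c("value", "rate"), names(x))[1]
      x[[col]]
    } else as.numeric(x)
    if (length(v) != nrow(estimate)) {
      rlang::abort(sprintf("`%s` must match the grid length.", nm))
    }
    if (any(v <= 0)) {
      rlang::abort(sprintf("`%s` interval values must be strictly positive.", nm))
    }
    v
  }
  up <- as_vals(upper, "upper")
  lo <- as_vals(lower, "lower")
  err <- estimate$rate - reference$rate
  C <- ifelse(estimate$rate >= reference$rate, up, lo)
  dt <- grid_dt(estimate$time)
  dt * sum((err / C)^2)
}

#' Simulation scenarios
#'
#' Bundles a ground-truth rate, a renewal model and the experiment sizes
#' into one benchmark scenario.
#'
#' @param rate A [rate_params].
#' @param model A [renewal_model].
#' @param duration Trial duration, s.
#' @param repetitions Number of independent repetitions.
#' @param trials_per_repetition Trials superimposed into each analysed
#'   train (1 = single-trial).
#' @param label Scenario name.
#' @return An object of class `scenario_spec`.
#' @export
scenario <- function(rate, model, duration = 2, repetitions = 100,
                     trials_per_repetition = 1, label = "") {
  stopifnot(inherits(rate, "rate_params"), inherits(model, "renewal_model"),
            duration > 0, repetitions >= 1, trials_per_repetition >= 1)
  structure(list(rate = rate, model = model, duration = duration,
                 repetitions = as.integer(repetitions),
                 trials_per_repetition = as.integer(trials_per_repetition),
                 label = label),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf(
    "<scenario: %s>  %s rate, %s model, T = %g s, %d reps x %d trial(s)\n",
    x$label, x$rate$kind, x$model$family, x$duration, x$repetitions,
    x$trials_per_repetition))
  invisible(x)
}

# Deterministic per-repetition substream: experiments are reproducible and
# individual repetitions re-derivable in isolation.
rep_seed <- function(seed, rep) (seed + 7919L * rep) %% .Machine$integer.max

# Generate the analysed (possibly pooled) train for one repetition.
# Zero-spike draws are re-drawn on the following substream (logged);
# vanishingly rare at the benchmark intensities.
draw_repetition <- function(spec, seed, rep, dt = 1e-3) {
  attempt <- 0L
  repeat {
    set.seed(rep_seed(seed, rep + attempt * spec$repetitions))
    trains <- lapply(seq_len(spec$trials_per_repetition), function(i) {
      generate_spike_train(spec$rate, spec$model, spec$duration, dt = dt)
    })
    st <- if (length(trains) == 1L) trains[[1]] else pool_trials(trains)
    if (length(st$times) > 0L) return(st)
    attempt <- attempt + 1L
    message(sprintf("repetition %d drew zero spikes; re-drawing (%s)",
                    rep, spec$label))
  }
}

# ISE of one train over a vector of alpha values, reusing the spike-distance
# log-terms across alphas (this is what makes the 19-point tuning grid
# affordable).  Superimposed trains are scored as per-trial rates: the raw
# estimate integrates to ~k*n spikes, so it is divided by the trial count
# before comparison with the single-trial ground truth.
ise_over_alphas <- function(st, spec, alphas, times, truth_rate) {
  ts <- st$times
  beta <- default_beta(length(ts))
  D2 <- outer(times, ts, `-`)^2
  Lq <- log(D2 / 2 + 1 / beta)
  dt <- grid_dt(times)
  k <- spec$trials_per_repetition
  vapply(alphas, function(a) {
    h <- bandwidth_from_logq(Lq, a)
    est <- rowSums(exp(-D2 / (2 * h^2))) / (sqrt(2 * pi) * h * k)
    dt * sum((est - truth_rate)^2)
  }, numeric(1))
}

#' Run a MISE experiment for one scenario
#'
#' For each repetition: simulate (and superimpose, if the scenario is
#' multi-trial) spike trains, estimate the rate with BAKS, and score the
#' integrated squared error against the ground truth on a 1 ms grid.  The
#' MISE is the mean ISE across repetitions with a normal-approximation 95%
#' confidence half-width (1.96 times the standard error).
#'
#' Multi-trial scenarios superimpose the trials into one compact train
#' before estimation (the prior scale resolves against the pooled spike
#' count); the estimated rate is then divided by the trial count so the
#' score is against the per-trial ground truth.
#'
#' @param spec A [scenario()].
#' @param alpha Prior shape used by the estimator.
#' @param beta Prior scale, or `"n^4/5"` (resolved against the pooled
#'   spike count).
#' @param seed Integer seed; repetitions use derived substreams.
#' @param dt Evaluation grid step, s.
#' @return An object of class `mise_result`: per-repetition ISEs plus
#'   summary fields; supports [tidy()] and [glance()].
#' @examples
#' sc <- benchmark_presets()[["tuning/IG/sine"]]
#' sc$repetitions <- 5L
#' mise_experiment(sc, alpha = 4, seed = 1)
#' @export
mise_experiment <- function(spec, alpha = 4, beta = "n^4/5", seed = 1,
                            dt = 1e-3) {
  stopifnot(inherits(spec, "scenario_spec"))
  times <- default_grid(spec$duration, dt)
  truth <- evaluate_rate(spec$rate, times)
  ise <- numeric(spec$repetitions)
  n_spikes <- integer(spec$repetitions)
  k <- spec$trials_per_repetition
  for (r in seq_len(spec$repetitions)) {
    st <- draw_repetition(spec, seed, r, dt = dt)
    n_spikes[r] <- length(st$times)
    fit <- estimate_rate(st, alpha = alpha, beta = beta, times = times)
    # superimposed trains estimate k * lambda; score the per-trial rate
    est <- tibble::tibble(time = fit$time, rate = fit$rate / k)
    ise[r] <- integrated_squared_error(est, truth)
  }
  new_mise_result(spec$label, alpha, ise, n_spikes)
}

new_mise_result <- function(label, alpha, ise, n_spikes) {
  structure(
    list(label = label, alpha = alpha, ise = ise, n_spikes = n_spikes,
         mise = mean(ise),
         ci95 = 1.96 * stats::sd(ise) / sqrt(length(ise))),
    class = "mise_result")
}

#' @export
print.mise_result <- function(x, ...) {
  cat(sprintf("<mise_result: %s, alpha = %g>  MISE = %.2f +/- %.2f (95%% CI, %d reps)\n",
              x$label, x$alpha, x$mise, x$ci95, length(x$ise)))
  invisible(x)
}

#' @rdname mise_experiment
#' @param x A `mise_result`.
#' @param ... Unused.
#' @export
tidy.mise_result <- function(x, ...) {
  tibble::tibble(scenario = x$label, alpha = x$alpha,
                 repetition = seq_along(x$ise),
                 n_spikes = x$n_spikes, ise = x$ise)
}

#' @rdname mise_experiment
#' @export
glance.mise_result <- function(x, ...) {
  tibble::tibble(scenario = x$label, alpha = x$alpha,
                 repetitions = length(x$ise),
                 mise = x$mise, ci95 = x$ci95)
}

#' Tune the prior shape by MISE minimisation
#'
#' Runs the MISE experiment for every combination of scenario and candidate
#' \eqn{\alpha} (with \eqn{\beta = n^{4/5}}), sharing the simulated trains
#' across the \eqn{\alpha} grid so each candidate is scored on identical
#' data.  The selected value minimises the MISE averaged across scenarios;
#' ties break toward the smallest \eqn{\alpha}.
#'
#' @param scenarios List of [scenario()] objects (or a single one).
#' @param alpha_grid Candidate shape values; default the 0.5-step grid from
#'   1 to 10.
#' @param seed Integer seed.
#' @param repetitions Optional override of every scenario's repetition
#'   count (used to scale the experiment down).
#' @param dt Evaluation grid step, s.
#' @return An object of class `alpha_tuning` with fields `alpha_best`
#'   (across-scenario argmin), `by_scenario` (per-scenario argmin tibble)
#'   and `table` (scenario x alpha MISE summary); supports [tidy()] and
#'   [autoplot()].
#' @examples
#' \donttest{
#' sc <- benchmark_presets()[c("tuning/IG/sine", "tuning/IG/sawtooth")]
#' tune_alpha(sc, alpha_grid = c(2, 4, 6), repetitions = 10, seed = 1)
#' }
#' @export
tune_alpha <- function(scenarios, alpha_grid = seq(1, 10, by = 0.5),
                       seed = 1, repetitions = NULL, dt = 1e-3) {
  if (inherits(scenarios, "scenario_spec")) scenarios <- list(scenarios)
  stopifnot(length(scenarios) >= 1L,
            all(vapply(scenarios, inherits, logical(1), "scenario_spec")))
  if (!length(alpha_grid)) rlang::abort("`alpha_grid` must be nonempty.")
  if (any(alpha_grid <= 0)) rlang::abort("`alpha_grid` must be positive.")

  per_scenario <- purrr::imap(scenarios, function(spec, idx) {
    if (!is.null(repetitions)) spec$repetitions <- as.integer(repetitions)
    times <- default_grid(spec$duration, dt)
    truth_rate <- rate_values(spec$rate, times)
    ise <- matrix(NA_real_, nrow = spec$repetitions,
                  ncol = length(alpha_grid))
    for (r in seq_len(spec$repetitions)) {
      st <- draw_repetition(spec, seed, r, dt = dt)
      ise[r, ] <- ise_over_alphas(st, spec, alpha_grid, times, truth_rate)
    }
    label <- if (nzchar(spec$label)) spec$label else paste0("scenario_", idx)
    tibble::tibble(
      scenario = label,
      alpha = alpha_grid,
      mise = colMeans(ise),
      ci95 = 1.96 * apply(ise, 2, stats::sd) / sqrt(nrow(ise))
    )
  })
  table <- dplyr::bind_rows(per_scenario)

  by_scenario <- table |>
    dplyr::group_by(.data$scenario) |>
    dplyr::slice_min(.data$mise, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select("scenario", alpha_min = "alpha", mise_min = "mise")

  avg <- table |>
    dplyr::group_by(.data$alpha) |>
    dplyr::summarise(mise = mean(.data$mise), .groups = "drop") |>
    dplyr::arrange(.data$alpha)
  alpha_best <- avg$alpha[which.min(avg$mise)]

  structure(list(alpha_best = alpha_best, by_scenario = by_scenario,
                 average = avg, table = table, alpha_grid = alpha_grid),
            class = "alpha_tuning")
}

#' @export
print.alpha_tuning <- function(x, ...) {
  cat(sprintf("<alpha_tuning>  selected alpha = %g (across %d scenario(s))\n",
              x$alpha_best, nrow(x$by_scenario)))
  print(x$by_scenario)
  invisible(x)
}

#' @rdname tune_alpha
#' @param x An `alpha_tuning` object.
#' @param ... Unused.
#' @export
tidy.alpha_tuning <- function(x, ...) x$table

#' @rdname tune_alpha
#' @export
glance.alpha_tuning <- function(x, ...) {
  tibble::tibble(alpha_best = x$alpha_best,
                 n_scenarios = nrow(x$by_scenario),
                 n_alphas = length(x$alpha_grid),
                 mise_at_best = x$average$mise[x$average$alpha == x$alpha_best])
}

#' @rdname tune_alpha
#' @param object An `alpha_tuning` object.
#' @export
autoplot.alpha_tuning <- function(object, ...) {
  ggplot2::ggplot(object$table,
                  ggplot2::aes(x = .data$alpha, y = .data$mise,
                               colour = .data$scenario)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mise - .data$ci95,
                                          ymax = .data$mise + .data$ci95),
                             size = 0.25) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$alpha_best, linetype = "dotted") +
    ggplot2::labs(x = expression(alpha), y = "MISE") +
    ggplot2::theme_minimal()
}

#' @rdname tune_alpha
#' @export
plot_mise_curves <- function(x, ...) autoplot.alpha_tuning(x, ...)

#' Benchmark scenario registry
#'
#' Programmatic registry of the tuning and testing simulation settings:
#' medium intensity is \eqn{\eta = 50, A = 25}; medium frequency is 0.5 Hz
#' for the chirp and 1 Hz for sine/sawtooth; the renewal defaults are IG
#' with \eqn{\gamma = 4, \theta = 1} and IIG with \eqn{\gamma = 4, \mu = 1};
#' all trials last 2 s with 100 repetitions.  Phases: chirp 0, sine
#' \eqn{-\pi/2}, sawtooth \eqn{-\pi/4}, Gaussian-damped sinusoid
#' \eqn{-\pi/2}.
#'
#' The registry keys are hierarchical:
#' * `tuning/<model>/<rate>` and `testing1/<model>/<rate>` — the six
#'   medium-setting scenarios (models IG, IIG; rates chirp, sine, sawtooth).
#' * `testing2/<model>/<rate>/<variation>` — variations `low_intensity`
#'   (\eqn{\eta = 11, A = 9}), `high_intensity` (\eqn{\eta = 100, A = 75}),
#'   `low_frequency` (chirp 0.25, sine/sawtooth 0.5 Hz), `high_frequency`
#'   (chirp 0.75, sine/sawtooth 1.5 Hz).
#' * `testing3/<model>/<rate>/gamma_<g>` — ISI shape \eqn{\gamma} from 1
#'   to 10.
#' * `testing4/<model>/<rate>/trials_<k>` — 5, 10, 20 or 30 superimposed
#'   trials.
#' * `testing5/<model>/gds/<variation>` — Gaussian-damped sinusoid with
#'   frequency 0.5/1.5/2 Hz at medium intensity, or intensity
#'   \eqn{\eta \in \{10, 50, 100\}} (with \eqn{A = 1}) at 1 Hz; envelope
#'   `t0 = 0.2` s, `sigma_env = 1` s.
#'
#' @return A named list of [scenario()] objects.
#' @examples
#' names(benchmark_presets())[1:8]
#' benchmark_presets()[["tuning/IG/sine"]]
#' @export
benchmark_presets <- function() {
  phases <- c(chirp = 0, sine = -pi / 2, sawtooth = -pi / 4)
  med_freq <- c(chirp = 0.5, sine = 1, sawtooth = 1)
  low_freq <- c(chirp = 0.25, sine = 0.5, sawtooth = 0.5)
  high_freq <- c(chirp = 0.75, sine = 1.5, sawtooth = 1.5)
  models <- list(
    IG = function(g = 4) renewal_model("IG", shape = g, scale = 1),
    IIG = function(g = 4) renewal_model("IIG", shape = g, location = 1)
  )
  rates <- c("chirp", "sine", "sawtooth")

  mk_rate <- function(kind, eta, amp, freq) {
    rate_params(kind, eta = eta, amp = amp, freq = freq,
                phase = phases[[kind]])
  }
  out <- list()
  add <- function(key, rate, model) {
    out[[key]] <<- scenario(rate, model, duration = 2, repetitions = 100,
                            trials_per_repetition = 1, label = key)
  }

  for (m in names(models)) {
    for (rk in rates) {
      med <- mk_rate(rk, 50, 25, med_freq[[rk]])
      add(paste0("tuning/", m, "/", rk), med, models[[m]]())
      add(paste0("testing1/", m, "/", rk), med, models[[m]]())
      add(paste0("testing2/", m, "/", rk, "/low_intensity"),
          mk_rate(rk, 11, 9, med_freq[[rk]]), models[[m]]())
      add(paste0("testing2/", m, "/", rk, "/high_intensity"),
          mk_rate(rk, 100, 75, med_freq[[rk]]), models[[m]]())
      add(paste0("testing2/", m, "/", rk, "/low_frequency"),
          mk_rate(rk, 50, 25, low_freq[[rk]]), models[[m]]())
      add(paste0("testing2/", m, "/", rk, "/high_frequency"),
          mk_rate(rk, 50, 25, high_freq[[rk]]), models[[m]]())
      for (g in 1:10) {
        add(paste0("testing3/", m, "/", rk, "/gamma_", g),
            med, models[[m]](g))
      }
      for (k in c(5L, 10L, 20L, 30L)) {
        key <- paste0("testing4/", m, "/", rk, "/trials_", k)
        out[[key]] <- scenario(med, models[[m]](), duration = 2,
                               repetitions = 100,
                               trials_per_repetition = k, label = key)
      }
    }
    gds <- function(eta, f) {
      rate_params("gds", eta = eta, amp = 1, freq = f, phase = -pi / 2,
                  t0 = 0.2, sigma_env = 1)
    }
    add(paste0("testing5/", m, "/gds/low_frequency"), gds(50, 0.5),
        models[[m]]())
    add(paste0("testing5/", m, "/gds/medium_frequency"), gds(50, 1.5),
        models[[m]]())
    add(paste0("testing5/", m, "/gds/high_frequency"), gds(50, 2),
        models[[m]]())
    add(paste0("testing5/", m, "/gds/low_intensity"), gds(10, 1),
        models[[m]]())
    add(paste0("testing5/", m, "/gds/medium_intensity"), gds(50, 1),
        models[[m]]())
    add(paste0("testing5/", m, "/gds/high_intensity"), gds(100, 1),
        models[[m]]())
  }
  out
}
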