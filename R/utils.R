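# Internal numerical helpers shared across modules.

# Row-wise log-sum-exp of a matrix: log(rowSums(exp(x))) without overflow.
# max.col() gives the per-row maximum position in C speed; ties are harmless
# (any maximum works as the shift).
logsumexp_rows <- function(x) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  j <- max.col(x, ties.method = "first")
  m <- x[cbind(seq_len(nrow(x)), j)]
  m + log(rowSums(exp(x - m)))
}

# Cumulative trapezoidal integral of y over x; result[1] == 0.
cumtrapz_vec <- function(x, y) {
  n <- length(x)
  if (n == 1L) return(0)
  c(0, cumsum(diff(x) * (y[-1] + y[-n]) / 2))
}

# Validate a strictly increasing, uniformly spaced time grid and return dt.
grid_dt <- function(times, arg = "times") {
  if (length(times) < 2L) {
    rlang::abort(sprintf("`%s` must contain at least two points.", arg))
  }
  d <- diff(times)
  if (any(d <= 0)) {
    rlang::abort(sprintf("`%s` must be strictly increasing.", arg))
  }
  if (diff(range(d)) > 1e-9 * max(d)) {
    rlang::abort(sprintf("`%s` must be uniformly spaced.", arg))
  }
  mean(d)
}

# Extract a numeric vector of spike times from the accepted input forms:
# a `spike_train`, a bare numeric vector, or a data frame with a `time`
# (or `time_s`) column.
spike_times_of <- function(spikes) {
  if (inherits(spikes, "spike_train")) return(spikes$times)
  if (is.data.frame(spikes)) {
    col <- intersect(c("time", "time_s"), names(spikes))[1]
    if (is.na(col)) {
      rlang::abort("data-frame spike input needs a `time` or `time_s` column.")
    }
    return(sort(as.numeric(spikes[[col]])))
  }
  if (is.numeric(spikes)) return(sort(as.numeric(spikes)))
  rlang::abort(
    "`spikes` must be a spike_train, a numeric vector, or a data frame.")
}

# Shared default evaluation grid: 1 ms steps over [0, duration].
default_grid <- function(duration, dt = 1e-3) {
  seq(0, duration, by = dt)
}
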