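# Independent brute-force oracles used across the suite.  Each is written
# in the most literal way possible and stays independent of the package
# code paths it cross-checks.

# O(n^2) discrete Fourier transform, full complex output.
naive_dft <- function(x) {
  n <- length(x)
  k <- 0:(n - 1)
  vapply(k, function(kk) {
    sum(x * exp(-2i * pi * kk * k / n))
  }, complex(1))
}

# Sliding-mean STA/LTA with explicit loops and prefix warm-up.
stalta_oracle <- function(series, sta_len, lta_len) {
  n <- length(series)
  out <- numeric(n)
  for (i in seq_len(n)) {
    sta <- mean(series[max(1, i - sta_len + 1):i])
    lta <- mean(series[max(1, i - lta_len + 1):i])
    out[i] <- if (lta == 0) 0 else sta / lta
  }
  out
}

# Full-sort version of the peak-ratio statistic.
peak_ratio_oracle <- function(spectrum) {
  v <- sort(spectrum, decreasing = TRUE)
  num <- v[1] + v[2]
  den <- v[5] + v[6]
  if (den == 0) {
    if (num == 0) 1 else NA_real_   # cap case not exercised by the oracle
  } else num / den
}

# One-line pairwise transition counter.
transitions_oracle <- function(f) {
  d <- sign(diff(f))
  c(n_down = sum(d == -1), n_up = sum(d == 1), n_stable = sum(d == 0))
}

# Boolean-OR simulation of periodic activations on a one-minute grid
# (schedules given in integer minutes).
merge_oracle_minutes <- function(on_min, period_min) {
  H <- Reduce(function(a, b) a * b / gcd2(a, b), period_min)
  minutes <- 0:(H - 1)
  active <- rep(FALSE, H)
  for (k in seq_along(on_min)) {
    active <- active | (minutes %% period_min[k]) < on_min[k]
  }
  mean(active)
}

gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)

# Exact event-driven simulation of preemptive rate-monotonic scheduling
# over one hyperperiod (integer periods, real execution times, deadline =
# period, synchronous release).  Returns TRUE if no job misses a deadline.
rm_sim_schedulable <- function(C, T) {
  stopifnot(length(C) == length(T), all(T == round(T)))
  H <- Reduce(function(a, b) a * b / gcd2(a, b), T)
  releases <- sort(unique(unlist(lapply(T, function(Ti) seq(0, H, by = Ti)))))
  prio <- order(T)                      # rate-monotonic: shortest T first
  remaining <- C                        # current job's remaining work
  for (e in seq_len(length(releases) - 1)) {
    t0 <- releases[e]
    t1 <- releases[e + 1]
    # release new jobs at t0; a still-unfinished previous job is a miss
    for (i in seq_along(T)) {
      if (t0 %% T[i] == 0) {
        if (t0 > 0 && remaining[i] > 1e-12) return(FALSE)
        remaining[i] <- C[i]
      }
    }
    budget <- t1 - t0
    for (i in prio) {
      run <- min(budget, remaining[i])
      remaining[i] <- remaining[i] - run
      budget <- budget - run
      if (budget <= 1e-12) break
    }
  }
  all(remaining < 1e-12)
}

# Exhaustive maximum-cardinality matching between detections and
# annotations under a collar (recursion over detection choices).
optimal_tp_oracle <- function(d, a, collar) {
  best <- 0
  recurse <- function(i, used, count) {
    if (count + (length(d) - i + 1) <= best) return()
    if (i > length(d)) {
      best <<- max(best, count)
      return()
    }
    recurse(i + 1, used, count)         # leave detection i unmatched
    for (j in seq_along(a)) {
      if (!used[j] && abs(d[i] - a[j]) <= collar) {
        used[j] <- TRUE
        recurse(i + 1, used, count + 1)
        used[j] <- FALSE
      }
    }
  }
  recurse(1, logical(length(a)), 0)
  best
}

# Standard high-SNR test scene: n_calls downward sweeps in `duration_s`
# of Gaussian noise (the reference study conditions for the synthetic
# detector checks).
make_dcall_scene <- function(n_calls = 20, duration_s = 1800, seed = 1,
                             amplitude = 0.5, noise_rms = 0.05) {
  spacing <- duration_s / (n_calls + 1)
  onsets <- spacing * seq_len(n_calls) +
    with_seed_jitter(seed, n_calls, spacing / 4)
  events <- lapply(onsets, function(o) {
    synthetic_event("dcall", o, 4, 80, 20, amplitude = amplitude)
  })
  gen_scene(events, duration_s, 200, noise_rms = noise_rms, seed = seed)
}

with_seed_jitter <- function(seed, n, half_width) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed + 1000)
  stats::runif(n, -half_width, half_width)
}
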