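# Static resource models for autonomous profiling floats: rate-monotonic
# processor utilization against the Liu-Layland bound, Poisson modelling of
# the parking-stage duration, merging of periodic sensor activations over
# their hyperperiod, satellite transmission volume, per-stage energy
# budgets, battery lifetime, and compatibility checks for composing two
# applications on one float.

#' Execution period of an acquisition mode
#'
#' Continuous modes process a packet each time the sensor fills the input
#' array, so the period is `input_array_len / sampling_hz`; short modes run
#' at the period set in the coordinator.
#'
#' @param mode A named list: `kind` (`"continuous"` or `"short"`); for
#'   continuous, `sampling_hz` and `input_array_len`; for short,
#'   `coordinator_period_s` (at least 60 s).
#' @return Period in seconds.
#' @examples
#' task_period(list(kind = "continuous", sampling_hz = 40,
#'                  input_array_len = 40))  # 1 s
#' @export
task_period <- function(mode) {
  kind <- mode$kind %||% stop("mode needs a `kind`")
  if (kind == "continuous") {
    if (is.null(mode$sampling_hz) || is.null(mode$input_array_len)) {
      stop("continuous mode needs `sampling_hz` and `input_array_len`")
    }
    stopifnot(mode$sampling_hz > 0, mode$input_array_len >= 1)
    mode$input_array_len / mode$sampling_hz
  } else if (kind == "short") {
    p <- mode$coordinator_period_s %||%
      stop("short mode needs `coordinator_period_s`")
    if (p < 60) stop("short-mode periods must be at least one minute")
    p
  } else {
    stop("unknown mode kind: ", kind)
  }
}

#' Processor utilization of a task set
#'
#' `U = sum(C_i / T_i)` over worst-case execution times `C` and periods
#' `T`.
#'
#' @param tasks Data frame or list of lists with fields
#'   `worst_case_exec_s` and `period_s`.
#' @return Total utilization (dimensionless).
#' @export
processor_usage <- function(tasks) {
  if (is.data.frame(tasks)) tasks <- split(tasks, seq_len(nrow(tasks)))
  if (length(tasks) == 0) stop("task set must be non-empty")
  u <- vapply(tasks, function(tk) {
    C <- tk$worst_case_exec_s
    T <- tk$period_s
    if (is.null(C) || is.null(T)) stop("tasks need worst_case_exec_s and period_s")
    if (T <= 0) stop("task periods must be positive")
    if (C < 0) stop("execution times must be non-negative")
    C / T
  }, numeric(1))
  sum(u)
}

#' Liu-Layland utilization bound
#'
#' Sufficient schedulability bound for rate-monotonic fixed priorities:
#' `n * (2^(1/n) - 1)`.  Equals 1 for one task, ~0.83 for two, ~0.76 for
#' four, and tends to `ln 2` (~0.69) as `n` grows.
#'
#' @param n Number of periodic tasks (>= 1).
#' @return The bound (fraction of processor capacity).
#' @export
ll_bound <- function(n) {
  if (any(n < 1)) stop("`n` must be at least 1")
  n * (2^(1 / n) - 1)
}

#' Poisson model of ascent requests during parking
#'
#' `ascent_lambda` is the expected number of ascent requests over the full
#' (maximum) parking duration; `poisson_p` the probability of exactly `k`
#' requests.
#'
#' @param rate_per_d Expected ascent requests per day (>= 0).
#' @param max_parking_d Maximum (default) parking duration, days.
#' @param k Non-negative integer count.
#' @param lambda Poisson mean.
#' @return `ascent_lambda`: the Poisson mean; `poisson_p`: a probability.
#' @examples
#' ascent_lambda(2 / 7, 10)     # 2.857...
#' 1 - poisson_p(0, 2.86)       # ~0.94: at least one request
#' @export
ascent_lambda <- function(rate_per_d, max_parking_d) {
  if (rate_per_d < 0) stop("`rate_per_d` must be non-negative")
  if (max_parking_d <= 0) stop("`max_parking_d` must be positive")
  rate_per_d * max_parking_d
}

#' @rdname ascent_lambda
#' @export
poisson_p <- function(k, lambda) {
  if (any(k < 0) || any(k != floor(k))) stop("`k` must be a non-negative integer")
  if (lambda < 0) stop("`lambda` must be non-negative")
  stats::dpois(k, lambda)
}

#' Mean parking-stage duration
#'
#' The mean time before the first ascent request, capped by the maximum
#' parking duration: mean inter-request interval (1/rate) times the
#' probability of at least one request within the window,
#' `(1/rate) * (1 - exp(-rate * max_parking_d))`.  For `rate = 0` the full
#' `max_parking_d` is returned (the continuous limit).  This expression is
#' also the exact expectation of `min(Exponential(rate), max_parking_d)`.
#'
#' @inheritParams ascent_lambda
#' @return Mean parking duration in days; never exceeds `max_parking_d`.
#' @examples
#' mean_parking_d(2 / 7, 10)  # ~3.3 days
#' @export
mean_parking_d <- function(rate_per_d, max_parking_d) {
  if (rate_per_d < 0) stop("`rate_per_d` must be non-negative")
  if (max_parking_d <= 0) stop("`max_parking_d` must be positive")
  if (rate_per_d == 0) return(max_parking_d)
  (1 / rate_per_d) * (1 - exp(-rate_per_d * max_parking_d))
}

#' Per-stage and total dive duration
#'
#' Descent and ascent last `depth / speed`; the surface stage is modelled
#' as a constant (one hour by default); parking uses the supplied mean.
#'
#' @param depth_m Dive depth in metres (>= 0).
#' @param descent_speed_m_s,ascent_speed_m_s Vertical speeds in m/s (> 0).
#' @param parking_d Mean parking duration in days.
#' @param surface_duration_h Surface-stage duration in hours (default 1).
#' @return Named list of stage durations in days (`descent`, `parking`,
#'   `ascent`, `surface`) plus `total`.
#' @export
dive_duration <- function(depth_m, descent_speed_m_s, ascent_speed_m_s,
                          parking_d, surface_duration_h = 1) {
  if (descent_speed_m_s <= 0 || ascent_speed_m_s <= 0) {
    stop("float speeds must be positive")
  }
  if (depth_m < 0) stop("`depth_m` must be non-negative")
  sec_per_d <- 86400
  stages <- list(descent = depth_m / descent_speed_m_s / sec_per_d,
                 parking = parking_d,
                 ascent = depth_m / ascent_speed_m_s / sec_per_d,
                 surface = surface_duration_h / 24)
  stages$total <- sum(unlist(stages))
  stages
}

#' Periodic activation schedule
#'
#' A sensor activation pattern: on for `on_s` at the start of every
#' `period_s`, phase-aligned at t = 0 (all schedules start active).
#'
#' @param on_s Active time per period (0 < on_s <= period_s).
#' @param period_s Repeat period.
#' @return List of class `periodic_schedule`.
#' @export
periodic_schedule <- function(on_s, period_s) {
  stopifnot(on_s > 0, on_s <= period_s)
  structure(list(on_s = on_s, period_s = period_s),
            class = "periodic_schedule")
}

hyperperiod <- function(periods, tol = 1e-9, max_mult = 100000L) {
  base <- max(periods)
  for (k in seq_len(max_mult)) {
    H <- k * base
    if (all(abs(H / periods - round(H / periods)) < tol)) return(H)
  }
  stop("schedule periods are not commensurate (no hyperperiod found)")
}

#' Merge periodic sensor activations into a duty cycle
#'
#' When several applications share one sensor, the sensor is powered
#' whenever any of them needs it.  The merged pattern repeats over the
#' hyperperiod (least common multiple of the periods); the duty cycle is
#' the active fraction of that pattern.  For example, 2 min on every 5 min
#' merged with 1 min on every 3 min repeats every 15 min with 9 active
#' minutes: duty 0.6.
#'
#' @param schedules List of [periodic_schedule()] objects (>= 1).
#' @return List with `duty_cycle`, `hyperperiod_s`, `active_s` (active
#'   time within one hyperperiod) and `intervals` (matrix of merged on
#'   intervals, seconds).
#' @export
merge_activation <- function(schedules) {
  stopifnot(length(schedules) >= 1)
  periods <- vapply(schedules, function(s) s$period_s, numeric(1))
  H <- hyperperiod(periods)
  iv <- do.call(rbind, lapply(schedules, function(s) {
    k <- seq_len(round(H / s$period_s)) - 1
    cbind(start = k * s$period_s,
          end = pmin(H, k * s$period_s + s$on_s))
  }))
  iv <- iv[order(iv[, "start"]), , drop = FALSE]
  merged <- iv[1, , drop = FALSE]
  for (i in seq_len(nrow(iv))[-1]) {
    last <- nrow(merged)
    if (iv[i, "start"] <= merged[last, "end"]) {
      merged[last, "end"] <- max(merged[last, "end"], iv[i, "end"])
    } else {
      merged <- rbind(merged, iv[i, , drop = FALSE])
    }
  }
  active <- sum(merged[, "end"] - merged[, "start"])
  list(duty_cycle = active / H, hyperperiod_s = H, active_s = active,
       intervals = merged)
}

#' Expected satellite transmission volume
#'
#' Each recording call contributes `bytes * prob * calls_per_dive` to the
#' expected volume of one dive; the monthly figure normalizes by the dive
#' duration over a 30-day month.
#'
#' @param calls List of recording calls, each a named list with `bytes`
#'   (per call), `prob` (branch probability in \[0, 1\]) and
#'   `calls_per_dive` (expected invocations per dive).
#' @param dive_duration_d Mean dive duration in days.
#' @return List with `per_dive` and `per_month` expected bytes.
#' @export
expected_tx_bytes <- function(calls, dive_duration_d) {
  stopifnot(dive_duration_d > 0)
  per_dive <- 0
  for (cl in calls) {
    b <- cl$bytes %||% 0
    p <- cl$prob %||% 1
    n <- cl$calls_per_dive %||% 0
    if (p < 0 || p > 1) stop("call probability outside [0, 1]")
    per_dive <- per_dive + b * p * n
  }
  list(per_dive = per_dive, per_month = per_dive * 30 / dive_duration_d)
}

#' Per-stage energy budget of one dive
#'
#' For each stage, `E = Eact + Esens + Eboard + Ecom` (all in Wh):
#' actuators consume a small constant on descent (valve operation),
#' nothing while parked, and a depth-dependent pump energy
#' `pump_coeff * depth^2 + surface_fill` on ascent; sensors consume
#' `power x duty x stage time`; the board consumes its constant power all
#' stage; satellite transmission happens only at the surface and costs
#' `tx_bytes / tx_speed * sat_power`.
#'
#' @param hardware Named list of hardware constants: `board_power_w`,
#'   `sensor_power_w` (named vector/list, W per sensor),
#'   `descent_energy_wh`, `ascent_pump_coeff_wh_m2`,
#'   `surface_fill_energy_wh`, `sat_power_w`, `tx_speed_bytes_s`.
#'   A missing constant raises an error naming it.
#' @param depth_m Dive depth in metres.
#' @param stage_durations_d Named list of stage durations in days, as from
#'   [dive_duration()].
#' @param sensor_duty Named list: for each sensor, a named numeric vector
#'   of duty cycles per stage (stages absent = sensor off).
#' @param tx_bytes Bytes transmitted per dive.
#' @return List with one `Estage` entry per stage (each itself split into
#'   `Eact`, `Esens`, `Eboard`, `Ecom`) and the dive total `Edive_wh`.
#' @export
energy_budget <- function(hardware, depth_m, stage_durations_d,
                          sensor_duty = list(), tx_bytes = 0) {
  need <- function(name) {
    v <- hardware[[name]]
    if (is.null(v)) stop("missing hardware constant: `", name, "`")
    v
  }
  board_w <- need("board_power_w")
  stages <- c("descent", "parking", "ascent", "surface")
  out <- list()
  total <- 0
  for (st in stages) {
    t_h <- (stage_durations_d[[st]] %||%
              stop("missing stage duration: ", st)) * 24
    Eact <- switch(st,
      descent = need("descent_energy_wh"),
      parking = 0,
      ascent = need("ascent_pump_coeff_wh_m2") * depth_m^2 +
        need("surface_fill_energy_wh"),
      surface = 0)
    Esens <- 0
    for (sensor in names(sensor_duty)) {
      duty <- unname(sensor_duty[[sensor]][st])
      if (is.null(duty) || is.na(duty)) next
      p_w <- need("sensor_power_w")[[sensor]]
      if (is.null(p_w)) stop("missing hardware constant: `sensor_power_w$",
                             sensor, "`")
      Esens <- Esens + p_w * duty * t_h
    }
    Eboard <- board_w * t_h
    Ecom <- if (st == "surface" && tx_bytes > 0) {
      tx_bytes / need("tx_speed_bytes_s") * need("sat_power_w") / 3600
    } else 0
    out[[st]] <- list(Eact = Eact, Esens = Esens, Eboard = Eboard,
                      Ecom = Ecom,
                      total = Eact + Esens + Eboard + Ecom)
    total <- total + out[[st]]$total
  }
  out$Edive_wh <- total
  out
}

#' Battery lifetime
#'
#' `LT = Ebat / Edive * Tdive`, converted from days to years.
#'
#' @param Ebat_wh Battery capacity in Wh.
#' @param Edive_wh Mean energy per dive in Wh (> 0).
#' @param Tdive_d Mean dive duration in days.
#' @param days_per_year Conversion constant (default 365.25).
#' @return Lifetime in years.
#' @export
lifetime_years <- function(Ebat_wh, Edive_wh, Tdive_d,
                           days_per_year = 365.25) {
  if (Edive_wh <= 0) stop("`Edive_wh` must be positive")
  if (Ebat_wh < 0 || Tdive_d <= 0) stop("invalid battery or dive inputs")
  Ebat_wh / Edive_wh * Tdive_d / days_per_year
}

#' Ascent-request rate from branch probabilities
#'
#' Helper aggregating a chain of branch probabilities into a daily rate:
#' `events_per_day * prod(probs)` — e.g. 10 candidate events per day, each
#' passing a 0.2-probability discrimination branch that requests ascent.
#' The mission-level rate remains a plain configuration value; this is a
#' convenience for deriving it.
#'
#' @param events_per_day Expected triggering-opportunity rate per day.
#' @param probs Probabilities along the path to the ascent-request call.
#' @return Requests per day.
#' @export
ascent_rate_from_branches <- function(events_per_day, probs = 1) {
  if (events_per_day < 0 || any(probs < 0 | probs > 1)) {
    stop("invalid rate or probabilities")
  }
  events_per_day * prod(probs)
}

# ---- full-mission analysis ------------------------------------------------

mode_worst_case_exec_s <- function(mode) {
  if (!is.null(mode$worst_case_exec_s)) return(mode$worst_case_exec_s)
  if (is.null(mode$calls)) stop("mode `", mode$name %||% "?",
                                "` has neither worst_case_exec_s nor calls")
  sum(vapply(mode$calls, function(cl) {
    e <- cl$exec_s %||% 0
    if (e < 0) stop("negative execution time in call `", cl$fn %||% "?", "`")
    e
  }, numeric(1)))
}

#' Static analysis of a float mission
#'
#' Combines every resource model into one report: task periods and
#' processor utilization against the Liu-Layland bound, the Poisson
#' parking model, stage durations, expected satellite volume, per-stage
#' energies and battery lifetime.
#'
#' @param spec Mission description, a named list with components
#'   `mission` (`depth_m`, `max_parking_d`, `descent_speed_m_s`,
#'   `ascent_speed_m_s`, `surface_duration_h`, `ascent_request_rate_per_d`),
#'   `hardware` (see [energy_budget()], plus `battery_capacity_wh`) and
#'   `modes` (list of acquisition modes: `name`, `kind`, `sensor`,
#'   `sampling_hz`, `input_array_len` or `coordinator_period_s`, `stages`
#'   the mode runs in, optional `activation` `(on_s, period_s)`, and
#'   `calls` with `fn`, `exec_s`, `bytes`, `prob`, `calls_per_dive`).
#' @return A list of class `resource_report`.
#' @export
analyze_mission <- function(spec) {
  m <- spec$mission %||% stop("spec needs a `mission` block")
  hw <- spec$hardware %||% stop("spec needs a `hardware` block")
  modes <- spec$modes %||% list()

  # -- scheduling
  tasks <- lapply(modes, function(md) {
    list(name = md$name %||% "mode",
         worst_case_exec_s = mode_worst_case_exec_s(md),
         period_s = task_period(md))
  })
  U <- if (length(tasks)) processor_usage(tasks) else 0
  bound <- if (length(tasks)) ll_bound(length(tasks)) else 1

  # -- dive timing
  rate <- m$ascent_request_rate_per_d %||% 0
  lam <- ascent_lambda(max(rate, 0), m$max_parking_d)
  parking <- mean_parking_d(rate, m$max_parking_d)
  stages <- dive_duration(m$depth_m, m$descent_speed_m_s,
                          m$ascent_speed_m_s, parking,
                          m$surface_duration_h %||% 1)

  # -- satellite volume
  all_calls <- do.call(c, c(lapply(modes, function(md) md$calls %||% list()),
                            list(list())))
  tx <- expected_tx_bytes(all_calls, stages$total)

  # -- sensor duties per stage
  sensor_duty <- list()
  for (md in modes) {
    if (is.null(md$sensor)) next
    duty <- if (!is.null(md$activation)) {
      merge_activation(list(periodic_schedule(md$activation$on_s,
                                              md$activation$period_s)))$duty_cycle
    } else 1
    run_in <- md$stages %||% "parking"
    cur <- sensor_duty[[md$sensor]] %||%
      c(descent = 0, parking = 0, ascent = 0, surface = 0)
    cur[run_in] <- pmin(1, cur[run_in] + duty)  # conservative union
    sensor_duty[[md$sensor]] <- cur
  }

  # -- energy and lifetime
  energy <- energy_budget(hw, m$depth_m, stages, sensor_duty, tx$per_dive)
  lt <- lifetime_years(hw$battery_capacity_wh %||%
                         stop("missing hardware constant: `battery_capacity_wh`"),
                       energy$Edive_wh, stages$total)

  structure(list(
    tasks = tasks,
    processor_utilization = U,
    ll_bound = bound,
    schedulable = U <= bound,
    lambda = lam,
    p_at_least_one_ascent = 1 - poisson_p(0, lam),
    mean_parking_d = parking,
    stage_durations_d = stages,
    dive_duration_d = stages$total,
    tx_bytes_per_dive = tx$per_dive,
    tx_bytes_per_month = tx$per_month,
    sensor_duty = sensor_duty,
    energy = energy,
    lifetime_years = lt
  ), class = "resource_report")
}

#' @export
print.resource_report <- function(x, ...) {
  cat("<resource_report>\n")
  cat(sprintf("  processor: U = %.4f%% of capacity, LL bound %.1f%% (n=%d) -> %s\n",
              100 * x$processor_utilization, 100 * x$ll_bound,
              length(x$tasks),
              if (x$schedulable) "schedulable" else "NOT schedulable"))
  cat(sprintf("  dive: parking %.2f d (lambda %.2f, P(>=1 ascent) %.2f), total %.2f d\n",
              x$mean_parking_d, x$lambda, x$p_at_least_one_ascent,
              x$dive_duration_d))
  cat(sprintf("  satellite: %.0f B/dive, %.0f B/month\n",
              x$tx_bytes_per_dive, x$tx_bytes_per_month))
  cat(sprintf("  energy: %.2f Wh/dive -> lifetime %.2f years\n",
              x$energy$Edive_wh, x$lifetime_years))
  invisible(x)
}

#' Compatibility check for composing applications on one float
#'
#' Applications deployed on the same float must agree on dive depth and
#' maximum parking duration; a sensor shared in the same stage must be
#' configured identically (same sampling rate); and the combined task set
#' must stay within the Liu-Layland bound.
#'
#' @param apps List (>= 2) of mission descriptions as for
#'   [analyze_mission()].
#' @return List with `ok` (logical) and `conflicts` (character vector of
#'   human-readable conflict descriptions; conflicts are data, not
#'   errors).
#' @export
compose_check <- function(apps) {
  stopifnot(length(apps) >= 2)
  conflicts <- character(0)
  depths <- vapply(apps, function(a) a$mission$depth_m, numeric(1))
  parks <- vapply(apps, function(a) a$mission$max_parking_d, numeric(1))
  if (length(unique(depths)) > 1) {
    conflicts <- c(conflicts, sprintf(
      "dive depth differs between applications: %s m",
      paste(depths, collapse = " vs ")))
  }
  if (length(unique(parks)) > 1) {
    conflicts <- c(conflicts, sprintf(
      "maximum dive duration differs between applications: %s d",
      paste(parks, collapse = " vs ")))
  }
  # sensor configuration conflicts: same sensor, overlapping stage,
  # different sampling frequency
  use <- list()
  for (ai in seq_along(apps)) {
    for (md in apps[[ai]]$modes %||% list()) {
      if (is.null(md$sensor)) next
      for (st in md$stages %||% "parking") {
        use[[length(use) + 1]] <- list(app = ai, sensor = md$sensor,
                                       stage = st,
                                       fs = md$sampling_hz %||% NA_real_)
      }
    }
  }
  if (length(use) >= 2) {
    for (i in seq_len(length(use) - 1)) {
      for (j in (i + 1):length(use)) {
        a <- use[[i]]; b <- use[[j]]
        if (a$app != b$app && a$sensor == b$sensor &&
            a$stage == b$stage && !isTRUE(all.equal(a$fs, b$fs))) {
          conflicts <- c(conflicts, sprintf(
            "sensor `%s` used in stage `%s` at %g Hz by app %d but %g Hz by app %d",
            a$sensor, a$stage, a$fs, a$app, b$fs, b$app))
        }
      }
    }
  }
  # combined schedulability
  tasks <- do.call(c, lapply(apps, function(a) {
    lapply(a$modes %||% list(), function(md) {
      list(worst_case_exec_s = mode_worst_case_exec_s(md),
           period_s = task_period(md))
    })
  }))
  if (length(tasks) > 0) {
    U <- processor_usage(tasks)
    bound <- ll_bound(length(tasks))
    if (U > bound) {
      conflicts <- c(conflicts, sprintf(
        "combined utilization %.3f exceeds Liu-Layland bound %.3f for %d tasks",
        U, bound, length(tasks)))
    }
  }
  list(ok = length(conflicts) == 0, conflicts = conflicts)
}

#' Load a mission description from YAML/JSON
#'
#' @param path Path to a YAML (or JSON; YAML is a superset) mission file
#'   with `mission`, `hardware` and `modes` blocks.
#' @return The parsed specification list.
#' @export
read_mission_spec <- function(path) {
  spec <- yaml::read_yaml(path)
  for (block in c("mission", "hardware")) {
    if (is.null(spec[[block]])) {
      stop("mission file lacks a `", block, "` block: ", path)
    }
  }
  spec
}
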