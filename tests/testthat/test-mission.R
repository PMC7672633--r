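test_that("task periods follow the acquisition-mode semantics", {
  expect_equal(task_period(list(kind = "continuous", sampling_hz = 40,
                                input_array_len = 40)), 1)
  expect_equal(task_period(list(kind = "short",
                                coordinator_period_s = 3600)), 3600)
  expect_equal(task_period(list(kind = "continuous", sampling_hz = 200,
                                input_array_len = 32)), 0.16)
  expect_error(task_period(list(kind = "short", coordinator_period_s = 30)),
               "minute")
  expect_error(task_period(list(kind = "continuous", sampling_hz = 40)),
               "input_array_len")
})

test_that("processor usage sums C/T and validates inputs", {
  expect_equal(processor_usage(list(list(worst_case_exec_s = 1,
                                         period_s = 1))), 1)
  expect_equal(processor_usage(list(list(worst_case_exec_s = 0.1, period_s = 1),
                                    list(worst_case_exec_s = 0.2, period_s = 2))),
               0.2)
  set.seed(21)
  for (i in 1:20) {
    n <- sample(1:6, 1)
    C <- runif(n, 0, 1); T <- runif(n, 1, 10)
    tasks <- Map(function(c, t) list(worst_case_exec_s = c, period_s = t),
                 C, T)
    expect_equal(processor_usage(tasks), sum(C / T))
  }
  expect_error(processor_usage(list(list(worst_case_exec_s = 1,
                                         period_s = 0))), "positive")
})

test_that("the Liu-Layland bound gives 100/83/76 percent and tends to ln 2", {
  expect_equal(ll_bound(1), 1)
  expect_equal(round(100 * ll_bound(2)), 83)
  expect_equal(round(100 * ll_bound(4)), 76)
  expect_equal(ll_bound(1e6), log(2), tolerance = 1e-5)
  expect_error(ll_bound(0), "at least 1")
})

test_that("the Poisson ascent model reproduces the 10-day / two-per-week example", {
  lam <- ascent_lambda(2 / 7, 10)
  expect_equal(lam, 20 / 7)
  expect_equal(round(lam, 2), 2.86)
  expect_equal(poisson_p(0, lam), exp(-lam))
  expect_equal(round(1 - poisson_p(0, 2.86), 2), 0.94)
  expect_equal(poisson_p(0, 0), 1)
  expect_error(ascent_lambda(-1, 10), "non-negative")
})

test_that("Poisson probabilities normalize for lambda up to 10", {
  for (lam in c(0.1, 1, 2.86, 5, 10)) {
    expect_equal(sum(poisson_p(0:50, lam)), 1, tolerance = 1e-9)
  }
})

test_that("mean parking duration matches the worked example and its limits", {
  expect_equal(round(mean_parking_d(2 / 7, 10), 1), 3.3)
  expect_equal(mean_parking_d(0, 10), 10)
  expect_lt(mean_parking_d(100, 10), 0.02)

  # continuity at rate -> 0, monotone decrease, never above the cap
  rates <- c(1e-9, 1e-4, 0.01, 0.1, 0.5, 1, 5)
  vals <- vapply(rates, mean_parking_d, 1, max_parking_d = 10)
  expect_equal(vals[1], 10, tolerance = 1e-6)
  expect_true(all(diff(vals) < 0))
  expect_true(all(vals <= 10))
})

test_that("dive durations follow depth, speeds and the fixed surface hour", {
  d <- dive_duration(1500, 0.1, 0.1, parking_d = 3.3)
  expect_equal(d$descent, 15000 / 86400)
  expect_equal(d$ascent, 15000 / 86400)
  expect_equal(d$surface, 1 / 24)
  expect_equal(d$total, 3.3 + 2 * 15000 / 86400 + 1 / 24)
  expect_equal(round(d$total, 2), 3.69)

  d0 <- dive_duration(0, 0.1, 0.1, parking_d = 5, surface_duration_h = 1)
  expect_equal(d0$descent, 0)
  expect_equal(d0$ascent, 0)
  expect_equal(d0$surface, 1 / 24)
  expect_error(dive_duration(1500, 0, 0.1, 3), "positive")
})

test_that("activation merging reproduces the 2/5 + 1/3 minute pattern", {
  m <- merge_activation(list(periodic_schedule(120, 300),
                             periodic_schedule(60, 180)))
  expect_equal(m$hyperperiod_s, 900)
  expect_equal(m$active_s, 540)
  expect_equal(m$duty_cycle, 0.6)
  expect_equal(merge_activation(list(periodic_schedule(120, 300)))$duty_cycle,
               0.4)
})

test_that("activation merging equals the minute-grid OR simulation", {
  set.seed(22)
  for (i in 1:30) {
    k <- sample(1:3, 1)
    period <- sample(2:60, k, replace = TRUE)
    on <- vapply(period, function(p) sample(seq_len(p), 1), 1L)
    got <- merge_activation(Map(function(o, p) {
      periodic_schedule(o * 60, p * 60)
    }, on, period))$duty_cycle
    expect_equal(got, merge_oracle_minutes(on, period), tolerance = 1e-12)
  }
})

test_that("expected satellite volume follows bytes x prob x calls", {
  expect_equal(expected_tx_bytes(list(), 5)$per_dive, 0)
  one <- expected_tx_bytes(list(list(bytes = 1000, prob = 0.5,
                                     calls_per_dive = 4)), 5)
  expect_equal(one$per_dive, 2000)
  expect_equal(one$per_month, 2000 * 30 / 5)
  sure <- expected_tx_bytes(list(list(bytes = 1000, prob = 1,
                                      calls_per_dive = 4)), 5)
  expect_equal(sure$per_dive, 4000)
  expect_error(expected_tx_bytes(list(list(bytes = 1, prob = 1.2,
                                           calls_per_dive = 1)), 5),
               "probability")
})

test_that("the energy budget composes actuator, sensor, board and satellite terms", {
  hw <- list(board_power_w = 0.1,
             sensor_power_w = list(hydro = 0.05),
             descent_energy_wh = 5,
             ascent_pump_coeff_wh_m2 = 1e-5,
             surface_fill_energy_wh = 2,
             sat_power_w = 2,
             tx_speed_bytes_s = 100,
             battery_capacity_wh = 4000)
  stages <- list(descent = 0.17, parking = 3.3, ascent = 0.17,
                 surface = 1 / 24)
  duty <- list(hydro = c(parking = 0.6))
  eb <- energy_budget(hw, 1500, stages, duty, tx_bytes = 1048576)
  # Esat = 1 MiB / 100 B/s * 2 W = 20971.52 J = 5.8254 Wh
  expect_equal(eb$surface$Ecom, 1048576 / 100 * 2 / 3600, tolerance = 1e-12)
  expect_equal(round(eb$surface$Ecom, 2), 5.83)
  expect_equal(eb$parking$Eact, 0)
  expect_equal(eb$descent$Eact, 5)
  expect_equal(eb$ascent$Eact, 1e-5 * 1500^2 + 2)
  expect_equal(eb$parking$Esens, 0.05 * 0.6 * 3.3 * 24)
  expect_equal(eb$descent$Eboard, 0.1 * 0.17 * 24)
  # no transmission -> no satellite energy
  expect_equal(energy_budget(hw, 1500, stages, duty,
                             tx_bytes = 0)$surface$Ecom, 0)
  # zero depth -> ascent actuators reduce to the surface fill energy
  expect_equal(energy_budget(hw, 0, stages, duty, 0)$ascent$Eact, 2)
  hw$sat_power_w <- NULL
  expect_error(energy_budget(hw, 1500, stages, duty, tx_bytes = 1),
               "sat_power_w")
})

test_that("lifetime follows Ebat/Edive x Tdive and is monotone", {
  expect_equal(round(lifetime_years(4000, 20, 10), 2), 5.48)
  expect_equal(lifetime_years(100, 100, 365.25), 1)
  expect_equal(lifetime_years(8000, 20, 10), 2 * lifetime_years(4000, 20, 10))
  # increasing any draw never increases lifetime
  expect_lt(lifetime_years(4000, 25, 10), lifetime_years(4000, 20, 10))
  expect_error(lifetime_years(4000, 0, 10), "positive")
})

test_that("LL-schedulable task sets pass exact rate-monotonic simulation", {
  set.seed(23)
  checked <- 0
  for (i in 1:200) {
    n <- sample(2:4, 1)
    T <- sample(c(2, 3, 4, 5, 6, 8, 10, 12), n)
    C <- runif(n, 0.05, 0.9) * T / n
    tasks <- Map(function(c, t) list(worst_case_exec_s = c, period_s = t),
                 C, T)
    U <- processor_usage(tasks)
    if (U <= ll_bound(n)) {
      checked <- checked + 1
      expect_true(rm_sim_schedulable(C, T))
    }
  }
  expect_gt(checked, 20)   # the property must actually have been exercised
})

test_that("analyze_mission assembles a coherent resource report", {
  spec <- list(
    mission = list(depth_m = 1500, max_parking_d = 10,
                   descent_speed_m_s = 0.1, ascent_speed_m_s = 0.1,
                   surface_duration_h = 1,
                   ascent_request_rate_per_d = 2 / 7),
    hardware = list(battery_capacity_wh = 4000, board_power_w = 0.02,
                    sensor_power_w = list(hydro_lf = 0.05),
                    descent_energy_wh = 5, ascent_pump_coeff_wh_m2 = 1e-5,
                    surface_fill_energy_wh = 2, sat_power_w = 2,
                    tx_speed_bytes_s = 100),
    modes = list(list(name = "dcall", kind = "continuous",
                      sensor = "hydro_lf", sampling_hz = 200,
                      input_array_len = 32, stages = "parking",
                      calls = list(list(fn = "record", exec_s = 0.001,
                                        bytes = 12, prob = 1,
                                        calls_per_dive = 400))))
  )
  rep <- analyze_mission(spec)
  expect_s3_class(rep, "resource_report")
  expect_equal(rep$tasks[[1]]$period_s, 0.16)
  expect_equal(rep$processor_utilization, 0.001 / 0.16)
  expect_true(rep$schedulable)
  expect_equal(round(rep$lambda, 2), 2.86)
  expect_equal(round(rep$mean_parking_d, 1), 3.3)
  expect_equal(rep$tx_bytes_per_dive, 4800)
  expect_gt(rep$lifetime_years, 0)
  expect_equal(rep$stage_durations_d$surface, 1 / 24)
  # energy must flow into the lifetime identity
  expect_equal(rep$lifetime_years,
               4000 / rep$energy$Edive_wh * rep$dive_duration_d / 365.25)
})

test_that("compose_check flags depth, duration and sensor conflicts", {
  base <- function(depth, parking, fs, sensor = "hydro") {
    list(mission = list(depth_m = depth, max_parking_d = parking),
         modes = list(list(name = "m", kind = "continuous", sensor = sensor,
                           sampling_hz = fs, input_array_len = fs,
                           stages = "parking",
                           worst_case_exec_s = 0.001)))
  }
  depth_conflict <- compose_check(list(base(1500, 10, 40),
                                       base(2000, 10, 40)))
  expect_false(depth_conflict$ok)
  expect_match(depth_conflict$conflicts, "depth", all = FALSE)

  sensor_conflict <- compose_check(list(base(1500, 10, 40),
                                        base(1500, 10, 200)))
  expect_false(sensor_conflict$ok)
  expect_match(sensor_conflict$conflicts, "sensor", all = FALSE)

  ok <- compose_check(list(base(1500, 10, 40, sensor = "hydro_lf"),
                           base(1500, 10, 200, sensor = "hydro_hf")))
  expect_true(ok$ok)
  expect_length(ok$conflicts, 0)
})

test_that("branch-probability aggregation yields a daily ascent rate", {
  expect_equal(ascent_rate_from_branches(10, c(0.5, 0.4)), 2)
  expect_equal(ascent_rate_from_branches(10), 10)
  expect_error(ascent_rate_from_branches(10, 1.5), "probabilities")
})
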