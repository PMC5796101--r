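test_that("air amount follows the ideal-gas law", {
  ch <- chamber_spec()
  expect_equal(air_moles(ch), 101325 * 2 / (8.314 * 305.15))
  expect_equal(round(air_moles(ch), 2), 79.88)
  # linear in volume, inverse in temperature
  expect_equal(air_moles(chamber_spec(dimensions = c(1, 1, 1))),
               air_moles(ch) / 2)
  expect_equal(air_moles(chamber_spec(air_temperature = 2 * 305.15)),
               air_moles(ch) / 2)
})

test_that("a linear drawdown maps to the expected constant rate", {
  ch <- chamber_spec()
  tt <- seq(0, 43200, by = 5)
  tr <- tibble::tibble(time = tt, co2 = 1000 - 400 * tt / 43200)
  rs <- drawdown_to_rate(tr, ch, leaf_area = 0.41948)
  expected <- (400 / 43200) * air_moles(ch) / 0.41948   # = 1.763
  expect_equal(range(rs$rate), rep(expected, 2), tolerance = 1e-6)
  expect_equal(round(expected, 3), 1.763)
  # windows only where they fully fit
  expect_gte(min(rs$time), 90)
  expect_lte(max(rs$time), 43200 - 90)

  # flat trace: zero rate; rising trace: negative rate (respiration sign)
  flat <- tibble::tibble(time = tt, co2 = rep(700, length(tt)))
  expect_equal(range(drawdown_to_rate(flat, ch, 0.4)$rate), c(0, 0))
  rising <- tibble::tibble(time = tt, co2 = 700 + 0.001 * tt)
  expect_true(all(drawdown_to_rate(rising, ch, 0.4)$rate < 0))

  expect_error(drawdown_to_rate(tr[1:10, ], ch, 0.4, window = 600),
               "shorter than")
})

test_that("leak correction inverts the simulated leak exactly", {
  ch <- chamber_spec(leak_coefficient = 2e-5)
  A <- 0.41948
  rate_true <- 1.5   # umol m^-2 s^-1, constant
  flux_fun <- function(co2, time) rate_true * A
  sim <- simulate_drawdown(flux_fun, ch, c0 = 1000, duration = 7200, dt = 1)
  rs <- drawdown_to_rate(sim[seq(1, nrow(sim), by = 5), ], ch, A)
  expect_lt(max(abs(rs$rate - rate_true)) / rate_true, 0.01)
})

test_that("chamber leak coefficient is recovered from decay traces", {
  ch <- chamber_spec()
  tt <- seq(0, 172800, by = 60)
  clean <- tibble::tibble(time = tt,
                          co2 = 400 + 900 * exp(-1e-6 * tt))
  est <- estimate_leak(clean, ch)
  expect_true(est$converged)
  expect_lt(abs(est$leak_coefficient - 1e-6) / 1e-6, 0.001)

  set.seed(12)
  noisy <- tibble::tibble(time = tt,
                          co2 = 400 + 900 * exp(-1e-6 * tt) +
                            rnorm(length(tt), 0, 5))
  est_n <- estimate_leak(noisy, ch)
  expect_true(est_n$converged)
  expect_lt(abs(est_n$leak_coefficient - 1e-6) / 1e-6, 0.10)

  const <- tibble::tibble(time = tt, co2 = rep(400, length(tt)))
  est_c <- estimate_leak(const, ch)
  expect_identical(est_c$leak_coefficient, 0)
  expect_match(est_c$warning, "does not decay")
})

test_that("the drawdown integrator matches closed forms and a stiff oracle", {
  ch <- chamber_spec()
  n_air <- air_moles(ch)
  # zero flux, no leak: conservation
  sim0 <- simulate_drawdown(function(co2, t) 0, ch, c0 = 800,
                            duration = 600, dt = 1)
  expect_equal(range(sim0$co2), c(800, 800))
  # constant flux: linear closed form
  simc <- simulate_drawdown(function(co2, t) 2, ch, c0 = 1000,
                            duration = 3600, dt = 1)
  expect_equal(simc$co2, 1000 - 2 * simc$time / n_air, tolerance = 1e-9)

  # saturated-canopy flux: independent stiff solver agrees at 12 h
  skip_if_not_installed("deSolve")
  A <- 0.41948
  m <- photo_model()
  flux_fun <- function(co2, time) {
    m$p_max * A * (1 - exp(-m$k_co2 * co2)) - m$r_dark * A
  }
  sim <- simulate_drawdown(flux_fun, ch, c0 = 1000, duration = 43200,
                           dt = 1)
  ode <- deSolve::ode(y = c(C = 1000), times = c(0, 43200),
                      func = function(t, y, p) list(-flux_fun(y, t) / n_air),
                      method = "lsoda", rtol = 1e-10, atol = 1e-10)
  expect_lt(abs(dplyr::last(sim$co2) - ode[2, 2]) / ode[2, 2], 0.001)
  # trajectory is convex decreasing
  expect_true(all(diff(sim$co2) < 0))
  expect_true(all(diff(diff(sim$co2[seq(1, nrow(sim), by = 600)])) > -1e-9))
})

test_that("analysis of a simulated drawdown recovers the generating rates", {
  ch <- chamber_spec()
  A <- 0.41948
  m <- photo_model()
  flux_fun <- function(co2, time) {
    m$p_max * A * (1 - exp(-m$k_co2 * co2)) - m$r_dark * A
  }
  sim <- simulate_drawdown(flux_fun, ch, c0 = 1000, duration = 43200, dt = 1)
  rs <- drawdown_to_rate(sim[seq(1, nrow(sim), by = 5), ], ch, A)
  truth <- vapply(rs$co2, function(cc) flux_fun(cc, 0) / A, 0)
  expect_lt(max(abs(rs$rate - truth) / truth), 0.01)

  # mass balance: moles removed equal the time-integrated flux
  n_air <- air_moles(ch)
  fluxes <- vapply(seq_len(nrow(sim)),
                   function(i) flux_fun(sim$co2[i], sim$time[i]), 0)
  integrated <- sum((fluxes[-1] + fluxes[-length(fluxes)]) / 2) * 1
  removed <- n_air * (1000 - dplyr::last(sim$co2))
  expect_lt(abs(removed - integrated) / integrated, 1e-6)
})

test_that("gas trace CSV I/O round-trips and accepts logger-style columns", {
  tr <- tibble::tibble(time = seq(0, 100, by = 10),
                       co2 = 1000 - seq(0, 100, by = 10) * 0.5)
  f <- withr::local_tempfile(fileext = ".csv")
  write_gas_trace(tr, f)
  back <- read_gas_trace(f)
  expect_equal(back$co2, tr$co2)

  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("timestamp,co2_ppm",
               "2016-07-15T08:00:00,1000",
               "2016-07-15T08:00:10,999.5",
               "2016-07-15T08:00:20,999.1"), f2)
  logger <- read_gas_trace(f2)
  expect_equal(logger$time, c(0, 10, 20))
  expect_equal(logger$co2, c(1000, 999.5, 999.1))
})
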