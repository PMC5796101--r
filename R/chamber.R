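#' Closed-chamber specification
#'
#' Geometry and air state of a sealed gas-exchange chamber.  The default is
#' a 1 x 1 x 2 m polycarbonate chamber held at 32 degC and ambient pressure.
#' Humidity is ignored in the air-mole calculation (a <= 2 percent effect at
#' 60-70 percent RH and 32 degC).
#'
#' @param dimensions chamber `c(x, y, z)` in metres.
#' @param air_temperature Kelvin.
#' @param pressure Pa.
#' @param leak_coefficient first-order leak exchange rate with ambient air,
#'   s^-1 (0 = perfectly sealed; estimate with [estimate_leak()]).
#' @param ambient_co2 ambient CO2 mole fraction, umol mol^-1.
#' @return An object of class `chamber_spec`.
#' @export
chamber_spec <- function(dimensions = c(1, 1, 2), air_temperature = 305.15,
                         pressure = 101325, leak_coefficient = 0,
                         ambient_co2 = 400) {
  stopifnot(length(dimensions) == 3, all(dimensions > 0),
            air_temperature > 0, pressure > 0, leak_coefficient >= 0,
            ambient_co2 >= 0)
  structure(list(dimensions = dimensions,
                 volume = prod(dimensions),
                 air_temperature = air_temperature,
                 pressure = pressure,
                 leak_coefficient = leak_coefficient,
                 ambient_co2 = ambient_co2),
            class = "chamber_spec")
}

#' Moles of air in a chamber (ideal gas)
#'
#' `n = p V / (R T)` with `R = 8.314` J mol^-1 K^-1.  Needed to convert a
#' mole-fraction trend (umol mol^-1 s^-1) into a molar CO2 flux
#' (umol s^-1).
#'
#' @param chamber a [chamber_spec()].
#' @return Moles of air.
#' @examples
#' air_moles(chamber_spec())   # 79.88 mol for 2 m^3 at 32 degC
#' @export
air_moles <- function(chamber) {
  stopifnot(inherits(chamber, "chamber_spec"))
  chamber$pressure * chamber$volume / (8.314 * chamber$air_temperature)
}

#' Whole-plant rate from a chamber CO2 drawdown
#'
#' Converts a closed-chamber CO2 time series into a whole-plant net
#' photosynthetic rate per unit leaf area.  At each sample where a full
#' window fits, the CO2 trend is the least-squares slope over the centred
#' window (default 180 s — robust to 1 Hz sensor noise, unlike an endpoint
#' difference), and
#'
#' `rate = (-slope + k (ambient - C)) * n_air / leaf_area`
#'
#' where `k` is the chamber leak coefficient and `C` the window-mean CO2:
#' when the chamber is above ambient, leakage contributes part of the
#' observed drawdown, so the plant is credited with correspondingly less.
#' Drawdown gives positive rates; rising CO2 (dark respiration) gives
#' negative rates.
#'
#' @param trace tibble/data.frame with `time` (s, monotone increasing) and
#'   `co2` (umol mol^-1).
#' @param chamber a [chamber_spec()].
#' @param leaf_area total one-sided leaf area, m^2.
#' @param window slope window, s (default 180).
#' @return A tibble of class `rate_series` with `time`, `co2` (window
#'   mean), `rate` (umolCO2 m^-2 s^-1); attribute `window`.
#' @export
drawdown_to_rate <- function(trace, chamber, leaf_area, window = 180) {
  stopifnot(inherits(chamber, "chamber_spec"), leaf_area > 0, window > 0,
            all(c("time", "co2") %in% names(trace)))
  t <- trace$time
  y <- trace$co2
  stopifnot(length(t) >= 2, !is.unsorted(t, strictly = TRUE), all(y >= 0))
  if (max(t) - min(t) < window) {
    stop("trace is shorter than the averaging window", call. = FALSE)
  }
  half <- window / 2
  # O(n) windowed least-squares slope via prefix sums
  ct <- cumsum(t); cy <- cumsum(y)
  ctt <- cumsum(t * t); cty <- cumsum(t * y)
  lo <- findInterval(t - half, t, left.open = TRUE) + 1L  # first idx >= t-half
  hi <- findInterval(t + half, t)                          # last idx <= t+half
  ok <- (t - min(t) >= half) & (max(t) - t >= half)
  n_w <- hi - lo + 1L
  s1 <- function(cs) {
    base <- numeric(length(lo))
    has_prev <- lo > 1L
    base[has_prev] <- cs[lo[has_prev] - 1L]
    cs[hi] - base
  }
  st <- s1(ct); sy <- s1(cy); stt <- s1(ctt); sty <- s1(cty)
  denom <- stt - st^2 / n_w
  slope <- (sty - st * sy / n_w) / denom
  cmean <- sy / n_w
  n_air <- air_moles(chamber)
  k <- chamber$leak_coefficient
  rate <- (-slope + k * (chamber$ambient_co2 - cmean)) * n_air / leaf_area
  out <- tibble::tibble(time = t[ok], co2 = cmean[ok], rate = rate[ok])
  attr(out, "window") <- window
  class(out) <- c("rate_series", class(out))
  out
}

#' Estimate the chamber leak coefficient
#'
#' Fits the plant-free decay `C(t) = ambient + (C0 - ambient) exp(-k t)` to
#' a leakage-test trace (chamber charged above ambient, no plant).  A
#' non-decaying trace returns `k = 0` with a warning status.
#'
#' @param trace tibble with `time` (s), `co2` (umol mol^-1).
#' @param chamber a [chamber_spec()] supplying the ambient concentration.
#' @return A list: `leak_coefficient` (s^-1), `rmse`, `converged`,
#'   `warning` (character or `NA`).
#' @export
estimate_leak <- function(trace, chamber) {
  stopifnot(all(c("time", "co2") %in% names(trace)),
            inherits(chamber, "chamber_spec"))
  t <- trace$time - min(trace$time)
  y <- trace$co2
  amb <- chamber$ambient_co2
  excess <- y - amb
  if (mean(tail(excess, max(1, length(y) %/% 10))) >=
      mean(head(excess, max(1, length(y) %/% 10)))) {
    return(list(leak_coefficient = 0, rmse = NA_real_, converged = FALSE,
                warning = "trace does not decay toward ambient; k set to 0"))
  }
  pos <- excess > 0
  init <- lm(log(excess[pos]) ~ t[pos])
  k0 <- max(1e-12, -coef(init)[2])
  c00 <- y[1]
  # Levenberg-Marquardt: robust to the zero-residual case of noiseless traces
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ amb + (c0 - amb) * exp(-k * t),
                      start = list(c0 = c00, k = k0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(list(leak_coefficient = unname(k0), rmse = NA_real_,
                converged = FALSE,
                warning = "nonlinear fit failed; log-linear estimate used"))
  }
  k <- unname(coef(fit)[["k"]])
  list(leak_coefficient = max(0, k),
       rmse = sqrt(mean(stats::residuals(fit)^2)),
       converged = TRUE, warning = NA_character_)
}

#' Forward-simulate a chamber CO2 drawdown
#'
#' Integrates the well-mixed chamber mass balance
#' `dC/dt = -flux(C, t) / n_air + k (ambient - C)` with the classical
#' fourth-order Runge-Kutta scheme, where `flux(C, t)` is the whole-plant
#' net CO2 uptake in umol s^-1 (may couple the full light -> per-leaf PPFD
#' -> leaf model pipeline).  Concentrations are clipped at zero with a
#' warning.
#'
#' @param flux_fun function of `(co2, time)` returning whole-plant net
#'   uptake, umolCO2 s^-1 (positive = uptake).
#' @param chamber a [chamber_spec()].
#' @param c0 initial CO2 mole fraction, umol mol^-1.
#' @param duration simulated span, s.
#' @param dt integrator step, s.
#' @return A tibble with `time` (s) and `co2` (umol mol^-1), at every step.
#' @export
simulate_drawdown <- function(flux_fun, chamber, c0 = 1000,
                              duration = 43200, dt = 1) {
  stopifnot(inherits(chamber, "chamber_spec"), c0 >= 0, dt > 0,
            duration >= dt)
  n_air <- air_moles(chamber)
  k <- chamber$leak_coefficient
  amb <- chamber$ambient_co2
  deriv <- function(co2, time) {
    -flux_fun(co2, time) / n_air + k * (amb - co2)
  }
  n_steps <- floor(duration / dt + 1e-9)
  times <- seq(0, by = dt, length.out = n_steps + 1)
  co2 <- numeric(n_steps + 1)
  co2[1] <- c0
  clipped <- FALSE
  y <- c0
  for (i in seq_len(n_steps)) {
    t0 <- times[i]
    k1 <- deriv(y, t0)
    k2 <- deriv(max(0, y + dt / 2 * k1), t0 + dt / 2)
    k3 <- deriv(max(0, y + dt / 2 * k2), t0 + dt / 2)
    k4 <- deriv(max(0, y + dt * k3), t0 + dt)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (y < 0) { y <- 0; clipped <- TRUE }
    co2[i + 1] <- y
  }
  if (clipped) {
    warning("CO2 concentration clipped at 0 during simulation",
            call. = FALSE)
  }
  tibble::tibble(time = times, co2 = co2)
}

#' Read / write chamber CO2 traces as CSV
#'
#' The expected columns are `time` (seconds from start, or ISO-8601
#' timestamps which are converted to seconds from the first sample) and
#' `co2` (umol mol^-1); `co2_ppm` is accepted as an alias, matching common
#' IRGA logger exports.
#'
#' @param path CSV file path.
#' @return `read_gas_trace()`: a tibble with `time` (s) and `co2`.
#' @export
read_gas_trace <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  nm <- names(df)
  if ("co2_ppm" %in% nm && !"co2" %in% nm) {
    df <- dplyr::rename(df, co2 = "co2_ppm")
  }
  if ("timestamp" %in% nm && !"time" %in% nm) {
    ts <- as.POSIXct(df$timestamp, tz = "UTC")
    df$time <- as.numeric(ts) - as.numeric(ts[1])
  }
  stopifnot(all(c("time", "co2") %in% names(df)))
  dplyr::select(df, "time", "co2")
}

#' @param trace a tibble with `time` and `co2`.
#' @rdname read_gas_trace
#' @return `write_gas_trace()`: `path`, invisibly.
#' @export
write_gas_trace <- function(trace, path) {
  readr::write_csv(dplyr::select(trace, "time", "co2"), path)
  invisible(path)
}
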