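#' Single-variable saturation response
#'
#' The two empirical saturation forms used for light- and CO2-response
#' curves: the rectangular hyperbola `P = a X / (X + b) + c` and the negative
#' exponential `P = a (1 - exp(-b X)) + c`.  Both saturate at `a + c` and
#' pass through `c` at `X = 0`.
#'
#' @param x driver variable (PPFD or CO2 mole fraction), >= 0; vectorised.
#' @param a asymptotic amplitude (> 0).
#' @param b curvature (> 0; units depend on the form).
#' @param c offset at `x = 0`.
#' @param form `"negative_exponential"` or `"rectangular_hyperbola"`.
#' @return Net photosynthetic rate, umolCO2 m^-2 s^-1.
#' @export
saturation_response <- function(x, a, b, c = 0,
                                form = c("negative_exponential",
                                         "rectangular_hyperbola")) {
  form <- match.arg(form)
  stopifnot(a > 0, b > 0, all(x >= 0))
  switch(form,
         negative_exponential = a * (1 - exp(-b * x)) + c,
         rectangular_hyperbola = a * x / (x + b) + c)
}

#' Two-variable leaf photosynthesis model
#'
#' Net leaf photosynthetic rate as the product of two negative-exponential
#' saturation terms in light and CO2, minus a dark-respiration offset:
#'
#' `P = p_max * (1 - exp(-k_light * I)) * (1 - exp(-k_co2 * C)) - r_dark`
#'
#' The defaults are the Irwin mango leaf parameterisation used throughout
#' the package: `p_max = 12.928` umolCO2 m^-2 s^-1, `k_light = 0.014`
#' (umol m^-2 s^-1)^-1, `k_co2 = 0.001` (umol mol^-1)^-1, `r_dark = 0.889`
#' umolCO2 m^-2 s^-1.  At `I = 0` the rate is exactly `-r_dark` for any CO2;
#' for finite inputs `P` is bounded in `(-r_dark, p_max - r_dark)`.
#'
#' @param p_max asymptotic gross rate, umolCO2 m^-2 s^-1 (> 0).
#' @param k_light light curvature, (umol m^-2 s^-1)^-1 (> 0).
#' @param k_co2 CO2 curvature, (umol mol^-1)^-1 (> 0).
#' @param r_dark dark-respiration offset, umolCO2 m^-2 s^-1 (> 0).
#' @return An object of class `photo_model`.
#' @export
photo_model <- function(p_max = 12.928, k_light = 0.014, k_co2 = 0.001,
                        r_dark = 0.889) {
  stopifnot(p_max > 0, k_light > 0, k_co2 > 0, r_dark > 0)
  structure(list(p_max = p_max, k_light = k_light, k_co2 = k_co2,
                 r_dark = r_dark),
            class = "photo_model")
}

#' @export
print.photo_model <- function(x, ...) {
  cat("<photo_model> P = ", x$p_max, " * (1 - exp(-", x$k_light,
      " I)) * (1 - exp(-", x$k_co2, " C)) - ", x$r_dark, "\n", sep = "")
  invisible(x)
}

#' Net leaf photosynthetic rate
#'
#' Evaluates the two-variable model at incident PPFD `I` and CO2 mole
#' fraction `C` (both vectorised, recycled).
#'
#' @param ppfd incident PPFD, umol m^-2 s^-1 (>= 0).
#' @param co2 CO2 mole fraction, umol mol^-1 (>= 0).
#' @param model a [photo_model()].
#' @return Net rate, umolCO2 m^-2 s^-1.
#' @examples
#' leaf_net_photosynthesis(0, 1000)      # -0.889 (dark respiration)
#' leaf_net_photosynthesis(1200, 500)    # 4.198 (light-saturated)
#' @export
leaf_net_photosynthesis <- function(ppfd, co2, model = photo_model()) {
  if (any(ppfd < 0) || any(co2 < 0)) {
    stop("ppfd and co2 must be non-negative", call. = FALSE)
  }
  model$p_max * (1 - exp(-model$k_light * ppfd)) *
    (1 - exp(-model$k_co2 * co2)) - model$r_dark
}

#' Whole-plant photosynthetic rate by area-weighted integration
#'
#' Applies the leaf model at each leaf's mean intercepted PPFD and sums the
#' per-leaf fluxes: `total_flux = sum(P_i * A_i)` (umolCO2 s^-1);
#' `rate_per_leaf_area = total_flux / sum(A_i)` — net CO2 uptake per unit
#' one-sided leaf area, the same basis as a closed-chamber measurement
#' divided by total leaf area.
#'
#' @param ppfd_table tibble with `leaf_id`, `ppfd` ([leaf_ppfd_table()]).
#' @param leaves tibble with `leaf_id` and `allometric_area` (cm^2), e.g.
#'   [build_plant()]'s `leaves`.
#' @param co2 CO2 mole fraction, umol mol^-1 (scalar).
#' @param model a [photo_model()].
#' @return An object of class `whole_plant_rate`: list with `per_leaf`
#'   (tibble `leaf_id`, `ppfd`, `area_cm2`, `rate`), `total_flux`
#'   (umolCO2 s^-1), `rate_per_leaf_area` (umolCO2 m^-2 s^-1),
#'   `total_leaf_area_m2`, `co2`.
#' @export
whole_plant_rate <- function(ppfd_table, leaves, co2,
                             model = photo_model()) {
  stopifnot(length(co2) == 1, co2 >= 0)
  if (!setequal(ppfd_table$leaf_id, leaves$leaf_id)) {
    stop("ppfd_table and leaves must describe the same set of leaf ids",
         call. = FALSE)
  }
  per_leaf <- dplyr::inner_join(
    dplyr::select(ppfd_table, "leaf_id", "ppfd"),
    dplyr::select(leaves, "leaf_id", area_cm2 = "allometric_area"),
    by = "leaf_id") |>
    dplyr::mutate(rate = leaf_net_photosynthesis(.data$ppfd, co2, model))
  area_m2 <- per_leaf$area_cm2 / 1e4
  total_flux <- sum(per_leaf$rate * area_m2)
  structure(list(per_leaf = per_leaf,
                 total_flux = total_flux,
                 rate_per_leaf_area = total_flux / sum(area_m2),
                 total_leaf_area_m2 = sum(area_m2),
                 co2 = co2),
            class = "whole_plant_rate")
}

#' @export
print.whole_plant_rate <- function(x, ...) {
  cat("<whole_plant_rate> at CO2 ", x$co2, " umol/mol: ",
      sprintf("%.3f", x$rate_per_leaf_area), " umolCO2 m^-2(leaf) s^-1 (",
      sprintf("%.3f", x$total_flux), " umolCO2/s over ",
      sprintf("%.3f", x$total_leaf_area_m2), " m^2 leaf)\n", sep = "")
  invisible(x)
}

#' Whole-plant CO2 response for a fixed light field
#'
#' Because the model is separable in light and CO2, one traced light field
#' yields the entire CO2-response curve: the light-dependent factor
#' `S = p_max * sum(A_i (1 - exp(-k_light I_i)))` is computed once and the
#' curve is `rate(C) = (S (1 - exp(-k_co2 C)) - r_dark A_tot) / A_tot`.
#'
#' @inheritParams whole_plant_rate
#' @param co2_grid vector of CO2 mole fractions.
#' @return A tibble of class `co2_response` with `co2`, `rate`
#'   (umolCO2 m^-2 s^-1) and `total_flux` (umolCO2 s^-1).
#' @export
co2_response <- function(ppfd_table, leaves, co2_grid,
                         model = photo_model()) {
  stopifnot(all(co2_grid >= 0))
  joined <- dplyr::inner_join(
    dplyr::select(ppfd_table, "leaf_id", "ppfd"),
    dplyr::select(leaves, "leaf_id", area_cm2 = "allometric_area"),
    by = "leaf_id")
  area_m2 <- joined$area_cm2 / 1e4
  a_tot <- sum(area_m2)
  s <- model$p_max * sum(area_m2 * (1 - exp(-model$k_light * joined$ppfd)))
  flux <- s * (1 - exp(-model$k_co2 * co2_grid)) - model$r_dark * a_tot
  out <- tibble::tibble(co2 = co2_grid, rate = flux / a_tot,
                        total_flux = flux)
  class(out) <- c("co2_response", class(out))
  out
}

#' Fit the two-variable model to (I, C, P) observations
#'
#' Levenberg-Marquardt nonlinear least squares over
#' `(p_max, k_light, k_co2, r_dark)` with an analytic residual Jacobian,
#' positivity enforced through log-parameterisation, and a seeded
#' multi-start (perturbed initial guesses) to guard against local minima.
#'
#' @param data tibble/data.frame with columns `ppfd`, `co2`, `rate`
#'   (>= 8 rows spanning both axes).
#' @param start optional named list with starting values (`p_max`,
#'   `k_light`, `k_co2`, `r_dark`).
#' @param n_starts number of multi-start attempts (first uses `start`
#'   unperturbed).
#' @param seed seed for the start perturbations.
#' @return An object of class `photo_fit`: `model` (a [photo_model()], if
#'   converged), `rmse`, `converged`, `n_obs`, `message`.  Supports
#'   [generics::tidy()] and [generics::glance()].
#' @export
fit_photo_model <- function(data, start = NULL, n_starts = 5, seed = 1L) {
  stopifnot(all(c("ppfd", "co2", "rate") %in% names(data)))
  data <- tibble::as_tibble(data)
  n <- nrow(data)
  fail <- function(msg) {
    structure(list(model = NULL, rmse = NA_real_, converged = FALSE,
                   n_obs = n, message = msg, data = data),
              class = "photo_fit")
  }
  if (n < 8) return(fail("need at least 8 observations"))
  if (sd(data$rate) < 1e-10 || sd(data$ppfd) < 1e-10 ||
      sd(data$co2) < 1e-10) {
    return(fail("observations do not span both axes (unidentifiable)"))
  }
  if (is.null(start)) {
    start <- list(p_max = max(data$rate) - min(data$rate) + 1,
                  k_light = 3 / max(data$ppfd),
                  k_co2 = 3 / max(data$co2),
                  r_dark = max(0.1, -min(data$rate)))
  }
  resid_fn <- function(theta) {
    p <- exp(theta)
    p[1] * (1 - exp(-p[2] * data$ppfd)) * (1 - exp(-p[3] * data$co2)) -
      p[4] - data$rate
  }
  jac_fn <- function(theta) {
    p <- exp(theta)
    fI <- 1 - exp(-p[2] * data$ppfd)
    fC <- 1 - exp(-p[3] * data$co2)
    cbind(p[1] * fI * fC,                                    # d/d log p_max
          p[1] * p[2] * data$ppfd * exp(-p[2] * data$ppfd) * fC,
          p[1] * p[3] * data$co2 * exp(-p[3] * data$co2) * fI,
          -p[4])
  }
  theta0 <- log(unlist(start))
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) {
    get(".Random.seed", .GlobalEnv)
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)
  })
  set.seed(seed)
  best <- NULL
  for (k in seq_len(n_starts)) {
    th <- if (k == 1) theta0 else theta0 + stats::rnorm(4, 0, 0.5)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = th, fn = resid_fn, jac = jac_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    ssr <- sum(resid_fn(fit$par)^2)
    if (is.null(best) || ssr < best$ssr) best <- list(fit = fit, ssr = ssr)
  }
  if (is.null(best)) return(fail("optimizer failed from every start"))
  p <- exp(best$fit$par)
  rmse <- sqrt(best$ssr / n)
  structure(list(model = photo_model(p[1], p[2], p[3], p[4]),
                 rmse = rmse, converged = TRUE, n_obs = n,
                 message = "converged", data = data,
                 n_iter = best$fit$niter),
            class = "photo_fit")
}

#' @export
print.photo_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<photo_fit> FAILED: ", x$message, "\n", sep = "")
  } else {
    cat("<photo_fit> RMSE ", sprintf("%.4g", x$rmse), " on ", x$n_obs,
        " observations\n", sep = "")
    print(x$model)
  }
  invisible(x)
}

#' Tidy a fitted two-variable photosynthesis model
#'
#' @param x a `photo_fit`.
#' @param ... unused.
#' @return A tibble with `term`, `estimate`.
#' @export
tidy.photo_fit <- function(x, ...) {
  if (!x$converged) {
    return(tibble::tibble(term = character(0), estimate = numeric(0)))
  }
  tibble::tibble(term = c("p_max", "k_light", "k_co2", "r_dark"),
                 estimate = unlist(x$model[c("p_max", "k_light",
                                             "k_co2", "r_dark")]))
}

#' One-row fit summary
#'
#' @param x a `photo_fit`.
#' @param ... unused.
#' @return A tibble with `rmse`, `converged`, `n_obs`.
#' @export
glance.photo_fit <- function(x, ...) {
  tibble::tibble(rmse = x$rmse, converged = x$converged, n_obs = x$n_obs)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
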