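test_that("saturation responses evaluate both canonical forms", {
  # rectangular hyperbola: 10 * 100 / (100 + 100) - 1 = 4
  expect_equal(saturation_response(100, a = 10, b = 100, c = -1,
                                   form = "rectangular_hyperbola"), 4)
  # x = 0 returns the offset for either form
  expect_equal(saturation_response(0, 5, 0.01, c = -2), -2)
  expect_equal(saturation_response(0, 5, 100, c = -2,
                                   form = "rectangular_hyperbola"), -2)
  # negative-exponential asymptote
  expect_equal(saturation_response(1e9, 5, 0.01, c = 1), 6)
  expect_error(saturation_response(-1, 5, 0.01))
})

test_that("the two-variable leaf model reproduces its anchor values", {
  # dark value: -r_dark at I = 0, for any CO2
  expect_equal(leaf_net_photosynthesis(0, 1000), -0.889)
  expect_equal(leaf_net_photosynthesis(0, 200), -0.889)
  # light-saturated rate at C = 500 is ~4.198 (rounds to 4)
  expect_equal(leaf_net_photosynthesis(1200, 500), 4.198, tolerance = 1e-4)
  expect_identical(round(leaf_net_photosynthesis(1200, 500)), 4)
  # top-sensor PPFD under the calibrated lamp at C = 1000
  expect_equal(leaf_net_photosynthesis(833.1, 1000), 7.283,
               tolerance = 1e-4)
  expect_error(leaf_net_photosynthesis(-5, 400), "non-negative")
})

test_that("the leaf model is monotone and bounded on random grids", {
  set.seed(31)
  m <- photo_model()
  for (rep in 1:20) {
    i <- sort(runif(10, 0, 2000))
    cc <- runif(1, 0, 1500)
    p <- leaf_net_photosynthesis(i, cc, m)
    expect_true(all(diff(p) > 0))                        # increasing in I
    p2 <- leaf_net_photosynthesis(runif(1, 0, 2000), sort(runif(10, 0, 1500)), m)
    expect_true(all(diff(p2) > 0))                       # increasing in C
    expect_true(all(p > -m$r_dark & p < m$p_max - m$r_dark))
  }
})

test_that("whole-plant integration reduces correctly and respects identities", {
  leaves <- tibble::tibble(leaf_id = 1:3,
                           allometric_area = c(50, 30, 20))
  tab <- tibble::tibble(leaf_id = 1:3, ppfd = c(1500, 1300, 2000))
  # all leaves saturated: whole-plant rate equals the single-leaf value
  w <- whole_plant_rate(tab, leaves, co2 = 500)
  expect_equal(w$rate_per_leaf_area, leaf_net_photosynthesis(1e6, 500),
               tolerance = 1e-4)
  # single leaf: exact equality
  w1 <- whole_plant_rate(tab[1, ], leaves[1, ], co2 = 700)
  expect_equal(w1$rate_per_leaf_area,
               leaf_net_photosynthesis(1500, 700))
  expect_equal(w1$total_flux,
               leaf_net_photosynthesis(1500, 700) * 50 / 1e4)
  # invariance to splitting a leaf into two with the same PPFD
  leaves_split <- tibble::tibble(leaf_id = 1:4,
                                 allometric_area = c(25, 25, 30, 20))
  tab_split <- tibble::tibble(leaf_id = 1:4, ppfd = c(1500, 1500, 1300, 2000))
  w_split <- whole_plant_rate(tab_split, leaves_split, co2 = 500)
  expect_equal(w_split$rate_per_leaf_area, w$rate_per_leaf_area,
               tolerance = 1e-12)
  expect_error(whole_plant_rate(tab, leaves[1:2, ], 500), "same set")
})

test_that("light/CO2 separability holds for any fixed light field", {
  set.seed(77)
  m <- photo_model()
  for (rep in 1:5) {
    n <- sample(3:30, 1)
    leaves <- tibble::tibble(leaf_id = seq_len(n),
                             allometric_area = runif(n, 20, 90))
    tab <- tibble::tibble(leaf_id = seq_len(n), ppfd = runif(n, 0, 1500))
    cs <- c(400, 600, 800, 1000)
    rates <- vapply(cs, function(cc) {
      whole_plant_rate(tab, leaves, cc, m)$rate_per_leaf_area
    }, 0)
    ratio <- (rates + m$r_dark) / (1 - exp(-m$k_co2 * cs))
    expect_lt(diff(range(ratio)) / abs(mean(ratio)), 1e-9)
    # co2_response computes the same curve from one light field
    resp <- co2_response(tab, leaves, cs, m)
    expect_equal(resp$rate, rates, tolerance = 1e-12)
  }
})

test_that("model parameters are recovered from clean and noisy grids", {
  truth <- c(p_max = 12.928, k_light = 0.014, k_co2 = 0.001, r_dark = 0.889)
  grid <- expand.grid(ppfd = seq(0, 1200, by = 100),
                      co2 = seq(200, 1000, by = 100))
  grid$rate <- leaf_net_photosynthesis(grid$ppfd, grid$co2)
  fit <- fit_photo_model(grid)
  expect_true(fit$converged)
  est <- tidy(fit)$estimate
  expect_lt(max(abs(est - truth) / truth), 0.001)
  expect_lt(glance(fit)$rmse, 1e-6)

  # gaussian noise sd 0.2, n = 108, fixed seed: within 5 percent
  set.seed(42)
  g2 <- expand.grid(ppfd = seq(0, 1200, length.out = 12),
                    co2 = seq(200, 1000, length.out = 9))
  g2$rate <- leaf_net_photosynthesis(g2$ppfd, g2$co2) +
    rnorm(nrow(g2), 0, 0.2)
  fit2 <- fit_photo_model(g2)
  expect_true(fit2$converged)
  expect_lt(max(abs(tidy(fit2)$estimate - truth) / truth), 0.05)
})

test_that("unidentifiable or insufficient data yield a failure status", {
  flat <- tibble::tibble(ppfd = seq(0, 1100, 100), co2 = seq(0, 1100, 100),
                         rate = 2)
  fit <- fit_photo_model(flat)
  expect_false(fit$converged)
  expect_match(fit$message, "unidentifiable")
  expect_identical(nrow(tidy(fit)), 0L)

  small <- tibble::tibble(ppfd = 1:5 * 100, co2 = 1:5 * 100,
                          rate = rnorm(5))
  expect_false(fit_photo_model(small)$converged)
})
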