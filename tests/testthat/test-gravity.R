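test_that("deterrence kernels evaluate to their closed forms", {
  expect_equal(deterrence(100, "exponential", 0.01), exp(-1))
  expect_equal(deterrence(0, "exponential", 0.37), 1)
  expect_equal(deterrence(10, "power", 2), 0.01)
  expect_error(deterrence(0, "power", 2), class = "mobiflux_domain_error")
  expect_error(deterrence(-1, "exponential", 1),
               class = "mobiflux_domain_error")

  # strictly decreasing in r for beta > 0
  r <- sort(runif(50, 1, 5000))
  for (kind in c("exponential", "power")) {
    f <- deterrence(r, kind, 0.004)
    expect_true(all(diff(f) < 0))
  }
})

test_that("gravity prediction evaluates K * m_i * m_j * f(r)", {
  # two locations 1000 km apart on the equator (1000 km = lon diff in rad * R)
  dlon <- 1000 / 6371 * 180 / pi
  locs <- equator_locations(c(0, dlon), c(1e6, 2e6))
  pairs <- data.frame(origin = "L01", destination = "L02")
  fit <- list(kind = "power", beta = 1, scale = 2e-9)
  pred <- gravity_predict(locs, pairs, fit)
  expect_equal(pred$flow, 2e-9 * 1e6 * 2e6 / 1000, tolerance = 1e-9)

  # linear in each mass
  locs2 <- equator_locations(c(0, dlon), c(2e6, 2e6))
  pred2 <- gravity_predict(locs2, pairs, fit)
  expect_equal(pred2$flow, 2 * pred$flow, tolerance = 1e-12)

  # invariant under relabelling of the locations
  relabel <- as.data.frame(locs)
  relabel$id <- c("X", "Y")
  locs3 <- mobi_locations(relabel, hub_id = "X")
  pred3 <- gravity_predict(locs3, data.frame(origin = "X",
                                             destination = "Y"), fit)
  expect_equal(pred3$flow, pred$flow)

  expect_error(gravity_predict(locs, data.frame(origin = "L01",
                                                destination = "ZZ"), fit),
               class = "mobiflux_unknown_location_error")
})

test_that("gravity fitting recovers noiseless parameters exactly", {
  cfg <- synth_config(n_countries = 25, seed = 42,
                      generator = list(model = "gravity_exp", K = 3e-10,
                                       beta = 0.004),
                      noise = list(law = "poisson"),
                      date_range = c("2020-03-05", "2020-03-06"))
  world <- generate_world(cfg)
  sim <- simulate_flows(world, direction = "incoming")
  for (kind_model in list(c("exponential", "gravity_exp"),
                          c("power", "gravity_pow"))) {
    gen <- if (kind_model[2] == "gravity_exp") {
      list(model = "gravity_exp", K = 3e-10, beta = 0.004)
    } else {
      list(model = "gravity_pow", K = 5e-4, beta = 1.7)
    }
    sim <- simulate_flows(world, generator = gen, direction = "incoming")
    fit <- gravity_fit(sim$mean_panel, world$locations, kind_model[1],
                       world$dist)
    expect_lt(abs(fit$beta - gen$beta) / gen$beta, 1e-6)
    expect_lt(abs(fit$scale - gen$K) / gen$K, 1e-6)
    expect_true(fit$converged)
    # fit-predict consistency: residual_norm is the realised objective,
    # checked on a noisy panel where the objective is meaningfully nonzero
    noisy <- gravity_fit(sim$panel, world$locations, kind_model[1],
                         world$dist)
    pred <- gravity_predict(world$locations, sim$panel, noisy, world$dist)
    expect_equal(sum((sim$panel$flow - pred$flow)^2),
                 noisy$residual_norm, tolerance = 1e-10)
  }
})

test_that("degenerate gravity inputs are reported, not silently fitted", {
  # all distances equal (points 120 degrees apart on the equator) and all
  # flows equal: beta is unidentifiable, K absorbs the deterrence factor
  locs <- equator_locations(c(0, 120, -120), rep(1e6, 3))
  panel <- data.frame(date = as.Date("2020-03-05"),
                      origin = c("L01", "L01", "L02"),
                      destination = c("L02", "L03", "L03"),
                      flow = c(50, 50, 50))
  expect_warning(fit <- gravity_fit(panel, locs, "exponential"),
                 class = "mobiflux_flat_residual_warning")
  expect_true(fit$flat)
  r <- distance_matrix(locs)["L01", "L02"]
  expect_equal(fit$beta, 1 / r, tolerance = 1e-12)  # the reference start

  zero <- panel
  zero$flow <- 0
  expect_error(gravity_fit(zero, locs, "exponential"),
               class = "mobiflux_fit_error")
  expect_error(gravity_fit(panel[1:2, ], locs, "exponential"),
               class = "mobiflux_fit_error")
})

test_that("per-day fitting scope returns one fit per calendar day", {
  cfg <- synth_config(n_countries = 10, seed = 9,
                      generator = list(model = "gravity_exp", K = NULL,
                                       beta = 0.004),
                      noise = list(law = "poisson"),
                      date_range = c("2020-03-05", "2020-03-09"))
  world <- generate_world(cfg)
  sim <- simulate_flows(world, direction = "incoming")
  fits <- fit_gravity(sim$panel, world$locations, "exponential",
                      scope = "per-day", dist = world$dist)
  expect_length(fits, 5)
  expect_named(fits, format(seq(as.Date("2020-03-05"), by = "day",
                                length.out = 5), "%Y-%m-%d"))
  pred <- predict_gravity_panel(sim$panel, world$locations, fits, world$dist)
  expect_equal(nrow(pred), nrow(sim$panel))
  expect_true(all(pred$flow >= 0))
})
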