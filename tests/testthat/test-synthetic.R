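test_that("world and flow generation are fully deterministic under a seed", {
  cfg <- synth_config(n_countries = 12, seed = 17,
                      date_range = c("2020-03-05", "2020-03-24"))
  w1 <- generate_world(cfg)
  w2 <- generate_world(cfg)
  expect_identical(as.data.frame(w1$locations), as.data.frame(w2$locations))
  expect_identical(w1$dist, w2$dist)
  expect_identical(as.data.frame(w1$stringency), as.data.frame(w2$stringency))

  s1 <- simulate_flows(w1)
  s2 <- simulate_flows(w2)
  expect_identical(as.data.frame(s1$panel), as.data.frame(s2$panel))
  expect_identical(s1$truth, s2$truth)

  r1 <- generate_reference_series(s1$panel, seed = 18)
  r2 <- generate_reference_series(s2$panel, seed = 18)
  expect_identical(r1$count, r2$count)

  expect_error(synth_config(n_countries = 1),
               class = "mobiflux_config_error")
})

test_that("stringency trajectories ramp from zero to the plateau", {
  dates <- as.Date("2020-03-01") + 0:30
  t0 <- as.Date("2020-03-10")

  si <- si_trajectory(dates, t0, ramp_days = 10, plateau = 80)
  expect_true(all(si[dates < t0] == 0))
  expect_equal(si[dates == t0], 0)                    # ramp starts at 0
  expect_equal(si[dates == t0 + 5], 40)               # halfway up
  expect_true(all(si[dates >= t0 + 10] == 80))        # plateau held
  expect_true(all(si >= 0 & si <= 100))

  # zero-length ramp is a step on the intervention date
  step <- si_trajectory(dates, t0, ramp_days = 0, plateau = 100)
  expect_true(all(step[dates < t0] == 0))
  expect_true(all(step[dates >= t0] == 100))
})

test_that("generated panels satisfy all data-model invariants", {
  cfg <- synth_config(n_countries = 10, seed = 4,
                      date_range = c("2020-03-05", "2020-03-19"))
  world <- generate_world(cfg)
  sim <- simulate_flows(world)
  # re-validating from scratch must succeed (star, integer counts, no dups)
  revalidated <- mobi_flows(as.data.frame(sim$panel), hub_id = "HUB")
  expect_equal(nrow(revalidated), nrow(sim$panel))
  expect_true(all(world$stringency$si >= 0 & world$stringency$si <= 100))
  expect_identical(world$dist, t(world$dist))
  expect_equal(unname(diag(world$dist)), rep(0, 10))
})

test_that("the emitted mean surface equals the model modules' predictions", {
  # gravity generator vs gravity_predict
  cfg_g <- synth_config(n_countries = 9, seed = 6,
                        generator = list(model = "gravity_exp", K = 2e-10,
                                         beta = 0.003),
                        date_range = c("2020-03-05", "2020-03-09"))
  world <- generate_world(cfg_g)
  sim <- simulate_flows(world)
  pred <- gravity_predict(
    world$locations,
    as.data.frame(sim$mean_panel)[c("date", "origin", "destination")],
    list(kind = "exponential", beta = 0.003, scale = 2e-10), world$dist)
  expect_equal(sim$mean_panel$flow, pred$flow, tolerance = 1e-10)

  # cgm generator vs cgm_predict (and its gravity reduction at zero deltas)
  cfg_c <- synth_config(n_countries = 9, seed = 6,
                        generator = list(model = "cgm", kind = "power",
                                         epsilon = -8, alpha = 0.8,
                                         beta = 0.7, gamma = -1.5,
                                         delta1 = 0, delta2 = 0),
                        date_range = c("2020-03-05", "2020-03-09"))
  world_c <- generate_world(cfg_c)
  sim_c <- simulate_flows(world_c)
  skel <- as.data.frame(sim_c$mean_panel)
  design <- build_design(skel, world_c$locations, world_c$stringency,
                         kind = "power", dist = world_c$dist)
  expect_equal(sim_c$mean_panel$flow,
               cgm_predict(sim_c$truth, design)$flow, tolerance = 1e-10)
})

test_that("a ramping destination stringency suppresses flows by exp(delta2 * SI)", {
  cfg <- synth_config(
    n_countries = 6, seed = 12,
    intervention_window = c("2020-03-10", "2020-03-10"),
    ramp_days = 5, plateau_range = c(80, 80),
    date_range = c("2020-03-05", "2020-04-03"),
    generator = list(model = "cgm", kind = "power", epsilon = NULL,
                     alpha = 0.8, beta = 0.7, gamma = -1.5,
                     delta1 = 0, delta2 = -0.03))
  world <- generate_world(cfg)
  sim <- simulate_flows(world, direction = "outgoing")
  mp <- sim$mean_panel
  one_dest <- mp[mp$destination == "C01", ]
  pre <- one_dest$flow[one_dest$date == as.Date("2020-03-06")]
  post <- one_dest$flow[one_dest$date == as.Date("2020-03-30")]
  expect_equal(post / pre, exp(-0.03 * 80), tolerance = 1e-10)
})

test_that("sampled flows are unbiased around the mean surface", {
  cfg <- synth_config(n_countries = 25, seed = 21,
                      noise = list(law = "poisson"),
                      generator = list(model = "gravity_exp", K = NULL,
                                       beta = 0.004),
                      date_range = c("2020-03-05", "2020-04-13"))
  world <- generate_world(cfg)
  sim <- simulate_flows(world)
  mu <- sim$mean_panel$flow
  z <- (sim$panel$flow - mu) / sqrt(mu)   # Poisson standardised residuals
  expect_lt(abs(mean(z)), 3 / sqrt(length(z)))
})

test_that("reference series construction scales, noises and floors", {
  cfg <- synth_config(n_countries = 8, seed = 3,
                      date_range = c("2020-03-05", "2020-03-24"))
  world <- generate_world(cfg)
  sim <- simulate_flows(world)
  agg <- aggregate_daily_total(sim$panel, "incoming")

  exact <- generate_reference_series(sim$panel, scale = 0.5,
                                     noise_sd_fraction = 0, seed = 1)
  expect_equal(exact$count, 0.5 * agg$total)

  # absurdly loud noise must trigger the zero floor and report it
  loud <- generate_reference_series(sim$panel, scale = 1,
                                    noise_sd_fraction = 5, seed = 2)
  expect_true(all(loud$count >= 0))
  expect_gt(attr(loud, "n_floored"), 0)
  expect_error(generate_reference_series(sim$panel, scale = 0),
               class = "mobiflux_config_error")
})

test_that("recovery experiments report one row per parameter", {
  cfg <- synth_config(n_countries = 10, seed = 5,
                      date_range = c("2020-03-05", "2020-04-03"))
  rec <- recovery_experiment(cfg, n_seeds = 1, model = "cgm")
  expect_equal(sort(rec$report$param),
               sort(c("epsilon", "alpha", "beta", "gamma",
                      "delta1", "delta2")))
  expect_equal(rec$n_failed, 0)
  expect_equal(nrow(rec$per_seed), 6)
})
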