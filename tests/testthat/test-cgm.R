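test_that("design construction joins populations, distance and stringency", {
  flows <- tiny_flows()
  locs <- tiny_locations()
  si <- tiny_stringency()
  design <- build_design(flows, locs, si, kind = "power")
  expect_equal(nrow(design), nrow(flows))
  expect_s3_class(design, "cgm_design")
  pop <- setNames(locs$population, locs$id)
  expect_equal(design$log_pop_origin, unname(log(pop[flows$origin])))
  d <- distance_matrix(locs)
  expect_equal(design$distance_covariate,
               unname(log(d[cbind(flows$origin, flows$destination)])))
  # exponential kind carries raw km
  design_e <- build_design(flows, locs, si, kind = "exponential")
  expect_equal(design_e$distance_covariate,
               unname(d[cbind(flows$origin, flows$destination)]))

  # a record dated before stringency coverage is a named error
  early <- as.data.frame(flows)
  early$date[1] <- as.Date("2020-02-01")
  expect_error(
    build_design(mobi_flows(early, "HUB"), locs, si, kind = "power"),
    "2020-02-01", class = "mobiflux_missing_covariate_error")
})

test_that("cgm prediction evaluates the log-linear mean surface", {
  # P_i = P_j = e, r = e km, power kind: T = exp(0 + 1 + 1 - 1) = e
  design <- structure(
    data.frame(date = as.Date("2020-03-05"), origin = "A",
               destination = "B", flow = 0,
               log_pop_origin = 1, log_pop_dest = 1,
               distance_covariate = 1, si_origin = 0, si_dest = 0),
    kind = "power", class = c("cgm_design", "data.frame"))
  params <- list(epsilon = 0, alpha = 1, beta = 1, gamma = -1,
                 delta1 = 0, delta2 = 0, kind = "power")
  expect_equal(cgm_predict(params, design)$flow, exp(1))

  # raising destination stringency by 10 points with delta2 = -0.03
  # multiplies the mean by exp(-0.3)
  design2 <- design
  design2$si_dest <- 10
  params2 <- params
  params2$delta2 <- -0.03
  expect_equal(cgm_predict(params2, design2)$flow /
                 cgm_predict(params2, design)$flow, exp(-0.3))

  # kind mismatch between fit and design is refused
  design_e <- design
  attr(design_e, "kind") <- "exponential"
  expect_error(cgm_predict(params, design_e),
               class = "mobiflux_schema_error")
})

test_that("with zero stringency effects the CGM surface is a gravity surface", {
  locs <- tiny_locations()
  flows <- tiny_flows()
  si0 <- tiny_stringency()
  design <- build_design(flows, locs, si0, kind = "power")
  params <- list(epsilon = -20, alpha = 1, beta = 1, gamma = -1.5,
                 delta1 = 0, delta2 = 0, kind = "power")
  pred_cgm <- cgm_predict(params, design)
  pred_grav <- gravity_predict(
    locs, as.data.frame(flows)[c("date", "origin", "destination")],
    list(kind = "power", beta = 1.5, scale = exp(-20)))
  expect_equal(pred_cgm$flow, pred_grav$flow, tolerance = 1e-12)
})

test_that("the NB fitter recovers simulated coefficients and their signs", {
  cfg <- synth_config(seed = 2024)
  world <- generate_world(cfg)
  sim <- simulate_flows(world, direction = "both")
  design <- build_design(sim$panel, world$locations, world$stringency,
                         kind = "power", dist = world$dist)
  fit <- cgm_fit(design)
  truth <- cgm_coef(sim$truth)
  est <- cgm_coef(fit)
  expect_true(fit$converged)
  expect_gt(fit$dispersion, 0)
  expect_true(all(abs((est - truth) / truth) < 0.15))
  expect_lt(fit$delta1, 0)
  expect_lt(fit$delta2, 0)
  expect_true(all(fit$standard_errors > 0))

  # in-sample prediction reproduces the fitted GLM's own mean
  pred <- cgm_predict(fit, design)
  expect_equal(pred$flow, unname(fitted(fit$model)), tolerance = 1e-8)

  # the full model cannot have lower likelihood than the intercept-only
  # NB fit (nested maximum likelihood)
  null_fit <- MASS::glm.nb(flow ~ 1, data = design)
  expect_gte(fit$log_likelihood, as.numeric(logLik(null_fit)))
})

test_that("singular and degenerate designs raise named errors", {
  flows <- tiny_flows()
  locs <- tiny_locations()
  si <- tiny_stringency()
  design <- build_design(flows, locs, si, kind = "power")

  # duplicated covariate column -> genuine collinearity
  dup <- design
  dup$si_dest <- dup$si_origin
  expect_error(cgm_fit(dup), class = "mobiflux_singular_design_error")

  expect_error(cgm_fit(design[1:5, ]), class = "mobiflux_fit_error")
})

test_that("per-direction star fits absorb the constant hub population", {
  cfg <- synth_config(n_countries = 12, seed = 8,
                      date_range = c("2020-03-05", "2020-04-03"))
  world <- generate_world(cfg)
  sim <- simulate_flows(world, direction = "incoming")
  design <- build_design(sim$panel, world$locations, world$stringency,
                         kind = "power", dist = world$dist)
  expect_warning(fit <- cgm_fit(design),
                 class = "mobiflux_constant_covariate_warning")
  expect_identical(fit$absorbed, "log_pop_dest")
  expect_identical(fit$beta, 0)
  expect_true(is.na(fit$standard_errors[["beta"]]))
  # predictions remain valid on the same star
  pred <- cgm_predict(fit, design)
  expect_true(all(is.finite(pred$flow) & pred$flow > 0))
})

test_that("near-Poisson data drives the NB fit towards the Poisson fit", {
  cfg <- synth_config(n_countries = 15, seed = 99,
                      noise = list(law = "poisson"),
                      date_range = c("2020-03-05", "2020-04-03"))
  world <- generate_world(cfg)
  sim <- simulate_flows(world, direction = "both")
  design <- build_design(sim$panel, world$locations, world$stringency,
                         kind = "power", dist = world$dist)
  fit <- tryCatch(cgm_fit(design),
                  warning = function(w) {
                    expect_s3_class(w, "mobiflux_poisson_limit_warning")
                    suppressWarnings(cgm_fit(design))
                  })
  pois <- stats::glm(flow ~ log_pop_origin + log_pop_dest +
                       distance_covariate + si_origin + si_dest,
                     family = stats::poisson(), data = design)
  expect_gt(fit$dispersion, 100)  # variance ~ mean
  expect_true(all(abs(cgm_coef(fit) - coef(pois)) /
                    pmax(abs(coef(pois)), 1e-8) < 0.01))
})
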