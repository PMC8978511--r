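#' Configuration for synthetic egocentric mobility worlds
#'
#' Describes a hub-and-spoke world emulating the structure of international
#' roaming panels observed by one national operator: a hub country plus
#' `n_countries - 1` counterpart countries with log-normal populations and
#' centroids drawn in a geographic box, a per-country policy-stringency
#' trajectory (zero before a country-specific intervention date, linear ramp
#' to a plateau), and daily star flows drawn around a gravity or
#' stringency-aware mean surface.
#'
#' Defaults describe a Europe-like scene: 30 countries, centroids in a
#' lat 36-62 / lon -10-25 box, populations log-normal around a 10-million
#' median (log-sd 0.8), a 67-million hub, 90 days starting 2020-03-05,
#' interventions starting between 2020-03-01 and 2020-03-20 with 14-day
#' ramps to plateaus of 60-90 index points, and negative-binomial counts
#' (dispersion 5) around a stringency-aware mean with
#' `(alpha, beta, gamma, delta1, delta2) = (0.8, 0.7, -1.5, -0.02, -0.03)`
#' and a median pre-intervention flow of about 1000 devices/day.
#'
#' @param n_countries total number of locations including the hub (>= 2).
#' @param seed integer seed controlling world generation.
#' @param pop_median,pop_log_sd log-normal population law of the
#'   counterpart countries (persons; natural-log sd).
#' @param lat_range,lon_range geographic box for counterpart centroids.
#' @param hub list: `id`, `name`, `lat`, `lon`, `population`.
#' @param intervention_window Date-coercible length-2 vector from which each
#'   country's intervention date is drawn uniformly.
#' @param ramp_days length of the linear stringency ramp (0 = step).
#' @param plateau_range range from which each country's plateau stringency
#'   is drawn uniformly (within \[0, 100\]).
#' @param date_range first and last simulated day (inclusive).
#' @param generator flow mean model: list with `model` one of
#'   `"gravity_exp"`, `"gravity_pow"`, `"cgm"` and its parameters
#'   (`K`, `beta` for gravity; `epsilon`, `alpha`, `beta`, `gamma`,
#'   `delta1`, `delta2`, `kind` for cgm). A `NULL` scale (`K` or `epsilon`)
#'   is calibrated so the median (pre-intervention, for cgm) mean flow
#'   equals `target_flow`.
#' @param target_flow calibration target for the flow scale (devices/day).
#' @param noise list: `law` = `"negative_binomial"` (with `dispersion`,
#'   variance `mu + mu^2/dispersion`) or `"poisson"`.
#' @return a validated `synth_config` list.
#' @export
synth_config <- function(n_countries = 30,
                         seed = 1L,
                         pop_median = 1e7,
                         pop_log_sd = 0.8,
                         lat_range = c(36, 62),
                         lon_range = c(-10, 25),
                         hub = list(id = "HUB", name = "hub-country",
                                    lat = 54.0, lon = -2.0,
                                    population = 6.7e7),
                         intervention_window = c("2020-03-01", "2020-03-20"),
                         ramp_days = 14,
                         plateau_range = c(60, 90),
                         date_range = c("2020-03-05", "2020-06-02"),
                         generator = list(model = "cgm", kind = "power",
                                          epsilon = NULL, alpha = 0.8,
                                          beta = 0.7, gamma = -1.5,
                                          delta1 = -0.02, delta2 = -0.03),
                         target_flow = 1000,
                         noise = list(law = "negative_binomial",
                                      dispersion = 5)) {
  if (n_countries < 2) {
    mf_abort("mobiflux_config_error", "a world needs at least 2 locations")
  }
  if (any(plateau_range < 0) || any(plateau_range > 100)) {
    mf_abort("mobiflux_config_error", "plateau range must lie in [0, 100]")
  }
  if (ramp_days < 0) {
    mf_abort("mobiflux_config_error", "ramp length must be >= 0")
  }
  date_range <- as.Date(date_range)
  if (date_range[2] < date_range[1]) {
    mf_abort("mobiflux_config_error", "empty date range")
  }
  if (!generator$model %in% c("gravity_exp", "gravity_pow", "cgm")) {
    mf_abort("mobiflux_config_error",
             "generator model must be gravity_exp, gravity_pow or cgm")
  }
  if (!noise$law %in% c("poisson", "negative_binomial")) {
    mf_abort("mobiflux_config_error",
             "noise law must be poisson or negative_binomial")
  }
  if (noise$law == "negative_binomial" &&
      (is.null(noise$dispersion) || noise$dispersion <= 0)) {
    mf_abort("mobiflux_config_error", "NB dispersion must be > 0")
  }
  structure(list(n_countries = n_countries, seed = as.integer(seed),
                 pop_median = pop_median, pop_log_sd = pop_log_sd,
                 lat_range = lat_range, lon_range = lon_range, hub = hub,
                 intervention_window = as.Date(intervention_window),
                 ramp_days = ramp_days, plateau_range = plateau_range,
                 date_range = date_range, generator = generator,
                 target_flow = target_flow, noise = noise),
            class = "synth_config")
}

# run fn() under a seeded, self-contained RNG state
with_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
         else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Generate a synthetic world: locations, distances and stringency
#'
#' Reproducible given the config (which includes the seed). Counterpart
#' country ids are `C01`, `C02`, ... Stringency is 0 before each country's
#' intervention date, rises linearly over `ramp_days` to the country's
#' plateau, then holds it; a zero-length ramp is a step.
#'
#' @param config a [synth_config()].
#' @return list with `locations` (`mobi_locations`), `dist` (km matrix),
#'   `stringency` (`mobi_stringency`), `dates` (Date vector) and
#'   `config`.
#' @export
generate_world <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed, function() {
    n_spokes <- config$n_countries - 1
    ids <- sprintf("C%02d", seq_len(n_spokes))
    locs <- data.frame(
      id = c(config$hub$id, ids),
      name = c(config$hub$name, paste0("country-", ids)),
      lat = c(config$hub$lat,
              runif(n_spokes, config$lat_range[1], config$lat_range[2])),
      lon = c(config$hub$lon,
              runif(n_spokes, config$lon_range[1], config$lon_range[2])),
      population = c(config$hub$population,
                     round(rlnorm(n_spokes, log(config$pop_median),
                                  config$pop_log_sd))))
    locations <- mobi_locations(locs, hub_id = config$hub$id)
    dates <- seq(config$date_range[1], config$date_range[2], by = "day")

    iw <- config$intervention_window
    t0 <- iw[1] + sample.int(as.integer(iw[2] - iw[1]) + 1L,
                             nrow(locs), replace = TRUE) - 1L
    plateau <- runif(nrow(locs), config$plateau_range[1],
                     config$plateau_range[2])
    si <- do.call(rbind, lapply(seq_len(nrow(locs)), function(i) {
      data.frame(date = dates, location = locs$id[i],
                 si = si_trajectory(dates, t0[i], config$ramp_days,
                                    plateau[i]))
    }))
    list(locations = locations, dist = distance_matrix(locations),
         stringency = mobi_stringency(si), dates = dates, config = config)
  })
}

si_trajectory <- function(dates, t0, ramp_days, plateau) {
  dt <- as.numeric(dates - t0)
  si <- ifelse(dt < 0, 0,
               if (ramp_days == 0) plateau
               else plateau * pmin(1, dt / ramp_days))
  pmin(pmax(si, 0), 100)
}

# star pair skeleton: one row per (date, pair, direction)
star_pairs <- function(world, direction = c("both", "incoming", "outgoing")) {
  direction <- match.arg(direction)
  hub <- hub_of(world$locations)
  spokes <- setdiff(world$locations$id, hub)
  inc <- expand.grid(date = world$dates, origin = spokes,
                     stringsAsFactors = FALSE)
  inc$destination <- hub
  out <- expand.grid(date = world$dates, destination = spokes,
                     stringsAsFactors = FALSE)
  out$origin <- hub
  cols <- c("date", "origin", "destination")
  switch(direction,
         incoming = inc[cols],
         outgoing = out[cols],
         both = rbind(inc[cols], out[cols]))
}

# noiseless mean surface for a generator spec; also resolves a NULL scale
mean_surface <- function(world, generator, pairs) {
  if (generator$model == "cgm") {
    kind <- if (!is.null(generator$kind)) generator$kind else "power"
    skel <- pairs
    skel$flow <- 0
    design <- build_design(skel, world$locations, world$stringency,
                           kind = kind, dist = world$dist)
    core <- generator$alpha * design$log_pop_origin +
      generator$beta * design$log_pop_dest +
      generator$gamma * design$distance_covariate
    if (is.null(generator$epsilon)) {
      generator$epsilon <- log(world$config$target_flow) - median(core)
    }
    eta <- generator$epsilon + core +
      generator$delta1 * design$si_origin + generator$delta2 * design$si_dest
    if (any(eta > 700)) {
      mf_abort("mobiflux_overflow_error",
               "generator parameters overflow the mean surface (exp arg > 700)")
    }
    mu <- exp(eta)
  } else {
    kind <- if (generator$model == "gravity_exp") "exponential" else "power"
    g <- pair_geometry(pairs, world$locations, world$dist)
    base <- g$mass * deterrence(g$r, kind, generator$beta)
    if (is.null(generator$K)) {
      generator$K <- world$config$target_flow / median(base)
    }
    if (any(log(generator$K) + log(base) > 700)) {
      mf_abort("mobiflux_overflow_error",
               "generator parameters overflow the mean surface (exp arg > 700)")
    }
    mu <- generator$K * base
  }
  list(mu = as.numeric(mu), generator = generator)
}

#' Simulate a daily star flow panel around a model mean surface
#'
#' Draws one count per (date, origin, destination) of the egocentric star
#' from the configured noise law around the generator's mean surface, and
#' also returns the noiseless mean panel for oracle checks.
#'
#' @param world output of [generate_world()].
#' @param generator overrides the config's generator spec (optional).
#' @param seed seed for the flow draws (independent of the world seed);
#'   defaults to `config$seed + 1`.
#' @param direction `"both"`, `"incoming"` or `"outgoing"`.
#' @return list: `panel` (`mobi_flows` with sampled counts), `mean_panel`
#'   (same rows, noiseless means), `truth` (generator with any calibrated
#'   scale resolved), `noise`.
#' @export
simulate_flows <- function(world, generator = world$config$generator,
                           seed = world$config$seed + 1L,
                           direction = c("both", "incoming", "outgoing")) {
  direction <- match.arg(direction)
  pairs <- star_pairs(world, direction)
  ms <- mean_surface(world, generator, pairs)
  noise <- world$config$noise
  flows <- with_seed(seed, function() {
    if (noise$law == "poisson") rpois(length(ms$mu), ms$mu)
    else rnbinom(length(ms$mu), size = noise$dispersion, mu = ms$mu)
  })
  panel <- pairs
  panel$flow <- as.numeric(flows)
  mean_panel <- pairs
  mean_panel$flow <- ms$mu
  list(panel = mobi_flows(panel, hub_id = hub_of(world$locations)),
       mean_panel = mean_panel, truth = ms$generator, noise = noise)
}

#' Construct a noisy reference arrivals series from a flow panel
#'
#' Stands in for an external daily arrivals series (such as air-passenger
#' counts) when validating the synchrony machinery: a positively scaled
#' copy of the aggregate daily flow with multiplicative Gaussian noise,
#' floored at 0.
#'
#' @param flow_panel a `mobi_flows` star panel.
#' @param scale positive multiplier applied to the aggregate series.
#' @param noise_sd_fraction Gaussian noise sd as a fraction of each day's
#'   signal level.
#' @param seed RNG seed.
#' @param direction which direction of the star to aggregate.
#' @return data frame `date, count` with attribute `n_floored` (number of
#'   days clipped at 0).
#' @export
generate_reference_series <- function(flow_panel, scale = 1,
                                      noise_sd_fraction = 0.05, seed = 1L,
                                      direction = "incoming") {
  if (scale <= 0) {
    mf_abort("mobiflux_config_error", "reference scale must be > 0")
  }
  agg <- aggregate_daily_total(flow_panel, direction)
  eta <- with_seed(seed, function() rnorm(nrow(agg), 0, noise_sd_fraction))
  count <- scale * agg$total * (1 + eta)
  n_floored <- sum(count < 0)
  count <- pmax(count, 0)
  out <- data.frame(date = agg$date, count = count)
  attr(out, "n_floored") <- n_floored
  out
}

#' Parameter-recovery experiment over seeded synthetic worlds
#'
#' Simulates `n_seeds` worlds from a config, fits the requested model to
#' each, and reports per-parameter recovery quality: bias, relative error
#' and (for the negative-binomial regression) 95% Wald CI coverage.
#' A failed fit in one seed is recorded, not fatal.
#'
#' @param config a [synth_config()] whose generator holds the truth.
#' @param n_seeds number of independent replicate worlds.
#' @param model `"cgm"` or `"gravity"` (must match the generator family).
#' @param direction star direction fitted. The default pools both
#'   directions: on an egocentric star a single direction keeps the hub
#'   population constant, which absorbs one mass coefficient into the
#'   intercept; pooling restores identifiability of all six coefficients.
#' @return list: `per_seed` (data frame seed/param/truth/estimate/
#'   rel_error/covered), `report` (one row per parameter: mean bias, median
#'   absolute relative error, CI coverage), `n_failed`.
#' @export
recovery_experiment <- function(config, n_seeds = 20,
                                model = c("cgm", "gravity"),
                                direction = "both") {
  model <- match.arg(model)
  per_seed <- list()
  n_failed <- 0L
  for (s in seq_len(n_seeds)) {
    cfg <- config
    cfg$seed <- config$seed + 1000L * (s - 1L)
    world <- generate_world(cfg)
    sim <- simulate_flows(world, direction = direction)
    res <- tryCatch({
      if (model == "cgm") {
        kind <- if (!is.null(sim$truth$kind)) sim$truth$kind else "power"
        design <- build_design(sim$panel, world$locations, world$stringency,
                               kind = kind, dist = world$dist)
        fit <- cgm_fit(design)
        truth <- cgm_coef(sim$truth)
        est <- cgm_coef(fit)
        se <- fit$standard_errors
        data.frame(seed = cfg$seed, param = names(truth),
                   truth = as.numeric(truth), estimate = as.numeric(est),
                   rel_error = as.numeric((est - truth) / truth),
                   covered = as.numeric(truth) >= est - 1.96 * se &
                             as.numeric(truth) <= est + 1.96 * se,
                   row.names = NULL)
      } else {
        kind <- if (sim$truth$model == "gravity_exp") "exponential" else "power"
        fit <- gravity_fit(sim$panel, world$locations, kind, world$dist)
        truth <- c(K = sim$truth$K, beta = sim$truth$beta)
        est <- c(K = fit$scale, beta = fit$beta)
        data.frame(seed = cfg$seed, param = names(truth),
                   truth = as.numeric(truth), estimate = as.numeric(est),
                   rel_error = as.numeric((est - truth) / truth),
                   covered = NA, row.names = NULL)
      }
    }, error = function(e) NULL)
    if (is.null(res)) n_failed <- n_failed + 1L else per_seed[[s]] <- res
  }
  per_seed <- do.call(rbind, per_seed)
  report <- do.call(rbind, lapply(split(per_seed, per_seed$param), function(d) {
    data.frame(param = d$param[1],
               mean_bias = mean(d$estimate - d$truth),
               median_abs_rel_error = median(abs(d$rel_error)),
               coverage = if (all(is.na(d$covered))) NA_real_
                          else mean(d$covered),
               n_seeds = nrow(d), row.names = NULL)
  }))
  rownames(report) <- NULL
  list(per_seed = per_seed, report = report, n_failed = n_failed)
}
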