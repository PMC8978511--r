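# Small in-code fixtures shared across the suite.

tiny_locations <- function() {
  mobi_locations(
    data.frame(id = c("HUB", "AA", "BB", "CC"),
               name = c("hub", "a", "b", "c"),
               lat = c(54, 48, 52, 40),
               lon = c(-2, 2, 13, -4),
               population = c(6.7e7, 6.5e7, 8.3e7, 4.7e7)),
    hub_id = "HUB")
}

tiny_flows <- function(dates = as.Date("2020-03-05") + 0:2) {
  spokes <- c("AA", "BB", "CC")
  inc <- expand.grid(date = dates, origin = spokes,
                     stringsAsFactors = FALSE)
  inc$destination <- "HUB"
  out <- expand.grid(date = dates, destination = spokes,
                     stringsAsFactors = FALSE)
  out$origin <- "HUB"
  df <- rbind(inc[c("date", "origin", "destination")],
              out[c("date", "origin", "destination")])
  df$flow <- seq(10, by = 7, length.out = nrow(df))
  mobi_flows(df, hub_id = "HUB")
}

tiny_stringency <- function(dates = as.Date("2020-03-05") + 0:2,
                            ids = c("HUB", "AA", "BB", "CC")) {
  grid <- expand.grid(date = dates, location = ids,
                      stringsAsFactors = FALSE)
  grid$si <- 10 * (as.numeric(grid$date - dates[1]) +
                   match(grid$location, ids))
  mobi_stringency(grid)
}

# world on the equator with chosen longitudes -- distances are exactly
# proportional to longitude differences (up to 180 degrees)
equator_locations <- function(lons, pops, hub = 1) {
  mobi_locations(
    data.frame(id = sprintf("L%02d", seq_along(lons)),
               name = sprintf("loc-%d", seq_along(lons)),
               lat = 0, lon = lons, population = pops),
    hub_id = sprintf("L%02d", hub))
}

# literal re-implementations of the two flow metrics, used as oracles
cpc_literal <- function(g, r) {
  num <- 0
  for (i in seq_along(g)) num <- num + min(g[i], r[i])
  2 * num / (sum(g) + sum(r))
}

ig_literal <- function(r, g, eps = 1e-10) {
  n_total <- sum(r)
  total <- 0
  for (i in seq_along(r)) {
    if (r[i] > 0) total <- total + r[i] / n_total * log(r[i] / max(g[i], eps))
  }
  total
}

# brute-force accuracy: expand both vectors into unit trips labelled by
# destination and count how many of the generated trips can be matched
# one-to-one with a real trip to the same destination
trip_accuracy <- function(g, r) {
  stopifnot(sum(g) == sum(r))
  gen_trips <- rep(seq_along(g), times = g)
  real_trips <- rep(seq_along(r), times = r)
  matched <- 0
  pool <- table(factor(real_trips, levels = seq_along(r)))
  for (t in gen_trips) {
    if (pool[t] > 0) {
      matched <- matched + 1
      pool[t] <- pool[t] - 1
    }
  }
  matched / sum(g)
}

# exhaustive O(n) scan oracle for the radiation opportunity term
s_ij_scan <- function(origin, dest, locations, dist,
                      rule = c("strict", "inclusive")) {
  rule <- match.arg(rule)
  r_ij <- dist[origin, dest]
  s <- 0
  for (k in seq_len(nrow(locations))) {
    id <- locations$id[k]
    if (id %in% c(origin, dest)) next
    r_ik <- dist[origin, id]
    inside <- if (rule == "strict") r_ik < r_ij else r_ik <= r_ij
    if (inside) s <- s + locations$population[k]
  }
  s
}

# random general-OD world for radiation property tests
random_world <- function(n, seed, equal_mass = FALSE) {
  set.seed(seed)
  pops <- if (equal_mass) rep(1e6, n) else round(runif(n, 1e5, 5e7))
  mobi_locations(
    data.frame(id = sprintf("R%02d", seq_len(n)),
               name = sprintf("r-%d", seq_len(n)),
               lat = runif(n, -60, 60), lon = runif(n, -170, 170),
               population = pops),
    hub_id = "R01")
}
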