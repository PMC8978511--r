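#' Distance-deterrence function
#'
#' The distance-decay kernel of the gravity model: exponential
#' `f(r) = exp(-beta * r)` or power-law `f(r) = r^(-beta)`. `beta` has units
#' km^-1 for the exponential kind and is a dimensionless exponent for the
#' power kind.
#'
#' @param r distance(s) in km, >= 0 (strictly > 0 for the power kind).
#' @param kind `"exponential"` or `"power"`.
#' @param beta decay parameter, >= 0.
#' @return the deterrence value(s), positive.
#' @examples
#' deterrence(100, "exponential", 0.01)  # exp(-1)
#' deterrence(10, "power", 2)            # 0.01
#' @export
deterrence <- function(r, kind = c("exponential", "power"), beta) {
  kind <- match.arg(kind)
  if (any(r < 0)) mf_abort("mobiflux_domain_error", "distances must be >= 0")
  if (kind == "power" && any(r == 0)) {
    mf_abort("mobiflux_domain_error",
             "power-law deterrence is singular at r = 0")
  }
  if (kind == "exponential") exp(-beta * r) else r^(-beta)
}

new_gravity_fit <- function(kind, beta, scale, residual_norm, n_obs,
                            converged, flat = FALSE) {
  structure(
    list(kind = kind, beta = beta, scale = scale,
         residual_norm = residual_norm, n_obs = n_obs,
         converged = converged, flat = flat),
    class = "gravity_fit")
}

#' @export
print.gravity_fit <- function(x, ...) {
  cat(sprintf("<gravity_fit> kind=%s  beta=%.6g  K=%.6g  rss=%.6g  n=%d%s\n",
              x$kind, x$beta, x$scale, x$residual_norm, x$n_obs,
              if (x$flat) "  [flat residual: beta unidentifiable]" else ""))
  invisible(x)
}

# mass product m_i * m_j and distance for each requested pair
pair_geometry <- function(pairs, locations, dist = NULL) {
  unknown <- setdiff(unique(c(pairs$origin, pairs$destination)), locations$id)
  if (length(unknown)) {
    mf_abort("mobiflux_unknown_location_error",
             paste0("unknown location id(s): ", paste(unknown, collapse = ", ")))
  }
  if (is.null(dist)) dist <- distance_matrix(locations)
  pop <- setNames(locations$population, locations$id)
  list(
    mass = pop[pairs$origin] * pop[pairs$destination],
    r = dist[cbind(pairs$origin, pairs$destination)]
  )
}

#' Predict gravity-model flows for a set of pairs
#'
#' Evaluates `T_ij = K * m_i * m_j * f(r_ij)` with the deterrence function
#' and parameters held by a [gravity_fit()] (or any list with elements
#' `kind`, `beta`, `scale`).
#'
#' @param locations a `mobi_locations` table.
#' @param pairs data frame with columns `origin` and `destination`
#'   (location ids); an optional `date` column is carried through.
#' @param fit a `gravity_fit` or list with `kind`, `beta`, `scale`.
#' @param dist optional precomputed distance matrix (km).
#' @return `pairs` with a `flow` column of predicted (non-negative,
#'   deterministic) mean flows.
#' @export
gravity_predict <- function(locations, pairs, fit, dist = NULL) {
  g <- pair_geometry(pairs, locations, dist)
  out <- pairs
  out$flow <- fit$scale * g$mass * deterrence(g$r, fit$kind, fit$beta)
  out
}

#' Fit gravity-model parameters by nonlinear least squares
#'
#' Estimates the proportionality constant `K` and the deterrence parameter
#' `beta` of `T_ij = K * m_i * m_j * f(r_ij)` by minimising the sum of
#' squared residuals against observed flows on the raw count scale.
#'
#' The least-squares problem is solved by variable projection: for any
#' `beta` the optimal `K` has the closed form
#' `K(beta) = sum(y * g) / sum(g^2)` with `g = m_i * m_j * f_beta(r)`, so the
#' search reduces to a one-dimensional minimisation over `beta >= 0`
#' (Brent's method), which is deterministic and cannot stall at a bad scale
#' for `K`. The starting/reference `beta` is `1/median(r)` for the
#' exponential kind and 1 for the power kind.
#'
#' When `beta` is unidentifiable (e.g. all distances equal, so the
#' deterrence factor is absorbed by `K`), the residual surface is flat in
#' `beta`; the fit then returns the reference `beta` and signals a
#' `mobiflux_flat_residual_warning`.
#'
#' @param panel a `mobi_flows` panel of observations.
#' @param locations a `mobi_locations` table covering all panel endpoints.
#' @param kind deterrence kind, `"exponential"` or `"power"`.
#' @param dist optional precomputed distance matrix.
#' @return a `gravity_fit`: `kind`, `beta`, `scale` (K), `residual_norm`
#'   (the minimised sum of squared residuals), `n_obs`, `converged`, `flat`.
#' @export
gravity_fit <- function(panel, locations, kind = c("exponential", "power"),
                        dist = NULL) {
  kind <- match.arg(kind)
  g <- pair_geometry(panel, locations, dist)
  y <- panel$flow
  n <- length(y)
  if (n < 3) {
    mf_abort("mobiflux_fit_error",
             "gravity fit needs at least 3 observations")
  }
  if (all(y == 0)) {
    mf_abort("mobiflux_fit_error",
             "all observed flows are zero; gravity scale is degenerate")
  }
  r <- g$r
  if (kind == "power" && any(r <= 0)) {
    mf_abort("mobiflux_fit_error",
             "power-law fit requires strictly positive distances")
  }

  beta0 <- if (kind == "exponential") 1 / median(r) else 1

  # profiled objective: optimal K in closed form given beta
  rss <- function(beta) {
    f <- if (kind == "exponential") exp(-beta * r) else r^(-beta)
    gg <- g$mass * f
    k <- sum(y * gg) / sum(gg * gg)
    sum((y - k * gg)^2)
  }
  k_at <- function(beta) {
    f <- if (kind == "exponential") exp(-beta * r) else r^(-beta)
    gg <- g$mass * f
    sum(y * gg) / sum(gg * gg)
  }

  # flat residual surface <=> beta unidentifiable (K absorbs f entirely);
  # flatness is judged against the scale of the objective, sum(y^2)
  probe <- vapply(beta0 * c(0.25, 0.5, 1, 2, 4), rss, numeric(1))
  if (diff(range(probe)) <= 1e-10 * sum(y^2)) {
    rlang::warn("residual surface is flat in beta; beta is unidentifiable",
                class = "mobiflux_flat_residual_warning")
    return(new_gravity_fit(kind, beta0, k_at(beta0), rss(beta0), n,
                           converged = TRUE, flat = TRUE))
  }

  upper <- if (kind == "exponential") 50 * beta0 else 25
  opt <- optimize(rss, interval = c(0, upper), tol = 1e-12)
  beta_hat <- opt$minimum
  # Brent can sit a hair inside the bracket; polish with a local refinement
  for (step in c(1e-6, 1e-8)) {
    grid <- beta_hat * (1 + step * c(-1, 0, 1))
    grid <- pmax(grid, 0)
    vals <- vapply(grid, rss, numeric(1))
    beta_hat <- grid[which.min(vals)]
  }
  new_gravity_fit(kind, beta_hat, k_at(beta_hat), rss(beta_hat), n,
                  converged = TRUE)
}

#' Fit gravity models per day or globally over a panel
#'
#' The per-day scope fits one `(K, beta)` for every calendar day in the
#' panel (a descriptive, in-sample protocol); the global scope fits a single
#' pair over the pooled panel.
#'
#' @inheritParams gravity_fit
#' @param scope `"per-day"` or `"global"`.
#' @return for `"global"`, a single `gravity_fit`; for `"per-day"`, a named
#'   list of `gravity_fit` objects keyed by ISO date.
#' @export
fit_gravity <- function(panel, locations, kind = c("exponential", "power"),
                        scope = c("per-day", "global"), dist = NULL) {
  kind <- match.arg(kind)
  scope <- match.arg(scope)
  if (is.null(dist)) dist <- distance_matrix(locations)
  if (scope == "global") return(gravity_fit(panel, locations, kind, dist))
  days <- sort(unique(panel$date))
  fits <- lapply(days, function(d) {
    gravity_fit(panel[panel$date == d, , drop = FALSE], locations, kind, dist)
  })
  names(fits) <- format(days, "%Y-%m-%d")
  fits
}

#' Predict a full dated flow panel from gravity fits
#'
#' @param panel observed panel whose (date, origin, destination) universe is
#'   predicted.
#' @param locations a `mobi_locations` table.
#' @param fits result of [fit_gravity()] (single fit or per-day list).
#' @param dist optional precomputed distance matrix.
#' @return data frame `date, origin, destination, flow` of predicted means.
#' @export
predict_gravity_panel <- function(panel, locations, fits, dist = NULL) {
  if (is.null(dist)) dist <- distance_matrix(locations)
  pairs <- as.data.frame(panel)[c("date", "origin", "destination")]
  if (inherits(fits, "gravity_fit")) {
    return(gravity_predict(locations, pairs, fits, dist))
  }
  parts <- lapply(split(pairs, format(pairs$date, "%Y-%m-%d")), function(p) {
    d <- format(p$date[1], "%Y-%m-%d")
    if (is.null(fits[[d]])) {
      mf_abort("mobiflux_fit_error", paste0("no gravity fit for day ", d))
    }
    gravity_predict(locations, p, fits[[d]], dist)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out[order(out$date, out$origin, out$destination), , drop = FALSE]
}
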