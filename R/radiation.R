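#' Intervening population between an origin and a destination
#'
#' The radiation model's opportunity term `s_ij`: total population of all
#' locations strictly closer to the origin than the destination is,
#' excluding the origin and the destination themselves. With
#' `radius_rule = "inclusive"` locations at exactly the origin-destination
#' distance are counted too; ties are a measure-zero event in generated
#' worlds but must resolve deterministically.
#'
#' @param origin,dest location ids.
#' @param locations a `mobi_locations` table.
#' @param dist optional precomputed distance matrix (km).
#' @param radius_rule `"strict"` (`r_ik < r_ij`) or `"inclusive"`
#'   (`r_ik <= r_ij`).
#' @return `s_ij` in persons (>= 0).
#' @export
intervening_population <- function(origin, dest, locations, dist = NULL,
                                   radius_rule = c("strict", "inclusive")) {
  radius_rule <- match.arg(radius_rule)
  if (origin == dest) {
    mf_abort("mobiflux_self_loop_error",
             "intervening population is undefined for origin == destination")
  }
  if (is.null(dist)) dist <- distance_matrix(locations)
  r_ij <- dist[origin, dest]
  r_ik <- dist[origin, locations$id]
  inside <- if (radius_rule == "strict") r_ik < r_ij else r_ik <= r_ij
  inside[locations$id %in% c(origin, dest)] <- FALSE
  sum(locations$population[inside])
}

#' Radiation-model flow prediction
#'
#' Parameter-free flow scores from populations and geometry. With origin
#' mass `m_i`, destination mass `m_j` and intervening population `s_ij`, the
#' canonical (standard) score is
#' `p_ij = m_i * m_j / ((m_i + s_ij) * (m_i + m_j + s_ij))`.
#' The `"as_printed"` variant replaces the first factor's `m_i` with `m_j`,
#' i.e. `(m_j + s_ij) * (m_i + m_j + s_ij)` in the denominator — a form that
#' circulates in parts of the applied literature; the two coincide whenever
#' `m_i = m_j`. Both are provided and the choice is explicit, never silent.
#'
#' When `normalize = "origin_outflow"`, scores from each origin are scaled
#' so the predicted flows out of origin `i` sum to a supplied total `O_i`:
#' `T_ij = O_i * p_ij / sum_k p_ik`. With `finite_size_correction = TRUE`
#' the normalising denominator is replaced by `1 - m_i / M` (`M` = total
#' population), the usual correction for systems with a finite number of
#' locations; flows then no longer sum exactly to `O_i`.
#'
#' @param locations a `mobi_locations` table.
#' @param origin_totals named numeric vector of total outflows `O_i` per
#'   origin id; required when `normalize = "origin_outflow"`.
#' @param pairs optional data frame `origin, destination` restricting the
#'   output; scores/normalisation are always computed over the full
#'   destination universe (all other locations).
#' @param first_factor `"standard"` or `"as_printed"` (see Details).
#' @param radius_rule passed to [intervening_population()].
#' @param normalize `"origin_outflow"` or `"none"` (raw scores).
#' @param finite_size_correction logical, see Details.
#' @param dist optional precomputed distance matrix.
#' @return data frame `origin, destination, flow` (deterministic).
#' @export
radiation_predict <- function(locations, origin_totals = NULL, pairs = NULL,
                              first_factor = c("standard", "as_printed"),
                              radius_rule = c("strict", "inclusive"),
                              normalize = c("origin_outflow", "none"),
                              finite_size_correction = FALSE,
                              dist = NULL) {
  first_factor <- match.arg(first_factor)
  radius_rule <- match.arg(radius_rule)
  normalize <- match.arg(normalize)
  if (is.null(dist)) dist <- distance_matrix(locations)
  ids <- locations$id
  pop <- setNames(locations$population, ids)

  origins <- if (is.null(pairs)) ids else unique(pairs$origin)
  if (normalize == "origin_outflow") {
    if (is.null(origin_totals)) {
      mf_abort("mobiflux_normalization_error",
               "origin_outflow normalisation requires origin_totals")
    }
    missing_o <- setdiff(origins, names(origin_totals))
    if (length(missing_o)) {
      mf_abort("mobiflux_normalization_error",
               paste0("no origin total for: ", paste(missing_o, collapse = ", ")))
    }
  }

  rows <- lapply(origins, function(i) {
    dests <- setdiff(ids, i)
    s <- vapply(dests, function(j)
      intervening_population(i, j, locations, dist, radius_rule), numeric(1))
    m_i <- pop[[i]]
    m_j <- pop[dests]
    first <- if (first_factor == "standard") m_i + s else m_j + s
    p <- m_i * m_j / (first * (m_i + m_j + s))
    flow <- if (normalize == "none") {
      p
    } else {
      denom <- if (finite_size_correction) 1 - m_i / sum(pop) else sum(p)
      if (denom <= 0) {
        mf_abort("mobiflux_normalization_error",
                 paste0("zero total radiation score from origin ", i))
      }
      origin_totals[[i]] * p / denom
    }
    data.frame(origin = i, destination = dests, flow = as.numeric(flow),
               row.names = NULL)
  })
  out <- do.call(rbind, rows)
  if (!is.null(pairs)) {
    key <- paste(out$origin, out$destination)
    want <- paste(pairs$origin, pairs$destination)
    missing_p <- setdiff(want, key)
    if (length(missing_p)) {
      mf_abort("mobiflux_unknown_location_error",
               paste0("pairs not in location universe: ",
                      paste(missing_p, collapse = "; ")))
    }
    out <- out[match(want, key), , drop = FALSE]
    if (!is.null(pairs$date)) out <- cbind(date = pairs$date, out)
  }
  rownames(out) <- NULL
  out
}

#' Radiation predictions over a dated egocentric panel
#'
#' For every day of the observed panel, takes each origin's observed total
#' outflow that day as `O_i`, normalises the radiation scores over the full
#' destination universe, and returns the predicted flow on exactly the
#' observed (origin, destination) pairs. On an egocentric star this means
#' only the component of each country's (or the hub's) redistributed outflow
#' that points at the observed counterpart is compared with the data.
#'
#' @inheritParams radiation_predict
#' @param panel observed `mobi_flows` panel.
#' @return data frame `date, origin, destination, flow`.
#' @export
predict_radiation_panel <- function(panel, locations,
                                    first_factor = c("standard", "as_printed"),
                                    radius_rule = c("strict", "inclusive"),
                                    finite_size_correction = FALSE,
                                    dist = NULL) {
  first_factor <- match.arg(first_factor)
  radius_rule <- match.arg(radius_rule)
  if (is.null(dist)) dist <- distance_matrix(locations)
  parts <- lapply(split(as.data.frame(panel),
                        format(panel$date, "%Y-%m-%d")), function(p) {
    totals <- tapply(p$flow, p$origin, sum)
    radiation_predict(locations,
                      origin_totals = setNames(as.numeric(totals), names(totals)),
                      pairs = p[c("date", "origin", "destination")],
                      first_factor = first_factor, radius_rule = radius_rule,
                      normalize = "origin_outflow",
                      finite_size_correction = finite_size_correction,
                      dist = dist)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out[order(out$date, out$origin, out$destination), , drop = FALSE]
}
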