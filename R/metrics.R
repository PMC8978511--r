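#' Common Part of Commuters (Sorensen-Dice flow similarity)
#'
#' `CPC = 2 * sum(min(g, r)) / (sum(g) + sum(r))` over matched
#' origin-destination pairs. 1 means the generated flows reproduce the
#' observed ones exactly, 0 means disjoint support. Symmetric in its
#' arguments and invariant to rescaling both by the same positive constant.
#' When the two totals coincide, CPC equals the fraction of unit trips
#' assigned to the correct destination (model accuracy).
#'
#' @param generated,real non-negative flow vectors on the same pair
#'   indexing.
#' @return CPC in \[0, 1\]; `NA_real_` (the explicit undefined marker) when
#'   both totals are zero.
#' @examples
#' cpc(c(3, 1), c(2, 2))  # 0.75
#' @export
cpc <- function(generated, real) {
  if (length(generated) != length(real)) {
    mf_abort("mobiflux_schema_error",
             "flow vectors must share the same pair indexing")
  }
  if (any(generated < 0) || any(real < 0)) {
    mf_abort("mobiflux_domain_error", "flows must be non-negative")
  }
  tot <- sum(generated) + sum(real)
  if (tot == 0) return(NA_real_)
  2 * sum(pmin(generated, real)) / tot
}

#' Information Gain between observed and generated flows
#'
#' `IG = sum_i (y_i^r / N) * log(y_i^r / y_i^g)` with `N = sum(y^r)` and
#' natural logarithm; terms with `y_i^r = 0` contribute 0 (the usual
#' `0 * log 0 = 0` convention). IG is a non-negative error whenever the two
#' totals match (Gibbs' inequality); 0 means identical flows. Note IG
#' compares raw flows, not shares, so it is not symmetric.
#'
#' A generated flow of exactly 0 against a positive observed flow makes IG
#' infinite; generated entries are floored at `floor_eps` and the number of
#' floored entries is reported via the `"n_floored"` attribute.
#'
#' @param real observed flow vector (defines `N`).
#' @param generated model flow vector, same indexing.
#' @param floor_eps floor applied to generated entries (default 1e-10).
#' @return IG (with attribute `n_floored`); `NA_real_` when `N = 0`.
#' @examples
#' information_gain(c(2, 2), c(1, 3))  # ~0.1438
#' @export
information_gain <- function(real, generated, floor_eps = 1e-10) {
  if (length(generated) != length(real)) {
    mf_abort("mobiflux_schema_error",
             "flow vectors must share the same pair indexing")
  }
  if (any(generated < 0) || any(real < 0)) {
    mf_abort("mobiflux_domain_error", "flows must be non-negative")
  }
  n_total <- sum(real)
  if (n_total == 0) return(NA_real_)
  floored <- generated < floor_eps
  g <- pmax(generated, floor_eps)
  pos <- real > 0
  ig <- sum(real[pos] / n_total * log(real[pos] / g[pos]))
  attr(ig, "n_floored") <- sum(floored & pos)
  ig
}

#' Relative improvement of one score over a baseline
#'
#' `rel(new, baseline) = (new - baseline) / baseline`. When applied to
#' per-day metric series, the convention is average-of-ratios: compute the
#' relative improvement day by day, then average.
#'
#' @param new_value,baseline_value numeric (vectorised).
#' @return the relative improvement(s); `NA_real_` where the baseline is 0.
#' @examples
#' relative_improvement(0.78, 0.348)  # ~1.2414
#' @export
relative_improvement <- function(new_value, baseline_value) {
  out <- (new_value - baseline_value) / baseline_value
  out[baseline_value == 0] <- NA_real_
  out
}

#' Per-day metrics and period-split summary for one or more models
#'
#' For every model and every day present in the observed panel, computes CPC
#' and IG over all (origin, destination) pairs observed that day, then
#' summarises: mean/max/min CPC over the whole window, mean CPC over two
#' periods (P1 up to `p1_end`, P2 after), and mean IG. The default split
#' separates the days before widespread non-pharmaceutical interventions
#' (through 2020-03-15) from the days under them.
#'
#' Every model must predict every observed (date, pair): a model covering
#' only a subset of the observed days, or predicting pairs absent from the
#' observed universe on a day, is an error rather than a silent drop.
#'
#' @param predictions named list of predicted panels
#'   (`date, origin, destination, flow`), one per model.
#' @param observed observed `mobi_flows` panel.
#' @param p1_end last calendar day of period P1 (Date or ISO string).
#' @param floor_eps IG floor, see [information_gain()].
#' @return list with `daily` (data frame: model, date, cpc, ig) and
#'   `summary` (data frame: model, mu_cpc, max_cpc, min_cpc, mu_cpc_p1,
#'   mu_cpc_p2, mu_ig).
#' @export
evaluate_models <- function(predictions, observed, p1_end = "2020-03-15",
                            floor_eps = 1e-10) {
  if (is.null(names(predictions)) || any(names(predictions) == "")) {
    mf_abort("mobiflux_schema_error", "predictions must be a named list")
  }
  p1_end <- as.Date(p1_end)
  obs <- as.data.frame(observed)
  obs_key <- paste(obs$date, obs$origin, obs$destination)
  days <- sort(unique(obs$date))

  daily <- do.call(rbind, lapply(names(predictions), function(model) {
    pred <- as.data.frame(predictions[[model]])
    missing_days <- setdiff(format(days, "%Y-%m-%d"),
                            format(unique(pred$date), "%Y-%m-%d"))
    if (length(missing_days)) {
      mf_abort("mobiflux_coverage_error",
               paste0("model '", model, "' predicts no flows for: ",
                      paste(head(missing_days, 5), collapse = ", ")))
    }
    pred_key <- paste(pred$date, pred$origin, pred$destination)
    extra <- setdiff(pred_key, obs_key)
    if (length(extra)) {
      mf_abort("mobiflux_coverage_error",
               paste0("model '", model, "' predicts pairs outside the ",
                      "observed universe: ", paste(head(extra, 3), collapse = "; ")))
    }
    idx <- match(obs_key, pred_key)
    if (anyNA(idx)) {
      mf_abort("mobiflux_coverage_error",
               paste0("model '", model, "' misses ", sum(is.na(idx)),
                      " observed (date, pair) records"))
    }
    g_all <- pred$flow[idx]
    do.call(rbind, lapply(days, function(d) {
      sel <- obs$date == d
      data.frame(model = model, date = d,
                 cpc = cpc(g_all[sel], obs$flow[sel]),
                 ig = as.numeric(information_gain(obs$flow[sel], g_all[sel],
                                                  floor_eps = floor_eps)))
    }))
  }))
  rownames(daily) <- NULL

  summary <- do.call(rbind, lapply(names(predictions), function(model) {
    d <- daily[daily$model == model, , drop = FALSE]
    p1 <- d$date <= p1_end
    data.frame(model = model,
               mu_cpc = mean(d$cpc), max_cpc = max(d$cpc),
               min_cpc = min(d$cpc),
               mu_cpc_p1 = if (any(p1)) mean(d$cpc[p1]) else NA_real_,
               mu_cpc_p2 = if (any(!p1)) mean(d$cpc[!p1]) else NA_real_,
               mu_ig = mean(d$ig))
  }))
  rownames(summary) <- NULL
  list(daily = daily, summary = summary)
}
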