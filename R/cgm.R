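#' Build the design table for the stringency-aware gravity regression
#'
#' One row per dated flow record, with the covariates of the
#' negative-binomial spatial-interaction model: log origin population,
#' log destination population, a distance term, and the origin and
#' destination stringency indices on that day.
#'
#' The distance term depends on the deterrence family: `log(r_ij)` for the
#' power kind (its coefficient is then the power-law exponent, sign
#' included) and raw `r_ij` in km for the exponential kind (its coefficient
#' is the exponential rate). Writing the covariate this way keeps the decay
#' rate identifiable instead of hiding it inside a pre-specified deterrence
#' function.
#'
#' @param panel a `mobi_flows` panel (the response).
#' @param locations a `mobi_locations` table covering all endpoints.
#' @param stringency a `mobi_stringency` panel covering every
#'   (date, origin) and (date, destination) of `panel`.
#' @param kind deterrence family: `"exponential"` or `"power"`.
#' @param dist optional precomputed distance matrix (km).
#' @return data frame of class `cgm_design` with columns `date`, `origin`,
#'   `destination`, `flow`, `log_pop_origin`, `log_pop_dest`,
#'   `distance_covariate`, `si_origin`, `si_dest`, and attribute `kind`.
#' @export
build_design <- function(panel, locations, stringency,
                         kind = c("exponential", "power"), dist = NULL) {
  kind <- match.arg(kind)
  g <- pair_geometry(panel, locations, dist)
  si_key <- paste(stringency$date, stringency$location)
  si <- setNames(stringency$si, si_key)
  k_o <- paste(panel$date, panel$origin)
  k_d <- paste(panel$date, panel$destination)
  missing_k <- unique(c(k_o[!k_o %in% si_key], k_d[!k_d %in% si_key]))
  if (length(missing_k)) {
    mf_abort("mobiflux_missing_covariate_error",
             paste0("no stringency value for (date, location): ",
                    paste(head(missing_k, 5), collapse = "; "),
                    if (length(missing_k) > 5)
                      paste0(" ... and ", length(missing_k) - 5, " more")))
  }
  if (kind == "power" && any(g$r <= 0)) {
    mf_abort("mobiflux_domain_error",
             "log-distance covariate requires strictly positive distances")
  }
  out <- data.frame(
    date = panel$date,
    origin = panel$origin,
    destination = panel$destination,
    flow = panel$flow,
    log_pop_origin = log(setNames(locations$population,
                                  locations$id)[panel$origin]),
    log_pop_dest = log(setNames(locations$population,
                                locations$id)[panel$destination]),
    distance_covariate = if (kind == "power") log(g$r) else g$r,
    si_origin = as.numeric(si[k_o]),
    si_dest = as.numeric(si[k_d]),
    row.names = NULL)
  structure(out, kind = kind, class = c("cgm_design", "data.frame"))
}

cgm_covariates <- c("log_pop_origin", "log_pop_dest", "distance_covariate",
                    "si_origin", "si_dest")

#' Fit the stringency-aware gravity model by negative-binomial regression
#'
#' Maximum-likelihood negative-binomial regression with log link of flow
#' counts on log origin/destination populations, the distance term, and the
#' two stringency covariates:
#' `E[T] = exp(epsilon + alpha*log(P_i) + beta*log(P_j) + gamma*x_dist
#'             + delta1*SI_i + delta2*SI_j)`.
#' The dispersion (NB shape `theta`, with `Var = mu + mu^2/theta`) is
#' estimated by maximum likelihood via alternating IWLS/theta updates
#' (`MASS::glm.nb`). Zero counts are legitimate responses and are never
#' dropped.
#'
#' On an egocentric star fitted per direction, one endpoint of every record
#' is the hub, so its log-population is the same in every row and the
#' corresponding coefficient cannot be separated from the intercept.
#' Zero-variance covariate columns are therefore absorbed into the
#' intercept: their coefficient is reported as 0 (the intercept carries
#' their constant contribution), their standard error as `NA`, the absorbed
#' names are listed in `$absorbed`, and a
#' `mobiflux_constant_covariate_warning` is signalled. Predictions are
#' unaffected as long as the covariate stays at that constant. Rank
#' deficiency among *varying* covariates (genuine collinearity) remains an
#' error.
#'
#' @param design a `cgm_design` from [build_design()].
#' @return a `cgm_fit` list: `epsilon`, `alpha`, `beta`, `gamma`, `delta1`,
#'   `delta2`, `dispersion`, `standard_errors` (named, same order),
#'   `log_likelihood`, `converged`, `n_obs`, `kind`, `absorbed`, and the
#'   underlying `model` object.
#' @export
cgm_fit <- function(design) {
  if (nrow(design) < 7) {
    mf_abort("mobiflux_fit_error",
             "negative-binomial fit needs at least 7 observations")
  }
  if (!all(complete.cases(design[cgm_covariates]))) {
    mf_abort("mobiflux_missing_covariate_error",
             "design contains missing covariate values")
  }
  constant <- vapply(design[cgm_covariates],
                     function(x) diff(range(x)) == 0, logical(1))
  active <- cgm_covariates[!constant]
  if (length(active) == 0) {
    mf_abort("mobiflux_singular_design_error",
             "all covariates are constant; nothing to fit beyond an intercept")
  }
  if (any(constant)) {
    rlang::warn(paste0("constant covariate(s) absorbed into the intercept: ",
                       paste(cgm_covariates[constant], collapse = ", ")),
                class = "mobiflux_constant_covariate_warning")
  }
  X <- cbind(1, as.matrix(design[active]))
  if (qr(X)$rank < ncol(X)) {
    mf_abort("mobiflux_singular_design_error",
             "design matrix is rank deficient (collinear covariates)")
  }
  form <- stats::as.formula(paste("flow ~", paste(active, collapse = " + ")))
  # the ML iteration for theta diverges when the data are (near-)Poisson
  # (variance ~ mean, theta -> infinity); in that regime the NB model
  # degenerates to Poisson regression, which is then the ML fit
  dispersion <- NULL
  fit <- tryCatch(
    suppressWarnings(MASS::glm.nb(
      form, data = design, control = stats::glm.control(maxit = 100))),
    error = function(e) NULL)
  if (is.null(fit)) {
    fit <- tryCatch(
      stats::glm(form, family = stats::poisson(), data = design),
      error = function(e) {
        mf_abort("mobiflux_fit_error",
                 paste0("negative-binomial fit failed: ",
                        conditionMessage(e)))
      })
    dispersion <- Inf
    rlang::warn(paste0("dispersion estimate diverged (variance ~ mean); ",
                       "returning the Poisson-limit fit"),
                class = "mobiflux_poisson_limit_warning")
  }
  cf <- coef(fit)
  se_fit <- sqrt(diag(vcov(fit)))
  coef_names <- c("epsilon", "alpha", "beta", "gamma", "delta1", "delta2")
  cf_all <- setNames(numeric(6), coef_names)
  se_all <- setNames(rep(NA_real_, 6), coef_names)
  cf_all["epsilon"] <- cf[["(Intercept)"]]
  se_all["epsilon"] <- se_fit[["(Intercept)"]]
  slot <- setNames(coef_names[-1], cgm_covariates)
  for (v in active) {
    cf_all[slot[[v]]] <- cf[[v]]
    se_all[slot[[v]]] <- se_fit[[v]]
  }
  structure(
    list(epsilon = unname(cf_all[["epsilon"]]),
         alpha = unname(cf_all[["alpha"]]),
         beta = unname(cf_all[["beta"]]),
         gamma = unname(cf_all[["gamma"]]),
         delta1 = unname(cf_all[["delta1"]]),
         delta2 = unname(cf_all[["delta2"]]),
         dispersion = dispersion %||% fit$theta,
         standard_errors = se_all,
         log_likelihood = as.numeric(logLik(fit)),
         converged = isTRUE(fit$converged),
         n_obs = nrow(design),
         kind = attr(design, "kind"),
         absorbed = cgm_covariates[constant],
         model = fit),
    class = "cgm_fit")
}

#' @export
print.cgm_fit <- function(x, ...) {
  cat(sprintf(paste0(
    "<cgm_fit> kind=%s  n=%d  logLik=%.2f  theta=%.3f%s\n",
    "  epsilon=%.4f alpha=%.4f beta=%.4f gamma=%.4f ",
    "delta1=%.5f delta2=%.5f\n"),
    x$kind, x$n_obs, x$log_likelihood, x$dispersion,
    if (x$converged) "" else "  [NOT converged]",
    x$epsilon, x$alpha, x$beta, x$gamma, x$delta1, x$delta2))
  invisible(x)
}

#' Coefficient vector of a CGM fit or generator truth, in canonical order
#' @param params a `cgm_fit` or named list.
#' @return named numeric vector (epsilon, alpha, beta, gamma, delta1, delta2).
#' @export
cgm_coef <- function(params) {
  c(epsilon = params$epsilon, alpha = params$alpha, beta = params$beta,
    gamma = params$gamma, delta1 = params$delta1, delta2 = params$delta2)
}

#' Predict mean flows from fitted (or true) CGM parameters
#'
#' Evaluates the log-linear mean surface on a design table. Deterministic
#' and strictly positive.
#'
#' @param params a `cgm_fit` or any list with elements `epsilon`, `alpha`,
#'   `beta`, `gamma`, `delta1`, `delta2` (and optionally `kind`).
#' @param design a `cgm_design` with the same covariate layout.
#' @return data frame `date, origin, destination, flow` of predicted means.
#' @export
cgm_predict <- function(params, design) {
  if (!all(cgm_covariates %in% names(design))) {
    mf_abort("mobiflux_schema_error",
             "design lacks the CGM covariate columns")
  }
  if (!is.null(params$kind) && !is.null(attr(design, "kind")) &&
      params$kind != attr(design, "kind")) {
    mf_abort("mobiflux_schema_error",
             paste0("covariate layout mismatch: fit is '", params$kind,
                    "' but design is '", attr(design, "kind"), "'"))
  }
  eta <- params$epsilon +
    params$alpha * design$log_pop_origin +
    params$beta * design$log_pop_dest +
    params$gamma * design$distance_covariate +
    params$delta1 * design$si_origin +
    params$delta2 * design$si_dest
  data.frame(date = design$date, origin = design$origin,
             destination = design$destination, flow = exp(eta),
             row.names = NULL)
}
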