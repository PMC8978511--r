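#' @section Domain containers:
#' All containers are plain data frames carrying light S3 classes and
#' attributes, so they print, subset and round-trip through CSV like any
#' other rectangular data.
#'
#' * a location table has columns `id`, `name`, `lat`, `lon`, `population`
#'   and an attribute `hub_id` naming the egocentric centre of the network;
#' * a flow panel has columns `date`, `origin`, `destination`, `flow`;
#' * a stringency panel has columns `date`, `location`, `si` with
#'   `si` in \[0, 100\].
#' @name data-model
NULL

# ---- error helpers ----------------------------------------------------------

mf_abort <- function(class, message, ...) {
  rlang::abort(message, class = c(class, "mobiflux_error"), ...)
}

# ---- locations --------------------------------------------------------------

#' Build and validate a location table
#'
#' A location table holds the masses (populations) and geometry (centroid
#' coordinates) that every spatial-interaction model in the package consumes.
#' One location is designated the *hub*: the centre of the egocentric
#' origin-destination star (e.g. the country whose operator observed the
#' roaming flows).
#'
#' @param df data frame with columns `id`, `name`, `lat`, `lon`, `population`.
#' @param hub_id identifier of the hub location; must appear in `df$id`.
#' @return the validated data frame with class `mobi_locations` and
#'   attribute `hub_id`.
#' @examples
#' locs <- mobi_locations(
#'   data.frame(id = c("UK", "FR"), name = c("hub", "spoke"),
#'              lat = c(54, 46), lon = c(-2, 2),
#'              population = c(6.7e7, 6.5e7)),
#'   hub_id = "UK")
#' @export
mobi_locations <- function(df, hub_id) {
  needed <- c("id", "name", "lat", "lon", "population")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    mf_abort("mobiflux_schema_error",
             paste0("location table lacks column(s): ",
                    paste(missing_cols, collapse = ", ")))
  }
  df <- as.data.frame(df)[needed]
  df$id <- as.character(df$id)
  df$name <- as.character(df$name)
  dup <- unique(df$id[duplicated(df$id)])
  if (length(dup)) {
    mf_abort("mobiflux_duplicate_id_error",
             paste0("duplicate location id(s): ", paste(dup, collapse = ", ")))
  }
  if (any(!is.finite(df$population) | df$population <= 0)) {
    bad <- df$id[!is.finite(df$population) | df$population <= 0]
    mf_abort("mobiflux_population_error",
             paste0("non-positive population for: ", paste(bad, collapse = ", ")))
  }
  if (any(!is.finite(df$lat) | abs(df$lat) > 90) ||
      any(!is.finite(df$lon) | abs(df$lon) > 180)) {
    mf_abort("mobiflux_coordinate_error",
             "latitude must lie in [-90, 90] and longitude in [-180, 180]")
  }
  if (missing(hub_id) || !hub_id %in% df$id) {
    mf_abort("mobiflux_hub_error", "hub_id must name a row of the location table")
  }
  structure(df, hub_id = hub_id,
            class = c("mobi_locations", "data.frame"))
}

#' Read a location table from CSV
#'
#' @param path CSV file with header `id,name,lat,lon,population`.
#' @param hub_id id of the egocentric hub.
#' @return a validated `mobi_locations` table.
#' @seealso [mobi_locations()]
#' @export
load_locations <- function(path, hub_id) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  mobi_locations(df, hub_id = hub_id)
}

#' @export
print.mobi_locations <- function(x, ...) {
  cat(sprintf("<mobi_locations> %d locations, hub = %s\n",
              nrow(x), attr(x, "hub_id")))
  print(as.data.frame(head(x, 6)), ...)
  if (nrow(x) > 6) cat(sprintf("... and %d more\n", nrow(x) - 6))
  invisible(x)
}

hub_of <- function(locations) attr(locations, "hub_id")

# ---- flows ------------------------------------------------------------------

parse_iso_date <- function(x, what = "date") {
  d <- as.Date(as.character(x), format = "%Y-%m-%d")
  if (anyNA(d)) {
    mf_abort("mobiflux_date_error",
             paste0("unparseable ISO ", what, "(s): ",
                    paste(unique(as.character(x)[is.na(d)])[1:5], collapse = ", ")))
  }
  d
}

#' Build and validate a daily origin-destination flow panel
#'
#' Each record is a count of travellers (or roaming devices) moving from
#' `origin` to `destination` on `date`. On an egocentric star network every
#' record has exactly one endpoint equal to the hub; that constraint is
#' enforced when `star = TRUE` (the default) and relaxed for general OD
#' matrices (needed e.g. to exercise the radiation model on full grids).
#'
#' @param df data frame with columns `date`, `origin`, `destination`, `flow`.
#' @param hub_id hub identifier used for the star-constraint check; may be
#'   `NULL` when `star = FALSE`.
#' @param star enforce the egocentric star constraint?
#' @return the validated panel, dates parsed as `Date`, with class
#'   `mobi_flows`.
#' @export
mobi_flows <- function(df, hub_id = NULL, star = TRUE) {
  needed <- c("date", "origin", "destination", "flow")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    mf_abort("mobiflux_schema_error",
             paste0("flow panel lacks column(s): ",
                    paste(missing_cols, collapse = ", ")))
  }
  df <- as.data.frame(df)[needed]
  df$date <- parse_iso_date(df$date)
  df$origin <- as.character(df$origin)
  df$destination <- as.character(df$destination)
  if (any(df$origin == df$destination)) {
    mf_abort("mobiflux_self_loop_error",
             "flow records with origin == destination are not allowed")
  }
  if (any(!is.finite(df$flow) | df$flow < 0)) {
    mf_abort("mobiflux_flow_error", "flows must be finite and >= 0")
  }
  if (any(abs(df$flow - round(df$flow)) > 1e-8)) {
    mf_abort("mobiflux_flow_error", "observed flows must be integer counts")
  }
  key <- paste(df$date, df$origin, df$destination)
  if (anyDuplicated(key)) {
    mf_abort("mobiflux_duplicate_record_error",
             "duplicate (date, origin, destination) records in flow panel")
  }
  if (isTRUE(star)) {
    if (is.null(hub_id)) {
      mf_abort("mobiflux_star_error", "hub_id is required when star = TRUE")
    }
    one_end <- xor(df$origin == hub_id, df$destination == hub_id)
    if (!all(one_end)) {
      mf_abort("mobiflux_star_error",
               "every record must have exactly one endpoint equal to the hub")
    }
  }
  structure(df, hub_id = hub_id, star = isTRUE(star),
            class = c("mobi_flows", "data.frame"))
}

#' Read a daily flow panel from CSV
#'
#' @param path CSV file with header `date,origin,destination,flow`
#'   (ISO dates).
#' @param hub_id hub identifier (for the star constraint).
#' @param star enforce the egocentric star constraint (default `TRUE`).
#' @return a validated `mobi_flows` panel.
#' @export
load_flows <- function(path, hub_id = NULL, star = TRUE) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  mobi_flows(df, hub_id = hub_id, star = star)
}

#' Restrict a star panel to one direction of travel
#'
#' @param flows a `mobi_flows` star panel.
#' @param direction `"incoming"` keeps records whose destination is the hub;
#'   `"outgoing"` keeps records whose origin is the hub; `"both"` keeps all.
#' @param hub_id hub identifier; defaults to the panel's own.
#' @return the filtered panel.
#' @export
flow_direction <- function(flows, direction = c("incoming", "outgoing", "both"),
                           hub_id = attr(flows, "hub_id")) {
  direction <- match.arg(direction)
  if (direction == "both") return(flows)
  if (is.null(hub_id)) {
    mf_abort("mobiflux_star_error", "hub_id needed to select a direction")
  }
  keep <- if (direction == "incoming") flows$destination == hub_id
          else flows$origin == hub_id
  out <- flows[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "hub_id") <- hub_id
  attr(out, "star") <- attr(flows, "star")
  class(out) <- class(flows)
  out
}

# ---- stringency -------------------------------------------------------------

#' Build and validate a daily stringency panel
#'
#' The stringency index is a composite 0-100 measure of how severe a
#' country's non-pharmaceutical interventions are on a given day (0 = no
#' restrictions), in the style of the Oxford Stringency Index. It provides
#' the origin/destination policy covariates of the stringency-aware gravity
#' regression.
#'
#' @param df data frame with columns `date`, `location`, `si`.
#' @return the validated panel with class `mobi_stringency`.
#' @export
mobi_stringency <- function(df) {
  needed <- c("date", "location", "si")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    mf_abort("mobiflux_schema_error",
             paste0("stringency panel lacks column(s): ",
                    paste(missing_cols, collapse = ", ")))
  }
  df <- as.data.frame(df)[needed]
  df$date <- parse_iso_date(df$date)
  df$location <- as.character(df$location)
  if (any(!is.finite(df$si) | df$si < 0 | df$si > 100)) {
    mf_abort("mobiflux_range_error", "stringency index must lie in [0, 100]")
  }
  key <- paste(df$date, df$location)
  if (anyDuplicated(key)) {
    mf_abort("mobiflux_duplicate_record_error",
             "duplicate (date, location) records in stringency panel")
  }
  structure(df, class = c("mobi_stringency", "data.frame"))
}

#' Read a stringency panel from CSV
#'
#' @param path CSV file with header `date,location,si` (ISO dates,
#'   `si` in \[0, 100\]).
#' @return a validated `mobi_stringency` panel.
#' @export
load_stringency <- function(path) {
  mobi_stringency(read.csv(path, stringsAsFactors = FALSE))
}

#' Read a reference daily time series from CSV
#'
#' Used for synchrony analysis against an external arrivals series
#' (e.g. daily air-passenger counts).
#'
#' @param path CSV file with header `date,count`.
#' @return data frame with `date` (Date) and `count` (numeric), sorted by
#'   date.
#' @export
load_reference <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(c("date", "count"), names(df))
  if (length(missing_cols)) {
    mf_abort("mobiflux_schema_error",
             paste0("reference series lacks column(s): ",
                    paste(missing_cols, collapse = ", ")))
  }
  df$date <- parse_iso_date(df$date)
  df <- df[order(df$date), c("date", "count")]
  rownames(df) <- NULL
  df
}

# ---- writers (round-trip I/O) ----------------------------------------------

#' Write package containers back to their CSV interchange formats
#'
#' Writers are exact inverses of the corresponding loaders: writing a valid
#' container and loading it again reproduces the container.
#'
#' @param x the container to write.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @name writers
NULL

#' @rdname writers
#' @export
write_locations <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writers
#' @export
write_flows <- function(x, path) {
  df <- as.data.frame(x)
  df$date <- format(df$date, "%Y-%m-%d")
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writers
#' @export
write_stringency <- function(x, path) {
  df <- as.data.frame(x)
  df$date <- format(df$date, "%Y-%m-%d")
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- geometry ---------------------------------------------------------------

#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371.0 km. Vectorised over all
#' arguments.
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees.
#' @return distance(s) in km.
#' @examples
#' haversine_km(0, 0, 0, 180)  # half the Earth's circumference
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = 6371) # km
}

#' Pairwise great-circle distance matrix for a location table
#'
#' @param locations a `mobi_locations` table with at least two rows.
#' @return symmetric numeric matrix (km) with zero diagonal, dimnames set to
#'   location ids.
#' @export
distance_matrix <- function(locations) {
  if (nrow(locations) < 2) {
    mf_abort("mobiflux_schema_error",
             "a distance matrix needs at least 2 locations")
  }
  p <- cbind(locations$lon, locations$lat)
  m <- geosphere::distm(p, fun = function(a, b)
    geosphere::distHaversine(a, b, r = 6371))
  # distm round-trips through doubles; enforce exact symmetry and diagonal
  m <- (m + t(m)) / 2
  diag(m) <- 0
  dimnames(m) <- list(locations$id, locations$id)
  m
}

# ---- aggregation ------------------------------------------------------------

#' Aggregate a star panel into a daily total series
#'
#' Sums the flows over all counterpart countries per day, i.e. the total
#' daily volume entering (or leaving) the hub. Days inside the requested
#' range with no record contribute 0, matching counting semantics (no
#' observed devices means a count of zero, not a missing value).
#'
#' @param flows a `mobi_flows` star panel.
#' @param direction `"incoming"`, `"outgoing"` or `"both"`.
#' @param date_range optional length-2 `Date` vector; defaults to the range
#'   of dates present. All days in `seq(from, to, by = "day")` appear in the
#'   output.
#' @return data frame with columns `date` and `total`, one row per day.
#' @export
aggregate_daily_total <- function(flows,
                                  direction = c("incoming", "outgoing", "both"),
                                  date_range = NULL) {
  direction <- match.arg(direction)
  sub <- flow_direction(flows, direction)
  if (nrow(sub) == 0 && is.null(date_range)) {
    return(data.frame(date = as.Date(character()), total = numeric()))
  }
  if (is.null(date_range)) date_range <- range(sub$date)
  days <- seq(date_range[1], date_range[2], by = "day")
  tot <- tapply(sub$flow, as.character(sub$date), sum)
  total <- as.numeric(tot[as.character(days)])
  total[is.na(total)] <- 0
  data.frame(date = days, total = total)
}
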