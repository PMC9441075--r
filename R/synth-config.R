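#' Configuration for the synthetic report-stream generator
#'
#' Defines the ground-truth data-generating process used to validate the
#' pipeline: per-site weekly counts follow a segmented log-linear NB2 model
#' around each site's intervention start date, which are then exploded into
#' point-level incident records inside geodesic buffers and optionally
#' contaminated with duplicate, off-category and off-site records.
#'
#' The latent weekly mean for site \eqn{i} in relative week \eqn{t}
#' (\eqn{t = 1, \ldots, 53}; the intervention start date falls in week 27) is
#' \deqn{\mu_{it} = \exp(\beta_{0i} + \beta_1 t + \beta_2 I_{it} +
#'   \beta_3 t I_{it} + a \sin(2\pi w_{it}/52))}
#' where \eqn{I_{it} = 1} iff \eqn{t \ge 28}, \eqn{a} is the optional
#' seasonal log-amplitude and \eqn{w_{it}} the calendar week of the bin.
#' Counts are NB2 with dispersion \code{theta}
#' (variance \eqn{\mu + \mu^2/\theta}).
#'
#' Defaults mirror the scale of the San Francisco Pit Stop evaluation:
#' 13 intervention sites observed 26 weeks before and 26 weeks after their
#' start dates, a pre-intervention slope of 0.013 log-reports per week, a
#' post-intervention slope change of -0.024, and NB2 dispersion 2.
#'
#' @param n_sites number of intervention sites.
#' @param neighborhoods character vector of per-site neighborhood labels,
#'   recycled to \code{n_sites}.
#' @param intervention_types per-site type, each one of
#'   \code{"new_restroom"}, \code{"attendants"}, \code{"hours_expansion"};
#'   recycled.
#' @param start_dates per-site intervention start dates (\code{Date} or
#'   parseable strings); recycled.  Must lie inside
#'   \code{[study_start, study_end]}.
#' @param beta0 per-site baseline log mean weekly reports (scalar recycled).
#' @param beta1 pre-intervention slope, log-reports per week.
#' @param beta2 level change at the intervention, log scale.
#' @param beta3 slope change after the intervention, log-reports per week.
#' @param theta NB2 dispersion (> 0); large values approach Poisson.
#' @param season_amplitude sinusoidal seasonal amplitude on the log scale
#'   (default 0: the fitted model has no seasonal term).
#' @param buffer_radius_m buffer radius in meters (default 500).
#' @param dup_rate,offcat_rate,offsite_rate contamination probabilities in
#'   \code{[0, 1]}: duplicated records flagged in the status notes,
#'   records in a non-target category, and records displaced 2--10 buffer
#'   radii away from their site.
#' @param lon,lat per-site coordinates (WGS84 degrees); defaults place
#'   sites on a well-separated grid so buffers do not overlap.
#' @param study_start,study_end study span bounds for start-date validation.
#' @param category target report category written for clean records.
#' @param seed integer RNG seed used by \code{\link{simulate_panel}} and
#'   \code{\link{materialize_reports}}.
#'
#' @return An object of class \code{"synth_config"}: a list with the
#'   validated fields above plus a \code{sites} data frame (one row per
#'   site: \code{site_id}, \code{name}, \code{neighborhood},
#'   \code{intervention_type}, \code{start_date}, \code{lon}, \code{lat}).
#' @seealso \code{\link{simulate_panel}}, \code{\link{materialize_reports}}
#' @examples
#' cfg <- synth_config(n_sites = 2, beta0 = log(5), seed = 1)
#' cfg$sites
#' @export
synth_config <- function(n_sites = 13,
                         neighborhoods = c("Downtown", "Midtown",
                                           "Riverside", "Parkside"),
                         intervention_types = "new_restroom",
                         start_dates = "2016-07-05",
                         beta0 = log(20),
                         beta1 = 0.013,
                         beta2 = -0.1,
                         beta3 = -0.024,
                         theta = 2,
                         season_amplitude = 0,
                         buffer_radius_m = 500,
                         dup_rate = 0,
                         offcat_rate = 0,
                         offsite_rate = 0,
                         lon = NULL,
                         lat = NULL,
                         study_start = "2014-01-01",
                         study_end = "2020-01-01",
                         category = "Human/Animal Waste",
                         seed = 1L) {
  stopifnot(is.numeric(n_sites), length(n_sites) == 1L, n_sites >= 1,
            n_sites == round(n_sites))
  n_sites <- as.integer(n_sites)
  types <- rep_len(as.character(intervention_types), n_sites)
  bad <- setdiff(unique(types),
                 c("new_restroom", "attendants", "hours_expansion"))
  if (length(bad))
    stop("unknown intervention type(s): ", paste(bad, collapse = ", "))
  start_dates <- rep_len(as.Date(start_dates), n_sites)
  study_start <- as.Date(study_start)
  study_end <- as.Date(study_end)
  if (any(start_dates < study_start | start_dates > study_end))
    stop("start_dates must lie within [study_start, study_end]")

  rates <- c(dup_rate = dup_rate, offcat_rate = offcat_rate,
             offsite_rate = offsite_rate)
  if (any(rates < 0 | rates > 1))
    stop("contamination rates must be in [0, 1]")
  if (!is.numeric(theta) || length(theta) != 1L || theta <= 0)
    stop("theta must be a single positive number")
  if (buffer_radius_m <= 0) stop("buffer_radius_m must be > 0")

  # default site grid: ~2.7 km east-west, ~2.2 km north-south spacing,
  # so 500 m buffers never overlap and round-trip counts are exact
  if (is.null(lon)) lon <- -122.45 + 0.03 * ((seq_len(n_sites) - 1L) %% 5L)
  if (is.null(lat)) lat <- 37.72 + 0.02 * ((seq_len(n_sites) - 1L) %/% 5L)
  lon <- rep_len(lon, n_sites)
  lat <- rep_len(lat, n_sites)
  if (any(abs(lat) > 90) || any(abs(lon) > 180))
    stop("site coordinates outside WGS84 bounds")

  sites <- data.frame(
    site_id = sprintf("S%02d", seq_len(n_sites)),
    name = sprintf("Synthetic Pit Stop %02d", seq_len(n_sites)),
    neighborhood = rep_len(as.character(neighborhoods), n_sites),
    intervention_type = types,
    start_date = start_dates,
    lon = lon, lat = lat,
    stringsAsFactors = FALSE
  )

  cfg <- list(
    n_sites = n_sites,
    sites = sites,
    beta0 = rep_len(beta0, n_sites),
    beta1 = beta1, beta2 = beta2, beta3 = beta3,
    theta = theta,
    season_amplitude = season_amplitude,
    buffer_radius_m = buffer_radius_m,
    dup_rate = dup_rate, offcat_rate = offcat_rate,
    offsite_rate = offsite_rate,
    study_start = study_start, study_end = study_end,
    category = category,
    seed = as.integer(seed)
  )
  class(cfg) <- "synth_config"
  cfg
}

#' @export
print.synth_config <- function(x, ...) {
  cat("Synthetic 311-report generator configuration\n")
  cat(sprintf("  sites: %d (%s)\n", x$n_sites,
              paste(unique(x$sites$intervention_type), collapse = ", ")))
  cat(sprintf("  model: beta1 = %.4g, beta2 = %.4g, beta3 = %.4g, theta = %.4g\n",
              x$beta1, x$beta2, x$beta3, x$theta))
  cat(sprintf("  buffer radius: %g m; contamination (dup/offcat/offsite): %g/%g/%g\n",
              x$buffer_radius_m, x$dup_rate, x$offcat_rate, x$offsite_rate))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
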