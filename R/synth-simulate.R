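#' Simulate the latent weekly count panel
#'
#' Draws the ground-truth site-by-week count table implied by a
#' \code{\link{synth_config}}.  For site \eqn{i} and relative week
#' \eqn{t \in 1..53} the latent mean is
#' \eqn{\mu_{it} = \exp(\beta_{0i} + \beta_1 t + \beta_2 I_{it} +
#' \beta_3 t I_{it} + \mathrm{season})} with \eqn{I_{it} = 1} iff
#' \eqn{t \ge 28}, and the count is NB2\eqn{(\mu_{it}, \theta)}.
#' Week 27 (the transition week containing the start date) is generated
#' like any other week; dropping it is the analysis pipeline's job, not
#' the generator's.
#'
#' @param config a \code{\link{synth_config}}.
#' @return data frame with one row per site-week: \code{site_id},
#'   \code{week_index} (1..53), \code{week_start} (Date), \code{mu}
#'   (latent mean), \code{count}.
#' @examples
#' panel <- simulate_panel(synth_config(n_sites = 2, seed = 7))
#' head(panel)
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  sites <- config$sites
  set.seed(config$seed)
  weeks <- 1:53
  out <- vector("list", nrow(sites))
  for (i in seq_len(nrow(sites))) {
    t0 <- sites$start_date[i]
    week_start <- t0 + (weeks - 27L) * 7L
    intervention <- as.integer(weeks >= 28L)
    seas <- if (config$season_amplitude != 0) {
      doy <- as.integer(strftime(week_start, "%j"))
      config$season_amplitude * sin(2 * pi * doy / 365.25)
    } else 0
    eta <- config$beta0[i] + config$beta1 * weeks +
      config$beta2 * intervention +
      config$beta3 * weeks * intervention + seas
    mu <- exp(eta)
    if (any(!is.finite(mu))) {
      w <- weeks[which(!is.finite(mu))[1L]]
      stop(sprintf("non-finite latent mean at site %s, week %d (betas too extreme)",
                   sites$site_id[i], w))
    }
    count <- stats::rnbinom(length(mu), size = config$theta, mu = mu)
    out[[i]] <- data.frame(site_id = sites$site_id[i],
                           week_index = weeks,
                           week_start = week_start,
                           mu = mu, count = count,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Materialize a latent panel as raw 311-style report records
#'
#' Explodes each latent weekly count into that many point records:
#' timestamps uniform within the 7-day bin and locations uniform on the
#' geodesic buffer disc (distance \eqn{r\sqrt{u}}, bearing \eqn{2\pi v}).
#' Contamination is then appended per the configuration: duplicated
#' records whose status notes flag them as duplicates, records assigned a
#' non-target category, and records displaced 2--10 radii from their site
#' so they fall outside every buffer.
#'
#' @param panel a latent panel from \code{\link{simulate_panel}}.
#' @param config the \code{\link{synth_config}} used to generate it.
#' @param dir optional directory; when supplied, writes
#'   \code{reports.csv} (311 export dialect), \code{sites.csv} and
#'   \code{sites.geojson} (WGS84 lon/lat) and returns the paths.
#' @return list with \code{reports} (data frame in the 311 export
#'   dialect), \code{sites}, and, if \code{dir} was given, \code{paths}.
#' @examples
#' cfg <- synth_config(n_sites = 1, beta0 = log(3), seed = 2)
#' out <- materialize_reports(simulate_panel(cfg), cfg)
#' head(out$reports)
#' @export
materialize_reports <- function(panel, config, dir = NULL) {
  stopifnot(inherits(config, "synth_config"))
  if (any(panel$count < 0) || any(panel$count != round(panel$count)))
    stop("latent counts must be non-negative integers")
  sites <- config$sites
  set.seed(config$seed + 1L)

  n_rec <- sum(panel$count)
  idx <- rep(seq_len(nrow(panel)), panel$count)
  site_row <- match(panel$site_id[idx], sites$site_id)

  # uniform timestamp within the week bin
  secs <- stats::runif(n_rec, 0, 7 * 86400)
  opened <- as.POSIXct(panel$week_start[idx], tz = "UTC") + secs

  # uniform location on the buffer disc
  r <- config$buffer_radius_m * sqrt(stats::runif(n_rec))
  brg <- stats::runif(n_rec, 0, 360)
  pts <- geosphere::destPoint(cbind(sites$lon[site_row], sites$lat[site_row]),
                              b = brg, d = r)

  reports <- data.frame(
    report_id = sprintf("R%07d", seq_len(n_rec)),
    category = config$category,
    agency = "DPW Ops Queue",
    opened_at = format(opened, "%Y-%m-%d %H:%M:%S", tz = "UTC"),
    lon = pts[, 1], lat = pts[, 2],
    status_notes = "",
    stringsAsFactors = FALSE
  )

  next_id <- n_rec
  new_ids <- function(n) {
    ids <- sprintf("R%07d", next_id + seq_len(n))
    next_id <<- next_id + n
    ids
  }

  if (config$offsite_rate > 0 && n_rec > 0) {
    move <- which(stats::runif(n_rec) < config$offsite_rate)
    if (length(move)) {
      d <- config$buffer_radius_m * stats::runif(length(move), 2, 10)
      b <- stats::runif(length(move), 0, 360)
      far <- geosphere::destPoint(cbind(sites$lon[site_row[move]],
                                        sites$lat[site_row[move]]),
                                  b = b, d = d)
      reports$lon[move] <- far[, 1]
      reports$lat[move] <- far[, 2]
    }
  }
  if (config$dup_rate > 0 && n_rec > 0) {
    dup <- which(stats::runif(n_rec) < config$dup_rate)
    if (length(dup)) {
      extra <- reports[dup, ]
      extra$report_id <- new_ids(length(dup))
      extra$status_notes <- sprintf("Duplicate of case %s", reports$report_id[dup])
      reports <- rbind(reports, extra)
    }
  }
  if (config$offcat_rate > 0 && n_rec > 0) {
    n_off <- stats::rbinom(1L, n_rec, config$offcat_rate)
    if (n_off > 0) {
      take <- sample.int(nrow(reports), n_off, replace = TRUE)
      extra <- reports[take, ]
      extra$report_id <- new_ids(n_off)
      extra$category <- "Graffiti"
      extra$status_notes <- ""
      reports <- rbind(reports, extra)
    }
  }
  rownames(reports) <- NULL
  reports <- reports[order(reports$report_id), , drop = FALSE]

  out <- list(reports = reports, sites = sites)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- c(reports = file.path(dir, "reports.csv"),
               sites = file.path(dir, "sites.csv"),
               sites_geojson = file.path(dir, "sites.geojson"))
    utils::write.csv(reports, paths[["reports"]], row.names = FALSE)
    sites_out <- sites
    sites_out$start_date <- format(sites_out$start_date)
    utils::write.csv(sites_out, paths[["sites"]], row.names = FALSE)
    write_sites_geojson(sites, paths[["sites_geojson"]])
    out$paths <- paths
  }
  out
}
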