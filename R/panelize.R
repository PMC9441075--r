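#' Assign a report timestamp to a relative week index
#'
#' Weeks are 7-day bins anchored at midnight (UTC) of the intervention
#' start date \code{t0}: week \eqn{k} covers
#' \code{[t0 + (k - 27)*7 days, t0 + (k - 26)*7 days)}, half-open, so
#' week 27 is \code{[t0, t0 + 7 days)} and contains the start date.
#' Weeks 1--26 are the pre-intervention period and 28--53 the post
#' period; the 53-week span partitions every timestamp exactly once.
#'
#' @param opened_at POSIXct timestamp(s).
#' @param t0 intervention start date (\code{Date} or parseable string).
#' @return integer week index in 1..53.
#' @examples
#' assign_week(as.POSIXct("2016-07-08 12:00:00", tz = "UTC"), "2016-07-05")
#' @export
assign_week <- function(opened_at, t0) {
  t0 <- as.POSIXct(format(as.Date(t0)), tz = "UTC")
  days <- as.numeric(difftime(opened_at, t0, units = "days"))
  wk <- 27L + as.integer(floor(days / 7))
  if (any(wk < 1L | wk > 53L))
    stop("timestamp outside the 53-week span around ", format(as.Date(t0)))
  wk
}

week_period <- function(week_index) {
  ifelse(week_index <= 26L, "pre",
         ifelse(week_index == 27L, "transition", "post"))
}

#' Build the zero-filled weekly analysis panel
#'
#' Converts matched reports into per-site weekly counts on the relative
#' week grid, zero-filling empty weeks (zero reports is a real
#' observation; omitting empty weeks would bias slope estimates) and
#' dropping the transition week 27, leaving exactly 52 rows per site
#' (26 pre + 26 post).
#'
#' @param matched match data frame from \code{\link{match_reports}}.
#' @param sites site data frame with \code{site_id}, \code{start_date}.
#' @return data frame with one row per retained site-week:
#'   \code{site_id}, \code{week_index} (1..26, 28..53), \code{period}
#'   (\code{"pre"}/\code{"post"}), \code{week_start} (Date),
#'   \code{count}.
#' @export
build_panel <- function(matched, sites) {
  weeks <- setdiff(1:53, 27L)
  grid <- expand.grid(week_index = weeks, site_id = sites$site_id,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("site_id", "week_index")]
  t0 <- as.Date(sites$start_date)[match(grid$site_id, sites$site_id)]
  grid$period <- week_period(grid$week_index)
  grid$week_start <- t0 + (grid$week_index - 27L) * 7L
  grid$count <- 0L
  if (nrow(matched)) {
    t0m <- as.Date(sites$start_date)[match(matched$site_id, sites$site_id)]
    wk <- mapply(function(ts, d) assign_week(ts, d), matched$opened_at, t0m)
    keep <- wk != 27L
    if (any(keep)) {
      key <- paste(matched$site_id[keep], wk[keep])
      tab <- table(key)
      gkey <- paste(grid$site_id, grid$week_index)
      hit <- match(names(tab), gkey)
      grid$count[hit] <- as.integer(tab)
    }
  }
  grid <- grid[order(grid$site_id, grid$week_index), , drop = FALSE]
  rownames(grid) <- NULL
  grid
}

#' Descriptive weekly-report summaries by season and year
#'
#' Computes calendar-weekly report totals (Monday-anchored bins over the
#' observed span), then the mean and SD of those weekly totals within
#' each meteorological season (DJF winter, MAM spring, JJA summer, SON
#' fall, by the week's start month) and within each calendar year.
#'
#' @param reports record data frame with \code{opened_at} (POSIXct).
#' @return list of two data frames, \code{by_season} (\code{season},
#'   \code{n_weeks}, \code{mean}, \code{sd}) and \code{by_year}
#'   (\code{year}, \code{n_weeks}, \code{mean}, \code{sd}).
#' @export
summarize_by_season_year <- function(reports) {
  if (!nrow(reports)) stop("no reports to summarize")
  day <- as.Date(reports$opened_at)
  wk_start <- day - (as.integer(format(day, "%u")) - 1L)  # Monday
  all_weeks <- seq(min(wk_start), max(wk_start), by = 7L)
  totals <- as.integer(table(factor(as.character(wk_start),
                                    levels = as.character(all_weeks))))
  mon <- as.integer(format(all_weeks, "%m"))
  season <- c("winter", "winter", "spring", "spring", "spring", "summer",
              "summer", "summer", "fall", "fall", "fall", "winter")[mon]
  year <- format(all_weeks, "%Y")

  agg <- function(g) {
    sp <- split(totals, g)
    data.frame(stratum = names(sp),
               n_weeks = vapply(sp, length, integer(1)),
               mean = vapply(sp, mean, numeric(1)),
               sd = vapply(sp, stats::sd, numeric(1)),
               row.names = NULL, stringsAsFactors = FALSE)
  }
  by_season <- agg(factor(season, levels = c("winter", "spring",
                                             "summer", "fall")))
  names(by_season)[1] <- "season"
  by_year <- agg(year)
  names(by_year)[1] <- "year"
  list(by_season = by_season, by_year = by_year)
}
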