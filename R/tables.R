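#' Weeks-observed bookkeeping
#'
#' Two table conventions for the number of site-weeks in a stratum:
#' the pre/post comparison reports weeks per six-month period
#' (26 weeks per intervention per period), while the regression table
#' reports the total across both periods (52 analysed weeks per
#' intervention, the transition week being excluded).
#'
#' @param n_interventions number of interventions in the stratum.
#' @return integer number of weeks.
#' @examples
#' weeks_observed_per_period(13)  # 338
#' weeks_observed_total(13)       # 676
#' @export
weeks_observed_per_period <- function(n_interventions) 26L * as.integer(n_interventions)

#' @rdname weeks_observed_per_period
#' @export
weeks_observed_total <- function(n_interventions) 52L * as.integer(n_interventions)

stratum_table1_row <- function(panel_sub, stratum, n_sites, n_perm, seed,
                               sidedness) {
  pre <- panel_sub$count[panel_sub$period == "pre"]
  post <- panel_sub$count[panel_sub$period == "post"]
  pt <- permutation_test(pre, post, n_perm = n_perm, seed = seed,
                         sidedness = sidedness)
  data.frame(stratum = stratum,
             n_interventions = n_sites,
             n_weeks_observed = weeks_observed_per_period(n_sites),
             pre_mean = mean(pre), pre_sd = stats::sd(pre),
             post_mean = mean(post), post_sd = stats::sd(post),
             delta = pt$delta_obs,
             p_perm = pt$p_value,
             stringsAsFactors = FALSE)
}

#' Pre/post mean comparison table by stratum
#'
#' Pools weekly counts across the interventions of each stratum (each
#' site-week is one observation) and reports pre- and post-period mean
#' weekly reports, SDs, the difference in means \eqn{\Delta} and its
#' permutation p-value, stratified by intervention type and, separately,
#' by neighborhood.  Weeks observed follow the per-six-month-period
#' convention (26 per intervention).
#'
#' @param panel panel from \code{\link{build_panel}}.
#' @param sites site data frame.
#' @param n_perm permutations per stratum (default 10000).
#' @param seed RNG seed for the permutation draws.
#' @param sidedness passed to \code{\link{permutation_test}}.
#' @return data frame of stratum summaries with a \code{stratum_kind}
#'   column (\code{"intervention_type"} or \code{"neighborhood"}).
#' @export
make_table1 <- function(panel, sites, n_perm = 10000, seed = 1L,
                        sidedness = "two_sided") {
  rows <- list()
  k <- 0L
  for (kind in c("intervention_type", "neighborhood")) {
    for (lev in sort(unique(sites[[kind]]))) {
      ids <- sites$site_id[sites[[kind]] == lev]
      sub <- panel[panel$site_id %in% ids, , drop = FALSE]
      if (!nrow(sub)) {
        warning("empty stratum omitted: ", kind, " = ", lev)
        next
      }
      k <- k + 1L
      row <- stratum_table1_row(sub, lev, length(ids), n_perm,
                                seed + k, sidedness)
      row$stratum_kind <- kind
      rows[[k]] <- row
    }
  }
  out <- do.call(rbind, rows)
  out[, c("stratum_kind", setdiff(names(out), "stratum_kind"))]
}

fit_stratum_its <- function(panel_sub, sites, adjust) {
  design <- build_design(panel_sub, sites, adjust_neighborhood = adjust)
  warn <- NULL
  fit <- withCallingHandlers(
    tryCatch(fit_nb_glm(design), error = function(e) e),
    warning = function(w) { warn <<- conditionMessage(w)
      invokeRestart("muffleWarning") })
  list(fit = fit, warning = warn)
}

#' Segmented-regression table by stratum
#'
#' Fits the NB2 interrupted time-series model per stratum and reports
#' the pre-intervention slope \eqn{m} and post-intervention slope change
#' \eqn{\Delta m} with robust 95\% CIs.  The intervention-type strata
#' are neighborhood-adjusted; the neighborhood-within-type strata are
#' unadjusted (each stratum is a single neighborhood).  Weeks observed
#' follow the total convention (52 per intervention).
#'
#' @param panel panel from \code{\link{build_panel}}.
#' @param sites site data frame.
#' @return data frame with columns \code{stratum_kind}, \code{stratum},
#'   \code{n_interventions}, \code{n_weeks_observed}, \code{pre_slope},
#'   \code{pre_slope_lo}, \code{pre_slope_hi}, \code{slope_change},
#'   \code{slope_change_lo}, \code{slope_change_hi}, \code{theta},
#'   \code{converged}, \code{note}.
#' @export
make_table2 <- function(panel, sites) {
  rows <- list()
  add_row <- function(kind, lev, ids, adjust) {
    sub <- panel[panel$site_id %in% ids, , drop = FALSE]
    if (!nrow(sub)) {
      warning("empty stratum omitted: ", kind, " = ", lev)
      return(NULL)
    }
    fs <- fit_stratum_its(sub, sites, adjust)
    if (inherits(fs$fit, "error")) {
      return(data.frame(stratum_kind = kind, stratum = lev,
                        n_interventions = length(ids),
                        n_weeks_observed = weeks_observed_total(length(ids)),
                        pre_slope = NA_real_, pre_slope_lo = NA_real_,
                        pre_slope_hi = NA_real_, slope_change = NA_real_,
                        slope_change_lo = NA_real_,
                        slope_change_hi = NA_real_, theta = NA_real_,
                        converged = FALSE,
                        note = conditionMessage(fs$fit),
                        stringsAsFactors = FALSE))
    }
    fit <- fs$fit
    m <- pre_slope(fit); dm <- slope_change(fit)
    data.frame(stratum_kind = kind, stratum = lev,
               n_interventions = length(ids),
               n_weeks_observed = weeks_observed_total(length(ids)),
               pre_slope = m$estimate, pre_slope_lo = m$ci[1],
               pre_slope_hi = m$ci[2],
               slope_change = dm$estimate, slope_change_lo = dm$ci[1],
               slope_change_hi = dm$ci[2],
               theta = fit$theta, converged = fit$converged,
               note = fs$warning %||% "",
               stringsAsFactors = FALSE)
  }
  for (lev in sort(unique(sites$intervention_type))) {
    ids <- sites$site_id[sites$intervention_type == lev]
    rows[[length(rows) + 1L]] <- add_row("intervention_type", lev, ids,
                                         adjust = TRUE)
  }
  for (ty in sort(unique(sites$intervention_type))) {
    for (nb in sort(unique(sites$neighborhood[sites$intervention_type == ty]))) {
      ids <- sites$site_id[sites$intervention_type == ty &
                             sites$neighborhood == nb]
      rows[[length(rows) + 1L]] <- add_row(paste0("neighborhood:", ty),
                                           nb, ids, adjust = FALSE)
    }
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  out
}

#' Round a summary table to print precision
#'
#' Rendered tables round to 2 decimals (the print convention of the
#' published summaries); machine-readable outputs keep full precision.
#'
#' @param tab data frame from \code{\link{make_table1}} or
#'   \code{\link{make_table2}}.
#' @param digits decimal places (default 2).
#' @return the table with numeric (non-count) columns rounded.
#' @export
render_table <- function(tab, digits = 2) {
  num <- vapply(tab, is.numeric, logical(1)) &
    !names(tab) %in% c("n_interventions", "n_weeks_observed")
  tab[num] <- lapply(tab[num], round, digits = digits)
  tab
}
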