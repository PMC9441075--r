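#' Build the segmented-regression design from a weekly panel
#'
#' One row per site-week with the interrupted time-series covariates:
#' the relative week index \eqn{t} (1..53 without the transition week
#' 27), the intervention indicator (1 iff \eqn{t \ge 28}; defined by the
#' week index, never by raw timestamps, so the transition-removal rule
#' is structural), their interaction, and the site's neighborhood label
#' for optional confounding adjustment.
#'
#' @param panel panel data frame from \code{\link{build_panel}}.
#' @param sites site data frame with \code{site_id},
#'   \code{neighborhood}.
#' @param adjust_neighborhood include neighborhood fixed effects
#'   (treatment-coded, alphabetically first level as reference) in
#'   downstream fits.
#' @return data frame (\code{site_id}, \code{week_t},
#'   \code{intervention}, \code{interaction}, \code{neighborhood},
#'   \code{y}) with attribute \code{"adjust_neighborhood"}.
#' @export
build_design <- function(panel, sites, adjust_neighborhood = TRUE) {
  if (any(panel$week_index == 27L))
    stop("panel must exclude the transition week (27)")
  nb <- sites$neighborhood[match(panel$site_id, sites$site_id)]
  if (adjust_neighborhood && any(is.na(nb) | nb == ""))
    stop("neighborhood label missing for site(s): ",
         paste(unique(panel$site_id[is.na(nb) | nb == ""]), collapse = ", "))
  d <- data.frame(site_id = panel$site_id,
                  week_t = as.numeric(panel$week_index),
                  intervention = as.numeric(panel$week_index >= 28L),
                  neighborhood = as.character(nb),
                  y = as.numeric(panel$count),
                  stringsAsFactors = FALSE)
  d$interaction <- d$week_t * d$intervention
  d <- d[, c("site_id", "week_t", "intervention", "interaction",
             "neighborhood", "y")]
  attr(d, "adjust_neighborhood") <- adjust_neighborhood
  d
}

design_matrix <- function(design) {
  X <- cbind("(Intercept)" = 1,
             week_t = design$week_t,
             intervention = design$intervention,
             "week_t:intervention" = design$interaction)
  if (isTRUE(attr(design, "adjust_neighborhood"))) {
    lev <- sort(unique(design$neighborhood))
    if (length(lev) > 1L) {
      for (l in lev[-1L]) {
        col <- as.numeric(design$neighborhood == l)
        X <- cbind(X, col)
        colnames(X)[ncol(X)] <- paste0("neighborhood", l)
      }
    }
  }
  X
}

nb_loglik <- function(y, mu, theta) {
  if (is.finite(theta)) sum(stats::dnbinom(y, size = theta, mu = mu, log = TRUE))
  else sum(stats::dpois(y, lambda = mu, log = TRUE))
}

# IRLS (Fisher scoring) for the log-link NB2/Poisson mean model at fixed
# theta.  Working weight mu/(1 + mu/theta) is (dmu/deta)^2 / Var.
nb_irls <- function(X, y, theta, beta_start = NULL, tol = 1e-10,
                    maxit = 200L) {
  if (is.null(beta_start)) {
    mu <- y + 0.1
    eta <- log(mu)
  } else {
    eta <- drop(X %*% beta_start)
    mu <- exp(eta)
  }
  beta <- beta_start %||% rep(NA_real_, ncol(X))
  ok <- FALSE
  for (it in seq_len(maxit)) {
    w <- if (is.finite(theta)) mu / (1 + mu / theta) else mu
    z <- eta + (y - mu) / mu
    qr_ <- qr(X * sqrt(w))
    if (qr_$rank < ncol(X)) {
      drop_cols <- colnames(X)[qr_$pivot[-seq_len(qr_$rank)]]
      stop("design matrix is rank deficient; collinear column(s): ",
           paste(drop_cols, collapse = ", "))
    }
    beta_new <- qr.coef(qr_, z * sqrt(w))
    eta <- drop(X %*% beta_new)
    if (max(eta) > 700) stop("linear predictor overflow during IRLS")
    mu <- exp(eta)
    step <- if (all(is.finite(beta))) max(abs(beta_new - beta)) else Inf
    beta <- beta_new
    if (step < tol) { ok <- TRUE; break }
  }
  list(beta = beta, eta = eta, mu = mu, converged = ok)
}

#' Fit the segmented negative-binomial interrupted time-series model
#'
#' Fits the NB2 log-link model
#' \deqn{\log E[y_{it}] = \beta_0 + \beta_1 \mathrm{week}_t +
#'   \beta_2 \mathrm{intervention}_{it} +
#'   \beta_3 \mathrm{week}_t \mathrm{intervention}_{it} +
#'   \beta_4 \mathrm{neighborhood}}
#' by coordinate ascent: \eqn{\beta} by iteratively reweighted least
#' squares at fixed dispersion \eqn{\theta}, then \eqn{\theta} by
#' one-dimensional profile maximum likelihood (on \eqn{\log\theta}),
#' until \eqn{\max|\Delta\beta| < 10^{-8}} and
#' \eqn{|\Delta\log\theta| < 10^{-6}} (at most 100 outer iterations).
#' The two blocks are information-orthogonal in NB2, so alternation
#' converges quickly.  When the data are equi- or under-dispersed the
#' profile in \eqn{\theta} is monotone increasing; the fit then falls
#' back to the Poisson limit (reported as \code{theta = Inf}) with a
#' warning.  Robust (HC0 sandwich) standard errors and Wald 95\%
#' confidence intervals (\eqn{\hat\beta \pm 1.96\,} SE) are attached via
#' \code{\link{robust_vcov}}.
#'
#' @param design design data frame from \code{\link{build_design}}.
#' @return object of class \code{"its_fit"}: list with \code{beta}
#'   (named coefficients, log scale per week), \code{theta},
#'   \code{vcov_robust}, \code{se_robust}, \code{ci_95} (matrix with
#'   columns \code{lo}, \code{hi}), \code{converged}, \code{n_obs},
#'   \code{loglik}, plus the internals (\code{X}, \code{y}, \code{mu})
#'   needed to recompute the sandwich.
#' @seealso \code{\link{slope_change}}, \code{\link{level_change}},
#'   \code{\link{pre_slope}}
#' @export
fit_nb_glm <- function(design) {
  X <- design_matrix(design)
  y <- design$y
  if (any(y < 0) || any(y != round(y)))
    stop("response must be non-negative integers")
  if (all(y == 0)) stop("all-zero response; nothing to fit")
  if (nrow(X) < ncol(X) + 2L)
    stop("too few rows (", nrow(X), ") for ", ncol(X), " coefficients")

  # beyond this the NB2 fit is numerically indistinguishable from Poisson
  log_theta_hi <- log(1e6)
  # Poisson start, then a moment estimate of theta
  f0 <- nb_irls(X, y, Inf)
  denom <- sum((y - f0$mu)^2 - f0$mu)
  theta <- if (denom > 0) max(min(sum(f0$mu^2) / denom, 1e4), 1e-3) else 1e4

  beta <- f0$beta
  ll <- -Inf
  ll_trace <- numeric(0)
  converged <- FALSE
  poisson_limit <- FALSE
  for (it in seq_len(100L)) {
    fb <- nb_irls(X, y, theta, beta_start = beta)
    step_beta <- max(abs(fb$beta - beta))
    beta <- fb$beta
    opt <- stats::optimize(function(lt) nb_loglik(y, fb$mu, exp(lt)),
                           interval = c(log(1e-4), log_theta_hi),
                           maximum = TRUE, tol = 1e-10)
    # a profile optimum this far out is a flat Poisson plateau (mu^2/theta
    # negligible against mu), whether truly monotone or merely noisy there
    if (opt$maximum > log(1e5)) { poisson_limit <- TRUE; break }
    step_theta <- abs(opt$maximum - log(theta))
    theta <- exp(opt$maximum)
    ll_new <- nb_loglik(y, fb$mu, theta)
    ll <- ll_new
    ll_trace <- c(ll_trace, ll_new)
    if (step_beta < 1e-8 && step_theta < 1e-6) { converged <- TRUE; break }
  }
  if (poisson_limit) {
    warning("dispersion profile is monotone (equi/under-dispersed data); ",
            "falling back to the Poisson limit (theta = Inf)")
    fb <- nb_irls(X, y, Inf)
    beta <- fb$beta
    theta <- Inf
    ll <- nb_loglik(y, fb$mu, Inf)
    converged <- fb$converged
  }
  if (!converged)
    warning("NB ITS fit did not converge within 100 outer iterations")

  fit <- structure(list(beta = beta, theta = theta, converged = converged,
                        n_obs = length(y), loglik = ll, ll_trace = ll_trace,
                        X = X, y = y, mu = fb$mu),
                   class = "its_fit")
  fit$vcov_robust <- robust_vcov(fit)
  fit$se_robust <- sqrt(diag(fit$vcov_robust))
  fit$ci_95 <- cbind(lo = beta - 1.96 * fit$se_robust,
                     hi = beta + 1.96 * fit$se_robust)
  fit
}

#' HC0 sandwich covariance for an ITS fit
#'
#' \eqn{A^{-1} B A^{-1}} with bread \eqn{A = X^\top W X} the expected
#' information for \eqn{\beta} at the fitted \eqn{(\beta, \theta)}
#' (working weights \eqn{w_i = \mu_i/(1 + \mu_i/\theta)}) and meat
#' \eqn{B = \sum_i s_i s_i^\top} the outer product of per-observation
#' score contributions \eqn{s_i = x_i (y_i - \mu_i)/(1 + \mu_i/\theta)}.
#' Valid under variance misspecification; \eqn{\theta} is treated as
#' fixed, as is standard for sandwich inference on GLM mean parameters.
#'
#' @param fit an \code{\link{fit_nb_glm}} object.
#' @return symmetric covariance matrix for \code{fit$beta}.
#' @export
robust_vcov <- function(fit) {
  stopifnot(inherits(fit, "its_fit"))
  X <- fit$X; y <- fit$y; mu <- fit$mu; theta <- fit$theta
  shrink <- if (is.finite(theta)) 1 + mu / theta else rep(1, length(mu))
  w <- mu / shrink
  A <- crossprod(X * sqrt(w))
  s <- X * ((y - mu) / shrink)
  B <- crossprod(s)
  Ainv <- tryCatch(solve(A), error = function(e)
    stop("singular bread matrix; check for collinear design columns"))
  V <- Ainv %*% B %*% Ainv
  (V + t(V)) / 2
}

coef_ci <- function(fit, name) {
  if (!name %in% names(fit$beta)) stop("coefficient not in fit: ", name)
  list(estimate = unname(fit$beta[name]),
       se = unname(fit$se_robust[name]),
       ci = unname(fit$ci_95[name, ]))
}

#' Extract the interrupted time-series effect estimates
#'
#' \code{pre_slope} returns the pre-intervention weekly trend
#' \eqn{m = \beta_1}; \code{level_change} the instantaneous shift
#' \eqn{\beta_2}; \code{slope_change} the post-intervention change in
#' trend \eqn{\Delta m = \beta_3}; \code{post_slope} the implied post
#' trend \eqn{\beta_1 + \beta_3}.  All are on the log scale in units of
#' log-reports per week, with robust Wald 95\% CIs.
#'
#' @param fit an \code{\link{fit_nb_glm}} object.
#' @return list with \code{estimate}, \code{se}, \code{ci} (length-2
#'   lo/hi).
#' @export
slope_change <- function(fit) coef_ci(fit, "week_t:intervention")

#' @rdname slope_change
#' @export
level_change <- function(fit) coef_ci(fit, "intervention")

#' @rdname slope_change
#' @export
pre_slope <- function(fit) coef_ci(fit, "week_t")

#' @rdname slope_change
#' @export
post_slope <- function(fit) {
  i <- match(c("week_t", "week_t:intervention"), names(fit$beta))
  est <- sum(fit$beta[i])
  v <- fit$vcov_robust
  se <- sqrt(v[i[1], i[1]] + v[i[2], i[2]] + 2 * v[i[1], i[2]])
  list(estimate = est, se = se, ci = c(est - 1.96 * se, est + 1.96 * se))
}

#' @export
print.its_fit <- function(x, ...) {
  cat("Segmented negative-binomial ITS fit\n")
  cat(sprintf("  n = %d site-weeks, theta = %s, logLik = %.2f%s\n",
              x$n_obs,
              if (is.finite(x$theta)) sprintf("%.4g", x$theta) else "Inf (Poisson)",
              x$loglik,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  tab <- cbind(estimate = x$beta, robust_se = x$se_robust, x$ci_95)
  print(round(tab, 4))
  invisible(x)
}
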