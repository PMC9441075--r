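test_that("design construction matches the segmented-model bookkeeping", {
  cfg <- synth_config(n_sites = 13, seed = 2)
  panel <- latent_to_panel(simulate_panel(cfg))
  d <- build_design(panel, cfg$sites)
  expect_equal(nrow(d), 13 * 52)                       # 676 rows
  expect_true(all(d$interaction == d$week_t * d$intervention))
  expect_true(all((d$intervention == 1) == (d$week_t >= 28)))
  # 4 neighborhoods -> intercept + 3 model terms + 3 dummies
  expect_equal(ncol(its311:::design_matrix(d)), 4 + 3)
  # single-neighborhood stratum: dummy block absorbed by the intercept
  one <- d[d$neighborhood == d$neighborhood[1], ]
  attr(one, "adjust_neighborhood") <- TRUE
  expect_equal(ncol(its311:::design_matrix(one)), 4)
  # week 27 must never reach the design
  bad <- panel; bad$week_index[3] <- 27L
  expect_error(build_design(bad, cfg$sites), "transition")
  # missing neighborhood label fails only when adjustment is on
  s2 <- cfg$sites; s2$neighborhood[1] <- ""
  expect_error(build_design(panel, s2), "neighborhood")
  expect_silent(build_design(panel, s2, adjust_neighborhood = FALSE))
})

test_that("constant response recovers its log mean (Poisson limit)", {
  sites <- data.frame(site_id = "A", neighborhood = "N",
                      intervention_type = "new_restroom",
                      start_date = as.Date("2016-07-05"), lon = 0, lat = 0,
                      stringsAsFactors = FALSE)
  panel <- data.frame(site_id = "A", week_index = setdiff(1:53, 27L),
                      period = "pre", week_start = as.Date("2016-01-05"),
                      count = 7L, stringsAsFactors = FALSE)
  d <- build_design(panel, sites, adjust_neighborhood = FALSE)
  expect_warning(f <- fit_nb_glm(d), "Poisson limit")
  expect_equal(unname(f$beta[1] + f$beta[2] * 10 + 0 + 0), log(7),
               tolerance = 1e-6)
  expect_equal(unname(f$beta[["week_t"]]), 0, tolerance = 1e-6)
  expect_identical(f$theta, Inf)
})

test_that("coefficients, theta and robust SEs match the reference GLM", {
  skip_if_not_installed("MASS")
  skip_if_not_installed("sandwich")
  for (seed in 1:5) {
    d <- oracle_design(seed)
    f <- fit_nb_glm(d)
    g <- MASS::glm.nb(
      y ~ week_t + intervention + interaction + factor(neighborhood),
      data = as.data.frame(d),
      control = stats::glm.control(epsilon = 1e-12, maxit = 100))
    expect_equal(unname(f$beta), unname(stats::coef(g)), tolerance = 1e-6)
    expect_equal(f$theta, g$theta, tolerance = 1e-4)
    se_ref <- sqrt(diag(sandwich::sandwich(g)))
    expect_equal(unname(f$se_robust), unname(se_ref), tolerance = 1e-4)
  }
})

test_that("simulated Poisson data reach the Poisson MLE in the theta limit", {
  set.seed(8)
  d <- oracle_design(3, theta = 1e8)
  f <- suppressWarnings(fit_nb_glm(d))
  g <- stats::glm(y ~ week_t + intervention + interaction +
                    factor(neighborhood),
                  family = stats::poisson(), data = as.data.frame(d),
                  control = stats::glm.control(epsilon = 1e-14))
  expect_equal(unname(f$beta), unname(stats::coef(g)), tolerance = 1e-4)
})

test_that("the sandwich meat equals explicit per-row arithmetic", {
  d <- oracle_design(11)
  f <- fit_nb_glm(d)
  X <- f$X; y <- f$y; mu <- f$mu; th <- f$theta
  p <- ncol(X)
  B <- matrix(0, p, p)
  A <- matrix(0, p, p)
  for (i in seq_len(nrow(X))) {
    xi <- X[i, ]
    si <- xi * (y[i] - mu[i]) / (1 + mu[i] / th)
    B <- B + tcrossprod(si)
    A <- A + tcrossprod(xi) * mu[i] / (1 + mu[i] / th)
  }
  V <- solve(A) %*% B %*% solve(A)
  expect_lt(max(abs(V - f$vcov_robust)), 1e-10)
})

test_that("robust SEs agree with model-based SEs on well-specified data", {
  skip_if_not_installed("MASS")
  set.seed(14)
  d <- oracle_design(21, n_sites = 96, theta = 2)   # ~5000 rows
  f <- fit_nb_glm(d)
  g <- MASS::glm.nb(
    y ~ week_t + intervention + interaction + factor(neighborhood),
    data = as.data.frame(d))
  se_model <- sqrt(diag(stats::vcov(g)))
  expect_true(all(abs(f$se_robust / se_model - 1) < 0.10))
})

test_that("duplicating every row roughly halves the sandwich variance", {
  d <- oracle_design(31, n_sites = 20)   # ~1000 rows
  f1 <- fit_nb_glm(d)
  d2 <- rbind(d, d)
  attr(d2, "adjust_neighborhood") <- TRUE
  f2 <- fit_nb_glm(d2)
  ratio <- diag(f2$vcov_robust) / diag(f1$vcov_robust)
  expect_true(all(abs(ratio - 0.5) < 0.05 * 0.5 + 1e-9))
})

test_that("effect accessors expose beta1, beta2, beta3 with 1.96-z CIs", {
  d <- oracle_design(41)
  f <- fit_nb_glm(d)
  expect_equal(pre_slope(f)$estimate, unname(f$beta[["week_t"]]))
  expect_equal(level_change(f)$estimate, unname(f$beta[["intervention"]]))
  expect_equal(slope_change(f)$estimate,
               unname(f$beta[["week_t:intervention"]]))
  sc <- slope_change(f)
  expect_equal(sc$ci, sc$estimate + c(-1.96, 1.96) * sc$se)
  ps <- post_slope(f)
  expect_equal(ps$estimate, pre_slope(f)$estimate + sc$estimate)
})

test_that("neighborhood reference recoding leaves the ITS terms unchanged", {
  d <- oracle_design(51)
  f1 <- fit_nb_glm(d)
  d2 <- d
  # relabel so the alphabetical reference level flips from A to B
  d2$neighborhood <- ifelse(d$neighborhood == "A", "zA", "B")
  attr(d2, "adjust_neighborhood") <- TRUE
  f2 <- fit_nb_glm(d2)
  keep <- c("(Intercept)", "week_t", "intervention", "week_t:intervention")
  expect_equal(f1$beta[keep][-1], f2$beta[keep][-1], tolerance = 1e-8)
  # intercept shifts by the (negated) contrast; main effects invariant
  expect_equal(unname(f1$beta["week_t:intervention"]),
               unname(f2$beta["week_t:intervention"]), tolerance = 1e-8)
})

test_that("the outer profile iterations never decrease the log-likelihood", {
  for (seed in c(3, 23)) {
    f <- fit_nb_glm(oracle_design(seed))
    expect_true(all(diff(f$ll_trace) > -1e-6))
  }
})

test_that("degenerate inputs fail with informative errors", {
  d <- oracle_design(61)
  d0 <- d; d0$y <- 0
  expect_error(fit_nb_glm(d0), "all-zero")
  dneg <- d; dneg$y[1] <- -1
  expect_error(fit_nb_glm(dneg), "non-negative")
  dcol <- d; dcol$interaction <- dcol$week_t   # collinear with week_t
  expect_error(fit_nb_glm(dcol), "collinear|rank")
})

test_that("slope-change recovery is unbiased with calibrated CI coverage", {
  # scaled-down recovery check; the full 200-replicate version runs in
  # the acceptance suite
  cfg <- synth_config(seed = 0)
  est <- se <- numeric(50)
  for (r in 1:50) {
    cfg$seed <- 1000L + r
    d <- build_design(latent_to_panel(simulate_panel(cfg)), cfg$sites)
    f <- quiet_fit(d)
    sc <- slope_change(f)
    est[r] <- sc$estimate; se[r] <- sc$se
  }
  expect_lt(abs(mean(est) - (-0.024)), 3 * sd(est) / sqrt(50))
  cover <- mean(abs(est - (-0.024)) <= 1.96 * se)
  expect_gte(cover, 0.85)
})
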