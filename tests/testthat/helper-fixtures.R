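# Shared fixture builders; everything is generated in code at test time.

# A latent panel turned into the analysis panel shape (week 27 dropped),
# bypassing the spatial pipeline when only the model layer is under test.
latent_to_panel <- function(panel) {
  p <- panel[panel$week_index != 27L, , drop = FALSE]
  p$period <- ifelse(p$week_index <= 26L, "pre", "post")
  p <- p[order(p$site_id, p$week_index),
         c("site_id", "week_index", "period", "week_start", "count")]
  rownames(p) <- NULL
  p
}

# Small paper-structure generator config for quick end-to-end runs.
quick_config <- function(n_sites = 3, seed = 1, ...) {
  synth_config(n_sites = n_sites, beta0 = log(8), seed = seed, ...)
}

# Fit while silencing the equi-dispersion fallback warning, which is
# expected on small Poisson-like fixtures.
quiet_fit <- function(design) suppressWarnings(fit_nb_glm(design))

# A deterministic synthetic design for NB fitter oracle checks.
oracle_design <- function(seed, n_sites = 4, theta = 2,
                          beta = c(2, 0.01, -0.2, -0.02)) {
  set.seed(seed)
  nb <- c("A", "B")[(seq_len(n_sites) - 1L) %% 2L + 1L]
  rows <- expand.grid(site = seq_len(n_sites),
                      week_t = setdiff(1:53, 27L))
  rows$intervention <- as.numeric(rows$week_t >= 28)
  rows$interaction <- rows$week_t * rows$intervention
  rows$neighborhood <- nb[rows$site]
  eta <- beta[1] + beta[2] * rows$week_t + beta[3] * rows$intervention +
    beta[4] * rows$interaction + 0.3 * (rows$neighborhood == "B")
  rows$y <- rnbinom(nrow(rows), size = theta, mu = exp(eta))
  d <- data.frame(site_id = paste0("S", rows$site), week_t = rows$week_t,
                  intervention = rows$intervention,
                  interaction = rows$interaction,
                  neighborhood = rows$neighborhood, y = rows$y,
                  stringsAsFactors = FALSE)
  attr(d, "adjust_neighborhood") <- TRUE
  d
}
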