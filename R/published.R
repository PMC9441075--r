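#' Published pre/post summary statistics for the San Francisco Pit Stop
#' program
#'
#' The printed stratum-level summaries from the published San Francisco
#' Pit Stop restroom evaluation (2014--2020): per intervention type and
#' per neighborhood, the number of interventions, pooled pre- and
#' post-period mean weekly exposed-feces reports with SDs, the printed
#' difference in means and permutation p-value.  Shipped so the
#' package's bookkeeping (difference-in-means arithmetic, weeks-observed
#' conventions) can be checked against a real study's printed numbers
#' without any download; the underlying report-level data are not
#' redistributed here.
#'
#' @return data frame with columns \code{block}, \code{stratum},
#'   \code{n_interventions}, \code{pre_mean}, \code{pre_sd},
#'   \code{post_mean}, \code{post_sd}, \code{delta_printed},
#'   \code{p_printed}.
#' @examples
#' s <- sf_pitstop_summary()
#' s$post_mean - s$pre_mean  # recomputes the printed deltas
#' @export
sf_pitstop_summary <- function() {
  utils::read.csv(system.file("extdata", "sf_pitstop_published_summary.csv",
                              package = "its311", mustWork = TRUE),
                  stringsAsFactors = FALSE, check.names = TRUE)
}
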