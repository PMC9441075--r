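site1 <- data.frame(site_id = "S01", name = "s", neighborhood = "A",
                    intervention_type = "new_restroom",
                    start_date = as.Date("2016-07-05"),
                    lon = -122.41, lat = 37.78, stringsAsFactors = FALSE)

test_that("geodesic circle buffer contains its center and defaults to 500 m", {
  b <- build_buffer(site1)
  expect_equal(b$radius_m, 500)
  expect_equal(b$method, "geodesic_circle")
  expect_gte(nrow(b$ring), 64)
  expect_true(point_in_buffer(site1$lon, site1$lat, b))
})

test_that("containment agrees with the direct geodesic-distance oracle", {
  b <- build_buffer(site1)
  for (bearing in c(0, 45, 137, 270)) {
    p_in <- geosphere::destPoint(c(site1$lon, site1$lat), bearing, 499)
    p_out <- geosphere::destPoint(c(site1$lon, site1$lat), bearing, 501)
    p_edge <- geosphere::destPoint(c(site1$lon, site1$lat), bearing, 500)
    expect_true(point_in_buffer(p_in[1], p_in[2], b))
    expect_false(point_in_buffer(p_out[1], p_out[2], b))
    expect_true(point_in_buffer(p_edge[1], p_edge[2], b))  # boundary inside
  }
})

test_that("user polygons are used verbatim with boundary-inclusive ray casting", {
  # 1 km square around the site (closed ring, as GeoJSON would carry it)
  sq <- rbind(c(-122.416, 37.775), c(-122.404, 37.775),
              c(-122.404, 37.785), c(-122.416, 37.785),
              c(-122.416, 37.775))
  b <- build_buffer(site1, polygon_override = sq)
  expect_equal(b$method, "user_polygon")
  expect_true(is.na(b$radius_m))
  expect_equal(nrow(b$ring), 4)  # closing vertex dropped internally
  expect_true(point_in_buffer(-122.41, 37.78, b))
  expect_false(point_in_buffer(-122.40, 37.78, b))
  # a vertex and an edge midpoint count as inside
  expect_true(point_in_buffer(-122.416, 37.775, b))
  expect_true(point_in_buffer(-122.410, 37.775, b))
  # just outside an edge does not
  expect_false(point_in_buffer(-122.410, 37.7749, b))
})

test_that("an override polygon must contain the site", {
  far <- rbind(c(-122.30, 37.70), c(-122.29, 37.70), c(-122.29, 37.71),
               c(-122.30, 37.71))
  expect_error(build_buffer(site1, polygon_override = far),
               "does not contain site")
})

test_that("matching equals brute-force all-pairs on a 200-report fixture", {
  cfg <- synth_config(n_sites = 5, seed = 13,
                      lon = -122.45 + 0.006 * (0:4),  # overlapping buffers
                      lat = 37.75)
  set.seed(99)
  n <- 200
  reports <- data.frame(
    report_id = sprintf("R%03d", 1:n),
    opened_at = as.POSIXct("2016-07-05", tz = "UTC") +
      runif(n, -27 * 7 * 86400, 28 * 7 * 86400),
    lon = runif(n, -122.47, -122.40), lat = runif(n, 37.74, 37.76),
    stringsAsFactors = FALSE
  )
  buffers <- build_buffers(cfg$sites)
  got <- match_reports(reports, cfg$sites, buffers)

  # oracle: exhaustive double loop, geodesic distance + raw time window
  oracle <- list()
  for (i in seq_len(nrow(cfg$sites))) {
    t0 <- as.POSIXct("2016-07-05", tz = "UTC")
    for (r in seq_len(n)) {
      d <- geosphere::distGeo(c(reports$lon[r], reports$lat[r]),
                              c(cfg$sites$lon[i], cfg$sites$lat[i]))
      in_t <- reports$opened_at[r] >= t0 - 26 * 7 * 86400 &&
        reports$opened_at[r] < t0 + 27 * 7 * 86400
      if (d <= 500 && in_t)
        oracle[[length(oracle) + 1L]] <-
          data.frame(report_id = reports$report_id[r],
                     site_id = cfg$sites$site_id[i],
                     stringsAsFactors = FALSE)
    }
  }
  oracle <- do.call(rbind, oracle)
  oracle <- oracle[order(oracle$site_id, oracle$report_id), ]
  expect_equal(got[, c("report_id", "site_id")], oracle,
               ignore_attr = TRUE)
  # multi-match conservation: per-site matches >= distinct matched reports
  expect_gte(nrow(got), length(unique(got$report_id)))
  expect_true(any(got$multi_matched))  # buffers overlap by construction
})

test_that("matching is independent of report ordering", {
  cfg <- quick_config(seed = 17)
  out <- materialize_reports(simulate_panel(cfg), cfg)
  buffers <- build_buffers(cfg$sites)
  m1 <- match_reports(out$reports, cfg$sites, buffers)
  shuffled <- out$reports[sample(nrow(out$reports)), ]
  m2 <- match_reports(shuffled, cfg$sites, buffers)
  rownames(m2) <- NULL
  expect_equal(m1, m2, ignore_attr = TRUE)
})

test_that("temporal window is half-open around the 53-week span", {
  b <- build_buffers(site1)
  t0 <- as.POSIXct("2016-07-05", tz = "UTC")
  mk <- function(ts) data.frame(report_id = "R1", opened_at = ts,
                                lon = site1$lon, lat = site1$lat,
                                stringsAsFactors = FALSE)
  inside_start <- match_reports(mk(t0 - 26 * 7 * 86400), site1, b)
  expect_equal(nrow(inside_start), 1L)
  before_start <- match_reports(mk(t0 - 26 * 7 * 86400 - 1), site1, b)
  expect_equal(nrow(before_start), 0L)
  at_end <- match_reports(mk(t0 + 27 * 7 * 86400), site1, b)
  expect_equal(nrow(at_end), 0L)
  # 3 days after T0: matched now, lands in transition week 27
  just_after <- match_reports(mk(t0 + 3 * 86400), site1, b)
  expect_equal(nrow(just_after), 1L)
  expect_equal(assign_week(t0 + 3 * 86400, "2016-07-05"), 27L)
})

test_that("reports far from every site go unmatched and are counted", {
  b <- build_buffers(site1)
  far <- data.frame(report_id = "R1",
                    opened_at = as.POSIXct("2016-07-10", tz = "UTC"),
                    lon = -122.30, lat = 37.70, stringsAsFactors = FALSE)
  m <- match_reports(far, site1, b)
  expect_equal(nrow(m), 0L)
  expect_equal(attr(m, "n_unmatched"), 1L)
})

test_that("buffers survive a GeoJSON round trip as user polygons", {
  b <- build_buffer(site1)
  path <- tempfile(fileext = ".geojson")
  write_buffers_geojson(list(S01 = b), path)
  rings <- read_buffers_geojson(path)
  expect_named(rings, "S01")
  b2 <- build_buffer(site1, polygon_override = rings$S01)
  expect_equal(b2$ring, b$ring, tolerance = 1e-12, ignore_attr = TRUE)
})
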