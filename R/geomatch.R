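#' Build a buffer polygon around an intervention site
#'
#' By default constructs a geodesic circle of radius \code{radius_m}
#' (WGS84 ellipsoid).  Containment tests against a circle buffer use the
#' exact geodesic distance to the center, so there is no discretization
#' error; the polygon ring (\code{n_vertices} vertices placed by direct
#' geodesic projection at equally spaced bearings, boundary within
#' \eqn{r(1 - \cos(\pi/n))}, < 1 m at 64 vertices and r = 500 m) is kept
#' for GeoJSON export and mapping.  A user-supplied polygon (for example
#' an externally computed walking-network buffer) overrides the circle
#' and is used verbatim with ray-casting containment.
#'
#' @param site one-row site data frame (\code{site_id}, \code{lon},
#'   \code{lat}).
#' @param radius_m geodesic radius in meters (default 500).
#' @param polygon_override optional two-column matrix (lon, lat) of ring
#'   vertices (open or closed); must contain the site point.
#' @param n_vertices number of circle vertices (>= 64 recommended).
#' @return object of class \code{"buffer"}: list with \code{site_id},
#'   \code{ring} (open lon/lat matrix), \code{method}
#'   (\code{"geodesic_circle"} or \code{"user_polygon"}), \code{radius_m}
#'   (NA for user polygons).
#' @examples
#' s <- data.frame(site_id = "S01", lon = -122.41, lat = 37.78)
#' b <- build_buffer(s)
#' point_in_buffer(-122.41, 37.78, b)
#' @export
build_buffer <- function(site, radius_m = 500, polygon_override = NULL,
                         n_vertices = 64) {
  stopifnot(nrow(site) == 1L)
  if (!is.null(polygon_override)) {
    ring <- as.matrix(polygon_override)
    if (ncol(ring) != 2L) stop("polygon_override must have two columns (lon, lat)")
    if (nrow(ring) > 1 && all(ring[1, ] == ring[nrow(ring), ]))
      ring <- ring[-nrow(ring), , drop = FALSE]
    colnames(ring) <- c("lon", "lat")
    b <- structure(list(site_id = site$site_id, ring = ring,
                        center = c(lon = site$lon, lat = site$lat),
                        method = "user_polygon", radius_m = NA_real_),
                   class = "buffer")
    if (!point_in_buffer(site$lon, site$lat, b))
      stop("override polygon does not contain site ", site$site_id)
    return(b)
  }
  if (radius_m <= 0) stop("radius_m must be > 0")
  bearings <- seq(0, 360, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  ring <- geosphere::destPoint(c(site$lon, site$lat), b = bearings,
                               d = radius_m)
  colnames(ring) <- c("lon", "lat")
  structure(list(site_id = site$site_id, ring = ring,
                 center = c(lon = site$lon, lat = site$lat),
                 method = "geodesic_circle", radius_m = radius_m),
            class = "buffer")
}

#' @export
print.buffer <- function(x, ...) {
  cat(sprintf("Buffer for site %s: %s, %d vertices%s\n", x$site_id,
              x$method, nrow(x$ring),
              if (!is.na(x$radius_m)) sprintf(", radius %g m", x$radius_m) else ""))
  invisible(x)
}

#' Build buffers for every site
#'
#' @param sites site data frame.
#' @param radius_m geodesic radius in meters.
#' @param polygon_overrides optional named list (by \code{site_id}) of
#'   override rings, e.g. from \code{\link{read_buffers_geojson}}.
#' @param n_vertices circle vertices.
#' @return named list of \code{\link{build_buffer}} objects.
#' @export
build_buffers <- function(sites, radius_m = 500, polygon_overrides = NULL,
                          n_vertices = 64) {
  out <- lapply(seq_len(nrow(sites)), function(i) {
    ov <- polygon_overrides[[sites$site_id[i]]]
    build_buffer(sites[i, , drop = FALSE], radius_m = radius_m,
                 polygon_override = ov, n_vertices = n_vertices)
  })
  names(out) <- sites$site_id
  out
}

#' Test points against a buffer
#'
#' Geodesic-circle buffers use the exact WGS84 geodesic distance to the
#' site center (inside iff distance <= radius).  User polygons use
#' even-odd (ray casting) containment in lon/lat coordinates, valid for
#' the small, pole- and antimeridian-free polygons this pipeline uses.
#' Points exactly on the boundary count as inside in both cases.
#'
#' @param lon,lat numeric vectors of point coordinates (degrees).
#' @param buffer a \code{\link{build_buffer}} object.
#' @return logical vector.
#' @export
point_in_buffer <- function(lon, lat, buffer) {
  if (buffer$method == "geodesic_circle") {
    d <- geosphere::distGeo(cbind(lon, lat),
                            c(buffer$center[["lon"]], buffer$center[["lat"]]))
    d <= buffer$radius_m + 1e-9
  } else {
    ring_contains(lon, lat, buffer$ring)
  }
}

# Vectorized over points; loops over the polygon's edges (few dozen).
# Boundary inclusion: a point on an edge segment (collinear within a
# ~1e-9 degree cross-product tolerance and inside the segment's bounding
# box) is inside regardless of the crossing parity.
ring_contains <- function(px, py, ring) {
  n <- nrow(ring)
  inside <- rep(FALSE, length(px))
  boundary <- rep(FALSE, length(px))
  xs <- ring[, 1]; ys <- ring[, 2]
  j <- n
  for (i in seq_len(n)) {
    xi <- xs[i]; yi <- ys[i]; xj <- xs[j]; yj <- ys[j]
    # on-segment test
    cross <- (px - xi) * (yj - yi) - (py - yi) * (xj - xi)
    within <- px >= pmin(xi, xj) - 1e-12 & px <= pmax(xi, xj) + 1e-12 &
      py >= pmin(yi, yj) - 1e-12 & py <= pmax(yi, yj) + 1e-12
    boundary <- boundary | (abs(cross) < 1e-9 & within)
    # even-odd crossing
    crosses <- (yi > py) != (yj > py)
    if (any(crosses)) {
      xint <- xi + (py - yi) * (xj - xi) / (yj - yi)
      flip <- crosses & px < xint
      inside <- xor(inside, flip)
    }
    j <- i
  }
  inside | boundary
}

#' Spatio-temporally match reports to intervention sites
#'
#' A report matches a site iff it falls inside the site's buffer polygon
#' and its timestamp lies in the site's 53-week observation span
#' \code{[T0 - 26*7 days, T0 + 27*7 days)}, half-open and anchored at
#' midnight (UTC) of the start date \code{T0}.  The transition week
#' (week 27, which begins at \code{T0}) is matched here and removed later
#' by \code{\link{build_panel}}.  A report inside several overlapping
#' buffers yields one match per site, flagged \code{multi_matched}.
#'
#' A longitude/latitude bounding-box prefilter (ring extent padded by a
#' generous margin) skips the containment test for reports far from a
#' site; it is conservative, so results equal exhaustive all-pairs
#' matching.
#'
#' @param reports record data frame (needs \code{report_id},
#'   \code{opened_at} as POSIXct, \code{lon}, \code{lat}).
#' @param sites site data frame with \code{start_date}.
#' @param buffers named list from \code{\link{build_buffers}}; must cover
#'   every site.
#' @param window_weeks weeks on each side of the transition week
#'   (default 26, i.e. six months).
#' @return data frame of matches (\code{report_id}, \code{site_id},
#'   \code{opened_at}, \code{multi_matched}), ordered by site then
#'   report id, with the number of unmatched reports in attribute
#'   \code{"n_unmatched"}.
#' @export
match_reports <- function(reports, sites, buffers, window_weeks = 26) {
  miss <- setdiff(sites$site_id, names(buffers))
  if (length(miss))
    stop("no buffer for site(s): ", paste(miss, collapse = ", "))
  out <- vector("list", nrow(sites))
  for (i in seq_len(nrow(sites))) {
    sid <- sites$site_id[i]
    t0 <- as.POSIXct(format(as.Date(sites$start_date[i])), tz = "UTC")
    lo <- t0 - window_weeks * 7 * 86400
    hi <- t0 + (window_weeks + 1) * 7 * 86400
    buf <- buffers[[sid]]
    ring <- buf$ring
    pad <- 1e-3  # degrees, ~100 m: covers circle-vs-inscribed-ring slack
    in_time <- reports$opened_at >= lo & reports$opened_at < hi
    in_box <- reports$lon >= min(ring[, 1]) - pad &
      reports$lon <= max(ring[, 1]) + pad &
      reports$lat >= min(ring[, 2]) - pad &
      reports$lat <= max(ring[, 2]) + pad
    cand <- which(in_time & in_box)
    if (!length(cand)) next
    hit <- cand[point_in_buffer(reports$lon[cand], reports$lat[cand], buf)]
    if (!length(hit)) next
    out[[i]] <- data.frame(report_id = reports$report_id[hit],
                           site_id = sid,
                           opened_at = reports$opened_at[hit],
                           stringsAsFactors = FALSE)
  }
  matched <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(matched))
    matched <- data.frame(report_id = character(), site_id = character(),
                          opened_at = as.POSIXct(character(), tz = "UTC"),
                          stringsAsFactors = FALSE)
  dupes <- matched$report_id[duplicated(matched$report_id)]
  matched$multi_matched <- matched$report_id %in% dupes
  matched <- matched[order(matched$site_id, matched$report_id), , drop = FALSE]
  rownames(matched) <- NULL
  attr(matched, "n_unmatched") <-
    sum(!(reports$report_id %in% matched$report_id))
  matched
}
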