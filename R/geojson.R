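# GeoJSON I/O (RFC 7946: WGS84, lon/lat order).  Assembled directly with
# jsonlite; only Point and Polygon features are needed by this pipeline.

#' Write intervention sites as a GeoJSON FeatureCollection of points
#'
#' @param sites site data frame (\code{site_id}, \code{name},
#'   \code{neighborhood}, \code{intervention_type}, \code{start_date},
#'   \code{lon}, \code{lat}).
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_sites_geojson <- function(sites, path) {
  feats <- lapply(seq_len(nrow(sites)), function(i) {
    list(
      type = "Feature",
      geometry = list(type = "Point",
                      coordinates = c(sites$lon[i], sites$lat[i])),
      properties = list(
        site_id = sites$site_id[i],
        name = sites$name[i],
        neighborhood = sites$neighborhood[i],
        intervention_type = sites$intervention_type[i],
        start_date = format(as.Date(sites$start_date[i]))
      )
    )
  })
  fc <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an intervention-site table from CSV or GeoJSON
#'
#' CSV needs columns \code{site_id}, \code{neighborhood},
#' \code{intervention_type}, \code{start_date}, \code{lon}, \code{lat}
#' (\code{name} optional).  GeoJSON must be a FeatureCollection of Point
#' features carrying the same properties.
#'
#' @param path file path; format inferred from the extension
#'   (\code{.geojson}/\code{.json} vs anything else as CSV).
#' @return data frame of sites with \code{start_date} as \code{Date}.
#' @export
read_sites <- function(path) {
  if (!file.exists(path)) stop("site file not found: ", path)
  if (grepl("\\.(geojson|json)$", path, ignore.case = TRUE)) {
    fc <- jsonlite::read_json(path)
    if (!identical(fc$type, "FeatureCollection"))
      stop("expected a GeoJSON FeatureCollection in ", path)
    rows <- lapply(fc$features, function(f) {
      co <- unlist(f$geometry$coordinates)
      p <- f$properties
      data.frame(site_id = as.character(p$site_id),
                 name = as.character(p$name %||% p$site_id),
                 neighborhood = as.character(p$neighborhood),
                 intervention_type = as.character(p$intervention_type),
                 start_date = as.Date(p$start_date),
                 lon = co[1], lat = co[2], stringsAsFactors = FALSE)
    })
    sites <- do.call(rbind, rows)
  } else {
    sites <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("site_id", "neighborhood", "intervention_type",
              "start_date", "lon", "lat")
    miss <- setdiff(need, names(sites))
    if (length(miss))
      stop("site table missing column(s): ", paste(miss, collapse = ", "))
    if (is.null(sites$name)) sites$name <- sites$site_id
    sites$start_date <- as.Date(sites$start_date)
  }
  if (any(abs(sites$lat) > 90) || any(abs(sites$lon) > 180))
    stop("site coordinates outside WGS84 bounds")
  rownames(sites) <- NULL
  sites
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write buffers as a GeoJSON FeatureCollection of polygons
#'
#' @param buffers a list of \code{\link{build_buffer}} objects or the
#'   result of \code{\link{build_buffers}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_buffers_geojson <- function(buffers, path) {
  if (inherits(buffers, "buffer")) buffers <- list(buffers)
  feats <- lapply(buffers, function(b) {
    ring <- rbind(b$ring, b$ring[1, , drop = FALSE])  # close the ring
    list(
      type = "Feature",
      geometry = list(type = "Polygon",
                      coordinates = list(lapply(seq_len(nrow(ring)), function(i)
                        c(ring[i, 1], ring[i, 2])))),
      properties = list(site_id = b$site_id, method = b$method,
                        radius_m = b$radius_m)
    )
  })
  fc <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read per-site buffer polygons from GeoJSON
#'
#' Used to supply externally computed polygons (for example
#' walking-network buffers) keyed by the \code{site_id} property.
#'
#' @param path GeoJSON FeatureCollection of Polygon features.
#' @return named list of two-column matrices (lon, lat), one open ring
#'   per \code{site_id}.
#' @export
read_buffers_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  if (!identical(fc$type, "FeatureCollection"))
    stop("expected a GeoJSON FeatureCollection in ", path)
  out <- list()
  for (f in fc$features) {
    if (!identical(f$geometry$type, "Polygon"))
      stop("buffer features must be Polygon geometries")
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]],
                                  function(v) unlist(v)[1:2]))
    # drop the closing vertex; rings are stored open internally
    if (nrow(ring) > 1 && all(ring[1, ] == ring[nrow(ring), ]))
      ring <- ring[-nrow(ring), , drop = FALSE]
    colnames(ring) <- c("lon", "lat")
    out[[as.character(f$properties$site_id)]] <- ring
  }
  out
}
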