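EARTH_RADIUS_KM <- 6371.0088

check_coords <- function(lat, lon) {
  if (any(!is.finite(lat)) || any(!is.finite(lon)) ||
      any(lat < -90) || any(lat > 90) || any(lon < -180) || any(lon > 180)) {
    stop_invalid("coordinates out of range: lat in [-90, 90], lon in [-180, 180]")
  }
}

#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of mean radius 6371.0088 km.
#' Vectorized over all four arguments.
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees.
#' @return numeric distance(s) in km.
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  check_coords(lat1, lon1)
  check_coords(lat2, lon2)
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = EARTH_RADIUS_KM * 1000) / 1000
}

#' Nearest facility for a single woman
#'
#' Returns the facility minimizing [haversine_km()] to the woman's
#' location. Exact ties are broken by the lexicographically lowest
#' `facility_id`, so the assignment does not depend on input order.
#'
#' @param woman one-row data.frame (or list) with `lat`, `lon` and
#'   optionally `woman_id`, `wave`.
#' @param facilities data.frame with `facility_id`, `lat`, `lon`.
#' @return one-row data.frame: `woman_id`, `facility_id`, `distance_km`,
#'   `wave`.
#' @export
nearest_facility <- function(woman, facilities) {
  if (is.null(facilities) || nrow(facilities) == 0) {
    stop_invalid("facilities must be non-empty")
  }
  d <- haversine_km(woman$lat, woman$lon, facilities$lat, facilities$lon)
  k <- order(d, facilities$facility_id)[1L]
  data.frame(
    woman_id = if (!is.null(woman$woman_id)) woman$woman_id else NA_character_,
    facility_id = facilities$facility_id[k],
    distance_km = d[k],
    wave = if (!is.null(woman$wave)) as.integer(woman$wave) else NA_integer_,
    stringsAsFactors = FALSE
  )
}

#' Link every woman to her nearest facility
#'
#' Computes the full catchment assignment: one linked record per woman,
#' each to the facility minimizing great-circle distance (ties broken by
#' lowest `facility_id`). Women are processed in blocks so the distance
#' matrix stays small. By default there is no maximum-distance cutoff
#' (women are assumed obliged to use their catchment facility); an
#' optional `max_distance_km` drops implausible links, with the count
#' logged.
#'
#' @param women data.frame with `woman_id`, `lat`, `lon`, `wave`.
#' @param facilities data.frame with `facility_id`, `lat`, `lon`.
#' @param max_distance_km optional cutoff; links beyond it are dropped.
#' @param block_size number of women per distance-matrix block.
#' @return data.frame of links (`woman_id`, `facility_id`, `distance_km`,
#'   `wave`) with a `summary` attribute: median and max distance and the
#'   distribution of women per facility.
#' @export
link_cohort <- function(women, facilities, max_distance_km = NULL,
                        block_size = 2000L) {
  if (is.null(facilities) || nrow(facilities) == 0) {
    stop_invalid("facilities must be non-empty")
  }
  assert_cols(facilities, c("facility_id", "lat", "lon"), "facilities")
  if (nrow(women) == 0) {
    links <- data.frame(woman_id = character(), facility_id = character(),
                        distance_km = numeric(), wave = integer(),
                        stringsAsFactors = FALSE)
    attr(links, "summary") <- list(n_women = 0L, n_linked = 0L, n_dropped = 0L,
                                   median_km = NA_real_, max_km = NA_real_,
                                   per_facility = integer())
    return(links)
  }
  assert_cols(women, c("woman_id", "lat", "lon", "wave"), "women")
  check_coords(women$lat, women$lon)
  check_coords(facilities$lat, facilities$lon)
  # order facilities by id once so which.min tie-breaks to the lowest id
  fac <- facilities[order(facilities$facility_id), , drop = FALSE]
  n <- nrow(women)
  idx <- integer(n)
  dist <- numeric(n)
  starts <- seq(1L, n, by = block_size)
  for (s in starts) {
    e <- min(s + block_size - 1L, n)
    D <- outer_haversine(women$lat[s:e], women$lon[s:e], fac$lat, fac$lon)
    idx[s:e] <- max.col(-D, ties.method = "first")
    dist[s:e] <- D[cbind(seq_len(e - s + 1L), idx[s:e])]
  }
  links <- data.frame(woman_id = women$woman_id,
                      facility_id = fac$facility_id[idx],
                      distance_km = dist,
                      wave = as.integer(women$wave),
                      stringsAsFactors = FALSE)
  n_dropped <- 0L
  if (!is.null(max_distance_km)) {
    keep <- links$distance_km <= max_distance_km
    n_dropped <- sum(!keep)
    if (n_dropped > 0) {
      fd_log("link_cohort: dropped %d of %d links beyond %.1f km",
             n_dropped, n, max_distance_km)
    }
    links <- links[keep, , drop = FALSE]
    rownames(links) <- NULL
  }
  attr(links, "summary") <- list(
    n_women = n, n_linked = nrow(links), n_dropped = n_dropped,
    median_km = stats::median(links$distance_km),
    max_km = if (nrow(links)) max(links$distance_km) else NA_real_,
    per_facility = table(links$facility_id)
  )
  links
}

# all-pairs haversine, rows = first set, cols = second set
outer_haversine <- function(lat1, lon1, lat2, lon2) {
  rad <- pi / 180
  la1 <- lat1 * rad; lo1 <- lon1 * rad
  la2 <- lat2 * rad; lo2 <- lon2 * rad
  dlat <- outer(la1, la2, function(a, b) (b - a) / 2)
  dlon <- outer(lo1, lo2, function(a, b) (b - a) / 2)
  a <- sin(dlat)^2 + outer(cos(la1), cos(la2)) * sin(dlon)^2
  d <- 2 * EARTH_RADIUS_KM * asin(pmin(sqrt(a), 1))
  dim(d) <- dim(a)
  d
}
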