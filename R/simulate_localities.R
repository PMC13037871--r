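#' Scenario for simulating dated locality tables
#'
#' One row per 10-ky time slice, describing how many localities to draw
#' and how their longitudes are distributed: either uniform on
#' `lon_center +/- lon_width/2` (when `n_clusters = 0`) or a Gaussian
#' mixture of `n_clusters` clusters (centres uniform within the width,
#' spread `cluster_sd` degrees). Latitudes are uniform on
#' `[lat_min, lat_max]`; date-range widths are uniform on
#' `[0, range_max_ky]` centred within the slice.
#'
#' @param slice_start_ka,slice_end_ka slice bounds, ka BP (start > end).
#' @param n localities per slice.
#' @param lon_center,lon_width longitude distribution centre and full
#'   width, degrees.
#' @param n_clusters number of Gaussian clusters (0 = uniform).
#' @param cluster_sd cluster spread, degrees.
#' @param lat_min,lat_max latitude band, degrees.
#' @param range_max_ky maximum date-range width, ky.
#' @return A `data.frame` of class `spread_scenario`.
#' @export
spread_scenario <- function(slice_start_ka, slice_end_ka, n,
                            lon_center = 10, lon_width = 40,
                            n_clusters = 0, cluster_sd = 2,
                            lat_min = 36, lat_max = 52,
                            range_max_ky = 8) {
  sc <- data.frame(slice_start_ka, slice_end_ka, n,
                   lon_center, lon_width, n_clusters, cluster_sd,
                   lat_min, lat_max, range_max_ky)
  if (any(sc$n < 0)) stop_invalid("locality counts must be >= 0")
  if (any(sc$lon_width <= 0)) stop_invalid("'lon_width' must be positive")
  if (any(sc$slice_start_ka <= sc$slice_end_ka))
    stop_invalid("'slice_start_ka' must exceed 'slice_end_ka'")
  class(sc) <- c("spread_scenario", "data.frame")
  sc
}

#' Simulate a dated-locality table
#'
#' Draws archaeological-locality records according to a
#' [spread_scenario()]: per-slice counts are honoured exactly and
#' longitudes are bounded by the stated widths. Output matches the
#' locality CSV schema `site_id, longitude, latitude, date_min_ka,
#' date_max_ka` consumed by [filter_and_slice()] and friends.
#'
#' @param scenario a [spread_scenario()].
#' @param seed optional RNG seed.
#' @return `data.frame` with columns `site_id`, `longitude`, `latitude`,
#'   `date_min_ka`, `date_max_ka`, and `slice` (the generating slice
#'   label, for truth bookkeeping).
#' @examples
#' sc <- spread_scenario(c(80, 70), c(70, 60), n = c(30, 40),
#'                       lon_width = c(30, 45))
#' loc <- simulate_localities(sc, seed = 1)
#' table(loc$slice)
#' @export
simulate_localities <- function(scenario, seed = NULL) {
  stopifnot(inherits(scenario, "spread_scenario"))
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(scenario)), function(i) {
      s <- scenario[i, ]
      if (s$n == 0) return(NULL)
      if (s$n_clusters > 0) {
        centers <- stats::runif(s$n_clusters, s$lon_center - s$lon_width / 2,
                                s$lon_center + s$lon_width / 2)
        lon <- stats::rnorm(s$n, sample(centers, s$n, replace = TRUE),
                            s$cluster_sd)
        lon <- pmin(pmax(lon, s$lon_center - s$lon_width / 2),
                    s$lon_center + s$lon_width / 2)
      } else {
        lon <- stats::runif(s$n, s$lon_center - s$lon_width / 2,
                            s$lon_center + s$lon_width / 2)
      }
      lat <- stats::runif(s$n, s$lat_min, s$lat_max)
      mid <- stats::runif(s$n, s$slice_end_ka, s$slice_start_ka)
      half <- stats::runif(s$n, 0, s$range_max_ky) / 2
      data.frame(
        site_id = sprintf("s%02d_%04d", i, seq_len(s$n)),
        longitude = lon, latitude = lat,
        date_min_ka = pmax(mid - half, 0),
        date_max_ka = mid + half,
        slice = sprintf("%g-%g", s$slice_start_ka, s$slice_end_ka),
        stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Write a locality table as CSV
#'
#' Writes the standard locality schema (without the simulation-truth
#' `slice` column) deterministically, so identical tables give identical
#' bytes.
#'
#' @param localities locality `data.frame`.
#' @param path output file.
#' @export
write_localities <- function(localities, path) {
  cols <- c("site_id", "longitude", "latitude", "date_min_ka", "date_max_ka")
  utils::write.csv(localities[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a locality table CSV
#' @param path CSV file with columns `site_id, longitude, latitude,
#'   date_min_ka, date_max_ka`.
#' @return locality `data.frame`.
#' @export
read_localities <- function(path) {
  loc <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site_id", "longitude", "latitude", "date_min_ka", "date_max_ka")
  if (!all(need %in% names(loc)))
    stop_invalid("locality CSV must have columns: ", paste(need, collapse = ", "))
  loc
}
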