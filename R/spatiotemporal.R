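# Time-sliced spatial analysis of dated localities: range filtering and
# slicing, kernel density, Getis-Ord Gi* hotspots with structured
# permutation tests, and rarefaction of longitudinal spread.

#' Filter dated localities and assign them to time slices
#'
#' Records whose date range exceeds `max_range_ky` are excluded (too
#' poorly dated to place in a window). A record is assigned to every
#' `window_ky`-wide slice its date range overlaps: a slice labelled
#' `start-end` (ka BP, `start > end`) contains a record when
#' `date_max > end` and `date_min <= start`, so a point date of 65 ka
#' falls in the 70-60 slice only. Midpoint assignment (each record in the
#' single slice containing its date midpoint) is available for
#' sensitivity analysis.
#'
#' @param records locality `data.frame` (`site_id`, `longitude`,
#'   `latitude`, `date_min_ka`, `date_max_ka`).
#' @param max_range_ky maximum date-range width in ky (default 30).
#' @param window_ky slice width in ky (default 10); slices are anchored
#'   at integer multiples of `window_ky`.
#' @param assignment `"overlap"` (default) or `"midpoint"`.
#' @return `data.frame` with one row per (record, slice) membership:
#'   the record columns plus `slice`, `slice_start_ka`, `slice_end_ka`.
#'   Attribute `excluded` lists records dropped by the range filter.
#' @examples
#' rec <- data.frame(site_id = "a", longitude = 5, latitude = 45,
#'                   date_min_ka = 55, date_max_ka = 75)
#' filter_and_slice(rec)$slice
#' @export
filter_and_slice <- function(records, max_range_ky = 30, window_ky = 10,
                             assignment = c("overlap", "midpoint")) {
  assignment <- match.arg(assignment)
  range_ky <- records$date_max_ka - records$date_min_ka
  if (any(range_ky < 0)) stop_invalid("date_max_ka must be >= date_min_ka")
  keep <- range_ky <= max_range_ky
  excluded <- records[!keep, , drop = FALSE]
  records <- records[keep, , drop = FALSE]
  rows <- lapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    if (assignment == "midpoint") {
      mid <- (r$date_min_ka + r$date_max_ka) / 2
      starts <- window_ky * ceiling(mid / window_ky)
      if (mid == 0) starts <- window_ky
    } else {
      # slices (end, start] overlapping [date_min, date_max]
      from <- window_ky * max(1, ceiling(r$date_min_ka / window_ky))
      to <- max(window_ky * ceiling(r$date_max_ka / window_ky), from)
      starts <- seq(from, to, by = window_ky)
      starts <- starts[r$date_max_ka > starts - window_ky &
                         r$date_min_ka <= starts]
    }
    if (!length(starts)) return(NULL)
    out <- r[rep(1L, length(starts)), , drop = FALSE]
    out$slice_start_ka <- starts
    out$slice_end_ka <- starts - window_ky
    out$slice <- sprintf("%g-%g", starts, starts - window_ky)
    out
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- records[0, , drop = FALSE]
    out$slice_start_ka <- numeric(0); out$slice_end_ka <- numeric(0)
    out$slice <- character(0)
  }
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

#' Gaussian kernel density of point locations on a grid
#'
#' Each point contributes unit mass through an axis-aligned Gaussian
#' kernel; grid values are intensities (not normalised to integrate
#' to 1). Bandwidth defaults to Silverman's rule per axis.
#'
#' @param lon,lat point coordinates in degrees.
#' @param bandwidth scalar bandwidth in degrees for both axes, or length-2
#'   `c(bw_lon, bw_lat)`; `NULL` for Silverman's rule.
#' @param lon_range,lat_range grid extents; default to the data range
#'   padded by one bandwidth.
#' @param n grid resolution, `c(n_lon, n_lat)`.
#' @return List with `lon`, `lat` (cell-centre coordinates), `z`
#'   (matrix `n_lon` x `n_lat` of densities) and `bandwidth`.
#' @export
kde_density <- function(lon, lat, bandwidth = NULL,
                        lon_range = NULL, lat_range = NULL, n = c(50, 50)) {
  if (length(lon) < 1) stop_invalid("at least one point required")
  silverman <- function(x) {
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) s <- 1
    1.06 * s * length(x)^(-1 / 5)
  }
  if (is.null(bandwidth)) bandwidth <- c(silverman(lon), silverman(lat))
  if (length(bandwidth) == 1L) bandwidth <- rep(bandwidth, 2L)
  if (any(bandwidth <= 0)) stop_invalid("'bandwidth' must be positive")
  lon_range <- lon_range %||% (range(lon) + c(-1, 1) * bandwidth[1])
  lat_range <- lat_range %||% (range(lat) + c(-1, 1) * bandwidth[2])
  gx <- seq(lon_range[1], lon_range[2], length.out = n[1])
  gy <- seq(lat_range[1], lat_range[2], length.out = n[2])
  Kx <- stats::dnorm(outer(gx, lon, "-") / bandwidth[1]) / bandwidth[1]
  Ky <- stats::dnorm(outer(gy, lat, "-") / bandwidth[2]) / bandwidth[2]
  z <- Kx %*% t(Ky)
  list(lon = gx, lat = gy, z = z, bandwidth = bandwidth)
}

# Binary distance-band spatial weights (self-inclusive) between grid
# cells, distances in cell units (Euclidean on the cell lattice).
grid_band_weights <- function(nx, ny, band) {
  ix <- rep(seq_len(nx), times = ny)
  iy <- rep(seq_len(ny), each = nx)
  d2 <- outer(ix, ix, "-")^2 + outer(iy, iy, "-")^2
  (d2 <= band^2) * 1
}

#' Local Getis-Ord Gi* statistic on a count grid
#'
#' Computes the self-inclusive Gi* z-score for every cell:
#' `z_i = (sum_j w_ij x_j - Xbar W_i) / (S * sqrt((n sum_j w_ij^2 - W_i^2)/(n-1)))`
#' with binary weights within a fixed distance band (in cell units,
#' Euclidean, self included). Positive z flags hotspots, negative z cold
#' spots. For a zero-variance field all z are defined as 0. Cell
#' p-values come from conditional permutations when `perm_reps > 0`,
#' otherwise from the normal approximation.
#'
#' @param counts numeric matrix of per-cell counts (rows = x/longitude
#'   cells, columns = y/latitude cells).
#' @param band weight band in cell units (default 3).
#' @param perm_reps optional permutation replicates for per-cell p.
#' @param seed RNG seed for the permutations.
#' @return Object of class `gi_star_field`: `z` (matrix like `counts`),
#'   `p` (matrix), `band`, `counts`.
#' @export
gi_star <- function(counts, band = 3, perm_reps = 0, seed = NULL) {
  x <- as.vector(counts)
  n <- length(x)
  if (n < 2) stop_invalid("need at least 2 cells")
  W <- grid_band_weights(nrow(counts), ncol(counts), band)
  xbar <- mean(x)
  S <- sqrt(sum(x^2) / n - xbar^2)
  Wi <- rowSums(W)
  num <- as.vector(W %*% x) - xbar * Wi
  den <- S * sqrt(pmax(n * rowSums(W^2) - Wi^2, 0) / (n - 1))
  z <- ifelse(den > 0, num / den, 0)
  if (S == 0) z <- rep(0, n)
  if (perm_reps > 0) {
    p <- with_seed(seed, {
      obs <- abs(z)
      cnt <- rep(0L, n)
      for (r in seq_len(perm_reps)) {
        xp <- sample(x)
        nump <- as.vector(W %*% xp) - xbar * Wi
        zp <- ifelse(den > 0, nump / den, 0)
        cnt <- cnt + (abs(zp) >= obs - 1e-12)
      }
      (1 + cnt) / (perm_reps + 1)
    })
  } else {
    p <- 2 * stats::pnorm(-abs(z))
    p[p == 0] <- .Machine$double.xmin
  }
  structure(list(z = matrix(z, nrow(counts), ncol(counts)),
                 p = matrix(p, nrow(counts), ncol(counts)),
                 band = band, counts = counts),
            class = "gi_star_field")
}

# Count localities per cell of a fixed grid.
grid_counts <- function(lon, lat, lon_breaks, lat_breaks) {
  ix <- findInterval(lon, lon_breaks, rightmost.closed = TRUE)
  iy <- findInterval(lat, lat_breaks, rightmost.closed = TRUE)
  nx <- length(lon_breaks) - 1L
  ny <- length(lat_breaks) - 1L
  ok <- ix >= 1 & ix <= nx & iy >= 1 & iy <= ny
  matrix(tabulate(ix[ok] + (iy[ok] - 1L) * nx, nbins = nx * ny), nx, ny)
}

#' Structured permutation test for per-slice hotspot patterns
#'
#' Tests whether the hotspot structure of each time slice could arise
#' from random spatial sampling: the observed statistic is the number of
#' grid cells with `|z| >= z_threshold` in the slice's Gi* field; the
#' null redistributes slice labels at random over the pooled locality
#' positions, preserving per-slice counts and the pooled spatial
#' distribution. One-sided p-values use add-one smoothing,
#' `p = (1 + #(null >= observed)) / (reps + 1)`.
#'
#' @param sliced output of [filter_and_slice()] (or any data frame with
#'   `longitude`, `latitude`, `slice`).
#' @param reps permutation replicates (default 199).
#' @param cell_deg grid cell size in degrees (default 1).
#' @param band Gi* weight band in cells (default 3).
#' @param z_threshold hotspot threshold on `|z|` (default 1.96).
#' @param seed RNG seed.
#' @return `data.frame` with per-slice `n`, `hotspot_cells` (observed)
#'   and `p`; attribute `null` holds the null statistics matrix.
#' @export
hotspot_permutation_test <- function(sliced, reps = 199, cell_deg = 1,
                                     band = 3, z_threshold = 1.96,
                                     seed = NULL) {
  if (reps < 1) stop_invalid("'reps' must be >= 1")
  slices <- sort(unique(sliced$slice))
  if (length(slices) < 2) stop_invalid("need at least 2 slices")
  lon_breaks <- seq(floor(min(sliced$longitude)),
                    ceiling(max(sliced$longitude)) + cell_deg, by = cell_deg)
  lat_breaks <- seq(floor(min(sliced$latitude)),
                    ceiling(max(sliced$latitude)) + cell_deg, by = cell_deg)
  stat_for <- function(lon, lat) {
    cnt <- grid_counts(lon, lat, lon_breaks, lat_breaks)
    sum(abs(gi_star(cnt, band = band)$z) >= z_threshold)
  }
  obs <- vapply(slices, function(s) {
    i <- sliced$slice == s
    stat_for(sliced$longitude[i], sliced$latitude[i])
  }, numeric(1))
  with_seed(seed, {
    null_mat <- matrix(0, reps, length(slices),
                       dimnames = list(NULL, slices))
    lab <- sliced$slice
    for (r in seq_len(reps)) {
      perm <- sample(lab)
      null_mat[r, ] <- vapply(slices, function(s) {
        i <- perm == s
        stat_for(sliced$longitude[i], sliced$latitude[i])
      }, numeric(1))
    }
    p <- vapply(seq_along(slices), function(k)
      (1 + sum(null_mat[, k] >= obs[k])) / (reps + 1), numeric(1))
    out <- data.frame(slice = slices,
                      n = as.integer(table(lab)[slices]),
                      hotspot_cells = as.integer(obs), p = p,
                      stringsAsFactors = FALSE)
    attr(out, "null") <- null_mat
    out
  })
}

# Longitudinal spread metrics on a set of localities.
spread_metrics <- function(lon, bin_width) {
  q <- stats::quantile(lon, c(0.025, 0.975), names = FALSE, type = 7)
  c(full_range = max(lon) - min(lon),
    central95_range = q[2] - q[1],
    occupied_bins = length(unique(floor((lon + 180) / bin_width))))
}

#' Rarefaction of longitudinal spread between two time slices
#'
#' Repeatedly downsamples the target slice to `n` unique localities and
#' compares its longitudinal spread to a baseline slice, removing the
#' effect of unequal sample sizes. Three metrics are computed per
#' replicate: full longitude range, central-95% range (2.5-97.5
#' percentile span) and the number of occupied `bin_width`-degree
#' longitude bins (bins anchored at multiples of `bin_width` from
#' -180). One-sided p-values (alternative: target spread broader than
#' baseline) are the add-one-smoothed proportion of replicates with
#' metric less than or equal to the baseline's.
#'
#' @param baseline,target locality data frames (`site_id`, `longitude`);
#'   duplicate `site_id`s within a slice count once.
#' @param n localities per rarefied replicate (default 60).
#' @param reps replicates (default 1000).
#' @param bin_width longitude bin width in degrees (default 2).
#' @param seed RNG seed.
#' @return Object of class `rarefaction_result`: `baseline_n`,
#'   `target_n`, `n`, `reps`, `baseline` (metrics), `medians` (median
#'   rarefied metrics), `p_perm` (per metric), `replicates` (matrix).
#' @export
rarefy_spread <- function(baseline, target, n = 60, reps = 1000,
                          bin_width = 2, seed = NULL) {
  b <- baseline[!duplicated(baseline$site_id), , drop = FALSE]
  t_ <- target[!duplicated(target$site_id), , drop = FALSE]
  if (nrow(b) < 1) stop_invalid("baseline slice is empty")
  if (nrow(t_) < n)
    stop_invalid("target slice has fewer than n = ", n, " localities; ",
                 "consider swapping baseline and target")
  base_m <- spread_metrics(b$longitude, bin_width)
  with_seed(seed, {
    rep_m <- t(vapply(seq_len(reps), function(r) {
      spread_metrics(sample(t_$longitude, n), bin_width)
    }, numeric(3)))
    colnames(rep_m) <- names(base_m)
    medians <- apply(rep_m, 2, stats::median)
    p_perm <- vapply(names(base_m), function(m)
      (1 + sum(rep_m[, m] <= base_m[m])) / (reps + 1), numeric(1))
    structure(list(baseline_n = nrow(b), target_n = nrow(t_), n = n,
                   reps = reps, bin_width = bin_width,
                   baseline = base_m, medians = medians, p_perm = p_perm,
                   replicates = rep_m, seed = seed),
              class = "rarefaction_result")
  })
}

#' @export
print.rarefaction_result <- function(x, ...) {
  cat(sprintf("Rarefaction: target %d localities downsampled to n = %d (%d reps)\n",
              x$target_n, x$n, x$reps))
  tab <- rbind(baseline = x$baseline, rarefied_median = x$medians,
               p_perm = x$p_perm)
  print(round(tab, 3))
  invisible(x)
}
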