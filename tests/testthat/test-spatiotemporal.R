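loc_row <- function(id, lon, min_ka, max_ka, lat = 45) {
  data.frame(site_id = id, longitude = lon, latitude = lat,
             date_min_ka = min_ka, date_max_ka = max_ka,
             stringsAsFactors = FALSE)
}

test_that("range filtering and slice assignment follow the overlap rule", {
  recs <- rbind(loc_row("wide", 0, 60, 100),     # 40 ky range: excluded
                loc_row("point", 1, 65, 65),     # slice 70-60 only
                loc_row("span", 2, 55, 75))      # slices 80-70, 70-60, 60-50
  out <- filter_and_slice(recs, max_range_ky = 30, window_ky = 10)
  expect_false("wide" %in% out$site_id)
  expect_identical(attr(out, "excluded")$site_id, "wide")
  expect_identical(out$slice[out$site_id == "point"], "70-60")
  expect_setequal(out$slice[out$site_id == "span"],
                  c("80-70", "70-60", "60-50"))
  # every retained record appears only in slices it overlaps
  for (i in seq_len(nrow(out)))
    expect_true(out$date_max_ka[i] > out$slice_end_ka[i] &&
                  out$date_min_ka[i] <= out$slice_start_ka[i])
  # boundary: a point date on a slice edge falls in the younger slice
  edge <- filter_and_slice(loc_row("edge", 0, 70, 70))
  expect_identical(edge$slice, "70-60")
})

test_that("midpoint assignment puts each record in exactly one slice", {
  recs <- rbind(loc_row("a", 0, 55, 75), loc_row("b", 1, 62, 64))
  out <- filter_and_slice(recs, assignment = "midpoint")
  expect_identical(nrow(out), 2L)
  expect_identical(out$slice, c("70-60", "70-60"))
})

test_that("kernel density peaks at the data and matches a brute-force sum", {
  one <- kde_density(10, 45, bandwidth = 1, n = c(21, 21))
  peak <- which(one$z == max(one$z), arr.ind = TRUE)
  expect_equal(one$lon[peak[1]], 10, tolerance = 0.2)
  expect_equal(one$lat[peak[2]], 45, tolerance = 0.2)
  # symmetry about the midline between two symmetric points
  two <- kde_density(c(-5, 5), c(40, 40), bandwidth = 2,
                     lon_range = c(-10, 10), lat_range = c(35, 45),
                     n = c(21, 21))
  expect_equal(two$z, two$z[21:1, ], tolerance = 1e-9)
  # brute-force double sum on random points
  set.seed(31)
  lon <- runif(50, 0, 30); lat <- runif(50, 40, 50)
  got <- kde_density(lon, lat, bandwidth = c(1.5, 1.2),
                     lon_range = c(0, 30), lat_range = c(40, 50),
                     n = c(20, 20))
  for (i in c(1, 7, 20)) for (j in c(1, 11, 20)) {
    direct <- sum(stats::dnorm((got$lon[i] - lon) / 1.5) / 1.5 *
                    stats::dnorm((got$lat[j] - lat) / 1.2) / 1.2)
    expect_equal(got$z[i, j], direct, tolerance = 1e-9)
  }
  expect_error(kde_density(1, 1, bandwidth = 0), "bandwidth")
})

test_that("Gi* matches direct formula evaluation on a 5x5 grid", {
  cnt <- matrix(0, 5, 5); cnt[3, 3] <- 10
  gf <- gi_star(cnt, band = 1.5)          # 3x3 neighbourhood incl. self
  x <- as.vector(cnt); n <- 25
  xbar <- mean(x); S <- sqrt(sum(x^2) / n - xbar^2)
  # direct evaluation at the centre cell (9 neighbours) and a corner (4)
  for (cell in list(list(idx = c(3, 3), wsum = 10, wn = 9),
                    list(idx = c(1, 1), wsum = 0, wn = 4))) {
    Wi <- cell$wn
    z_direct <- (cell$wsum - xbar * Wi) /
      (S * sqrt((n * Wi - Wi^2) / (n - 1)))
    expect_equal(gf$z[cell$idx[1], cell$idx[2]], z_direct, tolerance = 1e-9)
  }
  # constant field: all z defined as 0
  flat <- gi_star(matrix(4, 5, 5), band = 1.5)
  expect_true(all(flat$z == 0))
})

test_that("Gi* z-scores agree with a Monte-Carlo permutation z", {
  set.seed(37)
  cnt <- matrix(rpois(36, 2), 6, 6)
  gf <- gi_star(cnt, band = 2)
  x <- as.vector(cnt)
  W <- outer(seq_len(36), seq_len(36), function(i, j) {
    xi <- (i - 1) %% 6; yi <- (i - 1) %/% 6
    xj <- (j - 1) %% 6; yj <- (j - 1) %/% 6
    ((xi - xj)^2 + (yi - yj)^2 <= 4) * 1
  })
  sums <- replicate(20000, as.vector(W %*% sample(x)))
  mc_mean <- rowMeans(sums); mc_sd <- apply(sums, 1, sd)
  obs <- as.vector(W %*% x)
  z_mc <- (obs - mc_mean) / mc_sd
  expect_lt(max(abs(z_mc - as.vector(gf$z))), 0.1)
})

test_that("hotspot permutation p-values are well-formed and reproducible", {
  sc <- spread_scenario(c(80, 70), c(70, 60), n = c(50, 60),
                        lon_width = c(20, 20), range_max_ky = 0.5)
  loc <- simulate_localities(sc, seed = 41)
  loc$slice <- NULL
  sliced <- filter_and_slice(loc)
  h1 <- hotspot_permutation_test(sliced, reps = 49, seed = 42)
  h2 <- hotspot_permutation_test(sliced, reps = 49, seed = 42)
  expect_identical(h1, h2)
  expect_true(all(h1$p > 0 & h1$p <= 1))
  expect_error(hotspot_permutation_test(sliced, reps = 0), "reps")
})

test_that("slices clustered at distinct locations are detected", {
  # The label-shuffle null preserves pooled locations, so it detects
  # slices whose concentration is diluted by pooling: two slices
  # clustered at different centres. A high z threshold isolates the
  # full-strength observed clusters from their diluted null mixtures.
  set.seed(43)
  a <- data.frame(site_id = paste0("a", 1:100),
                  longitude = rnorm(100, 10, 0.8),
                  latitude = rnorm(100, 45, 0.8), slice = "early")
  b <- data.frame(site_id = paste0("b", 1:100),
                  longitude = rnorm(100, 30, 0.8),
                  latitude = rnorm(100, 45, 0.8), slice = "late")
  res <- hotspot_permutation_test(rbind(a, b), reps = 99,
                                  z_threshold = 5, seed = 44)
  expect_lt(res$p[res$slice == "early"], 0.05)
  expect_lt(res$p[res$slice == "late"], 0.05)
})

test_that("rarefaction is degenerate when target equals baseline at full n", {
  set.seed(47)
  base <- data.frame(site_id = paste0("s", 1:60),
                     longitude = runif(60, 0, 30))
  rar <- rarefy_spread(base, base, n = 60, reps = 50, seed = 48)
  expect_equal(unname(rar$medians), unname(rar$baseline))
  expect_true(all(apply(rar$replicates, 2, function(col)
    all(col == col[1]))))
  # central-95% range never exceeds the full range
  expect_true(all(rar$replicates[, "central95_range"] <=
                    rar$replicates[, "full_range"] + 1e-12))
})

test_that("rarefied medians are monotone non-decreasing in n", {
  set.seed(53)
  target <- data.frame(site_id = paste0("s", 1:300),
                       longitude = runif(300, 0, 45))
  base <- data.frame(site_id = paste0("b", 1:50),
                     longitude = runif(50, 0, 30))
  meds <- sapply(c(10, 30, 60), function(n)
    rarefy_spread(base, target, n = n, reps = 200, seed = 54)$medians)
  for (m in 1:3) expect_true(all(diff(meds[m, ]) >= -1e-9))
})

test_that("rarefaction errors suggest a baseline swap when the target is small", {
  small <- data.frame(site_id = paste0("s", 1:10), longitude = runif(10))
  base <- data.frame(site_id = "b1", longitude = 0)
  expect_error(rarefy_spread(base, small, n = 60), "swap")
})
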