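test_that("geo_point validates and normalises coordinates", {
  p <- geo_point(23.7, 90.4)
  expect_equal(unname(unclass(p)), c(23.7, 90.4))
  expect_equal(geo_point(0, 200)[["lon"]], -160)
  expect_equal(geo_point(0, -180)[["lon"]], 180)
  expect_error(geo_point(95, 0), "latitude")
})

test_that("haversine distances match closed-form values", {
  expect_equal(haversine_km(geo_point(10, 20), geo_point(10, 20)), 0)
  R <- 6371.0088
  expect_equal(haversine_km(geo_point(0, 0), geo_point(0, 180)), pi * R,
               tolerance = 1e-9)
  expect_equal(haversine_km(geo_point(0, 0), geo_point(0, 1)), R * pi / 180,
               tolerance = 1e-6)
  # symmetry and triangle inequality on random triples
  set.seed(8)
  for (r in 1:20) {
    pts <- lapply(1:3, function(i) geo_point(runif(1, -80, 80),
                                             runif(1, -180, 180)))
    d12 <- haversine_km(pts[[1]], pts[[2]])
    d21 <- haversine_km(pts[[2]], pts[[1]])
    d13 <- haversine_km(pts[[1]], pts[[3]])
    d23 <- haversine_km(pts[[2]], pts[[3]])
    expect_equal(d12, d21)
    expect_lte(d13, d12 + d23 + 1e-9)
  }
})

test_that("geo summaries identify the central feature and median centre", {
  one <- geo_summary(10, 100, "only")
  expect_equal(one$mean_pairwise_km, 0)
  expect_identical(one$gcf_id, "only")
  expect_equal(one$gmc[["lat"]], 10)

  # three points on a meridian: middle point is the GCF, GMC on the meridian
  s <- geo_summary(c(10, 12, 15), c(100, 100, 100), c("a", "b", "c"))
  expect_identical(s$gcf_id, "b")
  expect_equal(s$gmc[["lon"]], 100, tolerance = 1e-6)
  expect_gte(s$gmc[["lat"]], 10)
  expect_lte(s$gmc[["lat"]], 15)
  expect_error(geo_summary(numeric(0), numeric(0)), "at least one")
})

test_that("the GMC objective beats every local 0.01-degree grid point", {
  set.seed(14)
  for (r in 1:3) {
    n <- sample(4:8, 1)
    lat <- runif(n, 5, 30); lon <- runif(n, 80, 110)
    s <- geo_summary(lat, lon)
    obj <- function(p) mean(vapply(seq_len(n), function(i)
      haversine_km(p, c(lat[i], lon[i])), 0))
    best <- obj(c(s$gmc[["lat"]], s$gmc[["lon"]]))
    grid_lat <- seq(s$gmc[["lat"]] - 1, s$gmc[["lat"]] + 1, by = 0.01)
    grid_lon <- seq(s$gmc[["lon"]] - 1, s$gmc[["lon"]] + 1, by = 0.01)
    # vectorised objective over the whole neighbourhood
    gr <- expand.grid(lat = grid_lat, lon = grid_lon)
    tot <- numeric(nrow(gr))
    for (i in seq_len(n)) {
      tot <- tot + geosphere::distHaversine(cbind(gr$lon, gr$lat),
                                            c(lon[i], lat[i]),
                                            r = 6371008.8) / 1000
    }
    expect_lte(best, min(tot / n) + 1e-6)
  }
})

test_that("GMC is permutation-invariant and longitude-equivariant", {
  set.seed(19)
  lat <- runif(6, 0, 25); lon <- runif(6, 70, 100)
  s1 <- geo_summary(lat, lon)
  perm <- sample(6)
  s2 <- geo_summary(lat[perm], lon[perm])
  expect_equal(s1$gmc[["lat"]], s2$gmc[["lat"]], tolerance = 1e-8)
  expect_equal(s1$gmc[["lon"]], s2$gmc[["lon"]], tolerance = 1e-8)
  s3 <- geo_summary(lat, lon + 10)
  expect_equal(s3$gmc[["lon"]] - s1$gmc[["lon"]], 10, tolerance = 1e-6)
  expect_equal(s3$gmc[["lat"]], s1$gmc[["lat"]], tolerance = 1e-6)
})

test_that("kernel densities normalise and find the expected modes", {
  kd <- kernel_density(10, 100, bandwidth = c(1, 1), n = 50)
  expect_equal(sum(kd$density) * kd$cell_area, 1, tolerance = 1e-6)
  peak <- which(kd$density == max(kd$density), arr.ind = TRUE)
  expect_equal(kd$lon[peak[1]], 100, tolerance = diff(kd$lon)[1])
  expect_equal(kd$lat[peak[2]], 10, tolerance = diff(kd$lat)[1])

  # two well-separated clusters give two local maxima
  set.seed(3)
  lat <- c(rnorm(30, 10, 0.3), rnorm(30, 25, 0.3))
  lon <- c(rnorm(30, 80, 0.3), rnorm(30, 105, 0.3))
  kd2 <- kernel_density(lat, lon, n = 60)
  expect_equal(sum(kd2$density) * kd2$cell_area, 1, tolerance = 1e-6)
  z <- kd2$density
  is_peak <- function(i, j) {
    nb <- z[max(1, i - 1):min(nrow(z), i + 1), max(1, j - 1):min(ncol(z), j + 1)]
    z[i, j] == max(nb) && z[i, j] > 1e-6
  }
  peaks <- 0
  for (i in seq_len(nrow(z))) for (j in seq_len(ncol(z))) {
    if (is_peak(i, j)) peaks <- peaks + 1
  }
  expect_gte(peaks, 2)

  expect_error(kernel_density(c(10, 10), c(100, 100)), "zero-variance")
  expect_error(kernel_density(10, 100), "bandwidth")
})

test_that("Mantel r equals the direct triangle correlation", {
  set.seed(21)
  m1 <- as.matrix(dist(matrix(runif(24), 8)))
  m2 <- as.matrix(dist(matrix(runif(24), 8)))
  mt <- mantel_test(m1, m2, n_perm = 99, seed = 5)
  expect_equal(mt$r, cor(m1[lower.tri(m1)], m2[lower.tri(m2)]))
  expect_gte(mt$p, 1 / 100)

  self <- mantel_test(m1, m1, n_perm = 199, seed = 5)
  expect_equal(self$r, 1)
  expect_equal(self$p, 1 / 200)

  cst <- matrix(1, 5, 5) - diag(5)
  expect_error(mantel_test(cst, m1[1:5, 1:5]), "constant")
  expect_error(mantel_test(m1[1:4, 1:4], m2), "size")
  expect_error(mantel_test(m1[1:2, 1:2], m2[1:2, 1:2]), ">= 3")
})

test_that("a single-haplotype panel cannot reach the Mantel test", {
  pan <- simulate_null_panel(n_haplotypes = 1, seed = 2)
  expect_error(panel_distance_matrices(pan), "fewer than two")
})
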