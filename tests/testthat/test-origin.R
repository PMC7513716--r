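ref_groups <- function() {
  ht <- read_haplotype_table()
  setNames(ht$group, ht$haplotype)
}

test_that("the intersection filter reproduces the published haplotype sets", {
  groups <- ref_groups()
  rc <- read_region_haplotype_counts()
  h1_set <- filter_haplotype_set(groups, rc, c("AO-I", "AO-II"),
                                 c("SA-I", "SA-II"))
  expect_setequal(h1_set, c("H1", "H2", "H4", "H5", "H6", "H14"))

  h11_set <- filter_haplotype_set(groups, rc, "AO-III", c("EA", "SEA"),
                                  extra_include = "H1")
  expect_setequal(h11_set, c("H10", "H11", "H1"))

  none <- filter_haplotype_set(groups, rc, "AO-IV", c("SA-I", "SA-II"))
  expect_length(none, 0)
  expect_error(filter_haplotype_set(groups, rc, "AO-I", "Atlantis"),
               "unknown region")
})

test_that("mean distance vectors average over carriers correctly", {
  acc <- data.frame(
    lat = c(10, 10, 11, 20), lon = c(100, 100, 100, 100),
    haplotype = c("A", "A", "B", "T"))
  x <- mean_distance_vector(geo_point(10, 100), acc, c("A", "B", "T"), "T")
  expect_equal(unname(x["A"]), 0)
  expect_named(x, c("A", "B"))

  # two carriers equidistant at d km -> x = d
  d1 <- haversine_km(geo_point(10, 100), geo_point(11, 100))
  acc2 <- data.frame(lat = c(11, 9, 0), lon = c(100, 100, 100),
                     haplotype = c("A", "A", "T"))
  x2 <- mean_distance_vector(geo_point(10, 100), acc2, c("A", "T"), "T")
  d2 <- haversine_km(geo_point(10, 100), geo_point(9, 100))
  expect_equal(unname(x2["A"]), (d1 + d2) / 2)

  # brute-force recomputation on a random panel
  set.seed(31)
  pan <- simulate_dispersal_panel(dispersal_params(n_haplotypes = 5, seed = 31))
  cand <- geo_point(15, 95)
  x3 <- mean_distance_vector(cand, pan$accessions,
                             names(pan$haplotype_seqs), "HS01")
  for (h in names(x3)) {
    rows <- which(pan$accessions$haplotype == h)
    manual <- mean(vapply(rows, function(k)
      haversine_km(cand, c(pan$accessions$lat[k], pan$accessions$lon[k])), 0))
    expect_equal(unname(x3[h]), manual)
  }
  expect_error(
    mean_distance_vector(cand, data.frame(lat = NA_real_, lon = NA_real_,
                                          haplotype = "A"), c("A", "T"), "T"),
    "no located carrier")
})

test_that("the origin regression matches closed-form least squares", {
  # exactly collinear data recover slope and intercept with r2 = 1
  x <- c(0, 100, 200, 400)
  y <- 2e-5 * x + 0.003
  f <- fit_origin_regression(x, y)
  expect_equal(f$a, 2e-5)
  expect_equal(f$b, 0.003)
  expect_equal(f$r2, 1)

  # hand-derived toy: x=(0,1,2), y=(1,2,4)
  f2 <- fit_origin_regression(c(0, 1, 2), c(1, 2, 4))
  expect_equal(f2$a, 1.5)
  expect_equal(f2$b, 5 / 6)
  expect_equal(f2$r2, 27 / 28)
  # cross-check against the stats::lm fitter
  lmfit <- lm(y ~ x, data.frame(x = c(0, 1, 2), y = c(1, 2, 4)))
  expect_equal(f2$a, unname(coef(lmfit)[2]))
  expect_equal(f2$b, unname(coef(lmfit)[1]))
  expect_equal(f2$r2, summary(lmfit)$r.squared)

  # invariant under joint reordering
  ord <- c(3, 1, 2)
  f3 <- fit_origin_regression(c(0, 1, 2)[ord], c(1, 2, 4)[ord])
  expect_equal(f3$a, f2$a)
  expect_equal(f3$r2, f2$r2)

  expect_error(fit_origin_regression(c(1, 1, 1), c(1, 2, 3)), "degenerate")
  expect_error(fit_origin_regression(1:2, 1:2), "at least 3")
})

test_that("a one-cell scan equals a direct regression fit", {
  pan <- simulate_dispersal_panel(dispersal_params(n_haplotypes = 5, seed = 41))
  L <- pan$truth$seq_len
  pdist <- function(a, b) pairwise_differences(a, b) / L
  surf <- scan_origin(pan$accessions, "HS01", names(pan$haplotype_seqs),
                      seqs = pan$haplotype_seqs, genetic_fn = pdist,
                      grid_step = 200, pad = 0.01)
  expect_equal(length(surf$lat) * length(surf$lon), 1L)
  cand <- geo_point(surf$lat[1], surf$lon[1])
  x <- mean_distance_vector(cand, pan$accessions,
                            names(pan$haplotype_seqs), "HS01")
  direct <- fit_origin_regression(x, surf$y[names(x)])
  expect_equal(surf$r2[1, 1], direct$r2, tolerance = 1e-10)
  expect_equal(surf$a[1, 1], direct$a, tolerance = 1e-10)
})

test_that("shifting all coordinates shifts the best cell equivariantly", {
  pan <- simulate_dispersal_panel(dispersal_params(n_haplotypes = 6,
                                                   seed = 43, noise_sd = 0))
  L <- pan$truth$seq_len
  pdist <- function(a, b) pairwise_differences(a, b) / L
  surf1 <- scan_origin(pan$accessions, "HS01", names(pan$haplotype_seqs),
                       seqs = pan$haplotype_seqs, genetic_fn = pdist,
                       grid_step = 0.5, pad = 3)
  shifted <- pan$accessions
  shifted$lon <- shifted$lon + 10
  surf2 <- scan_origin(shifted, "HS01", names(pan$haplotype_seqs),
                       seqs = pan$haplotype_seqs, genetic_fn = pdist,
                       grid_step = 0.5, pad = 3)
  a1 <- surface_argmax(surf1); a2 <- surface_argmax(surf2)
  expect_equal(a2$lon - a1$lon, 10, tolerance = 1e-9)
  expect_equal(a2$lat, a1$lat, tolerance = 1e-9)
  expect_equal(a2$r2, a1$r2, tolerance = 1e-9)
})

test_that("hotspots honour thresholds, ties and emptiness", {
  surf <- structure(list(lat = c(10, 10.5), lon = c(100, 100.5),
                         r2 = matrix(c(0.95, 0.85, NA, 0.95), 2, 2),
                         step = 0.5), class = "origin_surface")
  hs <- hotspot_region(surf, threshold = 0.8)
  expect_equal(nrow(hs$cells), 3L)
  # peak tie resolved to smallest latitude then longitude
  expect_equal(hs$peak$lat, 10)
  expect_equal(hs$peak$lon, 100)
  expect_equal(unname(hs$bbox),
               c(10, 10.5, 100, 100.5))

  empty <- hotspot_region(surf, threshold = 0.99)
  expect_equal(nrow(empty$cells), 0L)
  expect_null(empty$bbox)

  # monotonicity: raising the threshold never adds cells
  for (th in c(0, 0.5, 0.84, 0.9, 1)) {
    expect_lte(nrow(hotspot_region(surf, threshold = th + 0.05)$cells),
               nrow(hotspot_region(surf, threshold = th)$cells))
  }
})

test_that("null panels rarely reach the hotspot threshold", {
  pan <- simulate_null_panel(n_haplotypes = 7, seq_len = 800,
                             mutation_rate = 0.01, seed = 51)
  L <- 800
  pdist <- function(a, b) pairwise_differences(a, b) / L
  surf <- scan_origin(pan$accessions, names(pan$haplotype_seqs)[1],
                      names(pan$haplotype_seqs), seqs = pan$haplotype_seqs,
                      genetic_fn = pdist, grid_step = 0.5, pad = 5)
  frac <- mean(surf$r2 >= 0.8, na.rm = TRUE)
  expect_lt(frac, 0.05)
})
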