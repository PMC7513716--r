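#' @importFrom stats cor complete.cases lm rnorm runif rpois sd setNames quantile
#' @importFrom utils read.delim write.table head
NULL

# Mean Earth radius, km (IUGG)
EARTH_RADIUS_KM <- 6371.0088

#' Construct a geographic point
#'
#' A validated latitude/longitude pair in WGS84 decimal degrees. Longitude is
#' normalised into the interval (-180, 180].
#'
#' @param lat_deg latitude in decimal degrees, in \[-90, 90\].
#' @param lon_deg longitude in decimal degrees; any finite value is accepted
#'   and wrapped into (-180, 180\].
#' @return an object of class `geo_point`: a named numeric vector with
#'   elements `lat` and `lon`.
#' @examples
#' geo_point(23.7, 90.4)
#' geo_point(0, 200)  # wraps to -160
#' @export
geo_point <- function(lat_deg, lon_deg) {
  if (!is.numeric(lat_deg) || !is.numeric(lon_deg) ||
      length(lat_deg) != 1L || length(lon_deg) != 1L ||
      !is.finite(lat_deg) || !is.finite(lon_deg)) {
    stop("lat_deg and lon_deg must be single finite numbers", call. = FALSE)
  }
  if (lat_deg < -90 || lat_deg > 90) {
    stop("latitude out of range [-90, 90]: ", lat_deg, call. = FALSE)
  }
  lon <- ((lon_deg + 180) %% 360) - 180
  if (lon == -180) lon <- 180
  structure(c(lat = lat_deg, lon = lon), class = "geo_point")
}

#' Great-circle distance between two points
#'
#' Haversine distance on a sphere of radius 6371.0088 km.
#'
#' @param p,q `geo_point` objects (or length-2 numeric `c(lat, lon)`).
#' @return distance in kilometres.
#' @examples
#' haversine_km(geo_point(0, 0), geo_point(0, 1))  # ~111.19 km
#' @export
haversine_km <- function(p, q) {
  p <- as_latlon(p); q <- as_latlon(q)
  geosphere::distHaversine(c(p[2], p[1]), c(q[2], q[1]),
                           r = EARTH_RADIUS_KM * 1000) / 1000
}

as_latlon <- function(p) {
  if (inherits(p, "geo_point")) return(unclass(p))
  if (is.numeric(p) && length(p) == 2L) return(c(lat = p[[1]], lon = p[[2]]))
  stop("not a geographic point: ", deparse(substitute(p)), call. = FALSE)
}

# Vectorised haversine: `pts` is a matrix/data.frame with columns lat, lon;
# `ref` a single point. Returns km to each row.
haversine_to_many <- function(ref, lat, lon) {
  ref <- as_latlon(ref)
  geosphere::distHaversine(cbind(lon, lat), c(ref[["lon"]], ref[["lat"]]),
                           r = EARTH_RADIUS_KM * 1000) / 1000
}

# Full pairwise great-circle distance matrix (km) from lat/lon vectors.
pairwise_km_matrix <- function(lat, lon) {
  n <- length(lat)
  m <- matrix(0, n, n)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      d <- haversine_to_many(c(lat[i], lon[i]), lat[(i + 1):n], lon[(i + 1):n])
      m[i, (i + 1):n] <- d
      m[(i + 1):n, i] <- d
    }
  }
  m
}

# Displace a point along a geodesic: bearing in degrees, distance in km.
displace_km <- function(p, bearing_deg, dist_km) {
  p <- as_latlon(p)
  xy <- geosphere::destPoint(c(p[["lon"]], p[["lat"]]), bearing_deg,
                             dist_km * 1000, r = EARTH_RADIUS_KM * 1000)
  data.frame(lat = xy[, "lat"], lon = xy[, "lon"])
}

#' Geographic summary of a set of located samples
#'
#' Computes the pairwise great-circle distance summary of a set of accessions,
#' the geographic central feature (GCF: the sampled accession with the
#' smallest mean distance to all the others) and the geographic median centre
#' (GMC: the unsampled coordinate minimising the mean great-circle distance to
#' all accessions, i.e. the spherical geometric median).
#'
#' The GMC is found by spherical Weiszfeld iteration on the unit sphere
#' (tolerance 1e-10 radians on the update step, at most 1000 iterations),
#' falling back to a 0.01-degree local grid search on non-convergence.
#'
#' @param lat,lon numeric vectors of coordinates (decimal degrees).
#' @param ids optional character vector of accession ids (defaults to
#'   `"p1"..."pn"`).
#' @return a list of class `geo_summary`: `n`, `mean_pairwise_km`, `min_km`,
#'   `max_km`, `gcf_id`, `gcf`, `gmc` (both `geo_point`), `gcf_tie` flag.
#' @export
geo_summary <- function(lat, lon, ids = NULL) {
  stopifnot(length(lat) == length(lon))
  keep <- is.finite(lat) & is.finite(lon)
  lat <- lat[keep]; lon <- lon[keep]
  n <- length(lat)
  if (n == 0L) stop("geo_summary needs at least one located point", call. = FALSE)
  if (is.null(ids)) ids <- paste0("p", seq_len(n)) else ids <- ids[keep]
  if (n == 1L) {
    pt <- geo_point(lat, lon)
    return(structure(list(n = 1L, mean_pairwise_km = 0, min_km = 0, max_km = 0,
                          gcf_id = ids, gcf = pt, gmc = pt, gcf_tie = FALSE),
                     class = "geo_summary"))
  }
  dm <- pairwise_km_matrix(lat, lon)
  ut <- dm[upper.tri(dm)]
  mean_to_others <- rowSums(dm) / (n - 1)
  best <- min(mean_to_others)
  cand <- which(mean_to_others <= best + 1e-9)
  gcf_i <- cand[order(ids[cand])][1]
  gmc <- spherical_median(lat, lon)
  structure(list(
    n = n,
    mean_pairwise_km = mean(ut),
    min_km = min(ut),
    max_km = max(ut),
    gcf_id = ids[gcf_i],
    gcf = geo_point(lat[gcf_i], lon[gcf_i]),
    gmc = gmc,
    gcf_tie = length(cand) > 1L
  ), class = "geo_summary")
}

# Spherical geometric median via Weiszfeld iteration in the tangent plane:
# the step is the 1/distance-weighted mean of the log-map images of the
# points, so the fixed point satisfies the stationarity condition
# sum of unit tangents = 0 of the mean-great-circle-distance objective.
spherical_median <- function(lat, lon, tol = 1e-10, max_iter = 1000L) {
  phi <- lat * pi / 180; lam <- lon * pi / 180
  X <- cbind(cos(phi) * cos(lam), cos(phi) * sin(lam), sin(phi))
  y <- colMeans(X)
  ny <- sqrt(sum(y^2))
  if (ny < 1e-12) y <- X[1, ] else y <- y / ny
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    cosang <- pmin(1, pmax(-1, as.numeric(X %*% y)))
    ang <- acos(cosang)
    active <- ang > 1e-12          # coincident points carry no pull
    if (!any(active)) { converged <- TRUE; break }
    # unit tangents from y toward each point
    U <- X[active, , drop = FALSE] -
      outer(cosang[active], y)
    nu <- sqrt(rowSums(U^2))
    ok <- nu > 1e-15
    if (!any(ok)) { converged <- TRUE; break }
    U <- U[ok, , drop = FALSE] / nu[ok]
    th <- ang[active][ok]
    t_vec <- colSums(U) / sum(1 / th)
    tl <- sqrt(sum(t_vec^2))
    if (tl < tol) { converged <- TRUE; break }
    y <- cos(tl) * y + sin(tl) * t_vec / tl
    y <- y / sqrt(sum(y^2))
  }
  pt <- vec_to_latlon(y)
  if (!converged) pt <- grid_refine_median(lat, lon, pt)
  pt
}

vec_to_latlon <- function(v) {
  geo_point(asin(pmin(1, pmax(-1, v[3]))) * 180 / pi, atan2(v[2], v[1]) * 180 / pi)
}

mean_dist_objective <- function(pt, lat, lon) {
  mean(haversine_to_many(pt, lat, lon))
}

grid_refine_median <- function(lat, lon, start, span = 1, step = 0.01) {
  gl <- seq(start[["lat"]] - span, start[["lat"]] + span, by = step)
  gl <- gl[gl >= -90 & gl <= 90]
  gn <- seq(start[["lon"]] - span, start[["lon"]] + span, by = step)
  best <- start; best_obj <- mean_dist_objective(start, lat, lon)
  for (la in gl) for (lo in gn) {
    obj <- mean_dist_objective(c(la, lo), lat, lon)
    if (obj < best_obj) { best_obj <- obj; best <- geo_point(la, lo) }
  }
  best
}

#' Spatial kernel density of sample coordinates
#'
#' Product-Gaussian kernel density estimate on a longitude/latitude grid,
#' computed with [MASS::kde2d()] and normalised so the discrete integral over
#' the grid is 1. The default bandwidth is the normal reference rule per axis.
#'
#' @param lat,lon coordinates of the samples (decimal degrees).
#' @param n grid resolution per axis (default 100).
#' @param lims optional `c(lon_min, lon_max, lat_min, lat_max)`; default pads
#'   the data range by 10 percent of its span (at least 1 degree).
#' @param bandwidth optional length-2 numeric `c(h_lon, h_lat)`; required when
#'   an axis has zero variance.
#' @return list of class `density_surface`: `lon`, `lat` (grid axes),
#'   `density` (matrix lon x lat summing to 1 over cells times cell area
#'   weights), `bandwidth`.
#' @export
kernel_density <- function(lat, lon, n = 100, lims = NULL, bandwidth = NULL) {
  stopifnot(length(lat) == length(lon))
  if (is.null(bandwidth)) {
    if (length(lat) < 2) {
      stop("automatic bandwidth needs >= 2 points; supply `bandwidth`", call. = FALSE)
    }
    h <- c(MASS::bandwidth.nrd(lon), MASS::bandwidth.nrd(lat))
    if (any(h <= 0)) {
      stop("zero-variance axis: supply an explicit `bandwidth`", call. = FALSE)
    }
  } else {
    h <- rep_len(bandwidth, 2L)
    if (any(h <= 0)) stop("bandwidth must be positive", call. = FALSE)
  }
  if (is.null(lims)) {
    pad_x <- max(1, diff(range(lon)) * 0.1)
    pad_y <- max(1, diff(range(lat)) * 0.1)
    lims <- c(range(lon) + c(-pad_x, pad_x), range(lat) + c(-pad_y, pad_y))
  }
  kd <- MASS::kde2d(lon, lat, h = h, n = n, lims = lims)
  cell <- diff(kd$x)[1] * diff(kd$y)[1]
  z <- kd$z / (sum(kd$z) * cell)
  structure(list(lon = kd$x, lat = kd$y, density = z, bandwidth = h,
                 cell_area = cell),
            class = "density_surface")
}

#' Mantel test between two distance matrices
#'
#' One-sided (positive association) permutation Mantel test: the statistic is
#' the Pearson correlation of the off-diagonal triangles, and the p-value is
#' `(1 + #\{permuted r >= observed r\}) / (n_perm + 1)` with rows and columns
#' permuted jointly. Delegates the permutation machinery to [vegan::mantel()].
#'
#' @param d1,d2 symmetric zero-diagonal distance matrices of the same size
#'   (>= 3).
#' @param n_perm number of permutations (default 9999).
#' @param seed integer seed controlling the permutations.
#' @return list of class `mantel_result`: `r`, `p`, `n_perm`, `seed`, `n`.
#' @export
mantel_test <- function(d1, d2, n_perm = 9999, seed = 1L) {
  d1 <- as.matrix(d1); d2 <- as.matrix(d2)
  check_dist_matrix(d1, "d1"); check_dist_matrix(d2, "d2")
  if (!all(dim(d1) == dim(d2))) stop("matrices differ in size", call. = FALSE)
  if (nrow(d1) < 3) stop("Mantel test needs matrices of size >= 3", call. = FALSE)
  v1 <- d1[lower.tri(d1)]; v2 <- d2[lower.tri(d2)]
  if (sd(v1) == 0 || sd(v2) == 0) {
    stop("constant distance matrix: Mantel r undefined", call. = FALSE)
  }
  set.seed(seed)
  mt <- vegan::mantel(stats::as.dist(d1), stats::as.dist(d2),
                      method = "pearson",
                      permutations = permute::how(nperm = n_perm, minperm = 2))
  structure(list(r = unname(mt$statistic), p = unname(mt$signif),
                 n_perm = n_perm, seed = seed, n = nrow(d1)),
            class = "mantel_result")
}

check_dist_matrix <- function(m, name) {
  if (nrow(m) != ncol(m)) stop(name, " is not square", call. = FALSE)
  if (max(abs(m - t(m))) > 1e-8) stop(name, " is not symmetric", call. = FALSE)
  if (max(abs(diag(m))) > 1e-8) stop(name, " has a nonzero diagonal", call. = FALSE)
}
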