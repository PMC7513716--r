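#' Intersection filter for the origin regression
#'
#' Restricts the haplotype set used by the genetic-spatial regression to
#' haplotypes belonging to the requested structure groups AND having at
#' least one carrier in the requested regions, eliminating interference
#' from foreign haplotypes. An explicit extra-include list can re-admit an
#' external reference haplotype.
#'
#' @param groups named character vector mapping haplotype id to AO group.
#' @param region_counts data.frame of carrier counts, rownames = haplotype
#'   ids, one column per region.
#' @param genotypic_groups AO groups to keep.
#' @param spatial_groups regions to keep.
#' @param extra_include haplotype ids admitted regardless of the filter.
#' @return character vector of haplotype ids (table order, extras last).
#' @export
filter_haplotype_set <- function(groups, region_counts, genotypic_groups,
                                 spatial_groups, extra_include = character(0)) {
  missing_regions <- setdiff(spatial_groups, colnames(region_counts))
  if (length(missing_regions)) {
    stop("unknown region(s): ", paste(missing_regions, collapse = ", "),
         call. = FALSE)
  }
  haps <- names(groups)
  in_group <- groups %in% genotypic_groups
  counts <- region_counts[haps, spatial_groups, drop = FALSE]
  counts[is.na(counts)] <- 0
  in_region <- rowSums(counts) >= 1
  keep <- haps[in_group & in_region]
  c(keep, setdiff(extra_include, keep))
}

#' Mean geographic distance vector from a candidate origin
#'
#' For each haplotype in the set (the target excluded),
#' `x_i = mean_j d(candidate, carrier_ij)` over that haplotype's located
#' carriers.
#'
#' @param candidate `geo_point` (or `c(lat, lon)`).
#' @param accessions data.frame with columns `lat`, `lon`, `haplotype`.
#' @param hap_set haplotype ids to use.
#' @param target target haplotype id (excluded from the vector).
#' @return named numeric vector of mean distances (km).
#' @export
mean_distance_vector <- function(candidate, accessions, hap_set, target) {
  haps <- setdiff(hap_set, target)
  vapply(haps, function(h) {
    sel <- accessions$haplotype == h & is.finite(accessions$lat) &
      is.finite(accessions$lon)
    if (!any(sel)) stop("haplotype ", h, " has no located carrier", call. = FALSE)
    mean(haversine_to_many(candidate, accessions$lat[sel], accessions$lon[sel]))
  }, 0)
}

#' Ordinary least squares fit of the distance-genetics regression
#'
#' Fits `y = a x + b` with an intercept and reports the coefficient of
#' determination `r2 = 1 - SSres/SStot`.
#'
#' @param x mean geographic distances (km).
#' @param y genetic distances from the target haplotype.
#' @return list of class `regression_fit`: `a` (slope), `b` (intercept),
#'   `r2`, `n`.
#' @export
fit_origin_regression <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 haplotypes", call. = FALSE)
  if (sd(x) == 0) stop("degenerate fit: x is constant", call. = FALSE)
  xc <- x - mean(x); yc <- y - mean(y)
  a <- sum(xc * yc) / sum(xc^2)
  b <- mean(y) - a * mean(x)
  sst <- sum(yc^2)
  r2 <- if (sst == 0) 1 else 1 - sum((y - (a * x + b))^2) / sst
  structure(list(a = a, b = b, r2 = r2, n = length(x)),
            class = "regression_fit")
}

#' Scan candidate origins on a geographic grid
#'
#' For every cell of a latitude/longitude lattice, recomputes the mean
#' distance vector `x` from the cell centre and fits the distance-genetics
#' regression against the fixed genetic distance vector `y` (computed once:
#' it does not depend on the candidate). The surface of `R^2` values
#' delineates candidate origin areas of the target haplotype.
#'
#' @param accessions data.frame with `lat`, `lon`, `haplotype` (located
#'   carriers of the haplotype set).
#' @param target target haplotype id.
#' @param hap_set haplotype ids to use (from [filter_haplotype_set()]);
#'   must contain the target plus >= 3 other haplotypes with located
#'   carriers.
#' @param y named genetic distance vector (target vs each other haplotype);
#'   if `NULL`, computed from `seqs` with `genetic_fn`.
#' @param seqs named sequences (needed when `y` is `NULL`).
#' @param genetic_fn pairwise distance function `f(a, b)` (default
#'   [tajima_nei_distance()]; any distance, e.g. a per-site p-distance, can
#'   be injected).
#' @param grid_step lattice step in degrees (default 0.1).
#' @param pad padding of the carrier bounding box in degrees (default 5).
#' @param weighted if `TRUE`, weight each haplotype by its carrier count in
#'   the fit (off by default: each haplotype is one point).
#' @return list of class `origin_surface`: `lat`, `lon` (cell-centre axes),
#'   `r2` (matrix lat x lon, `NA` = degenerate cell), `a`, `b` (coefficient
#'   matrices), `target`, `hap_set`, `step`, `y`.
#' @export
scan_origin <- function(accessions, target, hap_set, y = NULL, seqs = NULL,
                        genetic_fn = tajima_nei_distance,
                        grid_step = 0.1, pad = 5, weighted = FALSE) {
  others <- setdiff(hap_set, target)
  if (length(others) < 3) stop("need at least 3 non-target haplotypes", call. = FALSE)
  acc <- accessions[accessions$haplotype %in% hap_set &
                    is.finite(accessions$lat) & is.finite(accessions$lon), ,
                    drop = FALSE]
  for (h in others) {
    if (!any(acc$haplotype == h)) {
      stop("haplotype ", h, " has no located carrier", call. = FALSE)
    }
  }
  if (is.null(y)) {
    if (is.null(seqs)) stop("supply y or seqs", call. = FALSE)
    y <- vapply(others, function(h) genetic_fn(seqs[[target]], seqs[[h]]), 0)
  } else {
    y <- y[others]
    if (anyNA(y)) stop("y lacks entries for some haplotypes", call. = FALSE)
  }
  lat_axis <- seq(floor((min(acc$lat) - pad) / grid_step) * grid_step,
                  max(acc$lat) + pad, by = grid_step)
  lat_axis <- lat_axis[lat_axis >= -90 & lat_axis <= 90]
  lon_axis <- seq(floor((min(acc$lon) - pad) / grid_step) * grid_step,
                  max(acc$lon) + pad, by = grid_step)
  grid <- expand.grid(lat = lat_axis, lon = lon_axis)
  ncell <- nrow(grid)
  # cells x haplotypes matrix of mean carrier distances
  X <- matrix(0, ncell, length(others), dimnames = list(NULL, others))
  for (h in others) {
    sel <- which(acc$haplotype == h)
    s <- numeric(ncell)
    for (k in sel) {
      s <- s + geosphere::distHaversine(
        cbind(grid$lon, grid$lat), c(acc$lon[k], acc$lat[k]),
        r = EARTH_RADIUS_KM * 1000) / 1000
    }
    X[, h] <- s / length(sel)
  }
  wts <- if (weighted) {
    vapply(others, function(h) sum(acc$haplotype == h), 0)
  } else rep(1, length(others))
  wts <- wts / sum(wts)
  xbar <- as.numeric(X %*% wts)
  ybar <- sum(wts * y)
  Xc <- X - xbar
  ycw <- wts * (y - ybar)
  sxy <- as.numeric(Xc %*% ycw)
  sxx <- as.numeric((Xc^2) %*% wts)
  syy <- sum(wts * (y - ybar)^2)
  a <- ifelse(sxx > 0, sxy / sxx, NA_real_)
  b <- ybar - a * xbar
  r2 <- ifelse(sxx > 0 & syy > 0, (sxy^2) / (sxx * syy), NA_real_)
  shape <- c(length(lat_axis), length(lon_axis))
  structure(list(
    lat = lat_axis, lon = lon_axis,
    r2 = matrix(r2, shape[1], shape[2]),
    a = matrix(a, shape[1], shape[2]),
    b = matrix(b, shape[1], shape[2]),
    target = target, hap_set = hap_set, step = grid_step, y = y,
    carriers = acc[, c("lat", "lon", "haplotype")], weights = wts
  ), class = "origin_surface")
}

#' Hotspot region of an origin surface
#'
#' Member cells are those whose regression fit reaches the threshold
#' (default `R^2 >= 0.8`); degenerate (undefined) cells never qualify. The
#' peak cell maximises `R^2` (ties resolved to the smallest latitude, then
#' longitude); the bounding box is reported as latitude range x longitude
#' range.
#'
#' @param surface an `origin_surface`.
#' @param threshold membership threshold (default 0.8).
#' @return list of class `hotspot`: `cells` (lat, lon, r2), `threshold`,
#'   `peak` (or NULL when empty), `bbox`
#'   (`lat_min/lat_max/lon_min/lon_max`, NULL when empty), `step`.
#' @export
hotspot_region <- function(surface, threshold = 0.8) {
  idx <- which(!is.na(surface$r2) & surface$r2 >= threshold, arr.ind = TRUE)
  cells <- data.frame(lat = surface$lat[idx[, 1]], lon = surface$lon[idx[, 2]],
                      r2 = surface$r2[idx])
  cells <- cells[order(cells$lat, cells$lon), , drop = FALSE]
  rownames(cells) <- NULL
  peak <- NULL; bbox <- NULL
  if (nrow(cells)) {
    pk <- cells[abs(cells$r2 - max(cells$r2)) < 1e-12, , drop = FALSE]
    pk <- pk[order(pk$lat, pk$lon), , drop = FALSE][1, ]
    peak <- pk
    bbox <- c(lat_min = min(cells$lat), lat_max = max(cells$lat),
              lon_min = min(cells$lon), lon_max = max(cells$lon))
  }
  structure(list(cells = cells, threshold = threshold, peak = peak,
                 bbox = bbox, step = surface$step),
            class = "hotspot")
}

#' Peak of an origin surface
#'
#' Locates the cell maximising the regression fit (ties resolved to the
#' smallest latitude, then longitude). With `refine = TRUE` the peak is
#' polished by continuous local optimisation of the same R^2 objective
#' starting from that cell, removing the lattice discretisation from the
#' reported optimum (the R^2 surface is smooth in the candidate
#' coordinate).
#'
#' @param surface an `origin_surface`.
#' @param refine polish the peak off-lattice (default `FALSE`).
#' @return list with `lat`, `lon`, `r2` of the peak.
#' @export
surface_argmax <- function(surface, refine = FALSE) {
  mx <- max(surface$r2, na.rm = TRUE)
  idx <- which(!is.na(surface$r2) & abs(surface$r2 - mx) < 1e-12, arr.ind = TRUE)
  ord <- order(surface$lat[idx[, 1]], surface$lon[idx[, 2]])
  i <- idx[ord[1], ]
  peak <- list(lat = surface$lat[i[1]], lon = surface$lon[i[2]], r2 = mx)
  if (!refine) return(peak)
  if (is.null(surface$carriers)) {
    stop("surface lacks carrier coordinates; rebuild it with scan_origin()",
         call. = FALSE)
  }
  obj <- function(par) -origin_r2_at(geo_point(max(-90, min(90, par[1])),
                                               par[2]), surface)
  opt <- stats::optim(c(peak$lat, peak$lon), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 2000))
  if (-opt$value >= peak$r2) {
    peak <- list(lat = opt$par[1], lon = ((opt$par[2] + 180) %% 360) - 180,
                 r2 = -opt$value)
  }
  peak
}

# R^2 of the distance-genetics regression at an arbitrary candidate origin.
origin_r2_at <- function(candidate, surface) {
  others <- setdiff(surface$hap_set, surface$target)
  x <- mean_distance_vector(candidate, surface$carriers, surface$hap_set,
                            surface$target)[others]
  y <- surface$y[others]
  w <- surface$weights
  xbar <- sum(w * x); ybar <- sum(w * y)
  sxy <- sum(w * (x - xbar) * (y - ybar))
  sxx <- sum(w * (x - xbar)^2); syy <- sum(w * (y - ybar)^2)
  if (sxx <= 0 || syy <= 0) return(NA_real_)
  sxy^2 / (sxx * syy)
}
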