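BASES <- c("A", "C", "G", "T")
TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")

# Run `expr` with the global RNG stream untouched (library synthesis uses its
# own deterministic stream).
with_local_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

random_dna <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

# ---- sequence synthesis from a variant table -------------------------------

#' Deterministic filler-block library for a variant table
#'
#' Block substitutions and numeric insertion states in a variant table refer
#' to sequence blocks whose content is not part of the table. This helper
#' synthesises one distinct random filler sequence per required
#' (locus, length) combination, reproducibly. Real deposited block sequences
#' can be supplied instead through the same named-list interface.
#'
#' @param vt a `variant_table`.
#' @param seed RNG seed for the filler content (default 20200627).
#' @return named list of DNA strings; names are `"<start>-<end>:<len>"` for
#'   substitution blocks and `"ins:<pos>:<len>"` for insertions of unknown
#'   sequence.
#' @export
default_block_library <- function(vt, seed = 20200627) {
  haps <- attr(vt, "haplotype_ids")
  keys <- character(0)
  for (i in seq_len(nrow(vt))) {
    st <- as.character(vt[i, haps])
    if (vt$kind[i] == "Sub") {
      ref_len <- vt$ref_end[i] - vt$ref_pos[i] + 1L
      for (len in unique(as.integer(st[!is.na(st)]))) {
        if (len != ref_len) {
          keys <- c(keys, paste0(vt$ref_pos[i], "-", vt$ref_end[i], ":", len))
        }
      }
    } else if (vt$kind[i] == "Ins") {
      num <- suppressWarnings(as.integer(st))
      for (len in unique(num[!is.na(num)])) {
        keys <- c(keys, paste0("ins:", vt$ref_pos[i], ":", len))
      }
    }
  }
  keys <- unique(keys)
  with_local_seed(seed, {
    setNames(lapply(keys, function(k) {
      len <- as.integer(sub(".*:", "", k))
      random_dna(len)
    }), keys)
  })
}

#' Build aligned haplotype sequences from a variant table
#'
#' Realises every haplotype of a variant table as a gapped sequence on a
#' common alignment, starting from a template carrying the reference
#' haplotype's coordinate system. SNP states substitute single bases; block
#' substitutions replace the reference window with a block of the stated
#' length (the reference-length state keeps the template block, other lengths
#' come from `block_library`); insertions add columns padded with `-` for the
#' haplotypes lacking them. Shorter blocks are right-padded with `-`.
#'
#' @param template ungapped DNA string covering `max(ref_end)` positions.
#' @param vt a `variant_table`.
#' @param block_library named list of block sequences as produced by
#'   [default_block_library()]; blocks required by `vt` but absent from the
#'   library are an error.
#' @return named character vector of aligned sequences (equal lengths) with
#'   attributes `col_ref` (reference position per alignment column, `NA` in
#'   block/insertion columns), `col_kind` (`plain`/`snp`/`sub`/`ins`) and
#'   `loci` (data.frame mapping each variant record to its column range).
#' @export
build_sequences_from_variant_table <- function(template, vt,
                                               block_library = default_block_library(vt)) {
  haps <- attr(vt, "haplotype_ids")
  L <- nchar(template)
  if (nrow(vt) > 0 && L < max(vt$ref_end)) {
    stop("template shorter than the variant table's coordinate span", call. = FALSE)
  }
  pieces <- rep(list(character(0)), length(haps))
  names(pieces) <- haps
  col_ref <- integer(0); col_kind <- character(0)
  loci <- data.frame(row = seq_len(nrow(vt)), kind = vt$kind,
                     ref_pos = vt$ref_pos,
                     col_start = rep(NA_integer_, nrow(vt)),
                     col_end = rep(NA_integer_, nrow(vt)))
  cursor <- 1L
  ncol_now <- 0L

  # SNPs falling inside a Sub window are applied within the block content of
  # the haplotypes carrying the reference-length block (the variant exists
  # only in that block's coordinate frame); interior Ins are unsupported
  sub_rows <- which(vt$kind == "Sub")
  interior_of <- rep(NA_integer_, nrow(vt))
  for (i in seq_len(nrow(vt))) {
    if (vt$kind[i] == "Sub") next
    hit <- sub_rows[vt$ref_pos[sub_rows] <= vt$ref_pos[i] &
                    vt$ref_end[sub_rows] >= vt$ref_pos[i]]
    if (length(hit)) {
      if (vt$kind[i] == "Ins") {
        stop("insertion inside a block-substitution window is unsupported",
             call. = FALSE)
      }
      interior_of[i] <- hit[1]
    }
  }

  emit <- function(strs, refs, kinds) {
    for (h in haps) pieces[[h]] <<- c(pieces[[h]], strs[[h]])
    col_ref <<- c(col_ref, refs)
    col_kind <<- c(col_kind, kinds)
    ncol_now <<- ncol_now + length(refs)
  }
  emit_plain <- function(a, b) {
    if (b < a) return(invisible())
    seg <- substr(template, a, b)
    emit(setNames(rep(list(seg), length(haps)), haps), a:b, rep("plain", b - a + 1L))
  }
  pad <- function(s, w) paste0(s, strrep("-", w - nchar(s)))

  for (i in seq_len(nrow(vt))) {
    if (!is.na(interior_of[i])) next  # handled with its enclosing block
    kind <- vt$kind[i]; a <- vt$ref_pos[i]; b <- vt$ref_end[i]
    st <- as.character(vt[i, haps]); names(st) <- haps
    if (kind == "SNP") {
      emit_plain(cursor, a - 1L)
      start_col <- ncol_now + 1L
      emit(as.list(st), a, "snp")
      cursor <- a + 1L
    } else if (kind == "Sub") {
      emit_plain(cursor, a - 1L)
      ref_len <- b - a + 1L
      lens <- as.integer(st)
      if (anyNA(lens)) stop("missing Sub state in row ", i, call. = FALSE)
      w <- max(lens)
      blocks <- vapply(lens, function(len) {
        if (len == ref_len) substr(template, a, b)
        else {
          key <- paste0(a, "-", b, ":", len)
          blk <- block_library[[key]]
          if (is.null(blk)) stop("block library lacks ", key, call. = FALSE)
          if (nchar(blk) != len) stop("block ", key, " has wrong length", call. = FALSE)
          blk
        }
      }, "")
      names(blocks) <- haps
      for (s in which(interior_of == i)) {
        off <- vt$ref_pos[s] - a + 1L
        snp_states <- as.character(vt[s, haps])
        for (hi in seq_along(haps)) {
          if (lens[hi] == ref_len) {
            substr(blocks[hi], off, off) <- snp_states[hi]
          }
        }
        loci$col_start[s] <- ncol_now + off
        loci$col_end[s] <- ncol_now + off
      }
      start_col <- ncol_now + 1L
      emit(as.list(setNames(pad(blocks, w), haps)), rep(NA_integer_, w),
           rep("sub", w))
      cursor <- b + 1L
    } else { # Ins (anchored after position a)
      emit_plain(cursor, a)
      if (a >= cursor) cursor <- a + 1L
      ins_seq <- vapply(st, function(s) {
        if (is.na(s)) return("")
        n <- suppressWarnings(as.integer(s))
        if (!is.na(n) && !grepl("[ACGTN-]", s)) {
          key <- paste0("ins:", a, ":", n)
          blk <- block_library[[key]]
          if (is.null(blk)) stop("block library lacks ", key, call. = FALSE)
          blk
        } else s
      }, "")
      w <- max(nchar(ins_seq))
      start_col <- ncol_now + 1L
      if (w > 0) emit(as.list(setNames(pad(ins_seq, w), haps)),
                      rep(NA_integer_, w), rep("ins", w))
    }
    loci$col_start[i] <- start_col
    loci$col_end[i] <- ncol_now
  }
  emit_plain(cursor, L)
  seqs <- vapply(pieces, paste, "", collapse = "")
  structure(seqs, col_ref = col_ref, col_kind = col_kind, loci = loci,
            template = template)
}

# ---- dispersal panel -------------------------------------------------------

#' Parameters of the dispersal simulation
#'
#' Defines a panel in which derived haplotypes radiate from a single origin
#' and a haplotype's genetic distance from the ancestor grows linearly with
#' its carriers' mean great-circle distance from the origin:
#' `k_i / seq_len ~ slope_a * x_i + intercept_b + Normal(0, noise_sd)`.
#'
#' @param origin `geo_point` of the true origin.
#' @param slope_a genetic distance (substitutions/site) per km, >= 0.
#' @param intercept_b genetic distance at zero geographic distance.
#' @param noise_sd standard deviation of the Gaussian noise on the per-site
#'   distance (0 = exactly collinear up to integer rounding of k).
#' @param n_haplotypes number of haplotypes including the ancestral one (>= 2).
#' @param carriers_per_hap either a positive integer (fixed count) or a
#'   function `f(n)` returning `n` positive integers; the default draws
#'   `1 + Poisson(2)` to emulate skewed carrier counts.
#' @param dispersal_sd_km spread of carriers around each haplotype's focal
#'   point (bearing uniform, distance `|Normal(0, sd)|` along the geodesic).
#' @param focal_range_km range (km) from which each derived haplotype's focal
#'   distance from the origin is drawn uniformly.
#' @param seq_len sequence length in bp.
#' @param ts_tv transition:transversion odds used when mutating (default 2).
#' @param seed integer RNG seed.
#' @return a list of class `dispersal_params`.
#' @export
dispersal_params <- function(origin = geo_point(23.7, 90.4),
                             slope_a = 5e-6, intercept_b = 5e-4, noise_sd = 0,
                             n_haplotypes = 8,
                             carriers_per_hap = function(n) 1L + rpois(n, 2),
                             dispersal_sd_km = 150,
                             focal_range_km = c(100, 1500),
                             seq_len = 10000, ts_tv = 2, seed = 1L) {
  stopifnot(slope_a >= 0, noise_sd >= 0, n_haplotypes >= 2, seq_len > 0,
            length(focal_range_km) == 2L, focal_range_km[1] <= focal_range_km[2])
  if (!inherits(origin, "geo_point")) origin <- geo_point(origin[1], origin[2])
  exp_max <- seq_len * (slope_a * focal_range_km[2] + intercept_b)
  if (exp_max > seq_len / 4) {
    stop("expected mutation count exceeds seq_len/4; increase seq_len or ",
         "lower slope_a/intercept_b", call. = FALSE)
  }
  structure(list(origin = origin, slope_a = slope_a, intercept_b = intercept_b,
                 noise_sd = noise_sd, n_haplotypes = as.integer(n_haplotypes),
                 carriers_per_hap = carriers_per_hap,
                 dispersal_sd_km = dispersal_sd_km,
                 focal_range_km = focal_range_km,
                 seq_len = as.integer(seq_len), ts_tv = ts_tv,
                 seed = as.integer(seed)),
            class = "dispersal_params")
}

mutate_sequence <- function(seq, k, ts_tv) {
  if (k == 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  if (k > length(chars)) stop("mutation count exceeds sequence length", call. = FALSE)
  sites <- sample.int(length(chars), k)
  for (s in sites) {
    b <- chars[s]
    if (runif(1) < ts_tv / (ts_tv + 1)) {
      chars[s] <- TRANSITION[[b]]
    } else {
      chars[s] <- sample(setdiff(BASES, c(b, TRANSITION[[b]])), 1)
    }
  }
  paste(chars, collapse = "")
}

n_carriers <- function(sampler, n) {
  if (is.function(sampler)) out <- sampler(n) else out <- rep_len(sampler, n)
  out <- as.integer(out)
  if (anyNA(out) || any(out < 1)) stop("carriers_per_hap must be >= 1", call. = FALSE)
  out
}

#' Simulate a georeferenced dispersal panel
#'
#' Generates accessions carrying haplotypes that dispersed from a single
#' origin under the linear distance-genetics model of [dispersal_params()].
#' Haplotype `HS01` is the ancestral haplotype, seated at the origin; each
#' derived haplotype receives a focal point at a uniform distance from the
#' origin, carriers scattered around it, and a sequence derived from the
#' ancestor by `k_i` point mutations placed without replacement, with
#' `k_i = round(seq_len * (a x_i + b + noise))` and `x_i` the realised mean
#' carrier distance from the origin. Fully reproducible from the seed.
#'
#' @param params a `dispersal_params` object.
#' @return list of class `synthetic_panel`: `accessions` (an
#'   `accession_panel` data.frame), `haplotype_seqs` (named character) and
#'   `truth` (the parameters).
#' @export
simulate_dispersal_panel <- function(params = dispersal_params()) {
  stopifnot(inherits(params, "dispersal_params"))
  set.seed(params$seed)
  n <- params$n_haplotypes
  ids <- sprintf("HS%02d", seq_len(n))
  ancestor <- random_dna(params$seq_len)
  counts <- n_carriers(params$carriers_per_hap, n)
  origin <- params$origin

  acc <- list(); seqs <- setNames(character(n), ids)
  for (i in seq_len(n)) {
    if (i == 1L) {
      focal <- unclass(origin)
    } else {
      fd <- runif(1, params$focal_range_km[1], params$focal_range_km[2])
      focal <- unlist(displace_km(origin, runif(1, 0, 360), fd))
      focal <- c(lat = focal[["lat"]], lon = focal[["lon"]])
    }
    m <- counts[i]
    off <- displace_km(c(focal[["lat"]], focal[["lon"]]),
                       runif(m, 0, 360), abs(rnorm(m, 0, params$dispersal_sd_km)))
    x_i <- mean(haversine_to_many(origin, off$lat, off$lon))
    if (i == 1L) {
      k <- 0L
    } else {
      d <- params$slope_a * x_i + params$intercept_b +
        rnorm(1, 0, params$noise_sd)
      k <- max(0L, as.integer(round(params$seq_len * d)))
      if (k > params$seq_len) {
        stop("infeasible mutation count for haplotype ", ids[i], call. = FALSE)
      }
    }
    seqs[i] <- mutate_sequence(ancestor, k, params$ts_tv)
    acc[[i]] <- data.frame(
      id = sprintf("%s-%02d", ids[i], seq_len(m)),
      taxon = "rufipogon", subgroup = "unknown", cytotype = "unknown",
      region = "unknown", lat = off$lat, lon = off$lon, haplotype = ids[i])
  }
  accessions <- do.call(rbind, acc)
  class(accessions) <- c("accession_panel", "data.frame")
  structure(list(accessions = accessions, haplotype_seqs = seqs, truth = params),
            class = "synthetic_panel")
}

#' Simulate a null panel with no distance-genetics association
#'
#' Carrier coordinates are uniform in a bounding box, independent of the
#' mutation process, so the true correlation between genetic and geographic
#' distances is zero.
#'
#' @param n_haplotypes number of haplotypes (>= 1).
#' @param carriers_per_hap as in [dispersal_params()].
#' @param bbox `c(lat_min, lat_max, lon_min, lon_max)`, non-degenerate.
#' @param seq_len sequence length in bp.
#' @param mutation_rate per-site probability that a haplotype differs from
#'   the ancestor at a site.
#' @param seed integer RNG seed.
#' @return a `synthetic_panel` (with `truth = NULL`).
#' @export
simulate_null_panel <- function(n_haplotypes = 6,
                                carriers_per_hap = function(n) 1L + rpois(n, 2),
                                bbox = c(5, 30, 80, 110),
                                seq_len = 1000, mutation_rate = 0.01, seed = 1L) {
  stopifnot(length(bbox) == 4L)
  if (bbox[2] <= bbox[1] || bbox[4] <= bbox[3]) {
    stop("degenerate bounding box", call. = FALSE)
  }
  if (n_haplotypes < 1) stop("need at least one haplotype", call. = FALSE)
  set.seed(seed)
  ids <- sprintf("HN%02d", seq_len(n_haplotypes))
  ancestor <- random_dna(seq_len)
  counts <- n_carriers(carriers_per_hap, n_haplotypes)
  seqs <- setNames(character(n_haplotypes), ids)
  acc <- list()
  for (i in seq_len(n_haplotypes)) {
    k <- stats::rbinom(1, seq_len, mutation_rate)
    seqs[i] <- mutate_sequence(ancestor, k, 2)
    m <- counts[i]
    acc[[i]] <- data.frame(
      id = sprintf("%s-%02d", ids[i], seq_len(m)),
      taxon = "rufipogon", subgroup = "unknown", cytotype = "unknown",
      region = "unknown",
      lat = runif(m, bbox[1], bbox[2]), lon = runif(m, bbox[3], bbox[4]),
      haplotype = ids[i])
  }
  accessions <- do.call(rbind, acc)
  class(accessions) <- c("accession_panel", "data.frame")
  structure(list(accessions = accessions, haplotype_seqs = seqs, truth = NULL),
            class = "synthetic_panel")
}

#' Per-haplotype genetic and geographic distance matrices of a panel
#'
#' Genetic distances are per-site p-distances between the haplotype
#' sequences; geographic distances are great-circle distances between the
#' mean carrier coordinates of each haplotype. Used for Mantel tests of
#' isolation by distance.
#'
#' @param panel a `synthetic_panel` (or list with `accessions` and
#'   `haplotype_seqs`).
#' @return list with square matrices `genetic` and `geographic` (haplotype
#'   ids as dimnames).
#' @export
panel_distance_matrices <- function(panel) {
  ids <- names(panel$haplotype_seqs)
  n <- length(ids)
  if (n < 2) stop("panel has fewer than two haplotypes", call. = FALSE)
  gen <- matrix(0, n, n, dimnames = list(ids, ids))
  L <- nchar(panel$haplotype_seqs[[1]])
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    k <- pairwise_differences(panel$haplotype_seqs[[i]], panel$haplotype_seqs[[j]])
    gen[i, j] <- gen[j, i] <- k / L
  }
  lat <- tapply(panel$accessions$lat, panel$accessions$haplotype, mean)[ids]
  lon <- tapply(panel$accessions$lon, panel$accessions$haplotype, mean)[ids]
  geo <- pairwise_km_matrix(as.numeric(lat), as.numeric(lon))
  dimnames(geo) <- list(ids, ids)
  list(genetic = gen, geographic = geo)
}
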