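PIPELINE_STAGES <- c("typing", "popgen", "network", "geo", "origin")

#' Read a pipeline configuration file
#'
#' YAML key-value file; see [run_pipeline()] for the recognised keys.
#'
#' @param path YAML path.
#' @return named list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config must be a YAML mapping", call. = FALSE)
  cfg
}

validate_config <- function(cfg) {
  stages <- cfg$stages %||% PIPELINE_STAGES
  bad <- setdiff(stages, PIPELINE_STAGES)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  stochastic <- length(intersect(stages, c("geo", "popgen"))) > 0 ||
    !is.null(cfg$simulate)
  if (stochastic && is.null(cfg$seed)) {
    stop("seed is mandatory when a stochastic stage is enabled", call. = FALSE)
  }
  stages
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the analysis pipeline on a panel
#'
#' Orchestrates the stages typing -> popgen -> network -> geo -> origin on
#' either a simulated dispersal panel or externally supplied inputs, and
#' returns an analysis report whose provenance block records every
#' parameter. Re-running with the same configuration yields an identical
#' report.
#'
#' Recognised configuration keys: `seed` (mandatory whenever any stochastic
#' stage runs); `stages` (subset of the five, default all); `simulate`
#' (list of [dispersal_params()] overrides) or `accessions` (CSV path) +
#' `fasta` (haplotype sequences); `gap_policy`; `epsilon`; `n_perm` (Mantel
#' permutations, default 999); `target` (origin target haplotype, default
#' the panel's first); `grid_step` (default 0.1); `pad` (default 5);
#' `threshold` (hotspot, default 0.8); `out_dir` (when set, the report and
#' stage tables are written there).
#'
#' @param cfg named list or YAML path.
#' @return named list of class `analysis_report`.
#' @export
run_pipeline <- function(cfg = list()) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  stages <- validate_config(cfg)

  # ---- inputs (pre-flight before any compute) ----
  if (!is.null(cfg$accessions)) {
    accessions <- read_accession_table(cfg$accessions)
    seqs <- if (!is.null(cfg$fasta)) read_fasta(cfg$fasta) else NULL
    panel <- list(accessions = accessions, haplotype_seqs = seqs)
  } else {
    sim_args <- cfg$simulate %||% list()
    if (!is.null(cfg$seed) && is.null(sim_args$seed)) sim_args$seed <- cfg$seed
    if (!is.null(sim_args$origin) && !inherits(sim_args$origin, "geo_point")) {
      sim_args$origin <- geo_point(sim_args$origin[[1]], sim_args$origin[[2]])
    }
    panel <- simulate_dispersal_panel(do.call(dispersal_params, sim_args))
  }
  located <- is.finite(panel$accessions$lat) & is.finite(panel$accessions$lon)
  if (any(c("geo", "origin") %in% stages) && !any(located)) {
    stop("configuration error: geo/origin stages need located accessions",
         call. = FALSE)
  }
  if (any(c("typing", "network", "origin") %in% stages) &&
      is.null(panel$haplotype_seqs)) {
    stop("configuration error: typing/network/origin stages need sequences",
         call. = FALSE)
  }

  report <- list(provenance = list(
    tool = "haplogeo",
    version = as.character(utils::packageVersion("haplogeo")),
    seed = cfg$seed %||% NA,
    stages = stages,
    parameters = cfg[setdiff(names(cfg), c("stages", "out_dir"))]
  ))

  counts <- table(panel$accessions$haplotype)

  if ("typing" %in% stages) {
    # synthetic haplotypes are summarised by divergence from the panel's
    # first (ancestral) haplotype; reference-structure sequences go through
    # decompose_structure() directly
    anc <- names(panel$haplotype_seqs)[1]
    report$typing <- data.frame(
      haplotype = names(panel$haplotype_seqs),
      length = nchar(panel$haplotype_seqs),
      diff_from_first = vapply(panel$haplotype_seqs, function(s)
        pairwise_differences(panel$haplotype_seqs[[anc]], s), 0L),
      row.names = NULL)
  }

  if ("popgen" %in% stages) {
    freq <- data.frame(haplotype = names(counts),
                       carriers = as.integer(counts),
                       frequency = as.integer(counts) / sum(counts))
    div <- NULL
    if (!is.null(panel$haplotype_seqs)) {
      mult <- as.integer(counts[names(panel$haplotype_seqs)])
      mult[is.na(mult)] <- 0L
      keep <- mult > 0
      if (sum(mult) >= 2) {
        d <- nucleotide_diversity(as.character(panel$haplotype_seqs)[keep],
                                  mult[keep],
                                  gap_policy = cfg$gap_policy %||% "pairwise_deletion")
        div <- list(pi = d$pi, hd = d$hd, n = d$n, L = d$L,
                    gap_policy = d$gap_policy)
      }
    }
    report$popgen <- list(frequencies = freq, diversity = div)
  }

  if ("network" %in% stages) {
    chars <- do.call(rbind, strsplit(as.character(panel$haplotype_seqs), ""))
    rownames(chars) <- names(panel$haplotype_seqs)
    variable <- apply(chars, 2, function(col) length(unique(col)) > 1)
    states <- chars[, variable, drop = FALSE]
    g <- median_joining_network(states,
                                multiplicities = as.integer(
                                  counts[rownames(states)]),
                                epsilon = cfg$epsilon %||% 0L)
    report$network <- list(nodes = g$nodes, edges = g$edges, cost = g$cost,
                           epsilon = g$epsilon)
  }

  if ("geo" %in% stages) {
    acc <- panel$accessions[located, , drop = FALSE]
    sums <- lapply(split(acc, acc$haplotype), function(a) {
      s <- geo_summary(a$lat, a$lon, a$id)
      data.frame(haplotype = a$haplotype[1], n = s$n,
                 mean_pairwise_km = s$mean_pairwise_km,
                 min_km = s$min_km, max_km = s$max_km, gcf_id = s$gcf_id,
                 gmc_lat = s$gmc[["lat"]], gmc_lon = s$gmc[["lon"]])
    })
    geo_tab <- do.call(rbind, sums); rownames(geo_tab) <- NULL
    mant <- NULL
    if (!is.null(panel$haplotype_seqs) && length(panel$haplotype_seqs) >= 3) {
      dm <- panel_distance_matrices(panel)
      mt <- mantel_test(dm$genetic, dm$geographic,
                        n_perm = cfg$n_perm %||% 999, seed = cfg$seed)
      mant <- list(r = mt$r, p = mt$p, n_perm = mt$n_perm)
    }
    report$geo <- list(summaries = geo_tab, mantel = mant)
  }

  if ("origin" %in% stages) {
    target <- cfg$target %||% names(panel$haplotype_seqs)[1]
    hap_set <- cfg$hap_set %||% names(panel$haplotype_seqs)
    L <- nchar(panel$haplotype_seqs[[1]])
    pdist <- function(a, b) pairwise_differences(a, b) / L
    surf <- scan_origin(panel$accessions[located, , drop = FALSE], target,
                        hap_set, seqs = panel$haplotype_seqs,
                        genetic_fn = pdist,
                        grid_step = cfg$grid_step %||% 0.1,
                        pad = cfg$pad %||% 5)
    hs <- hotspot_region(surf, threshold = cfg$threshold %||% 0.8)
    report$origin <- list(
      target = target, hap_set = surf$hap_set,
      grid = list(step = surf$step, n_lat = length(surf$lat),
                  n_lon = length(surf$lon)),
      peak = surface_argmax(surf),
      hotspot_cells = nrow(hs$cells),
      hotspot_bbox = if (is.null(hs$bbox)) NULL else as.list(hs$bbox))
    attr(report, "origin_surface") <- surf
    attr(report, "hotspot") <- hs
  }

  class(report) <- c("analysis_report", "list")
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_report(report, file.path(cfg$out_dir, "report.json"))
    if (!is.null(attr(report, "hotspot"))) {
      write_hotspot_geojson(attr(report, "hotspot"),
                            file.path(cfg$out_dir, "hotspot.geojson"))
    }
  }
  report
}
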