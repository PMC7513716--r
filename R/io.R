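TAXA <- c("rufipogon", "sativa")
SUBGROUPS <- c("Indica", "Japonica", "Aus", "Aromatic", "Intermediate", "unknown")
CYTOTYPES <- c("Or-CT0", "Or-CT1", "Or-CT2", "unknown")
REGIONS <- c("SA-I", "SA-II", "EA", "SEA", "unknown")
VARIANT_KINDS <- c("SNP", "Sub", "Ins")

#' Path to a packaged reference table
#'
#' Convenience accessor for the plain-text reference tables shipped with the
#' package: the 23-locus variant matrix of the 16 structure haplotypes
#' (`"table2_variants.tsv"`), their segment compositions and carrier counts
#' (`"table1_haplotypes.tsv"`), the regional survey summary
#' (`"table3_regions.tsv"`) and the per-region carrier counts of each
#' haplotype in wild rice (`"region_haplotype_counts.tsv"`).
#'
#' @param file file name within the package's `extdata` directory.
#' @return absolute path to the file.
#' @export
hg_extdata <- function(file) {
  p <- system.file("extdata", file, package = "haplogeo")
  if (p == "") stop("no packaged file ", file, call. = FALSE)
  p
}

# ---- variant table ---------------------------------------------------------

#' Read a haplotype variant table
#'
#' Parses the tab-separated variant matrix describing SNPs, block
#' substitutions (`Sub`) and small insertions (`Ins`) across a panel of
#' haplotypes. The first column gives the 1-based position on the reference
#' haplotype's coordinate system, either a single position or a
#' `start-end` range for blocks; the second column the variant kind; the
#' remaining columns one state per haplotype. SNP states are single bases,
#' `Sub` states are block lengths in bp, `Ins` states are either the inserted
#' sequence, its length, or empty when the haplotype lacks the insertion.
#'
#' @param path path to the TSV file.
#' @return a `variant_table`: a data.frame with columns `ref_pos`, `ref_end`,
#'   `kind` followed by one character column per haplotype (`NA` = insertion
#'   absent), rows ordered by `ref_pos`, with attribute `haplotype_ids`.
#' @export
read_variant_table <- function(path) {
  d <- read.delim(path, colClasses = "character", check.names = FALSE)
  if (ncol(d) < 3 || names(d)[1] != "pos" || names(d)[2] != "kind") {
    stop("variant table must start with columns 'pos' and 'kind'", call. = FALSE)
  }
  haps <- names(d)[-(1:2)]
  if (anyDuplicated(haps)) stop("duplicate haplotype columns", call. = FALSE)
  bad_kind <- setdiff(unique(d$kind), VARIANT_KINDS)
  if (nrow(d) > 0 && length(bad_kind)) {
    stop("unknown variant kind(s): ", paste(bad_kind, collapse = ", "), call. = FALSE)
  }
  pos <- strsplit(d$pos, "-", fixed = TRUE)
  ref_pos <- vapply(pos, function(p) suppressWarnings(as.integer(p[1])), 1L)
  ref_end <- vapply(pos, function(p) {
    suppressWarnings(as.integer(if (length(p) > 1) p[2] else p[1]))
  }, 1L)
  if (nrow(d) > 0 && (anyNA(ref_pos) || anyNA(ref_end) || any(ref_end < ref_pos))) {
    stop("malformed position field", call. = FALSE)
  }
  if (anyDuplicated(paste(d$pos, d$kind))) {
    stop("duplicate (position, kind) records", call. = FALSE)
  }
  states <- d[, -(1:2), drop = FALSE]
  states[states == ""] <- NA_character_
  snp <- d$kind == "SNP"
  if (any(snp)) {
    sv <- unlist(states[snp, ], use.names = FALSE)
    if (anyNA(sv)) stop("missing SNP state", call. = FALSE)
    if (any(nchar(sv) != 1L) || !all(sv %in% strsplit("ACGTRYSWKMBDHVN", "")[[1]])) {
      stop("SNP states must be single IUPAC bases", call. = FALSE)
    }
  }
  sub <- d$kind == "Sub"
  if (any(sub)) {
    lv <- suppressWarnings(as.integer(unlist(states[sub, ], use.names = FALSE)))
    if (anyNA(lv) || any(lv <= 0)) {
      stop("Sub states must be positive integer block lengths", call. = FALSE)
    }
  }
  out <- cbind(data.frame(ref_pos = ref_pos, ref_end = ref_end,
                          kind = d$kind, stringsAsFactors = FALSE), states)
  out <- out[order(out$ref_pos, match(out$kind, VARIANT_KINDS)), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, haplotype_ids = haps, class = c("variant_table", "data.frame"))
}

#' Write a variant table
#'
#' Inverse of [read_variant_table()]; `read(write(x))` returns an equal table.
#'
#' @param vt a `variant_table`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(vt, path) {
  haps <- attr(vt, "haplotype_ids")
  pos <- ifelse(vt$ref_end > vt$ref_pos,
                paste0(vt$ref_pos, "-", vt$ref_end), as.character(vt$ref_pos))
  out <- cbind(data.frame(pos = pos, kind = vt$kind), vt[, haps, drop = FALSE])
  out[is.na(out)] <- ""
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Count variants by kind within a reference span
#'
#' @param vt a `variant_table`.
#' @param span optional `c(start, end)` closed interval of reference
#'   positions; default the whole table.
#' @return named integer vector with elements `SNP`, `Sub`, `Ins`.
#' @export
count_variants <- function(vt, span = NULL) {
  keep <- rep(TRUE, nrow(vt))
  if (!is.null(span)) {
    if (length(span) != 2L || span[2] < span[1]) {
      stop("span must be c(start, end) with start <= end", call. = FALSE)
    }
    keep <- vt$ref_pos >= span[1] & vt$ref_pos <= span[2]
  }
  tab <- table(factor(vt$kind[keep], levels = VARIANT_KINDS))
  setNames(as.integer(tab), VARIANT_KINDS)
}

# ---- haplotype composition table (Table 1 style) ---------------------------

#' Read a haplotype composition/count table
#'
#' Reads the segment-composition table of the reference haplotypes: columns
#' `haplotype`, `atp6`, `fs`, `ncs`, `orf79` (empty = absent) and carrier
#' counts `n_rufipogon`, `n_sativa`. When reading the packaged reference
#' table the carrier totals are checked against the published panel
#' (44 wild + 30 cultivated = 74 structure-bearing genotypes).
#'
#' @param path path to the TSV; defaults to the packaged reference table.
#' @param check_totals if `TRUE`, assert the packaged totals.
#' @return data.frame of class `haplotype_table`.
#' @export
read_haplotype_table <- function(path = hg_extdata("table1_haplotypes.tsv"),
                                 check_totals = missing(path)) {
  d <- read.delim(path, colClasses = c(rep("character", 5), "integer", "integer"))
  need <- c("haplotype", "atp6", "fs", "ncs", "orf79", "n_rufipogon", "n_sativa")
  if (!identical(names(d), need)) {
    stop("haplotype table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(d$haplotype)) stop("duplicate haplotype ids", call. = FALSE)
  if (any(d$n_rufipogon < 0) || any(d$n_sativa < 0)) {
    stop("carrier counts must be nonnegative", call. = FALSE)
  }
  if (check_totals &&
      !(sum(d$n_rufipogon) == 44L && sum(d$n_sativa) == 30L)) {
    stop("packaged reference panel totals corrupted", call. = FALSE)
  }
  d$group <- vapply(seq_len(nrow(d)),
                    function(i) assign_group(d$fs[i], d$ncs[i]), "")
  structure(d, class = c("haplotype_table", "data.frame"))
}

#' Read the regional survey summary table
#'
#' @param path TSV path; defaults to the packaged regional summary.
#' @return data.frame with one row per survey region.
#' @export
read_region_table <- function(path = hg_extdata("table3_regions.tsv")) {
  d <- read.delim(path)
  if (names(d)[1] != "region") stop("first column must be 'region'", call. = FALSE)
  d
}

#' Read per-region haplotype carrier counts
#'
#' The packaged default gives, for each structure haplotype observed in wild
#' rice, its number of carriers in each of the four survey regions
#' (reconstructed from the published regional summaries; row sums equal the
#' wild-rice carrier counts of the composition table).
#'
#' @param path TSV path with column `haplotype` then one column per region.
#' @return data.frame, rownames = haplotype ids.
#' @export
read_region_haplotype_counts <- function(path = hg_extdata("region_haplotype_counts.tsv")) {
  d <- read.delim(path, check.names = FALSE)
  rownames(d) <- d$haplotype
  d
}

# ---- accession panel -------------------------------------------------------

#' Read an accession panel
#'
#' CSV with columns `id, taxon, subgroup, cytotype, region, lat, lon,
#' haplotype`. Coordinates may be empty (unlocated accession); malformed or
#' out-of-range coordinates are an error, never a silent drop. Empty
#' `subgroup`/`cytotype`/`region` values become `"unknown"`.
#'
#' @param path CSV path.
#' @return data.frame of class `accession_panel`.
#' @export
read_accession_table <- function(path) {
  d <- utils::read.csv(path, colClasses = "character")
  need <- c("id", "taxon", "subgroup", "cytotype", "region", "lat", "lon", "haplotype")
  if (!identical(names(d), need)) {
    stop("accession table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(d$id)) stop("duplicate accession ids", call. = FALSE)
  for (col in c("subgroup", "cytotype", "region")) d[[col]][d[[col]] == ""] <- "unknown"
  if (!all(d$taxon %in% TAXA)) {
    stop("taxon must be one of: ", paste(TAXA, collapse = ", "), call. = FALSE)
  }
  if (!all(d$subgroup %in% SUBGROUPS)) stop("invalid subgroup value", call. = FALSE)
  if (!all(d$cytotype %in% CYTOTYPES)) stop("invalid cytotype value", call. = FALSE)
  if (!all(d$region %in% REGIONS)) stop("invalid region value", call. = FALSE)
  parse_coord <- function(x, what, lo, hi) {
    v <- suppressWarnings(as.numeric(x))
    bad <- (x != "" & is.na(v)) | (!is.na(v) & (v < lo | v > hi))
    if (any(bad)) {
      stop("malformed or out-of-range ", what, " for accession(s): ",
           paste(d$id[bad], collapse = ", "), call. = FALSE)
    }
    v
  }
  d$lat <- parse_coord(d$lat, "latitude", -90, 90)
  d$lon <- parse_coord(d$lon, "longitude", -360, 360)
  if (any(is.na(d$lat) != is.na(d$lon))) {
    stop("lat and lon must both be present or both absent", call. = FALSE)
  }
  d$lon <- ifelse(is.na(d$lon), NA_real_, ((d$lon + 180) %% 360) - 180)
  d$lon[!is.na(d$lon) & d$lon == -180] <- 180
  d$haplotype[d$haplotype == ""] <- NA_character_
  structure(d, class = c("accession_panel", "data.frame"))
}

#' Write an accession panel
#'
#' @param panel an `accession_panel` data.frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_accession_table <- function(panel, path) {
  out <- as.data.frame(panel)
  cols <- c("id", "taxon", "subgroup", "cytotype", "region", "lat", "lon", "haplotype")
  out <- out[, cols]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

# ---- FASTA -----------------------------------------------------------------

#' Read a FASTA file of nucleotide sequences
#'
#' Sequences are uppercased and RNA `U` is mapped to `T`; characters outside
#' `A, C, G, T, N, -` are rejected. Empty records are an error.
#'
#' @param path FASTA path (wrapped or single-line).
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(ss))
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  if (any(nchar(seqs) == 0)) stop("empty FASTA record", call. = FALSE)
  bad <- grepl("[^ACGTN-]", seqs)
  if (any(bad)) {
    stop("invalid characters in record(s): ",
         paste(names(seqs)[bad], collapse = ", "), call. = FALSE)
  }
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line wrap width (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  if (is.null(names(seqs)) || any(names(seqs) == "")) {
    stop("sequences must be named", call. = FALSE)
  }
  ss <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

# ---- analysis report -------------------------------------------------------

#' Write an analysis report to JSON
#'
#' The report is a named list whose first element should be a `provenance`
#' block (inputs, seed, parameters, package version). Data frames are stored
#' column-wise; numbers are written at full precision.
#'
#' @param report named list.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  if (is.null(report$provenance)) {
    stop("report must carry a provenance block", call. = FALSE)
  }
  report <- unclass(report)
  attributes(report) <- list(names = names(report))
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", null = "null", na = "null",
                       pretty = TRUE)
  invisible(path)
}

#' Read an analysis report written by [write_report()]
#'
#' @param path JSON path.
#' @return named list.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Write a hotspot as GeoJSON
#'
#' One square Polygon feature per member cell (coordinates in lon,lat order),
#' with the cell's fit statistic as a property. An empty hotspot yields a
#' FeatureCollection with zero features.
#'
#' @param hotspot a `hotspot` object from [hotspot_region()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hotspot_geojson <- function(hotspot, path) {
  step <- hotspot$step
  feats <- lapply(seq_len(nrow(hotspot$cells)), function(i) {
    la <- hotspot$cells$lat[i]; lo <- hotspot$cells$lon[i]
    h <- step / 2
    ring <- list(c(lo - h, la - h), c(lo + h, la - h), c(lo + h, la + h),
                 c(lo - h, la + h), c(lo - h, la - h))
    list(type = "Feature",
         properties = list(r2 = hotspot$cells$r2[i]),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  fc <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
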