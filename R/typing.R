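# Segment boundaries of the atp6-orf79-like structure, in reference
# (H1) coordinates; intervals closed.
SEGMENT_SPANS <- list(atp6 = c(1L, 1005L), fs = c(1006L, 1115L),
                      ncs = c(1116L, 1221L), orf79 = c(1222L, 1461L))
ORF79_SNP_POS <- c(1225L, 1234L, 1363L, 1367L, 1368L, 1399L)
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Segment spans of the reference structure
#'
#' @return named list of closed `c(start, end)` intervals in reference
#'   coordinates: `atp6` (1-1005), `fs` (1006-1115), `ncs` (1116-1221),
#'   `orf79` (1222-1461).
#' @export
segment_spans <- function() SEGMENT_SPANS

#' Assign a structure to one of the four groups
#'
#' Classification is by the flanking-segment type and the family of the
#' intergenic noncoding segment: `fs1* + ncs1*` is AO-I, `fs1* + ncs2*`
#' AO-II, `fs1* + ncs3*` AO-III, `fs2 + ncs1*` AO-IV; every other
#' combination is `"unclassified"`. Total function: never errors.
#'
#' @param fs_type flanking-segment type (e.g. `"fs1a"`, `"fs1b"`, `"fs2"`).
#' @param ncs_type noncoding-segment type (e.g. `"ncs1-BT"`, `"ncs3-a"`).
#' @return one of `"AO-I"`, `"AO-II"`, `"AO-III"`, `"AO-IV"`,
#'   `"unclassified"`.
#' @export
assign_group <- function(fs_type, ncs_type) {
  if (is.na(fs_type) || is.na(ncs_type)) return("unclassified")
  fs1 <- grepl("^fs1", fs_type); fs2 <- fs_type == "fs2"
  fam <- sub("^(ncs[0-9]).*", "\\1", ncs_type)
  if (!fam %in% c("ncs1", "ncs2", "ncs3")) return("unclassified")
  if (fs1 && fam == "ncs1") return("AO-I")
  if (fs1 && fam == "ncs2") return("AO-II")
  if (fs1 && fam == "ncs3") return("AO-III")
  if (fs2 && fam == "ncs1") return("AO-IV")
  "unclassified"
}

# Locus keys ("refpos/kind") in table order.
locus_keys <- function(vt) paste0(vt$ref_pos, "/", vt$kind)

# State matrix of a variant table: loci x haplotypes, NA = insertion absent.
variant_state_matrix <- function(vt) {
  haps <- attr(vt, "haplotype_ids")
  m <- as.matrix(vt[, haps, drop = FALSE])
  rownames(m) <- locus_keys(vt)
  m
}

#' Classify a haplotype from its per-locus variant states
#'
#' Compares a full state vector against every column of the variant table:
#' an exact match returns that haplotype's id, otherwise the call is
#' `"novel"` with the nearest haplotype and its distance reported.
#'
#' @param states named character vector of states keyed `"<ref_pos>/<kind>"`
#'   (as in `rownames(variant_state_matrix(vt))`); use `NA` for an absent
#'   insertion. All loci of the table must be present.
#' @param vt the reference `variant_table` (default: packaged panel).
#' @return list with `haplotype_id` (`"H1"..` or `"novel"`), `nearest`,
#'   `distance` (mismatching loci to the nearest haplotype).
#' @export
classify_haplotype <- function(states, vt = reference_panel()$variant_table) {
  m <- variant_state_matrix(vt)
  missing_loci <- setdiff(rownames(m), names(states))
  if (length(missing_loci)) {
    stop("missing state for loci: ", paste(missing_loci, collapse = ", "),
         call. = FALSE)
  }
  s <- states[rownames(m)]
  cmp <- function(a, b) sum(ifelse(is.na(a), "", a) != ifelse(is.na(b), "", b))
  d <- apply(m, 2, cmp, a = s)
  dmin <- min(d)
  nearest <- sort(names(d)[d == dmin])
  if (dmin == 0L) {
    list(haplotype_id = nearest[1], nearest = nearest[1], distance = 0L)
  } else {
    list(haplotype_id = "novel", nearest = nearest, distance = dmin)
  }
}

# ---- reference panel (built once, cached) ----------------------------------

.hg_cache <- new.env(parent = emptyenv())

# Synthetic 1461-bp template realising the reference coordinate system. The
# orf79 region [1222,1461] is an in-frame CDS built from stop-free codons,
# with the codons hit by the panel's CDS SNPs fixed so that no allele gains
# an internal stop.
reference_template <- function() {
  with_local_seed(13022, {
    pre <- random_dna(SEGMENT_SPANS$orf79[1] - 1L)
    codon_pool <- apply(expand.grid(BASES, BASES, BASES), 1, paste, collapse = "")
    codon_pool <- setdiff(codon_pool, STOP_CODONS)
    n_codon <- (SEGMENT_SPANS$orf79[2] - SEGMENT_SPANS$orf79[1] + 1L) / 3L
    codons <- sample(codon_pool, n_codon, replace = TRUE)
    codons[1] <- "ATG"
    # codons containing panel SNP positions; first base chosen so every
    # observed substitution stays stop-free
    codons[2] <- "GGT"   # pos 1225 in {G,A}
    codons[5] <- "GCT"   # pos 1234 in {G,C}
    codons[48] <- "ACA"  # pos 1363 in {A,T,G,C}
    codons[49] <- "CAA"  # pos 1367 in {A,C}, 1368 in {A,T,C}
    codons[60] <- "CTG"  # pos 1399 in {C,T}
    paste0(pre, paste(codons, collapse = ""))
  })
}

#' The packaged reference panel of the 16 structure haplotypes
#'
#' Builds (once per session) the aligned sequences of the 16 reference
#' haplotypes from the packaged variant table, on a synthetic template that
#' realises the reference coordinate system (variant states are the
#' published ones; invariant positions and block contents are synthetic
#' filler, which does not affect typing, distances restricted to variable
#' sites, or network topology).
#'
#' @return list with `variant_table`, `composition` (the haplotype table with
#'   AO groups), `aligned` (named aligned sequences with column annotations),
#'   `template` (ungapped reference sequence), `states` (locus x haplotype
#'   matrix), `orf79_alleles` (named character: allele id -> CDS).
#' @export
reference_panel <- function() {
  if (!is.null(.hg_cache$panel)) return(.hg_cache$panel)
  vt <- read_variant_table(hg_extdata("table2_variants.tsv"))
  comp <- read_haplotype_table()
  template <- reference_template()
  aligned <- build_sequences_from_variant_table(template, vt)
  states <- variant_state_matrix(vt)
  # one CDS per orf79 allele, taken from the first haplotype carrying it
  first_hap <- comp$haplotype[!duplicated(comp$orf79)]
  alle <- comp$orf79[!duplicated(comp$orf79)]
  cds <- vapply(first_hap, function(h) {
    extract_ref_span(aligned, h, SEGMENT_SPANS$orf79)
  }, "")
  panel <- list(variant_table = vt, composition = comp, aligned = aligned,
                template = template, states = states,
                orf79_alleles = setNames(cds, alle))
  .hg_cache$panel <- panel
  panel
}

# Ungapped subsequence of an aligned panel haplotype over a reference span
# (plain/snp columns only have reference coordinates; block columns between
# are included when their locus lies inside the span).
extract_ref_span <- function(aligned, hap, span) {
  col_ref <- attr(aligned, "col_ref")
  loci <- attr(aligned, "loci")
  keep <- !is.na(col_ref) & col_ref >= span[1] & col_ref <= span[2]
  for (i in seq_len(nrow(loci))) {
    if (loci$col_end[i] >= loci$col_start[i] &&
        loci$ref_pos[i] >= span[1] && loci$ref_pos[i] <= span[2] &&
        loci$kind[i] %in% c("Sub", "Ins")) {
      keep[loci$col_start[i]:loci$col_end[i]] <- TRUE
    }
  }
  s <- strsplit(aligned[[hap]], "")[[1]]
  paste(s[keep][s[keep] != "-"], collapse = "")
}

# ---- structure decomposition ----------------------------------------------

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# Map a query onto a panel haplotype: returns per-pattern-position query
# characters ("-" = deleted, NA = outside the aligned range) and insertions
# anchored after pattern positions.
align_to_pattern <- function(pattern, query) {
  al <- Biostrings::pairwiseAlignment(
    pattern = pattern, subject = query, type = "overlap",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 2, mismatch = -3, baseOnly = FALSE),
    gapOpening = 8, gapExtension = 2)
  pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  p_start <- Biostrings::start(Biostrings::pattern(al))
  np <- nchar(pattern)
  q_at <- rep(NA_character_, np)
  ins_after <- vector("list", np + 1L)
  p_pos <- p_start - 1L
  for (k in seq_along(pa)) {
    if (pa[k] != "-") {
      p_pos <- p_pos + 1L
      q_at[p_pos] <- sa[k]
    } else {
      idx <- p_pos + 1L
      ins_after[[idx]] <- c(ins_after[[idx]], sa[k])
    }
  }
  list(q_at = q_at, ins_after = ins_after, score = Biostrings::score(al),
       nmatch = Biostrings::nmatch(al))
}

#' Decompose a candidate sequence into structure segments
#'
#' Anchors the query on the atp6 coding sequence (semi-global alignment,
#' identity threshold 95 percent over 1005 bp; reverse-complement queries
#' are auto-detected), maps it onto the closest reference haplotype, reads
#' the per-locus variant states and calls the flanking-segment type, the
#' noncoding-segment type, the orf79 allele, the haplotype id and the AO
#' group. A query truncated before the orf79 (or ncs) region yields a
#' partial result with the missing segments `NA`.
#'
#' @param query DNA string (the assembled contig or structure sequence).
#' @param panel reference panel from [reference_panel()].
#' @param min_identity atp6 anchor identity threshold (default 0.95).
#' @return list of class `typing_result`: `composition` (list `atp6`, `fs`,
#'   `ncs`, `orf79`), `haplotype_id`, `group`, `partial`, `strand`,
#'   `atp6_identity`, `states`, `segments` (realised coverage per segment),
#'   `nearest`, `distance`.
#' @export
decompose_structure <- function(query, panel = reference_panel(),
                                min_identity = 0.95) {
  query <- toupper(gsub("-", "", query))
  atp6_ref <- substr(panel$template, SEGMENT_SPANS$atp6[1], SEGMENT_SPANS$atp6[2])
  fwd <- align_to_pattern(atp6_ref, query)
  rev <- align_to_pattern(atp6_ref, revcomp(query))
  strand <- if (rev$nmatch > fwd$nmatch) "-" else "+"
  if (strand == "-") query <- revcomp(query)
  anchor <- if (strand == "-") rev else fwd
  identity <- anchor$nmatch / nchar(atp6_ref)
  if (identity < min_identity) {
    stop("query has no atp6 anchor (identity ",
         sprintf("%.3f", identity), " < ", min_identity,
         "): not an atp6-orf79-like structure", call. = FALSE)
  }

  # best-matching reference haplotype carries the coordinate frame
  ungapped <- vapply(names(panel$aligned), function(h) {
    gsub("-", "", panel$aligned[[h]], fixed = TRUE)
  }, "")
  scores <- vapply(ungapped, function(s) align_to_pattern(s, query)$nmatch, 0)
  best <- names(scores)[order(-scores, names(scores))][1]
  map <- align_to_pattern(ungapped[[best]], query)

  # pattern position of each alignment column for the best haplotype
  bchars <- strsplit(panel$aligned[[best]], "")[[1]]
  pat_pos <- cumsum(bchars != "-")
  pat_pos[bchars == "-"] <- NA

  vt <- panel$variant_table
  loci <- attr(panel$aligned, "loci")
  keys <- locus_keys(vt)
  states <- setNames(rep(NA_character_, nrow(vt)), keys)
  covered <- setNames(rep(FALSE, nrow(vt)), keys)
  for (i in seq_len(nrow(vt))) {
    cols <- if (loci$col_end[i] >= loci$col_start[i])
      loci$col_start[i]:loci$col_end[i] else integer(0)
    pp <- pat_pos[cols]; pp <- pp[!is.na(pp)]
    if (vt$kind[i] == "SNP") {
      q <- if (length(pp)) map$q_at[pp] else NA_character_
      if (length(q) && !is.na(q) && q != "-") { states[i] <- q; covered[i] <- TRUE }
    } else if (vt$kind[i] == "Sub") {
      if (!length(pp)) next
      if (anyNA(map$q_at[pp])) next  # block outside the aligned range
      covered[i] <- TRUE
      aligned_n <- sum(map$q_at[pp] != "-")
      ins_n <- sum(lengths(map$ins_after[pp + 1L]))
      states[i] <- as.character(aligned_n + ins_n)
    } else { # Ins
      ins <- NULL
      if (length(pp)) {         # best haplotype carries the insertion
        if (anyNA(map$q_at[pp])) next
        covered[i] <- TRUE
        ins <- paste(map$q_at[pp][map$q_at[pp] != "-"], collapse = "")
      } else {                  # look for a query insertion at the anchor
        prev_col <- loci$col_start[i] - 1L
        anchor_pp <- if (prev_col >= 1) pat_pos[prev_col] else NA
        if (is.na(anchor_pp) || is.na(map$q_at[anchor_pp])) next
        covered[i] <- TRUE
        ins <- paste(map$ins_after[[anchor_pp + 1L]], collapse = "")
      }
      if (nchar(ins) == 0) {
        states[i] <- NA_character_
      } else {
        # follow the table's convention for this row: length-only states
        # are compared by length, literal states by sequence
        row_states <- as.character(vt[i, attr(vt, "haplotype_ids")])
        row_states <- row_states[!is.na(row_states)]
        numeric_row <- length(row_states) > 0 &&
          all(grepl("^[0-9]+$", row_states))
        states[i] <- if (numeric_row) as.character(nchar(ins)) else ins
      }
    }
  }

  # an SNP inside a block-substitution window is unreadable when the query
  # carries a different-length block there: the variant exists only in the
  # reference block's frame, so such haplotypes take the reference state
  ref_hap <- attr(vt, "haplotype_ids")[1]
  for (i in which(vt$kind == "SNP" & !covered)) {
    enclosing <- which(vt$kind == "Sub" & vt$ref_pos <= vt$ref_pos[i] &
                       vt$ref_end >= vt$ref_pos[i])
    if (length(enclosing) && covered[enclosing[1]] &&
        !is.na(states[enclosing[1]]) &&
        states[enclosing[1]] != as.character(
          vt$ref_end[enclosing[1]] - vt$ref_pos[enclosing[1]] + 1L)) {
      states[i] <- as.character(vt[i, ref_hap])
      covered[i] <- TRUE
    }
  }

  # segment coverage: fraction of reference positions of each segment with an
  # aligned query base (via the best haplotype's plain columns)
  col_ref <- attr(panel$aligned, "col_ref")
  seg_cov <- vapply(SEGMENT_SPANS, function(sp) {
    cols <- which(!is.na(col_ref) & col_ref >= sp[1] & col_ref <= sp[2])
    pp <- pat_pos[cols]; pp <- pp[!is.na(pp)]
    if (!length(pp)) return(0)
    mean(!is.na(map$q_at[pp]) & map$q_at[pp] != "-")
  }, 0)

  fs_ok <- seg_cov[["fs"]] >= 0.5
  ncs_ok <- seg_cov[["ncs"]] >= 0.5
  orf_ok <- seg_cov[["orf79"]] >= 0.5

  fs_type <- if (fs_ok) call_fs_type(states) else NA_character_
  ncs_type <- if (ncs_ok) call_ncs_type(states, panel) else NA_character_
  orf_allele <- if (orf_ok) call_orf79_allele(states, panel) else NA_character_

  partial <- !(fs_ok && ncs_ok && orf_ok)
  if (!partial && !anyNA(covered) && all(covered | vt$kind == "Ins")) {
    cl <- classify_haplotype(states, vt)
  } else {
    cl <- list(haplotype_id = NA_character_, nearest = NA_character_,
               distance = NA_integer_)
  }
  group <- if (partial) "unclassified" else assign_group(fs_type, ncs_type)
  structure(list(
    composition = list(atp6 = "atp6", fs = fs_type, ncs = ncs_type,
                       orf79 = orf_allele),
    haplotype_id = cl$haplotype_id, group = group, partial = partial,
    strand = strand, atp6_identity = identity, states = states,
    segments = seg_cov, nearest = cl$nearest, distance = cl$distance
  ), class = "typing_result")
}

call_fs_type <- function(states) {
  blk <- states[["1011/Sub"]]; s1008 <- states[["1008/SNP"]]
  s1063 <- states[["1063/SNP"]]
  if (is.na(blk)) {
    # truncated block: fall back to the diagnostic SNPs alone
    if (identical(s1008, "A")) return("fs2")
    if (identical(s1008, "T")) {
      if (identical(s1063, "G")) return("fs1b")
      if (identical(s1063, "C")) return("fs1a")
    }
    return(NA_character_)
  }
  if (blk == "49" && identical(s1008, "A")) return("fs2")
  if (blk == "105" && identical(s1008, "T")) {
    if (identical(s1063, "G")) return("fs1b")
    if (identical(s1063, "C")) return("fs1a")
    return("fs1-novel")
  }
  "fs-novel"
}

NCS_FAMILY_BY_LEN <- c(`45` = "ncs1", `46` = "ncs2", `55` = "ncs2",
                       `51` = "ncs3", `53` = "ncs3")

call_ncs_type <- function(states, panel) {
  vt <- panel$variant_table
  keys <- locus_keys(vt)
  in_ncs <- vt$ref_pos >= SEGMENT_SPANS$ncs[1] & vt$ref_pos <= SEGMENT_SPANS$ncs[2]
  s <- states[keys[in_ncs]]
  m <- panel$states[keys[in_ncs], , drop = FALSE]
  norm <- function(x) ifelse(is.na(x), "", x)
  hit <- which(apply(m, 2, function(col) all(norm(col) == norm(s))))
  if (length(hit)) {
    hap <- colnames(m)[hit[1]]
    return(panel$composition$ncs[panel$composition$haplotype == hap])
  }
  blk <- states[["1159/Sub"]]
  fam <- if (!is.na(blk)) NCS_FAMILY_BY_LEN[blk] else NA_character_
  if (!is.na(fam)) paste0(fam, "-novel") else "ncs-novel"
}

call_orf79_allele <- function(states, panel) {
  keys <- paste0(ORF79_SNP_POS, "/SNP")
  s <- states[keys]
  if (anyNA(s)) return(NA_character_)
  m <- panel$states[keys, , drop = FALSE]
  hit <- which(apply(m, 2, function(col) all(col == s)))
  if (length(hit)) {
    hap <- colnames(m)[hit[1]]
    return(panel$composition$orf79[panel$composition$haplotype == hap])
  }
  "orf79-novel"
}

#' Detect an isolate orf79 context
#'
#' Given gene annotations of a contig, decides whether an orf79 hit stands
#' alone: `TRUE` iff no atp6 CDS ends within `window` bp upstream of an
#' orf79 start on the same strand (window inclusive: a gap of exactly
#' `window` still counts as adjacent).
#'
#' @param annotations data.frame with columns `gene`, `start`, `end`,
#'   `strand` (`"+"`/`"-"`), genomic coordinates with `start <= end`.
#' @param window adjacency window in bp (default 2000).
#' @return `TRUE` if every orf79 hit is isolated from atp6.
#' @export
detect_isolate_orf79 <- function(annotations, window = 2000) {
  a <- annotations
  orf <- a[a$gene == "orf79", , drop = FALSE]
  if (nrow(orf) == 0) stop("no orf79 annotation", call. = FALSE)
  atp <- a[a$gene == "atp6", , drop = FALSE]
  for (i in seq_len(nrow(orf))) {
    same <- atp[atp$strand == orf$strand[i], , drop = FALSE]
    if (nrow(same) == 0) next
    gap <- if (orf$strand[i] == "+") orf$start[i] - same$end
           else same$start - orf$end[i]
    if (any(gap >= 0 & gap <= window)) return(FALSE)
  }
  TRUE
}
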