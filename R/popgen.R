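VALID_BASE <- function(x) x %in% BASES

# round half up (the display convention of the source tables; base round()
# is half-to-even)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Haplotype frequencies from carrier counts
#'
#' @param ht a `haplotype_table` (or data.frame with columns `haplotype`,
#'   `n_rufipogon`, `n_sativa`).
#' @return data.frame with `haplotype`, `carriers`, `frequency` (exact
#'   proportion) and `pct` (percent, half-up rounded to 1 decimal for
#'   display).
#' @export
haplotype_frequencies <- function(ht = read_haplotype_table()) {
  carriers <- ht$n_rufipogon + ht$n_sativa
  total <- sum(carriers)
  if (total <= 0) stop("zero total carrier count", call. = FALSE)
  data.frame(haplotype = ht$haplotype, carriers = carriers,
             frequency = carriers / total,
             pct = round_half_up(100 * carriers / total, 1))
}

#' Frequency of structure carriage in a sample
#'
#' @param carriers number of accessions carrying the structure.
#' @param sampled number of accessions sampled.
#' @return list with `frequency` (exact), `pct` (1-dp percent, half-up) and
#'   `prop2` (2-dp proportion, half-up; the regional-table display style).
#' @export
structure_frequency <- function(carriers, sampled) {
  if (sampled <= 0) stop("sampled must be positive", call. = FALSE)
  if (carriers < 0 || carriers > sampled) {
    stop("carriers must lie in [0, sampled]", call. = FALSE)
  }
  f <- carriers / sampled
  list(frequency = f, pct = round_half_up(100 * f, 1),
       prop2 = round_half_up(f, 2))
}

# ---- sequence distances ----------------------------------------------------

#' Count pairwise nucleotide differences between two aligned sequences
#'
#' Sites where either sequence has a gap, `N` or any non-ACGT character are
#' skipped (pairwise deletion at the pair level).
#'
#' @param a,b aligned sequences of equal length.
#' @param sites optional logical vector selecting eligible columns.
#' @return integer count of differing valid sites.
#' @export
pairwise_differences <- function(a, b, sites = NULL) {
  if (nchar(a) != nchar(b)) stop("aligned lengths differ", call. = FALSE)
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  ok <- VALID_BASE(ca) & VALID_BASE(cb)
  if (!is.null(sites)) ok <- ok & sites
  sum(ca[ok] != cb[ok])
}

# eligible-site count for a pair under pairwise deletion
pair_sites <- function(a, b, sites = NULL) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  ok <- VALID_BASE(ca) & VALID_BASE(cb)
  if (!is.null(sites)) ok <- ok & sites
  sum(ok)
}

#' Nucleotide and haplotype diversity of a sample
#'
#' Nucleotide diversity is the unbiased average per-site pairwise
#' difference: `pi = 2/(n(n-1)) * sum_{i<j expanded pairs} k_ij / L_ij`
#' (equivalently `n/(n-1) * sum_types w_i w_j k_ij / L`), with per-pair site
#' counts under `pairwise_deletion` or a common site set under
#' `complete_deletion`. Haplotype diversity is
#' `hd = n/(n-1) * (1 - sum p_i^2)`.
#'
#' @param seqs aligned sequences (character vector), one per haplotype.
#' @param multiplicities integer count of each haplotype (default 1 each).
#' @param gap_policy `"pairwise_deletion"` (default) or
#'   `"complete_deletion"`.
#' @param sites optional logical column mask (e.g. to exclude
#'   block-substitution and insertion columns, whose length changes are not
#'   nucleotide substitutions).
#' @return list of class `diversity_result`: `pi`, `hd`, `n`, `L`,
#'   `gap_policy`.
#' @export
nucleotide_diversity <- function(seqs, multiplicities = rep(1L, length(seqs)),
                                 gap_policy = c("pairwise_deletion",
                                                "complete_deletion"),
                                 sites = NULL) {
  gap_policy <- match.arg(gap_policy)
  stopifnot(length(seqs) == length(multiplicities))
  n <- sum(multiplicities)
  if (n < 2) stop("need at least 2 sequences after expansion", call. = FALSE)
  m <- length(seqs)
  chars <- lapply(seqs, function(s) strsplit(s, "")[[1]])
  len <- unique(lengths(chars))
  if (length(len) != 1) stop("aligned lengths differ", call. = FALSE)
  eligible <- if (is.null(sites)) rep(TRUE, len) else sites
  if (gap_policy == "complete_deletion") {
    valid_all <- Reduce(`&`, lapply(chars, VALID_BASE)) & eligible
    L <- sum(valid_all)
    if (L == 0) stop("no sites survive complete deletion", call. = FALSE)
  } else {
    L <- sum(eligible)
  }
  acc <- 0
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (j <= i) next
    w <- multiplicities[i] * multiplicities[j]
    if (w == 0) next
    if (gap_policy == "complete_deletion") {
      k <- pairwise_differences(seqs[i], seqs[j], sites = valid_all)
      acc <- acc + w * k / L
    } else {
      Lij <- pair_sites(seqs[i], seqs[j], sites = eligible)
      if (Lij == 0) stop("a pair shares no valid sites", call. = FALSE)
      k <- pairwise_differences(seqs[i], seqs[j], sites = eligible)
      acc <- acc + w * k / Lij
    }
  }
  pi <- 2 * acc / (n * (n - 1))
  p <- multiplicities / n
  hd <- n / (n - 1) * (1 - sum(p^2))
  structure(list(pi = pi, hd = hd, n = n, L = L, gap_policy = gap_policy),
            class = "diversity_result")
}

#' Tajima-Nei (equal-input) evolutionary distance
#'
#' `d = -b * log(1 - p/b)` with
#' `b = (1 - sum g_i^2 + p^2/h) / 2` and
#' `h = sum_{i<j} x_ij^2 / (2 g_i g_j)`, where `g_i` are the base
#' frequencies pooled over the pair, `x_ij` the relative frequencies of the
#' mismatch patterns and `p` the proportion of differing sites. Sites with a
#' gap or ambiguity in either sequence are excluded. Saturated pairs
#' (argument of the logarithm <= 0) return `Inf`.
#'
#' @param a,b aligned sequences of equal length.
#' @param sites optional logical column mask.
#' @return distance (substitutions per site).
#' @export
tajima_nei_distance <- function(a, b, sites = NULL) {
  if (nchar(a) != nchar(b)) stop("aligned lengths differ", call. = FALSE)
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  ok <- VALID_BASE(ca) & VALID_BASE(cb)
  if (!is.null(sites)) ok <- ok & sites
  ca <- ca[ok]; cb <- cb[ok]
  L <- length(ca)
  if (L == 0) stop("no shared valid sites", call. = FALSE)
  p <- mean(ca != cb)
  if (p == 0) return(0)
  g <- (table(factor(ca, BASES)) + table(factor(cb, BASES))) / (2 * L)
  g <- as.numeric(g)
  mism <- ca != cb
  h <- 0
  for (i in 1:3) for (j in (i + 1):4) {
    xij <- mean((ca == BASES[i] & cb == BASES[j]) |
                (ca == BASES[j] & cb == BASES[i]))
    if (xij > 0) {
      if (g[i] == 0 || g[j] == 0) next
      h <- h + xij^2 / (2 * g[i] * g[j])
    }
  }
  if (h == 0) return(Inf)
  b_hat <- (1 - sum(g^2) + p^2 / h) / 2
  arg <- 1 - p / b_hat
  if (arg <= 0) return(Inf)
  -b_hat * log(arg)
}

# ---- differentiation -------------------------------------------------------

mean_pairwise_k <- function(seqs, sites = NULL) {
  n <- length(seqs)
  if (n < 2) return(NA_real_)
  tot <- 0; cnt <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    tot <- tot + pairwise_differences(seqs[i], seqs[j], sites = sites)
    cnt <- cnt + 1
  }
  tot / cnt
}

#' Pairwise FST between two populations of sequences
#'
#' Hudson-style estimator computable from pairwise differences alone:
#' `FST = 1 - Hw/Hb`, where `Hw` is the size-weighted mean of the two
#' within-population mean pairwise differences and `Hb` the mean pairwise
#' difference between populations. Estimates are clipped to `[0, 1]`
#' (negative estimates arise by sampling noise); two identical monomorphic
#' populations have `FST = 0` by convention. An optional permutation
#' p-value shuffles individuals between population labels.
#'
#' @param popA,popB character vectors of aligned sequences (each n >= 2).
#' @param n_perm permutations for the p-value (0 = skip).
#' @param seed RNG seed for the permutations.
#' @param sites optional logical column mask.
#' @return list of class `differentiation_result`: `fst`, `nm`, `hw`, `hb`,
#'   `p` (NA unless permuted), `clipped`.
#' @export
pairwise_fst <- function(popA, popB, n_perm = 0, seed = 1L, sites = NULL) {
  if (length(popA) < 2 || length(popB) < 2) {
    stop("both populations need n >= 2", call. = FALSE)
  }
  stat <- function(A, B) {
    hw <- (length(A) * mean_pairwise_k(A, sites) +
           length(B) * mean_pairwise_k(B, sites)) / (length(A) + length(B))
    hb <- mean(outer(seq_along(A), seq_along(B), Vectorize(function(i, j) {
      pairwise_differences(A[i], B[j], sites = sites)
    })))
    if (hb == 0) return(list(fst = 0, hw = hw, hb = hb, clipped = FALSE))
    f <- 1 - hw / hb
    list(fst = min(1, max(0, f)), hw = hw, hb = hb, clipped = f < 0)
  }
  obs <- stat(popA, popB)
  p <- NA_real_
  if (n_perm > 0) {
    set.seed(seed)
    all_seqs <- c(popA, popB); nA <- length(popA)
    cnt <- 0
    for (r in seq_len(n_perm)) {
      idx <- sample(length(all_seqs))
      perm <- stat(all_seqs[idx[seq_len(nA)]], all_seqs[idx[-seq_len(nA)]])
      if (perm$fst >= obs$fst) cnt <- cnt + 1
    }
    p <- (1 + cnt) / (n_perm + 1)
  }
  structure(list(fst = obs$fst, nm = if (obs$fst > 0) nm_from_fst(obs$fst) else Inf,
                 hw = obs$hw, hb = obs$hb, p = p, clipped = obs$clipped),
            class = "differentiation_result")
}

#' Effective migration from FST (haploid island model)
#'
#' For a haploid, maternally inherited genome `FST = 1/(1 + 2 Nm)`, hence
#' `Nm = (1 - FST) / (2 FST)`.
#'
#' @param fst differentiation in (0, 1].
#' @return Nm at full precision (round to 3 decimals for display).
#' @export
nm_from_fst <- function(fst) {
  if (!is.numeric(fst) || fst <= 0 || fst > 1) {
    stop("fst must lie in (0, 1]", call. = FALSE)
  }
  (1 - fst) / (2 * fst)
}

# ---- substitution typology -------------------------------------------------

is_transition <- function(a, b) TRANSITION[[a]] == b

#' Transition/transversion counts over SNP loci
#'
#' Each SNP locus contributes one classified substitution per distinct
#' non-ancestral state observed at it, compared against the inferred
#' ancestral state (by default the reference haplotype's state).
#'
#' @param vt a `variant_table`.
#' @param ancestor haplotype id providing ancestral states (default `"H1"`).
#' @return list of class `selection_result`: `ts`, `tv`, `ts_tv` (NA when
#'   `tv` is 0).
#' @export
ts_tv_counts <- function(vt = reference_panel()$variant_table, ancestor = "H1") {
  haps <- attr(vt, "haplotype_ids")
  if (!ancestor %in% haps) stop("unknown ancestor haplotype", call. = FALSE)
  ts <- 0L; tv <- 0L
  for (i in which(vt$kind == "SNP")) {
    st <- as.character(vt[i, haps])
    anc <- as.character(vt[i, ancestor])
    for (alt in setdiff(unique(st), anc)) {
      if (is_transition(anc, alt)) ts <- ts + 1L else tv <- tv + 1L
    }
  }
  structure(list(ts = ts, tv = tv,
                 ts_tv = if (tv > 0) ts / tv else NA_real_),
            class = "selection_result")
}

# ---- Nei-Gojobori dN/dS ----------------------------------------------------

codon_aa <- function(codon) Biostrings::GENETIC_CODE[[codon]]

# synonymous site count of one codon (0..3): per position, the fraction of
# the three possible changes that preserve the amino acid (changes to stop
# codons count as nonsynonymous)
codon_syn_sites <- function(codon) {
  aa <- codon_aa(codon)
  s <- 0
  for (pos in 1:3) {
    for (b in setdiff(BASES, substr(codon, pos, pos))) {
      mut <- codon
      substr(mut, pos, pos) <- b
      if (codon_aa(mut) == aa && !(mut %in% STOP_CODONS)) s <- s + 1 / 3
    }
  }
  s
}

# average syn/nonsyn difference counts between two codons over all minimal
# mutation paths (equal path weighting)
codon_path_counts <- function(c1, c2) {
  diff_pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  m <- length(diff_pos)
  if (m == 0) return(c(sd = 0, nd = 0))
  perms <- all_permutations(diff_pos)
  sd_tot <- 0; nd_tot <- 0
  for (ord in perms) {
    cur <- c1
    for (pos in ord) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(c2, pos, pos)
      if (codon_aa(nxt) == codon_aa(cur) && !(nxt %in% STOP_CODONS)) {
        sd_tot <- sd_tot + 1
      } else {
        nd_tot <- nd_tot + 1
      }
      cur <- nxt
    }
  }
  c(sd = sd_tot / length(perms), nd = nd_tot / length(perms))
}

all_permutations <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in all_permutations(x[-i])) out <- c(out, list(c(x[i], rest)))
  }
  out
}

jukes_cantor <- function(p) {
  if (is.na(p)) return(NA_real_)
  if (p >= 0.75) return(Inf)
  -0.75 * log(1 - 4 * p / 3)
}

ng_pair <- function(a, b) {
  stopifnot(nchar(a) == nchar(b), nchar(a) %% 3 == 0)
  nc <- nchar(a) / 3
  S <- 0; Sd <- 0; Nd <- 0
  for (k in seq_len(nc)) {
    c1 <- substr(a, 3 * k - 2, 3 * k); c2 <- substr(b, 3 * k - 2, 3 * k)
    S <- S + (codon_syn_sites(c1) + codon_syn_sites(c2)) / 2
    cnt <- codon_path_counts(c1, c2)
    Sd <- Sd + cnt[["sd"]]; Nd <- Nd + cnt[["nd"]]
  }
  N <- 3 * nc - S
  list(S = S, N = N, Sd = Sd, Nd = Nd,
       pS = Sd / S, pN = Nd / N,
       dS = jukes_cantor(Sd / S), dN = jukes_cantor(Nd / N))
}

#' Nei-Gojobori dN/dS over a set of in-frame coding alleles
#'
#' Counting-method estimate of selection pressure: per-codon synonymous and
#' nonsynonymous site fractions, equal-weight averaging over all minimal
#' mutation paths between differing codons, Jukes-Cantor correction of the
#' per-pair proportions, and averaging of `dN` and `dS` over all allele
#' pairs. The ratio reported is `mean(dN)/mean(dS)` and is undefined
#' (`NA`) when the mean `dS` is 0. This counting estimate is not comparable
#' to likelihood site-model estimates of the same quantity.
#'
#' @param cds named character vector of aligned in-frame CDS alleles (equal
#'   lengths divisible by 3, no internal stops in the first allele).
#' @return list of class `selection_result`: `dn`, `ds` (means over pairs),
#'   `dnds`, `pairs` (data.frame of per-pair values).
#' @export
dnds_nei_gojobori <- function(cds) {
  if (length(cds) < 2) stop("need at least two alleles", call. = FALSE)
  if (any(nchar(cds) != nchar(cds[1]))) stop("allele lengths differ", call. = FALSE)
  if (nchar(cds[1]) %% 3 != 0) stop("length not divisible by 3", call. = FALSE)
  ref_codons <- substring(cds[1], seq(1, nchar(cds[1]), 3), seq(3, nchar(cds[1]), 3))
  if (any(ref_codons[-length(ref_codons)] %in% STOP_CODONS)) {
    stop("internal stop codon in reference allele", call. = FALSE)
  }
  ids <- names(cds); if (is.null(ids)) ids <- paste0("a", seq_along(cds))
  rows <- list()
  for (i in seq_len(length(cds) - 1)) for (j in (i + 1):length(cds)) {
    r <- ng_pair(cds[[i]], cds[[j]])
    rows[[length(rows) + 1]] <- data.frame(
      a = ids[i], b = ids[j], S = r$S, N = r$N, Sd = r$Sd, Nd = r$Nd,
      dS = r$dS, dN = r$dN)
  }
  pairs <- do.call(rbind, rows)
  dn <- mean(pairs$dN); ds <- mean(pairs$dS)
  structure(list(dn = dn, ds = ds,
                 dnds = if (is.finite(ds) && ds > 0) dn / ds else NA_real_,
                 pairs = pairs),
            class = "selection_result")
}

# ---- panel-level convenience ----------------------------------------------

#' Diversity and differentiation of the reference structure groups
#'
#' Expands the reference alignment by the published carrier counts, computes
#' nucleotide and haplotype diversity per AO group and Hudson FST between
#' groups, restricted to single-nucleotide columns (block-substitution and
#' insertion columns excluded: their length changes are not nucleotide
#' substitutions).
#'
#' @param panel a [reference_panel()].
#' @param groups groups to include (default the three multi-haplotype
#'   groups).
#' @param gap_policy passed to [nucleotide_diversity()].
#' @return list with `diversity` (per group) and `fst` (data.frame of group
#'   pairs).
#' @export
group_diversity <- function(panel = reference_panel(),
                            groups = c("AO-I", "AO-II", "AO-III"),
                            gap_policy = "pairwise_deletion") {
  comp <- panel$composition
  sites <- attr(panel$aligned, "col_kind") %in% c("plain", "snp")
  div <- list()
  seqs_by_group <- list()
  for (g in groups) {
    sel <- comp$group == g
    mult <- comp$n_rufipogon[sel] + comp$n_sativa[sel]
    seqs <- as.character(panel$aligned[comp$haplotype[sel]])
    div[[g]] <- nucleotide_diversity(seqs, mult, gap_policy, sites = sites)
    seqs_by_group[[g]] <- rep(seqs, mult)
  }
  fst <- list()
  if (length(groups) > 1) {
    for (i in seq_len(length(groups) - 1)) for (j in (i + 1):length(groups)) {
      f <- pairwise_fst(seqs_by_group[[groups[i]]], seqs_by_group[[groups[j]]],
                        sites = sites)
      fst[[length(fst) + 1]] <- data.frame(
        a = groups[i], b = groups[j], fst = f$fst,
        nm = if (is.finite(f$nm)) f$nm else NA_real_)
    }
  }
  list(diversity = div, fst = if (length(fst)) do.call(rbind, fst) else NULL)
}
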