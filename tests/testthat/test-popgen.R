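test_that("haplotype frequencies reproduce the published percentages", {
  f <- haplotype_frequencies()
  expect_equal(f$pct[f$haplotype == "H2"], 28.4)
  expect_equal(f$pct[f$haplotype == "H16"], 13.5)
  expect_equal(f$pct[f$haplotype == "H1"], 8.1)
  expect_equal(sum(f$frequency), 1)

  single <- data.frame(haplotype = "Hx", n_rufipogon = 3L, n_sativa = 0L)
  expect_equal(haplotype_frequencies(single)$pct, 100)
  zero <- data.frame(haplotype = "Hx", n_rufipogon = 0L, n_sativa = 0L)
  expect_error(haplotype_frequencies(zero), "zero total")
})

test_that("structure frequencies round the way the survey reports them", {
  expect_equal(structure_frequency(44, 221)$pct, 19.9)
  expect_equal(structure_frequency(30, 369)$pct, 8.1)
  expect_equal(structure_frequency(12, 37)$prop2, 0.32)
  expect_equal(structure_frequency(0, 10)$pct, 0)
  expect_error(structure_frequency(1, 0), "positive")
  expect_error(structure_frequency(5, 4), "carriers")
})

test_that("pairwise difference counts match a brute-force recount", {
  expect_equal(pairwise_differences("ACGT", "ACGT"), 0L)
  pan <- reference_panel()
  loci <- attr(pan$aligned, "loci")
  snp_cols <- loci$col_start[loci$kind == "SNP"]
  len <- nchar(pan$aligned[[1]])
  mask <- seq_len(len) %in% snp_cols
  expect_equal(pairwise_differences(pan$aligned[["H14"]], pan$aligned[["H15"]],
                                    sites = mask), 4L)
  set.seed(42)
  for (r in 1:100) {
    a <- random_seq(60, 1000 + r)
    b <- random_seq(60, 2000 + r)
    expect_equal(pairwise_differences(a, b), oracle_pair_diff(a, b))
  }
  expect_error(pairwise_differences("ACG", "ACGT"), "lengths differ")
})

test_that("nucleotide diversity follows its defining mean over expanded pairs", {
  d <- nucleotide_diversity(c("ACGTACGTAC", "ACGTACGTAT"))
  expect_equal(d$pi, 0.1)
  expect_equal(d$hd, 1)

  mono <- nucleotide_diversity(c("ACGT"), multiplicities = 5L)
  expect_equal(mono$pi, 0)
  expect_equal(mono$hd, 0)

  # oracle: expand multiplicities, average k/L over all unordered pairs
  set.seed(7)
  for (r in 1:5) {
    seqs <- vapply(1:4, function(i) random_seq(40, 300 + 10 * r + i), "")
    mult <- sample(1:3, 4, replace = TRUE)
    expanded <- rep(seqs, mult)
    n <- length(expanded)
    ks <- c()
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      ks <- c(ks, oracle_pair_diff(expanded[i], expanded[j]) / 40)
    }
    d <- nucleotide_diversity(seqs, mult)
    expect_equal(d$pi, mean(ks))
  }
  expect_error(nucleotide_diversity("ACGT"), "at least 2")
})

test_that("Tajima-Nei distances match an independent formula evaluation", {
  expect_equal(tajima_nei_distance("ACGTACGT", "ACGTACGT"), 0)
  set.seed(12)
  for (r in 1:20) {
    a <- random_seq(300, 500 + r)
    b <- a
    nmut <- sample(5:40, 1)
    pos <- sample(300, nmut)
    for (p in pos) {
      b <- mutate_at(b, p, sample(setdiff(c("A", "C", "G", "T"),
                                          substr(b, p, p)), 1))
    }
    d <- tajima_nei_distance(a, b)
    expect_equal(d, oracle_tajima_nei(a, b), tolerance = 1e-12)
    # model correction never shrinks the observed divergence
    expect_gte(d, mean(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]) - 1e-12)
  }
})

test_that("FST matches direct Hw/Hb enumeration and handles edge cases", {
  expect_equal(pairwise_fst(c("AAAA", "AAAA"), c("AAAA", "AAAA"))$fst, 0)
  expect_equal(pairwise_fst(c("AAAA", "AAAA"), c("TTAA", "TTAA"))$fst, 1)
  set.seed(33)
  for (r in 1:5) {
    A <- vapply(1:3, function(i) random_seq(30, 700 + 10 * r + i), "")
    B <- vapply(1:4, function(i) random_seq(30, 800 + 10 * r + i), "")
    f <- pairwise_fst(A, B)
    # direct enumeration oracle
    mean_k <- function(ss) {
      tot <- 0; cnt <- 0
      for (i in seq_len(length(ss) - 1)) for (j in (i + 1):length(ss)) {
        tot <- tot + oracle_pair_diff(ss[i], ss[j]); cnt <- cnt + 1
      }
      tot / cnt
    }
    hw <- (3 * mean_k(A) + 4 * mean_k(B)) / 7
    hb <- mean(outer(1:3, 1:4, Vectorize(function(i, j)
      oracle_pair_diff(A[i], B[j]))))
    expect_equal(f$fst, min(1, max(0, 1 - hw / hb)))
  }
  expect_error(pairwise_fst("AAAA", c("TTTT", "TTTT")), "n >= 2")
})

test_that("the island-model Nm transform reproduces the published pairs", {
  expect_equal(round(nm_from_fst(0.320), 3), 1.062)
  expect_equal(round(nm_from_fst(0.600), 3), 0.333)
  expect_equal(nm_from_fst(1), 0)
  expect_error(nm_from_fst(0), "fst")
  expect_error(nm_from_fst(-0.1), "fst")
  # involution with its inverse on (0, Inf)
  fst_from_nm <- function(nm) 1 / (1 + 2 * nm)
  for (nm in c(0.01, 0.248, 1.062, 5, 100)) {
    expect_equal(nm_from_fst(fst_from_nm(nm)), nm)
  }
})

test_that("transition/transversion classification matches the base lookup", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(paste(c("pos", "kind", "Ha", "Hb"), collapse = "\t"),
               "10\tSNP\tA\tG", "20\tSNP\tC\tT", "30\tSNP\tA\tC"), f)
  vt <- read_variant_table(f)
  r <- ts_tv_counts(vt, ancestor = "Ha")
  expect_equal(r$ts, 2L)
  expect_equal(r$tv, 1L)
  expect_equal(r$ts_tv, 2)

  mono <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(paste(c("pos", "kind", "Ha", "Hb"), collapse = "\t"),
               "10\tSNP\tA\tA"), mono)
  r0 <- ts_tv_counts(read_variant_table(mono), ancestor = "Ha")
  expect_equal(r0$ts + r0$tv, 0L)
  expect_true(is.na(r0$ts_tv))

  # exhaustive purine/pyrimidine lookup over all 12 ordered base pairs
  purine <- c("A", "G")
  for (a in c("A", "C", "G", "T")) for (b in setdiff(c("A", "C", "G", "T"), a)) {
    expected_ts <- (a %in% purine) == (b %in% purine)
    ff <- tempfile(fileext = ".tsv")
    writeLines(c(paste(c("pos", "kind", "Ha", "Hb"), collapse = "\t"),
                 paste("10", "SNP", a, b, sep = "\t")), ff)
    r1 <- ts_tv_counts(read_variant_table(ff), ancestor = "Ha")
    expect_equal(r1$ts == 1L, expected_ts)
  }
})

test_that("Nei-Gojobori counting agrees with exhaustive path enumeration", {
  same <- dnds_nei_gojobori(c(a = "ATGGGA", b = "ATGGGA"))
  expect_equal(same$dn, 0)
  expect_equal(same$ds, 0)
  expect_true(is.na(same$dnds))

  # one third-position synonymous change: forced by the genetic code
  syn <- dnds_nei_gojobori(c(a = "ATGGGAAAACTG", b = "ATGGGGAAACTG"))
  expect_equal(syn$dn, 0)
  expect_gt(syn$ds, 0)

  for (r in 1:10) {
    a <- random_cds(5, 900 + r)
    b <- a
    set.seed(950 + r)
    for (p in sample(15, sample(1:4, 1))) {
      b <- mutate_at(b, p, sample(setdiff(c("A", "C", "G", "T"),
                                          substr(b, p, p)), 1))
    }
    got <- dnds_nei_gojobori(c(x = a, y = b))
    want <- oracle_ng_pair(a, b)
    expect_equal(got$pairs$S, want$S, tolerance = 1e-12)
    expect_equal(got$pairs$Sd, want$Sd, tolerance = 1e-12)
    expect_equal(got$pairs$Nd, want$Nd, tolerance = 1e-12)
    expect_equal(got$dn, want$dN, tolerance = 1e-12)
    expect_equal(got$ds, want$dS, tolerance = 1e-12)
  }
})

test_that("diversity statistics are invariant to input order", {
  set.seed(5)
  seqs <- vapply(1:4, function(i) random_seq(50, 600 + i), "")
  mult <- c(2L, 1L, 3L, 1L)
  d1 <- nucleotide_diversity(seqs, mult)
  ord <- c(3, 1, 4, 2)
  d2 <- nucleotide_diversity(seqs[ord], mult[ord])
  expect_equal(d1$pi, d2$pi)
  expect_equal(d1$hd, d2$hd)
  f1 <- pairwise_fst(seqs[1:2], seqs[3:4])
  f2 <- pairwise_fst(rev(seqs[1:2]), rev(seqs[3:4]))
  expect_equal(f1$fst, f2$fst)
})
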