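test_that("decomposition recovers the published composition of all 16 haplotypes", {
  pan <- reference_panel()
  comp <- pan$composition
  for (h in comp$haplotype) {
    tr <- decompose_structure(gsub("-", "", pan$aligned[[h]]), pan)
    expect_identical(tr$haplotype_id, h)
    expect_identical(tr$composition$fs, comp$fs[comp$haplotype == h])
    expect_identical(tr$composition$ncs, comp$ncs[comp$haplotype == h])
    expect_identical(tr$composition$orf79, comp$orf79[comp$haplotype == h])
    expect_identical(tr$group, comp$group[comp$haplotype == h])
    expect_false(tr$partial)
  }
})

test_that("H1 and H16 type to their published segment compositions", {
  pan <- reference_panel()
  h1 <- decompose_structure(gsub("-", "", pan$aligned[["H1"]]), pan)
  expect_identical(unlist(h1$composition),
                   c(atp6 = "atp6", fs = "fs1a", ncs = "ncs1-BT",
                     orf79 = "orf79a"))
  h16 <- decompose_structure(gsub("-", "", pan$aligned[["H16"]]), pan)
  expect_identical(unlist(h16$composition),
                   c(atp6 = "atp6", fs = "fs2", ncs = "ncs1-e2",
                     orf79 = "orf79e"))
})

test_that("reverse-complement queries and flanked queries are handled", {
  pan <- reference_panel()
  q <- gsub("-", "", pan$aligned[["H11"]])
  tr <- decompose_structure(
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(q))), pan)
  expect_identical(tr$haplotype_id, "H11")
  expect_identical(tr$strand, "-")

  flanked <- paste0(random_seq(300, 21), q, random_seq(300, 22))
  tr2 <- decompose_structure(flanked, pan)
  expect_identical(tr2$haplotype_id, "H11")
})

test_that("a query truncated at position 1100 yields a partial call", {
  pan <- reference_panel()
  q <- substr(gsub("-", "", pan$aligned[["H1"]]), 1, 1100)
  tr <- decompose_structure(q, pan)
  expect_true(tr$partial)
  expect_identical(tr$composition$fs, "fs1a")
  expect_true(is.na(tr$composition$ncs))
  expect_true(is.na(tr$composition$orf79))
})

test_that("sequences without an atp6 anchor are rejected", {
  expect_error(decompose_structure(random_seq(2000, 5)), "anchor")
})

test_that("group assignment follows the segment rules", {
  expect_identical(assign_group("fs1a", "ncs1-c"), "AO-I")
  expect_identical(assign_group("fs1b", "ncs1-d"), "AO-I")
  expect_identical(assign_group("fs1a", "ncs2-a"), "AO-II")
  expect_identical(assign_group("fs1a", "ncs3-HL"), "AO-III")
  expect_identical(assign_group("fs2", "ncs1-e2"), "AO-IV")
  expect_identical(assign_group("fs2", "ncs3-a"), "unclassified")
  expect_identical(assign_group(NA_character_, "ncs1-a"), "unclassified")
  expect_identical(assign_group("fs1a", "weird"), "unclassified")
})

test_that("the published panel splits into the four published groups", {
  ht <- read_haplotype_table()
  groups <- split(ht$haplotype, ht$group)
  expect_setequal(groups[["AO-I"]], paste0("H", 1:9))
  expect_setequal(groups[["AO-II"]], c("H14", "H15"))
  expect_setequal(groups[["AO-III"]], paste0("H", 10:13))
  expect_setequal(groups[["AO-IV"]], "H16")
})

test_that("state-vector classification finds exact and nearest matches", {
  pan <- reference_panel()
  for (h in colnames(pan$states)) {
    expect_identical(classify_haplotype(pan$states[, h])$haplotype_id, h)
  }
  st <- pan$states[, "H11"]
  st[["1399/SNP"]] <- "C"
  cl <- classify_haplotype(st)
  expect_identical(cl$haplotype_id, "novel")
  expect_true("H11" %in% cl$nearest)
  expect_equal(cl$distance, 1L)

  expect_error(classify_haplotype(st[-1]), "missing state")
})

test_that("isolate orf79 detection applies an inclusive upstream window", {
  ann <- function(atp_end, orf_start, strand = "+") {
    data.frame(gene = c("atp6", "orf79"),
               start = c(atp_end - 999, orf_start),
               end = c(atp_end, orf_start + 239), strand = strand)
  }
  expect_false(detect_isolate_orf79(ann(9980, 10000)))
  expect_true(detect_isolate_orf79(ann(9980, 25000)))
  # gap exactly equal to the window is still adjacent
  expect_false(detect_isolate_orf79(ann(8000, 10000), window = 2000))
  expect_true(detect_isolate_orf79(ann(8000, 10001), window = 2000))
  expect_error(detect_isolate_orf79(
    data.frame(gene = "atp6", start = 1, end = 1005, strand = "+")),
    "no orf79")
})

test_that("variant counting respects spans and rejects inverted spans", {
  vt <- reference_panel()$variant_table
  expect_equal(count_variants(vt, c(1222, 1461)),
               c(SNP = 6L, Sub = 0L, Ins = 0L))
  expect_equal(unname(count_variants(vt, c(1, 1005))), c(0L, 0L, 0L))
  expect_error(count_variants(vt, c(100, 10)), "span")
})
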