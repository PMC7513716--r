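test_that("two haplotypes one step apart give a single unit edge", {
  g <- median_joining_network(rbind(a = c("0", "0"), b = c("0", "1")))
  expect_equal(nrow(g$edges), 1L)
  expect_equal(g$edges$weight, 1)
  expect_equal(sum(g$nodes$type == "median"), 0L)
})

test_that("a two-locus rectangle forms a 4-cycle without medians", {
  rect <- rbind(`00` = c("0", "0"), `01` = c("0", "1"),
                `10` = c("1", "0"), `11` = c("1", "1"))
  g <- median_joining_network(rect)
  expect_equal(sum(g$nodes$type == "median"), 0L)
  expect_equal(nrow(g$edges), 4L)
  expect_true(all(g$edges$weight == 1))
})

test_that("three equidistant haplotypes gain one degree-3 median", {
  star <- rbind(u = c("1", "0", "0"), v = c("0", "1", "0"),
                w = c("0", "0", "1"))
  g <- median_joining_network(star)
  meds <- g$nodes$id[g$nodes$type == "median"]
  expect_equal(length(meds), 1L)
  deg <- table(c(g$edges$from, g$edges$to))
  expect_equal(unname(deg[meds]), 3L)
  expect_equal(g$cost, 3)
  # the inferred median is the all-ancestral vector
  expect_equal(unname(g$states[meds, ]), c("0", "0", "0"))
})

test_that("network cost never exceeds the plain spanning tree cost", {
  set.seed(17)
  for (r in 1:10) {
    n <- sample(3:6, 1); l <- sample(4:8, 1)
    m <- matrix(sample(c("0", "1"), n * l, replace = TRUE), n,
                dimnames = list(paste0("h", 1:n), NULL))
    m <- m[!duplicated(apply(m, 1, paste, collapse = "")), , drop = FALSE]
    if (nrow(m) < 2) next
    g <- median_joining_network(m)
    obs <- m
    d <- matrix(0, nrow(obs), nrow(obs))
    for (i in seq_len(nrow(obs))) for (j in seq_len(nrow(obs))) {
      d[i, j] <- sum(obs[i, ] != obs[j, ])
    }
    mst <- vegan::spantree(as.dist(d))
    expect_lte(g$cost, sum(mst$dist))
  }
})

test_that("median joining matches exhaustive minimum-cost search on small fixtures", {
  fixtures <- list(
    rbind(`00` = c("0", "0"), `01` = c("0", "1"),
          `10` = c("1", "0"), `11` = c("1", "1")),
    rbind(u = c("1", "0", "0"), v = c("0", "1", "0"), w = c("0", "0", "1")),
    rbind(a = c("0", "0", "0", "0"), b = c("1", "1", "0", "0"),
          c = c("0", "0", "1", "1"), d = c("1", "1", "1", "1"))
  )
  set.seed(23)
  for (r in 1:4) {
    n <- sample(4:6, 1); l <- sample(4:6, 1)
    m <- matrix(sample(c("0", "1"), n * l, replace = TRUE), n,
                dimnames = list(paste0("h", 1:n), NULL))
    m <- m[!duplicated(apply(m, 1, paste, collapse = "")), , drop = FALSE]
    if (nrow(m) >= 3) fixtures[[length(fixtures) + 1]] <- m
  }
  for (m in fixtures) {
    g <- median_joining_network(m)
    oracle <- oracle_min_network_cost(m, max_medians = 3)
    expect_equal(g$cost, oracle)
  }
})

test_that("the network is deterministic and order-independent", {
  set.seed(29)
  m <- matrix(sample(c("0", "1"), 5 * 6, replace = TRUE), 5,
              dimnames = list(paste0("h", 1:5), NULL))
  m <- m[!duplicated(apply(m, 1, paste, collapse = "")), , drop = FALSE]
  g1 <- median_joining_network(m)
  perm <- sample(nrow(m))
  g2 <- median_joining_network(m[perm, , drop = FALSE])
  norm <- function(g) g$edges[order(g$edges$from, g$edges$to), ]
  obs1 <- subset(norm(g1), from %in% rownames(m) & to %in% rownames(m))
  obs2 <- subset(norm(g2), from %in% rownames(m) & to %in% rownames(m))
  expect_equal(obs1, obs2, ignore_attr = TRUE)
  expect_equal(g1$cost, g2$cost)
})

test_that("the reference AO-I subnetwork roots on the published ancestor", {
  pan <- reference_panel()
  ao1 <- pan$composition$haplotype[pan$composition$group == "AO-I"]
  st <- network_states(haplotypes = ao1)
  mult <- with(pan$composition[pan$composition$group == "AO-I", ],
               n_rufipogon + n_sativa)
  g <- median_joining_network(st, multiplicities = mult)
  rc <- root_candidates(g, ancestral_states = st["H1", ])
  expect_identical(rc$id[1], "H1")
})

test_that("a star topology roots on its hub and ranks survive relabeling", {
  star <- rbind(hub = c("0", "0", "0", "0"), s1 = c("1", "0", "0", "0"),
                s2 = c("0", "1", "0", "0"), s3 = c("0", "0", "1", "0"),
                s4 = c("0", "0", "0", "1"))
  g <- median_joining_network(star)
  rc <- root_candidates(g)
  expect_identical(rc$id[1], "hub")

  relab <- star
  rownames(relab) <- c("zhub", "a1", "a2", "a3", "a4")
  g2 <- median_joining_network(relab)
  rc2 <- root_candidates(g2)
  expect_identical(rc2$id[1], "zhub")
  expect_equal(rc$degree, rc2$degree)
})

test_that("fewer than two distinct haplotypes is an error", {
  expect_error(median_joining_network(rbind(a = c("0", "0"))), "at least two")
  expect_error(median_joining_network(rbind(a = c("0", "0"), b = c("0", "0"))),
               "duplicate")
})
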