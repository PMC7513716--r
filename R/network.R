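# Haplotype state vectors are character matrices (rows = haplotypes,
# columns = loci); every state change costs one mutational step, whatever
# the locus alphabet (base, block label, insertion presence).

hamming <- function(u, v) sum(u != v)

state_key <- function(v) paste(v, collapse = "\x1f")

pairwise_hamming <- function(m) {
  n <- nrow(m)
  d <- matrix(0L, n, n, dimnames = list(rownames(m), rownames(m)))
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- hamming(m[i, ], m[j, ])
    }
  }
  d
}

# minimum spanning tree cost over a complete graph given a distance matrix
mst_cost <- function(d) {
  n <- nrow(d)
  if (n < 2) return(0L)
  in_tree <- c(TRUE, rep(FALSE, n - 1))
  best <- as.numeric(d[1, ])
  cost <- 0
  for (step in seq_len(n - 1)) {
    cand <- which(!in_tree)
    v <- cand[which.min(best[cand])]
    cost <- cost + best[v]
    in_tree[v] <- TRUE
    best <- pmin(best, as.numeric(d[v, ]))
  }
  cost
}

# Minimum spanning network: an edge of weight w joins u,v iff they are not
# already connected through strictly cheaper pairs (threshold relaxed by
# epsilon, so epsilon > 0 admits near-minimal alternative connections).
msn_edges <- function(d, epsilon = 0L) {
  n <- nrow(d)
  ids <- rownames(d)
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  w <- d[upper.tri(d)]
  components_at <- function(max_w) {
    parent <- seq_len(n)
    find <- function(i) {
      while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }
      i
    }
    for (k in which(w <= max_w)) {
      a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
      if (a != b) parent[a] <- b
    }
    vapply(seq_len(n), find, 1L)
  }
  keep <- logical(length(w))
  for (lev in sort(unique(w))) {
    roots <- components_at(lev - 1 - epsilon)
    at <- which(w == lev)
    keep[at] <- roots[pairs[at, 1]] != roots[pairs[at, 2]]
  }
  out <- data.frame(from = ids[pairs[keep, 1]], to = ids[pairs[keep, 2]],
                    weight = w[keep])
  swap <- out$from > out$to
  tmp <- out$from[swap]; out$from[swap] <- out$to[swap]; out$to[swap] <- tmp
  out[order(out$weight, out$from, out$to), , drop = FALSE]
}

# majority-consensus median of three state vectors; NULL when some locus has
# three distinct states (no unique consensus)
triple_median <- function(u, v, w) {
  out <- character(length(u))
  for (k in seq_along(u)) {
    s <- c(u[k], v[k], w[k])
    tab <- table(s)
    if (max(tab) == 1) return(NULL)
    out[k] <- names(tab)[which.max(tab)]
  }
  out
}

#' Median-joining haplotype network
#'
#' Builds the minimum spanning network over the observed haplotype state
#' vectors, then repeatedly adds inferred intermediate (median) vectors --
#' majority consensus of node triples -- whenever doing so strictly reduces
#' the cost of spanning the node set, and finally prunes redundant medians.
#' Every state change at any locus counts one mutational step. Candidate
#' medians are processed deterministically (largest cost saving, then
#' lexicographic state order), so the result does not depend on input
#' order.
#'
#' @param states character matrix, rows = haplotypes (rownames = ids),
#'   columns = loci; encode SNPs as bases, insertions as present/absent
#'   labels, block substitutions as categorical labels. `NA` is treated as
#'   its own state.
#' @param multiplicities sample size per haplotype (default 1).
#' @param epsilon integer relaxation of the spanning-network criterion
#'   (default 0).
#' @param max_medians safety cap on added median vectors.
#' @return list of class `haplotype_network`: `nodes` (id, type
#'   observed/median, size), `edges` (from, to, weight), `states` (matrix
#'   incl. medians), `epsilon`, `cost` (spanning cost of the final node
#'   set).
#' @export
median_joining_network <- function(states, multiplicities = NULL, epsilon = 0L,
                                   max_medians = 64L) {
  if (is.null(rownames(states))) rownames(states) <- paste0("h", seq_len(nrow(states)))
  states[is.na(states)] <- ""
  if (anyDuplicated(apply(states, 1, state_key))) {
    stop("duplicate haplotype state vectors; aggregate multiplicities first",
         call. = FALSE)
  }
  if (nrow(states) < 2) stop("need at least two distinct haplotypes", call. = FALSE)
  if (is.null(multiplicities)) multiplicities <- rep(1L, nrow(states))
  observed <- rownames(states)
  m <- states
  repeat {
    d <- pairwise_hamming(m)
    base_cost <- mst_cost(d)
    if (nrow(m) < 3) break
    seen <- apply(m, 1, state_key)
    cand <- list()
    trip <- utils::combn(nrow(m), 3)
    for (t in seq_len(ncol(trip))) {
      med <- triple_median(m[trip[1, t], ], m[trip[2, t], ], m[trip[3, t], ])
      if (is.null(med)) next
      key <- state_key(med)
      if (key %in% seen || !is.null(cand[[key]])) next
      m2 <- rbind(m, matrix(med, 1))
      d2 <- pairwise_hamming(m2)
      delta <- base_cost - mst_cost(d2)
      if (delta > 0) cand[[key]] <- list(med = med, delta = delta)
    }
    if (!length(cand) || sum(!rownames(m) %in% observed) >= max_medians) break
    deltas <- vapply(cand, `[[`, 0, "delta")
    best <- names(cand)[order(-deltas, names(cand))][1]
    med_id <- sprintf("mv%02d", sum(!rownames(m) %in% observed) + 1L)
    m <- rbind(m, matrix(cand[[best]]$med, 1, dimnames = list(med_id, NULL)))
  }
  # prune medians that do not lower the spanning cost (e.g. degree <= 2
  # way-points on an already-minimal path)
  repeat {
    d <- pairwise_hamming(m)
    cost <- mst_cost(d)
    meds <- setdiff(rownames(m), observed)
    removed <- FALSE
    for (id in sort(meds)) {
      keep <- rownames(m) != id
      if (mst_cost(pairwise_hamming(m[keep, , drop = FALSE])) <= cost) {
        m <- m[keep, , drop = FALSE]
        removed <- TRUE
        break
      }
    }
    if (!removed) break
  }
  d <- pairwise_hamming(m)
  edges <- msn_edges(d, epsilon = epsilon)
  nodes <- data.frame(
    id = rownames(m),
    type = ifelse(rownames(m) %in% observed, "observed", "median"),
    size = ifelse(rownames(m) %in% observed,
                  multiplicities[match(rownames(m), observed)], 0L))
  structure(list(nodes = nodes, edges = edges, states = m, epsilon = epsilon,
                 cost = mst_cost(d)),
            class = "haplotype_network")
}

node_degrees <- function(g) {
  tab <- table(factor(c(g$edges$from, g$edges$to), levels = g$nodes$id))
  setNames(as.integer(tab), names(tab))
}

#' Rank candidate root haplotypes of a network
#'
#' Ranks observed nodes by agreement with externally supplied ancestral
#' states (when given), then by node degree, then by sample size. Ties are
#' reported, never broken silently.
#'
#' @param g a `haplotype_network`.
#' @param ancestral_states optional character vector of ancestral states
#'   (same locus order as the network's state matrix).
#' @return data.frame ranked best-first with columns `id`, `matches`,
#'   `degree`, `size`, `tied` (TRUE when the node ties the next-ranked one
#'   on every criterion).
#' @export
root_candidates <- function(g, ancestral_states = NULL) {
  obs <- g$nodes$id[g$nodes$type == "observed"]
  deg <- node_degrees(g)[obs]
  size <- g$nodes$size[match(obs, g$nodes$id)]
  if (!is.null(ancestral_states)) {
    matches <- vapply(obs, function(id) {
      sum(g$states[id, ] == ifelse(is.na(ancestral_states), "", ancestral_states))
    }, 0L)
  } else {
    matches <- rep(NA_integer_, length(obs))
  }
  key_m <- if (is.null(ancestral_states)) rep(0L, length(obs)) else matches
  ord <- order(-key_m, -deg, -size, obs)
  out <- data.frame(id = obs[ord], matches = matches[ord], degree = deg[ord],
                    size = size[ord])
  n <- nrow(out)
  out$tied <- c(vapply(seq_len(n - 1), function(i) {
    identical(key_m[ord][i], key_m[ord][i + 1]) &&
      deg[ord][i] == deg[ord][i + 1] && size[ord][i] == size[ord][i + 1]
  }, TRUE), FALSE)
  rownames(out) <- NULL
  out
}

#' State matrix of the reference haplotypes for network building
#'
#' Encodes the packaged variant table as network states: SNP bases,
#' insertion present/absent, block lengths as categorical labels.
#'
#' @param vt a `variant_table`.
#' @param haplotypes optional subset of haplotype ids.
#' @return character matrix (haplotypes x loci).
#' @export
network_states <- function(vt = reference_panel()$variant_table,
                           haplotypes = NULL) {
  m <- t(variant_state_matrix(vt))
  m[is.na(m)] <- ""
  if (!is.null(haplotypes)) m <- m[haplotypes, , drop = FALSE]
  m
}
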