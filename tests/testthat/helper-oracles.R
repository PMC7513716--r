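# Independent oracles used across the suite. Each reimplements the checked
# quantity from its definition, sharing no code path with the package.

# --- brute-force pairwise difference count on character vectors ------------
oracle_pair_diff <- function(a, b) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  n <- 0L
  for (k in seq_along(ca)) {
    if (ca[k] %in% c("A", "C", "G", "T") && cb[k] %in% c("A", "C", "G", "T") &&
        ca[k] != cb[k]) n <- n + 1L
  }
  n
}

# --- Tajima-Nei equal-input distance, coded directly from the formula ------
oracle_tajima_nei <- function(a, b) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  keep <- ca %in% c("A", "C", "G", "T") & cb %in% c("A", "C", "G", "T")
  ca <- ca[keep]; cb <- cb[keep]
  L <- length(ca)
  p <- sum(ca != cb) / L
  if (p == 0) return(0)
  bases <- c("A", "C", "G", "T")
  q <- sapply(bases, function(x) (sum(ca == x) + sum(cb == x)) / (2 * L))
  h <- 0
  for (i in 1:3) for (j in (i + 1):4) {
    x <- sum((ca == bases[i] & cb == bases[j]) |
             (ca == bases[j] & cb == bases[i])) / L
    if (x > 0) h <- h + x^2 / (2 * q[i] * q[j])
  }
  bb <- 0.5 * (1 - sum(q^2) + p^2 / h)
  unname(-bb * log(1 - p / bb))
}

# --- Nei-Gojobori by exhaustive path enumeration ---------------------------
oracle_codon_translate <- function(codon) Biostrings::GENETIC_CODE[[codon]]

oracle_syn_sites <- function(codon) {
  aa <- oracle_codon_translate(codon)
  tot <- 0
  for (pos in 1:3) {
    orig <- substr(codon, pos, pos)
    for (b in c("A", "C", "G", "T")) {
      if (b == orig) next
      mut <- codon; substr(mut, pos, pos) <- b
      if (!(mut %in% c("TAA", "TAG", "TGA")) &&
          oracle_codon_translate(mut) == aa) tot <- tot + 1
    }
  }
  tot / 3
}

oracle_paths <- function(positions) {
  if (length(positions) <= 1) return(list(positions))
  out <- list()
  for (i in seq_along(positions)) {
    for (tail in oracle_paths(positions[-i])) {
      out[[length(out) + 1]] <- c(positions[i], tail)
    }
  }
  out
}

oracle_ng_pair <- function(s1, s2) {
  nc <- nchar(s1) / 3
  S <- 0; Sd <- 0; Nd <- 0
  for (k in seq_len(nc)) {
    c1 <- substr(s1, 3 * k - 2, 3 * k); c2 <- substr(s2, 3 * k - 2, 3 * k)
    S <- S + (oracle_syn_sites(c1) + oracle_syn_sites(c2)) / 2
    dp <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
    if (!length(dp)) next
    paths <- oracle_paths(dp)
    sd_p <- 0; nd_p <- 0
    for (path in paths) {
      cur <- c1
      for (pos in path) {
        nxt <- cur; substr(nxt, pos, pos) <- substr(c2, pos, pos)
        syn <- oracle_codon_translate(nxt) == oracle_codon_translate(cur) &&
          !(nxt %in% c("TAA", "TAG", "TGA"))
        if (syn) sd_p <- sd_p + 1 else nd_p <- nd_p + 1
        cur <- nxt
      }
    }
    Sd <- Sd + sd_p / length(paths); Nd <- Nd + nd_p / length(paths)
  }
  N <- 3 * nc - S
  jc <- function(p) if (p >= 0.75) Inf else -0.75 * log(1 - 4 * p / 3)
  list(S = S, N = N, Sd = Sd, Nd = Nd, dS = jc(Sd / S), dN = jc(Nd / N))
}

# --- exhaustive minimum-cost network search (small binary instances) -------
# Minimal spanning cost achievable by augmenting the observed vectors with
# up to `max_medians` extra vectors drawn from the full state product.
oracle_min_network_cost <- function(states, max_medians = 3) {
  ham <- function(u, v) sum(u != v)
  dmat <- function(m) {
    n <- nrow(m); d <- matrix(0, n, n)
    if (n > 1) for (i in 1:(n - 1)) for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- ham(m[i, ], m[j, ])
    }
    d
  }
  prim <- function(d) {
    n <- nrow(d); if (n < 2) return(0)
    used <- c(TRUE, rep(FALSE, n - 1)); best <- d[1, ]; tot <- 0
    for (s in 1:(n - 1)) {
      v <- which(!used)[which.min(best[!used])]
      tot <- tot + best[v]; used[v] <- TRUE
      best <- pmin(best, d[v, ])
    }
    tot
  }
  alphabet <- lapply(seq_len(ncol(states)), function(j) unique(states[, j]))
  cands <- as.matrix(expand.grid(alphabet, stringsAsFactors = FALSE))
  keys <- apply(states, 1, paste, collapse = "|")
  ckeys <- apply(cands, 1, paste, collapse = "|")
  cands <- cands[!ckeys %in% keys, , drop = FALSE]
  best <- prim(dmat(states))
  if (max_medians >= 1 && nrow(cands) >= 1) {
    for (i in seq_len(nrow(cands))) {
      best <- min(best, prim(dmat(rbind(states, cands[i, ]))))
    }
  }
  if (max_medians >= 2 && nrow(cands) >= 2) {
    for (i in seq_len(nrow(cands) - 1)) for (j in (i + 1):nrow(cands)) {
      best <- min(best, prim(dmat(rbind(states, cands[i, ], cands[j, ]))))
    }
  }
  if (max_medians >= 3 && nrow(cands) >= 3 && nrow(cands) <= 40) {
    combs <- utils::combn(nrow(cands), 3)
    for (k in seq_len(ncol(combs))) {
      best <- min(best, prim(dmat(rbind(states, cands[combs[1, k], ],
                                        cands[combs[2, k], ],
                                        cands[combs[3, k], ]))))
    }
  }
  best
}

# --- misc -------------------------------------------------------------------
random_seq <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# non-stop random codons
random_cds <- function(n_codons, seed) {
  set.seed(seed)
  pool <- apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                            c("A","C","G","T")), 1, paste, collapse = "")
  pool <- setdiff(pool, c("TAA", "TAG", "TGA"))
  paste(sample(pool, n_codons, replace = TRUE), collapse = "")
}

mutate_at <- function(seq, pos, base) {
  substr(seq, pos, pos) <- base
  seq
}
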