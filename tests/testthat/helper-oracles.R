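# Independent oracles kept deliberately separate from the implementation
# paths they check.

# Pearson chi-square statistic (1 df, no continuity correction) of the
# 2x2 table [c_a, n_a - c_a; c_b, n_b - c_b], computed from the closed-form
# cross-product expression rather than from proportions.
oracle_chisq_2x2 <- function(c_a, n_a, c_b, n_b) {
  c_a <- as.numeric(c_a); n_a <- as.numeric(n_a)
  c_b <- as.numeric(c_b); n_b <- as.numeric(n_b)
  a <- c_a; b <- n_a - c_a; c <- c_b; d <- n_b - c_b
  n <- a + b + c + d
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

# exact binomial upper tail by direct summation of the mass function
oracle_binom_tail <- function(k, size, p) {
  sum(vapply(k:size, function(x) dbinom(x, size, p), numeric(1)))
}

# naive agglomerative clustering: clusters as index sets, inter-cluster
# distance recomputed from the original matrix at every step.
oracle_agglomerate <- function(dmat, linkage = "average") {
  agg <- switch(linkage, average = mean, complete = max, single = min)
  n <- nrow(dmat)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  coph <- matrix(0, n, n, dimnames = dimnames(dmat))
  while (length(clusters) > 1L) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i >= j) next
        d <- agg(dmat[clusters[[i]], clusters[[j]], drop = FALSE])
        if (d < best_d) { best_d <- d; best <- c(i, j) }
      }
    }
    for (a in clusters[[best[1L]]]) {
      for (b in clusters[[best[2L]]]) {
        coph[a, b] <- coph[b, a] <- best_d
      }
    }
    heights <- c(heights, best_d)
    clusters[[best[1L]]] <- c(clusters[[best[1L]]], clusters[[best[2L]]])
    clusters[[best[2L]]] <- NULL
  }
  list(heights = heights, cophenetic = coph)
}

# brute-force recount of category memberships
oracle_membership <- function(categories) {
  genes <- unique(unlist(categories$categories))
  counts <- vapply(genes, function(g)
    sum(vapply(categories$categories, function(s) g %in% s, logical(1))),
    integer(1))
  setNames(counts, genes)
}

# tiny deterministic gene-count fixtures used across files
fixture_counts <- function() {
  list(a = c(g1 = 50, g2 = 10, g3 = 5, g4 = 2, g5 = 1),
       b = c(g1 = 48, g2 = 30, g3 = 5, g6 = 4))
}
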