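# Independent oracles, kept deliberately naive and separate from the
# implementation paths they check.

# Smith-Waterman local alignment by direct affine-gap dynamic programming.
# A gap of length L costs gap_open + L * gap_extend (first gap character
# pays opening + extension).
oracle_sw <- function(a, b, gap_open = 10, gap_extend = 0.5, mat = NULL) {
  if (is.null(mat)) {
    env <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = env)
    mat <- env$BLOSUM62
  }
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A)
  m <- length(B)
  first <- gap_open + gap_extend
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  F <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - first, E[i, j - 1] - gap_extend)
      F[i, j] <- max(H[i - 1, j] - first, F[i - 1, j] - gap_extend)
      H[i, j] <- max(0, H[i - 1, j - 1] + mat[A[i - 1], B[j - 1]],
                     E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

oracle_normalized_sw <- function(a, b, gap_open = 10, gap_extend = 0.5) {
  oracle_sw(a, b, gap_open, gap_extend) /
    sqrt(oracle_sw(a, a, gap_open, gap_extend) *
           oracle_sw(b, b, gap_open, gap_extend))
}

# AUROC by brute-force counting over all positive x negative pairs,
# ties counted one half.
oracle_auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  pos <- scores[labels]
  neg <- scores[!labels]
  total <- 0
  for (p in pos) {
    total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  }
  total / (length(pos) * length(neg))
}

# Two-sided Fisher p by full enumeration of all 2x2 tables with the
# observed margins, using binomial coefficients only.
oracle_fisher <- function(n_c, n_a, n_b, N) {
  lo <- max(0, n_a + n_b - N)
  hi <- min(n_a, n_b)
  x <- lo:hi
  logp <- lchoose(n_a, x) + lchoose(N - n_a, n_b - x) - lchoose(N, n_b)
  p <- exp(logp)
  obs <- p[x == n_c]
  sum(p[p <= obs * (1 + 1e-7)])
}

# Steady state of the restart walk by dense linear solve:
# p = r (I - (1 - r) T)^{-1} p0, where T is the column-stochastic operator
# M^T with dangling columns replaced by the seed vector p0.
oracle_rwr <- function(network, seeds, restart = 0.7) {
  ids <- network$nodes$id
  n <- length(ids)
  M <- matrix(0, n, n, dimnames = list(ids, ids))
  for (k in seq_len(nrow(network$edges))) {
    M[network$edges$from[k], network$edges$to[k]] <-
      M[network$edges$from[k], network$edges$to[k]] + network$edges$weight[k]
  }
  out <- rowSums(M)
  dangling <- out == 0
  M[!dangling, ] <- M[!dangling, , drop = FALSE] / out[!dangling]
  p0 <- setNames(numeric(n), ids)
  p0[seeds] <- 1 / length(seeds)
  Tm <- t(M)
  if (any(dangling)) Tm[, dangling] <- matrix(p0, n, sum(dangling))
  solve(diag(n) - (1 - restart) * Tm, restart * p0)
}

# Random connected-ish directed test network over n nodes.
random_network <- function(n_nodes, n_edges, n_phenotypes = 0, weights = FALSE) {
  ids <- sprintf("v%02d", seq_len(n_nodes))
  kind <- rep("gene", n_nodes)
  if (n_phenotypes > 0) kind[seq_len(n_phenotypes) + n_nodes - n_phenotypes] <- "phenotype"
  from <- sample(ids, n_edges, replace = TRUE)
  to <- sample(ids, n_edges, replace = TRUE)
  keep <- from != to
  w <- if (weights) runif(sum(keep), 0.1, 2) else rep(1, sum(keep))
  suppressWarnings(association_network(
    data.frame(id = ids, kind = kind, stringsAsFactors = FALSE),
    data.frame(from = from[keep], to = to[keep], weight = w,
               stringsAsFactors = FALSE)
  ))
}

random_aa <- function(len) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len, replace = TRUE),
        collapse = "")
}
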