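# Independent brute-force oracles. These deliberately share no code with the
# package implementations they check.

# naive UPGMA cophenetic correlation: agglomerate by mean of ORIGINAL
# pairwise distances, record merge heights as cophenetic distances
oracle_cophenetic <- function(C) {
  D <- 1 - C
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  while (length(clusters) > 1) {
    m <- length(clusters)
    best <- c(NA, NA)
    best_d <- Inf
    for (i in 1:(m - 1)) for (j in (i + 1):m) {
      d <- mean(D[clusters[[i]], clusters[[j]]])
      if (d < best_d) { best_d <- d; best <- c(i, j) }
    }
    a <- clusters[[best[1]]]; b <- clusters[[best[2]]]
    coph[a, b] <- best_d; coph[b, a] <- best_d
    clusters[[best[1]]] <- c(a, b)
    clusters[[best[2]]] <- NULL
  }
  lo <- lower.tri(D)
  if (sd(D[lo]) == 0 || sd(coph[lo]) == 0) return(NA_real_)
  cor(D[lo], coph[lo])
}

# silhouette from the pairwise definition, loops only
oracle_silhouette <- function(C, labels) {
  D <- 1 - C
  n <- length(labels)
  s <- numeric(n)
  for (i in 1:n) {
    same <- setdiff(which(labels == labels[i]), i)
    if (length(same) == 0) { s[i] <- 0; next }
    a <- mean(sapply(same, function(j) D[i, j]))
    b <- Inf
    for (l in setdiff(unique(labels), labels[i])) {
      other <- which(labels == l)
      b <- min(b, mean(sapply(other, function(j) D[i, j])))
    }
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}

# BH from the definitional double loop: fdr_(i) = min_{j>=i} p_(j) m / j
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in 1:m) {
    vals <- sapply(i:m, function(j) ps[j] * m / j)
    adj[i] <- min(1, min(vals))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# exact hypergeometric upper tail by enumerating all |selected|-subsets
oracle_hypergeom <- function(n_universe, pathway_idx, n_selected, q_min) {
  subsets <- combn(n_universe, n_selected)
  hits <- apply(subsets, 2, function(s) length(intersect(s, pathway_idx)) >= q_min)
  mean(hits)
}

# adjusted Rand index
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  sa <- sum(choose(rowSums(tab), 2))
  sb <- sum(choose(colSums(tab), 2))
  expected <- sa * sb / choose(n, 2)
  maxv <- (sa + sb) / 2
  (sij - expected) / (maxv - expected)
}

# map fitted cluster ids onto truth ids by majority vote
map_clusters <- function(fitted, truth) {
  tt <- table(fitted, truth)
  stats::setNames(as.integer(colnames(tt)[apply(tt, 1, which.max)]),
                  rownames(tt))
}

# small well-separated two-block consensus matrix
two_block_consensus <- function(n1 = 4, n2 = 4) {
  lab <- rep(1:2, c(n1, n2))
  C <- outer(lab, lab, "==") * 1
  diag(C) <- 1
  C
}

# small normalized test matrix with planted 2-cluster structure
tiny_planted_matrix <- function(n_genes = 60, n_samples = 16, k = 2,
                                effect = 3, seed = 1) {
  set.seed(seed)
  lab <- rep_len(seq_len(k), n_samples)
  X <- matrix(rnorm(n_genes * n_samples), n_genes, n_samples)
  block <- split(seq_len(min(n_genes, k * 10)), rep(seq_len(k), each = 10))
  for (c_ in seq_len(k)) X[block[[c_]], lab == c_] <- X[block[[c_]], lab == c_] + effect
  X <- X - rowMeans(X)
  X <- X / sqrt(rowMeans(X^2))
  dimnames(X) <- list(sprintf("g%02d", 1:n_genes), sprintf("s%02d", 1:n_samples))
  attr(X, "labels") <- lab
  X
}
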