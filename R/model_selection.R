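#' Cophenetic correlation of a consensus matrix
#'
#' Measures how faithfully average-linkage hierarchical clustering of the
#' consensus dissimilarity `1 - C` preserves the original dissimilarities:
#' the Pearson correlation between the off-diagonal entries of `1 - C` and
#' the cophenetic distances of the dendrogram. Values near 1 indicate stable
#' clustering across restarts.
#'
#' @param C consensus matrix (n x n, symmetric, diagonal 1).
#' @return correlation in `[-1, 1]`, or `NA` with attribute
#'   `undefined = TRUE` when either distance vector is constant.
#' @export
cophenetic_coefficient <- function(C) {
  n <- nrow(C)
  if (n < 3) stop("cophenetic coefficient needs n >= 3 samples")
  d <- as.dist(1 - C)
  hc <- hclust(d, method = "average")
  cd <- cophenetic(hc)
  if (stats::sd(d) < 1e-15 || stats::sd(cd) < 1e-15)
    return(structure(NA_real_, undefined = TRUE))
  cor(as.vector(d), as.vector(cd))
}

#' Dispersion coefficient of a consensus matrix
#'
#' `(1/n^2) * sum(4 * (C - 0.5)^2)`: 1 when every consensus entry is 0 or 1
#' (perfectly reproducible co-clustering), 0 when all entries sit at 0.5.
#'
#' @param C consensus matrix.
#' @return value in `[0, 1]`.
#' @export
dispersion_coefficient <- function(C) {
  mean(4 * (C - 0.5)^2)
}

#' Explained variance, RSS and final residual of a factorization
#'
#' `rss = ||Y - WH||^2_F`, `evar = 1 - rss / ||Y||^2_F`, and `residuals` is
#' the final entry of the objective trace (identical to `rss` under the
#' Frobenius objective; both are reported because rank screening
#' conventionally lists them separately).
#'
#' @param fit an `snmf_fit`.
#' @param Y the factorized matrix.
#' @return list `(evar, rss, residuals)`.
#' @export
evar_rss_residuals <- function(fit, Y) {
  rss <- sum((Y - fit$W %*% fit$H)^2)
  list(evar = 1 - rss / sum(Y^2), rss = rss,
       residuals = fit$objective_trace[length(fit$objective_trace)])
}

#' Mean silhouette width on consensus dissimilarity
#'
#' Standard silhouette with distance `d = 1 - C`: for sample `i` with
#' within-cluster mean distance `a_i` and smallest other-cluster mean
#' distance `b_i`, `s_i = (b_i - a_i) / max(a_i, b_i)`. Singleton clusters
#' contribute `s_i = 0`. Returns the mean over samples.
#'
#' @param C consensus matrix.
#' @param labels integer cluster labels (label 0 = unassigned, excluded).
#' @return mean silhouette width in `[-1, 1]`.
#' @export
silhouette_score <- function(C, labels) {
  keep <- labels > 0
  D <- (1 - C)[keep, keep, drop = FALSE]
  labels <- labels[keep]
  if (length(unique(labels)) < 2) stop("silhouette needs >= 2 clusters")
  n <- length(labels)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    if (sum(own) == 1) { s[i] <- 0; next }
    a <- sum(D[i, own]) / (sum(own) - 1)  # exclude self (D[i,i] = 0)
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(D[i, labels == l]), numeric(1)))
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}

#' Hoyer sparseness of a vector
#'
#' `(sqrt(n) - l1/l2) / (sqrt(n) - 1)`: 1 for a one-hot vector, 0 for a
#' constant one.
#'
#' @param v non-zero numeric vector.
#' @return sparseness in `[0, 1]`.
#' @export
sparseness_hoyer <- function(v) {
  if (all(v == 0)) stop("sparseness of the zero vector is undefined")
  n <- length(v)
  if (n == 1) return(1)
  (sqrt(n) - sum(abs(v)) / sqrt(sum(v^2))) / (sqrt(n) - 1)
}

#' Mean Hoyer sparseness over basis columns
#' @param W basis matrix.
#' @return mean column sparseness.
#' @export
sparseness_basis <- function(W) {
  mean(apply(W, 2, sparseness_hoyer))
}

#' Row-wise permutation negative control
#'
#' Independently permutes each feature row across samples, preserving every
#' feature's marginal distribution exactly while destroying the sample
#' covariance that the factorization clusters on.
#'
#' @param X matrix (rows = features).
#' @param seed RNG seed.
#' @return matrix of the same shape and dimnames.
#' @export
randomize_matrix <- function(X, seed = 1L) {
  if (any(!is.finite(X))) stop("X must be finite")
  set.seed(seed)
  Xr <- t(apply(X, 1, sample))
  dimnames(Xr) <- dimnames(X)
  cls <- class(X)
  if ("normalized_matrix" %in% cls) class(Xr) <- cls
  Xr
}

compute_quality_metrics <- function(X, k, n_restarts, base_seed, ...) {
  Y <- split_signs(X)
  cons <- snmf_consensus(Y, k, n_restarts = n_restarts, base_seed = base_seed, ...)
  fit <- cons$best_fit
  err <- evar_rss_residuals(fit, Y)
  labels <- assign_samples(fit$H, fit$W)
  sil <- tryCatch(silhouette_score(cons$C, labels), error = function(e) NA_real_)
  data.frame(k = k,
             cophenetic = as.numeric(cophenetic_coefficient(cons$C)),
             dispersion = dispersion_coefficient(cons$C),
             evar = err$evar, residuals = err$residuals, rss = err$rss,
             silhouette = sil,
             sparseness = sparseness_basis(fit$W))
}

#' Screen the cluster number against a randomized negative control
#'
#' For each candidate `k`, runs the consensus factorization on the real data
#' and on a row-permuted randomization of it, and records seven quality
#' metrics (cophenetic, dispersion, evar, residuals, RSS, silhouette, Hoyer
#' sparseness) per condition. The selected rank is the `k` with the largest
#' real-data cophenetic coefficient among candidates whose real cophenetic
#' exceeds the randomized one (the negative-control gate); ties break by
#' higher dispersion, then smaller `k`.
#'
#' @param X signed normalized matrix (features x samples).
#' @param k_range candidate ranks (default `2:6`).
#' @param n_restarts restarts per consensus run (default 50).
#' @param seed base seed; restart seeds and the permutation seed derive from
#'   it.
#' @param ... passed to [snmf_factorize()] (`max_iter`, `tol`).
#' @return list of class `k_selection`: `k_best` and `metrics` (data.frame
#'   with columns `k`, `condition`, and the seven metrics).
#' @export
select_k <- function(X, k_range = 2:6, n_restarts = 50L, seed = 1L, ...) {
  n <- ncol(X)
  if (any(k_range < 2) || any(k_range >= min(2 * nrow(X), n)))
    stop("k_range must lie within [2, min(dim) - 1]")
  Xr <- randomize_matrix(unclass(X), seed = seed + 77003L)
  rows <- list()
  for (k in k_range) {
    real <- compute_quality_metrics(X, k, n_restarts, base_seed = seed + 1000L * k, ...)
    rand <- compute_quality_metrics(Xr, k, n_restarts, base_seed = seed + 1000L * k + 500L, ...)
    real$condition <- "real"; rand$condition <- "randomized"
    rows[[length(rows) + 1L]] <- real
    rows[[length(rows) + 1L]] <- rand
    .momics_log("select_k: k=%d cophenetic real=%.3f randomized=%.3f",
                k, real$cophenetic, rand$cophenetic)
  }
  metrics <- do.call(rbind, rows)
  metrics <- metrics[, c("k", "condition", "cophenetic", "dispersion", "evar",
                         "residuals", "rss", "silhouette", "sparseness")]
  re <- metrics[metrics$condition == "real", ]
  ra <- metrics[metrics$condition == "randomized", ]
  pass <- !is.na(re$cophenetic) & !is.na(ra$cophenetic) & re$cophenetic > ra$cophenetic
  if (!any(pass)) {
    err <- structure(class = c("momics_no_k_error", "error", "condition"),
                     list(message = "no candidate k passes the randomized negative control",
                          call = sys.call(), metrics = metrics))
    stop(err)
  }
  cand <- re[pass, ]
  ord <- order(-cand$cophenetic, -cand$dispersion, cand$k)
  structure(list(k_best = cand$k[ord[1]], metrics = metrics),
            class = "k_selection")
}

#' @export
print.k_selection <- function(x, ...) {
  cat(sprintf("<k_selection> k_best = %d\n", x$k_best))
  print(x$metrics, digits = 3, row.names = FALSE)
  invisible(x)
}
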