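#' Stack a signed matrix into its non-negative positive/negative parts
#'
#' Mean-centered (signed) expression cannot enter a non-negative
#' factorization directly. The signed matrix `X` (m x n) is stacked as
#' `Y = rbind(pmax(X, 0), pmax(-X, 0))` (2m x n), which is non-negative and
#' loses nothing: `X` is recovered exactly as the top half minus the bottom
#' half.
#'
#' @param X numeric matrix (typically a `normalized_matrix`).
#' @return non-negative matrix with `2 * nrow(X)` rows.
#' @export
split_signs <- function(X) {
  X <- unclass(as.matrix(X))
  if (any(!is.finite(X))) stop("X must be finite")
  Y <- rbind(pmax(X, 0), pmax(-X, 0))
  rownames(Y) <- c(paste0(rownames(X), "+"), paste0(rownames(X), "-"))
  Y
}

#' Non-negative matrix factorization by multiplicative updates
#'
#' Minimizes the squared Frobenius residual `||Y - WH||^2` over non-negative
#' `W` (2m x k) and `H` (k x n) with Lee-Seung multiplicative updates from a
#' seeded uniform(0, 1) random start. Iteration stops when the relative
#' objective change drops below `tol` or after `max_iter` updates; the
#' objective trace is monotone non-increasing.
#'
#' @param Y non-negative matrix, usually from [split_signs()].
#' @param k factorization rank, `1 <= k < min(dim(Y))`.
#' @param seed RNG seed for the random start.
#' @param max_iter maximum update sweeps (default 2000).
#' @param tol relative objective-change stopping threshold (default 1e-6).
#' @param eps denominator guard (default 1e-12).
#' @return list of class `snmf_fit`: `W`, `H`, `objective_trace`, `converged`,
#'   `seed`.
#' @export
snmf_factorize <- function(Y, k, seed = 1L, max_iter = 2000L, tol = 1e-6,
                           eps = 1e-12) {
  Y <- as.matrix(Y)
  if (any(Y < 0)) stop("Y must be non-negative; use split_signs() first")
  if (all(Y == 0)) stop("Y is all zero")
  if (k < 1 || k >= min(dim(Y))) stop("k out of range: need 1 <= k < min(dim(Y))")
  set.seed(seed)
  W0 <- matrix(runif(nrow(Y) * k), nrow(Y), k)
  H0 <- matrix(runif(k * ncol(Y)), k, ncol(Y))
  fit <- .nmf_mu_cpp(Y, W0, H0, as.integer(max_iter), tol, eps)
  dimnames(fit$W) <- list(rownames(Y), NULL)
  dimnames(fit$H) <- list(NULL, colnames(Y))
  fit$seed <- seed
  class(fit) <- "snmf_fit"
  fit
}

#' Assign samples to clusters from the factorization coefficients
#'
#' Columns of `W` are scaled to unit Euclidean norm with the scale absorbed
#' into the rows of `H` (the reconstruction `W %*% H` is unchanged); each
#' sample is labeled by the argmax of its scaled `H` column. Exact ties break
#' toward the lowest cluster index; an all-zero column is labeled 0
#' ("unassigned").
#'
#' @param H coefficient matrix (k x n).
#' @param W basis matrix (2m x k).
#' @return integer vector of labels in `0..k`, named by sample.
#' @export
assign_samples <- function(H, W) {
  d <- sqrt(colSums(W^2))
  Hs <- H * d  # row-wise scaling: (diag(d) %*% H)
  labels <- apply(Hs, 2, function(col) {
    if (all(col == 0)) return(0L)
    which.max(col)  # which.max already breaks ties toward the lowest index
  })
  if (any(labels == 0L))
    .momics_log("assign_samples: %d sample(s) unassigned (all-zero column)",
                sum(labels == 0L))
  labels <- as.integer(labels)
  names(labels) <- colnames(H)
  labels
}

#' Consensus matrix over factorization restarts
#'
#' Runs `n_restarts` seeded factorizations; entry `C[i, j]` is the fraction
#' of restarts assigning samples `i` and `j` to the same (assigned) cluster.
#' Restart seeds are `base_seed + 0:(n_restarts-1)`.
#'
#' @param Y non-negative stacked matrix.
#' @param k rank.
#' @param n_restarts restarts (default 50, minimum 2).
#' @param base_seed seed of the first restart.
#' @param ... passed to [snmf_factorize()] (`max_iter`, `tol`).
#' @return list of class `snmf_consensus`: `C` (n x n), `restart_assignments`
#'   (n_restarts x n), `best_restart`, `best_fit`, `final_objectives`.
#' @export
snmf_consensus <- function(Y, k, n_restarts = 50L, base_seed = 1L, ...) {
  if (n_restarts < 2) stop("n_restarts must be >= 2")
  n <- ncol(Y)
  C <- matrix(0, n, n, dimnames = list(colnames(Y), colnames(Y)))
  assignments <- matrix(0L, n_restarts, n)
  objectives <- numeric(n_restarts)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- snmf_factorize(Y, k, seed = base_seed + r - 1L, ...)
    lab <- assign_samples(fit$H, fit$W)
    assignments[r, ] <- lab
    objectives[r] <- fit$objective_trace[length(fit$objective_trace)]
    same <- outer(lab, lab, "==") & lab > 0
    C <- C + same
    if (is.null(best) || objectives[r] < objectives[best]) {
      best <- r; best_fit <- fit
    }
  }
  C <- C / n_restarts
  diag(C) <- 1
  structure(list(C = C, restart_assignments = assignments,
                 best_restart = best, best_fit = best_fit,
                 final_objectives = objectives),
            class = "snmf_consensus")
}

#' Signed gene-cluster associations from a stacked-basis factorization
#'
#' For a basis from split-sign stacking (2m rows), the signed loading of gene
#' `g` on cluster `c` is `W[g, c] - W[g + m, c]`. A gene is associated with
#' the cluster of its largest absolute signed loading when that loading
#' dominates: `max |loading| / sum |loadings| >= tau`.
#'
#' @param W basis matrix with `2m` rows from [snmf_factorize()] on
#'   [split_signs()] output.
#' @param tau dominance threshold in (0, 1] (default 0.5).
#' @return data.frame with columns `feature`, `cluster`, `loading`, `sign`,
#'   `dominance`, `associated`.
#' @export
gene_associations <- function(W, tau = 0.5) {
  if (nrow(W) %% 2L != 0L) stop("W must have 2m rows (split-sign stacking)")
  m <- nrow(W) %/% 2L
  S <- W[seq_len(m), , drop = FALSE] - W[m + seq_len(m), , drop = FALSE]
  feats <- sub("\\+$", "", rownames(W)[seq_len(m)])
  absS <- abs(S)
  tot <- rowSums(absS)
  cl <- max.col(absS, ties.method = "first")
  mx <- absS[cbind(seq_len(m), cl)]
  dominance <- ifelse(tot > 0, mx / tot, 0)
  loading <- S[cbind(seq_len(m), cl)]
  data.frame(feature = feats, cluster = cl, loading = loading,
             sign = sign(loading), dominance = dominance,
             associated = tot > 0 & dominance >= tau,
             stringsAsFactors = FALSE)
}

#' Fit the full subtype model at a chosen rank
#'
#' Convenience wrapper: consensus over restarts, labels from the best
#' (lowest-objective) restart, and gene associations from its basis.
#'
#' @param X signed normalized matrix (features x samples).
#' @param k cluster number.
#' @param n_restarts,base_seed,tau,... see [snmf_consensus()] and
#'   [gene_associations()].
#' @return list of class `subtype_model`: `k`, `sample_labels`,
#'   `gene_associations`, `consensus`, `fit`.
#' @export
fit_subtypes <- function(X, k, n_restarts = 50L, base_seed = 1L, tau = 0.5, ...) {
  Y <- split_signs(X)
  cons <- snmf_consensus(Y, k, n_restarts = n_restarts, base_seed = base_seed, ...)
  fit <- cons$best_fit
  labels <- assign_samples(fit$H, fit$W)
  assoc <- gene_associations(fit$W, tau = tau)
  structure(list(k = k, sample_labels = labels, gene_associations = assoc,
                 consensus = cons, fit = fit),
            class = "subtype_model")
}

#' @export
print.subtype_model <- function(x, ...) {
  cat(sprintf("<subtype_model> k=%d  cluster sizes: %s  associated genes: %d\n",
              x$k, paste(table(x$sample_labels), collapse = "/"),
              sum(x$gene_associations$associated)))
  invisible(x)
}
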