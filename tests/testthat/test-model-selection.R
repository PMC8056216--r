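test_that("cophenetic coefficient: analytic, degenerate and oracle cases", {
  C <- two_block_consensus(4, 4)
  expect_equal(cophenetic_coefficient(C), 1.0)
  # constant off-diagonal -> undefined flag
  Cu <- matrix(0.5, 6, 6); diag(Cu) <- 1
  out <- cophenetic_coefficient(Cu)
  expect_true(is.na(out))
  expect_true(attr(out, "undefined"))
  expect_error(cophenetic_coefficient(two_block_consensus(1, 1)), "n >= 3")
  # seeded random symmetric consensus vs independent brute-force UPGMA
  set.seed(31)
  for (r in 1:5) {
    M <- matrix(runif(144), 12, 12)
    C2 <- (M + t(M)) / 2; diag(C2) <- 1
    expect_equal(cophenetic_coefficient(C2), oracle_cophenetic(C2),
                 tolerance = 1e-9)
  }
})

test_that("dispersion coefficient matches its closed form", {
  expect_equal(dispersion_coefficient(two_block_consensus(3, 3)), 1.0)
  Cu <- matrix(0.5, 5, 5)
  expect_equal(dispersion_coefficient(Cu), 0.0)
  C <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  expect_equal(dispersion_coefficient(C), 0.5)
})

test_that("evar/rss/residuals identities hold", {
  set.seed(32)
  W <- matrix(runif(20 * 3), 20, 3); H <- matrix(runif(3 * 8), 3, 8)
  Y <- W %*% H
  fit_exact <- list(W = W, H = H, objective_trace = 0)
  e <- evar_rss_residuals(fit_exact, Y)
  expect_equal(e$rss, 0)
  expect_equal(e$evar, 1)
  fit_zero <- list(W = W * 0, H = H * 0, objective_trace = sum(Y^2))
  expect_equal(evar_rss_residuals(fit_zero, Y)$evar, 0)
  # evar + rss/||Y||^2 = 1 on a genuine fit
  Yr <- matrix(runif(200), 20, 10)
  fit <- snmf_factorize(Yr, 3, seed = 1, max_iter = 200)
  er <- evar_rss_residuals(fit, Yr)
  expect_equal(er$evar + er$rss / sum(Yr^2), 1, tolerance = 1e-12)
  # residuals = final trace entry = rss under the Frobenius objective
  expect_equal(er$residuals, er$rss, tolerance = 1e-6 * er$rss)
})

test_that("silhouette: separated blocks, random labels, and brute-force oracle", {
  C <- two_block_consensus(5, 5)
  expect_equal(silhouette_score(C, rep(1:2, each = 5)), 1.0)
  expect_error(silhouette_score(C, rep(1, 10)), ">= 2 clusters")
  # random labels on structureless consensus: near zero
  set.seed(33)
  vals <- vapply(1:20, function(r) {
    M <- matrix(runif(900), 30, 30)
    Cs <- (M + t(M)) / 2; diag(Cs) <- 1
    silhouette_score(Cs, sample(rep(1:3, each = 10)))
  }, numeric(1))
  expect_lt(abs(mean(vals)), 0.1)
  # oracle agreement on n = 15
  for (r in 1:5) {
    M <- matrix(runif(225), 15, 15)
    Cs <- (M + t(M)) / 2; diag(Cs) <- 1
    lab <- sample(1:3, 15, replace = TRUE)
    if (length(unique(lab)) < 2) next
    expect_equal(silhouette_score(Cs, lab), oracle_silhouette(Cs, lab),
                 tolerance = 1e-9)
  }
})

test_that("Hoyer sparseness analytic values", {
  expect_equal(sparseness_hoyer(c(1, 0, 0, 0)), 1.0)
  expect_equal(sparseness_hoyer(c(1, 1, 1, 1)), 0.0)
  expect_equal(sparseness_hoyer(c(1, 1, 0, 0)), (2 - sqrt(2)) / 1,
               tolerance = 1e-9)
  expect_error(sparseness_hoyer(c(0, 0)), "zero vector")
})

test_that("randomize_matrix permutes within rows, preserving row multisets", {
  set.seed(34)
  X <- matrix(rnorm(80), 8, 10)
  Xr <- randomize_matrix(X, seed = 2)
  for (i in 1:8) expect_equal(sort(Xr[i, ]), sort(X[i, ]))
  expect_identical(randomize_matrix(X, seed = 2), Xr)
  expect_false(identical(randomize_matrix(X, seed = 3), Xr))
})

test_that("randomization destroys planted structure (cophenetic gap)", {
  wins <- vapply(1:5, function(s) {
    X <- tiny_planted_matrix(n_genes = 80, n_samples = 20, seed = 500 + s)
    real <- snmf_consensus(split_signs(X), 2, n_restarts = 10,
                           base_seed = s, max_iter = 300)
    Xr <- randomize_matrix(X, seed = s)
    rand <- snmf_consensus(split_signs(Xr), 2, n_restarts = 10,
                           base_seed = s, max_iter = 300)
    cophenetic_coefficient(real$C) > cophenetic_coefficient(rand$C)
  }, logical(1))
  expect_gte(sum(wins), 4)
})

test_that("select_k recovers a two-block design and errors usefully", {
  X <- tiny_planted_matrix(n_genes = 80, n_samples = 20, k = 2, seed = 41)
  sel <- select_k(X, k_range = 2:2, n_restarts = 8, seed = 1, max_iter = 300)
  expect_equal(sel$k_best, 2L)
  expect_s3_class(sel, "k_selection")
  expect_equal(nrow(sel$metrics), 2)
  expect_error(select_k(X, k_range = 1:2), "k_range")
})

test_that("pure-noise input yields no-k error or a negligible cophenetic gap", {
  set.seed(42)
  X <- matrix(rnorm(60 * 18), 60, 18)
  X <- (X - rowMeans(X)) / sqrt(rowMeans((X - rowMeans(X))^2))
  dimnames(X) <- list(sprintf("g%d", 1:60), sprintf("s%d", 1:18))
  out <- tryCatch(select_k(X, 2:3, n_restarts = 10, seed = 7, max_iter = 300),
                  momics_no_k_error = function(e) e)
  if (inherits(out, "momics_no_k_error")) {
    expect_s3_class(out$metrics, "data.frame")  # error carries the table
  } else {
    re <- out$metrics[out$metrics$condition == "real", ]
    ra <- out$metrics[out$metrics$condition == "randomized", ]
    expect_lt(max(re$cophenetic - ra$cophenetic), 0.2)
  }
})

test_that("metrics are invariant under simultaneous sample permutation", {
  set.seed(43)
  M <- matrix(runif(100), 10, 10)
  C <- (M + t(M)) / 2; diag(C) <- 1
  p <- sample(10)
  expect_equal(dispersion_coefficient(C), dispersion_coefficient(C[p, p]))
  expect_equal(cophenetic_coefficient(C), cophenetic_coefficient(C[p, p]),
               tolerance = 1e-12)
})

test_that("evar is non-decreasing in k as a median trend", {
  set.seed(44)
  trends <- vapply(1:10, function(s) {
    X <- tiny_planted_matrix(n_genes = 50, n_samples = 14, seed = 600 + s)
    Y <- split_signs(X)
    evars <- vapply(2:4, function(k)
      evar_rss_residuals(snmf_factorize(Y, k, seed = s, max_iter = 400), Y)$evar,
      numeric(1))
    all(diff(evars) > -1e-6)
  }, logical(1))
  expect_gte(median(as.numeric(trends)), 1)
})
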