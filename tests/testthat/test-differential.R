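panel_matrix <- function(values, samples = paste0("s", seq_len(ncol(values)))) {
  colnames(values) <- samples
  omics_matrix(values, "metabolite")
}

test_that("indicator arithmetic matches the worked ratios", {
  v <- rbind(Orn = c(2, 4), Arg = c(4, 4))
  om <- panel_matrix(v)
  defs <- list(list(name = "Orn / Arg", numerator = "Orn", denominator = "Arg"),
               list(name = "Arg/(Arg+Orn)", numerator = "Arg",
                    denominator = c("Arg", "Orn")))
  out <- compute_indicators(om, defs)
  expect_equal(unname(out$values["Orn / Arg", ]), c(0.5, 1))
  expect_equal(unname(out$values["Arg/(Arg+Orn)", 1]), 4 / 6, tolerance = 1e-12)
  # summed species ratio
  v2 <- rbind(`SM (OH) C14:1` = c(1), `SM (OH) C16:1` = c(2),
              `SM C16:0` = c(3), `SM C18:0` = c(3))
  om2 <- panel_matrix(v2, "s1")
  defs2 <- list(list(name = "Total SM-OH / Total SM-non OH",
                     numerator = c("SM (OH) C14:1", "SM (OH) C16:1"),
                     denominator = c("SM C16:0", "SM C18:0")))
  out2 <- compute_indicators(om2, defs2)
  expect_equal(unname(out2$values["Total SM-OH / Total SM-non OH", ]), 0.5)
  # unknown metabolite errors by name
  expect_error(compute_indicators(om, list(list(name = "bad", numerator = "Foo",
                                                denominator = "Arg"))),
               "Foo")
  # zero denominator becomes missing
  v3 <- rbind(A = c(1, 1), B = c(0, 2))
  out3 <- compute_indicators(panel_matrix(v3),
                             list(list(name = "A / B", numerator = "A",
                                       denominator = "B")))
  expect_true(is.na(out3$values["A / B", 1]))
  expect_equal(unname(out3$values["A / B", 2]), 0.5)
})

test_that("default indicator definitions resolve against the p180-style panel", {
  co <- generate_cohort(synthetic_config(seed = 61, n_genes = 60,
                                         signature_size = 10))
  panel <- rownames(co$layers$metabolite$values)
  defs <- default_indicator_defs(panel)
  expect_gte(length(defs), 6)
  out <- compute_indicators(co$layers$metabolite, defs)
  expect_equal(nrow(out$values), 180 + length(defs))
})

test_that("eBayes prior: degenerate and recovery cases", {
  # identical variances -> infinite d0, s0^2 = the common value
  pr <- fit_ebayes_prior(rep(2, 100), df = 8)
  expect_true(is.infinite(pr$d0))
  expect_equal(pr$s0_sq, 2, tolerance = 1e-9)
  expect_error(fit_ebayes_prior(c(rep(1, 20), -1), 4), "positive")
  # parameter recovery: s2 ~ s0^2 * chi2_d0 / d0 mixed with residual chi2_dg
  set.seed(62)
  d0 <- 4; s0 <- 2; dg <- 6
  tv <- s0 * d0 / rchisq(5000, d0)          # true variances, inverse-chi2
  s2 <- tv * rchisq(5000, dg) / dg           # observed sample variances
  fit <- fit_ebayes_prior(s2, dg)
  expect_lt(abs(fit$d0 - d0) / d0, 0.2)
  expect_lt(abs(fit$s0_sq - s0) / s0, 0.1)
})

test_that("prior recovery improves with feature count", {
  set.seed(63)
  d0 <- 4; s0 <- 2; dg <- 6
  bias <- function(m) {
    mean(replicate(20, {
      tv <- s0 * d0 / rchisq(m, d0)
      s2 <- tv * rchisq(m, dg) / dg
      abs(fit_ebayes_prior(s2, dg)$d0 - d0)
    }))
  }
  expect_lte(bias(5000), bias(200))
})

test_that("moderated t: limma agreement, pooled-t limit, and analytic cases", {
  set.seed(64)
  X <- matrix(rnorm(300 * 14), 300, 14,
              dimnames = list(paste0("f", 1:300), paste0("s", 1:14)))
  grp <- rep(c("A", "B"), each = 7)
  tab <- moderated_t_test(X, grp)
  fitl <- limma::eBayes(limma::lmFit(X, stats::model.matrix(~ factor(grp))))
  expect_equal(attr(tab, "prior")$d0, fitl$df.prior, tolerance = 1e-6)
  expect_equal(attr(tab, "prior")$s0_sq, fitl$s2.prior, tolerance = 1e-6)
  expect_equal(tab$t_moderated, unname(fitl$t[, 2]), tolerance = 1e-9)
  # p-values: with an infinite prior df we use the normal reference exactly;
  # limma caps df.total at the summed residual df (3600 here), a ~1e-4 effect
  expect_equal(tab$p_value, unname(fitl$p.value[, 2]), tolerance = 1e-3)
  if (is.finite(attr(tab, "prior")$d0))
    expect_equal(tab$p_value, unname(fitl$p.value[, 2]), tolerance = 1e-9)
  expect_equal(tab$log_fc, unname(fitl$coefficients[, 2]), tolerance = 1e-12)
  # d0 = 0 degenerates to the ordinary pooled two-sample t
  tab0 <- moderated_t_test(X, grp, prior = list(d0 = 0, s0_sq = 1))
  ordinary <- apply(X, 1, function(x)
    stats::t.test(x[8:14], x[1:7], var.equal = TRUE)$statistic)
  expect_equal(tab0$t_moderated, unname(ordinary), tolerance = 1e-9)
  # identical group means -> log_fc 0, t 0, p 1
  Xc <- matrix(rep(c(1, 2, 3, 4, 1, 2, 3, 4), 20), 20, 8, byrow = TRUE,
               dimnames = list(paste0("f", 1:20), paste0("s", 1:8)))
  Xc <- Xc + matrix(rep(rnorm(20), 8), 20, 8)  # feature offsets, same per group
  tabc <- moderated_t_test(Xc, rep(c("A", "B"), each = 4))
  expect_true(all(abs(tabc$log_fc) < 1e-12))
  expect_true(all(tabc$p_value > 1 - 1e-9))
  # d0 = Inf: t = log_fc / (s0 sqrt(1/n1 + 1/n2)) exactly
  tabi <- moderated_t_test(X, grp, prior = list(d0 = Inf, s0_sq = 4))
  expect_equal(tabi$t_moderated, tabi$log_fc / (2 * sqrt(2 / 7)), tolerance = 1e-12)
  expect_error(moderated_t_test(X[, 1:3], c("A", "A", "B")), ">= 2 samples")
})

test_that("moderated t uses available-case sizes under missingness", {
  set.seed(65)
  X <- matrix(rnorm(50 * 10), 50, 10,
              dimnames = list(paste0("f", 1:50), paste0("s", 1:10)))
  X[1, 1:2] <- NA  # feature 1: group A has 3 of 5 values
  tab <- moderated_t_test(X, rep(c("A", "B"), each = 5))
  m_a <- mean(X[1, 3:5]); m_b <- mean(X[1, 6:10])
  expect_equal(tab$log_fc[1], m_b - m_a, tolerance = 1e-12)
})

test_that("BH adjustment matches the step-up definition and p.adjust", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  set.seed(66)
  for (r in 1:10) {
    p <- runif(sample(5:50, 1))
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
    expect_equal(bh_adjust(p), p.adjust(p, "BH"), tolerance = 1e-12)
  }
  # order invariance
  p <- runif(30)
  o <- sample(30)
  expect_equal(bh_adjust(p)[o], bh_adjust(p[o]))
})

test_that("planted metabolite fold-changes are detected with sensitivity >= 0.8", {
  sens <- vapply(1:10, function(s) {
    set.seed(800 + s)
    m <- 150; n <- 40
    lfc <- numeric(m)
    planted <- 1:30
    lfc[planted] <- sample(c(-1, 1), 30, TRUE) * runif(30, 0.5, 1.7)
    grp <- rep(c("A", "B"), each = 20)
    X <- matrix(rnorm(m * n), m, n,
                dimnames = list(paste0("f", 1:m), paste0("s", 1:n)))
    X <- X + outer(lfc, as.numeric(grp == "B"))
    tab <- moderated_t_test(X, grp)
    strong <- planted[abs(lfc[planted]) >= 1]
    mean(tab$significant[strong])
  }, numeric(1))
  expect_gte(mean(sens), 0.8)
})
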