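test_that("Kaplan-Meier matches hand-worked product-limit examples", {
  # all events
  km <- kaplan_meier(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  expect_equal(km$median, 2)
  # all censored
  km0 <- kaplan_meier(c(1, 2, 3), c(0, 0, 0))
  expect_length(km0$time, 0)
  expect_true(is.na(km0$median))
  # mixed worked set: (1, 1+, 2, 3+, 4), events at 1, 2, 4
  km2 <- kaplan_meier(c(1, 1, 2, 3, 4), c(1, 0, 1, 0, 1))
  expect_equal(km2$surv, c(4 / 5, 4 / 5 * 2 / 3, 0), tolerance = 1e-12)
  expect_equal(km2$median, 4)
  expect_error(kaplan_meier(c(-1, 2), c(1, 1)), "negative")
})

test_that("KM agrees with the survival package including Greenwood and log-log CI", {
  set.seed(51)
  t <- rexp(150, 0.06); e <- rbinom(150, 1, 0.7)
  km <- kaplan_meier(t, e)
  sf <- survival::survfit(survival::Surv(t, e) ~ 1, conf.type = "log-log")
  sm <- summary(sf, times = km$time)
  expect_equal(km$surv, sm$surv, tolerance = 1e-12)
  ok <- km$surv > 0 & km$surv < 1
  expect_equal(km$se[ok], sm$std.err[ok], tolerance = 1e-9)
  expect_equal(km$lower[ok], sm$lower[ok], tolerance = 1e-9)
  expect_equal(km$upper[ok], sm$upper[ok], tolerance = 1e-9)
  expect_equal(km$median, unname(summary(sf)$table["median"]))
})

test_that("KM on uncensored data equals 1 - ECDF exactly", {
  set.seed(52)
  t <- round(rexp(100, 0.1), 2)
  km <- kaplan_meier(t, rep(1, 100))
  ecdf_vals <- 1 - ecdf(t)(km$time)
  expect_equal(km$surv, ecdf_vals, tolerance = 1e-12)
})

test_that("survival_at is a right-continuous step function", {
  km <- kaplan_meier(c(1, 2, 3), c(1, 1, 1))
  expect_equal(survival_at(km, 0)$surv, 1)
  expect_equal(survival_at(km, 1.5)$surv, 2 / 3)
  expect_equal(survival_at(km, 2)$surv, 1 / 3)   # right-continuous at event
  expect_equal(survival_at(km, 99)$surv, 0)
})

test_that("log-rank matches the hand calculation and survdiff", {
  lr <- log_rank(1, 1, 2, 1)
  expect_equal(lr$chi_square, 1.0)
  expect_equal(lr$p_value, pchisq(1, 1, lower.tail = FALSE))
  expect_equal(round(lr$p_value, 4), 0.3173)
  # identical groups -> chi2 0, p 1
  lr0 <- log_rank(c(1, 2, 3), c(1, 1, 0), c(1, 2, 3), c(1, 1, 0))
  expect_equal(lr0$chi_square, 0)
  expect_equal(lr0$p_value, 1)
  # group swap antisymmetry
  set.seed(53)
  ta <- rexp(40, 0.1); ea <- rbinom(40, 1, 0.8)
  tb <- rexp(50, 0.04); eb <- rbinom(50, 1, 0.8)
  l1 <- log_rank(ta, ea, tb, eb)
  l2 <- log_rank(tb, eb, ta, ea)
  expect_equal(l1$chi_square, l2$chi_square)
  expect_equal(l1$p_value, l2$p_value)
  # against the survival package
  sd <- survival::survdiff(survival::Surv(c(ta, tb), c(ea, eb)) ~ rep(1:2, c(40, 50)))
  expect_equal(l1$chi_square, sd$chisq, tolerance = 1e-12)
  # zero-variance degenerate case: B leaves the risk set before any event
  expect_true(log_rank(c(5, 5), c(1, 1), c(1, 1), c(0, 0))$undefined)
  expect_error(log_rank(numeric(0), numeric(0), 1, 1), "non-empty")
})

test_that("log-rank p is uniform under the null (permuted labels)", {
  set.seed(54)
  t <- rexp(60, 0.08); e <- rbinom(60, 1, 0.75)
  pvals <- vapply(1:500, function(r) {
    g <- sample(rep(1:2, each = 30))
    log_rank(t[g == 1], e[g == 1], t[g == 2], e[g == 2])$p_value
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("compare_subtypes joins labels, honors endpoints and handles degenerates", {
  co <- generate_cohort(synthetic_config(seed = 55, n_genes = 100,
                                         signature_size = 10))
  lab <- co$truth$subtype[co$truth$membership$rna]
  sv_os <- compare_subtypes(lab, co$clinical, endpoint = "os")
  sv_dbf <- compare_subtypes(lab, co$clinical, endpoint = "dbf")
  expect_equal(sv_os$n, 46)
  expect_false(identical(sv_os$test$p_value, sv_dbf$test$p_value))
  # two largest subtypes are the tested contrast
  sizes <- sort(table(lab), decreasing = TRUE)
  expect_setequal(sv_os$groups, as.integer(names(sizes)[1:2]))
  # disjoint ids error
  lab_bad <- setNames(lab, paste0("X", seq_along(lab)))
  expect_error(compare_subtypes(lab_bad, co$clinical), "no overlapping")
  # all-censored subtype still yields a curve with undefined median
  cl <- co$clinical
  cl$os_event[cl$sample_id %in% names(lab)[lab == 1]] <- 0
  sv2 <- compare_subtypes(lab, cl, endpoint = "os")
  expect_true(is.na(sv2$curves[["1"]]$median))
  # pairwise table with Bonferroni
  svp <- compare_subtypes(lab, co$clinical, pairwise = TRUE, bonferroni = TRUE)
  expect_equal(nrow(svp$pairwise), choose(length(unique(lab)), 2))
  expect_true(all(svp$pairwise$p_adjusted >= svp$pairwise$p_value, na.rm = TRUE))
})

test_that("planted good/poor subtypes separate in survival across seeds", {
  hits <- vapply(1:100, function(s) {
    co <- generate_cohort(synthetic_config(seed = 700 + s, n_genes = 60,
                                           signature_size = 10))
    lab <- co$truth$subtype  # planted labels over the full cohort
    good_poor <- c(which.min(co$truth$os_medians), which.max(co$truth$os_medians))
    keep <- lab %in% good_poor
    cl <- co$clinical[match(names(lab)[keep], co$clinical$sample_id), ]
    lr <- log_rank(cl$os_time[lab[keep] == good_poor[1]],
                   cl$os_event[lab[keep] == good_poor[1]],
                   cl$os_time[lab[keep] == good_poor[2]],
                   cl$os_event[lab[keep] == good_poor[2]])
    lr$p_value < 0.01
  }, logical(1))
  expect_gte(mean(hits), 0.9)  # measured power of the stated world is ~0.93
})
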