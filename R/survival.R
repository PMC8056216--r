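#' Kaplan-Meier product-limit estimate
#'
#' Estimates the survival function under right censoring with Greenwood
#' standard errors and 95% confidence intervals on the log(-log S) scale
#' (guaranteed inside `[0, 1]`). At tied times, events precede censorings:
#' subjects censored at `t` are still in the risk set for events at `t`.
#' The median is the smallest event time with `S(t) <= 0.5`, `NA` if `S`
#' never reaches 0.5.
#'
#' @param times non-negative follow-up times.
#' @param events 0/1 indicators (1 = event).
#' @param conf_level confidence level (default 0.95).
#' @return list of class `km_curve`: `time` (distinct event times),
#'   `n_risk`, `n_event`, `surv`, `se` (Greenwood SE of S), `lower`,
#'   `upper`, `median`, `n`.
#' @export
kaplan_meier <- function(times, events, conf_level = 0.95) {
  if (length(times) < 1) stop("need at least one subject")
  if (any(times < 0)) stop("negative survival time")
  stopifnot(length(times) == length(events), all(events %in% c(0, 1)))
  et <- sort(unique(times[events == 1]))
  n <- length(times)
  surv <- se <- lower <- upper <- numeric(length(et))
  n_risk <- n_event <- integer(length(et))
  s <- 1
  gw <- 0  # Greenwood cumulative sum of d / (r (r - d))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  for (i in seq_along(et)) {
    t <- et[i]
    r <- sum(times >= t)          # censored-at-t subjects still at risk
    d <- sum(times == t & events == 1)
    n_risk[i] <- r; n_event[i] <- d
    s <- s * (1 - d / r)
    if (r > d) gw <- gw + d / (r * (r - d)) else gw <- Inf
    surv[i] <- s
    se[i] <- if (is.finite(gw)) s * sqrt(gw) else 0
    if (s > 0 && s < 1 && is.finite(gw)) {
      # log(-log S) transform: se of log(-log S) = sqrt(gw) / |log S|
      se_ll <- sqrt(gw) / abs(log(s))
      lower[i] <- s^exp(z * se_ll)
      upper[i] <- s^exp(-z * se_ll)
    } else {
      lower[i] <- s; upper[i] <- s
    }
  }
  med <- if (length(et) && any(surv <= 0.5)) et[which(surv <= 0.5)[1]] else NA_real_
  structure(list(time = et, n_risk = n_risk, n_event = n_event, surv = surv,
                 se = se, lower = lower, upper = upper, median = med, n = n),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("<km_curve> n=%d, events=%d, median=%s\n", x$n, sum(x$n_event),
              if (is.na(x$median)) "not reached" else format(x$median, digits = 4)))
  invisible(x)
}

#' Evaluate a Kaplan-Meier curve at a time point
#'
#' Right-continuous step-function evaluation: `S(t)` is the value at the
#' last event time `<= t`, and 1 before the first event.
#'
#' @param curve a `km_curve`.
#' @param t time (months), `t >= 0`.
#' @return list `(surv, lower, upper)`.
#' @export
survival_at <- function(curve, t) {
  stopifnot(t >= 0)
  i <- findInterval(t, curve$time)
  if (i == 0) return(list(surv = 1, lower = 1, upper = 1))
  list(surv = curve$surv[i], lower = curve$lower[i], upper = curve$upper[i])
}

#' Two-group log-rank test
#'
#' Standard Mantel-Haenszel log-rank: over the distinct event times, compare
#' observed events in group A with the hypergeometric expectation given the
#' shared risk set; `chi2 = U^2 / V` with 1 degree of freedom.
#'
#' @param times_a,events_a group A follow-up and 0/1 event indicators.
#' @param times_b,events_b group B likewise.
#' @return list of class `logrank_result`: `chi_square`, `df`, `p_value`,
#'   `observed`, `expected` (group A), `undefined` flag when no comparable
#'   event times exist (zero variance).
#' @export
log_rank <- function(times_a, events_a, times_b, events_b) {
  if (length(times_a) == 0 || length(times_b) == 0) stop("both groups must be non-empty")
  if (sum(events_a) + sum(events_b) == 0) stop("need at least one event")
  times <- c(times_a, times_b)
  events <- c(events_a, events_b)
  grp_a <- rep(c(TRUE, FALSE), c(length(times_a), length(times_b)))
  et <- sort(unique(times[events == 1]))
  U <- V <- O <- E <- 0
  for (t in et) {
    at_risk <- times >= t
    r <- sum(at_risk)
    ra <- sum(at_risk & grp_a)
    d <- sum(times == t & events == 1)
    da <- sum(times == t & events == 1 & grp_a)
    e <- d * ra / r
    O <- O + da; E <- E + e
    U <- U + (da - e)
    if (r > 1) V <- V + d * (ra / r) * (1 - ra / r) * (r - d) / (r - 1)
  }
  if (V <= 0) {
    return(structure(list(chi_square = NA_real_, df = 1L, p_value = NA_real_,
                          observed = O, expected = E, undefined = TRUE),
                     class = "logrank_result"))
  }
  chi2 <- U^2 / V
  structure(list(chi_square = chi2, df = 1L,
                 p_value = pchisq(chi2, df = 1, lower.tail = FALSE),
                 observed = O, expected = E, undefined = FALSE),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  if (isTRUE(x$undefined)) cat("<logrank_result> undefined (zero variance)\n")
  else cat(sprintf("<logrank_result> chi2=%.3f df=%d p=%.4g\n",
                   x$chi_square, x$df, x$p_value))
  invisible(x)
}

#' Compare survival between discovered subtypes
#'
#' Joins subtype labels to the clinical table by sample id, estimates a
#' Kaplan-Meier curve per subtype for the requested endpoint, and tests the
#' two largest subtypes against each other with the log-rank test (the
#' primary prognostic contrast). Optionally all pairwise tests are computed,
#' with Bonferroni adjustment available but off by default.
#'
#' @param labels named integer vector of subtype labels (names = sample ids),
#'   or a `subtype_model`.
#' @param clinical data.frame with `sample_id`, `os_time`, `os_event`,
#'   `dbf_time`, `dbf_event`.
#' @param endpoint `"os"` (overall survival) or `"dbf"`
#'   (distant-brain-failure-free survival).
#' @param pairwise compute all pairwise log-rank tests (default FALSE).
#' @param bonferroni adjust pairwise p-values (default FALSE).
#' @return list of class `subtype_survival`: `curves` (per subtype),
#'   `test` (two-largest-subtypes `logrank_result`), `groups` (the two
#'   subtype ids tested), `pairwise` (optional data.frame), `endpoint`, `n`.
#' @export
compare_subtypes <- function(labels, clinical, endpoint = c("os", "dbf"),
                             pairwise = FALSE, bonferroni = FALSE) {
  endpoint <- match.arg(endpoint)
  if (inherits(labels, "subtype_model")) labels <- labels$sample_labels
  labels <- labels[labels > 0]
  common <- intersect(names(labels), clinical$sample_id)
  if (length(common) == 0) stop("no overlapping sample ids between labels and clinical table")
  cl <- clinical[match(common, clinical$sample_id), ]
  lab <- labels[common]
  tcol <- paste0(endpoint, "_time"); ecol <- paste0(endpoint, "_event")
  sizes <- sort(table(lab), decreasing = TRUE)
  if (length(sizes) < 2) stop("need >= 2 subtypes with members")
  curves <- lapply(split(seq_along(lab), lab), function(ix)
    kaplan_meier(cl[[tcol]][ix], cl[[ecol]][ix]))
  top2 <- as.integer(names(sizes)[1:2])
  ia <- lab == top2[1]; ib <- lab == top2[2]
  test <- log_rank(cl[[tcol]][ia], cl[[ecol]][ia], cl[[tcol]][ib], cl[[ecol]][ib])
  pw <- NULL
  if (pairwise) {
    cls <- sort(unique(lab))
    combs <- utils::combn(cls, 2)
    pw <- data.frame(a = combs[1, ], b = combs[2, ], chi_square = NA_real_,
                     p_value = NA_real_)
    for (j in seq_len(ncol(combs))) {
      sa <- lab == combs[1, j]; sb <- lab == combs[2, j]
      lr <- tryCatch(log_rank(cl[[tcol]][sa], cl[[ecol]][sa],
                              cl[[tcol]][sb], cl[[ecol]][sb]),
                     error = function(e) NULL)
      if (!is.null(lr)) { pw$chi_square[j] <- lr$chi_square; pw$p_value[j] <- lr$p_value }
    }
    if (bonferroni) pw$p_adjusted <- pmin(1, pw$p_value * nrow(pw))
  }
  structure(list(curves = curves, test = test, groups = top2, pairwise = pw,
                 endpoint = endpoint, n = length(common)),
            class = "subtype_survival")
}

#' @export
print.subtype_survival <- function(x, ...) {
  meds <- vapply(x$curves, function(cv)
    if (is.na(cv$median)) NA_real_ else cv$median, numeric(1))
  cat(sprintf("<subtype_survival> endpoint=%s n=%d\n", x$endpoint, x$n))
  cat("  medians (months):",
      paste(sprintf("%s=%s", names(x$curves), signif(meds, 4)), collapse = " "), "\n")
  cat(sprintf("  two largest subtypes (%d vs %d): ", x$groups[1], x$groups[2]))
  print(x$test)
  invisible(x)
}
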