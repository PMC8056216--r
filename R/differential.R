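#' Append custom metabolite ratio indicators to a panel
#'
#' A metabolite indicator is a ratio of concentration sums, e.g. `Orn / Arg`
#' or `Arg / (Arg + Orn)`, computed per sample on the raw (pre-log)
#' concentrations and appended to the panel as a new feature. Samples whose
#' denominator sum is zero get a missing (undetected) value.
#'
#' @param metabolites an [omics_matrix()] of raw concentrations.
#' @param defs list of indicator definitions, each a list with `name`,
#'   `numerator` (character vector of metabolite names, summed) and
#'   `denominator` (likewise).
#' @return an [omics_matrix()] with the indicator rows appended.
#' @export
compute_indicators <- function(metabolites, defs) {
  stopifnot(inherits(metabolites, "omics_matrix"))
  v <- metabolites$values
  rows <- matrix(NA_real_, length(defs), ncol(v),
                 dimnames = list(vapply(defs, `[[`, "", "name"), colnames(v)))
  for (i in seq_along(defs)) {
    d <- defs[[i]]
    if (is.null(d$name) || length(d$numerator) == 0 || length(d$denominator) == 0)
      stop("indicator definitions need a name and non-empty numerator/denominator")
    missing_feats <- setdiff(c(d$numerator, d$denominator), rownames(v))
    if (length(missing_feats))
      stop(sprintf("indicator '%s' references unknown metabolite(s): %s",
                   d$name, paste(missing_feats, collapse = ", ")))
    num <- colSums(v[d$numerator, , drop = FALSE], na.rm = TRUE)
    den <- colSums(v[d$denominator, , drop = FALSE], na.rm = TRUE)
    bad <- !is.finite(den) | den == 0
    if (any(bad))
      .momics_log("indicator '%s': zero denominator in %d sample(s)", d$name, sum(bad))
    rows[i, ] <- ifelse(bad, NA_real_, num / den)
  }
  if (anyDuplicated(c(rownames(v), rownames(rows))))
    stop("indicator names collide with existing features")
  out <- rbind(v, rows)
  omics_matrix(out, metabolites$layer)
}

#' Default custom metabolite indicator definitions
#'
#' The ratio indicators used by the differential metabolite analysis:
#' ornithine/arginine metabolism (`Orn / Arg`, `Arg/(Arg+Orn)`, `Orn / Ser`),
#' sphingomyelin hydroxylation (`Total SM-OH / Total SM-non OH`),
#' lysophosphatidylcholine ratios, and branched-chain amino acid /
#' acylcarnitine ratios. Species lists for the SM totals are resolved
#' against the supplied panel by name prefix.
#'
#' @param panel character vector of available metabolite names.
#' @return list of indicator definitions for [compute_indicators()].
#' @export
default_indicator_defs <- function(panel) {
  sm_oh <- grep("^SM \\(OH\\)", panel, value = TRUE)
  sm_non <- grep("^SM C", panel, value = TRUE)
  defs <- list(
    list(name = "Orn / Arg", numerator = "Orn", denominator = "Arg"),
    list(name = "Arg/(Arg+Orn)", numerator = "Arg", denominator = c("Arg", "Orn")),
    list(name = "Total SM-OH / Total SM-non OH", numerator = sm_oh, denominator = sm_non),
    list(name = "lysoPC a C20:4 / lysoPC a C20:3",
         numerator = "lysoPC a C20:4", denominator = "lysoPC a C20:3"),
    list(name = "Val / C5", numerator = "Val", denominator = "C5"),
    list(name = "Orn / Ser", numerator = "Orn", denominator = "Ser"),
    list(name = "C3 / C4", numerator = "C3", denominator = "C4"))
  keep <- vapply(defs, function(d)
    all(c(d$numerator, d$denominator) %in% panel) &&
      length(d$numerator) > 0 && length(d$denominator) > 0, logical(1))
  defs[keep]
}

#' Estimate the empirical-Bayes variance prior
#'
#' Models per-feature sample variances as `s_g^2 ~ s0^2 * chi^2_{d_g} / d_g`
#' scaled by a feature-shared prior `s0^2` with prior degrees of freedom
#' `d0`. Following the standard moment-matching on the log scale, with
#' `e_g = log(s_g^2) - digamma(d_g/2) + log(d_g/2)`:
#' `var(e) - mean(trigamma(d_g/2))` estimates `trigamma(d0/2)`, solved for
#' `d0` by Newton iteration; the mean equation then gives `s0^2`. When the
#' empirical spread of `log s^2` does not exceed its sampling floor, `d0` is
#' infinite and `s0^2 = mean(s^2)` (all true variances coincide).
#'
#' @param s2 per-feature sample variances (positive).
#' @param df residual degrees of freedom, scalar or per feature.
#' @return list of class `ebayes_prior`: `d0` (possibly `Inf`), `s0_sq`.
#' @export
fit_ebayes_prior <- function(s2, df) {
  if (length(s2) < 10) stop("need >= 10 features to estimate the prior")
  if (any(!is.finite(s2) | s2 <= 0)) stop("variances must be positive and finite")
  df <- rep_len(df, length(s2))
  if (any(df < 1)) stop("residual df must be >= 1")
  e <- log(s2) - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- var(e) - mean(trigamma(df / 2))
  if (!is.finite(evar) || evar <= 0) {
    # no excess spread beyond the sampling floor: all true variances equal,
    # for which the mean of the (unbiased) sample variances estimates s0^2
    prior <- list(d0 = Inf, s0_sq = mean(s2))
  } else {
    d0 <- 2 * trigamma_inverse(evar)
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
    prior <- list(d0 = d0, s0_sq = s0_sq)
  }
  class(prior) <- "ebayes_prior"
  prior
}

# Newton solve of trigamma(y) = x for y > 0 (monotone decreasing, convex).
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif) / y < 1e-8) break
  }
  y
}

#' Empirical-Bayes moderated two-group t-test
#'
#' For each feature: `log_fc` is the group-2-minus-group-1 mean difference,
#' the pooled variance `s_g^2` (df `n1 + n2 - 2`) is shrunk toward the prior
#' as `s_tilde^2 = (d0 s0^2 + d_g s_g^2) / (d0 + d_g)`, and
#' `t = log_fc / (s_tilde * sqrt(1/n1 + 1/n2))` is referred to a t
#' distribution with `d0 + d_g` degrees of freedom (normal when `d0` is
#' infinite). Missing values use available-case sample sizes per feature.
#' P-values are two-sided; FDR is Benjamini-Hochberg.
#'
#' @param X numeric matrix on the log scale (features x samples), e.g. a
#'   `normalized_matrix` or a log2 abundance matrix.
#' @param groups two-level factor/vector over columns; `log_fc` is level 2
#'   minus level 1 (levels in sort order for non-factors).
#' @param prior optional `ebayes_prior`; estimated from the data when `NULL`.
#'   `d0 = 0` reproduces the ordinary pooled t-test.
#' @param fdr_threshold significance cut on the FDR (default 0.05).
#' @return data.frame of class `differential_table`: `feature`, `log_fc`,
#'   `t_moderated`, `p_value`, `fdr`, `significant`; prior in
#'   `attr(, "prior")`.
#' @export
moderated_t_test <- function(X, groups, prior = NULL, fdr_threshold = 0.05) {
  X <- as.matrix(unclass(X))
  groups <- factor(groups)
  if (nlevels(groups) != 2) stop("groups must have exactly two levels")
  g1 <- groups == levels(groups)[1]
  g2 <- groups == levels(groups)[2]
  if (sum(g1) < 2 || sum(g2) < 2) stop("each group needs >= 2 samples")
  n1 <- rowSums(!is.na(X[, g1, drop = FALSE]))
  n2 <- rowSums(!is.na(X[, g2, drop = FALSE]))
  ok <- n1 >= 2 & n2 >= 2
  m1 <- rowMeans(X[, g1, drop = FALSE], na.rm = TRUE)
  m2 <- rowMeans(X[, g2, drop = FALSE], na.rm = TRUE)
  ss1 <- rowSums((X[, g1, drop = FALSE] - m1)^2, na.rm = TRUE)
  ss2 <- rowSums((X[, g2, drop = FALSE] - m2)^2, na.rm = TRUE)
  dg <- n1 + n2 - 2
  s2 <- ifelse(ok & dg > 0, (ss1 + ss2) / pmax(dg, 1), NA_real_)
  if (is.null(prior)) {
    use <- ok & is.finite(s2) & s2 > 0
    prior <- fit_ebayes_prior(s2[use], dg[use])
  }
  d0 <- prior$d0; s0 <- prior$s0_sq
  s_tilde2 <- if (is.infinite(d0)) rep(s0, length(s2))
              else (d0 * s0 + dg * s2) / (d0 + dg)
  log_fc <- m2 - m1
  se <- sqrt(s_tilde2 * (1 / n1 + 1 / n2))
  t_mod <- ifelse(ok & se > 0, log_fc / se, NA_real_)
  df_total <- d0 + dg
  p <- 2 * pt(-abs(t_mod), df = df_total)  # pt with df = Inf is the normal
  fdr <- rep(NA_real_, length(p))
  fdr[!is.na(p)] <- bh_adjust(p[!is.na(p)])
  out <- data.frame(feature = rownames(X), log_fc = log_fc, t_moderated = t_mod,
                    p_value = p, fdr = fdr,
                    significant = !is.na(fdr) & fdr <= fdr_threshold,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "prior") <- prior
  class(out) <- c("differential_table", class(out))
  out
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' `fdr_(i) = min_{j >= i} p_(j) * m / j`, capped at 1, mapped back to the
#' input order.
#'
#' @param p p-values in `[0, 1]`.
#' @return adjusted values (same length and order).
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}
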