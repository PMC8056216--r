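#' Feature-by-sample abundance matrix for one omics layer
#'
#' Container for a raw abundance layer: RNA-seq FPKM-UQ values, LC-MS/MS
#' protein intensities, or targeted metabolite concentrations. Rows are
#' features, columns are samples. A logical `detected` mask marks cells with a
#' measurable signal; a value is considered detected when it is finite,
#' non-missing and strictly positive (FPKM-UQ and MS intensities encode
#' non-detection as 0 or NA).
#'
#' @param values numeric matrix with feature ids as rownames and sample ids as
#'   colnames; non-negative, NA allowed (treated as undetected).
#' @param layer one of `"rna"`, `"protein"`, `"metabolite"`.
#' @param detected optional logical matrix congruent with `values`; defaults
#'   to `is.finite(values) & values > 0`.
#' @return an object of class `omics_matrix`.
#' @export
omics_matrix <- function(values, layer = c("rna", "protein", "metabolite"),
                         detected = NULL) {
  layer <- match.arg(layer)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have feature ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (any(is.infinite(values)))
    stop("non-finite abundance values are not allowed")
  if (any(values < 0, na.rm = TRUE))
    stop("abundances must be non-negative")
  if (is.null(detected)) {
    detected <- is.finite(values) & values > 0
  } else {
    if (!is.logical(detected) || !identical(dim(detected), dim(values)))
      stop("`detected` must be a logical matrix congruent with `values`")
    bad <- detected & !(is.finite(values) & values > 0)
    if (any(bad)) detected[bad] <- FALSE
  }
  structure(list(values = values, layer = layer, detected = detected),
            class = "omics_matrix")
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("<omics_matrix> layer=%s  %d features x %d samples  (%.1f%% detected)\n",
              x$layer, nrow(x$values), ncol(x$values), 100 * mean(x$detected)))
  invisible(x)
}

#' @export
dim.omics_matrix <- function(x) dim(x$values)

feature_ids <- function(x) rownames(x$values)
sample_ids <- function(x) colnames(x$values)

#' Drop features undetected in more than half the samples
#'
#' Low-abundance features inflate zero counts and destabilize the
#' factorization, so any feature whose undetected-sample count exceeds `n/2`
#' is removed. The boundary is strict: a feature undetected in exactly half
#' of the samples survives. Feature order is preserved.
#'
#' @param x an [omics_matrix()].
#' @return the filtered `omics_matrix`.
#' @export
filter_low_detected <- function(x) {
  stopifnot(inherits(x, "omics_matrix"))
  n <- ncol(x$values)
  if (n == 0L || nrow(x$values) == 0L) stop("empty matrix")
  undet <- rowSums(!x$detected)
  keep <- undet <= n / 2
  if (!any(keep))
    stop("all features were removed by the low-detection filter")
  .momics_log("filter_low_detected: %d -> %d features (%s layer)",
              nrow(x$values), sum(keep), x$layer)
  omics_matrix(x$values[keep, , drop = FALSE], x$layer,
               x$detected[keep, , drop = FALSE])
}

#' Log-transform, center and RMS-scale each feature
#'
#' Each feature row is transformed to `log(value + pseudocount)`, centered by
#' its mean across samples, and divided by its root mean square (population
#' convention, divisor `n`). After this, every surviving row has mean 0 and
#' RMS 1. Rows that are constant after the log transform carry no contrast and
#' are dropped with a warning rather than divided by zero.
#'
#' Undetected cells are treated as abundance 0 before the transform, so the
#' pseudocount sets their position on the log scale. The default pseudocount
#' is 1 for RNA (FPKM-UQ) and half the smallest positive value in the layer
#' for protein/metabolite intensities, whose scales are arbitrary.
#'
#' @param x an [omics_matrix()], normally already filtered.
#' @param log_base base of the logarithm (default 2).
#' @param pseudocount value added before the log; `NULL` picks the layer
#'   default described above.
#' @return a numeric matrix of class `normalized_matrix` with a `provenance`
#'   attribute recording the parameters applied.
#' @export
normalize_omics <- function(x, log_base = 2, pseudocount = NULL) {
  stopifnot(inherits(x, "omics_matrix"))
  v <- x$values
  v[!x$detected | is.na(v)] <- 0
  if (any(!is.finite(v))) {
    idx <- which(!is.finite(v), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite value at feature '%s', sample '%s'",
                 rownames(v)[idx[1]], colnames(v)[idx[2]]))
  }
  if (is.null(pseudocount)) {
    pseudocount <- if (x$layer == "rna") 1 else {
      pos <- v[v > 0]
      if (length(pos) == 0) 1 else min(pos) / 2
    }
  }
  lv <- log(v + pseudocount, base = log_base)
  centered <- lv - rowMeans(lv)
  rms <- sqrt(rowMeans(centered^2))
  const <- rms < 1e-12
  if (any(const)) {
    warning(sprintf("dropping %d constant feature(s): %s", sum(const),
                    paste(head(rownames(v)[const], 5), collapse = ", ")),
            call. = FALSE)
    centered <- centered[!const, , drop = FALSE]
    rms <- rms[!const]
  }
  if (nrow(centered) == 0L) stop("no non-constant features left to normalize")
  out <- centered / rms
  structure(out,
            class = c("normalized_matrix", "matrix", "array"),
            provenance = list(layer = x$layer, log_base = log_base,
                              pseudocount = pseudocount,
                              n_dropped_constant = sum(const)))
}
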