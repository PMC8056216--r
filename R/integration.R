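#' Transfer subtype labels to another omics cohort
#'
#' Restricts fitted transcriptomic subtype labels to the samples also present
#' in a target layer (e.g. the proteomics cohort), so survival and
#' differential analyses can be repeated there.
#'
#' @param model a `subtype_model` or named label vector.
#' @param target_samples character vector of target-layer sample ids.
#' @return named integer labels on the intersection, with attributes
#'   `n_retained` and `n_dropped`.
#' @export
transfer_labels <- function(model, target_samples) {
  labels <- if (inherits(model, "subtype_model")) model$sample_labels else model
  common <- intersect(names(labels), target_samples)
  if (length(common) == 0) stop("no samples shared between the model and the target cohort")
  out <- labels[common]
  attr(out, "n_retained") <- length(common)
  attr(out, "n_dropped") <- length(labels) - length(common)
  .momics_log("transfer_labels: retained %d, dropped %d",
              length(common), length(labels) - length(common))
  out
}

#' One-sided hypergeometric enrichment of a feature set in a pathway
#'
#' Upper-tail probability of observing at least the achieved overlap between
#' the selected features and the pathway members, drawing `|selected|`
#' features without replacement from a universe of `universe_size`. The
#' pathway score is `-log10(p)`.
#'
#' @param selected character vector (or count-free set) of selected features.
#' @param pathway character vector of pathway members (subset of universe).
#' @param universe_size total features tested.
#' @return list `(overlap, p, score)`.
#' @export
enrich_hypergeometric <- function(selected, pathway, universe_size) {
  selected <- unique(selected); pathway <- unique(pathway)
  if (length(pathway) > universe_size || length(selected) > universe_size)
    stop("pathway and selected sets must fit inside the universe")
  q <- length(intersect(selected, pathway))
  p <- phyper(q - 1, length(pathway), universe_size - length(pathway),
              length(selected), lower.tail = FALSE)
  p <- min(max(p, 0), 1)
  list(overlap = q, p = p, score = -log10(p))
}

#' Sum per-layer pathway scores into the overall score
#'
#' The overall pathway score is the arithmetic sum of the transcriptomic and
#' proteomic `-log10(p)` scores.
#'
#' @param score_rna,score_prot non-negative numeric vectors.
#' @return elementwise sums.
#' @export
combine_scores <- function(score_rna, score_prot) {
  if (any(score_rna < 0) || any(score_prot < 0)) stop("scores must be >= 0")
  score_rna + score_prot
}

#' Two-layer pathway enrichment table
#'
#' Scores every gene set against the transcriptomic selection (genes
#' associated with a subtype) and the proteomic selection (proteins
#' significant in the differential analysis), and sums the two `-log10(p)`
#' scores into an overall score, sorted descending.
#'
#' @param gene_sets named list of member vectors (see [read_gmt()]).
#' @param selected_rna,selected_prot selected feature sets per layer.
#' @param universe_rna,universe_prot universe sizes per layer.
#' @param categories optional named character vector of pathway categories.
#' @return data.frame: `pathway`, `score_rna`, `score_prot`, `overall`,
#'   `category`, sorted by `overall` descending.
#' @export
pathway_scores <- function(gene_sets, selected_rna, selected_prot,
                           universe_rna, universe_prot, categories = NULL) {
  rows <- lapply(names(gene_sets), function(nm) {
    gs <- gene_sets[[nm]]
    er <- enrich_hypergeometric(selected_rna, gs, universe_rna)
    ep <- enrich_hypergeometric(selected_prot, gs, universe_prot)
    data.frame(pathway = nm, score_rna = er$score, score_prot = ep$score,
               overall = combine_scores(er$score, ep$score),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$category <- if (is.null(categories)) NA_character_
                  else unname(categories[out$pathway])
  out[order(-out$overall), , drop = FALSE]
}

#' Multi-layer cohort overlap accounting
#'
#' Computes, from per-layer sample-id sets, the union size, the pairwise
#' intersection sum, the triple overlap and the number of samples in at
#' least two layers — both by direct counting and by inclusion-exclusion,
#' verifying that the two routes agree.
#'
#' @param memberships named list of >= 2 character vectors of sample ids.
#' @return list of class `overlap_summary`: `set_sizes`, `union_size`,
#'   `pairwise_sum`, `triple_count` (3-set case, else NA),
#'   `at_least_two_count`.
#' @export
overlap_summary <- function(memberships) {
  if (length(memberships) < 2) stop("need at least two membership sets")
  memberships <- lapply(memberships, unique)
  all_ids <- unique(unlist(memberships))
  counts <- rowSums(vapply(memberships, function(s) all_ids %in% s,
                           logical(length(all_ids))))
  sizes <- vapply(memberships, length, 1L)
  pairs <- utils::combn(length(memberships), 2)
  pairwise_sum <- sum(vapply(seq_len(ncol(pairs)), function(j)
    length(intersect(memberships[[pairs[1, j]]], memberships[[pairs[2, j]]])), 1L))
  triple <- if (length(memberships) == 3)
    length(Reduce(intersect, memberships)) else NA_integer_
  at_least_two <- sum(counts >= 2)
  if (length(memberships) == 3) {
    # inclusion-exclusion cross-checks
    stopifnot(length(all_ids) == sum(sizes) - pairwise_sum + triple,
              at_least_two == pairwise_sum - 2L * triple)
  }
  structure(list(set_sizes = sizes, union_size = length(all_ids),
                 pairwise_sum = pairwise_sum, triple_count = triple,
                 at_least_two_count = at_least_two),
            class = "overlap_summary")
}

#' @export
print.overlap_summary <- function(x, ...) {
  cat(sprintf("<overlap_summary> sizes: %s | union %d | >=2 layers %d | all three %s\n",
              paste(x$set_sizes, collapse = "/"), x$union_size,
              x$at_least_two_count, x$triple_count))
  invisible(x)
}

#' Integer percentage of a cohort
#'
#' `round(100 * count / total)` with halves rounded away from zero (the
#' convention of clinical characteristics tables), e.g. 37 of 78 is 47%.
#'
#' @param count numerator, `0 <= count <= total`.
#' @param total denominator, `> 0`.
#' @return integer percentage.
#' @export
percent_of_cohort <- function(count, total) {
  if (any(total <= 0)) stop("total must be positive")
  if (any(count < 0 | count > total)) stop("count must be in [0, total]")
  as.integer(floor(100 * count / total + 0.5))
}

#' Read a GMT gene-set file
#'
#' Standard tab-separated format: set name, description, then member ids.
#'
#' @param path file path.
#' @return named list of member character vectors; descriptions in
#'   `attr(, "description")`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(fields, length, 1L) < 3
  if (any(bad)) stop(sprintf("malformed GMT line %d: need name, description, >= 1 member",
                             which(bad)[1]))
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(names(sets))) stop("duplicate gene-set names in GMT")
  attr(sets, "description") <- vapply(fields, `[[`, "", 2L)
  sets
}

#' Write a GMT gene-set file
#' @param sets named list of member vectors.
#' @param path output path.
#' @param descriptions optional character vector (defaults to set names).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- names(sets)
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}
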