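#' Read an omics matrix from TSV
#'
#' Dialect: header row of sample ids, first column feature ids, tab
#' separated. Cells must parse as numbers; empty or `NA` cells become
#' undetected. Ragged rows, duplicate ids and non-numeric cells are rejected
#' with the offending line.
#'
#' @param path TSV file.
#' @param layer layer tag (`rna`, `protein`, `metabolite`).
#' @return an [omics_matrix()].
#' @export
read_omics_matrix <- function(path, layer = "rna") {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2) stop("matrix file needs a header and >= 1 feature row")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- length(fields[[1]])
  ragged <- which(vapply(fields, length, 1L) != ncols)
  if (length(ragged))
    stop(sprintf("ragged row at line %d of %s", ragged[1], path))
  samples <- fields[[1]][-1]
  feats <- vapply(fields[-1], `[[`, "", 1L)
  if (anyDuplicated(feats))
    stop("duplicate feature id: ", feats[duplicated(feats)][1])
  if (anyDuplicated(samples))
    stop("duplicate sample id: ", samples[duplicated(samples)][1])
  vals <- matrix(NA_real_, length(feats), length(samples),
                 dimnames = list(feats, samples))
  for (i in seq_along(feats)) {
    cells <- fields[[i + 1]][-1]
    empty <- cells == "" | toupper(cells) == "NA"
    num <- suppressWarnings(as.numeric(cells))
    bad <- !empty & is.na(num)
    if (any(bad))
      stop(sprintf("non-numeric cell '%s' at line %d of %s",
                   cells[bad][1], i + 1, path))
    vals[i, ] <- num
  }
  omics_matrix(vals, layer)
}

#' Write an omics matrix (or plain matrix) as TSV
#' @param x [omics_matrix()] or numeric matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_omics_matrix <- function(x, path) {
  v <- if (inherits(x, "omics_matrix")) x$values else as.matrix(unclass(x))
  header <- paste(c("feature_id", colnames(v)), collapse = "\t")
  body <- vapply(seq_len(nrow(v)), function(i)
    paste(c(rownames(v)[i],
            ifelse(is.na(v[i, ]), "NA", format(v[i, ], digits = 15, trim = TRUE,
                                               scientific = FALSE))),
          collapse = "\t"), "")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a clinical table CSV
#'
#' Expected columns: `sample_id`, `os_time`, `os_event`, `dbf_time`,
#' `dbf_event`, `primary_site` (extra columns are kept).
#'
#' @param path CSV file.
#' @return data.frame.
#' @export
read_clinical <- function(path) {
  cl <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "os_time", "os_event", "dbf_time", "dbf_event")
  miss <- setdiff(need, names(cl))
  if (length(miss)) stop("clinical table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(cl$sample_id)) stop("duplicate sample ids in clinical table")
  if (any(cl$os_time < 0 | cl$dbf_time < 0, na.rm = TRUE)) stop("negative times")
  if (!all(unlist(cl[c("os_event", "dbf_event")]) %in% c(0, 1)))
    stop("event indicators must be 0/1")
  cl
}

#' Write a synthetic cohort to disk
#'
#' Layer matrices as TSV, the clinical table as CSV, and the planted truth
#' as JSON, under `dir`.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return named vector of written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(rna = file.path(dir, "rna.tsv"),
             protein = file.path(dir, "protein.tsv"),
             metabolite = file.path(dir, "metabolite.tsv"),
             clinical = file.path(dir, "clinical.csv"),
             truth = file.path(dir, "truth.json"))
  for (ly in names(cohort$layers)) write_omics_matrix(cohort$layers[[ly]], paths[[ly]])
  utils::write.csv(cohort$clinical, paths[["clinical"]], row.names = FALSE)
  truth <- cohort$truth
  truth$subtype <- as.list(truth$subtype)
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

read_config_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required to read YAML configs; use JSON instead")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}
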