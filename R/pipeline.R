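#' Assemble a pipeline configuration
#'
#' Validates paths and fills defaults for the end-to-end driver. Input is
#' either a synthetic-generation request (`simulate = TRUE`, with optional
#' overrides of [synthetic_config()] fields) or paths to layer TSVs and a
#' clinical CSV.
#'
#' @param out_dir output directory.
#' @param simulate generate the cohort instead of reading files.
#' @param synthetic named list of [synthetic_config()] overrides.
#' @param rna,protein,metabolite,clinical input paths (ignored when
#'   `simulate`).
#' @param gene_sets optional GMT path; in simulate mode a truth-derived GMT
#'   is generated when omitted.
#' @param protein_gene_map optional CSV (`protein,gene`) mapping protein ids
#'   to gene ids for enrichment; simulate mode uses the planted map.
#' @param k_range,n_restarts,tau,fdr_threshold,log_base,max_iter,tol
#'   analysis parameters (see the stage functions).
#' @param seed base seed recorded in every output.
#' @return validated `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, simulate = TRUE, synthetic = list(),
                            rna = NULL, protein = NULL, metabolite = NULL,
                            clinical = NULL, gene_sets = NULL,
                            protein_gene_map = NULL,
                            k_range = 2:6, n_restarts = 50L, tau = 0.5,
                            fdr_threshold = 0.05, log_base = 2,
                            max_iter = 2000L, tol = 1e-6, seed = 1L) {
  cfg <- list(out_dir = out_dir, simulate = isTRUE(simulate),
              synthetic = synthetic, rna = rna, protein = protein,
              metabolite = metabolite, clinical = clinical,
              gene_sets = gene_sets, protein_gene_map = protein_gene_map,
              k_range = as.integer(k_range), n_restarts = as.integer(n_restarts),
              tau = tau, fdr_threshold = fdr_threshold, log_base = log_base,
              max_iter = as.integer(max_iter), tol = tol, seed = as.integer(seed))
  if (!cfg$simulate) {
    paths <- c(rna = rna, clinical = clinical)
    missing_p <- paths[!vapply(paths, function(p) !is.null(p) && file.exists(p),
                               logical(1))]
    if (length(missing_p))
      stop("missing input file(s): ", paste(names(missing_p), collapse = ", "))
  }
  for (p in c(gene_sets, protein_gene_map))
    if (!is.null(p) && !file.exists(p)) stop("path does not exist: ", p)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full multi-omics subtyping pipeline
#'
#' Executes the eight stages in order — data (simulate/load), preprocess,
#' rank selection, subtyping, survival (OS and DBF), label transfer,
#' differential analysis (protein and metabolite + indicators), pathway
#' enrichment — writing each stage's outputs plus a JSON manifest carrying
#' the config hash, the seed and per-file checksums under `out_dir`. A stage
#' failure halts the run with the stage name; completed outputs persist.
#'
#' @param config a [pipeline_config()].
#' @return list of class `pipeline_result` with the in-memory stage results
#'   and the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_hash <- digest::digest(config[setdiff(names(config), "out_dir")])
  manifest <- list(config_hash = cfg_hash, seed = config$seed, stages = list(),
                   files = list())
  res <- list()
  record <- function(stage, outputs = character(0), info = list()) {
    for (f in outputs)
      manifest$files[[basename(f)]] <<- list(path = basename(f),
                                             md5 = digest::digest(file = f))
    manifest$stages[[length(manifest$stages) + 1L]] <<-
      c(list(name = stage, status = "complete", outputs = basename(outputs)), info)
    .momics_log("stage complete: %s", stage)
  }
  fail <- function(stage, e) {
    manifest$stages[[length(manifest$stages) + 1L]] <<-
      list(name = stage, status = "failed", error = conditionMessage(e))
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  }
  stage <- function(name, expr) tryCatch(expr, error = function(e) fail(name, e))

  # 1. data -------------------------------------------------------------
  stage("data", {
    if (config$simulate) {
      scfg <- do.call(synthetic_config,
                      modifyList(list(seed = config$seed), config$synthetic))
      cohort <- generate_cohort(scfg)
      paths <- write_cohort(cohort, config$out_dir)
      res$cohort <- cohort
      res$layers <- cohort$layers
      res$clinical <- cohort$clinical
      record("data", paths, list(mode = "simulate"))
    } else {
      res$layers <- list(
        rna = read_omics_matrix(config$rna, "rna"),
        protein = if (!is.null(config$protein)) read_omics_matrix(config$protein, "protein"),
        metabolite = if (!is.null(config$metabolite)) read_omics_matrix(config$metabolite, "metabolite"))
      res$layers <- Filter(Negate(is.null), res$layers)
      res$clinical <- read_clinical(config$clinical)
      record("data", character(0), list(mode = "load"))
    }
  })

  # 2. preprocess -------------------------------------------------------
  stage("preprocess", {
    filt <- filter_low_detected(res$layers$rna)
    norm <- normalize_omics(filt, log_base = config$log_base)
    res$rna_filtered <- filt
    res$rna_norm <- norm
    f <- file.path(config$out_dir, "rna_normalized.tsv")
    write_omics_matrix(norm, f)
    sidecar <- file.path(config$out_dir, "rna_normalized.meta.json")
    jsonlite::write_json(c(attr(norm, "provenance"),
                           list(config_hash = cfg_hash, seed = config$seed)),
                         sidecar, auto_unbox = TRUE, digits = NA)
    record("preprocess", c(f, sidecar),
           list(n_features_in = nrow(res$layers$rna$values),
                n_features_out = nrow(norm)))
  })

  # 3. rank selection ---------------------------------------------------
  stage("select_k", {
    sel <- select_k(res$rna_norm, k_range = config$k_range,
                    n_restarts = config$n_restarts, seed = config$seed,
                    max_iter = config$max_iter, tol = config$tol)
    res$selection <- sel
    f <- file.path(config$out_dir, "rank_metrics.csv")
    utils::write.csv(sel$metrics, f, row.names = FALSE)
    record("select_k", f, list(k_best = sel$k_best))
  })

  # 4. subtyping --------------------------------------------------------
  stage("subtype", {
    model <- fit_subtypes(res$rna_norm, k = res$selection$k_best,
                          n_restarts = config$n_restarts,
                          base_seed = config$seed, tau = config$tau,
                          max_iter = config$max_iter, tol = config$tol)
    res$model <- model
    f1 <- file.path(config$out_dir, "sample_labels.csv")
    utils::write.csv(data.frame(sample_id = names(model$sample_labels),
                                subtype = unname(model$sample_labels)),
                     f1, row.names = FALSE)
    f2 <- file.path(config$out_dir, "gene_associations.csv")
    utils::write.csv(model$gene_associations, f2, row.names = FALSE)
    f3 <- file.path(config$out_dir, "consensus.tsv")
    write_omics_matrix(model$consensus$C, f3)
    record("subtype", c(f1, f2, f3),
           list(k = model$k,
                cluster_sizes = as.list(table(model$sample_labels))))
  })

  # 5. survival ---------------------------------------------------------
  stage("survival", {
    outs <- character(0)
    for (ep in c("os", "dbf")) {
      sv <- compare_subtypes(res$model, res$clinical, endpoint = ep)
      res[[paste0("survival_", ep)]] <- sv
      f <- file.path(config$out_dir, sprintf("survival_%s.json", ep))
      jsonlite::write_json(list(
        endpoint = ep, groups = sv$groups,
        chi_square = sv$test$chi_square, p_value = sv$test$p_value,
        medians = lapply(sv$curves, `[[`, "median"),
        config_hash = cfg_hash, seed = config$seed),
        f, auto_unbox = TRUE, digits = NA, na = "null")
      outs <- c(outs, f)
      for (g in names(sv$curves)) {
        cv <- sv$curves[[g]]
        fc <- file.path(config$out_dir, sprintf("km_%s_subtype%s.csv", ep, g))
        utils::write.csv(data.frame(time = cv$time, surv = cv$surv, se = cv$se,
                                    lower = cv$lower, upper = cv$upper),
                         fc, row.names = FALSE)
        outs <- c(outs, fc)
      }
    }
    record("survival", outs)
  })

  # 6. label transfer ---------------------------------------------------
  stage("transfer", {
    targets <- if (!is.null(res$layers$protein))
      colnames(res$layers$protein$values) else character(0)
    tl <- transfer_labels(res$model, targets)
    res$transferred <- tl
    f <- file.path(config$out_dir, "transferred_labels.csv")
    utils::write.csv(data.frame(sample_id = names(tl), subtype = unname(tl)),
                     f, row.names = FALSE)
    record("transfer", f, list(n_retained = attr(tl, "n_retained"),
                               n_dropped = attr(tl, "n_dropped")))
  })

  # 7. differential -----------------------------------------------------
  stage("differential", {
    top2 <- res$survival_os$groups
    outs <- character(0)
    run_layer <- function(om, labels, tag, indicators = FALSE) {
      keep <- names(labels)[labels %in% top2]
      keep <- intersect(keep, colnames(om$values))
      if (length(keep) < 4) stop(sprintf("too few %s samples in the two subtypes", tag))
      om2 <- omics_matrix(om$values[, keep, drop = FALSE], om$layer)
      if (indicators) {
        defs <- default_indicator_defs(rownames(om2$values))
        if (length(defs)) om2 <- compute_indicators(om2, defs)
      }
      om2 <- filter_low_detected(om2)
      v <- om2$values
      v[!om2$detected] <- 0
      pos <- v[v > 0]
      pc <- if (length(pos)) min(pos) / 2 else 1
      lx <- log2(v + pc)
      grp <- factor(ifelse(labels[keep] == top2[1], "g1", "g2"),
                    levels = c("g1", "g2"))
      tab <- moderated_t_test(lx, grp, fdr_threshold = config$fdr_threshold)
      f <- file.path(config$out_dir, sprintf("differential_%s.csv", tag))
      utils::write.csv(tab, f, row.names = FALSE)
      outs <<- c(outs, f)
      tab
    }
    rna_labels <- res$model$sample_labels
    if (!is.null(res$layers$protein))
      res$diff_protein <- run_layer(res$layers$protein,
                                     transfer_labels(rna_labels, colnames(res$layers$protein$values)),
                                     "protein")
    if (!is.null(res$layers$metabolite))
      res$diff_metabolite <- run_layer(res$layers$metabolite,
                                        transfer_labels(rna_labels, colnames(res$layers$metabolite$values)),
                                        "metabolite", indicators = TRUE)
    record("differential", outs)
  })

  # 8. enrichment -------------------------------------------------------
  stage("enrich", {
    gmt_path <- config$gene_sets
    if (is.null(gmt_path) && config$simulate) {
      # truth-derived gene sets: one per planted cluster plus decoys
      truth <- res$cohort$truth
      sets <- split(truth$signature$gene, paste0("planted_cluster_", truth$signature$cluster))
      nonsig <- setdiff(rownames(res$layers$rna$values), truth$signature$gene)
      set.seed(config$seed + 13L)
      for (d in 1:5)
        sets[[sprintf("decoy_%d", d)]] <- sample(nonsig, min(50, length(nonsig)))
      gmt_path <- file.path(config$out_dir, "gene_sets.synthetic.gmt")
      write_gmt(sets, gmt_path)
    }
    if (is.null(gmt_path)) stop("no gene sets supplied for enrichment")
    sets <- read_gmt(gmt_path)
    top2 <- res$survival_os$groups
    assoc <- res$model$gene_associations
    sel_rna <- assoc$feature[assoc$associated & assoc$cluster %in% top2]
    pg_map <- if (!is.null(config$protein_gene_map)) {
      utils::read.csv(config$protein_gene_map, stringsAsFactors = FALSE)
    } else if (config$simulate) {
      res$cohort$truth$protein_map[, c("protein", "gene")]
    } else NULL
    sel_prot <- character(0)
    universe_prot <- 1L
    if (!is.null(res$diff_protein)) {
      sig <- res$diff_protein$feature[res$diff_protein$significant]
      universe_prot <- nrow(res$diff_protein)
      sel_prot <- if (!is.null(pg_map)) {
        unique(pg_map$gene[match(sig, pg_map$protein, nomatch = 0)])
      } else sig
    }
    scores <- pathway_scores(sets, sel_rna, sel_prot,
                             universe_rna = nrow(res$rna_norm),
                             universe_prot = universe_prot)
    res$pathway_scores <- scores
    f <- file.path(config$out_dir, "pathway_scores.csv")
    utils::write.csv(scores, f, row.names = FALSE)
    record("enrich", f, list(n_sets = length(sets),
                             n_selected_rna = length(sel_rna),
                             n_selected_prot = length(sel_prot)))
  })

  mf <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA)
  res$manifest <- manifest
  class(res) <- "pipeline_result"
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  st <- vapply(x$manifest$stages, `[[`, "", "name")
  cat(sprintf("<pipeline_result> %d stages complete: %s\n",
              length(st), paste(st, collapse = " -> ")))
  invisible(x)
}
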