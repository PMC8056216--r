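#' Configuration for the synthetic multi-omics cohort generator
#'
#' Describes a cohort of brain-metastasis-like patients in which three omics
#' layers (RNA, protein, metabolite) cover overlapping patient subsets, the
#' transcriptome carries `k_true` planted sample clusters with cluster-specific
#' signature-gene blocks, the protein layer carries an attenuated copy of the
#' transcript signatures, the metabolite panel carries planted log2
#' fold-changes between the poorest-prognosis subtype and the rest, and
#' survival is exponential with per-subtype medians.
#'
#' Defaults mirror the published cohort structure: 78 patients, layer sizes
#' 46/64/41 with a triple overlap of 17 (which forces 56 patients with at
#' least two layers), four transcriptomic subtypes, and subtype survival
#' medians spanning 7.89 to 42.27 months.
#'
#' @param n_patients total patients (the union of the three layers).
#' @param cohort_sizes integer vector `(rna, protein, metabolite)` layer sizes.
#' @param triple_overlap patients present in all three layers.
#' @param n_genes,n_proteins,n_metabolites features per layer.
#' @param k_true number of planted sample clusters.
#' @param signature_size signature genes per cluster (disjoint blocks).
#' @param effect_size mean log2-scale shift of a signature gene in its own
#'   cluster relative to the others.
#' @param noise_sd residual standard deviation on the log2 scale.
#' @param protein_attenuation multiplier in `[0, 1]` carrying transcript
#'   signature shifts into the mapped proteins.
#' @param n_signature_metabolites metabolites given a planted fold-change.
#' @param survival_medians per-subtype overall-survival medians in months
#'   (length `k_true`); `NULL` uses 7.89/13.0/15.9/42.27 for `k_true = 4` and
#'   a geometric interpolation between 7.89 and 42.27 otherwise.
#' @param censor_rate fraction of subjects censored per endpoint.
#' @param seed RNG seed; the cohort is a deterministic function of the config.
#' @return a validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_patients = 78,
                             cohort_sizes = c(rna = 46, protein = 64, metabolite = 41),
                             triple_overlap = 17,
                             n_genes = 2000,
                             k_true = 4,
                             signature_size = 100,
                             effect_size = 2.0,
                             noise_sd = 1.0,
                             protein_attenuation = 0.5,
                             n_proteins = 500,
                             n_metabolites = 180,
                             n_signature_metabolites = 30,
                             survival_medians = NULL,
                             censor_rate = 0.25,
                             seed = 1L) {
  cohort_sizes <- as.integer(cohort_sizes)
  if (length(cohort_sizes) != 3L) stop("cohort_sizes must have length 3 (rna, protein, metabolite)")
  names(cohort_sizes) <- c("rna", "protein", "metabolite")
  if (is.null(survival_medians)) {
    survival_medians <- if (k_true == 4) c(7.89, 13.0, 15.9, 42.27)
      else if (k_true == 1) sqrt(7.89 * 42.27)
      else exp(seq(log(7.89), log(42.27), length.out = k_true))
  }
  cfg <- list(n_patients = as.integer(n_patients), cohort_sizes = cohort_sizes,
              triple_overlap = as.integer(triple_overlap),
              n_genes = as.integer(n_genes), k_true = as.integer(k_true),
              signature_size = as.integer(signature_size),
              effect_size = effect_size, noise_sd = noise_sd,
              protein_attenuation = protein_attenuation,
              n_proteins = as.integer(n_proteins),
              n_metabolites = as.integer(n_metabolites),
              n_signature_metabolites = as.integer(n_signature_metabolites),
              survival_medians = survival_medians,
              censor_rate = censor_rate, seed = as.integer(seed))
  class(cfg) <- "synthetic_config"
  validate_synthetic_config(cfg)
  cfg
}

validate_synthetic_config <- function(cfg) {
  with(cfg, {
    if (any(cohort_sizes > n_patients)) stop("cohort sizes must not exceed n_patients")
    if (triple_overlap > min(cohort_sizes)) stop("triple_overlap exceeds the smallest layer")
    if (triple_overlap < 0) stop("triple_overlap must be non-negative")
    if (effect_size < 0) stop("effect_size must be >= 0")
    if (noise_sd <= 0) stop("noise_sd must be > 0")
    if (censor_rate < 0 || censor_rate >= 1) stop("censor_rate must be in [0, 1)")
    if (protein_attenuation < 0 || protein_attenuation > 1)
      stop("protein_attenuation must be in [0, 1]")
    if (k_true < 1) stop("k_true must be >= 1")
    if (length(survival_medians) != k_true)
      stop("survival_medians must have length k_true")
    if (k_true * signature_size > n_genes)
      stop("k_true * signature_size exceeds n_genes")
    if (n_signature_metabolites > n_metabolites)
      stop("n_signature_metabolites exceeds n_metabolites")
  })
  invisible(cfg)
}

# Solve the three-set overlap design from marginal sizes, the union and the
# triple count. With exclusive pairwise counts y12, y13, y23 the identities
#   sum(y) = sum(sizes) - union - 2 * triple
#   y_ij + y_ik <= sizes_i - triple      (exclusive singles non-negative)
# leave a small polytope; we start from an even split and deterministically
# move units off overloaded layers onto the opposite pair.
solve_overlap_design <- function(sizes, union_n, triple) {
  total_pairs <- sum(sizes) - union_n - 2L * triple
  if (total_pairs < 0 || triple > min(sizes) || union_n < max(sizes) ||
      union_n > sum(sizes))
    stop("infeasible overlap design: no membership assignment satisfies the ",
         "configured sizes, union and triple overlap")
  # pairs indexed (1,2), (1,3), (2,3); pair p touches layers touch[[p]]
  touch <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))
  y <- rep(total_pairs %/% 3L, 3L)
  for (p in seq_len(total_pairs %% 3L)) y[p] <- y[p] + 1L
  load <- function(y) vapply(1:3, function(i)
    sum(y[vapply(touch, function(tp) i %in% tp, logical(1))]), numeric(1))
  cap <- sizes - triple
  for (iter in 1:100) {
    over <- load(y) - cap
    if (all(over <= 0)) break
    i <- which.max(over)
    opp <- which(vapply(touch, function(tp) !(i %in% tp), logical(1)))
    src <- which(vapply(touch, function(tp) i %in% tp, logical(1)))
    # receiving layer of a move from src pair s to the opposite pair is the
    # member of touch[[opp]] not shared with s; prefer the slackest receiver
    moved <- FALSE
    for (s in src[order(-y[src])]) {
      recv <- setdiff(touch[[opp]], touch[[s]])
      slack <- cap[recv] - load(y)[recv]
      m <- min(over[i], y[s], slack)
      if (m > 0) { y[s] <- y[s] - m; y[opp] <- y[opp] + m; moved <- TRUE; break }
    }
    if (!moved)
      stop("infeasible overlap design: no membership assignment satisfies the ",
           "configured sizes, union and triple overlap")
  }
  if (any(load(y) > cap) || any(y < 0))
    stop("infeasible overlap design: no membership assignment satisfies the ",
         "configured sizes, union and triple overlap")
  singles <- sizes - triple - load(y)
  if (union_n != sum(singles) + sum(y) + triple)
    stop("infeasible overlap design: region counts do not tile the union")
  list(singles = singles, pairs = c(y12 = y[1], y13 = y[2], y23 = y[3]),
       triple = triple)
}

# Biocrates p180-style analyte names; the named species used by the custom
# metabolite indicators come first so they survive truncation to n.
p180_panel_names <- function(n) {
  key <- c("Arg", "Orn", "Ser", "Val", "C3", "C4", "C5",
           "lysoPC a C18:2", "lysoPC a C20:3", "lysoPC a C20:4",
           "PC ae C36:0", "PC ae C44:6", "Carnosine",
           "SM (OH) C14:1", "SM (OH) C16:1", "SM (OH) C22:1",
           "SM (OH) C22:2", "SM (OH) C24:1",
           "SM C16:0", "SM C16:1", "SM C18:0", "SM C18:1", "SM C20:2",
           "SM C24:0", "SM C24:1", "SM C26:0", "SM C26:1")
  aa <- c("Ala", "Asn", "Asp", "Cit", "Gln", "Glu", "Gly", "His", "Ile",
          "Leu", "Lys", "Met", "Phe", "Pro", "Thr", "Trp", "Tyr", "xLeu")
  amines <- c("Ac-Orn", "ADMA", "alpha-AAA", "Creatinine", "DOPA", "Dopamine",
              "Histamine", "Kynurenine", "Met-SO", "Nitro-Tyr", "PEA",
              "Putrescine", "Sarcosine", "SDMA", "Serotonin", "Spermidine",
              "Spermine", "Taurine", "t4-OH-Pro", "Sugars (H1)")
  acyl <- paste0("C", c("0", "2", "3:1", "4:1", "5:1", "5-OH", "6", "8", "10",
                        "12", "14", "14:1", "16", "16-OH", "18", "18:1"))
  lyso <- paste("lysoPC a", c("C16:0", "C16:1", "C17:0", "C18:0", "C18:1",
                              "C20:0", "C24:0", "C26:0", "C26:1", "C28:0"))
  pcs <- c(outer(c("PC aa", "PC ae"),
                 paste0("C", c("24:0", "28:1", "30:0", "32:0", "32:1", "32:2",
                               "34:1", "34:2", "34:3", "36:1", "36:2", "36:3",
                               "36:4", "38:3", "38:4", "38:5", "38:6", "40:4",
                               "40:5", "40:6", "42:1", "42:2", "42:4", "42:5",
                               "44:3", "44:4", "44:5")), paste))
  pool <- unique(c(key, aa, amines, acyl, lyso, pcs))
  if (n > length(pool))
    pool <- c(pool, sprintf("met_%03d", seq_len(n - length(pool))))
  pool[seq_len(n)]
}

#' Simulate right-censored exponential survival times
#'
#' Event times are exponential with the requested median (rate
#' `log(2) / median`). Censoring is by an independent exponential time whose
#' rate is calibrated so that `P(censored) = censor_rate` exactly
#' (`rate_c = rate * censor_rate / (1 - censor_rate)`); independence keeps
#' the Kaplan-Meier estimator unbiased, unlike censoring drawn below the
#' subject's own event time.
#'
#' @param n subjects.
#' @param median_months true median event time in months.
#' @param censor_rate expected fraction of subjects censored (default 0).
#' @param seed optional RNG seed.
#' @return data.frame with columns `time` (months) and `event` (1 = observed).
#' @export
simulate_survival_times <- function(n, median_months, censor_rate = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n >= 1, median_months > 0, censor_rate >= 0, censor_rate < 1)
  rate <- log(2) / median_months
  t_event <- rexp(n, rate = rate)
  if (censor_rate > 0) {
    t_cens <- rexp(n, rate = rate * censor_rate / (1 - censor_rate))
    data.frame(time = pmin(t_event, t_cens),
               event = as.integer(t_event <= t_cens))
  } else {
    data.frame(time = t_event, event = rep(1L, n))
  }
}

#' Generate a synthetic multi-omics cohort with planted structure
#'
#' Produces three overlapping omics layers, a clinical table, and the planted
#' ground truth, deterministically from the configuration seed. The RNA layer
#' is a positive FPKM-UQ-like matrix (log-normal baseline) in which each
#' cluster's signature block is shifted by `effect_size` on the log2 scale
#' (sign drawn per gene); the protein layer carries the signature shifts of
#' mapped genes attenuated by `protein_attenuation`; the metabolite layer
#' plants log2 fold-changes between the shortest-median subtype and the rest.
#' Survival is exponential per subtype with uniform-before-event censoring at
#' `censor_rate` for both the overall-survival and distant-brain-failure
#' endpoints.
#'
#' @param config a [synthetic_config()].
#' @return a `synthetic_cohort`: list with elements `layers` (named list of
#'   [omics_matrix()]), `clinical` (data.frame with `sample_id`, `os_time`,
#'   `os_event`, `dbf_time`, `dbf_event`, `primary_site`), `truth`, `config`.
#' @export
generate_cohort <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  validate_synthetic_config(config)
  set.seed(config$seed)
  n <- config$n_patients
  ids <- sprintf("P%03d", seq_len(n))

  design <- solve_overlap_design(config$cohort_sizes, n, config$triple_overlap)
  region <- rep(c("abc", "ab", "ac", "bc", "a", "b", "c"),
                times = c(design$triple, design$pairs, design$singles))
  membership <- list(
    rna        = ids[region %in% c("abc", "ab", "ac", "a")],
    protein    = ids[region %in% c("abc", "ab", "bc", "b")],
    metabolite = ids[region %in% c("abc", "ac", "bc", "c")])

  k <- config$k_true
  subtype <- sample(rep_len(seq_len(k), n))
  names(subtype) <- ids
  poor <- which.min(config$survival_medians)

  # --- RNA layer ------------------------------------------------------------
  genes <- sprintf("gene_%04d", seq_len(config$n_genes))
  n_sig <- k * config$signature_size
  sig_cluster <- rep(seq_len(k), each = config$signature_size)
  sig_sign <- sample(c(-1, 1), n_sig, replace = TRUE)
  rna_ids <- membership$rna
  mu_g <- rnorm(config$n_genes, mean = 5, sd = 1.5)
  shift <- matrix(0, n_sig, length(rna_ids))
  for (c_ in seq_len(k)) {
    rows <- which(sig_cluster == c_)
    cols <- which(subtype[rna_ids] == c_)
    if (length(cols)) shift[rows, cols] <- sig_sign[rows] * config$effect_size
  }
  logx <- mu_g + rbind(shift, matrix(0, config$n_genes - n_sig, length(rna_ids))) +
    matrix(rnorm(config$n_genes * length(rna_ids), sd = config$noise_sd),
           config$n_genes, length(rna_ids))
  rna <- 2^logx
  # a seeded subset of non-signature genes is lowly detected (mostly zero)
  nonsig <- setdiff(seq_len(config$n_genes), seq_len(n_sig))
  low <- sample(nonsig, size = max(0L, round(0.05 * length(nonsig))))
  for (g in low) {
    drop_cols <- runif(length(rna_ids)) < 0.7
    rna[g, drop_cols] <- 0
  }
  dimnames(rna) <- list(genes, rna_ids)

  # --- protein layer --------------------------------------------------------
  prots <- sprintf("prot_%04d", seq_len(config$n_proteins))
  prot_ids <- membership$protein
  n_map <- min(config$n_proteins %/% 2L, n_sig)
  map_gene <- seq_len(n_map)  # protein j tracks signature gene j
  nu_p <- rnorm(config$n_proteins, mean = 20, sd = 2)
  pshift <- matrix(0, config$n_proteins, length(prot_ids))
  for (j in seq_len(n_map)) {
    g <- map_gene[j]
    cols <- which(subtype[prot_ids] == sig_cluster[g])
    if (length(cols))
      pshift[j, cols] <- config$protein_attenuation * sig_sign[g] * config$effect_size
  }
  logp <- nu_p + pshift +
    matrix(rnorm(config$n_proteins * length(prot_ids), sd = config$noise_sd),
           config$n_proteins, length(prot_ids))
  protein <- 2^logp
  dimnames(protein) <- list(prots, prot_ids)

  # --- metabolite layer -----------------------------------------------------
  mets <- p180_panel_names(config$n_metabolites)
  met_ids <- membership$metabolite
  m0 <- rnorm(config$n_metabolites, mean = 3, sd = 1)
  sig_met <- sort(sample.int(config$n_metabolites, config$n_signature_metabolites))
  met_lfc <- setNames(numeric(config$n_metabolites), mets)
  met_lfc[sig_met] <- round(runif(length(sig_met), 0.5, 1.7), 2) *
    sample(c(-1, 1), length(sig_met), replace = TRUE)
  mshift <- outer(met_lfc, as.numeric(subtype[met_ids] == poor))
  logm <- m0 + mshift +
    matrix(rnorm(config$n_metabolites * length(met_ids), sd = config$noise_sd),
           config$n_metabolites, length(met_ids))
  metabolite <- 2^logm
  dimnames(metabolite) <- list(mets, met_ids)

  # --- clinical -------------------------------------------------------------
  os_med <- config$survival_medians[subtype]
  dbf_med <- os_med * (10.0 / 17.2)  # DBF precedes death; cohort-level ratio
  censor_draw <- function(med) {
    rate <- log(2) / med
    t_ev <- rexp(n, rate = rate)
    if (config$censor_rate > 0) {
      t_c <- rexp(n, rate = rate * config$censor_rate / (1 - config$censor_rate))
      list(time = pmin(t_ev, t_c), event = as.integer(t_ev <= t_c))
    } else list(time = t_ev, event = rep(1L, n))
  }
  os <- censor_draw(os_med)
  dbf <- censor_draw(dbf_med)
  dbf_time <- dbf$time
  dbf_event <- dbf$event
  primary_site <- sample(c("lung", "breast", "melanoma", "other"), n,
                         replace = TRUE, prob = c(37, 16, 14, 11) / 78)
  clinical <- data.frame(sample_id = ids,
                         os_time = os$time, os_event = os$event,
                         dbf_time = dbf_time, dbf_event = dbf_event,
                         primary_site = primary_site,
                         subtype_true = unname(subtype),
                         stringsAsFactors = FALSE)

  truth <- list(
    subtype = subtype,
    signature = data.frame(gene = genes[seq_len(n_sig)], cluster = sig_cluster,
                           sign = sig_sign, stringsAsFactors = FALSE),
    protein_map = data.frame(protein = prots[seq_len(n_map)],
                             gene = genes[map_gene],
                             cluster = sig_cluster[map_gene],
                             sign = sig_sign[map_gene], stringsAsFactors = FALSE),
    metabolite_logfc = met_lfc,
    poor_subtype = poor,
    os_medians = config$survival_medians,
    dbf_medians = config$survival_medians * (10.0 / 17.2),
    membership = membership)

  structure(list(
    layers = list(rna = omics_matrix(rna, "rna"),
                  protein = omics_matrix(protein, "protein"),
                  metabolite = omics_matrix(metabolite, "metabolite")),
    clinical = clinical, truth = truth, config = config),
    class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d patients, layers: %s\n",
              x$config$n_patients,
              paste(sprintf("%s(%d)", names(x$layers),
                            vapply(x$layers, function(l) ncol(l$values), 1L)),
                    collapse = ", ")))
  invisible(x)
}

#' Summarize the planted ground truth of a synthetic cohort
#'
#' Read-only report of the planted structure: subtype counts, signature gene
#' lists per cluster, planted survival medians and metabolite fold-changes.
#'
#' @param cohort a `synthetic_cohort` from [generate_cohort()].
#' @return a list of class `truth_report`.
#' @export
planted_truth_report <- function(cohort) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  tr <- cohort$truth
  structure(list(
    subtype_counts = table(factor(tr$subtype, levels = seq_len(cohort$config$k_true))),
    signature_genes = split(tr$signature$gene, tr$signature$cluster),
    n_signature_genes = nrow(tr$signature),
    os_medians = tr$os_medians,
    dbf_medians = tr$dbf_medians,
    planted_metabolites = tr$metabolite_logfc[tr$metabolite_logfc != 0],
    membership_sizes = vapply(tr$membership, length, 1L)),
    class = "truth_report")
}

#' @export
print.truth_report <- function(x, ...) {
  cat("<truth_report>\n  subtype counts:",
      paste(sprintf("%s=%d", names(x$subtype_counts), x$subtype_counts), collapse = " "),
      "\n  signature genes:", x$n_signature_genes,
      "\n  OS medians (months):", paste(signif(x$os_medians, 4), collapse = ", "),
      "\n  layer sizes:", paste(sprintf("%s=%d", names(x$membership_sizes),
                                        x$membership_sizes), collapse = " "), "\n")
  invisible(x)
}
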