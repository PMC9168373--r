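## End-to-end orchestration: preprocess -> deconvolve -> cluster samples ->
## stability-select genes -> cluster genes -> score -> cutpoint ->
## survival -> enrichment / mutations, with per-stage seeds derived from
## one global seed and a machine-readable run report.

all_stages <- c("preprocess", "deconvolve", "cluster_samples",
                "select_genes", "score", "survival", "enrichment",
                "mutations")

stage_deps <- list(cluster_samples = "deconvolve",
                   select_genes = "cluster_samples",
                   score = "select_genes",
                   survival = "score",
                   enrichment = "survival",
                   mutations = "survival")

#' Pipeline configuration
#'
#' Inputs may be in-memory objects or file paths (TSV/MAF/GMT, read with
#' the package readers).
#'
#' @param expression Genes x samples matrix or TSV path.
#' @param clinical Clinical data frame or TSV path; needs columns
#'   \code{sample_id, os_days, os_event}, optionally covariates and
#'   \code{batch}.
#' @param signature Signature matrix or TSV path.
#' @param maf Optional MAF data frame or path.
#' @param gene_sets Optional named list of gene sets or GMT path.
#' @param out_dir Optional output directory for TSV intermediates and the
#'   JSON report.
#' @param stages Character vector of stages to run (default all).
#' @param expression_unit \code{"TPM"} or \code{"FPKM"}.
#' @param max_bad_frac,knn_k Gene filter and imputation controls.
#' @param covariates Clinical covariate columns for the multivariable Cox
#'   model (used when present).
#' @param k_range_samples,k_range_genes Consensus-clustering scan ranges.
#' @param cluster_iterations,resample_frac Consensus-clustering controls.
#' @param rf_runs,rf_top,rf_trees,rf_subsample Stability-selection
#'   controls.
#' @param prognostic_alpha Per-gene Cox screen threshold.
#' @param minprop Minimum group proportion for the survival cutpoint.
#' @param cutoff Optional fixed TMEscore cutoff overriding the learned
#'   cutpoint.
#' @param n_perm GSEA phenotype permutations.
#' @param mutation_p_cut Differential-mutation threshold.
#' @param seed Global seed expanded deterministically into stage seeds.
#' @return List of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(expression, clinical, signature,
                            maf = NULL, gene_sets = NULL, out_dir = NULL,
                            stages = all_stages,
                            expression_unit = c("TPM", "FPKM"),
                            max_bad_frac = 0.7, knn_k = 10L,
                            covariates = c("age", "sex", "stage", "smoke"),
                            k_range_samples = 2:7, k_range_genes = 2:5,
                            cluster_iterations = 100L, resample_frac = 0.8,
                            rf_runs = 100L, rf_top = 100L, rf_trees = 200L,
                            rf_subsample = 0.5,
                            prognostic_alpha = 0.05, minprop = 0.1,
                            cutoff = NULL, n_perm = 1000L,
                            mutation_p_cut = 0.01, seed = 1L) {
  expression_unit <- match.arg(expression_unit)
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  for (st in intersect(stages, names(stage_deps))) {
    need <- stage_deps[[st]]
    if (!need %in% stages)
      stop("stage '", st, "' requires stage '", need, "'")
  }
  cfg <- list(expression = expression, clinical = clinical,
              signature = signature, maf = maf, gene_sets = gene_sets,
              out_dir = out_dir, stages = stages,
              expression_unit = expression_unit,
              max_bad_frac = max_bad_frac, knn_k = as.integer(knn_k),
              covariates = covariates,
              k_range_samples = k_range_samples,
              k_range_genes = k_range_genes,
              cluster_iterations = as.integer(cluster_iterations),
              resample_frac = resample_frac,
              rf_runs = as.integer(rf_runs), rf_top = as.integer(rf_top),
              rf_trees = as.integer(rf_trees), rf_subsample = rf_subsample,
              prognostic_alpha = prognostic_alpha, minprop = minprop,
              cutoff = cutoff, n_perm = as.integer(n_perm),
              mutation_p_cut = mutation_p_cut, seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Load and cross-check pipeline inputs
#'
#' Reads any path-valued inputs, checks sample-id agreement between
#' expression and clinical table (< 3 overlapping samples is fatal),
#' drops duplicated sample ids keeping the first occurrence, restricts
#' both to the common samples and verifies positive survival times.
#'
#' @param config A \code{\link{pipeline_config}}.
#' @return List \code{expression, clinical, signature, maf, gene_sets,
#'   warnings}.
#' @export
validate_inputs <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  warns <- character(0)
  note <- function(msg) { warns <<- c(warns, msg); warning(msg, call. = FALSE) }

  expr <- config$expression
  if (is.character(expr)) expr <- read_expression_tsv(expr, config$expression_unit)
  check_matrix(expr, "expression")
  clin <- config$clinical
  if (is.character(clin))
    clin <- utils::read.delim(clin, stringsAsFactors = FALSE)
  for (col in c("sample_id", "os_days", "os_event"))
    if (!col %in% colnames(clin)) stop("clinical table lacks column ", col)
  sig <- config$signature
  if (is.character(sig)) sig <- read_expression_tsv(sig)
  check_matrix(sig, "signature")
  maf <- config$maf
  if (is.character(maf)) maf <- read_maf(maf)
  sets <- config$gene_sets
  if (is.character(sets)) sets <- read_gmt(sets)

  if (anyDuplicated(clin$sample_id)) {
    note("duplicated clinical sample id(s); keeping first occurrence")
    clin <- clin[!duplicated(clin$sample_id), ]
  }
  common <- intersect(colnames(expr), clin$sample_id)
  if (length(common) < 3L)
    stop("fewer than 3 samples shared between expression and clinical table")
  lost_e <- setdiff(colnames(expr), common)
  lost_c <- setdiff(clin$sample_id, common)
  if (length(lost_e))
    note(paste0(length(lost_e), " expression sample(s) absent from clinical; excluded"))
  if (length(lost_c))
    note(paste0(length(lost_c), " clinical sample(s) absent from expression; excluded"))
  expr <- expr[, common, drop = FALSE]
  clin <- clin[match(common, clin$sample_id), ]
  if (any(clin$os_days <= 0)) stop("nonpositive survival times in clinical table")
  list(expression = expr, clinical = clin, signature = sig, maf = maf,
       gene_sets = sets, warnings = warns)
}

write_stage_tsv <- function(obj, out_dir, name) {
  if (is.null(out_dir)) return(invisible(NULL))
  path <- file.path(out_dir, name)
  if (is.matrix(obj)) write_expression_tsv(obj, path, id_col = "id")
  else utils::write.table(obj, path, sep = "\t", quote = FALSE,
                          row.names = FALSE)
  invisible(path)
}

#' Run the full pipeline
#'
#' Executes the configured stages in order, persisting every intermediate
#' as TSV when \code{out_dir} is set, and returns the results plus a run
#' report (per-stage parameters, item counts, warnings, output checksums).
#' Identical configuration and seed reproduce identical outputs.
#'
#' @param config A \code{\link{pipeline_config}}.
#' @return List of class \code{"pipeline_result"} with elements
#'   \code{expression} (processed log2 matrix), \code{fractions},
#'   \code{sample_clusters}, \code{selection}, \code{gene_clusters},
#'   \code{tmescore}, \code{cutpoint}, \code{survival}, \code{gsea},
#'   \code{mutations}, \code{report}.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  inp <- withCallingHandlers(validate_inputs(config),
                             warning = function(w) invokeRestart("muffleWarning"))
  out_dir <- config$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_plain <- unclass(config)
  report <- list(parameters = cfg_plain[!(names(cfg_plain) %in%
                                           c("expression", "clinical", "signature",
                                             "maf", "gene_sets"))],
                 counts = list(), warnings = inp$warnings)
  res <- list(report = NULL)
  on <- function(stage) stage %in% config$stages
  seed <- config$seed

  ## --- preprocess -------------------------------------------------------
  expr <- inp$expression
  if (on("preprocess")) {
    if (config$expression_unit == "FPKM") expr <- fpkm_to_tpm(expr)
    n0 <- nrow(expr)
    expr <- filter_genes(expr, config$max_bad_frac)
    report$counts$genes_in <- n0
    report$counts$genes_after_filter <- nrow(expr)
    if (anyNA(expr)) expr <- knn_impute(expr, config$knn_k)
  }
  expr_lin <- expr
  expr_log <- log2(expr + 1)
  if ("batch" %in% colnames(inp$clinical) &&
      length(unique(inp$clinical$batch)) > 1L && on("preprocess")) {
    expr_log <- combat_correct(expr_log, inp$clinical$batch)
    expr_lin <- pmax(2^expr_log - 1, 0)
  }
  res$expression <- expr_log
  write_stage_tsv(round(expr_log, 6), out_dir, "expression_log2.tsv")

  ## --- deconvolution ----------------------------------------------------
  if (on("deconvolve")) {
    fr <- deconvolve_matrix(expr_lin, inp$signature)
    res$fractions <- fr
    report$counts$cell_types <- ncol(fr$fractions)
    write_stage_tsv(cbind(fr$fractions, rmse = fr$rmse,
                          pearson_r = fr$pearson_r),
                    out_dir, "cell_fractions.tsv")
  }

  ## --- sample clustering ------------------------------------------------
  if (on("cluster_samples")) {
    cc <- consensus_cluster(res$fractions$fractions,
                            k_range = config$k_range_samples,
                            iterations = config$cluster_iterations,
                            resample_frac = config$resample_frac,
                            distance = "euclidean",
                            seed = stage_seed(seed, "cluster_samples"))
    res$sample_clusters <- cc
    report$counts$chosen_k_samples <- cc$chosen_k
    write_stage_tsv(data.frame(sample_id = names(cc$labels),
                               subtype = paste0("S", cc$labels)),
                    out_dir, "sample_subtypes.tsv")
  }

  ## --- gene stability selection ----------------------------------------
  if (on("select_genes")) {
    sel <- rf_stability_select(expr_log, res$sample_clusters$labels,
                               n_runs = config$rf_runs,
                               per_run_top = config$rf_top,
                               subsample_frac = config$rf_subsample,
                               num_trees = config$rf_trees,
                               seed = stage_seed(seed, "select_genes"))
    res$selection <- sel
    report$counts$genes_selected <- sum(sel$selected)
    write_stage_tsv(sel, out_dir, "gene_selection.tsv")
    if (sum(sel$selected) < 2L) stop("stage select_genes: < 2 stable genes")
  }

  ## --- gene clustering + TMEscore --------------------------------------
  surv <- data.frame(sample_id = inp$clinical$sample_id,
                     time = inp$clinical$os_days,
                     event = inp$clinical$os_event,
                     stringsAsFactors = FALSE)
  if (on("score")) {
    sel_genes <- res$selection$gene_id[res$selection$selected]
    scr <- screen_prognostic(expr_log, surv, genes = sel_genes,
                             alpha = config$prognostic_alpha)
    report$counts$genes_prognostic <- sum(scr$keep)
    gcs <- build_gene_clusters(expr_log[sel_genes, , drop = FALSE], surv,
                               k_range = config$k_range_genes,
                               restrict_to = scr$gene_id[scr$keep],
                               iterations = config$cluster_iterations,
                               resample_frac = config$resample_frac,
                               seed = stage_seed(seed, "cluster_genes"))
    res$gene_clusters <- gcs
    res$prognostic_screen <- scr
    report$counts$chosen_k_genes <- gcs$consensus$chosen_k
    score <- compute_tmescore(gcs)
    res$tmescore_raw <- score
    write_stage_tsv(data.frame(gene_id = unlist(gcs$all_members),
                               cluster = rep(names(gcs$all_members),
                                             lengths(gcs$all_members))),
                    out_dir, "gene_clusters.tsv")
  }

  ## --- cutpoint + survival ---------------------------------------------
  if (on("survival")) {
    score <- res$tmescore_raw
    cut <- if (!is.null(config$cutoff))
      list(cutoff = config$cutoff, statistic = NA_real_)
    else optimal_cutpoint(score, surv$time, surv$event,
                          minprop = config$minprop)
    res$cutpoint <- cut
    tab <- dichotomize(score, cut$cutoff)
    res$tmescore <- tab
    write_stage_tsv(tab, out_dir, "tmescore.tsv")
    lr <- logrank_test(tab$group, surv$time, surv$event)
    km <- lapply(split(seq_len(nrow(tab)), tab$group), function(i)
      km_estimate(surv$time[i], surv$event[i]))
    covs <- intersect(config$covariates, colnames(inp$clinical))
    cx_df <- cbind(data.frame(time = surv$time, event = surv$event,
                              tmescore = tab$score), inp$clinical[covs])
    cx <- cox_fit(cx_df, c("tmescore", covs))
    res$survival <- list(logrank = lr, km = km, cox = cx)
    report$counts$n_high <- sum(tab$group == "high")
    report$counts$n_low <- sum(tab$group == "low")
  }

  ## --- enrichment -------------------------------------------------------
  if (on("enrichment") && !is.null(inp$gene_sets)) {
    res$gsea <- gsea(expr_log, res$tmescore$group, inp$gene_sets,
                     positive_class = "high", n_perm = config$n_perm,
                     seed = stage_seed(seed, "gsea"))
    report$counts$gsea_sets <- nrow(res$gsea)
    write_stage_tsv(res$gsea, out_dir, "gsea.tsv")
  }

  ## --- mutations --------------------------------------------------------
  if (on("mutations") && !is.null(inp$maf)) {
    groups <- stats::setNames(res$tmescore$group, res$tmescore$sample_id)
    res$mutations <- mutation_compare(inp$maf, groups,
                                      p_cut = config$mutation_p_cut)
    res$tmb <- tmb_from_maf(inp$maf, samples = names(groups))
    report$counts$genes_mutation_flagged <- sum(res$mutations$flagged)
    write_stage_tsv(res$mutations, out_dir, "mutation_compare.tsv")
    write_stage_tsv(data.frame(sample_id = names(res$tmb), tmb = res$tmb),
                    out_dir, "tmb.tsv")
  }

  if (!is.null(out_dir)) {
    files <- list.files(out_dir, full.names = TRUE)
    report$checksums <- as.list(tools::md5sum(files))
    report$parameters$out_dir <- out_dir
    jsonlite::write_json(
      list(counts = report$counts, warnings = report$warnings,
           checksums = report$checksums),
      file.path(out_dir, "run_report.json"), auto_unbox = TRUE, digits = NA)
  }
  res$report <- report
  class(res) <- "pipeline_result"
  res
}
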