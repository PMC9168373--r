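## TMEscore construction: stability-select subtype-discriminating genes
## with repeated random forests, group them into gene clusters, screen for
## prognosis, form Cox-signed PC1 metagene scores and combine:
## TMEscore = sum(PC1 of hazard-positive clusters) -
##            sum(PC1 of hazard-negative clusters).

#' Random-forest stability selection of subtype-discriminating genes
#'
#' Runs a random-forest classifier of subtype from expression \code{n_runs}
#' times.  Each run subsamples \code{subsample_frac} of the samples and
#' uses a run-specific seed, then records the \code{per_run_top} genes by
#' impurity importance.  A gene is selected iff it appears in at least
#' \code{repeat_frac * n_runs} runs (boundary inclusive).  The per-run
#' subsampling makes chance gene-label correlations rotate across runs, so
#' repeatedly chosen genes reflect real signal rather than one dataset's
#' noise.
#'
#' @param expr Genes x samples matrix.
#' @param subtype Per-sample subtype labels (>= 2 levels, each >= 5
#'   samples).
#' @param n_runs Number of forests (default 100).
#' @param repeat_frac Selection threshold as a fraction of runs (default
#'   0.8).
#' @param per_run_top Genes recorded per run (default 100).
#' @param subsample_frac Fraction of samples drawn (without replacement)
#'   per run (default 0.5).
#' @param num_trees Trees per forest (default 200).
#' @param seed Master seed.
#' @return Data frame \code{gene_id, selection_count, selected}.
#' @export
rf_stability_select <- function(expr, subtype, n_runs = 100L,
                                repeat_frac = 0.8, per_run_top = 100L,
                                subsample_frac = 0.5, num_trees = 200L,
                                seed = 1L) {
  check_matrix(expr, "expression")
  subtype <- as.factor(as.character(subtype))
  if (nlevels(subtype) < 2L) stop("need >= 2 subtypes")
  if (any(table(subtype) < 5L)) stop("each subtype needs >= 5 samples")
  sds <- apply(expr, 1L, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant gene(s) dropped before fitting")
    expr <- expr[sds > 0, , drop = FALSE]
  }
  X <- t(expr)
  colnames(X) <- rownames(expr)
  n <- nrow(X)
  top <- min(per_run_top, ncol(X))
  cnt <- stats::setNames(integer(ncol(X)), colnames(X))
  for (r in seq_len(n_runs)) {
    rs <- stage_seed(seed, paste0("rf", r))
    set.seed(rs)
    idx <- sample.int(n, ceiling(subsample_frac * n))
    fit <- ranger::ranger(x = X[idx, , drop = FALSE], y = subtype[idx],
                          num.trees = num_trees, importance = "impurity",
                          seed = rs, num.threads = 1L)
    sel <- names(sort(fit$variable.importance, decreasing = TRUE))[seq_len(top)]
    cnt[sel] <- cnt[sel] + 1L
  }
  data.frame(gene_id = names(cnt), selection_count = unname(cnt),
             selected = unname(cnt) >= repeat_frac * n_runs,
             stringsAsFactors = FALSE)
}

#' Univariate Cox screen of candidate prognostic genes
#'
#' @param expr Genes x samples matrix.
#' @param surv Data frame with \code{sample_id, time, event} aligned to the
#'   columns of \code{expr} by sample id.
#' @param genes Genes to screen (default all rows).
#' @param alpha Significance threshold (default 0.05).
#' @return Data frame \code{gene_id, coef, p, keep}; constant or
#'   non-convergent genes are dropped with a warning.
#' @export
screen_prognostic <- function(expr, surv, genes = rownames(expr),
                              alpha = 0.05) {
  check_matrix(expr, "expression")
  surv <- surv[match(colnames(expr), surv$sample_id), ]
  check_surv(surv$time, surv$event)
  rows <- lapply(genes, function(g) {
    x <- expr[g, ]
    if (stats::sd(x) == 0) return(NULL)
    fit <- tryCatch(
      survival::coxph(survival::Surv(surv$time, surv$event) ~ x,
                      ties = "efron"),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(fit) || is.na(stats::coef(fit))) return(NULL)
    s <- summary(fit)$coefficients
    data.frame(gene_id = g, coef = s[1L, "coef"], p = s[1L, "Pr(>|z|)"],
               stringsAsFactors = FALSE)
  })
  dropped <- sum(vapply(rows, is.null, TRUE))
  if (dropped > 0)
    warning(dropped, " gene(s) dropped (constant or non-convergent)")
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(gene_id = character(0), coef = numeric(0),
                      p = numeric(0), keep = logical(0)))
  out$keep <- out$p < alpha
  rownames(out) <- NULL
  out
}

#' First-principal-component metagene score of a gene cluster
#'
#' Genes are z-scored across samples; samples are projected onto the first
#' principal component of the cluster submatrix.  The orientation is fixed
#' so the score correlates nonnegatively with the per-sample mean of the
#' cluster genes.
#'
#' @param expr Genes x samples matrix restricted to one gene cluster
#'   (>= 1 gene, no zero-variance gene).
#' @return Named per-sample score.
#' @export
pc1_score <- function(expr) {
  if (is.null(dim(expr))) expr <- matrix(expr, 1L, length(expr),
                                         dimnames = list("gene", names(expr)))
  z <- zscore_rows(expr)
  if (nrow(z) == 1L) {
    score <- z[1L, ]
  } else {
    pc <- stats::prcomp(t(z), center = FALSE, scale. = FALSE)
    score <- pc$x[, 1L]
  }
  if (stats::cor(score, colMeans(z)) < 0) score <- -score
  stats::setNames(as.vector(score), colnames(expr))
}

#' Build gene clusters with Cox-signed PC1 scores
#'
#' Consensus-clusters the supplied genes (1 - Pearson distance), computes
#' each cluster's PC1 metagene score, and assigns each cluster the sign of
#' the univariate Cox coefficient of its score.
#'
#' @param expr Genes x samples matrix restricted to the selected genes.
#' @param surv Survival data frame (\code{sample_id, time, event}).
#' @param k_range Candidate cluster counts (default 2:5).
#' @param k_override Optional fixed cluster count.
#' @param restrict_to Optional gene subset (e.g. the prognostic screen
#'   survivors) used for each cluster's PC1; clusters are still formed on
#'   all of \code{expr}.  A cluster with no retained member keeps all its
#'   members with a warning.
#' @param iterations,resample_frac,seed Consensus-clustering controls.
#' @return List of class \code{"gene_cluster_set"}: \code{clusters}
#'   (cluster id -> gene ids used for PC1), \code{all_members} (full
#'   cluster memberships), \code{pc1} (samples x clusters),
#'   \code{cox_sign} (named \code{"+"}/\code{"-"}), \code{cox_table}.
#' @export
build_gene_clusters <- function(expr, surv, k_range = 2:5, k_override = NULL,
                                restrict_to = NULL, iterations = 100L,
                                resample_frac = 0.8, seed = 1L) {
  check_matrix(expr, "expression")
  cc <- consensus_cluster(expr, k_range = k_range, iterations = iterations,
                          resample_frac = resample_frac,
                          distance = "pearson", k_override = k_override,
                          seed = seed)
  labels <- cc$labels
  ids <- paste0("G", sort(unique(labels)))
  all_members <- lapply(sort(unique(labels)),
                        function(c) names(labels)[labels == c])
  names(all_members) <- ids
  clusters <- all_members
  if (!is.null(restrict_to)) {
    clusters <- lapply(ids, function(cid) {
      kept <- intersect(all_members[[cid]], restrict_to)
      if (!length(kept)) {
        warning("cluster ", cid, " has no genes passing the screen; ",
                "keeping all members")
        all_members[[cid]]
      } else kept
    })
    names(clusters) <- ids
  }
  pc1 <- vapply(clusters, function(g)
    pc1_score(expr[g, , drop = FALSE]), numeric(ncol(expr)))
  rownames(pc1) <- colnames(expr)
  surv <- surv[match(colnames(expr), surv$sample_id), ]
  cox_rows <- lapply(ids, function(cid) {
    d <- data.frame(time = surv$time, event = surv$event, x = pc1[, cid])
    f <- cox_fit(d, "x")
    data.frame(cluster = cid, coef = f$table$coef, p = f$table$p,
               stringsAsFactors = FALSE)
  })
  cox_table <- do.call(rbind, cox_rows)
  cox_sign <- stats::setNames(ifelse(cox_table$coef >= 0, "+", "-"), ids)
  structure(list(clusters = clusters, all_members = all_members, pc1 = pc1,
                 cox_sign = cox_sign, cox_table = cox_table, consensus = cc),
            class = "gene_cluster_set")
}

#' Combine cluster scores into the TMEscore
#'
#' \code{score(s) = sum of PC1 over clusters with Cox sign "+" minus the
#' sum over clusters with sign "-"}.
#'
#' @param pc1 Samples x clusters matrix of PC1 scores.
#' @param cox_sign Named \code{"+"}/\code{"-"} per cluster.
#' @return Named per-sample TMEscore.
#' @export
compute_tmescore <- function(pc1, cox_sign) {
  if (inherits(pc1, "gene_cluster_set")) {
    cox_sign <- pc1$cox_sign
    pc1 <- pc1$pc1
  }
  if (is.null(names(cox_sign)) || !all(colnames(pc1) %in% names(cox_sign)))
    stop("every cluster needs a Cox sign")
  cox_sign <- cox_sign[colnames(pc1)]
  if (!all(cox_sign %in% c("+", "-"))) stop("Cox signs must be '+' or '-'")
  s <- ifelse(cox_sign == "+", 1, -1)
  stats::setNames(as.vector(pc1 %*% s), rownames(pc1))
}

#' Split scores into high/low groups at a cutoff
#'
#' @param score Named per-sample score.
#' @param cutoff Finite cutoff; \code{group = "high"} iff
#'   \code{score > cutoff}.
#' @return Data frame \code{sample_id, score, cutoff, group}.
#' @export
dichotomize <- function(score, cutoff) {
  if (!is.finite(cutoff)) stop("cutoff must be finite")
  if (cutoff >= max(score) || cutoff < min(score))
    warning("cutoff outside the score range: one group is empty")
  data.frame(sample_id = if (is.null(names(score)))
               as.character(seq_along(score)) else names(score),
             score = unname(score), cutoff = cutoff,
             group = ifelse(score > cutoff, "high", "low"),
             stringsAsFactors = FALSE)
}
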