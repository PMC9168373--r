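## Expression preprocessing: unit conversion, bad-gene filtering, KNN
## imputation, batch correction and the moderated-t differential front end.

#' Convert FPKM to TPM
#'
#' Per sample \code{j}: \code{tpm_ij = fpkm_ij / sum_i fpkm_ij * 1e6}, so
#' each column sums to one million.
#'
#' @param x Genes x samples FPKM matrix (nonnegative; missing entries
#'   \code{NA} are ignored in the column sums and propagated).
#' @return TPM matrix with unit attribute \code{"TPM"}.
#' @export
fpkm_to_tpm <- function(x) {
  check_matrix(x, "expression")
  if (any(x < 0, na.rm = TRUE)) stop("FPKM values must be nonnegative")
  cs <- colSums(x, na.rm = TRUE)
  if (any(cs == 0)) {
    bad <- colnames(x)[cs == 0]
    stop("all-zero sample column(s): ", paste(bad, collapse = ", "))
  }
  set_expr_unit(sweep(x, 2L, cs, "/") * 1e6, "TPM")
}

#' Remove genes dominated by missing or zero entries
#'
#' A gene is retained iff the fraction of its entries that are missing or
#' exactly zero is at most \code{max_bad_frac}; genes strictly above the
#' threshold are removed.  Samples are unchanged.
#'
#' @param x Expression matrix, missing entries \code{NA}.
#' @param max_bad_frac Maximum tolerated bad-entry fraction (default 0.7).
#' @return Filtered matrix.
#' @export
filter_genes <- function(x, max_bad_frac = 0.7) {
  check_matrix(x, "expression")
  bad <- (rowSums(is.na(x)) + rowSums(x == 0, na.rm = TRUE)) / ncol(x)
  keep <- bad <= max_bad_frac
  if (!any(keep))
    stop("no genes survive the bad-entry filter; review max_bad_frac")
  out <- x[keep, , drop = FALSE]
  attr(out, "unit") <- attr(x, "unit")
  out
}

#' K-nearest-neighbour imputation of missing expression
#'
#' Each missing entry (gene g, sample s) is replaced by the mean, at sample
#' s, of the k genes nearest to g in Euclidean distance computed over the
#' samples where both genes are observed (distance normalised per shared
#' sample count).  Only genes observed at sample s are candidate
#' neighbours.
#'
#' @param x Expression matrix with \code{NA} for missing.
#' @param k Number of neighbour genes (default 10).
#' @return Matrix with no missing entries.
#' @export
knn_impute <- function(x, k = 10L) {
  check_matrix(x, "expression")
  if (!anyNA(x)) return(x)
  na_row <- rowSums(is.na(x))
  if (any(na_row == ncol(x)))
    stop("cannot impute gene(s) with all entries missing: ",
         paste(utils::head(rownames(x)[na_row == ncol(x)], 5L), collapse = ", "))
  out <- x
  miss_genes <- which(na_row > 0L)
  obs <- !is.na(x)
  for (g in miss_genes) {
    xg <- x[g, ]
    ## squared distance to every other gene over shared observed samples
    diffs <- sweep(x, 2L, xg, "-")^2
    shared <- obs & matrix(obs[g, ], nrow(x), ncol(x), byrow = TRUE)
    nshared <- rowSums(shared)
    d2 <- rowSums(diffs * shared, na.rm = TRUE) / pmax(nshared, 1L)
    d2[g] <- Inf
    d2[nshared == 0L] <- Inf
    for (s in which(is.na(x[g, ]))) {
      cand <- which(is.finite(d2) & obs[, s])
      if (!length(cand))
        stop("no observed neighbours for gene ", rownames(x)[g],
             " at sample ", colnames(x)[s])
      nb <- cand[order(d2[cand])][seq_len(min(k, length(cand)))]
      out[g, s] <- mean(x[nb, s])
    }
  }
  out
}

#' Empirical-Bayes batch correction
#'
#' Location/scale ComBat adjustment (parametric empirical Bayes) on
#' log2-scale expression.  With a single batch the input is returned
#' unchanged.  Covariates supplied in \code{covariates} are protected by
#' inclusion in the standardization design.
#'
#' @param x Genes x samples log2-scale matrix.
#' @param batch Per-sample batch labels.
#' @param covariates Optional data frame of per-sample covariates to
#'   preserve.
#' @return Corrected matrix.
#' @export
combat_correct <- function(x, batch, covariates = NULL) {
  check_matrix(x, "expression")
  batch <- as.factor(batch)
  if (length(batch) != ncol(x)) stop("batch must have one label per sample")
  if (nlevels(batch) < 2L) return(x)
  if (any(table(batch) < 3L))
    warning("batches with < 3 samples: empirical-Bayes estimates unstable")
  mod <- NULL
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    mod <- stats::model.matrix(~., data = covariates)
    full <- stats::model.matrix(~batch + ., data = covariates)
    if (qr(full)$rank < ncol(full))
      stop("batch is confounded with a covariate column; cannot correct")
  }
  out <- tryCatch(
    suppressMessages(sva::ComBat(dat = x, batch = batch, mod = mod,
                                 par.prior = TRUE, prior.plots = FALSE)),
    error = function(e) stop("ComBat failed: ", conditionMessage(e)))
  attr(out, "unit") <- attr(x, "unit")
  out
}

#' Moderated-t differential expression between two groups
#'
#' Empirical-Bayes moderated t-statistics (limma) comparing tumor against
#' normal on log2-scale expression.  A gene is flagged as differentially
#' expressed iff BH-adjusted p < \code{fdr_cut} and |log2FC| >
#' \code{lfc_cut}.
#'
#' @param tumor,normal Log2-scale genes x samples matrices with identical
#'   gene sets and >= 2 samples each.
#' @param fdr_cut FDR threshold (default 0.05).
#' @param lfc_cut Absolute log2 fold-change threshold (default 1).
#' @return Data frame \code{gene_id, log2fc, moderated_t, p, fdr,
#'   direction, deg}.
#' @export
moderated_t_deg <- function(tumor, normal, fdr_cut = 0.05, lfc_cut = 1) {
  check_matrix(tumor, "tumor"); check_matrix(normal, "normal")
  if (!identical(rownames(tumor), rownames(normal)))
    stop("tumor and normal must share an identical gene set")
  if (ncol(tumor) < 2L || ncol(normal) < 2L)
    stop("need >= 2 samples per group")
  x <- cbind(tumor, normal)
  design <- cbind(Intercept = 1,
                  tumor = rep(c(1, 0), c(ncol(tumor), ncol(normal))))
  fit <- limma::eBayes(limma::lmFit(x, design))
  tt <- limma::topTable(fit, coef = "tumor", number = Inf, sort.by = "none")
  out <- data.frame(gene_id = rownames(x),
                    log2fc = tt$logFC, moderated_t = tt$t,
                    p = tt$P.Value, fdr = tt$adj.P.Val,
                    direction = ifelse(tt$logFC >= 0, "up", "down"),
                    stringsAsFactors = FALSE)
  out$deg <- out$fdr < fdr_cut & abs(out$log2fc) > lfc_cut
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg adjustment
#'
#' @param p Vector of p-values in [0, 1]; \code{NaN} is an error.
#' @return Adjusted values (step-up, capped at 1).
#' @export
bh_adjust <- function(p) {
  if (any(is.nan(p))) stop("NaN p-values")
  if (any(is.na(p))) stop("missing p-values")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
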