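## CIBERSORT-style immune-cell deconvolution: linear nu-support-vector
## regression of a standardized bulk mixture on standardized signature
## columns, over a small nu grid, keeping the best-reconstructing model.

#' Deconvolve one bulk mixture by nu-SVR
#'
#' The mixture and each signature column are z-scored over the shared gene
#' set; a linear nu-SVR is fitted for each value in \code{nus}; the model
#' with the lowest reconstruction RMSE is kept; negative coefficients are
#' clamped to zero and the remainder normalized to sum 1.
#'
#' @param mixture Named per-gene expression vector (linear scale).
#' @param signature Genes x cell-types signature matrix.
#' @param nus Grid of nu values (default 0.25, 0.5, 0.75).
#' @return List: \code{fractions} (named, sums to 1 unless degenerate),
#'   \code{rmse} and \code{pearson_r} of the reconstruction in the
#'   standardized space, \code{nu} chosen, \code{degenerate} flag.
#' @export
nusvr_deconvolve <- function(mixture, signature, nus = c(0.25, 0.5, 0.75)) {
  check_matrix(signature, "signature")
  if (ncol(signature) < 2L) stop("signature needs >= 2 cell types")
  if (!is.null(names(mixture))) {
    shared <- intersect(names(mixture), rownames(signature))
    mixture <- mixture[shared]
    signature <- signature[shared, , drop = FALSE]
  } else if (length(mixture) != nrow(signature)) {
    stop("unnamed mixture must match signature genes in length and order")
  }
  if (length(mixture) < 2L * ncol(signature))
    stop("need at least 2x more shared genes than cell types")
  X <- scale(signature)
  y <- as.vector(scale(mixture))
  best <- NULL
  for (nu in nus) {
    fit <- e1071::svm(X, y, type = "nu-regression", kernel = "linear",
                      nu = nu, cost = 1, scale = FALSE)
    w <- as.vector(t(fit$coefs) %*% fit$SV)
    recon <- as.vector(X %*% w) - fit$rho
    rmse <- sqrt(mean((recon - y)^2))
    if (is.null(best) || rmse < best$rmse)
      best <- list(w = w, rmse = rmse, r = stats::cor(recon, y), nu = nu)
  }
  w <- best$w
  w[w < 0] <- 0
  degenerate <- sum(w) == 0
  if (degenerate) {
    warning("all nu-SVR coefficients <= 0; returning all-zero fractions")
    fr <- w
  } else fr <- w / sum(w)
  names(fr) <- colnames(signature)
  list(fractions = fr, rmse = best$rmse, pearson_r = best$r, nu = best$nu,
       degenerate = degenerate)
}

#' Deconvolve every sample of an expression matrix
#'
#' @param x Genes x samples linear-scale (TPM) expression matrix.
#' @param signature Genes x cell-types signature matrix; at least half of
#'   its genes must be present in \code{x}.
#' @param nus Passed to \code{\link{nusvr_deconvolve}}.
#' @return List of class \code{"cell_fractions"}: \code{fractions}
#'   (samples x cell types), \code{rmse}, \code{pearson_r} per sample.
#' @export
deconvolve_matrix <- function(x, signature, nus = c(0.25, 0.5, 0.75)) {
  check_matrix(x, "expression"); check_matrix(signature, "signature")
  present <- rownames(signature) %in% rownames(x)
  if (mean(present) < 0.5) {
    missing <- rownames(signature)[!present]
    stop("only ", round(100 * mean(present)), "% of signature genes present; ",
         "missing e.g. ", paste(utils::head(missing, 5L), collapse = ", "))
  }
  res <- lapply(seq_len(ncol(x)), function(j) {
    m <- x[, j]
    names(m) <- rownames(x)
    nusvr_deconvolve(m[!is.na(m)], signature, nus = nus)
  })
  out <- list(
    fractions = do.call(rbind, lapply(res, `[[`, "fractions")),
    rmse = vapply(res, `[[`, 0, "rmse"),
    pearson_r = vapply(res, `[[`, 0, "pearson_r"))
  rownames(out$fractions) <- colnames(x)
  names(out$rmse) <- names(out$pearson_r) <- colnames(x)
  class(out) <- "cell_fractions"
  out
}
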