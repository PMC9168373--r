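#' @keywords internal
"_PACKAGE"

#' Read a genes-by-samples expression matrix from TSV
#'
#' The first column holds gene identifiers, the header row sample
#' identifiers.  Empty fields and the string \code{NA} are read as missing.
#'
#' @param path Path to a tab-separated file.
#' @param unit Expression unit tag attached to the result
#'   (\code{"FPKM"}, \code{"TPM"} or \code{"LOG2TPM"}).
#' @return Numeric matrix with gene rownames, sample colnames and an
#'   \code{"unit"} attribute.
#' @export
read_expression_tsv <- function(path, unit = "TPM") {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  if (ncol(df) < 2L) stop("expression TSV needs a gene-id column plus >= 1 sample")
  genes <- as.character(df[[1L]])
  if (anyDuplicated(genes)) stop("duplicate gene ids in ", path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  if (anyDuplicated(colnames(m))) stop("duplicate sample ids in ", path)
  set_expr_unit(m, unit)
}

#' Write an expression matrix as TSV
#'
#' @param x Numeric matrix, genes in rows.
#' @param path Output path.
#' @param id_col Name of the leading identifier column.
#' @export
write_expression_tsv <- function(x, path, id_col = "gene_id") {
  df <- data.frame(rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_expression_tsv
#' @param x Expression matrix.
#' @export
expr_unit <- function(x) {
  u <- attr(x, "unit")
  if (is.null(u)) NA_character_ else u
}

#' @rdname read_expression_tsv
#' @export
set_expr_unit <- function(x, unit) {
  unit <- match.arg(toupper(unit), c("FPKM", "TPM", "LOG2TPM"))
  attr(x, "unit") <- unit
  x
}

## Deterministic per-stage seed expansion: one global seed plus the stage
## name hash to a 31-bit integer, so stages can be rerun in isolation.
stage_seed <- function(global_seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(global_seed) * 7919 + h) %% 2147483647L)
}

check_matrix <- function(x, what = "matrix") {
  if (!is.matrix(x) || !is.numeric(x)) stop(what, " must be a numeric matrix")
  if (is.null(rownames(x))) stop(what, " must carry rownames")
  invisible(x)
}

## z-score rows (genes) across columns (samples); zero-variance rows error
## unless drop = TRUE, in which case they are removed with a warning.
zscore_rows <- function(x, drop = FALSE) {
  mu <- rowMeans(x)
  sd <- apply(x, 1L, stats::sd)
  zero <- sd == 0 | !is.finite(sd)
  if (any(zero)) {
    if (!drop) stop("zero-variance rows: ", paste(utils::head(rownames(x)[zero], 5L), collapse = ", "))
    warning(sum(zero), " zero-variance rows dropped before z-scoring")
    x <- x[!zero, , drop = FALSE]; mu <- mu[!zero]; sd <- sd[!zero]
  }
  (x - mu) / sd
}
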