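## MAF-based genomics: reader/writer, tumor mutational burden,
## group-wise differential mutation testing, and biomarker-combination
## survival stratification.

maf_required <- c("Hugo_Symbol", "Tumor_Sample_Barcode",
                  "Variant_Classification", "Variant_Type")

nonsilent_classes <- c("Missense_Mutation", "Nonsense_Mutation",
                       "Nonstop_Mutation", "Frame_Shift_Del",
                       "Frame_Shift_Ins", "In_Frame_Del", "In_Frame_Ins",
                       "Splice_Site", "Translation_Start_Site")

known_classes <- c(nonsilent_classes, "Silent", "Intron", "IGR", "RNA",
                   "3'UTR", "5'UTR", "3'Flank", "5'Flank")

#' Read a Mutation Annotation Format (MAF) file
#'
#' Tab-separated with a header; column lookup is case-insensitive and
#' extra columns are kept.  Comment lines starting with \code{#} are
#' skipped.
#'
#' @param path Path to the MAF file.
#' @return Data frame with at least the four standard columns.
#' @export
read_maf <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  lut <- stats::setNames(colnames(df), tolower(colnames(df)))
  for (col in maf_required) {
    hit <- lut[tolower(col)]
    if (is.na(hit)) stop("MAF is missing required column ", col)
    colnames(df)[colnames(df) == hit] <- col
  }
  df
}

#' @rdname read_maf
#' @param maf MAF data frame.
#' @export
write_maf <- function(maf, path) {
  utils::write.table(maf, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Tumor mutational burden from a MAF
#'
#' Per-sample count of non-silent variants (missense, nonsense, nonstop,
#' frameshift and in-frame indels, splice site, translation start site).
#' Unknown classifications are excluded with a warning.  Samples in
#' \code{samples} absent from the MAF get 0.
#'
#' @param maf MAF data frame.
#' @param samples Optional sample universe (default: barcodes in the MAF).
#' @param include Variant classifications counted as non-silent.
#' @return Named per-sample integer count.
#' @export
tmb_from_maf <- function(maf, samples = NULL,
                         include = nonsilent_classes) {
  if (is.null(samples)) samples <- unique(maf$Tumor_Sample_Barcode)
  unknown <- setdiff(unique(maf$Variant_Classification), known_classes)
  if (length(unknown))
    warning("unknown variant classification(s) excluded: ",
            paste(unknown, collapse = ", "))
  keep <- maf$Variant_Classification %in% include
  counts <- table(factor(maf$Tumor_Sample_Barcode[keep], levels = samples))
  stats::setNames(as.integer(counts), samples)
}

#' Differentially mutated genes between two score groups
#'
#' Per gene, the 2x2 table of mutated/wild-type by high/low group is
#' tested with \code{\link{fisher_2x2}}.  A sample counts as mutated in a
#' gene if it has any MAF row for that gene.  Barcodes without a group
#' label are dropped with a warning.
#'
#' @param maf MAF data frame.
#' @param groups Named per-sample labels \code{"high"}/\code{"low"}; the
#'   names define the sample universe.
#' @param p_cut Significance threshold (default 0.01).
#' @return Data frame \code{gene, n_high, n_low, freq_high, freq_low,
#'   odds_ratio, p, flagged}.
#' @export
mutation_compare <- function(maf, groups, p_cut = 0.01) {
  if (is.null(names(groups))) stop("groups must be named by sample")
  if (!all(groups %in% c("high", "low"))) stop("groups must be 'high'/'low'")
  unmapped <- !(maf$Tumor_Sample_Barcode %in% names(groups))
  if (any(unmapped)) {
    warning(sum(unmapped), " MAF row(s) with unmapped barcodes dropped")
    maf <- maf[!unmapped, , drop = FALSE]
  }
  n_high <- sum(groups == "high"); n_low <- sum(groups == "low")
  genes <- unique(maf$Hugo_Symbol)
  rows <- lapply(genes, function(g) {
    mut <- unique(maf$Tumor_Sample_Barcode[maf$Hugo_Symbol == g])
    if (!length(mut)) return(NULL)
    mh <- sum(groups[mut] == "high"); ml <- sum(groups[mut] == "low")
    ft <- fisher_2x2(matrix(c(mh, n_high - mh, ml, n_low - ml), 2L))
    data.frame(gene = g, n_high = mh, n_low = ml,
               freq_high = mh / n_high, freq_low = ml / n_low,
               odds_ratio = ft$odds_ratio, p = ft$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(gene = character(0), n_high = integer(0),
                      n_low = integer(0), freq_high = numeric(0),
                      freq_low = numeric(0), odds_ratio = numeric(0),
                      p = numeric(0), flagged = logical(0)))
  out$flagged <- out$p < p_cut
  out[order(out$p), ]
}

#' Survival stratification by score group and a second biomarker
#'
#' Splits samples into four strata (score high/low by marker high/low,
#' marker split at the cohort median unless a cutoff is given) and runs an
#' overall log-rank test across the nonempty strata.  An optional
#' categorical outcome is cross-tabulated against the strata (Fisher when
#' feasible, chi-square otherwise).
#'
#' @param score_group Per-sample \code{"high"}/\code{"low"}.
#' @param marker Per-sample numeric biomarker (defined for all samples).
#' @param time,event Survival data.
#' @param marker_cutoff Optional cutoff; default the median
#'   (\code{marker > median} is "high").
#' @param response Optional per-sample categorical outcome
#'   (e.g. CR/PR/SD/PD).
#' @return List \code{strata} (per-sample labels), \code{logrank},
#'   \code{response_table}, \code{response_p}.
#' @export
stratify_combination <- function(score_group, marker, time, event,
                                 marker_cutoff = NULL, response = NULL) {
  if (anyNA(marker)) stop("marker must be defined for all samples")
  if (!all(score_group %in% c("high", "low")))
    stop("score_group must be 'high'/'low'")
  if (is.null(marker_cutoff)) marker_cutoff <- stats::median(marker)
  mk <- ifelse(marker > marker_cutoff, "marker-high", "marker-low")
  strata <- paste(paste0("score-", score_group), mk, sep = "/")
  present <- unique(strata)
  if (length(present) < 4L)
    warning("only ", length(present), " nonempty strata; testing those")
  lr <- logrank_test(strata, time, event)
  response_table <- NULL; response_p <- NULL
  if (!is.null(response)) {
    response_table <- table(strata, response)
    response_p <- tryCatch(stats::fisher.test(response_table)$p.value,
                           error = function(e)
                             suppressWarnings(stats::chisq.test(response_table)$p.value))
  }
  list(strata = stats::setNames(strata, names(score_group)),
       logrank = lr, response_table = response_table,
       response_p = response_p)
}
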