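## Gene-set machinery: GMT IO, phenotype-permutation GSEA with
## signal-to-noise ranking, hypergeometric over-representation and the
## 2x2 Fisher test used for mutation comparison.

#' Read a GMT gene-set file
#'
#' @param path Tab-separated GMT: name, description, genes...
#' @return Named list of deduplicated gene-id vectors with a
#'   \code{"descriptions"} attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stop("GMT line ", short[1L], " has fewer than 3 fields")
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, "", 1L)
  attr(sets, "descriptions") <- stats::setNames(
    vapply(fields, `[[`, "", 2L), names(sets))
  sets
}

#' Write a GMT gene-set file
#'
#' @param sets Named list of gene-id vectors.
#' @param path Output path.
#' @param descriptions Optional named descriptions (defaults to the
#'   attribute set by \code{\link{read_gmt}}, else \code{"na"}).
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- attr(sets, "descriptions")
  if (is.null(descriptions))
    descriptions <- stats::setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, descriptions[[nm]], sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

## signal-to-noise ranking metric with the Broad-style sd floor
snr_metric <- function(expr, pos) {
  m1 <- rowMeans(expr[, pos, drop = FALSE])
  m0 <- rowMeans(expr[, !pos, drop = FALSE])
  s1 <- apply(expr[, pos, drop = FALSE], 1L, stats::sd)
  s0 <- apply(expr[, !pos, drop = FALSE], 1L, stats::sd)
  floor_sd <- function(s, m) pmax(s, pmax(0.2 * abs(m), 0.2))
  (m1 - m0) / (floor_sd(s1, m1) + floor_sd(s0, m0))
}

#' Running-sum enrichment score
#'
#' Genes are ranked by \code{metric} (decreasing); the running sum gains
#' \code{|metric|^weight} (normalized) at set members and loses
#' \code{1/(G - Nh)} elsewhere; ES is the maximum deviation from zero.
#' With \code{weight = 0} this is the classical Kolmogorov-Smirnov
#' statistic on the set indicator.
#'
#' @param metric Named per-gene ranking metric.
#' @param set Gene ids of the set.
#' @param weight Hit-increment exponent (default 1).
#' @return Scalar ES in [-1, 1].
#' @export
enrichment_score <- function(metric, set, weight = 1) {
  ord <- order(metric, decreasing = TRUE)
  m <- metric[ord]
  hit <- names(m) %in% set
  if (!any(hit) || all(hit)) stop("set must be a proper nonempty subset")
  w <- abs(m)^weight
  p_hit <- ifelse(hit, w, 0)
  sw <- sum(p_hit)
  if (sw == 0) p_hit <- ifelse(hit, 1 / sum(hit), 0) else p_hit <- p_hit / sw
  p_miss <- ifelse(hit, 0, 1 / sum(!hit))
  running <- cumsum(p_hit - p_miss)
  running[which.max(abs(running))]
}

## ES for many sets at once; hit_mat is genes x sets logical in the
## original gene order.
es_batch <- function(metric, hit_mat, weight = 1) {
  ord <- order(metric, decreasing = TRUE)
  m <- metric[ord]
  H <- hit_mat[ord, , drop = FALSE]
  w <- abs(m)^weight
  W <- H * w
  sw <- colSums(W)
  sw[sw == 0] <- 1
  sizes <- colSums(H)
  step <- sweep(W, 2L, sw, "/") -
    sweep((!H) * 1, 2L, length(m) - sizes, "/")
  cs <- apply(step, 2L, cumsum)
  idx <- max.col(t(abs(cs)), ties.method = "first")
  cs[cbind(idx, seq_len(ncol(cs)))]
}

#' Gene-set enrichment analysis with phenotype permutation
#'
#' Genes are ranked by signal-to-noise between the two phenotype classes;
#' the running-sum ES is normalized (NES) by the mean of same-sign
#' permutation ESs under phenotype-label permutation; nominal p comes from
#' the same-sign permutation tail and FDR q from the permutation NES-ratio
#' procedure.
#'
#' @param expr Genes x samples expression matrix (log2 scale recommended).
#' @param phenotype Two-class per-sample labels; both classes need >= 3
#'   samples.
#' @param sets Named list of gene sets (see \code{\link{read_gmt}}).
#' @param positive_class Class treated as the "high" side; default the
#'   first factor level.
#' @param n_perm Number of phenotype permutations (default 1000).
#' @param weight Hit-increment exponent (default 1).
#' @param min_size,max_size Set-size window after intersection with the
#'   expressed genes (defaults 15 and 500); out-of-window sets are skipped
#'   with a warning.
#' @param seed RNG seed.
#' @return Data frame \code{set, size, es, nes, nominal_p, fdr_q,
#'   direction}.
#' @export
gsea <- function(expr, phenotype, sets, positive_class = NULL,
                 n_perm = 1000L, weight = 1, min_size = 15L, max_size = 500L,
                 seed = 1L) {
  check_matrix(expr, "expression")
  phenotype <- as.factor(as.character(phenotype))
  if (nlevels(phenotype) != 2L) stop("phenotype must have exactly 2 classes")
  if (any(table(phenotype) < 3L)) stop("both classes need >= 3 samples")
  if (is.null(positive_class)) positive_class <- levels(phenotype)[1L]
  pos <- phenotype == positive_class
  genes <- rownames(expr)
  sets <- lapply(sets, intersect, genes)
  sizes <- lengths(sets)
  drop <- sizes < min_size | sizes > max_size
  if (any(drop)) {
    warning(sum(drop), " set(s) outside [", min_size, ", ", max_size,
            "] after intersection; skipped")
    sets <- sets[!drop]
  }
  if (!length(sets)) stop("no gene sets left to test")
  hit_mat <- vapply(sets, function(s) genes %in% s, logical(length(genes)))

  metric <- snr_metric(expr, pos)
  names(metric) <- genes
  es <- es_batch(metric, hit_mat, weight)

  set.seed(seed)
  perm_es <- matrix(0, n_perm, length(sets))
  for (b in seq_len(n_perm)) {
    pm <- snr_metric(expr, sample(pos))
    names(pm) <- genes
    perm_es[b, ] <- es_batch(pm, hit_mat, weight)
  }

  nes <- numeric(length(sets))
  nominal_p <- numeric(length(sets))
  perm_nes <- perm_es
  for (j in seq_along(sets)) {
    pe <- perm_es[, j]
    mpos <- mean(pe[pe >= 0]); mneg <- mean(abs(pe[pe < 0]))
    if (!is.finite(mpos) || mpos == 0) mpos <- 1
    if (!is.finite(mneg) || mneg == 0) mneg <- 1
    perm_nes[, j] <- ifelse(pe >= 0, pe / mpos, pe / mneg)
    if (es[j] >= 0) {
      tail_es <- pe[pe >= 0]
      nes[j] <- es[j] / mpos
      nominal_p[j] <- (1 + sum(tail_es >= es[j])) / (1 + length(tail_es))
    } else {
      tail_es <- pe[pe < 0]
      nes[j] <- es[j] / mneg
      nominal_p[j] <- (1 + sum(tail_es <= es[j])) / (1 + length(tail_es))
    }
  }

  ## FDR q: ratio of permutation to observed NES tail fractions
  all_perm <- as.vector(perm_nes)
  fdr_q <- vapply(seq_along(sets), function(j) {
    if (nes[j] >= 0) {
      num <- sum(all_perm >= nes[j]) / max(sum(all_perm >= 0), 1L)
      den <- sum(nes >= nes[j]) / max(sum(nes >= 0), 1L)
    } else {
      num <- sum(all_perm <= nes[j]) / max(sum(all_perm < 0), 1L)
      den <- sum(nes <= nes[j]) / max(sum(nes < 0), 1L)
    }
    min(1, num / max(den, .Machine$double.eps))
  }, 0)

  data.frame(set = names(sets), size = lengths(sets), es = es, nes = nes,
             nominal_p = nominal_p, fdr_q = fdr_q,
             direction = ifelse(es >= 0, "high-enriched", "low-enriched"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Hypergeometric over-representation analysis
#'
#' Upper-tail hypergeometric p of each set's overlap with the hit list,
#' BH-adjusted; significant iff adjusted p < \code{adj_p_cut}.
#'
#' @param hits Nonempty gene list, a subset of \code{universe}.
#' @param universe Background gene list.
#' @param sets Named list of gene sets.
#' @param adj_p_cut Adjusted-p threshold (default 0.2).
#' @return Data frame \code{set, size, overlap, p, adj_p, significant}.
#' @export
ora_hypergeom <- function(hits, universe, sets, adj_p_cut = 0.2) {
  hits <- unique(hits)
  universe <- unique(universe)
  if (!length(hits)) stop("empty hit list")
  if (!all(hits %in% universe)) stop("hits must be a subset of the universe")
  N <- length(universe)
  n <- length(hits)
  res <- lapply(names(sets), function(nm) {
    K <- length(intersect(sets[[nm]], universe))
    k <- length(intersect(sets[[nm]], hits))
    p <- if (K == 0) 1 else
      stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, size = K, overlap = k, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$adj_p <- bh_adjust(out$p)
  out$significant <- out$adj_p < adj_p_cut
  out
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Two-sided p by the minimum-likelihood rule (probabilities of all tables
#' with the same margins not exceeding the observed one are summed).  The
#' odds ratio is the sample odds ratio \code{ad/bc} (\code{Inf} or 0 with
#' zero cells), not the conditional MLE.
#'
#' @param tab 2x2 matrix of nonnegative integer counts.
#' @return List \code{odds_ratio}, \code{p}.
#' @export
fisher_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == 2L)) stop("need a 2x2 table")
  if (any(tab < 0) || any(tab != round(tab))) stop("counts must be nonnegative integers")
  p <- stats::fisher.test(tab)$p.value
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  list(odds_ratio = or, p = min(p, 1))
}
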