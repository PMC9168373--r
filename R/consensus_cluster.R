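## Resampling-based consensus clustering with CDF-area model selection.
## Used for samples (Euclidean on cell-fraction rows) and for genes
## (1 - Pearson on z-scored expression).

item_dist <- function(data, distance) {
  switch(distance,
         euclidean = stats::dist(data),
         pearson = stats::as.dist(1 - stats::cor(t(data))),
         stop("unknown distance: ", distance))
}

#' Consensus matrix for one cluster count
#'
#' For each iteration a fraction of items is subsampled without
#' replacement, hierarchically clustered, and cut at k; consensus(i, j) is
#' the number of times i and j co-clustered divided by the number of times
#' both were sampled.  Pairs never co-sampled get 0 (counted in the
#' \code{"never_cosampled"} attribute); the diagonal is 1.
#'
#' @param data Items x features numeric matrix.
#' @param k Cluster count, \code{2 <= k < nrow(data)}.
#' @param iterations Number of resampling iterations (default 100).
#' @param resample_frac Subsample fraction (default 0.8).
#' @param distance \code{"euclidean"} or \code{"pearson"} (1 - correlation).
#' @param linkage Hierarchical linkage (default \code{"ward.D2"}, which
#'   resists splitting off outlier singletons on resampled data).
#' @param seed RNG seed.
#' @return Symmetric items x items matrix in [0, 1].
#' @export
consensus_matrix <- function(data, k, iterations = 100L, resample_frac = 0.8,
                             distance = c("euclidean", "pearson"),
                             linkage = "ward.D2", seed = 1L) {
  distance <- match.arg(distance)
  n <- nrow(data)
  if (k < 2L || k >= n) stop("need 2 <= k < number of items")
  set.seed(seed)
  co <- matrix(0, n, n)
  cnt <- matrix(0, n, n)
  m <- ceiling(resample_frac * n)
  for (it in seq_len(iterations)) {
    idx <- sample.int(n, m)
    h <- stats::hclust(item_dist(data[idx, , drop = FALSE], distance),
                       method = linkage)
    lab <- stats::cutree(h, k)
    cnt[idx, idx] <- cnt[idx, idx] + 1
    for (c in unique(lab)) {
      mem <- idx[lab == c]
      co[mem, mem] <- co[mem, mem] + 1
    }
  }
  never <- sum(cnt[upper.tri(cnt)] == 0)
  cm <- ifelse(cnt > 0, co / cnt, 0)
  diag(cm) <- 1
  dimnames(cm) <- list(rownames(data), rownames(data))
  attr(cm, "never_cosampled") <- never
  if (never > 0)
    warning(never, " item pair(s) never co-sampled; consensus set to 0")
  cm
}

#' Empirical CDF of consensus values and its area
#'
#' CDF of the upper-triangle entries on a fixed grid of 101 points in
#' [0, 1]; area by the trapezoid rule.
#'
#' @param cm Consensus matrix.
#' @return List \code{grid}, \code{cdf}, \code{area}.
#' @export
cdf_area <- function(cm) {
  v <- cm[upper.tri(cm)]
  grid <- seq(0, 1, length.out = 101L)
  cdf <- vapply(grid, function(g) mean(v <= g), 0)
  area <- sum(diff(grid) * (utils::head(cdf, -1L) + utils::tail(cdf, -1L)) / 2)
  list(grid = grid, cdf = cdf, area = area)
}

#' Choose the cluster count from CDF areas
#'
#' Relative area increase \code{delta(k) = (A(k) - A(k-1)) / A(k-1)} with
#' \code{delta(2) = A(2)}; k grows while every step still adds at least
#' \code{delta_threshold} relative area, and the chosen k is the last one
#' before the first step that falls short (the elbow of the CDF-area
#' curve).  Splitting a real cluster keeps adding small amounts of area,
#' so the first sub-threshold step -- not the last super-threshold one --
#' marks the true cluster count.  If no k qualifies or the areas are
#' pathological the k with maximal delta is returned with a warning.
#'
#' @param areas Per-k CDF areas for consecutive k starting at
#'   \code{k_range[1]}.
#' @param k_range Integer vector of consecutive k (first must be 2).
#' @param delta_threshold Relative-increase threshold (default 0.1).
#' @return Chosen k.
#' @export
select_k <- function(areas, k_range, delta_threshold = 0.1) {
  if (length(areas) != length(k_range))
    stop("areas and k_range must align")
  if (k_range[1L] != 2L || any(diff(k_range) != 1L))
    stop("k_range must be consecutive integers starting at 2")
  delta <- c(areas[1L], diff(areas) / utils::head(areas, -1L))
  ok <- is.finite(delta) & delta >= delta_threshold
  if (!any(ok)) {
    warning("no k reaches the delta threshold; falling back to max delta")
    return(k_range[which.max(delta)])
  }
  run <- cumprod(ok) == 1          # leading run of super-threshold steps
  if (!run[1L]) {
    warning("first delta below threshold; falling back to max delta")
    return(k_range[which.max(delta)])
  }
  k_range[max(which(run))]
}

#' Final partition from a consensus matrix
#'
#' Hierarchical clustering of 1 - consensus as a distance, cut at k;
#' cluster ids are renumbered by decreasing cluster size.
#'
#' @param cm Consensus matrix.
#' @param k Number of clusters.
#' @param linkage Linkage (default \code{"average"}).
#' @return Integer labels named by item.
#' @export
assign_clusters <- function(cm, k, linkage = "average") {
  if (k >= nrow(cm)) stop("k must be smaller than the number of items")
  h <- stats::hclust(stats::as.dist(1 - cm), method = linkage)
  lab <- stats::cutree(h, k)
  sizes <- sort(table(lab), decreasing = TRUE)
  relabel <- stats::setNames(seq_along(sizes), names(sizes))
  out <- relabel[as.character(lab)]
  names(out) <- rownames(cm)
  out
}

#' Full consensus-clustering scan over a k range
#'
#' @inheritParams consensus_matrix
#' @param k_range Consecutive k values starting at 2 (default 2:7).
#' @param delta_threshold Passed to \code{\link{select_k}}.
#' @param k_override Optional manual k honored over the CDF rule.
#' @return List of class \code{"consensus_result"}: \code{k_range},
#'   \code{consensus_matrices}, \code{cdf_areas}, \code{chosen_k},
#'   \code{labels}.
#' @export
consensus_cluster <- function(data, k_range = 2:7, iterations = 100L,
                              resample_frac = 0.8,
                              distance = c("euclidean", "pearson"),
                              linkage = "ward.D2", delta_threshold = 0.1,
                              k_override = NULL, seed = 1L) {
  distance <- match.arg(distance)
  if (distance == "pearson") data <- zscore_rows(data, drop = TRUE)
  cms <- lapply(seq_along(k_range), function(i)
    consensus_matrix(data, k_range[i], iterations, resample_frac, distance,
                     linkage, seed = stage_seed(seed, paste0("k", k_range[i]))))
  areas <- vapply(cms, function(cm) cdf_area(cm)$area, 0)
  chosen <- if (!is.null(k_override)) as.integer(k_override) else
    select_k(areas, k_range, delta_threshold)
  labels <- assign_clusters(cms[[match(chosen, k_range)]], chosen, linkage)
  structure(list(k_range = k_range, consensus_matrices = cms,
                 cdf_areas = areas, chosen_k = chosen, labels = labels),
            class = "consensus_result")
}
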