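## Survival and association statistics: Kaplan-Meier, log-rank, Cox
## (Efron ties), maximally selected rank cutpoint, Wilcoxon and Spearman.

check_surv <- function(time, event) {
  if (length(time) != length(event)) stop("time and event must align")
  if (any(!is.finite(time)) || any(time <= 0)) stop("survival times must be positive")
  if (!all(event %in% c(0, 1))) stop("event must be 0/1")
  invisible(NULL)
}

#' Kaplan-Meier estimate
#'
#' Product-limit estimator; the median is the smallest time with
#' \code{S(t) <= 0.5}, \code{NA} if never reached.
#'
#' @param time Positive times (days).
#' @param event Event indicator, 1 = death.
#' @return List \code{time}, \code{surv}, \code{n_risk}, \code{n_event},
#'   \code{median}.
#' @export
km_estimate <- function(time, event) {
  check_surv(time, event)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  med <- if (any(fit$surv <= 0.5)) fit$time[which(fit$surv <= 0.5)[1L]] else NA_real_
  list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
       n_event = fit$n.event, median = med)
}

#' Multi-group log-rank test
#'
#' @param group Per-sample group labels (>= 2 nonempty groups).
#' @param time,event Survival data.
#' @return List \code{chi2}, \code{df}, \code{p}.
#' @export
logrank_test <- function(group, time, event) {
  check_surv(time, event)
  group <- as.factor(as.character(group))
  if (nlevels(group) < 2L) stop("need >= 2 nonempty groups")
  if (sum(event) == 0) return(list(chi2 = 0, df = nlevels(group) - 1L, p = 1))
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- nlevels(group) - 1L
  list(chi2 = unname(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Cox proportional hazards fit (Efron ties)
#'
#' Wald confidence intervals and p-values per term, plus the score test of
#' the whole model.
#'
#' @param data Data frame containing \code{time}, \code{event} and the
#'   covariates in \code{terms}.
#' @param terms Character vector of covariate names.
#' @param time_col,event_col Column names of time and event.
#' @return List of class \code{"cox_fit"}: \code{table} (term, coef, hr,
#'   lo95, hi95, p), \code{score_chi2}, \code{loglik}, \code{converged}.
#' @export
cox_fit <- function(data, terms, time_col = "time", event_col = "event") {
  check_surv(data[[time_col]], data[[event_col]])
  if (sum(data[[event_col]]) == 0) stop("need >= 1 event")
  fml <- stats::as.formula(paste0("survival::Surv(", time_col, ", ", event_col,
                                  ") ~ ", paste(terms, collapse = " + ")))
  fit <- tryCatch(survival::coxph(fml, data = data, ties = "efron"),
                  error = function(e) stop("Cox fit failed: ", conditionMessage(e)))
  s <- summary(fit)
  converged <- is.finite(fit$loglik[2L]) && !any(is.na(stats::coef(fit))) &&
    all(abs(stats::coef(fit)) < 15)
  tab <- data.frame(term = rownames(s$coefficients),
                    coef = s$coefficients[, "coef"],
                    hr = s$coefficients[, "exp(coef)"],
                    lo95 = s$conf.int[, "lower .95"],
                    hi95 = s$conf.int[, "upper .95"],
                    p = s$coefficients[, "Pr(>|z|)"],
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(table = tab, score_chi2 = unname(s$sctest["test"]),
                 loglik = fit$loglik, converged = converged),
            class = "cox_fit")
}

## signed standardized two-group log-rank statistic for a high/low split
signed_logrank_z <- function(high, time, event) {
  sd <- survival::survdiff(survival::Surv(time, event) ~ high)
  z <- sqrt(sd$chisq)
  ## positive when the high group has more events than expected
  sign(sd$obs[2L] - sd$exp[2L]) * z
}

#' Maximally selected rank cutpoint
#'
#' Scans candidate cutoffs (the observed score values leaving at least
#' \code{minprop} of the samples on each side) and returns the cutoff
#' maximizing the absolute standardized two-group log-rank statistic.
#' Ties are broken toward the median score.
#'
#' @param score Per-sample numeric score.
#' @param time,event Survival data.
#' @param minprop Minimum proportion of samples on each side (default 0.1).
#' @return List \code{cutoff}, \code{statistic} (signed z at the cutoff).
#' @export
optimal_cutpoint <- function(score, time, event, minprop = 0.1) {
  check_surv(time, event)
  if (length(unique(score)) < 2L) stop("all scores equal; no cutpoint")
  if (sum(event) < 20L) warning("fewer than 20 events; cutpoint unstable")
  n <- length(score)
  ord <- sort(unique(score))
  ## candidate cutoffs: split at c means high iff score > c
  cands <- ord[vapply(ord, function(c) {
    nh <- sum(score > c); nl <- n - nh
    nh >= ceiling(minprop * n) && nl >= ceiling(minprop * n)
  }, TRUE)]
  if (!length(cands)) stop("no candidate cutoffs satisfy minprop")
  zs <- vapply(cands, function(c)
    signed_logrank_z(factor(score > c, levels = c(FALSE, TRUE)), time, event), 0)
  best <- abs(zs) >= max(abs(zs)) - 1e-12
  med <- stats::median(score)
  pick <- which(best)[which.min(abs(cands[best] - med))]
  list(cutoff = cands[pick], statistic = zs[pick])
}

#' Wilcoxon rank-sum test
#'
#' Exact two-sided p for \code{min(n) <= 8} without ties, otherwise the
#' normal approximation with tie correction.
#'
#' @param x,y Nonempty numeric samples.
#' @return List \code{U}, \code{p}.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be nonempty")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- min(length(x), length(y)) <= 8L && !ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = !exact))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Spearman rank correlation
#'
#' Pearson correlation of midranks with a t-approximation p-value.
#'
#' @param x,y Numeric vectors, \code{n >= 3}, non-constant.
#' @return List \code{rho}, \code{p}.
#' @export
spearman_corr <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) stop("need aligned n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant input")
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}
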