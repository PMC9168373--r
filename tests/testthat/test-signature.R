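planted_expr <- function(n = 120L, n_genes = 200L, n_inf = 5L, effect = 1.5,
                         seed = 1L, n_subtypes = 4L) {
  set.seed(seed)
  sub <- sample(rep(seq_len(n_subtypes), length.out = n))
  X <- matrix(rnorm(n_genes * n), n_genes, n,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("s%03d", seq_len(n))))
  for (g in seq_len(n_inf))
    X[g, ] <- X[g, ] + effect * seq_len(n_subtypes)[sub]
  list(expr = X, subtype = sub)
}

test_that("stability selection finds planted informative genes", {
  d <- planted_expr(n = 100L, n_genes = 120L, n_inf = 3L, effect = 2,
                    seed = 3L)
  sel <- rf_stability_select(d$expr, d$subtype, n_runs = 25L,
                             per_run_top = 20L, seed = 3L)
  inf <- sprintf("g%03d", 1:3)
  expect_true(all(sel$selected[sel$gene_id %in% inf]))
  expect_true(all(sel$selection_count[sel$gene_id %in% inf] == 25L))
  ## the selected flag implements the inclusive >= 80% rule
  expect_identical(sel$selected, sel$selection_count >= 0.8 * 25L)
  expect_lte(sum(sel$selected) - 3L, 2L)
})

test_that("pure-noise genes do not reach the repetition threshold", {
  for (s in 1:2) {
    set.seed(s)
    X <- matrix(rnorm(150 * 80), 150, 80,
                dimnames = list(sprintf("g%03d", 1:150), sprintf("s%02d", 1:80)))
    sub <- rep(1:4, each = 20)
    sel <- rf_stability_select(X, sub, n_runs = 25L, per_run_top = 15L,
                               seed = s)
    expect_lte(sum(sel$selected), 2L)
  }
})

test_that("constant genes are dropped with a warning before fitting", {
  d <- planted_expr(n = 60L, n_genes = 50L, seed = 7L)
  d$expr[10, ] <- 3
  expect_warning(
    sel <- rf_stability_select(d$expr, d$subtype, n_runs = 5L,
                               per_run_top = 10L, seed = 7L),
    "constant")
  expect_false("g010" %in% sel$gene_id)
})

test_that("prognostic screen keeps hazard-linked genes with the right sign", {
  set.seed(11)
  n <- 300L
  latent <- rnorm(n)
  sv <- simulate_survival(latent, log_hr = 1, baseline_rate = 1e-3,
                          censoring_rate = 0.2, seed = 11L)
  expr <- rbind(risk = latent + rnorm(n, sd = 0.1),
                protective = -latent + rnorm(n, sd = 0.1),
                noise = rnorm(n))
  colnames(expr) <- sv$sample_id
  scr <- screen_prognostic(expr, sv)
  expect_true(scr$keep[scr$gene_id == "risk"])
  expect_gt(scr$coef[scr$gene_id == "risk"], 0)
  expect_true(scr$keep[scr$gene_id == "protective"])
  expect_lt(scr$coef[scr$gene_id == "protective"], 0)
})

test_that("prognostic screen has ~5% type-I error and drops constants", {
  set.seed(13)
  n <- 150L
  sv <- simulate_survival(rep(0, n), log_hr = 0, baseline_rate = 1e-3,
                          censoring_rate = 0.2, seed = 13L)
  expr <- matrix(rnorm(400 * n), 400, n,
                 dimnames = list(sprintf("g%03d", 1:400), sv$sample_id))
  scr <- screen_prognostic(expr, sv)
  expect_gt(mean(scr$keep), 0.01)
  expect_lt(mean(scr$keep), 0.10)

  expr[5, ] <- 1
  expect_warning(scr2 <- screen_prognostic(expr, sv), "dropped")
  expect_false("g005" %in% scr2$gene_id)
})

test_that("pc1_score matches direct eigendecomposition", {
  set.seed(17)
  expr <- matrix(rnorm(10 * 40), 10, 40,
                 dimnames = list(sprintf("g%d", 1:10), sprintf("s%d", 1:40)))
  score <- pc1_score(expr)
  ## oracle: project onto the leading eigenvector of the gene covariance
  z <- t(scale(t(expr)))
  v <- eigen(stats::cov(t(z)))$vectors[, 1]
  oracle <- as.vector(t(z) %*% v)
  if (stats::cor(oracle, colMeans(z)) < 0) oracle <- -oracle
  expect_lt(max(abs(unname(score) - oracle)), 1e-8)

  ## single gene: the z-scored gene itself
  one <- pc1_score(expr[1, , drop = FALSE])
  expect_equal(unname(one), as.vector(scale(expr[1, ])), tolerance = 1e-12)

  ## two perfectly correlated genes: PC1 explains everything
  two <- rbind(a = expr[1, ], b = 2 * expr[1, ] + 3)
  s2 <- pc1_score(two)
  expect_equal(abs(stats::cor(s2, expr[1, ])), 1, tolerance = 1e-10)

  expect_error(pc1_score(matrix(1, 2, 5,
                                dimnames = list(c("a", "b"), 1:5))),
               "zero-variance")
})

test_that("compute_tmescore follows the signed-sum formula", {
  pc1 <- cbind(G1 = c(1.5, 0.2), G2 = c(0.5, 0.3))
  rownames(pc1) <- c("s1", "s2")
  expect_equal(unname(compute_tmescore(pc1, c(G1 = "+", G2 = "-"))),
               c(1.0, -0.1))
  expect_equal(unname(compute_tmescore(cbind(G1 = c(0.2), G2 = c(0.3)),
                                       c(G1 = "-", G2 = "-"))), -0.5)
  ## invariant to cluster ordering
  expect_equal(compute_tmescore(pc1[, c(2, 1)], c(G1 = "+", G2 = "-")),
               compute_tmescore(pc1, c(G1 = "+", G2 = "-")))
  expect_error(compute_tmescore(pc1, c(G1 = "+")), "Cox sign")
})

test_that("flipping the survival effect flips the cluster contribution", {
  set.seed(19)
  n <- 250L
  latent <- stats::setNames(rnorm(n), sprintf("S%04d", 1:n))
  expr <- do.call(rbind, lapply(1:6, function(i) latent + rnorm(n, sd = 0.2)))
  rownames(expr) <- sprintf("m%d", 1:6)
  colnames(expr) <- names(latent)
  noise <- matrix(rnorm(6 * n), 6, n,
                  dimnames = list(sprintf("x%d", 1:6), colnames(expr)))
  for (dir in c(1, -1)) {
    sv <- simulate_survival(dir * latent, log_hr = 1, baseline_rate = 1e-3,
                            censoring_rate = 0.2, seed = 19L)
    gcs <- build_gene_clusters(rbind(expr, noise), sv, k_override = 2L,
                               seed = 19L)
    mod_cluster <- names(which(vapply(gcs$all_members, function(g)
      "m1" %in% g, TRUE)))
    sign_expected <- if (dir > 0) "+" else "-"
    expect_identical(unname(gcs$cox_sign[mod_cluster]), sign_expected)
    score <- compute_tmescore(gcs)
    expect_gt(stats::cor(score, dir * latent), 0)
  }
})

test_that("dichotomize applies the cutoff rule and is idempotent", {
  sc <- stats::setNames(c(-1, 0, 1), c("a", "b", "c"))
  tab <- dichotomize(sc, -0.92)
  expect_identical(tab$group, c("low", "high", "high"))
  all_low <- suppressWarnings(dichotomize(sc, max(sc)))
  expect_true(all(all_low$group == "low"))
  tab2 <- dichotomize(stats::setNames(tab$score, tab$sample_id), -0.92)
  expect_identical(tab2$group, tab$group)
  expect_warning(dichotomize(sc, 5), "outside")
})
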