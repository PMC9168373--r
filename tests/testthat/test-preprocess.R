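test_that("fpkm_to_tpm applies the column-normalization formula", {
  m <- matrix(c(1, 1, 2, 3, 3, 3, 3, 3), 4, 2,
              dimnames = list(paste0("g", 1:4), c("s1", "s2")))
  m[4, 1] <- 0
  out <- fpkm_to_tpm(m[1:3, 1, drop = FALSE])
  expect_equal(unname(out[, 1]), c(250000, 250000, 500000))

  eq <- matrix(7, 4, 1, dimnames = list(paste0("g", 1:4), "s"))
  expect_equal(unname(fpkm_to_tpm(eq)[, 1]), rep(250000, 4))

  set.seed(1)
  r <- matrix(rexp(300), 100, 3, dimnames = list(sprintf("g%d", 1:100), 1:3))
  out <- fpkm_to_tpm(r)
  expect_equal(unname(colSums(out)), rep(1e6, 3), tolerance = 1e-6)
  expect_identical(expr_unit(out), "TPM")
  ## idempotent up to scale: normalizing twice equals once
  expect_equal(fpkm_to_tpm(out), out, ignore_attr = TRUE, tolerance = 1e-12)

  z <- r; z[, 2] <- 0
  colnames(z) <- c("a", "badsample", "c")
  expect_error(fpkm_to_tpm(z), "badsample")
  expect_error(fpkm_to_tpm(-r), "nonnegative")
})

test_that("filter_genes removes genes strictly above the bad-entry threshold", {
  n <- 100L
  m <- matrix(1, 3, n, dimnames = list(c("bad71", "edge70", "dense"),
                                       sprintf("s%d", 1:n)))
  m["bad71", 1:71] <- 0
  m["edge70", 1:35] <- 0
  m["edge70", 36:70] <- NA          # zeros and missing pooled
  out <- filter_genes(m)
  expect_setequal(rownames(out), c("edge70", "dense"))
  expect_identical(ncol(out), n)

  dense <- matrix(runif(50) + 1, 10, 5,
                  dimnames = list(sprintf("g%d", 1:10), sprintf("s%d", 1:5)))
  expect_identical(filter_genes(dense), dense)
  allbad <- matrix(0, 2, 10, dimnames = list(c("a", "b"), sprintf("s%d", 1:10)))
  expect_error(filter_genes(allbad), "max_bad_frac")
})

test_that("knn_impute fills missing entries from nearest gene neighbours", {
  ## constant neighbours: imputed value is exactly their shared value
  m <- matrix(5, 12, 6, dimnames = list(sprintf("g%d", 1:12),
                                        sprintf("s%d", 1:6)))
  m[1, ] <- c(NA, 5, 5, 5, 5, 5)
  m <- m + matrix(rep(seq(0, 0.5, length.out = 6), each = 12), 12, 6) * 0
  out <- knn_impute(m, k = 5)
  expect_equal(out[1, 1], 5)
  expect_false(anyNA(out))

  ## no missing entries: identity
  full <- matrix(rnorm(60), 10, 6,
                 dimnames = list(sprintf("g%d", 1:10), sprintf("s%d", 1:6)))
  expect_identical(knn_impute(full), full)

  ## all-missing gene cannot be imputed
  gone <- full; gone[3, ] <- NA
  expect_error(knn_impute(gone), "all entries missing")
})

test_that("knn imputation beats gene-mean imputation on correlated data", {
  set.seed(11)
  n_g <- 120L; n_s <- 40L
  latent <- matrix(rnorm(4 * n_s), 4, n_s)
  load <- matrix(rnorm(n_g * 4), n_g, 4)
  truth <- load %*% latent + matrix(rnorm(n_g * n_s, sd = 0.3), n_g, n_s)
  dimnames(truth) <- list(sprintf("g%d", 1:n_g), sprintf("s%d", 1:n_s))
  masked <- truth
  idx <- sample(length(truth), round(0.05 * length(truth)))
  masked[idx] <- NA
  imp <- knn_impute(masked, k = 10)
  rmse_knn <- sqrt(mean((imp[idx] - truth[idx])^2))
  gm <- masked
  for (g in seq_len(n_g)) gm[g, is.na(gm[g, ])] <- mean(gm[g, ], na.rm = TRUE)
  rmse_mean <- sqrt(mean((gm[idx] - truth[idx])^2))
  expect_lt(rmse_knn, rmse_mean)
})

test_that("combat_correct removes batch shifts and keeps planted effects", {
  set.seed(21)
  n_g <- 150L; n_s <- 40L
  base <- matrix(rnorm(n_g * n_s, 8, 1), n_g, n_s,
                 dimnames = list(sprintf("g%d", 1:n_g), sprintf("s%d", 1:n_s)))
  batch <- rep(c("b1", "b2"), each = n_s / 2)

  ## single batch: identity
  expect_equal(combat_correct(base, rep("b1", n_s)), base, tolerance = 1e-8)

  ## two batches that differ only by a constant additive shift -> removed
  ## (equal per-gene variance so the EB shrinkage is exact)
  vals <- rnorm(n_s / 2, 8, 1)
  half <- t(vapply(seq_len(n_g), function(g) sample(vals), vals))
  dimnames(half) <- list(sprintf("g%d", 1:n_g), sprintf("s%d", 1:(n_s / 2)))
  shifted <- cbind(half, half + 2)
  colnames(shifted) <- sprintf("s%d", 1:n_s)
  corr <- combat_correct(shifted, batch)
  diffs <- rowMeans(corr[, batch == "b2"]) - rowMeans(corr[, batch == "b1"])
  expect_lt(max(abs(diffs)), 0.01)

  ## planted 2-fold (1 log2 unit) group effect orthogonal to batch survives
  group <- rep(c("g1", "g2"), times = n_s / 2)   # orthogonal to batch
  eff <- base
  eff[1:30, group == "g2"] <- eff[1:30, group == "g2"] + 1
  eff[, batch == "b2"] <- eff[, batch == "b2"] + 3
  corr <- combat_correct(eff, batch, covariates = data.frame(group = group))
  est <- rowMeans(corr[1:30, group == "g2"]) - rowMeans(corr[1:30, group == "g1"])
  expect_equal(mean(est), 1, tolerance = 0.1)

  ## exact confounding is refused
  expect_error(combat_correct(eff, batch, covariates = data.frame(x = batch)),
               "confounded")
})

test_that("moderated_t_deg gates on both FDR and fold change", {
  set.seed(31)
  n_g <- 500L
  tum <- matrix(rnorm(n_g * 10, 6), n_g, 10,
                dimnames = list(sprintf("g%d", 1:n_g), sprintf("t%d", 1:10)))
  nor <- matrix(rnorm(n_g * 10, 6), n_g, 10,
                dimnames = list(sprintf("g%d", 1:n_g), sprintf("n%d", 1:10)))
  ## strong DEG: log2fc = 2, near-zero within-group variance
  tum["g1", ] <- 8 + rnorm(10, sd = 0.01)
  nor["g1", ] <- 6 + rnorm(10, sd = 0.01)
  ## below the fold-change gate despite tiny p: log2fc = 0.9
  tum["g2", ] <- 6.9 + rnorm(10, sd = 0.001)
  nor["g2", ] <- 6 + rnorm(10, sd = 0.001)
  out <- moderated_t_deg(tum, nor)
  expect_true(out$deg[out$gene_id == "g1"])
  expect_false(out$deg[out$gene_id == "g2"])
  expect_lt(out$p[out$gene_id == "g2"], 1e-3)
  expect_identical(out$direction[out$gene_id == "g1"], "up")
})

test_that("moderated_t_deg is calibrated under the null", {
  set.seed(41)
  n_g <- 2000L
  tum <- matrix(rnorm(n_g * 8, 5), n_g, 8,
                dimnames = list(sprintf("g%d", 1:n_g), sprintf("t%d", 1:8)))
  nor <- matrix(rnorm(n_g * 8, 5), n_g, 8,
                dimnames = list(sprintf("g%d", 1:n_g), sprintf("n%d", 1:8)))
  out <- moderated_t_deg(tum, nor)
  rej <- mean(out$p < 0.05)
  expect_gte(rej, 0.03); expect_lte(rej, 0.07)
  expect_gt(stats::ks.test(out$p, "punif")$p.value, 0.01)
})

test_that("bh_adjust reproduces the step-up calculation", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  ## hand step-up on an uneven ladder
  expect_equal(bh_adjust(c(0.001, 0.04, 0.9)),
               c(0.003, 0.06, 0.9))
  expect_error(bh_adjust(c(0.1, NaN)), "NaN")
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
})
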