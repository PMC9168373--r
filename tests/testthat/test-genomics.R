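toy_maf <- function() {
  data.frame(
    Hugo_Symbol = c("TP53", "TP53", "TP53", "KRAS", "KRAS"),
    Tumor_Sample_Barcode = c("s1", "s1", "s2", "s1", "s3"),
    Variant_Classification = c("Missense_Mutation", "Silent",
                               "Nonsense_Mutation", "Silent",
                               "Frame_Shift_Del"),
    Variant_Type = c("SNP", "SNP", "SNP", "SNP", "DEL"),
    stringsAsFactors = FALSE)
}

test_that("MAF read/write round-trips with case-insensitive headers", {
  d <- withr::local_tempdir()
  p <- file.path(d, "toy.maf")
  maf <- toy_maf()
  colnames(maf) <- tolower(colnames(maf))
  utils::write.table(maf, p, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_maf(p)
  expect_true(all(c("Hugo_Symbol", "Tumor_Sample_Barcode",
                    "Variant_Classification", "Variant_Type") %in%
                    colnames(back)))
  expect_identical(nrow(back), 5L)
  utils::write.table(maf[, 1:2], p, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_error(read_maf(p), "Variant_Classification")
})

test_that("tmb counts only non-silent variants", {
  maf <- toy_maf()
  tmb <- tmb_from_maf(maf, samples = c("s1", "s2", "s3", "s4"))
  ## 5 rows, 2 silent -> s1: 1 non-silent, s2: 1, s3: 1, s4 absent: 0
  expect_identical(unname(tmb), c(1L, 1L, 1L, 0L))

  three <- data.frame(Hugo_Symbol = "X",
                      Tumor_Sample_Barcode = "s9",
                      Variant_Classification = rep("Missense_Mutation", 3),
                      Variant_Type = "SNP")
  expect_identical(unname(tmb_from_maf(three)), 3L)

  empty <- toy_maf()[0, ]
  expect_identical(unname(tmb_from_maf(empty, samples = c("a", "b"))),
                   c(0L, 0L))

  weird <- toy_maf()
  weird$Variant_Classification[1] <- "Mystery_Class"
  expect_warning(tmb_from_maf(weird), "Mystery_Class")
})

test_that("tmb is additive over disjoint MAF partitions", {
  co <- small_cohort()
  maf <- co$maf
  samples <- co$clinical$sample_id
  whole <- tmb_from_maf(maf, samples = samples)
  half <- nrow(maf) %/% 2
  part <- tmb_from_maf(maf[1:half, ], samples = samples) +
    tmb_from_maf(maf[(half + 1):nrow(maf), ], samples = samples)
  expect_identical(unname(whole), unname(part))
})

test_that("mutation_compare flags planted differential genes only", {
  set.seed(3)
  n <- 200L
  ids <- sprintf("p%03d", 1:(2 * n))
  groups <- stats::setNames(rep(c("high", "low"), each = n), ids)
  mk_rows <- function(gene, rate_h, rate_l) {
    hit <- c(ids[1:n][runif(n) < rate_h], ids[(n + 1):(2 * n)][runif(n) < rate_l])
    if (!length(hit)) return(NULL)
    data.frame(Hugo_Symbol = gene, Tumor_Sample_Barcode = hit,
               Variant_Classification = "Missense_Mutation",
               Variant_Type = "SNP", stringsAsFactors = FALSE)
  }
  maf <- rbind(mk_rows("DIFF", 0.5, 0.05), mk_rows("SAME", 0.4, 0.4))
  res <- mutation_compare(maf, groups)
  expect_true(res$flagged[res$gene == "DIFF"])
  expect_false(res$flagged[res$gene == "SAME"])
  expect_gt(res$odds_ratio[res$gene == "DIFF"], 1)

  ## identical rates across groups: p = 1 for an exactly balanced table
  bal <- rbind(
    data.frame(Hugo_Symbol = "EQ", Tumor_Sample_Barcode = ids[1:80],
               Variant_Classification = "Missense_Mutation",
               Variant_Type = "SNP"),
    data.frame(Hugo_Symbol = "EQ", Tumor_Sample_Barcode = ids[(n + 1):(n + 80)],
               Variant_Classification = "Missense_Mutation",
               Variant_Type = "SNP"))
  expect_equal(mutation_compare(bal, groups)$p, 1)

  stray <- maf
  stray$Tumor_Sample_Barcode[1] <- "unknown"
  expect_warning(mutation_compare(stray, groups), "unmapped")
})

test_that("stratification by score and marker behaves at the margins", {
  set.seed(7)
  n <- 120L
  score_group <- stats::setNames(rep(c("high", "low"), each = n / 2),
                                 sprintf("s%03d", 1:n))
  marker <- rnorm(n)
  sv <- simulate_survival(as.numeric(score_group == "high"), log_hr = 1,
                          baseline_rate = 1e-3, censoring_rate = 0.2,
                          seed = 7L)
  st <- stratify_combination(score_group, marker, sv$time, sv$event)
  expect_identical(st$logrank$df, 3L)
  expect_length(unique(st$strata), 4L)

  ## constant marker collapses to the two-group comparison
  expect_warning(
    st2 <- stratify_combination(score_group, rep(1, n), sv$time, sv$event),
    "nonempty")
  two <- logrank_test(score_group, sv$time, sv$event)
  expect_equal(st2$logrank$chi2, two$chi2, tolerance = 1e-12)
  expect_identical(st2$logrank$df, 1L)
})

test_that("additive score and marker effects order the strata", {
  set.seed(9)
  n <- 400L
  ids <- sprintf("s%03d", 1:n)
  score_high <- rep(c(TRUE, FALSE), each = n / 2)
  marker <- rnorm(n)
  hazard <- score_high * 1 + (marker > stats::median(marker)) * 1
  sv <- simulate_survival(hazard, log_hr = 1, baseline_rate = 1e-3,
                          censoring_rate = 0.1, seed = 9L)
  sg <- stats::setNames(ifelse(score_high, "high", "low"), ids)
  st <- stratify_combination(sg, marker, sv$time, sv$event)
  med <- vapply(split(seq_len(n), st$strata), function(i)
    km_estimate(sv$time[i], sv$event[i])$median, 0)
  expect_identical(names(which.min(med)), "score-high/marker-high")
  expect_lt(st$logrank$p, 0.01)
})
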