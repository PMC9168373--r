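## Synthetic cohorts with known cell fractions, planted infiltration
## subtypes, prognostic gene modules, batch structure, missingness and
## group-dependent mutation rates.  Every downstream stage of the pipeline
## can therefore be checked against ground truth.

#' Block-structured synthetic cell-type signature matrix
#'
#' Builds an LM22-like reference of \code{n_cell_types} cell types, each
#' with \code{markers_per_type} marker genes strongly elevated in its own
#' column over a shared gamma-distributed baseline.  A real signature
#' matrix (e.g. LM22) read with \code{\link{read_expression_tsv}} can be
#' used anywhere this one is.
#'
#' @param n_cell_types Number of cell types (default 22).
#' @param markers_per_type Marker genes per cell type.
#' @param marker_level Additive expression elevation of a marker gene in
#'   its own cell type (linear scale).
#' @param seed RNG seed; the matrix is deterministic given the seed.
#' @return Genes x cell-types numeric matrix.
#' @export
synthetic_signature <- function(n_cell_types = 22L, markers_per_type = 10L,
                                marker_level = 500, seed = 101L) {
  set.seed(seed)
  G <- n_cell_types * markers_per_type
  S <- matrix(stats::rgamma(G * n_cell_types, shape = 2, rate = 2) * 20,
              G, n_cell_types)
  for (t in seq_len(n_cell_types)) {
    rows <- ((t - 1L) * markers_per_type + 1L):(t * markers_per_type)
    S[rows, t] <- S[rows, t] + marker_level
  }
  rownames(S) <- sprintf("SIG%04d", seq_len(G))
  colnames(S) <- sprintf("CT%02d", seq_len(n_cell_types))
  S
}

default_fraction_profiles <- function(n_subtypes = 4L, n_cell_types = 22L,
                                      elevated_per_subtype = 5L, elevation = 5) {
  P <- matrix(1, n_subtypes, n_cell_types)
  for (s in seq_len(n_subtypes)) {
    cols <- ((s - 1L) * elevated_per_subtype + 1L):(s * elevated_per_subtype)
    cols <- cols[cols <= n_cell_types]
    P[s, cols] <- elevation
  }
  P / rowSums(P)
}

default_module_spec <- function() {
  list(risk       = list(n_genes = 30L, direction = +1, effect = 1),
       protective = list(n_genes = 15L, direction = -1, effect = 1))
}

default_mutation_rates <- function(n_genes = 30L) {
  gene <- sprintf("MUT%03d", seq_len(n_genes))
  rate_high <- rep(0.10, n_genes)
  rate_low <- rep(0.10, n_genes)
  rate_high[1:5] <- 0.45           # enriched in the score-high group
  rate_low[6:10] <- 0.40           # enriched in the score-low group
  rate_high[6:10] <- 0.08
  rate_low[1:5] <- 0.12
  data.frame(gene = gene, rate_high = rate_high, rate_low = rate_low,
             stringsAsFactors = FALSE)
}

#' Configuration for a synthetic cohort
#'
#' Defaults describe the study conditions the pipeline targets: a
#' 200-sample cohort with four infiltration subtypes over 22 cell types
#' (Dirichlet fractions, concentration 50), a 30-gene hazard-increasing and
#' a 15-gene hazard-decreasing prognostic module tied to a latent risk
#' score, log2-scale biological noise, two pseudo-cohort batches, 5\%
#' missingness and 30\% right-censoring.
#'
#' @param n_samples,n_genes,n_cell_types,n_subtypes Cohort dimensions;
#'   \code{n_genes} is the total gene count (signature markers + module
#'   genes + unstructured filler).
#' @param subtype_fraction_profiles Matrix (subtypes x cell types) of
#'   Dirichlet mean fraction profiles; rows must sum to 1.
#' @param dirichlet_concentration Common Dirichlet concentration; larger
#'   values give tighter within-subtype fraction spread.
#' @param module_spec Named list of modules, each
#'   \code{list(n_genes, direction = +1/-1, effect)}; \code{effect} is the
#'   log2 fold change per unit of latent score.
#' @param subtype_score_shift Per-subtype mean of the latent risk score.
#' @param log_hr Log hazard ratio per unit of latent score.
#' @param baseline_rate Baseline exponential event rate per day.
#' @param noise_sd SD of multiplicative log2-normal expression noise.
#' @param missing_frac Proportion of entries masked missing (must be < 0.7
#'   so informative genes survive the bad-entry filter).
#' @param n_batches,batch_shift_sd Number of pseudo-cohorts and the SD of
#'   the per-gene log2 batch shift.
#' @param censoring_rate Target proportion of censored samples.
#' @param mutation_rates Data frame \code{gene, rate_high, rate_low} of
#'   per-gene mutation probabilities by latent-score group.
#' @param seed Master RNG seed.
#' @return Validated list of class \code{"sim_config"}.
#' @export
sim_config <- function(n_samples = 200L, n_genes = 1000L, n_cell_types = 22L,
                       n_subtypes = 4L,
                       subtype_fraction_profiles = NULL,
                       dirichlet_concentration = 50,
                       module_spec = default_module_spec(),
                       subtype_score_shift = c(1, -1, 3, -3),
                       log_hr = 1, baseline_rate = 5e-4,
                       noise_sd = 0.3, missing_frac = 0.05,
                       n_batches = 2L, batch_shift_sd = 0.2,
                       censoring_rate = 0.3,
                       mutation_rates = default_mutation_rates(),
                       seed = 1L) {
  if (n_subtypes < 2L) stop("n_subtypes must be >= 2")
  if (missing_frac < 0 || missing_frac >= 0.7)
    stop("missing_frac must lie in [0, 0.7)")
  if (is.null(subtype_fraction_profiles))
    subtype_fraction_profiles <- default_fraction_profiles(n_subtypes, n_cell_types)
  P <- subtype_fraction_profiles
  if (nrow(P) != n_subtypes || ncol(P) != n_cell_types)
    stop("subtype_fraction_profiles must be ", n_subtypes, " x ", n_cell_types)
  if (any(P < 0) || any(abs(rowSums(P) - 1) > 1e-8))
    stop("each subtype fraction profile must be nonnegative and sum to 1")
  if (length(subtype_score_shift) != n_subtypes)
    stop("subtype_score_shift must have one entry per subtype")
  if (baseline_rate <= 0) stop("baseline_rate must be positive")
  if (censoring_rate < 0 || censoring_rate >= 1)
    stop("censoring_rate must lie in [0, 1)")
  cfg <- list(n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
              n_cell_types = as.integer(n_cell_types),
              n_subtypes = as.integer(n_subtypes),
              subtype_fraction_profiles = P,
              dirichlet_concentration = dirichlet_concentration,
              module_spec = module_spec,
              subtype_score_shift = subtype_score_shift,
              log_hr = log_hr, baseline_rate = baseline_rate,
              noise_sd = noise_sd, missing_frac = missing_frac,
              n_batches = as.integer(n_batches),
              batch_shift_sd = batch_shift_sd,
              censoring_rate = censoring_rate,
              mutation_rates = mutation_rates,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

rdirichlet <- function(n, alpha) {
  x <- matrix(stats::rgamma(n * length(alpha), shape = alpha),
              n, length(alpha), byrow = TRUE)
  x / rowSums(x)
}

#' Simulate right-censored survival driven by a latent score
#'
#' Event times are exponential with hazard
#' \code{baseline_rate * exp(log_hr * score)}.  Censoring is an independent
#' exponential whose rate is tuned by bisection so the expected censored
#' proportion matches \code{censoring_rate}.
#'
#' @param latent_score Per-sample real risk score.
#' @param log_hr Log hazard ratio per unit of score.
#' @param baseline_rate Positive baseline event rate (per day).
#' @param censoring_rate Target censored proportion in [0, 1).
#' @param seed RNG seed.
#' @return Data frame \code{sample_id, time, event} (event 1 = death).
#' @export
simulate_survival <- function(latent_score, log_hr = 1, baseline_rate = 5e-4,
                              censoring_rate = 0.3, seed = 1L) {
  if (baseline_rate <= 0) stop("baseline_rate must be positive")
  if (censoring_rate < 0 || censoring_rate >= 1)
    stop("censoring_rate must lie in [0, 1)")
  n <- length(latent_score)
  lambda <- baseline_rate * exp(log_hr * latent_score)
  set.seed(seed)
  T_ev <- stats::rexp(n, rate = lambda)
  if (censoring_rate == 0) {
    time <- T_ev; event <- rep(1L, n)
  } else {
    ## E[censored] = mean(mu / (mu + lambda)); monotone in mu -> bisection
    f <- function(mu) mean(mu / (mu + lambda)) - censoring_rate
    lo <- min(lambda) * 1e-6; hi <- max(lambda) * 1e6
    for (i in 1:200) {
      mid <- sqrt(lo * hi)
      if (f(mid) < 0) lo <- mid else hi <- mid
    }
    mu <- sqrt(lo * hi)
    C <- stats::rexp(n, rate = mu)
    event <- as.integer(T_ev <= C)
    time <- pmin(T_ev, C)
  }
  ids <- names(latent_score)
  if (is.null(ids)) ids <- sprintf("S%04d", seq_len(n))
  data.frame(sample_id = ids, time = time, event = event,
             stringsAsFactors = FALSE)
}

#' Simulate a full synthetic cohort
#'
#' Expression is a signature-weighted mixture of per-sample cell fractions
#' (Dirichlet within subtype), with prognostic module genes whose log2
#' expression is linked to a latent risk score, multiplicative log2-normal
#' noise, per-gene batch shifts, TPM column scaling and a uniform missing
#' mask.  Survival follows the latent score; mutations are drawn per gene
#' with probabilities depending on the latent-score group.
#'
#' @param config A \code{\link{sim_config}}.
#' @param signature Optional genes x cell-types signature matrix; defaults
#'   to \code{\link{synthetic_signature}} of matching dimension.
#' @return List of class \code{"sim_cohort"}: \code{expression} (genes x
#'   samples TPM matrix, missing entries \code{NA}), \code{clinical} (data
#'   frame with survival and covariates), \code{maf} (minimal MAF data
#'   frame), \code{signature}, and \code{truth} (true fractions, subtype,
#'   latent score, module membership, batch).
#' @export
simulate_cohort <- function(config, signature = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(signature))
    signature <- synthetic_signature(n_cell_types = config$n_cell_types)
  if (ncol(signature) != config$n_cell_types)
    stop("signature has ", ncol(signature), " cell types but config expects ",
         config$n_cell_types)
  n <- config$n_samples
  set.seed(config$seed)
  ids <- sprintf("S%04d", seq_len(n))

  ## subtypes and cell fractions
  subtype <- sample(rep(seq_len(config$n_subtypes), length.out = n))
  frac <- matrix(0, n, config$n_cell_types,
                 dimnames = list(ids, colnames(signature)))
  for (s in seq_len(config$n_subtypes)) {
    i <- which(subtype == s)
    alpha <- config$subtype_fraction_profiles[s, ] * config$dirichlet_concentration
    frac[i, ] <- rdirichlet(length(i), alpha)
  }

  ## latent risk score
  latent <- config$subtype_score_shift[subtype] + stats::rnorm(n)
  names(latent) <- ids

  ## expression: signature mixture + module genes + filler
  expr_sig <- signature %*% t(frac)
  mod_mem <- character(0)
  expr_mod <- NULL
  if (length(config$module_spec)) {
    blocks <- lapply(names(config$module_spec), function(m) {
      sp <- config$module_spec[[m]]
      base <- 2^stats::rnorm(sp$n_genes, mean = log2(50), sd = 1)
      b <- outer(base, rep(1, n)) * 2^(sp$direction * sp$effect * outer(rep(1, sp$n_genes), latent))
      rownames(b) <- sprintf("%s%03d", toupper(m), seq_len(sp$n_genes))
      b
    })
    expr_mod <- do.call(rbind, blocks)
    mod_mem <- rep(names(config$module_spec),
                   vapply(config$module_spec, `[[`, 1L, "n_genes"))
    names(mod_mem) <- rownames(expr_mod)
  }
  n_fill <- config$n_genes - nrow(expr_sig) - NROW(expr_mod)
  expr_fill <- NULL
  if (n_fill > 0) {
    base <- 2^stats::rnorm(n_fill, mean = log2(30), sd = 1.5)
    expr_fill <- outer(base, rep(1, n))
    rownames(expr_fill) <- sprintf("FILL%04d", seq_len(n_fill))
  }
  expr <- rbind(expr_sig, expr_mod, expr_fill)
  colnames(expr) <- ids

  ## multiplicative log2-normal noise
  if (config$noise_sd > 0)
    expr <- expr * 2^matrix(stats::rnorm(length(expr), 0, config$noise_sd),
                            nrow(expr))

  ## batch structure: per-gene multiplicative shift per batch
  batch <- sample(rep(seq_len(config$n_batches), length.out = n))
  names(batch) <- ids
  if (config$n_batches > 1L && config$batch_shift_sd > 0) {
    shifts <- matrix(stats::rnorm(nrow(expr) * config$n_batches, 0,
                                  config$batch_shift_sd),
                     nrow(expr), config$n_batches)
    expr <- expr * 2^shifts[, batch]
  }

  ## scale columns to TPM
  expr <- sweep(expr, 2L, colSums(expr), "/") * 1e6
  expr <- set_expr_unit(expr, "TPM")

  ## missing mask
  if (config$missing_frac > 0) {
    miss <- stats::runif(length(expr)) < config$missing_frac
    expr[miss] <- NA_real_
  }

  ## survival + clinical covariates
  surv <- simulate_survival(latent, config$log_hr, config$baseline_rate,
                            config$censoring_rate,
                            seed = stage_seed(config$seed, "survival"))
  clinical <- data.frame(
    sample_id = ids,
    os_days = surv$time, os_event = surv$event,
    age = round(stats::rnorm(n, 65, 8)),
    sex = sample(c("M", "F"), n, replace = TRUE),
    stage = sample(c("I", "II", "III"), n, replace = TRUE,
                   prob = c(0.5, 0.3, 0.2)),
    smoke = sample(c("ever", "never"), n, replace = TRUE),
    batch = paste0("B", batch),
    stringsAsFactors = FALSE)

  ## mutations: per-gene Bernoulli with rates by latent-score group
  grp_high <- latent > stats::median(latent)
  mr <- config$mutation_rates
  maf_rows <- list()
  nonsilent <- c("Missense_Mutation", "Nonsense_Mutation",
                 "Frame_Shift_Del", "Frame_Shift_Ins", "Splice_Site")
  for (g in seq_len(nrow(mr))) {
    p <- ifelse(grp_high, mr$rate_high[g], mr$rate_low[g])
    hit <- stats::runif(n) < p
    if (any(hit)) {
      vc <- sample(c(nonsilent, "Silent"), sum(hit), replace = TRUE,
                   prob = c(0.55, 0.1, 0.08, 0.07, 0.05, 0.15))
      maf_rows[[length(maf_rows) + 1L]] <- data.frame(
        Hugo_Symbol = mr$gene[g], Tumor_Sample_Barcode = ids[hit],
        Variant_Classification = vc,
        Variant_Type = ifelse(vc %in% c("Frame_Shift_Del", "Frame_Shift_Ins"),
                              "DEL", "SNP"),
        stringsAsFactors = FALSE)
    }
  }
  maf <- if (length(maf_rows)) do.call(rbind, maf_rows) else
    data.frame(Hugo_Symbol = character(0), Tumor_Sample_Barcode = character(0),
               Variant_Classification = character(0), Variant_Type = character(0))
  rownames(maf) <- NULL

  out <- list(expression = expr, clinical = clinical, maf = maf,
              signature = signature,
              truth = list(true_fractions = frac,
                           true_subtype = stats::setNames(subtype, ids),
                           true_latent_score = latent,
                           module_membership = mod_mem,
                           batch = stats::setNames(paste0("B", batch), ids)),
              config = config)
  class(out) <- "sim_cohort"
  out
}

#' Write a synthetic cohort to a directory of plain-text files
#'
#' Expression, clinical table, signature and ground truth as TSV; mutations
#' as minimal MAF.
#'
#' @param cohort A \code{"sim_cohort"}.
#' @param dir Output directory (created if absent).
#' @return \code{dir}, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression_tsv(cohort$expression, file.path(dir, "expression.tsv"))
  write_expression_tsv(cohort$signature, file.path(dir, "signature.tsv"))
  utils::write.table(cohort$clinical, file.path(dir, "clinical.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$maf, file.path(dir, "mutations.maf"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  tr <- cohort$truth
  utils::write.table(
    data.frame(sample_id = names(tr$true_subtype),
               subtype = tr$true_subtype,
               latent_score = tr$true_latent_score,
               batch = tr$batch, stringsAsFactors = FALSE),
    file.path(dir, "truth_samples.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  write_expression_tsv(tr$true_fractions, file.path(dir, "truth_fractions.tsv"),
                       id_col = "sample_id")
  utils::write.table(
    data.frame(gene_id = names(tr$module_membership),
               module = tr$module_membership, stringsAsFactors = FALSE),
    file.path(dir, "truth_modules.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(dir)
}
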