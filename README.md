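# tmekit

Classify bulk tumor transcriptomes by their immune-cell infiltration
pattern and score each patient's tumor microenvironment (TME) for
prognosis.

Bulk RNA-seq of a tumor measures a mixture: malignant cells plus the
immune and stromal cells infiltrating them. The composition of that
mixture predicts survival and response to checkpoint blockade. `tmekit`
implements the full analysis chain used to turn a genes × samples
expression matrix, a clinical table and (optionally) somatic mutations
into an interpretable risk score:

1. **Deconvolution** — per-sample fractions of 22 immune cell types by
   linear ν-support-vector regression against a signature matrix
   (CIBERSORT-style: z-scored system, ν grid {0.25, 0.5, 0.75}, best
   reconstruction kept, negative coefficients clamped, fractions
   normalized to 1).
2. **Infiltration subtypes** — consensus clustering of the fraction
   profiles (100 subsampling iterations at 80%, Ward inner linkage),
   with the cluster number chosen from the relative gain in area under
   the consensus CDF (Δ ≥ 0.1 elbow rule).
3. **TMEscore** — subtype-discriminating genes are stability-selected
   with 100 random forests (top-100 importance per run, 50% sample
   subsampling, selected at ≥ 80/100 repetitions), consensus-clustered
   into gene modules, screened by univariate Cox, and summarized per
   module by the first principal component. With β_k the Cox coefficient
   of module k's PC1 score,

       TMEscore(s) = Σ_{β_k>0} PC1_k(s) − Σ_{β_k<0} PC1_k(s),

   so a high score means high expected hazard. Patients are split
   high/low at a maximally selected rank (log-rank) cutpoint.
4. **Downstream characterization** — Kaplan–Meier / log-rank / Cox
   (Efron ties), phenotype-permutation GSEA with NES and permutation
   FDR, hypergeometric over-representation, differentially mutated
   genes by Fisher's exact test, tumor mutational burden, and survival
   stratification by score × a second biomarker.

A synthetic-cohort generator (`simulate_cohort()`) produces expression,
clinical, and MAF inputs with known ground truth — true cell fractions,
subtype labels, latent risk, prognostic modules, batch structure,
missingness, and group-dependent mutation rates — so every stage of the
pipeline can be validated end to end.

## Worked example

```r
library(tmekit)

co  <- simulate_cohort(sim_config(n_samples = 120, n_genes = 600, seed = 42))
cfg <- pipeline_config(
  expression = co$expression, clinical = co$clinical,
  signature  = co$signature,  maf = co$maf,
  seed = 42)
res <- run_pipeline(cfg)

str(res$report$counts)
#> List of 10
#>  $ genes_in              : int 600
#>  $ genes_after_filter    : int 600
#>  $ cell_types            : int 22
#>  $ chosen_k_samples      : int 4
#>  $ genes_selected        : int 37
#>  $ genes_prognostic      : int 27
#>  $ chosen_k_genes        : int 4
#>  $ n_high                : int 37
#>  $ n_low                 : int 83
#>  $ genes_mutation_flagged: int 7
```

The consensus CDF rule recovers the four planted infiltration subtypes
(`chosen_k_samples`), the random-forest stage keeps 37 stable genes of
which 27 pass the prognostic screen, and the learned cutpoint splits the
cohort into 37 high- and 83 low-score patients. The split separates
survival:

```r
res$survival$logrank
#> $chi2
#> [1] 105.2409
#> $df
#> [1] 1
#> $p
#> [1] 1.081551e-24

subset(res$survival$cox$table, term == "tmescore")
#>       term      coef       hr     lo95    hi95            p
#> 1 tmescore 0.2733278 1.314331 1.239118 1.39411 9.819124e-20
```

Each TMEscore unit multiplies the hazard by ≈ 1.31 after adjustment for
age, sex, stage and smoking, and the score correlates 0.97 with the
generator's latent risk:

```r
head(res$tmescore, 3)
#>       sample_id     score   cutoff group
#> S0001     S0001  4.660783 5.511293   low
#> S0002     S0002  4.993123 5.511293   low
#> S0003     S0003 12.779585 5.511293  high

cor(res$tmescore$score, co$truth$true_latent_score[res$tmescore$sample_id])
#> [1] 0.9659822
```

Individual stages are exported (`fpkm_to_tpm`, `filter_genes`,
`knn_impute`, `combat_correct`, `moderated_t_deg`, `deconvolve_matrix`,
`consensus_cluster`, `rf_stability_select`, `build_gene_clusters`,
`compute_tmescore`, `optimal_cutpoint`, `gsea`, `ora_hypergeom`,
`mutation_compare`, `tmb_from_maf`, `stratify_combination`, …) and work
on plain matrices and data frames; `inst/scripts/tmekit-pipeline.R` is a
thin command-line wrapper around `simulate_cohort()` + `run_pipeline()`.
See the methods vignette (`vignettes/tmekit-methods.Rmd`) for the model,
parameter meanings, and design decisions.

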