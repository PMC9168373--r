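## Shared fixtures, built in code at test time.

tiny_signature <- function(n_cell_types = 6L, markers_per_type = 8L,
                           seed = 42L) {
  synthetic_signature(n_cell_types = n_cell_types,
                      markers_per_type = markers_per_type, seed = seed)
}

## small default-condition cohort, memoised per session
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_cohort(sim_config(n_samples = 80L, n_genes = 400L,
                                           seed = 5L))
    cache
  }
})

## survival data with a known binary effect
sim_two_group_surv <- function(n, log_hr, seed, censoring = 0.2) {
  set.seed(seed)
  grp <- rep(c(0, 1), length.out = n)
  simulate_survival(grp, log_hr = log_hr, baseline_rate = 1e-3,
                    censoring_rate = censoring, seed = seed + 1L)[
                      , c("time", "event")] |> cbind(grp = grp)
}

expect_tsv_identical <- function(a, b) {
  expect_identical(unname(tools::md5sum(a)), unname(tools::md5sum(b)))
}
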