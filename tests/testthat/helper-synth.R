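# Shared fixtures: a reduced-scale generator config for module tests and a
# memoised full-scale pipeline run for the acceptance checks.

small_synth_config <- function(...) {
  synth_config(n_pgc = 30, n_supporting = 20, n_somatic = 10,
               n_genes = 900, n_peaks = 1500,
               n_de_genes = c(E11.5 = 8, E12.5 = 20, E13.5 = 60),
               n_extra_links = 10,
               ...)
}

.fixture_env <- new.env(parent = emptyenv())

# Small simulated dataset shared across module tests (computed once).
small_sim <- function() {
  if (is.null(.fixture_env$small_sim))
    .fixture_env$small_sim <- simulate_multiome(small_synth_config(), seed = 101L)
  .fixture_env$small_sim
}

# Reduced-scale end-to-end pipeline run shared by GRN/pipeline tests.
small_pipeline_run <- function() {
  if (is.null(.fixture_env$small_run)) {
    dir <- file.path(tempdir(), "small_run")
    .fixture_env$small_run <- suppressWarnings(suppressMessages(
      run_pipeline(dir, synth = small_synth_config(), seed = 7L)))
    .fixture_env$small_run_dir <- dir
  }
  .fixture_env$small_run
}

default_grn_run <- function() {
  res <- acceptance_run()
  de13 <- res$de$degs[["E13.5"]]
  list(sim = res$sim, net = res$grn$network, cand = res$grn$candidates,
       hits = res$motif$scan$hits, links = res$link$links,
       degs = de13$feature[de13$significant],
       all_peaks = res$qc$peaks$peak_id)
}

# Full default-scale pipeline run shared across acceptance checks; the same
# (outdir, seed) pair is reused by the determinism check as its first run.
acceptance_run <- function() {
  if (is.null(.fixture_env$acc_run)) {
    dir <- file.path(tempdir(), "acceptance_run1")
    .fixture_env$acc_run <- suppressWarnings(suppressMessages(
      run_pipeline(dir, seed = 42L)))
    .fixture_env$acc_dir <- dir
  }
  .fixture_env$acc_run
}

acceptance_dir <- function() {
  acceptance_run()
  .fixture_env$acc_dir
}

# two-sided exact Wilcoxon p by Monte-Carlo permutation (independent oracle)
mc_wilcox_p <- function(x, y, n_mc = 2e5) {
  n1 <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  mu <- n1 * mean(r)
  obs <- abs(sum(r[seq_len(n1)]) - mu)
  stat <- replicate(n_mc, abs(sum(r[sample.int(length(pooled), n1)]) - mu))
  mean(stat >= obs - 1e-9)
}

# adjusted Rand index (small self-contained implementation for tests)
ari_index <- function(a, b) {
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  sa <- sum(choose(rowSums(tab), 2)); sb <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  exp_ <- sa * sb / n2
  (sij - exp_) / ((sa + sb) / 2 - exp_)
}
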