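#' Pipeline configuration
#'
#' Every threshold of the workflow as a named default. The defaults are the
#' printed cutoffs of the upstream snRNA/snATAC processing for fetal mouse
#' gonads: RNA counts per nucleus in (1000, 25000), mitochondrial percentage
#' below 25, ATAC counts in (1000, 1e5), nucleosome signal below 2, TSS
#' enrichment above 1, peak widths in (20, 10000) bp, DE gene filters
#' min.pct = 0.25 / log2FC 0.25, DA peak filters min.pct = 0.001 / log2FC 0.1,
#' peak-gene linkage within 500 kb at p < 0.05, promoter window TSS +/- 3000,
#' chrY peak region 1-90,000,000 bp (excluding the pseudoautosomal region),
#' and 1000 label permutations for the ligand-receptor test. All inequalities
#' are strict, matching the printed operators.
#'
#' @param ... overrides for any default listed above.
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    rna_count_min = 1000, rna_count_max = 25000,
    pct_mito_max = 25,
    peak_width_min = 20, peak_width_max = 10000,
    atac_count_min = 1000, atac_count_max = 100000,
    nucleosome_signal_max = 2,
    tss_enrichment_min = 1,
    de_min_pct = 0.25, de_logfc = 0.25,
    dap_min_pct = 0.001, dap_logfc = 0.1,
    link_distance = 5e5, link_p = 0.05,
    alpha = 0.05,
    tss_region = c(-3000, 3000),
    chrY_region = c(1, 9e7),
    chrY_name = "chrY",
    permutations = 1000,
    n_background = 200,
    cluster_resolution = 0.3,
    cluster_k = 20,
    rna_dims = 1:18,
    atac_dims = 2:30,
    motif_threshold_frac = 0.8,
    deviation_iterations = 50,
    lr_min_frac = 0.1,
    seed = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  assert_that(length(unknown) == 0, "unknown config field(s): %s",
              paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  validate_config(cfg)
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

validate_config <- function(cfg) {
  pairs <- list(c("rna_count_min", "rna_count_max"),
                c("peak_width_min", "peak_width_max"),
                c("atac_count_min", "atac_count_max"))
  for (p in pairs)
    assert_that(cfg[[p[1]]] < cfg[[p[2]]], "%s must be < %s", p[1], p[2])
  assert_that(cfg$alpha > 0 && cfg$alpha < 1, "alpha must lie in (0, 1)")
  assert_that(cfg$tss_region[1] < cfg$tss_region[2], "tss_region must be increasing")
  assert_that(cfg$chrY_region[1] < cfg$chrY_region[2], "chrY_region must be increasing")
  invisible(cfg)
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys absent from the file keep their defaults; nested sections are
#' flattened one level (section names are dropped).
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  assert_that(file.exists(path), "config file not found: %s", path)
  raw <- yaml::read_yaml(path)
  flat <- list()
  for (nm in names(raw)) {
    v <- raw[[nm]]
    if (is.list(v)) flat <- c(flat, v) else flat[[nm]] <- v
  }
  do.call(pipeline_config, flat)
}
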