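#' Pipeline run configuration
#'
#' Bundles the tunable thresholds of the analysis pipeline with the RNG seed.
#' All stochastic stages (simulation, bootstrap) draw their randomness from
#' `rng_seed`, so a fixed configuration reproduces byte-identical outputs.
#'
#' @param identity_subgroup_threshold minimum pairwise nucleotide identity for
#'   two V genes to fall in the same subgroup (the conventional 0.75).
#' @param transcript_identity_threshold identity below which an expressed V
#'   segment is called the product of a gene absent from the assembly
#'   (the conventional 0.97).
#' @param orthology_identity_floor minimum mean identity to a reference
#'   subgroup for a cluster to inherit its name (default 0.631, the lower end
#'   of identities observed between orthologous bovine/human subgroups).
#' @param min_motif_genes minimum number of genes in a homology-unit motif.
#' @param merge_edit_distance label edits tolerated when merging motif
#'   variants into one homology unit.
#' @param bootstrap_replicates bootstrap replicates for tree support.
#' @param bias_over,bias_under expressed/genomic usage ratios above/below
#'   which a subgroup is called over-/under-represented.
#' @param rng_seed integer seed; mandatory, recorded in every report header.
#' @return a `trl_run_config` list.
#' @export
#' @examples
#' cfg <- run_config(rng_seed = 1)
#' cfg$identity_subgroup_threshold
run_config <- function(identity_subgroup_threshold = 0.75,
                       transcript_identity_threshold = 0.97,
                       orthology_identity_floor = 0.631,
                       min_motif_genes = 2L,
                       merge_edit_distance = 2L,
                       bootstrap_replicates = 100L,
                       bias_over = 2,
                       bias_under = 0.5,
                       rng_seed) {
  if (missing(rng_seed) || is.null(rng_seed)) {
    abort("run_config(): `rng_seed` is mandatory")
  }
  stopifnot(
    identity_subgroup_threshold > 0, identity_subgroup_threshold <= 1,
    transcript_identity_threshold > 0, transcript_identity_threshold <= 1,
    min_motif_genes >= 1, bootstrap_replicates >= 1
  )
  structure(
    list(
      identity_subgroup_threshold = identity_subgroup_threshold,
      transcript_identity_threshold = transcript_identity_threshold,
      orthology_identity_floor = orthology_identity_floor,
      min_motif_genes = as.integer(min_motif_genes),
      merge_edit_distance = as.integer(merge_edit_distance),
      bootstrap_replicates = as.integer(bootstrap_replicates),
      bias_over = bias_over,
      bias_under = bias_under,
      rng_seed = as.integer(rng_seed)
    ),
    class = "trl_run_config"
  )
}

#' Read / write a run configuration as JSON
#' @param path JSON file path.
#' @return `read_run_config()` returns a `trl_run_config`;
#'   `write_run_config()` returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, raw)
}

#' @rdname read_run_config
#' @param config a `trl_run_config`.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

report_header <- function(config) {
  c(
    paste0("config_hash=", config_hash(unclass(config))),
    paste0("seed=", config$rng_seed)
  )
}
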