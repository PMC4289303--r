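# Report writers and bundled reference count tables.

#' Write pipeline results as TSV reports
#'
#' Writes every recognised element of `results` as a TSV with fixed column
#' order; every file carries header comments with the configuration hash
#' and seed, so re-running with the same configuration gives byte-identical
#' reports. Empty results produce headers-only files.
#'
#' @param results named list; recognised names: `catalog_summary`,
#'   `clusters` (a `trl_clusters`), `units`, `matches`, `trichotomy`,
#'   `usage`, `bias`, `orders`, `groups`, `dotplot`.
#' @param out_dir output directory (created if needed).
#' @param config a [run_config()] providing the hash and seed.
#' @return invisibly, the written paths.
#' @export
write_reports <- function(results, out_dir, config) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(out_dir)) {
      abort(paste0("write_reports(): cannot create ", out_dir))
    }
  }
  hdr <- report_header(config)
  paths <- character(0)
  emit <- function(x, name) {
    if (inherits(x, "trl_clusters")) {
      paths <<- c(paths, emit(x$membership, paste0(name, "_membership")))
      paths <<- c(paths, emit(x$diagnostics, paste0(name, "_diagnostics")))
      return(invisible(NULL))
    }
    x <- as_tibble(x)
    drop <- vapply(x, function(col) {
      is.list(col) && !all(vapply(col, is.atomic, logical(1)))
    }, logical(1))
    x <- x[, !drop, drop = FALSE]
    p <- file.path(out_dir, paste0(name, ".tsv"))
    write_tsv_report(x, p, hdr)
    p
  }
  for (name in names(results)) {
    r <- emit(results[[name]], name)
    if (!is.null(r)) paths <- c(paths, r)
  }
  invisible(paths)
}

read_fixture <- function(file) {
  p <- system.file("extdata", file, package = "trlocus")
  if (p == "") p <- file.path("inst", "extdata", file)
  read_tsv_report(p)
}

#' Published bovine (UMD3.1) per-subgroup V-gene counts
#'
#' Per-subgroup total / functional / pseudogene / incomplete gene counts of
#' the bovine TRA/TRD V-gene germline repertoire as annotated on the UMD3.1
#' assembly (42 subgroups, 371 genes).
#'
#' @return tibble: `subgroup`, `total`, `functional`, `pseudogene`,
#'   `incomplete`.
#' @export
#' @examples
#' sum(bovine_catalog_counts()$total)  # 371
bovine_catalog_counts <- function() {
  read_fixture("bovine_umd31_subgroup_counts.tsv")
}

#' Published expressed-repertoire trichotomy counts
#'
#' Counts of unique expressed bovine TRA/TRD V sequences that matched a
#' UMD3.1 genomic gene exactly, at 97.0-99.5 percent identity, or below 97
#' percent.
#'
#' @return tibble: `category`, `n`.
#' @export
expressed_trichotomy_counts <- function() {
  read_fixture("bovine_expressed_trichotomy.tsv")
}

#' Functional TRA/TRD gene-segment counts by species
#'
#' Functional V (with subgroup counts), TRAJ, TRDD and TRDJ repertoire
#' sizes for the bovine UMD3.1 annotation and the human and murine
#' reference repertoires.
#'
#' @return tibble: `species`, `v_functional`, `v_subgroups`,
#'   `traj_functional`, `trdd_functional`, `trdj_functional`.
#' @export
species_functional_counts <- function() {
  read_fixture("species_functional_counts.tsv")
}
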