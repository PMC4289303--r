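# broom-style tidiers and ggplot2 autoplot methods for result objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a catalog summary into long status counts
#' @param x a `trl_catalog_summary`.
#' @param ... unused.
#' @return tibble: `subgroup`, `status`, `n`.
#' @method tidy trl_catalog_summary
#' @export
tidy.trl_catalog_summary <- function(x, ...) {
  x %>%
    filter(.data$subgroup != "Total") %>%
    tidyr::pivot_longer(
      c("functional", "pseudogene", "incomplete"),
      names_to = "status", values_to = "n"
    ) %>%
    select("subgroup", "status", "n")
}

#' One-row summary of a catalog
#' @param x a `trl_catalog_summary`.
#' @param ... unused.
#' @return one-row tibble with total counts and percentages.
#' @method glance trl_catalog_summary
#' @export
glance.trl_catalog_summary <- function(x, ...) {
  tot <- x[x$subgroup == "Total", ]
  tibble(
    n_subgroups = sum(x$subgroup != "Total"),
    total = tot$total, functional = tot$functional,
    pseudogene = tot$pseudogene, incomplete = tot$incomplete,
    pct_functional = tot$pct_functional,
    pct_pseudogene = round(100 * tot$pseudogene / tot$total, 1),
    pct_incomplete = round(100 * tot$incomplete / tot$total, 1)
  )
}

#' Tidy subgroup clusters
#' @param x a `trl_clusters`.
#' @param ... unused.
#' @return the membership tibble.
#' @method tidy trl_clusters
#' @export
tidy.trl_clusters <- function(x, ...) x$membership

#' One-row summary of a clustering
#' @param x a `trl_clusters`.
#' @param ... unused.
#' @method glance trl_clusters
#' @export
glance.trl_clusters <- function(x, ...) {
  tibble(
    n_genes = nrow(x$membership),
    n_clusters = length(unique(x$membership$cluster)),
    n_diagnostics = nrow(x$diagnostics),
    threshold = x$threshold
  )
}

#' Tidy homology units (list columns dropped)
#' @param x a `trl_units`.
#' @param ... unused.
#' @method tidy trl_units
#' @export
tidy.trl_units <- function(x, ...) {
  select(as_tibble(x), -"instances")
}

#' One-row summary of homology units
#' @param x a `trl_units`.
#' @param ... unused.
#' @method glance trl_units
#' @export
glance.trl_units <- function(x, ...) {
  tibble(
    n_units = nrow(x),
    n_instances = sum(x$n_instances),
    n_flagged_indel = sum(x$post_replication_indel)
  )
}

#' One-row trichotomy summary of transcript matches
#' @param x a `trl_matches`.
#' @param ... unused.
#' @method glance trl_matches
#' @export
glance.trl_matches <- function(x, ...) {
  s <- summarize_matches(x)
  tibble(
    n_unique = attr(s, "n_unique"),
    pct_identical = s$pct[s$category == "identical"],
    pct_allelic = s$pct[s$category == "allelic_or_unassembled"],
    pct_novel = s$pct[s$category == "novel"]
  )
}

#' Stacked status bars per subgroup
#' @param object a `trl_catalog_summary`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot trl_catalog_summary
#' @export
autoplot.trl_catalog_summary <- function(object, ...) {
  long <- tidy(object)
  ggplot2::ggplot(long, ggplot2::aes(
    x = factor(.data$subgroup, levels = unique(.data$subgroup)),
    y = .data$n, fill = .data$status
  )) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "subgroup", y = "genes", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Bar chart of the match trichotomy
#' @param object a `trl_trichotomy`.
#' @param ... unused.
#' @method autoplot trl_trichotomy
#' @export
autoplot.trl_trichotomy <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = factor(.data$category, levels = .data$category), y = .data$pct
  )) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = NULL, y = "% of unique expressed V sequences") +
    ggplot2::theme_minimal()
}

#' Expressed subgroup usage bars
#' @param object a `trl_usage`.
#' @param ... unused.
#' @method autoplot trl_usage
#' @export
autoplot.trl_usage <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = stats::reorder(.data$subgroup, -.data$pct), y = .data$pct
  )) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = "subgroup", y = "% of transcripts") +
    ggplot2::theme_minimal()
}

#' Dotplot segments
#' @param object a `trl_dotplot`.
#' @param ... unused.
#' @method autoplot trl_dotplot
#' @export
autoplot.trl_dotplot <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$a_start, xend = .data$a_end,
    y = .data$b_start, yend = .data$b_end,
    colour = .data$strand
  )) +
    ggplot2::geom_segment() +
    ggplot2::labs(x = "sequence A (bp)", y = "sequence B (bp)") +
    ggplot2::theme_minimal()
}
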