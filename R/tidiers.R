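# broom-style accessors for the result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a VPI result table
#'
#' @param x A `clanprof_vpi` from [vpi_by_category()].
#' @param ... Unused.
#' @return A plain tibble: one row per (functional category, partner group).
#' @export
tidy.clanprof_vpi <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- class(tibble())
  out
}

#' @rdname tidy.clanprof_vpi
#' @export
glance.clanprof_vpi <- function(x, ...) {
  tidy(x) |>
    group_by(.data$group) |>
    summarise(
      n_categories = n(),
      mean_vpi = mean(.data$vpi, na.rm = TRUE),
      max_vpi = max(.data$vpi, na.rm = TRUE),
      .groups = "drop"
    )
}

#' Tidy an affinity matrix
#'
#' @param x A `clanprof_affinity` from [affinity_matrix()].
#' @param ... Unused.
#' @return A plain long tibble (`category`, `lineage`, `n_trees`,
#'   `n_paired`, `prop`).
#' @export
tidy.clanprof_affinity <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- class(tibble())
  out
}

#' @rdname tidy.clanprof_affinity
#' @export
glance.clanprof_affinity <- function(x, ...) {
  tidy(x) |>
    summarise(
      n_categories = length(unique(.data$category)),
      n_lineages = length(unique(.data$lineage)),
      n_trees = sum(.data$n_paired > 0),
      max_prop = max(.data$prop, na.rm = TRUE)
    )
}

#' One-row overview of a pipeline report
#'
#' @param x A `clanprof_report` from [run_pipeline()].
#' @param ... Unused.
#' @return A one-row tibble with headline counts and rates.
#' @export
glance.clanprof_report <- function(x, ...) {
  cls <- x$classifications$classification
  nondeg <- sum(cls != "degenerate")
  coh <- x$treestats$cohesive
  tibble(
    n_clusters = nrow(x$clusters),
    n_single_copy = sum(x$clusters$copy_class == "single"),
    n_clean = sum(cls == "clean"),
    n_dirty = sum(cls == "dirty"),
    pct_clean = pct_half_up(sum(cls == "clean"), nondeg),
    n_cohesive = sum(coh, na.rm = TRUE),
    pct_cohesive = pct_half_up(sum(coh, na.rm = TRUE), sum(!is.na(coh)))
  )
}

#' @rdname glance.clanprof_report
#' @export
tidy.clanprof_report <- function(x, ...) {
  x$summary
}
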