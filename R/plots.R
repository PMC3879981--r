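# ggplot2 views of the result tables.

#' @importFrom ggplot2 autoplot ggplot aes geom_tile geom_col facet_wrap
#'   scale_fill_gradientn scale_fill_brewer labs theme_minimal
#'   position_dodge
#' @export
ggplot2::autoplot

#' Heatmap of category-by-lineage tree affinities
#'
#' Each cell is the proportion of a functional category's gene trees that
#' pair the focal clan with the lineage at the given bootstrap threshold.
#'
#' @param object A `clanprof_affinity` from [affinity_matrix()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.clanprof_affinity <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = .data$lineage, y = .data$category, fill = .data$prop)) +
    geom_tile(colour = "grey85") +
    scale_fill_gradientn(colours = c("#20306f", "#4575b4", "#ffffbf",
                                     "#f46d43", "#a50026"),
                         limits = c(0, 1), name = "prop. of trees") +
    labs(x = "partner lineage", y = "functional category",
         title = "Supported pairings of the focal clan by functional category") +
    theme_minimal()
}

#' Bar chart of VPI values per functional category
#'
#' @param object A `clanprof_vpi` from [vpi_by_category()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.clanprof_vpi <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = .data$cog_category, y = .data$vpi, fill = .data$group)) +
    geom_col(position = position_dodge()) +
    scale_fill_brewer(palette = "Set1", name = "partner group") +
    labs(x = "functional category", y = "VPI",
         title = "Variable Preference Index by functional category") +
    theme_minimal()
}

#' Bar chart of profile pattern categories split by classification
#'
#' @param profiles Profile tibble from [build_profiles()].
#' @param classifications Tibble from [rank_and_classify()].
#' @return A ggplot object.
#' @export
plot_profile_patterns <- function(profiles, classifications) {
  df <- profiles |>
    left_join(classifications |> select("cluster_id", "classification"),
              by = "cluster_id")
  ggplot(df, aes(x = .data$category, fill = .data$classification)) +
    ggplot2::geom_bar() +
    facet_wrap(~focal_subset) +
    scale_fill_brewer(palette = "Dark2", name = "ranked profile") +
    labs(x = "phyletic pattern", y = "clusters",
         title = "Phyletic patterns by focal subset") +
    theme_minimal()
}
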