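#' Thresholds for marker-gene classification
#'
#' Defaults follow the recurrence rules used for a 14-mitochondrial /
#' 13-chloroplast compendium: common markers respond in at least 6
#' perturbations of *both* classes; class-specific markers respond in at
#' least 7 mitochondrial (resp. 6 chloroplast) perturbations and in at most
#' 1 perturbation of the other class. `specific_max_other < common_min`
#' guarantees the labels are mutually exclusive.
#'
#' @param common_min Minimum recurrence in each class for a common marker.
#' @param specific_min_mito,specific_min_chloro Minimum recurrence in the
#'   matching class for a specific marker.
#' @param specific_max_other Maximum recurrence allowed in the other class.
#' @return A list of class `marker_thresholds`.
#' @export
marker_thresholds <- function(common_min = 6, specific_min_mito = 7,
                              specific_min_chloro = 6,
                              specific_max_other = 1) {
  th <- list(common_min = common_min,
             specific_min_mito = specific_min_mito,
             specific_min_chloro = specific_min_chloro,
             specific_max_other = specific_max_other)
  if (any(unlist(th) < 0)) {
    abort("marker thresholds must be non-negative",
          class = "retrosig_threshold_error")
  }
  if (th$specific_max_other >= th$common_min) {
    abort("specific_max_other must be smaller than common_min for disjoint labels",
          class = "retrosig_threshold_error")
  }
  structure(th, class = "marker_thresholds")
}

#' Classify genes as common or organelle-specific perturbation markers
#'
#' Applies the recurrence rules of [marker_thresholds()]: `common` when the
#' gene recurs at least `common_min` times in both classes; `mito_specific`
#' (resp. `chloro_specific`) when it reaches the class minimum while
#' recurring at most `specific_max_other` times in the other class;
#' otherwise `none`.
#'
#' @param counts Recurrence counts with `gene_id`, `n_mito`, `n_chloro`
#'   (from [recurrence_counts()]).
#' @param thresholds A [marker_thresholds()] object.
#' @return Tibble with `gene_id`, `n_mito`, `n_chloro`, `label`.
#' @export
classify_markers <- function(counts, thresholds = marker_thresholds()) {
  if (!inherits(thresholds, "marker_thresholds")) {
    abort("thresholds must come from marker_thresholds()",
          class = "retrosig_threshold_error")
  }
  stopifnot(all(c("gene_id", "n_mito", "n_chloro") %in% names(counts)))
  counts |>
    mutate(label = dplyr::case_when(
      .data$n_mito >= thresholds$common_min &
        .data$n_chloro >= thresholds$common_min ~ "common",
      .data$n_mito >= thresholds$specific_min_mito &
        .data$n_chloro <= thresholds$specific_max_other ~ "mito_specific",
      .data$n_chloro >= thresholds$specific_min_chloro &
        .data$n_mito <= thresholds$specific_max_other ~ "chloro_specific",
      .default = "none"
    )) |>
    select("gene_id", "n_mito", "n_chloro", "label")
}

#' Summarise marker classifications
#'
#' Tallies genes per marker label and, for each class and each requested
#' recurrence minimum `k`, the number of genes significantly changed in at
#' least `k` experiments of the class.
#'
#' @param records Output of [classify_markers()].
#' @param k Recurrence minimums to tally per class.
#' @return List with `labels` (tibble `label`, `n`) and `recurrence`
#'   (tibble `class`, `min_experiments`, `n_genes`).
#' @export
marker_summary <- function(records, k = c(4, 6)) {
  labels <- records |>
    count(.data$label, name = "n") |>
    tidyr::complete(label = c("common", "mito_specific", "chloro_specific",
                              "none"), fill = list(n = 0L)) |>
    arrange(.data$label)
  recurrence <- tidyr::expand_grid(class = c("mito", "chloro"),
                                   min_experiments = as.integer(k)) |>
    mutate(n_genes = purrr::map2_int(.data$class, .data$min_experiments,
      function(cl, m) {
        col <- paste0("n_", cl)
        sum(records[[col]] >= m)
      }))
  list(labels = labels, recurrence = recurrence)
}
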