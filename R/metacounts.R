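#' Build the gene-by-experiment response matrix
#'
#' Converts differential-calling results into ternary calls (`up`, `down`,
#' `ns`) tagged with each experiment's perturbation class. Gene-experiment
#' pairs missing from `de` (e.g. absent-filtered) are treated as `ns`.
#'
#' @param de Differential results from [call_differential()].
#' @param samples Sample metadata carrying `experiment` and `class`.
#' @return Tibble with `gene_id`, `experiment`, `class`, `call`.
#' @export
response_matrix <- function(de, samples) {
  classes <- samples |> distinct(.data$experiment, .data$class)
  de |>
    mutate(call = dplyr::case_when(
      .data$significant & .data$direction > 0 ~ "up",
      .data$significant & .data$direction < 0 ~ "down",
      .default = "ns"
    )) |>
    left_join(classes, by = "experiment") |>
    select("gene_id", "experiment", "class", "call")
}

#' Count per-gene recurrences across experiment classes
#'
#' Tallies, for every gene, the number of experiments in each class where
#' the gene was significantly changed (call `up` or `down`; direction is
#' ignored). Optionally only the majority-sign direction is counted.
#'
#' @param rm Response matrix from [response_matrix()].
#' @param consistent_direction If `TRUE`, count only calls sharing the
#'   gene's majority sign across all its significant calls.
#' @return Tibble with `gene_id` and one `n_<class>` column per experiment
#'   class (e.g. `n_mito`, `n_chloro`).
#' @export
recurrence_counts <- function(rm, consistent_direction = FALSE) {
  stopifnot(nrow(rm) > 0)
  sig <- rm |> mutate(hit = .data$call != "ns")
  if (consistent_direction) {
    majority <- sig |>
      filter(.data$hit) |>
      group_by(.data$gene_id) |>
      summarise(maj = ifelse(sum(.data$call == "up") >=
                               sum(.data$call == "down"), "up", "down"),
                .groups = "drop")
    sig <- sig |>
      left_join(majority, by = "gene_id") |>
      mutate(hit = .data$hit & .data$call == .data$maj)
  }
  sig |>
    group_by(.data$gene_id, .data$class) |>
    summarise(n = sum(.data$hit), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "class", values_from = "n",
                       names_prefix = "n_", values_fill = 0L) |>
    arrange(.data$gene_id)
}

#' Genes responsive in at least `min_experiments` of a class
#'
#' @param counts Recurrence counts from [recurrence_counts()].
#' @param class Experiment class, e.g. `"mito"` or `"chloro"`.
#' @param min_experiments Minimum number of experiments of the class in
#'   which the gene must be significantly changed.
#' @return Character vector of gene ids.
#' @export
responsive_set <- function(counts, class, min_experiments = 4) {
  stopifnot(min_experiments >= 1)
  col <- paste0("n_", class)
  if (!col %in% names(counts)) {
    abort(paste0("unknown experiment class: ", class),
          class = "retrosig_lookup_error")
  }
  counts$gene_id[counts[[col]] >= min_experiments]
}

#' Cardinalities of two gene sets and their overlap
#'
#' @param a,b Character vectors of gene ids.
#' @return One-row tibble with `n_a`, `n_b`, `n_intersect`, `n_union`.
#' @export
set_algebra <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  n_int <- length(intersect(a, b))
  tibble(n_a = length(a), n_b = length(b), n_intersect = n_int,
         n_union = length(a) + length(b) - n_int)
}
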