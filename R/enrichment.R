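#' Expected overlap of two sets under random draws from a universe
#'
#' The independence expectation `n_a * n_b / n_universe`, kept unrounded.
#'
#' @param n_a,n_b Sizes of the two sets.
#' @param n_universe Size of the universe both sets are drawn from.
#' @return A single numeric value.
#' @export
expected_overlap <- function(n_a, n_b, n_universe) {
  if (n_universe <= 0) {
    abort("universe must be nonempty", class = "retrosig_enrichment_error")
  }
  if (n_a > n_universe || n_b > n_universe) {
    abort("set sizes cannot exceed the universe",
          class = "retrosig_enrichment_error")
  }
  n_a * n_b / n_universe
}

#' Hypergeometric tail probability for a set overlap
#'
#' For `X ~ Hypergeometric(N = n_universe, K = n_a, n = n_b)`, the
#' over-representation tail is `P(X >= observed)` and the
#' under-representation tail `P(X <= observed)`.
#'
#' @param observed Observed overlap.
#' @param n_a,n_b,n_universe Set and universe sizes.
#' @param tail `"over"` or `"under"`.
#' @return A probability.
#' @export
hypergeom_pvalue <- function(observed, n_a, n_b, n_universe,
                             tail = c("over", "under")) {
  tail <- match.arg(tail)
  if (observed > min(n_a, n_b) || observed < 0) {
    abort("observed overlap impossible for these set sizes",
          class = "retrosig_enrichment_error")
  }
  if (n_a > n_universe || n_b > n_universe) {
    abort("set sizes cannot exceed the universe",
          class = "retrosig_enrichment_error")
  }
  if (tail == "over") {
    phyper(observed - 1, n_a, n_universe - n_a, n_b, lower.tail = FALSE)
  } else {
    phyper(observed, n_a, n_universe - n_a, n_b, lower.tail = TRUE)
  }
}

#' Overlap enrichment of a foreground set against a category
#'
#' Counts the observed intersection, computes the independence expectation
#' and observed/expected ratio (on the unrounded expectation), and both
#' hypergeometric tail probabilities.
#'
#' @param foreground,category,universe Character vectors of gene ids;
#'   `foreground` and `category` must be subsets of `universe`.
#' @return One-row tibble with `foreground_size`, `category_size`,
#'   `universe_size`, `observed`, `expected`, `ratio`, `p_over`, `p_under`.
#' @export
enrichment_test <- function(foreground, category, universe) {
  foreground <- unique(foreground)
  category <- unique(category)
  universe <- unique(universe)
  if (!all(foreground %in% universe) || !all(category %in% universe)) {
    abort("foreground and category must be subsets of the universe",
          class = "retrosig_enrichment_error")
  }
  obs <- length(intersect(foreground, category))
  exp_ <- expected_overlap(length(foreground), length(category),
                           length(universe))
  tibble(
    foreground_size = length(foreground),
    category_size = length(category),
    universe_size = length(universe),
    observed = obs,
    expected = exp_,
    ratio = if (exp_ > 0) obs / exp_ else NA_real_,
    p_over = hypergeom_pvalue(obs, length(foreground), length(category),
                              length(universe), "over"),
    p_under = hypergeom_pvalue(obs, length(foreground), length(category),
                               length(universe), "under")
  )
}

#' Permutation null for a set overlap
#'
#' Draws random foregrounds of the observed size from the universe and
#' compares the resulting overlap distribution with the observed overlap;
#' the empirical over-representation p-value uses add-one smoothing. A
#' Monte-Carlo cross-check of the analytic hypergeometric null.
#'
#' @param foreground,category,universe Character vectors of gene ids.
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed.
#' @return One-row tibble with `observed`, `p_perm`, `null_mean`, `null_sd`,
#'   `n_perm`; the full null distribution is attached as attribute
#'   `"null"`.
#' @export
permutation_null <- function(foreground, category, universe,
                             n_perm = 1000, seed = 1L) {
  stopifnot(n_perm >= 100)
  foreground <- unique(foreground)
  category <- unique(category)
  universe <- unique(universe)
  obs <- length(intersect(foreground, category))
  set.seed(seed)
  in_cat <- universe %in% category
  k <- length(foreground)
  null <- vapply(seq_len(n_perm), function(i) {
    sum(in_cat[sample.int(length(universe), k)])
  }, integer(1))
  out <- tibble(
    observed = obs,
    p_perm = (sum(null >= obs) + 1) / (n_perm + 1),
    null_mean = mean(null),
    null_sd = sd(null),
    n_perm = as.integer(n_perm)
  )
  attr(out, "null") <- null
  out
}

#' Scan a category map for over- and under-represented categories
#'
#' Runs [enrichment_test()] for every category and flags those with a tail
#' probability below `p_threshold` and an observed/expected ratio at least
#' `min_ratio`-fold away from 1 in either direction.
#'
#' @param foreground Character vector of gene ids.
#' @param categories Long tibble with `category` and `gene_id` columns.
#' @param universe Character vector of gene ids.
#' @param p_threshold Tail-probability threshold for retention.
#' @param min_ratio Minimum fold-distortion of the observed/expected ratio.
#' @return Tibble with one row per category (`category` column first),
#'   the [enrichment_test()] columns, the smaller tail as `p_value`, its
#'   `direction` (`over`/`under`) and a logical `retained`.
#' @export
category_scan <- function(foreground, categories, universe,
                          p_threshold = 0.05, min_ratio = 2) {
  stopifnot(nrow(categories) > 0)
  res <- categories |>
    group_by(.data$category) |>
    dplyr::group_modify(~ enrichment_test(foreground,
                                          intersect(.x$gene_id, universe),
                                          universe)) |>
    ungroup() |>
    mutate(
      direction = ifelse(.data$p_over <= .data$p_under, "over", "under"),
      p_value = pmin(.data$p_over, .data$p_under),
      retained = .data$p_value < p_threshold &
        (.data$ratio >= min_ratio | .data$ratio <= 1 / min_ratio)
    )
  res
}
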