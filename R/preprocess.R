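#' @noRd
as_gene_matrix <- function(tbl) {
  stopifnot(is.data.frame(tbl), "gene_id" %in% names(tbl))
  m <- as.matrix(tbl[setdiff(names(tbl), "gene_id")])
  rownames(m) <- tbl$gene_id
  m
}

#' @noRd
check_aligned <- function(expression, presence, samples) {
  if (!identical(dim(expression), dim(presence)) ||
      !identical(names(expression), names(presence)) ||
      !identical(expression$gene_id, presence$gene_id)) {
    abort("expression and presence tables are not aligned",
          class = "retrosig_alignment_error")
  }
  sample_cols <- setdiff(names(expression), "gene_id")
  if (!setequal(sample_cols, samples$sample_id)) {
    abort("sample metadata does not match expression columns",
          class = "retrosig_alignment_error")
  }
  if (anyDuplicated(expression$gene_id)) {
    abort("duplicate gene ids", class = "retrosig_alignment_error")
  }
  invisible(TRUE)
}

#' Presence filter per experiment
#'
#' A gene is retained in an experiment when, in at least one condition group
#' of that experiment, it is *not called absent in at least half of the
#' chips*: the number of present calls must reach
#' `ceiling(min_fraction * group size)` in some group. Each experiment
#' filters independently.
#'
#' @param expression Expression tibble (`gene_id` plus one column per sample).
#' @param presence Present/absent call tibble of the same shape (`TRUE` =
#'   present).
#' @param samples Sample metadata tibble (`sample_id`, `experiment`,
#'   `condition`, ...).
#' @param min_fraction Minimum fraction of present chips required in a
#'   group, default 0.5.
#'
#' @return Tibble with `gene_id`, `experiment` and a logical `retained`.
#' @export
presence_filter <- function(expression, presence, samples,
                            min_fraction = 0.5) {
  check_aligned(expression, presence, samples)
  stopifnot(min_fraction >= 0, min_fraction <= 1)
  pres <- as_gene_matrix(presence)
  groups <- samples |>
    mutate(group = paste(.data$experiment, .data$condition, sep = "/"))
  retained_by_exp <- lapply(split(groups, groups$experiment), function(g) {
    ok <- rep(FALSE, nrow(pres))
    for (grp in split(g$sample_id, g$condition)) {
      need <- ceiling(min_fraction * length(grp))
      ok <- ok | rowSums(pres[, grp, drop = FALSE]) >= need
    }
    unname(ok)
  })
  purrr::imap(retained_by_exp, function(ok, exp) {
    tibble(gene_id = rownames(pres), experiment = exp, retained = ok)
  }) |>
    bind_rows() |>
    arrange(.data$experiment, .data$gene_id)
}

#' Per-experiment fold changes with the absent-call rule
#'
#' Computes treatment-over-control fold changes per gene and experiment as
#' the ratio of geometric means, i.e. `2^(mean treatment log2 - mean control
#' log2)`. Genes failing the presence filter in an experiment are assigned a
#' fold change of exactly 1 (log2 fold change 0) for that experiment.
#'
#' @inheritParams presence_filter
#' @param mean_fun Either `"geometric"` (mean on the log2 scale, default) or
#'   `"arithmetic"` (mean of linear intensities, ratio re-logged).
#'
#' @return Tibble with `gene_id`, `experiment`, `log2_fc`, `fc`, `retained`.
#' @export
fold_changes <- function(expression, presence, samples, min_fraction = 0.5,
                         mean_fun = c("geometric", "arithmetic")) {
  mean_fun <- match.arg(mean_fun)
  check_aligned(expression, presence, samples)
  expr <- as_gene_matrix(expression)
  ret <- presence_filter(expression, presence, samples, min_fraction)
  per_exp <- lapply(split(samples, samples$experiment), function(g) {
    ctrl <- g$sample_id[g$condition == "control"]
    trt <- g$sample_id[g$condition == "treatment"]
    if (length(ctrl) == 0L || length(trt) == 0L) {
      abort(paste0("experiment ", g$experiment[1],
                   " lacks a control or treatment group"),
            class = "retrosig_empty_group_error")
    }
    l2 <- if (mean_fun == "geometric") {
      rowMeans(expr[, trt, drop = FALSE]) - rowMeans(expr[, ctrl, drop = FALSE])
    } else {
      log2(rowMeans(2^expr[, trt, drop = FALSE]) /
             rowMeans(2^expr[, ctrl, drop = FALSE]))
    }
    tibble(gene_id = rownames(expr), experiment = g$experiment[1],
           log2_fc = unname(l2))
  })
  bind_rows(per_exp) |>
    inner_join(ret, by = c("gene_id", "experiment")) |>
    mutate(log2_fc = ifelse(.data$retained, .data$log2_fc, 0),
           fc = 2^.data$log2_fc) |>
    arrange(.data$experiment, .data$gene_id)
}

#' Fold change for one gene in one experiment
#'
#' Scalar convenience wrapper around [fold_changes()]; returns the linear
#' treatment/control ratio, with the absent-call rule applied (fold change 1
#' when the gene fails the presence criterion in that experiment).
#'
#' @inheritParams presence_filter
#' @param gene,experiment Gene and experiment identifiers.
#' @return A single numeric ratio.
#' @export
fold_change <- function(expression, presence, samples, gene, experiment) {
  if (!gene %in% expression$gene_id) {
    abort(paste0("unknown gene: ", gene), class = "retrosig_lookup_error")
  }
  if (!experiment %in% samples$experiment) {
    abort(paste0("unknown experiment: ", experiment),
          class = "retrosig_lookup_error")
  }
  keep <- samples$experiment == experiment
  sub_samples <- samples[keep, , drop = FALSE]
  cols <- c("gene_id", sub_samples$sample_id)
  fc <- fold_changes(expression[expression$gene_id == gene, cols],
                     presence[presence$gene_id == gene, cols],
                     sub_samples)
  fc$fc[1]
}
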