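#' Fold-change profile matrix for clustering
#'
#' Arranges per-experiment log2 fold changes into an items-by-features
#' matrix. Absent-filtered entries already carry log2 fold change 0 (the
#' fold-change-1 rule), so every item shares a complete feature space.
#'
#' @param fc Long tibble with `gene_id`, `experiment`, `log2_fc` (from
#'   [fold_changes()] or [call_differential()]).
#' @param items Whether rows are `"experiment"`s (features = genes, the
#'   layout used to cluster experiments) or `"gene"`s.
#' @param genes Optional gene subset (e.g. a pooled responsive set).
#' @return Numeric matrix with item row names.
#' @export
profile_matrix <- function(fc, items = c("experiment", "gene"),
                           genes = NULL) {
  items <- match.arg(items)
  if (!is.null(genes)) fc <- fc |> filter(.data$gene_id %in% genes)
  wide <- fc |>
    select("gene_id", "experiment", "log2_fc") |>
    tidyr::pivot_wider(names_from = "experiment", values_from = "log2_fc")
  m <- as_gene_matrix(wide)
  if (items == "experiment") t(m) else m
}

#' Pearson correlation distance between profiles
#'
#' `d(i, j) = 1 - r(i, j)` over item rows; symmetric with zero diagonal and
#' range \[0, 2\].
#'
#' @param pm Items-by-features matrix, e.g. from [profile_matrix()].
#' @return A `dist` object.
#' @export
pearson_distance <- function(pm) {
  if (nrow(pm) < 2) {
    abort("need at least two items to compute distances",
          class = "retrosig_cluster_error")
  }
  vars <- apply(pm, 1, var)
  if (any(vars == 0)) {
    abort(paste0("zero-variance profile(s): ",
                 paste(rownames(pm)[vars == 0], collapse = ", ")),
          class = "retrosig_cluster_error")
  }
  as.dist(1 - cor(t(pm)))
}

#' Average-linkage (UPGMA) hierarchical clustering
#'
#' @param d A `dist` object, e.g. from [pearson_distance()].
#' @return An `hclust` tree.
#' @export
average_linkage <- function(d) {
  hclust(d, method = "average")
}

#' Serialize an hclust tree to Newick
#'
#' Branch lengths follow the ultrametric convention in which the path
#' between two leaves equals their merge height (each child edge spans half
#' the height difference between parent and child node). Leaf labels
#' containing characters outside `[A-Za-z0-9_.\-]` are single-quoted.
#'
#' @param tree An `hclust` object.
#' @return A Newick string terminated by `;`.
#' @seealso [from_newick()]
#' @export
to_newick <- function(tree) {
  if (!inherits(tree, "hclust")) {
    abort("tree must be an hclust object", class = "retrosig_cluster_error")
  }
  quote_label <- function(x) {
    ifelse(grepl("^[A-Za-z0-9_.-]+$", x), x,
           paste0("'", gsub("'", "''", x), "'"))
  }
  labels <- quote_label(tree$labels)
  node_height <- tree$height
  ser <- function(idx, parent_height) {
    if (idx < 0) {
      return(paste0(labels[-idx], ":",
                    format(parent_height / 2, digits = 12)))
    }
    h <- node_height[idx]
    children <- tree$merge[idx, ]
    inner <- paste(ser(children[1], h), ser(children[2], h), sep = ",")
    bl <- (parent_height - h) / 2
    if (is.na(parent_height)) {
      paste0("(", inner, ")")
    } else {
      paste0("(", inner, "):", format(bl, digits = 12))
    }
  }
  paste0(ser(nrow(tree$merge), NA_real_), ";")
}

#' Parse a Newick string
#'
#' @param text Newick string.
#' @return An `ape` `phylo` tree.
#' @export
from_newick <- function(text) {
  tr <- ape::read.tree(text = text)
  if (is.null(tr)) {
    abort("malformed Newick string", class = "retrosig_cluster_error")
  }
  # undo single-quoting of labels
  quoted <- grepl("^'.*'$", tr$tip.label)
  tr$tip.label[quoted] <- gsub("''", "'",
                               sub("^'(.*)'$", "\\1", tr$tip.label[quoted]))
  tr
}

#' Cluster experiments on fold-change profiles
#'
#' Convenience wrapper: builds the experiment profile matrix (optionally on
#' a pooled responsive gene set), computes Pearson distances, runs UPGMA
#' and optionally cuts the tree.
#'
#' @inheritParams profile_matrix
#' @param k Optional number of clusters to cut.
#' @return List with `tree` (`hclust`), `dist`, and (when `k` is given)
#'   `clusters`, a named integer vector.
#' @export
cluster_experiments <- function(fc, genes = NULL, k = NULL) {
  pm <- profile_matrix(fc, items = "experiment", genes = genes)
  d <- pearson_distance(pm)
  tree <- average_linkage(d)
  out <- list(tree = tree, dist = d)
  if (!is.null(k)) out$clusters <- cutree(tree, k = k)
  out
}
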