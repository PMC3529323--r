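#' Read and write compendium tables
#'
#' Expression and presence matrices are stored as tab-separated files with
#' genes in rows (`gene_id` first column) and one column per sample; sample
#' metadata, planted truth and effects as plain TSV. Presence flags are
#' encoded 1 = present, 0 = absent.
#'
#' @param compendium A `compendium` list as returned by
#'   [simulate_compendium()] (any subset of its tables is written).
#' @param dir Output directory, created if needed.
#' @return `write_compendium()` invisibly returns the paths written;
#'   `read_compendium()` returns a `compendium` list.
#' @export
write_compendium <- function(compendium, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  put <- function(tbl, name) {
    p <- file.path(dir, name)
    readr::write_tsv(tbl, p)
    paths[[name]] <<- p
  }
  put(compendium$expression, "expression.tsv")
  pres <- compendium$presence
  pres[setdiff(names(pres), "gene_id")] <-
    lapply(pres[setdiff(names(pres), "gene_id")], as.integer)
  put(pres, "presence.tsv")
  put(compendium$samples, "samples.tsv")
  if (!is.null(compendium$truth)) put(compendium$truth, "truth.tsv")
  if (!is.null(compendium$effects)) put(compendium$effects, "effects.tsv")
  if (!is.null(compendium$config)) {
    yaml::write_yaml(unclass(compendium$config), file.path(dir, "config.yaml"))
    paths[["config.yaml"]] <- file.path(dir, "config.yaml")
  }
  invisible(paths)
}

#' @rdname write_compendium
#' @export
read_compendium <- function(dir) {
  rd <- function(name) {
    p <- file.path(dir, name)
    if (!file.exists(p)) return(NULL)
    readr::read_tsv(p, show_col_types = FALSE)
  }
  pres <- rd("presence.tsv")
  if (!is.null(pres)) {
    pres[setdiff(names(pres), "gene_id")] <-
      lapply(pres[setdiff(names(pres), "gene_id")], function(x) x > 0)
  }
  cfg_path <- file.path(dir, "config.yaml")
  cfg <- if (file.exists(cfg_path)) {
    structure(yaml::read_yaml(cfg_path), class = "synthetic_config")
  }
  structure(list(
    expression = rd("expression.tsv"), presence = pres,
    samples = rd("samples.tsv"), truth = rd("truth.tsv"),
    effects = rd("effects.tsv"), config = cfg
  ), class = "compendium")
}

#' Read a gene list file
#'
#' One gene id per line, with an optional second tab-separated column giving
#' a compartment (or other category) label.
#'
#' @param path File path.
#' @return Tibble with `gene_id` and, when present in the file, `label`.
#' @export
read_gene_list <- function(path) {
  tbl <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE)
  names(tbl) <- c("gene_id", "label")[seq_along(tbl)]
  tbl
}

#' Read a category map file
#'
#' Each line: category id, a tab, gene id.
#'
#' @param path File path.
#' @return Long tibble with `category` and `gene_id`.
#' @export
read_category_map <- function(path) {
  readr::read_tsv(path, col_names = c("category", "gene_id"),
                  show_col_types = FALSE)
}

#' Read and write motif libraries
#'
#' Two tab-separated columns: motif name and IUPAC consensus string.
#'
#' @param motifs Tibble with `name` and `iupac`.
#' @param path File path.
#' @export
write_motif_library <- function(motifs, path) {
  readr::write_tsv(motifs[c("name", "iupac")], path, col_names = FALSE)
  invisible(path)
}

#' @rdname write_motif_library
#' @export
read_motif_library <- function(path) {
  readr::read_tsv(path, col_names = c("name", "iupac"),
                  show_col_types = FALSE)
}

#' Read and write promoter sets as FASTA
#'
#' @param promoters Tibble with `promoter_id` and `sequence` (e.g. from
#'   [simulate_promoters()]).
#' @param path FASTA file path.
#' @export
write_promoters_fasta <- function(promoters, path) {
  seqs <- Biostrings::DNAStringSet(setNames(promoters$sequence,
                                            promoters$promoter_id))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' @rdname write_promoters_fasta
#' @export
read_promoters_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  tibble(promoter_id = names(seqs), sequence = unname(as.character(seqs)))
}
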