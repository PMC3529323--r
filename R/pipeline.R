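#' Run the perturbation meta-analysis pipeline
#'
#' Orchestrates the analysis stages over a working directory of tabular
#' artifacts. Every stage reads the artifacts of its upstream stages from
#' `outdir` and writes its own as TSV/FASTA/Newick/JSON, so stage subsets
#' can be re-run against saved intermediates. A `manifest.json` with the
#' md5 checksum of every written file, a hash of the semantic
#' configuration, and the seeds used is refreshed on each call; re-running
#' with an identical configuration reproduces byte-identical numeric
#' artifacts.
#'
#' Stages and their artifacts:
#' \describe{
#'   \item{simulate}{synthetic compendium (`expression.tsv`,
#'     `presence.tsv`, `samples.tsv`, `truth.tsv`, `effects.tsv`,
#'     `config.yaml`) and synthetic promoters (`promoters.fasta`,
#'     `promoter_truth.tsv`).}
#'   \item{preprocess}{`fold_changes.tsv` (presence filter applied).}
#'   \item{diffcall}{`de_results.tsv`.}
#'   \item{metacounts}{`response_matrix.tsv` (calls coded -1/0/+1),
#'     `recurrence.tsv`, `venn.json`.}
#'   \item{enrich}{`enrichment.tsv`: each class's responsive set against
#'     every annotation category.}
#'   \item{markers}{`markers.tsv`.}
#'   \item{cluster}{`experiments.nwk`, `profile_matrix.tsv`.}
#'   \item{motifs}{`motif_counts.tsv`, `motif_enrichment.tsv`.}
#' }
#'
#' @param outdir Working directory for artifacts.
#' @param config [synthetic_config()] used by the `simulate` stage; its
#'   `seed` drives all pipeline randomness (the promoter simulation uses
#'   `seed + 1`).
#' @param stages Ordered subset of the stage names above.
#' @param fc_threshold,ppde_threshold,window,prior_df,min_fraction
#'   Differential-calling settings, see [call_differential()].
#' @param min_experiments Recurrence minimum defining a class's responsive
#'   set.
#' @param thresholds [marker_thresholds()] for marker classification.
#' @param enrich_p,enrich_min_ratio Retention thresholds of
#'   [category_scan()].
#' @param motifs Motif library tibble for the `motifs` stage.
#' @param promoter_args List of arguments for [simulate_promoters()]
#'   (defaults: 30 foreground and 100 background promoters, W-box motif,
#'   rates 2 and 0.3).
#' @return Invisibly, the manifest as a list (`files`, `config_hash`,
#'   `seed`).
#' @export
run_pipeline <- function(outdir,
                         config = synthetic_config(),
                         stages = c("simulate", "preprocess", "diffcall",
                                    "metacounts", "enrich", "markers",
                                    "cluster", "motifs"),
                         fc_threshold = 2, ppde_threshold = 0.95,
                         window = 101, prior_df = 10, min_fraction = 0.5,
                         min_experiments = 4,
                         thresholds = marker_thresholds(),
                         enrich_p = 0.05, enrich_min_ratio = 2,
                         motifs = motif_library(),
                         promoter_args = list()) {
  all_stages <- c("simulate", "preprocess", "diffcall", "metacounts",
                  "enrich", "markers", "cluster", "motifs")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(outdir, "run.log")
  log_line <- function(...) {
    cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), "|", ...,
        "\n", file = log_path, append = TRUE)
  }
  need <- function(stage, files) {
    missing <- files[!file.exists(file.path(outdir, files))]
    if (length(missing) > 0) {
      abort(paste0("stage '", stage, "' is missing upstream artifact(s): ",
                   paste(missing, collapse = ", ")),
            class = "retrosig_dependency_error")
    }
  }
  written <- character(0)
  emit <- function(tbl, name) {
    readr::write_tsv(tbl, file.path(outdir, name))
    written <<- c(written, name)
  }

  if ("simulate" %in% stages) {
    log_line("simulate: seed", config$seed)
    comp <- simulate_compendium(config)
    write_compendium(comp, outdir)
    written <- c(written, "expression.tsv", "presence.tsv", "samples.tsv",
                 "truth.tsv", "effects.tsv", "config.yaml")
    pargs <- utils::modifyList(
      list(n_foreground = 30, n_background = 100, motif = "TTGACY",
           planted_rate_fg = 2, planted_rate_bg = 0.3,
           seed = config$seed + 1L),
      promoter_args)
    prom <- do.call(simulate_promoters, pargs)
    write_promoters_fasta(prom, file.path(outdir, "promoters.fasta"))
    emit(prom |> select("promoter_id", "set", "planted_count"),
         "promoter_truth.tsv")
    written <- c(written, "promoters.fasta")
  }

  comp <- NULL
  get_comp <- function(stage) {
    need(stage, c("expression.tsv", "presence.tsv", "samples.tsv"))
    if (is.null(comp)) comp <<- read_compendium(outdir)
    comp
  }

  if ("preprocess" %in% stages) {
    cp <- get_comp("preprocess")
    log_line("preprocess")
    emit(fold_changes(cp$expression, cp$presence, cp$samples, min_fraction),
         "fold_changes.tsv")
  }

  if ("diffcall" %in% stages) {
    cp <- get_comp("diffcall")
    log_line("diffcall: fc >", fc_threshold, ", ppde >", ppde_threshold)
    de <- call_differential(cp$expression, cp$presence, cp$samples,
                            fc_threshold, ppde_threshold, window, prior_df,
                            min_fraction)
    emit(de, "de_results.tsv")
  }

  if ("metacounts" %in% stages) {
    need("metacounts", c("de_results.tsv", "samples.tsv"))
    log_line("metacounts: responsive at >=", min_experiments)
    de <- readr::read_tsv(file.path(outdir, "de_results.tsv"),
                          show_col_types = FALSE)
    smp <- readr::read_tsv(file.path(outdir, "samples.tsv"),
                           show_col_types = FALSE)
    rm_ <- response_matrix(de, smp)
    emit(rm_ |>
           mutate(code = dplyr::case_match(.data$call, "up" ~ 1L,
                                           "down" ~ -1L, "ns" ~ 0L)) |>
           select("gene_id", "experiment", "code") |>
           tidyr::pivot_wider(names_from = "experiment",
                              values_from = "code"),
         "response_matrix.tsv")
    counts <- recurrence_counts(rm_)
    emit(counts, "recurrence.tsv")
    sets <- lapply(c(mito = "mito", chloro = "chloro"), function(cl) {
      responsive_set(counts, cl, min_experiments)
    })
    venn <- set_algebra(sets$mito, sets$chloro)
    jsonlite::write_json(as.list(venn), file.path(outdir, "venn.json"),
                         auto_unbox = TRUE)
    written <- c(written, "venn.json")
  }

  if ("enrich" %in% stages) {
    need("enrich", c("recurrence.tsv", "truth.tsv", "expression.tsv"))
    log_line("enrich")
    counts <- readr::read_tsv(file.path(outdir, "recurrence.tsv"),
                              show_col_types = FALSE)
    truth <- readr::read_tsv(file.path(outdir, "truth.tsv"),
                             show_col_types = FALSE)
    categories <- category_map_from_truth(truth)
    universe <- truth$gene_id
    rep_ <- purrr::map(c("mito", "chloro"), function(cl) {
      fgset <- responsive_set(counts, cl, min_experiments)
      category_scan(fgset, categories, universe, enrich_p,
                    enrich_min_ratio) |>
        mutate(foreground = cl, .before = 1)
    }) |> bind_rows()
    emit(rep_, "enrichment.tsv")
  }

  if ("markers" %in% stages) {
    need("markers", "recurrence.tsv")
    log_line("markers")
    counts <- readr::read_tsv(file.path(outdir, "recurrence.tsv"),
                              show_col_types = FALSE)
    emit(classify_markers(counts, thresholds), "markers.tsv")
  }

  if ("cluster" %in% stages) {
    need("cluster", c("de_results.tsv", "recurrence.tsv"))
    log_line("cluster")
    de <- readr::read_tsv(file.path(outdir, "de_results.tsv"),
                          show_col_types = FALSE)
    counts <- readr::read_tsv(file.path(outdir, "recurrence.tsv"),
                              show_col_types = FALSE)
    pooled <- union(responsive_set(counts, "mito", min_experiments),
                    responsive_set(counts, "chloro", min_experiments))
    cl <- cluster_experiments(de, genes = pooled)
    writeLines(to_newick(cl$tree), file.path(outdir, "experiments.nwk"))
    written <- c(written, "experiments.nwk")
    pm <- profile_matrix(de, items = "experiment", genes = pooled)
    ord <- cl$tree$order
    emit(as_tibble(t(pm[ord, , drop = FALSE]), rownames = "gene_id"),
         "profile_matrix.tsv")
  }

  if ("motifs" %in% stages) {
    need("motifs", c("promoters.fasta", "promoter_truth.tsv"))
    log_line("motifs")
    prom <- read_promoters_fasta(file.path(outdir, "promoters.fasta"))
    truth <- readr::read_tsv(file.path(outdir, "promoter_truth.tsv"),
                             show_col_types = FALSE)
    prom <- prom |> left_join(truth, by = "promoter_id")
    counts <- count_motifs(prom, motifs)
    emit(counts, "motif_counts.tsv")
    fg <- counts |>
      filter(.data$promoter_id %in%
               truth$promoter_id[truth$set == "foreground"])
    bg <- counts |>
      filter(.data$promoter_id %in%
               truth$promoter_id[truth$set == "background"])
    enr <- bind_rows(
      motif_enrichment(fg, bg, "promoter_presence") |>
        mutate(mode = "promoter_presence", .before = 1),
      motif_enrichment(fg, bg, "occurrence_rate",
                       promoter_length = nchar(prom$sequence[1])) |>
        mutate(mode = "occurrence_rate", .before = 1)
    )
    emit(enr, "motif_enrichment.tsv")
  }

  settings <- list(
    config = unclass(config), fc_threshold = fc_threshold,
    ppde_threshold = ppde_threshold, window = window, prior_df = prior_df,
    min_fraction = min_fraction, min_experiments = min_experiments,
    thresholds = unclass(thresholds), enrich_p = enrich_p,
    enrich_min_ratio = enrich_min_ratio,
    motifs = as.list(motifs)
  )
  config_hash <- unname(tools::md5sum(
    textConnection_md5(yaml::as.yaml(settings))))
  files <- sort(unique(written))
  manifest <- list(
    files = setNames(as.list(unname(
      tools::md5sum(file.path(outdir, files)))), files),
    config_hash = config_hash,
    seed = config$seed
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  log_line("done:", length(files), "artifact(s), config", config_hash)
  invisible(manifest)
}

# md5 of an in-memory string via a temp file (tools::md5sum is file-based)
textConnection_md5 <- function(text) {
  tf <- tempfile()
  writeLines(text, tf)
  tf
}
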