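#' Configuration for a synthetic perturbation compendium
#'
#' Describes the statistical structure of a multi-experiment expression
#' compendium emulating a meta-analysis of organelle perturbation studies:
#' replicated log2-scale intensities per experiment, a shared
#' stress-responsive gene block responding under both mitochondrial and
#' chloroplast perturbations, organelle-specific blocks, non-responsive
#' background genes, and random present/absent detection calls.
#'
#' Defaults mirror the compendium analysed downstream: 14 mitochondrial and
#' 13 chloroplast perturbation experiments, 3 replicates per condition,
#' planted effects of 2 on the log2 scale with replicate noise of 0.25, and
#' a 0.7 probability that a responsive gene is actually perturbed in any
#' given experiment of its class.
#'
#' @param n_genes Number of genes (probe sets).
#' @param n_mito,n_chloro Number of mitochondrial / chloroplast perturbation
#'   experiments.
#' @param n_other Number of additional "mixed" experiments emulating generic
#'   (non-organellar) stress conditions; these perturb only the shared block.
#' @param n_replicates Replicates per condition (control and treatment).
#' @param frac_shared,frac_mito_specific,frac_chloro_specific Fractions of
#'   genes responsive in both classes / only mitochondrial / only chloroplast
#'   experiments. Must sum to at most 1.
#' @param respond_prob Probability that a responsive gene is perturbed in any
#'   single experiment of its class.
#' @param effect_size_log2 Absolute planted log2 fold change of a response.
#' @param noise_sd_log2 Replicate noise standard deviation (log2 scale).
#' @param absent_prob Probability that a probe is called absent on one chip,
#'   independently per chip.
#' @param frac_compartment_biased Fraction of class-specific responsive genes
#'   annotated to the matching compartment (mitochondria or chloroplasts).
#' @param fixed_sign If `TRUE` (default) the sign of a gene's response is
#'   fixed across experiments; otherwise it is redrawn per experiment.
#' @param n_forced_absent Number of gene/experiment pairs forced absent on
#'   every chip of the experiment, to exercise the absent-call fold-change
#'   rule.
#' @param baseline_mean,baseline_sd Mean and sd of per-gene baseline log2
#'   intensities.
#' @param seed Integer seed; all randomness in [simulate_compendium()] flows
#'   from it.
#'
#' @return A list of class `synthetic_config`.
#' @seealso [simulate_compendium()]
#' @export
synthetic_config <- function(n_genes = 2000,
                             n_mito = 14,
                             n_chloro = 13,
                             n_other = 0,
                             n_replicates = 3,
                             frac_shared = 0.06,
                             frac_mito_specific = 0.06,
                             frac_chloro_specific = 0.06,
                             respond_prob = 0.7,
                             effect_size_log2 = 2,
                             noise_sd_log2 = 0.25,
                             absent_prob = 0.05,
                             frac_compartment_biased = 0.8,
                             fixed_sign = TRUE,
                             n_forced_absent = 0,
                             baseline_mean = 8,
                             baseline_sd = 2,
                             seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes), n_mito = as.integer(n_mito),
    n_chloro = as.integer(n_chloro), n_other = as.integer(n_other),
    n_replicates = as.integer(n_replicates),
    frac_shared = frac_shared, frac_mito_specific = frac_mito_specific,
    frac_chloro_specific = frac_chloro_specific,
    respond_prob = respond_prob, effect_size_log2 = effect_size_log2,
    noise_sd_log2 = noise_sd_log2, absent_prob = absent_prob,
    frac_compartment_biased = frac_compartment_biased,
    fixed_sign = isTRUE(fixed_sign),
    n_forced_absent = as.integer(n_forced_absent),
    baseline_mean = baseline_mean, baseline_sd = baseline_sd,
    seed = as.integer(seed)
  )
  fracs <- c(cfg$frac_shared, cfg$frac_mito_specific, cfg$frac_chloro_specific,
             cfg$respond_prob, cfg$absent_prob, cfg$frac_compartment_biased)
  if (any(fracs < 0) || any(fracs > 1)) {
    abort("all fractions and probabilities must lie in [0, 1]",
          class = "retrosig_invalid_config")
  }
  if (cfg$frac_shared + cfg$frac_mito_specific + cfg$frac_chloro_specific > 1) {
    abort("responsive fractions must sum to at most 1",
          class = "retrosig_invalid_config")
  }
  if (cfg$n_genes < 1 || cfg$n_mito < 1 || cfg$n_chloro < 1 ||
      cfg$n_replicates < 1) {
    abort("counts must be >= 1", class = "retrosig_invalid_config")
  }
  if (cfg$noise_sd_log2 <= 0) {
    abort("noise_sd_log2 must be positive", class = "retrosig_invalid_config")
  }
  structure(cfg, class = "synthetic_config")
}

# Genome-wide compartment base rates used for unbiased genes; proportions of
# the 22810 ATH1 probe sets annotated to each list in the reference
# annotation tables (chloroplast 2198, mitochondrion 1178, peroxisome 287,
# transcription factor 1661).
.compartment_base_rates <- function() {
  n <- 22810
  p <- c(chloroplasts = 2198 / n, mitochondria = 1178 / n,
         peroxisome = 287 / n, transcription_factor = 1661 / n)
  c(p, none = 1 - sum(p))
}

#' Generate a synthetic perturbation compendium with planted truth
#'
#' Draws per-gene baseline log2 intensities, plants signed log2 effects for
#' responsive genes in experiments of their class (each with probability
#' `respond_prob`), adds replicate noise, and draws i.i.d. present/absent
#' calls per chip. Compartment annotations are planted so that a
#' configurable fraction of class-specific genes is annotated to the
#' matching organelle, the remainder following genome-wide base rates.
#'
#' @param config A [synthetic_config()].
#'
#' @return A list of class `compendium` with elements
#' \describe{
#'   \item{expression}{tibble, `gene_id` plus one column of log2 intensities
#'     per sample.}
#'   \item{presence}{tibble of the same shape; `TRUE` = present call.}
#'   \item{samples}{tibble with `sample_id`, `experiment`, `class`
#'     (`mito`/`chloro`/`other`), `condition` (`control`/`treatment`),
#'     `replicate`.}
#'   \item{truth}{tibble with `gene_id`, `label` (`shared`, `mito_specific`,
#'     `chloro_specific`, `background`), `sign`, `compartment`.}
#'   \item{effects}{long tibble `gene_id` x `experiment` -> planted signed
#'     log2 `effect` (0 for non-responses).}
#'   \item{config}{the input configuration.}
#' }
#' Identical configurations (including the seed) reproduce identical output.
#' @export
simulate_compendium <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_genes
  genes <- sprintf("g%05d", seq_len(n))

  n_shared <- round(config$frac_shared * n)
  n_mito_sp <- round(config$frac_mito_specific * n)
  n_chloro_sp <- round(config$frac_chloro_specific * n)
  labels <- rep("background", n)
  slots <- sample.int(n, n_shared + n_mito_sp + n_chloro_sp)
  labels[slots[seq_len(n_shared)]] <- "shared"
  labels[slots[n_shared + seq_len(n_mito_sp)]] <- "mito_specific"
  labels[slots[n_shared + n_mito_sp + seq_len(n_chloro_sp)]] <- "chloro_specific"

  signs <- ifelse(labels == "background", 0L,
                  sample(c(-1L, 1L), n, replace = TRUE))

  base_rates <- .compartment_base_rates()
  compartment <- sample(names(base_rates), n, replace = TRUE,
                        prob = base_rates)
  biased <- runif(n) < config$frac_compartment_biased
  compartment[labels == "mito_specific" & biased] <- "mitochondria"
  compartment[labels == "chloro_specific" & biased] <- "chloroplasts"

  experiments <- tibble(
    experiment = c(sprintf("mito_%02d", seq_len(config$n_mito)),
                   sprintf("chloro_%02d", seq_len(config$n_chloro)),
                   if (config$n_other > 0)
                     sprintf("other_%02d", seq_len(config$n_other))),
    class = c(rep("mito", config$n_mito), rep("chloro", config$n_chloro),
              rep("other", config$n_other))
  )
  n_exp <- nrow(experiments)

  # genes eligible to respond in each experiment class
  responds_in_class <- function(lab, cls) {
    lab == "shared" |
      (lab == "mito_specific" & cls == "mito") |
      (lab == "chloro_specific" & cls == "chloro")
  }
  effect_mat <- matrix(0, n, n_exp, dimnames = list(genes, experiments$experiment))
  for (j in seq_len(n_exp)) {
    eligible <- responds_in_class(labels, experiments$class[j])
    hit <- eligible & (runif(n) < config$respond_prob)
    sgn <- if (config$fixed_sign) signs else sample(c(-1L, 1L), n, replace = TRUE)
    effect_mat[, j] <- ifelse(hit, sgn * config$effect_size_log2, 0)
  }

  samples <- tidyr::expand_grid(
    experiment = experiments$experiment,
    condition = c("control", "treatment"),
    replicate = seq_len(config$n_replicates)
  ) |>
    left_join(experiments, by = "experiment") |>
    mutate(sample_id = paste(.data$experiment, .data$condition,
                             .data$replicate, sep = ".")) |>
    select("sample_id", "experiment", "class", "condition", "replicate")

  baseline <- rnorm(n, config$baseline_mean, config$baseline_sd)
  exp_idx <- match(samples$experiment, experiments$experiment)
  is_trt <- samples$condition == "treatment"
  planted <- effect_mat[, exp_idx, drop = FALSE] *
    rep(as.numeric(is_trt), each = n)
  expr <- baseline + planted +
    matrix(rnorm(n * nrow(samples), 0, config$noise_sd_log2), n)
  colnames(expr) <- samples$sample_id

  present <- matrix(runif(n * nrow(samples)) >= config$absent_prob, n,
                    dimnames = list(genes, samples$sample_id))
  if (config$n_forced_absent > 0) {
    fg <- sample.int(n, config$n_forced_absent, replace = TRUE)
    fe <- sample.int(n_exp, config$n_forced_absent, replace = TRUE)
    for (k in seq_len(config$n_forced_absent)) {
      cols <- samples$experiment == experiments$experiment[fe[k]]
      present[fg[k], cols] <- FALSE
    }
  }

  effects <- as_tibble(effect_mat, rownames = "gene_id") |>
    tidyr::pivot_longer(-"gene_id", names_to = "experiment",
                        values_to = "effect")

  structure(list(
    expression = bind_cols_genes(genes, expr),
    presence = bind_cols_genes(genes, present),
    samples = samples,
    truth = tibble(gene_id = genes, label = labels, sign = signs,
                   compartment = compartment),
    effects = effects,
    config = config
  ), class = "compendium")
}

bind_cols_genes <- function(genes, mat) {
  out <- as_tibble(mat)
  dplyr::bind_cols(tibble(gene_id = genes), out)
}

#' Derive a category map from planted compartment annotations
#'
#' @param truth The `truth` tibble of a [simulate_compendium()] result.
#' @return A long tibble with columns `category` and `gene_id`, one row per
#'   annotated gene (genes with compartment `"none"` are omitted).
#' @export
category_map_from_truth <- function(truth) {
  truth |>
    filter(.data$compartment != "none") |>
    select(category = "compartment", "gene_id") |>
    arrange(.data$category, .data$gene_id)
}

#' Generate synthetic promoter sequences with planted motif instances
#'
#' Builds random background sequences and plants a Poisson-distributed
#' number of concrete instances of an IUPAC motif at non-overlapping
#' positions; each degenerate position is instantiated with a uniformly
#' drawn compatible base. The default length of 1000 bases mirrors the 1 kb
#' upstream promoter regions conventionally used for cis-element scans.
#'
#' @param n_foreground,n_background Number of promoters in each set.
#' @param motif IUPAC consensus string to plant.
#' @param planted_rate_fg,planted_rate_bg Mean number of planted instances
#'   per foreground / background promoter.
#' @param promoter_length Sequence length in bases.
#' @param background_letters Alphabet for the background sequence; restrict
#'   it (e.g. to letters incompatible with the motif) to guarantee that no
#'   spurious matches can arise.
#' @param seed Integer seed.
#'
#' @return Tibble with `promoter_id`, `set` (`foreground`/`background`),
#'   `sequence`, and the true `planted_count` per promoter.
#' @export
simulate_promoters <- function(n_foreground, n_background,
                               motif = "TTGACY",
                               planted_rate_fg = 2, planted_rate_bg = 0.5,
                               promoter_length = 1000,
                               background_letters = c("A", "C", "G", "T"),
                               seed = 1L) {
  stopifnot(planted_rate_fg >= 0, planted_rate_bg >= 0, promoter_length >= 1)
  motif <- toupper(motif)
  check_iupac(motif)
  w <- nchar(motif)
  if (w > promoter_length) {
    abort("motif is longer than the promoter", class = "retrosig_motif_error")
  }
  set.seed(seed)
  spec <- tibble(
    promoter_id = c(sprintf("fg_%03d", seq_len(n_foreground)),
                    sprintf("bg_%03d", seq_len(n_background))),
    set = rep(c("foreground", "background"), c(n_foreground, n_background)),
    rate = rep(c(planted_rate_fg, planted_rate_bg),
               c(n_foreground, n_background))
  )
  motif_letters <- strsplit(motif, "")[[1]]
  one <- function(rate) {
    seq <- sample(background_letters, promoter_length, replace = TRUE)
    k <- rpois(1, rate)
    k <- min(k, promoter_length %/% w)
    placed <- 0L
    occupied <- rep(FALSE, promoter_length)
    while (placed < k) {
      free <- which(!vapply(seq_len(promoter_length - w + 1L), function(s) {
        any(occupied[s:(s + w - 1L)])
      }, logical(1)))
      if (length(free) == 0L) break
      s <- free[sample.int(length(free), 1L)]
      inst <- vapply(motif_letters, function(l) {
        opts <- iupac_expand(l)
        opts[sample.int(length(opts), 1L)]
      }, character(1))
      seq[s:(s + w - 1L)] <- inst
      occupied[s:(s + w - 1L)] <- TRUE
      placed <- placed + 1L
    }
    list(sequence = paste(seq, collapse = ""), planted_count = placed)
  }
  drawn <- purrr::map(spec$rate, one)
  spec |>
    mutate(sequence = purrr::map_chr(drawn, "sequence"),
           planted_count = purrr::map_int(drawn, ~ as.integer(.x$planted_count))) |>
    select(-"rate")
}
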