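#' Combine a sample variance with a background variance
#'
#' The Bayesian-regularized variance shrinks each gene's replicate variance
#' toward a local background estimate:
#' `(prior_df * background_var + (n - 1) * sample_var) / (prior_df + n - 1)`.
#'
#' @param sample_var Per-gene sample variance.
#' @param n Number of replicates behind `sample_var`.
#' @param background_var Background (prior) variance.
#' @param prior_df Prior degrees of freedom (pseudo-replicates) given to the
#'   background; 0 returns the ordinary sample variance.
#' @return Numeric vector of regularized variances.
#' @export
reg_var_combine <- function(sample_var, n, background_var, prior_df) {
  stopifnot(prior_df >= 0)
  denom <- prior_df + n - 1
  if (any(denom <= 0)) {
    abort("need prior_df + n - 1 > 0 to form a variance",
          class = "retrosig_variance_error")
  }
  (prior_df * background_var + (n - 1) * sample_var) / denom
}

#' Regularized per-gene variance with an intensity-ranked background window
#'
#' For each gene the background variance is the mean sample variance over
#' the `window` genes nearest in rank of mean expression (the window is
#' clamped at the extremes of the ranking so it always spans exactly
#' `window` genes). The background is then combined with the gene's own
#' sample variance via [reg_var_combine()].
#'
#' @param x Numeric matrix of replicate values, genes in rows.
#' @param window Odd number of genes in the background window.
#' @param prior_df Prior degrees of freedom for the background.
#' @return Tibble with `mean`, `n`, `sample_var`, `background_var`,
#'   `reg_var`, one row per gene (row order preserved; `gene_id` taken from
#'   rownames when present).
#' @export
regularized_variance <- function(x, window = 101, prior_df = 10) {
  x <- as.matrix(x)
  n_genes <- nrow(x)
  if (window %% 2 != 1) {
    abort("window must be odd", class = "retrosig_variance_error")
  }
  if (window > n_genes) {
    abort("window larger than the number of genes",
          class = "retrosig_variance_error")
  }
  n_rep <- rowSums(!is.na(x))
  means <- rowMeans(x, na.rm = TRUE)
  svar <- apply(x, 1, var, na.rm = TRUE)
  svar[n_rep < 2] <- 0
  ord <- order(means)
  sv_sorted <- svar[ord]
  half <- (window - 1) / 2
  csum <- cumsum(sv_sorted)
  starts <- pmin(pmax(seq_len(n_genes) - half, 1L), n_genes - window + 1L)
  ends <- starts + window - 1L
  bg_sorted <- (csum[ends] - c(0, csum)[starts]) / window
  bg <- numeric(n_genes)
  bg[ord] <- bg_sorted
  tibble(
    gene_id = rownames(x) %||% as.character(seq_len(n_genes)),
    mean = unname(means), n = unname(n_rep),
    sample_var = unname(svar), background_var = unname(bg),
    reg_var = reg_var_combine(unname(svar), unname(n_rep), unname(bg),
                              prior_df)
  )
}

#' Regularized two-sample t test
#'
#' A two-sample t statistic on group means with (regularized) group
#' variances pooled as
#' `((n1 + prior_df - 1) v1 + (n2 + prior_df - 1) v2) / (n1 + n2 + 2 prior_df - 2)`
#' and `n1 + n2 - 2 + 2 prior_df` degrees of freedom; two-sided p-value from
#' the t distribution. With `prior_df = 0` and raw sample variances this is
#' the ordinary pooled-variance t test. The statistic is oriented
#' treatment minus control.
#'
#' @param control,treatment Numeric matrices (genes x replicates) or vectors.
#' @param var_control,var_treatment Optional per-gene (regularized) group
#'   variances; defaults to the raw sample variances.
#' @param prior_df Prior degrees of freedom entering the pooled variance and
#'   the degrees of freedom.
#' @return Tibble with `reg_t`, `df`, `p_value` and a logical `zero_se`
#'   flagging genes whose pooled standard error vanished while the means
#'   differed (their p-value is set to the smallest representable positive
#'   number).
#' @export
reg_t_test <- function(control, treatment, var_control = NULL,
                       var_treatment = NULL, prior_df = 0) {
  ctl <- if (is.null(dim(control))) matrix(control, nrow = 1) else as.matrix(control)
  trt <- if (is.null(dim(treatment))) matrix(treatment, nrow = 1) else as.matrix(treatment)
  if (nrow(ctl) != nrow(trt)) {
    abort("control and treatment must cover the same genes",
          class = "retrosig_alignment_error")
  }
  n1 <- rowSums(!is.na(ctl))
  n2 <- rowSums(!is.na(trt))
  if (any(n1 == 0) || any(n2 == 0)) {
    abort("both groups must be nonempty", class = "retrosig_empty_group_error")
  }
  v1 <- var_control %||% {
    v <- apply(ctl, 1, var, na.rm = TRUE); v[n1 < 2] <- 0; v
  }
  v2 <- var_treatment %||% {
    v <- apply(trt, 1, var, na.rm = TRUE); v[n2 < 2] <- 0; v
  }
  df <- n1 + n2 - 2 + 2 * prior_df
  pooled <- ((n1 + prior_df - 1) * v1 + (n2 + prior_df - 1) * v2) /
    (n1 + n2 + 2 * prior_df - 2)
  se <- sqrt(pooled * (1 / n1 + 1 / n2))
  delta <- rowMeans(trt, na.rm = TRUE) - rowMeans(ctl, na.rm = TRUE)
  t_stat <- delta / se
  zero_se <- se == 0 & delta != 0
  t_stat[se == 0 & delta == 0] <- 0
  t_stat[zero_se] <- sign(delta[zero_se]) * Inf
  p <- 2 * pt(-abs(t_stat), df)
  p[zero_se] <- .Machine$double.xmin
  tibble(reg_t = unname(t_stat), df = unname(df), p_value = unname(p),
         zero_se = unname(zero_se))
}

#' Significance rule: fold change and PPDE thresholds
#'
#' A gene-experiment pair is called significant when its fold change exceeds
#' the threshold in either direction (strictly more than `fc_threshold`-fold
#' up or down) *and* its posterior probability of differential expression
#' strictly exceeds `ppde_threshold`.
#'
#' @param log2_fc Signed log2 fold change.
#' @param ppde Posterior probability of differential expression.
#' @param fc_threshold Linear fold-change threshold (default 2).
#' @param ppde_threshold PPDE threshold (default 0.95).
#' @return Logical vector.
#' @export
call_significant <- function(log2_fc, ppde, fc_threshold = 2,
                             ppde_threshold = 0.95) {
  pmax(2^log2_fc, 2^(-log2_fc)) > fc_threshold & ppde > ppde_threshold
}

#' Per-experiment differential-response calling
#'
#' For every experiment, computes fold changes (with the absent-call rule of
#' [fold_changes()]), a Bayesian-regularized t statistic per gene
#' ([regularized_variance()], [reg_t_test()]), fits a beta-uniform mixture
#' to the experiment's p-values ([fit_ppde()]) to obtain each gene's PPDE,
#' and applies the significance rule of [call_significant()]. Genes failing
#' the presence filter in an experiment carry fold change 1 there and are
#' never significant.
#'
#' @inheritParams presence_filter
#' @inheritParams call_significant
#' @param window,prior_df Background window and prior degrees of freedom of
#'   the regularized variance.
#' @param mean_fun Fold-change averaging, see [fold_changes()].
#' @return Tibble with `gene_id`, `experiment`, `log2_fc`, `reg_t`,
#'   `p_value`, `ppde`, `significant`, `direction` (-1/0/+1).
#' @export
call_differential <- function(expression, presence, samples,
                              fc_threshold = 2, ppde_threshold = 0.95,
                              window = 101, prior_df = 10,
                              min_fraction = 0.5,
                              mean_fun = c("geometric", "arithmetic")) {
  mean_fun <- match.arg(mean_fun)
  check_aligned(expression, presence, samples)
  expr <- as_gene_matrix(expression)
  fc <- fold_changes(expression, presence, samples, min_fraction, mean_fun)
  per_exp <- lapply(split(samples, samples$experiment), function(g) {
    ctl <- expr[, g$sample_id[g$condition == "control"], drop = FALSE]
    trt <- expr[, g$sample_id[g$condition == "treatment"], drop = FALSE]
    rv_c <- regularized_variance(ctl, window, prior_df)
    rv_t <- regularized_variance(trt, window, prior_df)
    tt <- reg_t_test(ctl, trt, rv_c$reg_var, rv_t$reg_var, prior_df)
    fit <- fit_ppde(tt$p_value)
    tibble(gene_id = rownames(expr), experiment = g$experiment[1],
           reg_t = tt$reg_t, p_value = tt$p_value,
           ppde = ppde(fit, tt$p_value))
  })
  bind_rows(per_exp) |>
    inner_join(fc, by = c("gene_id", "experiment")) |>
    mutate(
      significant = call_significant(.data$log2_fc, .data$ppde,
                                     fc_threshold, ppde_threshold) &
        .data$retained,
      direction = ifelse(.data$significant, sign(.data$log2_fc), 0)
    ) |>
    select("gene_id", "experiment", "log2_fc", "fc", "reg_t", "p_value",
           "ppde", "significant", "direction") |>
    arrange(.data$experiment, .data$gene_id)
}
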