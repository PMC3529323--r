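make_rm <- function(calls, classes) {
  # calls: genes x experiments character matrix of up/down/ns
  tibble::tibble(
    gene_id = rep(rownames(calls), ncol(calls)),
    experiment = rep(colnames(calls), each = nrow(calls)),
    class = rep(classes, each = nrow(calls)),
    call = as.vector(calls)
  )
}

test_that("recurrence counting tallies significant calls per class", {
  calls <- matrix("ns", 3, 13,
                  dimnames = list(c("a", "b", "c"),
                                  c(sprintf("m%02d", 1:10),
                                    sprintf("c%02d", 1:3))))
  classes <- rep(c("mito", "chloro"), c(10, 3))
  calls["b", 1:10] <- "up"            # significant in 10 mito, 0 chloro
  calls["c", c(1, 11)] <- c("up", "down")
  counts <- recurrence_counts(make_rm(calls, classes))
  expect_equal(counts$n_mito, c(0, 10, 1))
  expect_equal(counts$n_chloro, c(0, 0, 1))
})

test_that("recurrence counts match a brute-force tally on random matrices", {
  set.seed(41)
  for (rep_ in 1:5) {
    calls <- matrix(sample(c("up", "down", "ns"), 50 * 10, replace = TRUE,
                           prob = c(0.2, 0.2, 0.6)), 50, 10,
                    dimnames = list(sprintf("g%02d", 1:50),
                                    sprintf("e%02d", 1:10)))
    classes <- sample(c("mito", "chloro"), 10, replace = TRUE)
    classes[1:2] <- c("mito", "chloro")   # both classes present
    counts <- recurrence_counts(make_rm(calls, classes))
    brute_m <- rowSums(calls[, classes == "mito", drop = FALSE] != "ns")
    brute_c <- rowSums(calls[, classes == "chloro", drop = FALSE] != "ns")
    expect_equal(counts$n_mito[match(names(brute_m), counts$gene_id)],
                 unname(brute_m))
    expect_equal(counts$n_chloro[match(names(brute_c), counts$gene_id)],
                 unname(brute_c))
  }
})

test_that("responsive sets shrink as the recurrence minimum rises", {
  set.seed(42)
  calls <- matrix(sample(c("up", "ns"), 40 * 14, replace = TRUE), 40, 14,
                  dimnames = list(sprintf("g%02d", 1:40),
                                  sprintf("e%02d", 1:14)))
  counts <- recurrence_counts(make_rm(calls, rep("mito", 14)))
  sets <- lapply(1:8, function(k) responsive_set(counts, "mito", k))
  # min = 1 catches every gene significant anywhere in the class
  expect_setequal(sets[[1]], counts$gene_id[counts$n_mito >= 1])
  for (k in 2:8) expect_true(all(sets[[k]] %in% sets[[k - 1]]))
  expect_error(responsive_set(counts, "plastid"),
               class = "retrosig_lookup_error")
})

test_that("set algebra satisfies inclusion-exclusion", {
  # the published overlap arithmetic: 720 and 606 with 129 shared
  a <- c(sprintf("x%03d", 1:129), sprintf("a%03d", 1:591))
  b <- c(sprintf("x%03d", 1:129), sprintf("b%03d", 1:477))
  v <- set_algebra(a, b)
  expect_equal(v$n_a, 720)
  expect_equal(v$n_b, 606)
  expect_equal(v$n_intersect, 129)
  expect_equal(v$n_union, 1197)

  expect_equal(set_algebra(a, a)$n_union, 720)
  expect_equal(set_algebra(a, a)$n_intersect, 720)
  d <- set_algebra(sprintf("p%d", 1:10), sprintf("q%d", 1:7))
  expect_equal(d$n_union, 17)
  expect_equal(d$n_intersect, 0)

  set.seed(43)
  for (i in 1:10) {
    u <- sample(letters, 20)
    s1 <- sample(u, sample(5:15, 1)); s2 <- sample(u, sample(5:15, 1))
    v <- set_algebra(s1, s2)
    expect_equal(v$n_union, v$n_a + v$n_b - v$n_intersect)
  }
})

test_that("planted responsive genes are exactly recovered at full response", {
  cfg <- synthetic_config(n_genes = 500, n_mito = 5, n_chloro = 5,
                          respond_prob = 1, effect_size_log2 = 2,
                          noise_sd_log2 = 0.25, absent_prob = 0, seed = 19)
  comp <- simulate_compendium(cfg)
  de <- call_differential(comp$expression, comp$presence, comp$samples)
  counts <- recurrence_counts(response_matrix(de, comp$samples))
  mito_set <- responsive_set(counts, "mito", 4)
  truth_mito <- comp$truth$gene_id[comp$truth$label %in%
                                     c("shared", "mito_specific")]
  expect_setequal(mito_set, truth_mito)
  chloro_set <- responsive_set(counts, "chloro", 4)
  truth_chloro <- comp$truth$gene_id[comp$truth$label %in%
                                       c("shared", "chloro_specific")]
  expect_setequal(chloro_set, truth_chloro)
})

test_that("consistent-direction counting never exceeds the plain count", {
  set.seed(44)
  calls <- matrix(sample(c("up", "down", "ns"), 30 * 8, replace = TRUE),
                  30, 8, dimnames = list(sprintf("g%02d", 1:30),
                                         sprintf("e%02d", 1:8)))
  rm_ <- make_rm(calls, rep(c("mito", "chloro"), each = 4))
  plain <- recurrence_counts(rm_)
  dir_ <- recurrence_counts(rm_, consistent_direction = TRUE)
  expect_true(all(dir_$n_mito <= plain$n_mito))
  expect_true(all(dir_$n_chloro <= plain$n_chloro))
})
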