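# Independent oracle: exhaustive enumeration of all draws of size n from a
# universe of size N with K category members.
enum_tail <- function(observed, K, n, N, tail) {
  draws <- utils::combn(N, n)
  overlaps <- colSums(draws <= K)   # category = first K elements
  if (tail == "over") mean(overlaps >= observed) else mean(overlaps <= observed)
}

# helper: build id sets with a prescribed intersection
sets_with_overlap <- function(n_a, n_b, obs, n_universe) {
  u <- sprintf("u%05d", seq_len(n_universe))
  cat_ <- u[seq_len(n_b)]
  fg <- c(u[seq_len(obs)], u[(n_b + 1):(n_b + n_a - obs)])
  list(foreground = fg, category = cat_, universe = u)
}

test_that("expected overlap is the independence expectation", {
  expect_equal(expected_overlap(720, 606, 22810), 720 * 606 / 22810)
  expect_equal(round(expected_overlap(720, 606, 22810)), 19)
  expect_equal(expected_overlap(0, 100, 1000), 0)
  expect_equal(expected_overlap(50, 50, 50), 50)
  expect_equal(expected_overlap(12, 34, 567), expected_overlap(34, 12, 567))
  expect_error(expected_overlap(1, 1, 0), class = "retrosig_enrichment_error")
})

test_that("hypergeometric tails match exhaustive enumeration for N <= 12", {
  for (N in c(6, 9, 12)) {
    for (K in c(2, N %/% 2, N - 1)) {
      for (n in c(1, N %/% 2)) {
        for (obs in 0:min(K, n)) {
          expect_equal(hypergeom_pvalue(obs, K, n, N, "over"),
                       enum_tail(obs, K, n, N, "over"), tolerance = 1e-12,
                       info = sprintf("N=%d K=%d n=%d obs=%d", N, K, n, obs))
          expect_equal(hypergeom_pvalue(obs, K, n, N, "under"),
                       enum_tail(obs, K, n, N, "under"), tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("hypergeometric examples and tail identity", {
  expect_equal(hypergeom_pvalue(5, 5, 5, 10, "over"), 1 / 252,
               tolerance = 1e-12)
  expect_equal(hypergeom_pvalue(0, 5, 5, 10, "over"), 1)
  # over + under at the observed point double-count its mass
  for (obs in 0:4) {
    expect_equal(hypergeom_pvalue(obs, 6, 4, 12, "over") +
                   hypergeom_pvalue(obs, 6, 4, 12, "under"),
                 1 + dhyper(obs, 6, 6, 4), tolerance = 1e-12)
  }
  expect_error(hypergeom_pvalue(6, 5, 5, 10), class = "retrosig_enrichment_error")
})

test_that("enrichment_test reproduces published overlap arithmetic", {
  s <- sets_with_overlap(606, 2198, 177, 22810)
  et <- enrichment_test(s$foreground, s$category, s$universe)
  expect_equal(et$observed, 177)
  expect_equal(round(et$expected), 58)
  expect_equal(round(et$ratio, 2), 3.03)
  expect_lt(et$p_over, 0.001)

  s2 <- sets_with_overlap(606, 1178, 31, 22810)
  et2 <- enrichment_test(s2$foreground, s2$category, s2$universe)
  expect_equal(round(et2$ratio, 2), 0.99)
  expect_gt(et2$p_over, 0.05)

  # category = universe pins the overlap at the foreground size
  u <- sprintf("u%03d", 1:100)
  et3 <- enrichment_test(u[1:20], u, u)
  expect_equal(et3$observed, 20)
  expect_equal(et3$ratio, 1)

  expect_error(enrichment_test(c("zz", u[1]), u[1:10], u),
               class = "retrosig_enrichment_error")
})

test_that("enrichment ratio is symmetric in foreground and category", {
  set.seed(55)
  u <- sprintf("u%03d", 1:200)
  a <- sample(u, 60); b <- sample(u, 90)
  expect_equal(enrichment_test(a, b, u)$ratio, enrichment_test(b, a, u)$ratio)
  expect_equal(enrichment_test(a, b, u)$observed,
               enrichment_test(b, a, u)$observed)
})

test_that("permutation null agrees with the analytic tail", {
  set.seed(56)
  u <- sprintf("u%03d", 1:300)
  cat_ <- sample(u, 60)
  fg <- c(sample(cat_, 20), sample(setdiff(u, cat_), 40))
  perm <- permutation_null(fg, cat_, u, n_perm = 10000, seed = 9)
  analytic <- hypergeom_pvalue(perm$observed, 60, 60, 300, "over")
  mc_se <- sqrt(analytic * (1 - analytic) / 10000)
  expect_lt(abs(perm$p_perm - analytic), 3 * mc_se + 2 / 10000)
  # determinism under seed
  expect_identical(perm$p_perm,
                   permutation_null(fg, cat_, u, 10000, seed = 9)$p_perm)
  # category = universe: every draw overlaps completely
  full <- permutation_null(fg, u, u, n_perm = 200, seed = 1)
  expect_identical(attr(full, "null"), rep(60L, 200))
})

test_that("category_scan flags constructed over- and under-representation", {
  u <- sprintf("u%04d", 1:1000)
  fg <- u[1:100]
  cats <- dplyr::bind_rows(
    tibble::tibble(category = "hit", gene_id = u[1:80]),      # inside fg
    tibble::tibble(category = "avoided", gene_id = u[501:700]),
    tibble::tibble(category = "neutral", gene_id = u[seq(10, 1000, 10)])
  )
  res <- category_scan(fg, cats, u)
  hit <- res[res$category == "hit", ]
  expect_equal(hit$direction, "over")
  expect_true(hit$retained)
  avoided <- res[res$category == "avoided", ]
  expect_equal(avoided$observed, 0)
  expect_equal(avoided$direction, "under")
  expect_lt(avoided$p_under, 0.05)
  expect_lt(avoided$ratio, 1)
})

test_that("random foregrounds trip ~5% of categories before the ratio filter", {
  set.seed(58)
  u <- sprintf("u%04d", 1:2000)
  cats <- tibble::tibble(
    category = rep(sprintf("c%03d", 1:200), each = 50),
    gene_id = as.vector(replicate(200, sample(u, 50)))
  )
  fg <- sample(u, 200)
  res <- category_scan(fg, cats, u)
  frac <- mean(res$p_value < 0.05)
  # oracle: exact null rejection probability for one size-50 category
  ks <- 0:50
  reject <- pmin(phyper(ks - 1, 50, 1950, 200, lower.tail = FALSE),
                 phyper(ks, 50, 1950, 200)) < 0.05
  p_reject <- sum(dhyper(ks, 50, 1950, 200)[reject])
  expect_lt(abs(frac - p_reject), 3 * sqrt(p_reject * (1 - p_reject) / 200))
})
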