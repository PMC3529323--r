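test_that("motif counting conventions", {
  expect_equal(scan_motif("TTGACTTGAC", "TTGAC", strands = "forward"), 2)
  # reverse-complement hit counted on the forward coordinate system
  expect_equal(scan_motif("GTCAA", "TTGAC", strands = "both"), 1)
  expect_equal(scan_motif("GTCAA", "TTGAC", strands = "forward"), 0)
  # a palindromic site matching both strands counts once
  expect_equal(scan_motif("CACGTG", "CACGTG", strands = "both"), 1)
  # overlapping occurrences are all counted
  expect_equal(scan_motif("AAAA", "AA", strands = "forward"), 3)
  # IUPAC degeneracy: W-box TTGACY matches TTGACC and TTGACT
  expect_equal(scan_motif("TTGACCNTTGACT", "TTGACY", strands = "forward"), 2)
  expect_error(scan_motif("ACGT", "TTXAC"), class = "retrosig_motif_error")
})

test_that("N in the sequence matches no motif letter", {
  expect_equal(scan_motif("TTGAN", "TTGAC"), 0)
  expect_equal(scan_motif("TTNACTTGAC", "TTGAC", strands = "forward"), 1)
})

test_that("both-strand counts are strand symmetric", {
  set.seed(91)
  for (i in 1:10) {
    s <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
    for (m in c("TTGACY", "CACGTG", "GATAAG")) {
      expect_equal(scan_motif(s, m, strands = "both"),
                   scan_motif(revcomp(s), m, strands = "both"),
                   info = paste(m, i))
    }
  }
})

test_that("counts are additive over N-separated concatenation", {
  set.seed(92)
  for (i in 1:5) {
    s1 <- paste(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = "")
    s2 <- paste(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = "")
    joined <- paste0(s1, strrep("N", 10), s2)
    for (m in c("TTGAC", "CACGTG")) {
      expect_equal(scan_motif(joined, m),
                   scan_motif(s1, m) + scan_motif(s2, m))
    }
  }
})

test_that("planted promoter counts are recovered exactly", {
  # AATT is its own reverse complement; a C/G background cannot spawn
  # spurious matches, so scanning must recover the planted counts exactly
  prom <- simulate_promoters(10, 10, motif = "AATT", planted_rate_fg = 3,
                             planted_rate_bg = 1,
                             background_letters = c("C", "G"), seed = 4)
  counts <- count_motifs(prom, tibble::tibble(name = "aatt", iupac = "AATT"))
  joined <- dplyr::inner_join(prom, counts, by = "promoter_id")
  expect_equal(joined$count, joined$planted_count)
})

test_that("motif enrichment flags planted foreground excess", {
  prom <- simulate_promoters(25, 60, motif = "AATT", planted_rate_fg = 4,
                             planted_rate_bg = 0.3,
                             background_letters = c("C", "G"), seed = 5)
  lib <- tibble::tibble(name = c("aatt", "ccgg"), iupac = c("AATT", "CCGG"))
  counts <- count_motifs(prom, lib)
  fg <- counts[counts$promoter_id %in%
                 prom$promoter_id[prom$set == "foreground"], ]
  bg <- counts[counts$promoter_id %in%
                 prom$promoter_id[prom$set == "background"], ]
  for (mode in c("promoter_presence", "occurrence_rate")) {
    enr <- motif_enrichment(fg, bg, mode)
    expect_lt(enr$p_value[enr$motif == "aatt"], 0.01)
    expect_gt(enr$effect[enr$motif == "aatt"], 1)
    # the unplanted motif saturates both sets (C/G background is all CCGG
    # matches) or stays unenriched; either way it must not be flagged
    expect_gt(enr$p_value[enr$motif == "ccgg"], 0.05)
  }
})

test_that("promoter-presence mode equals the generic hypergeometric test", {
  prom <- simulate_promoters(15, 30, motif = "AATT", planted_rate_fg = 1,
                             planted_rate_bg = 0.5,
                             background_letters = c("C", "G"), seed = 6)
  counts <- count_motifs(prom, tibble::tibble(name = "aatt", iupac = "AATT"))
  fg_ids <- prom$promoter_id[prom$set == "foreground"]
  bg_ids <- prom$promoter_id[prom$set == "background"]
  enr <- motif_enrichment(counts[counts$promoter_id %in% fg_ids, ],
                          counts[counts$promoter_id %in% bg_ids, ],
                          "promoter_presence")
  with_hit <- counts$promoter_id[counts$count > 0]
  et <- enrichment_test(fg_ids, with_hit, prom$promoter_id)
  expect_equal(enr$p_value, et$p_over)
  expect_equal(enr$effect, et$ratio)
})

test_that("identical foreground and background content is unenriched", {
  set.seed(93)
  seqs <- vapply(1:20, function(i) {
    paste(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = "")
  }, character(1))
  fg_prom <- tibble::tibble(promoter_id = sprintf("f%02d", 1:20),
                            sequence = seqs)
  bg_prom <- tibble::tibble(promoter_id = sprintf("b%02d", 1:20),
                            sequence = seqs)
  lib <- motif_library()[1:3, ]
  enr <- motif_enrichment(count_motifs(fg_prom, lib),
                          count_motifs(bg_prom, lib), "occurrence_rate",
                          promoter_length = 500)
  expect_true(all(enr$p_value > 0.3))
  expect_true(all(abs(enr$effect - 1) < 0.3 | enr$fg_occurrences == 0))
})
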