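test_that("a lone enriched pile-up is called exactly once with its enrichment", {
  L <- 1000L
  tex <- coverage_track("TEX", L)
  tex$five_prime_plus[321] <- 100
  notex <- coverage_track("NOTEX", L)
  called <- call_tss(tex, notex)
  expect_equal(nrow(called), 1L)
  expect_equal(called$position, 321L)
  expect_equal(called$strand, "+")
  expect_equal(called$enrichment, 100)  # 100 / (0 + pseudocount 1)

  expect_equal(nrow(call_tss(coverage_track("TEX", L),
                             coverage_track("NOTEX", L))), 0L)
  expect_error(call_tss(tex, coverage_track("NOTEX", 500L)), "length")
})

test_that("candidates failing height, enrichment or local-max rules are dropped", {
  L <- 500L
  tex <- coverage_track("TEX", L)
  notex <- coverage_track("NOTEX", L)
  tex$five_prime_plus[100] <- 9        # below min_height 10
  tex$five_prime_plus[200] <- 40
  notex$five_prime_plus[200] <- 30     # enrichment 40/31 < 2
  tex$five_prime_plus[300] <- 50
  tex$five_prime_plus[302] <- 60       # within cluster_width: one TSS at 302
  called <- call_tss(tex, notex)
  expect_equal(called$position, 302L)
})

test_that("merging keeps the highest count and breaks ties leftward", {
  L <- 500L
  tex <- coverage_track("TEX", L)
  notex <- coverage_track("NOTEX", L)
  tex$five_prime_plus[c(100, 102)] <- 30  # tie within cluster_width
  called <- call_tss(tex, notex)
  expect_equal(called$position, 100L)
})

test_that("raising min_enrichment never adds a TSS", {
  set.seed(17)
  for (r in 1:8) {
    tr <- random_track_pair(2000L)
    prev <- NULL
    for (e in c(1.5, 2, 4, 8)) {
      called <- call_tss(tr$tex, tr$notex,
                         detection_params(min_enrichment = e))
      key <- paste(called$position, called$strand)
      if (!is.null(prev)) expect_true(all(key %in% prev))
      prev <- key
    }
  }
})

test_that("classification follows the positional rules and never moves a TSS", {
  rep <- replicon("chr", strrep("A", 3000), circular = FALSE)
  genes <- gene_table("g1", 1000L, 2000L, "+")
  ann <- genome_annotation(rep, genes)
  tss <- data.frame(
    position = c(987L, 950L, 1500L, 1500L),
    strand = c("+", "+", "-", "+"),
    tex_height = c(100, 40, 30, 25),
    notex_height = c(0, 0, 0, 0), enrichment = c(100, 40, 30, 25),
    stringsAsFactors = FALSE)
  cls <- classify_tss(tss, ann)
  a <- cls$assignments
  expect_equal(a$class[a$position == 987 & a$strand == "+"], "P")
  expect_equal(a$utr_length[a$class == "P"], 13L)
  expect_equal(a$class[a$position == 950], "S")
  expect_equal(a$class[a$position == 1500 & a$strand == "-"], "A")
  expect_equal(a$class[a$position == 1500 & a$strand == "+"], "I")
  expect_identical(cls$tss$position, tss$position)
  expect_identical(cls$tss$tex_height, tss$tex_height)
})

test_that("a leaderless TSS at the gene start is primary with UTR 0", {
  rep <- replicon("chr", strrep("A", 3000), circular = FALSE)
  ann <- genome_annotation(rep, gene_table("g1", 1000L, 2000L, "+"))
  tss <- data.frame(position = 1000L, strand = "+", tex_height = 50,
                    notex_height = 0, enrichment = 50,
                    stringsAsFactors = FALSE)
  cls <- classify_tss(tss, ann)
  expect_equal(cls$assignments$class, "P")
  expect_equal(cls$assignments$utr_length, 0L)
  u <- utr_lengths(cls)
  expect_equal(u$median, 0)
  expect_false(u$empty)
  expect_true(utr_lengths(classify_tss(tss[0, ], ann))$empty)
})

test_that("orphan TSS keep no class and are excluded from counts", {
  rep <- replicon("chr", strrep("A", 3000), circular = FALSE)
  ann <- genome_annotation(rep, gene_table("g1", 1000L, 1200L, "+"))
  tss <- data.frame(position = 2800L, strand = "+", tex_height = 50,
                    notex_height = 0, enrichment = 50,
                    stringsAsFactors = FALSE)
  cls <- classify_tss(tss, ann)
  expect_equal(cls$tss$classes, "")
  expect_equal(unname(class_counts(cls)), c(0L, 0L, 0L, 0L))
})

test_that("dual labels accumulate across genes (head-to-head pTSS/aTSS)", {
  rep <- replicon("chr", strrep("A", 4000), circular = FALSE)
  genes <- gene_table(c("g1", "g2"), c(1000L, 1600L), c(1480L, 2400L),
                      c("-", "+"))
  ann <- genome_annotation(rep, genes)
  # primary for g2, within 100 bp of minus-strand g1 -> also antisense
  tss <- data.frame(position = 1560L, strand = "+", tex_height = 80,
                    notex_height = 0, enrichment = 80,
                    stringsAsFactors = FALSE)
  cls <- classify_tss(tss, ann)
  expect_setequal(strsplit(cls$tss$classes, ",")[[1]], c("P", "A"))
})

test_that("circular wrap supplies upstream windows across the origin", {
  L <- 2000L
  rep <- replicon("chr", strrep("A", L), circular = TRUE)
  ann <- genome_annotation(rep, gene_table("g1", 50L, 600L, "+"))
  tss <- data.frame(position = 1990L, strand = "+", tex_height = 40,
                    notex_height = 0, enrichment = 40,
                    stringsAsFactors = FALSE)  # 60 bp upstream through origin
  cls <- classify_tss(tss, ann)
  expect_equal(cls$assignments$class, "P")
  expect_equal(cls$assignments$utr_length, 60L)
})
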