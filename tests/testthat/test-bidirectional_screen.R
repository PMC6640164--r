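test_that("meta_profile concentrates a delta in its bin and flattens constants", {
  L <- 5000L
  tr <- coverage_track("TEX", L)
  tr$cov_plus[2500] <- 10
  site <- data.frame(position = 2500L, strand = "+")
  mp <- meta_profile(site, tr)
  expect_equal(sum(mp$sense), 1)          # proportional scaling to unit mass
  expect_equal(mp$sense[mp$bin_start == 1], 1)  # the TSS base sits at +1
  expect_equal(sum(mp$antisense), 0)

  tr2 <- coverage_track("FRAG", L, cov_plus = rep(3, L),
                        cov_minus = rep(3, L))
  mp2 <- meta_profile(site, tr2)
  expect_true(all(abs(mp2$sense - mp2$sense[1]) < 1e-12))
  expect_equal(mp2$sense, mp2$antisense)
  expect_error(meta_profile(site[0, ], tr2), "empty")
})

test_that("meta_profile of two sites is the mean of their individual profiles", {
  set.seed(21)
  L <- 3000L
  tr <- coverage_track("TEX", L,
                       five_prime_plus = rpois(L, 0.5),
                       five_prime_minus = rpois(L, 0.5))
  s1 <- data.frame(position = 1000L, strand = "+")
  s2 <- data.frame(position = 2000L, strand = "-")
  m1 <- meta_profile(s1, tr, what = "five_prime")
  m2 <- meta_profile(s2, tr, what = "five_prime")
  m12 <- meta_profile(rbind(s1, s2), tr, what = "five_prime")
  expect_equal(m12$sense, (m1$sense + m2$sense) / 2, tolerance = 1e-12)
  expect_equal(m12$antisense, (m1$antisense + m2$antisense) / 2,
               tolerance = 1e-12)
})

test_that("minus-strand sites are flipped so sense means the site's own strand", {
  L <- 5000L
  tr <- coverage_track("TEX", L)
  tr$five_prime_minus[2450] <- 8   # downstream of a minus-strand site
  site <- data.frame(position = 2500L, strand = "-")
  mp <- meta_profile(site, tr, what = "five_prime")
  expect_equal(mp$sense[mp$bin_start == 51], 1)  # offset +51 (TSS is +1)
  expect_equal(sum(mp$antisense), 0)
})

test_that("orientation_split assigns head-to-tail and head-to-head by neighbour strand", {
  rep <- replicon("chr", strrep("A", 3000), circular = FALSE)
  mk <- function(sa) {
    ann <- genome_annotation(rep, gene_table(c("A", "B"), c(1L, 1000L),
                                             c(500L, 1500L), c(sa, "+")))
    ptss <- data.frame(position = 990L, strand = "+", gene_id = "B",
                       stringsAsFactors = FALSE)
    orientation_split(ptss, ann)
  }
  expect_equal(nrow(mk("+")$head_to_tail), 1L)
  expect_equal(nrow(mk("+")$head_to_head), 0L)
  expect_equal(nrow(mk("-")$head_to_head), 1L)
  # linear first gene without neighbour is excluded with a warning
  ann <- genome_annotation(rep, gene_table("A", 500L, 900L, "+"))
  expect_warning(
    sp <- orientation_split(data.frame(position = 490L, strand = "+",
                                       gene_id = "A"), ann),
    "excluded")
  expect_equal(nrow(sp$excluded), 1L)
})

test_that("intergene distances use the annotation gap with overlap clamped to 0", {
  rep <- replicon("chr", strrep("A", 3000), circular = FALSE)
  ann <- genome_annotation(rep, gene_table(c("A", "B"), c(1L, 618L),
                                           c(500L, 1200L), c("+", "+")))
  sp <- orientation_split(data.frame(position = 610L, strand = "+",
                                     gene_id = "B"), ann)
  expect_equal(sp$head_to_tail$intergene_distance, 117L)
  d <- intergene_distances(sp)
  expect_equal(d$median[d$orientation == "head-to-tail"], 117)

  ann2 <- genome_annotation(rep, gene_table(c("A", "B"), c(1L, 400L),
                                            c(500L, 1200L), c("+", "+")))
  sp2 <- orientation_split(data.frame(position = 395L, strand = "+",
                                      gene_id = "B"), ann2)
  expect_equal(sp2$head_to_tail$intergene_distance, 0L)
})

test_that("antisense_fraction follows its window and denominator rules", {
  L <- 3000L
  tex <- coverage_track("TEX", L)
  # all antisense signal in the upstream 100 bp of a plus pTSS at 1500
  tex$five_prime_minus[1450] <- 30
  expect_equal(antisense_fraction(1500L, "+", tex), 1.0)
  # no antisense signal anywhere -> 0 by the denominator rule
  expect_equal(antisense_fraction(1500L, "+", coverage_track("TEX", L)), 0)
  # uniform 1 per bp on the antisense strand: 100 / 800
  tex2 <- coverage_track("TEX", L, five_prime_minus = rep(1, L))
  expect_equal(antisense_fraction(1500L, "+", tex2), 0.125)
  # 'both' denominator halves the uniform fraction
  tex3 <- coverage_track("TEX", L, five_prime_plus = rep(1, L),
                         five_prime_minus = rep(1, L))
  expect_equal(antisense_fraction(1500L, "+", tex3, denominator = "both"),
               0.0625)
})

test_that("the screen applies a strict threshold and is monotone in it", {
  L <- 4000L
  rep <- replicon("chr", strrep("A", L), circular = FALSE)
  ann <- genome_annotation(rep, gene_table(c("A", "B"), c(500L, 2000L),
                                           c(1400L, 3000L), c("+", "+")))
  ptss <- data.frame(position = 1990L, strand = "+", gene_id = "B",
                     stringsAsFactors = FALSE)
  tex <- coverage_track("TEX", L)
  tex$five_prime_minus[1950] <- 40          # upstream window
  tex$five_prime_minus[2200] <- 60          # downstream, denominator only
  # fraction is exactly 0.40: strict inequality excludes the candidate
  expect_equal(antisense_fraction(1990L, "+", tex), 0.4)
  expect_equal(nrow(screen_bidirectional(ptss, tex, ann)), 0L)
  expect_equal(nrow(screen_bidirectional(ptss, tex, ann,
                                         threshold = 0.39)), 1L)
  expect_equal(nrow(screen_bidirectional(ptss[0, ], tex, ann)), 0L)

  # monotone: candidates at a higher threshold are a subset
  set.seed(31)
  sim <- screen_sim()
  cls <- classify_tss(call_tss(sim$tracks$TEX, sim$tracks$NOTEX),
                      sim$annotation)
  a <- cls$assignments
  ptss2 <- unique(a[a$class == "P", c("position", "strand", "gene_id")])
  prev <- NULL
  for (th in c(0.2, 0.4, 0.6, 0.8)) {
    cand <- screen_bidirectional(ptss2, sim$tracks$TEX, sim$annotation,
                                 threshold = th)
    if (!is.null(prev)) expect_true(all(cand$position %in% prev))
    prev <- cand$position
  }
})

test_that("candidates are paired with the nearest upstream antisense TSS", {
  L <- 4000L
  rep <- replicon("chr", strrep("A", L), circular = FALSE)
  ann <- genome_annotation(rep, gene_table(c("A", "B"), c(500L, 2100L),
                                           c(1400L, 3000L), c("+", "+")))
  ptss <- data.frame(position = 2090L, strand = "+", gene_id = "B",
                     stringsAsFactors = FALSE)
  tex <- coverage_track("TEX", L)
  tex$five_prime_minus[2090L - 49L] <- 80
  atss <- data.frame(position = c(2090L - 49L, 2090L - 90L),
                     strand = c("-", "-"), stringsAsFactors = FALSE)
  cand <- screen_bidirectional(ptss, tex, ann, atss = atss)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$spacing, 49L)
  expect_equal(cand$atss_position, 2090L - 49L)
})

test_that("pair_distances reports the modal spacing and handles empty sets", {
  ptss <- data.frame(position = c(1000L, 2000L, 3000L), strand = "+")
  atss <- data.frame(position = c(951L, 1951L, 2940L), strand = "-")
  pd <- pair_distances(ptss, atss)
  expect_equal(sort(pd$spacings), c(49L, 49L, 60L))
  expect_equal(pd$mode, 49L)
  empty <- pair_distances(ptss, atss[0, ])
  expect_length(empty$spacings, 0L)
  expect_true(is.na(empty$mode))
})

test_that("antisense_fraction matches its brute-force oracle on random tracks", {
  set.seed(23)
  for (r in 1:20) {
    L <- sample(1500:5000, 1)
    tr <- random_track_pair(L)$tex
    pos <- sample(seq.int(500L, L - 500L), 1)
    s <- sample(c("+", "-"), 1)
    expect_equal(antisense_fraction(pos, s, tr, circular = TRUE),
                 oracle_antisense_fraction(pos, s, tr))
  }
})
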