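test_that("scaled_position maps flanks and gene bodies strand-awarely", {
  gene <- data.frame(id = "g", start = 1001L, end = 2001L, strand = "+",
                     kind = "gene", stringsAsFactors = FALSE)
  at5 <- scaled_position(1001L, "+", gene)
  expect_equal(at5$zone, "body"); expect_equal(at5$value, 0)
  at3 <- scaled_position(2001L, "+", gene)
  expect_equal(at3$zone, "body"); expect_equal(at3$value, 1)
  mid <- scaled_position(1501L, "-", gene)  # 1001-bp gene, exact midpoint
  expect_equal(mid$value, 0.5)
  up <- scaled_position(951L, "+", gene)
  expect_equal(up$zone, "upstream"); expect_equal(up$value, -50L)
  dn <- scaled_position(2101L, "+", gene)
  expect_equal(dn$zone, "downstream"); expect_equal(dn$value, 100L)
  expect_error(scaled_position(100L, "+", gene), "outside")

  # minus-strand gene: upstream is genomically downstream
  gm <- data.frame(id = "g", start = 1001L, end = 2001L, strand = "-",
                   kind = "gene", stringsAsFactors = FALSE)
  upm <- scaled_position(2051L, "+", gm)
  expect_equal(upm$zone, "upstream"); expect_equal(upm$value, -50L)
  expect_equal(scaled_position(1001L, "+", gm)$value, 1)
})

test_that("scaled positions are invariant under a whole-replicon strand flip", {
  set.seed(41)
  L <- 10000L
  for (r in 1:20) {
    s <- sample(c("+", "-"), 1)
    start <- sample(2000:6000, 1)
    end <- start + sample(300:1500, 1)
    gene <- data.frame(id = "g", start = start, end = end, strand = s,
                       kind = "gene", stringsAsFactors = FALSE)
    pos <- sample((start - 300):(end + 300), 1)
    sp <- scaled_position(pos, "+", gene)
    flipped_gene <- data.frame(id = "g", start = L - end + 1L,
                               end = L - start + 1L,
                               strand = if (s == "+") "-" else "+",
                               kind = "gene", stringsAsFactors = FALSE)
    sp2 <- scaled_position(L - pos + 1L, "-", flipped_gene)
    expect_equal(sp$zone, sp2$zone)
    expect_equal(sp$value, sp2$value)
  }
})

test_that("is_element_profile maps antisense TSS onto the IS metagene scale", {
  isel <- gene_table("is1", 1000L, 2000L, "+", "IS_element")
  atss <- data.frame(position = c(950L, 1500L, 1100L),
                     strand = c("-", "-", "-"), stringsAsFactors = FALSE)
  prof <- is_element_profile(atss, isel)
  expect_equal(nrow(prof), 3L)
  expect_equal(prof$zone[prof$position == 950], "upstream")
  expect_equal(prof$value[prof$position == 950], -50L)
  expect_equal(prof$value[prof$position == 1500], 0.5)
  expect_equal(attr(prof, "fraction_orf_start"), 1)  # aTSS at body 10%
  expect_equal(nrow(is_element_profile(atss, isel[0, ])), 0L)
})

test_that("planted IS antisense TSS are recovered in the first 20% of the body", {
  sim <- screen_sim()
  cls <- classify_tss(call_tss(sim$tracks$TEX, sim$tracks$NOTEX),
                      sim$annotation)
  a <- cls$assignments
  atss <- unique(a[a$class == "A", c("position", "strand")])
  isel <- sim$annotation$genes[sim$annotation$genes$kind == "IS_element", ]
  prof <- is_element_profile(atss, isel)
  expect_gte(attr(prof, "fraction_orf_start"), 0.9)
})

test_that("infer_units merges on continuous coverage and splits on gaps", {
  L <- 6000L
  rep <- replicon("chr", strrep("A", L), circular = FALSE)
  genes <- gene_table(c("g1", "g2"), c(1000L, 2200L), c(2000L, 3000L),
                      c("+", "+"))
  ann <- genome_annotation(rep, genes)
  ptss <- data.frame(position = 990L, strand = "+", gene_id = "g1",
                     stringsAsFactors = FALSE)
  cov_on <- numeric(L); cov_on[990:3000] <- 20
  frag <- coverage_track("FRAG", L, cov_plus = cov_on)
  u1 <- infer_units(ann, ptss, frag)
  expect_equal(nrow(u1), 1L)
  expect_equal(u1$genes, "g1,g2")
  expect_equal(u1$leading_ptss, 990L)

  cov_gap <- cov_on; cov_gap[2050:2150] <- 0   # 101-bp hole > gap_threshold
  u2 <- infer_units(ann, ptss, coverage_track("FRAG", L, cov_plus = cov_gap))
  expect_equal(nrow(u2), 2L)
  # a second pTSS on the downstream gene also splits the unit
  ptss2 <- rbind(ptss, data.frame(position = 2190L, strand = "+",
                                  gene_id = "g2"))
  expect_equal(nrow(infer_units(ann, ptss2, frag)), 2L)
})

test_that("units partition the genes and grow monotonically with gap_threshold", {
  sim <- default_sim()
  cls <- classify_tss(call_tss(sim$tracks$TEX, sim$tracks$NOTEX),
                      sim$annotation)
  a <- cls$assignments
  ptss <- unique(a[a$class == "P", c("position", "strand", "gene_id")])
  prev_n <- Inf
  for (gt in c(5L, 25L, 100L, 400L)) {
    u <- infer_units(sim$annotation, ptss, sim$tracks$FRAG,
                     gap_threshold = gt)
    members <- unlist(strsplit(u$genes, ","))
    expect_setequal(members, sim$annotation$genes$id)
    expect_false(anyDuplicated(members) > 0)
    expect_lte(nrow(u), prev_n)   # merging only increases with the threshold
    prev_n <- nrow(u)
  }
})

test_that("planted operons are recovered from synthetic truth", {
  sim <- default_sim()
  cls <- classify_tss(call_tss(sim$tracks$TEX, sim$tracks$NOTEX),
                      sim$annotation)
  a <- cls$assignments
  ptss <- unique(a[a$class == "P", c("position", "strand", "gene_id")])
  units <- infer_units(sim$annotation, ptss, sim$tracks$FRAG)
  rec <- unit_recovery(units, sim$truth)
  expect_gte(rec$exact_match, 0.9)
})
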