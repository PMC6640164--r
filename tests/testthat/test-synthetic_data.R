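test_that("the generator is deterministic under a fixed seed", {
  spec <- simulation_spec(n_genes = 10L, genome_length = 15000L, seed = 1L)
  a <- generate_genome(spec)
  b <- generate_genome(spec)
  expect_identical(a$replicon$sequence, b$replicon$sequence)
  expect_identical(a$annotation$genes, b$annotation$genes)
  expect_identical(a$truth$tss, b$truth$tss)
  ta <- simulate_coverage(a$truth, spec)
  tb <- simulate_coverage(b$truth, spec)
  expect_identical(ta$TEX$five_prime_plus, tb$TEX$five_prime_plus)
  expect_identical(ta$FRAG$cov_minus, tb$FRAG$cov_minus)
})

test_that("spec validation rejects bad proportions and infeasible packing", {
  expect_error(simulation_spec(fraction_bidirectional = 1.2), "\\[0, 1\\]")
  expect_error(simulation_spec(ptss_atss_spacing = 0), "spacing")
  expect_error(generate_genome(simulation_spec(n_genes = 60L,
                                               genome_length = 30000L)),
               "capacity")
})

test_that("bidirectional planting follows the configured fraction", {
  spec0 <- simulation_spec(fraction_bidirectional = 0, seed = 5L)
  t0 <- generate_genome(spec0)$truth
  expect_false(any(t0$tss$bidirectional, na.rm = TRUE))

  spec <- simulation_spec(fraction_bidirectional = 0.2, seed = 5L)
  sim <- generate_genome(spec)
  tt <- sim$truth$tss
  n_pairs <- sum(tt$bidirectional & tt$class == "A")
  # head-to-tail primary promoters, re-derived from annotation + truth
  genes <- sim$annotation$genes
  p <- tt[tt$class == "P", ]
  n <- nrow(genes)
  ht <- 0L
  for (k in seq_len(nrow(p))) {
    i <- match(p$gene_id[k], genes$id)
    u <- if (genes$strand[i] == "+") {
      if (i > 1L) i - 1L else n
    } else {
      if (i < n) i + 1L else 1L
    }
    if (genes$strand[i] == genes$strand[u] &&
        genes$kind[i] != "IS_element") ht <- ht + 1L
  }
  expect_equal(n_pairs, round(0.2 * ht))
  # every partner sits exactly the configured spacing away, opposite strand
  bd <- tt[tt$bidirectional & tt$class == "A", ]
  part <- tt[match(bd$partner_position, tt$position), ]
  expect_true(all(abs(bd$position - bd$partner_position) ==
                    spec$ptss_atss_spacing))
  expect_true(all(bd$strand != part$strand))
})

test_that("every planted primary TSS lies upstream of its gene on the same strand", {
  sim <- default_sim()
  genes <- sim$annotation$genes
  p <- sim$truth$tss[sim$truth$tss$class == "P", ]
  g <- genes[match(p$gene_id, genes$id), ]
  expect_true(all(p$strand == g$strand))
  utr <- ifelse(p$strand == "+", g$start - p$position, p$position - g$end)
  expect_true(all(utr >= 0))
  expect_lt(abs(stats::median(utr) - 13), 2 + 1e-9)  # UTR calibration
})

test_that("TEX enrichment and FRAG body coverage behave as constructed", {
  sim <- cached_sim("enrich", simulation_spec(n_genes = 150L,
                                              genome_length = 150000L,
                                              seed = 42))
  tt <- sim$truth$tss
  tex <- sim$tracks$TEX; notex <- sim$tracks$NOTEX; frag <- sim$tracks$FRAG
  ratios <- vapply(seq_len(nrow(tt)), function(i) {
    s <- tt$strand[i]; p <- tt$position[i]
    tv <- if (s == "+") tex$five_prime_plus else tex$five_prime_minus
    nv <- if (s == "+") notex$five_prime_plus else notex$five_prime_minus
    tv[p] / max(nv[p], 1)
  }, numeric(1))
  expect_gte(mean(ratios), sim$spec$tex_enrichment / 2)

  genes <- sim$annotation$genes
  body <- logical(tex$length)
  for (i in seq_len(nrow(genes))) body[genes$start[i]:genes$end[i]] <- TRUE
  total_cov <- frag$cov_plus + frag$cov_minus
  expect_gt(mean(total_cov[body]), 5 * mean(total_cov[!body]))
})

test_that("a noiseless single-gene simulation confines TEX signal to planted sites", {
  spec <- simulation_spec(n_genes = 1L, genome_length = 5000L,
                          background_rate = 0, fraction_internal = 0,
                          fraction_secondary = 0, n_is_elements = 0L,
                          fraction_bidirectional = 0, seed = 3L)
  sim <- generate_genome(spec)
  tracks <- simulate_coverage(sim$truth, spec)
  fp <- tracks$TEX$five_prime_plus + tracks$TEX$five_prime_minus
  expect_setequal(which(fp > 0), sim$truth$tss$position)
})

test_that("planted promoter windows consensus-call the TATA core", {
  sim <- default_sim()
  p <- sim$truth$tss[sim$truth$tss$class == "P", ]
  wins <- extract_windows(p, sim$replicon, -50L, 10L)
  pwm <- build_pwm(wins, -50L)
  cons <- strsplit(pwm_consensus(pwm), "")[[1]]
  offs <- attr(pwm, "offsets")
  tata <- paste(cons[match(-30:-23, offs)], collapse = "")
  expect_gte(sum(iupac_agreement(tata, "WTTTAAAW")), 6)
})

test_that("truth tables round-trip through TSV including empty truths", {
  sim <- default_sim()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_truth(sim$truth, f)
  feat <- read_tsv(f)
  expect_equal(nrow(feat),
               nrow(sim$truth$tss) + nrow(sim$truth$is_elements))
  back <- read_truth(f)
  expect_equal(back$tss$position, sim$truth$tss$position)
  expect_equal(back$tss$class, sim$truth$tss$class)
  expect_equal(back$is_elements$start, sim$truth$is_elements$start)
  expect_identical(back$operons, sim$truth$operons)

  empty <- structure(list(
    tss = sim$truth$tss[0, ], is_elements = sim$truth$is_elements[0, ],
    operons = sim$truth$operons[0, ], transcripts = sim$truth$transcripts[0, ],
    genome_length = 1000L, circular = TRUE), class = "synthetic_truth")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_truth(empty, f2)
  expect_length(readLines(f2), 1L)  # header only
  expect_equal(nrow(read_truth(f2)$tss), 0L)
})
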