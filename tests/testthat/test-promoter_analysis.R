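test_that("window extraction follows the no-zero offset convention on both strands", {
  seq <- paste(rep(c("A", "C", "G", "T"), 50), collapse = "")  # period 4
  rep <- replicon("chr", seq, circular = TRUE)
  # plus strand: offsets -3..-1 are bases 97..99
  w <- extract_windows(data.frame(position = 100L, strand = "+"), rep,
                       -3L, -1L)
  expect_equal(unclass(w)[1], substr(seq, 97, 99))
  # minus strand: reverse complement of bases 101..103
  wm <- extract_windows(data.frame(position = 100L, strand = "-"), rep,
                        -3L, -1L)
  expect_equal(unclass(wm)[1], reverse_complement(substr(seq, 101, 103)))
  # window through the TSS: -2..+2 has 4 bases, +1 is the TSS base itself
  wt <- extract_windows(data.frame(position = 100L, strand = "+"), rep,
                        -2L, 2L)
  expect_equal(nchar(unclass(wt)[1]), 4L)
  expect_equal(substr(unclass(wt)[1], 3, 3), substr(seq, 100, 100))
})

test_that("windows wrap on circular replicons and are skipped on linear ones", {
  seq <- strrep("ACGTT", 200)
  rep_c <- replicon("chr", seq, circular = TRUE)
  w <- extract_windows(data.frame(position = 2L, strand = "+"), rep_c,
                       -5L, -1L)
  expect_equal(unclass(w)[1],
               paste0(substr(seq, 997, 1000), substr(seq, 1, 1)))
  rep_l <- replicon("chr", seq, circular = FALSE)
  expect_warning(
    w2 <- extract_windows(data.frame(position = 2L, strand = "+"), rep_l,
                          -5L, -1L),
    "skipped")
  expect_length(w2, 0L)
})

test_that("build_pwm normalises columns and honours the pseudocount", {
  wins <- rep("ACGT", 10)
  pwm <- build_pwm(wins, -2L, pseudocount = 0)
  expect_equal(dim(pwm), c(4L, 4L))
  expect_equal(unname(pwm["A", 1]), 1)
  expect_equal(unname(pwm["T", 4]), 1)
  expect_equal(unname(colSums(unclass(pwm))), rep(1, 4))
  expect_equal(attr(pwm, "offsets"), c(-2L, -1L, 1L, 2L))

  set.seed(2)
  rnd <- vapply(1:30, function(i)
    paste(sample(c("A", "C", "G", "T"), 12, replace = TRUE), collapse = ""),
    "")
  p2 <- build_pwm(rnd, -12L, pseudocount = 0.5)
  expect_equal(unname(colSums(unclass(p2))), rep(1, 12))
  ic <- apply(unclass(p2), 2, function(f) 2 + sum(f * log2(f)))
  expect_true(all(ic >= -1e-9 & ic <= 2 + 1e-9))
  expect_error(build_pwm(c("ACGT", "ACG")), "unequal")
})

test_that("majority-rule consensus reduces to the sequence for n = 1", {
  expect_equal(pwm_consensus(build_pwm("TATAAT", -6L, pseudocount = 0)),
               "TATAAT")
})

test_that("locate_tata finds a planted box, reports its 3' end, and flags no-hit", {
  set.seed(4)
  bg <- function() paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
                         collapse = "")
  win <- bg()
  # plant TTTTAAAT (a WTTTAAAW instance) at offsets -30..-23 of a -50..+10
  # window: columns 21..28
  substr(win, 21, 28) <- "TTTTAAAT"
  h <- locate_tata(win, window_from = -50L)
  expect_true(h$hit)
  expect_equal(h$offset, -23L)
  expect_equal(h$start_offset, -30L)

  allc <- strrep("C", 60)
  hc <- locate_tata(allc, window_from = -50L)
  expect_false(hc$hit)
  expect_lt(hc$score, 0)
  expect_error(locate_tata(win, search_range = c(-60L, -45L),
                           window_from = -50L), "outside")
})

test_that("locate_tata is strand-consistent under reverse complement", {
  set.seed(8)
  win <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
               collapse = "")
  substr(win, 27, 34) <- "ATTTAAAA"  # centred so the mirror stays in range
  model <- consensus_pwm("WTTTAAAW")
  h <- locate_element(win, model, search_range = c(-34L, -14L),
                      window_from = -50L)
  # mirrored scan: reverse-complement window and model; the element now sits
  # at mirrored columns
  rcwin <- reverse_complement(win)
  hrc <- locate_element(rcwin, rc_pwm(model), search_range = c(-34L, -14L),
                        window_from = -50L)
  offs <- divtss:::offset_seq(-50L, 10L)
  col <- match(h$offset, offs)             # column of 3' end, forward
  col_rc <- match(hrc$start_offset, offs)  # column of 5' end, mirrored
  expect_equal(col_rc, 61L - col)
  expect_equal(hrc$score, h$score, tolerance = 1e-9)
})

test_that("scan_bidirectional detects a planted divergent promoter at spacing 49", {
  set.seed(12)
  L <- 400L
  bases <- sample(c("A", "C", "G", "T"), L, replace = TRUE,
                  prob = c(0.3, 0.2, 0.2, 0.3))
  t0 <- 250L; a0 <- t0 - 49L
  bases <- divtss:::plant_promoter(bases, L, FALSE, t0, "+", -23L, 1)
  # reverse-strand BRE for the divergent partner (no second TATA: shared)
  bases <- divtss:::plant_promoter(bases, L, FALSE, a0, "-", -23L, 1,
                                   include_tata = FALSE)
  rep <- replicon("chr", paste(bases, collapse = ""))
  w <- extract_windows(data.frame(position = t0, strand = "+"), rep,
                       -60L, 1L)
  hit <- scan_bidirectional(unclass(w)[1], window_from = -60L)
  expect_false(is.null(hit))
  expect_equal(hit$tata$offset, -23L)
  expect_lte(abs(hit$implied_atss_offset - (-49L)), 2L)
  expect_error(scan_bidirectional(strrep("A", 30), window_from = -30L),
               "-60")
})

test_that("the shared-TATA configuration is symmetric at spacing 53", {
  # at 53 bp the shared WTTTAAAW occupies -30..-23 of BOTH starts (the box
  # is its own reverse complement), so swapping pTSS/aTSS roles mirrors the
  # hit exactly
  set.seed(13)
  L <- 400L
  bases <- sample(c("A", "C", "G", "T"), L, replace = TRUE,
                  prob = c(0.3, 0.2, 0.2, 0.3))
  t0 <- 250L; a0 <- t0 - 53L
  bases <- divtss:::plant_promoter(bases, L, FALSE, t0, "+", -23L, 1)
  bases <- divtss:::plant_promoter(bases, L, FALSE, a0, "-", -23L, 1,
                                   include_tata = FALSE)
  rep <- replicon("chr", paste(bases, collapse = ""))
  w <- extract_windows(data.frame(position = t0, strand = "+"), rep,
                       -60L, 1L)
  wm <- extract_windows(data.frame(position = a0, strand = "-"), rep,
                        -60L, 1L)
  hit <- scan_bidirectional(unclass(w)[1], window_from = -60L)
  hitm <- scan_bidirectional(unclass(wm)[1], window_from = -60L)
  expect_false(is.null(hit))
  expect_false(is.null(hitm))
  # poly-A/T runs can tie the BRE placement by one base either way
  expect_lte(abs(hit$implied_atss_offset - (-53L)), 1L)
  expect_lte(abs(hitm$implied_atss_offset - (-53L)), 1L)
  expect_equal(hit$tata$offset, hitm$tata$offset)
})

test_that("random sequence rarely produces a bidirectional hit", {
  set.seed(7)
  hits <- 0L
  for (r in 1:1000) {
    s <- paste(sample(c("A", "C", "G", "T"), 61, replace = TRUE),
               collapse = "")
    if (!is.null(scan_bidirectional(s, window_from = -60L))) hits <- hits + 1L
  }
  expect_lte(hits / 1000, 0.10)
})

test_that("pwm TSV serialisation keeps offsets and frequencies", {
  sim <- default_sim()
  p <- sim$truth$tss[sim$truth$tss$class == "P", ]
  wins <- extract_windows(p, sim$replicon, -50L, 10L)
  pwm <- build_pwm(wins, -50L)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_pwm(pwm, f)
  back <- read_tsv(f)
  expect_equal(back$base, c("A", "C", "G", "T"))
  expect_equal(as.numeric(back[["-23"]]),
               unname(unclass(pwm)[, match(-23L, attr(pwm, "offsets"))]),
               tolerance = 1e-6)
})
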