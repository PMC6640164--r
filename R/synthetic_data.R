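#' Simulation parameters for the synthetic dRNA-seq generator
#'
#' The generator emulates the regulatory architecture of a small, densely
#' packed, AT-rich archaeal chromosome: genes on both strands, promoters
#' carrying the archaeal consensus elements (BRE `RRAAA` ending 9 bp
#' upstream of the TATA 3' end, TATA box `WTTTAAAW` with a class-specific
#' 3'-end offset, an AT-rich initially melted region at -11..-2, and a
#' pyrimidine/purine initiator at -1/+1), operons, insertion-sequence
#' elements with antisense TSS over the transposase ORF start, and a
#' configurable fraction of head-to-tail promoters that are bidirectional:
#' a divergent antisense TSS on the opposite strand exactly
#' `ptss_atss_spacing` bp upstream of the primary TSS, initiated from the
#' shared (near-palindromic) TATA element.
#'
#' @param genome_length Replicon length in bp.
#' @param n_genes Number of genes (including IS elements).
#' @param mean_gene_length Mean gene length in bp (gamma-distributed).
#' @param fraction_minus_strand Stationary fraction of minus-strand genes.
#' @param fraction_head_to_head Probability that a promoter's upstream
#'   neighbour lies on the opposite strand (divergent arrangement).
#' @param fraction_bidirectional Fraction of head-to-tail primary promoters
#'   carrying a shared-TATA divergent antisense start.
#' @param ptss_atss_spacing Distance in bp between a primary TSS and its
#'   divergent antisense partner (default 49).
#' @param tex_height_mean Expected TEX 5'-end count at a primary TSS.
#' @param tex_enrichment Ratio of TEX to NOTEX 5'-end signal at a TSS.
#' @param background_rate Per-base Poisson noise rate on every track.
#' @param n_is_elements Number of IS elements among the genes.
#' @param utr_meanlog,utr_sdlog,utr_max Log-normal 5'-UTR model (median
#'   `exp(utr_meanlog)` = 13 nt, long right tail), truncated at `utr_max`.
#' @param fraction_secondary Fraction of primary promoters with an extra,
#'   weaker secondary TSS further upstream.
#' @param fraction_internal Fraction of genes with an internal TSS.
#' @param fraction_antisense Fraction of genes with a standalone antisense
#'   TSS (own class-A promoter) inside the gene body. Default 0: in the
#'   modelled system antisense starts arise from bidirectional promoters
#'   and IS elements; standalone antisense promoters are available as an
#'   extension.
#' @param fraction_operon Probability that a gene joins its co-directional
#'   neighbour's transcription unit (losing its own primary TSS).
#' @param atss_height_ratio Antisense TSS height relative to the primary
#'   (bidirectional partners) or to `tex_height_mean` (standalone/IS).
#' @param internal_height_ratio,secondary_height_ratio Height ratios for
#'   internal and secondary TSS.
#' @param dispersion Negative-binomial dispersion of TSS heights
#'   (variance = mu + dispersion * mu^2).
#' @param consensus_strength Per-base probability that a planted promoter
#'   position carries a consensus-drawn base (rest uniform).
#' @param gc_content Background GC fraction of the genome.
#' @param processed_per_kb Expected NOTEX processed 5' ends per kb of
#'   transcript.
#' @param frag_depth_ratio FRAG read depth per unit of TSS height.
#' @param circular Simulate a circular chromosome.
#' @param seed Integer seed; the whole generator is deterministic given it.
#' @return A list of class `simulation_spec`.
#' @export
simulation_spec <- function(genome_length = 60000L,
                            n_genes = 60L,
                            mean_gene_length = 600L,
                            fraction_minus_strand = 0.5,
                            fraction_head_to_head = 0.47,
                            fraction_bidirectional = 0.2,
                            ptss_atss_spacing = 49L,
                            tex_height_mean = 100,
                            tex_enrichment = 10,
                            background_rate = 0.02,
                            n_is_elements = 4L,
                            utr_meanlog = log(13),
                            utr_sdlog = 1.63,
                            utr_max = 150L,
                            fraction_secondary = 0.2,
                            fraction_internal = 0.3,
                            fraction_antisense = 0,
                            fraction_operon = 0.25,
                            atss_height_ratio = 0.8,
                            internal_height_ratio = 0.6,
                            secondary_height_ratio = 0.35,
                            dispersion = 0.3,
                            consensus_strength = 0.95,
                            gc_content = 0.4075,
                            processed_per_kb = 20,
                            frag_depth_ratio = 0.3,
                            circular = TRUE,
                            seed = 1L) {
  spec <- list(genome_length = as.integer(genome_length),
               n_genes = as.integer(n_genes),
               mean_gene_length = as.integer(mean_gene_length),
               fraction_minus_strand = fraction_minus_strand,
               fraction_head_to_head = fraction_head_to_head,
               fraction_bidirectional = fraction_bidirectional,
               ptss_atss_spacing = as.integer(ptss_atss_spacing),
               tex_height_mean = tex_height_mean,
               tex_enrichment = tex_enrichment,
               background_rate = background_rate,
               n_is_elements = as.integer(n_is_elements),
               utr_meanlog = utr_meanlog, utr_sdlog = utr_sdlog,
               utr_max = as.integer(utr_max),
               fraction_secondary = fraction_secondary,
               fraction_internal = fraction_internal,
               fraction_antisense = fraction_antisense,
               fraction_operon = fraction_operon,
               atss_height_ratio = atss_height_ratio,
               internal_height_ratio = internal_height_ratio,
               secondary_height_ratio = secondary_height_ratio,
               dispersion = dispersion,
               consensus_strength = consensus_strength,
               gc_content = gc_content,
               processed_per_kb = processed_per_kb,
               frag_depth_ratio = frag_depth_ratio,
               circular = circular,
               seed = as.integer(seed))
  props <- c("fraction_minus_strand", "fraction_head_to_head",
             "fraction_bidirectional", "fraction_secondary",
             "fraction_internal", "fraction_antisense", "fraction_operon")
  for (p in props) {
    if (spec[[p]] < 0 || spec[[p]] > 1) stop("simulation_spec: ", p,
                                             " must lie in [0, 1]")
  }
  if (spec$ptss_atss_spacing < 1L) stop("simulation_spec: spacing must be >= 1")
  if (spec$tex_enrichment <= 0) stop("simulation_spec: tex_enrichment must be > 0")
  if (spec$genome_length < spec$n_genes * (spec$mean_gene_length %/% 2L)) {
    stop("simulation_spec: genome_length too small for n_genes")
  }
  structure(spec, class = "simulation_spec")
}

# IUPAC code -> base set, for consensus sampling and matching.
IUPAC_SETS <- list(A = "A", C = "C", G = "G", T = "T",
                   R = c("A", "G"), Y = c("C", "T"), W = c("A", "T"),
                   S = c("C", "G"), K = c("G", "T"), M = c("A", "C"),
                   B = c("C", "G", "T"), D = c("A", "G", "T"),
                   H = c("A", "C", "T"), V = c("A", "C", "G"),
                   N = c("A", "C", "G", "T"))

# Sample one instance of an IUPAC consensus with per-base fidelity.
sample_consensus <- function(consensus, fidelity) {
  letters <- strsplit(consensus, "", fixed = TRUE)[[1]]
  vapply(letters, function(l) {
    b <- sample(IUPAC_SETS[[l]], 1L)
    if (stats::runif(1) > fidelity) b <- sample(c("A", "C", "G", "T"), 1L)
    b
  }, "", USE.NAMES = FALSE)
}

# Promoter element layout relative to a TATA 3'-end offset `e`:
# TATA occupies e-7..e, BRE (RRAAA) ends at e-9. Class-specific `e`:
TATA_END_BY_CLASS <- c(P = -23L, S = -27L, I = -22L, A = -25L)
BRE_CONSENSUS <- "RRAAA"
TATA_CONSENSUS <- "WTTTAAAW"

# Stamp bases (given in TSS-strand reading, ascending offsets) onto the
# plus-strand base vector; minus-strand TSS bases are complemented.
stamp_bases <- function(bases_vec, L, circular, tss_pos, strand,
                        offsets, letters) {
  pos <- offset_to_genomic(tss_pos, strand, offsets)
  if (circular) {
    pos <- wrap_position(pos, L)
  } else {
    keep <- pos >= 1L & pos <= L
    pos <- pos[keep]; letters <- letters[keep]
  }
  if (strand == "-") letters <- unname(COMPLEMENT_MAP[letters])
  bases_vec[pos] <- letters
  bases_vec
}

# Plant a full promoter (BRE + TATA + melted region + INR) for a TSS.
plant_promoter <- function(bases_vec, L, circular, tss_pos, strand,
                           tata_end, fidelity,
                           include_tata = TRUE) {
  if (include_tata) {
    bases_vec <- stamp_bases(bases_vec, L, circular, tss_pos, strand,
                             element_offsets(tata_end, 8L),
                             sample_consensus(TATA_CONSENSUS, fidelity))
  }
  bre_end <- tata_end - 9L
  bases_vec <- stamp_bases(bases_vec, L, circular, tss_pos, strand,
                           element_offsets(bre_end, 5L),
                           sample_consensus(BRE_CONSENSUS, fidelity))
  melted <- sample(c("A", "T", "C", "G"), 10L, replace = TRUE,
                   prob = c(0.4, 0.4, 0.1, 0.1))
  bases_vec <- stamp_bases(bases_vec, L, circular, tss_pos, strand,
                           offset_seq(-11L, -2L), melted)
  bases_vec <- stamp_bases(bases_vec, L, circular, tss_pos, strand,
                           c(-1L, 1L), sample_consensus("YR", fidelity))
  bases_vec
}

rnb_height <- function(n, mu, dispersion) {
  pmax(1, stats::rnbinom(n, size = 1 / dispersion, mu = mu))
}

#' Generate a synthetic genome with planted promoter architecture
#'
#' Packs genes sequentially along a (by default circular) replicon with
#' orientation-dependent intergenic gaps (divergent, "head-to-head", gaps
#' are drawn around a 117 bp median), assigns operon membership, plants a
#' promoter for every transcription-unit leader plus secondary, internal
#' and antisense TSS, makes the chosen fraction of head-to-tail promoters
#' bidirectional (shared TATA, divergent partner at the configured
#' spacing, reverse-strand BRE between the TATA and the primary TSS), and
#' plants an antisense TSS over the ORF start of every IS element. All
#' randomness derives from `spec$seed`.
#'
#' @param spec A [simulation_spec()].
#' @return List with elements `replicon` ([replicon()]), `annotation`
#'   ([genome_annotation()]) and `truth` (class `synthetic_truth`: data
#'   frames `tss`, `is_elements`, `operons`, `transcripts`).
#' @export
generate_genome <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  n <- spec$n_genes
  L <- spec$genome_length

  # Strands: Markov chain whose flip probability is the head-to-head rate.
  strand <- character(n)
  strand[1] <- if (stats::runif(1) < spec$fraction_minus_strand) "-" else "+"
  for (i in seq_len(n)[-1]) {
    flip <- stats::runif(1) < spec$fraction_head_to_head
    strand[i] <- if (flip) setdiff(c("+", "-"), strand[i - 1]) else strand[i - 1]
  }

  glen <- pmax(150L, round(stats::rgamma(n, shape = 4,
                                         scale = spec$mean_gene_length / 4)))
  is_idx <- if (spec$n_is_elements > 0L) {
    sort(sample(seq_len(n), min(spec$n_is_elements, n)))
  } else integer(0)
  is_flag <- seq_len(n) %in% is_idx

  # Operon membership: a gene may extend its co-directional predecessor's
  # unit; IS elements stay single-gene units.
  unit <- integer(n); unit[1] <- 1L
  for (i in seq_len(n)[-1]) {
    joins <- strand[i] == strand[i - 1] && !is_flag[i] && !is_flag[i - 1] &&
      stats::runif(1) < spec$fraction_operon
    unit[i] <- if (joins) unit[i - 1] else max(unit[seq_len(i - 1)]) + 1L
  }

  utr <- as.integer(pmin(spec$utr_max,
                         round(stats::rlnorm(n, spec$utr_meanlog,
                                             spec$utr_sdlog))))
  has_secondary <- stats::runif(n) < spec$fraction_secondary
  sec_gap <- 15L + stats::rpois(n, 20)   # sTSS this far upstream of pTSS

  # Leaders: the 5'-most gene of each unit carries the unit's primary TSS.
  leader <- logical(n)
  for (u in unique(unit)) {
    members <- which(unit == u)
    leader[if (strand[members[1]] == "+") members[1] else members[length(members)]] <- TRUE
  }
  has_secondary <- has_secondary & leader

  # Promoter room needed in the gap 5' of each leader.
  need <- ifelse(leader, utr + 55L + ifelse(has_secondary, sec_gap, 0L), 0L)

  # Sequential packing with orientation-dependent gaps.
  start <- integer(n); end <- integer(n)
  pos <- 350L + need[1]
  for (i in seq_len(n)) {
    if (i > 1L) {
      same_unit <- unit[i] == unit[i - 1]
      pair <- paste0(strand[i - 1], strand[i])
      gap <- if (same_unit) {
        10L + stats::rpois(1, 25)
      } else if (pair == "-+") {          # divergent promoters share the gap
        max(60L, round(stats::rlnorm(1, log(117), 0.35)))
      } else if (pair == "+-") {          # convergent: no promoter here
        20L + stats::rpois(1, 40)
      } else if (strand[i] == "+") {      # ++ : room for gene i's promoter
        need[i] + 10L + stats::rpois(1, 80)
      } else {                            # -- : room for gene i-1's promoter
        need[i - 1] + 10L + stats::rpois(1, 80)
      }
      pos <- end[i - 1] + as.integer(gap) + 1L
    }
    start[i] <- as.integer(pos)
    end[i] <- as.integer(pos + glen[i] - 1L)
  }
  if (end[n] + 350L > L) {
    stop("generate_genome: capacity error - ", n, " genes need ",
         end[n] + 350L, " bp but genome_length is ", L,
         "; increase genome_length or reduce n_genes")
  }

  ids <- ifelse(is_flag,
                sprintf("is_%03d", cumsum(is_flag)),
                sprintf("gene_%03d", seq_len(n)))
  genes <- data.frame(id = ids, start = start, end = end, strand = strand,
                      kind = ifelse(is_flag, "IS_element", "gene"),
                      stringsAsFactors = FALSE)

  # Background genome at the configured GC content.
  p_gc <- spec$gc_content / 2
  bases <- sample(c("A", "C", "G", "T"), L, replace = TRUE,
                  prob = c((1 - spec$gc_content) / 2, p_gc, p_gc,
                           (1 - spec$gc_content) / 2))

  fid <- spec$consensus_strength
  tss_rows <- list()
  add_tss <- function(position, strand, class, gene_id, height,
                      bidirectional = FALSE, partner = NA_integer_,
                      tata_end = NA_integer_, source = "promoter") {
    tss_rows[[length(tss_rows) + 1L]] <<- data.frame(
      position = as.integer(wrap_position(position, L)), strand = strand,
      class = class, gene_id = gene_id, height = as.numeric(height),
      bidirectional = bidirectional, partner_position =
        as.integer(if (is.na(partner)) NA else wrap_position(partner, L)),
      tata_end = tata_end, source = source, stringsAsFactors = FALSE)
  }

  ptss_pos <- rep(NA_integer_, n)
  p_height <- rep(NA_real_, n)

  # Primary (+ optional secondary) promoters for unit leaders.
  for (i in which(leader)) {
    t0 <- if (strand[i] == "+") start[i] - utr[i] else end[i] + utr[i]
    ptss_pos[i] <- t0
    h <- pmax(5, rnb_height(1, spec$tex_height_mean, spec$dispersion))
    p_height[i] <- h
    bases <- plant_promoter(bases, L, spec$circular, t0, strand[i],
                            TATA_END_BY_CLASS[["P"]], fid)
    add_tss(t0, strand[i], "P", ids[i], h, tata_end = TATA_END_BY_CLASS[["P"]])
    if (has_secondary[i]) {
      t1 <- if (strand[i] == "+") t0 - sec_gap[i] else t0 + sec_gap[i]
      hs <- max(3, min(h - 1, stats::rpois(1, spec$secondary_height_ratio * h)))
      bases <- plant_promoter(bases, L, spec$circular, t1, strand[i],
                              TATA_END_BY_CLASS[["S"]], fid)
      add_tss(t1, strand[i], "S", ids[i], hs,
              tata_end = TATA_END_BY_CLASS[["S"]])
    }
  }

  # Internal TSS on a fraction of sufficiently long genes.
  for (i in which(stats::runif(n) < spec$fraction_internal & glen >= 140L)) {
    off <- sample(seq.int(60L, glen[i] - 20L), 1L)
    t0 <- if (strand[i] == "+") start[i] + off else end[i] - off
    h <- rnb_height(1, spec$internal_height_ratio * spec$tex_height_mean,
                    spec$dispersion)
    bases <- plant_promoter(bases, L, spec$circular, t0, strand[i],
                            TATA_END_BY_CLASS[["I"]], fid)
    add_tss(t0, strand[i], "I", ids[i], h, tata_end = TATA_END_BY_CLASS[["I"]])
  }

  # Standalone antisense TSS with their own class-A promoter.
  for (i in which(stats::runif(n) < spec$fraction_antisense & glen >= 140L &
                  !is_flag)) {
    off <- sample(seq.int(40L, glen[i] - 40L), 1L)
    t0 <- if (strand[i] == "+") start[i] + off else end[i] - off
    a_strand <- setdiff(c("+", "-"), strand[i])
    h <- rnb_height(1, spec$atss_height_ratio * spec$tex_height_mean,
                    spec$dispersion)
    bases <- plant_promoter(bases, L, spec$circular, t0, a_strand,
                            TATA_END_BY_CLASS[["A"]], fid)
    add_tss(t0, a_strand, "A", ids[i], h, tata_end = TATA_END_BY_CLASS[["A"]],
            source = "standalone")
  }

  # IS elements: antisense TSS over the transposase ORF start.
  is_records <- list()
  for (i in is_idx) {
    off <- max(3L, round(0.1 * glen[i]))
    t0 <- if (strand[i] == "+") start[i] + off else end[i] - off
    a_strand <- setdiff(c("+", "-"), strand[i])
    h <- rnb_height(1, spec$atss_height_ratio * spec$tex_height_mean,
                    spec$dispersion)
    bases <- plant_promoter(bases, L, spec$circular, t0, a_strand,
                            TATA_END_BY_CLASS[["A"]], fid)
    add_tss(t0, a_strand, "A", ids[i], h, tata_end = TATA_END_BY_CLASS[["A"]],
            source = "is_element")
    is_records[[length(is_records) + 1L]] <- data.frame(
      id = ids[i], start = start[i], end = end[i], strand = strand[i],
      atss_position = as.integer(wrap_position(t0, L)),
      stringsAsFactors = FALSE)
  }

  # Bidirectional promoters: a fraction of head-to-tail leader promoters
  # gains a divergent antisense start at the configured spacing; the TATA
  # is shared (WTTTAAAW is its own reverse complement), so only the
  # reverse-strand BRE, melted region and initiator are added.
  upstream_neighbor_strand <- function(i) {
    if (strand[i] == "+") {
      if (i > 1L) strand[i - 1] else if (spec$circular) strand[n] else NA
    } else {
      if (i < n) strand[i + 1] else if (spec$circular) strand[1] else NA
    }
  }
  ht_leaders <- which(leader & !is_flag &
                        vapply(seq_len(n), function(i)
                          identical(upstream_neighbor_strand(i), strand[i]),
                          logical(1)))
  n_bidir <- round(spec$fraction_bidirectional * length(ht_leaders))
  bidir_genes <- if (n_bidir > 0L) {
    sort(sample(ht_leaders, n_bidir))
  } else integer(0)
  for (i in bidir_genes) {
    t0 <- ptss_pos[i]
    a_strand <- setdiff(c("+", "-"), strand[i])
    a0 <- if (strand[i] == "+") t0 - spec$ptss_atss_spacing else
      t0 + spec$ptss_atss_spacing
    h <- rnb_height(1, spec$atss_height_ratio * p_height[i], spec$dispersion)
    bases <- plant_promoter(bases, L, spec$circular, a0, a_strand,
                            TATA_END_BY_CLASS[["P"]], fid,
                            include_tata = FALSE)
    add_tss(a0, a_strand, "A", ids[i], h, bidirectional = TRUE, partner = t0,
            source = "bidirectional")
    k <- which(vapply(tss_rows, function(r)
      r$position == wrap_position(t0, L) && r$class == "P", logical(1)))
    for (j in k) {
      tss_rows[[j]]$bidirectional <- TRUE
      tss_rows[[j]]$partner_position <- as.integer(wrap_position(a0, L))
    }
  }

  tss <- do.call(rbind, tss_rows)
  tss <- tss[order(tss$position, tss$strand), , drop = FALSE]
  rownames(tss) <- NULL

  # Transcripts: unit leader TSS to unit 3' end (for FRAG coverage and
  # NOTEX processed ends); secondary/internal/antisense starts produce
  # shorter transcripts of their own.
  tx_rows <- list()
  add_tx <- function(strand, tss_position, from, to, height, unit_id) {
    tx_rows[[length(tx_rows) + 1L]] <<- data.frame(
      unit_id = unit_id, strand = strand,
      tss_position = as.integer(wrap_position(tss_position, L)),
      span_start = as.integer(from), span_end = as.integer(to),
      height = as.numeric(height), stringsAsFactors = FALSE)
  }
  for (u in unique(unit)) {
    members <- which(unit == u)
    lead <- members[leader[members]]
    s <- strand[lead]
    t0 <- ptss_pos[lead]
    if (s == "+") add_tx(s, t0, t0, max(end[members]), p_height[lead], u)
    else add_tx(s, t0, min(start[members]), t0, p_height[lead], u)
  }
  for (r in seq_len(nrow(tss))) {
    row <- tss[r, ]
    if (row$class == "P") next
    len_tx <- if (row$class == "S") 400L else 200L
    if (row$strand == "+") add_tx(row$strand, row$position, row$position,
                                  row$position + len_tx, row$height, NA_integer_)
    else add_tx(row$strand, row$position, row$position - len_tx,
                row$position, row$height, NA_integer_)
  }
  transcripts <- do.call(rbind, tx_rows)

  operons <- data.frame(gene_id = ids, unit_id = unit, leader = leader,
                        stringsAsFactors = FALSE)
  is_elements <- if (length(is_records)) do.call(rbind, is_records) else
    data.frame(id = character(), start = integer(), end = integer(),
               strand = character(), atss_position = integer(),
               stringsAsFactors = FALSE)

  rep <- replicon("synthetic", paste(bases, collapse = ""),
                  circular = spec$circular)
  truth <- structure(list(tss = tss, is_elements = is_elements,
                          operons = operons, transcripts = transcripts,
                          genome_length = L, circular = spec$circular),
                     class = "synthetic_truth")
  list(replicon = rep,
       annotation = genome_annotation(rep, genes),
       truth = truth)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(
    "<synthetic_truth> %d TSS (%s), %d bidirectional pairs, %d IS, %d units\n",
    nrow(x$tss),
    paste(sprintf("%s:%d", names(table(x$tss$class)), table(x$tss$class)),
          collapse = " "),
    sum(x$tss$bidirectional & x$tss$class == "A"),
    nrow(x$is_elements), length(unique(x$operons$unit_id))))
  invisible(x)
}

#' Simulate TEX / NOTEX / FRAG coverage tracks from a planted truth
#'
#' The TEX library places the planted height as a sharp 5'-end pile-up at
#' every planted TSS; the NOTEX library attenuates the TSS signal by
#' `tex_enrichment` and scatters processed 5' ends uniformly within
#' transcript bodies; the FRAG library lays quasi-uniform (per-base
#' Poisson) read coverage over each transcript from its TSS to its 3' end.
#' Poisson background at `background_rate` is added everywhere. The
#' simulation is deterministic given `spec$seed`.
#'
#' @param truth `synthetic_truth` from [generate_genome()].
#' @param spec The same [simulation_spec()].
#' @return Named list of [coverage_track()]s: `TEX`, `NOTEX`, `FRAG`.
#' @export
simulate_coverage <- function(truth, spec) {
  stopifnot(inherits(truth, "synthetic_truth"),
            inherits(spec, "simulation_spec"))
  set.seed(spec$seed + 1L)
  L <- truth$genome_length
  fp <- list(TEX = list("+" = numeric(L), "-" = numeric(L)),
             NOTEX = list("+" = numeric(L), "-" = numeric(L)))
  cov <- list(TEX = list("+" = numeric(L), "-" = numeric(L)),
              NOTEX = list("+" = numeric(L), "-" = numeric(L)),
              FRAG = list("+" = numeric(L), "-" = numeric(L)))

  for (r in seq_len(nrow(truth$tss))) {
    row <- truth$tss[r, ]
    p <- row$position; s <- row$strand
    fp$TEX[[s]][p] <- fp$TEX[[s]][p] + row$height
    fp$NOTEX[[s]][p] <- fp$NOTEX[[s]][p] +
      stats::rpois(1, row$height / spec$tex_enrichment)
  }

  depth_ratio <- c(TEX = 0.5, NOTEX = 0.8, FRAG = 1.0)
  for (r in seq_len(nrow(truth$transcripts))) {
    tx <- truth$transcripts[r, ]
    span <- wrap_position(seq.int(tx$span_start, tx$span_end), L)
    len <- length(span)
    d <- max(1, round(tx$height * spec$frag_depth_ratio))
    for (lib in names(cov)) {
      cov[[lib]][[tx$strand]][span] <- cov[[lib]][[tx$strand]][span] +
        stats::rpois(len, d * depth_ratio[[lib]])
    }
    n_proc <- stats::rpois(1, spec$processed_per_kb * len / 1000)
    if (n_proc > 0L) {
      at <- sample(span, n_proc, replace = TRUE)
      tab <- table(at)
      idx <- as.integer(names(tab))
      fp$NOTEX[[tx$strand]][idx] <- fp$NOTEX[[tx$strand]][idx] + as.numeric(tab)
    }
  }

  if (spec$background_rate > 0) {
    for (lib in names(fp)) for (s in c("+", "-")) {
      fp[[lib]][[s]] <- fp[[lib]][[s]] + stats::rpois(L, spec$background_rate)
    }
    for (lib in names(cov)) for (s in c("+", "-")) {
      cov[[lib]][[s]] <- cov[[lib]][[s]] + stats::rpois(L, spec$background_rate)
    }
  }

  list(
    TEX = coverage_track("TEX", L,
                         five_prime_plus = fp$TEX[["+"]],
                         five_prime_minus = fp$TEX[["-"]],
                         cov_plus = cov$TEX[["+"]], cov_minus = cov$TEX[["-"]]),
    NOTEX = coverage_track("NOTEX", L,
                           five_prime_plus = fp$NOTEX[["+"]],
                           five_prime_minus = fp$NOTEX[["-"]],
                           cov_plus = cov$NOTEX[["+"]],
                           cov_minus = cov$NOTEX[["-"]]),
    FRAG = coverage_track("FRAG", L,
                          cov_plus = cov$FRAG[["+"]],
                          cov_minus = cov$FRAG[["-"]])
  )
}

#' Write a synthetic truth to TSV
#'
#' One row per planted feature (TSS and IS elements) in the main file;
#' operon membership and transcript spans go to sibling files so the truth
#' round-trips completely through [read_truth()].
#'
#' @param truth `synthetic_truth`.
#' @param path Main TSV path; `*_operons.tsv` and `*_transcripts.tsv`
#'   siblings are derived from it.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  tss <- truth$tss
  feat <- data.frame(
    feature = c(rep("TSS", nrow(tss)), rep("IS", nrow(truth$is_elements))),
    position = c(tss$position, truth$is_elements$atss_position),
    strand = c(tss$strand, truth$is_elements$strand),
    class = c(tss$class, rep(NA_character_, nrow(truth$is_elements))),
    gene_id = c(tss$gene_id, truth$is_elements$id),
    height = c(tss$height, rep(NA_real_, nrow(truth$is_elements))),
    bidirectional = c(tss$bidirectional,
                      rep(NA, nrow(truth$is_elements))),
    partner_position = c(tss$partner_position,
                         rep(NA_integer_, nrow(truth$is_elements))),
    tata_end = c(tss$tata_end, rep(NA_integer_, nrow(truth$is_elements))),
    source = c(tss$source, rep("is_element", nrow(truth$is_elements))),
    start = c(rep(NA_integer_, nrow(tss)), truth$is_elements$start),
    end = c(rep(NA_integer_, nrow(tss)), truth$is_elements$end),
    stringsAsFactors = FALSE
  )
  write_tsv(feat, path)
  base <- sub("\\.tsv$", "", path)
  write_tsv(truth$operons, paste0(base, "_operons.tsv"))
  tx <- truth$transcripts
  tx$genome_length <- rep(truth$genome_length, nrow(tx))
  tx$circular <- rep(truth$circular, nrow(tx))
  write_tsv(tx, paste0(base, "_transcripts.tsv"))
  invisible(path)
}

#' Read a synthetic truth written by [write_truth()]
#' @param path Main truth TSV.
#' @return `synthetic_truth` object.
#' @export
read_truth <- function(path) {
  feat <- read_tsv(path)
  tss <- feat[feat$feature == "TSS",
              c("position", "strand", "class", "gene_id", "height",
                "bidirectional", "partner_position", "tata_end", "source")]
  rownames(tss) <- NULL
  isr <- feat[feat$feature == "IS", , drop = FALSE]
  is_elements <- data.frame(id = isr$gene_id, start = isr$start,
                            end = isr$end, strand = isr$strand,
                            atss_position = isr$position,
                            stringsAsFactors = FALSE)
  base <- sub("\\.tsv$", "", path)
  operons <- read_tsv(paste0(base, "_operons.tsv"))
  tx <- read_tsv(paste0(base, "_transcripts.tsv"))
  gl <- if (nrow(tx)) tx$genome_length[1] else NA_integer_
  circ <- if (nrow(tx)) tx$circular[1] else TRUE
  tx$genome_length <- NULL; tx$circular <- NULL
  structure(list(tss = tss, is_elements = is_elements, operons = operons,
                 transcripts = tx, genome_length = gl, circular = circ),
            class = "synthetic_truth")
}

#' Write a complete simulated dataset to a directory
#'
#' Produces `genome.fasta`, `annotation.gff3`, `is_elements.bed`,
#' `{tex,notex}_{plus,minus}.wig` (5'-end counts),
#' `frag_{plus,minus}.wig` (read coverage) and `truth.tsv` (+ siblings).
#'
#' @param spec A [simulation_spec()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the list from [generate_genome()] plus `tracks`.
#' @export
write_simulation <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- generate_genome(spec)
  tracks <- simulate_coverage(sim$truth, spec)
  name <- sim$replicon$name
  write_fasta(sim$replicon, file.path(dir, "genome.fasta"))
  write_gff(sim$annotation, file.path(dir, "annotation.gff3"))
  if (nrow(sim$truth$is_elements)) {
    write_bed(gene_table(sim$truth$is_elements$id,
                         sim$truth$is_elements$start,
                         sim$truth$is_elements$end,
                         sim$truth$is_elements$strand, "IS_element"),
              name, file.path(dir, "is_elements.bed"))
  }
  write_wiggle(tracks$TEX, name, file.path(dir, "tex_plus.wig"),
               file.path(dir, "tex_minus.wig"), what = "five_prime")
  write_wiggle(tracks$NOTEX, name, file.path(dir, "notex_plus.wig"),
               file.path(dir, "notex_minus.wig"), what = "five_prime")
  write_wiggle(tracks$FRAG, name, file.path(dir, "frag_plus.wig"),
               file.path(dir, "frag_minus.wig"), what = "coverage")
  write_truth(sim$truth, file.path(dir, "truth.tsv"))
  invisible(c(sim, list(tracks = tracks)))
}
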