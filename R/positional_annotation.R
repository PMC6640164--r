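#' Gene-scaled position of a TSS
#'
#' Positions around a gene are sorted into three zones, the metagene
#' convention used for positional TSS plots: a fixed upstream flank
#' (offsets -flank..-1 before the gene's 5' end, strand-aware), the gene
#' body (scaled to [0, 1] by gene length) and a fixed downstream flank
#' (+1..+flank past the 3' end).
#'
#' @param position,strand TSS coordinates (strand is recorded but zoning
#'   is relative to the gene's own orientation).
#' @param gene One-row gene data frame (`start`, `end`, `strand`).
#' @param flank Flank width in bp (default 300).
#' @return List of class `scaled_position`: `zone` (`"upstream"`,
#'   `"body"`, `"downstream"`) and `value` (bp offset in flanks, scaled
#'   proportion in the body).
#' @export
scaled_position <- function(position, strand, gene, flank = 300L) {
  glen <- gene$end - gene$start + 1L
  off5 <- if (gene$strand == "+") position - gene$start else
    gene$end - position
  if (off5 < -flank || off5 > glen - 1L + flank) {
    stop("scaled_position: TSS at ", position, " outside gene +-", flank,
         " bp range")
  }
  if (off5 < 0L) {
    structure(list(zone = "upstream", value = off5),
              class = "scaled_position")
  } else if (off5 <= glen - 1L) {
    v <- if (glen == 1L) 0 else off5 / (glen - 1L)
    structure(list(zone = "body", value = v), class = "scaled_position")
  } else {
    structure(list(zone = "downstream", value = off5 - (glen - 1L)),
              class = "scaled_position")
  }
}

#' Scaled positions for a TSS set against its genes
#'
#' Vectorised companion of [scaled_position()]: one row per (TSS, gene)
#' pair with the TSS inside the gene's flanked range.
#'
#' @param tss Data frame with `position`, `strand` and `gene_id`.
#' @param genes Gene table.
#' @param flank Flank width in bp.
#' @return Data frame: `position`, `strand`, `gene_id`, `zone`, `value`.
#' @export
scaled_positions <- function(tss, genes, flank = 300L) {
  rows <- list()
  for (i in seq_len(nrow(tss))) {
    g <- genes[genes$id == tss$gene_id[i], , drop = FALSE]
    if (nrow(g) != 1L) next
    sp <- tryCatch(scaled_position(tss$position[i], tss$strand[i], g, flank),
                   error = function(e) NULL)
    if (is.null(sp)) next
    rows[[length(rows) + 1L]] <- data.frame(
      position = tss$position[i], strand = tss$strand[i],
      gene_id = tss$gene_id[i], zone = sp$zone, value = sp$value,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(position = integer(), strand = character(),
                      gene_id = character(), zone = character(),
                      value = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Antisense TSS positions relative to IS elements
#'
#' Maps every antisense TSS within `flank` bp of an insertion-sequence
#' element onto the IS-oriented metagene scale (100 bp flanks, body
#' scaled by length) and reports the fraction of IS elements with at
#' least one antisense TSS over the first 20% of the body - the signature
#' of antisense starts overlapping the transposase ORF start.
#'
#' @param atss Data frame of antisense TSS (`position`, `strand`).
#' @param is_elements Gene table of IS elements.
#' @param flank Flank width in bp (default 100).
#' @return Data frame (one row per (aTSS, IS) pair in range: `is_id`,
#'   `position`, `strand`, `zone`, `value`) with attribute
#'   `fraction_orf_start` (IS with an aTSS in the first 20% of the body).
#' @export
is_element_profile <- function(atss, is_elements, flank = 100L) {
  rows <- list()
  hit_start <- logical(nrow(is_elements))
  for (j in seq_len(nrow(is_elements))) {
    g <- is_elements[j, , drop = FALSE]
    for (i in seq_len(nrow(atss))) {
      sp <- tryCatch(scaled_position(atss$position[i], atss$strand[i], g,
                                     flank),
                     error = function(e) NULL)
      if (is.null(sp)) next
      rows[[length(rows) + 1L]] <- data.frame(
        is_id = g$id, position = atss$position[i], strand = atss$strand[i],
        zone = sp$zone, value = sp$value, stringsAsFactors = FALSE)
      if (sp$zone == "body" && sp$value <= 0.2) hit_start[j] <- TRUE
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(is_id = character(), position = integer(),
               strand = character(), zone = character(), value = numeric(),
               stringsAsFactors = FALSE)
  attr(out, "fraction_orf_start") <- if (nrow(is_elements)) {
    mean(hit_start)
  } else NA_real_
  out
}

#' Infer transcription units from TSS, transcript coverage and genes
#'
#' Merges co-directional consecutive genes into one unit when the
#' intergenic region between them carries continuous FRAG coverage on
#' their strand (no run of positions below `min_body_coverage` longer
#' than `gap_threshold`) and the downstream gene has no primary TSS of
#' its own. Each unit's leader is the primary TSS of its 5'-most gene
#' when present.
#'
#' @param annotation [genome_annotation()].
#' @param ptss Data frame of primary TSS (`position`, `strand`,
#'   `gene_id`).
#' @param frag FRAG [coverage_track()] (read coverage).
#' @param gap_threshold Longest tolerated low-coverage run in bp.
#' @param min_body_coverage Per-base coverage floor.
#' @return Data frame of units: `unit_id`, `strand`, `genes`
#'   (comma-separated ids in transcription order), `n_genes`,
#'   `leading_ptss` (position or `NA`).
#' @export
infer_units <- function(annotation, ptss, frag, gap_threshold = 25L,
                        min_body_coverage = 3) {
  genes <- annotation$genes
  n <- nrow(genes)
  has_ptss <- genes$id %in% ptss$gene_id
  unit <- integer(n)
  if (n) unit[1] <- 1L
  for (i in seq_len(n)[-1]) {
    merge_ok <- genes$strand[i] == genes$strand[i - 1]
    if (merge_ok) {
      gap_lo <- genes$end[i - 1] + 1L
      gap_hi <- genes$start[i] - 1L
      if (gap_lo <= gap_hi) {
        cov <- track_vector(frag, genes$strand[i], "coverage")[gap_lo:gap_hi]
        low <- rle(cov < min_body_coverage)
        worst <- if (any(low$values)) max(low$lengths[low$values]) else 0L
        merge_ok <- worst <= gap_threshold
      }
      if (merge_ok) {
        # the downstream gene in transcription order must lack its own pTSS
        down <- if (genes$strand[i] == "+") i else i - 1L
        merge_ok <- !has_ptss[down]
      }
    }
    unit[i] <- if (merge_ok) unit[i - 1] else max(unit[seq_len(i - 1)]) + 1L
  }
  rows <- lapply(unique(unit), function(u) {
    members <- which(unit == u)
    s <- genes$strand[members[1]]
    ord <- if (s == "+") members else rev(members)
    lead_gene <- genes$id[ord[1]]
    lp <- ptss$position[ptss$gene_id == lead_gene]
    data.frame(unit_id = u, strand = s,
               genes = paste(genes$id[ord], collapse = ","),
               n_genes = length(members),
               leading_ptss = if (length(lp)) lp[1] else NA_integer_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare inferred units against a planted operon truth
#'
#' @param units Output of [infer_units()].
#' @param truth `synthetic_truth` (its `operons` table).
#' @return List: `exact_match` (fraction of truth units whose exact gene
#'   composition is recovered), `n_truth`, `n_inferred`.
#' @export
unit_recovery <- function(units, truth) {
  truth_sets <- tapply(truth$operons$gene_id, truth$operons$unit_id,
                       function(g) paste(sort(g), collapse = ","))
  inferred_sets <- vapply(units$genes, function(g)
    paste(sort(strsplit(g, ",", fixed = TRUE)[[1]]), collapse = ","), "")
  list(exact_match = mean(truth_sets %in% inferred_sets),
       n_truth = length(truth_sets), n_inferred = nrow(units))
}
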