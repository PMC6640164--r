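#' Metagene coverage profile around a set of TSS
#'
#' For every site, a window of `half_window` bp on each side (offsets
#' -half_window..-1 and +1..+half_window, the promoter convention with
#' no offset 0, so the window is exactly `2 * half_window` positions and
#' bins tile it without a split centre bin) is oriented so that upstream
#' lies left; for minus-strand sites the window is flipped and the strand
#' labels swapped, so "sense" always means the site's own strand. Each
#' site's window is scaled to unit total mass over both strands
#' (proportional scaling) before per-bin averaging, so highly expressed
#' sites do not dominate the mean.
#'
#' @param sites Data frame with `position` and `strand`.
#' @param track A [coverage_track()].
#' @param half_window Half window in bp (default 400).
#' @param bin_size Bin width in bp (default 10); must divide
#'   `2 * half_window`.
#' @param what `"coverage"` or `"five_prime"` field of the track.
#' @param circular Wrap windows around the origin.
#' @return Object of class `meta_profile`: data frame with `bin_start`
#'   (leftmost offset of each bin), `sense`, `antisense` mean scaled
#'   coverage; attributes `n_sites`, `bin_size`, `half_window`.
#' @export
meta_profile <- function(sites, track, half_window = 400L, bin_size = 10L,
                         what = c("coverage", "five_prime"),
                         circular = TRUE) {
  what <- match.arg(what)
  if (nrow(sites) == 0L) stop("meta_profile: empty site set")
  if ((2L * half_window) %% bin_size != 0L) {
    stop("meta_profile: bin_size must divide 2 * half_window")
  }
  n_bins <- 2L * half_window %/% bin_size
  offs <- offset_seq(-half_window, half_window)
  L <- track$length
  sense_acc <- numeric(n_bins)
  anti_acc <- numeric(n_bins)
  for (i in seq_len(nrow(sites))) {
    s <- sites$strand[i]
    a <- if (s == "+") "-" else "+"
    pos <- offset_to_genomic(sites$position[i], s, offs)
    pos <- wrap_position(pos, L)
    sv <- track_vector(track, s, what)[pos]
    av <- track_vector(track, a, what)[pos]
    if (!circular) {
      raw <- offset_to_genomic(sites$position[i], s, offs)
      out <- raw < 1L | raw > L
      sv[out] <- 0; av[out] <- 0
    }
    tot <- sum(sv) + sum(av)
    if (tot > 0) {
      sv <- sv / tot; av <- av / tot
    }
    sense_acc <- sense_acc + colSums(matrix(sv, nrow = bin_size))
    anti_acc <- anti_acc + colSums(matrix(av, nrow = bin_size))
  }
  n <- nrow(sites)
  df <- data.frame(
    bin_start = offset_seq(-half_window, half_window)[seq(1, 2L * half_window,
                                                          by = bin_size)],
    sense = as.numeric(sense_acc / n),
    antisense = as.numeric(anti_acc / n)
  )
  structure(df, class = c("meta_profile", "data.frame"), n_sites = n,
            bin_size = bin_size, half_window = half_window)
}

#' Split primary TSS by the orientation of the upstream gene
#'
#' The upstream neighbour of a pTSS's gene is the annotated gene
#' immediately on the 5' side of that gene on its own strand (genomically
#' previous for plus-strand genes, next for minus-strand genes; on a
#' circular replicon the neighbourhood wraps so every gene has one). Same
#' strand means head-to-tail; opposite strand means head-to-head, the
#' divergent arrangement in which two promoters share the intergenic
#' region.
#'
#' @param ptss Data frame of primary TSS with `position`, `strand` and
#'   `gene_id` (e.g. the `class == "P"` rows of
#'   `classify_tss()$assignments`).
#' @param annotation [genome_annotation()].
#' @return List of class `orientation_split`: `head_to_head` and
#'   `head_to_tail` (row subsets of `ptss` with added `neighbor_id`,
#'   `intergene_distance`), plus `excluded` (no neighbour, linear ends).
#' @export
orientation_split <- function(ptss, annotation) {
  genes <- annotation$genes
  circular <- annotation$replicon$circular
  n <- nrow(genes)
  idx <- match(ptss$gene_id, genes$id)
  if (anyNA(idx)) stop("orientation_split: pTSS gene_id not in annotation")
  up <- integer(nrow(ptss))
  for (k in seq_len(nrow(ptss))) {
    i <- idx[k]
    up[k] <- if (genes$strand[i] == "+") {
      if (i > 1L) i - 1L else if (circular) n else NA_integer_
    } else {
      if (i < n) i + 1L else if (circular) 1L else NA_integer_
    }
  }
  has <- !is.na(up)
  if (any(!has)) {
    warning("orientation_split: ", sum(!has),
            " pTSS at linear replicon ends excluded (no upstream neighbour)")
  }
  ptss$neighbor_id <- ifelse(has, genes$id[up], NA_character_)
  gap <- function(k) {
    i <- idx[k]; u <- up[k]
    lo <- if (genes$strand[i] == "+") u else i
    hi <- if (genes$strand[i] == "+") i else u
    d <- genes$start[hi] - genes$end[lo] - 1L
    if (circular && d < 0L && lo > hi) {
      d <- d %% annotation$replicon$length
    }
    max(0L, d)
  }
  ptss$intergene_distance <- rep(NA_integer_, nrow(ptss))
  ptss$intergene_distance[has] <- as.integer(vapply(which(has), gap,
                                                   numeric(1)))
  same <- has & genes$strand[idx] == genes$strand[up]
  structure(list(head_to_head = ptss[has & !same, , drop = FALSE],
                 head_to_tail = ptss[same & has, , drop = FALSE],
                 excluded = ptss[!has, , drop = FALSE]),
            class = "orientation_split")
}

#' @export
print.orientation_split <- function(x, ...) {
  cat(sprintf("<orientation_split> head-to-head: %d, head-to-tail: %d (%d excluded)\n",
              nrow(x$head_to_head), nrow(x$head_to_tail), nrow(x$excluded)))
  invisible(x)
}

#' Antisense signal fraction upstream of a primary TSS
#'
#' The fraction of antisense-strand TEX signal within `half_window` bp of
#' the pTSS that falls in the `upstream_window` bp immediately upstream
#' (offsets -upstream_window..-1). Read positions are approximated by
#' 5'-end counts by default. A zero denominator yields 0.
#'
#' @param position,strand The pTSS.
#' @param tex TEX [coverage_track()].
#' @param half_window Full-window half width (default 400).
#' @param upstream_window Upstream window (default 100).
#' @param what `"five_prime"` (default) or `"coverage"`.
#' @param denominator `"antisense"` (default: antisense-strand signal in
#'   the full window) or `"both"` (signal on both strands).
#' @param circular Wrap windows.
#' @return Numeric fraction in [0, 1].
#' @export
antisense_fraction <- function(position, strand, tex, half_window = 400L,
                               upstream_window = 100L,
                               what = c("five_prime", "coverage"),
                               denominator = c("antisense", "both"),
                               circular = TRUE) {
  what <- match.arg(what)
  denominator <- match.arg(denominator)
  anti <- if (strand == "+") "-" else "+"
  L <- tex$length
  full_off <- offset_seq(-half_window, half_window)
  up_off <- offset_seq(-upstream_window, -1L)
  full_pos <- offset_to_genomic(position, strand, full_off)
  up_pos <- offset_to_genomic(position, strand, up_off)
  av <- track_vector(tex, anti, what)
  num <- track_sum(av, up_pos, L, circular)
  den <- track_sum(av, full_pos, L, circular)
  if (denominator == "both") {
    den <- den + track_sum(track_vector(tex, strand, what), full_pos, L,
                           circular)
  }
  if (den == 0) return(0)
  num / den
}

#' Screen primary TSS for bidirectional (divergent antisense) promoters
#'
#' Applies the strong-antisense filter: a candidate is a pTSS (restricted
#' to head-to-tail orientation by default, where upstream antisense
#' signal cannot be explained by a divergent neighbour's own pTSS) whose
#' antisense-strand TEX signal in the 100 bp immediately upstream exceeds
#' `threshold` (strictly) as a fraction of the antisense signal in the
#' surrounding +-400 bp. Each candidate is annotated with the nearest
#' upstream opposite-strand antisense TSS within `max_spacing` bp and
#' the implied pTSS-aTSS spacing.
#'
#' @param ptss Data frame of primary TSS (`position`, `strand`,
#'   `gene_id`).
#' @param tex TEX [coverage_track()].
#' @param annotation [genome_annotation()] (needed when
#'   `head_to_tail_only`).
#' @param atss Data frame of antisense TSS (`position`, `strand`) used
#'   for pairing; may be `NULL`.
#' @param threshold Antisense-fraction cut-off (default 0.40, strict
#'   inequality).
#' @param head_to_tail_only Restrict to head-to-tail pTSS (default TRUE).
#' @param max_spacing Pairing window for the aTSS (default 100).
#' @param half_window,upstream_window,what,denominator Passed to
#'   [antisense_fraction()].
#' @return Data frame of candidates: the pTSS columns plus
#'   `antisense_fraction`, `atss_position`, `spacing`.
#' @export
screen_bidirectional <- function(ptss, tex, annotation = NULL, atss = NULL,
                                 threshold = 0.40, head_to_tail_only = TRUE,
                                 max_spacing = 100L, half_window = 400L,
                                 upstream_window = 100L,
                                 what = "five_prime",
                                 denominator = "antisense") {
  if (head_to_tail_only) {
    if (is.null(annotation)) {
      stop("screen_bidirectional: annotation required for orientation split")
    }
    ptss <- orientation_split(ptss, annotation)$head_to_tail
  }
  if (nrow(ptss) == 0L) {
    ptss$antisense_fraction <- numeric(0)
    ptss$atss_position <- integer(0)
    ptss$spacing <- integer(0)
    return(ptss)
  }
  circular <- if (!is.null(annotation)) annotation$replicon$circular else TRUE
  frac <- vapply(seq_len(nrow(ptss)), function(i) {
    antisense_fraction(ptss$position[i], ptss$strand[i], tex,
                       half_window, upstream_window,
                       what = what, denominator = denominator,
                       circular = circular)
  }, numeric(1))
  ptss$antisense_fraction <- frac
  keep <- frac > threshold
  out <- ptss[keep, , drop = FALSE]
  out$atss_position <- rep(NA_integer_, nrow(out))
  out$spacing <- rep(NA_integer_, nrow(out))
  if (!is.null(atss) && nrow(atss) && nrow(out)) {
    for (i in seq_len(nrow(out))) {
      opp <- atss[atss$strand != out$strand[i], , drop = FALSE]
      d <- if (out$strand[i] == "+") {
        out$position[i] - opp$position
      } else {
        opp$position - out$position[i]
      }
      ok <- which(d >= 1L & d <= max_spacing)
      if (length(ok)) {
        j <- ok[which.min(d[ok])]
        out$atss_position[i] <- opp$position[j]
        out$spacing[i] <- d[j]
      }
    }
  }
  rownames(out) <- NULL
  out
}

#' Distribution of pTSS-aTSS spacings
#'
#' For each primary TSS, finds the nearest upstream opposite-strand
#' antisense TSS within `max_spacing` bp and reports the spacing
#' distribution; an accumulation near 50 bp is the signature of
#' bidirectional transcription from a shared TATA element.
#'
#' @param ptss,atss Data frames with `position`, `strand`.
#' @param max_spacing Maximum spacing (default 100).
#' @return List: `spacings` (integer vector), `histogram` (table),
#'   `mode` (modal spacing, smallest on ties; `NA` when empty).
#' @export
pair_distances <- function(ptss, atss, max_spacing = 100L) {
  spac <- integer(0)
  if (nrow(ptss) && nrow(atss)) {
    for (i in seq_len(nrow(ptss))) {
      opp <- atss[atss$strand != ptss$strand[i], , drop = FALSE]
      d <- if (ptss$strand[i] == "+") {
        ptss$position[i] - opp$position
      } else {
        opp$position - ptss$position[i]
      }
      ok <- d[d >= 1L & d <= max_spacing]
      if (length(ok)) spac <- c(spac, min(ok))
    }
  }
  hist <- table(spac)
  mode <- if (length(spac)) {
    as.integer(names(hist)[which.max(hist)])
  } else NA_integer_
  list(spacings = spac, histogram = hist, mode = mode)
}

#' Intergene distance distributions by promoter orientation
#'
#' Distance between a pTSS's gene and its upstream neighbour, measured on
#' the annotation as the gap `downstream start - upstream end - 1`;
#' overlapping genes count as distance 0.
#'
#' @param split An `orientation_split`.
#' @return Data frame: `orientation`, `n`, `median`, `mean`.
#' @export
intergene_distances <- function(split) {
  stopifnot(inherits(split, "orientation_split"))
  rows <- lapply(c(head_to_head = "head_to_head",
                   head_to_tail = "head_to_tail"), function(k) {
    d <- split[[k]]$intergene_distance
    data.frame(orientation = sub("_", "-", sub("_to_", "-to-", k)),
               n = length(d),
               median = if (length(d)) stats::median(d) else NA_real_,
               mean = if (length(d)) mean(d) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
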