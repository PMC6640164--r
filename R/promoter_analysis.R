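#' Extract TSS-anchored promoter windows
#'
#' Offsets follow the promoter convention: the TSS base is +1, the base
#' immediately upstream is -1, and there is no offset 0, so the default
#' archaeal promoter window -50..+10 is 60 bases long. Minus-strand
#' windows are reverse-complemented so every window reads 5' to 3' toward
#' (and through) the TSS. On circular replicons windows wrap the origin;
#' on linear replicons a window running off an end skips the record with
#' a warning.
#'
#' @param tss Data frame with `position` and `strand` columns.
#' @param rep A [replicon()].
#' @param from,to Offset bounds (no 0), `from < to`.
#' @return Character vector of equal-length windows, one per retained
#'   record, with attribute `kept` (indices of retained rows).
#' @export
extract_windows <- function(tss, rep, from = -50L, to = 10L) {
  stopifnot(inherits(rep, "replicon"), from < to, from != 0L, to != 0L)
  offs <- offset_seq(from, to)
  bases <- base_vector(rep)
  L <- rep$length
  out <- character(0)
  kept <- integer(0)
  for (i in seq_len(nrow(tss))) {
    pos <- offset_to_genomic(tss$position[i], tss$strand[i], offs)
    if (rep$circular) {
      pos <- wrap_position(pos, L)
    } else if (any(pos < 1L | pos > L)) {
      warning("extract_windows: window for TSS at ", tss$position[i],
              " exceeds linear replicon; record skipped")
      next
    }
    w <- bases[pos]
    if (tss$strand[i] == "-") w <- unname(COMPLEMENT_MAP[w])
    out <- c(out, paste(w, collapse = ""))
    kept <- c(kept, i)
  }
  attr(out, "kept") <- kept
  attr(out, "from") <- from
  attr(out, "to") <- to
  out
}

#' Build a position weight matrix from aligned windows
#'
#' Column frequencies are `(count + pseudocount) / (n + 4 * pseudocount)`.
#'
#' @param windows Equal-length character vector of aligned sequences.
#' @param anchor_offset Offset (promoter convention, no 0) of the first
#'   column relative to the TSS.
#' @param pseudocount Added per base per column.
#' @return Object of class `pwm`: a 4 x W matrix (rows A, C, G, T) with
#'   attributes `anchor_offset`, `offsets`, `pseudocount`, `n`.
#' @export
build_pwm <- function(windows, anchor_offset = -50L, pseudocount = 0.5) {
  windows <- as.character(windows)
  if (length(windows) < 1L) stop("build_pwm: need at least one window")
  W <- unique(nchar(windows))
  if (length(W) != 1L) stop("build_pwm: windows have unequal lengths")
  n <- length(windows)
  mat <- matrix(0, nrow = 4, ncol = W, dimnames = list(c("A", "C", "G", "T")))
  chars <- matrix(unlist(strsplit(windows, "", fixed = TRUE)),
                  nrow = n, byrow = TRUE)
  for (b in rownames(mat)) {
    mat[b, ] <- colSums(chars == b)
  }
  freq <- sweep(mat + pseudocount, 2, colSums(mat) + 4 * pseudocount, "/")
  offs <- element_offsets(end = {
    o <- anchor_offset + W - 1L
    if (anchor_offset < 0L && o >= 0L) o <- o + 1L
    o
  }, len = W)
  structure(freq, class = "pwm", anchor_offset = anchor_offset,
            offsets = offs, pseudocount = pseudocount, n = n)
}

#' Build a PWM directly from an IUPAC consensus
#'
#' Each column distributes `strength` probability mass evenly over the
#' consensus letter's base set and the remainder uniformly over all four
#' bases; used as the scanning model for the canonical archaeal elements
#' (BRE `RRAAA`, TATA `WTTTAAAW`).
#'
#' @param consensus IUPAC string.
#' @param strength Mass on the consensus set per column.
#' @param anchor_offset Offset of the first column.
#' @return A `pwm`.
#' @export
consensus_pwm <- function(consensus, strength = 0.85, anchor_offset = -50L) {
  letters <- strsplit(toupper(consensus), "", fixed = TRUE)[[1]]
  W <- length(letters)
  mat <- matrix((1 - strength) / 4, nrow = 4, ncol = W,
                dimnames = list(c("A", "C", "G", "T")))
  for (j in seq_len(W)) {
    set <- IUPAC_SETS[[letters[j]]]
    mat[set, j] <- mat[set, j] + strength / length(set)
  }
  offs <- element_offsets(end = {
    o <- anchor_offset + W - 1L
    if (anchor_offset < 0L && o >= 0L) o <- o + 1L
    o
  }, len = W)
  structure(mat, class = "pwm", anchor_offset = anchor_offset,
            offsets = offs, pseudocount = 0, n = NA_integer_)
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> %d columns anchored at offset %d (n = %s)\n",
              ncol(x), attr(x, "anchor_offset"),
              format(attr(x, "n"))))
  cat("consensus:", pwm_consensus(x), "\n")
  invisible(x)
}

#' Majority-rule IUPAC consensus of a PWM
#'
#' Per column, bases are added in decreasing frequency until their
#' cumulative frequency reaches 0.5; the resulting set maps to its IUPAC
#' code. With a single input sequence this reduces to that sequence.
#'
#' @param pwm A `pwm`.
#' @return Character scalar of IUPAC codes.
#' @export
pwm_consensus <- function(pwm) {
  codes <- vapply(names(IUPAC_SETS), function(k)
    paste(sort(IUPAC_SETS[[k]]), collapse = ""), "")
  cons <- vapply(seq_len(ncol(pwm)), function(j) {
    f <- sort(pwm[, j], decreasing = TRUE)
    take <- which(cumsum(f) >= 0.5)[1]
    set <- paste(sort(names(f)[seq_len(take)]), collapse = "")
    names(codes)[codes == set]
  }, "")
  paste(cons, collapse = "")
}

#' Does an observed IUPAC symbol agree with an expected one?
#'
#' Agreement means the observed symbol's base set is a subset of the
#' expected symbol's set (e.g. `A` agrees with `W`).
#'
#' @param observed,expected Equal-length IUPAC strings.
#' @return Logical vector, one element per column.
#' @export
iupac_agreement <- function(observed, expected) {
  o <- strsplit(toupper(observed), "", fixed = TRUE)[[1]]
  e <- strsplit(toupper(expected), "", fixed = TRUE)[[1]]
  stopifnot(length(o) == length(e))
  mapply(function(a, b) all(IUPAC_SETS[[a]] %in% IUPAC_SETS[[b]]), o, e,
         USE.NAMES = FALSE)
}

#' Log-odds score of a sequence under a PWM
#'
#' @param pwm A `pwm`.
#' @param seq Sequence of length `ncol(pwm)`.
#' @param background Base composition for the null; uniform by default, a
#'   genome composition (e.g. 40.75% GC) may be supplied as a named
#'   vector over A, C, G, T.
#' @return Sum over columns of `log2(f / bg)`.
#' @export
pwm_score <- function(pwm, seq, background = NULL) {
  bg <- pwm_background(background)
  b <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  stopifnot(length(b) == ncol(pwm))
  idx <- match(b, rownames(pwm))
  if (anyNA(idx)) return(-Inf)  # N or other ambiguity: no finite score
  sum(log2(pwm[cbind(idx, seq_len(ncol(pwm)))] / bg[idx]))
}

pwm_background <- function(background) {
  if (is.null(background)) {
    c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  } else {
    stopifnot(all(c("A", "C", "G", "T") %in% names(background)))
    background[c("A", "C", "G", "T")] / sum(background[c("A", "C", "G", "T")])
  }
}

# Maximum achievable log-odds score of a model.
pwm_max_score <- function(pwm, background = NULL) {
  bg <- pwm_background(background)
  sum(apply(log2(unclass(pwm) / bg), 2, max))
}

#' Locate a promoter element in a TSS-anchored window
#'
#' Slides the model across the window and reports the best-scoring
#' placement by the offset of the element's 3' end (promoter convention).
#' Ties go to the most upstream (most negative) placement. Placements
#' scoring below `min_score` are reported as no-hit.
#'
#' @param window One window from [extract_windows()] (attributes `from`/
#'   `to` used when `window_from` is missing).
#' @param model A `pwm` for the element (e.g.
#'   `consensus_pwm("WTTTAAAW")`).
#' @param search_range Length-2 vector of allowed 3'-end offsets,
#'   default `c(-34, -18)` (covers the class-specific TATA positions).
#' @param window_from Offset of the window's first base.
#' @param min_score Score threshold; default 0 (better than background).
#' @param background Optional base composition for the null.
#' @return List of class `motif_hit`: `element` columns `strand`,
#'   `offset` (3' end), `start_offset`, `score`, `hit` (logical).
#' @export
locate_element <- function(window, model, search_range = c(-34L, -18L),
                           window_from = NULL, min_score = 0,
                           background = NULL) {
  if (is.null(window_from)) window_from <- attr(window, "from")
  if (is.null(window_from)) stop("locate_element: window_from missing")
  W <- ncol(model)
  win_offsets <- offset_seq(window_from, {
    o <- window_from + nchar(window[1]) - 1L
    if (window_from < 0L && o >= 0L) o <- o + 1L
    o
  })
  ends <- seq.int(search_range[1], search_range[2])
  ends <- ends[ends != 0L]
  best <- list(score = -Inf, offset = NA_integer_)
  for (e in ends) {
    offs <- element_offsets(e, W)
    idx <- match(offs, win_offsets)
    if (anyNA(idx)) stop("locate_element: search_range outside window")
    sc <- pwm_score(model, substr_idx(window, idx), background)
    if (sc > best$score + 1e-12) best <- list(score = sc, offset = e)
  }
  structure(list(strand = "sense", offset = best$offset,
                 start_offset = if (is.na(best$offset)) NA_integer_ else
                   element_offsets(best$offset, W)[1],
                 score = best$score, hit = is.finite(best$score) &&
                   best$score >= min_score),
            class = "motif_hit")
}

substr_idx <- function(s, idx) {
  paste(strsplit(s, "", fixed = TRUE)[[1]][idx], collapse = "")
}

#' Locate the TATA box in a promoter window
#'
#' Convenience wrapper around [locate_element()] with the archaeal TATA
#' model `WTTTAAAW`; the reported offset is the position of the last
#' conserved base of the box (e.g. -23 for primary TSS).
#'
#' @inheritParams locate_element
#' @param tata_pwm TATA model; default `consensus_pwm("WTTTAAAW")`.
#' @return A `motif_hit`.
#' @export
locate_tata <- function(window, tata_pwm = consensus_pwm(TATA_CONSENSUS),
                        search_range = c(-34L, -18L), window_from = NULL,
                        min_score = 0, background = NULL) {
  h <- locate_element(window, tata_pwm, search_range, window_from,
                      min_score, background)
  h$element <- "TATA"
  h
}

#' Scan a primary-TSS region for a bidirectional BRE-TATA-BRE promoter
#'
#' A bidirectional promoter initiates transcription on both strands from
#' one TATA element: the sense BRE-TATA drives the primary transcript and
#' a reverse-strand BRE on the primary-TSS side of the TATA recruits TFB
#' in the antisense direction, producing a divergent transcript starting
#' about 50 bp upstream. The scan requires (i) a sense TATA whose 3' end
#' falls in `tata_range` and (ii) a reverse-complement BRE whose genomic
#' left end lies 1-`bre_gap_max` bp downstream of the TATA (toward the
#' primary TSS), both above their score thresholds (fractions of each
#' model's maximum score, set so a single-base deviation from consensus
#' still passes while two deviations do not). The implied antisense start is derived from
#' the antisense BRE placement (the BRE ends 32 bp upstream of its TSS),
#' equivalently about 25 bp upstream of the shared TATA midpoint.
#'
#' @param window Promoter window spanning at least -60..+1.
#' @param window_from Offset of the window's first base (defaults to the
#'   `from` attribute).
#' @param tata_pwm,bre_pwm Element models.
#' @param tata_range Allowed sense TATA 3'-end offsets.
#' @param bre_gap_max Maximum gap (bp) between the TATA 3' end and the
#'   antisense BRE's genomic left end.
#' @param min_tata_frac,min_bre_frac Score thresholds as fractions of the
#'   model maxima.
#' @param background Optional base composition.
#' @return A list of class `bidirectional_hit` (`tata`, `bre_offset`,
#'   `bre_score`, `combined_score`, `implied_atss_offset`) or `NULL` when
#'   no qualifying configuration exists.
#' @export
scan_bidirectional <- function(window, window_from = NULL,
                               tata_pwm = consensus_pwm(TATA_CONSENSUS),
                               bre_pwm = consensus_pwm(BRE_CONSENSUS),
                               tata_range = c(-30L, -20L),
                               bre_gap_max = 10L,
                               min_tata_frac = 0.6, min_bre_frac = 0.4,
                               background = NULL) {
  if (is.null(window_from)) window_from <- attr(window, "from")
  if (is.null(window_from)) stop("scan_bidirectional: window_from missing")
  wlen <- nchar(window[1])
  win_to <- window_from + wlen - 1L
  if (window_from < 0L && win_to >= 0L) win_to <- win_to + 1L
  if (window_from > -60L || win_to < 1L) {
    stop("scan_bidirectional: region must span at least -60..+1")
  }
  min_tata <- min_tata_frac * pwm_max_score(tata_pwm, background)
  th <- locate_tata(window, tata_pwm, tata_range, window_from,
                    min_score = min_tata, background = background)
  if (!th$hit) return(NULL)

  win_offsets <- offset_seq(window_from, win_to)
  bases <- strsplit(window, "", fixed = TRUE)[[1]]
  min_bre <- min_bre_frac * pwm_max_score(bre_pwm, background)
  best <- list(score = -Inf, left = NA_integer_)
  for (gap in seq_len(bre_gap_max)) {
    left <- th$offset + gap            # genomic left end of the RC BRE
    offs <- seq_from_offset(left, 5L)
    if (max(offs) > -1L) break         # BRE must stay upstream of the TSS
    idx <- match(offs, win_offsets)
    if (anyNA(idx)) next
    rc <- reverse_complement(paste(bases[idx], collapse = ""))
    sc <- pwm_score(bre_pwm, rc, background)
    if (sc > best$score) best <- list(score = sc, left = left)
  }
  if (!is.finite(best$score) || best$score < min_bre) return(NULL)
  implied <- best$left - 32L
  structure(list(tata = th, bre_offset = best$left, bre_score = best$score,
                 combined_score = th$score + best$score,
                 implied_atss_offset = implied),
            class = "bidirectional_hit")
}

# `len` consecutive no-zero offsets starting at `from` (ascending).
seq_from_offset <- function(from, len) {
  out <- integer(len)
  o <- from
  for (i in seq_len(len)) {
    out[i] <- o
    o <- o + 1L
    if (o == 0L) o <- 1L
  }
  out
}

#' Per-class TATA offset summary
#'
#' Runs [locate_tata()] over TSS-anchored windows grouped by class and
#' summarises the 3'-end offsets (the class signature of archaeal
#' promoters: about -23 for primary, -27 secondary, -22 internal, -25
#' antisense TSS).
#'
#' @param windows_by_class Named list of window vectors (names = classes).
#' @param tata_pwm TATA model.
#' @param search_range Allowed 3'-end offsets.
#' @param min_score Hit threshold passed to [locate_tata()].
#' @return Data frame: `class`, `n`, `n_hit`, `median_offset`,
#'   `mean_offset`.
#' @export
tata_offsets_by_class <- function(windows_by_class,
                                  tata_pwm = consensus_pwm(TATA_CONSENSUS),
                                  search_range = c(-34L, -18L),
                                  min_score = 0) {
  rows <- lapply(names(windows_by_class), function(cl) {
    wins <- windows_by_class[[cl]]
    offs <- vapply(seq_along(wins), function(i) {
      h <- locate_tata(wins[i], tata_pwm, search_range,
                       window_from = attr(wins, "from"),
                       min_score = min_score)
      if (h$hit) h$offset else NA_integer_
    }, integer(1))
    data.frame(class = cl, n = length(offs), n_hit = sum(!is.na(offs)),
               median_offset = stats::median(offs, na.rm = TRUE),
               mean_offset = mean(offs, na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Serialise a PWM as TSV (rows A, C, G, T; columns named by offset)
#' @param pwm A `pwm`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_pwm <- function(pwm, path) {
  df <- as.data.frame(unclass(pwm))
  colnames(df) <- attr(pwm, "offsets")
  df <- cbind(base = rownames(pwm), df)
  write_tsv(df, path)
}
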