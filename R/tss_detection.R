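#' Detection parameters for the TSS caller and classifier
#'
#' @param min_height Minimum TEX 5'-end count at a candidate position.
#' @param min_enrichment Minimum TEX / (NOTEX + pseudocount) ratio; the
#'   hallmark of a primary (5'-triphosphate) end is its resistance to the
#'   terminator exonuclease, i.e. enrichment in the TEX library.
#' @param cluster_width Candidates within this many bp merge into one TSS.
#' @param pseudocount Added to the NOTEX denominator.
#' @param utr_window Search window (bp) upstream of a gene start for
#'   primary/secondary TSS, inclusive of the start itself (leaderless
#'   transcripts).
#' @param antisense_flank Opposite-strand TSS within this many bp of a gene
#'   are classified antisense.
#' @return List of class `detection_params`.
#' @export
detection_params <- function(min_height = 10, min_enrichment = 2,
                             cluster_width = 3L, pseudocount = 1,
                             utr_window = 300L, antisense_flank = 100L) {
  p <- list(min_height = min_height, min_enrichment = min_enrichment,
            cluster_width = as.integer(cluster_width),
            pseudocount = pseudocount,
            utr_window = as.integer(utr_window),
            antisense_flank = as.integer(antisense_flank))
  if (any(unlist(p) <= 0)) stop("detection_params: all parameters must be positive")
  structure(p, class = "detection_params")
}

# Local-max test for one strand's 5'-end vector with optional wrap.
is_local_max <- function(vec, pos, width, circular) {
  L <- length(vec)
  idx <- seq.int(pos - width, pos + width)
  if (circular) {
    idx <- wrap_position(idx, L)
  } else {
    idx <- idx[idx >= 1L & idx <= L]
  }
  vec[pos] >= max(vec[idx])
}

#' Call TSS from TEX versus NOTEX 5'-end coverage
#'
#' A position is a candidate if its TEX 5'-end count reaches `min_height`,
#' its TEX / (NOTEX + pseudocount) ratio reaches `min_enrichment`, and the
#' TEX count is a local maximum within `cluster_width` bp on its strand.
#' Surviving candidates closer than `cluster_width` merge, keeping the
#' highest-count position (ties: the smallest genomic coordinate).
#'
#' @param tex,notex [coverage_track()]s of equal length carrying 5'-end
#'   counts.
#' @param params [detection_params()].
#' @param circular Treat the replicon as circular for window arithmetic.
#' @return Data frame with one row per called TSS: `position`, `strand`,
#'   `tex_height`, `notex_height`, `enrichment`.
#' @export
call_tss <- function(tex, notex, params = detection_params(),
                     circular = TRUE) {
  stopifnot(inherits(tex, "coverage_track"), inherits(notex, "coverage_track"))
  if (tex$length != notex$length) {
    stop("call_tss: TEX and NOTEX tracks differ in length")
  }
  out <- list()
  for (s in c("+", "-")) {
    tv <- track_vector(tex, s, "five_prime")
    nv <- track_vector(notex, s, "five_prime")
    enr <- tv / (nv + params$pseudocount)
    cand <- which(tv >= params$min_height & enr >= params$min_enrichment)
    cand <- cand[vapply(cand, function(p)
      is_local_max(tv, p, params$cluster_width, circular), logical(1))]
    if (length(cand)) {
      merged <- merge_candidates(cand, tv, params$cluster_width)
      out[[s]] <- data.frame(position = merged, strand = s,
                             tex_height = tv[merged],
                             notex_height = nv[merged],
                             enrichment = enr[merged],
                             stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(position = integer(), strand = character(),
                      tex_height = numeric(), notex_height = numeric(),
                      enrichment = numeric(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$position, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Greedy merge of sorted candidate positions: within each run of
# candidates spaced <= width, keep the highest count (tie: leftmost).
merge_candidates <- function(cand, heights, width) {
  cand <- sort(cand)
  grp <- cumsum(c(1L, diff(cand) > width))
  vapply(split(cand, grp), function(g) {
    g[which.max(heights[g])]
  }, integer(1), USE.NAMES = FALSE)
}

#' Classify called TSS relative to an annotation
#'
#' Implements the positional classification of dRNA-seq start sites into
#' primary (P), secondary (S), internal (I) and antisense (A): for every
#' gene, the highest same-strand TSS within `utr_window` bp upstream of
#' its start (the start itself included, covering leaderless transcripts)
#' is its primary TSS and the remaining window TSS are secondary (ties go
#' to the TSS closest to the start); same-strand TSS strictly inside the
#' gene body are internal; opposite-strand TSS within `antisense_flank` bp
#' of the gene are antisense. A TSS accumulates every class it earns
#' across genes, so dual labels (e.g. P for one gene and A for a
#' head-to-head neighbour) are preserved. TSS earning no class are
#' orphans, excluded from class counts.
#'
#' @param tss Data frame from [call_tss()].
#' @param annotation [genome_annotation()].
#' @param params [detection_params()].
#' @return List of class `tss_classification`: `$tss` (the input plus a
#'   collapsed `classes` column), `$assignments` (long form, one row per
#'   TSS-class-gene triple with `utr_length` for P/S).
#' @export
classify_tss <- function(tss, annotation, params = detection_params()) {
  stopifnot(inherits(annotation, "genome_annotation"))
  genes <- annotation$genes
  L <- annotation$replicon$length
  circular <- annotation$replicon$circular
  n_tss <- nrow(tss)
  assign_rows <- list()
  push <- function(idx, class, gene_id, utr = NA_integer_) {
    assign_rows[[length(assign_rows) + 1L]] <<- data.frame(
      tss_index = idx, position = tss$position[idx],
      strand = tss$strand[idx], class = class, gene_id = gene_id,
      utr_length = as.integer(utr),
      tex_height = tss$tex_height[idx],
      enrichment = tss$enrichment[idx], stringsAsFactors = FALSE)
  }

  # Upstream distance from a TSS to a gene start on the gene's strand;
  # 0 at the start itself, positive upstream, NA when not upstream within
  # the window (circular distance used on circular replicons).
  upstream_dist <- function(positions, gene) {
    d <- if (gene$strand == "+") gene$start - positions else
      positions - gene$end
    if (circular) {
      d <- d %% L
      d[d > L / 2] <- NA  # far side of the circle is not "upstream"
    } else {
      d[d < 0] <- NA
    }
    d
  }

  for (g in seq_len(nrow(genes))) {
    gene <- genes[g, ]
    same <- which(tss$strand == gene$strand)
    opp <- which(tss$strand != gene$strand)

    if (length(same)) {
      d <- upstream_dist(tss$position[same], gene)
      in_win <- !is.na(d) & d <= params$utr_window
      win <- same[in_win]
      if (length(win)) {
        dw <- d[in_win]
        h <- tss$tex_height[win]
        best <- which(h == max(h))
        primary <- best[which.min(dw[best])]
        push(win[primary], "P", gene$id, dw[primary])
        for (k in setdiff(seq_along(win), primary)) {
          push(win[k], "S", gene$id, dw[k])
        }
      }
      # internal: strictly inside the body, excluding the 5' start base
      pos <- tss$position[same]
      inside <- if (gene$strand == "+") {
        pos > gene$start & pos <= gene$end
      } else {
        pos >= gene$start & pos < gene$end
      }
      for (k in which(inside)) push(same[k], "I", gene$id)
    }

    if (length(opp)) {
      pos <- tss$position[opp]
      lo <- gene$start - params$antisense_flank
      hi <- gene$end + params$antisense_flank
      hit <- pos >= lo & pos <= hi
      if (circular) {
        hit <- hit | wrap_position(pos, L) %in%
          wrap_position(seq.int(lo, hi), L)
      }
      for (k in which(hit)) push(opp[k], "A", gene$id)
    }
  }

  assignments <- if (length(assign_rows)) {
    do.call(rbind, assign_rows)
  } else {
    data.frame(tss_index = integer(), position = integer(),
               strand = character(), class = character(),
               gene_id = character(), utr_length = integer(),
               tex_height = numeric(), enrichment = numeric(),
               stringsAsFactors = FALSE)
  }
  classes <- vapply(seq_len(n_tss), function(i) {
    cl <- sort(unique(assignments$class[assignments$tss_index == i]))
    if (length(cl)) paste(cl, collapse = ",") else ""
  }, "")
  tss$classes <- classes
  structure(list(tss = tss, assignments = assignments,
                 replicon_name = annotation$replicon$name),
            class = "tss_classification")
}

#' @export
print.tss_classification <- function(x, ...) {
  counts <- class_counts(x)
  cat(sprintf("<tss_classification> %d TSS; %s; %d orphan\n",
              nrow(x$tss),
              paste(sprintf("%s:%d", names(counts), counts), collapse = " "),
              sum(x$tss$classes == "")))
  invisible(x)
}

#' Count distinct TSS per class
#' @param classified `tss_classification`.
#' @return Named integer vector over P, S, I, A.
#' @export
class_counts <- function(classified) {
  a <- classified$assignments
  vapply(c(P = "P", S = "S", I = "I", A = "A"), function(cl) {
    length(unique(a$tss_index[a$class == cl]))
  }, integer(1))
}

#' 5'-UTR length summary over primary TSS
#'
#' The 5' UTR is the distance from a TSS to its gene's start codon;
#' 0 marks a leaderless transcript.
#'
#' @param classified `tss_classification` (or its `assignments` frame).
#' @param class Class to summarise, default `"P"`.
#' @return List: `lengths` (per assignment), `median`, `mean`, `n`,
#'   `empty` (TRUE when no records of the class exist).
#' @export
utr_lengths <- function(classified, class = "P") {
  a <- if (inherits(classified, "tss_classification")) {
    classified$assignments
  } else classified
  u <- a$utr_length[a$class == class]
  u <- u[!is.na(u)]
  if (!length(u)) {
    return(list(lengths = integer(), median = NA_real_, mean = NA_real_,
                n = 0L, empty = TRUE))
  }
  list(lengths = u, median = stats::median(u), mean = mean(u),
       n = length(u), empty = FALSE)
}

#' Compare called TSS against a planted truth
#'
#' Matches truth and called TSS on the same strand within `tolerance` bp
#' (greedy nearest match, each called TSS used once) and reports
#' sensitivity, precision, and the fraction of matched truth TSS whose
#' planted class is among the called classes.
#'
#' @param classified `tss_classification` (classes used for the label
#'   match) or plain called data frame (label match skipped).
#' @param truth `synthetic_truth`.
#' @param tolerance Position tolerance in bp.
#' @return List: `sensitivity`, `precision`, `class_match`, `n_truth`,
#'   `n_called`, `matches` (data frame).
#' @export
tss_recovery <- function(classified, truth, tolerance = 1L) {
  called <- if (inherits(classified, "tss_classification")) {
    classified$tss
  } else classified
  tt <- truth$tss
  used <- rep(FALSE, nrow(called))
  match_idx <- rep(NA_integer_, nrow(tt))
  for (i in seq_len(nrow(tt))) {
    cand <- which(!used & called$strand == tt$strand[i] &
                    abs(called$position - tt$position[i]) <= tolerance)
    if (length(cand)) {
      j <- cand[which.min(abs(called$position[cand] - tt$position[i]))]
      match_idx[i] <- j
      used[j] <- TRUE
    }
  }
  matched <- !is.na(match_idx)
  class_match <- NA_real_
  if (!is.null(called$classes)) {
    ok <- vapply(which(matched), function(i) {
      cls <- strsplit(called$classes[match_idx[i]], ",", fixed = TRUE)[[1]]
      tt$class[i] %in% cls
    }, logical(1))
    class_match <- if (length(ok)) mean(ok) else NA_real_
  }
  list(sensitivity = mean(matched),
       precision = if (nrow(called)) sum(matched) / nrow(called) else NA_real_,
       class_match = class_match,
       n_truth = nrow(tt), n_called = nrow(called),
       matches = data.frame(truth_position = tt$position,
                            truth_class = tt$class,
                            called_position = ifelse(matched,
                                                     called$position[match_idx],
                                                     NA_integer_),
                            matched = matched))
}
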