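#' Construct a replicon
#'
#' A replicon is a single DNA molecule (chromosome or plasmid) holding the
#' sequence every downstream coordinate refers to. Coordinates are 1-based
#' inclusive throughout the package; when `circular = TRUE`, window
#' extraction near the ends wraps around the origin, so promoter windows of
#' genes close to position 1 are never truncated.
#'
#' @param name Text identifier (e.g. an accession).
#' @param sequence DNA string over `A`, `C`, `G`, `T`, `N`; lower case is
#'   accepted and upper-cased on construction.
#' @param circular Logical; does the molecule close on itself?
#' @return An object of class `replicon` with fields `name`, `sequence`
#'   (upper case), `length` and `circular`.
#' @export
replicon <- function(name, sequence, circular = FALSE) {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(sequence), length(sequence) == 1L,
            is.logical(circular), length(circular) == 1L)
  sequence <- toupper(sequence)
  if (nchar(sequence) < 1L) {
    stop("replicon '", name, "': sequence must have length >= 1")
  }
  if (grepl("[^ACGTN]", sequence)) {
    stop("replicon '", name, "': sequence contains characters outside ACGTN")
  }
  structure(
    list(name = name, sequence = sequence,
         length = nchar(sequence), circular = circular),
    class = "replicon"
  )
}

#' @export
print.replicon <- function(x, ...) {
  cat(sprintf("<replicon> %s: %s bp, %s\n", x$name,
              format(x$length, big.mark = ","),
              if (x$circular) "circular" else "linear"))
  invisible(x)
}

#' @export
length.replicon <- function(x) x$length

# Wrap genomic positions onto [1, len] (circular arithmetic).
wrap_position <- function(pos, len) ((pos - 1L) %% len) + 1L

#' Extract a genomic window from a replicon
#'
#' Returns the forward-strand sequence between two 1-based inclusive
#' positions. On a circular replicon, positions outside `[1, length]` wrap
#' around the origin; on a linear replicon they raise an error.
#'
#' @param rep A [replicon()].
#' @param start,end 1-based inclusive bounds, `start <= end` (in unwrapped
#'   coordinates, so a window spanning the origin of a circular replicon is
#'   expressed e.g. as `start = -3, end = 5`).
#' @return Character scalar of length `end - start + 1`.
#' @export
window_seq <- function(rep, start, end) {
  stopifnot(inherits(rep, "replicon"), start <= end)
  L <- rep$length
  if (start >= 1L && end <= L) {
    return(substr(rep$sequence, start, end))
  }
  if (!rep$circular) {
    stop("window [", start, ", ", end, "] exceeds linear replicon '",
         rep$name, "' of length ", L)
  }
  if (end - start + 1L > L) {
    stop("window longer than circular replicon '", rep$name, "'")
  }
  idx <- wrap_position(seq.int(start, end), L)
  paste(base_vector(rep)[idx], collapse = "")
}

# Cache the per-base character vector on the replicon's environment-free
# list: recompute on demand (cheap relative to downstream work) but allow
# callers holding many windows to split once.
base_vector <- function(rep) {
  strsplit(rep$sequence, "", fixed = TRUE)[[1]]
}

COMPLEMENT_MAP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Reverse complement of a DNA string
#'
#' @param x Character vector of DNA strings.
#' @return Character vector of reverse complements.
#' @export
reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Genes table constructor
#'
#' Builds the gene table used across the package: one row per feature with
#' 1-based inclusive coordinates. `kind` distinguishes ordinary genes from
#' insertion-sequence (IS) elements, the mobile transposase-encoding
#' features tracked separately by the antisense analyses.
#'
#' @param id Character vector of unique identifiers.
#' @param start,end Integer vectors, `1 <= start <= end`.
#' @param strand Character vector over `"+"`/`"-"`.
#' @param kind Character vector over `"gene"`, `"IS_element"`, `"other"`.
#' @return A `data.frame` sorted by `start`.
#' @export
gene_table <- function(id, start, end, strand, kind = "gene") {
  n <- length(id)
  kind <- rep_len(kind, n)
  df <- data.frame(id = as.character(id), start = as.integer(start),
                   end = as.integer(end), strand = as.character(strand),
                   kind = as.character(kind), stringsAsFactors = FALSE)
  validate_genes(df)
  df[order(df$start, df$end), , drop = FALSE]
}

validate_genes <- function(df, replicon_length = NULL) {
  if (anyDuplicated(df$id)) stop("gene ids must be unique")
  if (any(df$start > df$end)) stop("gene start > end")
  if (any(df$start < 1L)) stop("gene start < 1")
  if (!all(df$strand %in% c("+", "-"))) {
    stop("gene strand must be '+' or '-'")
  }
  if (!is.null(replicon_length) && any(df$end > replicon_length)) {
    stop("gene end exceeds replicon length")
  }
  invisible(df)
}

#' Bundle a replicon with its gene annotation
#'
#' @param rep A [replicon()].
#' @param genes A gene table as returned by [gene_table()].
#' @return An object of class `genome_annotation` with the genes sorted by
#'   start position.
#' @export
genome_annotation <- function(rep, genes) {
  stopifnot(inherits(rep, "replicon"), is.data.frame(genes))
  validate_genes(genes, rep$length)
  genes <- genes[order(genes$start, genes$end), , drop = FALSE]
  rownames(genes) <- NULL
  structure(list(replicon = rep, genes = genes), class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("<genome_annotation> %s (%s bp, %s): %d features (%d IS)\n",
              x$replicon$name, format(x$replicon$length, big.mark = ","),
              if (x$replicon$circular) "circular" else "linear",
              nrow(x$genes), sum(x$genes$kind == "IS_element")))
  invisible(x)
}

#' Strand-specific coverage container for one sequencing library
#'
#' Holds per-base counts of read 5' ends and per-base read coverage for the
#' plus and minus strand of one library. The three libraries of a dRNA-seq
#' experiment are TEX (terminator-exonuclease treated, enriching primary
#' 5' ends), NOTEX (untreated control, retaining processed 5' ends) and
#' FRAG (fragmented, giving quasi-uniform transcript-body coverage).
#'
#' @param library One of `"TEX"`, `"NOTEX"`, `"FRAG"`.
#' @param length Replicon length in bp.
#' @param five_prime_plus,five_prime_minus Numeric vectors of 5'-end counts
#'   (default all zero).
#' @param cov_plus,cov_minus Numeric vectors of read coverage (default all
#'   zero).
#' @return An object of class `coverage_track`.
#' @export
coverage_track <- function(library, length,
                           five_prime_plus = numeric(length),
                           five_prime_minus = numeric(length),
                           cov_plus = numeric(length),
                           cov_minus = numeric(length)) {
  library <- match.arg(library, c("TEX", "NOTEX", "FRAG"))
  vecs <- list(five_prime_plus = five_prime_plus,
               five_prime_minus = five_prime_minus,
               cov_plus = cov_plus, cov_minus = cov_minus)
  for (nm in names(vecs)) {
    v <- vecs[[nm]]
    if (length(v) != length) {
      stop("coverage_track: '", nm, "' has length ", base::length(v),
           ", expected ", length)
    }
    if (any(v < 0)) stop("coverage_track: '", nm, "' has negative values")
  }
  structure(c(list(library = library, length = as.integer(length)), vecs),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf(
    "<coverage_track> %s: %s bp; 5' ends %s(+)/%s(-); coverage sum %s(+)/%s(-)\n",
    x$library, format(x$length, big.mark = ","),
    format(sum(x$five_prime_plus), big.mark = ","),
    format(sum(x$five_prime_minus), big.mark = ","),
    format(round(sum(x$cov_plus)), big.mark = ","),
    format(round(sum(x$cov_minus)), big.mark = ",")))
  invisible(x)
}

# Pick a strand's vector from a track.
track_vector <- function(track, strand, what = c("five_prime", "coverage")) {
  what <- match.arg(what)
  key <- if (what == "five_prime") {
    if (strand == "+") "five_prime_plus" else "five_prime_minus"
  } else {
    if (strand == "+") "cov_plus" else "cov_minus"
  }
  track[[key]]
}

# Sum of a track vector over (possibly wrapping) genomic positions.
track_sum <- function(vec, positions, len, circular) {
  if (circular) {
    sum(vec[wrap_position(positions, len)])
  } else {
    keep <- positions >= 1L & positions <= len
    sum(vec[positions[keep]])
  }
}
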