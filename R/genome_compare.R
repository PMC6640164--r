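#' k-mer spectrum of a replicon
#'
#' Counts overlapping forward-strand words of length `k` (default 6,
#' "sixmers"). Windows containing `N` are skipped and excluded from the
#' total; circular sequences contribute the k-1 origin-spanning windows.
#' No strand canonicalisation is applied by default, so two assemblies of
#' the same molecule are compared in the same orientation.
#'
#' @param rep A [replicon()] (or plain DNA string).
#' @param k Word length.
#' @param canonical Collapse each word with its reverse complement.
#' @return Object of class `kmer_spectrum`: named integer vector of
#'   counts with attributes `k` and `total`.
#' @export
kmer_spectrum <- function(rep, k = 6L, canonical = FALSE) {
  seq <- if (inherits(rep, "replicon")) rep$sequence else toupper(rep)
  circular <- inherits(rep, "replicon") && rep$circular
  if (k < 1L) stop("kmer_spectrum: k must be >= 1")
  if (nchar(seq) < k) stop("kmer_spectrum: k exceeds sequence length")
  if (circular && k > 1L) {
    seq <- paste0(seq, substr(seq, 1L, k - 1L))
  }
  counts <- Biostrings::oligonucleotideFrequency(Biostrings::DNAString(seq),
                                                 width = k)
  if (canonical) {
    kmers <- names(counts)
    rc <- reverse_complement(kmers)
    canon <- ifelse(kmers <= rc, kmers, rc)
    counts <- tapply(counts, canon, sum)
    counts <- counts[order(names(counts))]
  }
  counts <- counts[counts > 0]
  structure(as.integer(counts), names = names(counts),
            class = "kmer_spectrum", k = k, total = sum(counts))
}

#' @export
print.kmer_spectrum <- function(x, ...) {
  cat(sprintf("<kmer_spectrum> k = %d, %d distinct words, total %s\n",
              attr(x, "k"), length(x),
              format(attr(x, "total"), big.mark = ",")))
  invisible(x)
}

#' Compare two k-mer spectra
#'
#' Aligns counts over the union of observed words (absent words count 0)
#' and reports the Pearson correlation, the statistic behind sixmer
#' scatter comparisons of assemblies.
#'
#' @param a,b `kmer_spectrum` objects with equal `k`.
#' @return List: `pairs` (data frame `kmer`, `count_a`, `count_b`),
#'   `correlation` (`NA` with `degenerate = TRUE` when either spectrum
#'   has zero variance).
#' @export
compare_spectra <- function(a, b) {
  if (attr(a, "k") != attr(b, "k")) {
    stop("compare_spectra: spectra have different k")
  }
  kmers <- sort(union(names(a), names(b)))
  ca <- unclass(a)[kmers]; ca[is.na(ca)] <- 0L
  cb <- unclass(b)[kmers]; cb[is.na(cb)] <- 0L
  degenerate <- length(kmers) < 2L || isTRUE(stats::sd(ca) == 0) ||
    isTRUE(stats::sd(cb) == 0)
  corr <- if (degenerate) NA_real_ else stats::cor(ca, cb)
  list(pairs = data.frame(kmer = kmers, count_a = as.integer(ca),
                          count_b = as.integer(cb),
                          stringsAsFactors = FALSE),
       correlation = corr, degenerate = degenerate)
}

#' Length and composition differences between two assemblies
#'
#' @param a,b [replicon()]s (reference first: the delta is `b - a`).
#' @return List: `length_a`, `length_b`, `delta` (signed `b - a`),
#'   `gc_a`, `gc_b` (GC fraction over unambiguous bases).
#' @export
assembly_delta <- function(a, b) {
  gc <- function(rep) {
    f <- Biostrings::letterFrequency(Biostrings::DNAString(rep$sequence),
                                     c("G", "C", "A", "T"))
    sum(f[c("G", "C")]) / sum(f)
  }
  list(length_a = a$length, length_b = b$length,
       delta = b$length - a$length, gc_a = gc(a), gc_b = gc(b))
}
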