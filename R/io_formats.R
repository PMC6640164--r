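#' Read replicons from a FASTA file
#'
#' @param path FASTA file.
#' @param circular Logical, recycled over records: is each molecule
#'   circular? (FASTA does not encode topology.)
#' @return List of [replicon()] objects, one per record, sequences
#'   upper-cased.
#' @export
read_fasta <- function(path, circular = FALSE) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop("FASTA format error: empty file at line 1: ", path)
  if (!startsWith(first, ">")) {
    stop("FASTA format error: line 1 does not start with '>': ", path)
  }
  set <- Biostrings::readDNAStringSet(path)
  circular <- rep_len(circular, length(set))
  ids <- sub("\\s.*$", "", names(set))
  mapply(function(id, seq, circ) replicon(id, seq, circ),
         ids, as.character(set), circular,
         SIMPLIFY = FALSE, USE.NAMES = TRUE)
}

#' Write replicons to a FASTA file
#'
#' @param reps A [replicon()] or list of them.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(reps, path) {
  if (inherits(reps, "replicon")) reps <- list(reps)
  set <- Biostrings::DNAStringSet(vapply(reps, `[[`, "", "sequence"))
  names(set) <- vapply(reps, `[[`, "", "name")
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

# Feature types mapped onto the internal `kind` vocabulary.
kind_from_type <- function(type) {
  ifelse(grepl("^IS", type) | tolower(type) %in%
           c("is_element", "insertion_sequence", "mobile_genetic_element"),
         "IS_element",
         ifelse(tolower(type) %in% c("gene", "cds"), "gene", "other"))
}

#' Read gene features from a GFF3 file
#'
#' Coordinates in GFF3 are 1-based inclusive and are kept as such. Gene
#' features must carry a defined strand; `.`/`*` is rejected.
#'
#' @param path GFF3 file.
#' @param rep Optional [replicon()] the annotation refers to; when `NULL` a
#'   placeholder replicon of `N`s spanning the features is created.
#' @param feature_filter Character vector of feature types to retain
#'   (matched against GFF column 3). Default keeps `gene` and IS-element
#'   records.
#' @return A [genome_annotation()].
#' @export
read_gff <- function(path, rep = NULL,
                     feature_filter = c("gene", "IS_element")) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  keep <- as.character(gr$type) %in% feature_filter
  gr <- gr[keep]
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(strand == "*")) {
    stop("GFF3 format error: gene feature with undefined strand '.' in ", path)
  }
  ids <- gff_feature_ids(gr)
  genes <- data.frame(
    id = ids,
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = strand,
    kind = kind_from_type(as.character(gr$type)),
    stringsAsFactors = FALSE
  )
  if (is.null(rep)) {
    len <- max(1L, suppressWarnings(max(genes$end)))
    nm <- if (length(gr)) as.character(GenomicRanges::seqnames(gr))[1] else "unknown"
    rep <- replicon(nm, paste(rep("N", len), collapse = ""))
  }
  genome_annotation(rep, genes)
}

gff_feature_ids <- function(gr) {
  ids <- if (!is.null(gr$ID)) as.character(gr$ID) else rep(NA_character_, length(gr))
  if (!is.null(gr$locus_tag)) {
    lt <- as.character(gr$locus_tag)
    ids <- ifelse(is.na(ids) | ids == "", lt, ids)
  }
  miss <- is.na(ids) | ids == ""
  ids[miss] <- sprintf("feature_%04d", which(miss))
  make.unique(ids)
}

#' Write a gene annotation to GFF3
#'
#' @param ann A [genome_annotation()].
#' @param path Output file; a `##gff-version 3` pragma is emitted.
#' @return `path`, invisibly.
#' @export
write_gff <- function(ann, path) {
  g <- ann$genes
  gr <- GenomicRanges::GRanges(
    seqnames = ann$replicon$name,
    ranges = IRanges::IRanges(g$start, g$end),
    strand = g$strand,
    type = ifelse(g$kind == "IS_element", "IS_element", "gene"),
    source = "divtss",
    ID = g$id
  )
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read IS-element coordinates from a BED file
#'
#' BED is 0-based half-open on disk; rtracklayer converts to the 1-based
#' inclusive convention used internally.
#'
#' @param path BED file.
#' @return Gene table (`kind = "IS_element"`).
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "+"
  ids <- if (!is.null(gr$name) && !all(is.na(gr$name))) {
    make.unique(as.character(gr$name))
  } else {
    sprintf("is_%03d", seq_along(gr))
  }
  gene_table(id = ids, start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr), strand = strand,
             kind = "IS_element")
}

#' Write features to a BED file
#' @param genes Gene table.
#' @param name Sequence name.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(genes, name, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = name,
    ranges = IRanges::IRanges(genes$start, genes$end),
    strand = genes$strand, name = genes$id
  )
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read a strand-separated wiggle pair into a coverage track
#'
#' Accepts both `fixedStep` and `variableStep` wiggle. Positions not listed
#' are zero. The minus-strand file may use the common viewer dialect of
#' negative values; values are stored as absolute counts.
#'
#' @param plus_path,minus_path Wiggle files for the two strands.
#' @param length Replicon length (track vectors are allocated to this).
#' @param library `"TEX"`, `"NOTEX"` or `"FRAG"`.
#' @param what Which field the files hold: `"five_prime"` (5'-end counts,
#'   the dRNA-seq convention for TEX/NOTEX) or `"coverage"` (read depth,
#'   the convention for FRAG).
#' @return A [coverage_track()].
#' @export
read_wiggle <- function(plus_path, minus_path, length, library,
                        what = c("five_prime", "coverage")) {
  what <- match.arg(what)
  plus <- wiggle_vector(plus_path, length)
  minus <- wiggle_vector(minus_path, length)
  if (what == "five_prime") {
    coverage_track(library, length,
                   five_prime_plus = plus, five_prime_minus = minus)
  } else {
    coverage_track(library, length, cov_plus = plus, cov_minus = minus)
  }
}

wiggle_vector <- function(path, length) {
  if (!file.exists(path)) stop("wiggle file not found: ", path)
  v <- numeric(length)
  info <- file.info(path)
  if (info$size == 0) return(v)
  gr <- tryCatch(rtracklayer::import(path, format = "wig"),
                 error = function(e) {
                   # a body with no data lines is a legal all-zero track
                   if (!any(grepl("^\\s*-?[0-9.]", readLines(path)))) {
                     return(NULL)
                   }
                   stop("wiggle format error in ", path, ": ",
                        conditionMessage(e))
                 })
  if (is.null(gr) || base::length(gr) == 0L) return(v)
  if (base::length(unique(as.character(GenomicRanges::seqnames(gr)))) > 1L) {
    stop("wiggle error: mixed chrom names in ", path)
  }
  starts <- GenomicRanges::start(gr)
  ends <- GenomicRanges::end(gr)
  if (any(starts < 1L) || any(ends > length)) {
    stop("wiggle error: position out of range [1, ", length, "] in ", path)
  }
  score <- abs(gr$score)
  for (i in seq_along(starts)) {
    v[starts[i]:ends[i]] <- score[i]
  }
  v
}

#' Write one strand vector of a coverage track as wiggle
#'
#' Emits `variableStep` records for non-zero positions. Minus-strand values
#' are written negated when `negate = TRUE`, matching the viewer dialect
#' read back (as absolute values) by [read_wiggle()].
#'
#' @param values Numeric per-base vector.
#' @param name Chromosome name.
#' @param path Output file.
#' @param negate Write values with flipped sign.
#' @return `path`, invisibly.
#' @export
write_wiggle_vector <- function(values, name, path, negate = FALSE) {
  nz <- which(values != 0)
  if (length(nz) == 0L) {
    writeLines(sprintf("variableStep chrom=%s span=1", name), path)
    return(invisible(path))
  }
  sc <- values[nz]
  if (negate) sc <- -sc
  gr <- GenomicRanges::GRanges(seqnames = name,
                               ranges = IRanges::IRanges(nz, width = 1L),
                               score = sc)
  rtracklayer::export(gr, path, format = "wig")
  invisible(path)
}

#' Write both strands of a coverage track as a wiggle pair
#'
#' @param track A [coverage_track()].
#' @param name Chromosome name.
#' @param plus_path,minus_path Output files.
#' @param what `"five_prime"` or `"coverage"` field selection.
#' @return Character vector of the two paths, invisibly.
#' @export
write_wiggle <- function(track, name, plus_path, minus_path,
                         what = c("five_prime", "coverage")) {
  what <- match.arg(what)
  write_wiggle_vector(track_vector(track, "+", what), name, plus_path)
  write_wiggle_vector(track_vector(track, "-", what), name, minus_path,
                      negate = TRUE)
  invisible(c(plus_path, minus_path))
}

# Class labels used in GFF attributes, both directions.
CLASS_LABELS <- c(P = "Primary", S = "Secondary", I = "Internal",
                  A = "Antisense")

class_to_label <- function(cls) {
  ifelse(is.na(cls), "orphan", unname(CLASS_LABELS[cls]))
}

label_to_class <- function(lab) {
  lab <- tolower(lab)
  out <- rep(NA_character_, length(lab))
  for (k in names(CLASS_LABELS)) {
    out[lab == tolower(CLASS_LABELS[[k]]) | lab == tolower(k)] <- k
  }
  out
}

#' Write classified TSS to GFF3
#'
#' One line per (TSS, class) assignment; the class and associated gene sit
#' in the attribute column, so a TSS with classes `{P, A}` produces two
#' lines. Orphan TSS (no class) are written with `class=orphan`.
#'
#' @param assignments Data frame with columns `position`, `strand`, `class`
#'   (single letters or `NA`), and optionally `gene_id`, `tex_height`,
#'   `enrichment`.
#' @param name Chromosome name.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_tss_gff <- function(assignments, name, path) {
  n <- nrow(assignments)
  if (n == 0L) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = name,
    ranges = IRanges::IRanges(assignments$position, width = 1L),
    strand = assignments$strand,
    type = "TSS", source = "divtss",
    ID = sprintf("tss_%05d_%s", assignments$position,
                 class_to_label(assignments$class)),
    class = class_to_label(assignments$class)
  )
  if (!is.null(assignments$gene_id)) gr$gene <- assignments$gene_id
  if (!is.null(assignments$tex_height)) gr$height <- assignments$tex_height
  if (!is.null(assignments$enrichment)) gr$enrichment <- assignments$enrichment
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read TSS assignments back from GFF3
#'
#' Accepts any attribute named `class` carrying one of
#' Primary/Secondary/Internal/Antisense (case-insensitive, full word or
#' single letter); `orphan` maps to `NA`.
#'
#' @param path GFF3 file written by [write_tss_gff()] (or equivalent).
#' @return Data frame with columns `position`, `strand`, `class`, and
#'   `gene_id`/`tex_height`/`enrichment` when present in the file.
#' @export
read_tss_gff <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) == "TSS"]
  if (base::length(gr) == 0L) {
    return(data.frame(position = integer(), strand = character(),
                      class = character(), stringsAsFactors = FALSE))
  }
  out <- data.frame(
    position = GenomicRanges::start(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    class = label_to_class(as.character(gr$class)),
    stringsAsFactors = FALSE
  )
  if (!is.null(gr$gene)) out$gene_id <- as.character(gr$gene)
  if (!is.null(gr$height)) out$tex_height <- as.numeric(gr$height)
  if (!is.null(gr$enrichment)) out$enrichment <- as.numeric(gr$enrichment)
  out
}

#' Write a result table as TSV
#' @param df Data frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a TSV result table
#' @param path File written by [write_tsv()].
#' @return Data frame.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, na.strings = "NA",
                    check.names = FALSE)
}
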