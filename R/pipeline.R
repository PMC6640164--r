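CONFIG_KEYS <- list(
  top = c("seed", "out_dir", "simulate", "inputs", "detection", "promoter",
          "screen", "units", "compare"),
  inputs = c("genome_fasta", "annotation_gff", "is_bed", "tex_plus",
             "tex_minus", "notex_plus", "notex_minus", "frag_plus",
             "frag_minus", "circular"),
  detection = c("min_height", "min_enrichment", "cluster_width",
                "pseudocount", "utr_window", "antisense_flank"),
  promoter = c("window_from", "window_to", "background", "blacklist"),
  screen = c("threshold", "head_to_tail_only", "denominator",
             "half_window", "upstream_window", "max_spacing"),
  units = c("gap_threshold", "min_body_coverage"),
  compare = c("k", "canonical", "fasta_b")
)

#' Build and validate a pipeline configuration
#'
#' A single configuration object drives [run_pipeline()]. It may come
#' from a YAML file or be assembled in code; unknown keys are rejected
#' before any stage runs. Either `simulate` (a list of
#' [simulation_spec()] overrides) or `inputs` (paths to FASTA, GFF3 and
#' the six wiggle files) must be supplied.
#'
#' @param config Named list or path to a YAML file.
#' @return Validated list of class `run_config`.
#' @export
pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  check_keys <- function(x, allowed, where) {
    bad <- setdiff(names(x), allowed)
    if (length(bad)) {
      stop("pipeline_config: unknown key(s) in ", where, ": ",
           paste(bad, collapse = ", "))
    }
  }
  check_keys(config, CONFIG_KEYS$top, "config")
  for (sec in c("inputs", "detection", "promoter", "screen", "units",
                "compare")) {
    if (!is.null(config[[sec]])) check_keys(config[[sec]], CONFIG_KEYS[[sec]], sec)
  }
  if (!is.null(config$simulate)) {
    check_keys(config$simulate, names(formals(simulation_spec)), "simulate")
  }
  if (is.null(config$seed)) config$seed <- 1L
  if (is.null(config$out_dir)) stop("pipeline_config: out_dir is required")
  if (is.null(config$simulate) && is.null(config$inputs)) {
    stop("pipeline_config: either 'simulate' or 'inputs' must be given")
  }
  if (!is.null(config$inputs)) {
    req <- c("genome_fasta", "annotation_gff", "tex_plus", "tex_minus",
             "notex_plus", "notex_minus", "frag_plus", "frag_minus")
    for (k in req) {
      if (is.null(config$inputs[[k]])) {
        stop("pipeline_config: inputs$", k, " is required")
      }
      if (!file.exists(config$inputs[[k]])) {
        stop("pipeline_config: input file not found: ", config$inputs[[k]])
      }
    }
  }
  structure(config, class = "run_config")
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(unclass(config)), f)
  unname(tools::md5sum(f))
}

#' Run the full dRNA-seq analysis pipeline
#'
#' Stages, in dependency order: (1) optional simulation, writing a
#' complete synthetic dataset; (2) input loading; (3) TSS calling and
#' classification; (4) promoter PWM, consensus and per-class TATA
#' offsets; (5) bidirectional screen with orientation split,
#' meta-profiles, pTSS-aTSS spacings and intergene distances; (6)
#' positional analyses and transcription-unit inference; (7) optional
#' assembly comparison; (8) summary. Every table lands in `out_dir`; the
#' log records the configuration hash, the seed and per-stage wall
#' times. Re-running with an identical configuration reproduces
#' identical outputs.
#'
#' @param config A [pipeline_config()] (or list / YAML path coercible to
#'   one).
#' @return Invisibly, a list with the principal in-memory results
#'   (`classified`, `split`, `candidates`, `pairs`, `units`, `summary`,
#'   ...).
#' @export
run_pipeline <- function(config) {
  config <- pipeline_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  log_lines <- c(sprintf("divtss pipeline run"),
                 sprintf("R %s; divtss %s", getRversion(),
                         as.character(utils::packageVersion("divtss"))),
                 sprintf("config_hash %s", config_hash(config)),
                 sprintf("seed %d", config$seed))
  t_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    log_lines <<- c(log_lines, sprintf("stage %s: %.2f s", name,
                                       proc.time()[["elapsed"]] - t0))
    res
  }
  set.seed(config$seed)

  data_dir <- file.path(config$out_dir, "data")
  if (!is.null(config$simulate)) {
    t_stage("simulate", {
      args <- config$simulate
      if (is.null(args$seed)) args$seed <- config$seed
      spec <- do.call(simulation_spec, args)
      write_simulation(spec, data_dir)
    })
    config$inputs <- list(
      genome_fasta = file.path(data_dir, "genome.fasta"),
      annotation_gff = file.path(data_dir, "annotation.gff3"),
      tex_plus = file.path(data_dir, "tex_plus.wig"),
      tex_minus = file.path(data_dir, "tex_minus.wig"),
      notex_plus = file.path(data_dir, "notex_plus.wig"),
      notex_minus = file.path(data_dir, "notex_minus.wig"),
      frag_plus = file.path(data_dir, "frag_plus.wig"),
      frag_minus = file.path(data_dir, "frag_minus.wig"),
      circular = if (is.null(config$simulate$circular)) TRUE else
        config$simulate$circular
    )
    if (file.exists(file.path(data_dir, "is_elements.bed"))) {
      config$inputs$is_bed <- file.path(data_dir, "is_elements.bed")
    }
  }

  inp <- config$inputs
  loaded <- t_stage("load", {
    circ <- isTRUE(inp$circular) || is.null(inp$circular)
    rep <- read_fasta(inp$genome_fasta, circular = circ)[[1]]
    ann <- read_gff(inp$annotation_gff, rep = rep)
    if (!is.null(inp$is_bed)) {
      isel <- read_bed(inp$is_bed)
      extra <- isel[!isel$id %in% ann$genes$id, , drop = FALSE]
      if (nrow(extra)) {
        ann <- genome_annotation(rep, rbind(ann$genes, extra))
      }
    }
    tex <- read_wiggle(inp$tex_plus, inp$tex_minus, rep$length, "TEX",
                       what = "five_prime")
    notex <- read_wiggle(inp$notex_plus, inp$notex_minus, rep$length,
                         "NOTEX", what = "five_prime")
    frag <- read_wiggle(inp$frag_plus, inp$frag_minus, rep$length, "FRAG",
                        what = "coverage")
    list(rep = rep, ann = ann, tex = tex, notex = notex, frag = frag)
  })
  rep <- loaded$rep; ann <- loaded$ann

  params <- do.call(detection_params,
                    if (is.null(config$detection)) list() else config$detection)
  classified <- t_stage("call", {
    called <- call_tss(loaded$tex, loaded$notex, params,
                       circular = rep$circular)
    cls <- classify_tss(called, ann, params)
    write_tss_gff(cls$assignments, rep$name,
                  file.path(config$out_dir, "tss.gff3"))
    write_tsv(cls$tss, file.path(config$out_dir, "tss_table.tsv"))
    write_tsv(cls$assignments, file.path(config$out_dir,
                                         "tss_assignments.tsv"))
    cls
  })

  prom_cfg <- config$promoter
  wf <- if (is.null(prom_cfg$window_from)) -50L else as.integer(prom_cfg$window_from)
  wt <- if (is.null(prom_cfg$window_to)) 10L else as.integer(prom_cfg$window_to)
  background <- NULL
  if (identical(prom_cfg$background, "genome")) {
    f <- Biostrings::letterFrequency(Biostrings::DNAString(rep$sequence),
                                     c("A", "C", "G", "T"))
    background <- f / sum(f)
  }
  promoter <- t_stage("promoter", {
    tss_df <- classified$tss
    if (!is.null(prom_cfg$blacklist)) {
      for (bl in prom_cfg$blacklist) {
        tss_df <- tss_df[!(tss_df$position >= bl[[1]] &
                             tss_df$position <= bl[[2]]), , drop = FALSE]
      }
    }
    res <- list()
    if (nrow(tss_df)) {
      wins <- extract_windows(tss_df, rep, wf, wt)
      res$pwm <- build_pwm(wins, anchor_offset = wf)
      res$consensus <- pwm_consensus(res$pwm)
      write_pwm(res$pwm, file.path(config$out_dir, "pwm.tsv"))
      by_class <- lapply(c(P = "P", S = "S", I = "I", A = "A"), function(cl) {
        a <- classified$assignments
        sub <- tss_df[tss_df$position %in% a$position[a$class == cl] &
                        grepl(cl, tss_df$classes), , drop = FALSE]
        w <- extract_windows(sub, rep, wf, wt)
        attr(w, "from") <- wf
        w
      })
      by_class <- by_class[vapply(by_class, length, 1L) > 0]
      if (length(by_class)) {
        res$tata_offsets <- tata_offsets_by_class(by_class)
        write_tsv(res$tata_offsets,
                  file.path(config$out_dir, "tata_offsets.tsv"))
      }
    }
    res
  })

  scr <- config$screen
  thr <- if (is.null(scr$threshold)) 0.40 else scr$threshold
  screen_res <- t_stage("screen", {
    a <- classified$assignments
    ptss <- unique(a[a$class == "P",
                     c("position", "strand", "gene_id", "tex_height")])
    atss <- unique(a[a$class == "A", c("position", "strand")])
    split <- if (nrow(ptss)) orientation_split(ptss, ann) else NULL
    res <- list(split = split)
    if (!is.null(split)) {
      write_tsv(intergene_distances(split),
                file.path(config$out_dir, "intergene_distances.tsv"))
      for (k in c("head_to_head", "head_to_tail")) {
        sites <- split[[k]]
        if (nrow(sites)) {
          mp <- meta_profile(sites, loaded$tex,
                             half_window = if (is.null(scr$half_window)) 400L
                             else scr$half_window,
                             what = "five_prime", circular = rep$circular)
          write_tsv(as.data.frame(mp),
                    file.path(config$out_dir,
                              paste0("profile_", k, ".tsv")))
          res[[paste0("profile_", k)]] <- mp
        }
      }
      cand <- screen_bidirectional(
        ptss, loaded$tex, ann, atss = atss, threshold = thr,
        head_to_tail_only = if (is.null(scr$head_to_tail_only)) TRUE else
          scr$head_to_tail_only,
        max_spacing = if (is.null(scr$max_spacing)) 100L else scr$max_spacing,
        denominator = if (is.null(scr$denominator)) "antisense" else
          scr$denominator)
      write_tsv(cand, file.path(config$out_dir, "candidates.tsv"))
      res$candidates <- cand
      res$pairs <- pair_distances(ptss, atss)
    }
    res
  })

  units_cfg <- config$units
  positions <- t_stage("positions", {
    a <- classified$assignments
    res <- list()
    ia <- a[a$class %in% c("I", "A"), c("position", "strand", "gene_id",
                                        "class")]
    res$scaled <- scaled_positions(ia, ann$genes)
    if (nrow(res$scaled)) {
      res$scaled$class <- ia$class[match(
        paste(res$scaled$position, res$scaled$gene_id),
        paste(ia$position, ia$gene_id))]
    }
    write_tsv(res$scaled, file.path(config$out_dir, "positions.tsv"))
    isel <- ann$genes[ann$genes$kind == "IS_element", , drop = FALSE]
    if (nrow(isel)) {
      atss <- unique(a[a$class == "A", c("position", "strand")])
      prof <- is_element_profile(atss, isel)
      write_tsv(prof, file.path(config$out_dir, "is_profile.tsv"))
      res$is_profile <- prof
    }
    ptss <- unique(a[a$class == "P", c("position", "strand", "gene_id")])
    res$units <- infer_units(
      ann, ptss, loaded$frag,
      gap_threshold = if (is.null(units_cfg$gap_threshold)) 25L else
        units_cfg$gap_threshold,
      min_body_coverage = if (is.null(units_cfg$min_body_coverage)) 3 else
        units_cfg$min_body_coverage)
    write_tsv(res$units, file.path(config$out_dir, "units.tsv"))
    res
  })

  compare_res <- NULL
  if (!is.null(config$compare$fasta_b)) {
    compare_res <- t_stage("compare", {
      k <- if (is.null(config$compare$k)) 6L else config$compare$k
      canonical <- isTRUE(config$compare$canonical)
      rep_b <- read_fasta(config$compare$fasta_b)[[1]]
      sa <- kmer_spectrum(rep, k, canonical)
      sb <- kmer_spectrum(rep_b, k, canonical)
      cmp <- compare_spectra(sa, sb)
      write_tsv(cmp$pairs, file.path(config$out_dir, "spectra.tsv"))
      delta <- assembly_delta(rep, rep_b)
      list(comparison = cmp, delta = delta)
    })
  }

  summary <- t_stage("summary", {
    s <- pipeline_summary(classified, screen_res)
    write_tsv(s, file.path(config$out_dir, "summary.tsv"))
    s
  })
  writeLines(log_lines, log_path)
  invisible(list(config = config, classified = classified,
                 promoter = promoter, screen = screen_res,
                 positions = positions, compare = compare_res,
                 summary = summary))
}

pipeline_summary <- function(classified, screen_res) {
  counts <- class_counts(classified)
  utr <- utr_lengths(classified)
  split <- screen_res$split
  ig <- if (!is.null(split)) intergene_distances(split) else NULL
  quantity <- c("n_tss", "n_primary", "n_secondary", "n_internal",
                "n_antisense", "utr_median", "utr_mean",
                "head_to_head", "head_to_tail", "n_candidates",
                "modal_spacing", "intergene_median_head_to_head",
                "intergene_median_head_to_tail")
  value <- c(nrow(classified$tss), counts[["P"]], counts[["S"]],
             counts[["I"]], counts[["A"]],
             if (utr$empty) 0 else utr$median,
             if (utr$empty) 0 else utr$mean,
             if (is.null(split)) 0 else nrow(split$head_to_head),
             if (is.null(split)) 0 else nrow(split$head_to_tail),
             if (is.null(screen_res$candidates)) 0 else
               nrow(screen_res$candidates),
             if (is.null(screen_res$pairs) ||
                 is.na(screen_res$pairs$mode)) NA_real_ else
               screen_res$pairs$mode,
             if (is.null(ig)) NA_real_ else ig$median[1],
             if (is.null(ig)) NA_real_ else ig$median[2])
  data.frame(quantity = quantity, value = value, stringsAsFactors = FALSE)
}

#' Summarise a completed run directory
#'
#' Recomputes the headline table (per-class counts, UTR median/mean,
#' orientation split sizes, candidate count, modal spacing, intergene
#' medians) from the tables a [run_pipeline()] call wrote.
#'
#' @param dir Run directory.
#' @return Data frame with `quantity` and `value` columns.
#' @export
summarize_run <- function(dir) {
  need <- c("tss_table.tsv", "tss_assignments.tsv", "summary.tsv")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing)) {
    stop("summarize_run: incomplete run directory, missing: ",
         paste(missing, collapse = ", "))
  }
  read_tsv(file.path(dir, "summary.tsv"))
}
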