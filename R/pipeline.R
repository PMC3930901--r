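#' Build and validate a pipeline run configuration
#'
#' Unknown keys are rejected; paths are checked before any stage runs.
#'
#' @param reference path to the reference FASTA (required)
#' @param alternates named character vector of alternate-assembly FASTA
#'   paths (may be empty)
#' @param annotation optional coding-intervals TSV (seq_id, start, end)
#' @param genotypes optional genotype CSV for the statistics stages
#' @param out_dir output directory
#' @param thresholds,overrides,flank_length scanner settings
#'   (see [scan_config()])
#' @param fold five-fold rule threshold
#' @param min_diff polymorphism length threshold in bp
#' @param select require polymorphism against "either" or "both"
#'   alternates before primer design
#' @param constraints a [primer_constraints()]
#' @param seed RNG seed recorded for provenance
#' @param ... rejected (catches unknown keys)
#' @return object of class `run_config`
#' @export
run_config <- function(reference, alternates = character(0),
                       annotation = NULL, genotypes = NULL,
                       out_dir = "ssrforge_out",
                       thresholds = default_thresholds(),
                       overrides = list(), flank_length = 200L,
                       fold = 5, min_diff = 1L,
                       select = c("either", "both"),
                       constraints = primer_constraints(), seed = 1L,
                       ...) {
  extra <- list(...)
  if (length(extra)) {
    stop("unknown config key(s): ", paste(names(extra), collapse = ", "))
  }
  select <- match.arg(select)
  for (p in c(reference, alternates, annotation, genotypes)) {
    if (!is.null(p) && !file.exists(p)) stop("input file not found: ", p)
  }
  if (length(alternates) && is.null(names(alternates))) {
    stop("alternate assemblies must be named")
  }
  structure(list(reference = reference, alternates = alternates,
                 annotation = annotation, genotypes = genotypes,
                 out_dir = out_dir,
                 scan = scan_config(thresholds, overrides, flank_length),
                 fold = fold, min_diff = as.integer(min_diff),
                 select = select, constraints = constraints,
                 seed = as.integer(seed)),
            class = "run_config")
}

.stage_report <- function(stage, n_in, n_out, reasons = character(0)) {
  data.frame(stage = stage, input = n_in, output = n_out,
             dropped = n_in - n_out,
             reasons = paste(names(table(reasons)), table(reasons),
                             sep = "=", collapse = ";"),
             stringsAsFactors = FALSE)
}

#' Run the full marker-development pipeline
#'
#' scan -> single-copy filter -> polymorphism comparison -> primer design
#' -> physical map, writing every stage's TSV outputs under
#' `config$out_dir` before the next stage starts, plus a Table 1-style
#' consolidated summary (per-sequence SSR counts, per-assembly polymorphic
#' counts and percentages, designed-primer counts). With a genotype CSV
#' configured, marker statistics, transferability, the Nei DA distance
#' matrix and the NJ tree are produced as well.
#'
#' @param config a [run_config()]
#' @param verbose print one line per stage
#' @return list with loci, retained, comparisons, primers, map, report
#'   (stage accounting) and summary (the consolidated table); statistics
#'   outputs when genotypes were configured
#' @export
run_all <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  write_resolved_config(config, file.path(config$out_dir, "config.txt"))

  ref <- read_fasta(config$reference)
  alts <- lapply(config$alternates, read_fasta)

  loci <- scan_genome(ref, config$scan)
  write_loci(loci, file.path(config$out_dir, "loci.tsv"))
  say("scan: %d loci", nrow(loci))
  report <- .stage_report("scan", nrow(loci), nrow(loci))

  fsc <- filter_single_copy(loci, genome = ref, fold = config$fold,
                            flank_length = config$scan$flank_length)
  retained <- fsc$retained
  write_loci(retained, file.path(config$out_dir, "loci_single_copy.tsv"))
  .write_tsv(fsc$log, file.path(config$out_dir, "single_copy_log.tsv"))
  say("unique: %d of %d single-copy", nrow(retained), nrow(loci))
  report <- rbind(report, .stage_report(
    "unique", nrow(loci), nrow(retained),
    fsc$log$verdict[fsc$log$verdict != "single-copy"]))

  comparisons <- NULL; selected <- retained
  if (length(alts)) {
    comparisons <- compare_loci(retained, ref, alts,
                                flank_length = config$scan$flank_length,
                                min_diff = config$min_diff)
    .write_tsv(comparisons, file.path(config$out_dir, "comparisons.tsv"))
    .write_tsv(summarize_rates(comparisons, "seq_id", config$min_diff),
               file.path(config$out_dir, "polymorphism_rates.tsv"))
    delta_cols <- grep("_delta$", names(comparisons), value = TRUE)
    poly_mat <- abs(as.matrix(comparisons[delta_cols])) >= config$min_diff
    poly_mat[is.na(poly_mat)] <- FALSE
    is_poly <- if (config$select == "either") {
      apply(poly_mat, 1, any)
    } else {
      apply(poly_mat, 1, all)
    }
    selected <- retained[is_poly, , drop = FALSE]
    say("compare: %d of %d polymorphic (%s)", nrow(selected),
        nrow(retained), config$select)
    report <- rbind(report, .stage_report(
      "compare", nrow(retained), nrow(selected),
      comparisons$status[!is_poly]))
  }

  design <- batch_design(selected, ref, config$constraints,
                         config$scan$flank_length)
  .write_tsv(design$primers, file.path(config$out_dir, "primers.tsv"))
  say("design: %d primer pairs", nrow(design$primers))
  report <- rbind(report, .stage_report(
    "design", nrow(selected), nrow(design$primers),
    design$failed$reason))

  designed_loci <- loci[loci$locus_id %in% design$primers$locus_id, ,
                        drop = FALSE]
  pm <- build_map(data.frame(marker = designed_loci$locus_id,
                             seq_id = designed_loci$seq_id,
                             position = designed_loci$start,
                             stringsAsFactors = FALSE))
  .write_tsv(pm$map, file.path(config$out_dir, "physical_map.tsv"))

  out <- list(loci = loci, retained = retained, comparisons = comparisons,
              primers = design$primers, map = pm, report = report,
              summary = report_table(loci, comparisons, design$primers,
                                     min_diff = config$min_diff))
  .write_tsv(out$summary, file.path(config$out_dir, "summary.tsv"))

  if (!is.null(config$genotypes)) {
    gm <- read_genotypes(config$genotypes)
    out$marker_stats <- marker_stats(gm)
    .write_tsv(out$marker_stats, file.path(config$out_dir,
                                           "marker_stats.tsv"))
    if (!is.null(gm$groups)) {
      tg <- unique(gm$groups)
      out$transferability <- data.frame(
        group = tg,
        pct = vapply(tg, function(g) transferability(gm, g), numeric(1)),
        stringsAsFactors = FALSE)
      .write_tsv(out$transferability,
                 file.path(config$out_dir, "transferability.tsv"))
    }
    dm <- distance_matrix(gm)
    write_distance_matrix(dm, file.path(config$out_dir, "distances.tsv"))
    out$tree <- neighbor_joining(dm)
    write_newick(out$tree, file.path(config$out_dir, "tree.nwk"))
  }
  out
}

#' Consolidated Table-1 style summary
#'
#' One row per sequence plus a Total row: number of SSRs, per-assembly
#' polymorphic counts with percentages, designed-primer counts. Every
#' percentage is recomputed from the two count cells of its own row,
#' rounded half-up to one decimal.
#'
#' @param loci scanned loci (data.frame)
#' @param comparisons output of [compare_loci()] or NULL
#' @param primers designed primers (data.frame with seq_id) or NULL
#' @param polymorphic_markers optional data.frame (seq_id, n) of validated
#'   polymorphic markers, to add a success-percentage column against the
#'   designed counts
#' @param min_diff polymorphism threshold used
#' @return data.frame
#' @export
report_table <- function(loci, comparisons = NULL, primers = NULL,
                         polymorphic_markers = NULL, min_diff = 1L) {
  sids <- sort(unique(loci$seq_id))
  out <- data.frame(seq_id = c(sids, "Total"), stringsAsFactors = FALSE)
  cnt <- function(ids) {
    v <- table(factor(ids, levels = sids))
    c(as.integer(v), length(ids))
  }
  out$n_ssr <- cnt(loci$seq_id)
  if (!is.null(comparisons) && nrow(comparisons)) {
    assemblies <- setdiff(
      sub("_delta$", "", grep("_delta$", names(comparisons), value = TRUE)),
      "ref")
    for (a in assemblies) {
      delta <- comparisons[[paste0(a, "_delta")]]
      poly <- !is.na(delta) & abs(delta) >= min_diff
      out[[paste0(a, "_polymorphic")]] <- cnt(comparisons$seq_id[poly])
      out[[paste0(a, "_pct")]] <- ifelse(
        out$n_ssr > 0,
        round_half_up(100 * out[[paste0(a, "_polymorphic")]] /
                        pmax(1L, out$n_ssr), 1),
        NA_real_)
    }
  }
  if (!is.null(primers)) out$designed <- cnt(primers$seq_id)
  if (!is.null(polymorphic_markers)) {
    v <- table(factor(polymorphic_markers$seq_id, levels = sids))
    out$polymorphic_markers <- c(as.integer(v), sum(v))
    out$success_pct <- ifelse(
      out$designed > 0,
      round_half_up(100 * out$polymorphic_markers / out$designed, 1),
      NA_real_)
  }
  out
}

#' Write / read a flat key=value config file
#'
#' Every run writes its resolved configuration beside the outputs for
#' provenance.
#'
#' @param config a [run_config()]
#' @param path file path
#' @export
write_resolved_config <- function(config, path) {
  kv <- c(reference = config$reference,
          if (length(config$alternates))
            stats::setNames(config$alternates,
                            paste0("alt.", names(config$alternates))),
          annotation = config$annotation %||% "",
          genotypes = config$genotypes %||% "",
          out_dir = config$out_dir,
          stats::setNames(as.character(config$scan$thresholds),
                          paste0("threshold.", motif_class_names())),
          flank_length = as.character(config$scan$flank_length),
          fold = as.character(config$fold),
          min_diff = as.character(config$min_diff),
          select = config$select,
          seed = as.character(config$seed))
  writeLines(paste0(names(kv), "=", kv), path)
  invisible(path)
}
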