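#' Run configuration for end-to-end analyses
#'
#' Bundles the filter and significance thresholds (defaults: at least 5
#' supporting reads, Fisher P < 0.01, FDR < 0.03, mitochondrial contigs
#' excluded) with either a simulation config or a directory of input files.
#' The configuration in force is echoed into every run's `summary.json`.
#'
#' @param simulation a [simulation_config()], or NULL when reading inputs
#'   from `input_dir`.
#' @param input_dir directory holding `genome.fa`, `annotation.gtf`,
#'   `gene_meta.tsv`, `samples.tsv`, `SJ.<sample>.tab`, `gene_counts.tsv`.
#' @param min_reads junction support filter (default 5).
#' @param strict_min strict per-replicate support filter (default 5).
#' @param p_cut,q_cut Fisher P and BH FDR thresholds (0.01, 0.03).
#' @param overhang_annotated,overhang_novel overhang filters (3, 12).
#' @param exclude_contigs contigs dropped (mitochondrial decoys).
#' @param seed integer seed for the model stage.
#' @return a `run_config` list.
#' @export
run_config <- function(simulation = NULL, input_dir = NULL,
                       min_reads = 5L, strict_min = 5L,
                       p_cut = 0.01, q_cut = 0.03,
                       overhang_annotated = 3L, overhang_novel = 12L,
                       exclude_contigs = c("chrM", "Mito"), seed = 1L) {
  if (is.null(simulation) && is.null(input_dir))
    stop("provide a simulation config or an input directory")
  structure(list(simulation = simulation, input_dir = input_dir,
                 min_reads = min_reads, strict_min = strict_min,
                 p_cut = p_cut, q_cut = q_cut,
                 overhang_annotated = overhang_annotated,
                 overhang_novel = overhang_novel,
                 exclude_contigs = exclude_contigs, seed = as.integer(seed)),
            class = "run_config")
}

# Load analysis inputs from a directory written by write_simulation() (or
# assembled by hand in the same layout).
load_inputs <- function(dir) {
  need <- c("genome.fa", "annotation.gtf", "gene_meta.tsv", "samples.tsv")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing))
    stop("input directory ", dir, " is missing: ", paste(missing, collapse = ", "))
  genome <- parse_gtf(file.path(dir, "annotation.gtf"),
                      gene_meta = file.path(dir, "gene_meta.tsv"))
  seqs <- Biostrings::readDNAStringSet(file.path(dir, "genome.fa"))
  names(seqs) <- sub(" .*", "", names(seqs))
  samples <- utils::read.delim(file.path(dir, "samples.tsv"),
                               colClasses = c(sample = "character",
                                              strain = "character"))
  tables <- lapply(samples$sample, function(s)
    parse_sj_tab(file.path(dir, paste0("SJ.", s, ".tab"))))
  names(tables) <- samples$sample
  jset <- junction_set(tables, samples)
  gc_path <- file.path(dir, "gene_counts.tsv")
  gene_counts <- if (file.exists(gc_path)) utils::read.delim(gc_path) else NULL
  list(genome = genome, seqs = seqs, jset = jset, gene_counts = gene_counts,
       samples = samples, dir = dir)
}

#' Run the full analysis (simulate, classify, quantify, contrast, predict)
#'
#' When the config carries a simulation, the synthetic inputs are written
#' to `<out_dir>/inputs` and read back through the standard parsers, so a
#' simulated run exercises the same file path as a real one. Stages:
#' junction filtering, event classification, per-strain SEF, mutant-vs-WT
#' Fisher contrasts with BH FDR, RP stratification, sequence-feature
#' extraction and the random-forest SEF predictor. Every output is a plain
#' text table plus a `summary.json`; runs are byte-reproducible for a
#' fixed seed.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created).
#' @return list with all stage outputs (invisibly also written to disk).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_stage <- function(...) message("[splicefid] ", sprintf(...))
  if (!is.null(config$simulation)) {
    log_stage("simulating inputs (seed %d)", config$simulation$seed)
    sim <- make_genome(config$simulation)
    counts <- simulate_junction_counts(sim$genome, sim$truth, config$simulation)
    write_simulation(sim, counts, file.path(out_dir, "inputs"))
    input_dir <- file.path(out_dir, "inputs")
  } else {
    input_dir <- config$input_dir
  }
  inp <- load_inputs(input_dir)
  jset <- annotate_junctions(inp$jset, inp$genome)
  n0 <- nrow(jset$junctions)
  jset <- filter_junctions(jset, min_reads = config$min_reads,
                           overhang_annotated = config$overhang_annotated,
                           overhang_novel = config$overhang_novel,
                           exclude_contigs = config$exclude_contigs)
  log_stage("junction filter: %d -> %d junctions", n0, nrow(jset$junctions))
  events <- classify_events(jset, inp$genome)
  log_stage("classified %d novel junctions", nrow(events))
  sef <- sef_table(events, jset, inp$genome, gene_counts = inp$gene_counts,
                   strict_min = config$strict_min)
  contrasts <- contrast_strains(sef, p_cut = config$p_cut, q_cut = config$q_cut)
  strata <- stratify(contrasts)

  # SEF vs abundance (annotated junction reads as the abundance proxy)
  sef_ok <- sef[!is.na(sef$sef) & sef$sef > 0 & !is.na(sef$annotated) &
                  sef$annotated > 0 & sef$passes_strict_filter, ]
  cor_sef_abundance <- NA_real_
  if (nrow(sef_ok) >= 3) {
    agg <- stats::aggregate(cbind(sef, annotated) ~ event_id, sef_ok, mean)
    if (nrow(agg) >= 3 && stats::sd(log10(agg$sef)) > 0 &&
        stats::sd(log10(agg$annotated)) > 0) {
      cor_sef_abundance <- pearson_r(log10(agg$annotated), log10(agg$sef))
    }
  }

  model <- NULL; fm <- NULL
  fit_events <- unique(sef$event_id[sef$passes_strict_filter &
                                      sef$sef_type == "intronic"])
  if (length(fit_events) >= 6) {
    fm <- build_feature_matrix(events[events$event_id %in% fit_events, ],
                               inp$genome, inp$seqs)
    target <- vapply(rownames(fm), function(id) {
      s <- sef$sef[sef$event_id == id & !is.na(sef$sef) & sef$sef > 0]
      if (length(s)) log2(mean(s)) else NA_real_
    }, numeric(1))
    ok <- is.finite(target)
    if (sum(ok) >= 6) {
      log_stage("fitting SEF predictor on %d events", sum(ok))
      model <- fit_cv(fm[ok, , drop = FALSE], target[ok], seed = config$seed)
    }
  }

  wt <- function(x, f) utils::write.table(
    x, file.path(out_dir, f), sep = "\t", row.names = FALSE, quote = FALSE)
  wt(events, "event_catalogue.tsv")
  wt(sef, "sef_table.tsv")
  if (!is.null(contrasts) && nrow(contrasts)) wt(contrasts, "contrasts.tsv")
  if (nrow(strata)) wt(strata, "strata.tsv")
  if (!is.null(fm)) {
    wt(data.frame(event_id = rownames(fm), fm, check.names = FALSE),
       "feature_matrix.tsv")
  }
  summary <- list(
    config = config[setdiff(names(config), "simulation")],
    simulated = !is.null(config$simulation),
    n_junctions_input = n0, n_junctions_filtered = nrow(jset$junctions),
    events_by_class = as.list(table(events$event_class)),
    strata = strata,
    cor_sef_abundance = cor_sef_abundance,
    log2_sef_ratios = if (!is.null(contrasts) && nrow(contrasts))
      split(contrasts$log2_ratio[contrasts$direction != "ns"],
            contrasts$contrast[contrasts$direction != "ns"]) else NULL,
    model = if (!is.null(model))
      list(r = model$r, r_fold = model$r_fold,
           r_fold_mean = model$r_fold_mean,
           top_features = names(importances(model))[1:10],
           hyperparameters = model$hyperparameters) else NULL)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       force = TRUE, pretty = TRUE)
  invisible(list(genome = inp$genome, jset = jset, events = events, sef = sef,
                 contrasts = contrasts, strata = strata, features = fm,
                 model = model, summary = summary, out_dir = out_dir))
}

#' Human-readable summary of a completed run
#'
#' @param run_dir directory written by [run_pipeline()].
#' @return the printed lines, invisibly.
#' @export
report_run <- function(run_dir) {
  sfile <- file.path(run_dir, "summary.json")
  if (!file.exists(sfile)) stop("no summary.json under ", run_dir)
  s <- jsonlite::read_json(sfile, simplifyVector = TRUE)
  lines <- c(sprintf("splicefid run: %s", run_dir),
             sprintf("junctions: %d in, %d after filters",
                     s$n_junctions_input, s$n_junctions_filtered))
  if (length(s$events_by_class)) {
    lines <- c(lines, "events by class:",
               sprintf("  %-16s %d", names(s$events_by_class),
                       unlist(s$events_by_class)))
  } else {
    lines <- c(lines, "zero novel events detected")
  }
  if (!is.null(s$strata) && length(s$strata)) {
    st <- as.data.frame(s$strata)
    lines <- c(lines, "fidelity direction by stratum:",
               sprintf("  %-14s %-7s reduced=%d increased=%d ratio=%s",
                       st$contrast, st$stratum, st$reduced, st$increased,
                       ifelse(is.na(st$ratio), "NA",
                              sprintf("%.2f", st$ratio))))
  }
  if (!is.null(s$cor_sef_abundance) && !is.na(s$cor_sef_abundance)) {
    lines <- c(lines, sprintf("SEF vs abundance Pearson R = %.3f (%s)",
                              s$cor_sef_abundance,
                              if (s$cor_sef_abundance < 0) "anti-correlated"
                              else "positively correlated"))
  }
  if (!is.null(s$model)) {
    lines <- c(lines, sprintf("SEF predictor: pooled out-of-fold R = %.3f (per-fold mean %.3f)",
                              s$model$r, s$model$r_fold_mean))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
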