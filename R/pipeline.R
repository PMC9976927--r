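# End-to-end orchestration: file bundle -> filtered transcripts ->
# pausing indices -> feature matrix -> model -> attributions, plus the
# two-cell-line comparison.

bundle_paths <- function(dir) {
  list(genome = file.path(dir, "genome.fa"),
       gtf = file.path(dir, "annotation.gtf"),
       expression = file.path(dir, "expression.tsv"),
       ncrna_expression = file.path(dir, "ncrna_expression.tsv"),
       ctss = file.path(dir, "ctss.tsv"),
       cpg = file.path(dir, "cpg_islands.tsv"),
       housekeeping = file.path(dir, "housekeeping.txt"),
       wig_plus = file.path(dir, "signal_plus.wig"),
       wig_minus = file.path(dir, "signal_minus.wig"),
       peaks_dir = file.path(dir, "peaks"))
}

read_peaks_dir <- function(dir) {
  files <- list.files(dir, pattern = "^(chip|clip)_.+\\.bed$",
                      full.names = TRUE)
  if (length(files) == 0L) stop("no peak BED files found in ", dir)
  rbindlist(lapply(files, function(f) {
    m <- regmatches(basename(f),
                    regexec("^(chip|clip)_(.+)\\.bed$", basename(f)))[[1L]]
    read_bed_peaks(f, factor = m[3L], assay = m[2L])
  }))
}

#' Run the full pausing-prediction pipeline on a file bundle
#'
#' Executes, in order: annotation loading, RefSeq-confidence and
#' expression filters, CAGE clustering and the dominant-CTSS filter, TSS
#' window optimization (optional), the pausing-index exclusion filters,
#' pausing-index quantification, feature-matrix assembly, holdout
#' training/evaluation, and factor-level attribution analysis.
#'
#' @param bundle directory containing a bundle in the layout written by
#'   [simulate_bundle()] (or a named path list with the same elements).
#' @param pi_cfg a [pi_config()]; its half-width is used when
#'   `optimize_window = FALSE`.
#' @param spec a [model_spec()].
#' @param optimize_window scan `window_grid` for the half-width with the
#'   most negative PI-expression correlation (default `TRUE`).
#' @param window_grid candidate half-widths for the scan.
#' @param target_share cumulative contribution share for the minimal
#'   factor set.
#' @return A list of class `pause_run`: filter report, window-scan
#'   profile, pausing table, `feature_matrix`, fit, holdout metrics,
#'   contribution table, factor ranking, minimal factor set, identified
#'   7SK binders and the seed/configuration used.
#' @export
run_pipeline <- function(bundle, pi_cfg = pi_config(),
                         spec = model_spec(),
                         optimize_window = TRUE,
                         window_grid = c(1L, 2L, 5L, 10L, 50L),
                         target_share = 0.5) {
  paths <- if (is.character(bundle)) bundle_paths(bundle) else bundle
  for (nm in c("genome", "gtf", "expression", "ctss", "wig_plus",
               "wig_minus", "peaks_dir")) {
    if (!file.exists(paths[[nm]]))
      stop(sprintf("bundle is missing '%s' (%s)", nm, paths[[nm]]))
  }
  genome <- read_fasta(paths$genome)
  txs <- read_gtf_transcripts(paths$gtf)
  expression <- read_expression_table(paths$expression)
  ctss <- read_ctss_table(paths$ctss)
  cpg <- read_cpg_islands(paths$cpg)
  housekeeping <- readLines(paths$housekeeping)
  peaks <- read_peaks_dir(paths$peaks_dir)
  track <- read_wig_signal(paths$wig_plus, paths$wig_minus)

  coding <- txs[biotype == "protein_coding"]
  ncrna <- txs[biotype != "protein_coding"]
  n_coding <- nrow(coding)
  coding <- filter_high_confidence(coding)
  n_hc <- nrow(coding)
  coding <- filter_expressed(coding, expression)
  n_expr <- nrow(coding)
  clusters <- cluster_ctss(ctss)
  coding <- filter_by_dominant_ctss(coding, clusters)
  n_cage <- nrow(coding)

  window_scan <- NULL
  if (optimize_window) {
    window_scan <- optimize_tss_window(track, coding, grid = window_grid,
                                       pseudocount = pi_cfg$pseudocount)
    pi_cfg <- pi_config(window_scan$best_halfwidth, pi_cfg$pseudocount)
  }
  filt <- apply_pi_filters(coding, genome, track, pi_cfg)
  retained <- filt$retained
  pit <- compute_pausing_table(track, retained, pi_cfg)
  y <- setNames(pit$pi, pit$transcript_id)

  filter_report <- data.table(
    stage = c("protein_coding", "high_confidence", "expressed",
              "dominant_ctss", "pi_filtered"),
    n = c(n_coding, n_hc, n_expr, n_cage, nrow(retained)))

  ncrna_expr <- if (file.exists(paths$ncrna_expression)) {
    ncx <- read_expression_table(paths$ncrna_expression)
    filter_expressed(ncrna, ncx)
  } else ncrna
  regions <- derive_regions_table(retained)
  binding <- encode_binding_features(regions, peaks, retained$transcript_id)
  ncflags <- proximal_ncrna_features(retained, ncrna_expr, peaks)
  cpgX <- cpg_features(retained, cpg)
  annX <- annotation_features(retained, genome, housekeeping)
  fm <- assemble_matrix(binding, ncflags, cpgX, annX)

  sp <- split_holdout(rownames(fm$X), spec$holdout_fraction, spec$seed)
  fit <- train_model(fm$X[sp$train, , drop = FALSE], y[sp$train], spec)
  ev <- evaluate_model(fit, fm$X[sp$test, , drop = FALSE], y[sp$test])

  ct <- compute_attributions(fit, fm$X[sp$test, , drop = FALSE])
  ranking <- aggregate_by_factor(ct, fm$meta)
  minimal <- select_minimal_factor_set(ranking, target_share)

  sevenk <- identify_7sk_binders(
    ncrna, peaks[assay == "clip"],
    if (file.exists(paths$ncrna_expression))
      read_expression_table(paths$ncrna_expression) else expression)

  structure(list(filter_report = filter_report,
                 exclusion_report = filt$report,
                 window_scan = window_scan, pi_cfg = pi_cfg,
                 pausing = pit, y = y, feature_matrix = fm,
                 split = sp, fit = fit, holdout_r2 = ev$r2,
                 holdout_rho = ev$rho, predictions = ev$predictions,
                 contributions = ct, ranking = ranking,
                 minimal_set = minimal, sevenk_binders = sevenk,
                 seed = spec$seed),
            class = "pause_run")
}

#' @export
print.pause_run <- function(x, ...) {
  cat("pause_run:\n")
  cat(sprintf("  transcripts modeled: %d\n", length(x$y)))
  cat(sprintf("  TSS halfwidth: %d\n", x$pi_cfg$tss_halfwidth))
  cat(sprintf("  holdout R2: %.3f (rho %.3f)\n", x$holdout_r2, x$holdout_rho))
  cat(sprintf("  minimal factor set: %d factors (>= %.0f%% of contributions)\n",
              nrow(x$minimal_set), 100 * x$minimal_set$cumulative[nrow(x$minimal_set)]))
  invisible(x)
}

#' Cross-cell-line comparison of two pipeline runs
#'
#' Synchronizes the two feature matrices to their common columns,
#' retrains each cell line's model on its training split over the
#' synchronized features, and evaluates each model on the other cell
#' line: on all transcripts, on transcripts exclusive to the other cell
#' line, and on the differential-pausing groups of shared transcripts.
#'
#' @param runA,runB `pause_run` objects ([run_pipeline()]).
#' @param spec a [model_spec()] for the synchronized models.
#' @param log2_fc_threshold threshold for the differential groups.
#' @return A list with per-direction cross R-squared (`a_on_b`,
#'   `b_on_a`), exclusive-transcript R-squared, and the
#'   [differential_pausing_eval()] table.
#' @export
compare_cell_lines <- function(runA, runB, spec = model_spec(),
                               log2_fc_threshold = 1) {
  sync <- synchronize_features(runA$feature_matrix, runB$feature_matrix)
  fitA <- train_model(sync$a$X[runA$split$train, , drop = FALSE],
                      runA$y[runA$split$train], spec)
  fitB <- train_model(sync$b$X[runB$split$train, , drop = FALSE],
                      runB$y[runB$split$train], spec)
  evAB <- evaluate_model(fitA, sync$b$X, runB$y[rownames(sync$b$X)])
  evBA <- evaluate_model(fitB, sync$a$X, runA$y[rownames(sync$a$X)])

  onlyB <- setdiff(rownames(sync$b$X), rownames(sync$a$X))
  onlyA <- setdiff(rownames(sync$a$X), rownames(sync$b$X))
  r2_exclusive_b <- if (length(onlyB) >= 3L)
    evaluate_model(fitA, sync$b$X[onlyB, , drop = FALSE], runB$y[onlyB])$r2
  else NA_real_
  r2_exclusive_a <- if (length(onlyA) >= 3L)
    evaluate_model(fitB, sync$a$X[onlyA, , drop = FALSE], runA$y[onlyA])$r2
  else NA_real_

  shared <- intersect(rownames(sync$a$X), rownames(sync$b$X))
  predA_by_B <- evaluate_model(fitB, sync$a$X[shared, , drop = FALSE],
                               runA$y[shared])$predictions
  predB_by_A <- evaluate_model(fitA, sync$b$X[shared, , drop = FALSE],
                               runB$y[shared])$predictions
  differential <- differential_pausing_eval(
    runA$y[shared], runB$y[shared], predA_by_B, predB_by_A,
    log2_fc_threshold)

  list(n_common_features = ncol(sync$a$X),
       r2_a_on_b = evAB$r2, r2_b_on_a = evBA$r2,
       r2_exclusive_b = r2_exclusive_b, r2_exclusive_a = r2_exclusive_a,
       differential = differential,
       fits = list(a = fitA, b = fitB))
}
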