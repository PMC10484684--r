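# End-to-end orchestration: bin -> rank/select -> per-QDA fit ->
# validate -> classify, in memory (analyse_dataset) or from a config
# file with all inputs and outputs on disk (run_pipeline).

#' Analyse one dataset end to end (in memory)
#'
#' The core of the pipeline: tiles the genome, selects training and
#' validation bins by ChIP peak content, fits (N, lambda) per QDA value,
#' validates by AUC and classifies the dataset's accessibility
#' dependence.
#'
#' @param genome named character vector of sequences.
#' @param access_signal raw accessibility [signal_track()].
#' @param chip_signal ChIP [signal_track()].
#' @param peaks ChIP peak intervals.
#' @param pfm motif `PFM`.
#' @param bin_bp genomic bin width.
#' @param n_train,n_validate training / validation bin counts.
#' @param qda_grid,N_grid,lambda_grid analysis grids.
#' @param pseudocount,background PWM options.
#' @param kernel,bandwidth_bp smoothing kernel.
#' @param window_bp validation window width.
#' @param thresholds classification thresholds
#'   ([classification_thresholds()]).
#' @param L,n genome length and ploidy for the occupancy equation.
#' @param dataset dataset id for the classification record.
#' @return List with `auc` (named row over the QDA grid), `fits`,
#'   `classification`, `regions` (the selected bins).
#' @export
analyse_dataset <- function(genome, access_signal, chip_signal, peaks,
                            pfm, bin_bp = 50000, n_train = 10,
                            n_validate = 50,
                            qda_grid = default_qda_grid(),
                            N_grid = default_N_grid(),
                            lambda_grid = default_lambda_grid(),
                            pseudocount = 1, background = rep(0.25, 4),
                            kernel = "gaussian", bandwidth_bp = 100,
                            window_bp = 100,
                            thresholds = classification_thresholds(),
                            L = sum(nchar(genome)), n = 1,
                            dataset = "dataset") {
  pwm <- pfm_to_pwm(pfm, pseudocount, background)
  seq_lengths <- setNames(nchar(genome), names(genome))
  bins <- bin_genome(seq_lengths, bin_bp)
  sel <- rank_and_select(bins, peaks, n_train, n_validate)
  res <- auc_over_qda(genome, access_signal, chip_signal, peaks,
                      sel$training, sel$validation, pwm,
                      qda_grid = qda_grid, N_grid = N_grid,
                      lambda_grid = lambda_grid, L = L, n = n,
                      kernel = kernel, bandwidth_bp = bandwidth_bp,
                      window_bp = window_bp)
  cls <- classify_tf(res$auc, qda_grid, thresholds, dataset = dataset)
  list(auc = res$auc, fits = res$fits, classification = cls,
       regions = sel)
}

#' Build a pipeline run configuration
#'
#' Either a `scenario` (synthetic run) or explicit input paths
#' (`genome_fasta`, `pfm_file`, `chip_signal_file`, `chip_peaks_file`,
#' `access_signal_file`) must be supplied. Every default is resolved
#' here so the run manifest records the exact values used.
#'
#' @param scenario optional [synthetic_scenario()].
#' @param genome_fasta,pfm_file,chip_signal_file,chip_peaks_file,access_signal_file
#'   input paths for a real-data run.
#' @param chip_signal_dialect,access_signal_dialect signal dialects.
#' @param chip_peaks_dialect `"bed"` or `"narrowPeak"`.
#' @param ... overrides for any [analyse_dataset()] argument.
#' @param seed integer seed.
#' @param dataset dataset id.
#' @return A `PipelineConfig` list.
#' @export
pipeline_config <- function(scenario = NULL, genome_fasta = NULL,
                            pfm_file = NULL, chip_signal_file = NULL,
                            chip_peaks_file = NULL,
                            access_signal_file = NULL,
                            chip_signal_dialect = "bedGraph",
                            access_signal_dialect = "bedGraph",
                            chip_peaks_dialect = "bed",
                            seed = 1L, dataset = "dataset", ...) {
  analysis <- list(bin_bp = 50000, n_train = 10, n_validate = 50,
                   qda_grid = default_qda_grid(),
                   N_grid = default_N_grid(),
                   lambda_grid = default_lambda_grid(),
                   pseudocount = 1, background = rep(0.25, 4),
                   kernel = "gaussian", bandwidth_bp = 100,
                   window_bp = 100,
                   thresholds = classification_thresholds())
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(analysis))
  if (length(unknown))
    stop("unknown analysis option(s): ", paste(unknown, collapse = ", "))
  # numeric-vector options may arrive as YAML lists; flatten them
  num_vec <- c("qda_grid", "N_grid", "lambda_grid", "background")
  for (k in intersect(names(overrides), num_vec))
    overrides[[k]] <- as.numeric(unlist(overrides[[k]]))
  analysis[names(overrides)] <- overrides
  cfg <- list(scenario = scenario, genome_fasta = genome_fasta,
              pfm_file = pfm_file, chip_signal_file = chip_signal_file,
              chip_peaks_file = chip_peaks_file,
              access_signal_file = access_signal_file,
              chip_signal_dialect = chip_signal_dialect,
              access_signal_dialect = access_signal_dialect,
              chip_peaks_dialect = chip_peaks_dialect,
              seed = as.integer(seed), dataset = dataset,
              analysis = analysis)
  validate_config(cfg)
  structure(cfg, class = "PipelineConfig")
}

validate_config <- function(cfg) {
  synthetic <- !is.null(cfg$scenario)
  file_inputs <- c("genome_fasta", "pfm_file", "chip_signal_file",
                   "chip_peaks_file", "access_signal_file")
  if (!synthetic) {
    missing_in <- file_inputs[vapply(cfg[file_inputs], is.null, logical(1))]
    if (length(missing_in))
      stop("config schema violation: missing input(s) ",
           paste(missing_in, collapse = ", "))
    absent <- unlist(cfg[file_inputs])[!file.exists(unlist(cfg[file_inputs]))]
    if (length(absent))
      stop("missing input file(s): ", paste(absent, collapse = ", "))
  }
  a <- cfg$analysis
  stopifnot(a$bin_bp >= 1, a$n_train >= 1, a$n_validate >= 1,
            length(a$qda_grid) >= 1, length(a$N_grid) >= 1,
            length(a$lambda_grid) >= 1, a$window_bp >= 1,
            a$bandwidth_bp >= 1)
  invisible(cfg)
}

#' Run the full pipeline from a configuration
#'
#' Stages run in order (synthesize -> scan/fit per QDA -> validate ->
#' classify); a failure aborts with the stage name. With an output
#' directory the AUC row, fitted parameters and classification are
#' written as tab-separated files together with a YAML manifest of every
#' resolved configuration value.
#'
#' @param config a [pipeline_config()].
#' @param outdir optional output directory.
#' @param force overwrite existing outputs.
#' @return The [analyse_dataset()] result (invisibly when writing).
#' @export
run_pipeline <- function(config, outdir = NULL, force = FALSE) {
  stopifnot(inherits(config, "PipelineConfig"))
  validate_config(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  if (!is.null(config$scenario)) {
    ds <- stage("synthesize", generate_dataset(config$scenario))
    genome <- ds$genome; access <- ds$access
    chip <- ds$chip; peaks <- ds$peaks; pfm <- config$scenario$pfm
  } else {
    genome <- stage("read_inputs", read_fasta(config$genome_fasta))
    seq_lengths <- setNames(nchar(genome), names(genome))
    pfm <- stage("read_inputs", read_jaspar_pfm(config$pfm_file))
    chip <- stage("read_inputs",
                  read_signal(config$chip_signal_file,
                              config$chip_signal_dialect, seq_lengths))
    access <- stage("read_inputs",
                    read_signal(config$access_signal_file,
                                config$access_signal_dialect, seq_lengths))
    peaks <- stage("read_inputs",
                   read_intervals(config$chip_peaks_file,
                                  config$chip_peaks_dialect))
  }
  set.seed(config$seed)
  res <- stage("analyse",
               do.call(analyse_dataset,
                       c(list(genome = genome, access_signal = access,
                              chip_signal = chip, peaks = peaks,
                              pfm = pfm, dataset = config$dataset),
                         config$analysis)))
  if (!is.null(outdir)) {
    if (dir.exists(outdir) && length(dir(outdir)) && !force)
      stop("output directory not empty (use force = TRUE): ", outdir)
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_pipeline_outputs(res, config, outdir)
    return(invisible(res))
  }
  res
}

write_pipeline_outputs <- function(res, config, outdir) {
  qda <- config$analysis$qda_grid
  auc_df <- data.frame(dataset = config$dataset,
                       t(setNames(res$auc, format_qda(qda))),
                       check.names = FALSE)
  write_tsv_commented(auc_df, file.path(outdir, "auc_matrix.tsv"),
                      "AUC per QDA value")
  cl <- res$classification
  cls_df <- data.frame(dataset = cl$dataset,
                       mean_dense_auc = cl$mean_dense_auc,
                       mean_open_auc = cl$mean_open_auc,
                       difference = cl$difference, label = cl$label)
  write_tsv_commented(cls_df, file.path(outdir, "classification.tsv"),
                      "TF accessibility-dependence classification")
  fit_rows <- lapply(names(res$fits), function(q) {
    f <- res$fits[[q]]
    if (is.null(f)) return(NULL)
    data.frame(qda = q, N = f$N, lambda = f$lambda,
               mse = if (!is.null(f$mse)) f$mse else NA_real_)
  })
  write_tsv_commented(do.call(rbind, Filter(Negate(is.null), fit_rows)),
                      file.path(outdir, "fitted_parameters.tsv"),
                      "optimal (N, lambda) per QDA value")
  manifest <- list(package_version =
                     as.character(utils::packageVersion("tfoccupancy")),
                   seed = config$seed, dataset = config$dataset,
                   synthetic = !is.null(config$scenario),
                   analysis = config$analysis)
  manifest$analysis$thresholds <-
    config$analysis$thresholds[c("high", "poor", "small", "large")]
  yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))
  invisible(outdir)
}

write_tsv_commented <- function(df, path, comment) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", comment), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
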