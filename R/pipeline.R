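# End-to-end orchestration: generate (or read) -> preprocess -> detect/
# cluster/filter -> screen -> GA+SVM model -> protein matching, with
# per-stage seed fan-out, intermediate artifacts, and a machine-readable
# run report.

#' Pipeline configuration
#'
#' One nested configuration object driving [run_pipeline()]. Every stage
#' block has the defaults of its module constructor.
#'
#' @param seed Master integer seed; per-stage seeds are derived with
#'   [derive_seed()].
#' @param cohort A [cohort_config()] (the synthetic-cohort block). The
#'   cohort's own seed is overridden by the derived stage seed.
#' @param preprocess A [preprocess_config()].
#' @param peaks List with `snr_min`, `noise_window` (Da),
#'   `tolerance_frac`, `prevalence_min`.
#' @param screening List with `alpha` and `p_adjust`.
#' @param classifier A [classifier_spec()].
#' @param ga A [ga_params()].
#' @param tagident List with `tolerance_frac`, `pi_min`, `pi_max`, and
#'   optionally `db_path` (defaults to the packaged peptide-hormone
#'   database).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            cohort = cohort_config(),
                            preprocess = preprocess_config(),
                            peaks = list(snr_min = 3, noise_window = 250,
                                         tolerance_frac = 0.003,
                                         prevalence_min = 0.10),
                            screening = list(alpha = 0.05,
                                             p_adjust = "none"),
                            classifier = classifier_spec(),
                            ga = ga_params(),
                            tagident = list(tolerance_frac = 0.003,
                                            pi_min = 4, pi_max = 14,
                                            db_path = NULL)) {
  structure(list(seed = as.integer(seed), cohort = cohort,
                 preprocess = preprocess, peaks = peaks,
                 screening = screening, classifier = classifier, ga = ga,
                 tagident = tagident),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; omitted keys
#' keep their defaults.
#'
#' @param path A `.yaml`/`.yml` or `.json` file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!length(path) || !nzchar(path) || !file.exists(path))
    stop_config("config file not found: '%s'", paste(path, collapse = ""))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  defaults <- pipeline_config()
  merge_block <- function(ctor, block, current) {
    if (is.null(block)) return(current)
    args <- utils::modifyList(unclass(current), block)
    args <- args[names(args) %in% names(formals(ctor))]
    do.call(ctor, args)
  }
  cfg <- pipeline_config(
    seed = if (!is.null(raw$seed)) raw$seed else defaults$seed,
    cohort = merge_block(cohort_config, raw$cohort, defaults$cohort),
    preprocess = merge_block(preprocess_config, raw$preprocess,
                             defaults$preprocess),
    peaks = utils::modifyList(defaults$peaks, raw$peaks %||% list()),
    screening = utils::modifyList(defaults$screening,
                                  raw$screening %||% list()),
    classifier = merge_block(classifier_spec, raw$classifier,
                             defaults$classifier),
    ga = merge_block(ga_params, raw$ga, defaults$ga),
    tagident = utils::modifyList(defaults$tagident, raw$tagident %||% list())
  )
  cfg
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full biomarker-discovery pipeline
#'
#' Executes generate -> preprocess -> peaks -> screen -> model -> protein
#' matching, writing every intermediate artifact under `out_dir`
#' (per-sample spectra, `labels.csv`, `peak_matrix.csv`, `features.csv`,
#' `scatter.csv`, `report.json`) and returning a run report. Fully
#' reproducible from `(config, seed)`.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param spectra Optional named list of `mass_spectrum` to analyze instead
#'   of generating a synthetic cohort; requires `labels`.
#' @param labels Label data frame when `spectra` is supplied.
#' @param write_artifacts Write intermediate files (default `TRUE`). Turn
#'   off for replication loops where thousands of spectra files would be
#'   produced.
#' @param stop_after `"full"` (default) runs everything; `"screen"` stops
#'   after univariate screening (no model or protein matching), for
#'   screening-stage replication studies.
#' @return An object of class `pipeline_report`: stage record counts,
#'   screening table, model report, protein matches per selected feature,
#'   selected m/z, software version and the config echo.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("run"),
                         spectra = NULL, labels = NULL,
                         write_artifacts = TRUE,
                         stop_after = c("full", "screen")) {
  stop_after <- match.arg(stop_after)
  if (write_artifacts)
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  counts <- list()

  if (is.null(spectra)) {
    cohort <- .stage("generate", {
      cc <- config$cohort
      cc$seed <- derive_seed(config$seed, "generate")
      co <- make_cohort(cc)
      if (write_artifacts) write_cohort(co, file.path(out_dir, "spectra"))
      co
    })
    spectra <- cohort$spectra
    labels <- cohort$labels
    ground_truth <- cohort$ground_truth
  } else {
    if (is.null(labels)) stop_config("labels required with user spectra")
    ground_truth <- NULL
  }
  counts$spectra_in <- length(spectra)

  # Preprocess, carrying a raw-signal noise estimate alongside: the SNR
  # filter is referenced to instrument noise before denoising (the denoised
  # residual would understate it), measured on the baseline-subtracted raw
  # signal and rescaled with the TIC normalization factor.
  pp <- config$preprocess
  prep <- .stage("preprocess", {
    per_sample <- lapply(spectra, function(s) {
      dn <- udwt_denoise(s, levels = pp$levels, threshold = pp$threshold)
      bl <- subtract_baseline(dn, half_window = pp$baseline_half_window)
      raw_resid <- mass_spectrum(s$sample_id, s$mz,
                                 abs(s$intensity - bl$baseline))
      final <- crop_low_mass(bl$spectrum, cutoff = pp$low_mass_cutoff)
      raw_resid <- crop_low_mass(raw_resid, cutoff = pp$low_mass_cutoff)
      list(spectrum = final,
           noise = estimate_noise(raw_resid,
                                  window = config$peaks$noise_window))
    })
    finals <- lapply(per_sample, `[[`, "spectrum")
    noise <- lapply(per_sample, `[[`, "noise")
    if (pp$normalization == "tic") {
      tics <- vapply(finals, tic, numeric(1))
      factors <- mean(tics) / tics
      finals <- normalize_tic(finals)
      noise <- lapply(seq_along(noise), function(i) noise[[i]] * factors[i])
    }
    names(finals) <- vapply(finals, function(s) s$sample_id, character(1))
    names(noise) <- names(finals)
    if (write_artifacts) {
      pdir <- file.path(out_dir, "preprocessed")
      dir.create(pdir, showWarnings = FALSE)
      for (s in finals)
        write_spectrum(s, file.path(pdir, paste0(s$sample_id, ".tsv")))
    }
    list(spectra = finals, noise = noise)
  })

  peaks_by_sample <- .stage("detect_peaks", {
    out <- lapply(names(prep$spectra), function(id)
      detect_peaks(prep$spectra[[id]], snr_min = config$peaks$snr_min,
                   window = config$peaks$noise_window,
                   noise = prep$noise[[id]]))
    names(out) <- names(prep$spectra)
    out
  })
  counts$peaks_detected <- sum(vapply(peaks_by_sample, nrow, integer(1)))

  clusters <- .stage("cluster",
                     cluster_peaks(peaks_by_sample,
                                   tolerance_frac = config$peaks$tolerance_frac))
  counts$clusters <- length(clusters)
  clusters <- .stage("prevalence_filter",
                     prevalence_filter(clusters,
                                       min_frac = config$peaks$prevalence_min))
  counts$clusters_after_prevalence <- length(clusters)

  pm <- .stage("build_matrix", build_matrix(clusters, labels))
  if (write_artifacts)
    write_peak_matrix(pm, file.path(out_dir, "peak_matrix.csv"))

  screened <- .stage("screen",
                     screen_features(pm, alpha = config$screening$alpha,
                                     p_adjust = config$screening$p_adjust))
  counts$features_screened <- nrow(screened)
  if (write_artifacts)
    utils::write.csv(screened, file.path(out_dir, "features.csv"),
                     row.names = FALSE)

  model <- NULL
  if (stop_after == "full" && nrow(screened) >= 1L) {
    model <- .stage("model", {
      rows <- match(screened$mz, pm$mz)
      x <- t(pm$intensity[rows, , drop = FALSE])
      colnames(x) <- sprintf("%.2f", screened$mz)
      rownames(x) <- colnames(pm$intensity)
      ga <- config$ga
      ga$seed <- derive_seed(config$seed, "model")
      ga_svm(x, pm$labels$group, spec = config$classifier, ga = ga)
    })
    if (write_artifacts)
      utils::write.csv(model$final$scatter, file.path(out_dir, "scatter.csv"),
                       row.names = FALSE)
  }

  matches <- NULL
  if (!is.null(model)) {
    matches <- .stage("tagident", {
      db <- if (!is.null(config$tagident$db_path))
        read_protein_db(config$tagident$db_path) else tagident_db()
      out <- lapply(model$selected_mz, function(mz)
        match_proteins(db, mz,
                       tolerance_frac = config$tagident$tolerance_frac,
                       pi_min = config$tagident$pi_min,
                       pi_max = config$tagident$pi_max))
      names(out) <- sprintf("%.2f", model$selected_mz)
      out
    })
  }

  report <- structure(list(
    counts = counts,
    screened = screened,
    selected_mz = if (!is.null(model)) model$selected_mz else numeric(),
    model = if (!is.null(model)) list(
      accuracy = model$report$accuracy,
      sensitivity = model$report$sensitivity,
      specificity = model$report$specificity,
      youden_j = model$report$youden_j,
      confusion = list(tp = model$report$tp, fn = model$report$fn,
                       tn = model$report$tn, fp = model$report$fp),
      fitness = model$fitness),
    tagident = if (!is.null(matches))
      lapply(matches, function(m)
        if (nrow(m)) m[, c("accession", "name", "mw", "pi", "delta_mw")]
        else NULL),
    version = as.character(utils::packageVersion("maldiscreen")),
    seed = config$seed,
    out_dir = out_dir,
    ground_truth = ground_truth
  ), class = "pipeline_report")
  attr(report, "model") <- model

  if (write_artifacts) {
    json <- report
    json$ground_truth <- NULL
    json$out_dir <- NULL  # report JSON must be identical across output paths
    jsonlite::write_json(unclass(json), file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Serum peptidome biomarker-discovery run\n")
  cat(sprintf("  spectra in:                 %d\n", x$counts$spectra_in))
  cat(sprintf("  peaks detected (all samples): %d\n", x$counts$peaks_detected))
  cat(sprintf("  clusters (pre/post prevalence): %d / %d\n",
              x$counts$clusters, x$counts$clusters_after_prevalence))
  cat(sprintf("  features past screening:    %d\n", x$counts$features_screened))
  if (length(x$selected_mz)) {
    cat(sprintf("  selected m/z:               %s\n",
                paste(sprintf("%.1f", x$selected_mz), collapse = ", ")))
    cat(sprintf("  LOOCV accuracy/sens/spec:   %.2f / %.2f / %.2f\n",
                x$model$accuracy, x$model$sensitivity, x$model$specificity))
    for (nm in names(x$tagident)) {
      m <- x$tagident[[nm]]
      hit <- if (is.null(m) || !nrow(m)) "no database match"
             else sprintf("%s (%s, Mw %.1f, pI %.2f)",
                          m$name[1L], m$accession[1L], m$mw[1L], m$pi[1L])
      cat(sprintf("  m/z %s -> %s\n", nm, hit))
    }
  } else cat("  no features passed screening; model stage skipped\n")
  invisible(x)
}
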