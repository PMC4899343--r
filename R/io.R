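# On-disk formats: two-column TSV spectra (mz <TAB> intensity, no header),
# labels.csv (sample_id,group), peak_matrix.csv (rows = clusters keyed by
# representative m/z, columns = samples), proteins.tsv. Decimal point only,
# UTF-8. Round trips are lossless to 6 significant digits.

#' Read a spectrum from a two-column text file
#'
#' Expects two numeric whitespace- or tab-separated columns (m/z,
#' intensity), no header. The sample id is the file name without extension.
#'
#' @param path File path.
#' @return A `mass_spectrum`.
#' @export
read_spectrum <- function(path) {
  if (!file.exists(path)) stop_config("no such file: %s", path)
  dat <- tryCatch(
    utils::read.table(path, header = FALSE,
                      colClasses = c("numeric", "numeric")),
    error = function(e)
      stop_config("parse error in '%s': %s", path, conditionMessage(e)))
  if (ncol(dat) < 2L)
    stop_config("'%s': expected two columns (mz, intensity)", path)
  mz <- dat[[1L]]
  bad <- which(diff(mz) <= 0)
  if (length(bad))
    stop_config("'%s': m/z not strictly ascending at line %d", path,
                bad[1L] + 1L)
  mass_spectrum(tools::file_path_sans_ext(basename(path)), mz, dat[[2L]])
}

#' Write a spectrum as two-column TSV
#'
#' @param spectrum A `mass_spectrum`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  writeLines(sprintf("%.8g\t%.8g", spectrum$mz, spectrum$intensity), path)
  invisible(path)
}

#' Read a multi-sample wide CSV of spectra
#'
#' First column `mz`, one intensity column per sample (header row gives the
#' sample ids).
#'
#' @param path File path.
#' @return A named list of `mass_spectrum`.
#' @export
read_spectra_wide <- function(path) {
  dat <- utils::read.csv(path, check.names = FALSE)
  if (ncol(dat) < 2L) stop_config("'%s': need mz plus >= 1 sample column", path)
  mz <- dat[[1L]]
  out <- lapply(names(dat)[-1L], function(id)
    mass_spectrum(id, mz, dat[[id]]))
  names(out) <- names(dat)[-1L]
  out
}

#' Read a sample label table
#'
#' CSV with header columns `sample_id` and `group`; groups must be `case`
#' or `control`; duplicate sample ids are an error.
#'
#' @param path File path.
#' @return A data frame with columns `sample_id`, `group`.
#' @export
read_labels <- function(path) {
  dat <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "group")
  miss <- setdiff(need, names(dat))
  if (length(miss))
    stop_config("'%s': missing required column(s): %s", path,
                paste(miss, collapse = ", "))
  dup <- dat$sample_id[duplicated(dat$sample_id)]
  if (length(dup))
    stop_config("'%s': duplicate sample id '%s'", path, dup[1L])
  bad <- setdiff(unique(dat$group), c("case", "control"))
  if (length(bad))
    stop_config("'%s': group must be 'case' or 'control' (found '%s')",
                path, bad[1L])
  dat[need]
}

#' Write a sample label table
#' @param labels Data frame with `sample_id`, `group`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  utils::write.csv(labels[c("sample_id", "group")], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Write a peak matrix as CSV
#'
#' Rows are clusters keyed by representative m/z (2 decimals), columns are
#' samples.
#'
#' @param pm A `peak_matrix` (see [build_matrix()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peak_matrix <- function(pm, path) {
  out <- data.frame(mz = sprintf("%.2f", pm$mz),
                    as.data.frame(pm$intensity, check.names = FALSE),
                    check.names = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a peak matrix written by [write_peak_matrix()]
#'
#' @param path File path.
#' @param labels Optional label data frame (`sample_id`, `group`) to attach.
#' @return A `peak_matrix`.
#' @export
read_peak_matrix <- function(path, labels = NULL) {
  dat <- utils::read.csv(path, check.names = FALSE)
  if (!"mz" %in% names(dat)) stop_config("'%s': missing 'mz' column", path)
  mz <- as.numeric(dat$mz)
  m <- as.matrix(dat[setdiff(names(dat), "mz")])
  if (is.null(labels))
    labels <- data.frame(sample_id = colnames(m),
                         group = NA_character_, stringsAsFactors = FALSE)
  peak_matrix(m, mz, labels)
}

#' Read a candidate-protein database
#'
#' Tab-separated with a header; required columns `accession`, `name`, `mw`
#' (average molecular weight, Da) and `pi`; optional `sequence`
#' (one-letter codes).
#'
#' @param path File path.
#' @return A data frame of protein records.
#' @export
#' @examples
#' db <- read_protein_db(system.file("extdata", "peptide_hormones.tsv",
#'                                   package = "maldiscreen"))
#' nrow(db)
read_protein_db <- function(path) {
  dat <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("accession", "name", "mw", "pi")
  miss <- setdiff(need, names(dat))
  if (length(miss))
    stop_config("'%s': missing required column(s): %s", path,
                paste(miss, collapse = ", "))
  if (nrow(dat)) {
    if (any(dat$mw <= 0)) stop_config("'%s': mw must be > 0", path)
    if (any(dat$pi <= 0 | dat$pi >= 14)) stop_config("'%s': pi must be in (0, 14)", path)
  }
  if (!"sequence" %in% names(dat))
    dat$sequence <- rep(NA_character_, nrow(dat))
  dat[c(need, "sequence")]
}

#' The packaged peptide-hormone fixture database
#'
#' A constructed database of human peptide hormones (average Mw and pI from
#' the literature) used to emulate a protein-identification lookup. The
#' secretin row carries the published record values (Mw 3040 Da, pI 9.46);
#' its sequence field holds the mature-chain residues (UniProt P09683,
#' 28-54), included only as an external-sourced cross-check.
#'
#' @return A protein record data frame (see [read_protein_db()]).
#' @export
tagident_db <- function() {
  read_protein_db(system.file("extdata", "peptide_hormones.tsv",
                              package = "maldiscreen"))
}

#' Write a synthetic cohort to disk
#'
#' One two-column TSV per sample, plus `labels.csv` and
#' `ground_truth.json`.
#'
#' @param cohort A `synthetic_cohort` (see [make_cohort()]).
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in cohort$spectra)
    write_spectrum(s, file.path(dir, paste0(s$sample_id, ".tsv")))
  write_labels(cohort$labels, file.path(dir, "labels.csv"))
  jsonlite::write_json(cohort$ground_truth,
                       file.path(dir, "ground_truth.json"),
                       digits = NA)
  invisible(dir)
}
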