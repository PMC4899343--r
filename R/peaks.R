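# Peak detection, cross-sample clustering at fractional m/z tolerance,
# prevalence filtering, and feature-matrix assembly.

#' Estimate the local noise level of a spectrum
#'
#' Rolling robust scale estimate: MAD/0.6745 of the signal within a
#' +/- `window` (Da) neighbourhood of each point, median-centred (which
#' removes the local trend). Evaluated on a stride and interpolated; the
#' median makes the estimate robust to peaks occupying a minority of the
#' window.
#'
#' @param spectrum A `mass_spectrum`.
#' @param window Half-width of the noise window in Da; must be smaller than
#'   the m/z span.
#' @return Numeric vector of per-point noise levels.
#' @export
estimate_noise <- function(spectrum, window = 250) {
  if (window <= 0) stop_config("noise window must be > 0")
  span <- diff(range(spectrum$mz))
  if (window >= span) stop_config("noise window (%.0f Da) >= m/z span (%.0f Da)",
                                  window, span)
  step <- spectrum$mz[2L] - spectrum$mz[1L]
  h <- max(2L, as.integer(round(window / step)))
  rolling_mad(spectrum$intensity, h)
}

#' Detect peaks in a preprocessed spectrum
#'
#' Peak apexes are strict local maxima of the (denoised,
#' baseline-subtracted) intensity; each apex's signal-to-noise ratio is its
#' height divided by the local noise level, and apexes with SNR below
#' `snr_min` are discarded.
#'
#' @param spectrum A preprocessed `mass_spectrum`.
#' @param snr_min Minimum signal-to-noise ratio (default 3).
#' @param window Noise-estimation window (Da), see [estimate_noise()].
#' @param noise Optional per-point noise vector overriding the internal
#'   estimate. Denoising removes most of the very noise the SNR should be
#'   referenced to, so pipelines pass the noise level of the raw
#'   (pre-denoise, baseline-subtracted) signal here.
#' @return A data frame with columns `mz`, `intensity`, `snr`, sorted by
#'   m/z. Zero rows if nothing passes.
#' @export
detect_peaks <- function(spectrum, snr_min = 3, window = 250, noise = NULL) {
  x <- spectrum$intensity
  n <- length(x)
  if (n < 3L)
    return(data.frame(mz = numeric(), intensity = numeric(), snr = numeric()))
  core <- 2:(n - 1L)
  apex <- core[x[core] > x[core - 1L] & x[core] > x[core + 1L] & x[core] > 0]
  if (!length(apex))
    return(data.frame(mz = numeric(), intensity = numeric(), snr = numeric()))
  if (is.null(noise)) noise <- estimate_noise(spectrum, window = window)
  else if (length(noise) != n)
    stop_config("noise vector length (%d) != spectrum length (%d)",
                length(noise), n)
  snr <- x[apex] / pmax(noise[apex], .Machine$double.eps)
  keep <- snr >= snr_min
  data.frame(mz = spectrum$mz[apex][keep], intensity = x[apex][keep],
             snr = snr[keep])
}

#' Cluster peaks across samples at a fractional m/z tolerance
#'
#' Greedy single-linkage over the pooled, m/z-sorted peak list: a peak
#' joins the currently open cluster iff its distance to the cluster's
#' running representative m/z (intensity-weighted mean of the members) is
#' below `tolerance_frac` times that representative, and otherwise starts a
#' new cluster. Anchoring the tolerance at the representative rather than
#' the nearest member prevents single-linkage chaining: a run of closely
#' spaced artifact apexes cannot bridge two genuine features. At most one
#' member per sample is allowed: on a conflict the more intense peak stays
#' and the displaced one becomes its own singleton cluster (typically
#' eliminated later by the prevalence filter). Deterministic and
#' order-independent in the sample ordering.
#'
#' @param peaks_by_sample Named list (by sample id) of peak data frames as
#'   returned by [detect_peaks()].
#' @param tolerance_frac Fractional m/z tolerance (default 0.003 = 0.3%).
#' @return An object of class `peak_clusters`: a list of clusters sorted by
#'   representative m/z, each with `representative_mz`, `members` (data
#'   frame `sample_id`, `mz`, `intensity`, `snr`) and `prevalence`; the
#'   cohort size is attached as attribute `"n_samples"`.
#' @export
cluster_peaks <- function(peaks_by_sample, tolerance_frac = 0.003) {
  if (tolerance_frac <= 0) stop_config("tolerance_frac must be > 0")
  n_samples <- length(peaks_by_sample)
  ids <- names(peaks_by_sample)
  if (is.null(ids)) ids <- as.character(seq_len(n_samples))
  pooled <- do.call(rbind, lapply(seq_along(peaks_by_sample), function(i) {
    p <- peaks_by_sample[[i]]
    if (is.null(p) || nrow(p) == 0L) return(NULL)
    data.frame(sample_id = ids[i], mz = p$mz, intensity = p$intensity,
               snr = if ("snr" %in% names(p)) p$snr else NA_real_,
               stringsAsFactors = FALSE)
  }))
  finished <- list()
  if (!is.null(pooled) && nrow(pooled)) {
    pooled <- pooled[order(pooled$mz, pooled$sample_id), , drop = FALSE]
    rownames(pooled) <- NULL
    n <- nrow(pooled)
    # open cluster state: member row indices into `pooled`
    open <- integer(0)
    rep_mz <- NA_real_
    recompute_rep <- function(idx) {
      w <- pooled$intensity[idx]
      if (sum(w) <= 0) w <- rep(1, length(idx))
      sum(pooled$mz[idx] * w) / sum(w)
    }
    close_open <- function() {
      if (length(open)) {
        m <- pooled[open, , drop = FALSE]
        m <- m[order(m$mz), , drop = FALSE]
        rownames(m) <- NULL
        finished[[length(finished) + 1L]] <<-
          list(representative_mz = rep_mz, members = m,
               prevalence = nrow(m) / n_samples)
      }
      open <<- integer(0); rep_mz <<- NA_real_
    }
    singleton <- function(i) {
      m <- pooled[i, , drop = FALSE]
      rownames(m) <- NULL
      finished[[length(finished) + 1L]] <<-
        list(representative_mz = m$mz, members = m,
             prevalence = 1 / n_samples)
    }
    for (i in seq_len(n)) {
      if (!length(open)) {
        open <- i; rep_mz <- pooled$mz[i]
        next
      }
      if (pooled$mz[i] - rep_mz < tolerance_frac * rep_mz) {
        dup <- open[pooled$sample_id[open] == pooled$sample_id[i]]
        if (length(dup)) {
          if (pooled$intensity[i] > pooled$intensity[dup]) {
            open <- c(setdiff(open, dup), i)
            singleton(dup)
          } else singleton(i)
        } else open <- c(open, i)
        rep_mz <- recompute_rep(open)
      } else {
        close_open()
        open <- i; rep_mz <- pooled$mz[i]
      }
    }
    close_open()
    finished <- finished[order(vapply(finished, `[[`, numeric(1),
                                      "representative_mz"))]
  }
  structure(finished, class = "peak_clusters", n_samples = n_samples)
}

#' @export
print.peak_clusters <- function(x, ...) {
  cat(sprintf("<peak_clusters: %d clusters over %d samples>\n",
              length(x), attr(x, "n_samples")))
  invisible(x)
}

#' Remove rare peak clusters
#'
#' Keeps a cluster when its prevalence (fraction of samples contributing a
#' member) is at least `min_frac`. The boundary is kept: the removal rule
#' is "present in fewer than 10% of samples", so exactly 10% survives.
#'
#' @param clusters A `peak_clusters` object.
#' @param min_frac Minimum prevalence fraction (default 0.10).
#' @return The filtered `peak_clusters`.
#' @export
prevalence_filter <- function(clusters, min_frac = 0.10) {
  if (min_frac <= 0 || min_frac > 1) stop_config("min_frac must be in (0, 1]")
  keep <- vapply(clusters, function(cl) cl$prevalence >= min_frac, logical(1))
  structure(unclass(clusters)[keep], class = "peak_clusters",
            n_samples = attr(clusters, "n_samples"))
}

#' Construct a peak matrix
#'
#' @param intensity Clusters x samples numeric matrix.
#' @param mz Representative m/z per row.
#' @param labels Label data frame (`sample_id`, `group`) covering the
#'   columns.
#' @return An object of class `peak_matrix`.
#' @export
peak_matrix <- function(intensity, mz, labels) {
  if (nrow(intensity) != length(mz))
    stop_config("row count (%d) != number of representative m/z (%d)",
                nrow(intensity), length(mz))
  if (is.null(colnames(intensity)))
    stop_config("intensity matrix must carry sample ids as column names")
  if (!all(colnames(intensity) %in% labels$sample_id))
    stop_config("labels do not cover all samples")
  structure(list(intensity = intensity, mz = mz,
                 labels = labels[match(colnames(intensity),
                                       labels$sample_id), , drop = FALSE]),
            class = "peak_matrix")
}

#' @export
print.peak_matrix <- function(x, ...) {
  cat(sprintf("<peak_matrix: %d clusters x %d samples (%d case / %d control)>\n",
              nrow(x$intensity), ncol(x$intensity),
              sum(x$labels$group == "case"),
              sum(x$labels$group == "control")))
  invisible(x)
}

#' Build the clusters-by-samples feature matrix
#'
#' Absent members contribute intensity 0; rows are sorted by representative
#' m/z.
#'
#' @param clusters A `peak_clusters` object.
#' @param labels Label data frame (`sample_id`, `group`).
#' @return A `peak_matrix`.
#' @export
build_matrix <- function(clusters, labels) {
  if (length(clusters) == 0L) stop_config("no clusters to build a matrix from")
  ids <- labels$sample_id
  unknown <- setdiff(
    unique(unlist(lapply(clusters, function(cl) cl$members$sample_id))), ids)
  if (length(unknown))
    stop_config("cluster member sample id '%s' not in the label table",
                unknown[1L])
  mz <- vapply(clusters, `[[`, numeric(1), "representative_mz")
  ord <- order(mz)
  m <- matrix(0, nrow = length(clusters), ncol = length(ids),
              dimnames = list(NULL, ids))
  for (i in seq_along(clusters)) {
    mem <- clusters[[ord[i]]]$members
    m[i, mem$sample_id] <- mem$intensity
  }
  peak_matrix(m, mz[ord], labels)
}
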