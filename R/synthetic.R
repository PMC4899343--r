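# Synthetic serum-peptidome cohort generator. Emulates the statistical
# structure the downstream analysis assumes: ~133 Gaussian peaks on a
# 1000-20000 Da grid, an exponentially decaying chemical baseline, additive
# detector noise, and two discriminating peaks (1699 Da up in cases, 3038 Da
# down in cases) whose per-sample apex amplitudes follow the published
# group means/SDs.

#' Published group parameters of the two discriminating peaks
#'
#' Per-sample apex-amplitude means and standard deviations of the two
#' discriminating serum peptide peaks: 1699 Da (higher in osteopenia cases)
#' and 3038 Da (lower in cases, later attributed to secretin).
#'
#' @return A data frame with columns `mz`, `mean_case`, `sd_case`,
#'   `mean_control`, `sd_control`.
#' @export
#' @examples
#' discriminating_peaks()
discriminating_peaks <- function() {
  data.frame(
    mz           = c(1699, 3038),
    mean_case    = c(299.04, 383.78),
    sd_case      = c(140.72, 332.46),
    mean_control = c(164.32, 649.97),
    sd_control   = c(105.04, 236.04)
  )
}

#' Cohort generator configuration
#'
#' Defaults describe the study conditions the pipeline was designed around:
#' 10 cases + 10 controls, 133 true peaks between 1000 and 20000 Da, the two
#' discriminating peaks of [discriminating_peaks()], a decaying baseline and
#' additive Gaussian noise. Peak shape is Gaussian with width (sigma)
#' `mz / 2000` — a crude constant-resolution model. Non-discriminating peak
#' base amplitudes are drawn once per cohort (lognormal), shared across
#' groups, with multiplicative per-sample lognormal jitter.
#'
#' @param n_case,n_control Samples per group (each >= 2).
#' @param n_peaks_total Total true peaks including discriminating ones.
#' @param discriminating Data frame as from [discriminating_peaks()].
#' @param baseline_amplitude,baseline_decay Exponential baseline
#'   `A * exp(-decay * (mz - grid_start))`; decay in 1/Da.
#' @param noise_sd Additive Gaussian noise SD (intensity units).
#' @param grid_start,grid_end,grid_step m/z grid (Da).
#' @param amp_meanlog,amp_sdlog Lognormal parameters of null-peak base
#'   amplitudes.
#' @param jitter_sdlog Per-sample lognormal jitter SD (log scale) of
#'   null-peak amplitudes.
#' @param width_divisor Peak sigma = mz / width_divisor.
#' @param seed Integer seed.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_case = 10L, n_control = 10L,
                          n_peaks_total = 133L,
                          discriminating = discriminating_peaks(),
                          baseline_amplitude = 100, baseline_decay = 5e-4,
                          noise_sd = 5,
                          grid_start = 1000, grid_end = 20000,
                          grid_step = 0.5,
                          amp_meanlog = log(200), amp_sdlog = 0.5,
                          jitter_sdlog = 0.25,
                          width_divisor = 2000,
                          seed = 1L) {
  cfg <- list(n_case = as.integer(n_case), n_control = as.integer(n_control),
              n_peaks_total = as.integer(n_peaks_total),
              discriminating = discriminating,
              baseline_amplitude = baseline_amplitude,
              baseline_decay = baseline_decay, noise_sd = noise_sd,
              grid_start = grid_start, grid_end = grid_end,
              grid_step = grid_step,
              amp_meanlog = amp_meanlog, amp_sdlog = amp_sdlog,
              jitter_sdlog = jitter_sdlog, width_divisor = width_divisor,
              seed = as.integer(seed))
  if (cfg$n_case < 2L || cfg$n_control < 2L)
    stop_config("n_case and n_control must both be >= 2")
  if (!is.null(cfg$discriminating) && nrow(cfg$discriminating) > cfg$n_peaks_total)
    stop_config("n_peaks_total smaller than the number of discriminating peaks")
  if (cfg$grid_start >= cfg$grid_end) stop_config("grid_start must be < grid_end")
  if (cfg$grid_step <= 0) stop_config("grid_step must be > 0")
  if (cfg$noise_sd < 0) stop_config("noise_sd must be >= 0")
  if (!is.null(cfg$discriminating)) {
    d <- cfg$discriminating
    if (any(d$sd_case < 0) || any(d$sd_control < 0))
      stop_config("discriminating peak SDs must be >= 0")
    if (any(d$mz < cfg$grid_start | d$mz > cfg$grid_end))
      stop_config("discriminating peak m/z outside the grid range")
  }
  class(cfg) <- "cohort_config"
  cfg
}

# Adds Gaussian peaks to an intensity vector, evaluating each only within
# +/- 6 sigma of its centre (grids are large; full outer products are not).
#' @noRd
.add_peaks <- function(intensity, grid, mz, amplitude, width) {
  for (i in seq_along(mz)) {
    if (amplitude[i] <= 0) next
    lo <- findInterval(mz[i] - 6 * width[i], grid) + 1L
    hi <- findInterval(mz[i] + 6 * width[i], grid)
    if (hi < lo) next
    seg <- lo:hi
    intensity[seg] <- intensity[seg] +
      amplitude[i] * exp(-(grid[seg] - mz[i])^2 / (2 * width[i]^2))
  }
  intensity
}

#' Synthesize a single mass spectrum
#'
#' Builds one spectrum as a sum of Gaussian peaks, an exponentially decaying
#' baseline, and additive Gaussian noise, clipped at zero (intensities are
#' physical).
#'
#' @param peaks Data frame with columns `mz`, `amplitude`, `width`
#'   (Gaussian sigma, Da). May have zero rows.
#' @param baseline_amplitude,baseline_decay Baseline parameters (see
#'   [cohort_config()]).
#' @param noise_sd Gaussian noise SD (>= 0).
#' @param grid Ascending, uniformly spaced m/z vector.
#' @param seed Optional integer seed; if `NULL` the current RNG stream is
#'   used.
#' @param sample_id Sample identifier.
#' @param clip Clip negative intensities at zero (default `TRUE`).
#' @return A `mass_spectrum`.
#' @export
#' @examples
#' g <- seq(1000, 5000, by = 1)
#' s <- make_spectrum(data.frame(mz = 3038, amplitude = 100, width = 3),
#'                    grid = g, seed = 1)
#' g[which.max(s$intensity)]
make_spectrum <- function(peaks = data.frame(mz = numeric(), amplitude = numeric(),
                                             width = numeric()),
                          baseline_amplitude = 0, baseline_decay = 0,
                          noise_sd = 0, grid, seed = NULL,
                          sample_id = "sample", clip = TRUE) {
  if (missing(grid) || length(grid) == 0L) stop_config("empty m/z grid")
  if (noise_sd < 0) stop_config("noise_sd must be >= 0")
  steps <- diff(grid)
  if (any(steps <= 0)) stop_config("grid must be ascending")
  if (length(steps) > 1L && diff(range(steps)) > 1e-8 * steps[1L])
    stop_config("grid must be uniformly spaced")
  if (nrow(peaks)) {
    if (any(peaks$amplitude < 0)) stop_config("peak amplitudes must be >= 0")
    if (any(peaks$width <= 0)) stop_config("peak widths must be > 0")
  }
  if (!is.null(seed)) set.seed(seed)
  intensity <- numeric(length(grid))
  if (nrow(peaks))
    intensity <- .add_peaks(intensity, grid, peaks$mz, peaks$amplitude,
                            peaks$width)
  if (baseline_amplitude != 0)
    intensity <- intensity +
      baseline_amplitude * exp(-baseline_decay * (grid - grid[1L]))
  if (noise_sd > 0)
    intensity <- intensity + stats::rnorm(length(grid), 0, noise_sd)
  if (clip) intensity <- pmax(intensity, 0)
  mass_spectrum(sample_id, grid, intensity)
}

#' Generate a synthetic two-group cohort of spectra
#'
#' Draws null-peak positions and base amplitudes once per cohort, then
#' synthesizes each sample's spectrum: null peaks get multiplicative
#' lognormal jitter (shared biology, individual variation); discriminating
#' peaks get per-sample amplitudes drawn from their group-specific normal
#' distributions, clipped at zero. Fully deterministic given the config
#' seed.
#'
#' @param config A [cohort_config()].
#' @return A list of class `synthetic_cohort` with elements `spectra` (list
#'   of `mass_spectrum`), `labels` (data frame `sample_id`, `group`), and
#'   `ground_truth` (data frame of every true peak: `mz`, `width`,
#'   `discriminating`, `direction`, `base_amplitude`; the per-sample
#'   amplitude matrix is attached as attribute `"amplitudes"`).
#' @export
#' @examples
#' co <- make_cohort(cohort_config(n_peaks_total = 5, grid_end = 5000,
#'                                 seed = 7))
#' co$labels$group
make_cohort <- function(config = cohort_config()) {
  if (!inherits(config, "cohort_config")) config <- do.call(cohort_config, config)
  set.seed(config$seed)
  grid <- seq(config$grid_start, config$grid_end, by = config$grid_step)
  disc <- config$discriminating
  n_disc <- if (is.null(disc)) 0L else nrow(disc)
  n_null <- config$n_peaks_total - n_disc

  # Null peak positions: uniform over the grid interior, rejected until at
  # least 0.8% of m/z from every previously placed peak so that features
  # stay resolvable by the 0.3% clustering tolerance.
  margin <- 50
  placed <- if (n_disc) disc$mz else numeric()
  null_mz <- numeric(0)
  tries <- 0L
  while (length(null_mz) < n_null) {
    cand <- stats::runif(1, config$grid_start + margin, config$grid_end - margin)
    if (all(abs(placed - cand) > 0.008 * pmin(placed, cand))) {
      null_mz <- c(null_mz, cand)
      placed <- c(placed, cand)
    }
    tries <- tries + 1L
    if (tries > 1e5) stop_config("could not place %d separated peaks", n_null)
  }
  null_mz <- sort(null_mz)
  base_amp <- stats::rlnorm(n_null, config$amp_meanlog, config$amp_sdlog)

  all_mz <- c(if (n_disc) disc$mz else numeric(), null_mz)
  widths <- all_mz / config$width_divisor
  direction <- rep(NA_character_, length(all_mz))
  if (n_disc)
    direction[seq_len(n_disc)] <-
      ifelse(disc$mean_case > disc$mean_control, "up", "down")

  labels <- data.frame(
    sample_id = c(sprintf("case_%02d", seq_len(config$n_case)),
                  sprintf("control_%02d", seq_len(config$n_control))),
    group = c(rep("case", config$n_case), rep("control", config$n_control)),
    stringsAsFactors = FALSE
  )

  amp_matrix <- matrix(0, nrow = length(all_mz), ncol = nrow(labels),
                       dimnames = list(NULL, labels$sample_id))
  spectra <- vector("list", nrow(labels))
  for (s in seq_len(nrow(labels))) {
    grp <- labels$group[s]
    amps <- numeric(length(all_mz))
    if (n_disc) {
      mu <- if (grp == "case") disc$mean_case else disc$mean_control
      sg <- if (grp == "case") disc$sd_case else disc$sd_control
      amps[seq_len(n_disc)] <- pmax(0, stats::rnorm(n_disc, mu, sg))
    }
    if (n_null)
      amps[n_disc + seq_len(n_null)] <-
        base_amp * stats::rlnorm(n_null, 0, config$jitter_sdlog)
    amp_matrix[, s] <- amps
    spectra[[s]] <- make_spectrum(
      data.frame(mz = all_mz, amplitude = amps, width = widths),
      baseline_amplitude = config$baseline_amplitude,
      baseline_decay = config$baseline_decay,
      noise_sd = config$noise_sd, grid = grid, seed = NULL,
      sample_id = labels$sample_id[s]
    )
  }

  ground_truth <- data.frame(
    mz = all_mz, width = widths,
    discriminating = c(rep(TRUE, n_disc), rep(FALSE, n_null)),
    direction = direction,
    base_amplitude = c(if (n_disc) rep(NA_real_, n_disc) else numeric(),
                       base_amp)
  )
  attr(ground_truth, "amplitudes") <- amp_matrix

  structure(list(spectra = spectra, labels = labels,
                 ground_truth = ground_truth, config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort: %d case + %d control, %d true peaks, grid %.0f-%.0f Da>\n",
              sum(x$labels$group == "case"), sum(x$labels$group == "control"),
              nrow(x$ground_truth), x$config$grid_start, x$config$grid_end))
  invisible(x)
}

#' ELISA validation cohort configuration
#'
#' Defaults are the published secretin ELISA validation parameters:
#' osteopenia cases 157.41 +/- 82.62 pg/mL, normal bone mass controls
#' 307.48 +/- 74.68 pg/mL, 40 per group.
#'
#' @param mean_case,sd_case,mean_control,sd_control Group mean/SD (pg/mL).
#' @param n_case,n_control Group sizes (>= 2).
#' @param seed Integer seed.
#' @return A list of class `elisa_config`.
#' @export
elisa_config <- function(mean_case = 157.41, sd_case = 82.62,
                         mean_control = 307.48, sd_control = 74.68,
                         n_case = 40L, n_control = 40L, seed = 1L) {
  if (sd_case < 0 || sd_control < 0) stop_config("SDs must be >= 0")
  if (n_case < 2L || n_control < 2L) stop_config("group sizes must be >= 2")
  structure(list(mean_case = mean_case, sd_case = sd_case,
                 mean_control = mean_control, sd_control = sd_control,
                 n_case = as.integer(n_case), n_control = as.integer(n_control),
                 seed = as.integer(seed)),
            class = "elisa_config")
}

#' Generate synthetic ELISA concentrations for two groups
#'
#' Normal draws per group, clipped at zero (concentrations are physical).
#'
#' @param config An [elisa_config()].
#' @return A list with numeric vectors `case` and `control` (pg/mL).
#' @export
#' @examples
#' e <- make_elisa_cohort(elisa_config(seed = 3))
#' sapply(e, mean)
make_elisa_cohort <- function(config = elisa_config()) {
  if (!inherits(config, "elisa_config")) config <- do.call(elisa_config, config)
  set.seed(config$seed)
  list(case = pmax(0, stats::rnorm(config$n_case, config$mean_case,
                                   config$sd_case)),
       control = pmax(0, stats::rnorm(config$n_control, config$mean_control,
                                      config$sd_control)))
}

#' Demographic summary parameters of the discovery and validation cohorts
#'
#' Published clinical-feature summaries (mean, SD, n per group) for age
#' (years), weight (kg), height (cm) and duration of menopause (years), for
#' the n=10+10 discovery cohort and the n=40+40 ELISA validation cohort.
#'
#' @param study `"discovery"` (n = 10 per group) or `"validation"`
#'   (n = 40 per group).
#' @return A data frame with columns `variable`, `mean_case`, `sd_case`,
#'   `mean_control`, `sd_control`, `n_case`, `n_control`.
#' @export
demographics_config <- function(study = c("discovery", "validation")) {
  study <- match.arg(study)
  vars <- c("age", "weight", "height", "menopause_duration")
  if (study == "discovery") {
    out <- data.frame(
      variable = vars,
      mean_case = c(56.32, 53.16, 160.50, 5.26),
      sd_case = c(3.61, 5.36, 10.53, 2.61),
      mean_control = c(55.00, 52.24, 161.48, 4.76),
      sd_control = c(3.48, 3.97, 11.00, 1.57),
      n_case = 10L, n_control = 10L
    )
  } else {
    out <- data.frame(
      variable = vars,
      mean_case = c(56.56, 54.09, 161.43, 5.34),
      sd_case = c(3.78, 4.98, 10.29, 2.56),
      mean_control = c(56.10, 53.29, 162.52, 4.95),
      sd_control = c(3.50, 3.85, 10.58, 1.63),
      n_case = 40L, n_control = 40L
    )
  }
  out
}

#' Generate per-subject demographic covariates
#'
#' Draws per-subject values from the group summaries of
#' [demographics_config()]. The covariates are descriptive only; they do not
#' influence the spectra.
#'
#' @param config Output of [demographics_config()].
#' @param seed Integer seed.
#' @return A data frame with one row per subject: `sample_id`, `group`, and
#'   one column per variable.
#' @export
make_demographics <- function(config = demographics_config(), seed = 1L) {
  set.seed(seed)
  n_case <- config$n_case[1L]; n_control <- config$n_control[1L]
  out <- data.frame(
    sample_id = c(sprintf("case_%02d", seq_len(n_case)),
                  sprintf("control_%02d", seq_len(n_control))),
    group = c(rep("case", n_case), rep("control", n_control)),
    stringsAsFactors = FALSE
  )
  for (i in seq_len(nrow(config))) {
    v <- config$variable[i]
    out[[v]] <- pmax(0, c(
      stats::rnorm(n_case, config$mean_case[i], config$sd_case[i]),
      stats::rnorm(n_control, config$mean_control[i], config$sd_control[i])
    ))
  }
  out
}

#' Classify bone mineral density by T-score
#'
#' T-score = (measured BMD - young-adult peak mean) / young-adult reference
#' SD. Following WHO convention: `normal` for T > -1, `osteopenia` for
#' -2.5 < T <= -1, `osteoporosis` for T <= -2.5.
#'
#' @param measured_bmd Measured bone mineral density (vectorized).
#' @param peak_bone_mass_mean Young-adult peak bone mass mean, same units.
#' @param reference_sd Young-adult reference SD (> 0).
#' @return A data frame with columns `t_score` and `category`.
#' @export
#' @examples
#' t_score_label(c(1.0, 0.85, 0.6), 1.0, 0.1)
t_score_label <- function(measured_bmd, peak_bone_mass_mean, reference_sd) {
  if (reference_sd <= 0) stop_config("reference_sd must be > 0")
  t <- (measured_bmd - peak_bone_mass_mean) / reference_sd
  category <- ifelse(t > -1, "normal",
                     ifelse(t > -2.5, "osteopenia", "osteoporosis"))
  data.frame(t_score = t, category = category, stringsAsFactors = FALSE)
}
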