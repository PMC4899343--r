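#' Construct a mass spectrum
#'
#' The elementary data unit of the pipeline: one sample's intensity profile
#' over a strictly ascending m/z grid (Da). All preprocessing operates on
#' this container.
#'
#' @param sample_id Character scalar identifying the sample.
#' @param mz Numeric vector of m/z values (Da), strictly ascending.
#' @param intensity Numeric vector of intensities (arbitrary units), same
#'   length as `mz`, all finite.
#' @return An object of class `mass_spectrum`: a list with elements
#'   `sample_id`, `mz` and `intensity`.
#' @export
#' @examples
#' s <- mass_spectrum("a", c(1000, 1001, 1002), c(5, 7, 6))
#' s
mass_spectrum <- function(sample_id, mz, intensity) {
  if (!is.character(sample_id) || length(sample_id) != 1L)
    stop_config("sample_id must be a single string")
  mz <- as.numeric(mz); intensity <- as.numeric(intensity)
  if (length(mz) == 0L) stop_config("spectrum '%s': empty m/z grid", sample_id)
  if (length(mz) != length(intensity))
    stop_config("spectrum '%s': mz and intensity lengths differ (%d vs %d)",
                sample_id, length(mz), length(intensity))
  bad <- which(diff(mz) <= 0)
  if (length(bad))
    stop_config("spectrum '%s': m/z not strictly ascending at position %d",
                sample_id, bad[1L] + 1L)
  if (!all(is.finite(intensity)))
    stop_config("spectrum '%s': non-finite intensity at position %d",
                sample_id, which(!is.finite(intensity))[1L])
  structure(list(sample_id = sample_id, mz = mz, intensity = intensity),
            class = "mass_spectrum")
}

#' @export
print.mass_spectrum <- function(x, ...) {
  cat(sprintf("<mass_spectrum '%s': %d points, m/z %.2f-%.2f, TIC %.4g>\n",
              x$sample_id, length(x$mz), min(x$mz), max(x$mz),
              sum(x$intensity)))
  invisible(x)
}

#' @export
length.mass_spectrum <- function(x) length(x$mz)

#' @export
plot.mass_spectrum <- function(x, ...) {
  graphics::plot(x$mz, x$intensity, type = "l",
                 xlab = "m/z (Da)", ylab = "intensity",
                 main = x$sample_id, ...)
  invisible(x)
}

#' Total ion current of a spectrum
#'
#' @param spectrum A `mass_spectrum`.
#' @return Sum of all intensities.
#' @export
tic <- function(spectrum) sum(spectrum$intensity)
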