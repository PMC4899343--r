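# Internal numeric helpers shared across modules.

#' @keywords internal
#' @noRd
stop_config <- function(...) stop(sprintf(...), call. = FALSE)

# Running minimum over a centred window of half-width `k` points.
# Sparse-table trick: M[i] = min over [i, i + 2^J), window min is the min of
# two overlapping power-of-two blocks. Edges are extended with the edge value.
#' @noRd
running_min <- function(x, k) {
  if (k <= 0L) return(x)
  n <- length(x)
  xp <- c(rep(x[1L], k), x, rep(x[n], k))
  w <- 2L * k + 1L
  J <- floor(log2(w))
  len <- as.integer(2^J)
  m <- xp
  s <- 1L
  while (s < len) {
    m <- pmin(m, c(m[-seq_len(s)], rep(m[length(m)], s)))
    s <- 2L * s
  }
  # m[i] = min over [i, i+len); window [i, i+w) = min(m[i], m[i + w - len])
  np <- length(xp)
  idx2 <- pmin(seq_len(np) + (w - len), np)
  res <- pmin(m, m[idx2])
  res[seq_len(n)]
}

# Centred moving average of half-width k, edges extended with edge values.
#' @noRd
running_mean <- function(x, k) {
  if (k <= 0L) return(x)
  n <- length(x)
  xp <- c(rep(x[1L], k), x, rep(x[n], k))
  cs <- cumsum(c(0, xp))
  w <- 2L * k + 1L
  (cs[(w + 1L):(n + w)] - cs[seq_len(n)]) / w
}

# Rolling MAD-based scale estimate (MAD / 0.6745), evaluated on a stride and
# linearly interpolated between evaluation points. Median-centring within each
# window performs the local detrending.
#' @noRd
rolling_mad <- function(x, half_window_pts, stride = NULL) {
  n <- length(x)
  h <- max(2L, as.integer(half_window_pts))
  if (is.null(stride)) stride <- max(1L, h %/% 2L)
  centers <- unique(c(seq(1L, n, by = stride), n))
  est <- vapply(centers, function(c0) {
    w <- x[max(1L, c0 - h):min(n, c0 + h)]
    stats::mad(w)  # constant 1.4826 = 1/0.6745
  }, numeric(1))
  if (length(centers) == 1L) return(rep(est, n))
  stats::approx(centers, est, xout = seq_len(n), rule = 2)$y
}

# Deterministic per-stage seed derivation from one master seed: a small
# documented LCG over the stage name's bytes, kept below 2^31 - 1 so the
# result is a valid R integer seed.
#' Derive a reproducible per-stage seed from a master seed
#'
#' Fans one master integer seed out to independent stage seeds so that each
#' pipeline stage is reproducible in isolation. The derivation is a fixed
#' linear-congruential hash of the stage name, so it is stable across
#' platforms and sessions.
#'
#' @param seed Master integer seed.
#' @param stage Character stage name.
#' @return An integer in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1, "preprocess")
derive_seed <- function(seed, stage) {
  m <- 2147483647
  s <- as.numeric(seed) %% m
  for (b in utf8ToInt(stage)) s <- (s * 69069 + b) %% m
  as.integer(s %% (m - 2) + 1)
}
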