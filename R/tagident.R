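# Candidate-protein matching by average molecular weight and isoelectric
# point, emulating a molecular-weight/pI database lookup, plus sequence-
# based average mass and pI computation.

# Average (not monoisotopic) residue masses in Da; appropriate for matching
# MALDI-TOF peaks of singly charged peptides in the 1-20 kDa range.
.residue_avg_mass <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132
)
.water_avg_mass <- 18.0153

# Fixed Bjellqvist-style pK table (documented constants) so computed pI
# values are reproducible. Side-chain pKs plus terminal groups; the
# N-terminal pK is the generic value.
.pk_table <- list(
  nterm = 7.50, cterm = 3.55,
  positive = c(K = 10.00, R = 12.00, H = 5.98),
  negative = c(D = 4.05, E = 4.45, C = 9.00, Y = 10.00)
)

#' @noRd
.check_sequence <- function(sequence) {
  chars <- strsplit(toupper(sequence), "")[[1L]]
  bad <- which(!chars %in% names(.residue_avg_mass))
  if (length(bad))
    stop_config("illegal residue code '%s' at position %d", chars[bad[1L]],
                bad[1L])
  chars
}

#' Average molecular weight of a peptide sequence
#'
#' Sum of average residue masses plus one water. With `oxidized_cys`, each
#' cysteine pair forms a disulfide bridge and loses two hydrogens
#' (2 x 1.008 Da).
#'
#' @param sequence One-letter amino acid string.
#' @param oxidized_cys Treat cysteines as pairwise oxidized (-SS-).
#' @return Average mass in Da.
#' @export
#' @examples
#' peptide_avg_mw("G")   # 75.07
#' peptide_avg_mw("GG")  # 132.12
peptide_avg_mw <- function(sequence, oxidized_cys = FALSE) {
  chars <- .check_sequence(sequence)
  mw <- sum(.residue_avg_mass[chars]) + .water_avg_mass
  if (oxidized_cys) {
    n_bridges <- sum(chars == "C") %/% 2L
    mw <- mw - n_bridges * 2 * 1.008
  }
  unname(mw)
}

#' @noRd
.net_charge <- function(chars, pH) {
  pos_pk <- c(.pk_table$nterm, .pk_table$positive[
    chars[chars %in% names(.pk_table$positive)]])
  neg_pk <- c(.pk_table$cterm, .pk_table$negative[
    chars[chars %in% names(.pk_table$negative)]])
  sum(1 / (1 + 10^(pH - pos_pk))) - sum(1 / (1 + 10^(neg_pk - pH)))
}

#' Isoelectric point of a peptide sequence
#'
#' Solves net charge(pH) = 0 by bisection on `[0, 14]` using the fixed pK
#' table shipped with the package; the net charge is monotone decreasing in
#' pH, so the root is unique. Converges to |charge| < 1e-6 within 100
#' iterations.
#'
#' @param sequence One-letter amino acid string.
#' @return pI in pH units.
#' @export
#' @examples
#' peptide_pi("GG")  # no ionizable side chains: (pK_N + pK_C) / 2
peptide_pi <- function(sequence) {
  chars <- .check_sequence(sequence)
  lo <- 0; hi <- 14
  for (i in seq_len(100L)) {
    mid <- (lo + hi) / 2
    q <- .net_charge(chars, mid)
    if (abs(q) < 1e-6) return(mid)
    if (q > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Molecular-weight search window
#'
#' @param observed_mz Observed peak m/z (Da, > 0).
#' @param tolerance_frac Fractional tolerance (default 0.003 = 0.3%).
#' @return Numeric `c(low, high)` = `observed_mz * (1 -/+ tolerance)`.
#' @export
#' @examples
#' mass_window(3038, 0.003)
mass_window <- function(observed_mz, tolerance_frac = 0.003) {
  if (observed_mz <= 0) stop_config("observed_mz must be > 0")
  c(observed_mz * (1 - tolerance_frac), observed_mz * (1 + tolerance_frac))
}

#' Match an observed peak mass against a protein database
#'
#' Keeps records whose average Mw falls inside the fractional mass window
#' and whose pI lies in `[pi_min, pi_max]`, ranked by absolute mass
#' difference (ties broken by accession).
#'
#' @param db Protein record data frame (see [read_protein_db()]).
#' @param observed_mz Observed peak m/z (Da).
#' @param tolerance_frac Fractional Mw tolerance (default 0.003).
#' @param pi_min,pi_max pI window (defaults 4 and 14).
#' @return The matching records with an extra `delta_mw` column, best
#'   first. Zero rows when nothing matches.
#' @export
#' @examples
#' match_proteins(tagident_db(), 3038)[1, c("accession", "name", "mw", "pi")]
match_proteins <- function(db, observed_mz, tolerance_frac = 0.003,
                           pi_min = 4, pi_max = 14) {
  if (tolerance_frac < 0) stop_config("tolerance_frac must be >= 0")
  if (pi_min >= pi_max) stop_config("pi_min must be < pi_max")
  win <- observed_mz * c(1 - tolerance_frac, 1 + tolerance_frac)
  hit <- db$mw >= win[1L] & db$mw <= win[2L] & db$pi >= pi_min & db$pi <= pi_max
  out <- db[hit, , drop = FALSE]
  out$delta_mw <- abs(out$mw - observed_mz)
  out <- out[order(out$delta_mw, out$accession), , drop = FALSE]
  rownames(out) <- NULL
  out
}
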