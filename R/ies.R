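#' Surrogate-corrected inter-electrode synchrony
#'
#' For every contact pair (a, b) and frequency, the phase-locking factor R is
#' the resultant length of `exp(1i * (phase_a - phase_b))` averaged over
#' trials and the timepoints of the analysis window. Because two contacts can
#' appear phase-locked merely by both locking to stimulus onset, a surrogate
#' R is computed identically but pairing contact b's phases from a different
#' trial of the same stimulus (`surrogate_offset` trials in the future, with
#' wrap-around so every trial is used exactly once); the corrected IES is
#' `R - R_surrogate`.
#'
#' @param tf a `tf_tensor` from [morlet_decompose()] (one context).
#' @param window_ms analysis window, ms (e.g. 50--250 early, 250--450 late).
#' @param surrogate_offset trial shift of the surrogate pairing.
#' @param symmetrize average IES(a,b) and IES(b,a) (the raw R is symmetric;
#'   only the surrogate pairing is not).
#' @return list of class `"ies_spectra"`: `R` (raw), `R_surr`, `ies` --
#'   contacts x contacts x frequency arrays -- plus `freqs`, `window_ms`,
#'   `contact_labels`. Diagonal cells are NA (non-informative).
#' @export
compute_ies <- function(tf, window_ms = c(50, 250), surrogate_offset = 2,
                        symmetrize = FALSE) {
  ntr <- dim(tf$coef)[1]
  if (ntr < 4) stop("IES needs at least 4 trials (surrogate pairing degenerate)")
  tsel <- which(tf$time_ms >= window_ms[1] & tf$time_ms <= window_ms[2])
  if (!length(tsel)) stop("IES window contains no time bins")
  nc <- dim(tf$coef)[2]
  nf <- dim(tf$coef)[3]
  nT <- length(tsel)
  perm <- ((seq_len(ntr) - 1 + surrogate_offset) %% ntr) + 1
  R <- Rs <- array(NA_real_, c(nc, nc, nf))
  for (j in seq_len(nf)) {
    Z <- tf$coef[, , j, tsel, drop = FALSE]
    dim(Z) <- c(ntr, nc, nT)
    m <- Mod(Z)
    Z <- Z / ifelse(m == 0, 1, m)  # unit phasors
    A <- matrix(aperm(Z, c(2, 1, 3)), nc, ntr * nT)
    As <- matrix(aperm(Z[perm, , , drop = FALSE], c(2, 1, 3)), nc, ntr * nT)
    R[, , j] <- Mod(A %*% Conj(t(A))) / (ntr * nT)
    Rs[, , j] <- Mod(A %*% Conj(t(As))) / (ntr * nT)
  }
  ies <- R - Rs
  if (symmetrize)
    for (j in seq_len(nf)) ies[, , j] <- (ies[, , j] + t(ies[, , j])) / 2
  for (j in seq_len(nf)) diag(R[, , j]) <- diag(Rs[, , j]) <- diag(ies[, , j]) <- NA
  structure(list(R = R, R_surr = Rs, ies = ies, freqs = tf$freqs,
                 window_ms = window_ms, contact_labels = tf$contact_labels,
                 surrogate_offset = surrogate_offset),
            class = "ies_spectra")
}

#' Seed-referenced synchrony map
#'
#' Averages the IES rows of one or more seed contacts, yielding a
#' target-contact x frequency map (e.g. the superficial seed uses kept
#' contacts 1 and 2; the granular seed uses kept contacts 8 and 9).
#'
#' @param spectra an [compute_ies()] result.
#' @param seed_contacts seed contact labels.
#' @return targets x frequency matrix (row names = contact labels); seed
#'   columns averaged, seed-to-seed cells retained as NA-safe means.
#' @export
ies_seed_map <- function(spectra, seed_contacts) {
  idx <- match(seed_contacts, spectra$contact_labels)
  if (any(is.na(idx))) stop("seed contact(s) not in the kept set")
  nc <- dim(spectra$ies)[1]
  nf <- dim(spectra$ies)[3]
  out <- matrix(NA_real_, nc, nf,
                dimnames = list(spectra$contact_labels, NULL))
  for (j in seq_len(nf)) {
    sl <- spectra$ies[idx, , j, drop = FALSE]
    out[, j] <- colMeans(sl, na.rm = TRUE)
  }
  out[is.nan(out)] <- NA
  out
}
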