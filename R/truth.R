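#' Ground-truth description of a synthetic recording
#'
#' Collects every injected component of the forward model: the noise model,
#' the stimulus-evoked dipole, the spiking model, and a catalogue of
#' context-dependent effects. Effect gains are expressed per context relative
#' to control and act on *power* (burst amplitudes scale with `sqrt(gain)`)
#' or on MUA event rate (linear in `gain`); amplitudes are in units of the
#' per-contact baseline noise SD, except MUA rates which are in Hz.
#'
#' @param effects list of effect records (see [default_ground_truth()] for the
#'   fields). Each record must name at least one context whose gain differs
#'   from 1, and all gains must be positive.
#' @param noise list: `exponent` (1/f slope), `sd_uv` (per-contact SD of the
#'   LFP background, microvolts), `corr_length` (Gaussian inter-contact
#'   correlation length, contacts), `mua_floor_sd` (broadband white floor,
#'   microvolts), `gamma_sd`/`albeta_sd` (depth-profiled band backgrounds
#'   that create the supragranular-gamma / infragranular-beta spectral
#'   gradient used for layer-4 alignment).
#' @param evoked list: `amp` (peak LFP amplitude, baseline-SD units),
#'   `latency_ms`, `width_ms`, plus `sup_amp`/`sup_latency_ms` for the later
#'   superficial dipole.
#' @param spikes list: `background_hz`, `evoked_hz`, `latency_ms` (granular
#'   peak latency), `latency_step_ms` (added per contact away from layer 4),
#'   `width_ms`, `amp_uv` (spike amplitude).
#' @param l4_contact true granular alignment contact of the simulated probe.
#' @param target_orientation orientation (degrees) carrying the strongest
#'   spiking response, and the one the oddball pair is built around.
#' @param orientation_gain MUA rate multiplier for the target orientation.
#' @param epoch_ms epoch the effect windows must fit in.
#' @return list of class `"ground_truth"`.
#' @export
ground_truth <- function(effects = list(),
                         noise = list(exponent = 1, sd_uv = 20, corr_length = 2,
                                      mua_floor_sd = 3, gamma_sd = 18, albeta_sd = 8),
                         evoked = list(amp = 1.2, latency_ms = 45, width_ms = 12,
                                       sup_amp = 0.7, sup_latency_ms = 85),
                         spikes = list(background_hz = 20, evoked_hz = 250,
                                       latency_ms = 40, latency_step_ms = 6,
                                       width_ms = 12, amp_uv = 60),
                         l4_contact = 8, target_orientation = 45,
                         orientation_gain = 2, epoch_ms = c(-250, 750)) {
  for (e in effects) {
    if (any(unlist(e$gains) <= 0)) stop("validation error: effect gains must be > 0")
    if (all(abs(unlist(e$gains) - 1) < 1e-12))
      stop("validation error: effect '", e$name, "' modulates no context")
    if (e$window_ms[1] < epoch_ms[1] || e$window_ms[2] > epoch_ms[2])
      stop("validation error: window of effect '", e$name, "' outside the epoch")
  }
  structure(list(effects = effects, noise = noise, evoked = evoked,
                 spikes = spikes, l4_contact = as.integer(l4_contact),
                 target_orientation = target_orientation,
                 orientation_gain = orientation_gain, epoch_ms = epoch_ms),
            class = "ground_truth")
}

#' Default injected-effect catalogue
#'
#' The canonical simulation truth: six context effects mirroring the laminar
#' oddball phenomenology --
#' \itemize{
#'   \item granular (L4) MUA adaptation: redundant rate gain < 1 at 50--80 ms;
#'   \item supragranular (L2/3) MUA deviance detection: deviant gain > 1 at
#'     140--230 ms;
#'   \item L2/3 delta/theta (2--7 Hz) deviant power increase at 100--150 ms;
#'   \item L2/3 high-gamma (68--77 Hz) deviant increase at 110--260 ms;
#'   \item superficial (L1) high-beta (26--35 Hz) deviant decrease at
#'     90--120 ms;
#'   \item deviant-specific loss of L1 to deep-L2/3 phase coupling at
#'     34--41 Hz (shared versus independent burst phase).
#' }
#' Contact indices are absolute probe contacts for a granular contact at 8
#' (kept window 1--12, so L1 = contacts 1--2, L2/3 = 3--7, L4 = 8--9,
#' L5 = 10--12).
#'
#' @param l4_contact granular contact the catalogue is anchored to.
#' @return a [ground_truth()].
#' @export
default_ground_truth <- function(l4_contact = 8) {
  k <- l4_contact
  eff <- list(
    list(name = "l4_mua_ssa", kind = "mua_rate", layer = "L4",
         contacts = k + 0:1, window_ms = c(50, 80), band_hz = NULL,
         gains = c(control = 1, redundant = 0.4, deviant = 1), amplitude = 120),
    list(name = "l23_mua_dd", kind = "mua_rate", layer = "L2/3",
         contacts = k - 5:1, window_ms = c(140, 230), band_hz = NULL,
         gains = c(control = 1, redundant = 1, deviant = 2.5), amplitude = 100),
    list(name = "l23_theta_dd", kind = "burst", layer = "L2/3",
         contacts = k - 5:1, window_ms = c(100, 150), band_hz = c(2, 7),
         f0 = 4.5, gains = c(control = 1, redundant = 1, deviant = 4),
         amplitude = 1.8),
    list(name = "l23_hgamma_dd", kind = "burst", layer = "L2/3",
         contacts = k - 5:1, window_ms = c(110, 260), band_hz = c(68, 77),
         f0 = 72.5, gains = c(control = 1, redundant = 1, deviant = 2.5),
         amplitude = 0.8),
    list(name = "l1_hbeta_dd", kind = "burst", layer = "L1",
         contacts = k - 7:6, window_ms = c(70, 150), band_hz = c(26, 35),
         f0 = 30.5, gains = c(control = 1, redundant = 1, deviant = 0.1),
         amplitude = 2.4),
    list(name = "l1_l23_ies", kind = "coupling", layer = "L1->L2/3",
         contacts = c(k - 7, k - 6, k - 2, k - 1), seed_contacts = k - 7:6,
         target_contacts = k - 2:1, window_ms = c(50, 250), band_hz = c(34, 41),
         f0 = 37.5, gains = c(control = 1, redundant = 1, deviant = 0.05),
         amplitude = 2.2)
  )
  ground_truth(effects = eff, l4_contact = l4_contact)
}

#' A truth with no noise and no effects (all-zero signal)
#' @keywords internal
#' @export
zero_truth <- function() {
  ground_truth(effects = list(),
               noise = list(exponent = 1, sd_uv = 0, corr_length = 2,
                            mua_floor_sd = 0, gamma_sd = 0, albeta_sd = 0),
               evoked = list(amp = 0, latency_ms = 45, width_ms = 12,
                             sup_amp = 0, sup_latency_ms = 85),
               spikes = list(background_hz = 0, evoked_hz = 0, latency_ms = 40,
                             latency_step_ms = 6, width_ms = 12, amp_uv = 0))
}

context_gain <- function(effect, ctx) {
  g <- effect$gains[ctx]
  ifelse(is.na(g), 1, g)
}
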