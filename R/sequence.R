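#' Stimulus sequence specification
#'
#' Defaults reproduce the oddball protocol: 500 ms drifting-grating stimuli
#' with a ~500 ms inter-stimulus interval (uniform +/- 50 ms jitter), a
#' many-standards control run of ~250 trials over 8 orientations (each
#' ~12.5% likely), and oddball runs of ~150 trials in which one orientation
#' is redundant (~87.5%) and the orthogonal one deviant (~12.5%).
#'
#' @param kind `"many_standards"` or `"oddball"`.
#' @param n_trials trials in the run.
#' @param orientations orientation set, degrees.
#' @param deviant_orientation,redundant_orientation the oddball pair; must be
#'   orthogonal (90 degrees apart).
#' @param stim_ms,isi_ms,isi_jitter_ms stimulus duration and inter-stimulus
#'   interval (ms); ISI is drawn uniformly in `isi_ms +/- isi_jitter_ms`.
#' @param lead_in_ms silent period before the first trial.
#' @param fs sampling rate the event samples refer to.
#' @param seed RNG seed.
#' @return list of class `"sequence_spec"`.
#' @export
sequence_spec <- function(kind = c("many_standards", "oddball"),
                          n_trials = if (match.arg(kind) == "many_standards") 250 else 150,
                          orientations = c(30, 45, 60, 90, 120, 135, 150, 180),
                          deviant_orientation = 45,
                          redundant_orientation = 135,
                          stim_ms = 500, isi_ms = 500, isi_jitter_ms = 50,
                          lead_in_ms = 1000, fs = 10000, seed = 1) {
  kind <- match.arg(kind)
  if (kind == "oddball" &&
      abs(deviant_orientation - redundant_orientation) %% 180 != 90)
    stop("validation error: deviant and redundant orientations must be orthogonal")
  structure(list(kind = kind, n_trials = as.integer(n_trials),
                 orientations = orientations,
                 deviant_orientation = deviant_orientation,
                 redundant_orientation = redundant_orientation,
                 stim_ms = stim_ms, isi_ms = isi_ms,
                 isi_jitter_ms = isi_jitter_ms, lead_in_ms = lead_in_ms,
                 fs = fs, seed = seed),
            class = "sequence_spec")
}

#' Generate a stimulus sequence
#'
#' Many-standards runs assign orientations in balanced counts (differing by at
#' most one trial across the 8 orientations) and shuffle the order; oddball
#' runs contain `round(0.125 * n_trials)` deviants, the remainder redundant,
#' shuffled under the constraint that the first trial is redundant.
#'
#' @param spec a [sequence_spec()].
#' @param run run label; defaults to `"control"` or `"oddball_A"` by kind.
#' @param t0_ms start offset of the run, ms.
#' @return an [event_table()].
#' @export
generate_stimulus_sequence <- function(spec, run = NULL, t0_ms = NULL) {
  stopifnot(inherits(spec, "sequence_spec"))
  n <- spec$n_trials
  with_seed(spec$seed, {
    if (spec$kind == "many_standards") {
      run <- run %||% "control"
      k <- length(spec$orientations)
      base <- rep(spec$orientations, each = n %/% k)
      extra <- if (n %% k > 0) sample(spec$orientations, n %% k) else numeric(0)
      ori <- sample(c(base, extra))
      ctx <- rep("control", n)
    } else {
      run <- run %||% "oddball_A"
      n_dev <- round(0.125 * n)
      ori <- sample(c(rep(spec$deviant_orientation, n_dev),
                      rep(spec$redundant_orientation, n - n_dev)))
      if (ori[1] == spec$deviant_orientation) {
        j <- sample(which(ori == spec$redundant_orientation), 1)
        ori[c(1, j)] <- ori[c(j, 1)]
      }
      ctx <- ifelse(ori == spec$deviant_orientation, "deviant", "redundant")
    }
    isi <- runif(n, spec$isi_ms - spec$isi_jitter_ms, spec$isi_ms + spec$isi_jitter_ms)
    onset_ms <- (t0_ms %||% spec$lead_in_ms) +
      cumsum(c(0, (spec$stim_ms + isi)[-n]))
    event_table(onset_sample = round(onset_ms * spec$fs / 1000) + 1L,
                orientation_deg = ori, context = ctx, run = run,
                duration_samples = round(spec$stim_ms * spec$fs / 1000),
                fs = spec$fs)
  })
}

#' Generate a flip-flop oddball pair
#'
#' Two consecutive oddball runs in which the deviant and redundant roles are
#' exchanged, so that both orientations of the orthogonal pair participate in
#' every sensory context.
#'
#' @param spec an oddball [sequence_spec()].
#' @param gap_ms silent gap between the two runs, ms.
#' @return an [event_table()] with runs `oddball_A` and `oddball_B`.
#' @export
generate_oddball_pair <- function(spec, gap_ms = 2000) {
  stopifnot(inherits(spec, "sequence_spec"), spec$kind == "oddball")
  a <- generate_stimulus_sequence(spec, run = "oddball_A")
  spec_b <- spec
  spec_b$deviant_orientation <- spec$redundant_orientation
  spec_b$redundant_orientation <- spec$deviant_orientation
  spec_b$seed <- spec$seed + 1L
  end_a <- max(a$onset_sample + a$duration_samples)
  b <- generate_stimulus_sequence(spec_b, run = "oddball_B",
                                  t0_ms = end_a / spec$fs * 1000 + gap_ms)
  ev <- rbind(as.data.frame(a), as.data.frame(b))
  attr(ev, "fs") <- spec$fs
  class(ev) <- c("event_table", "data.frame")
  validate_events(ev)
  ev
}

# Concatenate event tables from consecutive runs of one session.
bind_events <- function(...) {
  tabs <- list(...)
  fs <- attr(tabs[[1]], "fs")
  ev <- do.call(rbind, lapply(tabs, as.data.frame))
  attr(ev, "fs") <- fs
  class(ev) <- c("event_table", "data.frame")
  validate_events(ev)
  ev
}
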