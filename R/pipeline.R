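subset_trials <- function(ep, idx) { ep$data <- ep$data[idx, , , drop = FALSE]; ep }

subset_contacts <- function(ep, contacts) {
  idx <- match(contacts, ep$contact_labels)
  ep$data <- ep$data[, idx, , drop = FALSE]
  ep$contact_labels <- contacts
  ep
}

# Welch-style per-contact power spectra of a continuous recording.
contact_power_spectra <- function(rec, seg_s = 1, fmax = 120) {
  n <- ncol(rec$signal)
  L <- round(seg_s * rec$fs)
  nseg <- max(1, n %/% L)
  win <- 0.5 - 0.5 * cos(2 * pi * seq(0, 1, length.out = L))
  freqs <- (seq_len(L) - 1) * rec$fs / L
  keep <- freqs > 0 & freqs <= fmax
  acc <- matrix(0, nrow(rec$signal), sum(keep))
  for (s in seq_len(nseg)) {
    seg <- rec$signal[, ((s - 1) * L + 1):(s * L), drop = FALSE]
    seg <- sweep(seg, 2, win, `*`) - 0
    sp <- Mod(t(mvfft(t(seg))))^2
    acc <- acc + sp[, keep, drop = FALSE]
  }
  list(power = acc / nseg, freqs = freqs[keep])
}

bin_grid <- function(cfg) seq(cfg$bin_range_ms[1], cfg$bin_range_ms[2] - cfg$bin_ms,
                              by = cfg$bin_ms)

bin_mean <- function(trace, time_ms, t_lo, width) {
  sel <- time_ms >= t_lo & time_ms < t_lo + width
  mean(trace[sel])
}

#' Analyse a single subject
#'
#' Runs the full per-subject chain: LFP low-pass and decimation, MUA envelope
#' extraction and normalisation, layer-4 alignment and layer partition, best
#' orientation selection, trial-count matching across contexts, per-context
#' CSD/av-rec, induced power, and seed-referenced synchrony; returns the
#' per-subject summary tables the cohort statistics consume.
#'
#' @param rec a [new_recording()] (raw, at the acquisition rate).
#' @param events its [event_table()].
#' @param cfg an [analysis_config()].
#' @param seed per-subject seed (trial matching).
#' @return list of class `"subject_summary"`.
#' @export
analyze_subject <- function(rec, events, cfg = analysis_config(), seed = 1) {
  hash <- config_hash(cfg)
  log_stage("lowpass", hash, seed, shape = dim(rec$signal))
  Xt <- t(rec$signal)  # samples x contacts, shared by both chains
  lfp1k <- rec
  lfp1k$signal <- t(lowpass_decimate_mat(Xt, rec$fs, cfg$lowpass_hz, cfg$lfp_rate))
  lfp1k$fs <- cfg$lfp_rate
  log_stage("mua", hash, seed)
  mua <- rec
  mua$signal <- t(mua_envelope_mat(Xt, rec$fs, cfg$mua_band,
                                   cfg$mua_smooth_fwhm_ms, cfg$mua_smooth_is_sd,
                                   cfg$mua_rate))
  mua$fs <- cfg$mua_rate
  mua$domain <- "mua"
  rm(Xt)
  ongoing_sd <- sd(mua$signal)

  ## ---- layer-4 alignment on stimulus-triggered averages of all stimuli ----
  ep_mua_all <- epoch_recording(mua, events, cfg$epoch_ms)
  ep_mua_all <- normalize_mua(ep_mua_all, continuous = mua)
  ep_lfp_all <- epoch_recording(lfp1k, events, cfg$epoch_ms)
  mua_avg <- colMeans(ep_mua_all$data, dims = 1)
  lfp_avg <- colMeans(ep_lfp_all$data, dims = 1)
  csd_avg_t <- compute_csd(epoch_tensor(array(lfp_avg, c(1, dim(lfp_avg))),
                                        ep_lfp_all$time_ms, "lfp", fs = lfp1k$fs),
                           rec$geometry, cfg$csd_smoothing, cfg$csd_boundary)
  spec <- contact_power_spectra(lfp1k)
  l4 <- align_layer4(mua_avg, csd_avg_t$data[1, , ], spec$power,
                     ep_mua_all$time_ms, spec$freqs, cfg$crossover_bands)
  layers <- layer_partition(l4, rec$geometry)
  log_stage("align", hash, seed, l4 = l4)

  ## ---- best orientation -----------------------------------------------------
  by_ori <- lapply(split(seq_len(nrow(events)), events$orientation_deg),
                   function(idx) subset_trials(ep_mua_all, idx))
  best <- select_best_orientation(by_ori, kept_contacts = layers$kept_contacts,
                                  floor = cfg$mua_floor)
  ori <- best$orientation

  ## ---- matched trials per context ------------------------------------------
  idx_ctx <- list(
    control = which(events$orientation_deg == ori & events$context == "control"),
    redundant = which(events$orientation_deg == ori & events$context == "redundant"),
    deviant = which(events$orientation_deg == ori & events$context == "deviant"))
  mua_ctx <- lapply(idx_ctx, function(i) subset_trials(ep_mua_all, i))
  mua_ctx <- match_trial_counts(mua_ctx, seed = seed, n_max = cfg$matched_max)
  sel <- attr(mua_ctx, "selected")
  matched_n <- n_trials(mua_ctx[[1]])
  ep_lfp_wide <- epoch_recording(lfp1k, events, cfg$lfp_epoch_ms)
  lfp_ctx <- Map(function(i, s) subset_trials(ep_lfp_wide, i[s]), idx_ctx, sel)
  log_stage("match", hash, seed, n = matched_n)

  ## ---- CSD / av-rec ---------------------------------------------------------
  csd_ctx <- lapply(lfp_ctx, compute_csd, geometry = rec$geometry,
                    smoothing = cfg$csd_smoothing, boundary = cfg$csd_boundary)
  avrec_ctx <- lapply(csd_ctx, avrec, layers = layers)

  ## ---- wavelets, induced power, synchrony ----------------------------------
  grid <- wavelet_grid(cfg$wavelet_n, cfg$wavelet_fmin, cfg$wavelet_fmax,
                       cfg$wavelet_cycles, cfg$wavelet_hop_ms)
  tf_ctx <- lapply(lfp_ctx, function(e)
    morlet_decompose(subset_contacts(e, layers$kept_contacts), grid,
                     cfg$tf_window_ms))
  base_w <- if (cfg$baseline_alt) c(-200, 50) else cfg$baseline_ms
  tfp <- induced_power(tf_ctx, layers, base_w)
  log_stage("wavelets", hash, seed)

  ies_maps <- list()
  for (wname in names(cfg$ies_windows)) {
    per_ctx <- lapply(tf_ctx, compute_ies, window_ms = cfg$ies_windows[[wname]],
                      surrogate_offset = cfg$surrogate_offset,
                      symmetrize = cfg$symmetrize_ies)
    ies_maps[[wname]] <- list(
      l1 = lapply(per_ctx, ies_seed_map, seed_contacts = layers$kept_contacts[1:2]),
      granular = lapply(per_ctx, ies_seed_map,
                        seed_contacts = layers$kept_contacts[8:9]))
  }
  log_stage("ies", hash, seed)

  ## ---- summary tables -------------------------------------------------------
  bins <- bin_grid(cfg)
  avrec_bins <- do.call(rbind, lapply(names(avrec_ctx), function(ctx) {
    w <- avrec_ctx[[ctx]]
    do.call(rbind, lapply(layer_names(), function(ly)
      data.frame(layer = ly, t_lo = bins, context = ctx,
                 value = vapply(bins, function(b)
                   bin_mean(w$data[ly, ], w$time_ms, b, cfg$bin_ms), numeric(1)),
                 stringsAsFactors = FALSE)))
  }))
  mua_bins <- do.call(rbind, lapply(names(mua_ctx), function(ctx) {
    e <- mua_ctx[[ctx]]
    tr <- colMeans(e$data, dims = 1)
    do.call(rbind, lapply(seq_along(layers$kept_contacts), function(pos) {
      k <- layers$kept_contacts[pos]
      data.frame(kept_pos = pos, contact = k,
                 layer = unname(layers$layer_of_contact[as.character(k)]),
                 t_lo = bins, context = ctx,
                 value = vapply(bins, function(b)
                   bin_mean(tr[k, ], e$time_ms, b, cfg$bin_ms), numeric(1)),
                 stringsAsFactors = FALSE)
    }))
  }))
  roi_tab <- do.call(rbind, lapply(seq_len(nrow(cfg$rois)), function(i) {
    roi <- cfg$rois[i, ]
    do.call(rbind, lapply(names(tfp$power), function(ctx)
      data.frame(roi = roi$name, layer = layer_names(), context = ctx,
                 value = vapply(layer_names(), function(ly)
                   roi_power(tfp, roi, ctx, ly), numeric(1)),
                 stringsAsFactors = FALSE)))
  }))

  mean_power <- lapply(tfp$power, identity)
  structure(list(
    subject_id = rec$subject_id, l4_contact = as.integer(l4), layers = layers,
    best_orientation = ori, no_clear_response = best$no_clear_response,
    ongoing_sd = ongoing_sd, matched_n = matched_n,
    avrec_bins = avrec_bins, mua_bins = mua_bins, roi_power = roi_tab,
    ies_maps = ies_maps, tf_power = mean_power, tf_freqs = tfp$freqs,
    tf_time_ms = tfp$time_ms,
    avrec_traces = lapply(avrec_ctx, function(w) w$data),
    avrec_time_ms = avrec_ctx[[1]]$time_ms,
    mua_traces = lapply(mua_ctx, function(e) colMeans(e$data, dims = 1)),
    mua_time_ms = mua_ctx[[1]]$time_ms,
    ies_freqs = seq(cfg$wavelet_fmin, cfg$wavelet_fmax, length.out = cfg$wavelet_n),
    config_hash = hash, seed = seed), class = "subject_summary")
}

#' Cohort-level statistics
#'
#' Pools per-subject summaries and runs the three statistical surfaces:
#' 30 ms windowed paired contrasts on av-rec CSD (per layer, two-tailed) and
#' normalised MUA (per kept contact, one-tailed), layer x context
#' repeated-measures ANOVAs with planned contrasts on each time-frequency
#' ROI, and the cluster-mass permutation test on deviant-minus-control
#' superficial-seed synchrony maps. Subjects flagged as having no clear MUA
#' response are excluded from the MUA contrasts only.
#'
#' @param summaries list of [analyze_subject()] results.
#' @param cfg an [analysis_config()].
#' @return list of class `"cohort_stats"` with elements `windowed`,
#'   `roi_tests`, `ies_cluster` (superficial seed, early window, DD),
#'   `ies_cluster_granular`, `n_subjects`, `mua_excluded`.
#' @export
cohort_stats <- function(summaries, cfg = analysis_config()) {
  ns <- length(summaries)
  ids <- vapply(summaries, `[[`, character(1), "subject_id")
  bins <- bin_grid(cfg)

  gather <- function(field) {
    do.call(rbind, lapply(seq_along(summaries), function(i) {
      x <- summaries[[i]][[field]]
      x$subject <- ids[i]
      x
    }))
  }
  mua_ok <- !vapply(summaries, `[[`, logical(1), "no_clear_response")

  windowed <- list()
  av_tab <- gather("avrec_bins")
  for (ly in layer_names()) for (b in bins) for (ctr in c("SSA", "DD")) {
    ctx <- if (ctr == "DD") "deviant" else "redundant"
    v0 <- av_tab$value[av_tab$layer == ly & av_tab$t_lo == b & av_tab$context == "control"]
    v1 <- av_tab$value[av_tab$layer == ly & av_tab$t_lo == b & av_tab$context == ctx]
    row <- windowed_ttest(v0, v1, ctr, "csd_avrec", ly, c(b, b + cfg$bin_ms))
    row$kept_pos <- NA
    windowed[[length(windowed) + 1]] <- row
  }
  mu_tab <- gather("mua_bins")
  mu_tab <- mu_tab[mu_tab$subject %in% ids[mua_ok], ]
  if (sum(mua_ok) >= 3) {
    for (pos in sort(unique(mu_tab$kept_pos))) for (b in bins)
      for (ctr in c("SSA", "DD")) {
        ctx <- if (ctr == "DD") "deviant" else "redundant"
        sel0 <- mu_tab$kept_pos == pos & mu_tab$t_lo == b
        v0 <- mu_tab$value[sel0 & mu_tab$context == "control"]
        v1 <- mu_tab$value[sel0 & mu_tab$context == ctx]
        ly <- mu_tab$layer[sel0][1]
        row <- windowed_ttest(v0, v1, ctr, "mua", ly, c(b, b + cfg$bin_ms))
        row$kept_pos <- pos
        windowed[[length(windowed) + 1]] <- row
      }
  }
  windowed <- do.call(rbind, windowed)

  roi_tab <- gather("roi_power")
  roi_tests <- list()
  for (rn in unique(roi_tab$roi)) {
    sub <- roi_tab[roi_tab$roi == rn, ]
    names(sub)[names(sub) == "value"] <- "value"
    planned <- if (rn == "early_delta_theta") "L2/3" else NA
    roi_tests[[rn]] <- roi_anova(sub, planned_layer = planned,
                                 sphericity = cfg$sphericity)
  }
  if (isTRUE(cfg$roi_holm)) {
    ips <- vapply(roi_tests, `[[`, numeric(1), "interaction_p")
    adj <- stats::p.adjust(ips, "holm")
    for (i in seq_along(roi_tests)) roi_tests[[i]]$interaction_p_holm <- adj[i]
  }

  dd_maps <- function(seed_name) {
    arr <- array(NA_real_, c(ns, 12, cfg$wavelet_n))
    for (i in seq_len(ns)) {
      m <- summaries[[i]]$ies_maps$early[[seed_name]]
      arr[i, , ] <- m$deviant - m$control
    }
    arr
  }
  ies_cluster <- cluster_permutation(dd_maps("l1"), cfg$n_perm, cfg$z_crit,
                                     cfg$cluster_alpha, cfg$adjacency,
                                     seed = cfg$seed + 101L)
  ies_cluster_gran <- cluster_permutation(dd_maps("granular"), cfg$n_perm,
                                          cfg$z_crit, cfg$cluster_alpha,
                                          cfg$adjacency, seed = cfg$seed + 102L)
  structure(list(windowed = windowed, roi_tests = roi_tests,
                 ies_cluster = ies_cluster,
                 ies_cluster_granular = ies_cluster_gran,
                 n_subjects = ns, mua_excluded = ids[!mua_ok],
                 rois = cfg$rois, freqs = summaries[[1]]$ies_freqs,
                 config_hash = config_hash(cfg)),
            class = "cohort_stats")
}

#' Simulate and analyse a cohort end to end
#'
#' Streams subject-by-subject (generate, analyse, discard the raw signal) so
#' memory stays bounded, then runs the cohort statistics and, when a truth is
#' supplied, the effect-recovery report.
#'
#' @param n_subjects cohort size.
#' @param truth a [ground_truth()].
#' @param cfg an [analysis_config()].
#' @param seed master seed (drives sequences, noise and trial matching).
#' @param n_control,n_oddball trials per run (defaults are the package's
#'   simulation-study scale; full-session scale is 250/150).
#' @param between_subject_sd log-normal SD of per-subject effect amplitudes.
#' @return list: `subjects` (summaries), `stats` (a `cohort_stats`),
#'   `recovery` (from [run_effect_recovery()]).
#' @export
run_cohort <- function(n_subjects = 10, truth = default_ground_truth(),
                       cfg = analysis_config(), seed = 1,
                       n_control = 56, n_oddball = 56,
                       between_subject_sd = 0.2) {
  subs <- cohort_subject_truths(n_subjects, truth, between_subject_sd, seed)
  summaries <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    s <- subs[[i]]
    evs <- cohort_session_events(s$truth, n_control, n_oddball, cfg$fs, s$seed)
    rec <- simulate_recording(evs, s$truth, probe_geometry(), cfg$fs, s$seed,
                              s$subject_id)
    summaries[[i]] <- analyze_subject(rec, evs, cfg, seed = s$seed)
    rm(rec)
  }
  st <- cohort_stats(summaries, cfg)
  list(subjects = summaries, stats = st,
       recovery = run_effect_recovery(st, truth), seed = seed,
       config = cfg)
}

#' Run the pipeline over a directory of recording containers
#'
#' Applies [analyze_subject()] to every `*.lrec.rds` container in `data_dir`,
#' runs [cohort_stats()], and writes tidy CSV outputs plus a JSON run
#' manifest to `out_dir`. On a stage failure the partial outputs are removed
#' and the error names the stage and subject.
#'
#' @param cfg an [analysis_config()].
#' @param data_dir directory of containers written by [write_recording()].
#' @param out_dir results directory (created).
#' @param truth optional [ground_truth()] for an effect-recovery report.
#' @return `out_dir`, invisibly; see the written `manifest.json`.
#' @export
run_pipeline <- function(cfg = analysis_config(), data_dir, out_dir,
                         truth = NULL) {
  files <- sort(list.files(data_dir, pattern = "\\.lrec\\.rds$", full.names = TRUE))
  if (!length(files)) stop("no recording containers found in ", data_dir)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  t0 <- Sys.time()
  current <- "setup"
  res <- tryCatch({
    seeds <- derive_seeds(cfg$seed, length(files))
    summaries <- vector("list", length(files))
    for (i in seq_along(files)) {
      current <- paste0("subject ", basename(files[i]))
      dat <- read_recording(files[i])
      summaries[[i]] <- analyze_subject(dat$recording, dat$events, cfg, seeds[i])
    }
    current <- "cohort statistics"
    st <- cohort_stats(summaries, cfg)
    current <- "outputs"
    write.csv(st$windowed, file.path(out_dir, "windowed_tests.csv"), row.names = FALSE)
    write.csv(do.call(rbind, lapply(summaries, function(s)
      cbind(subject = s$subject_id, s$avrec_bins))),
      file.path(out_dir, "avrec_bins.csv"), row.names = FALSE)
    write.csv(do.call(rbind, lapply(summaries, function(s)
      cbind(subject = s$subject_id, s$mua_bins))),
      file.path(out_dir, "mua_bins.csv"), row.names = FALSE)
    write.csv(do.call(rbind, lapply(summaries, function(s)
      cbind(subject = s$subject_id, s$roi_power))),
      file.path(out_dir, "roi_power.csv"), row.names = FALSE)
    anova_tab <- do.call(rbind, lapply(names(st$roi_tests), function(rn)
      cbind(roi = rn, st$roi_tests[[rn]]$anova)))
    write.csv(anova_tab, file.path(out_dir, "roi_anova.csv"), row.names = FALSE)
    cl <- st$ies_cluster$clusters
    cl_tab <- if (length(cl)) do.call(rbind, lapply(seq_along(cl), function(k)
      data.frame(cluster = k, sign = cl[[k]]$sign, mass = cl[[k]]$mass,
                 n_bins = nrow(cl[[k]]$members), p = cl[[k]]$p,
                 significant = cl[[k]]$significant)))
      else data.frame(cluster = integer(0), sign = character(0),
                      mass = numeric(0), n_bins = integer(0), p = numeric(0),
                      significant = logical(0))
    write.csv(cl_tab, file.path(out_dir, "ies_clusters.csv"), row.names = FALSE)
    z <- st$ies_cluster$z_obs
    if (length(z)) {
      sig_members <- do.call(rbind, lapply(cl[vapply(cl, `[[`, logical(1), "significant")],
                                           `[[`, "members"))
      zm <- data.frame(depth = rep(seq_len(nrow(z)), ncol(z)),
                       frequency_hz = rep(st$freqs, each = nrow(z)),
                       z = as.vector(z), in_cluster = FALSE)
      if (!is.null(sig_members))
        zm$in_cluster <- paste(zm$depth, rep(seq_len(ncol(z)), each = nrow(z))) %in%
          paste(sig_members[, "depth"], sig_members[, "frequency"])
      write.csv(zm, file.path(out_dir, "ies_z_map.csv"), row.names = FALSE)
    }
    if (!is.null(truth)) {
      rec_tab <- run_effect_recovery(st, truth)
      write.csv(rec_tab, file.path(out_dir, "effect_recovery.csv"), row.names = FALSE)
    }
    manifest <- list(package_version = as.character(utils::packageVersion("laminarodd")),
                     config_hash = config_hash(cfg), seed = cfg$seed,
                     inputs = basename(files),
                     n_subjects = length(files),
                     mua_excluded = st$mua_excluded,
                     elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
                     outputs = list.files(out_dir))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    summaries
  }, error = function(e) {
    unlink(list.files(out_dir, full.names = TRUE))
    stop("pipeline failed at ", current, ": ", conditionMessage(e), call. = FALSE)
  })
  invisible(out_dir)
}
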