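csd_depth_kernel <- function(kind = c("hamming", "gaussian")) {
  kind <- match.arg(kind)
  k <- if (kind == "hamming") 0.54 - 0.46 * cos(2 * pi * (0:4) / 4)
       else exp(-((-2:2)^2) / 2)
  k / sum(k)
}

#' Current source density of epoched LFP
#'
#' Second spatial difference of the voltage along depth (sinks negative,
#' `-d2V/dz2`), followed by depth smoothing with a normalised 5-point kernel
#' (Hamming by default, Gaussian as an alternative). Boundary contacts are
#' handled by Vaknin replication of the edge voltages (default), which keeps
#' the full contact count so the 12-contact layer window fits, or by
#' dropping the contacts whose second difference is undefined.
#'
#' @param epochs an [epoch_tensor()] in the `lfp` domain.
#' @param geometry a [probe_geometry()] (supplies the pitch).
#' @param smoothing `"hamming"`, `"gaussian"` or `"none"`.
#' @param boundary `"vaknin"` or `"drop"`.
#' @return an [epoch_tensor()] in the `csd` domain (units uV/um^2 up to the
#'   extracellular conductivity).
#' @export
compute_csd <- function(epochs, geometry, smoothing = "hamming",
                        boundary = c("vaknin", "drop")) {
  boundary <- match.arg(boundary)
  stopifnot(inherits(epochs, "epoch_tensor"))
  A <- epochs$data
  nc <- dim(A)[2]
  if (nc < 5) stop("compute_csd needs at least 5 contacts")
  h2 <- geometry$pitch_um^2
  if (boundary == "vaknin") {
    P <- A[, c(1, seq_len(nc), nc), , drop = FALSE]
    labels <- epochs$contact_labels
  } else {
    P <- A
    labels <- epochs$contact_labels[2:(nc - 1)]
  }
  np <- dim(P)[2]
  csd <- -(P[, 1:(np - 2), , drop = FALSE] - 2 * P[, 2:(np - 1), , drop = FALSE] +
             P[, 3:np, , drop = FALSE]) / h2
  if (smoothing != "none") {
    k5 <- csd_depth_kernel(smoothing)
    m <- dim(csd)[2]
    Q <- csd[, c(1, 1, seq_len(m), m, m), , drop = FALSE]  # edge replication
    sm <- array(0, dim(csd))
    for (j in 1:5)
      sm <- sm + k5[j] * Q[, j:(j + m - 1), , drop = FALSE]
    csd <- sm
  }
  out <- epoch_tensor(csd, epochs$time_ms, domain = "csd",
                      context = epochs$context, fs = epochs$fs,
                      contact_labels = labels)
  attr(out, "smoothing") <- smoothing
  attr(out, "boundary") <- boundary
  out
}

#' Layer partition around the granular alignment contact
#'
#' Keeps the 12 contacts from 7 above to 4 below the layer-4 contact and
#' assigns, from the top: 2 contacts to superficial/L1, 5 to supragranular
#' L2/3, 2 to granular L4 (the alignment contact is the first of the two),
#' and 3 to infragranular L5.
#'
#' @param l4_contact alignment contact index (1 = most superficial).
#' @param geometry a [probe_geometry()].
#' @return list of class `"layer_map"` with `l4_contact`, `kept_contacts`
#'   (absolute indices, superficial first) and `layer_of_contact`.
#' @export
layer_partition <- function(l4_contact, geometry = probe_geometry()) {
  if (l4_contact - 7 < 1 || l4_contact + 4 > geometry$n_contacts)
    stop("the 12-contact window (7 above, 5 below) does not fit around contact ",
         l4_contact, "; re-insertion at a different depth would be required")
  kept <- (l4_contact - 7):(l4_contact + 4)
  lab <- rep(c("L1", "L2/3", "L4", "L5"), c(2, 5, 2, 3))
  structure(list(l4_contact = as.integer(l4_contact),
                 kept_contacts = kept,
                 layer_of_contact = setNames(lab, kept)),
            class = "layer_map")
}

layer_contacts <- function(layers, layer) {
  as.integer(names(layers$layer_of_contact)[layers$layer_of_contact == layer])
}

layer_names <- function() c("L1", "L2/3", "L4", "L5")

#' Rectified per-layer CSD waveform (av-rec montage)
#'
#' Averages the CSD across trials at the individual-channel level, takes the
#' absolute value, and averages the rectified currents within each layer,
#' yielding one non-negative waveform per layer.
#'
#' @param csd an [epoch_tensor()] in the `csd` domain.
#' @param layers a [layer_partition()].
#' @return list of class `"avrec_waveform"`: `data` (layer x time, >= 0) and
#'   `time_ms`.
#' @export
avrec <- function(csd, layers) {
  stopifnot(inherits(csd, "epoch_tensor"), dim(csd$data)[1] >= 1)
  chan_mean <- colMeans(csd$data, dims = 1)  # contacts x time
  rect <- abs(chan_mean)
  out <- matrix(0, 4, dim(rect)[2], dimnames = list(layer_names(), NULL))
  for (ly in layer_names()) {
    idx <- match(layer_contacts(layers, ly), csd$contact_labels)
    if (any(is.na(idx)) || length(idx) == 0)
      stop("layer ", ly, " has no channels in the CSD tensor")
    out[ly, ] <- colMeans(rect[idx, , drop = FALSE])
  }
  structure(list(data = out, time_ms = csd$time_ms, context = csd$context),
            class = "avrec_waveform")
}

#' Locate the granular (layer 4) alignment contact
#'
#' Combines three criteria by rank sum: (i) earliest multiunit response peak,
#' (ii) earliest current sink, and (iii) the depth at which the power
#' spectrum shifts from gamma (30--80 Hz) dominance to alpha/beta (8--30 Hz)
#' dominance (the shift marks the supragranular/infragranular transition, two
#' contacts below the granular contact). Contacts whose MUA peak or sink is
#' weak (< 25% of the strongest) do not compete on the latency criteria.
#' Ties break toward the more superficial contact. A warning is raised when
#' the per-criterion winners disagree by more than 3 contacts; the rank-sum
#' winner is still returned.
#'
#' @param mua_avg contacts x time matrix of trial-averaged MUA.
#' @param csd_avg contacts x time matrix of trial-averaged CSD (sinks
#'   negative).
#' @param power_by_contact contacts x frequency matrix of spectral power.
#' @param time_ms time axis of the two averages.
#' @param freqs frequency axis of `power_by_contact`, Hz.
#' @param bands crossover bands, `list(gamma =, albeta =)`.
#' @param search_ms latency search window, ms.
#' @return the alignment contact index, with attribute `"votes"` (the three
#'   per-criterion winners) and `"ranks"`.
#' @export
align_layer4 <- function(mua_avg, csd_avg, power_by_contact, time_ms, freqs,
                         bands = list(gamma = c(30, 80), albeta = c(8, 30)),
                         search_ms = c(0, 200)) {
  nc <- nrow(mua_avg)
  stopifnot(nrow(csd_avg) == nc, nrow(power_by_contact) == nc)
  win <- which(time_ms >= search_ms[1] & time_ms <= search_ms[2])

  # latency scores discounted by relative amplitude: among contacts whose
  # responses onset together, the strongest (granular) one wins
  peak_amp <- apply(mua_avg[, win, drop = FALSE], 1, max)
  lat_mua <- time_ms[win][apply(mua_avg[, win, drop = FALSE], 1, which.max)]
  lat_mua <- lat_mua + 15 * (1 - peak_amp / max(peak_amp))
  lat_mua[peak_amp < 0.25 * max(peak_amp) | max(peak_amp) == 0] <- Inf

  sink_amp <- apply(csd_avg[, win, drop = FALSE], 1, min)
  lat_csd <- time_ms[win][apply(csd_avg[, win, drop = FALSE], 1, which.min)]
  lat_csd <- lat_csd + 15 * (1 - sink_amp / min(sink_amp))
  lat_csd[sink_amp > 0.25 * min(sink_amp) | min(sink_amp) >= 0] <- Inf

  gsel <- freqs >= bands$gamma[1] & freqs <= bands$gamma[2]
  bsel <- freqs >= bands$albeta[1] & freqs <= bands$albeta[2]
  ratio <- rowMeans(power_by_contact[, gsel, drop = FALSE]) /
    rowMeans(power_by_contact[, bsel, drop = FALSE])
  cross <- which(ratio < 1)[1]
  score_x <- if (is.na(cross) || cross <= 1 || all(ratio < 1)) rep(NA_real_, nc)
             else abs(seq_len(nc) - (cross - 2))

  crits <- list(mua = lat_mua, csd = lat_csd, crossover = score_x)
  ranks <- vapply(crits, function(s) {
    if (all(!is.finite(s)) || all(is.na(s))) return(rep((nc + 1) / 2, nc))
    rank(s, ties.method = "average")
  }, numeric(nc))
  total <- rowSums(ranks)
  winner <- which(total == min(total))[1]  # superficial tie-break

  votes <- vapply(crits, function(s)
    if (all(!is.finite(s)) || all(is.na(s))) NA_integer_
    else which(s == min(s, na.rm = TRUE))[1], integer(1))
  vv <- votes[!is.na(votes)]
  if (length(vv) > 1 && diff(range(vv)) > 3)
    warning("layer-4 alignment criteria disagree by more than 3 contacts (",
            paste(names(votes), votes, sep = "=", collapse = ", "), ")")
  structure(as.integer(winner), votes = votes, ranks = ranks)
}
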