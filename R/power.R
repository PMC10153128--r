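#' Baseline-corrected induced power per layer
#'
#' Induced power is the across-trial average of the squared wavelet
#' coefficient magnitudes, averaged over each layer's contacts. A global
#' baseline -- the mean power in the baseline window pooled over *all*
#' contexts and trials, one scalar per frequency and layer -- is subtracted
#' from every context's map, so between-context differences are untouched by
#' the correction.
#'
#' @param tf_by_context named list (context -> `tf_tensor` from
#'   [morlet_decompose()]), all on the same grid.
#' @param layers a [layer_partition()].
#' @param baseline_ms baseline window, ms (default -200 to -50 pre-stimulus).
#' @return list of class `"tf_power"`: `power` (named list of layer x
#'   frequency x time arrays, baseline-subtracted), `baseline` (layer x
#'   frequency matrix), `freqs`, `time_ms`.
#' @export
induced_power <- function(tf_by_context, layers, baseline_ms = c(-200, -50)) {
  stopifnot(length(tf_by_context) >= 1)
  f0 <- tf_by_context[[1]]
  bsel <- f0$time_ms >= baseline_ms[1] & f0$time_ms <= baseline_ms[2]
  if (!any(bsel)) stop("baseline window contains no time bins")
  lys <- layer_names()
  raw <- lapply(tf_by_context, function(tf) {
    p <- colMeans(Mod(tf$coef)^2, dims = 1)  # contacts x f x t
    out <- array(0, c(length(lys), dim(p)[2], dim(p)[3]),
                 dimnames = list(lys, NULL, NULL))
    for (i in seq_along(lys)) {
      idx <- match(layer_contacts(layers, lys[i]), tf$contact_labels)
      out[i, , ] <- colMeans(p[idx, , , drop = FALSE], dims = 1)
    }
    out
  })
  ntr <- vapply(tf_by_context, function(tf) dim(tf$coef)[1], numeric(1))
  base <- Reduce(`+`, Map(function(r, w) w * r[, , bsel, drop = FALSE] , raw, ntr))
  base <- apply(base, c(1, 2), sum) / (sum(ntr) * sum(bsel))  # layer x f
  corrected <- lapply(raw, function(r) r - as.vector(base))
  structure(list(power = corrected, baseline = base, freqs = f0$freqs,
                 time_ms = f0$time_ms, layers = lys),
            class = "tf_power")
}

#' Mean induced power in a time-frequency region of interest
#'
#' @param tfp a [induced_power()] result.
#' @param roi one row of [default_rois()] (fields f_lo, f_hi, t_lo, t_hi).
#' @param context context name.
#' @param layer layer name.
#' @return scalar mean power in the ROI.
#' @export
roi_power <- function(tfp, roi, context, layer) {
  fs <- tfp$freqs >= roi$f_lo & tfp$freqs <= roi$f_hi
  ts <- tfp$time_ms >= roi$t_lo & tfp$time_ms <= roi$t_hi
  mean(tfp$power[[context]][layer, fs, ts])
}
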