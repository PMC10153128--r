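overlaps <- function(a_lo, a_hi, b_lo, b_hi) a_lo <= b_hi & a_hi >= b_lo

#' Effect-recovery report
#'
#' Cross-references the cohort statistics against the injected ground truth:
#' an effect counts as recovered when a test of the matching kind is
#' significant (p < 0.05; clusters at their own corrected threshold) in the
#' correct layer, with the correct sign, and with overlapping time window
#' and/or frequency band.
#'
#' @param stats a [cohort_stats()].
#' @param truth the generating [ground_truth()].
#' @param alpha significance level for the windowed and ROI tests.
#' @return data.frame: effect, kind, layer, expected_sign, detected,
#'   statistic, p.
#' @export
run_effect_recovery <- function(stats, truth, alpha = 0.05) {
  kept <- (truth$l4_contact - 7):(truth$l4_contact + 4)
  rows <- lapply(truth$effects, function(e) {
    dev_g <- context_gain(e, "deviant")
    red_g <- context_gain(e, "redundant")
    contrast <- if (abs(red_g - 1) > abs(dev_g - 1)) "SSA" else "DD"
    gain <- if (contrast == "SSA") red_g else dev_g
    expected_sign <- if (gain > 1) 1 else -1
    det <- FALSE; stat <- NA_real_; pval <- NA_real_

    if (e$kind == "mua_rate") {
      w <- stats$windowed
      sel <- w$domain == "mua" & w$contrast == contrast & w$layer == e$layer &
        overlaps(w$t_lo, w$t_hi, e$window_ms[1], e$window_ms[2]) &
        !is.na(w$kept_pos) & kept[w$kept_pos] %in% e$contacts
      hits <- w[sel & w$p < alpha & sign(w$estimate) == expected_sign, ]
      if (nrow(hits)) { det <- TRUE; stat <- hits$t[which.min(hits$p)]
                        pval <- min(hits$p) }
      else if (any(sel)) { k <- which(sel)[which.min(w$p[sel])]
                           stat <- w$t[k]; pval <- w$p[k] }
    } else if (e$kind == "burst") {
      rois <- stats$rois %||% default_rois()
      for (rn in names(stats$roi_tests)) {
        rt <- stats$roi_tests[[rn]]
        def <- rois[rois$name == rn, ]
        if (!nrow(def)) next
        if (!overlaps(def$f_lo, def$f_hi, e$band_hz[1], e$band_hz[2])) next
        if (!overlaps(def$t_lo, def$t_hi, e$window_ms[1], e$window_ms[2])) next
        cand <- NULL
        if (!is.null(rt$planned) && rt$planned$layer == e$layer &&
            contrast == "DD" && expected_sign > 0)
          cand <- rbind(cand, rt$planned[, c("layer", "contrast", "estimate", "t", "df", "p")])
        if (!is.null(rt$contrasts))
          cand <- rbind(cand, rt$contrasts[rt$contrasts$layer == e$layer &
                                             rt$contrasts$contrast == contrast, ])
        if (is.null(cand) || !nrow(cand)) next
        ok <- cand$p < alpha & sign(cand$estimate) == expected_sign
        if (any(ok)) {
          det <- TRUE
          stat <- cand$t[ok][which.min(cand$p[ok])]
          pval <- min(cand$p[ok])
          break
        } else if (is.na(pval)) { stat <- cand$t[1]; pval <- cand$p[1] }
      }
    } else if (e$kind == "coupling") {
      targ_pos <- match(e$target_contacts, kept)
      for (cl in stats$ies_cluster$clusters) {
        if (!cl$significant) next
        if ((cl$sign == "negative") != (expected_sign < 0)) next
        fr <- stats$freqs[cl$members[, "frequency"]]
        hit <- any(cl$members[, "depth"] %in% targ_pos &
                     overlaps(fr, fr, e$band_hz[1], e$band_hz[2]))
        if (hit) { det <- TRUE; stat <- cl$mass; pval <- cl$p; break }
      }
      if (is.na(pval) && length(stats$ies_cluster$clusters)) {
        cl <- stats$ies_cluster$clusters[[1]]
        stat <- cl$mass; pval <- cl$p
      }
    }
    data.frame(effect = e$name, kind = e$kind, layer = e$layer,
               contrast = contrast, expected_sign = expected_sign,
               detected = det, statistic = stat, p = pval,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
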