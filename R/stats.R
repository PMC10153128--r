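#' Windowed paired contrast
#'
#' Paired t-test on per-subject values of one 30 ms spatiotemporal bin,
#' comparing a context against control. MUA contrasts are one-tailed in the
#' hypothesised direction (adaptation to redundants = reduction, deviance
#' detection = increase); CSD contrasts are two-tailed, since more or less
#' transsynaptic current is compatible with either phenomenon.
#'
#' @param control,other per-subject values (paired, same order).
#' @param contrast `"DD"` (deviant - control) or `"SSA"` (redundant -
#'   control).
#' @param domain `"mua"` or `"csd_avrec"` (sets the tail convention).
#' @param layer,window_ms bookkeeping fields copied to the output.
#' @return one-row data.frame: domain, layer, window start/end, contrast,
#'   tail, estimate (mean difference), t, df, p.
#' @export
windowed_ttest <- function(control, other, contrast = c("DD", "SSA"),
                           domain = c("mua", "csd_avrec"), layer = NA,
                           window_ms = c(NA, NA)) {
  contrast <- match.arg(contrast)
  domain <- match.arg(domain)
  if (length(control) != length(other) || anyNA(control) || anyNA(other))
    stop("paired values incomplete: ",
         paste(which(is.na(control) | is.na(other)), collapse = ", "))
  if (length(control) < 3) stop("need at least 3 subjects")
  tail <- if (domain == "mua") {
    if (contrast == "DD") "greater" else "less"
  } else "two.sided"
  tt <- t.test(other, control, paired = TRUE, alternative = tail)
  data.frame(domain = domain, layer = layer, t_lo = window_ms[1],
             t_hi = window_ms[2], contrast = contrast, tail = tail,
             estimate = unname(tt$estimate), t = unname(tt$statistic),
             df = unname(tt$parameter), p = tt$p.value,
             stringsAsFactors = FALSE)
}

#' Layer-by-context repeated-measures ANOVA on one time-frequency ROI
#'
#' Two-way repeated-measures ANOVA (LAYER x CONTEXT, both within subject)
#' with Greenhouse--Geisser sphericity correction by default, followed by
#' planned paired contrasts: per-layer deviant-vs-control (DD) and
#' redundant-vs-control (SSA) t-tests are reported when the interaction is
#' significant, and the single a-priori planned test -- supragranular (L2/3)
#' delta/theta DD, one-tailed increase -- is always run.
#'
#' @param tbl data.frame with columns `subject`, `layer` (4 levels),
#'   `context` (control/redundant/deviant), `value`; must be complete.
#' @param planned_layer layer of the always-run planned DD test (`NA` to
#'   skip).
#' @param sphericity `"GG"`, `"HF"` or `"none"`.
#' @param alpha significance level gating the post-hoc contrasts.
#' @return list: `anova` (data.frame with effect, df, F, p, p_corrected),
#'   `interaction_p`, `contrasts` (per-layer DD/SSA paired tests),
#'   `planned` (the a-priori test row or NULL).
#' @export
roi_anova <- function(tbl, planned_layer = "L2/3", sphericity = "GG",
                      alpha = 0.05) {
  need <- c("subject", "layer", "context", "value")
  stopifnot(all(need %in% names(tbl)))
  tbl$layer <- factor(tbl$layer, levels = layer_names())
  tbl$context <- factor(tbl$context, levels = c("control", "redundant", "deviant"))
  # wide matrix: subjects x (layer x context) cells
  subs <- sort(unique(tbl$subject))
  cells <- expand.grid(context = levels(tbl$context), layer = levels(tbl$layer))
  Y <- matrix(NA_real_, length(subs), nrow(cells))
  for (i in seq_along(subs)) {
    for (j in seq_len(nrow(cells))) {
      v <- tbl$value[tbl$subject == subs[i] & tbl$layer == cells$layer[j] &
                       tbl$context == cells$context[j]]
      if (length(v) != 1) stop("incomplete subject x layer x context table")
      Y[i, j] <- v
    }
  }
  idata <- data.frame(layer = cells$layer, context = cells$context)
  fit <- stats::lm(Y ~ 1)
  av <- car::Anova(fit, idata = idata, idesign = ~ layer * context, type = "III")
  # suppress the benign "HF eps > 1 treated as 1" note
  s <- suppressWarnings(summary(av, multivariate = FALSE))
  uni <- s$univariate.tests
  eff <- c("layer", "context", "layer:context")
  res <- data.frame(effect = eff,
                    df1 = uni[eff, "num Df"], df2 = uni[eff, "den Df"],
                    F = uni[eff, "F value"], p = uni[eff, "Pr(>F)"],
                    stringsAsFactors = FALSE)
  res$p_corrected <- res$p
  if (sphericity %in% c("GG", "HF") && !is.null(s$pval.adjustments) &&
      nrow(s$pval.adjustments) > 0) {
    col <- if (sphericity == "GG") "Pr(>F[GG])" else "Pr(>F[HF])"
    adj <- s$pval.adjustments
    for (e in rownames(adj)) res$p_corrected[res$effect == e] <- adj[e, col]
  }
  ip <- res$p_corrected[res$effect == "layer:context"]

  cell_values <- function(ly, ctx) {
    sel <- tbl$layer == ly & tbl$context == ctx
    tbl$value[sel][match(subs, tbl$subject[sel])]
  }
  per_layer <- function() {
    out <- list()
    for (ly in layer_names()) {
      for (ctr in c("DD", "SSA")) {
        ctx <- if (ctr == "DD") "deviant" else "redundant"
        x <- cell_values(ly, ctx)
        x0 <- cell_values(ly, "control")
        tt <- t.test(x, x0, paired = TRUE)
        out[[length(out) + 1]] <- data.frame(layer = ly, contrast = ctr,
                                             estimate = unname(tt$estimate),
                                             t = unname(tt$statistic),
                                             df = unname(tt$parameter),
                                             p = tt$p.value,
                                             stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, out)
  }
  contrasts <- if (!is.na(ip) && ip < alpha) per_layer() else NULL

  planned <- NULL
  if (!is.na(planned_layer)) {
    x <- cell_values(planned_layer, "deviant")
    x0 <- cell_values(planned_layer, "control")
    tt <- t.test(x, x0, paired = TRUE, alternative = "greater")
    planned <- data.frame(layer = planned_layer, contrast = "DD",
                          estimate = unname(tt$estimate), t = unname(tt$statistic),
                          df = unname(tt$parameter), p = tt$p.value,
                          tail = "greater", stringsAsFactors = FALSE)
  }
  list(anova = res, interaction_p = ip, contrasts = contrasts, planned = planned)
}
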