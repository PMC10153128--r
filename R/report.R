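#' Render the analysis report
#'
#' Builds the three figure analogues from a [run_pipeline()] results
#' directory -- (1) per-layer av-rec and MUA traces by context with
#' significant 30 ms bins shaded, (2) ROI induced-power scatter by layer and
#' context, (3) the deviant-minus-control superficial-seed synchrony
#' difference map with significant cluster bins marked -- plus the test and
#' (if present) effect-recovery tables, into a single Markdown document with
#' standalone PNG figures.
#'
#' @param results_dir directory written by [run_pipeline()].
#' @param out_file report path (defaults to `report.md` inside
#'   `results_dir`).
#' @return path of the report, invisibly.
#' @export
make_report <- function(results_dir, out_file = file.path(results_dir, "report.md")) {
  need <- c("windowed_tests.csv", "avrec_bins.csv", "mua_bins.csv",
            "roi_power.csv", "roi_anova.csv", "ies_clusters.csv", "manifest.json")
  missing <- need[!file.exists(file.path(results_dir, need))]
  if (length(missing))
    stop("results directory incomplete; missing: ", paste(missing, collapse = ", "))
  wt <- read.csv(file.path(results_dir, "windowed_tests.csv"))
  av <- read.csv(file.path(results_dir, "avrec_bins.csv"))
  mu <- read.csv(file.path(results_dir, "mua_bins.csv"))
  rp <- read.csv(file.path(results_dir, "roi_power.csv"))
  an <- read.csv(file.path(results_dir, "roi_anova.csv"))
  cl <- read.csv(file.path(results_dir, "ies_clusters.csv"))

  figs <- character(0)
  agg <- aggregate(value ~ layer + t_lo + context, av, mean)
  sig <- wt[wt$p < 0.05 & wt$domain == "csd_avrec", c("layer", "t_lo", "contrast")]
  p1 <- ggplot2::ggplot(agg, ggplot2::aes(t_lo, value, colour = context)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~layer, scales = "free_y") +
    ggplot2::labs(x = "bin start (ms)", y = "av-rec CSD (a.u.)",
                  title = "Rectified CSD by layer and context (30 ms bins)") +
    ggplot2::theme_minimal()
  if (nrow(sig))
    p1 <- p1 + ggplot2::geom_vline(data = sig, ggplot2::aes(xintercept = t_lo),
                                   linetype = 3, colour = "grey40")
  f1 <- file.path(results_dir, "fig_responses.png")
  ggplot2::ggsave(f1, p1, width = 7, height = 5, dpi = 110)
  figs <- c(figs, f1)

  aggm <- aggregate(value ~ layer + t_lo + context, mu, mean)
  p1b <- ggplot2::ggplot(aggm, ggplot2::aes(t_lo, value, colour = context)) +
    ggplot2::geom_line() + ggplot2::facet_wrap(~layer, scales = "free_y") +
    ggplot2::labs(x = "bin start (ms)", y = "normalised MUA",
                  title = "MUA envelope by layer and context") +
    ggplot2::theme_minimal()
  f1b <- file.path(results_dir, "fig_mua.png")
  ggplot2::ggsave(f1b, p1b, width = 7, height = 5, dpi = 110)
  figs <- c(figs, f1b)

  p2 <- ggplot2::ggplot(rp, ggplot2::aes(context, value, colour = context)) +
    ggplot2::geom_jitter(width = 0.15, size = 0.8) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          linewidth = 0.3) +
    ggplot2::facet_grid(roi ~ layer, scales = "free_y") +
    ggplot2::labs(y = "baseline-corrected induced power (a.u.)",
                  title = "Time-frequency ROI power by layer and context") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  f2 <- file.path(results_dir, "fig_roi_power.png")
  ggplot2::ggsave(f2, p2, width = 8, height = 9, dpi = 110)
  figs <- c(figs, f2)

  zfile <- file.path(results_dir, "ies_z_map.csv")
  if (file.exists(zfile)) {
    zm <- read.csv(zfile)
    p3 <- ggplot2::ggplot(zm, ggplot2::aes(frequency_hz, depth, fill = z)) +
      ggplot2::geom_tile() +
      ggplot2::scale_y_reverse() +
      ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red") +
      ggplot2::labs(x = "frequency (Hz)", y = "kept contact (superficial = 1)",
                    title = "Deviant - control synchrony (L1 seed), z map") +
      ggplot2::theme_minimal()
    if (any(zm$in_cluster))
      p3 <- p3 + ggplot2::geom_point(data = zm[zm$in_cluster, ], size = 0.4,
                                     colour = "black")
    f3 <- file.path(results_dir, "fig_ies.png")
    ggplot2::ggsave(f3, p3, width = 7, height = 4, dpi = 110)
    figs <- c(figs, f3)
  }

  fmt_tab <- function(df) {
    if (!nrow(df)) return("(none)\n")
    df <- as.data.frame(lapply(df, function(x) if (is.numeric(x)) signif(x, 4) else x))
    paste0("| ", paste(names(df), collapse = " | "), " |\n",
           "|", paste(rep("---", ncol(df)), collapse = "|"), "|\n",
           paste(apply(df, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |")),
                 collapse = "\n"), "\n")
  }
  sig_w <- wt[wt$p < 0.05, ]
  lines <- c(
    "# Laminar oddball analysis report", "",
    "## Figure 1: evoked responses (av-rec CSD and MUA)",
    paste0("![responses](", basename(figs[1]), ")"),
    paste0("![mua](", basename(figs[2]), ")"), "",
    "## Figure 2: induced power ROIs",
    paste0("![roi](", basename(figs[3]), ")"), "",
    "## Figure 3: inter-electrode synchrony",
    if (length(figs) > 3) paste0("![ies](", basename(figs[4]), ")")
    else "(synchrony z map not exported)", "",
    "## Table 1: significant windowed contrasts (p < 0.05, uncorrected)",
    fmt_tab(sig_w[, c("domain", "layer", "t_lo", "t_hi", "contrast", "t", "df", "p")]),
    "## Table 2: IES clusters",
    fmt_tab(cl))
  rec_file <- file.path(results_dir, "effect_recovery.csv")
  if (file.exists(rec_file))
    lines <- c(lines, "", "## Table 3: effect recovery",
               fmt_tab(read.csv(rec_file)))
  writeLines(unlist(lines), out_file)
  invisible(out_file)
}
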