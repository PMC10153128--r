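#' Analysis configuration
#'
#' Bundles every tunable of the pipeline with defaults matching the reference
#' laminar oddball protocol: 110 Hz LFP low-pass, 500--4000 Hz MUA band with
#' 10 ms Gaussian smoothing and a 1000 Hz output rate, a 100-wavelet Morlet
#' grid (2--101 Hz, 0.5 to 20 cycles, 4 ms hop), a -200 to -50 ms pre-stimulus
#' baseline, 30 ms statistical bins, 50--250 / 250--450 ms synchrony windows
#' with a +2-trial surrogate, and a 2500-permutation cluster test at
#' alpha = 0.025 per tail.
#'
#' @param ... named overrides of any default field.
#' @return A list of class `"analysis_config"`.
#' @export
analysis_config <- function(...) {
  cfg <- list(
    fs = 10000,                   # acquisition rate, Hz
    lowpass_hz = 110,             # LFP low-pass cutoff (passband edge), Hz
    lfp_rate = 1000,              # LFP working rate after decimation, Hz
    mua_band = c(500, 4000),      # MUA band edges, Hz
    mua_smooth_fwhm_ms = 10,      # Gaussian envelope smoothing, FWHM in ms
    mua_smooth_is_sd = FALSE,     # alternative reading: 10 ms is the SD
    mua_rate = 1000,              # MUA envelope output rate, Hz
    mua_floor = 0.5,              # "no clear response" floor, normalised units
    epoch_ms = c(-250, 750),      # stored epoch window relative to onset
    lfp_epoch_ms = c(-400, 900),  # wider LFP epoch so wavelet support fits
    wavelet_n = 100,
    wavelet_fmin = 2,
    wavelet_fmax = 101,
    wavelet_cycles = c(0.5, 20),
    wavelet_hop_ms = 4,
    tf_window_ms = c(-250, 750),  # -250 pre-onset .. 250 post-offset (500 ms stim)
    baseline_ms = c(-200, -50),   # induced-power global baseline window
    baseline_alt = FALSE,         # alternative reading: -200 .. +50 ms
    bin_ms = 30,                  # windowed-contrast bin width
    bin_range_ms = c(50, 260),    # analysed bin grid
    ssa_range_ms = c(50, 140),    # a-priori SSA (early, granular) range
    dd_range_ms = c(140, 260),    # a-priori DD (late, supragranular) range
    ies_windows = list(early = c(50, 250), late = c(250, 450)),
    surrogate_offset = 2,         # trials-in-the-future surrogate pairing
    n_perm = 2500,
    cluster_alpha = 0.025,        # per tail
    z_crit = 1.96,                # cluster-forming threshold
    adjacency = 4,                # 4- or 8-neighbourhood in depth x frequency
    csd_smoothing = "hamming",    # "hamming" or "gaussian", 5-point depth kernel
    csd_boundary = "vaknin",      # "vaknin" or "drop"
    crossover_bands = list(gamma = c(30, 80), albeta = c(8, 30)),
    rois = default_rois(),
    roi_holm = FALSE,             # optional Holm correction across the 6 ROIs
    sphericity = "GG",            # Greenhouse-Geisser ("GG"), "HF" or "none"
    matched_max = 12,             # cap on matched trials per context
    merge_0_180 = FALSE,          # treat 0 deg as synonymous with 180 deg
    symmetrize_ies = FALSE,
    seed = 1
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
    cfg <- modifyList(cfg, over)
  }
  validate_config(cfg)
  structure(cfg, class = "analysis_config")
}

validate_config <- function(cfg) {
  stopifnot(cfg$fs > 0, cfg$lowpass_hz > 0, cfg$n_perm >= 100,
            cfg$bin_ms > 0, cfg$cluster_alpha > 0, cfg$cluster_alpha < 0.5)
  if (cfg$fs <= 2 * cfg$mua_band[2])
    stop("fs must exceed twice the upper MUA band edge")
  invisible(cfg)
}

#' Default time-frequency regions of interest
#'
#' The six induced-power ROIs identified on the grand-average spectrogram:
#' bands in Hz, windows in ms post-onset. `caption_variant = TRUE` switches
#' high beta to 26--36 Hz and high gamma to 67--76 Hz (the figure-caption
#' values; the defaults follow the results text).
#'
#' @param caption_variant logical.
#' @return data.frame with columns name, f_lo, f_hi, t_lo, t_hi.
#' @export
default_rois <- function(caption_variant = FALSE) {
  r <- data.frame(
    name = c("early_delta_theta", "early_low_beta", "early_high_beta",
             "mid_high_gamma", "alpha_desync", "late_delta_theta"),
    f_lo = c(2, 12, 26, 68, 6, 2),
    f_hi = c(7, 22, 35, 77, 12, 7),
    t_lo = c(100, 65, 90, 110, 240, 350),
    t_hi = c(150, 180, 120, 260, 310, 560),
    stringsAsFactors = FALSE
  )
  if (caption_variant) {
    r$f_lo[r$name == "early_high_beta"] <- 26; r$f_hi[r$name == "early_high_beta"] <- 36
    r$f_lo[r$name == "mid_high_gamma"] <- 67; r$f_hi[r$name == "mid_high_gamma"] <- 76
  }
  r
}

#' Read or write a configuration file
#'
#' YAML or JSON, keyed on the exact `analysis_config()` field names.
#'
#' @param path file path; format chosen from the extension (.yaml/.yml/.json).
#' @param cfg an `analysis_config`.
#' @return `read_config` returns an `analysis_config`.
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!is.null(raw$ies_windows)) raw$ies_windows <- lapply(raw$ies_windows, as.numeric)
  if (!is.null(raw$rois)) raw$rois <- as.data.frame(raw$rois, stringsAsFactors = FALSE)
  do.call(analysis_config, raw)
}

#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "analysis_config"))
  ext <- tolower(tools::file_ext(path))
  x <- unclass(cfg)
  if (ext %in% c("yaml", "yml")) yaml::write_yaml(x, path)
  else jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Hash of a configuration
#'
#' MD5 of the canonical JSON serialisation; stamped on all derived artifacts
#' so every output is traceable to the configuration and seed that made it.
#'
#' @param cfg an `analysis_config`.
#' @return character scalar.
#' @export
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(cfg), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

# Evaluate code under a temporary RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic per-subject seeds below 2^31.
derive_seeds <- function(master_seed, n) {
  with_seed(master_seed, sample.int(.Machine$integer.max - 1L, n))
}

# One structured log line per pipeline stage (suppressed unless
# options(laminarodd.verbose = TRUE)).
log_stage <- function(stage, cfg_hash = NULL, seed = NULL, ...) {
  if (!isTRUE(getOption("laminarodd.verbose"))) return(invisible(NULL))
  extras <- list(...)
  kv <- if (length(extras))
    paste(names(extras), vapply(extras, function(x) paste(format(x), collapse = "x"),
                                character(1)), sep = "=", collapse = " ")
  else ""
  message(sprintf("[laminarodd] stage=%s hash=%s seed=%s %s",
                  stage, substr(cfg_hash %||% "", 1, 8), seed %||% "", kv))
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stamp <- function(x, cfg, seed = NULL) {
  attr(x, "config_hash") <- config_hash(cfg)
  attr(x, "seed") <- seed %||% cfg$seed
  x
}
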