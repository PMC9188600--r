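# End-to-end orchestration: dataset loading (or synthesis), the 17-feature
# extraction chain per recording, the group statistics table, and the LOOCV
# classification report.

#' Pipeline run configuration
#'
#' Bundles every analysis setting with defaults matching the pipeline's
#' reference front-end: 0.5 s center trim, 4th-order 50 Hz--4 kHz
#' Butterworth band-pass, 75--500 Hz pitch search, Burg formant tracking
#' with a 5.5 kHz ceiling (25 ms window, 6.25 ms step, pre-emphasis from
#' 50 Hz), and a Gaussian-kernel SVM under leave-one-out cross-validation.
#'
#' @param input_dir dataset root laid out as
#'   `<root>/<group>/<subject>/<phoneme>_<rep>.wav`, or `NULL` to synthesize.
#' @param trim_duration seconds kept from the center of each recording.
#' @param band Hz, band-pass edges.
#' @param band_order Butterworth order.
#' @param pitch_range Hz, pulse-detection search range.
#' @param max_formant,formant_window,formant_step,preemph_from,lpc_order
#'   formant-tracker settings (see [formant_track()]).
#' @param feature_set one of `"all"`, `"intensity"`, `"glottal"`,
#'   `"formant_sd"`, `"vtl"`, `"relieff_top10"`.
#' @param phonemes phoneme labels to analyze.
#' @param combine if `TRUE`, concatenate the phoneme tables into one
#'   multi-phoneme classifier input.
#' @param gamma,cost SVM hyperparameters (see [loocv_svm()]).
#' @param relief_k Relief-F neighbor count.
#' @param n_per_class synthetic subjects per class when `input_dir` is NULL.
#' @param seed master seed for synthesis.
#' @return a list of class `run_config`.
#' @export
run_config <- function(input_dir = NULL, trim_duration = 0.5,
                       band = c(50, 4000), band_order = 4,
                       pitch_range = c(75, 500), max_formant = 5500,
                       formant_window = 0.025, formant_step = 0.00625,
                       preemph_from = 50, lpc_order = 12,
                       feature_set = "all", phonemes = "a",
                       combine = FALSE, gamma = NULL, cost = 1,
                       relief_k = 10, n_per_class = 15, seed = 1) {
  structure(as.list(environment()), class = "run_config")
}

FEATURE_SETS <- list(
  intensity = c("intensity_sd", "intensity_range"),
  glottal = c("jitter_abs", "jitter_rel", "shimmer_db", "shimmer_rel",
              "pitch_sd", "hnr", "nhr"),
  formant_sd = c("sd_f1", "sd_f2", "sd_f3", "sd_f4"),
  vtl = c("vtl_f1", "vtl_f2", "vtl_f3", "vtl_f4"))
FEATURE_SETS$all <- unname(unlist(FEATURE_SETS))

#' Extract the 17-feature vector of one recording
#'
#' The full per-recording chain: center trim to the configured duration;
#' band-pass; glottal pulse detection; jitter (abs/rel), shimmer (dB/rel),
#' pitch SD and HNR/NHR from the pulse train; intensity SD and range from
#' the framewise contour; formant SDs and the four apparent vocal tract
#' lengths from the Burg formant track. Formant analysis runs on the
#' trimmed, un-bandpassed signal with its own pre-emphasis front-end, since
#' the 5.5 kHz formant ceiling exceeds the 4 kHz analysis band edge.
#'
#' @param seg an [audio_segment()], at least `trim_duration` long and
#'   voiced.
#' @param config a [run_config()].
#' @return named numeric vector of 17 features.
#' @export
extract_features <- function(seg, config = run_config()) {
  trimmed <- trim_uniform(seg, config$trim_duration)
  filtered <- bandpass(trimmed, config$band[1], config$band[2],
                       config$band_order)
  pt <- detect_pulses(filtered, config$pitch_range[1], config$pitch_range[2])
  harm <- harmonicity(filtered, pt)
  ic <- intensity_contour(filtered)
  istats <- intensity_stats(ic)
  track <- formant_track(trimmed, max_formant = config$max_formant,
                         window = config$formant_window,
                         step = config$formant_step,
                         preemph_from = config$preemph_from,
                         lpc_order = config$lpc_order)
  fstats <- formant_stats(track)
  vtl <- vtl_from_formants(fstats$mean)
  c(intensity_sd = unname(istats["sd"]),
    intensity_range = unname(istats["range"]),
    jitter_abs = jitter_abs(pt), jitter_rel = jitter_rel(pt),
    shimmer_db = shimmer_db(pt), shimmer_rel = shimmer_rel(pt),
    pitch_sd = pitch_sd(pt), hnr = harm$hnr_db, nhr = harm$nhr,
    sd_f1 = unname(fstats$sd[1]), sd_f2 = unname(fstats$sd[2]),
    sd_f3 = unname(fstats$sd[3]), sd_f4 = unname(fstats$sd[4]),
    vtl_f1 = unname(vtl$vtl[1]), vtl_f2 = unname(vtl$vtl[2]),
    vtl_f3 = unname(vtl$vtl[3]), vtl_f4 = unname(vtl$vtl[4]))
}

#' Scan a dataset directory into a recording manifest
#'
#' Walks a dataset root laid out as
#' `<root>/<group>/<subject>/<phoneme>_<rep>.wav` and returns one manifest
#' row per recording.
#'
#' @param root dataset root directory.
#' @return data.frame with columns `path`, `group`, `subject_id`,
#'   `phoneme`, `repetition`.
#' @export
scan_dataset <- function(root) {
  wavs <- list.files(root, pattern = "\\.wav$", recursive = TRUE,
                     full.names = TRUE)
  if (length(wavs) == 0L) {
    pm_stop(sprintf("no WAV files under '%s'", root), "phonemark_no_input")
  }
  rel <- sub(paste0("^", root, "/?"), "", wavs)
  parts <- strsplit(rel, "/")
  ok <- lengths(parts) == 3L
  base <- vapply(parts[ok], `[`, character(1), 3L)
  m <- regmatches(base, regexec("^(.+)_([0-9]+)\\.wav$", base))
  data.frame(path = wavs[ok],
             group = vapply(parts[ok], `[`, character(1), 1L),
             subject_id = vapply(parts[ok], `[`, character(1), 2L),
             phoneme = vapply(m, `[`, character(1), 2L),
             repetition = as.integer(vapply(m, `[`, character(1), 3L)),
             stringsAsFactors = FALSE)
}

#' Build a feature table from a recording manifest
#'
#' Runs [extract_features()] over every row of a manifest and assembles the
#' per-recording feature table. Recordings that fail extraction (unvoiced,
#' too short, unstable formants) are skipped with a logged reason, never
#' silently dropped.
#'
#' @param manifest data.frame with columns `path`, `group`, `subject_id`,
#'   `phoneme`, `repetition` (as produced by [synth_dataset()]).
#' @param config a [run_config()].
#' @param verbose print one line per skipped recording.
#' @return a feature table data.frame; skipped rows are recorded in
#'   `attr(, "skipped")`.
#' @export
build_feature_table <- function(manifest, config = run_config(),
                                verbose = TRUE) {
  rows <- list()
  skipped <- list()
  for (i in seq_len(nrow(manifest))) {
    rec <- manifest[i, ]
    feats <- tryCatch(extract_features(read_wav(rec$path), config),
                      phonemark_error = function(e) e)
    if (inherits(feats, "condition")) {
      reason <- class(feats)[1]
      skipped[[length(skipped) + 1L]] <-
        data.frame(path = rec$path, reason = reason,
                   message = conditionMessage(feats),
                   stringsAsFactors = FALSE)
      if (verbose) {
        message(sprintf("skip %s [%s]: %s", rec$path, reason,
                        conditionMessage(feats)))
      }
      next
    }
    rows[[length(rows) + 1L]] <-
      cbind(rec[c("subject_id", "group", "phoneme", "repetition")],
            as.data.frame(as.list(feats)))
  }
  if (length(rows) == 0L) {
    pm_stop("no recording survived feature extraction", "phonemark_no_input")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(path = character(0), reason = character(0),
               message = character(0))
  out
}

#' Run the full pipeline
#'
#' Synthesizes (or loads) a dataset, extracts the per-recording features,
#' writes the feature table and group-statistics table as CSV and the
#' classification report as JSON under `out_dir`, and returns all three.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created); `NULL` skips writing.
#' @return list with `features` (data.frame), `stats` (data.frame),
#'   `report` (`classification_report`), and `skipped`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  if (is.null(config$input_dir)) {
    synth_root <- file.path(tempdir(),
                            sprintf("phonemark_synth_%d", config$seed))
    manifest <- synth_dataset(synth_root, n_per_class = config$n_per_class,
                              phonemes = config$phonemes, seed = config$seed)
  } else {
    manifest <- scan_dataset(config$input_dir)
    manifest <- manifest[manifest$phoneme %in% config$phonemes, ,
                         drop = FALSE]
    if (nrow(manifest) == 0L) {
      pm_stop("no recordings for the requested phonemes",
              "phonemark_no_input")
    }
  }
  features <- build_feature_table(manifest, config)
  stats_tab <- group_stats_table(features)
  per_ph <- split(features, features$phoneme)
  cls_tab <- if (config$combine && length(per_ph) > 1L) {
    do.call(combine_phonemes, list(per_ph))
  } else features
  feats_used <- classifier_features(cls_tab, config)
  report <- loocv_svm(cls_tab, gamma = config$gamma, cost = config$cost,
                      features = feats_used)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(features, file.path(out_dir, "features.csv"),
              row.names = FALSE)
    write.csv(stats_tab, file.path(out_dir, "group_stats.csv"),
              row.names = FALSE)
    jsonlite::write_json(
      list(tp = report$tp, tn = report$tn, fp = report$fp, fn = report$fn,
           metrics = as.list(report$metrics),
           selected_features = report$selected_features),
      file.path(out_dir, "classification.json"), auto_unbox = TRUE,
      digits = NA)
  }
  list(features = features, stats = stats_tab, report = report,
       skipped = attr(features, "skipped"))
}

# Resolve the configured feature_set into concrete column names of `table`
# (which may carry phoneme prefixes after combine_phonemes).
classifier_features <- function(table, config) {
  fs <- config$feature_set
  cols <- feature_cols(table)
  if (identical(fs, "relieff_top10")) {
    ranked <- relief_f(table, k = min(config$relief_k,
                                      min(table(table$group)) - 1L))
    return(head(ranked$feature, 10L))
  }
  base <- FEATURE_SETS[[fs]]
  if (is.null(base)) {
    pm_stop(sprintf("unknown feature_set '%s'", fs),
            "phonemark_invalid_argument")
  }
  keep <- cols[sub("^[^.]*\\.", "", cols) %in% base]
  if (length(keep) == 0L) {
    pm_stop("feature_set selects no columns", "phonemark_invalid_argument")
  }
  keep
}
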