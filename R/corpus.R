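#' Read a corpus manifest
#'
#' A manifest is a CSV with columns `path` (audio file), `label`, `split`
#' (`train` or `test`) and optionally `sample_rate`. Paths must be unique.
#'
#' @param path CSV file path.
#' @param base_dir directory to resolve relative audio paths against
#'   (default: the manifest's directory).
#' @return A data.frame of class `corpus_manifest`.
#' @export
read_manifest <- function(path, base_dir = dirname(path)) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("path", "label", "split")
  if (!all(required %in% names(m))) {
    stop("manifest needs columns: ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(m$path)) {
    stop("manifest paths must be unique", call. = FALSE)
  }
  bad <- !m$split %in% c("train", "test")
  if (any(bad)) {
    stop("manifest `split` must be 'train' or 'test'", call. = FALSE)
  }
  attr(m, "base_dir") <- base_dir
  class(m) <- c("corpus_manifest", class(m))
  m
}

#' Encoder configuration bundle
#'
#' Collects every knob of the encoding pipeline in one object so corpus
#' conversions are reproducible and fingerprintable.
#'
#' @param bank a [build_filterbank()] result.
#' @param framing a [framing_config()] (default 30 ms / 15 ms at the bank
#'   rate).
#' @param thresholds a [threshold_set()].
#' @param map a [neuron_map()].
#' @param sim_cfg a [simultaneous_mask_config()].
#' @param temp_cfg a [temporal_mask_config()].
#' @param mask apply auditory masking to the encoded patterns.
#' @return A list of class `encoder_config` with a `digest` fingerprint.
#' @export
encoder_config <- function(bank = build_filterbank(),
                           framing = framing_config(bank$fs),
                           thresholds = threshold_set(),
                           map = neuron_map(),
                           sim_cfg = simultaneous_mask_config(),
                           temp_cfg = temporal_mask_config(),
                           mask = TRUE) {
  cfg <- list(bank = bank, framing = framing, thresholds = thresholds,
              map = map, sim_cfg = sim_cfg, temp_cfg = temp_cfg,
              mask = isTRUE(mask))
  cfg$digest <- config_digest(cfg[c("framing", "thresholds", "sim_cfg",
                                    "temp_cfg", "mask")])
  class(cfg) <- "encoder_config"
  cfg
}

#' Encode one utterance with the full pipeline
#'
#' Spectrogram, masking surfaces, pattern-path threshold encoding, and
#' (optionally) masked-spike deletion.
#'
#' @param x an [audio_signal()].
#' @param config an [encoder_config()].
#' @return A list: `pattern` (the final [spike_pattern()]), `raw_pattern`,
#'   `spectrogram`, `map`.
#' @export
encode_utterance <- function(x, config = encoder_config()) {
  x <- as_audio(x)
  if (x$sample_rate != config$bank$fs) {
    x <- resample_audio(x, config$bank$fs)
  }
  spec <- spectrogram(x, config$bank, config$framing)
  raw <- threshold_encode(spec, config$thresholds, config$map)
  if (config$mask) {
    masking <- compute_masking(spec, config$sim_cfg, config$temp_cfg)
    pat <- apply_mask(raw, masking$map, spec)
    list(pattern = pat, raw_pattern = raw, spectrogram = spec,
         map = masking$map)
  } else {
    list(pattern = raw, raw_pattern = raw, spectrogram = spec, map = NULL)
  }
}

#' Convert an audio corpus to a spike dataset
#'
#' Applies [encode_utterance()] to every manifest row and writes a dataset
#' directory: `metadata.json` (encoder fingerprint and settings summary),
#' `events/<stem>.txt` spike event files, and `index.csv` tying each file to
#' its label, split, event count and duration. Unreadable utterances are
#' logged, skipped and counted in the summary.
#'
#' @param manifest a [read_manifest()] result (or a path to a manifest CSV).
#' @param out_dir output directory (created if needed).
#' @param config an [encoder_config()].
#' @param verbose print per-file progress.
#' @return A list of class `spike_dataset`: `index` data.frame, `summary`
#'   (utterance counts, mean spike rate, mean reduction %), `dir`.
#' @export
convert_corpus <- function(manifest, out_dir, config = encoder_config(),
                           verbose = FALSE) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  stopifnot(inherits(manifest, "corpus_manifest"))
  dir.create(file.path(out_dir, "events"), recursive = TRUE,
             showWarnings = FALSE)
  base_dir <- attr(manifest, "base_dir")

  rows <- vector("list", nrow(manifest))
  failures <- character(0)
  rates <- numeric(0); reductions <- numeric(0)
  for (i in seq_len(nrow(manifest))) {
    rel <- manifest$path[i]
    audio_path <- if (file.exists(rel)) rel else file.path(base_dir, rel)
    stem <- sub("\\.[^.]+$", "", basename(rel))
    out <- tryCatch({
      x <- read_wav(audio_path, target_fs = config$bank$fs)
      enc <- encode_utterance(x, config)
      event_file <- file.path("events", paste0(stem, ".txt"))
      write_spike_events(enc$pattern, file.path(out_dir, event_file),
                         config_digest = config$digest)
      st <- spike_stats(enc$raw_pattern, enc$pattern)
      rates <- c(rates, st$rate)
      reductions <- c(reductions, st$reduction_pct)
      data.frame(file = event_file, label = manifest$label[i],
                 split = manifest$split[i], n_events = n_events(enc$pattern),
                 duration = enc$pattern$duration,
                 reduction_pct = st$reduction_pct)
    }, error = function(e) {
      failures <<- c(failures, sprintf("%s: %s", rel, conditionMessage(e)))
      NULL
    })
    if (verbose) {
      message(sprintf("[%d/%d] %s %s", i, nrow(manifest), rel,
                      if (is.null(out)) "FAILED" else "ok"))
    }
    rows[[i]] <- out
  }
  index <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(index)) {
    index <- data.frame(file = character(), label = character(),
                        split = character(), n_events = integer(),
                        duration = numeric(), reduction_pct = numeric())
  }
  utils::write.csv(index, file.path(out_dir, "index.csv"), row.names = FALSE)

  summary <- list(
    n_utterances = nrow(index),
    n_train = sum(index$split == "train"),
    n_test = sum(index$split == "test"),
    n_failed = length(failures),
    mean_spike_rate = if (length(rates)) mean(rates) else NA_real_,
    mean_reduction_pct = if (length(reductions)) mean(reductions) else NA_real_
  )
  metadata <- list(
    format = "spikecodec-dataset/1",
    config_digest = config$digest,
    masking = config$mask,
    n_channels = nrow(config$bank$specs),
    n_neurons = attr(config$map, "K") * attr(config$map, "per_channel"),
    thresholds = config$thresholds$levels,
    summary = summary,
    failures = failures,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(metadata, file.path(out_dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  structure(list(index = index, summary = summary, dir = out_dir,
                 failures = failures),
            class = "spike_dataset")
}

#' @export
print.spike_dataset <- function(x, ...) {
  cat(sprintf(
    "<spike_dataset: %d utterances (%d train / %d test), %d failed>\n",
    x$summary$n_utterances, x$summary$n_train, x$summary$n_test,
    x$summary$n_failed
  ))
  if (!is.na(x$summary$mean_reduction_pct)) {
    cat(sprintf("  mean spike rate %.0f /s, mean reduction %.2f%%\n",
                x$summary$mean_spike_rate, x$summary$mean_reduction_pct))
  }
  invisible(x)
}
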