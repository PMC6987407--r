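#' Write a spike pattern to a text event file
#'
#' The file dialect is a single JSON header line (format tag, sample rate,
#' duration, codec path, provenance, neuron population, level table, event
#' count and column names) followed by one tab-separated row per event:
#' `neuron time channel kind level amplitude`, with times printed at full
#' double precision so that write-then-read round-trips are event-exact.
#' Neuron indices are 0-based.
#'
#' @param pattern a [spike_pattern()].
#' @param path output file path.
#' @param config_digest optional digest string recorded in the header.
#' @return `path`, invisibly.
#' @export
write_spike_events <- function(pattern, path, config_digest = NULL) {
  stopifnot(inherits(pattern, "spike_pattern"))
  header <- list(
    format = "spikecodec-events/1",
    sample_rate = pattern$fs,
    duration = pattern$duration,
    path_kind = pattern$path,
    provenance = pattern$provenance,
    n_events = nrow(pattern$events),
    columns = c("neuron", "time", "channel", "kind", "level", "amplitude")
  )
  if (!is.na(pattern$neurons)) header$neurons <- pattern$neurons
  if (!is.null(pattern$levels)) header$levels <- pattern$levels
  if (!is.null(config_digest)) header$config_digest <- config_digest
  lines <- jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA)
  ev <- pattern$events
  if (nrow(ev) > 0) {
    rows <- sprintf("%d\t%.17g\t%d\t%s\t%s\t%s",
                    ev$neuron, ev$time, ev$channel, ev$kind,
                    ifelse(is.na(ev$level), "NA", as.character(ev$level)),
                    ifelse(is.na(ev$amplitude), "NA",
                           sprintf("%.17g", ev$amplitude)))
    lines <- c(lines, rows)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a spike pattern from a text event file
#'
#' Inverse of [write_spike_events()]; the round trip is lossless.
#'
#' @param path event file path.
#' @return A [spike_pattern()].
#' @export
read_spike_events <- function(path) {
  lines <- readLines(path)
  header <- jsonlite::fromJSON(lines[1], simplifyVector = TRUE)
  if (!identical(header$format, "spikecodec-events/1")) {
    stop("not a spikecodec event file: ", path, call. = FALSE)
  }
  if (length(lines) > 1L) {
    parts <- strsplit(lines[-1], "\t", fixed = TRUE)
    m <- do.call(rbind, parts)
    events <- data.frame(
      neuron = as.integer(m[, 1]), time = as.numeric(m[, 2]),
      channel = as.integer(m[, 3]), kind = m[, 4],
      level = suppressWarnings(as.integer(m[, 5])),
      amplitude = suppressWarnings(as.numeric(m[, 6]))
    )
  } else {
    events <- data.frame(neuron = integer(), time = numeric(),
                         channel = integer(), kind = character(),
                         level = integer(), amplitude = numeric())
  }
  levels <- header$levels
  if (!is.null(levels) && is.list(levels)) {
    levels <- lapply(levels, as.numeric)
  }
  spike_pattern(events, duration = header$duration,
                fs = header$sample_rate, path = header$path_kind,
                provenance = header$provenance,
                neurons = if (is.null(header$neurons)) NA_integer_ else
                  as.integer(header$neurons),
                levels = levels)
}

# Stable digest of an R object (used to fingerprint encoder configs).
config_digest <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  # version 2 serialization is stable across R sessions for plain lists
  saveRDS(x, tmp, version = 2, compress = FALSE)
  unname(tools::md5sum(tmp))
}
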