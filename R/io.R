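# File I/O: delimited-text tables with YAML sidecars, and minimal RIFF/WAVE
# support (PCM 16-bit and IEEE float32) written directly with readBin /
# writeBin.

#' Read and write event tables
#'
#' Events travel as delimited text with the header
#' `onset_s,category,condition,duration_s`; write-then-read round-trips the
#' table exactly (up to numeric print precision).
#'
#' @param events An [event_table()].
#' @param path File path.
#' @return `read_events()` returns an [event_table()].
#' @export
write_events <- function(events, path) {
  validate_event_table(events)
  readr::write_csv(events[, c("onset_s", "category", "condition",
                              "duration_s")], path)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  tb <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          onset_s = readr::col_double(),
                          category = readr::col_character(),
                          condition = readr::col_character(),
                          duration_s = readr::col_double()))
  prob <- readr::problems(tb)
  if (nrow(prob) > 0) {
    abort(sprintf("malformed event file %s at line %d", path, prob$row[1]))
  }
  event_table(tb$onset_s, tb$category, tb$condition, tb$duration_s)
}

#' Read and write WAV audio
#'
#' Minimal RIFF/WAVE support: 16-bit PCM (default) or 32-bit IEEE float.
#' Stereo files are converted to mono on read by averaging the channels.
#'
#' @param audio An [audio_track()].
#' @param path File path.
#' @param bits 16 (PCM) or 32 (float).
#' @return `read_wav()` returns a mono [audio_track()].
#' @export
write_wav <- function(audio, path, bits = 16) {
  stopifnot(inherits(audio, "audio_track"), bits %in% c(16, 32))
  x <- audio$samples
  rate <- as.integer(round(audio$rate))
  n <- length(x)
  bytes_per <- bits / 8
  data_size <- n * bytes_per
  fmt_code <- if (bits == 16) 1L else 3L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt_code, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")          # mono
  writeBin(rate, con, size = 4, endian = "little")
  writeBin(as.integer(rate * bytes_per), con, size = 4, endian = "little")
  writeBin(as.integer(bytes_per), con, size = 2, endian = "little")
  writeBin(as.integer(bits), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  if (bits == 16) {
    writeBin(as.integer(pmax(-32767, pmin(32767, round(x * 32767)))),
             con, size = 2, endian = "little")
  } else {
    writeBin(x, con, size = 4, endian = "little")
  }
  invisible(path)
}

#' @rdname write_wav
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") abort("not a RIFF file")
  invisible(readBin(con, integer(), size = 4, endian = "little"))
  if (readChar(con, 4) != "WAVE") abort("not a WAVE file")
  fmt <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) abort("no data chunk found")
    size <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmt_code <- readBin(con, integer(), size = 2, endian = "little")
      n_ch <- readBin(con, integer(), size = 2, endian = "little")
      rate <- readBin(con, integer(), size = 4, endian = "little")
      invisible(readBin(con, integer(), size = 4, endian = "little"))
      invisible(readBin(con, integer(), size = 2, endian = "little"))
      bits <- readBin(con, integer(), size = 2, endian = "little")
      fmt <- list(code = fmt_code, n_ch = n_ch, rate = rate, bits = bits)
      if (size > 16) invisible(readBin(con, raw(), size - 16))
    } else if (id == "data") {
      if (is.null(fmt)) abort("data chunk precedes fmt chunk")
      n_val <- size / (fmt$bits / 8)
      x <- if (fmt$code == 1 && fmt$bits == 16) {
        readBin(con, integer(), n = n_val, size = 2,
                endian = "little") / 32767
      } else if (fmt$code == 3 && fmt$bits == 32) {
        readBin(con, numeric(), n = n_val, size = 4, endian = "little")
      } else {
        abort(sprintf("unsupported WAV format (code %d, %d bits)",
                      fmt$code, fmt$bits))
      }
      if (fmt$n_ch > 1) {
        x <- colMeans(matrix(x, nrow = fmt$n_ch))  # stereo -> mono average
      }
      return(audio_track(x, fmt$rate))
    } else {
      invisible(readBin(con, raw(), size))
    }
  }
}

#' Read and write EEG recordings
#'
#' The samples go to delimited text (one row per sample, one column per
#' channel); the sampling rate and channel names go to a YAML sidecar
#' (`<path>.yml`). Reading refuses to guess a missing rate.
#'
#' @param eeg An [eeg_recording()].
#' @param path File path for the sample table.
#' @return `read_eeg()` returns an [eeg_recording()].
#' @export
write_eeg <- function(eeg, path) {
  stopifnot(inherits(eeg, "eeg_recording"))
  readr::write_csv(tibble::as_tibble(eeg$data), path)
  yaml::write_yaml(list(rate = eeg$rate,
                        channel_names = as.list(eeg$channel_names)),
                   sidecar_path(path))
  invisible(path)
}

#' @rdname write_eeg
#' @export
read_eeg <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(sc)) {
    abort(sprintf("sidecar %s not found: the sampling rate is mandatory", sc))
  }
  meta <- yaml::read_yaml(sc)
  if (is.null(meta$rate)) abort("sidecar lacks `rate`; refusing to guess")
  tb <- readr::read_csv(path, show_col_types = FALSE)
  eeg_recording(as.matrix(tb), meta$rate,
                unlist(meta$channel_names) %||% colnames(tb))
}

#' Read and write feature sets
#'
#' Delimited text plus a YAML sidecar carrying the rate and per-column
#' discreteness flags.
#'
#' @param features A [feature_set()].
#' @param path File path.
#' @return `read_features()` returns a [feature_set()].
#' @export
write_features <- function(features, path) {
  stopifnot(inherits(features, "feature_set"))
  readr::write_csv(tibble::as_tibble(features$data), path)
  yaml::write_yaml(list(rate = features$rate,
                        names = as.list(features$names),
                        discrete = as.list(features$discrete)),
                   sidecar_path(path))
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(sc)) abort(sprintf("sidecar %s not found", sc))
  meta <- yaml::read_yaml(sc)
  if (is.null(meta$rate)) abort("sidecar lacks `rate`; refusing to guess")
  tb <- readr::read_csv(path, show_col_types = FALSE)
  feature_set(as.matrix(tb), meta$rate, names = unlist(meta$names),
              discrete = unlist(meta$discrete))
}

#' Serialize a fitted TRF
#'
#' Long-format delimited text (feature, lag index, channel, weight) plus a
#' YAML sidecar with the lag window, lambda, rate and names.
#'
#' @param trf A [fit_trf()] result.
#' @param path File path.
#' @return `read_trf()` returns a `trf`.
#' @export
write_trf <- function(trf, path) {
  stopifnot(inherits(trf, "trf"))
  readr::write_csv(tidy(trf), path)
  yaml::write_yaml(list(lambda = trf$lambda, tmin_ms = trf$tmin_ms,
                        tmax_ms = trf$tmax_ms, rate = trf$rate,
                        feature_names = as.list(trf$feature_names),
                        channel_names = as.list(trf$channel_names),
                        residual_rms = as.list(unname(trf$residual_rms))),
                   sidecar_path(path))
  invisible(path)
}

#' @rdname write_trf
#' @export
read_trf <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(sc)) abort(sprintf("sidecar %s not found", sc))
  meta <- yaml::read_yaml(sc)
  tb <- readr::read_csv(path, show_col_types = FALSE)
  fn <- unlist(meta$feature_names)
  cn <- unlist(meta$channel_names)
  lags <- seq.int(round(meta$tmin_ms * meta$rate / 1000),
                  round(meta$tmax_ms * meta$rate / 1000))
  w <- array(0, dim = c(length(fn), length(lags), length(cn)),
             dimnames = list(fn, NULL, cn))
  w[cbind(match(tb$feature, fn), tb$lag_index, match(tb$channel, cn))] <-
    tb$weight
  structure(list(weights = w, lambda = meta$lambda, tmin_ms = meta$tmin_ms,
                 tmax_ms = meta$tmax_ms, rate = meta$rate, lags = lags,
                 feature_names = fn, channel_names = cn,
                 residual_rms = unlist(meta$residual_rms)),
            class = "trf")
}

sidecar_path <- function(path) paste0(path, ".yml")
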