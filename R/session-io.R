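## File interchange: WAV audio, channel-matrix CSV for EEG, CSV for
## NIRS/COMFORT, tab-separated annotation files, JSON ground-truth sidecar.

#' Write a mono waveform as a PCM WAV file
#'
#' Plain RIFF/WAVE writer supporting 16- and 24-bit integer PCM (24-bit is
#' the acquisition default).
#'
#' @param wave numeric vector in `[-1, 1]`.
#' @param path output path.
#' @param fs sampling rate, Hz.
#' @param bits 16 or 24.
#' @return `path`, invisibly.
#' @export
write_wav <- function(wave, path, fs = attr(wave, "fs") %||% cs_default("audio_fs"),
                      bits = cs_default("audio_bits")) {
  cs_assert(bits %in% c(16L, 24L), "bits must be 16 or 24")
  wave <- pmin(pmax(as.numeric(wave), -1), 1)
  n <- length(wave)
  bytes_per <- bits %/% 8L
  data_size <- n * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")          # PCM
  writeBin(1L, con, size = 2, endian = "little")          # mono
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs * bytes_per), con, size = 4, endian = "little")
  writeBin(as.integer(bytes_per), con, size = 2, endian = "little")
  writeBin(as.integer(bits), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  scale <- 2^(bits - 1) - 1
  ints <- as.integer(round(wave * scale))
  if (bits == 16L) {
    writeBin(ints, con, size = 2, endian = "little")
  } else {
    ## 24-bit: three little-endian bytes per sample
    u <- ints %% (2^24)
    b <- rbind(u %% 256, (u %/% 256) %% 256, (u %/% 65536) %% 256)
    writeBin(as.raw(as.integer(b)), con)
  }
  invisible(path)
}

#' Read a mono PCM WAV file
#'
#' @param path WAV path (16- or 24-bit integer PCM, single channel).
#' @return numeric waveform in `[-1, 1]` with attribute `fs`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 4)
  cs_assert(hdr == "RIFF", "not a RIFF file")
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  cs_assert(readChar(con, 4) == "WAVE", "not a WAVE file")
  fs <- NULL; bits <- NULL; wave <- NULL
  repeat {
    tag <- readChar(con, 4)
    if (length(tag) == 0 || nchar(tag) < 4) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (tag == "fmt ") {
      fmt <- readBin(con, "integer", 2, size = 2, endian = "little")
      cs_assert(fmt[1] == 1, "only integer PCM supported")
      cs_assert(fmt[2] == 1, "only mono supported")
      fs <- readBin(con, "integer", 1, size = 4, endian = "little")
      invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
      invisible(readBin(con, "integer", 1, size = 2, endian = "little"))
      bits <- readBin(con, "integer", 1, size = 2, endian = "little")
      if (size > 16) invisible(readBin(con, "raw", size - 16))
    } else if (tag == "data") {
      cs_assert(!is.null(bits), "data chunk before fmt chunk")
      if (bits == 16L) {
        wave <- readBin(con, "integer", size %/% 2, size = 2,
                        endian = "little") / (2^15 - 1)
      } else if (bits == 24L) {
        raw <- as.integer(readBin(con, "raw", size))
        m <- matrix(raw, nrow = 3)
        u <- m[1, ] + 256 * m[2, ] + 65536 * m[3, ]
        u[u >= 2^23] <- u[u >= 2^23] - 2^24
        wave <- u / (2^23 - 1)
      } else stop("unsupported bit depth: ", bits, call. = FALSE)
      break
    } else {
      invisible(readBin(con, "raw", size + size %% 2))
    }
  }
  cs_assert(!is.null(wave), "no data chunk found")
  structure(wave, fs = fs)
}

#' Write / read condition annotations as tab-separated label files
#'
#' Format: `start_s<TAB>end_s<TAB>label`, no header.
#'
#' @param annotations tibble with `start`, `end`, `condition`.
#' @param path file path.
#' @return `path` / tibble.
#' @export
write_annotations <- function(annotations, path) {
  readr::write_tsv(annotations[c("start", "end", "condition")], path,
                   col_names = FALSE)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  readr::read_tsv(path, col_names = c("start", "end", "condition"),
                  col_types = "ddc")
}

#' Write an EEG recording as a channel-matrix CSV
#'
#' Header row of channel names; one row per sample, in uV.
#'
#' @param rec an [eeg_recording()].
#' @param path file path.
#' @return `path` / an [eeg_recording()].
#' @export
write_eeg_csv <- function(rec, path) {
  readr::write_csv(tibble::as_tibble(rec$data), path)
  invisible(path)
}

#' @rdname write_eeg_csv
#' @param fs sampling rate of the stored matrix, Hz.
#' @export
read_eeg_csv <- function(path, fs = cs_default("eeg_fs")) {
  eeg_recording(as.matrix(readr::read_csv(path, show_col_types = FALSE)), fs = fs)
}

#' Write a whole session bundle to a directory
#'
#' Emits `audio.wav` (24-bit PCM), `labels.tsv`, `eeg.csv`, `nirs.csv`,
#' `comfort.csv` and a `truth.json` sidecar with the generator ground truth.
#'
#' @param bundle a `session_bundle`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_wav(bundle$audio, file.path(dir, "audio.wav"), fs = bundle$fs)
  write_annotations(bundle$annotations, file.path(dir, "labels.tsv"))
  write_eeg_csv(bundle$eeg, file.path(dir, "eeg.csv"))
  readr::write_csv(tibble::as_tibble(bundle$nirs), file.path(dir, "nirs.csv"))
  readr::write_csv(bundle$comfort, file.path(dir, "comfort.csv"))
  truth <- bundle$truth
  jsonlite::write_json(list(
    seed = truth$seed,
    episodes = truth$episodes,
    units = dplyr::bind_rows(truth$units),
    unit_params = lapply(truth$unit_params, function(eps)
      lapply(eps, function(p) p[c("f0_mean", "f0_sd", "f0_contour_shape",
                                  "jitter_frac", "shimmer_frac", "hnr_db",
                                  "formants", "level_db")]))
  ), file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
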