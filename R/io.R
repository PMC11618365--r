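# Minimal RIFF/WAVE I/O for 32-bit float PCM, with a JSON calibration
# sidecar recording that samples are sound pressure in pascal. Written
# in-package because the toolchain targets calibrated float audio and a
# sidecar convention of its own.

#' Write a waveform (or binaural waveform) to a float WAV file
#'
#' Samples are written as IEEE float32, one or two channels, with no
#' rescaling: the file stores sound pressure in pascal. A JSON sidecar
#' `<path>.json` records `{"units": "pascal", "fs": ..., "level_dbspl":
#' ...}` so the calibration survives the round trip.
#'
#' @param w a `waveform` or `binaural_waveform`
#' @param path output file path (".wav")
#' @param sidecar write the JSON calibration sidecar (default TRUE)
#' @return `path`, invisibly
#' @export
write_wav <- function(w, path, sidecar = TRUE) {
  if (inherits(w, "binaural_waveform")) {
    chans <- list(w$left$samples, w$right$samples)
    fs <- w$left$fs
    lvl <- db_spl(waveform(c(w$left$samples, w$right$samples), fs))
  } else {
    stopifnot(inherits(w, "waveform"))
    chans <- list(w$samples)
    fs <- w$fs
    lvl <- db_spl(w)
  }
  n_ch <- length(chans)
  n <- length(chans[[1]])
  interleaved <- numeric(n * n_ch)
  for (c in seq_len(n_ch)) interleaved[seq(c, by = n_ch, length.out = n)] <-
    chans[[c]]
  con <- file(path, "wb")
  on.exit(close(con))
  data_bytes <- 4L * n * n_ch
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(3L, con, size = 2, endian = "little")        # IEEE float
  writeBin(n_ch, con, size = 2, endian = "little")
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs * 4L * n_ch), con, size = 4, endian = "little")
  writeBin(as.integer(4L * n_ch), con, size = 2, endian = "little")
  writeBin(32L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(interleaved, con, size = 4, endian = "little")
  if (sidecar) {
    jsonlite::write_json(
      list(units = "pascal", fs = fs, level_dbspl = lvl, channels = n_ch),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a float WAV file written by [write_wav()]
#'
#' @param path WAV file path; a `<path>.json` sidecar, if present, is
#'   checked for the pascal units convention
#' @return a `waveform` (mono) or `binaural_waveform` (two channels)
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file")
  invisible(readBin(con, "integer", size = 4, endian = "little"))
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file")
  fs <- NULL; n_ch <- NULL; bits <- NULL; fmt <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, "integer", size = 2, endian = "little")
      n_ch <- readBin(con, "integer", size = 2, endian = "little")
      fs <- readBin(con, "integer", size = 4, endian = "little")
      invisible(readBin(con, "integer", size = 4, endian = "little"))
      invisible(readBin(con, "integer", size = 2, endian = "little"))
      bits <- readBin(con, "integer", size = 2, endian = "little")
      if (sz > 16) invisible(readBin(con, "raw", n = sz - 16L))
    } else if (id == "data") {
      if (is.null(fmt)) stop("data chunk before fmt chunk")
      if (fmt != 3L || bits != 32L)
        stop("only 32-bit float WAV is supported")
      samples <- readBin(con, "numeric", n = sz / 4L, size = 4,
                         endian = "little")
      break
    } else {
      invisible(readBin(con, "raw", n = sz))
    }
  }
  if (is.null(samples)) stop("no data chunk found")
  sidecar_path <- paste0(path, ".json")
  meta <- ""
  if (file.exists(sidecar_path)) {
    sc <- jsonlite::read_json(sidecar_path)
    if (!identical(sc$units, "pascal"))
      warning("sidecar units are not pascal; samples used as-is")
    meta <- "pascal (sidecar)"
  }
  if (n_ch == 1L) return(waveform(samples, fs, meta))
  if (n_ch == 2L) {
    n <- length(samples) / 2L
    return(binaural_waveform(
      waveform(samples[seq(1, by = 2, length.out = n)], fs, meta),
      waveform(samples[seq(2, by = 2, length.out = n)], fs, meta)))
  }
  stop("only mono or stereo files are supported")
}
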