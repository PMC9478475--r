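#' Read a RIFF WAV file (PCM-16 mono)
#'
#' @param path file path.
#' @return numeric waveform on the unit amplitude scale with attributes `fs` (sample rate).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  if (!identical(readChar(con, 4, useBytes = TRUE), "WAVE")) stop("not a WAVE file")
  fs <- NULL; bits <- NULL; channels <- NULL; data <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", size %/% 2, 2, endian = "little", signed = FALSE)
      if (fmt[1] != 1) stop("only PCM WAV is supported")
      channels <- fmt[2]
      fs <- fmt[3] + 65536 * fmt[4]
      bits <- fmt[8]
    } else if (identical(id, "data")) {
      if (is.null(bits)) stop("malformed WAV: data before fmt")
      data <- readBin(con, "integer", size %/% 2, 2, endian = "little")
      break
    } else {
      invisible(readBin(con, "raw", size + size %% 2))
    }
  }
  if (is.null(data)) stop("no data chunk found")
  if (bits != 16) stop("only 16-bit PCM is supported")
  if (channels != 1) stop("only mono WAV is supported")
  structure(data / 32768, fs = fs)
}

#' Write a RIFF WAV file (PCM-16 mono)
#'
#' Samples beyond full scale are clipped.
#'
#' @param audio numeric waveform on the unit amplitude scale.
#' @param path output path.
#' @param fs sample rate (Hz); defaults to the `fs` attribute or 44100.
#' @return `path`, invisibly.
#' @export
write_wav <- function(audio, path, fs = NULL) {
  if (is.null(fs)) fs <- attr(audio, "fs") %||% 44100
  pcm <- as.integer(pmax(-32768, pmin(32767, round(as.numeric(audio) * 32768))))
  con <- file(path, "wb")
  on.exit(close(con))
  nbytes <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + nbytes), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(c(1L, 1L), con, 2, endian = "little")            # PCM, mono
  writeBin(as.integer(fs), con, 4, endian = "little")
  writeBin(as.integer(fs * 2), con, 4, endian = "little")   # byte rate
  writeBin(c(2L, 16L), con, 2, endian = "little")           # align, bits
  writeChar("data", con, eos = NULL)
  writeBin(nbytes, con, 4, endian = "little")
  writeBin(pcm, con, 2, endian = "little")
  invisible(path)
}
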