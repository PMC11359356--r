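# Minimal PCM16 RIFF/WAVE reader and writer (mono or multi-channel,
# 16-bit only). Samples are exchanged as numeric vectors in [-1, 1].

#' Write a mono PCM16 WAV file
#'
#' @param samples numeric vector in `[-1, 1]`; values outside are clipped.
#' @param path output file path.
#' @param fs sampling rate (Hz).
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, path, fs = 44100) {
  x <- pmax(-1, pmin(1, samples))
  pcm <- as.integer(round(x * 32767))
  data_size <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")          # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")           # PCM
  writeBin(1L, con, size = 2, endian = "little")           # mono
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs * 2), con, size = 4, endian = "little")  # byte rate
  writeBin(2L, con, size = 2, endian = "little")           # block align
  writeBin(16L, con, size = 2, endian = "little")          # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a PCM16 WAV file
#'
#' Walks the RIFF chunk list, parses the `fmt ` chunk and returns the PCM
#' samples rescaled to `[-1, 1]`. Only 16-bit PCM is supported; malformed
#' files are rejected rather than coerced.
#'
#' @param path WAV file path.
#' @return list with `samples` (numeric vector, one channel) , `fs` and
#'   `n_channels`.
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop("WAV file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  if (!identical(readChar(con, 4, useBytes = TRUE), "RIFF"))
    stop("not a RIFF file: ", path, call. = FALSE)
  readBin(con, "integer", size = 4, endian = "little")
  if (!identical(readChar(con, 4, useBytes = TRUE), "WAVE"))
    stop("not a WAVE file: ", path, call. = FALSE)
  fs <- NULL; n_channels <- NULL; bits <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, "integer", n = 2, size = 2, endian = "little")
      if (fmt[1] != 1L) stop("only PCM WAV supported: ", path, call. = FALSE)
      n_channels <- fmt[2]
      fs <- readBin(con, "integer", size = 4, endian = "little")
      readBin(con, "integer", size = 4, endian = "little")
      readBin(con, "integer", size = 2, endian = "little")
      bits <- readBin(con, "integer", size = 2, endian = "little")
      if (bits != 16L) stop("only 16-bit WAV supported: ", path, call. = FALSE)
      if (size > 16) readBin(con, "raw", n = size - 16L)
    } else if (id == "data") {
      samples <- readBin(con, "integer", n = size / 2L, size = 2,
                         endian = "little")
      break
    } else {
      readBin(con, "raw", n = size + size %% 2L)
    }
  }
  if (is.null(fs) || is.null(samples))
    stop("incomplete WAV file: ", path, call. = FALSE)
  list(samples = samples / 32767, fs = fs, n_channels = n_channels)
}
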