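# Minimal RIFF/WAVE I/O (PCM 16-bit, mono or interleaved stereo).
# Kept deliberately small: stimuli are written for inspection and for
# external playback software; nothing in the analysis path reads audio.

#' Write a waveform to a 16-bit PCM WAV file
#'
#' @param samples numeric vector in [-1, 1] (mono) or a 2-row matrix
#'   (stereo, one channel per row). Values are clipped to [-1, 1].
#' @param path output file path.
#' @param sample_rate sampling rate in Hz.
#' @return `path`, invisibly.
#' @seealso [read_wav()]
#' @export
write_wav <- function(samples, path, sample_rate = 44100) {
  if (is.matrix(samples)) {
    n_chan <- nrow(samples)
    x <- as.vector(samples) # column-major interleaves channels
  } else {
    n_chan <- 1L
    x <- samples
  }
  x <- pmax(pmin(x, 1), -1)
  pcm <- as.integer(round(x * 32767))
  byte_rate <- sample_rate * n_chan * 2L
  data_size <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")            # PCM
  writeBin(as.integer(n_chan), con, size = 2, endian = "little")
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(byte_rate, con, size = 4, endian = "little")
  writeBin(as.integer(n_chan * 2L), con, size = 2, endian = "little") # block align
  writeBin(16L, con, size = 2, endian = "little")           # bits/sample
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM WAV file written by [write_wav()]
#'
#' @param path file path.
#' @return list with `samples` (numeric vector, or matrix with one row
#'   per channel) and `sample_rate`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file: ", path)
  readBin(con, integer(), size = 4, endian = "little")
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file: ", path)
  sample_rate <- NULL; n_chan <- NULL; bits <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk found in ", path)
    size <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, integer(), n = 2, size = 2, endian = "little")
      if (fmt[1] != 1) stop("only PCM supported")
      n_chan <- fmt[2]
      sample_rate <- readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 2, endian = "little")
      bits <- readBin(con, integer(), size = 2, endian = "little")
      if (bits != 16) stop("only 16-bit supported")
      if (size > 16) readBin(con, raw(), n = size - 16)
    } else if (id == "data") {
      pcm <- readBin(con, integer(), n = size / 2, size = 2,
                     signed = TRUE, endian = "little")
      break
    } else {
      readBin(con, raw(), n = size)
    }
  }
  x <- pcm / 32767
  if (n_chan > 1) x <- matrix(x, nrow = n_chan)
  list(samples = x, sample_rate = sample_rate)
}
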