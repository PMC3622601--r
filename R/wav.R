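# Minimal multichannel RIFF/WAVE (16-bit PCM, little-endian) I/O. Samples
# are stored interleaved; channel order is sensor order.

#' Read and write multichannel WAV files
#'
#' `write_wav()` scales the waveform matrix by its peak (to 90% full scale)
#' and writes 16-bit PCM; `read_wav()` returns the samples as a matrix in
#' [-1, 1]. Absolute amplitude is not preserved — all downstream processing
#' uses normalized cross-correlations, which are scale-invariant.
#'
#' @param wave Numeric matrix, samples x channels.
#' @param fs Sampling rate in Hz.
#' @param file Output path.
#' @return `read_wav()` returns `list(wave, fs)`.
#' @export
write_wav <- function(wave, fs, file) {
  wave <- as.matrix(wave)
  nch <- ncol(wave)
  nsamp <- nrow(wave)
  peak <- max(abs(wave), 1e-12)
  pcm <- as.integer(round(t(wave) / peak * 0.9 * 32767))
  data_bytes <- nsamp * nch * 2L
  con <- file(file, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")             # PCM
  writeBin(nch, con, size = 2, endian = "little")
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs * nch * 2L), con, size = 4, endian = "little")
  writeBin(as.integer(nch * 2L), con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")            # bits/sample
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(file)
}

#' @rdname write_wav
#' @export
read_wav <- function(file) {
  if (!file.exists(file)) {
    stop(sprintf("missing recording file: %s", file), call. = FALSE)
  }
  con <- file(file, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file", call. = FALSE)
  readBin(con, integer(), size = 4, endian = "little")
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file", call. = FALSE)
  fs <- NULL; nch <- NULL; bits <- NULL; wave <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0L || nchar(id) < 4) break
    size <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, integer(), n = 2, size = 2, endian = "little")
      nch <- fmt[2]
      fs <- readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 2, endian = "little")
      bits <- readBin(con, integer(), size = 2, endian = "little")
      if (fmt[1] != 1L || bits != 16L) {
        stop("only 16-bit PCM WAV is supported", call. = FALSE)
      }
      seek(con, size - 16, origin = "current")
    } else if (id == "data") {
      n <- size %/% 2L
      pcm <- readBin(con, integer(), n = n, size = 2, endian = "little")
      wave <- t(matrix(pcm / 32767, nrow = nch))
      break
    } else {
      seek(con, size, origin = "current")
    }
  }
  if (is.null(wave)) stop("no data chunk found", call. = FALSE)
  list(wave = wave, fs = fs)
}
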