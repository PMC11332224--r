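#' Read a mono PCM WAV file
#'
#' Minimal RIFF/WAVE reader for uncompressed 16-bit (or 8/24/32-bit integer)
#' PCM audio, the format used throughout this package. Multichannel files are
#' mixed down to mono by averaging channels.
#'
#' @param path Path to a `.wav` file.
#' @return A list with elements `wave` (numeric vector scaled to \[-1, 1\]),
#'   `sample_rate` (Hz) and `bit_depth`.
#' @seealso [write_wav()]
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- list(
        audio_format = readBin(con, "integer", 1, size = 2, endian = "little"),
        n_channels   = readBin(con, "integer", 1, size = 2, endian = "little"),
        sample_rate  = readBin(con, "integer", 1, size = 4, endian = "little"),
        byte_rate    = readBin(con, "integer", 1, size = 4, endian = "little"),
        block_align  = readBin(con, "integer", 1, size = 2, endian = "little"),
        bit_depth    = readBin(con, "integer", 1, size = 2, endian = "little")
      )
      if (sz > 16) invisible(readBin(con, "raw", sz - 16))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
      if (sz %% 2 == 1) invisible(readBin(con, "raw", 1))
    } else {
      invisible(readBin(con, "raw", sz + sz %% 2))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("malformed WAV (missing fmt or data chunk): ", path)
  if (fmt$audio_format != 1L) stop("only PCM WAV supported, got format tag ", fmt$audio_format)

  bytes <- fmt$bit_depth / 8
  n <- length(data_raw) %/% (bytes * fmt$n_channels) * fmt$n_channels
  x <- switch(as.character(fmt$bit_depth),
    "8"  = as.numeric(as.integer(data_raw[seq_len(n)])) / 127.5 - 1,
    "16" = pmax(-1, readBin(data_raw, "integer", n, size = 2, signed = TRUE, endian = "little") / 32767),
    "24" = {
      r <- matrix(as.integer(data_raw[seq_len(n * 3)]), nrow = 3)
      v <- r[1, ] + r[2, ] * 256L + r[3, ] * 65536L
      ifelse(v >= 8388608, v - 16777216, v) / 8388608
    },
    "32" = readBin(data_raw, "integer", n, size = 4, endian = "little") / 2147483648,
    stop("unsupported bit depth: ", fmt$bit_depth)
  )
  if (fmt$n_channels > 1L) {
    x <- colMeans(matrix(x, nrow = fmt$n_channels))
  }
  list(wave = x, sample_rate = fmt$sample_rate, bit_depth = fmt$bit_depth)
}

#' Write a mono PCM16 WAV file
#'
#' @param wave Numeric vector in \[-1, 1\]; values outside are clipped.
#' @param path Output path.
#' @param sample_rate Sampling rate in Hz.
#' @return `path`, invisibly.
#' @export
write_wav <- function(wave, path, sample_rate = 44100) {
  stopifnot(is.numeric(wave), length(wave) > 0, sample_rate > 0)
  x <- as.integer(round(pmax(-1, pmin(1, wave)) * 32767))
  n_bytes <- length(x) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")          # PCM
  writeBin(1L, con, size = 2, endian = "little")          # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * 2), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")          # block align
  writeBin(16L, con, size = 2, endian = "little")         # bit depth
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(n_bytes), con, size = 4, endian = "little")
  writeBin(x, con, size = 2, endian = "little")
  invisible(path)
}
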