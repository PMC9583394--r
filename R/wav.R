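# Minimal uncompressed PCM WAV I/O (RIFF, mono or interleaved
# multichannel, 16-bit). Kept deliberately small: the experiment needs
# uncompressed audio output and byte-identical re-renders, nothing more.

#' Write samples to an uncompressed PCM WAV file
#'
#' @param samples Numeric vector in \[-1, 1\] (values are clipped), or a
#'   matrix with one column per channel.
#' @param path Output file path.
#' @param sample_rate Sampling rate in Hz.
#' @param bit_depth Bits per sample; 16 (default) or 8.
#' @return Invisibly, `path`.
#' @export
write_wav <- function(samples, path, sample_rate = 44100, bit_depth = 16) {
  stopifnot(is.numeric(samples), bit_depth %in% c(8, 16))
  if (is.matrix(samples)) {
    n_channels <- ncol(samples)
    interleaved <- as.vector(t(samples))
  } else {
    n_channels <- 1L
    interleaved <- samples
  }
  interleaved <- pmin(1, pmax(-1, interleaved))
  bytes_per_sample <- bit_depth %/% 8
  block_align <- n_channels * bytes_per_sample
  data_size <- length(interleaved) * bytes_per_sample
  con <- file(path, "wb")
  on.exit(close(con))
  w32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  w16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  writeChar("RIFF", con, eos = NULL)
  w32(36 + data_size)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  w32(16); w16(1)                       # PCM
  w16(n_channels); w32(sample_rate)
  w32(sample_rate * block_align)        # byte rate
  w16(block_align); w16(bit_depth)
  writeChar("data", con, eos = NULL)
  w32(data_size)
  if (bit_depth == 16) {
    writeBin(as.integer(round(interleaved * 32767)), con,
             size = 2, endian = "little")
  } else {
    writeBin(as.raw(round((interleaved + 1) / 2 * 255)), con)
  }
  invisible(path)
}

#' Read an uncompressed PCM WAV file
#'
#' Supports the files [write_wav()] produces (PCM, 8 or 16 bit).
#'
#' @param path Input file path.
#' @return A list with `samples` (numeric vector, or matrix for
#'   multichannel), `sample_rate`, and `bit_depth`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  r32 <- function() readBin(con, integer(), size = 4, endian = "little")
  r16 <- function() readBin(con, integer(), size = 2, endian = "little")
  tag <- function() readChar(con, 4, useBytes = TRUE)
  if (tag() != "RIFF") stop("not a RIFF file: ", path, call. = FALSE)
  r32()
  if (tag() != "WAVE") stop("not a WAVE file: ", path, call. = FALSE)
  fmt <- NULL
  repeat {
    id <- tag()
    if (!length(id) || !nzchar(id)) stop("no data chunk in ", path, call. = FALSE)
    size <- r32()
    if (id == "fmt ") {
      audio_format <- r16(); n_channels <- r16()
      sample_rate <- r32(); r32(); r16()
      bit_depth <- r16()
      if (audio_format != 1) stop("only PCM WAV is supported", call. = FALSE)
      if (size > 16) readBin(con, raw(), size - 16)
      fmt <- TRUE
    } else if (id == "data") {
      if (is.null(fmt)) stop("data chunk precedes fmt chunk", call. = FALSE)
      n <- size %/% (bit_depth %/% 8)
      raw_samples <- if (bit_depth == 16) {
        readBin(con, integer(), n = n, size = 2, signed = TRUE,
                endian = "little") / 32767
      } else {
        as.integer(readBin(con, raw(), n = n)) / 255 * 2 - 1
      }
      samples <- if (n_channels > 1)
        matrix(raw_samples, ncol = n_channels, byrow = TRUE) else raw_samples
      return(list(samples = samples, sample_rate = sample_rate,
                  bit_depth = bit_depth))
    } else {
      readBin(con, raw(), size)
    }
  }
}
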