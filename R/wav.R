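# Minimal 16-bit PCM mono WAV reader/writer. Physical units do not
# survive WAV normalization, so bundle writers store the full-scale range
# in a JSON side-car next to the WAV files.

#' Write a 16-bit PCM mono WAV file
#'
#' Samples are scaled by `full_scale` (mapped to the maximum 16-bit code)
#' and clipped. Store `full_scale` separately to recover physical units.
#'
#' @param x numeric samples.
#' @param path output file.
#' @param fs sample rate (Hz).
#' @param full_scale value mapped to full scale; defaults to
#'   `max(abs(x))`.
#' @return `full_scale`, invisibly.
#' @export
write_wav <- function(x, path, fs, full_scale = max(abs(x))) {
  stopifnot(is.numeric(x), length(x) > 0, fs > 0)
  if (full_scale <= 0) full_scale <- 1
  q <- as.integer(pmax(-32767L, pmin(32767L, round(x / full_scale * 32767))))
  con <- file(path, "wb")
  on.exit(close(con))
  n_data <- 2L * length(q)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_data), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")         # PCM
  writeBin(1L, con, size = 2, endian = "little")         # mono
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs * 2), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(n_data, con, size = 4, endian = "little")
  writeBin(q, con, size = 2, endian = "little")
  invisible(full_scale)
}

#' Read a 16-bit PCM mono WAV file
#'
#' @param path WAV file.
#' @param full_scale physical value of the full-scale code; with the
#'   default 1 the samples are returned normalized to \[-1, 1\].
#' @return list with `x` (samples) and `fs` (Hz).
#' @export
read_wav <- function(path, full_scale = 1) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file", call. = FALSE)
  readBin(con, integer(), size = 4, endian = "little")
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file", call. = FALSE)
  fs <- NULL; bits <- NULL; x <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, integer(), n = 2, size = 2, endian = "little")
      if (fmt[1] != 1 || fmt[2] != 1)
        stop("only 16-bit PCM mono supported", call. = FALSE)
      fs <- readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 2, endian = "little")
      bits <- readBin(con, integer(), size = 2, endian = "little")
      if (bits != 16) stop("only 16-bit PCM supported", call. = FALSE)
    } else if (id == "data") {
      x <- readBin(con, integer(), n = sz / 2, size = 2, signed = TRUE,
                   endian = "little")
      break
    } else {
      readBin(con, raw(), n = sz)
    }
  }
  if (is.null(x) || is.null(fs)) stop("malformed WAV file", call. = FALSE)
  list(x = x / 32767 * full_scale, fs = fs)
}
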