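# Minimal mono RIFF/WAVE codec (16-bit PCM and 32-bit IEEE float).
# Implemented in-package because the pipeline's on-disk audio interface is
# WAV and the installed stack carries no audio I/O package.

#' Write a recording as a mono WAV file
#'
#' @param rec a [PCGRecording-class]; samples are clipped to `[-1, 1]` for
#'   16-bit output.
#' @param path output file.
#' @param bits 16 (PCM) or 32 (IEEE float).
#' @return `path`, invisibly.
#' @export
writeWavePCG <- function(rec, path, bits = 16) {
  if (!bits %in% c(16, 32)) stop("bits must be 16 or 32")
  x <- rec@samples
  fs <- as.integer(round(rec@samplingRate))
  con <- file(path, "wb")
  on.exit(close(con))
  fmt <- if (bits == 16) 1L else 3L
  blockAlign <- as.integer(bits / 8)
  dataSize <- length(x) * blockAlign
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + dataSize), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")          # mono
  writeBin(fs, con, size = 4, endian = "little")
  writeBin(fs * blockAlign, con, size = 4, endian = "little")
  writeBin(blockAlign, con, size = 2, endian = "little")
  writeBin(as.integer(bits), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(dataSize), con, size = 4, endian = "little")
  if (bits == 16) {
    q <- as.integer(round(pmax(pmin(x, 1), -1) * 32767))
    writeBin(q, con, size = 2, endian = "little")
  } else {
    writeBin(x, con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a mono WAV file
#'
#' Supports the 16-bit PCM and 32-bit float files written by
#' [writeWavePCG()].
#'
#' @param path WAV file.
#' @param subjectId,classLabel optional provenance to attach.
#' @return a [PCGRecording-class].
#' @export
readWavePCG <- function(path, subjectId = NA_character_,
                        classLabel = NA_character_) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file")
  readBin(con, "integer", size = 4, endian = "little")
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file")
  fmt <- NULL; fs <- NULL; bits <- NULL; audioFormat <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk found")
    sz <- readBin(con, "integer", size = 4, endian = "little")
    if (id == "fmt ") {
      audioFormat <- readBin(con, "integer", size = 2, endian = "little")
      nch <- readBin(con, "integer", size = 2, endian = "little")
      fs <- readBin(con, "integer", size = 4, endian = "little")
      readBin(con, "integer", size = 4, endian = "little")
      readBin(con, "integer", size = 2, endian = "little")
      bits <- readBin(con, "integer", size = 2, endian = "little")
      if (nch != 1) stop("only mono WAV supported")
      if (sz > 16) readBin(con, "raw", n = sz - 16)
    } else if (id == "data") {
      n <- sz / (bits / 8)
      x <- if (audioFormat == 3) {
        readBin(con, "numeric", n = n, size = 4, endian = "little")
      } else if (bits == 16) {
        readBin(con, "integer", n = n, size = 2, endian = "little",
                signed = TRUE) / 32767
      } else stop("unsupported WAV encoding")
      return(PCGRecording(x, fs, subjectId, classLabel))
    } else {
      readBin(con, "raw", n = sz)
    }
  }
}
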