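#' Spectrogram imaging configuration
#'
#' Hanning window of 256 samples (equal to the FFT length), hop of 10
#' samples, log magnitude with a small floor, and a fixed 128x128 output:
#' the one-sided spectrum keeps bins 0..127 (the Nyquist bin is dropped)
#' and the 135 STFT columns of a 1600-sample frame are centre-cropped to
#' 128.
#'
#' @param windowLength window and FFT length in samples.
#' @param hop hop size in samples.
#' @param logEpsilon floor inside the log.
#' @param outputSize image side lengths, fixed `c(128, 128)`.
#' @param channelMode `"replicate3"` (grayscale copied to 3 channels) or
#'   `"colormap"` (viridis-like palette).
#' @return a `SpectrogramConfig` list.
#' @export
spectrogramConfig <- function(windowLength = 256, hop = 10,
                              logEpsilon = 1e-10,
                              outputSize = c(128, 128),
                              channelMode = c("replicate3", "colormap")) {
  if (hop < 1) stop("hop must be >= 1")
  channelMode <- match.arg(channelMode)
  structure(list(windowLength = windowLength, fftLength = windowLength,
                 hop = hop, logEpsilon = logEpsilon,
                 outputSize = outputSize, channelMode = channelMode),
            class = "SpectrogramConfig")
}

.hanning <- function(n) 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))

#' Short-time Fourier transform
#'
#' Column `t` is the one-sided DFT (bins `0..L/2`) of the Hanning-windowed
#' samples starting at offset `(t-1) * hop`.
#'
#' @param x numeric signal or a [PCGFrame-class].
#' @param cfg a [spectrogramConfig()].
#' @return complex matrix, `L/2 + 1` frequency bins x time columns, with
#'   attribute `window` (the window used).
#' @export
stft <- function(x, cfg = spectrogramConfig()) {
  if (is(x, "PCGFrame")) x <- x@samples
  L <- cfg$windowLength
  if (length(x) < L) stop("signal shorter than the analysis window")
  if (cfg$hop < 1) stop("hop must be >= 1")
  w <- .hanning(L)
  nCols <- floor((length(x) - L) / cfg$hop) + 1
  starts <- (seq_len(nCols) - 1) * cfg$hop
  seg <- vapply(starts, function(s) x[(s + 1):(s + L)] * w, numeric(L))
  S <- stats::mvfft(seg)[1:(L / 2 + 1), , drop = FALSE]
  attr(S, "window") <- w
  S
}

# viridis-like 3-stop palette, linear interpolation
.colormap3 <- function(v) {
  stops <- rbind(c(0.267, 0.005, 0.329),
                 c(0.128, 0.567, 0.551),
                 c(0.993, 0.906, 0.144))
  lo <- pmin(floor(v * 2) + 1, 2)
  f <- v * 2 - (lo - 1)
  sapply(1:3, function(ch) stops[lo, ch] * (1 - f) + stops[lo + 1, ch] * f)
}

#' Render a log-spectrogram image from an STFT matrix
#'
#' `log(|S|^2 + eps)`, min-max rescaled to `[0, 1]` per image, frequency
#' axis truncated to the lowest 128 bins (lowest frequencies at the top
#' row), time axis centre-cropped to 128 columns, and expanded to 3
#' channels.
#'
#' @param S complex STFT matrix from [stft()].
#' @param cfg a [spectrogramConfig()].
#' @return numeric array (128, 128, 3) in `[0, 1]`.
#' @export
spectrogramImage <- function(S, cfg = spectrogramConfig()) {
  h <- cfg$outputSize[1]; wid <- cfg$outputSize[2]
  if (nrow(S) < h) stop("too few frequency bins for the requested size")
  if (ncol(S) < wid)
    stop("too few STFT columns (", ncol(S), ") for a ", wid,
         "-column image")
  P <- log(Mod(S[seq_len(h), , drop = FALSE])^2 + cfg$logEpsilon)
  extra <- ncol(P) - wid
  from <- floor(extra / 2) + 1
  P <- P[, from:(from + wid - 1), drop = FALSE]
  rng <- range(P)
  if (rng[1] == rng[2]) {
    warning("constant spectrogram; returning zeros")
    G <- matrix(0, h, wid)
  } else {
    G <- (P - rng[1]) / (rng[2] - rng[1])
  }
  out <- array(0, c(h, wid, 3))
  if (cfg$channelMode == "replicate3") {
    out[, , 1] <- G; out[, , 2] <- G; out[, , 3] <- G
  } else {
    cm <- .colormap3(as.vector(G))
    for (ch in 1:3) out[, , ch] <- matrix(cm[, ch], h, wid)
  }
  out
}

#' Convert frames to a SpectrogramSet
#'
#' @param frames list of [PCGFrame-class].
#' @param cfg a [spectrogramConfig()].
#' @param origin provenance tag for all images.
#' @return a [SpectrogramSet-class].
#' @export
framesToSpectrograms <- function(frames, cfg = spectrogramConfig(),
                                 origin = "real") {
  if (length(frames) == 0) stop("empty frame list")
  h <- cfg$outputSize[1]; wid <- cfg$outputSize[2]
  px <- array(0, c(h, wid, 3, length(frames)))
  info <- data.frame(frameId = character(length(frames)),
                     subjectId = character(length(frames)),
                     classLabel = character(length(frames)),
                     origin = origin, stringsAsFactors = FALSE)
  for (i in seq_along(frames)) {
    fr <- frames[[i]]
    px[, , , i] <- spectrogramImage(stft(fr, cfg), cfg)
    info$frameId[i] <- paste0(fr@subjectId, "_f", fr@startIndex)
    info$subjectId[i] <- fr@subjectId
    info$classLabel[i] <- fr@classLabel
  }
  SpectrogramSet(px, info)
}

#' Write spectrogram images as 8-bit PNG files
#'
#' @param set a [SpectrogramSet-class].
#' @param dir output directory.
#' @return written file paths, invisibly.
#' @export
writeSpectrogramPNGs <- function(set, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  info <- imageInfo(set)
  paths <- character(nImages(set))
  for (i in seq_len(nImages(set))) {
    img <- imageData(set, i)
    paths[i] <- file.path(dir, paste0(make.names(info$frameId[i]), "_",
                                      i, ".png"))
    png::writePNG(img, paths[i])
  }
  invisible(paths)
}
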