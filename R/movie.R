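# Movie container, TIFF + JSON-sidecar I/O, spatial filtering, beat
# segmentation and per-beat normalization.

#' Construct an optical-mapping movie
#'
#' @param frames Numeric 3-D array, `time x rows x cols`, finite
#'   intensities, at least 2 frames.
#' @param frame_rate Sampling rate, Hz.
#' @param pixel_pitch Pixel size, mm.
#' @param channel `"voltage"` or `"calcium"`.
#' @param stimulus_times Stimulus delivery times, ms (may be empty for
#'   unpaced recordings).
#' @return An `om_movie` object.
#' @export
movie <- function(frames, frame_rate, pixel_pitch,
                  channel = c("voltage", "calcium"),
                  stimulus_times = numeric(0)) {
  channel <- match.arg(channel)
  if (!is.array(frames) || length(dim(frames)) != 3L) {
    stop_invalid("frames must be a time x rows x cols array")
  }
  if (dim(frames)[1] < 2L) stop_invalid("a movie needs at least 2 frames")
  if (!all(is.finite(frames))) stop_invalid("intensities must be finite")
  check_positive(frame_rate, "frame_rate")
  check_positive(pixel_pitch, "pixel_pitch")
  structure(list(frames = frames, frame_rate = frame_rate,
                 pixel_pitch = pixel_pitch, channel = channel,
                 stimulus_times = as.numeric(stimulus_times)),
            class = "om_movie")
}

#' @export
print.om_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat("<om_movie>", x$channel, "channel:", d[1], "frames of", d[2], "x",
      d[3], "pixels @", x$frame_rate, "Hz,",
      x$pixel_pitch, "mm/pixel,", length(x$stimulus_times), "stimuli\n")
  invisible(x)
}

#' @export
dim.om_movie <- function(x) dim(x$frames)

frame_period_ms <- function(m) 1000 / m$frame_rate

sidecar_path <- function(path) sub("\\.tiff?$", ".json", path)

#' Write a movie as a multi-page TIFF with a JSON metadata sidecar
#'
#' Frames are stored as 32-bit float TIFF pages rescaled to `[0, 1]`; the
#' affine rescaling (`scale`, `offset`) and the acquisition metadata
#' (`frame_rate_hz`, `pixel_pitch_mm`, `stimulus_times_ms`, `channel`) go
#' to a JSON sidecar next to the TIFF, so the round trip is lossless to
#' single precision.
#'
#' @param m An [movie()].
#' @param path Output TIFF path (`.tif`/`.tiff`); the sidecar replaces the
#'   extension with `.json`.
#' @return `path`, invisibly.
#' @export
write_movie <- function(m, path) {
  stopifnot(inherits(m, "om_movie"))
  rng <- range(m$frames)
  scale <- if (diff(rng) > 0) diff(rng) else 1
  offset <- rng[1]
  norm <- (m$frames - offset) / scale
  pages <- lapply(seq_len(dim(norm)[1]), function(i) norm[i, , ])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none")
  meta <- list(frame_rate_hz = m$frame_rate,
               pixel_pitch_mm = m$pixel_pitch,
               stimulus_times_ms = m$stimulus_times,
               channel = m$channel,
               n_frames = dim(m$frames)[1],
               scale = scale, offset = offset)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a movie written by [write_movie()]
#'
#' @param path TIFF path; the JSON sidecar must sit next to it.
#' @return An [movie()].
#' @export
read_movie <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(path)) stop_invalid("TIFF not found: ", path)
  if (!file.exists(sp)) stop_invalid("metadata sidecar not found: ", sp)
  meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  for (f in c("frame_rate_hz", "pixel_pitch_mm", "channel")) {
    if (is.null(meta[[f]])) stop_invalid("sidecar missing field `", f, "`")
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (!is.null(meta$n_frames) && meta$n_frames != length(pages)) {
    stop_invalid("sidecar frame count (", meta$n_frames,
                 ") does not match TIFF pages (", length(pages), ")")
  }
  arr <- array(0, c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
  for (i in seq_along(pages)) arr[i, , ] <- pages[[i]]
  scale <- if (is.null(meta$scale)) 1 else meta$scale
  offset <- if (is.null(meta$offset)) 0 else meta$offset
  movie(arr * scale + offset, frame_rate = meta$frame_rate_hz,
        pixel_pitch = meta$pixel_pitch_mm, channel = meta$channel,
        stimulus_times = if (is.null(meta$stimulus_times_ms)) numeric(0)
                         else as.numeric(meta$stimulus_times_ms))
}

#' Apply a 3x3 Gaussian spatial filter to every frame
#'
#' Convolves each frame with the binomial kernel
#' `[1 2 1]' [1 2 1] / 16`, the canonical discrete 3x3 Gaussian. Borders
#' are handled by edge replication, so a spatially constant frame is
#' unchanged and the frame mean is preserved up to a small edge bias.
#'
#' @param m An [movie()] with at least 3 rows and 3 columns.
#' @return The filtered movie.
#' @export
spatial_gaussian3 <- function(m) {
  stopifnot(inherits(m, "om_movie"))
  d <- dim(m$frames)
  if (d[2] < 3 || d[3] < 3) stop_invalid("grid must be at least 3 x 3")
  k <- outer(c(1, 2, 1), c(1, 2, 1)) / 16
  out <- m$frames
  nr <- d[2]; nc <- d[3]
  ri <- c(1, seq_len(nr), nr)   # replicated-edge index maps
  ci <- c(1, seq_len(nc), nc)
  for (f in seq_len(d[1])) {
    pad <- m$frames[f, ri, ci]
    acc <- matrix(0, nr, nc)
    for (dr in 0:2) for (dc in 0:2) {
      acc <- acc + k[dr + 1, dc + 1] * pad[dr + seq_len(nr), dc + seq_len(nc)]
    }
    out[f, , ] <- acc
  }
  m$frames <- out
  m
}

#' Normalize a beat window to the unit interval
#'
#' Rescales the trace segment inside the window so its minimum maps to 0
#' and its maximum to 1, making fractional repolarization levels (30%,
#' 80%, 90%) well defined.
#'
#' @param trace Numeric pixel trace (whole recording).
#' @param window A window row (list/data.frame with `start_frame`,
#'   `end_frame`) as produced by [segment_beats()].
#' @param min_amplitude Amplitude floor below which the segment is
#'   considered degenerate (flat / noise only).
#' @return Normalized segment in `[0, 1]`.
#' @export
normalize_beat <- function(trace, window, min_amplitude = 1e-9) {
  seg <- trace[window$start_frame:window$end_frame]
  rng <- range(seg)
  if (!all(is.finite(rng)) || diff(rng) <= min_amplitude) {
    stop_invalid("degenerate signal: beat amplitude below the noise floor")
  }
  (seg - rng[1]) / diff(rng)
}

# Detect upstrokes on a single trace: upward crossings of `threshold`
# (fraction of the global amplitude) with a refractory lockout.
detect_upstrokes <- function(trace, frame_period, threshold = 0.5,
                             lockout_ms = 40) {
  rng <- range(trace)
  if (diff(rng) <= 0) return(numeric(0))
  x <- (trace - rng[1]) / diff(rng)
  up <- which(x[-1] > threshold & x[-length(x)] <= threshold)
  if (!length(up)) return(numeric(0))
  keep <- up[1]
  for (i in up[-1]) {
    if ((i - keep[length(keep)]) * frame_period >= lockout_ms) {
      keep <- c(keep, i)
    }
  }
  (keep - 1) * frame_period
}

#' Segment a recording into beat windows
#'
#' When the movie carries stimulus times (paced protocols) windows are
#' stimulus-locked: one window per stimulus, spanning from that stimulus
#' to the next (the last window extends one median inter-stimulus interval
#' or to the end of the recording). For unpaced recordings upstrokes are
#' detected on the masked-field mean trace by 50%-amplitude crossings with
#' a 40 ms refractory lockout, and windows are anchored 10 ms before each
#' detection. Windows tile the recording without overlap and are shared by
#' all pixels (beat indices are therefore aligned across the map).
#'
#' @param m An [movie()].
#' @param mask Optional logical matrix of analyzable pixels.
#' @param threshold,lockout_ms Detection parameters for unpaced data.
#' @return A data.frame of class `beat_windows` with columns
#'   `start_frame`, `end_frame`, `ref_time_ms` (stimulus or detection
#'   time) and `beat`. Zero rows (with a warning) when no beat is found.
#' @export
segment_beats <- function(m, mask = NULL, threshold = 0.5, lockout_ms = 40) {
  stopifnot(inherits(m, "om_movie"))
  fp <- frame_period_ms(m)
  n <- dim(m$frames)[1]
  if (length(m$stimulus_times)) {
    ref <- sort(m$stimulus_times)
  } else {
    if (is.null(mask)) mask <- matrix(TRUE, dim(m$frames)[2], dim(m$frames)[3])
    mean_trace <- apply(m$frames, 1, function(fr) mean(fr[mask]))
    det <- detect_upstrokes(mean_trace, fp, threshold, lockout_ms)
    # require genuine beats: amplitude must dominate the residual spread
    amp <- diff(range(mean_trace))
    noise_sd <- sd(diff(mean_trace)) / sqrt(2)
    if (length(det) && amp < 6 * noise_sd) det <- numeric(0)
    ref <- det - 10  # pre-roll so the upstroke foot is inside the window
    ref[ref < 0] <- 0
  }
  if (!length(ref)) {
    warning("no beats detected")
    out <- data.frame(start_frame = integer(0), end_frame = integer(0),
                      ref_time_ms = numeric(0), beat = integer(0))
    class(out) <- c("beat_windows", class(out))
    return(out)
  }
  start <- pmax(1L, floor(ref / fp) + 1L)
  gap <- if (length(ref) > 1) median(diff(ref)) else (n - start[1]) * fp
  end <- pmin(n, c(start[-1] - 1L,
                   start[length(start)] + ceiling(gap / fp)))
  out <- data.frame(start_frame = as.integer(start),
                    end_frame = as.integer(end),
                    ref_time_ms = ref, beat = seq_along(ref))
  class(out) <- c("beat_windows", class(out))
  out
}
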