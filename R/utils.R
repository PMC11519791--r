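# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random stream.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

stop_invalid <- function(...) {
  stop(paste0(...), call. = FALSE)
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop_invalid("`", name, "` must be a single positive finite number")
  }
  invisible(x)
}

# Linear-interpolated crossing time of `level` between samples, searching
# from index `from`, in the given direction ("down" = first downward
# crossing, "up" = first upward crossing). Returns fractional index (1-based)
# or NA when the level is never crossed.
crossing_index <- function(y, level, from = 1L, direction = c("down", "up")) {
  direction <- match.arg(direction)
  n <- length(y)
  if (from >= n) return(NA_real_)
  for (i in seq(from, n - 1L)) {
    y0 <- y[i]; y1 <- y[i + 1L]
    hit <- if (direction == "down") (y0 >= level && y1 < level)
           else (y0 <= level && y1 > level)
    if (hit) {
      if (y1 == y0) return(i)
      return(i + (level - y0) / (y1 - y0))
    }
  }
  NA_real_
}

# Parabolic refinement of a discrete argmax: given values at (i-1, i, i+1),
# return the sub-sample offset of the vertex in [-0.5, 0.5].
parabolic_offset <- function(ym1, y0, yp1) {
  denom <- ym1 - 2 * y0 + yp1
  if (!is.finite(denom) || abs(denom) < .Machine$double.eps) return(0)
  off <- 0.5 * (ym1 - yp1) / denom
  max(-0.5, min(0.5, off))
}
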