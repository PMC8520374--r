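#' Acquisition time grid
#'
#' The discrete time axis on which the arterial input, tissue curves and
#' residue functions live. A dynamic CTP acquisition samples `n_frames`
#' volumes at a fixed inter-frame spacing `dt`, starting at `t0`; frame `k`
#' (0-based) is acquired at `t0 + k * dt`.
#'
#' @param n_frames Number of acquired frames (cycles). Default 20, the usual
#'   short CTP protocol length.
#' @param dt Seconds between frames. Default 2.
#' @param t0 Acquisition start offset in seconds. Default 0.
#' @return An object of class `time_grid`.
#' @examples
#' g <- time_grid(20, 2)
#' grid_times(g)[1:4]
#' @export
time_grid <- function(n_frames = 20L, dt = 2, t0 = 0) {
  n_frames <- as.integer(n_frames)
  if (!is.finite(n_frames) || n_frames < 4L)
    stop("n_frames must be a finite integer >= 4", call. = FALSE)
  if (!is.finite(dt) || dt <= 0) stop("dt must be > 0", call. = FALSE)
  if (!is.finite(t0) || t0 < 0) stop("t0 must be finite and >= 0", call. = FALSE)
  structure(list(n_frames = n_frames, dt = dt, t0 = t0), class = "time_grid")
}

#' Frame times of a grid
#'
#' @param grid A [time_grid()].
#' @return Numeric vector of length `n_frames`: `t0 + (0:(n-1)) * dt`.
#' @export
grid_times <- function(grid) {
  stopifnot(inherits(grid, "time_grid"))
  grid$t0 + seq_len(grid$n_frames) * grid$dt - grid$dt
}

#' @export
print.time_grid <- function(x, ...) {
  cat(sprintf("<time_grid> %d frames, dt = %g s, t0 = %g s (window %g s)\n",
              x$n_frames, x$dt, x$t0, x$dt * x$n_frames))
  invisible(x)
}

#' Refine a time grid
#'
#' Returns a grid covering the same window with `factor` times finer
#' sampling. Used internally for quasi-continuous oracles (true time-to-peak,
#' residue areas).
#'
#' @param grid A [time_grid()].
#' @param factor Integer refinement factor.
#' @return A `time_grid` with `n_frames * factor` frames and `dt / factor`.
#' @export
refine_grid <- function(grid, factor = 10L) {
  stopifnot(inherits(grid, "time_grid"))
  factor <- as.integer(factor)
  if (factor < 1L) stop("factor must be >= 1", call. = FALSE)
  time_grid(grid$n_frames * factor, grid$dt / factor, grid$t0)
}
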