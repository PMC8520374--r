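#' Arterial input function parameters
#'
#' Gamma-variate parameterization of the contrast bolus measured in a feeding
#' artery: `B(t) = amplitude * (t - onset)^alpha * exp(-(t - onset)/beta)`
#' for `t > onset`, zero before bolus arrival. The gamma-variate is the
#' standard analytic first-pass bolus model in the CTP literature; its
#' continuous-time peak sits at `onset + alpha * beta`.
#'
#' @param amplitude Positive scale factor (HU s^-alpha).
#' @param onset Bolus arrival time, seconds, >= 0.
#' @param alpha Dimensionless shape parameter, > 0.
#' @param beta Timescale, seconds, > 0.
#' @return An object of class `aif_params`.
#' @examples
#' p <- aif_params()
#' # peak enhancement of the default bolus, in HU:
#' max(make_aif(p, time_grid(40, 1)))
#' @export
aif_params <- function(amplitude = 66, onset = 4, alpha = 3, beta = 1.5) {
  vals <- c(amplitude = amplitude, onset = onset, alpha = alpha, beta = beta)
  if (any(!is.finite(vals)))
    stop("AIF parameters must all be finite", call. = FALSE)
  if (amplitude <= 0 || alpha <= 0 || beta <= 0 || onset < 0)
    stop("require amplitude > 0, alpha > 0, beta > 0, onset >= 0", call. = FALSE)
  structure(as.list(vals), class = "aif_params")
}

#' Evaluate a gamma-variate AIF on a time grid
#'
#' @param params An [aif_params()].
#' @param grid A [time_grid()].
#' @return An `aif_curve`: numeric vector of length `grid$n_frames` with the
#'   grid attached as attribute `grid`. All values are finite and >= 0;
#'   frames at or before `onset` are exactly 0.
#' @export
make_aif <- function(params, grid) {
  stopifnot(inherits(params, "aif_params"), inherits(grid, "time_grid"))
  tt <- grid_times(grid)
  b <- numeric(length(tt))
  up <- tt > params$onset
  s <- tt[up] - params$onset
  b[up] <- params$amplitude * s^params$alpha * exp(-s / params$beta)
  structure(b, grid = grid, class = c("aif_curve", "numeric"))
}

#' @export
print.aif_curve <- function(x, ...) {
  g <- attr(x, "grid")
  cat(sprintf("<aif_curve> %d frames, peak %.4g HU at t = %g s\n",
              length(x), max(x), grid_times(g)[which.max(x)]))
  invisible(x)
}
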