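#' Mean squared error over a mask
#'
#' `(1/Q) * sum_mask (X - X_true)^2` where Q is the number of evaluated
#' pixels.
#'
#' @param X,X_true Conformable numeric arrays.
#' @param mask Logical array (default: everything).
#' @return Non-negative scalar; 0 iff the arrays agree on the mask.
#' @export
img_mse <- function(X, X_true, mask = NULL) {
  v <- .masked_pair(X, X_true, mask)
  mean((v$x - v$xt)^2)
}

#' Mean absolute error over a mask
#'
#' `(1/Q) * sum_mask |X - X_true|`. By Jensen's inequality
#' `mae <= sqrt(mse)` on any input.
#'
#' @inheritParams img_mse
#' @return Non-negative scalar.
#' @export
img_mae <- function(X, X_true, mask = NULL) {
  v <- .masked_pair(X, X_true, mask)
  mean(abs(v$x - v$xt))
}

#' Peak signal-to-noise ratio over a mask
#'
#' `10 * log10(peak^2 / mse)` in dB. The default peak rule is the maximum
#' of the reference on the mask (perfusion maps are physical quantities,
#' not 8-bit images); a fixed peak may be supplied instead. `mse = 0` is
#' reported as the `+Inf` sentinel.
#'
#' @inheritParams img_mse
#' @param peak Positive reference peak, or `NULL` for `max(X_true[mask])`.
#' @return PSNR in dB (possibly `Inf`).
#' @export
img_psnr <- function(X, X_true, mask = NULL, peak = NULL) {
  v <- .masked_pair(X, X_true, mask)
  if (is.null(peak)) peak <- max(v$xt)
  if (!is.finite(peak) || peak <= 0) .fail_validation("peak must be > 0")
  mse <- mean((v$x - v$xt)^2)
  if (mse == 0) return(Inf)
  10 * log10(peak^2 / mse)
}

.masked_pair <- function(X, X_true, mask) {
  if (length(X) != length(X_true)) .fail_validation("X and X_true must be conformable")
  if (is.null(mask)) mask <- rep(TRUE, length(X))
  if (length(mask) != length(X)) .fail_validation("mask must be conformable")
  m <- as.logical(mask)
  if (!any(m)) .fail_validation("empty evaluation mask")
  list(x = as.numeric(X)[m], xt = as.numeric(X_true)[m])
}

#' Paired solver comparison on a phantom
#'
#' The evaluation harness: for each noise seed, one noisy realization of the
#' phantom series is shared by all solvers (paired design); each solver's
#' residue estimate is converted to CBF/CBV/MTT/TTP maps and scored against
#' the ground-truth maps on the brain mask with PSNR, MSE and MAE.
#'
#' CBV and TTP are computed from the solver-denoised curves
#' `A %*% G_hat` (default), so that every parameter map reflects the
#' reconstruction under comparison; `curves = "measured"` scores the raw
#' noisy curves instead.
#'
#' @param phantom A [build_phantom()] result.
#' @param solvers Named list of [solver_config()]s.
#' @param seeds Integer vector of noise seeds (>= 1 seed).
#' @param sigma Noise SD in HU; default the phantom spec's `noise_sigma`.
#' @param curves `"denoised"` or `"measured"`.
#' @return Object of class `metric_report`: `summary` (solver, parameter,
#'   metric, mean, sd, n_seeds), `per_seed` (long format with seed), and
#'   `meta` (mask size Q, peaks, reference means, failures).
#' @export
evaluate_solvers <- function(phantom, solvers, seeds, sigma = NULL,
                             curves = c("denoised", "measured")) {
  stopifnot(inherits(phantom, "ctp_phantom"))
  curves <- match.arg(curves)
  if (length(seeds) < 1L) .fail_validation("need at least one seed")
  if (is.null(names(solvers)) || any(names(solvers) == ""))
    .fail_validation("solvers must be a named list")
  for (s in solvers) stopifnot(inherits(s, "solver_config"))
  spec <- phantom$spec
  if (is.null(sigma)) sigma <- spec$noise_sigma
  grid <- spec$time
  sys <- build_conv_matrix(phantom$aif, grid$dt)
  mask <- phantom$masks$brain
  truth <- phantom$truth
  params <- c("cbf", "cbv", "mtt", "ttp")
  peaks <- vapply(params, function(p) max(truth[[p]][mask], na.rm = TRUE), numeric(1))

  rows <- list()
  failures <- list()
  for (sd_i in seeds) {
    noisy <- add_noise(phantom$series, sigma, sd_i)
    for (nm in names(solvers)) {
      maps <- tryCatch({
        fit <- ctp_solve(noisy, sys, solvers[[nm]])
        Cuse <- if (curves == "denoised") conv_forward(sys, fit$G_hat) else noisy
        perfusion_maps(fit$G_hat, Cuse, phantom$aif, grid,
                       rho = spec$rho, k_h = spec$k_h)
      }, error = function(e) e)
      if (inherits(maps, "error")) {
        failures[[length(failures) + 1L]] <-
          data.frame(solver = nm, seed = sd_i, message = conditionMessage(maps))
        for (p in params) for (met in c("psnr", "mse", "mae"))
          rows[[length(rows) + 1L]] <- data.frame(
            solver = nm, parameter = p, metric = met, seed = sd_i, value = NA_real_)
        next
      }
      for (p in params) {
        X <- maps[[p]]; Xt <- truth[[p]]
        mk <- mask & is.finite(X) & is.finite(Xt)
        mse <- img_mse(X, Xt, mk)
        rows[[length(rows) + 1L]] <- data.frame(solver = nm, parameter = p,
                                                metric = "psnr", seed = sd_i,
                                                value = img_psnr(X, Xt, mk, peaks[[p]]))
        rows[[length(rows) + 1L]] <- data.frame(solver = nm, parameter = p,
                                                metric = "mse", seed = sd_i, value = mse)
        rows[[length(rows) + 1L]] <- data.frame(solver = nm, parameter = p,
                                                metric = "mae", seed = sd_i,
                                                value = img_mae(X, Xt, mk))
      }
    }
  }
  per_seed <- do.call(rbind, rows)
  agg <- stats::aggregate(value ~ solver + parameter + metric, data = per_seed,
                          FUN = function(v) c(mean = mean(v), sd = stats::sd(v)),
                          na.action = stats::na.pass)
  summary_df <- data.frame(solver = agg$solver, parameter = agg$parameter,
                           metric = agg$metric,
                           mean = agg$value[, "mean"], sd = agg$value[, "sd"],
                           n_seeds = length(seeds))
  structure(list(summary = summary_df, per_seed = per_seed,
                 meta = list(Q = sum(mask), peaks = peaks, sigma = sigma,
                             seeds = seeds, curves = curves,
                             ref_mean = vapply(params, function(p)
                               mean(truth[[p]][mask], na.rm = TRUE), numeric(1)),
                             failures = if (length(failures)) do.call(rbind, failures) else NULL)),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report> %d solver(s), %d seed(s), sigma = %g HU, Q = %d\n",
              length(unique(x$summary$solver)), length(x$meta$seeds),
              x$meta$sigma, x$meta$Q))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
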