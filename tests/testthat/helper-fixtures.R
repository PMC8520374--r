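# shared fixtures, built in code

`%||%` <- function(a, b) if (is.null(a)) b else a

# small default-physiology phantom (fast to build, reused across files)
small_phantom_spec <- function(nx = 32, ny = 32, ...) {
  phantom_spec(nx = nx, ny = ny, lesions = default_lesions(nx, ny), ...)
}

# full noiseless pipeline with an exact solver; curves = measured by default
run_exact_pipeline <- function(spec, curves = "measured") {
  ph <- build_phantom(spec)
  sys <- build_conv_matrix(ph$aif, spec$time$dt)
  fit <- ctp_solve(ph$series, sys, solver_config("tsvd", tsvd_threshold = 0))
  Cuse <- if (curves == "denoised") conv_forward(sys, fit$G_hat) else ph$series
  maps <- perfusion_maps(fit$G_hat, Cuse, ph$aif, spec$time,
                         rho = spec$rho, k_h = spec$k_h)
  list(ph = ph, sys = sys, fit = fit, maps = maps)
}

region_means <- function(rel, mask) {
  vapply(c("rcbf", "rcbv", "rmtt", "rttp"),
         function(p) mean(rel[[p]][mask], na.rm = TRUE), numeric(1))
}

max_rel_err <- function(est, ref, mask) {
  i <- mask & is.finite(est) & is.finite(ref) & ref > 0
  max(abs(est[i] - ref[i]) / ref[i])
}
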