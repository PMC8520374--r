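#' Tissue class parameters
#'
#' Perfusion parameters of one tissue compartment. MTT follows from the
#' central-volume theorem, `MTT = 60 * CBV / CBF` seconds.
#'
#' @param cbf Cerebral blood flow, mL/100g/min, > 0.
#' @param cbv Cerebral blood volume, mL/100g, > 0.
#' @param delay Bolus arrival delay in seconds, or `NULL` to calibrate the
#'   delay so the tissue time-to-peak lands on the phantom's `ttp_target`.
#' @param shape Residue shape. The default is the plug-flow (`"box"`)
#'   compartment, whose enhancement curves complete within a standard
#'   acquisition window so curve-area CBV estimates are discretization- not
#'   truncation-limited; `"exponential"` is the well-mixed compartment.
#' @return An object of class `tissue_class`.
#' @export
tissue_class <- function(cbf = 60, cbv = 4, delay = NULL,
                         shape = c("box", "exponential")) {
  shape <- match.arg(shape)
  if (!is.finite(cbf) || cbf <= 0 || !is.finite(cbv) || cbv <= 0)
    .fail_validation("cbf and cbv must be > 0")
  if (!is.null(delay) && (!is.finite(delay) || delay < 0))
    .fail_validation("delay must be >= 0 or NULL")
  structure(list(cbf = cbf, cbv = cbv, mtt = 60 * cbv / cbf,
                 delay = delay, shape = shape), class = "tissue_class")
}

#' Lesion region description
#'
#' An ellipsoidal lesion confined to one hemisphere, with relative-severity
#' parameters expressed as percent of the contralateral (normal) value.
#' Severities must lie in (0, 500].
#'
#' The four printed severities of a clinical report are generally not
#' mutually consistent with the central-volume theorem, and a residue
#' function only has flow, transit-time and delay degrees of freedom. The
#' phantom therefore honors `rcbf`, `rmtt` and `rttp` exactly and *derives*
#' the achievable `rcbv = rcbf * rmtt / 100`; the stored `rcbv` is kept as
#' metadata. See [severity_achieved()].
#'
#' @param center Ellipsoid center in voxel coordinates (length 2 or 3,
#'   1-based, may be fractional).
#' @param radii Semi-axes in voxels (length 2 or 3).
#' @param severity Named percent severities: `rcbf`, `rcbv`, `rmtt`, `rttp`.
#' @return An object of class `lesion_spec`.
#' @export
lesion_spec <- function(center, radii,
                        severity = c(rcbf = 100, rcbv = 100, rmtt = 100, rttp = 100)) {
  need <- c("rcbf", "rcbv", "rmtt", "rttp")
  if (!all(need %in% names(severity)))
    .fail_validation("severity must name rcbf, rcbv, rmtt, rttp")
  severity <- severity[need]
  if (any(!is.finite(severity)) || any(severity <= 0) || any(severity > 500))
    .fail_validation("severities must be in (0, 500]")
  center <- c(center, 1)[1:3]
  radii <- c(radii, 0.5)[1:3]
  if (any(radii <= 0)) .fail_validation("lesion radii must be > 0")
  structure(list(center = center, radii = radii, severity = severity),
            class = "lesion_spec")
}

#' Achievable severity set of a lesion
#'
#' Returns the severity percentages the phantom actually realizes:
#' `rcbf`, `rmtt`, `rttp` as specified and `rcbv = rcbf * rmtt / 100`
#' (central-volume identity).
#'
#' @param lesion A [lesion_spec()].
#' @return Named numeric vector (`rcbf`, `rcbv`, `rmtt`, `rttp`).
#' @export
severity_achieved <- function(lesion) {
  s <- lesion$severity
  c(rcbf = unname(s["rcbf"]), rcbv = unname(s["rcbf"] * s["rmtt"] / 100),
    rmtt = unname(s["rmtt"]), rttp = unname(s["rttp"]))
}

#' Default core-infarct and penumbra lesions
#'
#' Severity defaults are the pre-treatment region means reported for acute
#' cerebral infarct cohorts: core infarct (CIA) rCBF 43.17, rCBV 71.56,
#' rMTT 124.83, rTTP 122.57; penumbra (PI) rCBF 18.37, rCBV 23.66,
#' rMTT 183.17, rTTP 150.74 (percent of contralateral).
#'
#' @param nx,ny Grid size the geometry is scaled to.
#' @return Named list with elements `cia` and `pi`.
#' @export
default_lesions <- function(nx = 64, ny = 64) {
  # penumbra first so its label (2) matches the classify_regions code
  list(
    pi = lesion_spec(center = c(0.30 * nx, 0.64 * ny),
                     radii = c(0.11 * nx, 0.09 * ny),
                     severity = c(rcbf = 18.37, rcbv = 23.66,
                                  rmtt = 183.17, rttp = 150.74)),
    cia = lesion_spec(center = c(0.30 * nx, 0.42 * ny),
                      radii = c(0.09 * nx, 0.08 * ny),
                      severity = c(rcbf = 43.17, rcbv = 71.56,
                                   rmtt = 124.83, rttp = 122.57)))
}

#' Digital brain perfusion phantom specification
#'
#' Describes a synthetic CTP acquisition: a mid-sagittally symmetric
#' elliptical "brain" of normal tissue on a `nx x ny x nz` grid, optional
#' ellipsoidal core-infarct and penumbra lesions in the left hemisphere,
#' a gamma-variate arterial input, and an acquisition time grid. `nx` must
#' be even so the mirror map `x -> nx + 1 - x` is voxel-exact.
#'
#' Lesion transit times receive a small deterministic equidistributed
#' multiplicative jitter (`mtt_jitter`, half-range fraction). This models
#' within-lesion heterogeneity and, because the tissue peak time varies
#' continuously with MTT, it decorrelates the frame quantization of
#' time-to-peak estimates so that region-mean TTP ratios are unbiased at
#' clinical frame spacings.
#'
#' @param nx,ny,nz Grid dimensions; `nx` even.
#' @param time A [time_grid()] (default 20 frames at 2 s).
#' @param aif An [aif_params()].
#' @param normal A [tissue_class()] for normal tissue.
#' @param lesions Named list of [lesion_spec()]s (names become region
#'   labels; defaults [default_lesions()]). Use `list()` for a lesion-free
#'   phantom.
#' @param ttp_target Normal-tissue time-to-peak, seconds; snapped to the
#'   nearest acquisition frame time so the contralateral TTP is
#'   quantization-free. Default 12.
#' @param mtt_jitter Half-range of the lesion MTT jitter as a fraction of
#'   the lesion MTT. Default 0.1.
#' @param texture_cbf,texture_mtt Amplitude of the deterministic smooth
#'   spatial texture multiplying the CBF and MTT fields (fraction of the
#'   local class value; defaults 0.2 and 0.1). The texture emulates the
#'   smooth within-tissue variation of real perfusion (gray/white-matter
#'   structure) and is symmetric about the mirror plane, so relative maps
#'   remain voxel-exact. Set 0 for piecewise-constant tissue.
#' @param noise_sigma Default measurement noise SD in HU for downstream
#'   experiments (the built series itself is noiseless). Default 2.
#' @param rho Tissue density, g/mL (default 1.04).
#' @param k_h Hematocrit correction factor (default 1).
#' @param seed Integer seed recorded in the spec; [build_phantom()] is
#'   deterministic, the seed feeds noise realizations.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(nx = 64, ny = 64, nz = 1,
                         time = time_grid(20, 2),
                         aif = aif_params(),
                         normal = tissue_class(),
                         lesions = default_lesions(nx, ny),
                         ttp_target = 12, mtt_jitter = 0.1,
                         texture_cbf = 0.2, texture_mtt = 0.1,
                         noise_sigma = 2, rho = 1.04, k_h = 1, seed = 42L) {
  if (nx %% 2L != 0L) .fail_validation("nx must be even for a voxel-exact mirror")
  if (nx < 8 || ny < 8 || nz < 1) .fail_validation("grid too small")
  stopifnot(inherits(time, "time_grid"), inherits(aif, "aif_params"),
            inherits(normal, "tissue_class"))
  if (length(lesions) && (is.null(names(lesions)) || any(names(lesions) == "")))
    .fail_validation("lesions must be a named list")
  for (l in lesions) stopifnot(inherits(l, "lesion_spec"))
  if (noise_sigma < 0) .fail_validation("noise_sigma must be >= 0")
  if (mtt_jitter < 0 || mtt_jitter >= 1) .fail_validation("mtt_jitter must be in [0, 1)")
  if (texture_cbf < 0 || texture_cbf >= 1 || texture_mtt < 0 || texture_mtt >= 1)
    .fail_validation("texture amplitudes must be in [0, 1)")
  structure(list(nx = as.integer(nx), ny = as.integer(ny), nz = as.integer(nz),
                 time = time, aif = aif, normal = normal, lesions = lesions,
                 ttp_target = ttp_target, mtt_jitter = mtt_jitter,
                 texture_cbf = texture_cbf, texture_mtt = texture_mtt,
                 noise_sigma = noise_sigma, rho = rho, k_h = k_h,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# internal flow units: peak of G (1/s) for a CBF in mL/100g/min
.flow_internal <- function(cbf, rho, k_h) cbf * rho / (6000 * k_h)

# deterministic smooth spatial pattern in [-1, 1], symmetric about the
# mid-sagittal plane (depends on x only through the distance to it)
.texture_field <- function(nx, ny, nz, phase = 0) {
  u <- abs(seq_len(nx) - (nx + 1) / 2) / (nx / 2)
  v <- seq_len(ny) / ny
  w <- if (nz > 1) seq_len(nz) / nz else 0.5
  f <- array(0, dim = c(nx, ny, nz))
  for (k in seq_len(nz)) {
    f[, , k] <- outer(u, v, function(a, b)
      0.6 * sin(2 * pi * (1.3 * a + 0.7 * b) + phase) +
      0.4 * sin(2 * pi * (0.9 * b - 2.1 * a * b) + 2 * phase + 3 * w[k]))
  }
  f / max(abs(f))
}

# ellipsoid membership on the voxel lattice
.ellipsoid_mask <- function(nx, ny, nz, center, radii) {
  x <- seq_len(nx); y <- seq_len(ny); z <- seq_len(nz)
  dx2 <- ((x - center[1]) / radii[1])^2
  dy2 <- ((y - center[2]) / radii[2])^2
  dz2 <- if (nz > 1) ((z - center[3]) / radii[3])^2 else rep(0, nz)
  outer(outer(dx2, dy2, `+`), dz2, `+`) <= 1
}

# quasi-continuous tissue peak time for an exponential/box residue at delay 0,
# from a refined-grid convolution
.cont_ttp_shape <- function(aif, grid, mtts, shape, refine = 40L) {
  fg <- refine_grid(grid, refine)
  Bf <- make_aif(aif, fg)
  tf <- grid_times(fg)
  vapply(mtts, function(m) {
    Rf <- if (shape == "exponential") exp(-(tf - fg$t0) / m)
          else as.numeric(tf - fg$t0 < m)
    Cf <- fg$dt * stats::convolve(as.numeric(Bf), rev(Rf), type = "open")[seq_along(tf)]
    tf[which.max(Cf)]
  }, numeric(1))
}

#' Build a phantom acquisition with ground truth
#'
#' Evaluates the forward tracer-kinetic model voxel by voxel: every brain
#' voxel gets a flow-scaled residue function from its tissue class (normal,
#' or a lesion class scaled by its severities), and the noiseless tissue
#' series is the convolution of the arterial input with those residues.
#' Hemispheric mirror symmetry holds exactly outside lesion regions. Noise
#' is never added here (see [add_noise()]).
#'
#' CBF, CBV and MTT ground truth are the analytic per-voxel parameters.
#' TTP ground truth is the argmax of the noiseless acquisition-grid curve
#' (clinically, TTP is a property of the measured time-dose curve): the
#' normal-tissue delay is calibrated so the normal curve peaks on the frame
#' nearest `ttp_target`, and each lesion delay is calibrated by direct
#' search so the region-mean discrete TTP equals `rttp/100 *` the normal
#' TTP (sub-frame delay dithering across the region makes that mean vary
#' continuously with delay).
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `ctp_phantom`: list with
#'   * `series`: noiseless 4D enhancement array `(nx, ny, nz, T)` in HU;
#'   * `aif`: the arterial input on the acquisition grid;
#'   * `truth`: ground-truth maps `cbf`, `cbv`, `mtt`, `ttp` (3D arrays),
#'     `G_true` (4D, internal 1/s units), `labels` (3D integer: 0
#'     background, 1 normal, 2... lesions in spec order);
#'   * `masks`: logical arrays `brain` plus one per lesion;
#'   * `meta`: calibrated delays, normal TTP, achieved severities;
#'   * `spec`: the input spec.
#' @export
build_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  nx <- spec$nx; ny <- spec$ny; nz <- spec$nz
  grid <- spec$time
  T_ <- grid$n_frames

  brain <- .ellipsoid_mask(nx, ny, nz, c((nx + 1) / 2, (ny + 1) / 2, (nz + 1) / 2),
                           c(0.45 * nx, 0.45 * ny, max(0.45 * nz, 0.5)))
  labels <- array(0L, dim = c(nx, ny, nz))
  labels[brain] <- 1L

  lesion_masks <- list()
  xmid <- (nx + 1) / 2
  for (nm in names(spec$lesions)) {
    l <- spec$lesions[[nm]]
    m <- .ellipsoid_mask(nx, ny, nz, l$center, l$radii)
    if (!any(m)) .fail_validation(sprintf("lesion '%s' contains no voxels", nm))
    if (any(m & !brain)) .fail_validation(sprintf("lesion '%s' extends outside the brain", nm))
    xs <- slice.index(m, 1)[m]
    if (any(xs >= xmid))
      .fail_validation(sprintf("lesion '%s' crosses the mid-sagittal plane", nm))
    for (other in lesion_masks)
      if (any(m & other)) .fail_validation("lesion regions overlap")
    lesion_masks[[nm]] <- m
  }
  for (i in seq_along(lesion_masks)) labels[lesion_masks[[i]]] <- i + 1L

  # per-voxel perfusion parameters: smooth mirror-symmetric texture times
  # the class value; lesions scale the local (textured) normal value, so
  # every affected/contralateral ratio equals the severity voxel-exactly
  norm <- spec$normal
  tex_f <- 1 + spec$texture_cbf * .texture_field(nx, ny, nz, phase = 0.4)
  tex_m <- 1 + spec$texture_mtt * .texture_field(nx, ny, nz, phase = 2.1)
  cbf_map <- array(0, dim = c(nx, ny, nz)); cbf_map[brain] <- (norm$cbf * tex_f)[brain]
  mtt_map <- array(0, dim = c(nx, ny, nz)); mtt_map[brain] <- (norm$mtt * tex_m)[brain]
  for (i in seq_along(lesion_masks)) {
    l <- spec$lesions[[i]]
    m <- lesion_masks[[i]]
    n_v <- sum(m)
    jit <- 1 + spec$mtt_jitter * .golden_jitter(n_v)
    cbf_map[m] <- cbf_map[m] * l$severity["rcbf"] / 100
    mtt_map[m] <- mtt_map[m] * l$severity["rmtt"] / 100 * jit
  }
  cbv_map <- cbf_map * mtt_map / 60

  # delay calibration against the *discrete* time-to-peak. TTP is a
  # property of the sampled enhancement curve, so targets are met on the
  # acquisition grid itself: the normal delay centers the normal curve's
  # argmax on the frame nearest ttp_target, and each lesion delay is found
  # by direct search so the region-mean discrete TTP (with sub-frame delay
  # dithering across the region) hits rttp/100 * normal TTP.
  shape <- norm$shape
  B <- make_aif(spec$aif, grid)
  sys <- build_conv_matrix(B, grid$dt)
  tt <- grid_times(grid)
  dt <- grid$dt
  ttp_disc <- function(mtts, dels) {
    G <- .residue_matrix(shape, rep(1, length(mtts)), mtts, dels, grid)
    C <- G %*% t(sys$A)
    tt[max.col(C, ties.method = "first")]
  }
  ttp_target <- tt[which.min(abs(tt - spec$ttp_target))]
  if (!is.null(norm$delay)) {
    delay_n <- norm$delay
    ttp_normal <- ttp_disc(norm$mtt, delay_n)
  } else {
    cand <- seq(0, max(tt) / 2, by = dt / 40)
    resp <- ttp_disc(rep(norm$mtt, length(cand)), cand)
    hit <- which(resp == ttp_target)
    delay_n <- if (length(hit)) cand[hit[ceiling(length(hit) / 2)]] else
      cand[which.min(abs(resp - ttp_target))]
    ttp_normal <- ttp_disc(norm$mtt, delay_n)
  }

  delay_map <- array(0, dim = c(nx, ny, nz)); delay_map[brain] <- delay_n
  delays <- c(normal = delay_n)
  for (i in seq_along(lesion_masks)) {
    l <- spec$lesions[[i]]
    m <- lesion_masks[[i]]
    n_v <- sum(m)
    # sub-frame dither, equidistributed and zero-mean over the region
    dj <- dt * (((seq_len(n_v) * 0.41421356237309515) %% 1) - 0.5)
    dj <- dj - mean(dj)
    # the contralateral mirror voxels share the texture, so the target is
    # the mean per-voxel TTP ratio against their discrete peak times
    ttp_mirror <- ttp_disc((norm$mtt * tex_m)[m], rep(delay_n, n_v))
    target <- l$severity["rttp"]
    resp_of <- function(d) mean(100 * ttp_disc(mtt_map[m], pmax(d + dj, 0)) / ttp_mirror)
    guess <- target / 100 * ttp_normal -
      mean(.cont_ttp_shape(spec$aif, grid, mtt_map[m], shape))
    cand <- seq(max(guess - 2 * dt, 0), max(guess + 2 * dt, 2 * dt), by = dt / 40)
    resp <- vapply(cand, resp_of, numeric(1))
    d_l <- cand[which.min(abs(resp - target))]
    if (min(abs(resp - target)) > 100 * dt / ttp_normal) {  # widen if guess poor
      cand <- seq(0, max(tt) - dt, by = dt / 20)
      resp <- vapply(cand, resp_of, numeric(1))
      d_l <- cand[which.min(abs(resp - target))]
    }
    delay_map[m] <- pmax(d_l + dj, 0)
    delays[names(lesion_masks)[i]] <- d_l
  }

  # per-voxel flow-scaled residues (internal 1/s units) and forward series
  idx <- which(brain)
  G <- matrix(0, nrow = nx * ny * nz, ncol = T_)
  G[idx, ] <- .residue_matrix(shape,
                              .flow_internal(cbf_map[idx], spec$rho, spec$k_h),
                              mtt_map[idx], delay_map[idx], grid)
  series <- array(G %*% t(sys$A), dim = c(nx, ny, nz, T_))
  ttp_map <- compute_ttp(series, grid)
  ttp_map[!brain] <- 0

  achieved <- lapply(spec$lesions, severity_achieved)
  structure(list(series = series, aif = B,
                 truth = list(cbf = cbf_map, cbv = cbv_map, mtt = mtt_map,
                              ttp = ttp_map,
                              G_true = array(G, dim = c(nx, ny, nz, T_)),
                              labels = labels),
                 masks = c(list(brain = brain), lesion_masks),
                 meta = list(delays = delays, ttp_normal = ttp_normal,
                             severity_achieved = achieved),
                 spec = spec),
            class = "ctp_phantom")
}

#' @export
print.ctp_phantom <- function(x, ...) {
  s <- x$spec
  cat(sprintf("<ctp_phantom> %dx%dx%d, %d frames (dt = %g s), %d lesion region(s)\n",
              s$nx, s$ny, s$nz, s$time$n_frames, s$time$dt, length(s$lesions)))
  invisible(x)
}

#' Add measurement noise to an enhancement series
#'
#' i.i.d. zero-mean Gaussian noise of standard deviation `sigma` (HU),
#' seeded and reproducible; the caller's RNG state is left untouched.
#' `sigma = 0` returns the input unchanged.
#'
#' @param vol Numeric array (any shape).
#' @param sigma Noise SD in HU, >= 0.
#' @param seed Integer seed.
#' @return Array of the same shape.
#' @export
add_noise <- function(vol, sigma, seed) {
  if (!is.finite(sigma) || sigma < 0) .fail_validation("sigma must be >= 0")
  if (sigma == 0) return(vol)
  noise <- .with_seed(seed, stats::rnorm(length(vol), 0, sigma))
  vol + array(noise, dim = dim(vol) %||% length(vol))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a treatment response in the phantom spec
#'
#' Returns a post-treatment spec in which every severity of the penumbra
#' (region `"pi"`) moves linearly toward 100% by `recovery_fraction`, while
#' core-infarct (`"cia"`) severities are unchanged — the salvageable
#' penumbra reperfuses, the infarct core does not.
#'
#' @param spec A [phantom_spec()] containing regions named `pi` and `cia`.
#' @param recovery_fraction Fraction of the deficit recovered, in \[0, 1\].
#' @return A new `phantom_spec`.
#' @export
simulate_treatment_effect <- function(spec, recovery_fraction) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!is.finite(recovery_fraction) || recovery_fraction < 0 || recovery_fraction > 1)
    .fail_validation("recovery_fraction must be in [0, 1]")
  if (!all(c("pi", "cia") %in% names(spec$lesions)))
    .fail_validation("spec must contain both 'pi' and 'cia' regions")
  post <- spec
  s <- post$lesions$pi$severity
  post$lesions$pi$severity <- s + recovery_fraction * (100 - s)
  post
}
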