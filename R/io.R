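#' Write a volume as NIfTI
#'
#' Writes 3D maps, 4D series and integer label volumes. Voxel size defaults
#' to 1 mm isotropic; for 4D series the frame spacing of `grid` is stored in
#' the time dimension of `pixdim`, and a JSON sidecar (`<path>.json`)
#' records the time axis and units explicitly.
#'
#' @param arr Numeric or integer array (3D or 4D).
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param grid Optional [time_grid()] for 4D series.
#' @param units Free-text unit string recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_volume <- function(arr, path, grid = NULL, units = "") {
  pixdim <- c(1, 1, 1)
  if (!is.null(grid)) pixdim <- c(pixdim, grid$dt)
  img <- RNifti::asNifti(arr, pixdim = pixdim)
  RNifti::writeNifti(img, path)
  side <- list(units = units, dim = dim(arr))
  if (!is.null(grid))
    side <- c(side, list(n_frames = grid$n_frames, dt_s = grid$dt, t0_s = grid$t0))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a volume written by [write_volume()]
#'
#' @param path NIfTI path.
#' @return Plain numeric array (sidecar metadata, when present, as
#'   attribute `"meta"`).
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim = dim(img))
  sc <- paste0(path, ".json")
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    # restore singleton axes the NIfTI writer may have dropped
    if (!is.null(meta$dim) && prod(meta$dim) == length(arr))
      dim(arr) <- meta$dim
    attr(arr, "meta") <- meta
  }
  arr
}

#' Write an AIF as CSV
#'
#' Two columns: `time_s`, `value_hu`.
#'
#' @param B AIF values ([make_aif()] output, or numeric with `grid`).
#' @param path Output CSV path.
#' @param grid A [time_grid()]; defaults to the grid attached to `B`.
#' @return `path`, invisibly.
#' @export
write_aif_csv <- function(B, path, grid = attr(B, "grid")) {
  if (is.null(grid)) .fail_validation("no time grid available for the AIF")
  utils::write.csv(data.frame(time_s = grid_times(grid), value_hu = as.numeric(B)),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read an AIF CSV (columns time_s, value_hu)
#'
#' The time column must be uniformly spaced; the inferred grid is attached.
#'
#' @param path CSV path.
#' @return An `aif_curve`.
#' @export
read_aif_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "value_hu") %in% names(df)))
    .fail_validation("AIF CSV must have columns time_s, value_hu")
  dts <- diff(df$time_s)
  if (length(dts) < 1L || any(abs(dts - dts[1]) > 1e-9 * max(dts[1], 1)))
    .fail_validation("AIF time axis must be uniformly spaced")
  g <- time_grid(nrow(df), dts[1], df$time_s[1])
  structure(as.numeric(df$value_hu), grid = g, class = c("aif_curve", "numeric"))
}

# read a YAML or JSON config file into a list
.read_config <- function(path) {
  if (!file.exists(path)) .fail_validation(sprintf("config file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) yaml::read_yaml(path)
  else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
  else .fail_validation(sprintf("unsupported config extension: .%s", ext))
}

#' Build a phantom spec from a configuration list
#'
#' Accepts the nested list produced by reading the YAML/JSON phantom
#' configuration; absent fields fall back to the package defaults.
#'
#' @param cfg List (possibly empty) with optional fields `nx`, `ny`, `nz`,
#'   `n_frames`, `dt`, `t0`, `aif` (amplitude/onset/alpha/beta), `normal`
#'   (cbf/cbv/shape/delay), `lesions` (named: center/radii/severity),
#'   `ttp_target`, `mtt_jitter`, `noise_sigma`, `rho`, `k_h`, `seed`.
#' @return A [phantom_spec()].
#' @export
phantom_spec_from_config <- function(cfg = list()) {
  if (is.character(cfg)) cfg <- .read_config(cfg)
  gv <- function(name, default) cfg[[name]] %||% default
  nx <- gv("nx", 64); ny <- gv("ny", 64); nz <- gv("nz", 1)
  grid <- time_grid(gv("n_frames", 20), gv("dt", 2), gv("t0", 0))
  a <- cfg$aif %||% list()
  aif <- aif_params(a$amplitude %||% 66, a$onset %||% 4,
                    a$alpha %||% 3, a$beta %||% 1.5)
  n <- cfg$normal %||% list()
  normal <- tissue_class(n$cbf %||% 60, n$cbv %||% 4, n$delay,
                         n$shape %||% "box")
  lesions <- if (is.null(cfg$lesions)) default_lesions(nx, ny) else {
    lapply(cfg$lesions, function(l)
      lesion_spec(unlist(l$center), unlist(l$radii),
                  severity = unlist(l$severity)))
  }
  phantom_spec(nx = nx, ny = ny, nz = nz, time = grid, aif = aif,
               normal = normal, lesions = lesions,
               ttp_target = gv("ttp_target", 12),
               mtt_jitter = gv("mtt_jitter", 0.1),
               noise_sigma = gv("noise_sigma", 2),
               rho = gv("rho", 1.04), k_h = gv("k_h", 1),
               seed = gv("seed", 42L))
}

#' Build solver configs from a configuration list
#'
#' @param cfg Named list of solver entries (each with a `method` plus any
#'   [solver_config()] field), or `NULL` for the default trio
#'   wa_tv / tv / tikhonov.
#' @return Named list of `solver_config` objects.
#' @export
solver_configs_from_config <- function(cfg = NULL) {
  if (is.null(cfg) || length(cfg) == 0)
    return(list(wa_tv = solver_config("wa_tv"), tv = solver_config("tv"),
                tikhonov = solver_config("tikhonov")))
  if (is.null(names(cfg)) || any(names(cfg) == ""))
    .fail_validation("solver entries must be named")
  lapply(cfg, function(s) {
    solver_config(method = s$method %||% "wa_tv", lambda = s$lambda,
                  delta = s$delta, max_iter = s$max_iter %||% 200L,
                  tol = s$tol %||% 1e-6,
                  nonnegativity = s$nonnegativity %||% TRUE,
                  tsvd_threshold = s$tsvd_threshold %||% 0.1,
                  inner_prox_iters = s$inner_prox_iters %||% 20L,
                  adaptive_weights = s$adaptive_weights %||% TRUE)
  })
}
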