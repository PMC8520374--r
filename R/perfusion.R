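#' Cerebral blood flow from the residue estimate
#'
#' `CBF(v) = k_h * 100 * 60 * max_t G(v, t) / rho` in mL/100g/min: the peak
#' of the flow-scaled residue function, converted from internal 1/s units
#' with tissue density `rho` (g/mL) and hematocrit factor `k_h`.
#'
#' @param G_hat Residue estimates: 4D array `(nx, ny, nz, T)` or voxels x T
#'   matrix.
#' @param rho Tissue density, g/mL. Default 1.04.
#' @param k_h Hematocrit factor. Default 1.
#' @return 3D array (or vector) of CBF values, >= 0 wherever `G_hat` is.
#' @export
compute_cbf <- function(G_hat, rho = 1.04, k_h = 1) {
  if (any(!is.finite(G_hat))) .fail_validation("G_hat must be finite")
  d <- dim(G_hat)
  m <- if (is.null(d)) matrix(G_hat, nrow = 1) else matrix(G_hat, ncol = d[length(d)])
  peak <- do.call(pmax, c(asplit(m, 2), list(na.rm = FALSE)))
  out <- k_h * 6000 * peak / rho
  if (is.null(d) || length(d) < 2) out else array(out, dim = d[-length(d)])
}

#' Cerebral blood volume from curve areas
#'
#' `CBV(v) = k_h * 100 * (integral C_v / integral B) / rho` in mL/100g,
#' with trapezoid quadrature on the acquisition grid. Linear in C.
#'
#' @param C Tissue curves: 4D array or voxels x T matrix.
#' @param B Arterial input on the same grid.
#' @param grid A [time_grid()].
#' @param rho,k_h Conversion constants as in [compute_cbf()].
#' @return 3D array (or vector) of CBV values.
#' @export
compute_cbv <- function(C, B, grid, rho = 1.04, k_h = 1) {
  stopifnot(inherits(grid, "time_grid"))
  ib <- .trapz(as.numeric(B), grid$dt)
  if (ib <= 0) .fail_validation("AIF integral must be > 0")
  d <- dim(C)
  m <- if (is.null(d)) matrix(C, nrow = 1) else matrix(C, ncol = d[length(d)])
  T_ <- ncol(m)
  wts <- c(0.5, rep(1, T_ - 2L), 0.5) * grid$dt
  ic <- drop(m %*% wts)
  out <- k_h * 100 * (ic / ib) / rho
  if (is.null(d) || length(d) < 2) out else array(out, dim = d[-length(d)])
}

#' Mean transit time by the central-volume theorem
#'
#' `MTT = 60 * CBV / CBF` seconds where `CBF > 0`; voxels with `CBF <= 0`
#' are flagged invalid (`NA`), never infinite.
#'
#' @param cbf CBF map, mL/100g/min.
#' @param cbv CBV map, mL/100g (same shape).
#' @return MTT map in seconds.
#' @export
compute_mtt <- function(cbf, cbv) {
  if (!identical(dim(cbf), dim(cbv)) || length(cbf) != length(cbv))
    .fail_validation("CBF and CBV maps must be conformable")
  out <- cbf
  out[] <- NA_real_
  ok <- is.finite(cbf) & cbf > 0
  out[ok] <- 60 * cbv[ok] / cbf[ok]
  out
}

#' Time to peak of the tissue curve
#'
#' `TTP(v) = t0 + dt * argmax_k C_v(k)` (0-based frames), ties broken toward
#' the earliest frame. All-zero curves are flagged invalid (`NA`).
#'
#' @param C Tissue curves: 4D array or voxels x T matrix.
#' @param grid A [time_grid()].
#' @return 3D array (or vector) of peak times in seconds.
#' @export
compute_ttp <- function(C, grid) {
  stopifnot(inherits(grid, "time_grid"))
  d <- dim(C)
  m <- if (is.null(d)) matrix(C, nrow = 1) else matrix(C, ncol = d[length(d)])
  k <- max.col(m, ties.method = "first")
  out <- grid$t0 + grid$dt * (k - 1)
  out[rowSums(m != 0) == 0L] <- NA_real_
  if (is.null(d) || length(d) < 2) out else array(out, dim = d[-length(d)])
}

#' All four perfusion parameter maps
#'
#' Convenience wrapper producing CBF (residue peak), CBV (curve-area
#' ratio), MTT (central-volume theorem) and TTP (curve argmax) from a
#' residue estimate and a set of tissue curves. Pass the solver-denoised
#' curves `conv_forward(sys, G_hat)` as `C` to make every map reflect the
#' reconstruction, or the measured curves for estimator-independent CBV/TTP.
#'
#' @param G_hat Residue estimates (4D array).
#' @param C Tissue curves used for CBV and TTP (4D array).
#' @param B Arterial input.
#' @param grid A [time_grid()].
#' @param rho,k_h Conversion constants.
#' @return Object of class `perfusion_maps`: list `cbf`, `cbv`, `mtt`,
#'   `ttp` plus conversion metadata.
#' @export
perfusion_maps <- function(G_hat, C, B, grid, rho = 1.04, k_h = 1) {
  cbf <- compute_cbf(G_hat, rho, k_h)
  cbv <- compute_cbv(C, B, grid, rho, k_h)
  structure(list(cbf = cbf, cbv = cbv, mtt = compute_mtt(cbf, cbv),
                 ttp = compute_ttp(C, grid),
                 meta = list(rho = rho, k_h = k_h, dt = grid$dt, t0 = grid$t0)),
            class = "perfusion_maps")
}

.mirror_index <- function(nx) rev(seq_len(nx))

#' Relative (affected / contralateral) maps by mirror symmetry
#'
#' For every voxel on the affected side,
#' `rX(v) = 100 * X(v) / X(mirror(v))` for X in CBF, CBV, MTT, TTP, with the
#' mirror taken about the mid-sagittal plane between columns nx/2 and
#' nx/2 + 1 (`nx` even). Values are percent of contralateral; voxels whose
#' mirror partner has a non-positive or missing value, or lies outside the
#' brain mask, are undefined (`NA`).
#'
#' @param maps A [perfusion_maps()] object (or list with cbf/cbv/mtt/ttp).
#' @param brain_mask Logical 3D array.
#' @param affected `"left"` (x <= nx/2) or `"right"`.
#' @return Object of class `relative_maps`: list `rcbf`, `rcbv`, `rmtt`,
#'   `rttp` plus the mirror-axis description.
#' @export
compute_relative_maps <- function(maps, brain_mask, affected = c("left", "right")) {
  affected <- match.arg(affected)
  d <- dim(brain_mask)
  nx <- d[1]
  if (nx %% 2L != 0L) .fail_validation("mirror requires an even first dimension")
  side <- slice.index(brain_mask, 1) <= nx / 2
  if (affected == "right") side <- !side
  rel_one <- function(X) {
    if (!identical(dim(X), d)) .fail_validation("map/mask dimension mismatch")
    Xm <- X[.mirror_index(nx), , , drop = FALSE]
    ok <- side & brain_mask & brain_mask[.mirror_index(nx), , , drop = FALSE] &
      is.finite(Xm) & Xm > 0 & is.finite(X)
    out <- array(NA_real_, dim = d)
    out[ok] <- 100 * X[ok] / Xm[ok]
    out
  }
  structure(list(rcbf = rel_one(maps$cbf), rcbv = rel_one(maps$cbv),
                 rmtt = rel_one(maps$mtt), rttp = rel_one(maps$ttp),
                 affected = affected,
                 axis = sprintf("mid-sagittal plane between x = %d and x = %d",
                                nx %/% 2L, nx %/% 2L + 1L)),
            class = "relative_maps")
}

#' Threshold-based core/penumbra classification
#'
#' Labels affected-side voxels by their relative CBF: core infarct where
#' `rCBF < cia_cut`, penumbra where `cia_cut <= rCBF < pi_cut`, normal
#' otherwise. A configurable utility, not a clinical triage rule.
#'
#' @param rel A [compute_relative_maps()] result.
#' @param cia_cut,pi_cut Ordered rCBF percent thresholds
#'   (`cia_cut < pi_cut`); defaults 30 and 70.
#' @return Integer array: `NA` undefined, 1 normal, 2 penumbra, 3 core.
#' @export
classify_regions <- function(rel, cia_cut = 30, pi_cut = 70) {
  if (!(cia_cut < pi_cut) && !(cia_cut == 0 && pi_cut == 0))
    .fail_validation("thresholds must satisfy cia_cut < pi_cut")
  r <- rel$rcbf
  out <- array(NA_integer_, dim = dim(r))
  def <- is.finite(r)
  out[def] <- 1L
  out[def & r < pi_cut] <- 2L
  out[def & r < cia_cut] <- 3L
  out
}

#' Region summary of relative parameters
#'
#' Mean, SD and voxel count of each relative parameter over each region
#' mask — the per-region report a perfusion workstation prints.
#'
#' @param rel A [compute_relative_maps()] result.
#' @param masks Named list of logical arrays (regions).
#' @param phase Optional label (e.g. `"pre"`, `"post"`) copied to a column.
#' @return Data frame: region, parameter, phase, mean, sd, n_voxels.
#' @export
region_summary <- function(rel, masks, phase = "pre") {
  params <- c("rcbf", "rcbv", "rmtt", "rttp")
  rows <- list()
  for (rn in names(masks)) {
    for (pn in params) {
      v <- rel[[pn]][masks[[rn]]]
      v <- v[is.finite(v)]
      rows[[length(rows) + 1L]] <- data.frame(
        region = rn, parameter = pn, phase = phase,
        mean = if (length(v)) mean(v) else NA_real_,
        sd = if (length(v) > 1) stats::sd(v) else NA_real_,
        n_voxels = length(v))
    }
  }
  do.call(rbind, rows)
}
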