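#' Discrete tracer-kinetic convolution system
#'
#' The tissue enhancement curve of a voxel is modeled as the causal
#' convolution of the arterial input function B with the voxel's flow-scaled
#' residue function G: `c(t) = integral B(s) G(t - s) ds`. On the acquisition
#' grid this becomes the linear system `c = A g` with
#' `A[i, j] = dt * B[i - j]` for `i >= j` (0-based) and 0 above the
#' diagonal: a lower-triangular Toeplitz matrix whose first column is
#' `dt * B`. The quadrature factor `dt` lives in the matrix so that G keeps
#' physical units of flow-scaled residue (1/s).
#'
#' @param B Arterial input values on the grid ([make_aif()] output or any
#'   finite numeric vector of length >= 2).
#' @param dt Seconds per frame; taken from `attr(B, "grid")` when present.
#' @return An object of class `conv_system` with elements `A` (T x T
#'   matrix), `B`, `dt`.
#' @examples
#' sys <- build_conv_matrix(c(1, 0, 0), dt = 1)
#' sys$A  # identity: a delta-function AIF leaves G unchanged
#' @export
build_conv_matrix <- function(B, dt = NULL) {
  if (is.null(dt)) {
    g <- attr(B, "grid")
    if (is.null(g)) stop("dt must be given when B carries no time grid", call. = FALSE)
    dt <- g$dt
  }
  B <- as.numeric(B)
  if (length(B) < 2L) stop("B must have length >= 2", call. = FALSE)
  if (any(!is.finite(B))) stop("B must be finite", call. = FALSE)
  if (!is.finite(dt) || dt <= 0) stop("dt must be > 0", call. = FALSE)
  T_ <- length(B)
  A <- matrix(0, T_, T_)
  idx <- which(lower.tri(A, diag = TRUE), arr.ind = TRUE)
  A[idx] <- dt * B[idx[, 1L] - idx[, 2L] + 1L]
  structure(list(A = A, B = B, dt = dt), class = "conv_system")
}

#' Forward convolution of residue functions
#'
#' Applies the convolution matrix to every voxel's residue independently.
#' Linear in G: `forward(a G1 + b G2) = a forward(G1) + b forward(G2)`, and
#' causal (frame k of the output depends only on residue frames <= k).
#'
#' @param sys A [build_conv_matrix()] system.
#' @param G Residue values: a numeric vector of length T, a voxels x T
#'   matrix, or a 4D array with time as the last axis.
#' @return Tissue curves with the same shape as `G`.
#' @export
conv_forward <- function(sys, G) {
  stopifnot(inherits(sys, "conv_system"))
  T_ <- ncol(sys$A)
  if (is.null(dim(G))) {
    if (length(G) != T_) stop("G length must equal system size", call. = FALSE)
    return(drop(sys$A %*% G))
  }
  d <- dim(G)
  if (d[length(d)] != T_)
    stop(sprintf("time axis mismatch: G has %d frames, system has %d",
                 d[length(d)], T_), call. = FALSE)
  Gm <- matrix(G, ncol = T_)          # voxels x T
  Cm <- Gm %*% t(sys$A)
  array(Cm, dim = d)
}

#' Squared-spectral-norm bound for the ISTA step size
#'
#' Returns `L >= sigma_max(A)^2`, the Lipschitz constant of the gradient of
#' the per-voxel data-fidelity term `0.5 * ||A g - c||^2`. Computed by power
#' iteration on `A'A` (two deterministic starts, tight convergence, then a
#' 1e-7 relative inflation so the bound errs on the safe side).
#'
#' @param sys A `conv_system`.
#' @return Positive scalar.
#' @export
lipschitz_bound <- function(sys) {
  stopifnot(inherits(sys, "conv_system"))
  A <- sys$A
  T_ <- ncol(A)
  AtA <- crossprod(A)
  rayleigh <- function(v) {
    lam <- 0
    for (i in seq_len(500L)) {
      w <- AtA %*% v
      nw <- sqrt(sum(w * w))
      if (nw == 0) return(0)
      w <- w / nw
      lam_new <- drop(crossprod(w, AtA %*% w))
      if (abs(lam_new - lam) <= 1e-13 * max(1, lam_new)) { lam <- lam_new; break }
      lam <- lam_new
      v <- w
    }
    lam
  }
  # two fixed starts: the constant vector can be orthogonal to the top
  # eigenvector in contrived cases, so add a quasi-random second start
  v1 <- rep(1 / sqrt(T_), T_)
  v2 <- ((seq_len(T_) * 0.6180339887498949) %% 1) - 0.5
  v2 <- v2 / sqrt(sum(v2 * v2))
  L <- max(rayleigh(v1), rayleigh(v2))
  L * (1 + 1e-7)
}
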