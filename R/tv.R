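#' Soft-thresholding (shrinkage) operator
#'
#' `sign(x) * max(|x| - theta, 0)`, elementwise: the proximal operator of
#' `theta * |.|`, the elementary shrinkage step of iterative
#' shrinkage-thresholding methods.
#'
#' @param x Numeric scalar or array.
#' @param theta Threshold, >= 0.
#' @return Same shape as `x`.
#' @export
soft_threshold <- function(x, theta) {
  if (!is.numeric(theta) || length(theta) != 1L || !is.finite(theta) || theta < 0)
    stop("theta must be a finite scalar >= 0", call. = FALSE)
  sign(x) * pmax(abs(x) - theta, 0)
}

# number of spatial axes of a field (a bare vector counts as 1D)
.n_axes <- function(x) if (is.null(dim(x))) 1L else length(dim(x))

#' Forward spatial differences
#'
#' Forward differences along every spatial axis with replicate (Neumann)
#' boundary: the last difference along each axis is 0, so the gradient of a
#' constant field vanishes identically. The result stacks the per-axis
#' differences along one extra trailing axis.
#'
#' @param x Numeric vector (1D) or 2D/3D array.
#' @return Array of dimension `c(dim(x), n_axes)`.
#' @seealso [spatial_divergence()] for the negative adjoint.
#' @export
spatial_gradient <- function(x) {
  d <- if (is.null(dim(x))) length(x) else dim(x)
  na <- length(d)
  if (na > 3L) stop("at most 3 spatial axes supported", call. = FALSE)
  x <- array(as.numeric(x), dim = d)
  out <- array(0, dim = c(d, na))
  idx_all <- lapply(d, seq_len)
  for (ax in seq_len(na)) {
    if (d[ax] < 2L) next
    ip <- idx_all; ip[[ax]] <- c(seq_len(d[ax] - 1L) + 1L, d[ax])  # shifted, clamp
    g <- do.call(`[`, c(list(x), ip, list(drop = FALSE))) - x
    out[slice.index(out, na + 1L) == ax] <- g
  }
  out
}

#' Discrete divergence (negative adjoint of [spatial_gradient()])
#'
#' Satisfies `sum(spatial_gradient(x) * p) == -sum(x * spatial_divergence(p))`
#' for all conformable `x`, `p`.
#'
#' @param p Array of dimension `c(field dims, n_axes)` as produced by
#'   [spatial_gradient()].
#' @return Array with the field dimensions.
#' @export
spatial_divergence <- function(p) {
  dp <- dim(p)
  if (is.null(dp) || length(dp) < 2L)
    stop("p must stack per-axis components on its last axis", call. = FALSE)
  na <- dp[length(dp)]
  d <- dp[-length(dp)]
  if (length(d) != na)
    stop("last axis of p must index the spatial axes", call. = FALSE)
  out <- array(0, dim = d)
  idx_all <- lapply(d, seq_len)
  for (ax in seq_len(na)) {
    if (d[ax] < 2L) next
    pk <- array(p[slice.index(p, na + 1L) == ax], dim = d)
    # (div p)_j = p_j [j <= n-1] - p_{j-1} [j >= 2]; p at the last index is
    # never read (the matching gradient entry is structurally 0)
    term <- pk
    last <- idx_all; last[[ax]] <- d[ax]
    term[do.call(cbind, expand.grid(last))] <- 0
    ishift <- idx_all; ishift[[ax]] <- c(1L, seq_len(d[ax] - 1L))
    pk_sh <- do.call(`[`, c(list(term), ishift, list(drop = FALSE)))
    first <- idx_all; first[[ax]] <- 1L
    pk_sh[do.call(cbind, expand.grid(first))] <- 0
    out <- out + term - array(pk_sh, dim = d)
  }
  out
}

# Euclidean norm of the stacked gradient at each voxel
.grad_norm <- function(g) {
  dg <- dim(g)
  na <- dg[length(dg)]
  d <- dg[-length(dg)]
  m <- matrix(g, ncol = na)
  array(sqrt(rowSums(m * m)), dim = d)
}

#' Weighted-adaptive TV weights
#'
#' Perona-Malik-type edge weights `w = 1 / (1 + (||grad x|| / delta)^2)` in
#' (0, 1]: the weight decays where the local gradient magnitude is large
#' relative to the scale factor `delta`, so strong edges are penalized less
#' and survive the TV prior. Constant fields give `w == 1` (plain TV); so
#' does the limit `delta -> Inf`.
#'
#' @param x Current residue frame (or any intensity field).
#' @param delta Positive scale factor: the gradient magnitude at which the
#'   weight has decayed to 1/2.
#' @return Array of weights, same dimensions as `x`.
#' @export
wa_weights <- function(x, delta) {
  if (!is.finite(delta) || delta <= 0) stop("delta must be > 0", call. = FALSE)
  gn <- .grad_norm(spatial_gradient(x))
  1 / (1 + (gn / delta)^2)
}

#' Weighted isotropic total variation
#'
#' `sum_v w_v * ||grad x(v)||` with the forward-difference gradient of
#' [spatial_gradient()]. Weights identically 1 give the plain isotropic TV.
#'
#' @param x Field (vector or 2D/3D array).
#' @param weights Per-voxel weights, same shape as `x` (or scalar 1).
#' @return Non-negative scalar; 0 iff `x` is constant.
#' @export
wa_tv_value <- function(x, weights = 1) {
  gn <- .grad_norm(spatial_gradient(x))
  if (length(weights) != 1L && !all(dim(weights) == dim(gn) |
                                    length(weights) == length(gn)))
    stop("weights must conform to the field", call. = FALSE)
  sum(weights * gn)
}

#' Proximal operator of weighted TV
#'
#' Approximately solves `argmin_u 0.5 ||u - x||^2 + theta * sum w ||grad u||`
#' by a fixed number of Chambolle-type projected-gradient iterations on the
#' dual problem (dual step `1/(4 d)` for d active axes). `theta = 0` returns
#' `x` unchanged; large `theta` drives the output toward the field mean.
#'
#' The dual variable is returned as attribute `"dual"`, which may be passed
#' back via `p_init` to warm-start the next call (used by the ISTA outer
#' loop, where successive proximal subproblems are close).
#'
#' @param x Field (vector or 2D/3D array).
#' @param weights Per-voxel weights in (0, 1] (scalar 1 for plain TV).
#' @param theta Proximal weight, >= 0.
#' @param inner_iters Number of dual iterations (default 20).
#' @param p_init Optional dual warm start from a previous call.
#' @return Field of the same shape, with attribute `"dual"`.
#' @export
tv_prox <- function(x, weights = 1, theta, inner_iters = 20L, p_init = NULL) {
  if (!is.finite(theta) || theta < 0) stop("theta must be >= 0", call. = FALSE)
  d <- if (is.null(dim(x))) length(x) else dim(x)
  if (theta == 0 || inner_iters < 1L) {
    out <- x
    attr(out, "dual") <- p_init
    return(out)
  }
  d3 <- c(d, 1L, 1L)[1:3]
  z <- array(as.numeric(x), dim = d3)
  w <- if (length(weights) == 1L) array(weights, dim = d3) else array(as.numeric(weights), dim = d3)
  if (any(w <= 0)) stop("weights must be > 0", call. = FALSE)
  p <- if (is.null(p_init)) array(0, dim = c(d3, 3L)) else p_init
  res <- chambolle_wtv(z, w, theta, as.integer(inner_iters), p)
  u <- res$u
  out <- if (is.null(dim(x))) as.numeric(u) else array(u, dim = d)
  attr(out, "dual") <- res$p
  out
}
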