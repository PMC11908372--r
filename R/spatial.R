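# Volumes, displacement fields, the differentiable warp, the displacement
# regularizer and deformation diagnostics.

#' Construct a 3D intensity volume
#'
#' A single-channel 3D grid with voxel spacing, the basic image container
#' used throughout the package. Warping never changes the grid shape.
#'
#' @param intensities numeric 3D array (D x H x W)
#' @param spacing positive length-3 numeric, mm per voxel along each axis
#' @param affine optional 4x4 voxel-to-world matrix kept for NIfTI round-trips
#' @return an object of class \code{volume}
#' @export
volume <- function(intensities, spacing = c(1, 1, 1), affine = NULL) {
  stopifnot(is.numeric(intensities), length(dim(intensities)) == 3)
  if (!all(is.finite(intensities))) stop("volume intensities must be finite")
  stopifnot(length(spacing) == 3, all(spacing > 0))
  structure(list(intensities = intensities, spacing = as.numeric(spacing),
                 affine = affine), class = "volume")
}

#' @export
print.volume <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("<volume %dx%dx%d, spacing %s mm, range [%.3f, %.3f]>\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 3), collapse = "x"),
              min(x$intensities), max(x$intensities)))
  invisible(x)
}

#' @export
dim.volume <- function(x) dim(x$intensities)

as_volume <- function(x, spacing = c(1, 1, 1)) {
  if (inherits(x, "volume")) x else volume(x, spacing)
}

#' Construct a displacement field
#'
#' A 3-channel 3D vector grid \eqn{u}, channel \eqn{d} holding the
#' displacement along axis \eqn{d} in voxel units. The deformation it
#' represents is \eqn{v = Id + u}, with \eqn{Id} the identity sampling grid.
#'
#' @param u numeric 4D array with dim \code{c(3, D, H, W)}
#' @param spacing voxel spacing of the grid the field acts on
#' @return an object of class \code{displacement_field}
#' @export
displacement_field <- function(u, spacing = c(1, 1, 1)) {
  stopifnot(is.numeric(u), length(dim(u)) == 4, dim(u)[1] == 3)
  if (!all(is.finite(u))) stop("displacement field must be finite")
  structure(list(u = u, grid_shape = dim(u)[-1], spacing = as.numeric(spacing)),
            class = "displacement_field")
}

#' @export
print.displacement_field <- function(x, ...) {
  d <- x$grid_shape
  cat(sprintf("<displacement_field %dx%dx%d, max |u| = %.3f voxels>\n",
              d[1], d[2], d[3], max(abs(x$u))))
  invisible(x)
}

#' The identity (zero-displacement) field
#'
#' @param grid_shape length-3 integer grid size
#' @param spacing voxel spacing
#' @return a \code{displacement_field} with \eqn{u \equiv 0}
#' @export
identity_field <- function(grid_shape, spacing = c(1, 1, 1)) {
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 1))
  displacement_field(array(0, dim = c(3, grid_shape)), spacing)
}

#' Warp a volume by a displacement field
#'
#' Pull-style resampling through a differentiable grid sampler:
#' \code{out(p) = volume(p + u(p))}. Trilinear interpolation is used for
#' intensity images; nearest-neighbour is provided for label maps.
#'
#' @param vol a \code{volume} (or plain 3D array)
#' @param field a \code{displacement_field} on the same grid
#' @param interpolation \code{"trilinear"} or \code{"nearest"}
#' @param padding out-of-bounds rule, \code{"border"} (replicate) or
#'   \code{"zeros"}
#' @return a \code{volume} on the same grid
#' @export
warp <- function(vol, field, interpolation = c("trilinear", "nearest"),
                 padding = c("border", "zeros")) {
  interpolation <- match.arg(interpolation)
  padding <- match.arg(padding)
  vol <- as_volume(vol)
  if (!identical(dim(vol$intensities), as.integer(field$grid_shape)))
    stop(sprintf("shape mismatch: volume is %s, field acts on %s",
                 paste(dim(vol$intensities), collapse = "x"),
                 paste(field$grid_shape, collapse = "x")))
  out <- .warp_fwd(vol$intensities, field$u,
                   if (interpolation == "trilinear") 0L else 1L,
                   if (padding == "border") 0L else 1L)
  volume(out, vol$spacing, vol$affine)
}

#' Displacement-field regularizer
#'
#' Penalizes the magnitude and the spatial gradient of the displacement:
#' \deqn{R(u) = \alpha\,\mathrm{mean}_p \|u(p)\|^2 +
#'       \beta\,\mathrm{mean}_p \sum_{c,a} (\Delta_a u_c(p))^2,}
#' where \eqn{\Delta_a} is the forward finite difference along axis \eqn{a}
#' with a replicated edge (zero difference at the last slice). The mean runs
#' over voxels, so \code{alpha} and \code{beta} are resolution-independent.
#'
#' By default displacements are taken in voxel units. With
#' \code{normalized = TRUE} they are first rescaled to grid-sampler
#' coordinates (half grid extent = 1, the convention of standard
#' differentiable-warp implementations), which is the scale the default
#' alpha = 5, beta = 1 are calibrated for and the form used inside the
#' training objective.
#'
#' @param field a \code{displacement_field}
#' @param alpha weight on the squared magnitude (default 5)
#' @param beta weight on the squared spatial gradient (default 1)
#' @param normalized rescale displacements by the half grid extent first
#' @return list with \code{total}, \code{magnitude} and \code{gradient}
#'   components (the latter two unweighted means, \code{total} the weighted sum)
#' @export
displacement_regularizer <- function(field, alpha = 5, beta = 1,
                                     normalized = FALSE) {
  stopifnot(alpha >= 0, beta >= 0)
  u <- field$u
  if (normalized) u <- normalize_u(u)
  nvox <- prod(dim(u)[-1])
  mag <- sum(u^2) / nvox
  grad <- 0
  for (a in 1:3) grad <- grad + sum(fwd_diff(u, a)^2)
  grad <- grad / nvox
  list(total = alpha * mag + beta * grad, magnitude = mag, gradient = grad)
}

# forward difference of a (3,D,H,W) array along spatial axis a (1..3),
# replicated edge => zero at the last index
fwd_diff <- function(u, a) {
  d <- dim(u)
  n <- d[a + 1]
  idx_hi <- c(2:n, n)
  g <- switch(a,
    u[, idx_hi, , , drop = FALSE] - u,
    u[, , idx_hi, , drop = FALSE] - u,
    u[, , , idx_hi, drop = FALSE] - u)
  g
}

# adjoint of fwd_diff (for gradients of the regularizer)
fwd_diff_adj <- function(g, a) {
  d <- dim(g)
  n <- d[a + 1]
  out <- -g
  shift <- switch(a,
    g[, c(1, seq_len(n - 1)), , , drop = FALSE],
    g[, , c(1, seq_len(n - 1)), , drop = FALSE],
    g[, , , c(1, seq_len(n - 1)), drop = FALSE])
  zero_first <- function(x, a) {
    switch(a,
      { x[, 1, , ] <- 0; x },
      { x[, , 1, ] <- 0; x },
      { x[, , , 1] <- 0; x })
  }
  shift <- zero_first(shift, a)
  # the replicated last difference is identically zero, so its adjoint
  # contribution at the last slice must be dropped
  kill_last <- function(x, a) {
    switch(a,
      { x[, n, , ] <- 0; x },
      { x[, , n, ] <- 0; x },
      { x[, , , n] <- 0; x })
  }
  out <- kill_last(out, a)
  out + shift
}

# rescale a voxel-unit field to grid-sampler coordinates (half extent = 1)
normalize_u <- function(u) {
  d <- dim(u)[-1]
  for (a in 1:3) u[a, , , ] <- u[a, , , ] / ((d[a] - 1) / 2)
  u
}

# gradient of displacement_regularizer w.r.t. the voxel-unit u
regularizer_grad <- function(u, alpha, beta, normalized = FALSE) {
  half <- (dim(u)[-1] - 1) / 2
  if (normalized) u <- normalize_u(u)
  nvox <- prod(dim(u)[-1])
  g <- 2 * alpha * u / nvox
  if (beta > 0) {
    for (a in 1:3) g <- g + 2 * beta * fwd_diff_adj(fwd_diff(u, a), a) / nvox
  }
  if (normalized) for (a in 1:3) g[a, , , ] <- g[a, , , ] / half[a]
  g
}

#' Per-voxel Jacobian determinant of a deformation
#'
#' Computes \eqn{\det(\nabla(Id + u))} by forward finite differences
#' (replicated edge), a standard diagnostic of deformation quality: values
#' near 1 indicate near-volume-preserving deformation, nonpositive values
#' indicate folding.
#'
#' @param field a \code{displacement_field}
#' @return list with \code{det} (3D array) and \code{frac_nonpositive}
#' @export
jacobian_determinant <- function(field) {
  u <- field$u
  stopifnot(all(dim(u)[-1] >= 2))
  J <- vector("list", 9)  # J[[3*(a-1)+c]] = d u_c / d x_a (+ delta_ca)
  for (a in 1:3) {
    g <- fwd_diff(u, a)
    for (cc in 1:3) {
      m <- g[cc, , , ]
      if (a == cc) m <- m + 1
      J[[3 * (a - 1) + cc]] <- m
    }
  }
  # det of rows (du_c/dx_a): arrange as M[c, a]
  M <- function(cc, a) J[[3 * (a - 1) + cc]]
  det <- M(1, 1) * (M(2, 2) * M(3, 3) - M(2, 3) * M(3, 2)) -
         M(1, 2) * (M(2, 1) * M(3, 3) - M(2, 3) * M(3, 1)) +
         M(1, 3) * (M(2, 1) * M(3, 2) - M(2, 2) * M(3, 1))
  list(det = det, frac_nonpositive = mean(det <= 0))
}
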