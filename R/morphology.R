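## Binary 3D morphology and separable Gaussian smoothing.
## Masks are logical 3D arrays; all operations are voxel-based.

#' Label connected components of a 3D mask
#'
#' 6-connected component labelling.
#'
#' @param mask Logical 3D array.
#' @return Integer array of the same shape, 0 for background; attribute
#'   `n` holds the number of components.
#' @export
label_components <- function(mask) {
  stopifnot(is.array(mask), length(dim(mask)) == 3)
  lab <- cc_label3d(as.logical(mask), as.integer(dim(mask)))
  n <- attr(lab, "n")
  lab <- array(lab, dim(mask))
  attr(lab, "n") <- n
  lab
}

## Offsets of the Euclidean ball of the given voxel radius.
ball_offsets <- function(radius) {
  r <- ceiling(radius)
  g <- expand.grid(dx = -r:r, dy = -r:r, dz = -r:r)
  g[g$dx^2 + g$dy^2 + g$dz^2 <= radius^2, , drop = FALSE]
}

## Zero-padded integer shift of a 3D array.
shift3d <- function(a, d) {
  dm <- dim(a)
  out <- array(if (is.logical(a)) FALSE else 0, dm)
  src <- dst <- vector("list", 3)
  for (ax in 1:3) {
    n <- dm[ax]; s <- d[ax]
    if (abs(s) >= n) return(out)
    if (s >= 0) { dst[[ax]] <- (1 + s):n; src[[ax]] <- 1:(n - s) }
    else        { dst[[ax]] <- 1:(n + s); src[[ax]] <- (1 - s):n }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

#' Dilate or erode a binary mask with a spherical structuring element
#'
#' @param mask Logical 3D array.
#' @param radius Radius in voxels of the Euclidean ball.
#' @return Logical array of the same shape.
#' @export
dilate_mask <- function(mask, radius) {
  if (radius <= 0) return(mask)
  off <- ball_offsets(radius)
  out <- array(FALSE, dim(mask))
  for (i in seq_len(nrow(off)))
    out <- out | shift3d(mask, c(off$dx[i], off$dy[i], off$dz[i]))
  out
}

#' @rdname dilate_mask
#' @export
erode_mask <- function(mask, radius) {
  if (radius <= 0) return(mask)
  !dilate_mask(!mask, radius)
}

#' Morphological closing (dilation followed by erosion)
#' @inheritParams dilate_mask
#' @export
close_mask <- function(mask, radius) erode_mask(dilate_mask(mask, radius), radius)

#' Fill enclosed cavities of a binary mask
#'
#' Background components that do not touch the volume border are
#' interior holes and are added to the mask.
#'
#' @param mask Logical 3D array.
#' @export
fill_holes <- function(mask) {
  lab <- label_components(!mask)
  if (attr(lab, "n") == 0L) return(mask)
  dm <- dim(mask)
  border <- unique(c(lab[c(1, dm[1]), , ], lab[, c(1, dm[2]), ], lab[, , c(1, dm[3])]))
  border <- border[border > 0L]
  mask | (lab > 0L & !(lab %in% border))
}

## Banded Gaussian convolution matrix with renormalised rows (flux is
## preserved in the interior; edge rows renormalise rather than darken).
gauss_row_matrix <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  K <- outer(seq_len(n), seq_len(n), function(i, j) dnorm(j - i, sd = sigma))
  K[abs(row(K) - col(K)) > ceiling(4 * sigma)] <- 0
  K / rowSums(K)
}

#' Separable Gaussian blur of a 3D volume
#'
#' Approximates a scanner point-spread function. The kernel width is
#' given as full width at half maximum in millimetres and converted to
#' voxels with the volume spacing.
#'
#' @param a Numeric 3D array.
#' @param fwhm_mm Full width at half maximum, mm (scalar).
#' @param spacing Voxel spacing, mm per axis (length 3).
#' @return Blurred array, same shape.
#' @export
blur_volume <- function(a, fwhm_mm, spacing) {
  if (fwhm_mm <= 0) return(a)
  sigmas <- (fwhm_mm / 2.354820045) / spacing
  for (ax in 1:3) {
    if (sigmas[ax] <= 1e-8) next
    perm <- c(ax, setdiff(1:3, ax))
    a <- aperm(a, perm)
    d <- dim(a)
    a <- array(gauss_row_matrix(d[1], sigmas[ax]) %*% matrix(a, d[1]), d)
    a <- aperm(a, order(perm))
  }
  a
}
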