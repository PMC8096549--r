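#' Network homogeneity map
#'
#' For every voxel inside the network mask, NH is the mean Pearson
#' correlation between its time series and the series of every other
#' in-mask voxel. Computed in the O(m T) matrix form: series are
#' standardized, the full correlation matrix is a scaled cross-product, and
#' each voxel's NH is its correlation-row mean excluding the diagonal.
#' Zero-variance voxels receive NH 0, are excluded from every other voxel's
#' mean, and are counted in a message.
#'
#' @param run a preprocessed `bold_run`.
#' @param mask a `network_mask` on the same grid (>= 2 voxels).
#' @param subject_id optional id carried on the map.
#' @return object of class `nh_map`: `values` (3D array, zero outside the
#'   mask), `mask`, `affine`, `subject_id`.
#' @export
compute_nh <- function(run, mask, subject_id = NULL) {
  stopifnot(inherits(mask, "network_mask"))
  if (!identical(as.integer(mask$dim), as.integer(run$dim)))
    abort("mask grid does not match the run")
  midx <- which(mask$mask)
  if (length(midx) < 2) abort("mask must contain at least 2 voxels")
  cols <- match(midx, run$voxels)
  if (anyNA(cols)) abort("mask voxels outside the run's active voxels")
  x <- run$data[, cols, drop = FALSE]
  nt <- nrow(x)
  sds <- apply(x, 2, sd)
  valid <- sds > 0
  n_zero <- sum(!valid)
  if (n_zero > 0)
    message(sprintf("compute_nh: %d zero-variance voxel(s) set to NH 0", n_zero))
  vals <- numeric(length(midx))
  m <- sum(valid)
  if (m >= 2) {
    Z <- scale(x[, valid, drop = FALSE])
    cc <- crossprod(Z) / (nt - 1)
    vals[valid] <- (rowSums(cc) - 1) / (m - 1)
  }
  out <- array(0, run$dim)
  out[midx] <- vals
  structure(list(values = out, mask = mask, affine = mask$affine,
                 subject_id = subject_id),
            class = "nh_map")
}

# separable Gaussian convolution of a 3D array (zero padding outside)
gaussian_smooth_3d <- function(arr, sigma_vox) {
  d <- dim(arr)
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    n <- d[ax]
    dist <- outer(seq_len(n), seq_len(n), `-`)
    K <- exp(-dist^2 / (2 * s^2))
    K[abs(dist) > ceiling(4 * s)] <- 0
    perm <- c(ax, setdiff(1:3, ax))
    a <- aperm(arr, perm)
    dd <- dim(a)
    a <- array(K %*% matrix(a, nrow = n), dd)
    arr <- aperm(a, order(perm))
  }
  arr
}

#' Smooth an NH map within its mask
#'
#' Gaussian smoothing with kernel standard deviation
#' `fwhm / (2 sqrt(2 log 2))` per axis (mm converted to voxels), restricted
#' to the mask with edge renormalization: the smoothed map is the ratio of
#' the smoothed masked values to the smoothed mask indicator, so constants
#' are preserved and no signal bleeds in from outside. `fwhm_mm = 0` is the
#' identity.
#'
#' @param nh_map an `nh_map`.
#' @param fwhm_mm full width at half maximum in mm (>= 0).
#' @param voxel_size_mm voxel edge; taken from the affine diagonal when NULL.
#' @return the smoothed `nh_map`.
#' @export
smooth_nh <- function(nh_map, fwhm_mm = 4, voxel_size_mm = NULL) {
  if (fwhm_mm < 0) abort("fwhm_mm must be >= 0")
  if (fwhm_mm == 0) return(nh_map)
  vs <- voxel_size_mm %||% abs(diag(nh_map$affine)[1:3])
  if (length(vs) == 1) vs <- rep(vs, 3)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / vs
  m <- nh_map$mask$mask
  num <- gaussian_smooth_3d(nh_map$values * m, sigma)
  den <- gaussian_smooth_3d(m * 1, sigma)
  out <- array(0, dim(nh_map$values))
  out[m] <- num[m] / den[m]
  nh_map$values <- out
  nh_map
}

#' Stack per-subject NH maps for group statistics
#'
#' @param maps list of `nh_map` objects sharing one mask.
#' @param subject_ids optional ids (default taken from the maps).
#' @return object of class `nh_stack`: `values` (subjects x mask voxels),
#'   `mask`, `voxels` (linear indices), `subject_ids`.
#' @export
nh_stack <- function(maps, subject_ids = NULL) {
  stopifnot(length(maps) >= 1)
  mask <- maps[[1]]$mask
  midx <- which(mask$mask)
  vals <- t(vapply(maps, function(m) m$values[midx],
                   numeric(length(midx))))
  ids <- subject_ids %||% vapply(maps, function(m)
    m$subject_id %||% NA_character_, character(1))
  structure(list(values = vals, mask = mask, voxels = midx,
                 subject_ids = ids),
            class = "nh_stack")
}
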