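#' @importFrom rlang %||% abort warn .data
#' @importFrom stats rnorm runif rbinom sd var cor qnorm pnorm pt pf qt qf
#' @importFrom stats fft mvfft coef lm.fit pchisq complete.cases
#' @importFrom utils combn
NULL

# Derive a per-stage RNG seed from a global seed. Keeps results < 2^31 and
# decouples the stages so each can be re-run in isolation.
stage_seed <- function(seed, stage) {
  offs <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + offs) %% 2147483647L)
}

`%||%` <- rlang::`%||%`

# linear index <-> (i,j,k) voxel subscripts for a 3D grid
vox_index <- function(ijk, dim) {
  (ijk[, 3] - 1L) * dim[1] * dim[2] + (ijk[, 2] - 1L) * dim[1] + ijk[, 1]
}

vox_subscript <- function(idx, dim) {
  idx0 <- idx - 1L
  i <- idx0 %% dim[1]
  j <- (idx0 %/% dim[1]) %% dim[2]
  k <- idx0 %/% (dim[1] * dim[2])
  cbind(i + 1L, j + 1L, k + 1L)
}

# voxel (1-based) subscripts -> mm coordinates under a NIfTI-style affine
voxel_to_mm <- function(ijk, affine) {
  ijk <- matrix(ijk, ncol = 3)
  mm <- affine %*% rbind(t(ijk) - 1, 1)
  t(mm[1:3, , drop = FALSE])
}

# Diagonal MNI-style affine: +x/+y/+z in mm, centered origin.
make_affine <- function(grid_shape, voxel_size_mm) {
  origin <- -voxel_size_mm * (grid_shape - 1) / 2
  aff <- diag(c(rep(voxel_size_mm, 3), 1))
  aff[1:3, 4] <- origin
  aff
}

skewness <- function(x) {
  x <- x - mean(x)
  mean(x^3) / (mean(x^2)^1.5 + .Machine$double.eps)
}
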