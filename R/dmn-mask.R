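#' Labeled network mask
#'
#' @param mask logical 3D array (nonempty).
#' @param affine 4x4 voxel-to-mm map.
#' @param region_labels optional integer 3D array of sub-parcel labels.
#' @param region_names optional character vector naming the labels.
#' @return object of class `network_mask`.
#' @export
network_mask <- function(mask, affine, region_labels = NULL,
                         region_names = NULL) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3)
  if (!any(mask)) abort("network mask is empty")
  structure(list(mask = mask, affine = affine, dim = dim(mask),
                 region_labels = region_labels, region_names = region_names),
            class = "network_mask")
}

#' @export
print.network_mask <- function(x, ...) {
  cat(sprintf("<network_mask> %d voxels on %s grid\n", sum(x$mask),
              paste(x$dim, collapse = "x")))
  invisible(x)
}

# symmetric fixed-point ICA on whitened C x V data. The default skewness
# contrast (g = x^2) targets sparse, positively skewed spatial sources —
# the structure of brain network maps — where symmetric contrasts can
# settle on sign-symmetric mixtures.
fastica_core <- function(X, seed, tol = 1e-6, maxit = 500L,
                         contrast = c("skew", "tanh", "pow3")) {
  contrast <- match.arg(contrast)
  g <- switch(contrast,
              skew = function(x) x^2,
              tanh = function(x) tanh(x),
              pow3 = function(x) x^3)
  gprime <- switch(contrast,
                   skew = function(x) 2 * x,
                   tanh = function(x) 1 - tanh(x)^2,
                   pow3 = function(x) 3 * x^2)
  C <- nrow(X)
  V <- ncol(X)
  set.seed(seed)
  W <- matrix(rnorm(C * C), C, C)
  sym_decorrelate <- function(W) {
    e <- eigen(W %*% t(W), symmetric = TRUE)
    e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-12)), C) %*%
      t(e$vectors) %*% W
  }
  W <- sym_decorrelate(W)
  for (it in seq_len(maxit)) {
    WX <- W %*% X
    W1 <- g(WX) %*% t(X) / V - diag(rowMeans(gprime(WX)), C) %*% W
    W1 <- sym_decorrelate(W1)
    conv <- max(abs(abs(diag(W1 %*% t(W))) - 1))
    W <- W1
    if (conv < tol) break
  }
  W
}

#' Group spatial independent component analysis
#'
#' Two-stage reduction followed by fixed-point ICA: each subject's
#' voxel-demeaned run is reduced in time by PCA, the reduced data are
#' temporally concatenated and reduced again to `n_components` at the group
#' level, the whitened group data are unmixed by symmetric fixed-point ICA
#' (deterministic seeded initialization), and subject maps
#' are recovered by back-reconstruction (dual regression of each subject's
#' run on its component time courses). Component sign is fixed so every
#' spatial map has positive skewness; maps are z-scored over the analysis
#' voxels.
#'
#' @param runs list of `bold_run` objects on a common grid with identical
#'   active voxels.
#' @param n_components number of components C.
#' @param seed integer seed for the ICA initialization.
#' @param subject_dim per-subject PCA dimension (default
#'   `min(T - 1, 2 * n_components + 5)`).
#' @param tol,maxit fixed-point iteration control.
#' @param contrast ICA contrast function: `"skew"` (default; suited to
#'   sparse positively skewed spatial maps), `"tanh"`, or `"pow3"`.
#' @return object of class `ica_result`: `component_maps` (C x V, z-scored),
#'   `subject_maps` (list of C x V), `subject_loadings` (list of T x C time
#'   courses), plus grid info.
#' @export
group_ica <- function(runs, n_components, seed = 1L, subject_dim = NULL,
                      tol = 1e-6, maxit = 500L,
                      contrast = c("skew", "tanh", "pow3")) {
  stopifnot(length(runs) >= 2)
  vox <- runs[[1]]$voxels
  for (r in runs)
    if (!identical(r$voxels, vox) || !identical(r$dim, runs[[1]]$dim))
      abort("all runs must share one grid and active-voxel set")
  C <- as.integer(n_components)
  nt <- nrow(runs[[1]]$data)
  d1 <- subject_dim %||% min(nt - 1L, 2L * C + 5L)
  if (C > d1 * length(runs))
    abort("n_components exceeds the total reduced dimension")
  demeaned <- lapply(runs, function(r) {
    x <- r$data
    sweep(x, 2, colMeans(x))
  })
  reduced <- lapply(demeaned, function(x) {
    sv <- svd(x, nu = d1, nv = 0)
    t(sv$u) %*% x
  })
  G <- do.call(rbind, reduced)
  if (C > min(dim(G))) abort("n_components exceeds the data rank")
  svg <- svd(G, nu = C, nv = 0)
  Gr <- t(svg$u) %*% G                       # C x V
  Gr <- sweep(Gr, 1, rowMeans(Gr))
  cv <- Gr %*% t(Gr) / ncol(Gr)
  e <- eigen(cv, symmetric = TRUE)
  K <- diag(1 / sqrt(pmax(e$values, 1e-12)), C) %*% t(e$vectors)
  Xw <- K %*% Gr
  W <- fastica_core(Xw, seed = seed, tol = tol, maxit = maxit,
                    contrast = match.arg(contrast))
  S <- W %*% Xw                              # C x V spatial sources
  flip <- vapply(seq_len(C), function(i) skewness(S[i, ]) < 0, logical(1))
  S[flip, ] <- -S[flip, ]
  maps <- t(scale(t(S)))                     # z-score within analysis voxels
  pinvS <- t(maps) %*% solve(maps %*% t(maps))
  loadings <- lapply(demeaned, function(x) x %*% pinvS)    # T x C
  subject_maps <- Map(function(x, A) {
    sv <- svd(A)
    keep <- sv$d > max(sv$d) * 1e-10
    (sv$v[, keep, drop = FALSE] %*%
       diag(1 / sv$d[keep], sum(keep)) %*%
       t(sv$u[, keep, drop = FALSE])) %*% x
  }, demeaned, loadings)
  structure(list(component_maps = maps, subject_maps = subject_maps,
                 subject_loadings = loadings, n_components = C,
                 voxels = vox, dim = runs[[1]]$dim,
                 affine = runs[[1]]$affine),
            class = "ica_result")
}

#' Select network components by template match
#'
#' Ranks components by the absolute spatial correlation between their
#' z-scored map and the template over the analysis voxels; every component
#' at or above `threshold` is selected, and the best-matching component is
#' always selected even when no score reaches the threshold (with a
#' warning).
#'
#' @param ica an `ica_result`.
#' @param template a `network_mask` or 3D numeric/logical array on the same
#'   grid.
#' @param threshold minimum absolute correlation (default 0.3).
#' @return tibble with `component`, `score`, `selected`, ordered by score.
#' @export
select_dmn_components <- function(ica, template, threshold = 0.3) {
  tpl <- if (inherits(template, "network_mask")) template$mask else template
  stopifnot(identical(dim(tpl), as.integer(ica$dim)) ||
              identical(dim(tpl), ica$dim))
  tv <- as.numeric(tpl)[ica$voxels]
  if (sd(tv) == 0) abort("template is constant over the analysis voxels")
  score <- abs(as.numeric(cor(tv, t(ica$component_maps))))
  sel <- score >= threshold
  if (!any(sel)) {
    warn(sprintf("no component reaches match threshold %.2f; keeping best (%.3f)",
                 threshold, max(score)))
    sel[which.max(score)] <- TRUE
  }
  out <- tibble::tibble(component = seq_len(ica$n_components), score = score,
                        selected = sel)
  dplyr::arrange(out, dplyr::desc(score))
}

#' Build the network mask from selected components
#'
#' For each group, the mean back-reconstructed subject map of every selected
#' component is z-scored and thresholded at `z_threshold`; the group mask is
#' the union over selected components, and the final mask is the union
#' across groups. Without group assignments the group-level component maps
#' are thresholded directly.
#'
#' @param ica an `ica_result`.
#' @param selected integer component indices (or the tibble from
#'   [select_dmn_components()], from which selected rows are taken).
#' @param groups optional character vector (one per run) of group labels.
#' @param z_threshold binarization threshold on the z-scored maps.
#' @return a `network_mask`.
#' @export
build_mask <- function(ica, selected, groups = NULL, z_threshold = 1) {
  if (is.data.frame(selected)) selected <- selected$component[selected$selected]
  if (!length(selected)) abort("no components selected")
  zmaps <- list()
  if (is.null(groups)) {
    zmaps <- lapply(selected, function(ci) ica$component_maps[ci, ])
  } else {
    stopifnot(length(groups) == length(ica$subject_maps))
    for (g in unique(groups)) {
      gm <- Reduce(`+`, ica$subject_maps[groups == g]) / sum(groups == g)
      for (ci in selected)
        zmaps <- c(zmaps, list(as.numeric(scale(gm[ci, ]))))
    }
  }
  keep <- Reduce(`|`, lapply(zmaps, function(z) z > z_threshold))
  mask <- array(FALSE, ica$dim)
  mask[ica$voxels[keep]] <- TRUE
  if (!any(mask)) abort("resulting network mask is empty; lower z_threshold")
  network_mask(mask, ica$affine)
}
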