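#' Build a voxelwise design from the subject table
#'
#' Group indicators plus mean-centered covariates and an intercept.
#' Covariate columns that are collinear with the rest of the design are
#' pruned with a warning.
#'
#' @param subjects tibble with a `group` column and the covariate columns.
#' @param covariates character vector of covariate column names (default
#'   age, education, mean framewise displacement).
#' @param groups which groups to include (default: all present, in order of
#'   appearance).
#' @return object of class `nh_design`: model matrix `X`, `group` factor,
#'   `group_cols`, `covariate_cols`.
#' @export
nh_design <- function(subjects, covariates = c("age", "education", "mean_fd"),
                      groups = NULL) {
  groups <- groups %||% unique(subjects$group)
  subjects <- subjects[subjects$group %in% groups, , drop = FALSE]
  g <- factor(subjects$group, levels = groups)
  stopifnot(all(table(g) >= 2))
  Xg <- stats::model.matrix(~ 0 + g)
  colnames(Xg) <- paste0("group_", groups)
  Xc <- NULL
  if (length(covariates)) {
    Xc <- as.matrix(subjects[, covariates, drop = FALSE])
    Xc <- scale(Xc, center = TRUE, scale = FALSE)
  }
  X <- cbind(Xg, Xc)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop_idx <- qrX$pivot[-seq_len(qrX$rank)]
    dropped <- colnames(X)[drop_idx]
    if (any(drop_idx <= ncol(Xg)))
      abort("group indicators are rank deficient")
    warn(paste0("dropping collinear covariate(s): ",
                paste(dropped, collapse = ", ")))
    X <- X[, -drop_idx, drop = FALSE]
    covariates <- setdiff(covariates, dropped)
  }
  structure(list(X = X, group = g, groups = groups,
                 group_cols = seq_along(groups),
                 covariate_cols = setdiff(seq_len(ncol(X)),
                                          seq_along(groups)),
                 subjects = subjects, covariates = covariates),
            class = "nh_design")
}

#' Voxelwise GLM: omnibus F or pairwise t on NH maps
#'
#' Per in-mask voxel, ordinary least squares on the design. With
#' `contrast = NULL` the omnibus group effect is tested by a partitioned F
#' (full model vs covariates-plus-intercept only). With
#' `contrast = c(g1, g2)` the subjects of the two named groups are fit with
#' covariates and the t statistic for `g1 - g2` is returned. Residuals are
#' kept for smoothness estimation.
#'
#' @param stack an `nh_stack`.
#' @param subjects subject tibble aligned with the stack rows (must contain
#'   `group` and the covariates).
#' @param covariates covariate column names.
#' @param contrast NULL for the omnibus F, or a length-2 character vector of
#'   group labels for a pairwise t.
#' @return object of class `stat_map`: `stat` (3D array), `type` ("F" or
#'   "t"), `df`, `residuals` (subjects x voxels), `voxels`, `mask`.
#' @export
voxelwise_glm <- function(stack, subjects, covariates = c("age", "education",
                                                          "mean_fd"),
                          contrast = NULL) {
  stopifnot(nrow(subjects) == nrow(stack$values))
  if (!is.null(contrast)) {
    stopifnot(length(contrast) == 2)
    keep <- subjects$group %in% contrast
    subjects <- subjects[keep, , drop = FALSE]
    Y <- stack$values[keep, , drop = FALSE]
    des <- nh_design(subjects, covariates, groups = contrast)
  } else {
    Y <- stack$values
    des <- nh_design(subjects, covariates)
  }
  X <- des$X
  n <- nrow(X)
  p <- ncol(X)
  fit <- stats::lm.fit(X, Y)
  res <- fit$residuals
  rss <- colSums(res^2)
  df2 <- n - p
  if (is.null(contrast)) {
    k <- length(des$groups)
    X0 <- cbind(1, X[, des$covariate_cols, drop = FALSE])
    rss0 <- colSums(stats::lm.fit(X0, Y)$residuals^2)
    q <- k - 1
    stat <- ((rss0 - rss) / q) / (rss / df2)
    type <- "F"
    df <- c(q, df2)
  } else {
    XtXi <- chol2inv(chol(crossprod(X)))
    cvec <- numeric(p)
    cvec[1:2] <- c(1, -1)                  # group_1 - group_2
    se2 <- drop(t(cvec) %*% XtXi %*% cvec)
    beta_diff <- fit$coefficients[1, ] - fit$coefficients[2, ]
    sigma2 <- rss / df2
    stat <- beta_diff / sqrt(sigma2 * se2)
    type <- "t"
    df <- df2
  }
  vol <- array(0, stack$mask$dim)
  vol[stack$voxels] <- stat
  structure(list(stat = vol, type = type, df = df, residuals = res,
                 voxels = stack$voxels, mask = stack$mask,
                 design = des, n = n),
            class = "stat_map")
}

#' Estimate residual spatial smoothness
#'
#' Residual maps are scaled per voxel to unit norm over the stack (they
#' are zero-mean by construction under a model with intercept);
#' along each axis the pooled variance of first differences between in-mask
#' neighbors is inverted under a Gaussian autocorrelation model
#' (`rho(1) = 1 - v/2`, `FWHM = sqrt(8 log 2) * sqrt(-1 / (4 log rho(1)))`
#' voxels), floored at one voxel (independent voxels). The RESEL count is
#' the mask volume divided by the product of the per-axis FWHMs in voxels.
#'
#' @param residuals subjects x mask-voxels matrix (>= 3 rows), e.g.
#'   `stat_map$residuals`.
#' @param mask a `network_mask` whose in-mask voxels index the columns.
#' @param voxel_size_mm voxel edge (taken from the mask affine when NULL).
#' @return object of class `smoothness_estimate`: `fwhm_mm`, `fwhm_vox`
#'   (per axis), `resel_count`, `n_mask_vox`.
#' @export
estimate_smoothness <- function(residuals, mask, voxel_size_mm = NULL) {
  if (nrow(residuals) < 3) abort("smoothness estimation needs >= 3 residual maps")
  vs <- voxel_size_mm %||% abs(diag(mask$affine)[1:3])
  if (length(vs) == 1) vs <- rep(vs, 3)
  d <- mask$dim
  midx <- which(mask$mask)
  nrm <- sqrt(colSums(residuals^2))
  ok <- nrm > 0
  Z <- residuals[, ok, drop = FALSE]
  # unit-norm scaling (residuals have zero mean by construction when the
  # model holds an intercept); multiply by sqrt(n) to get unit variance
  Z <- sweep(Z, 2, nrm[ok], `/`) * sqrt(nrow(residuals))
  pos <- vox_subscript(midx[ok], d)
  lut <- array(NA_integer_, d)
  lut[midx[ok]] <- seq_len(sum(ok))
  fwhm_vox <- numeric(3)
  for (ax in 1:3) {
    nb <- pos
    nb[, ax] <- nb[, ax] + 1L
    inb <- nb[, ax] <= d[ax]
    j <- lut[vox_index(nb[inb, , drop = FALSE], d)]
    i <- which(inb)[!is.na(j)]
    j <- j[!is.na(j)]
    if (!length(j)) { fwhm_vox[ax] <- 1; next }
    v <- mean((Z[, i, drop = FALSE] - Z[, j, drop = FALSE])^2)
    rho1 <- 1 - v / 2
    fwhm_vox[ax] <- if (rho1 <= 0) 1 else
      max(1, sqrt(8 * log(2)) * sqrt(-1 / (4 * log(rho1))))
  }
  structure(list(fwhm_vox = fwhm_vox, fwhm_mm = fwhm_vox * vs,
                 resel_count = length(midx) / prod(fwhm_vox),
                 n_mask_vox = length(midx)),
            class = "smoothness_estimate")
}

# connected components of a voxel index set; 6/18/26 connectivity
label_clusters <- function(idx, dim, connectivity = 26L) {
  if (!length(idx)) return(integer(0))
  sh <- switch(as.character(connectivity),
               "6" = rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
               "18" = {
                 g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
                 g[rowSums(abs(g)) %in% 1:2, , drop = FALSE]
               },
               "26" = {
                 g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
                 g[rowSums(abs(g)) > 0, , drop = FALSE]
               },
               abort("connectivity must be 6, 18 or 26"))
  lut <- array(0L, dim)
  lut[idx] <- seq_along(idx)
  labels <- integer(length(idx))
  cur <- 0L
  pos <- vox_subscript(idx, dim)
  for (s in seq_along(idx)) {
    if (labels[s] > 0L) next
    cur <- cur + 1L
    queue <- s
    labels[s] <- cur
    while (length(queue)) {
      v <- queue[length(queue)]
      queue <- queue[-length(queue)]
      nb <- sweep(sh, 2, pos[v, ], `+`)
      ok <- nb[, 1] >= 1 & nb[, 1] <= dim[1] & nb[, 2] >= 1 &
        nb[, 2] <= dim[2] & nb[, 3] >= 1 & nb[, 3] <= dim[3]
      cand <- lut[vox_index(nb[ok, , drop = FALSE], dim)]
      cand <- cand[cand > 0L]
      cand <- cand[labels[cand] == 0L]
      if (length(cand)) {
        labels[cand] <- cur
        queue <- c(queue, cand)
      }
    }
  }
  labels
}

# map a stat map to z (Gaussianization via probit of the p-value)
stat_to_z <- function(stat, type, df) {
  if (type == "z") return(stat)
  if (type == "t") {
    z <- numeric(length(stat))
    pos <- stat >= 0
    z[pos] <- qnorm(pt(stat[pos], df, lower.tail = FALSE, log.p = TRUE),
                    lower.tail = FALSE, log.p = TRUE)
    z[!pos] <- -qnorm(pt(-stat[!pos], df, lower.tail = FALSE, log.p = TRUE),
                      lower.tail = FALSE, log.p = TRUE)
    return(z)
  }
  if (type == "F")
    return(qnorm(pf(stat, df[1], df[2], lower.tail = FALSE, log.p = TRUE),
                 lower.tail = FALSE, log.p = TRUE))
  abort(sprintf("unknown stat type '%s'", type))
}

# expected cluster count above u in a 3D Gaussian field with R3 resels
grf_expected_clusters <- function(u, resels) {
  resels * (4 * log(2))^1.5 * (2 * pi)^(-2) * (u^2 - 1) * exp(-u^2 / 2)
}

#' Gaussian random field cluster-extent correction
#'
#' Thresholds a statistic map at the voxelwise p-quantile of its null
#' (t and F maps are Gaussianized by probit transform of their p-values),
#' forms connected components within the mask, and assigns each cluster a
#' family-wise corrected p from the expected cluster count (3D
#' Euler-characteristic density times the RESEL count) and the
#' exponential cluster-extent approximation
#' `P(extent >= k) = exp(-beta k^(2/3))`. Signed maps are processed per
#' tail, each thresholded one-sided at `voxel_p` and corrected at
#' `cluster_p` (the convention of the GRF lineage this mirrors, whose
#' extent approximation runs conservative on discrete lattices); set
#' `split_tails = TRUE` to Bonferroni-split the cluster alpha across the
#' two tails instead.
#'
#' @param stat_map a `stat_map` (or a z-valued one built by hand with
#'   `type = "z"`).
#' @param smoothness a `smoothness_estimate` for the residual field.
#' @param voxel_p voxelwise (cluster-forming) threshold, in (0, 1).
#' @param cluster_p family-wise cluster significance level, in (0, 1).
#' @param connectivity 6, 18 or 26 (default 26, vertex connectivity).
#' @param tails `"both"` (default for t/z), `"positive"` or `"negative"`;
#'   F maps are always one-tailed positive.
#' @param split_tails divide `cluster_p` across the two tails?
#' @return tibble of class `cluster_table`: one row per surviving cluster
#'   with `cluster`, `sign`, `n_voxels`, `peak_stat`, peak voxel subscripts,
#'   `p_corrected`, and a `voxels` list-column of linear indices.
#' @export
grf_cluster_correct <- function(stat_map, smoothness, voxel_p = 0.001,
                                cluster_p = 0.05, connectivity = 26L,
                                tails = c("both", "positive", "negative"),
                                split_tails = FALSE) {
  tails <- match.arg(tails)
  stopifnot(voxel_p > 0, voxel_p < 1, cluster_p > 0, cluster_p < 1)
  if (stat_map$type == "F") tails <- "positive"
  midx <- stat_map$voxels %||% which(stat_map$mask$mask)
  zvals <- stat_to_z(stat_map$stat[midx], stat_map$type, stat_map$df)
  u <- qnorm(1 - voxel_p)
  Em <- grf_expected_clusters(u, smoothness$resel_count)
  EN <- smoothness$n_mask_vox * pnorm(u, lower.tail = FALSE)
  nbar <- EN / max(Em, .Machine$double.eps)
  beta <- (gamma(2.5) / nbar)^(2 / 3)
  alpha_tail <- if (tails == "both" && split_tails) cluster_p / 2 else cluster_p
  dims <- stat_map$mask$dim
  do_tail <- function(sign_label) {
    zz <- if (sign_label == "positive") zvals else -zvals
    sup <- which(zz > u)
    if (!length(sup)) return(NULL)
    vox <- midx[sup]
    lab <- label_clusters(vox, dims, connectivity)
    purrr::map_dfr(seq_len(max(lab)), function(ci) {
      members <- vox[lab == ci]
      k <- length(members)
      pk <- exp(-beta * k^(2 / 3))
      p_corr <- 1 - exp(-Em * pk)
      sel <- sup[lab == ci]
      peak_i <- sel[which.max(zz[sel])]
      peak_sub <- vox_subscript(midx[peak_i], dims)
      tibble::tibble(sign = sign_label, n_voxels = k,
                     peak_stat = stat_map$stat[midx[peak_i]],
                     peak_i = peak_sub[1], peak_j = peak_sub[2],
                     peak_k = peak_sub[3], p_corrected = p_corr,
                     voxels = list(members))
    })
  }
  res <- switch(tails,
                both = dplyr::bind_rows(do_tail("positive"), do_tail("negative")),
                positive = do_tail("positive"),
                negative = do_tail("negative"))
  if (is.null(res) || !nrow(res)) {
    res <- tibble::tibble(sign = character(), n_voxels = integer(),
                          peak_stat = numeric(), peak_i = integer(),
                          peak_j = integer(), peak_k = integer(),
                          p_corrected = numeric(), voxels = list())
  }
  res <- res[res$p_corrected < alpha_tail, , drop = FALSE]
  res <- dplyr::arrange(res, dplyr::desc(.data$n_voxels))
  res <- dplyr::mutate(res, cluster = dplyr::row_number(),
                       .before = 1)
  class(res) <- c("cluster_table", class(res))
  res
}

#' Report clusters with mm peak coordinates and region labels
#'
#' @param clusters a `cluster_table` from [grf_cluster_correct()].
#' @param affine 4x4 voxel-to-mm map.
#' @param label_atlas optional `network_mask` with `region_labels`; the
#'   label of each cluster's peak voxel is attached as `location`.
#' @return tibble with `location`, `x`, `y`, `z` (mm), `n_voxels`,
#'   `peak_stat`, `sign`, `p_corrected`, sorted by extent.
#' @export
cluster_report <- function(clusters, affine, label_atlas = NULL) {
  if (!nrow(clusters)) {
    return(tibble::tibble(location = character(), x = numeric(),
                          y = numeric(), z = numeric(), n_voxels = integer(),
                          peak_stat = numeric(), sign = character(),
                          p_corrected = numeric()))
  }
  mm <- voxel_to_mm(cbind(clusters$peak_i, clusters$peak_j, clusters$peak_k),
                    affine)
  loc <- rep(NA_character_, nrow(clusters))
  if (!is.null(label_atlas) && !is.null(label_atlas$region_labels)) {
    for (r in seq_len(nrow(clusters))) {
      labs <- label_atlas$region_labels[clusters$voxels[[r]]]
      labs <- labs[labs > 0]
      if (length(labs)) {
        best <- as.integer(names(which.max(table(labs))))
        loc[r] <- label_atlas$region_names[best]
      }
    }
  }
  out <- tibble::tibble(location = loc, x = mm[, 1], y = mm[, 2], z = mm[, 3],
                        n_voxels = clusters$n_voxels,
                        peak_stat = clusters$peak_stat, sign = clusters$sign,
                        p_corrected = clusters$p_corrected)
  dplyr::arrange(out, dplyr::desc(.data$n_voxels))
}

#' Per-subject mean NH over a cluster
#'
#' @param stack an `nh_stack`.
#' @param cluster_voxels integer linear voxel indices (e.g. one entry of the
#'   `voxels` list-column of a `cluster_table`).
#' @return numeric vector, one mean NH per subject.
#' @export
extract_cluster_nh <- function(stack, cluster_voxels) {
  if (!length(cluster_voxels)) abort("empty cluster")
  cols <- match(cluster_voxels, stack$voxels)
  if (anyNA(cols)) abort("cluster voxels outside the stack's mask")
  rowMeans(stack$values[, cols, drop = FALSE])
}

#' Simulate a smooth stationary Gaussian null field
#'
#' White Gaussian noise convolved circularly (FFT) with a 3D Gaussian kernel
#' of the requested FWHM and rescaled to exact unit variance; the result is
#' a stationary z-valued field with Gaussian autocorrelation, suitable for
#' false-positive-rate studies of cluster inference.
#'
#' @param dim 3-vector of grid dimensions.
#' @param fwhm_mm kernel FWHM in mm.
#' @param voxel_size_mm voxel edge in mm.
#' @return 3D array of unit-variance Gaussian values.
#' @export
simulate_smooth_null_field <- function(dim, fwhm_mm = 6, voxel_size_mm = 3) {
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size_mm
  k1 <- function(n) {
    d <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
    exp(-d^2 / (2 * sigma^2))
  }
  kern <- outer(outer(k1(dim[1]), k1(dim[2])), k1(dim[3]))
  dim(kern) <- dim
  noise <- array(rnorm(prod(dim)), dim)
  f <- fft(fft(noise) * fft(kern), inverse = TRUE) / prod(dim)
  Re(f) / sqrt(sum(kern^2))
}

#' Wrap a z-valued array as a `stat_map`
#'
#' @param z 3D array of z values.
#' @param mask a `network_mask` (defaults to the whole volume).
#' @param affine affine for a whole-volume mask.
#' @return a `stat_map` with `type = "z"`.
#' @export
z_stat_map <- function(z, mask = NULL, affine = diag(4)) {
  if (is.null(mask))
    mask <- network_mask(array(TRUE, dim(z)), affine)
  structure(list(stat = z, type = "z", df = Inf, residuals = NULL,
                 voxels = which(mask$mask), mask = mask),
            class = "stat_map")
}
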