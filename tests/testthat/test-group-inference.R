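test_that("pairwise t matches the closed-form pooled two-sample t", {
  set.seed(21)
  dim <- c(2L, 3L, 1L)
  groups <- rep(c("melancholic", "nonmelancholic"), each = 3)
  vals <- matrix(rnorm(6 * 6), 6)
  mask <- full_mask(dim)
  stack <- structure(list(values = vals, mask = mask,
                          voxels = which(mask$mask),
                          subject_ids = paste0("s", 1:6)),
                     class = "nh_stack")
  subjects <- tibble::tibble(subject_id = stack$subject_ids, group = groups)
  fit <- voxelwise_glm(stack, subjects, covariates = character(0),
                       contrast = c("melancholic", "nonmelancholic"))
  for (v in 1:6) {
    tt <- t.test(vals[1:3, v], vals[4:6, v], var.equal = TRUE)
    expect_equal(fit$stat[v], unname(tt$statistic), tolerance = 1e-10)
  }
  expect_equal(fit$df, 4)

  # two-group omnibus F equals t^2
  fitF <- voxelwise_glm(stack, subjects, covariates = character(0))
  expect_equal(fitF$stat[seq_len(6)], fit$stat[seq_len(6)]^2,
               tolerance = 1e-8)
})

test_that("covariate-adjusted F matches a reference per-voxel linear model", {
  x <- toy_stack(n_per = 8, n_vox = 10, seed = 22)
  fit <- voxelwise_glm(x$stack, x$subjects)
  for (v in c(1, 5, 10)) {
    df <- dplyr::mutate(x$subjects, y = x$stack$values[, v])
    ref <- anova(lm(y ~ age + education + mean_fd + group, data = df))
    expect_equal(fit$stat[v], ref["group", "F value"], tolerance = 1e-8)
  }
})

test_that("collinear covariates are pruned and the map still produced", {
  x <- toy_stack(n_per = 5, n_vox = 6, seed = 23)
  x$subjects$dup <- 2 * x$subjects$age + 1
  expect_warning(
    fit <- voxelwise_glm(x$stack, x$subjects,
                         covariates = c("age", "dup")),
    "collinear")
  expect_true(all(is.finite(fit$stat[x$stack$voxels])))
})

test_that("null voxelwise p values are uniform", {
  x <- toy_stack(n_per = 20, n_vox = 400, seed = 24)
  fit <- voxelwise_glm(x$stack, x$subjects)
  p <- pf(fit$stat[x$stack$voxels], fit$df[1], fit$df[2], lower.tail = FALSE)
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("smoothness estimation recovers known field smoothness", {
  set.seed(25)
  dimv <- c(20L, 20L, 12L)
  mask <- full_mask(dimv)
  # white noise -> about one voxel (3 mm)
  wn <- do.call(rbind, lapply(1:12, function(i) rnorm(prod(dimv))))
  est_wn <- estimate_smoothness(wn, mask, 3)
  expect_equal(mean(est_wn$fwhm_mm), 3, tolerance = 0.15)
  # noise smoothed to 6 mm -> 6 mm within 15%
  sm <- do.call(rbind, lapply(1:12, function(i)
    as.numeric(simulate_smooth_null_field(dimv, 6, 3))))
  est_sm <- estimate_smoothness(sm, mask, 3)
  expect_equal(mean(est_sm$fwhm_mm), 6, tolerance = 0.15)
  # resels double when the mask volume doubles at fixed smoothness
  half <- array(FALSE, dimv); half[1:10, , ] <- TRUE
  est_half <- estimate_smoothness(sm[, as.numeric(half[mask$mask]) == 1],
                                  network_mask(half, mask$affine), 3)
  expect_equal(est_sm$n_mask_vox / est_half$n_mask_vox, 2, tolerance = 1e-12)
  expect_equal(est_sm$resel_count / est_half$resel_count, 2, tolerance = 0.1)
  expect_error(estimate_smoothness(wn[1:2, ], mask, 3), "3 residual")
})

test_that("cluster labeling respects the connectivity scheme", {
  dimv <- c(5L, 5L, 1L)
  # two voxels touching only diagonally
  idx <- nhkit:::vox_index(rbind(c(1, 1, 1), c(2, 2, 1)), dimv)
  expect_equal(max(nhkit:::label_clusters(idx, dimv, 26L)), 1)
  expect_equal(max(nhkit:::label_clusters(idx, dimv, 6L)), 2)
  # a connected bar plus an isolated voxel
  idx2 <- nhkit:::vox_index(rbind(c(1, 1, 1), c(2, 1, 1), c(3, 1, 1),
                                  c(5, 5, 1)), dimv)
  lab <- nhkit:::label_clusters(idx2, dimv, 26L)
  expect_equal(sort(table(lab), decreasing = TRUE)[[1]], 3)
  expect_equal(max(lab), 2)
})

test_that("GRF correction returns an empty table without suprathreshold voxels", {
  dimv <- c(10L, 10L, 4L)
  mask <- full_mask(dimv)
  zm <- z_stat_map(array(0, dimv), mask)
  sm <- structure(list(fwhm_vox = rep(2, 3), fwhm_mm = rep(6, 3),
                       resel_count = prod(dimv) / 8,
                       n_mask_vox = prod(dimv)),
                  class = "smoothness_estimate")
  cl <- grf_cluster_correct(zm, sm)
  expect_equal(nrow(cl), 0)
  expect_error(grf_cluster_correct(zm, sm, voxel_p = 0), "voxel_p")
})

test_that("an injected strong blob survives correction with the right sign", {
  set.seed(26)
  dimv <- c(12L, 12L, 6L)
  mask <- full_mask(dimv)
  z <- simulate_smooth_null_field(dimv, 6, 3)
  z[4:8, 4:8, 3:4] <- z[4:8, 4:8, 3:4] - 8
  sm <- estimate_smoothness(
    do.call(rbind, lapply(1:10, function(i)
      as.numeric(simulate_smooth_null_field(dimv, 6, 3)))), mask, 3)
  cl <- grf_cluster_correct(z_stat_map(z, mask), sm)
  expect_gte(nrow(cl), 1)
  expect_equal(cl$sign[1], "negative")
  expect_gte(cl$n_voxels[1], 40)
  # one-tailed positive mode must not report it
  clp <- grf_cluster_correct(z_stat_map(z, mask), sm, tails = "positive")
  expect_true(nrow(clp) == 0 || all(clp$sign == "positive"))
})

test_that("cluster reports map peaks to mm and label atlases", {
  dimv <- c(10L, 10L, 4L)
  aff <- nhkit:::make_affine(dimv, 3)
  clusters <- tibble::tibble(
    cluster = 1L, sign = "positive", n_voxels = 2L, peak_stat = 4.2,
    peak_i = 3L, peak_j = 4L, peak_k = 2L, p_corrected = 0.01,
    voxels = list(nhkit:::vox_index(rbind(c(3, 4, 2), c(4, 4, 2)), dimv)))
  class(clusters) <- c("cluster_table", class(clusters))
  labels <- array(0L, dimv); labels[3:4, 4, 2] <- 1L
  atlas <- network_mask(array(TRUE, dimv), aff, region_labels = labels,
                        region_names = "roi_a")
  rep <- cluster_report(clusters, aff, atlas)
  expect_equal(rep$location, "roi_a")
  expect_equal(c(rep$x, rep$y, rep$z),
               as.numeric(aff %*% c(2, 3, 1, 1))[1:3])
  # empty table -> empty report
  empty <- clusters[0, ]
  class(empty) <- c("cluster_table", class(empty))
  expect_equal(nrow(cluster_report(empty, aff)), 0)
})

test_that("cluster NH extraction equals the brute-force mean", {
  set.seed(27)
  x <- toy_stack(n_per = 4, n_vox = 25, seed = 27)
  vox <- x$stack$voxels[c(3, 7, 11)]
  got <- extract_cluster_nh(x$stack, vox)
  want <- apply(x$stack$values[, c(3, 7, 11)], 1, mean)
  expect_equal(got, want, tolerance = 1e-12)
  # single-voxel cluster is just that column
  expect_equal(extract_cluster_nh(x$stack, x$stack$voxels[5]),
               x$stack$values[, 5])
  expect_error(extract_cluster_nh(x$stack, max(x$stack$voxels) + 1L),
               "outside")
})
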