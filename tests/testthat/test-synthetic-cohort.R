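test_that("uncoupled regions produce near-zero pairwise correlation", {
  set.seed(1)
  reg <- tiny_region(rho = 0, i = 2:6, j = 2:3, k = 2)
  run <- generate_bold(list(reg), "control", n_volumes = 400,
                       grid_shape = tiny_grid, active = "regions")
  cc <- cor(run$data[, match(nhkit:::vox_index(reg$voxels, tiny_grid),
                             run$voxels)])
  expect_lt(abs(mean(cc[upper.tri(cc)])), 3 / sqrt(400))
})

test_that("coupling near one collapses a region onto its shared latent", {
  set.seed(2)
  reg <- tiny_region(rho = 1 - 1e-6)
  run <- generate_bold(list(reg), "control", n_volumes = 100,
                       grid_shape = tiny_grid, active = "regions")
  cc <- cor(run$data[, match(nhkit:::vox_index(reg$voxels, tiny_grid),
                             run$voxels)])
  expect_gt(min(cc), 0.999)
})

test_that("within-region correlation matches the generative coupling", {
  # Monte-Carlo check of the one-factor model: mean pairwise r ~= rho
  set.seed(3)
  reg <- region_spec("r", as.matrix(expand.grid(i = 1:5, j = 1:4, k = 1)),
                     c(control = 0.5))
  grid <- c(5L, 4L, 1L)
  cols_of <- function(run) match(nhkit:::vox_index(reg$voxels, grid),
                                 run$voxels)
  mean_r <- replicate(200, {
    run <- generate_bold(list(reg), "control", n_volumes = 190,
                         grid_shape = grid, active = "regions")
    cc <- cor(run$data[, cols_of(run)])
    mean(cc[upper.tri(cc)])
  })
  expect_equal(mean(mean_r), 0.5, tolerance = 0.02 / 0.5)
})

test_that("overlapping regions are rejected with the offending labels", {
  a <- region_spec("alpha", cbind(2:4, 2, 2), c(control = 0.3))
  b <- region_spec("beta", cbind(3:5, 2, 2), c(control = 0.3))
  expect_error(generate_bold(list(a, b), "control", 50,
                             grid_shape = tiny_grid),
               "alpha.*beta")
})

test_that("motion traces honour spike and drift settings", {
  set.seed(4)
  expect_true(all(generate_motion(50, spike_prob = 0, drift_amp_mm = 0,
                                  drift_amp_rad = 0) == 0))
  spiky <- generate_motion(50, spike_prob = 1, spike_mm = 5)
  expect_false(motion_exclude(spiky)$keep)
  set.seed(99)
  a <- generate_motion(80)
  set.seed(99)
  b <- generate_motion(80)
  expect_identical(a, b)
})

test_that("clinical scores match configured distributions", {
  set.seed(5)
  rec <- generate_clinical("melancholic", 500, corr_spec = NULL)
  expect_equal(mean(rec$hrsd17), 21.77, tolerance = 0.4 / 21.77)
  expect_true(all(is.na(generate_clinical("control", 20,
                                          corr_spec = NULL)$teps_total)))
  expect_error(generate_clinical("unknown", 10), "unknown")
})

test_that("NH-score coupling hits the target correlation exactly", {
  set.seed(6)
  nh <- rnorm(31, 0.3, 0.05)
  rec <- generate_clinical("melancholic", 31, region_nh = list(right_mtg = nh))
  expect_equal(cor(rec$teps_total, nh), -0.5, tolerance = 1e-10)
  expect_equal(cor(rec$teps_contextual_anticipatory, nh), -0.5,
               tolerance = 1e-10)
  # zero target -> zero sample correlation with the supplied NH
  spec0 <- tibble::tibble(group = "melancholic", region = "right_mtg",
                          score = "teps_total", r = 0)
  nh0 <- rnorm(500, 0.3, 0.05)
  rec0 <- generate_clinical("melancholic", 500,
                            region_nh = list(right_mtg = nh0),
                            corr_spec = spec0)
  expect_equal(cor(rec0$teps_total, nh0), 0, tolerance = 1e-10)
})

test_that("cohort generation is complete, reproducible and truth-consistent", {
  spec <- cohort_spec(group_sizes = c(melancholic = 3L, nonmelancholic = 3L,
                                      control = 3L),
                      n_volumes = 40L, seed = 10L)
  co1 <- generate_cohort(spec, active = "regions", coupling_preprocess = NULL)
  co2 <- generate_cohort(spec, active = "regions", coupling_preprocess = NULL)
  expect_length(co1$subjects, 9)
  expect_identical(co1$table, co2$table)
  expect_identical(co1$subjects[[1]]$bold$data, co2$subjects[[1]]$bold$data)
  expect_identical(co1$manifest$subject_ids, co2$manifest$subject_ids)
  s <- co1$subjects[[1]]
  expect_equal(nrow(s$bold$data), nrow(s$motion))
  expect_named(s$truth, vapply(spec$regions, `[[`, "", "label"))
})

test_that("the default cohort has the full study-size group structure", {
  spec <- cohort_spec(n_volumes = 20L, seed = 2L)
  expect_equal(unname(spec$group_sizes),
               c(31L, 28L, 32L))
  co <- generate_cohort(spec, active = "regions", coupling_preprocess = NULL)
  expect_length(co$subjects, 91)
  expect_equal(unname(table(co$table$group)[c("melancholic",
                                              "nonmelancholic", "control")]),
               c(31L, 28L, 32L), ignore_attr = TRUE)
})

test_that("cohort files round-trip through disk", {
  dir <- withr::local_tempdir()
  spec <- cohort_spec(group_sizes = c(melancholic = 2L, nonmelancholic = 2L,
                                      control = 2L),
                      grid_shape = c(24L, 28L, 22L), n_volumes = 12L,
                      seed = 3L)
  co <- generate_cohort(spec, out_dir = dir, coupling_preprocess = NULL)
  expect_true(file.exists(file.path(dir, "subjects.tsv")))
  expect_true(file.exists(file.path(dir, "manifest.json")))
  img <- RNifti::readNifti(file.path(dir, "sub-001_bold.nii.gz"))
  expect_equal(dim(img), c(24, 28, 22, 12))
  expect_equal(as.numeric(img), as.numeric(bold_array(co$subjects[[1]]$bold)),
               tolerance = 1e-6)
  mo <- read_motion(file.path(dir, "rp_sub-001.txt"))
  expect_equal(unclass(mo), unclass(co$subjects[[1]]$motion),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("empirical NH converges to the coupling on a region mask", {
  set.seed(7)
  reg <- tiny_region(rho = 0.4, i = 2:6, j = 2:6, k = 2:4)
  run <- generate_bold(list(reg), "control", n_volumes = 800,
                       grid_shape = tiny_grid, active = "regions")
  nh <- compute_nh(run, region_mask(reg, tiny_grid))
  expect_equal(mean(nh$values[nh$mask$mask]), 0.4, tolerance = 0.05)
})
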