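# Small fixtures shared across test files. Everything is generated in code.

# a one-region spec on a small grid, for fast unit tests
tiny_region <- function(rho = 0.5, label = "roi",
                        i = 2:4, j = 2:4, k = 2:3) {
  region_spec(label, as.matrix(expand.grid(i = i, j = j, k = k)),
              c(melancholic = rho, nonmelancholic = rho, control = rho))
}

tiny_grid <- c(8L, 8L, 6L)

# full-volume mask on an arbitrary grid
full_mask <- function(dim, voxel_mm = 3) {
  network_mask(array(TRUE, dim), diag(c(rep(voxel_mm, 3), 1)))
}

# mask covering exactly one region
region_mask <- function(region, dim, voxel_mm = 3) {
  m <- array(FALSE, dim)
  m[as.matrix(region$voxels)] <- TRUE
  network_mask(m, diag(c(rep(voxel_mm, 3), 1)))
}

# wrap a time x voxel matrix as a bold_run over the full grid
matrix_run <- function(data, dim, tr_s = 2.5, voxel_mm = 3) {
  stopifnot(ncol(data) == prod(dim))
  nhkit:::bold_run(data, seq_len(prod(dim)), dim,
                   diag(c(rep(voxel_mm, 3), 1)), tr_s)
}

# independent oracle for NH: literal double loop over all voxel pairs
nh_pairwise_oracle <- function(x) {
  m <- ncol(x)
  out <- numeric(m)
  for (v in seq_len(m)) {
    acc <- 0
    for (u in seq_len(m)) {
      if (u != v) acc <- acc + cor(x[, v], x[, u])
    }
    out[v] <- acc / (m - 1)
  }
  out
}

# a small three-group subject table with NH stack, for GLM tests
toy_stack <- function(n_per = 10, n_vox = 25, seed = 1, effect = 0) {
  dim <- c(as.integer(n_vox), 1L, 1L)
  set.seed(seed)
  groups <- rep(c("melancholic", "nonmelancholic", "control"), each = n_per)
  vals <- matrix(rnorm(length(groups) * n_vox), length(groups))
  vals[groups == "melancholic", ] <- vals[groups == "melancholic", ] + effect
  mask <- full_mask(dim)
  stack <- structure(list(values = vals, mask = mask,
                          voxels = which(mask$mask),
                          subject_ids = sprintf("s%02d", seq_along(groups))),
                     class = "nh_stack")
  subjects <- tibble::tibble(
    subject_id = stack$subject_ids, group = groups,
    age = rnorm(length(groups), 30, 5),
    education = rnorm(length(groups), 14, 3),
    mean_fd = abs(rnorm(length(groups), 0.1, 0.03)))
  list(stack = stack, subjects = subjects)
}
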