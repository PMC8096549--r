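#' Specify a synthetic resting-state cohort
#'
#' A `cohort_spec` describes a three-group resting-state fMRI study —
#' melancholic depression, nonmelancholic depression, and healthy controls —
#' with known ground truth: region-structured BOLD coupling per group,
#' head-motion traces, and clinical scales whose distributions follow the
#' configured group means/SDs. The defaults encode the study conditions the
#' package is designed around: 31/28/32 subjects, TR 2.5 s, 200 volumes,
#' a 3 mm isotropic grid, and clinical distributions for a first-episode,
#' drug-naive depression sample.
#'
#' @param group_sizes named integer vector of subjects per group
#'   (melancholic, nonmelancholic, control).
#' @param grid_shape 3-vector of voxel lattice dimensions.
#' @param voxel_size_mm isotropic voxel edge in mm.
#' @param tr_s repetition time in seconds.
#' @param n_volumes timepoints acquired before any volume discard.
#' @param regions list of [region_spec()] objects; defaults to
#'   [default_dmn_regions()].
#' @param clinical_params tibble of per-group mean/SD for each scale;
#'   defaults to [default_clinical_params()].
#' @param nh_score_corr tibble with columns `group`, `region`, `score`, `r`
#'   giving target correlations between a region's realized network
#'   homogeneity and a clinical score. Default: r = -0.5 between right
#'   middle temporal gyrus NH and the two anticipatory-pleasure scores in
#'   the melancholic group.
#' @param subject_rho_sd between-subject SD of the within-region coupling
#'   (individual coupling is drawn around the group value and truncated to
#'   `[0.02, 0.9]`).
#' @param noise_sd SD of the voxelwise BOLD noise.
#' @param motion list with `spike_prob`, `spike_mm`, `drift_amp_mm`,
#'   `drift_amp_rad` controlling the motion model.
#' @param n_high_motion integer vector per group: how many subjects are
#'   given large-amplitude motion (5 mm spikes) so they fail the 2 mm
#'   exclusion rule downstream.
#' @param seed integer seed; all cohort randomness derives from it.
#'
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(group_sizes = c(melancholic = 31L, nonmelancholic = 28L,
                                        control = 32L),
                        grid_shape = c(24L, 28L, 22L),
                        voxel_size_mm = 3,
                        tr_s = 2.5,
                        n_volumes = 200L,
                        regions = default_dmn_regions(grid_shape),
                        clinical_params = default_clinical_params(),
                        nh_score_corr = default_nh_score_corr(),
                        subject_rho_sd = 0.06,
                        noise_sd = 1,
                        motion = list(spike_prob = 0.02, spike_mm = 0.5,
                                      drift_amp_mm = 0.2, drift_amp_rad = 0.002),
                        n_high_motion = c(melancholic = 0L, nonmelancholic = 0L,
                                          control = 0L),
                        seed = 1L) {
  stopifnot(length(group_sizes) == 3, all(group_sizes >= 2),
            length(grid_shape) == 3, n_volumes >= 2)
  if (is.null(names(group_sizes)))
    names(group_sizes) <- c("melancholic", "nonmelancholic", "control")
  labs <- vapply(regions, `[[`, "", "label")
  if (anyDuplicated(labs))
    abort(paste0("duplicate region labels: ",
                 paste(unique(labs[duplicated(labs)]), collapse = ", ")))
  check_region_overlap(regions, grid_shape)
  if (!is.null(nh_score_corr) && nrow(nh_score_corr) &&
      any(abs(nh_score_corr$r) >= 1))
    abort("|nh_score_corr| must be < 1")
  structure(list(group_sizes = group_sizes, grid_shape = as.integer(grid_shape),
                 voxel_size_mm = voxel_size_mm, tr_s = tr_s,
                 n_volumes = as.integer(n_volumes), regions = regions,
                 clinical_params = clinical_params,
                 nh_score_corr = nh_score_corr,
                 subject_rho_sd = subject_rho_sd, noise_sd = noise_sd,
                 motion = motion, n_high_motion = n_high_motion,
                 affine = make_affine(grid_shape, voxel_size_mm),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Define one coupled region of the synthetic network
#'
#' @param label region name.
#' @param voxels integer matrix (m x 3) of 1-based voxel subscripts.
#' @param coupling_by_group named numeric vector: within-region pairwise
#'   correlation per group, each in `[0, 1)`.
#' @return an object of class `region_spec`.
#' @export
region_spec <- function(label, voxels, coupling_by_group) {
  voxels <- matrix(as.integer(voxels), ncol = 3)
  if (any(coupling_by_group < 0 | coupling_by_group >= 1))
    abort(sprintf("region '%s': coupling must be in [0, 1)", label))
  structure(list(label = label, voxels = voxels,
                 coupling_by_group = coupling_by_group),
            class = "region_spec")
}

check_region_overlap <- function(regions, grid_shape) {
  idx <- lapply(regions, function(r) vox_index(r$voxels, grid_shape))
  all_idx <- unlist(idx)
  if (!anyDuplicated(all_idx)) return(invisible(TRUE))
  dup <- unique(all_idx[duplicated(all_idx)])
  bad <- vapply(regions, function(r)
    any(vox_index(r$voxels, grid_shape) %in% dup), logical(1))
  abort(paste0("overlapping regions: ",
               paste(vapply(regions[bad], `[[`, "", "label"), collapse = ", ")))
}

box_voxels <- function(i, j, k) {
  as.matrix(expand.grid(i = i, j = j, k = k))
}

#' Default default-mode-network region layout
#'
#' Six disjoint box-shaped regions on the default 24 x 28 x 22 grid, sized
#' near typical cluster extents (27-80 voxels) and placed with left/right
#' laterality on the x axis and anterior/posterior position on y. The
#' per-group coupling values plant the qualitative effect pattern the
#' pipeline is meant to recover: in melancholic depression, raised coupling
#' in bilateral superior medial frontal gyrus and lowered coupling in left
#' inferior temporal gyrus relative to both other groups; in both patient
#' groups, lowered right middle temporal and raised right posterior
#' cingulate/precuneus and right angular coupling relative to controls.
#'
#' @param grid_shape 3-vector of lattice dimensions (>= c(24, 28, 22) of the
#'   default layout).
#' @return list of [region_spec()] objects.
#' @export
default_dmn_regions <- function(grid_shape = c(24L, 28L, 22L)) {
  stopifnot(all(grid_shape >= c(23, 26, 16)))
  list(
    region_spec("left_itg", box_voxels(3:7, 8:11, 4:7),
                c(melancholic = 0.16, nonmelancholic = 0.36, control = 0.36)),
    region_spec("right_mtg", box_voxels(19:22, 10:13, 5:7),
                c(melancholic = 0.22, nonmelancholic = 0.25, control = 0.48)),
    region_spec("left_smfg", box_voxels(8:11, 22:25, 11:13),
                c(melancholic = 0.46, nonmelancholic = 0.18, control = 0.30)),
    region_spec("right_smfg", box_voxels(13:15, 22:25, 11:14),
                c(melancholic = 0.42, nonmelancholic = 0.22, control = 0.32)),
    region_spec("right_pcc_precuneus", box_voxels(13:16, 5:8, 11:13),
                c(melancholic = 0.42, nonmelancholic = 0.42, control = 0.30)),
    region_spec("right_angular", box_voxels(19:21, 4:6, 13:15),
                c(melancholic = 0.40, nonmelancholic = 0.40, control = 0.27))
  )
}

#' Default white-matter and CSF nuisance boxes
#'
#' Small boxes away from the network regions, used as tissue-signal seeds by
#' the nuisance regression stage.
#' @param grid_shape 3-vector of lattice dimensions.
#' @return list with logical-index matrices `wm` and `csf` (voxel subscripts).
#' @export
default_tissue_masks <- function(grid_shape = c(24L, 28L, 22L)) {
  clamp <- function(b) b[b[, 1] <= grid_shape[1] & b[, 2] <= grid_shape[2] &
                           b[, 3] <= grid_shape[3], , drop = FALSE]
  list(wm = clamp(box_voxels(11:13, 14:16, 5:6)),
       csf = clamp(box_voxels(11:13, 14:16, 17:18)))
}

#' Default per-group clinical score distributions
#'
#' Group means and SDs for age, education, illness duration, depression
#' severity (HRSD-17), anxiety (BAI), anhedonia (SHAPS-C), and the four
#' TEPS pleasure-experience subscales plus the total, for a melancholic /
#' nonmelancholic / control design. Controls carry no illness-duration or
#' TEPS entries (NA), matching the usual reporting for scales administered
#' to patients only.
#'
#' @return tibble with columns `scale`, `group`, `mean`, `sd`.
#' @export
default_clinical_params <- function() {
  g <- c("melancholic", "nonmelancholic", "control")
  row <- function(scale, m, s) tibble::tibble(scale = scale, group = g,
                                              mean = m, sd = s)
  dplyr::bind_rows(
    row("age", c(28.65, 32.04, 29.59), c(5.30, 8.18, 5.00)),
    row("education", c(15.16, 12.54, 14.59), c(3.20, 3.00, 2.82)),
    row("illness_duration", c(6.75, 5.96, NA), c(4.26, 4.64, NA)),
    row("hrsd17", c(21.77, 21.00, 0.94), c(3.79, 3.14, 0.95)),
    row("bai", c(44.00, 38.77, 22.63), c(11.51, 9.84, 2.28)),
    row("shapsc", c(37.23, 31.89, 21.59), c(6.04, 5.24, 5.36)),
    row("teps_total", c(58.30, 69.46, NA), c(14.19, 11.16, NA)),
    row("teps_abstract_anticipatory", c(13.17, 17.04, NA), c(4.79, 3.85, NA)),
    row("teps_contextual_anticipatory", c(13.13, 16.68, NA), c(3.96, 3.64, NA)),
    row("teps_abstract_consummatory", c(20.20, 22.39, NA), c(5.21, 5.28, NA)),
    row("teps_contextual_consummatory", c(11.80, 13.36, NA), c(3.23, 3.27, NA))
  )
}

#' @rdname default_clinical_params
#' @export
default_sex_male_prob <- function() {
  c(melancholic = 10 / 31, nonmelancholic = 10 / 28, control = 15 / 32)
}

#' Default NH-score coupling targets
#'
#' In the melancholic group, right middle temporal gyrus network homogeneity
#' is negatively coupled (r = -0.5) to the TEPS total and contextual
#' anticipatory scores.
#' @return tibble with columns `group`, `region`, `score`, `r`.
#' @export
default_nh_score_corr <- function() {
  tibble::tibble(group = "melancholic", region = "right_mtg",
                 score = c("teps_total", "teps_contextual_anticipatory"),
                 r = -0.5)
}

#' Generate one subject's BOLD run
#'
#' Each voxel inside a region follows the one-factor equicorrelated model
#' `sqrt(rho) * latent + sqrt(1 - rho) * noise` with the latent shared across
#' the region's voxels, so the population pairwise correlation within the
#' region equals `rho`; all other voxels are pure noise. Everything is scaled
#' by `noise_sd`.
#'
#' @param regions list of [region_spec()] objects (disjoint).
#' @param group group label selecting each region's coupling.
#' @param n_volumes number of timepoints.
#' @param noise_sd noise scale (> 0).
#' @param grid_shape,voxel_size_mm,tr_s geometry of the run.
#' @param subject_rho optional named vector overriding the group coupling
#'   per region (e.g. an individual draw around the group value).
#' @param active `"all"` for a full-grid run, `"regions"` to simulate only
#'   region plus tissue-seed voxels (all other series identically zero);
#'   the sparse form is statistically identical downstream of a fixed mask.
#' @return a `bold_run`: time x voxel matrix with geometry attributes.
#' @export
generate_bold <- function(regions, group, n_volumes = 200L, noise_sd = 1,
                          grid_shape = c(24L, 28L, 22L), voxel_size_mm = 3,
                          tr_s = 2.5, subject_rho = NULL,
                          active = c("all", "regions")) {
  active <- match.arg(active)
  stopifnot(noise_sd > 0, n_volumes >= 2)
  check_region_overlap(regions, grid_shape)
  nv <- as.integer(n_volumes)
  V <- prod(grid_shape)
  if (active == "all") {
    vox <- seq_len(V)
  } else {
    tis <- default_tissue_masks(grid_shape)
    vox <- sort(unique(c(
      unlist(lapply(regions, function(r) vox_index(r$voxels, grid_shape))),
      vox_index(tis$wm, grid_shape), vox_index(tis$csf, grid_shape))))
  }
  data <- matrix(rnorm(nv * length(vox), sd = noise_sd), nrow = nv)
  truth <- numeric(0)
  for (r in regions) {
    rho <- if (!is.null(subject_rho) && r$label %in% names(subject_rho))
      subject_rho[[r$label]] else r$coupling_by_group[[group]]
    if (is.null(rho) || is.na(rho))
      abort(sprintf("no coupling for group '%s' in region '%s'", group, r$label))
    stopifnot(rho >= 0, rho < 1)
    cols <- match(vox_index(r$voxels, grid_shape), vox)
    latent <- rnorm(nv, sd = noise_sd)
    data[, cols] <- sqrt(rho) * latent + sqrt(1 - rho) * data[, cols]
    truth[r$label] <- rho
  }
  bold_run(data, vox, grid_shape,
           make_affine(grid_shape, voxel_size_mm), tr_s, truth = truth)
}

bold_run <- function(data, voxels, dim, affine, tr_s, truth = NULL) {
  stopifnot(nrow(data) >= 2, ncol(data) == length(voxels))
  structure(list(data = data, voxels = as.integer(voxels),
                 dim = as.integer(dim), affine = affine, tr_s = tr_s,
                 truth = truth),
            class = "bold_run")
}

#' Convert a 4D array to a `bold_run`
#' @param arr 4D array (x, y, z, t).
#' @param affine 4x4 voxel-to-mm map.
#' @param tr_s repetition time in seconds.
#' @return a `bold_run` over all voxels.
#' @export
as_bold_run <- function(arr, affine, tr_s) {
  d <- dim(arr)
  stopifnot(length(d) == 4)
  data <- t(matrix(arr, nrow = prod(d[1:3]), ncol = d[4]))
  bold_run(data, seq_len(prod(d[1:3])), d[1:3], affine, tr_s)
}

#' Expand a `bold_run` back to a 4D array
#' @param run a `bold_run`.
#' @return 4D array (x, y, z, t); inactive voxels are zero.
#' @export
bold_array <- function(run) {
  nt <- nrow(run$data)
  arr <- array(0, c(run$dim, nt))
  flat <- matrix(0, prod(run$dim), nt)
  flat[run$voxels, ] <- t(run$data)
  array(flat, c(run$dim, nt))
}

#' @export
print.bold_run <- function(x, ...) {
  cat(sprintf("<bold_run> %d timepoints, %d active voxels on %s grid, TR %.2f s\n",
              nrow(x$data), ncol(x$data), paste(x$dim, collapse = "x"), x$tr_s))
  invisible(x)
}

#' Generate a rigid-body motion trace
#'
#' Smooth sinusoidal drift per parameter plus Bernoulli single-frame spikes
#' on a random translation axis. Columns are tx, ty, tz (mm) then rx, ry, rz
#' (radians), the SPM rp-file layout.
#'
#' @param n_volumes number of frames.
#' @param spike_prob per-frame spike probability in `[0, 1]`.
#' @param spike_mm spike amplitude in mm.
#' @param drift_amp_mm,drift_amp_rad maximum drift amplitude for
#'   translations / rotations (0 disables drift).
#' @return T x 6 matrix of class `motion_trace`.
#' @export
generate_motion <- function(n_volumes, spike_prob = 0.02, spike_mm = 0.5,
                            drift_amp_mm = 0.2, drift_amp_rad = 0.002) {
  stopifnot(spike_prob >= 0, spike_prob <= 1, n_volumes >= 2)
  nv <- as.integer(n_volumes)
  tt <- seq_len(nv) / nv
  amp <- c(rep(drift_amp_mm, 3), rep(drift_amp_rad, 3))
  params <- vapply(1:6, function(j) {
    a <- runif(1, 0, amp[j])
    f <- runif(1, 0.5, 2)
    phi <- runif(1, 0, 2 * pi)
    a * sin(2 * pi * f * tt + phi)
  }, numeric(nv))
  spikes <- which(rbinom(nv, 1, spike_prob) == 1)
  for (s in spikes) {
    ax <- sample.int(3, 1)
    params[s, ax] <- params[s, ax] + sample(c(-1, 1), 1) * spike_mm
  }
  structure(params, class = c("motion_trace", "matrix"),
            dimnames = list(NULL, c("tx", "ty", "tz", "rx", "ry", "rz")))
}

#' Generate clinical records for one group
#'
#' Scales are drawn from the configured group mean/SD. A score listed in
#' `corr_spec` for this group is constructed as an affine mix of the
#' standardized realized region NH and residualized Gaussian noise, rescaled
#' to the configured mean/SD, so the in-sample correlation with `region_nh`
#' equals the target exactly. Controls receive NA for illness duration and
#' all TEPS scales; scores are truncated at zero.
#'
#' @param group group label.
#' @param n number of subjects.
#' @param region_nh named list of numeric vectors (length `n`) of realized
#'   region-mean NH, one per region named in `corr_spec`.
#' @param params clinical parameter tibble ([default_clinical_params()]).
#' @param corr_spec NH-score coupling tibble ([default_nh_score_corr()]).
#' @param sex_male_prob named per-group probability of male sex.
#' @return tibble of subject records (one row per subject).
#' @export
generate_clinical <- function(group, n, region_nh = NULL,
                              params = default_clinical_params(),
                              corr_spec = default_nh_score_corr(),
                              sex_male_prob = default_sex_male_prob()) {
  p <- params[params$group == group, ]
  if (!nrow(p)) abort(sprintf("no clinical parameters for group '%s'", group))
  out <- tibble::tibble(.rows = n)
  for (i in seq_len(nrow(p))) {
    sc <- p$scale[i]
    if (is.na(p$mean[i])) { out[[sc]] <- rep(NA_real_, n); next }
    cs <- if (!is.null(corr_spec))
      corr_spec[corr_spec$group == group & corr_spec$score == sc, ] else NULL
    if (!is.null(cs) && nrow(cs) == 1 && n >= 3) {
      nh <- region_nh[[cs$region]]
      if (is.null(nh) || length(nh) != n)
        abort(sprintf("region_nh['%s'] of length %d required for score '%s'",
                      cs$region, n, sc))
      out[[sc]] <- p$mean[i] + p$sd[i] * corr_calibrated(nh, cs$r, n)
    } else {
      out[[sc]] <- p$mean[i] + p$sd[i] * rnorm(n)
    }
    if (!sc %in% c("age", "education"))
      out[[sc]] <- pmax(out[[sc]], 0)
  }
  out$age <- pmax(out$age, 18)
  out$sex <- ifelse(runif(n) < sex_male_prob[[group]], "male", "female")
  out$group <- group
  out
}

# standardized vector with exact sample correlation `r` against x
corr_calibrated <- function(x, r, n) {
  stopifnot(n >= 3, abs(r) < 1)
  z1 <- as.numeric(scale(x))
  e <- rnorm(n)
  e <- e - z1 * sum(e * z1) / sum(z1^2)   # residualize on x
  e <- as.numeric(scale(e))
  as.numeric(scale(r * z1 + sqrt(1 - r^2) * e))
}

# mean NH over one region's voxels, with NH computed against the whole
# network mask (union of all regions) — the quantity the analysis extracts
region_mean_nh <- function(run, region, all_regions = list(region)) {
  midx <- sort(unique(unlist(lapply(all_regions, function(r)
    vox_index(r$voxels, run$dim)))))
  cols <- match(midx, run$voxels)
  cc <- cor(run$data[, cols, drop = FALSE])
  M <- length(midx)
  nh <- (rowSums(cc) - 1) / (M - 1)
  mean(nh[midx %in% vox_index(region$voxels, run$dim)])
}

#' Generate a full synthetic cohort
#'
#' Draws, for every subject, an individual within-region coupling around the
#' group value, a BOLD run, a motion trace, and a clinical record whose
#' coupled score tracks the realized region NH. Subjects flagged as
#' high-motion receive 5 mm motion spikes so they fail the standard 2 mm
#' exclusion rule. With `out_dir` set, writes per-subject NIfTI runs,
#' rp-style motion text files, a subject TSV, and a JSON manifest.
#'
#' The score coupled to a region's NH is calibrated against the subject's
#' *realized* region-mean NH — by default after the standard temporal
#' preprocessing (discard, detrend, bandpass, nuisance regression) and with
#' NH computed against the union of all regions, i.e. the same quantity the
#' analysis pipeline later extracts from the network mask. Set
#' `coupling_preprocess = NULL` to couple against the raw series instead.
#'
#' @param spec a [cohort_spec()].
#' @param out_dir optional output directory.
#' @param active passed to [generate_bold()] (`"all"` or `"regions"`).
#' @param coupling_preprocess a [preprocess_config()] applied (to a sparse
#'   copy of the run) before the coupling NH is measured, or NULL for raw.
#' @return list with `subjects` (list of per-subject records), `table`
#'   (subject tibble), and `manifest`.
#' @export
generate_cohort <- function(spec, out_dir = NULL, active = "all",
                            coupling_preprocess = preprocess_config()) {
  stopifnot(inherits(spec, "cohort_spec"))
  labels <- vapply(spec$regions, `[[`, "", "label")
  corr_spec <- spec$nh_score_corr
  if (!is.null(corr_spec))
    corr_spec <- corr_spec[corr_spec$region %in% labels, , drop = FALSE]
  if (!is.null(corr_spec) && !nrow(corr_spec)) corr_spec <- NULL
  groups <- names(spec$group_sizes)
  subjects <- list()
  records <- list()
  sid <- 0L
  for (g in groups) {
    ng <- spec$group_sizes[[g]]
    nh_regions <- if (!is.null(corr_spec))
      unique(corr_spec$region[corr_spec$group == g]) else character(0)
    region_nh <- stats::setNames(
      replicate(length(nh_regions), numeric(ng), simplify = FALSE), nh_regions)
    grp_subjects <- vector("list", ng)
    hi <- seq_len(spec$n_high_motion[[g]] %||% 0L)
    for (s in seq_len(ng)) {
      sid <- sid + 1L
      set.seed(stage_seed(spec$seed, paste0("subject_", g, "_", s)))
      rho <- vapply(spec$regions, function(r) {
        base <- r$coupling_by_group[[g]]
        min(max(base + rnorm(1, sd = spec$subject_rho_sd), 0.02), 0.9)
      }, numeric(1))
      names(rho) <- vapply(spec$regions, `[[`, "", "label")
      run <- generate_bold(spec$regions, g, spec$n_volumes, spec$noise_sd,
                           spec$grid_shape, spec$voxel_size_mm, spec$tr_s,
                           subject_rho = rho, active = active)
      mo <- spec$motion
      motion <- if (s %in% hi)
        generate_motion(spec$n_volumes, spike_prob = 1, spike_mm = 5,
                        drift_amp_mm = mo$drift_amp_mm,
                        drift_amp_rad = mo$drift_amp_rad)
      else
        generate_motion(spec$n_volumes, mo$spike_prob, mo$spike_mm,
                        mo$drift_amp_mm, mo$drift_amp_rad)
      if (length(nh_regions)) {
        crun <- run
        if (!is.null(coupling_preprocess)) {
          pp <- suppressWarnings(preprocess_run(
            run, motion, coupling_preprocess,
            tissue = default_tissue_masks(spec$grid_shape)))
          if (!is.null(pp$run)) crun <- pp$run
        }
        for (rg in nh_regions)
          region_nh[[rg]][s] <- region_mean_nh(
            crun, spec$regions[[match(rg, names(rho))]], spec$regions)
      }
      grp_subjects[[s]] <- list(
        subject_id = sprintf("sub-%03d", sid), group = g, bold = run,
        motion = motion, truth = rho)
    }
    set.seed(stage_seed(spec$seed, paste0("clinical_", g)))
    rec <- generate_clinical(g, ng, region_nh, spec$clinical_params,
                             corr_spec)
    rec$subject_id <- vapply(grp_subjects, `[[`, "", "subject_id")
    records[[g]] <- rec
    subjects <- c(subjects, grp_subjects)
  }
  table <- dplyr::bind_rows(records)
  table <- dplyr::relocate(table, "subject_id", "group")
  manifest <- list(seed = spec$seed, group_sizes = as.list(spec$group_sizes),
                   n_volumes = spec$n_volumes, tr_s = spec$tr_s,
                   grid_shape = spec$grid_shape,
                   regions = lapply(spec$regions, function(r)
                     list(label = r$label, n_voxels = nrow(r$voxels),
                          coupling = as.list(r$coupling_by_group))),
                   subject_ids = vapply(subjects, `[[`, "", "subject_id"))
  cohort <- list(subjects = subjects, table = table, manifest = manifest,
                 spec = spec)
  if (!is.null(out_dir)) write_cohort(cohort, out_dir)
  cohort
}

#' Write a cohort to disk
#'
#' One gzipped NIfTI run and one 6-column rp-style motion text file per
#' subject, plus `subjects.tsv` and `manifest.json`.
#' @param cohort result of [generate_cohort()].
#' @param out_dir output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    abort(sprintf("cannot create output directory '%s'", out_dir))
  for (s in cohort$subjects) {
    arr <- bold_array(s$bold)
    img <- RNifti::asNifti(arr)
    img <- RNifti::`sform<-`(img, structure(s$bold$affine, code = 2L))
    RNifti::pixdim(img) <- c(rep(cohort$spec$voxel_size_mm, 3), cohort$spec$tr_s)
    RNifti::writeNifti(img, file.path(out_dir, paste0(s$subject_id, "_bold.nii.gz")))
    utils::write.table(unclass(s$motion),
                       file.path(out_dir, paste0("rp_", s$subject_id, ".txt")),
                       row.names = FALSE, col.names = FALSE)
  }
  readr::write_tsv(cohort$table, file.path(out_dir, "subjects.tsv"))
  jsonlite::write_json(cohort$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Read an rp-style motion trace
#' @param path 6-column whitespace-delimited text file (tx ty tz in mm,
#'   rx ry rz in radians).
#' @return T x 6 `motion_trace` matrix.
#' @export
read_motion <- function(path) {
  m <- as.matrix(utils::read.table(path))
  stopifnot(ncol(m) == 6)
  structure(unname(m), class = c("motion_trace", "matrix"),
            dimnames = list(NULL, c("tx", "ty", "tz", "rx", "ry", "rz")))
}

#' Ground-truth network template of a cohort spec
#'
#' Union of the spec's region voxels, as a labeled network mask — the
#' synthetic analogue of an a-priori network template volume.
#' @param spec a [cohort_spec()].
#' @return a `network_mask` (see [build_mask()]).
#' @export
cohort_template <- function(spec) {
  mask <- array(FALSE, spec$grid_shape)
  labels <- array(0L, spec$grid_shape)
  for (i in seq_along(spec$regions)) {
    idx <- vox_index(spec$regions[[i]]$voxels, spec$grid_shape)
    mask[idx] <- TRUE
    labels[idx] <- i
  }
  network_mask(mask, spec$affine,
               region_labels = labels,
               region_names = vapply(spec$regions, `[[`, "", "label"))
}
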