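#' Preprocessing configuration
#'
#' @param n_discard initial volumes to drop.
#' @param band_hz length-2 passband in Hz (must sit inside (0, Nyquist)).
#' @param max_translation_mm,max_rotation_deg motion exclusion thresholds;
#'   a subject is excluded when any translation axis exceeds
#'   `max_translation_mm` (strictly) in displacement from the first retained
#'   frame, or any rotation exceeds `max_rotation_deg`.
#' @param nuisance character vector of nuisance families to regress:
#'   any of `"wm"`, `"csf"`, `"friston24"`. The global mean signal is never
#'   regressed (global-signal preservation).
#' @param fwhm_mm smoothing kernel applied to NH maps downstream.
#' @return list of class `preprocess_config`.
#' @export
preprocess_config <- function(n_discard = 10L, band_hz = c(0.01, 0.08),
                              max_translation_mm = 2, max_rotation_deg = 2,
                              nuisance = c("wm", "csf", "friston24"),
                              fwhm_mm = 4) {
  stopifnot(length(band_hz) == 2, band_hz[1] > 0, band_hz[2] > band_hz[1])
  structure(list(n_discard = as.integer(n_discard), band_hz = band_hz,
                 max_translation_mm = max_translation_mm,
                 max_rotation_deg = max_rotation_deg,
                 nuisance = nuisance, fwhm_mm = fwhm_mm),
            class = "preprocess_config")
}

#' Discard initial volumes
#'
#' Drops the first `n` frames from the run and its motion trace,
#' synchronized, to remove initial scanner-signal instability.
#' @param run a `bold_run`.
#' @param motion companion T x 6 motion trace.
#' @param n number of frames to drop (0 <= n < T).
#' @return list with elements `run` and `motion`.
#' @export
discard_initial <- function(run, motion, n = 10L) {
  nt <- nrow(run$data)
  if (n >= nt) abort(sprintf("cannot discard %d of %d frames", n, nt))
  stopifnot(nrow(motion) == nt)
  if (n > 0) {
    run$data <- run$data[-seq_len(n), , drop = FALSE]
    motion <- motion[-seq_len(n), , drop = FALSE]
    class(motion) <- c("motion_trace", "matrix")
  }
  list(run = run, motion = motion)
}

#' Motion-based subject exclusion
#'
#' Excludes a subject when the absolute displacement of any translation axis
#' from the first retained frame strictly exceeds the translation threshold
#' (mm), or any rotation axis strictly exceeds the rotation threshold
#' (degrees). The reason names the offending axis and frame.
#'
#' @param motion T x 6 motion trace (mm, radians).
#' @param config a [preprocess_config()] (thresholds used).
#' @return tibble with `keep`, `reason`, `max_abs_translation_mm`,
#'   `max_abs_rotation_deg`.
#' @export
motion_exclude <- function(motion, config = preprocess_config()) {
  stopifnot(nrow(motion) >= 1)
  disp <- sweep(unclass(motion), 2, motion[1, ])
  trans <- abs(disp[, 1:3, drop = FALSE])
  rot_deg <- abs(disp[, 4:6, drop = FALSE]) * 180 / pi
  max_t <- max(trans)
  max_r <- max(rot_deg)
  keep <- TRUE
  reason <- NA_character_
  if (max_t > config$max_translation_mm) {
    w <- which(trans == max_t, arr.ind = TRUE)[1, ]
    keep <- FALSE
    reason <- sprintf("translation %s = %.2f mm at frame %d exceeds %g mm",
                      c("tx", "ty", "tz")[w[2]], max_t, w[1],
                      config$max_translation_mm)
  } else if (max_r > config$max_rotation_deg) {
    w <- which(rot_deg == max_r, arr.ind = TRUE)[1, ]
    keep <- FALSE
    reason <- sprintf("rotation %s = %.2f deg at frame %d exceeds %g deg",
                      c("rx", "ry", "rz")[w[2]], max_r, w[1],
                      config$max_rotation_deg)
  }
  tibble::tibble(keep = keep, reason = reason,
                 max_abs_translation_mm = max_t, max_abs_rotation_deg = max_r)
}

#' Framewise displacement
#'
#' Power-style FD: per frame, the sum of absolute frame-to-frame changes of
#' the three translations (mm) plus the three rotations converted to arc
#' length on a 50 mm sphere. The first frame has FD 0.
#'
#' @param motion T x 6 motion trace (>= 2 frames).
#' @return list of class `motion_summary`: `fd` (length T), `mean_fd`,
#'   `max_abs_translation` (mm), `max_abs_rotation` (degrees).
#' @export
framewise_displacement <- function(motion) {
  if (nrow(motion) < 2) abort("FD needs at least 2 frames")
  d <- abs(diff(unclass(motion)))
  fd <- c(0, rowSums(d[, 1:3, drop = FALSE]) +
            50 * rowSums(d[, 4:6, drop = FALSE]))
  structure(list(fd = fd, mean_fd = mean(fd),
                 max_abs_translation = max(abs(motion[, 1:3])),
                 max_abs_rotation = max(abs(motion[, 4:6])) * 180 / pi),
            class = "motion_summary")
}

#' Linear detrending
#'
#' Removes, per voxel, the least-squares line over time; each residual
#' series has zero mean and zero linear trend.
#' @param run a `bold_run` with >= 3 timepoints.
#' @return the detrended `bold_run`.
#' @export
detrend_linear <- function(run) {
  nt <- nrow(run$data)
  stopifnot(nt >= 3)
  X <- cbind(1, seq_len(nt))
  run$data <- stats::lm.fit(X, run$data)$residuals
  run
}

#' Zero-phase frequency-domain bandpass filter
#'
#' Ideal (hard-edged) bandpass via the discrete Fourier transform: bins with
#' frequency inside `[low_hz, high_hz]` are kept, all others (including DC)
#' are zeroed, and the series is inverse-transformed. Zero-phase by
#' construction.
#'
#' @param run a `bold_run`.
#' @param low_hz,high_hz band edges, `0 < low < high < 1/(2 tr_s)`.
#' @return the filtered `bold_run`.
#' @export
bandpass <- function(run, low_hz = 0.01, high_hz = 0.08) {
  nyq <- 1 / (2 * run$tr_s)
  if (!(low_hz > 0 && high_hz > low_hz && high_hz < nyq))
    abort(sprintf("band [%g, %g] Hz must lie inside (0, %g) Hz", low_hz,
                  high_hz, nyq))
  run$data <- bandpass_matrix(run$data, run$tr_s, low_hz, high_hz)
  run
}

bandpass_matrix <- function(x, tr_s, low_hz, high_hz) {
  nt <- nrow(x)
  freq <- (seq_len(nt) - 1) / (nt * tr_s)
  freq <- pmin(freq, 1 / tr_s - freq)  # fold to [0, Nyquist]
  keep <- freq >= low_hz & freq <= high_hz
  xf <- stats::mvfft(x)
  xf[!keep, ] <- 0
  Re(stats::mvfft(xf, inverse = TRUE)) / nt
}

#' Friston 24-parameter motion expansion
#'
#' The 6 rigid-body parameters, the same lagged by one frame (first frame
#' zero-padded), and the squares of both sets: 24 columns.
#' @param motion T x 6 motion trace.
#' @return T x 24 matrix.
#' @export
friston24 <- function(motion) {
  m <- unclass(motion)
  lag <- rbind(0, m[-nrow(m), , drop = FALSE])
  out <- cbind(m, lag, m^2, lag^2)
  colnames(out) <- c(colnames(motion),
                     paste0(colnames(motion), "_lag"),
                     paste0(colnames(motion), "_sq"),
                     paste0(colnames(motion), "_lag_sq"))
  out
}

#' Nuisance regression
#'
#' Regresses, per voxel, the mean white-matter series, the mean CSF series,
#' and the Friston-24 motion expansion (plus an intercept) out of the data
#' by OLS, keeping the residuals. The global mean signal is not a regressor.
#' Nuisance regressors are bandpass-filtered with the run's passband before
#' regression when `band_hz` is supplied, so regression cannot reintroduce
#' frequencies the filter removed. Collinear regressor columns are dropped
#' with a warning.
#'
#' @param run a `bold_run` (typically already filtered).
#' @param motion companion motion trace (same frame count).
#' @param wm_vox,csf_vox voxel subscript matrices (m x 3) of the tissue
#'   seeds; NULL skips the corresponding regressor.
#' @param use_friston24 include the motion expansion?
#' @param band_hz optional passband applied to the regressors.
#' @return the residual `bold_run`.
#' @export
regress_nuisance <- function(run, motion, wm_vox = NULL, csf_vox = NULL,
                             use_friston24 = TRUE, band_hz = NULL) {
  nt <- nrow(run$data)
  if (!is.null(motion)) stopifnot(nrow(motion) == nt)
  regs <- NULL
  seed_mean <- function(vox) {
    if (is.null(vox) || nrow(vox) == 0) return(NULL)
    cols <- match(vox_index(matrix(as.integer(vox), ncol = 3), run$dim),
                  run$voxels)
    if (anyNA(cols)) abort("tissue seed outside the run's active voxels")
    rowMeans(run$data[, cols, drop = FALSE])
  }
  regs <- cbind(wm = seed_mean(wm_vox), csf = seed_mean(csf_vox))
  if (use_friston24) {
    if (is.null(motion)) abort("motion trace required for the 24-parameter expansion")
    regs <- cbind(regs, friston24(motion))
  }
  if (is.null(regs) || ncol(regs) == 0) return(run)
  if (!is.null(band_hz))
    regs <- bandpass_matrix(regs, run$tr_s, band_hz[1], band_hz[2])
  X <- cbind(intercept = 1, regs)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[-seq_len(qrX$rank)]]
    warn(paste0("dropping collinear nuisance columns: ",
                paste(dropped, collapse = ", ")))
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  }
  run$data <- stats::lm.fit(X, run$data)$residuals
  run
}

#' Run the full temporal preprocessing chain on one subject
#'
#' Order: discard initial volumes -> motion exclusion test -> linear
#' detrend -> bandpass -> nuisance regression (with identically filtered
#' regressors). Returns NULL components downstream when the subject is
#' excluded.
#'
#' @param run a `bold_run`.
#' @param motion companion motion trace.
#' @param config a [preprocess_config()].
#' @param tissue list with `wm` and `csf` voxel subscripts
#'   ([default_tissue_masks()]); NULL skips tissue regressors.
#' @return list: `run` (preprocessed or NULL), `motion` (post-discard),
#'   `qc` (tibble: keep, reason, mean_fd).
#' @export
preprocess_run <- function(run, motion, config = preprocess_config(),
                           tissue = default_tissue_masks(run$dim)) {
  d <- discard_initial(run, motion, config$n_discard)
  decision <- motion_exclude(d$motion, config)
  fd <- framewise_displacement(d$motion)
  qc <- dplyr::mutate(decision, mean_fd = fd$mean_fd)
  if (!decision$keep)
    return(list(run = NULL, motion = d$motion, qc = qc))
  out <- detrend_linear(d$run)
  out <- bandpass(out, config$band_hz[1], config$band_hz[2])
  out <- regress_nuisance(out, d$motion,
                          wm_vox = if ("wm" %in% config$nuisance) tissue$wm,
                          csf_vox = if ("csf" %in% config$nuisance) tissue$csf,
                          use_friston24 = "friston24" %in% config$nuisance,
                          band_hz = config$band_hz)
  list(run = out, motion = d$motion, qc = qc)
}
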