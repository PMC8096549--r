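#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a cluster table
#'
#' One row per surviving cluster, without the voxel list-column; peak
#' coordinates are reported in mm when an affine is supplied.
#' @param x a `cluster_table` from [grf_cluster_correct()].
#' @param affine optional 4x4 voxel-to-mm map.
#' @param ... unused.
#' @return a tibble.
#' @method tidy cluster_table
#' @export
tidy.cluster_table <- function(x, affine = NULL, ...) {
  out <- dplyr::select(tibble::as_tibble(x), -"voxels")
  if (!is.null(affine) && nrow(out)) {
    mm <- voxel_to_mm(cbind(x$peak_i, x$peak_j, x$peak_k), affine)
    out$x <- mm[, 1]; out$y <- mm[, 2]; out$z <- mm[, 3]
  }
  out
}

#' Tidy a voxelwise GLM fit
#'
#' @param x a `stat_map`.
#' @param ... unused.
#' @return tibble with one row per in-mask voxel: subscripts, statistic and
#'   its uncorrected p value.
#' @method tidy stat_map
#' @export
tidy.stat_map <- function(x, ...) {
  sub <- vox_subscript(x$voxels, x$mask$dim)
  stat <- x$stat[x$voxels]
  p <- if (x$type == "F")
    pf(stat, x$df[1], x$df[2], lower.tail = FALSE)
  else 2 * pt(-abs(stat), x$df)
  tibble::tibble(i = sub[, 1], j = sub[, 2], k = sub[, 3],
                 statistic = stat, type = x$type, p_value = p)
}

#' @method glance stat_map
#' @export
glance.stat_map <- function(x, ...) {
  tibble::tibble(type = x$type,
                 df1 = if (x$type == "F") x$df[1] else NA_real_,
                 df2 = if (x$type == "F") x$df[2] else x$df,
                 n_subjects = x$n %||% NA_integer_,
                 n_voxels = length(x$voxels),
                 max_abs_stat = max(abs(x$stat[x$voxels])))
}

#' @method glance nh_pipeline
#' @export
glance.nh_pipeline <- function(x, ...) {
  best <- if (!is.null(x$classification))
    x$classification[x$classification$best, ] else NULL
  tibble::tibble(
    n_retained = nrow(x$subjects),
    n_excluded = sum(!x$qc$keep),
    n_mask_voxels = sum(x$mask$mask),
    n_ancova_clusters = nrow(x$ancova$clusters),
    best_combination = if (!is.null(best)) best$combination else NA_character_,
    best_accuracy = if (!is.null(best)) best$accuracy else NA_real_)
}

#' Plot an NH map slice
#'
#' Axial slice heatmap of the (masked) NH values.
#' @param object an `nh_map`.
#' @param slice axial (k) slice index; defaults to the mask's busiest slice.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot nh_map
#' @export
autoplot.nh_map <- function(object, slice = NULL, ...) {
  m <- object$mask$mask
  slice <- slice %||% which.max(apply(m, 3, sum))
  v <- object$values[, , slice]
  df <- tidyr::expand_grid(i = seq_len(nrow(v)), j = seq_len(ncol(v)))
  df$nh <- v[as.matrix(df)]
  df$in_mask <- m[, , slice][as.matrix(df[, c("i", "j")])]
  ggplot2::ggplot(df, ggplot2::aes(.data$i, .data$j)) +
    ggplot2::geom_raster(ggplot2::aes(fill = ifelse(.data$in_mask, .data$nh,
                                                    NA_real_))) +
    ggplot2::scale_fill_viridis_c(na.value = "grey90", name = "NH") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = paste0("NH map", if (!is.null(object$subject_id))
      paste0(" - ", object$subject_id)), subtitle = sprintf("slice k = %d", slice),
      x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a feature-combination search
#'
#' Accuracy per feature combination, the best one highlighted.
#' @param object an `nh_combination_search`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot nh_combination_search
#' @export
autoplot.nh_combination_search <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$combination <- stats::reorder(df$combination, df$accuracy)
  ggplot2::ggplot(df, ggplot2::aes(.data$combination, .data$accuracy,
                                   fill = .data$best)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60",
                                          `TRUE` = "#2166ac")) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "LOOCV accuracy (%)") +
    ggplot2::theme_minimal()
}

#' Plot NH-symptom correlations
#'
#' Correlation coefficients per cluster and score; solid points pass the
#' Benjamini-Hochberg threshold.
#' @param object an `nh_correlations`.
#' @param alpha BH significance level for highlighting.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot nh_correlations
#' @export
autoplot.nh_correlations <- function(object, alpha = 0.05, ...) {
  df <- tibble::as_tibble(object)
  df$significant <- !is.na(df$p_bh) & df$p_bh < alpha
  ggplot2::ggplot(df, ggplot2::aes(.data$score, .data$r,
                                   colour = .data$cluster,
                                   alpha = .data$significant)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(size = 3) +
    ggplot2::scale_alpha_manual(values = c(`FALSE` = 0.35, `TRUE` = 1),
                                guide = "none") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Pearson r") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
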