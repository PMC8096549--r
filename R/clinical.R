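#' One-way ANOVA from group summary statistics
#'
#' Reconstructs the between/within sums of squares from per-group means,
#' SDs, and sizes, yielding the omnibus F with Fisher LSD pairwise
#' comparisons (pooled within-group mean square, t with N - k df) — the
#' test one would run on the raw data, recovered from printed summary
#' cells.
#'
#' @param summaries tibble with columns `group`, `mean`, `sd`, `n`
#'   (k >= 2 rows, each n >= 2).
#' @return list with `statistic` (F), `df`, `p_value`, and `pairwise`
#'   (tibble: group1, group2, estimate, statistic, p_value).
#' @export
anova_from_summary <- function(summaries) {
  k <- nrow(summaries)
  stopifnot(k >= 2, all(summaries$n >= 2))
  n <- summaries$n
  m <- summaries$mean
  s <- summaries$sd
  N <- sum(n)
  grand <- sum(n * m) / N
  ssb <- sum(n * (m - grand)^2)
  ssw <- sum((n - 1) * s^2)
  df1 <- k - 1
  df2 <- N - k
  if (ssw == 0 && ssb > 0)
    return(list(statistic = Inf, df = c(df1, df2), p_value = 0,
                pairwise = NULL, note = "zero within-group variance"))
  mse <- ssw / df2
  f <- (ssb / df1) / mse
  pairs <- utils::combn(k, 2)
  pairwise <- purrr::map_dfr(seq_len(ncol(pairs)), function(c_i) {
    i <- pairs[1, c_i]; j <- pairs[2, c_i]
    est <- m[i] - m[j]
    se <- sqrt(mse * (1 / n[i] + 1 / n[j]))
    tt <- est / se
    tibble::tibble(group1 = summaries$group[i], group2 = summaries$group[j],
                   estimate = est, statistic = tt,
                   p_value = 2 * pt(-abs(tt), df2))
  })
  list(statistic = f, df = c(df1, df2),
       p_value = pf(f, df1, df2, lower.tail = FALSE), pairwise = pairwise)
}

#' Pooled two-sample t test from summary statistics
#'
#' Student's t with pooled variance and `n1 + n2 - 2` degrees of freedom,
#' two-tailed, from means, SDs and sizes.
#'
#' @param m1,s1,n1 mean, SD, size of group 1.
#' @param m2,s2,n2 mean, SD, size of group 2.
#' @return list with `statistic`, `df`, `p_value`, `estimate` (m1 - m2).
#' @export
ttest_from_summary <- function(m1, s1, n1, m2, s2, n2) {
  stopifnot(n1 >= 2, n2 >= 2)
  if (s1 == 0 && s2 == 0) abort("both group variances are zero")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tt <- (m1 - m2) / se
  list(statistic = tt, df = df, p_value = 2 * pt(-abs(tt), df),
       estimate = m1 - m2)
}

#' Pearson chi-square test on a contingency table
#'
#' Plain Pearson chi-square without continuity correction,
#' `df = (r - 1)(c - 1)`.
#' @param counts integer matrix of observed counts (all expected counts
#'   must be positive).
#' @return list with `statistic`, `df`, `p_value`, `expected`.
#' @export
chi_square_table <- function(counts) {
  counts <- as.matrix(counts)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    abort("zero marginal in contingency table")
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  stat <- sum((counts - expected)^2 / expected)
  df <- (nrow(counts) - 1) * (ncol(counts) - 1)
  list(statistic = stat, df = df,
       p_value = pchisq(stat, df, lower.tail = FALSE), expected = expected)
}

#' Pearson correlation with two-tailed t-based p
#'
#' Pairwise-complete observations only; requires >= 3 complete pairs and
#' nonzero variance in both vectors.
#' @param x,y numeric vectors of equal length.
#' @return list with `r`, `p_value`, `n`.
#' @export
pearson_corr <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) abort("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) abort("zero variance in x or y")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = n)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `p_adj_(i) = min_(j >= i) ( p_(j) * m / j )`, capped at 1, returned in
#' the input order.
#' @param p numeric vector of raw p values in (0, 1].
#' @return adjusted p values, same length and order.
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p > 0), all(p <= 1))
  m <- length(p)
  ord <- order(p)
  adj <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  pmax(out, p)   # guard the step-up floor against one-ulp rounding
}

#' Group-comparison table for the cohort's demographic and clinical data
#'
#' For each variable measured in all three groups, a one-way ANOVA (from the
#' raw data); for patient-only variables (illness duration, TEPS scales), a
#' pooled two-sample t between the patient groups; for sex, a Pearson
#' chi-square on the group-by-sex counts. Missing values are dropped
#' listwise per variable.
#'
#' @param subjects subject tibble (columns `group`, `sex`, and the scales).
#' @param patient_groups the two patient group labels.
#' @return tibble: `variable`, per-group `mean`/`sd`/`n` nested in
#'   `summary`, `test` ("anova", "t", "chisq"), `statistic`, `p_value`.
#' @export
summarize_clinical <- function(subjects,
                               patient_groups = c("melancholic",
                                                  "nonmelancholic")) {
  groups <- unique(subjects$group)
  num_vars <- setdiff(names(subjects)[vapply(subjects, is.numeric, TRUE)],
                      c("mean_fd"))
  rows <- purrr::map_dfr(num_vars, function(v) {
    per <- dplyr::summarise(
      dplyr::group_by(subjects, .data$group),
      mean = mean(.data[[v]], na.rm = TRUE),
      sd = sd(.data[[v]], na.rm = TRUE),
      n = sum(!is.na(.data[[v]])), .groups = "drop")
    measured <- per$group[per$n >= 2]
    if (setequal(measured, groups)) {
      res <- anova_from_summary(
        dplyr::rename(per, group = "group")[per$n >= 2, ])
      test <- "anova"
    } else if (setequal(measured, patient_groups)) {
      a <- per[per$group == patient_groups[1], ]
      b <- per[per$group == patient_groups[2], ]
      res <- ttest_from_summary(a$mean, a$sd, a$n, b$mean, b$sd, b$n)
      test <- "t"
    } else {
      return(NULL)
    }
    tibble::tibble(variable = v, test = test, statistic = res$statistic,
                   p_value = res$p_value, summary = list(per))
  })
  if ("sex" %in% names(subjects)) {
    counts <- table(subjects$sex, subjects$group)
    res <- chi_square_table(unclass(counts))
    rows <- dplyr::bind_rows(rows, tibble::tibble(
      variable = "sex", test = "chisq", statistic = res$statistic,
      p_value = res$p_value,
      summary = list(tibble::as_tibble(as.data.frame(counts)))))
  }
  rows
}

#' NH-symptom correlations with Benjamini-Hochberg adjustment
#'
#' Pearson correlation between each cluster's per-subject mean NH and each
#' clinical score within one group. The adjustment family is, per score,
#' the set of clusters tested for that score (step-up over clusters within
#' score).
#'
#' @param cluster_nh tibble with columns `cluster` (id) and `nh`
#'   (list-column of per-subject NH vectors aligned with `subjects`).
#' @param subjects subject tibble of the group being tested.
#' @param scores character vector of score column names.
#' @return tibble of class `nh_correlations`: `cluster`, `score`, `n`, `r`,
#'   `p_raw`, `p_bh`.
#' @export
nh_score_correlations <- function(cluster_nh, subjects, scores) {
  res <- purrr::map_dfr(seq_len(nrow(cluster_nh)), function(i) {
    nh <- cluster_nh$nh[[i]]
    purrr::map_dfr(scores, function(sc) {
      y <- subjects[[sc]]
      ok <- stats::complete.cases(nh, y)
      if (sum(ok) < 3 || sd(y[ok]) == 0)
        return(tibble::tibble(cluster = cluster_nh$cluster[i], score = sc,
                              n = sum(ok), r = NA_real_, p_raw = NA_real_))
      pc <- pearson_corr(nh, y)
      tibble::tibble(cluster = cluster_nh$cluster[i], score = sc, n = pc$n,
                     r = pc$r, p_raw = pc$p_value)
    })
  })
  bh_with_na <- function(p) {
    out <- rep(NA_real_, length(p))
    ok <- !is.na(p)
    if (any(ok)) out[ok] <- bh_adjust(p[ok])
    out
  }
  res <- dplyr::group_by(res, .data$score)
  res <- dplyr::mutate(res, p_bh = bh_with_na(.data$p_raw))
  res <- dplyr::ungroup(res)
  class(res) <- c("nh_correlations", class(res))
  res
}
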