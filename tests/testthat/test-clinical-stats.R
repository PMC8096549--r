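test_that("summary-statistic ANOVA reproduces printed group comparisons", {
  age <- tibble::tibble(group = c("mel", "nonmel", "hc"),
                        mean = c(28.65, 32.04, 29.59),
                        sd = c(5.30, 8.18, 5.00), n = c(31, 28, 32))
  res <- anova_from_summary(age)
  expect_equal(res$statistic, 2.291, tolerance = 0.005)
  expect_equal(res$df, c(2, 88))

  same <- tibble::tibble(group = c("a", "b", "c"), mean = rep(5, 3),
                         sd = rep(1, 3), n = rep(10, 3))
  expect_equal(anova_from_summary(same)$statistic, 0)

  # two-group F equals the square of the pooled t
  two <- tibble::tibble(group = c("a", "b"), mean = c(1, 2),
                        sd = c(1.1, 0.9), n = c(12, 15))
  f2 <- anova_from_summary(two)$statistic
  t2 <- ttest_from_summary(1, 1.1, 12, 2, 0.9, 15)$statistic
  expect_equal(f2, t2^2, tolerance = 1e-10)
})

test_that("summary ANOVA equals a raw-data one-way ANOVA", {
  set.seed(31)
  y <- rnorm(60)
  g <- rep(c("a", "b", "c"), each = 20)
  summaries <- tibble::tibble(
    group = c("a", "b", "c"),
    mean = tapply(y, g, mean), sd = tapply(y, g, sd),
    n = as.numeric(table(g)))
  res <- anova_from_summary(summaries)
  ref <- anova(lm(y ~ g))
  expect_equal(res$statistic, ref["g", "F value"], tolerance = 1e-10)
  expect_equal(res$p_value, ref["g", "Pr(>F)"], tolerance = 1e-10)
  # LSD pairwise t against direct pooled-MSE computation
  mse <- ref["Residuals", "Mean Sq"]
  t_ab <- (mean(y[g == "a"]) - mean(y[g == "b"])) / sqrt(mse * (2 / 20))
  expect_equal(unname(res$pairwise$statistic[1]), t_ab,
               tolerance = 1e-10)
})

test_that("pooled two-sample t from summaries matches raw data and prints", {
  res <- ttest_from_summary(6.75, 4.26, 31, 5.96, 4.64, 28)
  expect_equal(abs(res$statistic), 0.68, tolerance = 0.005 / 0.68)
  expect_equal(res$df, 57)

  set.seed(32)
  a <- rnorm(14); b <- rnorm(17, 0.5)
  ref <- t.test(a, b, var.equal = TRUE)
  res2 <- ttest_from_summary(mean(a), sd(a), 14, mean(b), sd(b), 17)
  expect_equal(res2$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(res2$p_value, ref$p.value, tolerance = 1e-10)

  eq <- ttest_from_summary(3, 1, 10, 3, 1, 10)
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_value, 1)
  expect_error(ttest_from_summary(1, 0, 5, 2, 0, 5), "zero")
})

test_that("chi-square reproduces the printed sex-distribution test", {
  counts <- rbind(male = c(10, 10, 15), female = c(21, 18, 17))
  res <- chi_square_table(counts)
  expect_equal(res$statistic, 1.55, tolerance = 0.005 / 1.55)
  expect_equal(res$p_value, 0.461, tolerance = 0.001 / 0.461)
  expect_equal(res$df, 2)
  ref <- suppressWarnings(chisq.test(counts, correct = FALSE))
  expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-12)

  balanced <- matrix(5, 2, 2)
  res2 <- chi_square_table(balanced)
  expect_equal(res2$statistic, 0)
  expect_equal(res2$p_value, 1)
  expect_error(chi_square_table(rbind(c(0, 0), c(1, 2))), "marginal")
})

test_that("Pearson correlation matches the covariance formula", {
  x <- c(1, 3, 2, 5, 4, 7)
  expect_equal(pearson_corr(x, 2 * x + 1)$r, 1, tolerance = 1e-12)
  expect_equal(pearson_corr(x, -x)$r, -1, tolerance = 1e-12)
  set.seed(33)
  a <- rnorm(29); b <- -0.5 * a + rnorm(29, sd = sqrt(0.75))
  res <- pearson_corr(a, b)
  oracle <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(res$r, oracle, tolerance = 1e-12)
  expect_equal(res$r, -0.5, tolerance = 0.25 / 0.5)
  # pairwise-complete handling
  a[3] <- NA
  expect_equal(pearson_corr(a, b)$n, 28)
  expect_error(pearson_corr(rep(1, 10), rnorm(10)), "variance")
})

test_that("BH step-up adjustment matches its definition and worked values", {
  fam9 <- c(0.005, seq(0.5, 0.98, length.out = 8))
  expect_equal(bh_adjust(fam9)[1], 0.045, tolerance = 1e-12)
  fam9b <- c(0.004, seq(0.5, 0.98, length.out = 8))
  expect_equal(bh_adjust(fam9b)[1], 0.036, tolerance = 1e-12)
  expect_equal(bh_adjust(0.03), 0.03)

  set.seed(34)
  for (i in 1:20) {
    p <- runif(sample(2:12, 1))
    expect_equal(bh_adjust(p), p.adjust(p, "BH"), tolerance = 1e-12)
    expect_true(all(bh_adjust(p) >= p))
  }
  # exhaustive step-up definition on permutations of a 5-element family
  base <- c(0.01, 0.04, 0.2, 0.5, 0.9)
  stepup <- function(p) {
    m <- length(p); ord <- order(p)
    sapply(seq_len(m), function(i) {
      rank_i <- match(i, ord)
      min(1, min(sapply(rank_i:m, function(j) p[ord[j]] * m / j)))
    })
  }
  perms <- list(1:5, 5:1, c(3, 1, 5, 2, 4), c(2, 4, 1, 5, 3))
  for (pp in perms) {
    p <- base[pp]
    expect_equal(bh_adjust(p), stepup(p), tolerance = 1e-12)
  }
})

test_that("cohort clinical tables use the right test per variable", {
  set.seed(35)
  spec <- cohort_spec(n_volumes = 20L, seed = 5L)
  co <- generate_cohort(spec, active = "regions")
  tab <- summarize_clinical(co$table)
  expect_true(all(c("age", "education", "hrsd17", "teps_total", "sex") %in%
                    tab$variable))
  expect_equal(tab$test[tab$variable == "age"], "anova")
  expect_equal(tab$test[tab$variable == "teps_total"], "t")
  expect_equal(tab$test[tab$variable == "sex"], "chisq")
  expect_equal(tab$test[tab$variable == "illness_duration"], "t")
  # anova row equals aov on the raw synthetic data
  ref <- anova(lm(age ~ group, data = co$table))
  expect_equal(tab$statistic[tab$variable == "age"], ref["group", "F value"],
               tolerance = 1e-10)
  # t rows compare the two patient groups only
  pat <- co$table[co$table$group != "control", ]
  reft <- t.test(teps_total ~ group, data = pat, var.equal = TRUE)
  expect_equal(abs(tab$statistic[tab$variable == "teps_total"]),
               abs(unname(reft$statistic)), tolerance = 1e-10)
})

test_that("NH-score correlations adjust within score across clusters", {
  set.seed(36)
  n <- 30
  subjects <- tibble::tibble(s1 = rnorm(n), s2 = c(rnorm(n - 2), NA, NA))
  cl <- tibble::tibble(cluster = c("c1", "c2", "c3"),
                       nh = list(rnorm(n), rnorm(n), rnorm(n)))
  res <- nh_score_correlations(cl, subjects, c("s1", "s2"))
  expect_equal(nrow(res), 6)
  for (sc in c("s1", "s2")) {
    sub <- res[res$score == sc, ]
    expect_equal(sub$p_bh, bh_adjust(sub$p_raw), tolerance = 1e-12)
  }
  expect_true(all(res$p_bh >= res$p_raw))
  expect_equal(unique(res$n[res$score == "s2"]), n - 2)
})
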