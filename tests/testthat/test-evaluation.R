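test_that("ROC AUC equals the exhaustive concordant-pair statistic", {
  s <- c(0.9, 0.8, 0.3, 0.1)
  y <- c(1, 1, 0, 0)
  expect_equal(compute_roc(s, y)$auc, 1.0)
  expect_equal(compute_roc(s, y)$auc, pair_auc(s, y))

  set.seed(17)
  for (rep in 1:20) {
    n <- sample(6:50, 1)
    sc <- round(runif(n), 2)          # rounding forces ties
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    expect_equal(compute_roc(sc, y)$auc, pair_auc(sc, y), tolerance = 1e-12)
  }
  expect_error(compute_roc(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("ROC of label-independent scores is near one half at large n", {
  set.seed(5)
  sc <- runif(4000)
  y <- rbinom(4000, 1, 0.5)
  expect_lt(abs(compute_roc(sc, y)$auc - 0.5), 0.05)
})

test_that("ROC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(23)
  sc <- runif(60)
  y <- rbinom(60, 1, 0.5)
  ref <- as.numeric(pROC::auc(pROC::roc(y, sc, quiet = TRUE,
                                        direction = "<",
                                        levels = c(0, 1))))
  expect_equal(compute_roc(sc, y)$auc, ref, tolerance = 1e-10)
})

test_that("Youden threshold maximizes J and breaks ties toward specificity", {
  roc <- compute_roc(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0))
  pick <- select_optimal_threshold(roc)
  expect_equal(pick$j, 1)
  expect_gt(pick$threshold, 0.2)
  expect_lte(pick$threshold, 0.8)

  expect_warning(
    p0 <- select_optimal_threshold(compute_roc(rep(0.5, 6),
                                               c(1, 0, 1, 0, 1, 0))),
    "degenerate")
  expect_equal(p0$j, 0)

  # never beaten by an exhaustive threshold scan
  set.seed(71)
  for (rep in 1:10) {
    sc <- round(runif(12), 1)
    y <- rbinom(12, 1, 0.5)
    if (length(unique(y)) < 2) next
    roc <- compute_roc(sc, y)
    pick <- suppressWarnings(select_optimal_threshold(roc))
    for (t in c(sc, -Inf, Inf)) {
      pred <- sc >= t
      j <- sum(pred & y == 1) / sum(y == 1) +
           sum(!pred & y == 0) / sum(y == 0) - 1
      expect_lte(j, pick$j + 1e-12)
    }
  }
})

test_that("confusion_from_counts derives the standard screening metrics", {
  cm <- confusion_from_counts(p = 10, tp = 9, n = 90, fp = 5)
  expect_equal(cm$fn, 1)
  expect_equal(cm$tn, 85)
  expect_equal(cm$sensitivity, 0.9)
  expect_equal(cm$accuracy, 94 / 100)
  cm2 <- confusion_from_counts(p = 7, tp = 7, n = 7, fp = 0)
  expect_equal(cm2$accuracy, 1)
  expect_error(confusion_from_counts(5, 6, 10, 0), "exceeds")
  expect_error(confusion_from_counts(5, 2, 10, 11), "exceeds")
})

test_that("micro/macro AUROC match hand-computed one-vs-rest values", {
  # 3-class toy, 6 images
  sc <- rbind(c(.8, .1, .1), c(.6, .3, .1), c(.2, .7, .1),
              c(.1, .8, .1), c(.3, .2, .5), c(.1, .2, .7))
  colnames(sc) <- c("A", "B", "C")
  y <- c("A", "A", "B", "B", "C", "C")
  got <- micro_macro_auroc(sc, y)
  hand <- vapply(colnames(sc), function(k) pair_auc(sc[, k], as.integer(y == k)),
                 numeric(1))
  expect_equal(got$per_class, hand)
  expect_equal(got$macro, mean(hand))
  expect_equal(got$micro,
               pair_auc(as.vector(sc),
                        as.integer(as.vector(outer(y, colnames(sc), "==")))))
  # perfect classifier
  perf <- diag(3); colnames(perf) <- c("A", "B", "C")
  got2 <- micro_macro_auroc(perf, c("A", "B", "C"))
  expect_equal(got2$micro, 1)
  expect_equal(got2$macro, 1)
  # absent class is dropped with a warning
  expect_warning(got3 <- micro_macro_auroc(sc, c("A", "A", "B", "B", "A", "B")),
                 "absent")
  expect_equal(got3$macro, mean(got3$per_class[c("A", "B")]))
})

test_that("Byar CI matches exact Poisson quantile inversion within 2%", {
  expect_equal(byar_poisson_ci(0)[["lower"]], 0)
  for (x in c(5, 10, 20, 50, 100)) {
    got <- byar_poisson_ci(x)
    exact <- c(qgamma(0.025, x), qgamma(0.975, x + 1))
    expect_lt(max(abs(got - exact) / exact), 0.02)
  }
  got10 <- byar_poisson_ci(10)
  expect_equal(got10[["lower"]], 4.79, tolerance = 0.01)
  expect_equal(got10[["upper"]], 18.39, tolerance = 0.001)
  expect_error(byar_poisson_ci(-1), "non-negative")
})

test_that("odds ratio uses Haldane correction only when needed", {
  expect_equal(odds_ratio_with_ci(10, 5, 2, 8)$or, 8.0)
  eq <- odds_ratio_with_ci(6, 3, 10, 5)
  expect_equal(eq$or, 1)
  expect_false(eq$haldane)
  z <- odds_ratio_with_ci(5, 0, 2, 8)
  expect_true(z$haldane)
  expect_true(is.finite(z$or))
  # CI always contains the point estimate
  set.seed(12)
  for (rep in 1:20) {
    cc <- rpois(4, 6)
    r <- odds_ratio_with_ci(cc[1], cc[2], cc[3], cc[4])
    expect_lte(r$lower, r$or)
    expect_gte(r$upper, r$or)
  }
})

test_that("chi-square matches the textbook 2x2 formula", {
  r0 <- chi_square_2x2(c(10, 10, 10, 10))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p, 1)
  tab <- c(20, 10, 10, 20)
  got <- chi_square_2x2(tab)
  n <- sum(tab)
  want <- n * (tab[1] * tab[4] - tab[2] * tab[3])^2 /
    (30 * 30 * 30 * 30)
  expect_equal(got$statistic, want)
  strong <- chi_square_2x2(c(90, 10, 10, 90))
  expect_lt(strong$p, 0.001)
  expect_error(chi_square_2x2(c(0, 0, 5, 5)), "margins")
})

test_that("bootstrap rate CI is seeded, degenerate at the extremes, and
           close to the binomial interval", {
  expect_equal(bootstrap_rate_ci(rep(1, 20), seed = 4),
               c(lower = 1, upper = 1))
  expect_equal(bootstrap_rate_ci(rep(0, 20), seed = 4),
               c(lower = 0, upper = 0))
  flags <- rep(c(0, 1), 200)
  ci <- bootstrap_rate_ci(flags, reps = 1000, seed = 9)
  expect_equal(unname(ci[1]), 0.45, tolerance = 0.02)
  expect_equal(unname(ci[2]), 0.55, tolerance = 0.02)
  expect_true(ci[1] <= 0.5 && 0.5 <= ci[2])
  expect_identical(bootstrap_rate_ci(flags, seed = 9),
                   bootstrap_rate_ci(flags, seed = 9))
})

test_that("median stratification reports groups, OR and chi-square", {
  # scores equal to labels: perfect separation, Haldane-corrected OR
  rec <- data.frame(true_label = rep(c("GLAU", "NORM"), each = 30),
                    GLAU = rep(c(1, 0), each = 30))
  rep1 <- stratify_by_median(rec, "GLAU", seed = 2)
  expect_equal(rep1$high$n, 30)
  expect_equal(rep1$low$events, 0)
  expect_true(rep1$odds_ratio$haldane)
  expect_true(is.finite(rep1$odds_ratio$or))
  expect_lt(rep1$chi_square$p, 0.001)

  # boundary: two records stratify into 1 + 1
  rec2 <- data.frame(true_label = c("GLAU", "NORM"), GLAU = c(0.9, 0.1))
  rep2 <- stratify_by_median(rec2, "GLAU", reps = 50, seed = 1)
  expect_equal(rep2$low$n, 1)
  expect_equal(rep2$high$n, 1)

  expect_error(stratify_by_median(
    data.frame(true_label = c("A", "B"), A = c(.5, .5)), "A"),
    "identical")

  df <- as.data.frame(rep1)
  expect_equal(nrow(df), 2)
  expect_true(all(c("positive_rate", "share_of_positives", "or",
                    "p_value") %in% names(df)))
})

test_that("independent scores give an OR interval covering 1 most of the time", {
  set.seed(33)
  cover <- 0L
  reps <- 40
  for (r in seq_len(reps)) {
    n <- 400
    rec <- data.frame(true_label = ifelse(rbinom(n, 1, 0.3) == 1, "D", "N"),
                      D = runif(n))
    rr <- stratify_by_median(rec, "D", reps = 100, seed = r)
    if (rr$odds_ratio$lower <= 1 && 1 <= rr$odds_ratio$upper) {
      cover <- cover + 1L
    }
  }
  expect_gte(cover / reps, 0.9)
})

test_that("prediction tables survive a CSV round trip", {
  rec <- data.frame(image_id = c("a", "b"), patient_id = c("p1", "p2"),
                    true_label = c("GLAU", "NORM"),
                    GLAU = c(0.9, 0.2), NORM = c(0.1, 0.8),
                    stringsAsFactors = FALSE)
  tf <- withr::local_tempfile(fileext = ".csv")
  write_predictions(rec, tf)
  expect_equal(read_predictions(tf), rec)
})
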