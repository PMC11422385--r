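#' ROC curve of a binary score
#'
#' One operating point per distinct score plus the two endpoints; a sample
#' is called positive when its score is >= the threshold. The area under the
#' curve is computed by the trapezoidal rule and equals the rank
#' (concordant-pair) statistic with ties counted one half.
#'
#' @param scores numeric vector of risk scores.
#' @param labels binary vector (0/1, logical, or two-level factor) with the
#'   positive class coded 1 / `TRUE` / second level.
#' @return Object of class `roc_curve`: list with `thresholds`,
#'   `sensitivity`, `specificity`, `auc`.
#' @export
compute_roc <- function(scores, labels) {
  y <- if (is.factor(labels)) as.integer(labels) - 1L else as.integer(labels)
  stopifnot(length(scores) == length(y))
  if (length(unique(y)) < 2) {
    stop("both classes must be present to compute a ROC curve",
         call. = FALSE)
  }
  np <- sum(y == 1)
  nn <- sum(y == 0)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  sens <- spec <- numeric(length(thr))
  for (k in seq_along(thr)) {
    pred <- scores >= thr[k]
    sens[k] <- sum(pred & y == 1) / np
    spec[k] <- sum(!pred & y == 0) / nn
  }
  fpr <- 1 - spec
  auc <- sum(diff(fpr) * (utils::head(sens, -1) + utils::tail(sens, -1)) / 2)
  structure(list(thresholds = thr, sensitivity = sens, specificity = spec,
                 auc = auc),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> %d operating points, AUC = %.4f\n",
              length(x$thresholds), x$auc))
  invisible(x)
}

#' Youden-optimal operating threshold
#'
#' Picks the threshold maximizing Youden's J = sensitivity + specificity - 1;
#' ties are broken toward higher specificity (fewer false positives, the
#' hospital-mode preference). When every score is identical J = 0 at every
#' point and the degenerate threshold is returned with a warning.
#'
#' @param roc a [compute_roc()] result.
#' @return list with `threshold`, `j`, `sensitivity`, `specificity`.
#' @export
select_optimal_threshold <- function(roc) {
  stopifnot(inherits(roc, "roc_curve"))
  j <- roc$sensitivity + roc$specificity - 1
  best_j <- max(j)
  cand <- which(j >= best_j - 1e-12)
  pick <- cand[which.max(roc$specificity[cand])]
  if (best_j <= 1e-12) {
    warning("degenerate ROC curve: J = 0 at every threshold", call. = FALSE)
  }
  list(threshold = roc$thresholds[pick], j = j[pick],
       sensitivity = roc$sensitivity[pick],
       specificity = roc$specificity[pick])
}

#' 2x2 confusion matrix from positive/negative counts
#'
#' @param p number of truly positive samples.
#' @param tp number of those predicted positive (true positives).
#' @param n number of truly negative samples.
#' @param fp number of those predicted positive (false positives).
#' @return Object of class `confusion_2x2`: counts `tp`, `fp`, `fn`, `tn`
#'   plus derived `sensitivity = tp/(tp+fn)`, `specificity = tn/(tn+fp)`,
#'   `accuracy = (tp+tn)/total`.
#' @export
confusion_from_counts <- function(p, tp, n, fp) {
  if (any(c(p, tp, n, fp) < 0)) stop("counts must be non-negative",
                                     call. = FALSE)
  if (tp > p) stop("tp (", tp, ") exceeds positives (", p, ")", call. = FALSE)
  if (fp > n) stop("fp (", fp, ") exceeds negatives (", n, ")", call. = FALSE)
  fn <- p - tp
  tn <- n - fp
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 sensitivity = tp / p, specificity = tn / n,
                 accuracy = (tp + tn) / (p + n)),
            class = "confusion_2x2")
}

#' @export
print.confusion_2x2 <- function(x, ...) {
  cat(sprintf("<confusion_2x2> tp=%d fp=%d fn=%d tn=%d\n", x$tp, x$fp,
              x$fn, x$tn))
  cat(sprintf("  sensitivity %.4f, specificity %.4f, accuracy %.4f\n",
              x$sensitivity, x$specificity, x$accuracy))
  invisible(x)
}

#' Micro- and macro-averaged one-vs-rest AUROC
#'
#' Macro: unweighted mean of the per-class one-vs-rest AUCs (classes absent
#' from the labels are dropped with a warning). Micro: single AUC over the
#' flattened (class, sample) indicator/score pairs.
#'
#' @param scores numeric matrix, one column per class (named).
#' @param labels vector of class labels matching the column names.
#' @return list with `micro`, `macro`, and `per_class` AUCs.
#' @export
micro_macro_auroc <- function(scores, labels) {
  classes <- colnames(scores)
  stopifnot(!is.null(classes))
  labels <- as.character(labels)
  if (length(unique(labels)) < 2) stop("need >= 2 classes present",
                                       call. = FALSE)
  present <- classes %in% labels
  if (any(!present)) {
    warning("class(es) absent from labels excluded from macro AUROC: ",
            paste(classes[!present], collapse = ", "), call. = FALSE)
  }
  per <- rep(NA_real_, length(classes))
  names(per) <- classes
  for (k in which(present)) {
    per[k] <- compute_roc(scores[, k], labels == classes[k])$auc
  }
  flat_scores <- as.vector(scores)
  flat_y <- as.vector(outer(labels, classes, "=="))
  list(micro = compute_roc(flat_scores, flat_y)$auc,
       macro = mean(per[present]), per_class = per)
}

#' Byar approximate confidence interval for a Poisson count
#'
#' Closed-form approximation to the exact Poisson interval:
#' `lower = x (1 - 1/(9x) - z/(3 sqrt(x)))^3` and
#' `upper = (x+1) (1 - 1/(9(x+1)) + z/(3 sqrt(x+1)))^3`, with `lower = 0`
#' when `x = 0`.
#'
#' @param x non-negative event count.
#' @param level confidence level (default 0.95).
#' @return Numeric vector `c(lower, upper)`.
#' @export
byar_poisson_ci <- function(x, level = 0.95) {
  if (length(x) != 1 || is.na(x) || x < 0) {
    stop("x must be a single non-negative count", call. = FALSE)
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  lower <- if (x == 0) 0 else x * (1 - 1 / (9 * x) - z / (3 * sqrt(x)))^3
  xu <- x + 1
  upper <- xu * (1 - 1 / (9 * xu) + z / (3 * sqrt(xu)))^3
  c(lower = lower, upper = upper)
}

#' Odds ratio with Woolf (log) confidence interval
#'
#' `OR = (a d)/(b c)` from the 2x2 table `[a b; c d]`. When any cell is
#' zero the Haldane correction adds 0.5 to every cell. The interval is
#' `exp(log OR +/- z sqrt(1/a + 1/b + 1/c + 1/d))`.
#'
#' @param a,b,c,d non-negative cell counts (`a`, `b` = exposed
#'   events/non-events; `c`, `d` = unexposed).
#' @param level confidence level.
#' @return list with `or`, `lower`, `upper`, `haldane` (logical).
#' @export
odds_ratio_with_ci <- function(a, b, c, d, level = 0.95) {
  if (any(c(a, b, c, d) < 0)) stop("counts must be non-negative",
                                   call. = FALSE)
  hald <- any(c(a, b, c, d) == 0)
  if (hald) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  or <- (a * d) / (b * c)
  z <- stats::qnorm(1 - (1 - level) / 2)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(or = or, lower = exp(log(or) - z * se), upper = exp(log(or) + z * se),
       haldane = hald)
}

#' Pearson chi-square test on a 2x2 table
#'
#' Pearson statistic without continuity correction; p-value from the
#' chi-square distribution with 1 degree of freedom.
#'
#' @param tab 2x2 matrix (or vector `c(a, b, c, d)` filled by row).
#' @return list with `statistic`, `p`.
#' @export
chi_square_2x2 <- function(tab) {
  if (!is.matrix(tab)) tab <- matrix(tab, 2, 2, byrow = TRUE)
  if (any(tab < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("all table margins must be positive", call. = FALSE)
  }
  ht <- stats::chisq.test(tab, correct = FALSE)
  list(statistic = unname(ht$statistic), p = ht$p.value)
}

#' Percentile bootstrap confidence interval for a positive rate
#'
#' @param flags 0/1 (or logical) event indicators.
#' @param reps number of resamplings with replacement (default 1000).
#' @param seed RNG seed; the interval is reproducible per seed.
#' @param level confidence level.
#' @return Numeric `c(lower, upper)` - the (2.5, 97.5) percentile interval
#'   of the resampled rates at the default level.
#' @export
bootstrap_rate_ci <- function(flags, reps = 1000L, seed = 1L, level = 0.95) {
  flags <- as.integer(flags)
  n <- length(flags)
  if (n < 1) stop("need at least one observation", call. = FALSE)
  set.seed(seed)
  rates <- vapply(seq_len(reps),
                  function(i) mean(flags[sample.int(n, n, replace = TRUE)]),
                  numeric(1))
  alpha <- (1 - level) / 2
  q <- stats::quantile(rates, c(alpha, 1 - alpha), names = FALSE, type = 7)
  c(lower = q[1], upper = q[2])
}

#' Median-split risk stratification report
#'
#' Splits a prediction table at the median risk score for `disease`
#' (low: score < median; high: score >= median - ties go to the high-risk
#' group) and reports, per group: size, positive events, the within-group
#' positive rate and the share of all positive events captured by the group
#' (both readings, labelled), a 1000-rep bootstrap CI of the within-group
#' rate, a Byar CI of the event count, plus the high-vs-low odds ratio with
#' Woolf CI and the Pearson chi-square test of the 2x2 group-by-outcome
#' table.
#'
#' @param records data.frame with columns `true_label` and one score column
#'   per class (see [predict_proba()]).
#' @param disease class name: its score column is the risk score and
#'   `true_label == disease` is the positive outcome.
#' @param reps,seed bootstrap parameters.
#' @return Object of class `risk_strata_report`.
#' @export
stratify_by_median <- function(records, disease, reps = 1000L, seed = 1L) {
  stopifnot(is.data.frame(records), disease %in% names(records),
            "true_label" %in% names(records))
  score <- records[[disease]]
  if (length(unique(score)) < 2) {
    stop("cannot stratify: all risk scores are identical", call. = FALSE)
  }
  med <- stats::median(score)
  high <- score >= med
  if (all(high) || all(!high)) {
    # all-ties-on-one-side guard: put strictly-below-median cases low
    high <- score > med
    if (all(high) || all(!high)) {
      stop("cannot stratify: median split produces an empty group",
           call. = FALSE)
    }
  }
  event <- records$true_label == disease
  grp <- function(sel, seed_off) {
    ev <- sum(event[sel])
    list(n = sum(sel), events = ev,
         rate_within = ev / sum(sel),
         rate_share_of_positives = if (sum(event) > 0) ev / sum(event)
                                   else NA_real_,
         rate_ci = bootstrap_rate_ci(event[sel], reps = reps,
                                     seed = seed + seed_off),
         events_ci = byar_poisson_ci(ev))
  }
  lo <- grp(!high, 0L)
  hi <- grp(high, 1L)
  or <- odds_ratio_with_ci(hi$events, hi$n - hi$events,
                           lo$events, lo$n - lo$events)
  tab <- matrix(c(hi$events, hi$n - hi$events,
                  lo$events, lo$n - lo$events), 2, 2, byrow = TRUE)
  chi <- chi_square_2x2(tab)
  structure(list(disease = disease, median_threshold = med,
                 low = lo, high = hi, odds_ratio = or,
                 chi_square = chi),
            class = "risk_strata_report")
}

#' @export
print.risk_strata_report <- function(x, ...) {
  cat(sprintf("<risk_strata_report> %s, median threshold %.4f\n",
              x$disease, x$median_threshold))
  for (g in c("low", "high")) {
    s <- x[[g]]
    cat(sprintf("  %-4s n=%d events=%d rate=%.3f (%.3f, %.3f)\n", g, s$n,
                s$events, s$rate_within, s$rate_ci[1], s$rate_ci[2]))
  }
  cat(sprintf("  OR %.2f (%.2f, %.2f), chi-square %.2f, p %s\n",
              x$odds_ratio$or, x$odds_ratio$lower, x$odds_ratio$upper,
              x$chi_square$statistic, format.pval(x$chi_square$p)))
  invisible(x)
}

#' Flatten a risk stratification report to a one-row-per-group data.frame
#' @param x a `risk_strata_report`.
#' @return data.frame shaped like a risk-stratified summary table.
#' @export
as.data.frame.risk_strata_report <- function(x, ...) {
  row <- function(gname, g, or, chi) {
    data.frame(disease = x$disease, group = gname, n = g$n,
               positive_events = g$events,
               positive_rate = g$rate_within,
               rate_ci_lower = g$rate_ci[1], rate_ci_upper = g$rate_ci[2],
               share_of_positives = g$rate_share_of_positives,
               events_ci_lower = g$events_ci[1],
               events_ci_upper = g$events_ci[2],
               or = or[1], or_lower = or[2], or_upper = or[3],
               chi_square = chi[1], p_value = chi[2],
               stringsAsFactors = FALSE)
  }
  rbind(row("low", x$low, c(NA, NA, NA), c(NA, NA)),
        row("high", x$high,
            c(x$odds_ratio$or, x$odds_ratio$lower, x$odds_ratio$upper),
            c(x$chi_square$statistic, x$chi_square$p)))
}

#' Read / write prediction tables
#'
#' Prediction tables are CSV files with columns `image_id`, `patient_id`,
#' `true_label`, and one score column per class.
#'
#' @param records prediction data.frame.
#' @param path CSV path.
#' @return `read_predictions` returns the data.frame.
#' @export
write_predictions <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_predictions
#' @export
read_predictions <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
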