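# Absolute-error metrics and the evaluation harness.
#
# AE = |estimate - truth|; MAE = mean(AE); MRE% = mean(AE / truth) * 100.
# The relative error is taken with absolute values per term: every published
# value of the percent MRE is non-negative, and the manual start-frame figure
# is only reproducible with |.| applied inside the sum, so the signed reading
# of the formula is rejected.

#' Absolute error
#'
#' @param estimate,truth numeric scalars or vectors (recycled).
#' @return `|estimate - truth|`.
#' @export
absolute_error <- function(estimate, truth) abs(estimate - truth)

#' Mean absolute error
#'
#' @param estimates,truths equal-length numeric vectors, length >= 1.
#' @return Scalar MAE.
#' @export
mean_absolute_error <- function(estimates, truths) {
  if (length(estimates) != length(truths)) stop("length mismatch")
  if (!length(estimates)) stop("empty series")
  mean(abs(estimates - truths))
}

#' Percent mean relative error
#'
#' @param estimates,truths equal-length numeric vectors; every truth must be
#'   non-zero (a zero truth makes the relative error undefined and raises an
#'   error rather than being skipped).
#' @return Scalar MRE in percent.
#' @export
mean_relative_error_percent <- function(estimates, truths) {
  if (length(estimates) != length(truths)) stop("length mismatch")
  if (!length(estimates)) stop("empty series")
  if (any(truths == 0)) stop("zero truth value: relative error undefined")
  mean(abs(estimates - truths) / abs(truths)) * 100
}

#' Per-item error summary
#'
#' @param estimates,truths equal-length numeric vectors.
#' @return A list of class `metrics_result`: `ae` (per-item absolute
#'   errors), `mae`, `mre_percent`, `n`.
#' @export
error_metrics <- function(estimates, truths) {
  structure(list(ae = absolute_error(estimates, truths),
                 mae = mean_absolute_error(estimates, truths),
                 mre_percent = mean_relative_error_percent(estimates, truths),
                 n = length(estimates)),
            class = "metrics_result")
}

#' @export
print.metrics_result <- function(x, ...) {
  cat(sprintf("n = %d, MAE = %.3f, MRE = %.3f%%\n", x$n, x$mae,
              x$mre_percent))
  invisible(x)
}

# collapse a possibly multi-segment SetParam table to one row per test:
# first SF, last EF
collapse_sessions <- function(st) {
  tests <- unique(st$test_number)
  data.frame(test_number = tests,
             sf = vapply(tests, function(t)
               min(as.numeric(st$sf[st$test_number == t])), numeric(1)),
             ef = vapply(tests, function(t)
               max(as.numeric(st$ef[st$test_number == t])), numeric(1)))
}

#' Score SF/EF tables and action counts against ground truth
#'
#' Produces the performance summary of the automatic (and optionally
#' manual) start/end-frame estimates and of the detected action counts:
#' one row per quantity (SFA, EFA, SFM, EFM, ACT) with its MAE and percent
#' MRE, aligned to the ground truth by test number.
#'
#' @param setparam_auto [session_table()] (or data.frame with
#'   `test_number`, `sf`, `ef`) from the automatic detector; multi-segment
#'   tests are collapsed to first SF / last EF.
#' @param ground_truth annotations data.frame (`test_number`, `sf_gt`,
#'   `ef_gt`, and `actions_gt` when `actions` is given).
#' @param setparam_manual optional manually set table, same layout as
#'   `setparam_auto`.
#' @param actions optional data.frame with `test_number` and `detected`
#'   action counts.
#' @return A `data.frame` of class `intake_report`: `metric`, `mae`,
#'   `mre_percent`, `n`.
#' @export
evaluate_tables <- function(setparam_auto, ground_truth,
                            setparam_manual = NULL, actions = NULL) {
  gt <- ground_truth
  align <- function(d, what) {
    missing <- setdiff(gt$test_number, d$test_number)
    extra <- setdiff(d$test_number, gt$test_number)
    if (length(missing) || length(extra))
      stop(what, ": unmatched test numbers: ",
           paste(c(missing, extra), collapse = ", "))
    d[match(gt$test_number, d$test_number), , drop = FALSE]
  }
  auto <- align(collapse_sessions(setparam_auto), "automatic table")
  rows <- list(
    data.frame(metric = "SFA",
               mae = mean_absolute_error(auto$sf, gt$sf_gt),
               mre_percent = mean_relative_error_percent(auto$sf, gt$sf_gt),
               n = nrow(gt)),
    data.frame(metric = "EFA",
               mae = mean_absolute_error(auto$ef, gt$ef_gt),
               mre_percent = mean_relative_error_percent(auto$ef, gt$ef_gt),
               n = nrow(gt)))
  if (!is.null(setparam_manual)) {
    man <- align(collapse_sessions(setparam_manual), "manual table")
    rows <- c(rows, list(
      data.frame(metric = "SFM",
                 mae = mean_absolute_error(man$sf, gt$sf_gt),
                 mre_percent = mean_relative_error_percent(man$sf, gt$sf_gt),
                 n = nrow(gt)),
      data.frame(metric = "EFM",
                 mae = mean_absolute_error(man$ef, gt$ef_gt),
                 mre_percent = mean_relative_error_percent(man$ef, gt$ef_gt),
                 n = nrow(gt))))
  }
  if (!is.null(actions)) {
    act <- align(actions, "action counts")
    rows <- c(rows, list(
      data.frame(metric = "ACT",
                 mae = mean_absolute_error(act$detected, gt$actions_gt),
                 mre_percent = mean_relative_error_percent(act$detected,
                                                          gt$actions_gt),
                 n = nrow(gt))))
  }
  out <- do.call(rbind, rows)
  class(out) <- c("intake_report", "data.frame")
  out
}

#' @export
print.intake_report <- function(x, ...) {
  d <- as.data.frame(x)
  d$mae <- sprintf("%.3f", d$mae)
  d$mre_percent <- sprintf("%.3f%%", d$mre_percent)
  print(d, row.names = FALSE)
  invisible(x)
}

#' Evaluate the packaged per-test fixtures
#'
#' Loads the packaged 33-test fixtures (automatic and manual SF/EF, detected
#' action counts, ground truth) and computes the full metric report.
#'
#' @return An `intake_report` with rows SFA, EFA, SFM, EFM, ACT.
#' @export
evaluate_fixtures <- function() {
  t3 <- read.csv(mealscan_fixture("table3"))
  t7 <- read.csv(mealscan_fixture("table7"))
  gt <- data.frame(test_number = t3$test_number, sf_gt = t3$sf_gt,
                   ef_gt = t3$ef_gt, actions_gt = t7$agt)
  evaluate_tables(
    setparam_auto = data.frame(test_number = t3$test_number,
                               sf = t3$sf_auto, ef = t3$ef_auto),
    ground_truth = gt,
    setparam_manual = data.frame(test_number = t3$test_number,
                                 sf = t3$sf_manual, ef = t3$ef_manual),
    actions = data.frame(test_number = t7$test_number, detected = t7$nad))
}
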