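#' Screening metrics at a decision threshold
#'
#' Computes the confusion matrix and screening proportions for predicted
#' CD probabilities against binary labels. A probability at or above the
#' threshold is called CD (positive). With a single-class input the
#' undefined proportions are returned as `NA` and flagged, never silently 0.
#'
#' @param probability Predicted probabilities in \[0, 1\].
#' @param label True labels, 0 (CN) or 1 (CD).
#' @param threshold Decision cutoff (default 0.5; ties resolve to CD).
#' @return A list of class `screen_eval`: `tp`, `fp`, `tn`, `fn`,
#'   `accuracy`, `sensitivity`, `specificity`, `threshold`, plus
#'   `undefined` naming any metric that could not be computed.
#' @examples
#' fx <- screening_test_fixture()
#' evaluate_screening(fx$probability, fx$label)
#' @export
evaluate_screening <- function(probability, label, threshold = 0.5) {
  check_pairs(probability, label, require_both = FALSE)
  pred <- probability >= threshold
  tp <- sum(pred & label == 1); fn <- sum(!pred & label == 1)
  tn <- sum(!pred & label == 0); fp <- sum(pred & label == 0)
  undefined <- character(0)
  sens <- if (tp + fn > 0) tp / (tp + fn) else { undefined <- c(undefined, "sensitivity"); NA_real_ }
  spec <- if (tn + fp > 0) tn / (tn + fp) else { undefined <- c(undefined, "specificity"); NA_real_ }
  if (length(undefined))
    warnf("evaluate_screening: only one class present; %s undefined",
          paste(undefined, collapse = ", "))
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 accuracy = (tp + tn) / length(label),
                 sensitivity = sens, specificity = spec,
                 threshold = threshold, undefined = undefined),
            class = "screen_eval")
}

#' @export
print.screen_eval <- function(x, ...) {
  cat(sprintf("Screening evaluation at threshold %.2f (n = %d)\n",
              x$threshold, x$tp + x$fp + x$tn + x$fn))
  cat(sprintf("  TP %d  FP %d  TN %d  FN %d\n", x$tp, x$fp, x$tn, x$fn))
  cat(sprintf("  accuracy %.3f  sensitivity %s  specificity %s\n", x$accuracy,
              format3(x$sensitivity), format3(x$specificity)))
  invisible(x)
}

format3 <- function(v) if (is.na(v)) "NA" else sprintf("%.3f", v)

check_pairs <- function(probability, label, require_both = TRUE) {
  if (length(probability) != length(label))
    stopf("probability and label lengths differ (%d vs %d)", length(probability), length(label))
  if (!length(label)) stopf("no (probability, label) pairs supplied")
  if (!all(label %in% c(0, 1))) stopf("labels must be 0 (CN) or 1 (CD)")
  if (any(probability < 0 | probability > 1)) stopf("probabilities must lie in [0, 1]")
  if (require_both) {
    if (!any(label == 1)) stopf("no positive (CD) examples present")
    if (!any(label == 0)) stopf("no negative (CN) examples present")
  }
  invisible(TRUE)
}

#' ROC curve and concordance AUC
#'
#' The AUC is computed by pairwise concordance: the fraction of
#' (CD, CN) pairs in which the CD member scores strictly higher, counting
#' ties as 1/2 — evaluated exactly through midranks. The ROC curve is
#' traced by sweeping every distinct probability as a cutoff (decision by
#' the >= rule); it starts at (0, 0), ends at (1, 1) and both coordinates
#' are non-decreasing. The trapezoidal area under this curve equals the
#' concordance AUC when no ties exist and is kept as a cross-check.
#'
#' @inheritParams evaluate_screening
#' @return A list of class `screen_roc`: `auc`, `roc` (data frame of
#'   `threshold`, `fpr`, `tpr`) and `auc_trapezoid`.
#' @export
roc_auc <- function(probability, label) {
  check_pairs(probability, label, require_both = TRUE)
  n_pos <- sum(label == 1); n_neg <- sum(label == 0)
  r <- rank(probability)                       # midranks handle ties exactly
  auc <- (sum(r[label == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  cuts <- sort(unique(probability), decreasing = TRUE)
  tpr <- vapply(cuts, function(ct) sum(probability >= ct & label == 1) / n_pos, numeric(1))
  fpr <- vapply(cuts, function(ct) sum(probability >= ct & label == 0) / n_neg, numeric(1))
  roc <- data.frame(threshold = c(Inf, cuts), fpr = c(0, fpr), tpr = c(0, tpr))
  if (roc$fpr[nrow(roc)] < 1 || roc$tpr[nrow(roc)] < 1)
    roc <- rbind(roc, data.frame(threshold = -Inf, fpr = 1, tpr = 1))
  auc_trap <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
  structure(list(auc = auc, roc = roc, auc_trapezoid = auc_trap), class = "screen_roc")
}

#' @export
print.screen_roc <- function(x, ...) {
  cat(sprintf("ROC with %d operating points; concordance AUC %.3f\n", nrow(x$roc), x$auc))
  invisible(x)
}

#' Published 20-subject discrimination test fixture
#'
#' The complete per-subject output of the reported discrimination test on
#' 20 held-out one-minute conversations: clinical diagnosis, MMSE score,
#' MMSE-derived label (1 = CD for MMSE <= 23) and the classifier's CD
#' probability. Twelve subjects are CN (SCD or MCI) and eight CD (AD, DLB
#' or VaD). Evaluating this fixture at the 0.5 threshold reproduces the
#' published screening metrics exactly: accuracy 0.950, sensitivity 0.875,
#' specificity 1.000 and AUC 0.990.
#'
#' @return A data frame with columns `no`, `diagnosis`, `mmse`, `label`,
#'   `probability`.
#' @examples
#' fx <- screening_test_fixture()
#' evaluate_screening(fx$probability, fx$label)
#' roc_auc(fx$probability, fx$label)$auc
#' @export
screening_test_fixture <- function() {
  path <- system.file("extdata", "screening_test.csv", package = "vocog", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(identical(df$label, label_from_mmse(df$mmse)))
  df
}
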