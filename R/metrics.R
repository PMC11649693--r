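#' Confusion counts for trial-level detection
#'
#' @param tp True positives (perturbed trials with at least one recovery
#'   call).
#' @param fp False positives (unperturbed trials with a recovery call).
#' @param tn True negatives.
#' @param fn False negatives.
#' @return A list of class `confusion_counts` with the four counts plus the
#'   totals `P = tp + fn` and `N = tn + fp`.
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("confusion counts must be non-negative integers", call. = FALSE)
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 P = tp + fn, N = tn + fp),
            class = "confusion_counts")
}

#' Classification performance statistics
#'
#' Standard quality criteria of binary classification at trial level:
#' sensitivity `tp / P`, specificity `tn / N`, positive predictive value
#' `tp / (tp + fp)`, its prevalence extrapolation via Bayes' theorem, and
#' the F1 score (harmonic mean of PPV and sensitivity). All return
#' fractions in `[0, 1]`.
#'
#' @param cc A [confusion_counts].
#' @return A fraction in `[0, 1]`.
#' @examples
#' cc <- confusion_counts(tp = 179, fp = 7, tn = 441, fn = 0)
#' sensitivity(cc); specificity(cc); ppv(cc)
#' @export
sensitivity <- function(cc) {
  if (cc$P <= 0) stop("sensitivity undefined: no positive trials", call. = FALSE)
  cc$tp / cc$P
}

#' @rdname sensitivity
#' @export
specificity <- function(cc) {
  if (cc$N <= 0) stop("specificity undefined: no negative trials", call. = FALSE)
  cc$tn / cc$N
}

#' @rdname sensitivity
#' @export
ppv <- function(cc) {
  if (cc$tp + cc$fp <= 0)
    stop("positive predictive value undefined: no positive predictions",
         call. = FALSE)
  cc$tp / (cc$tp + cc$fp)
}

#' @rdname sensitivity
#' @param sens,spec Sensitivity and specificity in `[0, 1]`.
#' @param prev Prevalence in `[0, 1]`: the perturbed share of all trials in
#'   the target population.
#' @export
ppv_from_prevalence <- function(sens, spec, prev) {
  if (any(c(sens, spec, prev) < 0) || any(c(sens, spec, prev) > 1))
    stop("sensitivity, specificity and prevalence must lie in [0, 1]",
         call. = FALSE)
  denom <- sens * prev + (1 - spec) * (1 - prev)
  if (denom <= 0)
    stop("positive predictive value undefined: zero positive probability",
         call. = FALSE)
  sens * prev / denom
}

#' @rdname sensitivity
#' @param p Positive predictive value in `[0, 1]`.
#' @export
f1 <- function(p, sens) {
  if (p + sens <= 0) stop("F1 undefined: ppv + sensitivity is zero", call. = FALSE)
  2 * p * sens / (p + sens)
}

#' Evaluate trial-level predictions against labels
#'
#' A trial counts as predicted positive when it received at least one
#' recovery call; extra recovery calls within a perturbed trial are
#' reported separately (`extra_events`) but counted once at trial level.
#' Prevalence is reported as the perturbed share of all trials.
#'
#' @param predictions Data frame with columns `trial` (identifier) and
#'   `n_recovery` (number of recovery calls in that trial); alternatively a
#'   logical vector of per-trial positivity aligned with `labels`.
#' @param labels Data frame with columns `trial` and `perturbed` (logical),
#'   or a logical vector.
#' @return A list of class `detection_metrics`: the [confusion_counts], all
#'   metrics, `prevalence`, and `extra_events`.
#' @export
evaluate_detection <- function(predictions, labels) {
  if (is.logical(labels)) labels <- data.frame(trial = seq_along(labels),
                                               perturbed = labels)
  if (is.logical(predictions))
    predictions <- data.frame(trial = labels$trial,
                              n_recovery = as.integer(predictions))
  if (!all(c("trial", "perturbed") %in% names(labels)))
    stop("labels need columns `trial` and `perturbed`", call. = FALSE)
  if (!all(c("trial", "n_recovery") %in% names(predictions)))
    stop("predictions need columns `trial` and `n_recovery`", call. = FALSE)
  if (nrow(predictions) != nrow(labels) ||
      !setequal(predictions$trial, labels$trial))
    stop("invalid input: predictions and labels must cover the same trials",
         call. = FALSE)
  m <- match(labels$trial, predictions$trial)
  pos <- predictions$n_recovery[m] > 0
  lab <- as.logical(labels$perturbed)
  cc <- confusion_counts(tp = sum(pos & lab), fp = sum(pos & !lab),
                         tn = sum(!pos & !lab), fn = sum(!pos & lab))
  extra <- sum(pmax(predictions$n_recovery[m][lab] - 1L, 0L))
  sens <- sensitivity(cc)
  spec <- specificity(cc)
  p <- if (cc$tp + cc$fp > 0) ppv(cc) else NA_real_
  structure(list(counts = cc, sensitivity = sens, specificity = spec,
                 ppv = p,
                 f1 = if (!is.na(p) && p + sens > 0) f1(p, sens) else NA_real_,
                 prevalence = cc$P / (cc$P + cc$N),
                 extra_events = extra),
            class = "detection_metrics")
}

#' @export
print.detection_metrics <- function(x, ...) {
  cc <- x$counts
  cat(sprintf("<detection_metrics> tp %d fp %d tn %d fn %d\n",
              cc$tp, cc$fp, cc$tn, cc$fn))
  cat(sprintf("  sensitivity %.3f  specificity %.3f  ppv %s  f1 %s  prevalence %.3f\n",
              x$sensitivity, x$specificity,
              ifelse(is.na(x$ppv), "NA", sprintf("%.3f", x$ppv)),
              ifelse(is.na(x$f1), "NA", sprintf("%.3f", x$f1)),
              x$prevalence))
  invisible(x)
}

#' Prevalence sweep of the positive predictive value
#'
#' Extrapolates the PPV over a prevalence grid via Bayes' theorem,
#' quantifying how quickly a detector's positive calls lose credibility as
#' near-falls become rarer than in a controlled study.
#'
#' @param sens,spec Sensitivity and specificity in `[0, 1]`.
#' @param prevalences Numeric vector of prevalences (default 1-50%).
#' @return Data frame with columns `prevalence` and `ppv`.
#' @export
ppv_prevalence_sweep <- function(sens, spec, prevalences = seq(0.01, 0.5, 0.01)) {
  data.frame(prevalence = prevalences,
             ppv = vapply(prevalences, function(p)
               ppv_from_prevalence(sens, spec, p), numeric(1)))
}
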