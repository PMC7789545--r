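#' Per-class confusion counts for single-label predictions
#'
#' @param gold gold-standard labels
#' @param pred predicted labels (same length)
#' @param classes label universe (default: union of observed labels)
#' @return data.frame with one row per class: tp, fp, fn, tn
#' @export
confusion_counts <- function(gold, pred, classes = sort(unique(c(as.character(gold), as.character(pred))))) {
  gold <- as.character(gold); pred <- as.character(pred)
  stopifnot(length(gold) == length(pred))
  n <- length(gold)
  rows <- lapply(classes, function(cl) {
    tp <- sum(gold == cl & pred == cl)
    fp <- sum(gold != cl & pred == cl)
    fn <- sum(gold == cl & pred != cl)
    data.frame(class = cl, tp = tp, fp = fp, fn = fn, tn = n - tp - fp - fn,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Precision, recall and F-measure from confusion counts
#'
#' Precision = TP/(TP+FP), Recall = TP/(TP+FN),
#' F = 2TP/(2TP+FP+FN). Computed in exact arithmetic and optionally rounded.
#' A zero denominator yields NaN with a warning.
#'
#' @param tp,fp,fn nonnegative integer counts (vectorized)
#' @param digits rounding for the returned values; NULL for full precision
#' @return data.frame with columns precision, recall, f_measure
#' @export
prf <- function(tp, fp, fn, digits = 3) {
  stopifnot(all(tp >= 0), all(fp >= 0), all(fn >= 0))
  if (any(tp + fp == 0) || any(tp + fn == 0))
    warning("zero denominator: metric undefined (NaN)")
  p <- ifelse(tp + fp == 0, NaN, tp / (tp + fp))
  r <- ifelse(tp + fn == 0, NaN, tp / (tp + fn))
  f <- ifelse(2 * tp + fp + fn == 0, NaN, 2 * tp / (2 * tp + fp + fn))
  out <- data.frame(precision = p, recall = r, f_measure = f)
  if (!is.null(digits)) out[] <- lapply(out, round, digits = digits)
  out
}

#' Full evaluation table for a labeled prediction set
#'
#' Per-class precision/recall/F plus two overall aggregates: micro (pooled
#' counts; equals accuracy for single-label predictions) and support-weighted
#' macro.
#'
#' @inheritParams confusion_counts
#' @param digits rounding (default 3)
#' @return list with \code{per_class} data.frame (class, support, precision,
#'   recall, f_measure) and \code{overall} data.frame (rows micro, weighted)
#' @export
prf_table <- function(gold, pred, classes = sort(unique(c(as.character(gold), as.character(pred)))), digits = 3) {
  cc <- confusion_counts(gold, pred, classes)
  per <- cbind(class = cc$class,
               support = cc$tp + cc$fn,
               suppressWarnings(prf(cc$tp, cc$fp, cc$fn, digits = digits)))
  micro <- prf(sum(cc$tp), sum(cc$fp), sum(cc$fn), digits = NULL)
  w <- per$support / sum(per$support)
  full <- suppressWarnings(prf(cc$tp, cc$fp, cc$fn, digits = NULL))
  weighted <- data.frame(precision = sum(w * full$precision, na.rm = TRUE),
                         recall = sum(w * full$recall, na.rm = TRUE),
                         f_measure = sum(w * full$f_measure, na.rm = TRUE))
  overall <- rbind(micro = micro, weighted = weighted)
  if (!is.null(digits)) overall[] <- lapply(overall, round, digits = digits)
  list(per_class = per, overall = overall)
}

#' Cohen's kappa for inter-rater agreement
#'
#' Unweighted kappa for nominal labels:
#' \deqn{\kappa = (p_o - p_e)/(1 - p_e)}
#' with expected agreement \eqn{p_e} from the raters' marginal label
#' frequencies. When both raters use a single identical label (\eqn{p_e = 1})
#' kappa is returned as 1 by convention, with a warning.
#'
#' @param labels_a,labels_b equal-length label vectors from the two raters
#' @return kappa (scalar)
#' @export
cohens_kappa <- function(labels_a, labels_b) {
  a <- as.character(labels_a); b <- as.character(labels_b)
  stopifnot(length(a) == length(b), length(a) >= 1)
  n <- length(a)
  p_o <- mean(a == b)
  lv <- union(a, b)
  pa <- table(factor(a, lv)) / n
  pb <- table(factor(b, lv)) / n
  p_e <- sum(pa * pb)
  if (p_e >= 1) {
    warning("both raters constant and equal: kappa = 1 by convention")
    return(1)
  }
  (p_o - p_e) / (1 - p_e)
}
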