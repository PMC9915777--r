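# Threshold calibration on labeled variants: confusion-matrix machinery
# at ddG/CADD threshold pairs and the PPV-targeted CADD search. The
# calibration convention is positives = P only and negatives = B only;
# LB, LP and VUS records never enter the calibration set (overridable via
# the positive_label/negative_label arguments).

#' A ddG/CADD threshold pair
#'
#' At least one of the two thresholds must be given. `direction` selects
#' which tail of the ddG distribution is called: `"destabilizing"` calls
#' `ddg_fold > ddg_threshold`, `"overstabilizing"` calls
#' `ddg_fold < -|ddg_threshold|`. Both comparisons are strict, as is the
#' CADD comparison `cadd > cadd_threshold`; equality is a negative call.
#'
#' @param ddg_threshold ddG threshold in kcal/mol, or NULL to ignore ddG.
#' @param cadd_threshold CADD threshold, or NULL to ignore CADD.
#' @param direction `"destabilizing"` (default) or `"overstabilizing"`.
#' @return List of class `"threshold_pair"`.
#' @export
threshold_pair <- function(ddg_threshold = NULL, cadd_threshold = NULL,
                           direction = c("destabilizing",
                                         "overstabilizing")) {
  direction <- match.arg(direction)
  if (is.null(ddg_threshold) && is.null(cadd_threshold)) {
    stop("at least one of ddg_threshold and cadd_threshold is required")
  }
  if (!is.null(ddg_threshold)) stopifnot(is.finite(ddg_threshold))
  if (!is.null(cadd_threshold)) stopifnot(is.finite(cadd_threshold))
  structure(list(ddg_threshold = ddg_threshold,
                 cadd_threshold = cadd_threshold,
                 direction = direction),
            class = "threshold_pair")
}

# TRUE where a record has every score the threshold pair requires.
score_complete <- function(records, thresholds) {
  ok <- rep(TRUE, nrow(records))
  if (!is.null(thresholds$ddg_threshold)) ok <- ok & !is.na(records$ddg_fold)
  if (!is.null(thresholds$cadd_threshold)) ok <- ok & !is.na(records$cadd)
  ok
}

#' Call variants at a threshold pair
#'
#' Vectorized positive/negative call: in the destabilizing direction a
#' record is positive iff `ddg_fold > ddg_threshold` and (when a CADD
#' threshold is set) `cadd > cadd_threshold`; in the overstabilizing
#' direction the ddG conjunct is `ddg_fold < -|ddg_threshold|`.
#' Inequalities are strict. Records missing a required score are an
#' error: exclude them upstream (see [score_complete()] callers such as
#' [confusion_at()]) rather than treating them as negative.
#'
#' @param records A variant table.
#' @param thresholds A [threshold_pair()].
#' @return Logical vector, one call per record.
#' @export
classify_call <- function(records, thresholds) {
  stopifnot(inherits(thresholds, "threshold_pair"))
  if (!all(score_complete(records, thresholds))) {
    stop("records missing a required score; exclude them before calling")
  }
  call <- rep(TRUE, nrow(records))
  if (!is.null(thresholds$ddg_threshold)) {
    call <- if (thresholds$direction == "destabilizing") {
      call & records$ddg_fold > thresholds$ddg_threshold
    } else {
      call & records$ddg_fold < -abs(thresholds$ddg_threshold)
    }
  }
  if (!is.null(thresholds$cadd_threshold)) {
    call <- call & records$cadd > thresholds$cadd_threshold
  }
  call
}

#' Confusion matrix at a threshold pair
#'
#' Restricts to records carrying the positive or negative label and
#' having every required score, calls them with [classify_call()], and
#' tabulates TP/FP/TN/FN with the derived rates: PPV = TP/(TP+FP)
#' (NA when nothing is called positive), specificity = TN/(TN+FP),
#' sensitivity = TP/(TP+FN).
#'
#' @param records A variant table.
#' @param thresholds A [threshold_pair()].
#' @param positive_label Label counted as positive (default `"P"`).
#' @param negative_label Label counted as negative (default `"B"`).
#' @return List of class `"confusion_summary"` with `tp`, `fp`, `tn`,
#'   `fn`, `ppv`, `specificity`, `sensitivity`, `n_called`,
#'   `n_excluded_missing`.
#' @export
confusion_at <- function(records, thresholds,
                         positive_label = "P", negative_label = "B") {
  stopifnot(inherits(thresholds, "threshold_pair"))
  lab <- records$classification
  in_set <- lab %in% c(positive_label, negative_label)
  complete <- score_complete(records, thresholds)
  n_excluded <- sum(in_set & !complete)
  use <- records[in_set & complete, , drop = FALSE]
  if (nrow(use) == 0) stop("no score-complete records with the two labels")
  pos <- use$classification == positive_label
  call <- classify_call(use, thresholds)
  tp <- sum(call & pos); fp <- sum(call & !pos)
  fn <- sum(!call & pos); tn <- sum(!call & !pos)
  if (fp + tn == 0) stop("no negative-label records; specificity undefined")
  structure(list(
    tp = tp, fp = fp, tn = tn, fn = fn,
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    specificity = tn / (tn + fp),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    n_called = tp + fp,
    n_excluded_missing = n_excluded
  ), class = "confusion_summary")
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat(sprintf("confusion: tp=%d fp=%d tn=%d fn=%d\n", x$tp, x$fp, x$tn,
              x$fn))
  cat(sprintf("  ppv=%.3f specificity=%.3f sensitivity=%.3f (n called %d)\n",
              x$ppv, x$specificity, x$sensitivity, x$n_called))
  invisible(x)
}

#' Smallest CADD threshold reaching a target PPV
#'
#' Searches the observed CADD values (the candidate grid is the sorted
#' distinct CADD scores of the score-complete calibration records) for
#' the smallest threshold c such that the joint rule
#' `ddg_fold > ddg_threshold & cadd > c` attains PPV >= `target_ppv` on
#' the labeled records. Comparisons use unrounded PPV values.
#'
#' @param records A variant table.
#' @param ddg_threshold The fixed ddG threshold, kcal/mol.
#' @param target_ppv Target positive predictive value in (0, 1).
#' @param positive_label,negative_label Calibration labels (defaults P/B).
#' @return The threshold, with attributes `ppv` (the PPV attained) and
#'   `summary` (its [confusion_at()] result). Errors with the best
#'   attainable PPV when no candidate reaches the target.
#' @export
find_cadd_threshold <- function(records, ddg_threshold, target_ppv,
                                positive_label = "P",
                                negative_label = "B") {
  stopifnot(target_ppv > 0, target_ppv < 1)
  base <- threshold_pair(ddg_threshold = ddg_threshold, cadd_threshold = 0)
  lab <- records$classification
  use <- records[lab %in% c(positive_label, negative_label) &
                   score_complete(records, base), , drop = FALSE]
  if (nrow(use) == 0) stop("no score-complete records with the two labels")
  candidates <- sort(unique(use$cadd))
  pos <- use$classification == positive_label
  pass_ddg <- use$ddg_fold > ddg_threshold
  best_ppv <- -Inf
  for (c in candidates) {
    call <- pass_ddg & use$cadd > c
    tp <- sum(call & pos); fp <- sum(call & !pos)
    if (tp + fp == 0) next
    ppv <- tp / (tp + fp)
    if (ppv > best_ppv) best_ppv <- ppv
    if (ppv >= target_ppv) {
      summ <- confusion_at(records,
                           threshold_pair(ddg_threshold, c),
                           positive_label, negative_label)
      return(structure(c, ppv = ppv, summary = summ))
    }
  }
  stop(sprintf(
    "target PPV %.3f unachievable; best attainable PPV is %.3f",
    target_ppv, best_ppv))
}

#' PPV curve over a grid of threshold pairs
#'
#' Evaluates [confusion_at()] at each grid point and returns one row per
#' point, in grid order.
#'
#' @param records A variant table.
#' @param thresholds_grid List of [threshold_pair()] objects.
#' @param positive_label,negative_label Calibration labels (defaults P/B).
#' @return data.frame with columns `ddg_threshold`, `cadd_threshold`,
#'   `direction`, `tp`, `fp`, `tn`, `fn`, `ppv`, `specificity`,
#'   `sensitivity`, `n_called`.
#' @export
ppv_curve <- function(records, thresholds_grid,
                      positive_label = "P", negative_label = "B") {
  stopifnot(length(thresholds_grid) > 0)
  rows <- lapply(thresholds_grid, function(th) {
    s <- confusion_at(records, th, positive_label, negative_label)
    data.frame(
      ddg_threshold = ifelse(is.null(th$ddg_threshold), NA_real_,
                             th$ddg_threshold),
      cadd_threshold = ifelse(is.null(th$cadd_threshold), NA_real_,
                              th$cadd_threshold),
      direction = th$direction,
      tp = s$tp, fp = s$fp, tn = s$tn, fn = s$fn,
      ppv = s$ppv, specificity = s$specificity,
      sensitivity = s$sensitivity, n_called = s$n_called,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
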