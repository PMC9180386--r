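# Epoch-level evaluation: confusion counts under an explicit positive
# class, and the four derived metrics used throughout the pipeline.

#' Epoch-level confusion counts
#'
#' Compares per-epoch binary predictions with reference labels, restricted
#' to usable epochs, under a declared positive class. Both series encode
#' sleep = 1 / awake = 0 (or event = 1 / no-event = 0); the positive class
#' determines which value counts as positive: `"sleep"` and `"event"` take
#' 1, `"awake"` takes 0. Results always carry their convention, because
#' sensitivity/specificity swap when the positive class flips.
#'
#' @param pred Integer 0/1 predictions.
#' @param truth Integer 0/1 reference labels, same length.
#' @param usable Optional logical mask of evaluable epochs.
#' @param positive_class `"sleep"`, `"awake"`, or `"event"`.
#' @return Object of class `psg_confusion` with fields `tp`, `tn`, `fp`,
#'   `fn`, `n`, `positive_class`.
#' @export
confusion <- function(pred, truth, usable = NULL,
                      positive_class = c("sleep", "awake", "event")) {
  positive_class <- match.arg(positive_class)
  if (length(pred) != length(truth)) {
    abort(sprintf("pred (%d) and truth (%d) differ in length.",
                  length(pred), length(truth)))
  }
  pred <- as.integer(pred); truth <- as.integer(truth)
  if (!is.null(usable)) {
    if (length(usable) != length(pred)) abort("usable mask has wrong length.")
    pred <- pred[usable]; truth <- truth[usable]
  }
  pos <- if (positive_class == "awake") 0L else 1L
  structure(
    list(
      tp = sum(pred == pos & truth == pos),
      tn = sum(pred != pos & truth != pos),
      fp = sum(pred == pos & truth != pos),
      fn = sum(pred != pos & truth == pos),
      n = length(pred),
      positive_class = positive_class
    ),
    class = "psg_confusion"
  )
}

#' @export
print.psg_confusion <- function(x, ...) {
  cat(sprintf(
    "<psg_confusion> positive = %s | tp %d  fn %d  fp %d  tn %d (n = %d)\n",
    x$positive_class, x$tp, x$fn, x$fp, x$tn, x$n))
  invisible(x)
}

#' Sensitivity: TP / (TP + FN)
#' @param c A `psg_confusion`.
#' @return Fraction in [0, 1]; `NA` with a warning when the denominator is
#'   zero (undefined, not 0).
#' @export
sensitivity <- function(c) {
  if (c$tp + c$fn == 0) {
    warn("Sensitivity undefined: no positive reference epochs.")
    return(NA_real_)
  }
  c$tp / (c$tp + c$fn)
}

#' Specificity: TN / (TN + FP)
#' @inheritParams sensitivity
#' @return Fraction in [0, 1]; `NA` with a warning on a zero denominator.
#' @export
specificity <- function(c) {
  if (c$tn + c$fp == 0) {
    warn("Specificity undefined: no negative reference epochs.")
    return(NA_real_)
  }
  c$tn / (c$tn + c$fp)
}

#' Success rate: (TP + TN) / evaluated epochs
#' @inheritParams sensitivity
#' @export
success_rate <- function(c) {
  if (c$n == 0) abort("No evaluated epochs.")
  (c$tp + c$tn) / c$n
}

#' False-positive-based accuracy: (N - FP) / N
#'
#' The accuracy figure used for threshold-capped staging: the fraction of
#' epochs not erroneously scored positive.
#' @inheritParams sensitivity
#' @export
fp_accuracy <- function(c) {
  if (c$n == 0) abort("No evaluated epochs.")
  (c$n - c$fp) / c$n
}

#' @rdname confusion
#' @param x A `psg_confusion`.
#' @param ... Unused.
#' @method tidy psg_confusion
#' @export
tidy.psg_confusion <- function(x, ...) {
  tibble(tp = x$tp, tn = x$tn, fp = x$fp, fn = x$fn, n = x$n,
         positive_class = x$positive_class)
}

#' @rdname confusion
#' @method glance psg_confusion
#' @export
glance.psg_confusion <- function(x, ...) {
  tibble(
    sensitivity = suppressWarnings(sensitivity(x)),
    specificity = suppressWarnings(specificity(x)),
    success_rate = success_rate(x),
    fp_accuracy = fp_accuracy(x),
    n = x$n,
    positive_class = x$positive_class
  )
}

#' Epoch-level confusion for respiratory event detection
#'
#' Maps a reference event list onto epochs (an epoch is event-positive when
#' any qualifying event overlaps it), restricts both sides to the event
#' types compared -- by default obstructive apneas and hypopneas --
#' excludes unusable epochs, and counts an epoch-level confusion matrix
#' with `event` as the positive class.
#'
#' @param pred_flags Tibble of predicted per-epoch binaries with columns
#'   `epoch_index`, `obstructive_apnea`, `central_apnea`, `hypopnea`
#'   (as returned by [score_record()]).
#' @param expert_events Tibble of reference events (`onset_sec`,
#'   `duration_sec`, `type`, ...).
#' @param grid The record's [epoch_grid()] (supplies the usable mask).
#' @param types Event types entering the comparison.
#' @return A `psg_confusion` with `positive_class = "event"`.
#' @export
event_confusion <- function(pred_flags, expert_events, grid,
                            types = c("obstructive_apnea", "hypopnea")) {
  stopifnot(inherits(grid, "psg_epoch_grid"))
  n <- grid$n_epochs
  truth <- integer(n)
  ev <- expert_events[expert_events$type %in% types, , drop = FALSE]
  if (nrow(ev) > 0) {
    for (i in seq_len(nrow(ev))) {
      first <- floor(ev$onset_sec[i] / grid$epoch_sec)
      last <- floor((ev$onset_sec[i] + ev$duration_sec[i] - 1e-9) / grid$epoch_sec)
      span <- seq(max(0, first), min(n - 1, last))
      truth[span + 1L] <- 1L
    }
  }
  cols <- intersect(types, names(pred_flags))
  if (length(cols) == 0) abort("pred_flags has no column matching the compared event types.")
  pred <- as.integer(Reduce(`|`, lapply(cols, function(cl) pred_flags[[cl]] == 1)))
  if (length(pred) != n) abort("pred_flags length does not match the epoch grid.")
  confusion(pred, truth, usable = grid$usable, positive_class = "event")
}
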