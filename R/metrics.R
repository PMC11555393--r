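#' @title Classification metrics
#' @description
#' Confusion-matrix bookkeeping and the five derived metrics used for
#' benign/malignant patch classification: accuracy, F1, precision,
#' sensitivity (true-positive rate on malignant/nodule patches) and
#' specificity (true-negative rate on benign patches), all reported as
#' percentages.
#' @name metrics
NULL

#' Metrics from confusion counts
#'
#' The positive class is malignant/nodule (label 1).  Ratios with a zero
#' denominator are reported as `NA` ("undefined"), never coerced to 0.
#'
#' @param tp,fp,tn,fn confusion counts (non-negative; total > 0).
#' @return An object of class `mifnet_metrics`: a list with `confusion`
#'   (named counts) and `acc`, `f1`, `prec`, `sens`, `spec` as
#'   percentages in `[0, 100]` (or `NA` when undefined).
#' @examples
#' m <- metrics_from_confusion(90, 10, 40, 10)
#' m$acc   # 86.666...
#' @export
metrics_from_confusion <- function(tp, fp, tn, fn) {
  counts <- c(tp = as.numeric(tp)[1], fp = as.numeric(fp)[1],
              tn = as.numeric(tn)[1], fn = as.numeric(fn)[1])
  tp <- counts[["tp"]]; fp <- counts[["fp"]]
  tn <- counts[["tn"]]; fn <- counts[["fn"]]
  if (any(counts < 0)) stop("confusion counts must be >= 0", call. = FALSE)
  total <- sum(counts)
  if (total == 0) stop("confusion error: no evaluated samples", call. = FALSE)
  ratio <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  prec <- ratio(tp, tp + fp)
  sens <- ratio(tp, tp + fn)
  f1 <- if (is.na(prec) || is.na(sens) || (prec + sens) == 0) NA_real_
        else 2 * prec * sens / (prec + sens)
  structure(list(confusion = counts,
                 acc = 100 * (tp + tn) / total,
                 f1 = f1, prec = prec, sens = sens,
                 spec = ratio(tn, tn + fp)),
            class = "mifnet_metrics")
}

#' @export
print.mifnet_metrics <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undef." else sprintf("%.2f%%", v)
  cat("confusion:  tp", x$confusion["tp"], " fp", x$confusion["fp"],
      " tn", x$confusion["tn"], " fn", x$confusion["fn"], "\n")
  cat(sprintf("Acc %s  F1 %s  Prec %s  Sens %s  Spec %s\n",
              fmt(x$acc), fmt(x$f1), fmt(x$prec), fmt(x$sens), fmt(x$spec)))
  invisible(x)
}

#' Evaluate a trained network on a labelled patch set
#'
#' Predictions are the argmax of the class probabilities; an exact tie
#' goes to the positive (malignant) class.  Returns the confusion
#' counts, the five metrics, and a per-sample prediction table (label,
#' predicted label, confidence = the winning probability) for
#' visualisation.
#'
#' @param network a trained `mifnet_network` (or a [train()] fit).
#' @param test_set a list with `images` and binary `labels`.
#' @param chunk_size forward-pass batch size (memory knob; default 64).
#' @return A `mifnet_metrics` object with an additional `predictions`
#'   data frame.
#' @export
evaluate <- function(network, test_set, chunk_size = 64L) {
  if (inherits(network, "mifnet_fit")) network <- network$network
  stopifnot(inherits(network, "mifnet_network"))
  cfg <- network$graph$config
  ds <- as_dataset(test_set, cfg$input_size)
  n <- length(ds$labels)
  pred <- integer(n); conf <- numeric(n); ppos <- numeric(n)
  for (start in seq(1L, n, by = chunk_size)) {
    idx <- start:min(start + chunk_size - 1L, n)
    probs <- forward(network, ds$x[, , , idx, drop = FALSE])
    p1 <- probs[, 2]
    pred[idx] <- as.integer(p1 >= probs[, 1])   # tie -> positive class
    conf[idx] <- pmax(probs[, 1], p1)
    ppos[idx] <- p1
  }
  lab <- ds$labels
  m <- metrics_from_confusion(tp = sum(pred == 1L & lab == 1L),
                              fp = sum(pred == 1L & lab == 0L),
                              tn = sum(pred == 0L & lab == 0L),
                              fn = sum(pred == 0L & lab == 1L))
  m$predictions <- data.frame(label = lab, predicted = pred,
                              confidence = conf, prob_positive = ppos)
  m
}
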