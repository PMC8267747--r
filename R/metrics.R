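#' Confusion matrix from labels and predictions
#'
#' Counts true positives, true negatives, false positives and false
#' negatives for 0/1 vectors (1 = binder = positive class).
#'
#' @param labels observed 0/1 labels
#' @param preds predicted 0/1 classes
#' @return object of class `confusion` with integer fields `TP`, `TN`,
#'   `FP`, `FN`
#' @examples
#' confusion(c(1, 1, 0, 0), c(1, 0, 0, 1))
#' @export
confusion <- function(labels, preds) {
  labels <- as.integer(labels)
  preds <- as.integer(preds)
  if (length(labels) != length(preds)) {
    stop("labels and predictions differ in length", call. = FALSE)
  }
  if (length(labels) == 0L) stop("empty inputs", call. = FALSE)
  if (anyNA(labels) || anyNA(preds) ||
      !all(labels %in% 0:1) || !all(preds %in% 0:1)) {
    stop("labels and predictions must be 0/1", call. = FALSE)
  }
  confusion_counts(TP = sum(labels == 1L & preds == 1L),
                   TN = sum(labels == 0L & preds == 0L),
                   FP = sum(labels == 0L & preds == 1L),
                   FN = sum(labels == 1L & preds == 0L))
}

#' @rdname confusion
#' @param TP,TN,FP,FN non-negative counts, e.g. transcribed from a
#'   published table
#' @export
confusion_counts <- function(TP, TN, FP, FN) {
  v <- c(TP = TP, TN = TN, FP = FP, FN = FN)
  if (anyNA(v) || any(v < 0) || any(v != round(v))) {
    stop("confusion counts must be non-negative integers", call. = FALSE)
  }
  if (sum(v) == 0) stop("confusion matrix is empty", call. = FALSE)
  structure(as.list(v), class = "confusion")
}

#' @export
print.confusion <- function(x, ...) {
  m <- matrix(c(x$TP, x$FN, x$FP, x$TN), 2, 2,
              dimnames = list(observed = c("binder", "non-binder"),
                              predicted = c("binder", "non-binder")))
  print(m)
  invisible(x)
}

#' Performance statistics for unbalanced binary classification
#'
#' Computes from a confusion matrix the full suite used to judge binding
#' classifiers on strongly unbalanced screens:
#' specificity SP = TN/(TN+FP), sensitivity SE = TP/(TP+FN), accuracy
#' Acc = (TP+TN)/n, Matthews correlation coefficient
#' \deqn{MCC = \frac{TP \cdot TN - FP \cdot FN}
#'   {\sqrt{(TN+FN)(TN+FP)(TP+FN)(TP+FP)}}}
#' positive and negative predictive values PPV = TP/(TP+FP),
#' NPV = TN/(TN+FN), likelihood ratios +LR = SE/(1-SP),
#' -LR = (1-SE)/SP, and the balanced classification rate
#' \deqn{BCR = \frac{SE+SP}{2}\,(1 - |SE - SP|)}
#' which rewards models whose sensitivity and specificity are balanced.
#'
#' SP, SE, Acc, PPV and NPV are reported in percent (0-100); SE and SP
#' enter the likelihood ratios and BCR as fractions, and BCR/MCC are on
#' their natural 0-1 / -1..1 scales. Degenerate denominators follow fixed
#' conventions: a zero factor under the MCC root gives MCC = 0 with
#' `mcc_degenerate = TRUE`; +LR at SP = 100% is `Inf`; PPV (NPV) with no
#' positive (negative) predictions is `NA`.
#'
#' @param cm a [confusion()] object
#' @return one-row data frame: TP, TN, FP, FN, SP, SE, Acc, MCC, NPV,
#'   PPV, plusLR, minusLR, BCR, mcc_degenerate
#' @examples
#' metrics_from_confusion(confusion_counts(75, 1469, 11, 130))
#' @export
metrics_from_confusion <- function(cm) {
  stopifnot(inherits(cm, "confusion"))
  # counts as doubles: the MCC denominator product overflows integers
  TP <- as.numeric(cm$TP); TN <- as.numeric(cm$TN)
  FP <- as.numeric(cm$FP); FN <- as.numeric(cm$FN)
  n <- TP + TN + FP + FN
  if ((TP + FN) == 0 || (TN + FP) == 0) {
    stop("confusion matrix has an empty class; metrics undefined",
         call. = FALSE)
  }
  sp <- TN / (TN + FP)
  se <- TP / (TP + FN)
  acc <- (TP + TN) / n
  mcc_den <- (TN + FN) * (TN + FP) * (TP + FN) * (TP + FP)
  mcc_degenerate <- mcc_den == 0
  mcc <- if (mcc_degenerate) 0 else (TP * TN - FP * FN) / sqrt(mcc_den)
  ppv <- if ((TP + FP) == 0) NA_real_ else TP / (TP + FP)
  npv <- if ((TN + FN) == 0) NA_real_ else TN / (TN + FN)
  plus_lr <- if (sp == 1) Inf else se / (1 - sp)
  minus_lr <- (1 - se) / sp
  bcr <- (se + sp) / 2 * (1 - abs(se - sp))
  data.frame(TP = TP, TN = TN, FP = FP, FN = FN,
             SP = 100 * sp, SE = 100 * se, Acc = 100 * acc, MCC = mcc,
             NPV = 100 * npv, PPV = 100 * ppv,
             plusLR = plus_lr, minusLR = minus_lr, BCR = bcr,
             mcc_degenerate = mcc_degenerate)
}

#' Rank-based ROC AUC
#'
#' Area under the ROC curve computed as the Mann-Whitney U statistic with
#' midrank tie handling: the probability that a random positive outranks a
#' random negative, ties counting one half. Midranks matter here because
#' docking-score data carry a heavy tie at the sentinel value 0.
#' `orientation = "lower"` (the default) treats more-negative scores as
#' more binder-like, matching docking energies.
#'
#' @param scores numeric scores
#' @param labels 0/1 labels (1 = positive)
#' @param orientation `"lower"` if small scores indicate positives,
#'   `"higher"` otherwise
#' @return AUC in \[0, 1\]
#' @export
roc_auc <- function(scores, labels, orientation = c("lower", "higher")) {
  orientation <- match.arg(orientation)
  scores <- as.numeric(scores)
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) {
    stop("scores and labels differ in length", call. = FALSE)
  }
  if (anyNA(scores) || anyNA(labels) || !all(labels %in% 0:1)) {
    stop("scores must be non-missing and labels 0/1", call. = FALSE)
  }
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop("both classes must be present to compute AUC", call. = FALSE)
  }
  if (orientation == "lower") scores <- -scores
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
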