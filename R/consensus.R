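#' Fit the consensus androgen-receptor binding classifier
#'
#' Fits, on one labelled training set, every component model used by the
#' thirteen classification procedures:
#' \itemize{
#'   \item the class-conditional Gaussian ("naive Bayesian") model of
#'     docking scores ([fit_gaussian_classes()], sentinel 0 scores
#'     excluded from the fit);
#'   \item the reference fingerprint panels of known binders and
#'     non-binders, used for average Tanimoto distances;
#'   \item the logistic regressions, fitted by maximum likelihood on the
#'     training descriptors: on the Bayesian density ratio (procedure 3),
#'     on docking score and fingerprint-distance difference (8), with the
#'     density ratio added (11), on the distance averages and the two
#'     class densities (12), and the final five-descriptor consensus
#'     model (13).
#' }
#'
#' Training descriptors use leave-self-out panel distances: a training
#' compound's own fingerprint is excluded when averaging distances to its
#' own class, since the zero self-distance would bias the average low.
#'
#' @param data data frame with columns `id`, `dock_score` (kcal/mol, 0 =
#'   no docking pose) and `label` (0/1, 1 = binder)
#' @param fingerprints 0/1 matrix, row names covering every `data$id`
#' @param dock_threshold classification threshold on the docking score,
#'   kcal/mol (scores <= threshold are binder-like); must be negative
#' @param exclude_zero exclude sentinel 0 scores when fitting the
#'   Gaussians?
#' @param leave_self_out exclude each training compound from its own
#'   panel average?
#' @param use_reference use the packaged [compara_model()] coefficients
#'   for procedure 13 instead of refitting on `data`?
#' @param tol,max_iter logistic-fit controls, see [fit_logistic()]
#' @return object of class `ar_consensus`
#' @seealso [predict.ar_consensus()], [summary.ar_consensus()],
#'   [run_suite()]
#' @examples
#' d <- simulate_dataset(synth_config(n_active = 30, n_inactive = 80,
#'                                    fp_length = 64), seed = 7)
#' fit <- ar_consensus(d$data, d$fingerprints)
#' fit
#' @export
ar_consensus <- function(data, fingerprints,
                         dock_threshold = -7,
                         exclude_zero = TRUE,
                         leave_self_out = TRUE,
                         use_reference = FALSE,
                         tol = 1e-8, max_iter = 100L) {
  if (inherits(data, "ar_dataset")) {
    fingerprints <- data$fingerprints
    data <- data$data
  }
  data <- validate_dataset(data, require_label = TRUE)
  fingerprints <- as_fingerprint_matrix(fingerprints)
  if (is.null(rownames(fingerprints))) {
    stop("fingerprint matrix must carry compound ids as row names",
         call. = FALSE)
  }
  missing_fp <- setdiff(data$id, rownames(fingerprints))
  if (length(missing_fp)) {
    stop("no fingerprint for id(s): ",
         paste(utils::head(missing_fp, 5L), collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(dock_threshold) || dock_threshold >= 0) {
    stop("'dock_threshold' must be a negative docking score", call. = FALSE)
  }
  fp <- fingerprints[data$id, , drop = FALSE]
  act <- data$label == 1L
  if (sum(act) < 2L || sum(!act) < 2L) {
    stop("each class needs at least 2 compounds", call. = FALSE)
  }

  gauss <- fit_gaussian_classes(data$dock_score[act], data$dock_score[!act],
                                exclude_zero = exclude_zero)
  object <- structure(
    list(gauss = gauss,
         panel_act = fp[act, , drop = FALSE],
         panel_inact = fp[!act, , drop = FALSE],
         config = list(dock_threshold = dock_threshold,
                       exclude_zero = exclude_zero,
                       leave_self_out = leave_self_out,
                       use_reference = use_reference,
                       tol = tol, max_iter = max_iter),
         models = list()),
    class = "ar_consensus")

  desc <- compute_descriptors(data$dock_score, fp, object,
                              self_class = if (leave_self_out) data$label else NULL)
  y <- data$label
  object$models <- list(
    m3 = fit_logistic(desc[, "bayes_ratio", drop = FALSE], y,
                      tol = tol, max_iter = max_iter),
    m8 = fit_logistic(desc[, c("ChimpDockScore", "dDiff")], y,
                      tol = tol, max_iter = max_iter),
    m11 = fit_logistic(desc[, c("ChimpDockScore", "dDiff", "bayes_ratio")], y,
                       tol = tol, max_iter = max_iter),
    m12 = fit_logistic(desc[, c("avgD_Act", "avgD_Inact",
                                "P_Act_dockChimp", "P_Inact")], y,
                       tol = tol, max_iter = max_iter),
    m13 = if (use_reference) compara_model() else
      fit_logistic(desc[, c("ChimpDockScore", "avgD_Act", "avgD_Inact",
                            "P_Act_dockChimp", "P_Inact")], y,
                    tol = tol, max_iter = max_iter))
  object$train <- list(data = data, descriptors = desc)
  object$n <- nrow(data)
  object
}

validate_dataset <- function(data, require_label = FALSE) {
  data <- as.data.frame(data)
  need <- c("id", "dock_score", if (require_label) "label")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop("dataset is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(data$id)) {
    stop("duplicate compound id(s): ",
         paste(utils::head(unique(data$id[duplicated(data$id)]), 5L),
               collapse = ", "), call. = FALSE)
  }
  data$dock_score <- as.numeric(data$dock_score)
  if (anyNA(data$dock_score)) {
    warning("missing docking scores treated as the no-pose sentinel 0",
            call. = FALSE)
    data$dock_score[is.na(data$dock_score)] <- 0
  }
  if ("label" %in% names(data) && !all(is.na(data$label))) {
    data$label <- as.integer(data$label)
    if (anyNA(data$label) || !all(data$label %in% 0:1)) {
      stop("labels must be 0/1", call. = FALSE)
    }
  } else if (require_label) {
    stop("dataset has no usable 'label' column", call. = FALSE)
  }
  data
}

# The five consensus descriptors plus the two derived features the
# intermediate logistic procedures use. `self_class` (0/1 per row) marks
# rows that are themselves panel members, so the average distance to
# their own class leaves them out (their self-distance is exactly 0,
# hence the exclusion is a denominator correction).
compute_descriptors <- function(scores, fp, object, self_class = NULL) {
  n_act <- nrow(object$panel_act)
  n_inact <- nrow(object$panel_inact)
  d_act_sum <- rowSums(1 - tanimoto_matrix(fp, object$panel_act))
  d_inact_sum <- rowSums(1 - tanimoto_matrix(fp, object$panel_inact))
  div_act <- rep(n_act, nrow(fp))
  div_inact <- rep(n_inact, nrow(fp))
  if (!is.null(self_class)) {
    if (any(self_class == 1L) && n_act < 2L || any(self_class == 0L) && n_inact < 2L) {
      stop("leave-self-out needs panels with more than one member", call. = FALSE)
    }
    div_act[self_class == 1L] <- n_act - 1L
    div_inact[self_class == 0L] <- n_inact - 1L
  }
  avgD_Act <- d_act_sum / div_act
  avgD_Inact <- d_inact_sum / div_inact
  p_act <- gaussian_density(scores, object$gauss$mu_act, object$gauss$sigma_act)
  p_inact <- gaussian_density(scores, object$gauss$mu_inact, object$gauss$sigma_inact)
  data.frame(ChimpDockScore = scores,
             avgD_Act = avgD_Act, avgD_Inact = avgD_Inact,
             P_Act_dockChimp = p_act, P_Inact = p_inact,
             dDiff = avgD_Act - avgD_Inact,
             bayes_ratio = p_act / p_inact)
}

procedure_descriptions <- c(
  "Docking score threshold",
  "Bayesian on scores",
  "Logistic regression on Bayesian",
  "Modified Bayesian (zeroes non-binding)",
  "Fingerprints (ECFP distances)",
  "Docking scores then fingerprints",
  "Fingerprints then docking scores",
  "Logistic regr. on docking scores and fingerprints",
  "Consensus docking and fingerprints else 8",
  "Consensus Bayesian and fingerprints else 8",
  "Logistic regr. on docking scores, fingerprints and Bayesian ratio",
  "Logistic regr. on Bayesian averages and fingerprints",
  "Logistic regr. on docking scores, Bayesian averages and fingerprints")

# All 13 procedure classifications for a descriptor frame.
# Returns list(class = n x 13 integer matrix, prob = n x 13 numeric matrix
# with probabilities where the deciding model is a logistic one).
classify_all_procedures <- function(object, desc) {
  s <- desc$ChimpDockScore
  thr <- object$config$dock_threshold
  n <- nrow(desc)
  cls <- matrix(NA_integer_, n, 13L)
  prob <- matrix(NA_real_, n, 13L)

  cls[, 1L] <- as.integer(s <= thr)                 # threshold; 0 stays above
  cls[, 2L] <- classify_bayes(s, object$gauss)$class
  prob[, 3L] <- predict_prob(object$models$m3, desc)
  cls[, 3L] <- as.integer(prob[, 3L] >= 0.5)
  cls[, 4L] <- ifelse(s == 0, 0L, cls[, 2L])
  cls[, 5L] <- as.integer(desc$avgD_Act < desc$avgD_Inact)
  cls[, 6L] <- ifelse(s != 0, cls[, 1L], cls[, 5L])
  cls[, 7L] <- ifelse(cls[, 5L] == 1L, 1L, cls[, 1L])
  prob[, 8L] <- predict_prob(object$models$m8, desc)
  cls[, 8L] <- as.integer(prob[, 8L] >= 0.5)
  unresolved <- s == 0 & abs(desc$avgD_Act - desc$avgD_Inact) < 1e-12
  cls[, 9L] <- ifelse(unresolved, cls[, 8L], cls[, 6L])
  cls[, 10L] <- ifelse(cls[, 2L] == cls[, 5L], cls[, 2L], cls[, 8L])
  prob[, 11L] <- predict_prob(object$models$m11, desc)
  cls[, 11L] <- as.integer(prob[, 11L] >= 0.5)
  prob[, 12L] <- predict_prob(object$models$m12, desc)
  cls[, 12L] <- as.integer(prob[, 12L] >= 0.5)
  prob[, 13L] <- predict_prob(object$models$m13, desc)
  cls[, 13L] <- as.integer(prob[, 13L] >= 0.5)
  list(class = cls, prob = prob)
}

#' Classify compounds with a fitted consensus model
#'
#' Applies one of the thirteen classification procedures to new compounds
#' (or, with `newdata = NULL`, to the training set with leave-self-out
#' panel distances). The procedures are:
#' \enumerate{
#'   \item docking score <= threshold is a binder (the sentinel 0 is
#'     always a non-binder);
#'   \item Gaussian class-density comparison on the raw score;
#'   \item univariate logistic regression on the Bayesian density ratio;
#'   \item as 2, but sentinel 0 scores are forced non-binder;
#'   \item binder when the average fingerprint distance to known binders
#'     is smaller than to known non-binders;
#'   \item procedure 1 for non-zero scores, procedure 5 for the zeros;
#'   \item procedure 5 first; its non-binders are re-decided by 1;
#'   \item logistic regression on docking score and the distance
#'     difference avgD_Act - avgD_Inact;
#'   \item procedure 6, with compounds still unresolved (zero score and
#'     tied distances) sent to 8;
#'   \item if 2 and 5 agree take that class, otherwise 8;
#'   \item logistic regression on score, distance difference and density
#'     ratio;
#'   \item logistic regression on the two distance averages and the two
#'     class densities;
#'   \item the five-descriptor consensus logistic model.
#' }
#'
#' @param object an [ar_consensus()] fit
#' @param newdata data frame with `id` and `dock_score`, or `NULL` for
#'   the training set
#' @param fingerprints fingerprint matrix for `newdata` ids (ignored when
#'   `newdata` is `NULL`)
#' @param procedure procedure number 1-13, or `"all"` for every procedure
#' @param type `"class"` for 0/1 classes, `"prob"` to also return the
#'   deciding logistic probability where the procedure has one
#' @param ... unused
#' @return for one procedure: integer 0/1 vector (or, with
#'   `type = "prob"`, data frame `id`, `procedure`, `probability`,
#'   `class`); for `"all"`: matrix or long data frame over procedures
#' @export
predict.ar_consensus <- function(object, newdata = NULL, fingerprints = NULL,
                                 procedure = 13L, type = c("class", "prob"),
                                 ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    desc <- object$train$descriptors
    ids <- object$train$data$id
  } else {
    if (inherits(newdata, "ar_dataset")) {
      fingerprints <- newdata$fingerprints
      newdata <- newdata$data
    }
    newdata <- validate_dataset(newdata)
    if (is.null(fingerprints)) {
      stop("'fingerprints' are required with 'newdata'", call. = FALSE)
    }
    fingerprints <- as_fingerprint_matrix(fingerprints)
    missing_fp <- setdiff(newdata$id, rownames(fingerprints))
    if (length(missing_fp)) {
      stop("no fingerprint for id(s): ",
           paste(utils::head(missing_fp, 5L), collapse = ", "), call. = FALSE)
    }
    desc <- compute_descriptors(newdata$dock_score,
                                fingerprints[newdata$id, , drop = FALSE],
                                object)
    ids <- newdata$id
  }
  res <- classify_all_procedures(object, desc)
  if (identical(procedure, "all")) {
    if (type == "class") {
      colnames(res$class) <- paste0("procedure_", 1:13)
      rownames(res$class) <- ids
      return(res$class)
    }
    return(do.call(rbind, lapply(1:13, function(p) {
      data.frame(id = ids, procedure = p,
                 probability = res$prob[, p], class = res$class[, p],
                 stringsAsFactors = FALSE)
    })))
  }
  procedure <- as.integer(procedure)
  if (is.na(procedure) || procedure < 1L || procedure > 13L) {
    stop("unknown procedure: must be 1..13 or \"all\"", call. = FALSE)
  }
  if (type == "class") return(stats::setNames(res$class[, procedure], ids))
  data.frame(id = ids, procedure = procedure,
             probability = res$prob[, procedure],
             class = res$class[, procedure], stringsAsFactors = FALSE)
}

#' Per-procedure training-set performance of a consensus fit
#'
#' Classifies the training set with all thirteen procedures
#' (leave-self-out panel distances) and tabulates the confusion counts
#' and the full metrics suite, one row per procedure.
#'
#' @param object an [ar_consensus()] fit
#' @param ... unused
#' @return data frame of class `summary.ar_consensus`: `procedure`,
#'   `description`, then the [metrics_from_confusion()] columns
#' @export
summary.ar_consensus <- function(object, ...) {
  cls <- classify_all_procedures(object, object$train$descriptors)$class
  y <- object$train$data$label
  rows <- lapply(1:13, function(p) {
    metrics_from_confusion(confusion(y, cls[, p]))
  })
  out <- cbind(data.frame(procedure = 1:13,
                          description = procedure_descriptions,
                          stringsAsFactors = FALSE),
               do.call(rbind, rows))
  class(out) <- c("summary.ar_consensus", "data.frame")
  out
}

#' @export
print.summary.ar_consensus <- function(x, digits = 4, ...) {
  cat("Training-set performance of the 13 classification procedures\n\n")
  shown <- x[c("procedure", "TP", "TN", "FP", "FN",
               "SP", "SE", "Acc", "MCC", "BCR")]
  shown[c("SP", "SE", "Acc", "MCC", "BCR")] <-
    lapply(shown[c("SP", "SE", "Acc", "MCC", "BCR")], round, digits = digits)
  print.data.frame(shown, row.names = FALSE)
  invisible(x)
}

#' Fit and evaluate all thirteen procedures on a labelled dataset
#'
#' Convenience wrapper: fits [ar_consensus()] on the dataset and returns
#' the 13-row training-set performance table of
#' [summary.ar_consensus()].
#'
#' @param data labelled data frame (`id`, `dock_score`, `label`) or an
#'   `ar_dataset`
#' @param fingerprints fingerprint matrix (ignored for an `ar_dataset`)
#' @param ... passed to [ar_consensus()]
#' @return the per-procedure metrics table
#' @export
run_suite <- function(data, fingerprints = NULL, ...) {
  summary(ar_consensus(data, fingerprints, ...))
}

#' @export
print.ar_consensus <- function(x, ...) {
  cat(sprintf("Consensus AR binding classifier fitted on %d compounds (%d binders, %d non-binders)\n",
              x$n, nrow(x$panel_act), nrow(x$panel_inact)))
  cat(sprintf("  docking threshold: %g kcal/mol\n", x$config$dock_threshold))
  print(x$gauss)
  src <- if (x$config$use_reference) "packaged reference coefficients"
         else "refit on the training set"
  cat("Five-descriptor consensus logistic model (", src, "):\n", sep = "")
  print(x$models$m13)
  invisible(x)
}

#' @export
coef.ar_consensus <- function(object, ...) {
  coef(object$models$m13)
}

#' @export
residuals.ar_consensus <- function(object, ...) {
  p <- predict_prob(object$models$m13, object$train$descriptors)
  object$train$data$label - p
}

#' Docking-score distributions and fitted class Gaussians
#'
#' Plots the training docking-score histograms per class (sentinel zeros
#' shown as a separate bar at 0), overlays the fitted class-conditional
#' Gaussian densities, and marks the docking threshold.
#'
#' @param x an [ar_consensus()] fit
#' @param ... passed to [graphics::hist()]
#' @export
plot.ar_consensus <- function(x, ...) {
  d <- x$train$data
  s_act <- d$dock_score[d$label == 1L]
  s_inact <- d$dock_score[d$label == 0L]
  rng <- range(c(s_act, s_inact, x$config$dock_threshold))
  breaks <- seq(floor(rng[1]), ceiling(rng[2]) + 1, by = 0.5)
  h1 <- graphics::hist(s_act, breaks = breaks, plot = FALSE)
  h2 <- graphics::hist(s_inact, breaks = breaks, plot = FALSE)
  ylim <- c(0, max(h1$density, h2$density))
  graphics::plot(h1, freq = FALSE, col = grDevices::adjustcolor("firebrick", 0.5),
                 border = NA, ylim = ylim, xlab = "docking score (kcal/mol)",
                 main = "Docking-score distributions by class", ...)
  graphics::plot(h2, freq = FALSE, col = grDevices::adjustcolor("steelblue", 0.4),
                 border = NA, add = TRUE)
  xs <- seq(rng[1], min(0, rng[2]), length.out = 300)
  graphics::lines(xs, gaussian_density(xs, x$gauss$mu_act, x$gauss$sigma_act),
                  col = "firebrick", lwd = 2)
  graphics::lines(xs, gaussian_density(xs, x$gauss$mu_inact, x$gauss$sigma_inact),
                  col = "steelblue", lwd = 2)
  graphics::abline(v = x$config$dock_threshold, lty = 2)
  graphics::legend("topleft", c("binders", "non-binders", "threshold"),
                   col = c("firebrick", "steelblue", "black"),
                   lty = c(1, 1, 2), lwd = c(2, 2, 1), bty = "n")
  invisible(x)
}

#' Simulate datasets from a fitted consensus model
#'
#' Draws synthetic datasets whose docking-score structure matches the
#' fit: class sizes, per-class sentinel-zero fractions and class Gaussian
#' parameters are taken from the training data; fingerprint structure
#' uses the generator defaults.
#'
#' @param object an [ar_consensus()] fit
#' @param nsim number of datasets
#' @param seed integer seed
#' @param ... unused
#' @return list of [simulate_dataset()] results (an `ar_dataset` when
#'   `nsim = 1`)
#' @export
simulate.ar_consensus <- function(object, nsim = 1, seed = NULL, ...) {
  d <- object$train$data
  act <- d$label == 1L
  cfg <- synth_config(
    n_active = sum(act), n_inactive = sum(!act),
    zero_fraction_act = mean(d$dock_score[act] == 0),
    zero_fraction_inact = mean(d$dock_score[!act] == 0),
    mu_act = object$gauss$mu_act, sd_act = object$gauss$sigma_act,
    mu_inact = object$gauss$mu_inact, sd_inact = object$gauss$sigma_inact,
    fp_length = ncol(object$panel_act))
  if (!is.null(seed)) set.seed(as.integer(seed))
  sims <- replicate(nsim, simulate_dataset(cfg, seed = NULL), simplify = FALSE)
  if (nsim == 1) sims[[1L]] else sims
}

#' Published benchmark confusion counts
#'
#' The per-procedure confusion counts (TP, TN, FP, FN) reported for the
#' thirteen procedures on the CoMPARA AR training set, and for the two
#' procedures evaluated on the CoMPARA evaluation set, shipped with the
#' package as plain-text reference tables. They serve as fixed inputs for
#' benchmarking the metrics engine against published statistics.
#'
#' @param set `"training"` (13 rows) or `"evaluation"` (2 rows)
#' @return data frame with `procedure`, `TP`, `TN`, `FP`, `FN` (training
#'   rows also carry `description`)
#' @export
published_confusion_counts <- function(set = c("training", "evaluation")) {
  set <- match.arg(set)
  path <- system.file("extdata", paste0(set, "_confusion.csv"),
                      package = "arbind", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
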