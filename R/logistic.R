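#' Logistic regression by maximum likelihood
#'
#' Fits the binary logistic model
#' \deqn{P(y=1\mid x) = \frac{1}{1 + e^{-Y}}, \qquad
#'       Y = \beta + \alpha_1 X_1 + \dots + \alpha_n X_n}
#' by unpenalised maximum likelihood using iteratively reweighted least
#' squares (Newton scoring). Features enter on their raw scales — the
#' fitted coefficients are directly interpretable against the descriptor
#' units — and convergence is declared when the relative change in the
#' log-likelihood falls below `tol`.
#'
#' Complete separation has no finite MLE; the fit detects it (all fitted
#' probabilities at their labels to within numerical precision, or a
#' diverging likelihood path), warns with a diagnostic, and returns the
#' last iterate flagged `converged = FALSE` rather than silently reporting
#' huge coefficients.
#'
#' @param x numeric feature matrix or data frame, one row per observation;
#'   column names become the model's feature names
#' @param y 0/1 response (1 = binder)
#' @param tol relative log-likelihood convergence tolerance
#' @param max_iter maximum IRLS iterations
#' @return object of class `logit_ml`: `beta` (intercept), `alphas` (named
#'   coefficients), `feature_names`, `ll` (log-likelihood at the fit),
#'   `converged`, `n_iter`, `separation`
#' @seealso [predict_prob()], [log_likelihood()], [compara_model()]
#' @export
fit_logistic <- function(x, y, tol = 1e-8, max_iter = 100L) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.numeric(y)
  if (nrow(x) != length(y)) stop("nrow(x) must equal length(y)", call. = FALSE)
  if (ncol(x) < 1L) stop("need at least one feature column", call. = FALSE)
  if (anyNA(x) || anyNA(y) || any(!is.finite(x))) {
    stop("features and labels must be finite and non-missing", call. = FALSE)
  }
  if (!all(y %in% c(0, 1)) || length(unique(y)) < 2L) {
    stop("'y' must be 0/1 with both classes present", call. = FALSE)
  }
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))

  design <- cbind(`(Intercept)` = 1, x)
  if (qr(design)$rank < ncol(design)) {
    stop("singular design matrix: features are collinear", call. = FALSE)
  }

  coefs <- numeric(ncol(design))
  ll_old <- -Inf
  ll <- ll_logistic(design %*% coefs, y)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    eta <- drop(design %*% coefs)
    p <- stats::plogis(eta)
    w <- pmax(p * (1 - p), 1e-12)
    z <- eta + (y - p) / w
    fit <- stats::lm.wfit(design, z, w)
    coefs_new <- fit$coefficients
    if (anyNA(coefs_new) || any(!is.finite(coefs_new))) break
    ll_new <- ll_logistic(drop(design %*% coefs_new), y)
    # step-halve if Newton overshoots
    half <- 0L
    while (ll_new < ll && half < 20L) {
      coefs_new <- (coefs_new + coefs) / 2
      ll_new <- ll_logistic(drop(design %*% coefs_new), y)
      half <- half + 1L
    }
    ll_old <- ll
    ll <- ll_new
    coefs <- coefs_new
    if (abs(ll - ll_old) < tol * (abs(ll_old) + tol)) {
      converged <- TRUE
      break
    }
  }

  p_hat <- stats::plogis(drop(design %*% coefs))
  separation <- all(abs(p_hat - y) < 1e-8)
  if (separation) {
    converged <- FALSE
    warning("complete separation detected: the maximum-likelihood estimate ",
            "does not exist (fitted probabilities are 0/1 everywhere); ",
            "returning the last iterate with converged = FALSE",
            call. = FALSE)
  }

  structure(
    list(beta = unname(coefs[1L]),
         alphas = stats::setNames(coefs[-1L], colnames(x)),
         feature_names = colnames(x),
         ll = ll, converged = converged, n_iter = iter,
         separation = separation),
    class = "logit_ml")
}

# Bernoulli log-likelihood of linear predictor eta against labels y,
# with probabilities clamped away from 0/1 at machine epsilon.
ll_logistic <- function(eta, y) {
  p <- clamp_prob(stats::plogis(eta))
  sum(y * log(p) + (1 - y) * log(1 - p))
}

clamp_prob <- function(p) {
  eps <- .Machine$double.eps
  pmin(pmax(p, eps), 1 - eps)
}

#' Predicted binding probability from a logistic model
#'
#' Evaluates \eqn{1 / (1 + e^{-Y})} with
#' \eqn{Y = \beta + \sum_i \alpha_i X_i}. Feature columns are matched by
#' name against the model's `feature_names`; a missing or misnamed column
#' is an error rather than a silent misalignment. Callers classify at the
#' canonical threshold P >= 0.5 (binder).
#'
#' @param model a `logit_ml` model
#' @param x data frame or matrix whose named columns include the model's
#'   features; extra columns are ignored
#' @return probabilities in (0, 1), clamped at machine-epsilon bounds
#' @export
predict_prob <- function(model, x) {
  stopifnot(inherits(model, "logit_ml"))
  x <- as.data.frame(x)
  missing <- setdiff(model$feature_names, names(x))
  if (length(missing)) {
    stop("feature name mismatch: model needs missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  xm <- as.matrix(x[model$feature_names])
  storage.mode(xm) <- "double"
  eta <- model$beta + drop(xm %*% model$alphas)
  clamp_prob(stats::plogis(eta))
}

#' Log-likelihood of a logistic model on labelled data
#'
#' \eqn{LL = \sum_i [y_i \log p_i + (1-y_i)\log(1-p_i)]} with the
#' probabilities from [predict_prob()], clamped at machine-epsilon bounds
#' so the sum is always finite. LL is never positive.
#'
#' @inheritParams predict_prob
#' @param y 0/1 labels
#' @return log-likelihood (<= 0)
#' @export
log_likelihood <- function(model, x, y) {
  p <- predict_prob(model, x)
  y <- as.numeric(y)
  if (length(p) != length(y)) stop("x and y sizes differ", call. = FALSE)
  sum(y * log(p) + (1 - y) * log(1 - p))
}

#' @export
print.logit_ml <- function(x, ...) {
  cat("Logistic model (maximum likelihood)\n")
  cat("  intercept:", format(x$beta), "\n  coefficients:\n")
  print(x$alphas)
  if (!is.null(x$ll) && is.finite(x$ll)) {
    cat(sprintf("  log-likelihood: %.4f\n", x$ll))
  }
  cat(sprintf("  converged: %s (%d iterations)\n", x$converged, x$n_iter))
  invisible(x)
}

#' @export
coef.logit_ml <- function(object, ...) {
  c(`(Intercept)` = object$beta, object$alphas)
}

#' @export
logLik.logit_ml <- function(object, ...) {
  structure(object$ll, df = length(object$alphas) + 1L, class = "logLik")
}

#' @export
predict.logit_ml <- function(object, newdata, type = c("response", "class"), ...) {
  type <- match.arg(type)
  p <- predict_prob(object, newdata)
  if (type == "class") as.integer(p >= 0.5) else p
}

#' The packaged reference consensus model
#'
#' The pre-trained five-descriptor logistic consensus model distributed
#' with the package (trained on the CoMPARA androgen-receptor training
#' set; shipped as a versioned JSON file). Its linear predictor is
#' \deqn{Y = 26.169 - 0.0175\,\mathrm{ChimpDockScore}
#'   - 98.582\,\mathrm{avgD_{Act}} + 66.953\,\mathrm{avgD_{Inact}}
#'   + 3.584\,\mathrm{P_{Act\_dockChimp}} - 8.594\,\mathrm{P_{Inact}}}
#' over the docking score against the chimpanzee AR structure, the average
#' Tanimoto distances to the known binders and non-binders, and the two
#' class-conditional Gaussian density values of the docking score.
#'
#' @return a `logit_ml` model ready for [predict_prob()]
#' @examples
#' m <- compara_model()
#' m$beta  # 26.169
#' @export
compara_model <- function() {
  path <- system.file("extdata", "compara_logistic_v1.json", package = "arbind",
                      mustWork = TRUE)
  read_model(path)
}
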