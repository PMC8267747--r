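#' Class-conditional Gaussian model of docking scores
#'
#' Fits one Gaussian per class — binders ("actives") and non-binders
#' ("inactives") — to docking scores, by per-class sample mean and sample
#' standard deviation (n-1 denominator). The pair of densities is the
#' "naive Bayesian" score classifier: a compound is assigned the class
#' whose density is higher at its score.
#'
#' A docking score of exactly 0 kcal/mol is a sentinel meaning "no docking
#' pose produced", not a measured energy. By default such scores are
#' excluded from the fit (`exclude_zero = TRUE`): mixing a point mass at 0
#' into either Gaussian would badly distort the means. Classification of a
#' 0 score is still defined — both densities are simply evaluated at 0.
#'
#' @param scores_act docking scores (kcal/mol) of known binders
#' @param scores_inact docking scores of known non-binders
#' @param exclude_zero drop sentinel 0 scores before fitting?
#' @return object of class `gaussian_classes` with fields `mu_act`,
#'   `sigma_act`, `mu_inact`, `sigma_inact`, `n_act`, `n_inact`,
#'   `zeros_excluded`
#' @examples
#' m <- fit_gaussian_classes(c(-8, -9, -10), c(-5, -6, -7))
#' m$mu_act    # -9
#' m$mu_inact  # -6
#' @export
fit_gaussian_classes <- function(scores_act, scores_inact, exclude_zero = TRUE) {
  fit_one <- function(x, side) {
    x <- as.numeric(x)
    if (anyNA(x)) stop("docking scores must not contain NA", call. = FALSE)
    if (exclude_zero) x <- x[x != 0]
    if (length(x) < 2L) {
      stop(sprintf("need at least 2 %s scores after zero exclusion", side),
           call. = FALSE)
    }
    s <- stats::sd(x)
    if (s == 0) {
      stop(sprintf("%s scores are all identical; class SD is zero", side),
           call. = FALSE)
    }
    list(mu = mean(x), sigma = s, n = length(x))
  }
  a <- fit_one(scores_act, "active")
  i <- fit_one(scores_inact, "inactive")
  structure(
    list(mu_act = a$mu, sigma_act = a$sigma,
         mu_inact = i$mu, sigma_inact = i$sigma,
         n_act = a$n, n_inact = i$n,
         zeros_excluded = isTRUE(exclude_zero)),
    class = "gaussian_classes")
}

#' @export
print.gaussian_classes <- function(x, ...) {
  cat("Class-conditional Gaussian docking-score model\n")
  cat(sprintf("  binders:     mu = %.4f, sd = %.4f kcal/mol  (n = %d)\n",
              x$mu_act, x$sigma_act, x$n_act))
  cat(sprintf("  non-binders: mu = %.4f, sd = %.4f kcal/mol  (n = %d)\n",
              x$mu_inact, x$sigma_inact, x$n_inact))
  cat(sprintf("  sentinel 0 scores excluded from fit: %s\n", x$zeros_excluded))
  invisible(x)
}

#' Gaussian density
#'
#' The normal probability density
#' \deqn{P(x) = \frac{1}{\sqrt{2\pi\sigma^2}} e^{-(x-\mu)^2 / (2\sigma^2)}}
#' used as the class-conditional likelihood of a docking score. The
#' `printed_form` flag substitutes \eqn{2\pi\sigma^2} for \eqn{2\sigma^2}
#' in the exponent denominator — a non-normalised variant kept solely for
#' sensitivity checks against sources that print the density that way; it
#' is never used by the classifiers.
#'
#' @param x evaluation point(s), kcal/mol
#' @param mu mean
#' @param sigma standard deviation, must be > 0
#' @param printed_form use the non-standard exponent denominator?
#' @return density value(s), >= 0
#' @export
gaussian_density <- function(x, mu, sigma, printed_form = FALSE) {
  if (!is.numeric(sigma) || length(sigma) != 1L || is.na(sigma) || sigma <= 0) {
    stop("'sigma' must be a single positive number", call. = FALSE)
  }
  if (printed_form) {
    exp(-(x - mu)^2 / (2 * pi * sigma^2)) / sqrt(2 * pi * sigma^2)
  } else {
    stats::dnorm(x, mean = mu, sd = sigma)
  }
}

#' Classify docking scores by class-conditional density ratio
#'
#' Evaluates both class densities at each score and assigns class binder
#' (1) when the binder density strictly exceeds the non-binder density.
#' Exact density ties classify as non-binder — the conservative choice in
#' an imbalanced screen, where positives are rare. The density ratio
#' (binder density / non-binder density) is returned alongside, because
#' downstream consensus models use it as a feature.
#'
#' @param score docking score(s), kcal/mol (the sentinel 0 is allowed)
#' @param model a [fit_gaussian_classes()] model
#' @return list with `class` (integer 0/1 vector, 1 = binder) and `ratio`
#'   (binder density over non-binder density)
#' @examples
#' m <- structure(list(mu_act = -8.91, sigma_act = 1.94,
#'                     mu_inact = -5.97, sigma_inact = 2.01,
#'                     n_act = 100, n_inact = 100, zeros_excluded = TRUE),
#'                class = "gaussian_classes")
#' classify_bayes(-12, m)$class  # 1: deep score is binder-like
#' classify_bayes(0, m)$class    # 0: no-pose sentinel is non-binder-like
#' @export
classify_bayes <- function(score, model) {
  stopifnot(inherits(model, "gaussian_classes"))
  d_act <- gaussian_density(score, model$mu_act, model$sigma_act)
  d_inact <- gaussian_density(score, model$mu_inact, model$sigma_inact)
  list(class = as.integer(d_act > d_inact), ratio = d_act / d_inact)
}
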