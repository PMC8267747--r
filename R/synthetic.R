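#' Configuration for the synthetic screening-data generator
#'
#' Describes the statistical structure the consensus method assumes:
#' a strongly unbalanced two-class compound set (205 binders against 1480
#' non-binders by default, the CoMPARA AR training-set proportions);
#' zero-inflated docking scores, where each class produces the sentinel
#' score 0 ("no pose") with its own probability (default one half for
#' both) and otherwise a negative score drawn from a class Gaussian
#' (defaults mu = -8.91, sd = 1.94 kcal/mol for binders and mu = -5.97,
#' sd = 2.01 for non-binders, truncated below 0 so the sentinel stays
#' unambiguous); and binary fingerprints built from one random template
#' bitstring per class (bit density `fp_template_density`) with every bit
#' flipped independently with probability `fp_flip_prob`, which makes the
#' expected within-class Tanimoto similarity exceed the between-class one
#' whenever the flip probability is below one half. The default flip
#' probability is deliberately close to one half (0.45): 1024 independent
#' informative bits would otherwise carry far more class information than
#' real fingerprints, whose bits are strongly correlated, and
#' fingerprint-based classification would become unrealistically perfect.
#'
#' @param n_active,n_inactive class sizes
#' @param zero_fraction_act,zero_fraction_inact probability of the
#'   sentinel 0 score per class
#' @param mu_act,sd_act,mu_inact,sd_inact class Gaussian parameters for
#'   non-zero docking scores, kcal/mol
#' @param fp_length fingerprint length in bits
#' @param fp_template_density expected fraction of set bits in each class
#'   template
#' @param fp_flip_prob per-bit flip probability applied to the template
#' @param seed optional default seed used by [simulate_dataset()]
#' @return validated list of class `synth_config`
#' @export
synth_config <- function(n_active = 205L, n_inactive = 1480L,
                         zero_fraction_act = 0.5, zero_fraction_inact = 0.5,
                         mu_act = -8.91, sd_act = 1.94,
                         mu_inact = -5.97, sd_inact = 2.01,
                         fp_length = 1024L,
                         fp_template_density = 0.05, fp_flip_prob = 0.45,
                         seed = NULL) {
  cfg <- list(n_active = as.integer(n_active),
              n_inactive = as.integer(n_inactive),
              zero_fraction_act = zero_fraction_act,
              zero_fraction_inact = zero_fraction_inact,
              mu_act = mu_act, sd_act = sd_act,
              mu_inact = mu_inact, sd_inact = sd_inact,
              fp_length = as.integer(fp_length),
              fp_template_density = fp_template_density,
              fp_flip_prob = fp_flip_prob,
              seed = seed)
  with(cfg, {
    stopifnot(n_active > 0L, n_inactive > 0L, fp_length > 0L,
              sd_act > 0, sd_inact > 0,
              zero_fraction_act >= 0, zero_fraction_act <= 1,
              zero_fraction_inact >= 0, zero_fraction_inact <= 1,
              fp_template_density > 0, fp_template_density < 1,
              fp_flip_prob >= 0, fp_flip_prob < 1)
  })
  structure(cfg, class = "synth_config")
}

# Inverse-CDF draw from N(mu, sd) truncated to (-Inf, 0): every compound
# consumes exactly one uniform, so the stream layout is independent of
# the realised zero pattern.
rtruncnorm_neg <- function(n, mu, sd) {
  u <- stats::runif(n)
  stats::qnorm(u * stats::pnorm(0, mu, sd), mu, sd)
}

#' Generate a synthetic labelled screening dataset
#'
#' Draws a dataset with the structure described by [synth_config()]. The
#' draw order within the single seeded stream is fixed and documented —
#' active template bits, inactive template bits, active zero indicators,
#' active truncated-normal scores (one uniform per compound regardless of
#' the zero pattern), inactive zero indicators, inactive scores, active
#' flip matrix, inactive flip matrix — so one seed fully determines the
#' dataset across platforms.
#'
#' @param config a [synth_config()]
#' @param seed integer seed; overrides `config$seed` when given
#' @return list of class `ar_dataset` with `data` (data frame `id`,
#'   `dock_score`, `label`; binders first, label 1) and `fingerprints`
#'   (0/1 matrix with matching row names)
#' @examples
#' d <- simulate_dataset(synth_config(n_active = 5, n_inactive = 10), seed = 1)
#' table(d$data$label)
#' @export
simulate_dataset <- function(config = synth_config(), seed = NULL) {
  stopifnot(inherits(config, "synth_config"))
  seed <- if (!is.null(seed)) seed else config$seed
  if (!is.null(seed)) set.seed(as.integer(seed))

  L <- config$fp_length
  tmpl_act <- stats::rbinom(L, 1L, config$fp_template_density)
  tmpl_inact <- stats::rbinom(L, 1L, config$fp_template_density)

  draw_scores <- function(n, zero_frac, mu, sd) {
    zero <- stats::runif(n) < zero_frac
    raw <- rtruncnorm_neg(n, mu, sd)
    ifelse(zero, 0, raw)
  }
  s_act <- draw_scores(config$n_active, config$zero_fraction_act,
                       config$mu_act, config$sd_act)
  s_inact <- draw_scores(config$n_inactive, config$zero_fraction_inact,
                         config$mu_inact, config$sd_inact)

  flip_from <- function(template, n) {
    flips <- matrix(stats::runif(n * L) < config$fp_flip_prob, nrow = n)
    fp <- matrix(rep(template, each = n), nrow = n)
    fp[flips] <- 1L - fp[flips]
    fp
  }
  fp <- rbind(flip_from(tmpl_act, config$n_active),
              flip_from(tmpl_inact, config$n_inactive))

  ids <- c(sprintf("act%04d", seq_len(config$n_active)),
           sprintf("ina%04d", seq_len(config$n_inactive)))
  rownames(fp) <- ids
  data <- data.frame(id = ids,
                     dock_score = c(s_act, s_inact),
                     label = rep(c(1L, 0L),
                                 c(config$n_active, config$n_inactive)),
                     stringsAsFactors = FALSE)
  structure(list(data = data, fingerprints = as_fingerprint_matrix(fp),
                 config = config),
            class = "ar_dataset")
}

#' @export
print.ar_dataset <- function(x, ...) {
  cat(sprintf("Labelled screening dataset: %d compounds (%d binders, %d non-binders)\n",
              nrow(x$data), sum(x$data$label == 1L), sum(x$data$label == 0L)))
  cat(sprintf("  fingerprints: %d bits; zero docking scores: %d\n",
              ncol(x$fingerprints), sum(x$data$dock_score == 0)))
  invisible(x)
}

#' Default-sized synthetic training fixture
#'
#' A default-configuration dataset (205 binders, 1480 non-binders, 1685
#' compounds) for end-to-end exercises of the 13-procedure suite.
#'
#' @param seed integer seed
#' @return an `ar_dataset`
#' @export
make_training_fixture <- function(seed = 1L) {
  simulate_dataset(synth_config(), seed = seed)
}
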