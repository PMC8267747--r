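test_that("maximum likelihood recovers a planted logistic model", {
  set.seed(77)
  n <- 5000L
  x <- matrix(rnorm(n), ncol = 1, dimnames = list(NULL, "x"))
  eta <- -1 + 2 * x[, 1]
  y <- rbinom(n, 1L, plogis(eta))
  fit <- fit_logistic(x, y)
  expect_true(fit$converged)
  expect_lt(abs(fit$beta - (-1)), 0.15)
  expect_lt(abs(fit$alphas[["x"]] - 2), 0.15)
})

test_that("a null-effect feature gets a near-zero coefficient", {
  set.seed(8)
  n <- 4000L
  x <- cbind(signal = rnorm(n), noise = rnorm(n))
  y <- rbinom(n, 1L, plogis(x[, "signal"]))
  fit <- fit_logistic(x, y)
  # the null coefficient should sit within ~3 standard errors of zero;
  # with n = 4000 its SE is below ~0.06
  expect_lt(abs(fit$alphas[["noise"]]), 0.18)
})

test_that("fits agree with an independent IRLS implementation (glm)", {
  set.seed(12)
  n <- 600L
  x <- cbind(a = rnorm(n), b = runif(n, -2, 2))
  y <- rbinom(n, 1L, plogis(0.5 + x[, 1] - 1.5 * x[, 2]))
  fit <- fit_logistic(x, y)
  ref <- glm(y ~ a + b, data = data.frame(y = y, x), family = binomial())
  expect_equal(unname(coef(fit)), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(fit$ll, as.numeric(logLik(ref)), tolerance = 1e-8)
})

test_that("the score vector vanishes at every converged optimum", {
  set.seed(13)
  for (k in 1:10) {
    n <- 400L
    p <- sample(1:4, 1)
    x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
    y <- rbinom(n, 1L, plogis(drop(x %*% runif(p, -1, 1))))
    if (length(unique(y)) < 2L) next
    fit <- fit_logistic(x, y)
    if (!fit$converged) next
    probs <- predict_prob(fit, x)
    grad <- crossprod(cbind(1, x), y - probs)
    expect_lt(max(abs(grad)), 1e-6)
  }
})

test_that("log-likelihood obeys nesting, closed forms, and a per-row oracle", {
  set.seed(21)
  n <- 500L
  x <- matrix(rnorm(n), ncol = 1, dimnames = list(NULL, "x"))
  y <- rbinom(n, 1L, plogis(1 + x[, 1]))
  fit <- fit_logistic(x, y)
  # intercept-only model at its MLE (the observed base rate)
  n1 <- sum(y)
  null_model <- structure(list(beta = qlogis(n1 / n), alphas = c(x = 0),
                               feature_names = "x", ll = NA_real_,
                               converged = TRUE, n_iter = 0L,
                               separation = FALSE), class = "logit_ml")
  ll_null <- log_likelihood(null_model, x, y)
  expect_gte(fit$ll, ll_null)                           # nesting
  expect_lte(fit$ll, 0)
  # intercept-only closed form: n1 log(n1/n) + n0 log(n0/n)
  expect_equal(ll_null, n1 * log(n1 / n) + (n - n1) * log(1 - n1 / n),
               tolerance = 1e-9)

  # naive per-row loop oracle
  p <- predict_prob(fit, x)
  ll_loop <- 0
  for (i in seq_len(n)) {
    ll_loop <- ll_loop + if (y[i] == 1) log(p[i]) else log(1 - p[i])
  }
  expect_equal(log_likelihood(fit, x, y), ll_loop, tolerance = 1e-9)

  # perfectly predicted labels give LL ~ 0 after clamping
  sure <- structure(list(beta = 1000, alphas = c(x = 0), feature_names = "x",
                         ll = NA_real_, converged = TRUE, n_iter = 1L,
                         separation = FALSE), class = "logit_ml")
  expect_equal(log_likelihood(sure, x, rep(1, n)), 0, tolerance = 1e-10)
})

test_that("probabilities are well-formed and feature-name checked", {
  m <- structure(list(beta = 0, alphas = c(u = 1), feature_names = "u",
                      ll = NA_real_, converged = TRUE, n_iter = 1L,
                      separation = FALSE), class = "logit_ml")
  expect_equal(predict_prob(m, data.frame(u = 0)), 0.5)   # Y = 0
  probs <- predict_prob(m, data.frame(u = seq(-50, 50, 1)))
  expect_true(all(diff(probs) >= 0))                      # monotone in Y
  expect_true(all(probs > 0 & probs < 1))                 # strict after clamping
  expect_error(predict_prob(m, data.frame(v = 1)), "name mismatch")
})

test_that("row order does not change the fit", {
  set.seed(30)
  n <- 300L
  x <- matrix(rnorm(2 * n), n, 2, dimnames = list(NULL, c("a", "b")))
  y <- rbinom(n, 1L, plogis(x[, 1]))
  fit1 <- fit_logistic(x, y)
  perm <- sample(n)
  fit2 <- fit_logistic(x[perm, ], y[perm])
  expect_equal(coef(fit1), coef(fit2), tolerance = 1e-8)
})

test_that("complete separation is diagnosed, not silently returned", {
  x <- matrix(c(-(10:1), 1:10), ncol = 1, dimnames = list(NULL, "x"))
  y <- rep(c(0, 1), each = 10)
  expect_warning(fit <- fit_logistic(x, y), "separation")
  expect_false(fit$converged)
  expect_true(fit$separation)
})

test_that("degenerate designs and inputs are explicit errors", {
  x <- cbind(a = rnorm(20), b = 0)
  x <- cbind(x, c = x[, "a"] * 2)
  y <- rep(c(0, 1), 10)
  expect_error(fit_logistic(x, y), "singular")
  expect_error(fit_logistic(cbind(a = rnorm(20)), rep(1, 20)), "both classes")
  expect_error(fit_logistic(cbind(a = c(NA, rnorm(19))), y), "finite")
})

test_that("the packaged reference model carries the expected coefficients", {
  m <- compara_model()
  expect_identical(m$feature_names,
                   c("ChimpDockScore", "avgD_Act", "avgD_Inact",
                     "P_Act_dockChimp", "P_Inact"))
  expect_identical(m$beta, 26.169)
  expect_identical(unname(m$alphas),
                   c(-0.0175, -98.582, 66.953, 3.584, -8.594))
  expect_identical(m$ll, -407.619)
})
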