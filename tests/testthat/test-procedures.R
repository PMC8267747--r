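test_that("the docking-score threshold rule classifies as documented", {
  f <- small_fit()$fit
  set.seed(40)
  fp <- random_fp(4, 256)
  nd <- data.frame(id = rownames(fp),
                   dock_score = c(-11.91, 0, -7, -6.99))
  cls <- predict(f, nd, fp, procedure = 1)
  expect_identical(unname(cls), c(1L, 0L, 1L, 0L))
  # a strong score is a binder under every score-threshold cascade too
  expect_identical(unname(predict(f, nd, fp, procedure = 6))[1:2][1], 1L)
})

test_that("cascade and consensus procedures are consistent with their parts", {
  f <- small_fit()$fit
  all_cls <- predict(f, procedure = "all")
  s <- f$train$data$dock_score
  d <- f$train$descriptors

  # 6 agrees with 1 wherever a docking pose exists; zeros go to rule 5
  nz <- s != 0
  expect_identical(all_cls[nz, 6], all_cls[nz, 1])
  expect_identical(all_cls[!nz, 6], all_cls[!nz, 5])

  # 7: a fingerprint binder stays a binder, fingerprint non-binders are
  # re-decided by the threshold rule
  expect_true(all(all_cls[all_cls[, 5] == 1L, 7] == 1L))
  fp_nb <- all_cls[, 5] == 0L
  expect_identical(all_cls[fp_nb, 7], all_cls[fp_nb, 1])

  # 4 forces the no-pose sentinel to non-binder, otherwise follows 2
  expect_true(all(all_cls[s == 0, 4] == 0L))
  expect_identical(all_cls[nz, 4], all_cls[nz, 2])

  # 9 equals 6 except at the zero-score distance ties, which fall to 8
  unresolved <- s == 0 & abs(d$avgD_Act - d$avgD_Inact) < 1e-12
  expect_identical(all_cls[!unresolved, 9], all_cls[!unresolved, 6])
  expect_identical(all_cls[unresolved, 9], all_cls[unresolved, 8])

  # 10: agreement of 2 and 5 decides without 8, disagreement goes to 8
  agree <- all_cls[, 2] == all_cls[, 5]
  expect_identical(all_cls[agree, 10], all_cls[agree, 2])
  expect_identical(all_cls[!agree, 10], all_cls[!agree, 8])

  # 5 compares the panel-averaged distances directly
  expect_identical(unname(all_cls[, 5]),
                   as.integer(d$avgD_Act < d$avgD_Inact))
})

test_that("the five-descriptor reference procedure is a pure function", {
  f1 <- ar_consensus(small_fit()$data, use_reference = TRUE)
  f2 <- ar_consensus(small_fit()$data, use_reference = TRUE)
  desc <- data.frame(ChimpDockScore = c(-9.1, 0, -4),
                     avgD_Act = c(0.31, 0.62, 0.55),
                     avgD_Inact = c(0.58, 0.60, 0.52),
                     P_Act_dockChimp = c(0.2, 0.0, 0.01),
                     P_Inact = c(0.03, 0.01, 0.1))
  p1 <- predict_prob(f1$models$m13, desc)
  p2 <- predict_prob(f2$models$m13, desc)
  expect_identical(p1, p2)
  expect_identical(f1$models$m13$beta, 26.169)
})

test_that("unknown procedures and missing inputs raise explicit errors", {
  f <- small_fit()$fit
  expect_error(predict(f, procedure = 14), "unknown procedure")
  expect_error(predict(f, procedure = 0), "unknown procedure")
  nd <- data.frame(id = "zz", dock_score = -8)
  expect_error(predict(f, nd, procedure = 1), "fingerprints")
  fp <- random_fp(1, 256)
  expect_error(predict(f, nd, fp, procedure = 1), "zz")
})

test_that("leave-self-out removes the self-distance bias from panel averages", {
  d <- small_fit()$data
  fit_lso <- small_fit()$fit
  # without leave-self-out the leaked self-distances separate the classes,
  # so the internal logistic fits legitimately warn about separation
  fit_raw <- suppressWarnings(ar_consensus(d, leave_self_out = FALSE))
  act <- d$data$label == 1L
  # averaging in the zero self-distance pulls the own-class average down
  expect_true(all(fit_raw$train$descriptors$avgD_Act[act] <
                    fit_lso$train$descriptors$avgD_Act[act]))
  expect_equal(fit_raw$train$descriptors$avgD_Inact[act],
               fit_lso$train$descriptors$avgD_Inact[act])
})

test_that("the suite reports all thirteen procedures with coherent counts", {
  tab <- summary(small_fit()$fit)
  expect_identical(nrow(tab), 13L)
  expect_identical(tab$procedure, 1:13)
  n1 <- sum(small_fit()$data$data$label == 1L)
  n0 <- sum(small_fit()$data$data$label == 0L)
  expect_true(all(tab$TP + tab$FN == n1))
  expect_true(all(tab$TN + tab$FP == n0))

  # labels of one class only cannot be fitted or scored
  bad <- small_fit()$data$data
  bad$label <- 1L
  expect_error(ar_consensus(bad, small_fit()$data$fingerprints),
               "at least 2")
})

test_that("model-based consensus outperforms the bare threshold on generator data", {
  tab <- summary(default_fit()$fit)
  expect_gte(tab$MCC[13], tab$MCC[1])
})

test_that("the fitted object exposes the standard modelling verbs", {
  f <- small_fit()$fit
  expect_output(print(f), "Consensus AR binding classifier")
  expect_identical(names(coef(f))[1], "(Intercept)")
  r <- residuals(f)
  expect_length(r, f$n)
  expect_true(all(abs(r) < 1))
  sim <- simulate(f, seed = 4)
  expect_s3_class(sim, "ar_dataset")
  expect_identical(nrow(sim$data), f$n)
  pdf_file <- withr::local_tempfile(fileext = ".pdf")
  grDevices::pdf(pdf_file)
  expect_silent(plot(f))
  grDevices::dev.off()
  expect_true(file.exists(pdf_file))
})
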