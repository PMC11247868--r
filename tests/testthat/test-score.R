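test_that("logit transform applies the continuity correction and handles boundaries", {
  expect_equal(logit_mfr(5, 10), 0)                       # (5.5/11) = 0.5
  expect_equal(logit_mfr(0, 9), log(0.05 / 0.95), tolerance = 1e-12)
  expect_true(is.na(logit_mfr(0, 0)))
  expect_true(is.finite(logit_mfr(40, 40)))               # MFR = 1 stays finite
  expect_error(logit_mfr(-1, 5), class = "methtrace_input_error")
  expect_error(logit_mfr(6, 5), class = "methtrace_input_error")
})

test_that("baseline fit gives per-marker mean/sd with floor and usability flags", {
  mm <- tibble::tibble(
    sample_id = rep(c("H1", "H2"), each = 3),
    mcb_id = rep(c("A", "B", "C"), 2),
    mfc = c(3L, 2L, 0L, 1L, 2L, 0L),
    n_informative = c(10L, 10L, 0L, 10L, 10L, 0L),
    coverage = 12L
  ) |> dplyr::mutate(mfr = ifelse(n_informative > 0, mfc / n_informative, NA))
  base <- fit_baseline(mm, c("H1", "H2"))
  a <- base[base$mcb_id == "A", ]
  x1 <- logit_mfr(3, 10); x2 <- logit_mfr(1, 10)
  expect_equal(a$mu, mean(c(x1, x2)))
  expect_equal(a$sigma, sd(c(x1, x2)))
  b <- base[base$mcb_id == "B", ]                 # identical values -> floored sd
  expect_equal(b$sigma, 1e-6)
  expect_false(base$usable[base$mcb_id == "C"])   # never observed
  expect_error(fit_baseline(mm, character(0)), class = "methtrace_input_error")
})

test_that("Z-scores and one-sided p-values follow the closed forms", {
  expect_equal(marker_z(1, 1, 0.5), 0)
  expect_equal(marker_z(1.5, 1, 0.5), 1)
  expect_equal(marker_z(2.5, 1, 0.5), 3)
  expect_error(marker_z(1, 0, 0), class = "methtrace_state_error")
  expect_equal(z_to_p(0), 0.5)
  expect_equal(z_to_p(1.959964), 0.025, tolerance = 1e-6)
  expect_equal(z_to_p(1e6), 1e-300)   # clipped at the floor
  expect_equal(z_to_p(-1e6), 1)
})

test_that("methylation score matches Fisher's weighted form exactly", {
  expect_equal(methylation_score(c(1, 1, 1), c(1, 2, 3)), 0)
  expect_equal(methylation_score(0.5, 1), -2 * log(0.5), tolerance = 1e-12)
  p <- c(0.1, 0.6, 0.9); w <- c(2, 5, 1)
  expect_equal(methylation_score(p, 3 * w), methylation_score(p, w),
               tolerance = 1e-12)
  # missing markers drop out of both sums
  expect_equal(methylation_score(c(0.2, NA), c(1, 10)),
               methylation_score(0.2, 1))
  expect_error(methylation_score(c(NA, 0.5), c(1, 0)),
               class = "methtrace_score_error")
})

test_that("score is monotone: smaller p (larger x) raises it", {
  set.seed(10)
  w <- runif(8, 1, 5)
  p <- runif(8, 0.05, 0.95)
  s0 <- methylation_score(p, w)
  for (i in 1:8) {
    p2 <- p; p2[i] <- p[i] * 0.5
    expect_gt(methylation_score(p2, w), s0)
    x <- rnorm(1); mu <- 0; sig <- 1
    expect_gt(methylation_score(z_to_p(marker_z(x + 0.3, mu, sig)), 1),
              methylation_score(z_to_p(marker_z(x, mu, sig)), 1))
  }
})

test_that("baseline-level samples give scores near the chi-square expectation of 2", {
  set.seed(123)
  n_mark <- 400
  p <- z_to_p(rnorm(n_mark))           # truly at baseline
  s <- methylation_score(p, rep(1, n_mark))
  expect_equal(s, 2, tolerance = 0.25)  # MC error ~ 2/sqrt(400)
})

test_that("threshold calibration hits the specificity target under the lower-quantile rule", {
  set.seed(6)
  sc <- rnorm(100)
  th <- calibrate_threshold(sc, specificity = 0.98)
  expect_equal(th$cutoff, sort(sc)[98])
  expect_equal(sum(classify_scores(sc, th)), 2)
  th1 <- calibrate_threshold(sc, specificity = 1)
  expect_equal(th1$cutoff, max(sc))
  expect_equal(sum(classify_scores(sc, th1)), 0)
  tied <- rep(1.5, 50)
  th2 <- calibrate_threshold(tied)
  expect_equal(th2$cutoff, 1.5)
  expect_equal(sum(classify_scores(tied, th2)), 0)
  expect_error(calibrate_threshold(rnorm(5)), class = "methtrace_input_error")
})

test_that("rank AUC equals exhaustive pair counting and a reference implementation", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1.0)
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 1, 0, 1)), 0.75)
  expect_equal(roc_auc(rep(1, 10), rep(c(0, 1), 5)), 0.5)
  expect_error(roc_auc(1:4, rep(1, 4)), class = "methtrace_input_error")
  set.seed(99)
  for (i in 1:25) {
    n <- sample(4:30, 1)
    sc <- sample(seq(0, 2, by = 0.25), n, replace = TRUE)  # forces ties
    lb <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (length(unique(lb)) < 2) next
    expect_equal(roc_auc(sc, lb), oracle_auc(sc, lb), tolerance = 1e-12)
  }
  # independent reference: pROC on a continuous case
  sc <- rnorm(40); lb <- rep(c(0, 1), 20)
  ref <- suppressMessages(pROC::roc(lb, sc, levels = c(0, 1), direction = "<"))
  expect_equal(roc_auc(sc, lb), as.numeric(ref$auc), tolerance = 1e-12)
})

test_that("Wilson intervals match the reference implementation and edge cases", {
  w <- wilson_ci(8, 10)
  ref <- stats::prop.test(8, 10, correct = FALSE)$conf.int
  expect_equal(c(w$conf_low, w$conf_high), as.numeric(ref), tolerance = 1e-9)
  w0 <- wilson_ci(0, 12)
  expect_equal(w0$estimate, 0)
  expect_equal(w0$conf_low, 0)
  expect_gt(w0$conf_high, 0)
  w1 <- wilson_ci(12, 12)
  expect_equal(w1$estimate, 1)
  expect_equal(w1$conf_high, 1)
})

test_that("sensitivity report aggregates strata and Spearman correctly", {
  samples <- tibble::tibble(
    sample_id = c(paste0("H", 1:20), paste0("C", 1:12)),
    label = c(rep("healthy", 20), rep(c("LIHC", "STAD"), 6)),
    stage = c(rep("none", 20), rep(c("I", "II", "III", "IV"), 3))
  )
  set.seed(2)
  scores <- tibble::tibble(
    sample_id = samples$sample_id,
    methylation_score = c(rnorm(20, 2, 0.1),
                          2 + 0.8 * rep(1:4, 3) + rnorm(12, 0, 0.05))
  )
  th <- calibrate_threshold(scores$methylation_score[1:20], specificity = 0.95)
  ev <- sensitivity_report(scores, samples, th)
  expect_s3_class(ev, "mt_eval")
  expect_equal(nrow(ev$by_stage), 4)
  expect_true(all(ev$by_stage$estimate >= 0 & ev$by_stage$estimate <= 1))
  # stage-graded construction: sensitivity non-decreasing, Spearman positive
  expect_true(all(diff(ev$by_stage$estimate) >= 0))
  expect_gt(ev$spearman$rho, 0.5)
  expect_lt(ev$spearman$p_value, 0.05)
  # cross-check one stratum against direct counting
  lihc <- ev$by_class[ev$by_class$class == "LIHC", ]
  calls <- classify_scores(scores$methylation_score, th)
  expect_equal(lihc$k, sum(calls[samples$label == "LIHC"]))
})
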