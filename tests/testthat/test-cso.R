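# small separable 3-class fixture used across ensemble tests
make_cso_fixture <- function(n_per_class = 20, sep = 4, seed = 31) {
  set.seed(seed)
  classes <- c("BRCA", "LIHC", "PAAD")
  labels <- rep(classes, each = n_per_class)
  n <- length(labels)
  centers <- matrix(c(sep, 0, 0, 0, sep, 0, 0, 0, sep), 3, byrow = TRUE)
  x <- centers[rep(1:3, each = n_per_class), ] + matrix(rnorm(n * 3), n, 3)
  x <- cbind(x, matrix(rnorm(n * 3), n, 3))
  colnames(x) <- sprintf("MCB%05d", 1:6)
  rownames(x) <- sprintf("S%03d", seq_len(n))
  list(x = x, labels = labels, classes = classes)
}

test_that("preprocessor normalizes training features and imputes missing to zero", {
  set.seed(17)
  mm <- tidyr::expand_grid(sample_id = sprintf("S%02d", 1:20),
                           mcb_id = c("A", "B")) |>
    dplyr::mutate(n_informative = rpois(40, 30) + 1L,
                  mfc = rbinom(40, n_informative, 0.2),
                  mfr = mfc / n_informative,
                  coverage = n_informative + 2L)
  mm$n_informative[1] <- 0L; mm$mfc[1] <- 0L; mm$mfr[1] <- NA  # one missing cell
  pp <- fit_cso_preprocessor(mm, c("A", "B"))
  f <- predict(pp, mm)
  expect_equal(f[1, "A"], 0)                      # imputed to the mean
  nonmiss <- f[-1, "A"]
  expect_equal(mean(nonmiss), 0, tolerance = 1e-9)
  expect_equal(sd(nonmiss), 1, tolerance = 1e-6)
  expect_equal(predict(pp, mm), f)                # idempotent on stored stats
})

test_that("ensemble separates wide-margin classes and is seed-deterministic", {
  fx <- make_cso_fixture()
  idx <- rep(rep(c(TRUE, FALSE), c(15, 5)), 3)    # 15 train / 5 test per class
  m1 <- train_cso_ensemble(fx$x[idx, ], fx$labels[idx], seed = 9)
  m2 <- train_cso_ensemble(fx$x[idx, ], fx$labels[idx], seed = 9)
  expect_identical(m1$weights, m2$weights)
  p1 <- predict(m1, fx$x[!idx, ])
  p2 <- predict(m2, fx$x[!idx, ])
  expect_equal(p1, p2)
  truth <- fx$labels[!idx]
  expect_gte(top_k_accuracy(p1, truth, 1)$accuracy, 0.95)
  # probability conservation
  prob <- as.matrix(p1[paste0("p_", fx$classes)])
  expect_equal(unname(rowSums(prob)), rep(1, nrow(prob)), tolerance = 1e-9)
})

test_that("label-shuffled training yields chance-level held-out accuracy", {
  fx <- make_cso_fixture(n_per_class = 25, sep = 0, seed = 55)  # no signal at all
  idx <- rep(rep(c(TRUE, FALSE), c(17, 8)), 3)
  m <- train_cso_ensemble(fx$x[idx, ], fx$labels[idx], seed = 12)
  acc <- top_k_accuracy(predict(m, fx$x[!idx, ]), fx$labels[!idx], 1)$accuracy
  # chance = 1/3; allow generous binomial slack at n = 24
  expect_lt(acc, 1 / 3 + 2.5 * sqrt((1 / 3) * (2 / 3) / 24))
})

test_that("ensemble validates inputs", {
  fx <- make_cso_fixture(n_per_class = 4)
  expect_error(train_cso_ensemble(fx$x, fx$labels, k_folds = 5),
               class = "methtrace_input_error")
  expect_error(train_cso_ensemble(fx$x, rep("BRCA", nrow(fx$x))),
               class = "methtrace_input_error")
  m <- train_cso_ensemble(fx$x, fx$labels, k_folds = 3)
  bad <- fx$x; colnames(bad)[1] <- "OTHER"
  expect_error(predict(m, bad), class = "methtrace_input_error")
})

test_that("top-k accuracy equals the enumeration oracle, with deterministic ties", {
  set.seed(44)
  classes <- c("BRCA", "COREAD", "ESCA", "LIHC")
  for (i in 1:20) {
    n <- sample(3:20, 1)
    prob <- matrix(sample(seq(0, 1, 0.2), n * 4, replace = TRUE), n, 4,
                   dimnames = list(NULL, classes))
    prob <- prob + 1e-3
    prob <- prob / rowSums(prob)
    truth <- sample(classes, n, replace = TRUE)
    pred <- methtrace:::prediction_tibble(prob)
    for (k in 1:4) {
      expect_equal(top_k_accuracy(pred, truth, k)$accuracy,
                   oracle_top_k(prob, truth, k),
                   label = sprintf("i=%d k=%d", i, k))
    }
    expect_gte(top_k_accuracy(pred, truth, 2)$accuracy,
               top_k_accuracy(pred, truth, 1)$accuracy)
  }
  pred <- methtrace:::prediction_tibble(
    matrix(c(0.6, 0.4, 0.2, 0.8), 2, 2, byrow = TRUE,
           dimnames = list(NULL, c("BRCA", "LIHC"))))
  expect_error(top_k_accuracy(pred, c("BRCA", "LIHC"), 3),
               class = "methtrace_input_error")
  # enumeration example: true classes ranked 1st, 2nd, 3rd
  prob <- matrix(c(.5, .3, .2, 0,
                   .5, .3, .2, 0,
                   .5, .3, .2, 0), 3, 4, byrow = TRUE,
                 dimnames = list(NULL, classes))
  pred3 <- methtrace:::prediction_tibble(prob)
  truth3 <- classes[1:3]
  expect_equal(top_k_accuracy(pred3, truth3, 1)$accuracy, 1 / 3)
  expect_equal(top_k_accuracy(pred3, truth3, 2)$accuracy, 2 / 3)
})

test_that("HPCA merge sums the two probabilities and never harms LIHC/PAAD-true samples", {
  classes <- cso_classes()
  set.seed(13)
  for (i in 1:25) {
    n <- 12
    prob <- matrix(rexp(n * 7), n, 7, dimnames = list(NULL, classes))
    prob <- prob / rowSums(prob)
    pred <- methtrace:::prediction_tibble(prob)
    merged <- merge_hpca(pred)
    mp <- methtrace:::pred_prob_matrix(merged)
    expect_equal(unname(mp[, "HPCA"]), unname(prob[, "LIHC"] + prob[, "PAAD"]),
                 tolerance = 1e-12)
    expect_equal(unname(rowSums(mp)), rep(1, n), tolerance = 1e-9)
    truth <- sample(c("LIHC", "PAAD"), n, replace = TRUE)
    hit_before <- pred$top1 == truth
    hit_after <- merged$top1 == "HPCA"
    expect_true(all(hit_after >= hit_before))
  }
  pred_no <- methtrace:::prediction_tibble(
    matrix(0.5, 2, 2, dimnames = list(NULL, c("BRCA", "LIHC"))))
  expect_error(merge_hpca(pred_no), class = "methtrace_input_error")
})

test_that("single-stacker and convex-combination behavior of the blend", {
  # two synthetic stacker outputs blended 0.5/0.5
  p1 <- c(1, 0, 0); p2 <- c(0, 1, 0)
  blend <- 0.5 * p1 + 0.5 * p2
  expect_equal(blend, c(0.5, 0.5, 0))
  # model with all weight on one stacker predicts that stacker's output
  fx <- make_cso_fixture()
  m <- train_cso_ensemble(fx$x, fx$labels, k_folds = 4, seed = 3)
  expect_equal(sum(m$weights), 1)
  expect_true(all(m$weights >= 0))
})
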