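test_that("mutual information matches the plug-in formula and basic identities", {
  # 2x2 table [[40,10],[10,40]]: MI = 0.8 log2(1.6) + 0.2 log2(0.4)
  vals <- c(rep(0, 50), rep(1, 50))
  labs <- c(rep("a", 40), rep("b", 10), rep("a", 10), rep("b", 40))
  want <- 0.8 * log2(1.6) + 0.2 * log2(0.4)
  expect_equal(mutual_information(vals, labs, binarize = TRUE), want,
               tolerance = 1e-12)

  # perfectly label-matched binary values on balanced labels: 1 bit
  expect_equal(
    mutual_information(rep(c(0, 3), each = 20), rep(c("h", "c"), each = 20),
                       binarize = TRUE), 1.0)

  # independence: MI near zero for large n
  set.seed(3)
  v <- rnorm(4000)
  l <- rep(c("h", "c"), 2000)
  expect_lt(mutual_information(v, l), 0.005)

  expect_error(mutual_information(1:10, rep("a", 10)),
               class = "methtrace_input_error")
  expect_error(mutual_information(1:3, c("a", "a", "b")),
               class = "methtrace_input_error")
})

test_that("MI is symmetric, non-negative, and invariant to bin relabeling", {
  set.seed(8)
  for (i in 1:20) {
    v <- rpois(60, 2)
    l <- sample(c("x", "y"), 60, replace = TRUE, prob = c(0.4, 0.6))
    if (min(table(l)) < 2) next
    mi <- mutual_information(v, l)
    expect_gte(mi, 0)
    # symmetry of the underlying estimator: swap roles via the table
    tab <- table(v > median(v), l)
    expect_equal(methtrace:::mi_from_table(tab), methtrace:::mi_from_table(t(tab)),
                 tolerance = 1e-12)
    # relabeling bins (reversing values) leaves quantile-bin MI unchanged
    expect_equal(mutual_information(-v, l), mi, tolerance = 1e-12)
  }
})

make_selection_cohort <- function(n_per_class = 8, n_healthy = 30, seed = 5) {
  # one planted marker per class (strong count shift), plus noise markers
  set.seed(seed)
  classes <- cso_classes()
  markers <- sprintf("MCB%05d", 1:20)
  planted <- setNames(markers[1:7], classes)
  samples <- dplyr::bind_rows(
    tibble::tibble(sample_id = sprintf("H%03d", 1:n_healthy), label = "healthy",
                   stage = "none"),
    purrr::map_dfr(classes, function(cl) {
      tibble::tibble(sample_id = paste0(cl, 1:n_per_class), label = cl,
                     stage = "III")
    })
  )
  mm <- tidyr::expand_grid(sample_id = samples$sample_id, mcb_id = markers) |>
    dplyr::left_join(samples, by = "sample_id") |>
    dplyr::mutate(
      n_informative = 40L,
      rate = dplyr::if_else(mcb_id == planted[label] & !is.na(planted[label]),
                            0.5, 0.02, missing = 0.02),
      mfc = rbinom(dplyr::n(), n_informative, rate),
      mfr = mfc / n_informative, coverage = 48L
    ) |>
    dplyr::select(sample_id, mcb_id, mfc, n_informative, mfr, coverage)
  list(samples = samples, mm = mm, planted = planted)
}

test_that("diagnostic selection recovers planted per-class markers and unions correctly", {
  cc <- make_selection_cohort()
  sel <- select_diagnostic_markers(cc$mm, cc$samples, top_x = 1)
  expect_setequal(sel$union_markers, unname(cc$planted))
  top1 <- sel$rankings[sel$rankings$rank == 1, ]
  expect_equal(setNames(top1$mcb_id, top1$class), cc$planted)
  # union size bounds: X <= |union| <= 7X
  sel3 <- select_diagnostic_markers(cc$mm, cc$samples, top_x = 3)
  expect_gte(length(sel3$union_markers), 3)
  expect_lte(length(sel3$union_markers), 21)
  # sample order must not matter
  sel_perm <- select_diagnostic_markers(
    cc$mm[sample(nrow(cc$mm)), ], cc$samples[sample(nrow(cc$samples)), ], top_x = 3)
  expect_identical(sel3$union_markers, sel_perm$union_markers)
  # missing class errors
  expect_error(
    select_diagnostic_markers(cc$mm, cc$samples[cc$samples$label != "BRCA", ], 1),
    class = "methtrace_input_error")
})

test_that("optimize_top_x returns the smallest X on AUC ties and respects the grid", {
  cc <- make_selection_cohort()
  expect_error(optimize_top_x(cc$mm, cc$samples, grid = integer(0)),
               class = "methtrace_input_error")
  one <- optimize_top_x(cc$mm, cc$samples, grid = 5)
  expect_equal(one$top_x, 5L)
  opt <- optimize_top_x(cc$mm, cc$samples, grid = 1:6)
  # planted signal is rank 1 per class: AUC plateaus at X = 1
  expect_equal(opt$top_x, 1L)
  expect_true(all(diff(opt$auc_by_x$n_markers) >= 0))
})

test_that("pairwise CSO candidates rank pair-discriminative markers first", {
  cc <- make_selection_cohort(n_per_class = 10)
  cancers <- cc$samples[cc$samples$label != "healthy", ]
  mm_c <- cc$mm[cc$mm$sample_id %in% cancers$sample_id, ]
  cand <- select_cso_candidates(mm_c, cancers, top_k = 2)
  expect_equal(nrow(cand$pair_rankings |> dplyr::distinct(class_a, class_b)), 21)
  # each pair's top-2 should be dominated by the two planted markers
  top <- cand$pair_rankings[cand$pair_rankings$rank <= 2, ]
  hit <- mapply(function(a, b, m) m %in% cc$planted[c(a, b)],
                top$class_a, top$class_b, top$mcb_id)
  expect_gte(mean(hit), 0.8)
  expect_error(select_cso_candidates(mm_c, cancers[cancers$label != "ESCA", ]),
               class = "methtrace_input_error")
})

test_that("backward elimination keeps a separating marker and stops when AIC cannot improve", {
  set.seed(21)
  n <- 60
  labels <- rep(c("a", "b", "c"), each = n / 3)
  x_signal <- c(rnorm(n / 3, -3), rnorm(n / 3, 0), rnorm(n / 3, 3))
  noise <- matrix(rnorm(n * 12), n, 12)
  features <- cbind(sig = x_signal, noise)
  colnames(features) <- c("sig", paste0("noise", sprintf("%02d", 1:12)))
  kept <- backward_eliminate(features, labels, l2_strength = 0.05)
  expect_true("sig" %in% kept)
  expect_lt(length(kept), 13)

  expect_error(backward_eliminate(features[, 0], labels),
               class = "methtrace_input_error")
  expect_error(backward_eliminate(features, rep("a", n)),
               class = "methtrace_input_error")

  # two strong complementary markers, no noise: nothing should be dropped
  strong <- cbind(f1 = x_signal, f2 = as.numeric(labels == "b") * 4 + rnorm(n, sd = 0.1))
  expect_setequal(backward_eliminate(strong, labels, l2_strength = 0.05),
                  c("f1", "f2"))
})

test_that("bootstrapped selection applies the strict retention rule deterministically", {
  set.seed(77)
  n <- 45
  labels <- rep(c("a", "b", "c"), each = 15)
  features <- cbind(
    sig = rep(c(-3, 0, 3), each = 15) + rnorm(n, sd = 0.3),
    matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("n", 1:6)))
  )
  sel1 <- bootstrap_cso_selection(features, labels, seed = 42)
  sel2 <- bootstrap_cso_selection(features, labels, seed = 42)
  expect_identical(sel1$retention, sel2$retention)
  expect_true(all(sel1$retention$retention_count %in% 0:10))
  # strictly-greater rule: a count of exactly 6 is excluded
  expect_identical(sel1$final_markers,
                   sel1$retention$mcb_id[sel1$retention$retention_count > 6])
  expect_true("sig" %in% sel1$final_markers)
  # final set size is non-increasing in the retention threshold
  sizes <- vapply(0:9, function(t) sum(sel1$retention$retention_count > t), integer(1))
  expect_true(all(diff(sizes) <= 0))
  expect_error(bootstrap_cso_selection(features[1:5, ], labels[1:5]),
               class = "methtrace_input_error")
})
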