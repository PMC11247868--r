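test_that("config validation rejects inconsistent settings", {
  expect_error(sim_config(theta_by_stage = c(I = 0.05, II = 0.01, III = 0.03, IV = 0.08)),
               class = "methtrace_input_error")
  expect_error(sim_config(tumor_meth_rate = 1.5), class = "methtrace_input_error")
  expect_error(sim_config(coverage_inflation = 0.5), class = "methtrace_input_error")
  expect_error(sim_config(n_markers = 20), class = "methtrace_input_error")
})

test_that("marker-matrix simulation is reproducible and internally consistent", {
  cfg <- small_config(seed = 3)
  c1 <- simulate_marker_matrix(cfg)
  c2 <- simulate_marker_matrix(small_config(seed = 3))
  expect_identical(c1$marker_matrix, c2$marker_matrix)
  mm <- c1$marker_matrix
  expect_true(all(mm$mfc <= mm$n_informative))
  expect_true(all(mm$n_informative <= mm$coverage))
  expect_true(all(is.na(mm$mfr) | (mm$mfr >= 0 & mm$mfr <= 1)))
  expect_equal(nrow(c1$samples), 12 + 7 * 3)
  expect_equal(length(c1$truth$signatures), 7)
  expect_true(all(lengths(c1$truth$signatures) == 3))
})

test_that("tumor-fraction mixture raises signature MFR in expectation, theta = 0 is null", {
  cfg <- sim_config(n_markers = 90, n_healthy = 150, n_per_class = 60,
                    signature_size = 12, seed = 5,
                    stage_probs = c(I = 0, II = 0, III = 0, IV = 1))
  co <- simulate_marker_matrix(cfg)
  mm <- dplyr::inner_join(co$marker_matrix, co$samples, by = "sample_id")
  sig <- co$truth$signatures$NSCLC
  m_sig_cancer <- mean(mm$mfr[mm$label == "NSCLC" & mm$mcb_id %in% sig], na.rm = TRUE)
  m_sig_healthy <- mean(mm$mfr[mm$label == "healthy" & mm$mcb_id %in% sig], na.rm = TRUE)
  # closed-form expectation: E[MFR] = (1 - theta) E[r0] + theta r_tumor
  theta <- 0.08
  want <- (1 - theta) * m_sig_healthy + theta * 0.6
  expect_equal(m_sig_cancer, want, tolerance = 0.05)
  # non-signature markers unchanged
  other <- setdiff(co$truth$markers, sig)
  expect_equal(mean(mm$mfr[mm$label == "NSCLC" & mm$mcb_id %in% other], na.rm = TRUE),
               mean(mm$mfr[mm$label == "healthy" & mm$mcb_id %in% other], na.rm = TRUE),
               tolerance = 0.1)

  cfg0 <- sim_config(n_markers = 90, n_healthy = 100, n_per_class = 30, seed = 6,
                     theta_by_stage = c(I = 0, II = 0, III = 0, IV = 0))
  co0 <- simulate_marker_matrix(cfg0)
  mm0 <- dplyr::inner_join(co0$marker_matrix, co0$samples, by = "sample_id")
  sig0 <- unique(unlist(co0$truth$signatures))
  expect_equal(
    mean(mm0$mfr[mm0$label != "healthy" & mm0$mcb_id %in% sig0], na.rm = TRUE),
    mean(mm0$mfr[mm0$label == "healthy" & mm0$mcb_id %in% sig0], na.rm = TRUE),
    tolerance = 0.1)
})

test_that("beta-matrix simulation plants recoverable blocks", {
  cfg <- sim_config(seed = 21, n_beta_blocks = 3, beta_block_size = 4)
  sim <- simulate_beta_matrix(cfg)
  mcbs <- call_mcbs(sim$beta)
  expect_equal(nrow(mcbs), 3)
  expect_identical(mcbs$cpg_positions, sim$block_members)
  # same seed -> identical matrix
  sim2 <- simulate_beta_matrix(sim_config(seed = 21, n_beta_blocks = 3,
                                          beta_block_size = 4))
  expect_identical(sim$beta, sim2$beta)
  # zero within-block correlation -> no MCBs
  cfg0 <- sim_config(seed = 22, n_beta_blocks = 3, beta_block_size = 4,
                     beta_noise_sd = 50)
  expect_equal(nrow(call_mcbs(simulate_beta_matrix(cfg0)$beta)), 0)
})

test_that("fragment emission round-trips through quantification bit-exactly", {
  cfg <- small_config(seed = 9)
  co <- simulate_marker_matrix(cfg)
  mcbs <- toy_mcb_panel(cfg$n_markers)
  reads <- simulate_fragments(co, mcbs)
  frags <- filter_fragments(merge_read_pairs(reads))
  got <- quantify_fragments(frags, mcbs) |>
    dplyr::arrange(sample_id, mcb_id)
  want <- co$marker_matrix |> dplyr::arrange(sample_id, mcb_id)
  expect_equal(as.data.frame(got), as.data.frame(want))
  # same seed -> identical read table
  reads2 <- simulate_fragments(co, mcbs)
  expect_identical(reads, reads2)
})

test_that("stratified split honors the ratio per stratum deterministically", {
  samples <- tibble::tibble(
    sample_id = sprintf("S%03d", 1:41),
    label = c(rep("healthy", 10), rep("LIHC", 20), rep("STAD", 10), "BRCA"),
    stage = c(rep("none", 10), rep(c("I", "II"), 10), rep("III", 10), "IV")
  )
  sp1 <- stratified_split(samples, ratio = 0.7, seed = 5)
  sp2 <- stratified_split(samples, ratio = 0.7, seed = 5)
  expect_identical(sp1, sp2)
  counts <- sp1 |>
    dplyr::count(.data$label, .data$stage, .data$split) |>
    tidyr::pivot_wider(names_from = "split", values_from = "n", values_fill = 0)
  ten <- counts[counts$label == "LIHC" & counts$stage == "I", ]
  expect_equal(ten$train, 7)  # 10 * 0.7 exactly
  expect_equal(ten$test, 3)
  singleton <- counts[counts$label == "BRCA", ]
  expect_equal(singleton$train, 1)   # singleton stratum goes to train
  expect_error(stratified_split(samples[0, ]), class = "methtrace_input_error")
})

test_that("cohorts write to plain-text artifacts", {
  co <- simulate_marker_matrix(small_config(seed = 2))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_true(all(file.exists(file.path(dir, c("samples.tsv", "marker_matrix.tsv",
                                               "truth.json")))))
  back <- read_marker_matrix(file.path(dir, "marker_matrix.tsv"))
  expect_equal(nrow(back), nrow(co$marker_matrix))
})
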