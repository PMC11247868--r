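#' End-to-end two-step pipeline
#'
#' Runs the full two-step procedure on a marker matrix with a sample sheet:
#' diagnostic marker selection (MI, AUC-optimized top-X union), healthy
#' baseline + methylation score + specificity-calibrated threshold,
#' evaluation on the held-out split, true-positive gating, CSO marker
#' selection (pairwise MI + bootstrapped backward elimination) and the
#' stacked CSO ensemble with top-1/top-2 and HPCA-merged accuracies.
#'
#' @param mm long marker-matrix tibble.
#' @param samples sample sheet (`sample_id, label, stage`); a `split`
#'   column is honored, otherwise a stratified 7:3 split is drawn from
#'   `seed`.
#' @param top_x_grid candidate values of X for the diagnostic union.
#' @param specificity training-specificity target (default 0.98).
#' @param cso_top_k markers per pairwise MI list for CSO candidates.
#' @param n_bootstraps,retention_threshold,l2_strength CSO selection
#'   parameters, see [bootstrap_cso_selection()].
#' @param k_folds,n_repeats ensemble bagging scheme.
#' @param value,mi_bins,binarize MI input statistic and discretization.
#' @param seed run seed; every stochastic step derives from it.
#' @param min_class_tp smallest per-class true-positive count eligible for
#'   CSO training (classes below it are dropped with a warning; CSO is
#'   skipped entirely when fewer than two classes remain).
#' @return Object of class `mt_report`; see [glance.mt_report()].
#' @export
run_pipeline <- function(mm, samples,
                         top_x_grid = 1:20,
                         specificity = 0.98,
                         cso_top_k = 10,
                         n_bootstraps = 10,
                         retention_threshold = 6,
                         l2_strength = 0.05,
                         k_folds = 5,
                         n_repeats = 2,
                         value = "mfc",
                         mi_bins = 4,
                         binarize = FALSE,
                         seed = 1,
                         min_class_tp = NULL) {
  min_class_tp <- max(min_class_tp %||% k_folds, k_folds)
  check_marker_matrix(mm); check_sample_sheet(samples)
  if (!"split" %in% names(samples)) {
    samples <- stratified_split(samples, ratio = 0.7, seed = seed)
  }
  train <- samples[samples$split == "train", ]
  test <- samples[samples$split == "test", ]
  mm_train <- mm[mm$sample_id %in% train$sample_id, ]

  # -- step 1: diagnostic markers, score model, threshold -------------------
  opt <- optimize_top_x(mm_train, train, grid = top_x_grid, value = value,
                        n_bins = mi_bins, binarize = binarize,
                        specificity = specificity)
  diag_markers <- opt$selection$union_markers
  healthy_train <- train$sample_id[train$label == "healthy"]
  baseline <- fit_baseline(mm, healthy_train, markers = diag_markers)
  scores <- score_samples(mm, baseline, markers = diag_markers)
  train_scores <- scores[scores$sample_id %in% train$sample_id, ]
  test_scores <- scores[scores$sample_id %in% test$sample_id, ]
  threshold <- calibrate_threshold(
    train_scores$methylation_score[train_scores$sample_id %in% healthy_train],
    specificity = specificity
  )
  lab <- setNames(samples$label, samples$sample_id)
  auc_train <- roc_auc(train_scores$methylation_score,
                       lab[train_scores$sample_id] != "healthy")
  auc_test <- roc_auc(test_scores$methylation_score,
                      lab[test_scores$sample_id] != "healthy")
  eval_train <- sensitivity_report(train_scores, train, threshold)
  eval_test <- sensitivity_report(test_scores, test, threshold)

  # -- step 2: true-positive gating and CSO ---------------------------------
  positive <- scores$sample_id[classify_scores(scores$methylation_score, threshold)]
  tp_train <- train[train$label != "healthy" & train$sample_id %in% positive, ]
  tp_test <- test[test$label != "healthy" & test$sample_id %in% positive, ]

  cso <- NULL
  tp_counts <- table(tp_train$label)
  eligible <- names(tp_counts)[tp_counts >= min_class_tp]
  if (length(eligible) < length(unique(tp_train$label))) {
    dropped <- setdiff(unique(tp_train$label), eligible)
    if (length(dropped)) {
      rlang::warn(paste("classes with too few true positives dropped from CSO:",
                        paste(dropped, collapse = ", ")))
    }
  }
  if (length(eligible) >= 2) {
    tp_train <- tp_train[tp_train$label %in% eligible, ]
    tp_test <- tp_test[tp_test$label %in% eligible, ]
    mm_tp <- mm[mm$sample_id %in% tp_train$sample_id, ]
    cand <- select_cso_candidates(mm_tp, tp_train, top_k = cso_top_k,
                                  classes = eligible, value = value,
                                  n_bins = mi_bins, binarize = binarize)
    preproc_all <- fit_cso_preprocessor(mm_tp, cand$candidates)
    feats_train_all <- predict(preproc_all, mm_tp)
    feats_train_all <- feats_train_all[tp_train$sample_id, , drop = FALSE]
    sel <- bootstrap_cso_selection(
      feats_train_all, setNames(tp_train$label, tp_train$sample_id),
      n_bootstraps = n_bootstraps, retention_threshold = retention_threshold,
      l2_strength = l2_strength, seed = derive_seed(seed, 7)
    )
    final_markers <- sel$final_markers
    if (!length(final_markers)) {
      rlang::warn("no marker passed the retention threshold; falling back to max-retention markers")
      mx <- max(sel$retention$retention_count)
      final_markers <- sel$retention$mcb_id[sel$retention$retention_count == mx]
    }
    preproc <- fit_cso_preprocessor(mm_tp, final_markers)
    feats_train <- predict(preproc, mm_tp)[tp_train$sample_id, , drop = FALSE]
    model <- train_cso_ensemble(feats_train, tp_train$label,
                                k_folds = k_folds, n_repeats = n_repeats,
                                seed = derive_seed(seed, 8))
    cso_metrics <- NULL; pred_test <- NULL
    if (nrow(tp_test) >= 2) {
      mm_tp_test <- mm[mm$sample_id %in% tp_test$sample_id, ]
      feats_test <- predict(preproc, mm_tp_test)[tp_test$sample_id, , drop = FALSE]
      pred_test <- predict(model, feats_test)
      truth <- setNames(tp_test$label, tp_test$sample_id)[pred_test$sample_id]
      cso_metrics <- bind_rows(
        top_k_accuracy(pred_test, truth, 1) |> mutate(schema = "7-class"),
        top_k_accuracy(pred_test, truth, 2) |> mutate(schema = "7-class")
      )
      if (all(c("p_LIHC", "p_PAAD") %in% names(pred_test))) {
        merged <- merge_hpca(pred_test)
        cso_metrics <- bind_rows(
          cso_metrics,
          top_k_accuracy(merged, hpca_labels(truth), 1) |> mutate(schema = "HPCA-merged"),
          top_k_accuracy(merged, hpca_labels(truth), 2) |> mutate(schema = "HPCA-merged")
        )
      }
    }
    cso <- list(candidates = cand, selection = sel, final_markers = final_markers,
                preprocessor = preproc, model = model,
                prediction_test = pred_test, metrics = cso_metrics,
                n_tp_train = nrow(tp_train), n_tp_test = nrow(tp_test))
  } else {
    rlang::warn("fewer than two classes with enough true positives: CSO step skipped")
  }

  structure(
    list(samples = samples, selection = opt$selection, auc_by_x = opt$auc_by_x,
         top_x = opt$top_x, diag_markers = diag_markers,
         baseline = baseline, threshold = threshold, scores = scores,
         auc = tibble(cohort = c("train", "test"), auc = c(auc_train, auc_test)),
         eval_train = eval_train, eval_test = eval_test,
         cso = cso, seed = seed,
         params = list(specificity = specificity, cso_top_k = cso_top_k,
                       n_bootstraps = n_bootstraps,
                       retention_threshold = retention_threshold,
                       l2_strength = l2_strength, k_folds = k_folds,
                       n_repeats = n_repeats, value = value)),
    class = "mt_report"
  )
}

#' @export
print.mt_report <- function(x, ...) {
  cat("<mt_report>\n")
  cat(sprintf("  diagnostic markers: %d (top-X = %d per class)\n",
              length(x$diag_markers), x$top_x))
  cat(sprintf("  cutoff %.4f at %.0f%% training specificity\n",
              x$threshold$cutoff, 100 * x$threshold$specificity))
  cat(sprintf("  AUC: train %.3f / test %.3f\n",
              x$auc$auc[1], x$auc$auc[2]))
  ov <- x$eval_test$overall
  for (i in seq_len(nrow(ov))) {
    cat(sprintf("  test %s: %.3f (95%% CI %.3f-%.3f, n=%d)\n", ov$metric[i],
                ov$estimate[i], ov$conf_low[i], ov$conf_high[i], ov$n[i]))
  }
  if (!is.null(x$cso)) {
    cat(sprintf("  CSO markers: %d; true positives train/test: %d/%d\n",
                length(x$cso$final_markers), x$cso$n_tp_train, x$cso$n_tp_test))
    if (!is.null(x$cso$metrics)) {
      m <- x$cso$metrics
      for (i in seq_len(nrow(m))) {
        cat(sprintf("  CSO top-%d (%s): %.3f (95%% CI %.3f-%.3f)\n",
                    m$k[i], m$schema[i], m$accuracy[i], m$conf_low[i], m$conf_high[i]))
      }
    }
  } else cat("  CSO step skipped\n")
  invisible(x)
}

#' Marker-count pruning sweeps
#'
#' Diagnostic AUC as a function of the per-class marker count X, and the
#' CSO marker count as a function of the bootstrap-retention threshold.
#' Marker counts are always reported; CSO ensembles are only retrained over
#' the retention grid when `evaluate_cso = TRUE` (each point refits the
#' full stack).
#'
#' @param report `mt_report` from [run_pipeline()].
#' @param mm,samples the matrix and sample sheet the report was built from.
#' @param x_grid top-X grid (default 1..max fitted X).
#' @param retention_grid retention thresholds (default 0:9).
#' @param evaluate_cso retrain the CSO ensemble per retention point.
#' @return List of tibbles `diagnostic` (`top_x, n_markers, auc_train,
#'   auc_test`) and `cso` (`retention_threshold, n_markers[, top1, top2]`).
#' @export
marker_count_sweep <- function(report, mm, samples,
                               x_grid = NULL, retention_grid = 0:9,
                               evaluate_cso = FALSE) {
  stopifnot(inherits(report, "mt_report"))
  rankings <- report$selection$rankings
  max_x <- max(rankings$rank)
  x_grid <- x_grid %||% seq_len(min(20, max_x))
  if (any(x_grid > max_x)) {
    rlang::warn("X grid exceeds ranked markers; truncated")
    x_grid <- x_grid[x_grid <= max_x]
  }
  train <- samples[samples$split == "train", ]
  healthy_train <- train$sample_id[train$label == "healthy"]
  grand <- diag_union(rankings, max(x_grid))
  baseline <- fit_baseline(mm, healthy_train, markers = grand)
  contrib <- score_contributions(mm, baseline)
  lab <- setNames(samples$label, samples$sample_id)
  split <- setNames(samples$split, samples$sample_id)
  diagnostic <- purrr::map_dfr(x_grid, function(x) {
    mk <- diag_union(rankings, x)
    sc <- combine_contributions(contrib, mk)
    is_case <- lab[sc$sample_id] != "healthy"
    tr <- split[sc$sample_id] == "train"
    tibble(top_x = x, n_markers = length(mk),
           auc_train = roc_auc(sc$methylation_score[tr], is_case[tr]),
           auc_test = roc_auc(sc$methylation_score[!tr], is_case[!tr]))
  })

  cso_tbl <- NULL
  if (!is.null(report$cso)) {
    retention <- report$cso$selection$retention
    cso_tbl <- purrr::map_dfr(retention_grid, function(t) {
      mk <- retention$mcb_id[retention$retention_count > t]
      row <- tibble(retention_threshold = t, n_markers = length(mk))
      if (evaluate_cso && length(mk) >= 2) {
        res <- retrain_cso_at(report, mm, samples, mk)
        row$top1 <- res$top1; row$top2 <- res$top2
      }
      row
    })
  }
  list(diagnostic = diagnostic, cso = cso_tbl)
}

retrain_cso_at <- function(report, mm, samples, markers) {
  positive <- report$scores$sample_id[
    classify_scores(report$scores$methylation_score, report$threshold)]
  eligible <- report$cso$model$classes
  tp <- samples[samples$label %in% eligible & samples$sample_id %in% positive, ]
  tp_train <- tp[tp$split == "train", ]; tp_test <- tp[tp$split == "test", ]
  preproc <- fit_cso_preprocessor(mm[mm$sample_id %in% tp_train$sample_id, ], markers)
  ftr <- predict(preproc, mm[mm$sample_id %in% tp_train$sample_id, ])[tp_train$sample_id, , drop = FALSE]
  model <- train_cso_ensemble(ftr, tp_train$label,
                              k_folds = report$params$k_folds,
                              n_repeats = report$params$n_repeats,
                              seed = derive_seed(report$seed, 8))
  fte <- predict(preproc, mm[mm$sample_id %in% tp_test$sample_id, ])[tp_test$sample_id, , drop = FALSE]
  pred <- predict(model, fte)
  truth <- setNames(tp_test$label, tp_test$sample_id)[pred$sample_id]
  list(top1 = top_k_accuracy(pred, truth, 1)$accuracy,
       top2 = top_k_accuracy(pred, truth, 2)$accuracy)
}

#' Serialize / restore the fitted score model
#'
#' The diagnostic score model (marker ids, baseline mean/sd, sigma floor,
#' logit correction, cutoff, specificity target, quantile convention)
#' round-trips through JSON.
#'
#' @param report `mt_report` (or a list with `baseline`, `threshold`,
#'   `diag_markers`).
#' @param path JSON path.
#' @return [read_score_model()]: list with `baseline` (`mt_baseline`) and
#'   `threshold` (`mt_threshold`).
#' @export
write_score_model <- function(report, path) {
  b <- as_tibble(report$baseline)
  jsonlite::write_json(
    list(
      markers = report$diag_markers,
      baseline = b,
      sigma_floor = attr(report$baseline, "sigma_floor"),
      logit_correction = "p = (mfc + 0.5) / (n_informative + 1)",
      cutoff = report$threshold$cutoff,
      specificity = report$threshold$specificity,
      quantile_convention = report$threshold$convention,
      n_controls = report$threshold$n_controls
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_score_model
#' @export
read_score_model <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  baseline <- as_tibble(m$baseline)
  attr(baseline, "sigma_floor") <- m$sigma_floor
  class(baseline) <- c("mt_baseline", class(baseline))
  threshold <- structure(
    list(cutoff = m$cutoff, specificity = m$specificity,
         convention = m$quantile_convention, n_controls = m$n_controls),
    class = "mt_threshold"
  )
  list(markers = m$markers, baseline = baseline, threshold = threshold)
}
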