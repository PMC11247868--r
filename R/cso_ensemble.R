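#' Cancer-signal-origin (CSO) stacked ensemble
#'
#' Seven-class localization of a detected cancer signal from the MFR
#' profile over the CSO marker set. Features are logit-MFR values Z-score
#' normalized with training-sample statistics. A base layer of four
#' learner families (gradient-boosted trees, random forest, L2 multinomial
#' regression, single-hidden-layer neural network) is trained under
#' repeated stratified k-fold bagging; their out-of-fold class
#' probabilities, concatenated with the preprocessed features, feed two
#' stacker models (multinomial regression and gradient boosting); the
#' final probability is a convex combination of the stackers chosen by
#' greedy forward selection on out-of-fold log-loss. No sample's stacking
#' input ever comes from a base model trained on it.
#'
#' @name cso_ensemble
NULL

#' Fit the CSO feature preprocessor
#'
#' Stores, per marker, the training mean and standard deviation of
#' logit-MFR (continuity-corrected, see [logit_mfr()]); applying it yields
#' `(x - mean) / sd` with missing MFRs imputed to the training mean
#' (feature 0 after normalization).
#'
#' @param mm long marker-matrix tibble of the training samples.
#' @param markers CSO marker ids.
#' @param sd_floor lower bound on the stored standard deviation.
#' @return Object of class `mt_cso_preproc`.
#' @export
fit_cso_preprocessor <- function(mm, markers, sd_floor = 1e-6) {
  check_marker_matrix(mm)
  mm <- mm[mm$mcb_id %in% markers, ]
  stats_tbl <- mm |>
    filter(.data$n_informative > 0) |>
    mutate(x = logit_mfr(.data$mfc, .data$n_informative)) |>
    group_by(.data$mcb_id) |>
    summarise(center = mean(.data$x), scale = max(sd(.data$x), sd_floor),
              .groups = "drop")
  missing <- setdiff(markers, stats_tbl$mcb_id)
  if (length(missing)) {
    stats_tbl <- bind_rows(stats_tbl,
                           tibble(mcb_id = missing, center = 0, scale = 1))
  }
  stats_tbl <- stats_tbl[match(sort(markers), stats_tbl$mcb_id), ]
  structure(list(stats = stats_tbl, markers = sort(markers), sd_floor = sd_floor),
            class = "mt_cso_preproc")
}

#' Apply a fitted CSO preprocessor
#'
#' @param object `mt_cso_preproc` from [fit_cso_preprocessor()].
#' @param mm long marker-matrix tibble to transform.
#' @param ... unused.
#' @return Numeric matrix (samples x markers) of normalized logit-MFR
#'   features; rownames are sample ids.
#' @export
predict.mt_cso_preproc <- function(object, mm, ...) {
  check_marker_matrix(mm)
  unknown <- setdiff(unique(mm$mcb_id[mm$mcb_id %in% object$markers]), object$markers)
  mm <- mm[mm$mcb_id %in% object$markers, ]
  if (!nrow(mm)) stop_input("no rows for the preprocessor's markers")
  mm <- mm |> mutate(x = logit_mfr(.data$mfc, .data$n_informative))
  xw <- mm_wide(mm, "x", markers = object$markers)
  if (!setequal(colnames(xw), object$markers)) {
    add <- setdiff(object$markers, colnames(xw))
    xw <- cbind(xw, matrix(NA_real_, nrow(xw), length(add),
                           dimnames = list(NULL, add)))
    xw <- xw[, object$markers, drop = FALSE]
  }
  ctr <- setNames(object$stats$center, object$stats$mcb_id)[colnames(xw)]
  scl <- setNames(object$stats$scale, object$stats$mcb_id)[colnames(xw)]
  feats <- sweep(sweep(xw, 2, ctr), 2, scl, "/")
  feats[is.na(feats)] <- 0   # missing -> training mean
  feats
}

# ---- learner registry ------------------------------------------------------
# each learner: fit(x, y, seed) -> model; prob(model, x) -> n x K matrix with
# colnames = class levels (alphabetical)

learner_glmnet <- list(
  fit = function(x, y, seed) {
    # glmnet needs >= 2 columns; pad single-feature models with a zero dummy
    if (ncol(x) < 2) x <- cbind(x, `.pad` = 0)
    suppressWarnings(
      glmnet::glmnet(x, y, family = "multinomial", alpha = 0, lambda = 0.05,
                     standardize = FALSE))
  },
  prob = function(m, x) {
    if (ncol(x) < 2) x <- cbind(x, `.pad` = 0)
    predict(m, newx = x, type = "response")[, , 1]
  }
)

learner_ranger <- list(
  fit = function(x, y, seed) {
    ranger::ranger(x = as.data.frame(x), y = factor(y), probability = TRUE,
                   num.trees = 300, seed = seed, num.threads = 1)
  },
  prob = function(m, x) {
    p <- predict(m, data = as.data.frame(x), num.threads = 1)$predictions
    p[, sort(colnames(p)), drop = FALSE]
  }
)

xgb_fit <- function(x, y, seed, max_depth, nrounds, colsample = 1) {
  yl <- factor(y)
  dtrain <- xgboost::xgb.DMatrix(x, label = as.integer(yl) - 1L, nthread = 1)
  m <- xgboost::xgb.train(
    params = list(objective = "multi:softprob", num_class = nlevels(yl),
                  max_depth = max_depth, eta = 0.3, subsample = 0.9,
                  colsample_bytree = colsample, nthread = 1,
                  seed = seed %% .Machine$integer.max),
    data = dtrain, nrounds = nrounds, verbose = 0
  )
  attr(m, "classes") <- levels(yl)
  m
}

xgb_prob <- function(m, x) {
  p <- predict(m, x)
  colnames(p) <- attr(m, "classes")
  p
}

learner_xgboost <- list(
  fit = function(x, y, seed) xgb_fit(x, y, seed, max_depth = 3, nrounds = 60,
                                     colsample = 0.8),
  prob = xgb_prob
)

learner_nnet <- list(
  fit = function(x, y, seed) {
    set.seed(seed)
    m <- suppressWarnings(
      nnet::nnet(x = x, y = stats::model.matrix(~ factor(y) - 1),
                 size = 8, decay = 0.5, maxit = 300, MaxNWts = 1e5,
                 softmax = TRUE, trace = FALSE))
    attr(m, "classes") <- sort(unique(as.character(y)))
    m
  },
  prob = function(m, x) {
    p <- predict(m, x)
    colnames(p) <- attr(m, "classes")
    p
  }
)

base_learners <- function() {
  list(gbt = learner_xgboost, rf = learner_ranger,
       mlr = learner_glmnet, nnet = learner_nnet)
}

stacker_learners <- function() {
  list(
    mlr = learner_glmnet,
    gbt = list(
      fit = function(x, y, seed) xgb_fit(x, y, seed, max_depth = 2, nrounds = 60),
      prob = xgb_prob
    )
  )
}

# stratified fold assignment, deterministic under the given seed
stratified_folds <- function(labels, k, seed) {
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in sort(unique(labels))) {
    rows <- which(labels == cl)
    fold[rows] <- sample(rep_len(seq_len(k), length(rows)))
  }
  fold
}

mean_log_loss <- function(prob, truth) {
  i <- cbind(seq_along(truth), match(truth, colnames(prob)))
  -mean(log(pmax(prob[i], 1e-15)))
}

# renormalize rows to sum exactly 1 (guards numeric drift from learners)
normalize_rows <- function(p) {
  p <- pmax(p, 0)
  sweep(p, 1, rowSums(p), "/")
}

#' Train the CSO stacked ensemble
#'
#' @param features numeric matrix (samples x markers) from
#'   [predict.mt_cso_preproc()]; rownames are sample ids.
#' @param labels cancer class per row.
#' @param k_folds folds for repeated stratified k-fold bagging (default 5).
#' @param n_repeats fold repeats (default 2).
#' @param seed run seed controlling folds and every learner.
#' @param n_blend_iter greedy forward-selection iterations for the final
#'   stacker weights (default 25).
#' @return Object of class `mt_cso_model`.
#' @export
train_cso_ensemble <- function(features, labels, k_folds = 5, n_repeats = 2,
                               seed = 1, n_blend_iter = 25) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop_input("need >= 2 classes")
  counts <- table(labels)
  if (any(counts < k_folds)) {
    stop_input("every class needs >= k_folds samples; short: ",
               paste(names(counts)[counts < k_folds], collapse = ", "))
  }
  n <- nrow(features); K <- length(classes)
  bases <- base_learners()

  # --- out-of-fold base probabilities, averaged over repeats --------------
  oof <- array(0, dim = c(n, K, length(bases)),
               dimnames = list(NULL, classes, names(bases)))
  fold_of <- matrix(0L, n, n_repeats)
  for (r in seq_len(n_repeats)) {
    fold <- stratified_folds(labels, k_folds, derive_seed(seed, 100 + r))
    fold_of[, r] <- fold
    for (f in seq_len(k_folds)) {
      tr <- fold != f; te <- fold == f
      for (b in seq_along(bases)) {
        m <- bases[[b]]$fit(features[tr, , drop = FALSE], labels[tr],
                            derive_seed(seed, 1000 * r + 10 * f + b))
        pr <- bases[[b]]$prob(m, features[te, , drop = FALSE])
        oof[te, , b] <- oof[te, , b] + pr[, classes, drop = FALSE] / n_repeats
      }
    }
  }
  oof_flat <- do.call(cbind, lapply(seq_along(bases), function(b) {
    m <- oof[, , b, drop = TRUE]
    colnames(m) <- paste0(names(bases)[b], ".", classes)
    m
  }))
  stack_x <- cbind(oof_flat, features)

  # --- stackers: out-of-fold predictions for weight selection -------------
  stackers <- stacker_learners()
  sfold <- stratified_folds(labels, k_folds, derive_seed(seed, 555))
  stacker_oof <- lapply(seq_along(stackers), function(s) {
    p <- matrix(NA_real_, n, K, dimnames = list(NULL, classes))
    for (f in seq_len(k_folds)) {
      tr <- sfold != f; te <- sfold == f
      m <- stackers[[s]]$fit(stack_x[tr, , drop = FALSE], labels[tr],
                             derive_seed(seed, 2000 + 10 * f + s))
      p[te, ] <- stackers[[s]]$prob(m, stack_x[te, , drop = FALSE])[, classes]
    }
    p
  })

  # --- greedy forward selection (with replacement) of stacker weights -----
  picks <- integer(0)
  ens <- matrix(0, n, K)
  best_ll <- Inf
  for (it in seq_len(n_blend_iter)) {
    lls <- vapply(seq_along(stackers), function(s) {
      mean_log_loss(normalize_rows((ens * length(picks) + stacker_oof[[s]]) /
                                     (length(picks) + 1)), labels)
    }, numeric(1))
    s_best <- which.min(lls)   # first index on ties: deterministic
    if (length(picks) && lls[s_best] >= best_ll) break
    picks <- c(picks, s_best)
    ens <- (ens * (length(picks) - 1) + stacker_oof[[s_best]]) / length(picks)
    best_ll <- lls[s_best]
  }
  weights <- tabulate(picks, nbins = length(stackers)) / length(picks)
  names(weights) <- names(stackers)

  # --- refit everything on the full training data --------------------------
  base_full <- lapply(seq_along(bases), function(b) {
    bases[[b]]$fit(features, labels, derive_seed(seed, 9000 + b))
  })
  names(base_full) <- names(bases)
  stacker_full <- lapply(seq_along(stackers), function(s) {
    stackers[[s]]$fit(stack_x, labels, derive_seed(seed, 9500 + s))
  })
  names(stacker_full) <- names(stackers)

  structure(
    list(classes = classes, base_models = base_full,
         stacker_models = stacker_full, weights = weights,
         marker_names = colnames(features),
         k_folds = k_folds, n_repeats = n_repeats, seed = seed,
         oof_log_loss = best_ll),
    class = "mt_cso_model"
  )
}

#' @export
print.mt_cso_model <- function(x, ...) {
  cat("<mt_cso_model>", length(x$classes), "classes,",
      length(x$marker_names), "markers; stacker weights:",
      paste(sprintf("%s=%.2f", names(x$weights), x$weights), collapse = ", "),
      "\n")
  invisible(x)
}

#' Predict CSO class probabilities
#'
#' @param object `mt_cso_model` from [train_cso_ensemble()].
#' @param features preprocessed feature matrix with the training marker
#'   columns; rownames are sample ids.
#' @param ... unused.
#' @return Tibble: `sample_id`, one probability column `p_<class>` per
#'   class (rows sum to 1), `top1`, `top2` (ties broken by class order).
#' @export
predict.mt_cso_model <- function(object, features, ...) {
  features <- as.matrix(features)
  if (!setequal(colnames(features), object$marker_names)) {
    stop_input("feature schema mismatch with the fitted model")
  }
  features <- features[, object$marker_names, drop = FALSE]
  bases <- base_learners()
  base_prob <- lapply(names(object$base_models), function(b) {
    p <- bases[[b]]$prob(object$base_models[[b]], features)
    p <- p[, object$classes, drop = FALSE]
    colnames(p) <- paste0(b, ".", object$classes)
    p
  })
  stack_x <- cbind(do.call(cbind, base_prob), features)
  stackers <- stacker_learners()
  prob <- matrix(0, nrow(features), length(object$classes),
                 dimnames = list(NULL, object$classes))
  for (s in names(object$stacker_models)) {
    if (object$weights[s] > 0) {
      ps <- stackers[[s]]$prob(object$stacker_models[[s]], stack_x)
      prob <- prob + object$weights[s] * ps[, object$classes, drop = FALSE]
    }
  }
  prob <- normalize_rows(prob)
  prediction_tibble(prob, rownames(features))
}

# prob matrix (+ sample ids) -> prediction tibble with ranked classes
prediction_tibble <- function(prob, sample_ids = NULL) {
  classes <- colnames(prob)
  ranks <- t(apply(prob, 1, function(p) order(-p, classes)))
  out <- as_tibble(prob, .name_repair = "minimal")
  names(out) <- paste0("p_", classes)
  out <- bind_cols(
    tibble(sample_id = sample_ids %||% as.character(seq_len(nrow(prob)))),
    out,
    tibble(top1 = classes[ranks[, 1]],
           top2 = if (ncol(prob) >= 2) classes[ranks[, 2]] else NA_character_)
  )
  out
}

pred_prob_matrix <- function(pred) {
  cols <- grep("^p_", names(pred), value = TRUE)
  m <- as.matrix(pred[cols])
  colnames(m) <- sub("^p_", "", cols)
  rownames(m) <- pred$sample_id
  m
}

#' Top-k accuracy with a Wilson interval
#'
#' Fraction of samples whose true class is among the k most probable
#' predicted classes (probability ties broken by class order before
#' evaluation).
#'
#' @param pred prediction tibble from [predict.mt_cso_model()] (columns
#'   `p_<class>`).
#' @param truth true class per row.
#' @param k number of top classes considered (1 <= k <= number of classes).
#' @return Tibble `k, accuracy, conf_low, conf_high, n`.
#' @export
top_k_accuracy <- function(pred, truth, k = 1) {
  prob <- pred_prob_matrix(pred)
  classes <- colnames(prob)
  if (k < 1 || k > length(classes)) stop_input("k must be in 1..n_classes")
  hit <- vapply(seq_len(nrow(prob)), function(i) {
    topk <- classes[order(-prob[i, ], classes)][seq_len(k)]
    as.character(truth[i]) %in% topk
  }, logical(1))
  wilson_ci(sum(hit), length(hit)) |>
    rename(accuracy = "estimate") |>
    mutate(k = as.integer(k), .before = 1)
}

#' Merge LIHC and PAAD into a hepatopancreatic (HPCA) class
#'
#' The HPCA probability is the sum of the LIHC and PAAD probabilities;
#' other classes are unchanged and rows still sum to 1. For scoring, map
#' LIHC/PAAD truth labels to "HPCA" (see [hpca_labels()]).
#'
#' @param pred prediction tibble with `p_LIHC` and `p_PAAD` columns.
#' @return Prediction tibble over the merged 6-class schema, re-ranked.
#' @export
merge_hpca <- function(pred) {
  if (!all(c("p_LIHC", "p_PAAD") %in% names(pred))) {
    stop_input("prediction schema must include LIHC and PAAD")
  }
  prob <- pred_prob_matrix(pred)
  merged <- prob[, setdiff(colnames(prob), c("LIHC", "PAAD")), drop = FALSE]
  merged <- cbind(merged, HPCA = prob[, "LIHC"] + prob[, "PAAD"])
  merged <- merged[, sort(colnames(merged)), drop = FALSE]
  prediction_tibble(merged, pred$sample_id)
}

#' @rdname merge_hpca
#' @param labels true class labels.
#' @return [hpca_labels()]: labels with LIHC/PAAD replaced by "HPCA".
#' @export
hpca_labels <- function(labels) {
  ifelse(labels %in% c("LIHC", "PAAD"), "HPCA", as.character(labels))
}
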