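#' Marker selection by mutual information
#'
#' Diagnostic markers are chosen per cancer type by the mutual information
#' (MI) between a marker's methylated fragment count (MFC) and the
#' cancer-vs-healthy label on training samples; the union of per-class
#' top-X lists is the multi-cancer diagnostic set. CSO (cancer signal
#' origin) markers start from the union of pairwise top-k MI lists over the
#' 21 unordered cancer-type pairs and are pruned by AIC-guided backward
#' elimination of an L2-penalized multinomial model over bootstrap
#' subsamples, keeping markers retained in more than `retention_threshold`
#' bootstraps.
#'
#' @name marker_selection
NULL

# Equal-frequency discretization on average ranks. Rank-based cutting keeps
# tied values (the zero-inflated mass of MFC distributions) in one bin while
# still splitting the non-tied tail; constant vectors collapse to one bin.
discretize_quantile <- function(values, n_bins = 4) {
  if (length(unique(values)) <= 1) return(rep(1L, length(values)))
  r <- rank(values, ties.method = "average")
  as.integer(cut(r, breaks = n_bins))
}

#' Plug-in mutual information between a marker statistic and group labels
#'
#' Values are discretized (equal-frequency quantile bins, degenerate bins
#' merged; or binarized at `value > 0`) and the plug-in MI
#' \eqn{\sum p(x,y) \log_2 p(x,y) / (p(x)p(y))} is computed in bits.
#'
#' @param values numeric per-sample statistic (typically MFC).
#' @param labels group label per sample; must contain at least two groups
#'   with two or more samples each.
#' @param n_bins number of quantile bins (default 4).
#' @param binarize if `TRUE`, discretize as `values > 0` instead of
#'   quantile binning.
#' @return MI in bits (non-negative scalar).
#' @examples
#' mutual_information(c(0, 0, 1, 5, 6, 9), rep(c("a", "b"), each = 3))
#' @export
mutual_information <- function(values, labels, n_bins = 4, binarize = FALSE) {
  ok <- !is.na(values) & !is.na(labels)
  values <- values[ok]; labels <- as.character(labels[ok])
  tab_lab <- table(labels)
  if (length(tab_lab) < 2) stop_input("labels must contain at least two groups")
  if (any(tab_lab < 2)) stop_input("each group needs >= 2 samples")
  bins <- if (binarize) as.integer(values > 0) else discretize_quantile(values, n_bins)
  mi_from_table(table(bins, labels))
}

# plug-in MI (bits) from a contingency table
mi_from_table <- function(tab) {
  n <- sum(tab)
  pxy <- tab / n
  px <- rowSums(pxy); py <- colSums(pxy)
  idx <- pxy > 0
  sum(pxy[idx] * log2(pxy[idx] / outer(px, py)[idx]))
}

# MI of every column of a samples x markers matrix against labels
mi_by_marker <- function(vals, labels, n_bins = 4, binarize = FALSE) {
  apply(vals, 2, function(v) {
    ok <- !is.na(v)
    if (sum(ok) < 4) return(NA_real_)
    bins <- if (binarize) as.integer(v[ok] > 0) else discretize_quantile(v[ok], n_bins)
    mi_from_table(table(bins, labels[ok]))
  })
}

#' Select multi-cancer diagnostic markers
#'
#' For each cancer class, markers are ranked by MI between the marker
#' statistic and the class-vs-healthy label on training samples
#' (descending, ties broken by marker id); the union of per-class top-X
#' lists is the diagnostic marker set.
#'
#' @param mm long marker-matrix tibble (see [quantify_fragments()]).
#' @param samples sample sheet tibble (`sample_id`, `label`, optionally
#'   `stage`, `split`); pass the *training* samples.
#' @param top_x number of markers per class (X).
#' @param value which statistic feeds MI: `"mfc"` (default) or `"mfr"`.
#' @param n_bins,binarize discretization, see [mutual_information()].
#' @return An object of class `mt_diag_selection`: list with `rankings`
#'   (tibble `class, rank, mcb_id, mi_bits`), `top_x`, `union_markers`.
#' @export
select_diagnostic_markers <- function(mm, samples, top_x = 10, value = "mfc",
                                      n_bins = 4, binarize = FALSE) {
  check_marker_matrix(mm); check_sample_sheet(samples)
  classes <- sort(setdiff(unique(samples$label), "healthy"))
  if (!"healthy" %in% samples$label) stop_input("no healthy training samples")
  missing <- setdiff(cso_classes(), classes)
  if (length(missing)) stop_input("missing cancer classes: ", paste(missing, collapse = ", "))
  mm <- mm[mm$sample_id %in% samples$sample_id, ]
  vals <- mm_wide(mm, value)
  labs <- setNames(samples$label, samples$sample_id)[rownames(vals)]
  rankings <- purrr::map_dfr(classes, function(cl) {
    keep <- labs %in% c("healthy", cl)
    mi <- mi_by_marker(vals[keep, , drop = FALSE], labs[keep] == cl,
                       n_bins = n_bins, binarize = binarize)
    ord <- order(-mi, names(mi))
    tibble(class = cl, rank = seq_along(mi), mcb_id = names(mi)[ord],
           mi_bits = unname(mi[ord]))
  })
  sel <- structure(
    list(rankings = rankings, top_x = top_x,
         union_markers = diag_union(rankings, top_x),
         value = value, n_bins = n_bins, binarize = binarize),
    class = "mt_diag_selection"
  )
  sel
}

# union of per-class top-X markers, deterministic order
diag_union <- function(rankings, top_x) {
  rankings |>
    filter(.data$rank <= top_x, !is.na(.data$mi_bits)) |>
    pull(.data$mcb_id) |>
    unique() |>
    sort()
}

#' @export
print.mt_diag_selection <- function(x, ...) {
  cat("<mt_diag_selection> top_x =", x$top_x, "->",
      length(x$union_markers), "markers in union\n")
  invisible(x)
}

#' Optimize the per-class marker count X on training AUC
#'
#' Scores the training cohort with the diagnostic methylation score built
#' from the top-X union for every X in `grid` and returns the X that
#' maximizes training AUC (smallest X on ties).
#'
#' @inheritParams select_diagnostic_markers
#' @param grid candidate values of X (default `1:100`).
#' @param specificity training-specificity target carried through to the
#'   fitted threshold (default 0.98).
#' @return List: `top_x` (chosen X), `auc_by_x` tibble
#'   (`top_x, n_markers, auc`), `selection` (the `mt_diag_selection` at the
#'   chosen X).
#' @export
optimize_top_x <- function(mm, samples, grid = 1:100, value = "mfc",
                           n_bins = 4, binarize = FALSE, specificity = 0.98) {
  if (!length(grid)) stop_input("empty X grid")
  grid <- sort(unique(as.integer(grid)))
  sel <- select_diagnostic_markers(mm, samples, top_x = max(grid), value = value,
                                   n_bins = n_bins, binarize = binarize)
  healthy_ids <- samples$sample_id[samples$label == "healthy"]
  all_union <- diag_union(sel$rankings, max(grid))
  baseline <- fit_baseline(mm, healthy_ids, markers = all_union)
  contrib <- score_contributions(mm, baseline,
                                 sample_ids = samples$sample_id)
  is_cancer <- setNames(samples$label != "healthy", samples$sample_id)
  auc_by_x <- purrr::map_dfr(grid, function(x) {
    mk <- diag_union(sel$rankings, x)
    sc <- combine_contributions(contrib, mk)
    tibble(top_x = x, n_markers = length(mk),
           auc = roc_auc(sc$methylation_score, is_cancer[sc$sample_id]))
  })
  best <- auc_by_x$top_x[which.max(auc_by_x$auc)]  # which.max: first (smallest X) on ties
  sel$top_x <- best
  sel$union_markers <- diag_union(sel$rankings, best)
  list(top_x = best, auc_by_x = auc_by_x, selection = sel)
}

#' Candidate CSO markers from pairwise mutual information
#'
#' For each unordered pair of cancer classes, markers are ranked by MI on
#' that pair's samples; the union of the per-pair top-k lists is the CSO
#' candidate set.
#'
#' @param mm long marker-matrix tibble restricted to true-positive cancer
#'   samples (see [run_pipeline()] for the gating).
#' @param samples sample sheet for those samples (labels must include every
#'   class in `classes`, each with >= 2 samples).
#' @param top_k markers per pair (default 100).
#' @param classes cancer classes to compare; defaults to the full
#'   seven-class set.
#' @inheritParams select_diagnostic_markers
#' @return List: `pair_rankings` tibble
#'   (`class_a, class_b, rank, mcb_id, mi_bits`), `candidates` (character
#'   union, sorted).
#' @export
select_cso_candidates <- function(mm, samples, top_k = 100, classes = NULL,
                                  value = "mfc", n_bins = 4, binarize = FALSE) {
  check_marker_matrix(mm); check_sample_sheet(samples)
  classes <- classes %||% cso_classes()
  counts <- table(samples$label)
  missing <- setdiff(classes, names(counts)[counts >= 2])
  if (length(missing)) stop_input("classes absent or with < 2 samples: ",
                                  paste(missing, collapse = ", "))
  mm <- mm[mm$sample_id %in% samples$sample_id, ]
  vals <- mm_wide(mm, value)
  labs <- setNames(samples$label, samples$sample_id)[rownames(vals)]
  pairs <- utils::combn(sort(classes), 2)
  pair_rankings <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    keep <- labs %in% c(a, b)
    mi <- mi_by_marker(vals[keep, , drop = FALSE], labs[keep] == a,
                       n_bins = n_bins, binarize = binarize)
    ord <- order(-mi, names(mi))
    tibble(class_a = a, class_b = b, rank = seq_along(mi),
           mcb_id = names(mi)[ord], mi_bits = unname(mi[ord]))
  })
  candidates <- pair_rankings |>
    filter(.data$rank <= top_k, !is.na(.data$mi_bits)) |>
    pull(.data$mcb_id) |> unique() |> sort()
  list(pair_rankings = pair_rankings, candidates = candidates, top_k = top_k)
}

# unpenalized multinomial log-likelihood and AIC at a (penalized) fit
multinom_aic <- function(x, y, lambda) {
  classes <- sort(unique(as.character(y)))
  y <- factor(as.character(y), levels = classes)
  p <- ncol(x)
  # glmnet needs >= 2 columns; pad with an all-zero dummy (coefficient 0)
  xx <- if (p < 2) cbind(x, `.dummy` = 0) else x
  fit <- tryCatch(
    suppressWarnings(
      glmnet::glmnet(xx, y, family = "multinomial", alpha = 0,
                     lambda = lambda, standardize = FALSE)),
    error = function(e) {
      # small single lambdas can fail to converge; retry with a short
      # warm-start path and read off the target lambda
      suppressWarnings(
        glmnet::glmnet(xx, y, family = "multinomial", alpha = 0,
                       lambda = lambda * c(100, 20, 5, 1), standardize = FALSE))
    }
  )
  pr <- predict(fit, newx = xx, type = "response", s = lambda)[, , 1]
  ll <- sum(log(pmax(pr[cbind(seq_along(y), as.integer(y))], 1e-300)))
  if (!is.finite(ll)) ll <- -Inf
  k <- (length(classes) - 1) * (p + 1)
  list(aic = -2 * ll + 2 * k, ll = ll, fit = fit)
}

#' AIC-guided backward elimination of an L2 multinomial model
#'
#' Fits an L2-penalized multinomial logistic regression on all features,
#' then repeatedly removes the single feature whose removal most improves
#' (lowers) AIC, stopping when no single removal improves it. AIC uses the
#' unpenalized log-likelihood at the penalized estimate with
#' k = (n_classes - 1) x (n_features + 1) free parameters.
#'
#' @param features numeric matrix (samples x markers) with column names.
#' @param labels class label per row (>= 2 classes).
#' @param l2_strength ridge penalty (glmnet `lambda`, default 0.05).
#' @return Character vector of retained feature names.
#' @export
backward_eliminate <- function(features, labels, l2_strength = 0.05) {
  features <- as.matrix(features)
  if (!ncol(features)) stop_input("empty feature set")
  if (is.null(colnames(features))) stop_input("features need column names")
  if (length(unique(labels)) < 2) stop_input("need >= 2 classes")
  current <- sort(colnames(features))
  aic_cur <- multinom_aic(features[, current, drop = FALSE], labels, l2_strength)$aic
  while (length(current) > 1) {
    cand_aic <- vapply(current, function(j) {
      multinom_aic(features[, setdiff(current, j), drop = FALSE],
                   labels, l2_strength)$aic
    }, numeric(1))
    cand_aic[is.na(cand_aic)] <- Inf
    best <- min(cand_aic)
    if (best < aic_cur) {
      drop_j <- current[which.min(cand_aic)]  # first = lexicographically smallest on ties
      current <- setdiff(current, drop_j)
      aic_cur <- best
    } else break
  }
  current
}

#' Bootstrapped CSO marker selection
#'
#' Runs [backward_eliminate()] on `n_bootstraps` independent stratified
#' subsamples (fraction `subsample` of each class, without replacement) and
#' keeps markers retained in more than `retention_threshold` bootstraps.
#'
#' @inheritParams backward_eliminate
#' @param n_bootstraps number of bootstrap draws (default 10).
#' @param subsample per-class subsampling fraction (default 0.80).
#' @param retention_threshold keep markers with retention strictly greater
#'   than this (default 6, i.e. >= 7 of 10).
#' @param seed run seed; all draws derive from it.
#' @return Object of class `mt_cso_selection`: list with `retention`
#'   (tibble `mcb_id, retention_count, selected`), `final_markers`,
#'   and the parameters.
#' @export
bootstrap_cso_selection <- function(features, labels, n_bootstraps = 10,
                                    subsample = 0.80, retention_threshold = 6,
                                    l2_strength = 0.05, seed = 1) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  counts <- table(labels)
  if (any(counts < 3)) stop_input("every class needs >= 3 samples for stratified draws")
  draws <- lapply(seq_len(n_bootstraps), function(b) {
    set.seed(derive_seed(seed, b))
    idx <- unlist(lapply(sort(names(counts)), function(cl) {
      rows <- which(labels == cl)
      sample(rows, max(2, round_half_up(subsample * length(rows))))
    }), use.names = FALSE)
    backward_eliminate(features[idx, , drop = FALSE], labels[idx], l2_strength)
  })
  retention <- tibble(mcb_id = sort(colnames(features))) |>
    mutate(retention_count = vapply(.data$mcb_id, function(m) {
      sum(vapply(draws, function(d) m %in% d, logical(1)))
    }, integer(1)),
    selected = .data$retention_count > retention_threshold)
  structure(
    list(retention = retention,
         final_markers = retention$mcb_id[retention$selected],
         n_bootstraps = n_bootstraps, subsample = subsample,
         retention_threshold = retention_threshold,
         l2_strength = l2_strength, seed = seed),
    class = "mt_cso_selection"
  )
}

#' @export
print.mt_cso_selection <- function(x, ...) {
  cat("<mt_cso_selection>", nrow(x$retention), "candidates ->",
      length(x$final_markers), "markers retained in >",
      x$retention_threshold, "of", x$n_bootstraps, "bootstraps\n")
  invisible(x)
}
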