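#' Diagnostic methylation score
#'
#' Each marker's methylated fragment ratio (MFR) is logit-transformed with
#' a continuity correction, standardized against the healthy training
#' baseline (`Z_i = (x_i - mu_i) / sigma_i`), converted to a one-sided
#' upper-tail normal p-value (the panel targets hypermethylation), and the
#' per-marker p-values are combined by a coverage-weighted Fisher score
#'
#' \deqn{S = \frac{-2 \sum_i w_i \ln p_i}{\sum_i w_i}}
#'
#' with `w_i` the sample's own fragment coverage of marker `i`. A sample is
#' called positive when its score exceeds the empirical quantile of
#' training-control scores matching the specificity target (default the
#' 98th percentile).
#'
#' @name diagnostic_score
NULL

#' Logit-transform an MFR with continuity correction
#'
#' `x = log(p / (1 - p))` with `p = (mfc + 0.5) / (n_informative + 1)`,
#' finite for any counts with at least one informative fragment; markers
#' with zero informative fragments are `NA`.
#'
#' @param mfc methylated fragment count(s).
#' @param n_informative informative fragment count(s).
#' @return Numeric vector of logit-MFR values.
#' @examples
#' logit_mfr(0, 9)    # log(0.05/0.95)
#' logit_mfr(5, 10)   # exactly 0
#' @export
logit_mfr <- function(mfc, n_informative) {
  if (any(mfc < 0 | n_informative < 0 | mfc > n_informative, na.rm = TRUE)) {
    stop_input("need 0 <= mfc <= n_informative")
  }
  ifelse(n_informative > 0, qlogis((mfc + 0.5) / (n_informative + 1)), NA_real_)
}

#' Fit the healthy-baseline model
#'
#' Per marker, the mean and sample standard deviation (n-1 denominator,
#' floored at `sigma_floor`) of logit-MFR across healthy training samples.
#' Markers observed (with informative fragments) in fewer than two controls
#' are flagged unusable.
#'
#' @param mm long marker-matrix tibble.
#' @param healthy_ids sample ids of the training healthy controls.
#' @param markers marker ids to fit; default all in `mm`.
#' @param sigma_floor lower bound for `sigma` (default 1e-6).
#' @return Object of class `mt_baseline`: tibble `mcb_id, mu, sigma,
#'   n_obs, usable` with the floor in `attr(, "sigma_floor")`.
#' @export
fit_baseline <- function(mm, healthy_ids, markers = NULL, sigma_floor = 1e-6) {
  check_marker_matrix(mm)
  if (!length(healthy_ids)) stop_input("no healthy training samples")
  mm <- mm[mm$sample_id %in% healthy_ids, ]
  if (!nrow(mm)) stop_input("no healthy training samples present in the matrix")
  markers <- markers %||% sort(unique(mm$mcb_id))
  base <- mm |>
    filter(.data$mcb_id %in% markers, .data$n_informative > 0) |>
    mutate(x = logit_mfr(.data$mfc, .data$n_informative)) |>
    group_by(.data$mcb_id) |>
    summarise(mu = mean(.data$x), sigma = sd(.data$x), n_obs = n(),
              .groups = "drop")
  out <- tibble(mcb_id = markers) |>
    left_join(base, by = "mcb_id") |>
    mutate(
      n_obs = if_else(is.na(.data$n_obs), 0L, .data$n_obs),
      usable = .data$n_obs >= 2,
      sigma = pmax(.data$sigma, sigma_floor)
    )
  structure(out, class = c("mt_baseline", class(out)), sigma_floor = sigma_floor)
}

#' Marker Z-score against the baseline
#'
#' @param x logit-MFR value(s).
#' @param mu,sigma baseline mean and standard deviation (`sigma > 0`).
#' @return `(x - mu) / sigma`.
#' @export
marker_z <- function(x, mu, sigma) {
  if (any(sigma <= 0, na.rm = TRUE)) rlang::abort("sigma must be positive",
                                                  class = "methtrace_state_error")
  (x - mu) / sigma
}

#' One-sided upper-tail normal p-value
#'
#' @param z Z-score(s).
#' @param floor lower clip (default 1e-300) so `log(p)` stays finite.
#' @return p in `[floor, 1]`.
#' @export
z_to_p <- function(z, floor = 1e-300) {
  pmin(pmax(pnorm(z, lower.tail = FALSE), floor), 1)
}

#' Coverage-weighted Fisher combination of per-marker p-values
#'
#' @param p per-marker p-values; `NA` markers are excluded from both sums.
#' @param w non-negative coverage weights, same length.
#' @return The methylation score (non-negative scalar).
#' @examples
#' methylation_score(0.5, 1)           # -2 log(0.5)
#' methylation_score(c(1, 1), c(3, 7)) # 0
#' @export
methylation_score <- function(p, w) {
  stopifnot(length(p) == length(w))
  if (any(w < 0, na.rm = TRUE)) stop_input("weights must be non-negative")
  ok <- !is.na(p) & !is.na(w) & w > 0
  if (!any(ok)) rlang::abort("sum of weights is zero: score undefined",
                             class = "methtrace_score_error")
  -2 * sum(w[ok] * log(p[ok])) / sum(w[ok])
}

# per-sample, per-marker score ingredients: w * (-2 ln p) and w.
# Returned as two samples x markers matrices so that scores for any marker
# subset are a cheap column subset (used by the top-X optimizer and sweeps).
score_contributions <- function(mm, baseline, sample_ids = NULL) {
  check_marker_matrix(mm)
  usable <- baseline$mcb_id[baseline$usable]
  mm <- mm[mm$mcb_id %in% usable, ]
  if (!is.null(sample_ids)) mm <- mm[mm$sample_id %in% sample_ids, ]
  mm <- mm |>
    left_join(as_tibble(baseline)[, c("mcb_id", "mu", "sigma")], by = "mcb_id") |>
    mutate(
      x = logit_mfr(.data$mfc, .data$n_informative),
      z = marker_z(.data$x, .data$mu, .data$sigma),
      p = z_to_p(.data$z),
      w = if_else(.data$n_informative > 0, as.numeric(.data$coverage), NA_real_),
      wlp = -2 * .data$w * log(.data$p)
    )
  list(
    wlp = mm_wide(mm, "wlp"),
    w = mm_wide(mm, "w")
  )
}

combine_contributions <- function(contrib, markers) {
  mk <- intersect(markers, colnames(contrib$w))
  w <- contrib$w[, mk, drop = FALSE]
  wlp <- contrib$wlp[, mk, drop = FALSE]
  sw <- rowSums(w, na.rm = TRUE)
  sc <- rowSums(wlp, na.rm = TRUE) / sw
  sc[sw == 0] <- NA_real_
  tibble(sample_id = rownames(w), methylation_score = unname(sc),
         n_markers_used = unname(rowSums(!is.na(w))))
}

#' Score samples against a fitted baseline
#'
#' Applies the logit / Z / one-sided-p / weighted-Fisher chain to every
#' sample in the matrix, over the baseline's usable markers (optionally a
#' subset). Markers without informative fragments in a sample are excluded
#' from both sums; samples with no usable marker get `NA`.
#'
#' @param mm long marker-matrix tibble.
#' @param baseline `mt_baseline` from [fit_baseline()].
#' @param markers optional marker subset.
#' @return Tibble `sample_id, methylation_score, n_markers_used`.
#' @export
score_samples <- function(mm, baseline, markers = NULL) {
  markers <- markers %||% baseline$mcb_id[baseline$usable]
  contrib <- score_contributions(mm, baseline)
  combine_contributions(contrib, markers)
}

#' Calibrate the positivity threshold on training controls
#'
#' The cutoff is the empirical lower quantile of training-control scores:
#' the smallest control score such that the fraction of controls at or
#' below it reaches the specificity target. A sample is called positive
#' iff its score is strictly greater than the cutoff, so training
#' specificity is >= the target by construction.
#'
#' @param control_scores methylation scores of training healthy controls
#'   (>= 10 required).
#' @param specificity target training specificity (default 0.98, i.e. the
#'   98th quantile).
#' @return Object of class `mt_threshold`: list with `cutoff`,
#'   `specificity`, `convention`, `n_controls`.
#' @export
calibrate_threshold <- function(control_scores, specificity = 0.98) {
  control_scores <- control_scores[!is.na(control_scores)]
  n <- length(control_scores)
  if (n < 10) stop_input("need >= 10 control scores")
  if (specificity <= 0 || specificity > 1) stop_input("specificity in (0, 1]")
  cutoff <- sort(control_scores)[ceiling(specificity * n)]
  structure(
    list(cutoff = cutoff, specificity = specificity,
         convention = "empirical lower quantile; positive iff score > cutoff",
         n_controls = n),
    class = "mt_threshold"
  )
}

#' @export
print.mt_threshold <- function(x, ...) {
  cat(sprintf("<mt_threshold> cutoff %.4f at %.0f%% training specificity (n = %d controls)\n",
              x$cutoff, 100 * x$specificity, x$n_controls))
  invisible(x)
}

#' Classify scores at a calibrated threshold
#'
#' @param scores numeric methylation scores.
#' @param threshold `mt_threshold` from [calibrate_threshold()].
#' @return Logical vector: positive call.
#' @export
classify_scores <- function(scores, threshold) {
  scores > threshold$cutoff
}

#' Rank-based ROC AUC (Mann-Whitney)
#'
#' @param scores numeric scores (higher = more cancer-like).
#' @param is_case logical or 0/1 labels; both classes must be present.
#' @return AUC in `[0, 1]`; ties count 1/2.
#' @export
roc_auc <- function(scores, is_case) {
  ok <- !is.na(scores) & !is.na(is_case)
  scores <- scores[ok]; is_case <- as.logical(is_case[ok])
  n1 <- sum(is_case); n0 <- sum(!is_case)
  if (n1 == 0 || n0 == 0) stop_input("both classes required for AUC")
  r <- rank(scores)
  (sum(r[is_case]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Sensitivity / specificity report with Wilson intervals
#'
#' Per-class, per-stage and overall sensitivity at a calibrated threshold,
#' specificity on controls, and the Spearman rank correlation between the
#' methylation score and ordinal stage (healthy < I < II < III < IV) with a
#' one-sided (positive-association) p-value.
#'
#' @param scores tibble `sample_id, methylation_score` (e.g. from
#'   [score_samples()]).
#' @param samples sample sheet with `sample_id`, `label`, `stage`.
#' @param threshold `mt_threshold`.
#' @return Object of class `mt_eval`: list of tibbles `overall`,
#'   `by_class`, `by_stage`, `by_class_stage`, and `spearman`
#'   (`rho`, `p_value`). Empty strata are absent rather than errors.
#' @export
sensitivity_report <- function(scores, samples, threshold) {
  check_sample_sheet(samples)
  df <- scores |>
    inner_join(samples, by = "sample_id") |>
    mutate(positive = classify_scores(.data$methylation_score, threshold),
           cancer = .data$label != "healthy")
  sens_of <- function(d) {
    k <- sum(d$positive & d$cancer); n <- sum(d$cancer)
    wilson_ci(k, n) |> mutate(metric = "sensitivity", .before = 1)
  }
  cancer <- df[df$cancer, ]
  ctrl <- df[!df$cancer, ]
  overall <- bind_rows(
    if (nrow(cancer)) sens_of(cancer),
    if (nrow(ctrl)) wilson_ci(sum(!ctrl$positive), nrow(ctrl)) |>
      mutate(metric = "specificity", .before = 1)
  )
  by_class <- cancer |>
    group_by(class = .data$label) |>
    summarise(k = sum(.data$positive), n = n(), .groups = "drop") |>
    mutate(wilson_ci(.data$k, .data$n) |> select(-"n"))
  by_stage <- cancer |>
    filter(!is.na(.data$stage), .data$stage != "none") |>
    group_by(.data$stage) |>
    summarise(k = sum(.data$positive), n = n(), .groups = "drop") |>
    mutate(wilson_ci(.data$k, .data$n) |> select(-"n"))
  by_class_stage <- cancer |>
    filter(!is.na(.data$stage), .data$stage != "none") |>
    group_by(class = .data$label, .data$stage) |>
    summarise(k = sum(.data$positive), n = n(), .groups = "drop") |>
    mutate(wilson_ci(.data$k, .data$n) |> select(-"n"))
  stage_num <- c(healthy = 0, I = 1, II = 2, III = 3, IV = 4)
  df$stage_ord <- ifelse(df$cancer, stage_num[as.character(df$stage)], 0)
  ok <- !is.na(df$stage_ord) & !is.na(df$methylation_score)
  sp <- if (sum(ok) >= 3 && length(unique(df$stage_ord[ok])) > 1) {
    ct <- suppressWarnings(stats::cor.test(df$methylation_score[ok], df$stage_ord[ok],
                                           method = "spearman",
                                           alternative = "greater", exact = FALSE))
    tibble(rho = unname(ct$estimate), p_value = ct$p.value)
  } else tibble(rho = NA_real_, p_value = NA_real_)
  structure(list(overall = overall, by_class = by_class, by_stage = by_stage,
                 by_class_stage = by_class_stage, spearman = sp,
                 cutoff = threshold$cutoff),
            class = "mt_eval")
}

#' @export
print.mt_eval <- function(x, ...) {
  cat("<mt_eval> at cutoff", format(x$cutoff, digits = 4), "\n")
  print(x$overall)
  cat(sprintf("Spearman score~stage: rho = %.3f (one-sided p = %.3g)\n",
              x$spearman$rho, x$spearman$p_value))
  invisible(x)
}
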