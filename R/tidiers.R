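#' Broom-style tidiers
#'
#' `tidy()` returns per-term (per-marker, per-stratum) tibbles; `glance()`
#' returns one-row model summaries.
#'
#' @name tidiers
NULL

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @rdname tidiers
#' @param x a fitted methtrace object.
#' @param ... unused.
#' @method tidy mt_baseline
#' @export
tidy.mt_baseline <- function(x, ...) {
  as_tibble(x)
}

#' @rdname tidiers
#' @method glance mt_baseline
#' @export
glance.mt_baseline <- function(x, ...) {
  tibble(n_markers = nrow(x), n_usable = sum(x$usable),
         sigma_floor = attr(x, "sigma_floor"))
}

#' @rdname tidiers
#' @method tidy mt_diag_selection
#' @export
tidy.mt_diag_selection <- function(x, ...) x$rankings

#' @rdname tidiers
#' @method glance mt_diag_selection
#' @export
glance.mt_diag_selection <- function(x, ...) {
  tibble(top_x = x$top_x, n_union = length(x$union_markers),
         value = x$value, n_bins = x$n_bins, binarize = x$binarize)
}

#' @rdname tidiers
#' @method tidy mt_cso_selection
#' @export
tidy.mt_cso_selection <- function(x, ...) x$retention

#' @rdname tidiers
#' @method glance mt_cso_selection
#' @export
glance.mt_cso_selection <- function(x, ...) {
  tibble(n_candidates = nrow(x$retention),
         n_selected = length(x$final_markers),
         n_bootstraps = x$n_bootstraps,
         retention_threshold = x$retention_threshold,
         subsample = x$subsample, l2_strength = x$l2_strength)
}

#' @rdname tidiers
#' @method tidy mt_eval
#' @export
tidy.mt_eval <- function(x, ...) {
  bind_rows(
    x$overall |> mutate(stratum = "overall", class = NA_character_,
                        stage = NA_character_),
    x$by_class |> mutate(metric = "sensitivity", stratum = "class",
                         stage = NA_character_),
    x$by_stage |> mutate(metric = "sensitivity", stratum = "stage",
                         class = NA_character_),
    x$by_class_stage |> mutate(metric = "sensitivity", stratum = "class_stage")
  ) |>
    select("stratum", "metric", "class", "stage", "estimate",
           "conf_low", "conf_high", "n")
}

#' @rdname tidiers
#' @method glance mt_eval
#' @export
glance.mt_eval <- function(x, ...) {
  sens <- x$overall[x$overall$metric == "sensitivity", ]
  spec <- x$overall[x$overall$metric == "specificity", ]
  tibble(
    sensitivity = if (nrow(sens)) sens$estimate else NA_real_,
    specificity = if (nrow(spec)) spec$estimate else NA_real_,
    spearman_rho = x$spearman$rho,
    spearman_p = x$spearman$p_value,
    cutoff = x$cutoff
  )
}

#' @rdname tidiers
#' @method glance mt_cso_model
#' @export
glance.mt_cso_model <- function(x, ...) {
  tibble(n_classes = length(x$classes), n_markers = length(x$marker_names),
         k_folds = x$k_folds, n_repeats = x$n_repeats,
         oof_log_loss = x$oof_log_loss, seed = x$seed)
}

#' @rdname tidiers
#' @method glance mt_report
#' @export
glance.mt_report <- function(x, ...) {
  out <- tibble(
    top_x = x$top_x,
    n_diag_markers = length(x$diag_markers),
    cutoff = x$threshold$cutoff,
    specificity_target = x$threshold$specificity,
    auc_train = x$auc$auc[x$auc$cohort == "train"],
    auc_test = x$auc$auc[x$auc$cohort == "test"],
    sensitivity_test = glance(x$eval_test)$sensitivity,
    specificity_test = glance(x$eval_test)$specificity,
    spearman_rho_test = x$eval_test$spearman$rho
  )
  if (!is.null(x$cso)) {
    out$n_cso_markers <- length(x$cso$final_markers)
    if (!is.null(x$cso$metrics)) {
      m <- x$cso$metrics
      pick <- function(k, schema) {
        v <- m$accuracy[m$k == k & m$schema == schema]
        if (length(v)) v else NA_real_
      }
      out$cso_top1 <- pick(1, "7-class")
      out$cso_top2 <- pick(2, "7-class")
      out$cso_top1_hpca <- pick(1, "HPCA-merged")
      out$cso_top2_hpca <- pick(2, "HPCA-merged")
    }
  }
  out
}
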