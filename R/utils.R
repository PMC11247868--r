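#' @importFrom rlang .data abort warn %||%
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   left_join inner_join anti_join bind_rows bind_cols n distinct rename
#'   across all_of pull slice count if_else row_number desc first
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom stats cor pnorm qnorm quantile rbeta rbinom rnbinom rnorm
#'   runif sd setNames predict plogis qlogis aggregate complete.cases
#' @importFrom utils head tail
NULL

stop_input <- function(...) rlang::abort(paste0(...), class = "methtrace_input_error")

`%||%` <- rlang::`%||%`

#' Wilson score confidence interval for a binomial proportion
#'
#' Closed-form Wilson interval, the convention used for all sensitivity,
#' specificity and accuracy intervals reported by this package.
#'
#' @param k number of successes.
#' @param n number of trials.
#' @param conf confidence level (default 0.95).
#' @return A tibble with columns `estimate`, `conf_low`, `conf_high`, `n`.
#' @examples
#' wilson_ci(8, 10)
#' @export
wilson_ci <- function(k, n, conf = 0.95) {
  stopifnot(length(k) == length(n))
  if (any(k < 0 | n < 0 | k > n, na.rm = TRUE)) stop_input("need 0 <= k <= n")
  z <- qnorm(1 - (1 - conf) / 2)
  p <- ifelse(n > 0, k / n, NA_real_)
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- (z / denom) * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  tibble(
    estimate  = p,
    conf_low  = pmax(0, centre - half),
    conf_high = pmin(1, centre + half),
    n         = as.integer(n)
  )
}

# Deterministic per-stream seeds derived from one run seed; kept < 2^31.
derive_seed <- function(seed, stream) {
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(stream) * 9973L
}

# round-half-up used for stratified splits so a singleton stratum trains
round_half_up <- function(x) floor(x + 0.5)

# canonical class labels for the seven-cancer problem
#' Cancer class labels used throughout the package
#'
#' The seven cancer types (TCGA-style codes) plus `"healthy"`.
#' @return Character vector of the seven cancer class labels.
#' @export
cso_classes <- function() {
  c("BRCA", "COREAD", "ESCA", "LIHC", "NSCLC", "PAAD", "STAD")
}

all_labels <- function() c("healthy", cso_classes())

check_sample_sheet <- function(samples) {
  need <- c("sample_id", "label")
  if (!all(need %in% names(samples))) {
    stop_input("sample sheet needs columns: ", paste(need, collapse = ", "))
  }
  bad <- setdiff(unique(samples$label), all_labels())
  if (length(bad)) stop_input("unknown labels: ", paste(bad, collapse = ", "))
  invisible(samples)
}

check_marker_matrix <- function(mm) {
  need <- c("sample_id", "mcb_id", "mfc", "n_informative", "mfr", "coverage")
  if (!all(need %in% names(mm))) {
    stop_input("marker matrix needs columns: ", paste(need, collapse = ", "))
  }
  invisible(mm)
}

# samples x markers numeric matrix from the long marker table
mm_wide <- function(mm, value = "mfr", markers = NULL, samples = NULL) {
  check_marker_matrix(mm)
  if (!is.null(markers)) mm <- mm[mm$mcb_id %in% markers, , drop = FALSE]
  if (!is.null(samples)) mm <- mm[mm$sample_id %in% samples, , drop = FALSE]
  wide <- tidyr::pivot_wider(
    mm[, c("sample_id", "mcb_id", value)],
    names_from = "mcb_id", values_from = all_of(value)
  )
  out <- as.matrix(wide[, -1, drop = FALSE])
  rownames(out) <- wide$sample_id
  if (!is.null(markers)) out <- out[, markers[markers %in% colnames(out)], drop = FALSE]
  out
}
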