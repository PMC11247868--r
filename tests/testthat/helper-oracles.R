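# Independent brute-force oracles. These re-derive expected results from
# first principles (exhaustive enumeration / direct formulas) and must stay
# independent of the package implementations they check.

# -- MCB calling: enumerate every contiguous window, keep maximal qualifying
oracle_mcbs <- function(beta, max_gap = 100, min_r = 0.95, min_cpgs = 3) {
  sample_cols <- setdiff(names(beta), c("chrom", "pos"))
  vals <- as.matrix(beta[sample_cols])
  n <- nrow(beta)
  pair_ok <- function(i, j) {
    if (beta$chrom[i] != beta$chrom[j]) return(FALSE)
    if (beta$pos[j] - beta$pos[i] >= max_gap) return(FALSE)
    a <- vals[i, ]; b <- vals[j, ]
    keep <- !is.na(a) & !is.na(b)
    if (sum(keep) < 3) return(FALSE)
    a <- a[keep]; b <- b[keep]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(FALSE)
    stats::cor(a, b) > min_r
  }
  adj_ok <- if (n > 1) vapply(seq_len(n - 1), function(k) pair_ok(k, k + 1),
                              logical(1)) else logical(0)
  qualifies <- function(i, j) {          # window [i, j] (site indices)
    if (j - i + 1 < min_cpgs) return(FALSE)
    all(adj_ok[i:(j - 1)])
  }
  wins <- list()
  for (i in seq_len(n)) for (j in i:n) {
    if (qualifies(i, j)) wins[[length(wins) + 1]] <- c(i, j)
  }
  if (!length(wins)) return(list())
  contains <- function(v, w) v[1] <= w[1] && v[2] >= w[2] && !identical(v, w)
  maximal <- Filter(function(w) {
    !any(vapply(wins, contains, logical(1), w = w))
  }, wins)
  maximal <- maximal[order(vapply(maximal, `[`, numeric(1), 1))]
  lapply(maximal, function(w) as.integer(beta$pos[w[1]:w[2]]))
}

# -- quantification: test every fragment x MCB pair directly
oracle_quantify <- function(fragments, mcbs, min_marker_cpgs = 3) {
  out <- list()
  for (s in unique(fragments$sample_id)) {
    fs <- fragments[fragments$sample_id == s, ]
    for (k in seq_len(nrow(mcbs))) {
      members <- mcbs$cpg_positions[[k]]
      cov <- 0L; ninf <- 0L; mfc <- 0L
      for (f in seq_len(nrow(fs))) {
        if (fs$chrom[f] != mcbs$chrom[k]) next
        if (fs$start[f] < mcbs$end[k] && fs$end[f] > mcbs$start[k]) cov <- cov + 1L
        pos <- fs$cpg_pos[[f]]; calls <- fs$call[[f]]
        covered <- pos %in% members
        if (sum(covered) >= min_marker_cpgs) {
          ninf <- ninf + 1L
          if (all(calls[covered] == "M")) mfc <- mfc + 1L
        }
      }
      out[[length(out) + 1]] <- tibble::tibble(
        sample_id = s, mcb_id = mcbs$mcb_id[k], mfc = mfc,
        n_informative = ninf,
        mfr = if (ninf > 0) mfc / ninf else NA_real_, coverage = cov
      )
    }
  }
  dplyr::bind_rows(out)
}

# -- AUC by exhaustive case-control pair counting
oracle_auc <- function(scores, is_case) {
  cases <- scores[as.logical(is_case)]
  ctrls <- scores[!as.logical(is_case)]
  tot <- 0
  for (a in cases) for (b in ctrls) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(cases) * length(ctrls))
}

# -- top-k accuracy by direct counting of strictly-better / tied classes
oracle_top_k <- function(prob, truth, k) {
  classes <- colnames(prob)
  hits <- vapply(seq_len(nrow(prob)), function(i) {
    p_true <- prob[i, truth[i]]
    n_gt <- sum(prob[i, ] > p_true)
    tied <- classes[prob[i, ] == p_true]
    n_tied_before <- sum(tied < truth[i])   # alphabetical tie-break
    (n_gt + n_tied_before) < k
  }, logical(1))
  mean(hits)
}

# -- random test-instance generators ----------------------------------------
random_beta_matrix <- function(n_cpgs, n_samples = 6, p_missing = 0.05) {
  n_chrom <- sample(1:2, 1)
  chrom <- sort(sample(paste0("chr", 1:n_chrom), n_cpgs, replace = TRUE))
  pos <- unlist(lapply(split(seq_len(n_cpgs), chrom), function(i) {
    sort(sample.int(60, length(i))) * sample(c(20, 60), 1)
  }), use.names = FALSE)
  base <- matrix(runif(n_cpgs * n_samples), n_cpgs, n_samples)
  # make stretches correlated so runs occur
  for (i in seq_len(n_cpgs - 1)) {
    if (runif(1) < 0.6) base[i + 1, ] <- pmin(pmax(base[i, ] + rnorm(n_samples, sd = 0.01), 0), 1)
  }
  base[matrix(runif(n_cpgs * n_samples) < p_missing, n_cpgs, n_samples)] <- NA
  out <- tibble::tibble(chrom = chrom, pos = as.integer(pos))
  for (s in seq_len(n_samples)) out[[paste0("s", s)]] <- base[, s]
  ord <- order(out$chrom, out$pos)
  out <- out[ord, ]
  out[!duplicated(out[c("chrom", "pos")]), ]
}

random_fragments <- function(n_frags, mcbs) {
  all_pos <- sort(unique(c(unlist(mcbs$cpg_positions),
                           max(mcbs$end) + c(50L, 150L, 250L))))
  rows <- lapply(seq_len(n_frags), function(i) {
    chrom <- sample(unique(mcbs$chrom), 1)
    k <- sort(sample(all_pos, sample(1:6, 1)))
    tibble::tibble(
      sample_id = sample(c("A", "B"), 1),
      fragment_id = sprintf("f%04d", i),
      chrom = chrom,
      start = min(k), end = max(k) + 2L,
      cpg_pos = list(as.integer(k)),
      call = list(sample(c("M", "U"), length(k), replace = TRUE))
    )
  })
  dplyr::bind_rows(rows)
}

# small cohort configs used by round-trip and pipeline smoke tests
small_config <- function(seed, ...) {
  sim_config(n_markers = 21, n_healthy = 12, n_per_class = 3,
             signature_size = 3, frag_mean = 8, seed = seed, ...)
}
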