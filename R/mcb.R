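#' Methylation-correlated block (MCB) calling
#'
#' Adjacent CpGs on the same DNA molecule tend to share methylation state
#' because DNA methyltransferases are processive. A methylation-correlated
#' block (MCB) is a run of nearby CpG sites whose methylation levels are
#' almost perfectly correlated across samples; using the block rather than
#' the single CpG as the marker unit averages out technical noise. A run
#' qualifies when every *adjacent* CpG pair satisfies both criteria:
#' genomic gap below `max_gap` (default 100 bp) and Pearson correlation of
#' beta values above `min_r` (default 0.95); runs of fewer than `min_cpgs`
#' (default 3) CpGs are discarded.
#'
#' @name mcb_calling
NULL

check_beta_matrix <- function(beta) {
  need <- c("chrom", "pos")
  if (!all(need %in% names(beta))) {
    stop_input("beta matrix needs `chrom` and `pos` columns before sample columns")
  }
  sample_cols <- setdiff(names(beta), need)
  if (length(sample_cols) < 2) stop_input("beta matrix needs >= 2 sample columns")
  vals <- as.matrix(beta[sample_cols])
  if (!is.numeric(vals)) stop_input("sample columns must be numeric beta values")
  if (any(vals < 0 | vals > 1, na.rm = TRUE)) stop_input("beta values must lie in [0, 1]")
  ord <- order(beta$chrom, beta$pos)
  if (!identical(ord, seq_len(nrow(beta)))) {
    stop_input("CpG sites must be sorted by (chrom, pos)")
  }
  if (anyDuplicated(beta[c("chrom", "pos")])) stop_input("duplicate (chrom, pos) entries")
  sample_cols
}

#' Pearson correlation between consecutive CpG pairs
#'
#' Computes, per chromosome, the Pearson correlation of beta values between
#' each pair of consecutive CpG sites, using pairwise-complete samples.
#' Pairs with fewer than 3 complete observations or zero variance in either
#' site get `NA` (and later fail the block criterion).
#'
#' @param beta A data frame with columns `chrom`, `pos` (0-based CpG
#'   coordinate) followed by one numeric beta-value column per sample;
#'   missing values allowed as `NA`.
#' @return A tibble with one row per consecutive same-chromosome pair:
#'   `chrom`, `pos`, `next_pos`, `gap` (bp), `r`, `n_complete`.
#' @examples
#' beta <- tibble::tibble(
#'   chrom = "chr1", pos = c(10L, 40L, 90L),
#'   s1 = c(0.1, 0.1, 0.9), s2 = c(0.2, 0.2, 0.8),
#'   s3 = c(0.3, 0.3, 0.7), s4 = c(0.4, 0.4, 0.1)
#' )
#' adjacent_correlations(beta)
#' @export
adjacent_correlations <- function(beta) {
  sample_cols <- check_beta_matrix(beta)
  vals <- as.matrix(beta[sample_cols])
  n <- nrow(beta)
  if (n < 2) {
    return(tibble(chrom = character(), pos = integer(), next_pos = integer(),
                  gap = integer(), r = double(), n_complete = integer()))
  }
  i <- seq_len(n - 1)
  same_chrom <- beta$chrom[i] == beta$chrom[i + 1]
  i <- i[same_chrom]
  pair_r <- function(a, b) {
    ok <- stats::complete.cases(a, b)
    if (sum(ok) < 3) return(c(NA_real_, sum(ok)))
    a <- a[ok]; b <- b[ok]
    if (sd(a) == 0 || sd(b) == 0) return(c(NA_real_, length(a)))
    c(cor(a, b), length(a))
  }
  rs <- vapply(i, function(k) pair_r(vals[k, ], vals[k + 1, ]), numeric(2))
  tibble(
    chrom      = beta$chrom[i],
    pos        = beta$pos[i],
    next_pos   = beta$pos[i + 1],
    gap        = beta$pos[i + 1] - beta$pos[i],
    r          = rs[1, ],
    n_complete = as.integer(rs[2, ])
  )
}

#' Call methylation-correlated blocks from a beta-value matrix
#'
#' Chains consecutive CpGs left to right: an adjacent pair joins the current
#' run when its gap is strictly below `max_gap` and its Pearson r strictly
#' above `min_r` (missing r breaks the run). Maximal runs with at least
#' `min_cpgs` CpGs become MCBs. Intervals are 0-based half-open; `end`
#' covers the final CpG dinucleotide (`last pos + 2`).
#'
#' @inheritParams adjacent_correlations
#' @param max_gap maximum distance in bp between consecutive member CpGs
#'   (exclusive; default 100).
#' @param min_r minimum adjacent Pearson correlation (exclusive; default 0.95).
#' @param min_cpgs minimum CpGs per block (default 3).
#' @return A tibble of MCBs: `mcb_id`, `chrom`, `start`, `end`, `n_cpgs`,
#'   `cpg_positions` (list column of integer vectors).
#' @examples
#' beta <- tibble::tibble(
#'   chrom = "chr1", pos = c(10L, 50L, 90L, 300L),
#'   s1 = c(0.1, 0.12, 0.11, 0.5), s2 = c(0.4, 0.41, 0.40, 0.2),
#'   s3 = c(0.7, 0.69, 0.72, 0.9), s4 = c(0.9, 0.93, 0.91, 0.1)
#' )
#' call_mcbs(beta)
#' @export
call_mcbs <- function(beta, max_gap = 100, min_r = 0.95, min_cpgs = 3) {
  if (max_gap <= 0 || min_cpgs < 2) stop_input("max_gap must be positive and min_cpgs >= 2")
  pairs <- adjacent_correlations(beta)
  ok <- !is.na(pairs$r) & pairs$r > min_r & pairs$gap < max_gap
  # run-length scan over sites; a site index k links to k+1 iff its pair qualifies
  blocks <- list()
  if (nrow(beta)) {
    link <- logical(nrow(beta) - 1)
    key <- paste(beta$chrom[-nrow(beta)], beta$pos[-nrow(beta)])
    qual <- setNames(ok, paste(pairs$chrom, pairs$pos))
    link[key %in% names(qual)] <- qual[key[key %in% names(qual)]]
    runs <- rle(link)
    idx <- 1L
    start_site <- 1L
    for (j in seq_along(runs$lengths)) {
      len <- runs$lengths[j]
      if (runs$values[j]) {
        sites <- seq(start_site, start_site + len)  # len links -> len+1 sites
        if (length(sites) >= min_cpgs) {
          blocks[[length(blocks) + 1L]] <- sites
        }
      }
      start_site <- start_site + len
      idx <- idx + 1L
    }
  }
  if (!length(blocks)) {
    return(tibble(mcb_id = character(), chrom = character(), start = integer(),
                  end = integer(), n_cpgs = integer(), cpg_positions = list()))
  }
  tibble(
    mcb_id = sprintf("MCB%05d", seq_along(blocks)),
    chrom  = vapply(blocks, function(s) beta$chrom[s[1]], character(1)),
    start  = vapply(blocks, function(s) beta$pos[s[1]], numeric(1)) |> as.integer(),
    end    = vapply(blocks, function(s) beta$pos[s[length(s)]] + 2, numeric(1)) |> as.integer(),
    n_cpgs = lengths(blocks),
    cpg_positions = lapply(blocks, function(s) as.integer(beta$pos[s]))
  )
}

#' Read a beta-value matrix TSV
#'
#' Expects columns `chrom`, `pos`, then one column per sample; `NA` for
#' missing beta values.
#'
#' @param path TSV file path.
#' @return A beta-matrix tibble.
#' @export
read_beta_matrix <- function(path) {
  beta <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  check_beta_matrix(beta)
  beta
}

#' Write called MCBs as BED6 plus a CpG-membership sidecar
#'
#' @param mcbs MCB tibble from [call_mcbs()].
#' @param path output BED path; the sidecar is written next to it with
#'   suffix `.cpgs.tsv`.
#' @return `path`, invisibly.
#' @export
write_mcb_bed <- function(mcbs, path) {
  bed <- tibble(
    chrom = mcbs$chrom, start = mcbs$start, end = mcbs$end,
    name = mcbs$mcb_id, score = mcbs$n_cpgs, strand = "."
  )
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  sidecar <- tibble(
    mcb_id = mcbs$mcb_id,
    cpg_positions = vapply(mcbs$cpg_positions, paste, character(1), collapse = ",")
  )
  readr::write_tsv(sidecar, paste0(path, ".cpgs.tsv"), progress = FALSE)
  invisible(path)
}

#' Read an MCB BED (with CpG sidecar) back into a tibble
#'
#' @param path BED path written by [write_mcb_bed()], or any BED6 whose
#'   name column is the MCB id; the `.cpgs.tsv` sidecar is read when present.
#' @return MCB tibble as produced by [call_mcbs()].
#' @export
read_mcb_bed <- function(path) {
  bed <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "name", "score", "strand"),
                         show_col_types = FALSE, progress = FALSE)
  out <- tibble(
    mcb_id = as.character(bed$name), chrom = bed$chrom,
    start = as.integer(bed$start), end = as.integer(bed$end),
    n_cpgs = as.integer(bed$score)
  )
  sidecar <- paste0(path, ".cpgs.tsv")
  if (file.exists(sidecar)) {
    cp <- readr::read_tsv(sidecar, show_col_types = FALSE, progress = FALSE,
                          col_types = readr::cols(cpg_positions = "c"))
    cp$cpg_positions <- lapply(strsplit(cp$cpg_positions, ","), as.integer)
    out <- left_join(out, cp, by = "mcb_id")
  }
  out
}
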