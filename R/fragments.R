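#' Fragment-level methylation quantification
#'
#' cfDNA methylation evidence is carried by sequenced fragments: a merged
#' read pair's CpG calls. Per marker (MCB) and sample we count
#' * `coverage`   - fragments whose span overlaps the MCB,
#' * `n_informative` - fragments covering at least `min_marker_cpgs` of the
#'   MCB's member CpGs,
#' * `mfc` (methylated fragment count) - informative fragments whose covered
#'   member CpGs are *all* methylated,
#' * `mfr` (methylated fragment ratio) - `mfc / n_informative`.
#'
#' @name fragment_quant
NULL

check_read_calls <- function(reads) {
  need <- c("sample_id", "read_id", "mate", "chrom", "pos", "call")
  if (!all(need %in% names(reads))) {
    stop_input("read calls need columns: ", paste(need, collapse = ", "))
  }
  bad <- setdiff(unique(reads$call), c("M", "U"))
  if (length(bad)) stop_input("calls must be 'M' or 'U'; ambiguous calls are dropped upstream")
  invisible(reads)
}

#' Merge one read pair into a fragment call set
#'
#' Calls from both mates are unioned by position. Where the mates overlap,
#' agreeing calls are kept once and disagreeing calls are removed (treated
#' as missing) - a conservative rule that never fabricates a state.
#'
#' @param r1,r2 tibbles with columns `pos`, `call` ("M"/"U") for each mate;
#'   `r2` may be `NULL` for an unpaired read.
#' @return A tibble `pos`, `call` sorted by position, conflicts removed.
#' @examples
#' r1 <- tibble::tibble(pos = c(100L, 130L), call = c("M", "M"))
#' r2 <- tibble::tibble(pos = c(130L, 160L), call = c("U", "U"))
#' merge_read_pair(r1, r2)  # 130 dropped as a mate conflict
#' @export
merge_read_pair <- function(r1, r2 = NULL) {
  calls <- bind_rows(r1, r2)
  if (!nrow(calls)) return(tibble(pos = integer(), call = character()))
  agg <- calls |>
    group_by(.data$pos) |>
    summarise(n_states = dplyr::n_distinct(.data$call), call = first(.data$call),
              .groups = "drop")
  agg |>
    filter(.data$n_states == 1) |>
    select("pos", "call") |>
    arrange(.data$pos)
}

#' Merge a table of per-read CpG calls into fragments
#'
#' Reads sharing (`sample_id`, `read_id`) are merged with the
#' [merge_read_pair()] rules; a mate pair mapping to different chromosomes
#' is an error. The fragment span is the union span of the mates' CpG
#' positions (half-open, covering the final CpG dinucleotide).
#'
#' @param reads long tibble: `sample_id, read_id, mate, chrom, pos, call`.
#' @return Fragment tibble: `sample_id, fragment_id, chrom, start, end`,
#'   plus list columns `cpg_pos` and `call` with the merged, conflict-free
#'   calls.
#' @export
merge_read_pairs <- function(reads) {
  check_read_calls(reads)
  if (!nrow(reads)) {
    return(tibble(sample_id = character(), fragment_id = character(),
                  chrom = character(), start = integer(), end = integer(),
                  cpg_pos = list(), call = list()))
  }
  chrom_chk <- reads |>
    group_by(.data$sample_id, .data$read_id) |>
    summarise(n_chrom = dplyr::n_distinct(.data$chrom), .groups = "drop")
  if (any(chrom_chk$n_chrom > 1)) {
    stop_input("read pair maps to different chromosomes: invalid pair")
  }
  merged <- reads |>
    group_by(.data$sample_id, .data$read_id, .data$chrom, .data$pos) |>
    summarise(n_states = dplyr::n_distinct(.data$call), call = first(.data$call),
              .groups = "drop_last") |>
    mutate(start = min(.data$pos), end = max(.data$pos) + 2L) |>
    ungroup()
  merged |>
    filter(.data$n_states == 1) |>
    arrange(.data$sample_id, .data$read_id, .data$pos) |>
    group_by(.data$sample_id, .data$read_id, .data$chrom, .data$start, .data$end) |>
    summarise(cpg_pos = list(as.integer(.data$pos)), call = list(.data$call),
              .groups = "drop") |>
    rename(fragment_id = "read_id")
}

#' Keep fragments informative for methylation analysis
#'
#' Fragments must carry at least `min_cpgs` CpG calls after pair merging
#' (default 3) to enter quantification.
#'
#' @param fragments fragment tibble from [merge_read_pairs()].
#' @param min_cpgs minimum retained CpG calls per fragment.
#' @return The retained fragments.
#' @export
filter_fragments <- function(fragments, min_cpgs = 3) {
  fragments[lengths(fragments$cpg_pos) >= min_cpgs, , drop = FALSE]
}

#' Quantify MFC, MFR and coverage per sample and MCB
#'
#' @param fragments pair-merged, filtered fragment tibble
#'   (see [merge_read_pairs()], [filter_fragments()]).
#' @param mcbs MCB tibble with `mcb_id`, `chrom`, `start`, `end` and list
#'   column `cpg_positions` (member CpG coordinates).
#' @param min_marker_cpgs member CpGs a fragment must cover to be
#'   informative for that MCB (default 3, mirroring the global fragment
#'   filter).
#' @return Long marker-matrix tibble: `sample_id, mcb_id, mfc,
#'   n_informative, mfr, coverage` (one row per sample x MCB; `mfr` is `NA`
#'   when no informative fragment exists).
#' @export
quantify_fragments <- function(fragments, mcbs, min_marker_cpgs = 3) {
  if (is.null(mcbs) || !nrow(mcbs)) stop_input("empty MCB list")
  if (!"cpg_positions" %in% names(mcbs)) stop_input("mcbs need a cpg_positions list column")
  samples <- unique(fragments$sample_id)
  grid <- tidyr::expand_grid(sample_id = samples, mcb_id = mcbs$mcb_id)

  if (!nrow(fragments)) {
    return(grid |>
      mutate(mfc = 0L, n_informative = 0L, mfr = NA_real_, coverage = 0L))
  }

  # long call table once; member map once
  calls <- tibble(
    sample_id = rep(fragments$sample_id, lengths(fragments$cpg_pos)),
    fragment_id = rep(fragments$fragment_id, lengths(fragments$cpg_pos)),
    chrom = rep(fragments$chrom, lengths(fragments$cpg_pos)),
    pos = unlist(fragments$cpg_pos),
    call = unlist(fragments$call)
  )
  members <- tibble(
    mcb_id = rep(mcbs$mcb_id, lengths(mcbs$cpg_positions)),
    chrom = rep(mcbs$chrom, lengths(mcbs$cpg_positions)),
    pos = unlist(mcbs$cpg_positions)
  )
  per_frag <- inner_join(calls, members, by = c("chrom", "pos"),
                         relationship = "many-to-many") |>
    group_by(.data$sample_id, .data$fragment_id, .data$mcb_id) |>
    summarise(n_member = n(), all_m = all(.data$call == "M"), .groups = "drop")
  informative <- per_frag |>
    filter(.data$n_member >= min_marker_cpgs) |>
    group_by(.data$sample_id, .data$mcb_id) |>
    summarise(mfc = sum(.data$all_m), n_informative = n(), .groups = "drop")

  # span-overlap coverage: fragment [start,end) vs MCB [start,end)
  cov_one <- function(k) {
    hit <- fragments$chrom == mcbs$chrom[k] &
      fragments$start < mcbs$end[k] & fragments$end > mcbs$start[k]
    if (!any(hit)) return(NULL)
    fragments[hit, ] |>
      count(.data$sample_id, name = "coverage") |>
      mutate(mcb_id = mcbs$mcb_id[k])
  }
  coverage <- bind_rows(lapply(seq_len(nrow(mcbs)), cov_one))

  out <- grid |>
    left_join(informative, by = c("sample_id", "mcb_id"))
  if (nrow(coverage)) {
    out <- left_join(out, coverage, by = c("sample_id", "mcb_id"))
  } else {
    out$coverage <- NA_integer_
  }
  out |>
    mutate(
      mfc = if_else(is.na(.data$mfc), 0L, as.integer(.data$mfc)),
      n_informative = if_else(is.na(.data$n_informative), 0L,
                              as.integer(.data$n_informative)),
      coverage = if_else(is.na(.data$coverage), 0L, as.integer(.data$coverage)),
      mfr = if_else(.data$n_informative > 0,
                    .data$mfc / .data$n_informative, NA_real_)
    ) |>
    select("sample_id", "mcb_id", "mfc", "n_informative", "mfr", "coverage")
}

#' Read per-read CpG methylation calls from TSV
#'
#' Columns: `sample_id, read_id, mate, chrom, cpg_pos_csv, call_string`
#' with `call_string` a string over \{M,U\} aligned to the comma-separated
#' positions (Bismark-style call convention, one row per mate).
#'
#' @param path TSV path.
#' @return Long call tibble suitable for [merge_read_pairs()].
#' @export
read_methylation_calls <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(cpg_pos_csv = "c",
                                                 call_string = "c"))
  pos <- lapply(strsplit(raw$cpg_pos_csv, ","), as.integer)
  call <- strsplit(raw$call_string, "")
  if (!all(lengths(pos) == lengths(call))) {
    stop_input("call_string length must match cpg_pos_csv length")
  }
  tibble(
    sample_id = rep(raw$sample_id, lengths(pos)),
    read_id = rep(raw$read_id, lengths(pos)),
    mate = rep(raw$mate, lengths(pos)),
    chrom = rep(raw$chrom, lengths(pos)),
    pos = unlist(pos),
    call = unlist(call)
  ) |> check_read_calls()
}

#' Write per-read calls in the TSV convention read by
#' [read_methylation_calls()]
#'
#' @param reads long call tibble (`sample_id, read_id, mate, chrom, pos, call`).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_methylation_calls <- function(reads, path) {
  check_read_calls(reads)
  rows <- reads |>
    arrange(.data$sample_id, .data$read_id, .data$mate, .data$pos) |>
    group_by(.data$sample_id, .data$read_id, .data$mate, .data$chrom) |>
    summarise(cpg_pos_csv = paste(.data$pos, collapse = ","),
              call_string = paste(.data$call, collapse = ""), .groups = "drop")
  readr::write_tsv(rows, path, progress = FALSE)
  invisible(path)
}

#' Read / write the long marker-matrix TSV
#'
#' @param path TSV path.
#' @return [read_marker_matrix()]: the long marker-matrix tibble.
#' @export
read_marker_matrix <- function(path) {
  mm <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  check_marker_matrix(mm)
  mm
}

#' @rdname read_marker_matrix
#' @param mm long marker-matrix tibble.
#' @export
write_marker_matrix <- function(mm, path) {
  check_marker_matrix(mm)
  readr::write_tsv(mm, path, progress = FALSE)
  invisible(path)
}
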