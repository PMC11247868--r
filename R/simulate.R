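#' Synthetic cfDNA methylation cohorts
#'
#' Generates beta matrices, fragment-level call tables and marker matrices
#' with the statistical structure the pipeline assumes: healthy-baseline
#' MFR distributions, class-specific hypermethylated marker signatures, and
#' a tumor fraction that scales with stage. The generative model for a
#' cancer sample's methylation rate at a signature marker is the standard
#' liquid-biopsy dilution mixture
#' \deqn{r = (1 - \theta)\, r_0 + \theta\, r_{tumor}}
#' with \eqn{r_0} the sample's healthy background rate and \eqn{\theta} the
#' stage-dependent tumor fraction.
#'
#' @name synthetic_cohort
NULL

#' Simulation configuration
#'
#' Defaults describe a desk-scale seven-cancer cohort: 150-marker panel,
#' healthy background MFR ~ Beta(1, 60) (mean ~1.6%), 12-marker
#' hypermethylated signature per class of which a quarter is a shared
#' pan-cancer core, tumor methylation rate 0.6 at signature markers, tumor
#' fraction (0.004, 0.01, 0.03, 0.08) for stages I-IV, informative-fragment
#' depth ~ NegBin(mean 40, size 5), and per-class stage mix 16/20/30/34%
#' (a late-stage-weighted mix typical of symptomatic cohorts).
#'
#' @param n_markers panel size (number of MCB markers).
#' @param n_healthy healthy controls.
#' @param n_per_class cancer samples per class.
#' @param classes cancer class labels.
#' @param stage_probs named stage proportions (I-IV) per class.
#' @param baseline_shape1,baseline_shape2 Beta parameters of the
#'   *marker-level* mean background methylation rate: background is a locus
#'   property, so each marker draws one mean rate `m_j ~ Beta(a0, b0)` and
#'   samples vary around it.
#' @param baseline_concentration Beta concentration of the per-sample
#'   background rate around the marker mean,
#'   `r0_ij ~ Beta(m_j k, (1 - m_j) k)`; larger = less inter-individual
#'   variability (default 200, about 0.9% rate s.d. at the mean background
#'   of 1.6%).
#' @param tumor_meth_rate methylation rate of tumor DNA at signature
#'   markers.
#' @param signature_size hypermethylated markers per class.
#' @param signature_overlap fraction of the signature shared by all
#'   classes (pan-cancer core).
#' @param theta_by_stage named tumor fractions for stages I-IV
#'   (non-decreasing).
#' @param frag_mean,frag_dispersion negative-binomial mean and size of the
#'   informative fragment count per marker.
#' @param coverage_inflation total coverage = ceiling(inflation x
#'   informative count); must be >= 1.
#' @param n_beta_samples,n_beta_blocks,beta_block_size samples, planted
#'   blocks and CpGs per block for beta-matrix mode.
#' @param beta_within_gap,beta_between_gap intra-/inter-block CpG spacing
#'   in bp.
#' @param beta_noise_sd site-level noise around the per-block latent factor
#'   (controls the planted adjacent correlation).
#' @param seed simulation seed.
#' @return A validated config list of class `mt_sim_config`.
#' @export
sim_config <- function(n_markers = 150,
                       n_healthy = 200,
                       n_per_class = 40,
                       classes = cso_classes(),
                       stage_probs = c(I = 0.16, II = 0.20, III = 0.30, IV = 0.34),
                       baseline_shape1 = 1,
                       baseline_shape2 = 60,
                       baseline_concentration = 200,
                       tumor_meth_rate = 0.6,
                       signature_size = 12,
                       signature_overlap = 0.25,
                       theta_by_stage = c(I = 0.004, II = 0.01, III = 0.03, IV = 0.08),
                       frag_mean = 40,
                       frag_dispersion = 5,
                       coverage_inflation = 1.2,
                       n_beta_samples = 130,
                       n_beta_blocks = 8,
                       beta_block_size = 4,
                       beta_within_gap = 30,
                       beta_between_gap = 1000,
                       beta_noise_sd = 0.1,
                       seed = 1) {
  cfg <- as.list(environment())
  if (any(cfg$theta_by_stage < 0 | cfg$theta_by_stage > 1)) stop_input("theta in [0,1]")
  if (is.unsorted(cfg$theta_by_stage)) stop_input("theta must be non-decreasing across stages")
  if (cfg$tumor_meth_rate < 0 || cfg$tumor_meth_rate > 1) stop_input("tumor_meth_rate in [0,1]")
  if (abs(sum(cfg$stage_probs) - 1) > 1e-8) stop_input("stage_probs must sum to 1")
  if (cfg$coverage_inflation < 1) stop_input("coverage_inflation >= 1")
  if (cfg$n_markers < length(cfg$classes) * cfg$signature_size) {
    stop_input("panel too small for the per-class signatures")
  }
  if (cfg$signature_overlap < 0 || cfg$signature_overlap > 1) stop_input("overlap in [0,1]")
  structure(cfg, class = "mt_sim_config")
}

# stage counts per class: largest-remainder allocation, deterministic
allocate_stages <- function(n, probs) {
  base <- floor(probs * n)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(probs * n - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  base
}

#' Simulate a marker-matrix cohort
#'
#' Per sample and marker: background rate `r0 ~ Beta(a0, b0)`; cancer
#' samples mix in tumor signal at their class-signature markers,
#' `r = (1 - theta) r0 + theta r_tumor`; `n_informative ~ NegBin`,
#' `mfc ~ Binomial(n_informative, r)`, `coverage = ceiling(inflation x
#' n_informative)`, `mfr = mfc / n_informative`.
#'
#' @param config `mt_sim_config` from [sim_config()].
#' @return Object of class `mt_cohort`: list with `samples` (sample sheet
#'   tibble `sample_id, label, stage`), `marker_matrix` (long tibble),
#'   `truth` (list: `signatures` per class, `core_markers`, `theta` per
#'   sample, `markers`).
#' @export
simulate_marker_matrix <- function(config) {
  stopifnot(inherits(config, "mt_sim_config"))
  set.seed(derive_seed(config$seed, 1))
  markers <- sprintf("MCB%05d", seq_len(config$n_markers))

  n_core <- round_half_up(config$signature_size * config$signature_overlap)
  n_specific <- config$signature_size - n_core
  shuffled <- sample(markers)
  core <- shuffled[seq_len(n_core)]
  signatures <- list()
  offset <- n_core
  for (cl in config$classes) {
    signatures[[cl]] <- sort(c(core, shuffled[offset + seq_len(n_specific)]))
    offset <- offset + n_specific
  }

  stage_counts <- allocate_stages(config$n_per_class, config$stage_probs)
  samples <- bind_rows(
    tibble(sample_id = sprintf("H%04d", seq_len(config$n_healthy)),
           label = "healthy", stage = "none"),
    purrr::map_dfr(config$classes, function(cl) {
      tibble(
        sample_id = sprintf("%s%04d", cl, seq_len(config$n_per_class)),
        label = cl,
        stage = rep(names(config$stage_probs), stage_counts)
      )
    })
  )
  theta <- ifelse(samples$label == "healthy", 0,
                  config$theta_by_stage[samples$stage])

  ns <- nrow(samples); nm <- config$n_markers
  marker_mean <- rbeta(nm, config$baseline_shape1, config$baseline_shape2)
  kap <- config$baseline_concentration
  r0 <- matrix(rbeta(ns * nm,
                     rep(marker_mean * kap, each = ns),
                     rep((1 - marker_mean) * kap, each = ns)), ns, nm)
  r <- r0
  for (i in which(samples$label != "healthy")) {
    sig <- match(signatures[[samples$label[i]]], markers)
    r[i, sig] <- (1 - theta[i]) * r0[i, sig] + theta[i] * config$tumor_meth_rate
  }
  n_inf <- matrix(rnbinom(ns * nm, mu = config$frag_mean,
                          size = config$frag_dispersion), ns, nm)
  mfc <- matrix(rbinom(ns * nm, as.vector(n_inf), as.vector(r)), ns, nm)

  mm <- tibble(
    sample_id = rep(samples$sample_id, times = nm),
    mcb_id = rep(markers, each = ns),
    mfc = as.integer(as.vector(mfc)),
    n_informative = as.integer(as.vector(n_inf)),
    coverage = as.integer(ceiling(config$coverage_inflation * as.vector(n_inf)))
  ) |>
    mutate(mfr = if_else(.data$n_informative > 0,
                         .data$mfc / .data$n_informative, NA_real_)) |>
    select("sample_id", "mcb_id", "mfc", "n_informative", "mfr", "coverage")

  structure(
    list(samples = samples, marker_matrix = mm,
         truth = list(signatures = signatures, core_markers = sort(core),
                      theta = setNames(theta, samples$sample_id),
                      marker_mean_rate = setNames(marker_mean, markers),
                      markers = markers),
         config = config),
    class = "mt_cohort"
  )
}

#' @export
print.mt_cohort <- function(x, ...) {
  cat("<mt_cohort>", nrow(x$samples), "samples x",
      length(x$truth$markers), "markers;",
      sum(x$samples$label == "healthy"), "healthy\n")
  invisible(x)
}

#' Simulate a beta-value matrix with planted correlated blocks
#'
#' CpGs come in blocks sharing a per-sample latent factor plus independent
#' site noise, so adjacent within-block Pearson correlations exceed the MCB
#' criterion in expectation while inter-block correlations are near zero.
#' Within-block CpG spacing is below, and between-block spacing above, the
#' default 100 bp gap rule.
#'
#' @param config `mt_sim_config`.
#' @return List: `beta` (tibble `chrom, pos, <samples>`), `block_members`
#'   (list of planted member positions per block).
#' @export
simulate_beta_matrix <- function(config) {
  stopifnot(inherits(config, "mt_sim_config"))
  if (config$beta_block_size < 3) stop_input("block size >= 3 required")
  set.seed(derive_seed(config$seed, 2))
  ns <- config$n_beta_samples
  rows <- list(); members <- list()
  pos <- 1000L
  for (b in seq_len(config$n_beta_blocks)) {
    f <- rnorm(ns)
    block_pos <- pos + cumsum(c(0L, rep(config$beta_within_gap, config$beta_block_size - 1)))
    for (j in seq_len(config$beta_block_size)) {
      z <- f + rnorm(ns, sd = config$beta_noise_sd)
      rows[[length(rows) + 1L]] <- c(chrom = "chr1", pos = block_pos[j],
                                     setNames(pnorm(z, sd = sqrt(1 + config$beta_noise_sd^2)),
                                              sprintf("S%03d", seq_len(ns))))
    }
    members[[b]] <- as.integer(block_pos)
    pos <- block_pos[config$beta_block_size] + config$beta_between_gap
  }
  beta <- as_tibble(do.call(rbind, rows))
  beta$pos <- as.integer(beta$pos)
  beta[sprintf("S%03d", seq_len(ns))] <-
    lapply(beta[sprintf("S%03d", seq_len(ns))], as.numeric)
  list(beta = beta, block_members = members)
}

#' A toy MCB panel laid out on the genome
#'
#' Deterministic MCB coordinates for fragment-level simulation: each marker
#' is a block of `cpgs_per_mcb` CpGs spaced `within_gap` bp apart, blocks
#' separated by `between_gap` bp, cycling over chromosomes.
#'
#' @param n_markers number of MCBs.
#' @param cpgs_per_mcb member CpGs per MCB (>= 3).
#' @param within_gap,between_gap spacing in bp.
#' @param n_chroms chromosomes to cycle over.
#' @return MCB tibble compatible with [quantify_fragments()].
#' @export
toy_mcb_panel <- function(n_markers, cpgs_per_mcb = 4, within_gap = 30,
                          between_gap = 1000, n_chroms = 7) {
  stopifnot(cpgs_per_mcb >= 3)
  per_chrom <- ceiling(n_markers / n_chroms)
  purrr::map_dfr(seq_len(n_markers), function(k) {
    chrom <- sprintf("chr%d", ((k - 1) %% n_chroms) + 1)
    slot <- (k - 1) %/% n_chroms
    start <- 1000L + slot * as.integer(between_gap + cpgs_per_mcb * within_gap)
    cpgs <- start + as.integer(within_gap) * (seq_len(cpgs_per_mcb) - 1L)
    tibble(mcb_id = sprintf("MCB%05d", k), chrom = chrom,
           start = cpgs[1], end = cpgs[cpgs_per_mcb] + 2L,
           n_cpgs = cpgs_per_mcb, cpg_positions = list(cpgs))
  })
}

#' Emit per-read calls that reproduce a simulated marker matrix
#'
#' For every (sample, MCB) cell, writes `n_informative` read pairs covering
#' all member CpGs - `mfc` of them fully methylated, the rest unmethylated
#' at one random member CpG - plus `coverage - n_informative` span-
#' overlapping but non-informative pairs (two member CpGs and one filler
#' CpG between blocks). Quantifying these reads reproduces the matrix cell
#' for cell.
#'
#' @param cohort `mt_cohort` from [simulate_marker_matrix()].
#' @param mcbs MCB tibble, e.g. [toy_mcb_panel()] with matching marker ids.
#' @param seed reproducibility seed (defaults to the cohort's).
#' @return Long read-call tibble (see [read_methylation_calls()]).
#' @export
simulate_fragments <- function(cohort, mcbs, seed = NULL) {
  stopifnot(inherits(cohort, "mt_cohort"))
  seed <- seed %||% cohort$config$seed
  set.seed(derive_seed(seed, 3))
  mm <- cohort$marker_matrix
  mcb_idx <- match(mm$mcb_id, mcbs$mcb_id)
  if (anyNA(mcb_idx)) stop_input("marker ids missing from the MCB panel")

  out <- vector("list", nrow(mm))
  for (row in seq_len(nrow(mm))) {
    k <- mcb_idx[row]
    pos <- mcbs$cpg_positions[[k]]
    npos <- length(pos)
    n_inf <- mm$n_informative[row]
    n_extra <- mm$coverage[row] - n_inf
    if (n_inf + n_extra == 0) next
    frags <- list()
    if (n_inf > 0) {
      u_site <- sample.int(npos, n_inf, replace = TRUE)  # the one U call per non-full fragment
      calls <- matrix("M", n_inf, npos)
      not_full <- seq_len(n_inf) > mm$mfc[row]
      calls[cbind(which(not_full), u_site[not_full])] <- "U"
      frags$inf <- calls
    }
    sid <- mm$sample_id[row]; mid <- mm$mcb_id[row]; chrom <- mcbs$chrom[k]
    # split each informative fragment into two mates sharing one agreeing call
    half <- ceiling(npos / 2)
    rec <- function(i, mate, p, cl) {
      tibble(sample_id = sid, read_id = sprintf("%s_%s_f%03d", sid, mid, i),
             mate = mate, chrom = chrom, pos = p, call = cl)
    }
    if (n_inf > 0) {
      for (i in seq_len(n_inf)) {
        cl <- frags$inf[i, ]
        out[[length(out) + 1L]] <- bind_rows(
          rec(i, 1L, pos[1:half], cl[1:half]),
          rec(i, 2L, pos[half:npos], cl[half:npos])
        )
      }
    }
    if (n_extra > 0) {
      filler <- mcbs$end[k] + 300L
      for (i in seq_len(n_extra)) {
        out[[length(out) + 1L]] <- bind_rows(
          rec(n_inf + i, 1L, pos[1:2], c("M", "M")),
          rec(n_inf + i, 2L, filler, "U")
        )
      }
    }
  }
  bind_rows(out)
}

#' Stratified train/test split
#'
#' Assigns each sample to `train` or `test`, stratified by label x stage,
#' with `round(ratio x n)` (half-up) training samples per stratum and at
#' least one (a singleton stratum trains).
#'
#' @param samples sample sheet tibble (`sample_id`, `label`, `stage`).
#' @param ratio training fraction (default 0.7).
#' @param seed split seed.
#' @return The sample sheet with a `split` column.
#' @export
stratified_split <- function(samples, ratio = 0.7, seed = 1) {
  check_sample_sheet(samples)
  if (!nrow(samples)) stop_input("empty sample sheet")
  stage <- if ("stage" %in% names(samples)) samples$stage else "none"
  strata <- paste(samples$label, stage)
  set.seed(derive_seed(seed, 4))
  split <- character(nrow(samples))
  for (s in unique(strata)) {
    rows <- which(strata == s)
    n_train <- max(1L, round_half_up(ratio * length(rows)))
    tr <- sample(rows, n_train)
    split[tr] <- "train"
    split[setdiff(rows, tr)] <- "test"
  }
  samples$split <- split
  samples
}

#' Write a simulated cohort to disk
#'
#' Emits the sample sheet, long marker matrix and ground truth (JSON);
#' plain-text formats only.
#'
#' @param cohort `mt_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(cohort$samples, file.path(dir, "samples.tsv"), progress = FALSE)
  write_marker_matrix(cohort$marker_matrix, file.path(dir, "marker_matrix.tsv"))
  jsonlite::write_json(
    list(signatures = cohort$truth$signatures,
         core_markers = cohort$truth$core_markers,
         theta = as.list(cohort$truth$theta)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
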