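# Synthetic-cohort generator. Emulates a dense longitudinal methylation
# study: 2 individuals x 2 blood sample types (PBMC, monocyte) x 24
# timepoints over 84 days, with per-timepoint six-cell-type composition
# estimates, probe metadata, a genomic annotation track on one synthetic
# chromosome, a between-individual RI reference table, and a multi-study,
# multi-trait EWAS marker catalog with planted category-level enrichment.
# Every planted property is recorded in a ground-truth ledger so parameter
# recovery by the analysis pipeline is measurable.

#' Configuration for the synthetic-cohort generator
#'
#' Builds and validates the parameter set that defines a synthetic cohort.
#' Defaults emulate the reference study design: two individuals sampled 24
#' times over 84 days, with PBMC and monocyte fractions assayed each time.
#' The default category mix places roughly 80% of CpGs below a
#' within-individual reference interval (RI) of 5 percentage points, with
#' small minorities in the stable (< 1), dynamic (10-50) and hyperdynamic
#' (>= 50, binary-switching) regimes.
#'
#' @param master_seed Integer seed; all randomness derives from it through a
#'   fixed per-component child-seed scheme, so identical configurations give
#'   byte-identical cohorts.
#' @param n_cpgs Number of CpG probes to simulate.
#' @param n_timepoints Number of timepoints per series (default 24, spread
#'   over 84 days).
#' @param n_individuals Number of individuals (default 2, labelled A, B, ...).
#' @param tissues Character vector of sample-type labels; `"PBMC"` and
#'   `"monocyte"` have built-in cell-composition baselines.
#' @param category_mix Named proportions over
#'   `c("stable","intermediate","dynamic","hyperdynamic")`; must sum to 1.
#' @param frac_cell_driven Proportion of CpGs whose level is a convolution of
#'   cell-type proportions with fixed cell-type-specific levels.
#' @param frac_snp_overlap Proportion of probes tagged with an overlapping
#'   SNP of MAF >= 0.05 (a further 2% receive a benign MAF < 0.05).
#' @param frac_missing Proportion of CpGs given at least one missing value.
#' @param noise_sd_by_category Named list of trajectory noise scales in
#'   percentage points; the `intermediate` entry is a length-2 range from
#'   which a per-CpG raw noise SD is drawn uniformly, then attenuated by
#'   the bounded-methylation factor `sqrt(4 m (1 - m))` of the CpG's mean
#'   level `m` and capped below the dynamic band.
#' @param tissue_noise_sd SD of independent per-tissue measurement noise
#'   added on top of the shared per-individual latent trajectory.
#' @param tissue_effect_sd SD of the fixed per-CpG offset distinguishing
#'   sample types (drives the tissue separation seen in a PCA overview).
#' @param prop_perturb_scale Scale of the mean-reverting perturbation of
#'   cell-type proportions around the tissue baseline; 0 gives constant
#'   compositions.
#' @param n_traits,studies_per_trait Size of the synthetic EWAS catalog.
#' @param planted_or_by_category Named true enrichment odds ratios (marker
#'   odds in a category relative to background odds) used when planting
#'   EWAS markers; all must be positive.
#' @param marker_base_rate Background per-study probability that a CpG is a
#'   marker.
#'
#' @return An object of class `"generator_config"` (a validated list).
#' @examples
#' cfg <- generator_config(master_seed = 1, n_cpgs = 500)
#' @export
generator_config <- function(master_seed = 1L,
                             n_cpgs = 2000L,
                             n_timepoints = 24L,
                             n_individuals = 2L,
                             tissues = c("PBMC", "monocyte"),
                             category_mix = c(stable = 0.06,
                                              intermediate = 0.90,
                                              dynamic = 0.035,
                                              hyperdynamic = 0.005),
                             frac_cell_driven = 0.033,
                             frac_snp_overlap = 0.05,
                             frac_missing = 0.002,
                             noise_sd_by_category = list(stable = 0.15,
                                                         intermediate = c(0.6, 4.5),
                                                         dynamic = 0.5,
                                                         hyperdynamic = 1.0),
                             tissue_noise_sd = 0.1,
                             tissue_effect_sd = 5,
                             prop_perturb_scale = 0.04,
                             n_traits = 8L,
                             studies_per_trait = 5L,
                             planted_or_by_category = c(stable = 0.7,
                                                        intermediate = 1,
                                                        dynamic = 3,
                                                        hyperdynamic = 1),
                             marker_base_rate = 0.01) {
  regimes <- c("stable", "intermediate", "dynamic", "hyperdynamic")
  counts <- c(n_cpgs = n_cpgs, n_timepoints = n_timepoints,
              n_individuals = n_individuals, n_traits = n_traits,
              studies_per_trait = studies_per_trait)
  if (any(counts < 1) || any(counts != round(counts)))
    stop("generator_config: counts must be positive integers")
  if (!is.character(tissues) || length(tissues) < 1)
    stop("generator_config: 'tissues' must be a non-empty character vector")
  if (!setequal(names(category_mix), regimes))
    stop("generator_config: category_mix must name exactly the regimes ",
         paste(regimes, collapse = ", "))
  category_mix <- category_mix[regimes]
  if (abs(sum(category_mix) - 1) > 1e-9)
    stop("generator_config: category_mix must sum to 1")
  props <- c(category_mix, frac_cell_driven, frac_snp_overlap, frac_missing,
             marker_base_rate)
  if (any(props < 0 | props > 1))
    stop("generator_config: all proportions must lie in [0, 1]")
  if (!setequal(names(noise_sd_by_category), regimes))
    stop("generator_config: noise_sd_by_category must name every regime")
  if (!setequal(names(planted_or_by_category), regimes))
    stop("generator_config: planted_or_by_category must name every regime")
  if (any(planted_or_by_category <= 0))
    stop("generator_config: planted odds ratios must be positive")
  cfg <- list(master_seed = as.integer(master_seed),
              n_cpgs = as.integer(n_cpgs),
              n_timepoints = as.integer(n_timepoints),
              n_individuals = as.integer(n_individuals),
              tissues = tissues,
              category_mix = category_mix,
              frac_cell_driven = frac_cell_driven,
              frac_snp_overlap = frac_snp_overlap,
              frac_missing = frac_missing,
              noise_sd_by_category = noise_sd_by_category,
              tissue_noise_sd = tissue_noise_sd,
              tissue_effect_sd = tissue_effect_sd,
              prop_perturb_scale = prop_perturb_scale,
              n_traits = as.integer(n_traits),
              studies_per_trait = as.integer(studies_per_trait),
              planted_or_by_category = planted_or_by_category[regimes],
              marker_base_rate = marker_base_rate)
  class(cfg) <- "generator_config"
  cfg
}

#' Series table of a configuration
#'
#' One row per (individual, tissue) series, in generation order.
#' @param config A [generator_config()].
#' @return data.frame with columns `individual`, `tissue`, `series`.
#' @export
series_table <- function(config) {
  inds <- LETTERS[seq_len(config$n_individuals)]
  out <- data.frame(individual = rep(inds, each = length(config$tissues)),
                    tissue = rep(config$tissues, times = length(inds)),
                    stringsAsFactors = FALSE)
  out$series <- paste(out$individual, out$tissue, sep = "_")
  out
}

#' Day grid of a configuration
#' @param config A [generator_config()].
#' @return Integer vector of day offsets, evenly spread over 84 days.
#' @export
timepoint_days <- function(config) {
  as.integer(round(seq(0, 84, length.out = config$n_timepoints)))
}

# --- ground truth -----------------------------------------------------------

#' Draw the planted ground truth of a synthetic cohort
#'
#' Samples each CpG's stability category, cell-driven flag, SNP MAF tag,
#' missing-value slots, cell-type-specific levels (cell-driven CpGs only),
#' and the between-individual RI reference value, recording everything in a
#' ledger against which recovery can be scored.
#'
#' @param config A [generator_config()].
#' @return A list of class `"synthetic_truth"` with per-CpG vectors
#'   `category`, `cell_driven`, `snp_maf`, `between_ri`, `cdmv`, a
#'   `cell_levels` matrix, a `missing` data.frame, and the config snapshot.
#' @export
generate_truth <- function(config) {
  n <- config$n_cpgs
  cpg_id <- sprintf("cg%06d", seq_len(n))
  set.seed(child_seed(config$master_seed, 1))
  category <- sample(names(config$category_mix), n, replace = TRUE,
                     prob = config$category_mix)
  cell_driven <- runif(n) < config$frac_cell_driven
  # Per-CpG methylation level and trajectory noise of intermediate CpGs,
  # shared across individuals. The raw noise scale is attenuated by the
  # bounded-methylation factor sqrt(4 m (1 - m)) — CpGs pinned near 0 or
  # 100% cannot fluctuate much — and capped so intermediate CpGs stay out
  # of the dynamic band.
  irange <- config$noise_sd_by_category$intermediate
  inter <- category == "intermediate"
  n_int <- sum(inter)
  intermediate_base <- rep(NA_real_, n)
  intermediate_sd <- rep(NA_real_, n)
  if (n_int > 0) {
    u_b <- runif(n_int)
    b1 <- runif(n_int, 1, 8); b2 <- runif(n_int, 92, 99)
    b3 <- runif(n_int, 10, 90)
    intermediate_base[inter] <- ifelse(u_b < 0.4, b1,
                                       ifelse(u_b < 0.8, b2, b3))
    raw_sd <- runif(n_int, irange[1], irange[2])
    m <- intermediate_base[inter] / 100
    intermediate_sd[inter] <- pmin(raw_sd * sqrt(4 * m * (1 - m)), 2.8)
  }
  u <- runif(n)
  snp_maf <- rep(NA_real_, n)
  hi <- u < config$frac_snp_overlap
  lo <- !hi & u < config$frac_snp_overlap + 0.02
  snp_maf[hi] <- runif(sum(hi), 0.05, 0.5)
  snp_maf[lo] <- runif(sum(lo), 0.01, 0.049)
  cell_levels <- matrix(NA_real_, n, length(CELL_TYPES),
                        dimnames = list(cpg_id, CELL_TYPES))
  ncd <- sum(cell_driven)
  if (ncd > 0)
    cell_levels[cell_driven, ] <- matrix(runif(ncd * length(CELL_TYPES), 0, 100),
                                         ncd)
  n_series <- config$n_individuals * length(config$tissues)
  miss_cpg <- which(runif(n) < config$frac_missing)
  missing <- data.frame(cpg_idx = integer(0), series_idx = integer(0),
                        t_idx = integer(0))
  if (length(miss_cpg) > 0) {
    rows <- lapply(miss_cpg, function(i) {
      k <- sample(1:3, 1)
      data.frame(cpg_idx = i,
                 series_idx = sample(n_series, 1),
                 t_idx = sample(config$n_timepoints, k))
    })
    missing <- do.call(rbind, rows)
  }
  # Between-individual RI reference, drawn so category-level CDMV overlap
  # mirrors the published pattern: essentially no stable CpGs are CDMV, a
  # third of dynamic and a fifth of hyperdynamic CpGs are, and CDMV CpGs are
  # numerous enough that dynamic CpGs make up only a few percent of them.
  # For intermediate CpGs the CDMV probability grows with the CpG's own
  # within-individual noise (between- and within-individual variability are
  # correlated), averaging ~0.2 over the noise range.
  set.seed(child_seed(config$master_seed, 5))
  between_ri <- numeric(n)
  idx <- category == "stable"
  between_ri[idx] <- runif(sum(idx), 0, 8)
  idx <- category == "intermediate"
  v <- runif(sum(idx))
  cdmv_p <- pmin(0.78 * (intermediate_sd[idx] / 2.8)^2, 1)
  between_ri[idx] <- ifelse(v < cdmv_p, runif(sum(idx), 30, 65),
                            runif(sum(idx), 0, 28))
  idx <- category == "dynamic"
  v <- runif(sum(idx))
  between_ri[idx] <- ifelse(v < 0.38, runif(sum(idx), 30, 70),
                            runif(sum(idx), 5, 30))
  idx <- category == "hyperdynamic"
  v <- runif(sum(idx))
  between_ri[idx] <- ifelse(v < 0.18, runif(sum(idx), 30, 70),
                            runif(sum(idx), 3, 28))
  truth <- list(cpg_id = cpg_id,
                category = category,
                intermediate_base = intermediate_base,
                intermediate_sd = intermediate_sd,
                cell_driven = cell_driven,
                snp_maf = snp_maf,
                cell_levels = cell_levels,
                missing = missing,
                between_ri = between_ri,
                cdmv = between_ri > 30,
                config = config,
                master_seed = config$master_seed)
  class(truth) <- "synthetic_truth"
  truth
}

# --- cell-type proportions --------------------------------------------------

tissue_baseline <- function(tissue) {
  switch(tissue,
         PBMC = c(CD4T = 0.35, CD8T = 0.20, NK = 0.15, B = 0.12,
                  Mono = 0.16, Gran = 0.02),
         monocyte = c(CD4T = 0.03, CD8T = 0.02, NK = 0.02, B = 0.01,
                      Mono = 0.90, Gran = 0.02),
         stop("generate_cell_proportions: no cell-composition baseline for ",
              "tissue label '", tissue, "'"))
}

#' Generate per-timepoint cell-type proportions for one series
#'
#' Proportions of the six major blood cell types (CD4+ T, CD8+ T, NK, B,
#' monocytes, granulocytes) follow a mean-reverting (AR(1)) perturbation
#' around a tissue-specific baseline; monocyte-fraction series are dominated
#' by the monocyte component. Rows are estimated compositions and need not
#' sum exactly to 1, but stay within [0.9, 1.1].
#'
#' @param config A [generator_config()].
#' @param series_key List or one-row data.frame with `individual`, `tissue`.
#' @return List with `series_key`, `days` and a timepoints x 6 `proportions`
#'   matrix, deterministic given `(master_seed, series_key)`.
#' @export
generate_cell_proportions <- function(config, series_key) {
  st <- series_table(config)
  sidx <- which(st$individual == series_key$individual &
                st$tissue == series_key$tissue)
  if (length(sidx) != 1)
    stop("generate_cell_proportions: unknown series (individual '",
         series_key$individual, "', tissue '", series_key$tissue, "')")
  base <- tissue_baseline(series_key$tissue)
  n_t <- config$n_timepoints
  set.seed(child_seed(config$master_seed, 100 + sidx))
  e <- matrix(0, n_t, length(CELL_TYPES))
  for (j in seq_along(CELL_TYPES)) {
    sdc <- config$prop_perturb_scale * sqrt(base[j] * (1 - base[j]))
    ej <- numeric(n_t)
    ej[1] <- rnorm(1, 0, sdc)
    # fast mean reversion: deconvolution estimates jitter between visits
    for (t in seq_len(n_t)[-1]) ej[t] <- 0.2 * ej[t - 1] + rnorm(1, 0, sdc)
    e[, j] <- ej
  }
  # Mostly compensate the row-sum drift so compositions stay near (but not
  # exactly at) unit sum, keeping the design matrix near- but not exactly
  # collinear with the intercept.
  e <- e - outer(rowSums(e) * 0.8, base)
  x <- clip01(sweep(e, 2, base, "+"))
  colnames(x) <- CELL_TYPES
  rownames(x) <- sprintf("T%02d", seq_len(n_t))
  list(series_key = list(individual = series_key$individual,
                         tissue = series_key$tissue),
       days = timepoint_days(config),
       proportions = x)
}

# --- methylation trajectories -----------------------------------------------

# Latent per-individual trajectories, shared across that individual's
# tissues (dynamic and hyperdynamic fluctuations are synchronized between
# PBMC and monocytes within an individual).
simulate_latent <- function(config, truth, ind_idx) {
  n <- config$n_cpgs
  n_t <- config$n_timepoints
  days <- timepoint_days(config)
  nz <- config$noise_sd_by_category
  set.seed(child_seed(config$master_seed, 200 + ind_idx))
  lat <- matrix(0, n, n_t)

  idx <- which(truth$category == "stable")
  if (length(idx) > 0) {
    k <- length(idx)
    u <- runif(k)
    b_lo <- runif(k, 0.2, 3)
    b_hi <- runif(k, 97, 99.8)
    base <- ifelse(u < 0.5, b_lo, b_hi)
    lat[idx, ] <- base + matrix(rnorm(k * n_t, 0, nz$stable), k)
  }
  idx <- which(truth$category == "intermediate")
  if (length(idx) > 0) {
    k <- length(idx)
    # CpG-level mean is conserved across individuals up to a small offset,
    # attenuated near the 0/100 boundaries like every bounded-scale shift
    m <- truth$intermediate_base[idx] / 100
    base <- truth$intermediate_base[idx] +
      rnorm(k, 0, 1.5) * sqrt(4 * m * (1 - m))
    lat[idx, ] <- base + matrix(rnorm(k * n_t), k) * truth$intermediate_sd[idx]
  }
  idx <- which(truth$category == "dynamic")
  if (length(idx) > 0) {
    k <- length(idx)
    amp <- runif(k, 15, 42)
    per <- runif(k, 25, 90)
    ph <- runif(k, 0, 2 * pi)
    base <- runif(k, amp / 2 + 3, 97 - amp / 2)
    osc <- (amp / 2) * sin(outer(2 * pi / per, days) + ph)
    lat[idx, ] <- base + osc + matrix(rnorm(k * n_t, 0, nz$dynamic), k)
  }
  idx <- which(truth$category == "hyperdynamic")
  if (length(idx) > 0) {
    k <- length(idx)
    l0 <- runif(k, 0, 4)
    l1 <- runif(k, 96, 100)
    state <- matrix(FALSE, k, n_t)
    state[, 1] <- runif(k) < 0.5
    sw <- matrix(runif(k * n_t), k) < 0.3  # per-timepoint switch probability
    for (t in seq_len(n_t)[-1]) state[, t] <- xor(state[, t - 1], sw[, t])
    lat[idx, ] <- ifelse(state, l1, l0) + matrix(rnorm(k * n_t, 0, nz$hyperdynamic), k)
  }
  lat
}

#' Generate one (individual, tissue) methylation series
#'
#' Stable CpGs sit near 0 or 100 with small noise; intermediate CpGs carry
#' moderate noise; dynamic CpGs drift smoothly with a peak-to-trough tuned
#' into 10-50 percentage points; hyperdynamic CpGs switch between near-0 and
#' near-100 states. Dynamic and hyperdynamic trajectories share the
#' per-individual latent signal across that individual's tissues.
#' Cell-driven CpGs are the convolution of the series' cell-type proportions
#' with fixed cell-type-specific levels. All values are clipped to [0, 100];
#' planted missing slots are `NA`.
#'
#' @param config A [generator_config()].
#' @param truth Ground truth from [generate_truth()].
#' @param props Proportions from [generate_cell_proportions()] for the same
#'   series.
#' @param series_key List with `individual` and `tissue`.
#' @return List with `series_key`, `days`, and a CpG x timepoint `values`
#'   matrix (percent scale).
#' @export
generate_beta_series <- function(config, truth, props, series_key) {
  st <- series_table(config)
  sidx <- which(st$individual == series_key$individual &
                st$tissue == series_key$tissue)
  if (length(sidx) != 1)
    stop("generate_beta_series: unknown series")
  ind_idx <- match(series_key$individual, LETTERS[seq_len(config$n_individuals)])
  tis_idx <- match(series_key$tissue, config$tissues)
  n <- config$n_cpgs
  n_t <- config$n_timepoints

  lat <- simulate_latent(config, truth, ind_idx)
  # Fixed per-CpG sample-type offset, shared across individuals.
  set.seed(child_seed(config$master_seed, 250 + tis_idx))
  delta <- rnorm(n, 0, config$tissue_effect_sd)
  # Series-specific measurement noise and cell-driven convolution. The
  # sample-type offset, like any shift on the bounded methylation scale,
  # attenuates near the 0/100 boundaries.
  set.seed(child_seed(config$master_seed, 300 + ind_idx * 10 + tis_idx))
  m_row <- pmin(pmax(rowMeans(lat) / 100, 0.01), 0.99)
  delta <- delta * sqrt(4 * m_row * (1 - m_row))
  obs <- lat + delta + matrix(rnorm(n * n_t, 0, config$tissue_noise_sd), n)
  cd <- which(truth$cell_driven)
  if (length(cd) > 0) {
    conv <- truth$cell_levels[cd, , drop = FALSE] %*% t(props$proportions)
    obs[cd, ] <- conv + matrix(rnorm(length(cd) * n_t, 0, 0.5), length(cd))
  }
  obs <- clip0100(obs)
  miss <- truth$missing[truth$missing$series_idx == sidx, , drop = FALSE]
  if (nrow(miss) > 0) obs[cbind(miss$cpg_idx, miss$t_idx)] <- NA_real_
  dimnames(obs) <- list(truth$cpg_id, sprintf("T%02d", seq_len(n_t)))
  list(series_key = list(individual = series_key$individual,
                         tissue = series_key$tissue),
       days = timepoint_days(config),
       values = obs)
}

# --- annotation track and probe metadata ------------------------------------

# Synthetic chromosome layout: genes at a fixed 20 kb pitch, TSS at
# 10000 + (i-1)*20000 (0-based), alternating strands. Feature windows are
# expressed as offsets d from the TSS in transcription direction.
GENE_PITCH <- 20000
FIRST_TSS <- 10000

gene_feature_offsets <- function() {
  feats <- rbind(
    data.frame(feature_class = "upstream_1to5kb", u = -5000, v = -1000),
    data.frame(feature_class = "promoter",        u = -1000, v = 0),
    data.frame(feature_class = "utr5",            u = 0,     v = 100),
    data.frame(feature_class = "exon",            u = 100,   v = 250),
    data.frame(feature_class = "intron",          u = 250,   v = 1050),
    data.frame(feature_class = "exon",            u = 1050,  v = 1200),
    data.frame(feature_class = "intron",          u = 1200,  v = 2000),
    data.frame(feature_class = "exon",            u = 2000,  v = 2150),
    data.frame(feature_class = "utr3",            u = 2150,  v = 2250))
  junctions <- c(250, 1050, 1200, 2000)  # +/- 100 bp around splice junctions
  bounds <- data.frame(feature_class = "exon_intron_boundary",
                       u = junctions - 100, v = junctions + 100)
  rbind(feats, bounds)
}

# CpG-context offsets, symmetric in layout around each TSS (in
# transcription direction): 1 kb island over the promoter/TSS, 2 kb shores,
# 2 kb shelves, open sea elsewhere. Blocks of neighboring genes never
# collide (pitch 20 kb > 2 x 4.8 kb), so contexts partition the chromosome.
context_offsets <- function() {
  rbind(data.frame(feature_class = "island", u = -200, v = 800),
        data.frame(feature_class = "shore", u = c(-2200, 800), v = c(-200, 2800)),
        data.frame(feature_class = "shelf", u = c(-4200, 2800), v = c(-2200, 4800)))
}

# Signed offset of a 0-based position from its nearest gene's TSS, in that
# gene's transcription direction; returns gene index and offset.
nearest_gene_offset <- function(pos0, n_genes, strands) {
  g <- pmin(pmax(round((pos0 - FIRST_TSS) / GENE_PITCH) + 1, 1), n_genes)
  tss <- FIRST_TSS + (g - 1) * GENE_PITCH
  d <- pos0 - tss
  d[strands[g] == "-"] <- -d[strands[g] == "-"]
  list(gene = g, d = d)
}

#' Generate the synthetic annotation track and probe metadata
#'
#' Tiles a single synthetic chromosome (`chrS`) with genes (promoter,
#' 1-5 kb upstream, 5'UTR, exons, introns, exon-intron boundary windows,
#' 3'UTR) and mutually exclusive CpG-context intervals (island, shore,
#' shelf, open sea), places probes with known feature memberships recorded
#' in the truth ledger, and assigns Infinium design labels, GC fractions,
#' and overlapping-SNP MAFs. Stable CpGs are preferentially placed in
#' islands and dynamic CpGs in open sea, mirroring the composition
#' differences seen in real categories.
#'
#' @param config A [generator_config()].
#' @param truth Ground truth from [generate_truth()].
#' @return List with `annotation` (0-based half-open intervals), `probes`
#'   (1-based positions), and truth memberships `context` (one class per
#'   probe) and `genic` (>= 1 row per probe).
#' @export
generate_annotation_and_probes <- function(config, truth) {
  n <- config$n_cpgs
  n_genes <- max(3L, as.integer(ceiling(n / 60)))
  chrom_len <- FIRST_TSS + n_genes * GENE_PITCH
  strands <- rep(c("+", "-"), length.out = n_genes)
  tss <- FIRST_TSS + (seq_len(n_genes) - 1) * GENE_PITCH
  gene_id <- sprintf("gene%04d", seq_len(n_genes))

  offs <- gene_feature_offsets()
  to_interval <- function(u, v, g) {
    # offsets (u, v) in transcription direction -> absolute 0-based half-open
    if (strands[g] == "+") c(tss[g] + u, tss[g] + v) else c(tss[g] - v, tss[g] - u)
  }
  rows <- vector("list", n_genes * (nrow(offs) + nrow(context_offsets())))
  ri <- 1
  ctx <- context_offsets()
  for (g in seq_len(n_genes)) {
    for (j in seq_len(nrow(offs))) {
      iv <- to_interval(offs$u[j], offs$v[j], g)
      rows[[ri]] <- data.frame(chrom = "chrS", start = iv[1], end = iv[2],
                               feature_class = offs$feature_class[j],
                               gene_id = gene_id[g], strand = strands[g])
      ri <- ri + 1
    }
    for (j in seq_len(nrow(ctx))) {
      iv <- to_interval(ctx$u[j], ctx$v[j], g)
      rows[[ri]] <- data.frame(chrom = "chrS", start = iv[1], end = iv[2],
                               feature_class = ctx$feature_class[j],
                               gene_id = NA_character_, strand = "*")
      ri <- ri + 1
    }
  }
  annotation <- do.call(rbind, rows)
  # open-sea complement of the context blocks
  blocks <- annotation[annotation$feature_class %in% c("island", "shore", "shelf"), ]
  blocks <- blocks[order(blocks$start), ]
  merged_s <- c()
  merged_e <- c()
  for (i in seq_len(nrow(blocks))) {
    if (length(merged_e) > 0 && blocks$start[i] <= merged_e[length(merged_e)]) {
      merged_e[length(merged_e)] <- max(merged_e[length(merged_e)], blocks$end[i])
    } else {
      merged_s <- c(merged_s, blocks$start[i])
      merged_e <- c(merged_e, blocks$end[i])
    }
  }
  sea_s <- c(0, merged_e)
  sea_e <- c(merged_s, chrom_len)
  keep <- sea_e > sea_s
  annotation <- rbind(annotation,
                      data.frame(chrom = "chrS", start = sea_s[keep],
                                 end = sea_e[keep], feature_class = "open_sea",
                                 gene_id = NA_character_, strand = "*"))
  annotation <- annotation[order(annotation$start, annotation$end), ]
  rownames(annotation) <- NULL

  # probe placement, biased by planted category
  set.seed(child_seed(config$master_seed, 400))
  r <- runif(n)
  pos0 <- integer(n)
  in_island <- truth$category == "stable" & r < 0.55
  in_sea <- truth$category == "dynamic" & r < 0.60
  uniform <- !(in_island | in_sea)
  if (any(in_island)) {
    k <- sum(in_island)
    g <- sample(n_genes, k, replace = TRUE)
    off <- sample.int(1000, k, replace = TRUE) - 1  # within the 1 kb island
    pos0[in_island] <- ifelse(strands[g] == "+", tss[g] - 200 + off,
                              tss[g] - 800 + off)
  }
  if (any(in_sea)) {
    k <- sum(in_sea)
    got <- numeric(0)
    while (length(got) < k) {
      cand <- sample.int(chrom_len, 2 * (k - length(got))) - 1
      ng <- nearest_gene_offset(cand, n_genes, strands)
      got <- c(got, cand[abs(ng$d) >= 4800])
    }
    pos0[in_sea] <- got[seq_len(k)]
  }
  pos0[uniform] <- sample.int(chrom_len, sum(uniform)) - 1
  while (anyDuplicated(pos0)) {
    dup <- duplicated(pos0)
    pos0[dup] <- sample.int(chrom_len, sum(dup)) - 1
  }

  ng <- nearest_gene_offset(pos0, n_genes, strands)
  d <- ng$d
  context <- rep("open_sea", n)
  context[d >= -200 & d < 800] <- "island"
  context[(d >= -2200 & d < -200) | (d >= 800 & d < 2800)] <- "shore"
  context[(d >= -4200 & d < -2200) | (d >= 2800 & d < 4800)] <- "shelf"

  genic_rows <- list()
  for (j in seq_len(nrow(offs))) {
    hit <- d >= offs$u[j] & d < offs$v[j]
    if (any(hit))
      genic_rows[[length(genic_rows) + 1]] <-
        data.frame(cpg_id = truth$cpg_id[hit],
                   feature_class = offs$feature_class[j],
                   gene_id = gene_id[ng$gene[hit]])
  }
  genic <- do.call(rbind, genic_rows)
  no_genic <- setdiff(truth$cpg_id, genic$cpg_id)
  genic <- rbind(genic, data.frame(cpg_id = no_genic,
                                   feature_class = "intergenic",
                                   gene_id = NA_character_))
  genic <- genic[order(match(genic$cpg_id, truth$cpg_id)), ]
  rownames(genic) <- NULL

  isl <- context == "island"
  gc_fraction <- ifelse(isl, runif(n, 0.55, 0.85), runif(n, 0.30, 0.60))
  design <- ifelse(runif(n) < ifelse(isl, 0.6, 0.25), "I", "II")
  probes <- data.frame(cpg_id = truth$cpg_id, chrom = "chrS", pos = pos0 + 1L,
                       design = design, gc_fraction = gc_fraction,
                       snp_maf = truth$snp_maf, stringsAsFactors = FALSE)
  list(annotation = annotation, probes = probes,
       context = context, genic = genic, chrom_len = chrom_len)
}

# --- EWAS catalog ------------------------------------------------------------

#' Generate a synthetic EWAS marker catalog
#'
#' For each trait and study, a CpG is recorded as a marker with the
#' background probability, or with an elevated probability when its planted
#' category carries an enrichment odds ratio, such that
#' `odds(enriched) / odds(background)` equals the planted OR. Records are
#' unique `(cpg, trait, study)` triples by construction.
#'
#' @param config A [generator_config()].
#' @param truth Ground truth from [generate_truth()].
#' @return data.frame with columns `cpg_id`, `trait`, `study_id`.
#' @export
generate_ewas_catalog <- function(config, truth) {
  p0 <- config$marker_base_rate
  odds0 <- p0 / (1 - p0)
  ors <- config$planted_or_by_category
  p_cat <- (ors * odds0) / (1 + ors * odds0)
  p_cpg <- unname(p_cat[truth$category])
  set.seed(child_seed(config$master_seed, 500))
  recs <- list()
  for (t in seq_len(config$n_traits)) {
    trait <- sprintf("trait%02d", t)
    for (s in seq_len(config$studies_per_trait)) {
      hit <- runif(config$n_cpgs) < p_cpg
      if (any(hit))
        recs[[length(recs) + 1]] <-
          data.frame(cpg_id = truth$cpg_id[hit], trait = trait,
                     study_id = sprintf("%s_study%02d", trait, s),
                     stringsAsFactors = FALSE)
    }
  }
  catalog <- do.call(rbind, recs)
  rownames(catalog) <- NULL
  catalog
}

# --- full cohort -------------------------------------------------------------

#' Generate a complete synthetic cohort
#'
#' Runs every generator component under the child-seed scheme and returns
#' the full input bundle consumed by the analysis pipeline, together with
#' the ground-truth ledger.
#'
#' @param config A [generator_config()].
#' @return An object of class `"meth_cohort"`: a list with `config`,
#'   `truth`, `probes`, `annotation`, `props` (per-series proportion
#'   objects), `betas` (per-series methylation series), `between_ri`
#'   (reference table), and `catalog` (EWAS records).
#' @examples
#' coh <- generate_cohort(generator_config(master_seed = 7, n_cpgs = 300))
#' names(coh$betas)
#' @export
generate_cohort <- function(config) {
  truth <- generate_truth(config)
  ap <- generate_annotation_and_probes(config, truth)
  truth$context <- ap$context
  truth$genic <- ap$genic
  st <- series_table(config)
  props <- list()
  betas <- list()
  for (i in seq_len(nrow(st))) {
    key <- list(individual = st$individual[i], tissue = st$tissue[i])
    props[[st$series[i]]] <- generate_cell_proportions(config, key)
    betas[[st$series[i]]] <- generate_beta_series(config, truth,
                                                  props[[st$series[i]]], key)
  }
  catalog <- generate_ewas_catalog(config, truth)
  out <- list(config = config,
              truth = truth,
              probes = ap$probes,
              annotation = ap$annotation,
              props = props,
              betas = betas,
              between_ri = data.frame(cpg_id = truth$cpg_id,
                                      between_ri = truth$between_ri),
              catalog = catalog)
  class(out) <- "meth_cohort"
  out
}
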