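# Probe-exclusion cascade: missingness across all series, overlap with
# common SNPs, and association with cell-type composition tested by
# comparing the fits of an intercept-only model against a six-cell-type
# multiple regression (nested-model ANOVA F-test). Exclusion reasons are
# attributed in the fixed order missing -> SNP -> cell-type so the cascade
# accounting is deterministic; the retained set is order-invariant.

harmonized_cpgs <- function(series_list) {
  if (length(series_list) == 0)
    stop("empty series list")
  ids <- rownames(series_list[[1]]$values)
  for (s in series_list)
    if (!identical(rownames(s$values), ids))
      stop("series are not harmonized to a common probe universe")
  ids
}

#' Filter CpGs with missing methylation values
#'
#' A CpG is retained iff it has zero missing values across every series in
#' the cohort (every dataset of every individual and tissue).
#'
#' @param series_list List of series objects as returned by
#'   [generate_beta_series()] (elements with a CpG x timepoint `values`
#'   matrix sharing rownames).
#' @return List with `retained` (character vector of CpG ids) and `report`
#'   (data.frame `cpg_id`, `reason = "missing"` for excluded CpGs).
#' @export
filter_missing <- function(series_list) {
  ids <- harmonized_cpgs(series_list)
  any_na <- Reduce(`|`, lapply(series_list, function(s) {
    rowSums(is.na(s$values)) > 0
  }))
  list(retained = ids[!any_na],
       report = data.frame(cpg_id = ids[any_na],
                           reason = if (any(any_na)) "missing" else character(0),
                           stringsAsFactors = FALSE))
}

#' Filter CpGs overlapping common SNPs
#'
#' Excludes probes whose recorded overlapping-SNP minor allele frequency is
#' present and greater than or equal to the threshold (inclusive, i.e.
#' MAF >= 5% by default). Probes without a recorded SNP are retained.
#'
#' @param probes Probe metadata data.frame with `cpg_id` and `snp_maf`
#'   (NA when no SNP overlaps the probe).
#' @param maf_threshold Exclusion threshold on the MAF (default 0.05).
#' @return List with `retained` ids and `report` (`reason = "snp"`).
#' @export
filter_snp <- function(probes, maf_threshold = 0.05) {
  if (maf_threshold < 0)
    stop("filter_snp: maf_threshold must be non-negative")
  excl <- !is.na(probes$snp_maf) & probes$snp_maf >= maf_threshold
  list(retained = probes$cpg_id[!excl],
       report = data.frame(cpg_id = probes$cpg_id[excl],
                           reason = if (any(excl)) "snp" else character(0),
                           stringsAsFactors = FALSE))
}

# Vectorized nested-model ANOVA for one series: fits, for every CpG row of
# Y, (1) the intercept-only model and (2) intercept + six cell-type
# proportions, by least squares on a pivoted (rank-revealing) QR; df of the
# full model is the numerical rank of the design, which guards against the
# near-collinearity of compositions with the intercept.
celltype_anova_series <- function(values, proportions, alpha = 0.05,
                                  warn = TRUE) {
  if (nrow(proportions) != ncol(values))
    stop("series and proportions do not share the timepoint grid")
  n_t <- ncol(values)
  X <- cbind(`(Intercept)` = 1, as.matrix(proportions))
  fit <- lm.fit(X, t(values))
  r <- fit$rank
  if (n_t <= r)
    stop("not enough timepoints for the cell-type model (n = ", n_t,
         ", rank = ", r, ")")
  sse_full <- colSums(as.matrix(fit$residuals)^2)
  mu <- rowMeans(values)
  sse_null <- rowSums((values - mu)^2)
  eps <- 1e-9
  f <- ((sse_null - sse_full) / (r - 1)) / (sse_full / (n_t - r))
  p <- pf(f, r - 1, n_t - r, lower.tail = FALSE)
  const <- sse_null < eps
  perfect <- !const & sse_full < eps
  if (warn && any(const))
    warning(sum(const), " CpG(s) with constant response: p set to 1")
  if (warn && any(perfect))
    warning(sum(perfect), " CpG(s) with an exact cell-type fit: p set to 0")
  p[const] <- 1
  f[const] <- 0
  p[perfect] <- 0
  f[perfect] <- Inf
  data.frame(cpg_id = rownames(values),
             sse_null = unname(sse_null), sse_full = unname(sse_full),
             df_null = 1L, df_full = r,
             f_stat = unname(f), p_value = unname(p),
             flagged = unname(p < alpha),
             stringsAsFactors = FALSE)
}

#' Test one CpG for association with cell-type composition
#'
#' Compares an intercept-only linear model against a multiple regression on
#' the six estimated cell-type proportions by an ANOVA F-test:
#' `F = ((SSE0 - SSE1) / (df1 - df0)) / (SSE1 / (n - df1))`, with the
#' full-model degrees of freedom taken as the numerical rank of the design.
#' A constant response gives p = 1 (not flagged); an exact full-model fit
#' of a non-constant response gives p = 0 (flagged); both warn.
#'
#' @param series A series object with a `values` matrix.
#' @param props The matching [generate_cell_proportions()] object.
#' @param cpg_id The CpG to test.
#' @param alpha Flagging threshold on the p-value (default 0.05).
#' @return One-row data.frame with `sse_null`, `sse_full`, `df_null`,
#'   `df_full`, `f_stat`, `p_value`, `flagged`.
#' @export
cell_type_association_test <- function(series, props, cpg_id, alpha = 0.05) {
  if (!cpg_id %in% rownames(series$values))
    stop("cell_type_association_test: unknown cpg_id '", cpg_id, "'")
  res <- celltype_anova_series(series$values[cpg_id, , drop = FALSE],
                               props$proportions, alpha = alpha)
  res$individual <- series$series_key$individual
  res$tissue <- series$series_key$tissue
  res
}

#' Combine per-series cell-type tests into an exclusion set
#'
#' A CpG is excluded iff it is flagged in at least one series (union rule:
#' each (individual, tissue) series is tested separately over its own
#' timepoints, which is conservative for downstream stability claims).
#'
#' @param results_list List of per-series data.frames from
#'   [celltype_anova_series()]-style tests (columns `cpg_id`, `p_value`,
#'   `flagged`).
#' @return List with `retained`, `report` (`reason = "celltype"`), and
#'   `p_values` (data.frame of per-series p-value columns).
#' @export
filter_cell_type <- function(results_list) {
  ids <- results_list[[1]]$cpg_id
  pmat <- data.frame(cpg_id = ids, stringsAsFactors = FALSE)
  flag <- rep(FALSE, length(ids))
  for (nm in names(results_list)) {
    res <- results_list[[nm]]
    if (!identical(res$cpg_id, ids))
      stop("filter_cell_type: result tables are not aligned")
    pmat[[paste0("p_", nm)]] <- res$p_value
    flag <- flag | res$flagged
  }
  list(retained = ids[!flag],
       report = data.frame(cpg_id = ids[flag],
                           reason = if (any(flag)) "celltype" else character(0),
                           stringsAsFactors = FALSE),
       p_values = pmat)
}

#' Run the full probe-exclusion cascade
#'
#' Applies the three filters in the fixed order missing -> SNP ->
#' cell-type; each CpG is attributed to the first filter that triggers, so
#' the universe size equals the retained count plus the per-reason
#' exclusion counts. The cell-type test is run only on CpGs surviving the
#' first two filters.
#'
#' @param series_list Named list of series objects (one per
#'   (individual, tissue)).
#' @param props_list Named list of matching proportion objects.
#' @param probes Probe metadata data.frame.
#' @param maf_threshold SNP MAF exclusion threshold (default 0.05).
#' @param alpha Cell-type ANOVA threshold (default 0.05, uncorrected).
#' @return List with `retained` ids, `report` (data.frame `cpg_id`,
#'   `status` in retained / excluded_missing / excluded_snp /
#'   excluded_celltype, plus per-series p-value columns where tested) and
#'   `counts` (named exclusion accounting).
#' @examples
#' coh <- generate_cohort(generator_config(master_seed = 2, n_cpgs = 200))
#' qc <- qc_cascade(coh$betas, coh$props, coh$probes)
#' qc$counts
#' @export
qc_cascade <- function(series_list, props_list, probes,
                       maf_threshold = 0.05, alpha = 0.05) {
  ids <- harmonized_cpgs(series_list)
  if (!setequal(probes$cpg_id, ids))
    stop("qc_cascade: probe table and series do not share a probe universe")
  status <- setNames(rep("retained", length(ids)), ids)

  fm <- filter_missing(series_list)
  status[fm$report$cpg_id] <- "excluded_missing"

  fs <- filter_snp(probes[match(ids, probes$cpg_id), ], maf_threshold)
  snp_new <- setdiff(fs$report$cpg_id, fm$report$cpg_id)
  status[snp_new] <- "excluded_snp"

  survivors <- ids[status == "retained"]
  tests <- lapply(names(series_list), function(nm) {
    celltype_anova_series(series_list[[nm]]$values[survivors, , drop = FALSE],
                          props_list[[nm]]$proportions, alpha = alpha,
                          warn = FALSE)
  })
  names(tests) <- names(series_list)
  fc <- filter_cell_type(tests)
  status[fc$report$cpg_id] <- "excluded_celltype"

  report <- data.frame(cpg_id = ids, status = unname(status),
                       stringsAsFactors = FALSE)
  report <- merge(report, fc$p_values, by = "cpg_id", all.x = TRUE,
                  sort = FALSE)
  report <- report[match(ids, report$cpg_id), ]
  rownames(report) <- NULL
  counts <- c(universe = length(ids),
              excluded_missing = sum(status == "excluded_missing"),
              excluded_snp = sum(status == "excluded_snp"),
              excluded_celltype = sum(status == "excluded_celltype"),
              retained = sum(status == "retained"))
  list(retained = ids[status == "retained"], report = report, counts = counts)
}
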