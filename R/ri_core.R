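# Reference-interval statistics and stability categories. The
# within-individual RI of a CpG in one (individual, tissue) series is the
# difference between the 95th and 5th percentiles of its methylation
# percentage across the timepoints; percentiles use linear interpolation
# between order statistics at rank 1 + (n - 1) q. Categories: stable
# (RI < 1), dynamic (10 <= RI < 50), hyperdynamic (RI >= 50), otherwise
# unclassified. CpGs with a between-individual RI above 30 are flagged as
# common DNA methylation variation (CDMV).

#' Within-individual reference interval of one series of values
#'
#' Difference between the 95th and 5th percentiles of the methylation
#' percentages, with percentiles computed by linear interpolation between
#' order statistics (rank `1 + (n - 1) q` on the sorted values).
#'
#' @param values Numeric vector of at least 2 non-missing methylation
#'   percentages.
#' @return The RI in percentage points, in `[0, max - min]`.
#' @examples
#' within_individual_ri(1:24)  # 20.70
#' @export
within_individual_ri <- function(values) {
  if (length(values) < 2)
    stop("within_individual_ri: need at least 2 values")
  if (anyNA(values))
    stop("within_individual_ri: missing values are not allowed ",
         "(run the missingness filter first)")
  q <- quantile(values, c(0.05, 0.95), names = FALSE, type = 7)
  q[2] - q[1]
}

# Row-wise RI for a CpG x timepoint matrix (no NA).
ri_rows <- function(values) {
  n <- ncol(values)
  if (n < 2) stop("ri_rows: need at least 2 timepoints")
  if (anyNA(values)) stop("ri_rows: missing values are not allowed")
  srt <- t(apply(values, 1, sort.int, method = "quick"))
  interp <- function(q) {
    h <- 1 + (n - 1) * q
    lo <- floor(h)
    srt[, lo] + (h - lo) * (srt[, lo + 1L] - srt[, lo])
  }
  if (1 + (n - 1) * 0.95 >= n) {
    hi <- srt[, n]
  } else hi <- interp(0.95)
  lo <- interp(0.05)
  unname(hi - lo)
}

#' Assign a stability category from a within-individual RI
#'
#' @param within_ri Numeric vector of within-individual RIs in `[0, 100]`.
#' @param thresholds Named list: `stable_max` (default 1), `dynamic_min`
#'   (10) and `dynamic_max` (50). Stable iff `ri < stable_max`; dynamic iff
#'   `dynamic_min <= ri < dynamic_max`; hyperdynamic iff `ri >= dynamic_max`
#'   (the 50% boundary belongs to hyperdynamic); otherwise unclassified.
#' @return Factor with levels stable, unclassified, dynamic, hyperdynamic.
#' @export
assign_category <- function(within_ri,
                            thresholds = list(stable_max = 1,
                                              dynamic_min = 10,
                                              dynamic_max = 50)) {
  if (any(within_ri < 0 | within_ri > 100, na.rm = TRUE) || anyNA(within_ri))
    stop("assign_category: RI values must lie in [0, 100]")
  out <- rep("unclassified", length(within_ri))
  out[within_ri < thresholds$stable_max] <- "stable"
  out[within_ri >= thresholds$dynamic_min &
      within_ri < thresholds$dynamic_max] <- "dynamic"
  out[within_ri >= thresholds$dynamic_max] <- "hyperdynamic"
  factor(out, levels = STABILITY_LEVELS)
}

#' Flag common DNA methylation variation (CDMV) CpGs
#'
#' @param between_ri Numeric vector of between-individual RIs (percentage
#'   points, non-negative).
#' @param threshold CDMV threshold (default 30); the flag is strict
#'   (`between_ri > threshold`), so exactly 30 is not CDMV.
#' @return Logical vector.
#' @export
flag_cdmv <- function(between_ri, threshold = 30) {
  if (any(between_ri < 0, na.rm = TRUE))
    stop("flag_cdmv: between-individual RI must be non-negative")
  !is.na(between_ri) & between_ri > threshold
}

#' Per-CpG, per-series RI table
#'
#' Computes the within-individual RI and arithmetic mean methylation level
#' of every CpG in every series, optionally restricted to a retained set,
#' and attaches the between-individual RI reference where available.
#'
#' @param series_list Named list of series objects.
#' @param retained Optional character vector of CpG ids to keep.
#' @param between_ri Optional data.frame `cpg_id`, `between_ri`.
#' @return data.frame `cpg_id`, `individual`, `tissue`, `series`,
#'   `within_ri`, `mean_level`, `between_ri` (NA when no reference).
#' @export
ri_table <- function(series_list, retained = NULL, between_ri = NULL) {
  rows <- lapply(names(series_list), function(nm) {
    s <- series_list[[nm]]
    v <- s$values
    if (!is.null(retained)) v <- v[rownames(v) %in% retained, , drop = FALSE]
    data.frame(cpg_id = rownames(v),
               individual = s$series_key$individual,
               tissue = s$series_key$tissue,
               series = nm,
               within_ri = ri_rows(v),
               mean_level = unname(rowMeans(v)),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (!is.null(between_ri)) {
    tab$between_ri <- between_ri$between_ri[match(tab$cpg_id,
                                                  between_ri$cpg_id)]
  } else tab$between_ri <- NA_real_
  tab
}

#' Categorize an RI table
#'
#' Adds the stability category (from the within-individual RI alone) and
#' the cohort-level CDMV flag (from the between-individual RI alone).
#'
#' @param ri_tab Output of [ri_table()].
#' @param thresholds Category thresholds, see [assign_category()].
#' @param cdmv_threshold CDMV threshold, see [flag_cdmv()].
#' @return `ri_tab` with `category` and `cdmv` columns.
#' @export
categorize_cpgs <- function(ri_tab,
                            thresholds = list(stable_max = 1,
                                              dynamic_min = 10,
                                              dynamic_max = 50),
                            cdmv_threshold = 30) {
  ri_tab$category <- assign_category(ri_tab$within_ri, thresholds)
  ri_tab$cdmv <- flag_cdmv(ifelse(is.na(ri_tab$between_ri), 0,
                                  ri_tab$between_ri), cdmv_threshold)
  ri_tab
}

five_number <- function(x) {
  q <- quantile(x, c(0, 0.25, 0.5, 0.75, 1), names = FALSE, type = 7)
  data.frame(n = length(x), min = q[1], q1 = q[2], median = q[3],
             q3 = q[4], max = q[5])
}

#' Summaries of the RI landscape
#'
#' Produces (a) a per-series histogram of within-individual RIs, (b)
#' five-number summaries of the within-RI binned by mean methylation level,
#' and (c) five-number summaries of the within-RI binned by
#' between-individual RI (series with a reference only).
#'
#' @param records Categorized or plain [ri_table()] output.
#' @param ri_bin_width Histogram bin width for the RI distribution
#'   (default 5 percentage points).
#' @param level_bin_width Bin width for mean level and between-RI summaries
#'   (default 10).
#' @return List of data.frames `histogram`, `by_mean_level`, `by_between_ri`.
#' @export
summarize_ri <- function(records, ri_bin_width = 5, level_bin_width = 10) {
  if (nrow(records) == 0)
    stop("summarize_ri: empty record set")
  bin_of <- function(x, w) pmin(floor(x / w), floor(100 / w) - 1) * w
  records$ri_bin <- bin_of(records$within_ri, ri_bin_width)
  hist <- aggregate(list(count = records$cpg_id),
                    by = list(series = records$series,
                              ri_bin = records$ri_bin), FUN = length)
  hist <- hist[order(hist$series, hist$ri_bin), ]
  records$mean_bin <- bin_of(records$mean_level, level_bin_width)
  by_mean <- do.call(rbind, by(records, list(records$series, records$mean_bin),
    function(d) if (nrow(d) == 0) NULL else
      cbind(series = d$series[1], mean_bin = d$mean_bin[1],
            five_number(d$within_ri))))
  has_b <- records[!is.na(records$between_ri), ]
  by_between <- NULL
  if (nrow(has_b) > 0) {
    has_b$between_bin <- bin_of(has_b$between_ri, level_bin_width)
    by_between <- do.call(rbind, by(has_b, list(has_b$series, has_b$between_bin),
      function(d) if (nrow(d) == 0) NULL else
        cbind(series = d$series[1], between_bin = d$between_bin[1],
              five_number(d$within_ri))))
  }
  rownames(hist) <- NULL
  list(histogram = hist, by_mean_level = by_mean, by_between_ri = by_between)
}

#' Overlap fractions between two CpG sets
#'
#' @param a,b Character vectors of CpG ids.
#' @return List with `frac_a` = |A n B| / |A|, `frac_b` = |A n B| / |B| and
#'   `jaccard`; fractions are `NA` (undefined) for an empty set, not 0.
#' @export
overlap_fractions <- function(a, b) {
  a <- unique(a); b <- unique(b)
  i <- length(intersect(a, b))
  u <- length(union(a, b))
  list(frac_a = if (length(a) == 0) NA_real_ else i / length(a),
       frac_b = if (length(b) == 0) NA_real_ else i / length(b),
       jaccard = if (u == 0) NA_real_ else i / u)
}

#' Category overlaps with the CDMV set and across series
#'
#' For every series and stability category, reports the fraction of the
#' category overlapping the cohort-level CDMV set and vice versa, plus a
#' cross-series Jaccard index for each category (how consistently the same
#' CpGs are assigned to the category across series).
#'
#' @param assignments Categorized table from [categorize_cpgs()].
#' @param cdmv_cpgs Character vector of CDMV CpG ids.
#' @return List of data.frames `vs_cdmv` (series, category, sizes,
#'   `frac_category_in_cdmv`, `frac_cdmv_in_category`) and
#'   `cross_series_jaccard` (category, series pair, jaccard).
#' @export
category_overlap <- function(assignments, cdmv_cpgs) {
  cdmv_cpgs <- unique(cdmv_cpgs)
  cats <- c("stable", "dynamic", "hyperdynamic")
  sers <- unique(assignments$series)
  rows <- list()
  for (s in sers) for (ct in cats) {
    set <- assignments$cpg_id[assignments$series == s &
                              assignments$category == ct]
    ov <- overlap_fractions(set, cdmv_cpgs)
    rows[[length(rows) + 1]] <- data.frame(series = s, category = ct,
      n_category = length(set), n_cdmv = length(cdmv_cpgs),
      frac_category_in_cdmv = ov$frac_a, frac_cdmv_in_category = ov$frac_b)
  }
  jac <- list()
  if (length(sers) > 1) {
    prs <- utils::combn(sers, 2)
    for (ct in cats) for (j in seq_len(ncol(prs))) {
      s1 <- assignments$cpg_id[assignments$series == prs[1, j] &
                               assignments$category == ct]
      s2 <- assignments$cpg_id[assignments$series == prs[2, j] &
                               assignments$category == ct]
      jac[[length(jac) + 1]] <- data.frame(category = ct,
        series_1 = prs[1, j], series_2 = prs[2, j],
        jaccard = overlap_fractions(s1, s2)$jaccard)
    }
  }
  list(vs_cdmv = do.call(rbind, rows),
       cross_series_jaccard = if (length(jac)) do.call(rbind, jac) else NULL)
}

#' PCA overview of all datasets
#'
#' Treats each (series, timepoint) dataset as an observation over CpGs,
#' centers each CpG (no scaling) and computes principal components,
#' reporting per-sample scores and a nearest-centroid grouping accuracy by
#' (individual, tissue) — a check that global methylation profiles
#' segregate by sample rather than by time.
#'
#' @param series_list Named list of series objects (harmonized CpG rows).
#' @param retained Optional CpG ids to restrict to.
#' @param n_components Number of components for scores and the grouping
#'   diagnostic (default 3, capped at what the data support).
#' @return List with `scores` (data.frame: sample, series, timepoint,
#'   PC columns), `sdev`, and `grouping_accuracy`.
#' @export
pca_overview <- function(series_list, retained = NULL, n_components = 3) {
  ids <- harmonized_cpgs(series_list)
  if (!is.null(retained)) ids <- ids[ids %in% retained]
  mats <- lapply(series_list, function(s) s$values[ids, , drop = FALSE])
  X <- do.call(cbind, mats)  # CpG x sample
  grp <- rep(names(series_list), vapply(mats, ncol, 0L))
  tp <- unlist(lapply(mats, colnames), use.names = FALSE)
  if (ncol(X) < 3)
    stop("pca_overview: need at least 3 samples")
  if (anyNA(X))
    stop("pca_overview: missing values present; filter first")
  pc <- prcomp(t(X), center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  sc <- pc$x[, seq_len(k), drop = FALSE]
  cent <- rowsum(sc, grp) / as.vector(table(grp)[sort(unique(grp))])
  cent <- cent[order(rownames(cent)), , drop = FALSE]
  d2 <- outer(rowSums(sc^2), rowSums(cent^2), "+") - 2 * sc %*% t(cent)
  assigned <- rownames(cent)[max.col(-d2, ties.method = "first")]
  scores <- data.frame(sample = paste(grp, tp, sep = "."), series = grp,
                       timepoint = tp, stringsAsFactors = FALSE)
  scores <- cbind(scores, as.data.frame(sc))
  rownames(scores) <- NULL
  list(scores = scores, sdev = pc$sdev,
       grouping_accuracy = mean(assigned == grp))
}
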