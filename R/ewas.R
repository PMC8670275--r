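# EWAS-marker enrichment per CpG category. The marker likelihood of a
# category is the count of marker CpGs divided by the count of non-marker
# CpGs in the category; it is compared against the likelihood over the full
# probe background (which includes the category) via a 2x2 Fisher exact
# test with a cross-product odds ratio. Trait-level analyses compute one
# odds ratio per study and pool the log odds ratios with the
# DerSimonian-Laird random-effects estimator; between-study heterogeneity
# is assessed by Cochran's Q at the 0.05 level.

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by summing the hypergeometric probabilities (margins
#' fixed) of every table at most as probable as the observed one, with a
#' 1e-7 relative tolerance on the comparison. The odds ratio is the
#' cross-product `(a d) / (b c)`; when any cell is zero the
#' Haldane-Anscombe correction (+0.5 on all four cells) is applied to the
#' odds ratio only (`corrected = TRUE`) — the p-value always uses the raw
#' counts.
#'
#' @param a,b,c,d Non-negative counts; rows are (a, b) and (c, d).
#' @return List with `odds_ratio`, `p_value`, `corrected`. An empty row or
#'   column margin gives `p_value = 1` and an undefined (`NA`) odds ratio.
#' @examples
#' fisher_exact_2x2(3, 1, 1, 3)$p_value  # 34/70
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(is.na(cells)) || any(cells < 0))
    stop("fisher_exact_2x2: counts must be non-negative")
  if (any(cells != round(cells)))
    stop("fisher_exact_2x2: counts must be integers")
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0)
    return(list(odds_ratio = NA_real_, p_value = 1, corrected = FALSE))
  corrected <- any(cells == 0)
  oc <- if (corrected) cells + 0.5 else cells
  or <- (oc[1] * oc[4]) / (oc[2] * oc[3])
  support <- max(0, c1 - r2):min(c1, r1)
  dens <- dhyper(support, r1, r2, c1)
  d_obs <- dhyper(a, r1, r2, c1)
  p <- min(1, sum(dens[dens <= d_obs * (1 + 1e-7)]))
  list(odds_ratio = or, p_value = p, corrected = corrected)
}

#' EWAS marker likelihood and enrichment of one CpG category
#'
#' Builds the 2x2 table `a` = |category n markers|, `b` = |category \
#' markers|, `c` = |background n markers|, `d` = |background \ markers|,
#' where the background is the full retained probe set including the
#' category. Reports the marker likelihood `a / b`, the Fisher exact test
#' of the table, and a 95% Woolf (normal on the log odds ratio) confidence
#' interval on the (possibly Haldane-Anscombe-corrected) counts.
#'
#' @param category_cpgs CpG ids of the category (must be a subset of the
#'   background).
#' @param marker_cpgs CpG ids recorded as EWAS markers.
#' @param background_cpgs The full probe background.
#' @return List with counts `a`-`d`, `likelihood`, `odds_ratio`, `ci_low`,
#'   `ci_high`, `p_value`, `corrected`.
#' @export
marker_likelihood <- function(category_cpgs, marker_cpgs, background_cpgs) {
  category_cpgs <- unique(category_cpgs)
  background_cpgs <- unique(background_cpgs)
  marker_cpgs <- unique(marker_cpgs)
  if (length(setdiff(category_cpgs, background_cpgs)) > 0)
    stop("marker_likelihood: category is not a subset of the background")
  in_cat <- category_cpgs %in% marker_cpgs
  in_bg <- background_cpgs %in% marker_cpgs
  a <- sum(in_cat); b <- length(category_cpgs) - a
  c <- sum(in_bg); d <- length(background_cpgs) - c
  ft <- fisher_exact_2x2(a, b, c, d)
  cc <- if (ft$corrected) c(a, b, c, d) + 0.5 else c(a, b, c, d)
  if (is.na(ft$odds_ratio)) {
    ci <- c(NA_real_, NA_real_)
  } else {
    se <- sqrt(sum(1 / cc))
    ci <- exp(log(ft$odds_ratio) + c(-1, 1) * 1.96 * se)
  }
  list(a = a, b = b, c = c, d = d,
       likelihood = if (b == 0) NA_real_ else a / b,
       odds_ratio = ft$odds_ratio, ci_low = ci[1], ci_high = ci[2],
       p_value = ft$p_value, corrected = ft$corrected)
}

#' Per-trait summaries of an EWAS catalog
#'
#' @param catalog data.frame with `cpg_id`, `trait`, `study_id`; summaries
#'   are always recomputed from the records.
#' @return data.frame `trait`, `n_studies`, `n_marker_cpgs` (distinct CpGs).
#' @export
trait_summaries <- function(catalog) {
  sp <- split(catalog, catalog$trait)
  out <- data.frame(trait = names(sp),
    n_studies = vapply(sp, function(d) length(unique(d$study_id)), 0L),
    n_marker_cpgs = vapply(sp, function(d) length(unique(d$cpg_id)), 0L),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Select traits for trait-level analyses
#'
#' Keeps traits with at least `min_studies` published studies and at least
#' `min_markers` distinct marker CpGs (defaults 5 and 100).
#'
#' @param catalog EWAS catalog data.frame.
#' @param min_studies,min_markers Selection thresholds.
#' @return Character vector of trait names.
#' @export
select_traits <- function(catalog, min_studies = 5, min_markers = 100) {
  ts <- trait_summaries(catalog)
  ts$trait[ts$n_studies >= min_studies & ts$n_marker_cpgs >= min_markers]
}

#' Per-study log odds ratios for one trait and category
#'
#' For each study of the trait, builds the category-vs-background 2x2 table
#' from the study's distinct marker CpGs (restricted to the background) and
#' returns the log cross-product odds ratio and its Woolf variance
#' `sum(1/cell)`; the Haldane-Anscombe +0.5 correction is applied to all
#' four cells iff any cell is zero. Studies with no usable markers are
#' skipped with a message.
#'
#' @param category_cpgs CpG ids of the category.
#' @param catalog EWAS catalog data.frame.
#' @param trait Trait name.
#' @param background_cpgs Full probe background.
#' @return data.frame `study_id`, `log_or` (`yi`), `variance` (`vi`),
#'   `corrected`; zero rows if no study is usable.
#' @export
per_study_effects <- function(category_cpgs, catalog, trait, background_cpgs) {
  category_cpgs <- unique(category_cpgs)
  background_cpgs <- unique(background_cpgs)
  if (length(setdiff(category_cpgs, background_cpgs)) > 0)
    stop("per_study_effects: category is not a subset of the background")
  recs <- catalog[catalog$trait == trait, ]
  rows <- list()
  for (sid in sort(unique(recs$study_id))) {
    markers <- intersect(unique(recs$cpg_id[recs$study_id == sid]),
                         background_cpgs)
    if (length(markers) == 0) {
      message("per_study_effects: study '", sid, "' has no markers in the ",
              "background; skipped")
      next
    }
    a <- sum(category_cpgs %in% markers)
    b <- length(category_cpgs) - a
    cc <- length(markers)
    dd <- length(background_cpgs) - cc
    cells <- c(a, b, cc, dd)
    corrected <- any(cells == 0)
    if (corrected) cells <- cells + 0.5
    rows[[length(rows) + 1]] <- data.frame(study_id = sid,
      log_or = log((cells[1] * cells[4]) / (cells[2] * cells[3])),
      variance = sum(1 / cells), corrected = corrected,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0)
    return(data.frame(study_id = character(0), log_or = numeric(0),
                      variance = numeric(0), corrected = logical(0)))
  do.call(rbind, rows)
}

#' DerSimonian-Laird random-effects pooling
#'
#' Given per-study effects `y_i` with variances `v_i`: fixed weights
#' `w_i = 1/v_i`; `Q = sum w_i (y_i - ybar)^2` with `ybar` the fixed-effect
#' mean; the moment estimator
#' `tau2 = max(0, (Q - (k-1)) / (sum w - sum w^2 / sum w))`; random-effects
#' weights `1 / (v_i + tau2)` give the pooled estimate, its standard error
#' `(sum w*)^(-1/2)`, a 95% normal CI, and a two-sided normal p-value.
#' With a single study the estimate passes through (`tau2 = 0`, `Q`
#' undefined).
#'
#' @param effects data.frame with columns `log_or` and `variance` (e.g.
#'   from [per_study_effects()]), or a numeric vector of effects with
#'   `variances` supplied separately.
#' @param variances Optional numeric vector of variances when `effects` is
#'   a numeric vector.
#' @return List with `k`, `tau2`, `Q`, `df`, `p_q`, `heterogeneous`,
#'   `pooled_log_or`, `pooled_se`, `pooled_or`, `ci_low`, `ci_high`,
#'   `p_pooled`.
#' @examples
#' dersimonian_laird(c(0, 1), c(0.25, 0.25))  # Q = 2, tau2 = 0.25, pooled 0.5
#' @export
dersimonian_laird <- function(effects, variances = NULL) {
  if (is.data.frame(effects)) {
    y <- effects$log_or
    v <- effects$variance
  } else {
    y <- effects
    v <- variances
  }
  k <- length(y)
  if (k < 1) stop("dersimonian_laird: need at least one effect")
  if (any(v <= 0)) stop("dersimonian_laird: variances must be positive")
  if (k == 1) {
    pooled <- y[1]; se <- sqrt(v[1]); tau2 <- 0; Q <- NA_real_; p_q <- NA_real_
  } else {
    w <- 1 / v
    ybar <- sum(w * y) / sum(w)
    Q <- sum(w * (y - ybar)^2)
    tau2 <- max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
    ws <- 1 / (v + tau2)
    pooled <- sum(ws * y) / sum(ws)
    se <- 1 / sqrt(sum(ws))
    p_q <- pchisq(Q, df = k - 1, lower.tail = FALSE)
  }
  list(k = k, tau2 = tau2, Q = Q, df = if (k >= 2) k - 1L else NA_integer_,
       p_q = p_q, heterogeneous = if (k >= 2) p_q < 0.05 else NA,
       pooled_log_or = pooled, pooled_se = se, pooled_or = exp(pooled),
       ci_low = exp(pooled - 1.96 * se), ci_high = exp(pooled + 1.96 * se),
       p_pooled = 2 * pnorm(-abs(pooled / se)))
}

#' Cochran's Q heterogeneity test
#'
#' `Q = sum w_i (y_i - ybar)^2` with fixed-effect weights `w_i = 1/v_i`;
#' under homogeneity Q is chi-square with `k - 1` degrees of freedom.
#' Heterogeneity is declared at `p_q < 0.05`.
#'
#' @inheritParams dersimonian_laird
#' @return List with `Q`, `df`, `p_q`, `heterogeneous`; all `NA` for fewer
#'   than 2 effects (undefined).
#' @export
cochran_q <- function(effects, variances = NULL) {
  if (is.data.frame(effects)) {
    y <- effects$log_or
    v <- effects$variance
  } else {
    y <- effects
    v <- variances
  }
  k <- length(y)
  if (k < 2)
    return(list(Q = NA_real_, df = NA_integer_, p_q = NA_real_,
                heterogeneous = NA))
  w <- 1 / v
  ybar <- sum(w * y) / sum(w)
  Q <- sum(w * (y - ybar)^2)
  p_q <- pchisq(Q, df = k - 1, lower.tail = FALSE)
  list(Q = Q, df = k - 1L, p_q = p_q, heterogeneous = p_q < 0.05)
}

#' Single-table marker enrichment for a list of CpG sets
#'
#' Runs [marker_likelihood()] for every named set (stability categories,
#' the CDMV set, CpG-context classes, ...) against the distinct marker CpGs
#' of the whole catalog, with Benjamini-Hochberg adjusted p-values reported
#' alongside the raw ones.
#'
#' @param category_sets Named list of CpG-id vectors.
#' @param catalog EWAS catalog data.frame.
#' @param background_cpgs Full probe background.
#' @return data.frame, one row per set.
#' @export
marker_likelihood_table <- function(category_sets, catalog, background_cpgs) {
  markers <- unique(catalog$cpg_id)
  rows <- lapply(names(category_sets), function(nm) {
    ml <- marker_likelihood(category_sets[[nm]], markers, background_cpgs)
    data.frame(set = nm, a = ml$a, b = ml$b, c = ml$c, d = ml$d,
               likelihood = ml$likelihood, odds_ratio = ml$odds_ratio,
               ci_low = ml$ci_low, ci_high = ml$ci_high,
               p_value = ml$p_value, corrected = ml$corrected,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- p.adjust(out$p_value, method = "BH")
  out
}

#' Trait-level meta-analytic scan of category enrichment
#'
#' For each selected trait (at least `min_studies` studies and
#' `min_markers` distinct marker CpGs) and each supplied category set,
#' computes per-study odds ratios against the common probe background and
#' pools them with the DerSimonian-Laird estimator; Cochran's Q assesses
#' between-study heterogeneity. The hyperdynamic category is excluded from
#' trait-level analyses (too few CpGs for study-level tables) — a set named
#' `"hyperdynamic"` is dropped with a message. Raw and Benjamini-Hochberg
#' adjusted pooled p-values are reported side by side.
#'
#' @param category_sets Named list of CpG-id vectors (e.g. stable, dynamic,
#'   CDMV).
#' @param catalog EWAS catalog data.frame.
#' @param background_cpgs Full probe background.
#' @param min_studies,min_markers Trait selection thresholds (defaults 5
#'   and 100).
#' @return data.frame with one row per (trait, category): `k`, `pooled_or`,
#'   `ci_low`, `ci_high`, `p_value`, `p_adj`, `tau2`, `Q`, `df`, `p_q`,
#'   `heterogeneous`. Traits with fewer than 2 usable studies keep their
#'   row with `Q` undefined.
#' @export
trait_category_scan <- function(category_sets, catalog, background_cpgs,
                                min_studies = 5, min_markers = 100) {
  if ("hyperdynamic" %in% names(category_sets)) {
    message("trait_category_scan: hyperdynamic category excluded from ",
            "trait-level analyses")
    category_sets <- category_sets[names(category_sets) != "hyperdynamic"]
  }
  traits <- select_traits(catalog, min_studies, min_markers)
  rows <- list()
  for (tr in traits) for (nm in names(category_sets)) {
    eff <- per_study_effects(category_sets[[nm]], catalog, tr, background_cpgs)
    if (nrow(eff) == 0) next
    dl <- dersimonian_laird(eff)
    rows[[length(rows) + 1]] <- data.frame(trait = tr, category = nm,
      k = dl$k, pooled_or = dl$pooled_or, ci_low = dl$ci_low,
      ci_high = dl$ci_high, p_value = dl$p_pooled, tau2 = dl$tau2,
      Q = dl$Q, df = dl$df, p_q = dl$p_q, heterogeneous = dl$heterogeneous,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0)
    return(data.frame())
  out <- do.call(rbind, rows)
  out$p_adj <- p.adjust(out$p_value, method = "BH")
  out
}
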