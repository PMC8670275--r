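test_that("Fisher 2x2 matches its worked examples", {
  # proportional rows: cross-product OR is exactly 1
  expect_equal(fisher_exact_2x2(10, 90, 100, 900)$odds_ratio, 1)
  expect_equal(fisher_exact_2x2(20, 80, 100, 900)$odds_ratio, 2.25)
  # full hypergeometric enumeration: p = (1 + 16 + 16 + 1) / 70
  expect_equal(fisher_exact_2x2(3, 1, 1, 3)$p_value, 34 / 70,
               tolerance = 1e-12)
  expect_error(fisher_exact_2x2(-1, 2, 3, 4), "non-negative")
  expect_error(fisher_exact_2x2(1.5, 2, 3, 4), "integers")
  empty <- fisher_exact_2x2(0, 0, 5, 5)
  expect_true(is.na(empty$odds_ratio) && empty$p_value == 1)
  z <- fisher_exact_2x2(0, 100, 50, 950)
  expect_true(z$corrected)
  expect_equal(z$odds_ratio, (0.5 * 950.5) / (100.5 * 50.5))
})

test_that("Fisher p agrees with stats::fisher.test and is row-swap symmetric", {
  set.seed(99)
  for (i in 1:60) {
    t4 <- as.integer(rpois(4, sample(c(3, 10, 40), 1)))
    a <- t4[1]; b <- t4[2]; c <- t4[3]; d <- t4[4]
    if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0) next
    mine <- fisher_exact_2x2(a, b, c, d)
    ref <- stats::fisher.test(matrix(c(a, c, b, d), 2))
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-6)
    swapped <- fisher_exact_2x2(c, d, a, b)
    expect_equal(swapped$p_value, mine$p_value, tolerance = 1e-12)
    if (!mine$corrected)
      expect_equal(swapped$odds_ratio, 1 / mine$odds_ratio, tolerance = 1e-12)
  }
})

test_that("marker likelihood builds the stated 2x2 against the full background", {
  bg <- paste0("cg", 1:1000)
  cat_cpgs <- paste0("cg", 1:100)
  markers <- paste0("cg", c(1:10, 500:589))   # 10 in category, 100 in bg
  ml <- marker_likelihood(cat_cpgs, markers, bg)
  expect_identical(c(ml$a, ml$b, ml$c, ml$d), c(10L, 90L, 100L, 900L))
  expect_equal(ml$likelihood, 10 / 90)
  expect_equal(ml$odds_ratio, 1)
  # category = background: OR exactly 1
  ml2 <- marker_likelihood(bg, markers, bg)
  expect_equal(ml2$odds_ratio, 1)
  # empty marker set: undefined OR, p = 1
  ml3 <- marker_likelihood(cat_cpgs, character(0), bg)
  expect_true(is.na(ml3$odds_ratio) && ml3$p_value == 1)
  expect_error(marker_likelihood(c(cat_cpgs, "zz"), markers, bg), "subset")
})

test_that("trait selection applies both thresholds", {
  mk <- function(trait, n_st, n_cpg)
    expand.grid(cpg_id = paste0(trait, "_cg", seq_len(n_cpg)),
                trait = trait,
                study_id = paste0(trait, "_s", seq_len(n_st)),
                stringsAsFactors = FALSE)
  catalog <- rbind(mk("ok", 5, 150), mk("few_studies", 4, 500),
                   mk("few_markers", 10, 99))
  ts <- trait_summaries(catalog)
  expect_identical(ts$n_studies[ts$trait == "few_studies"], 4L)
  expect_identical(ts$n_marker_cpgs[ts$trait == "few_markers"], 99L)
  expect_identical(select_traits(catalog), "ok")
})

test_that("per-study effects reproduce the worked arithmetic", {
  bg <- paste0("cg", 1:1000)
  cat_cpgs <- paste0("cg", 1:100)
  catalog <- rbind(
    data.frame(cpg_id = paste0("cg", c(1:20, 101:180)), trait = "t",
               study_id = "s1"),                       # (20, 80, 100, 900)
    data.frame(cpg_id = paste0("cg", c(1:10, 101:190)), trait = "t",
               study_id = "s2"),                       # proportional
    data.frame(cpg_id = paste0("cg", 101:150), trait = "t",
               study_id = "s3"))                       # zero cell in category
  eff <- per_study_effects(cat_cpgs, catalog, "t", bg)
  e1 <- eff[eff$study_id == "s1", ]
  expect_equal(e1$log_or, log(2.25), tolerance = 1e-12)
  expect_equal(e1$variance, 1 / 20 + 1 / 80 + 1 / 100 + 1 / 900,
               tolerance = 1e-12)
  expect_false(e1$corrected)
  expect_equal(eff$log_or[eff$study_id == "s2"], 0, tolerance = 1e-12)
  e3 <- eff[eff$study_id == "s3", ]
  expect_true(e3$corrected)
  expect_equal(e3$log_or, log((0.5 * 950.5) / (100.5 * 50.5)),
               tolerance = 1e-12)
  expect_equal(e3$variance, 1 / 0.5 + 1 / 100.5 + 1 / 50.5 + 1 / 950.5,
               tolerance = 1e-12)
})

test_that("DerSimonian-Laird matches its worked examples and limits", {
  r <- dersimonian_laird(c(0, 1), c(0.25, 0.25))
  expect_equal(r$Q, 2)
  expect_equal(r$tau2, 0.25)
  expect_equal(r$pooled_log_or, 0.5)
  # truncation: Q below its degrees of freedom gives tau2 = 0
  r2 <- dersimonian_laird(c(0, 0.1), c(1, 1))
  expect_equal(r2$Q, 0.005)
  expect_equal(r2$tau2, 0)
  expect_equal(r2$pooled_log_or, 0.05)
  # identical studies: tau2 = 0, pooled = common value, Q = 0
  r3 <- dersimonian_laird(c(0.7, 0.7), c(0.1, 0.1))
  expect_equal(r3$tau2, 0)
  expect_equal(r3$pooled_log_or, 0.7)
  expect_equal(r3$Q, 0)
  # k = 1 passthrough
  r4 <- dersimonian_laird(0.3, 0.04)
  expect_equal(r4$pooled_log_or, 0.3)
  expect_equal(r4$pooled_se, 0.2)
  expect_equal(r4$tau2, 0)
  expect_true(is.na(r4$Q))
  expect_error(dersimonian_laird(c(0, 1), c(0.1, 0)), "positive")
})

test_that("DL pooling stays within the effects and matches metafor", {
  set.seed(11)
  for (i in 1:20) {
    k <- sample(2:8, 1)
    y <- rnorm(k, 0.5, 0.6)
    v <- runif(k, 0.02, 0.4)
    r <- dersimonian_laird(y, v)
    expect_gte(r$pooled_log_or, min(y) - 1e-12)
    expect_lte(r$pooled_log_or, max(y) + 1e-12)
    if (r$tau2 == 0) {
      w <- 1 / v
      expect_equal(r$pooled_log_or, sum(w * y) / sum(w), tolerance = 1e-12)
    }
    ref <- metafor::rma(yi = y, vi = v, method = "DL")
    expect_equal(r$tau2, ref$tau2, tolerance = 1e-8, ignore_attr = TRUE)
    expect_equal(r$pooled_log_or, as.numeric(ref$beta), tolerance = 1e-8)
    expect_equal(r$pooled_se, ref$se, tolerance = 1e-8, ignore_attr = TRUE)
    expect_equal(r$Q, ref$QE, tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("Cochran's Q follows the chi-square reference", {
  q0 <- cochran_q(c(0.4, 0.4, 0.4), c(0.1, 0.2, 0.1))
  expect_equal(q0$Q, 0)
  expect_equal(q0$p_q, 1)
  expect_false(q0$heterogeneous)
  q2 <- cochran_q(c(0, 1), c(0.25, 0.25))
  expect_equal(q2$Q, 2)
  expect_identical(q2$df, 1L)
  expect_equal(q2$p_q, 0.1572992, tolerance = 1e-6)
  expect_true(is.na(cochran_q(0.5, 0.1)$Q))
  het <- cochran_q(c(-1, 1, -1, 1), c(0.05, 0.05, 0.05, 0.05))
  expect_true(het$heterogeneous)
})

test_that("trait-level scan excludes hyperdynamic and detects planted enrichment", {
  cfg <- generator_config(master_seed = 1234, n_cpgs = 12000, n_traits = 2,
                          marker_base_rate = 0.02,
                          planted_or_by_category = c(stable = 1,
                                                     intermediate = 1,
                                                     dynamic = 3,
                                                     hyperdynamic = 1))
  tr <- generate_truth(cfg)
  catalog <- generate_ewas_catalog(cfg, tr)
  sets <- list(stable = tr$cpg_id[tr$category == "stable"],
               dynamic = tr$cpg_id[tr$category == "dynamic"],
               hyperdynamic = tr$cpg_id[tr$category == "hyperdynamic"],
               CDMV = tr$cpg_id[tr$cdmv])
  expect_message(res <- trait_category_scan(sets, catalog, tr$cpg_id),
                 "hyperdynamic")
  expect_false("hyperdynamic" %in% res$category)
  expect_setequal(unique(res$category), c("stable", "dynamic", "CDMV"))
  dyn <- res[res$category == "dynamic", ]
  expect_true(all(dyn$ci_low > 1))       # planted OR = 3 detected
  expect_true(all(dyn$k == 5))
  expect_true(all(res$tau2 >= 0))
})
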