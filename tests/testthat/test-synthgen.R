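test_that("identical configurations give identical cohorts and files", {
  cfg <- generator_config(master_seed = 42, n_cpgs = 150)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$betas[["A_PBMC"]]$values, c2$betas[["A_PBMC"]]$values)
  expect_identical(c1$props[["B_monocyte"]]$proportions,
                   c2$props[["B_monocyte"]]$proportions)
  expect_identical(c1$catalog, c2$catalog)
  expect_identical(c1$probes, c2$probes)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_cohort(c1, d1)
  write_cohort(c2, d2)
  f1 <- sort(list.files(d1))
  expect_identical(f1, sort(list.files(d2)))
  for (f in f1)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = paste("md5 of", f))
})

test_that("generated values respect their bounds", {
  coh <- small_cohort()
  for (s in coh$betas) {
    v <- s$values[!is.na(s$values)]
    expect_true(all(v >= 0 & v <= 100))
  }
  for (p in coh$props) {
    expect_true(all(p$proportions >= 0 & p$proportions <= 1))
    expect_true(all(rowSums(p$proportions) >= 0.9 &
                    rowSums(p$proportions) <= 1.1))
  }
  expect_true(all(coh$between_ri$between_ri >= 0 &
                  coh$between_ri$between_ri <= 100))
})

test_that("truth ledger is consistent with the configuration", {
  coh <- small_cohort()
  tr <- coh$truth
  cfg <- coh$config
  expect_identical(tr$cpg_id, sprintf("cg%06d", seq_len(cfg$n_cpgs)))
  expect_false(anyDuplicated(tr$cpg_id) > 0)
  # planted counts match the mix within multinomial sampling error (4 sd)
  for (ct in names(cfg$category_mix)) {
    n <- cfg$n_cpgs
    p <- cfg$category_mix[[ct]]
    expect_lt(abs(sum(tr$category == ct) - n * p), 4 * sqrt(n * p * (1 - p)) + 1)
  }
  expect_true(all(is.na(tr$snp_maf) | tr$snp_maf >= 0.01))
  expect_true(all(tr$cell_levels[tr$cell_driven, ] >= 0 &
                  tr$cell_levels[tr$cell_driven, ] <= 100))
  expect_identical(tr$cdmv, tr$between_ri > 30)
  # every probe has exactly one CpG-context class
  expect_true(all(tr$context %in% c("island", "shore", "shelf", "open_sea")))
  # every probe has at least one genic annotation
  expect_true(setequal(unique(tr$genic$cpg_id), tr$cpg_id))
})

test_that("zero perturbation scale gives constant baseline compositions", {
  cfg <- generator_config(master_seed = 5, n_cpgs = 50, prop_perturb_scale = 0)
  p <- generate_cell_proportions(cfg, list(individual = "A", tissue = "monocyte"))
  expect_true(all(apply(p$proportions, 2, function(x) length(unique(x))) == 1))
  expect_equal(unname(p$proportions[1, "Mono"]), 0.9)
  expect_error(generate_cell_proportions(cfg, list(individual = "A",
                                                   tissue = "liver")),
               "unknown series")
})

test_that("zero noise makes stable CpGs exactly constant with RI 0", {
  cfg <- generator_config(master_seed = 8, n_cpgs = 40,
                          category_mix = c(stable = 1, intermediate = 0,
                                           dynamic = 0, hyperdynamic = 0),
                          noise_sd_by_category = list(stable = 0,
                                                      intermediate = c(0, 0),
                                                      dynamic = 0,
                                                      hyperdynamic = 0),
                          tissue_noise_sd = 0, frac_cell_driven = 0,
                          frac_missing = 0)
  coh <- generate_cohort(cfg)
  v <- coh$betas[["A_PBMC"]]$values
  expect_true(all(apply(v, 1, function(x) length(unique(x))) == 1))
  expect_true(all(ri_table(coh$betas["A_PBMC"])$within_ri == 0))
})

test_that("planted regimes land in their RI bands", {
  cfg <- generator_config(master_seed = 99, n_cpgs = 1200,
                          category_mix = c(stable = 0.5, intermediate = 0,
                                           dynamic = 0, hyperdynamic = 0.5),
                          frac_cell_driven = 0, frac_missing = 0)
  coh <- generate_cohort(cfg)
  ri <- ri_table(coh$betas)
  planted <- coh$truth$category[match(ri$cpg_id, coh$truth$cpg_id)]
  expect_gte(mean(ri$within_ri[planted == "stable"] < 1), 0.95)
  expect_gte(mean(ri$within_ri[planted == "hyperdynamic"] >= 50), 0.90)
})

test_that("dynamic and hyperdynamic trajectories are synchronized across tissues", {
  coh <- small_cohort()
  dyn <- coh$truth$cpg_id[coh$truth$category %in% c("dynamic", "hyperdynamic") &
                          !coh$truth$cell_driven]
  a_p <- coh$betas[["A_PBMC"]]$values[dyn, , drop = FALSE]
  a_m <- coh$betas[["A_monocyte"]]$values[dyn, , drop = FALSE]
  cors <- vapply(seq_len(nrow(a_p)), function(i) {
    x <- a_p[i, ]; y <- a_m[i, ]
    if (anyNA(x) || anyNA(y) || sd(x) == 0 || sd(y) == 0) return(NA_real_)
    cor(x, y)
  }, 0)
  expect_gt(median(cors, na.rm = TRUE), 0.9)
})

test_that("catalog records are unique and respond to the planted odds ratios", {
  coh <- small_cohort()
  expect_identical(anyDuplicated(coh$catalog), 0L)
  cfg <- generator_config(master_seed = 77, n_cpgs = 6000, n_traits = 2,
                          marker_base_rate = 0.05,
                          planted_or_by_category = c(stable = 1,
                                                     intermediate = 1,
                                                     dynamic = 4,
                                                     hyperdynamic = 1))
  tr <- generate_truth(cfg)
  cat2 <- generate_ewas_catalog(cfg, tr)
  markers <- unique(cat2$cpg_id[cat2$trait == "trait01"])
  dyn <- tr$cpg_id[tr$category == "dynamic"]
  other <- setdiff(tr$cpg_id, dyn)
  odds <- function(set) {
    k <- sum(set %in% markers)
    k / (length(set) - k)
  }
  # pooled over 5 studies the empirical per-study OR target is 4; the
  # trait-level distinct-marker OR is attenuated but must be well above 1
  expect_gt(odds(dyn) / odds(other), 2)
})

test_that("invalid generator configurations are rejected", {
  expect_error(generator_config(category_mix = c(stable = 0.5,
                                                 intermediate = 0.6,
                                                 dynamic = 0,
                                                 hyperdynamic = 0)),
               "sum to 1")
  expect_error(generator_config(category_mix = c(stable = 1, dynamic = 0)),
               "regimes")
  expect_error(generator_config(planted_or_by_category = c(stable = 0,
                                                           intermediate = 1,
                                                           dynamic = 1,
                                                           hyperdynamic = 1)),
               "positive")
  expect_error(generator_config(n_cpgs = 0), "positive")
  expect_error(generator_config(marker_base_rate = 1.5), "proportions")
})
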