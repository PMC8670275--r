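# Constructed track: one chromosome, an island over [100, 200), the rest
# open sea, gene A promoter [100, 200) and gene B exon [150, 300).
toy_track <- function() {
  data.frame(chrom = "chr1",
             start = c(100, 0, 200, 100, 150),
             end = c(200, 100, 1000, 200, 300),
             feature_class = c("island", "open_sea", "open_sea",
                               "promoter", "exon"),
             gene_id = c(NA, NA, NA, "geneA", "geneB"),
             strand = c("*", "*", "*", "+", "+"),
             stringsAsFactors = FALSE)
}

toy_probes <- function() {
  data.frame(cpg_id = c("cg_both", "cg_island", "cg_sea"),
             chrom = "chr1",
             pos = c(171, 121, 501),  # 1-based; 0-based points 170, 120, 500
             design = c("I", "II", "II"),
             gc_fraction = c(0.7, 0.6, 0.4),
             snp_maf = NA_real_,
             stringsAsFactors = FALSE)
}

test_that("probes receive one context and all overlapping genic classes", {
  ann <- annotate_cpgs(toy_probes(), toy_track())
  expect_identical(ann$context$context, c("island", "island", "open_sea"))
  both <- ann$genic[ann$genic$cpg_id == "cg_both", ]
  # promoter of gene A and exon of gene B: both recorded
  expect_setequal(paste(both$feature_class, both$gene_id),
                  c("promoter geneA", "exon geneB"))
  # no genic overlap: intergenic
  expect_identical(ann$genic$feature_class[ann$genic$cpg_id == "cg_sea"],
                   "intergenic")
  # annotation does not depend on interval order
  tr <- toy_track()
  ann2 <- annotate_cpgs(toy_probes(), tr[rev(seq_len(nrow(tr))), ])
  expect_identical(ann$context, ann2$context)
  expect_identical(ann$genic, ann2$genic)
})

test_that("overlapping context classes and off-track chromosomes are handled", {
  tr <- toy_track()
  bad <- rbind(tr, data.frame(chrom = "chr1", start = 110, end = 130,
                              feature_class = "shore", gene_id = NA,
                              strand = "*"))
  expect_error(annotate_cpgs(toy_probes(), bad), "overlapping CpG-context")
  off <- toy_probes()
  off$chrom[3] <- "chrZ"
  expect_warning(ann <- annotate_cpgs(off, tr), "absent from the track")
  expect_identical(ann$context$context[3], "open_sea")
  expect_identical(ann$genic$feature_class[ann$genic$cpg_id == "cg_sea"],
                   "intergenic")
})

test_that("fractional counting splits multi-annotated CpGs and conserves totals", {
  ann <- annotate_cpgs(toy_probes(), toy_track())
  comp <- fractional_composition(list(all = toy_probes()$cpg_id), ann)
  gen <- comp[comp$kind == "genic", ]
  # cg_both has 2 genic annotations (promoter of A, exon of B): 1/2 each;
  # cg_island adds a whole promoter count, cg_sea a whole intergenic count
  expect_equal(gen$fractional_count[gen$feature_class == "promoter"], 1.5)
  expect_equal(gen$fractional_count[gen$feature_class == "exon"], 0.5)
  expect_equal(gen$fractional_count[gen$feature_class == "intergenic"], 1)
  expect_equal(sum(gen$fractional_count), 3)  # = number of CpGs
  expect_equal(sum(gen$fraction_of_category), 1, tolerance = 1e-9)
  ctx <- comp[comp$kind == "context", ]
  expect_equal(sum(ctx$fractional_count), 3)
  # conservation on a generated cohort
  coh <- small_cohort()
  ann2 <- annotate_cpgs(coh$probes, coh$annotation)
  comp2 <- fractional_composition(list(all = coh$probes$cpg_id), ann2)
  g2 <- comp2[comp2$kind == "genic", ]
  expect_equal(sum(g2$fractional_count), nrow(coh$probes), tolerance = 1e-9)
  expect_equal(sum(g2$fraction_of_category), 1, tolerance = 1e-9)
})

test_that("module annotation agrees with the generator's independent ledger", {
  coh <- small_cohort()
  ann <- annotate_cpgs(coh$probes, coh$annotation)
  expect_identical(ann$context$context, coh$truth$context)
  key <- function(g) sort(paste(g$cpg_id, g$feature_class,
                                ifelse(is.na(g$gene_id), ".", g$gene_id)))
  expect_identical(key(ann$genic), key(coh$truth$genic))
})

test_that("BED round trip is bit-exact on coordinates and names", {
  coh <- small_cohort()
  path <- withr::local_tempfile(fileext = ".bed")
  write_annotation_bed(coh$annotation, path)
  back <- read_annotation_bed(path)
  expect_identical(back$start, as.integer(coh$annotation$start))
  expect_identical(back$end, as.integer(coh$annotation$end))
  expect_identical(back$feature_class, coh$annotation$feature_class)
  expect_identical(back$gene_id, coh$annotation$gene_id)
})

test_that("design ratio uses the all-probe background", {
  probes <- data.frame(cpg_id = paste0("cg", 1:1000),
                       design = rep(c("I", "II"), 500),
                       gc_fraction = 0.5, stringsAsFactors = FALSE)
  # proportional category: OR = 1
  prop_cat <- list(half = paste0("cg", 1:100))
  dr <- probe_design_ratio(prop_cat, probes)
  expect_equal(dr$odds_ratio, 1)
  # category of 100 all design-I probes vs a 50/50 background of 1000
  probes2 <- probes
  probes2$design[1:100] <- "I"
  dr2 <- probe_design_ratio(list(allI = paste0("cg", 1:100)), probes2)
  expect_gt(dr2$odds_ratio, 1)
  expect_lt(dr2$p_value, 0.05)
  dr3 <- probe_design_ratio(list(none = character(0)), probes)
  expect_true(is.na(dr3$odds_ratio) && is.na(dr3$p_value))
})

test_that("GC comparison detects a planted shift and not a null one", {
  set.seed(77)
  gc <- c(runif(200, 0.2, 0.6), runif(200, 0.2, 0.6))
  probes <- data.frame(cpg_id = paste0("cg", 1:400), design = "II",
                       gc_fraction = gc, stringsAsFactors = FALSE)
  null_res <- gc_content_compare(list(a = paste0("cg", 1:200)), probes)
  expect_gt(null_res$p_value, 0.05)
  probes$gc_fraction[1:200] <- probes$gc_fraction[1:200] + 0.2
  shift_res <- gc_content_compare(list(a = paste0("cg", 1:200)), probes)
  expect_lt(shift_res$p_value, 0.01)
  expect_gt(shift_res$median_gc, shift_res$background_median_gc)
  tiny <- gc_content_compare(list(a = "cg1"), probes)
  expect_true(is.na(tiny$p_value))
})
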