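# End-to-end orchestration: (optional) simulate -> validate -> QC -> RI ->
# categorize -> annotate -> EWAS enrichment, with a manifest that makes
# runs reproducible (input hashes, config snapshot, seed, versions). All
# thresholds are surfaced in the config; the published cut-offs are
# defaults, not constants.

#' Pipeline configuration
#'
#' @param input_dir Directory holding (or receiving, when `generator` is
#'   supplied) the input bundle.
#' @param output_dir Directory for result tables and the manifest.
#' @param generator Optional [generator_config()]; when given, the simulate
#'   stage writes a synthetic bundle into `input_dir` first.
#' @param stable_max,dynamic_min,dynamic_max Stability-category thresholds
#'   on the within-individual RI (defaults 1, 10, 50; must be increasing).
#' @param cdmv_min CDMV threshold on the between-individual RI (default 30,
#'   strict).
#' @param maf_max SNP-overlap exclusion threshold (default 0.05, inclusive).
#' @param alpha Cell-type ANOVA threshold (default 0.05).
#' @param min_studies,min_markers EWAS trait selection thresholds (5, 100).
#' @param master_seed Seed recorded in the manifest and used for simulation.
#' @param stages Named logical vector toggling `simulate`, `qc`, `ri`,
#'   `annotate`, `ewas`.
#' @return An object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(input_dir, output_dir,
                            generator = NULL,
                            stable_max = 1, dynamic_min = 10, dynamic_max = 50,
                            cdmv_min = 30, maf_max = 0.05, alpha = 0.05,
                            min_studies = 5, min_markers = 100,
                            master_seed = 1L,
                            stages = c(simulate = !is.null(generator),
                                       qc = TRUE, ri = TRUE,
                                       annotate = TRUE, ewas = TRUE)) {
  if (!(stable_max > 0 && stable_max < dynamic_min &&
        dynamic_min < dynamic_max))
    stop("pipeline_config: thresholds must satisfy 0 < stable_max < ",
         "dynamic_min < dynamic_max")
  if (cdmv_min <= 0 || maf_max < 0 || alpha <= 0 || alpha >= 1)
    stop("pipeline_config: invalid threshold")
  cfg <- list(input_dir = input_dir, output_dir = output_dir,
              generator = generator,
              thresholds = list(stable_max = stable_max,
                                dynamic_min = dynamic_min,
                                dynamic_max = dynamic_max,
                                cdmv_min = cdmv_min, maf_max = maf_max,
                                alpha = alpha, min_studies = min_studies,
                                min_markers = min_markers),
              master_seed = as.integer(master_seed),
              stages = stages)
  class(cfg) <- "pipeline_config"
  cfg
}

finding <- function(file, line, issue) {
  data.frame(file = file, line = line, issue = issue, stringsAsFactors = FALSE)
}

#' Validate an input bundle
#'
#' Pure schema and range checks on every input file: methylation values in
#' [0, 100] (with file and line of the first violation per file), cell
#' proportions in [0, 1] with row sums in [0.9, 1.1], a shared timepoint
#' grid across series, probe-universe consistency between series and probe
#' table, between-RI coverage, and catalog uniqueness. Nothing is written.
#'
#' @param input_dir Bundle directory.
#' @return data.frame of findings (`file`, `line`, `issue`); zero rows for
#'   a well-formed bundle.
#' @export
validate_inputs <- function(input_dir) {
  findings <- list()
  add <- function(f) findings[[length(findings) + 1]] <<- f
  cohort <- tryCatch(read_cohort(input_dir), error = function(e) e)
  if (inherits(cohort, "error"))
    return(finding("(bundle)", NA_integer_, conditionMessage(cohort)))

  n_t <- vapply(cohort$betas, function(s) ncol(s$values), 0L)
  if (length(unique(n_t)) > 1)
    add(finding("betas_*.tsv", NA_integer_,
                paste0("timepoint misalignment across series: ",
                       paste(unique(n_t), collapse = " vs "))))
  ids <- rownames(cohort$betas[[1]]$values)
  for (nm in names(cohort$betas)) {
    f <- sprintf("betas_%s.tsv", nm)
    v <- cohort$betas[[nm]]$values
    bad <- which(rowSums(v < 0 | v > 100, na.rm = TRUE) > 0)
    if (length(bad) > 0)
      add(finding(f, bad[1] + 1L,  # +1 for the header line
                  sprintf("methylation value outside [0, 100] for %s",
                          rownames(v)[bad[1]])))
    if (!identical(rownames(v), ids))
      add(finding(f, NA_integer_, "probe order differs between series"))
    p <- cohort$props[[nm]]$proportions
    fpr <- sprintf("cellprops_%s.tsv", nm)
    if (nrow(p) != ncol(v))
      add(finding(fpr, NA_integer_,
                  "proportion rows do not match series timepoints"))
    badp <- which(rowSums(p < 0 | p > 1) > 0)
    if (length(badp) > 0)
      add(finding(fpr, badp[1] + 1L, "proportion outside [0, 1]"))
    bads <- which(rowSums(p) < 0.9 | rowSums(p) > 1.1)
    if (length(bads) > 0)
      add(finding(fpr, bads[1] + 1L, "composition row sum outside [0.9, 1.1]"))
  }
  if (!setequal(cohort$probes$cpg_id, ids))
    add(finding("probes.tsv", NA_integer_,
                "probe universe differs from the series"))
  bad_gc <- which(cohort$probes$gc_fraction < 0 | cohort$probes$gc_fraction > 1)
  if (length(bad_gc) > 0)
    add(finding("probes.tsv", bad_gc[1] + 1L, "gc_fraction outside [0, 1]"))
  bad_maf <- which(!is.na(cohort$probes$snp_maf) &
                   (cohort$probes$snp_maf <= 0 | cohort$probes$snp_maf > 0.5))
  if (length(bad_maf) > 0)
    add(finding("probes.tsv", bad_maf[1] + 1L, "snp_maf outside (0, 0.5]"))
  if (!all(cohort$annotation$start < cohort$annotation$end))
    add(finding("annotations.bed", NA_integer_, "interval with start >= end"))
  bad_b <- which(cohort$between_ri$between_ri < 0 |
                 cohort$between_ri$between_ri > 100)
  if (length(bad_b) > 0)
    add(finding("between_ri.tsv", bad_b[1] + 1L,
                "between-individual RI outside [0, 100]"))
  if (length(findings) == 0)
    return(finding(character(0), integer(0), character(0)))
  do.call(rbind, findings)
}

#' Run the full analysis pipeline
#'
#' Executes simulate (optional) -> validate -> QC cascade -> RI ->
#' categorize -> annotate -> EWAS enrichment, writing one TSV per result
#' table plus `manifest.json` (input hashes, config snapshot, seed,
#' versions). A schema violation or stage failure stops the run with an
#' error. One structured log line per stage reports input/output counts in
#' the exclusion-accounting style.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress per-stage log lines.
#' @return Invisibly, a list with the in-memory results (`qc`, `ri`,
#'   `categories`, `summaries`, `pca`, `composition`, `design_ratio`, `gc`,
#'   `likelihood_overall`, `meta_by_trait`) and the output directory.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  th <- config$thresholds
  say <- function(...) if (!quiet) message(sprintf(...))

  if (isTRUE(config$stages["simulate"])) {
    if (is.null(config$generator))
      stop("run_pipeline: simulate stage enabled but no generator config")
    write_cohort(generate_cohort(config$generator), config$input_dir)
    say("simulate: wrote synthetic bundle to %s", config$input_dir)
  }
  findings <- validate_inputs(config$input_dir)
  if (nrow(findings) > 0)
    stop("run_pipeline: input validation failed: ", findings$file[1],
         if (!is.na(findings$line[1])) paste0(" line ", findings$line[1]),
         ": ", findings$issue[1])
  cohort <- read_cohort(config$input_dir)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- list(output_dir = config$output_dir)

  if (isTRUE(config$stages["qc"])) {
    qc <- qc_cascade(cohort$betas, cohort$props, cohort$probes,
                     maf_threshold = th$maf_max, alpha = th$alpha)
    say("qc: %d probes; %d with missing values, %d overlapping SNPs and %d associated with cell-type components were removed; %d retained",
        qc$counts["universe"], qc$counts["excluded_missing"],
        qc$counts["excluded_snp"], qc$counts["excluded_celltype"],
        qc$counts["retained"])
    write_tsv(qc$report, file.path(config$output_dir, "qc_report.tsv"))
    out$qc <- qc
  } else {
    out$qc <- list(retained = rownames(cohort$betas[[1]]$values))
  }
  retained <- out$qc$retained

  if (isTRUE(config$stages["ri"])) {
    ri <- ri_table(cohort$betas, retained = retained,
                   between_ri = cohort$between_ri)
    cats <- categorize_cpgs(ri,
                            thresholds = list(stable_max = th$stable_max,
                                              dynamic_min = th$dynamic_min,
                                              dynamic_max = th$dynamic_max),
                            cdmv_threshold = th$cdmv_min)
    say("ri: %d (CpG, series) records; %d stable, %d dynamic, %d hyperdynamic assignments; %d CDMV CpGs",
        nrow(cats), sum(cats$category == "stable"),
        sum(cats$category == "dynamic"),
        sum(cats$category == "hyperdynamic"),
        length(unique(cats$cpg_id[cats$cdmv])))
    summaries <- summarize_ri(cats)
    pca <- pca_overview(cohort$betas, retained = retained)
    write_tsv(ri, file.path(config$output_dir, "ri_table.tsv"))
    write_tsv(cats[c("cpg_id", "series", "category", "cdmv")],
              file.path(config$output_dir, "categories.tsv"))
    write_tsv(summaries$histogram,
              file.path(config$output_dir, "ri_histogram.tsv"))
    write_tsv(pca$scores, file.path(config$output_dir, "pca_scores.tsv"))
    out$ri <- ri; out$categories <- cats; out$summaries <- summaries
    out$pca <- pca
  }

  sets <- NULL
  if (!is.null(out$categories)) {
    cats <- out$categories
    sets <- list()
    for (s in unique(cats$series)) for (ct in c("stable", "dynamic",
                                                "hyperdynamic")) {
      sets[[paste(ct, s, sep = ".")]] <-
        cats$cpg_id[cats$series == s & cats$category == ct]
    }
    sets$CDMV <- unique(cats$cpg_id[cats$cdmv])
  }

  if (isTRUE(config$stages["annotate"]) && !is.null(sets)) {
    pr <- cohort$probes[cohort$probes$cpg_id %in% retained, ]
    ann <- annotate_cpgs(pr, cohort$annotation)
    comp <- fractional_composition(c(sets, list(background = retained)), ann)
    dr <- probe_design_ratio(sets, pr)
    gc <- gc_content_compare(sets, pr)
    say("annotate: %d retained probes annotated; %d composition rows",
        nrow(pr), nrow(comp))
    write_tsv(comp, file.path(config$output_dir, "composition.tsv"))
    write_tsv(dr, file.path(config$output_dir, "design_ratio.tsv"))
    write_tsv(gc, file.path(config$output_dir, "gc_content.tsv"))
    out$annotations <- ann; out$composition <- comp
    out$design_ratio <- dr; out$gc <- gc
    ctx_sets <- split(ann$context$cpg_id, ann$context$context)
  } else ctx_sets <- NULL

  if (isTRUE(config$stages["ewas"]) && !is.null(sets)) {
    all_sets <- c(sets, ctx_sets)
    lik <- marker_likelihood_table(all_sets, cohort$catalog, retained)
    meta_sets <- sets[!grepl("^hyperdynamic", names(sets))]
    meta <- suppressMessages(
      trait_category_scan(meta_sets, cohort$catalog, retained,
                          min_studies = th$min_studies,
                          min_markers = th$min_markers))
    say("ewas: %d enrichment rows; %d (trait, category) meta-analysis cells",
        nrow(lik), nrow(meta))
    write_tsv(lik, file.path(config$output_dir, "likelihood_overall.tsv"))
    write_tsv(meta, file.path(config$output_dir, "meta_by_trait.tsv"))
    out$likelihood_overall <- lik
    out$meta_by_trait <- meta
  }

  inputs <- sort(list.files(config$input_dir, full.names = TRUE))
  manifest <- list(
    inputs = as.list(setNames(unname(tools::md5sum(inputs)),
                              basename(inputs))),
    thresholds = th,
    master_seed = config$master_seed,
    stages = as.list(config$stages),
    package_version = as.character(utils::packageVersion("methylRI")),
    r_version = paste(R.version$major, R.version$minor, sep = "."))
  jsonlite::write_json(manifest, file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out)
}
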