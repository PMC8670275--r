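# Plain-text input bundle. Formats:
#   betas_<ind>_<tissue>.tsv    cpg_id, T01..Tnn (percent, NA = missing)
#   cellprops_<ind>_<tissue>.tsv day, CD4T, CD8T, NK, B, Mono, Gran
#   probes.tsv                  cpg_id, chrom, pos_1based, design, gc_fraction, snp_maf
#   annotations.bed             BED6, name = "featureclass:gene_or_dot"
#   between_ri.tsv              cpg_id, between_ri
#   ewas_catalog.tsv            cpg_id, trait, study_id
#   truth.json                  ground-truth ledger (synthetic cohorts only)

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
}

#' Write an annotation track as BED6
#'
#' Intervals are written in BED native coordinates (0-based half-open) with
#' `name = "featureclass:gene_id"` (`.` for intervals without a gene) and
#' score 0; the round trip through [read_annotation_bed()] is bit-exact.
#'
#' @param track Annotation data.frame (`chrom`, `start`, `end`,
#'   `feature_class`, `gene_id`, `strand`).
#' @param path Output file.
#' @export
write_annotation_bed <- function(track, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = track$chrom,
    ranges = IRanges::IRanges(start = track$start + 1L, end = track$end),
    strand = ifelse(is.na(track$strand) | track$strand == "*", "*",
                    track$strand))
  gr$name <- paste0(track$feature_class, ":",
                    ifelse(is.na(track$gene_id), ".", track$gene_id))
  gr$score <- 0L
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a BED6 annotation track
#'
#' @param path BED file written by [write_annotation_bed()] (name field
#'   `featureclass:gene_or_dot`).
#' @return Annotation data.frame with 0-based half-open `start`/`end`.
#' @export
read_annotation_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  parts <- strsplit(gr$name, ":", fixed = TRUE)
  track <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    feature_class = vapply(parts, `[`, "", 1),
    gene_id = vapply(parts, function(p) if (length(p) < 2 || p[2] == ".")
      NA_character_ else p[2], ""),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE)
  track
}

#' Write a cohort bundle to a directory
#'
#' Writes every input file consumed by the pipeline, plus `truth.json` when
#' the cohort carries a ground-truth ledger. Duplicate
#' `(cpg, trait, study)` catalog records are rejected.
#'
#' @param cohort A `"meth_cohort"` from [generate_cohort()] or
#'   [read_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (anyDuplicated(cohort$catalog[c("cpg_id", "trait", "study_id")]))
    stop("write_cohort: duplicate (cpg, trait, study) records in the catalog")
  for (nm in names(cohort$betas)) {
    s <- cohort$betas[[nm]]
    df <- data.frame(cpg_id = rownames(s$values), s$values, check.names = FALSE)
    write_tsv(df, file.path(dir, sprintf("betas_%s.tsv", nm)))
    p <- cohort$props[[nm]]
    write_tsv(data.frame(day = p$days, p$proportions, check.names = FALSE),
              file.path(dir, sprintf("cellprops_%s.tsv", nm)))
  }
  pr <- cohort$probes
  write_tsv(data.frame(cpg_id = pr$cpg_id, chrom = pr$chrom,
                       pos_1based = pr$pos, design = pr$design,
                       gc_fraction = pr$gc_fraction, snp_maf = pr$snp_maf),
            file.path(dir, "probes.tsv"))
  write_annotation_bed(cohort$annotation, file.path(dir, "annotations.bed"))
  write_tsv(cohort$between_ri, file.path(dir, "between_ri.tsv"))
  write_tsv(cohort$catalog, file.path(dir, "ewas_catalog.tsv"))
  if (!is.null(cohort$truth)) {
    tr <- cohort$truth
    cfg <- unclass(tr$config)
    jsonlite::write_json(
      list(cpg_id = tr$cpg_id, category = tr$category,
           cell_driven = tr$cell_driven, snp_maf = tr$snp_maf,
           between_ri = tr$between_ri, cdmv = tr$cdmv,
           context = tr$context, missing = tr$missing,
           master_seed = tr$master_seed, config = cfg),
      file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA,
      na = "null")
  }
  invisible(dir)
}

#' Read a cohort bundle from a directory
#'
#' Loads all `betas_*.tsv` / `cellprops_*.tsv` pairs, probe metadata, the
#' BED annotation track, the between-individual RI reference, and the EWAS
#' catalog (duplicate records are rejected). `truth.json`, if present, is
#' attached as the ground-truth ledger.
#'
#' @param dir Bundle directory.
#' @return A `"meth_cohort"` list.
#' @export
read_cohort <- function(dir) {
  beta_files <- sort(list.files(dir, pattern = "^betas_.*\\.tsv$"))
  if (length(beta_files) == 0)
    stop("read_cohort: no betas_*.tsv in ", dir)
  betas <- list()
  props <- list()
  for (bf in beta_files) {
    nm <- sub("^betas_(.*)\\.tsv$", "\\1", bf)
    parts <- strsplit(nm, "_", fixed = TRUE)[[1]]
    key <- list(individual = parts[1],
                tissue = paste(parts[-1], collapse = "_"))
    df <- read.delim(file.path(dir, bf), check.names = FALSE)
    vals <- as.matrix(df[, -1, drop = FALSE])
    rownames(vals) <- df$cpg_id
    cf <- file.path(dir, sprintf("cellprops_%s.tsv", nm))
    if (!file.exists(cf))
      stop("read_cohort: missing ", basename(cf))
    pd <- read.delim(cf, check.names = FALSE)
    pm <- as.matrix(pd[, CELL_TYPES, drop = FALSE])
    if (nrow(pm) != ncol(vals))
      stop("read_cohort: timepoint misalignment between ", bf, " (",
           ncol(vals), " timepoints) and ", basename(cf), " (", nrow(pm),
           " rows)")
    rownames(pm) <- colnames(vals)
    betas[[nm]] <- list(series_key = key, days = pd$day, values = vals)
    props[[nm]] <- list(series_key = key, days = pd$day, proportions = pm)
  }
  for (req in c("probes.tsv", "annotations.bed", "between_ri.tsv",
                "ewas_catalog.tsv"))
    if (!file.exists(file.path(dir, req)))
      stop("read_cohort: missing input file ", req)
  pr <- read.delim(file.path(dir, "probes.tsv"))
  probes <- data.frame(cpg_id = pr$cpg_id, chrom = pr$chrom,
                       pos = pr$pos_1based, design = pr$design,
                       gc_fraction = pr$gc_fraction, snp_maf = pr$snp_maf,
                       stringsAsFactors = FALSE)
  annotation <- read_annotation_bed(file.path(dir, "annotations.bed"))
  between_ri <- read.delim(file.path(dir, "between_ri.tsv"))
  catalog <- read.delim(file.path(dir, "ewas_catalog.tsv"),
                        colClasses = "character")
  if (anyDuplicated(catalog))
    stop("read_cohort: duplicate (cpg, trait, study) records in the catalog")
  truth <- NULL
  tf <- file.path(dir, "truth.json")
  if (file.exists(tf)) truth <- jsonlite::read_json(tf, simplifyVector = TRUE)
  out <- list(config = truth$config, truth = truth, probes = probes,
              annotation = annotation, props = props, betas = betas,
              between_ri = between_ri, catalog = catalog)
  class(out) <- "meth_cohort"
  out
}
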