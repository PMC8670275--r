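# Genomic annotation of probes and per-category composition. Coordinates
# are 0-based half-open internally (BED native); probe manifest positions
# are 1-based and converted on load. A probe receives exactly one
# CpG-context class (island / shore / shelf / open sea — mutually exclusive
# by construction) and one or more genic annotations (intergenic if none
# overlaps). Genic composition uses fractional counting: a CpG with k genic
# annotations contributes 1/k to each.

annotation_granges <- function(track) {
  GenomicRanges::GRanges(seqnames = track$chrom,
                         ranges = IRanges::IRanges(start = track$start + 1L,
                                                   end = track$end),
                         strand = ifelse(is.na(track$strand) |
                                         track$strand == "*", "*",
                                         track$strand),
                         feature_class = track$feature_class,
                         gene_id = track$gene_id)
}

probe_granges <- function(probes) {
  GenomicRanges::GRanges(seqnames = probes$chrom,
                         ranges = IRanges::IRanges(start = probes$pos,
                                                   width = 1L),
                         cpg_id = probes$cpg_id)
}

#' Annotate probes against an annotation track
#'
#' Overlaps each probe position (a 1 bp point interval) with the track,
#' ignoring strand. Each probe gets exactly one CpG-context class — more
#' than one context hit is a malformed track and a hard failure — and at
#' least one genic annotation (`intergenic` when nothing genic overlaps).
#' Probes on chromosomes absent from the track are annotated
#' `open_sea` + `intergenic` with a warning.
#'
#' @param probes Probe metadata data.frame (`cpg_id`, `chrom`, `pos`
#'   1-based, ...).
#' @param track Annotation data.frame (`chrom`, `start` 0-based half-open,
#'   `end`, `feature_class`, `gene_id`, `strand`), e.g. from
#'   [generate_annotation_and_probes()] or [read_annotation_bed()].
#' @return List with `context` (data.frame `cpg_id`, `context`) and `genic`
#'   (data.frame `cpg_id`, `feature_class`, `gene_id`; one or more rows per
#'   probe).
#' @export
annotate_cpgs <- function(probes, track) {
  tr_gr <- annotation_granges(track)
  pr_gr <- probe_granges(probes)
  off_chrom <- !(probes$chrom %in% unique(track$chrom))
  if (any(off_chrom))
    warning(sum(off_chrom), " probe(s) on chromosomes absent from the ",
            "track; annotated open_sea + intergenic")
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(pr_gr, tr_gr, ignore.strand = TRUE))
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  feat <- track$feature_class[sh]
  is_ctx <- feat %in% CPG_CONTEXTS

  ctx_count <- tabulate(qh[is_ctx], nbins = nrow(probes))
  if (any(ctx_count > 1))
    stop("annotate_cpgs: overlapping CpG-context classes in the track (",
         sum(ctx_count > 1), " probe(s) hit more than one context)")
  context <- rep("open_sea", nrow(probes))
  context[qh[is_ctx]] <- feat[is_ctx]
  if (any(ctx_count == 0 & !off_chrom))
    stop("annotate_cpgs: ", sum(ctx_count == 0 & !off_chrom),
         " probe(s) on covered chromosomes fall outside every ",
         "CpG-context interval; the context classes must tile the genome")

  gen <- data.frame(cpg_id = probes$cpg_id[qh[!is_ctx]],
                    feature_class = feat[!is_ctx],
                    gene_id = track$gene_id[sh[!is_ctx]],
                    stringsAsFactors = FALSE)
  gen <- unique(gen)
  no_genic <- setdiff(probes$cpg_id, gen$cpg_id)
  if (length(no_genic) > 0)
    gen <- rbind(gen, data.frame(cpg_id = no_genic,
                                 feature_class = "intergenic",
                                 gene_id = NA_character_))
  gen <- gen[order(match(gen$cpg_id, probes$cpg_id), gen$feature_class,
                   gen$gene_id), ]
  rownames(gen) <- NULL
  list(context = data.frame(cpg_id = probes$cpg_id, context = context,
                            stringsAsFactors = FALSE),
       genic = gen)
}

#' Annotation composition of CpG categories with fractional counting
#'
#' For each named CpG set, tabulates the genic composition with fractional
#' counting — a CpG with k genic annotations contributes 1/k to each, so a
#' CpG mapped to, say, a promoter of one gene and an exon of another
#' contributes 1/2 and 1/2 — and the CpG-context composition with whole
#' counts (each CpG has exactly one context). Fractional genic counts sum
#' to the number of annotated CpGs in the set.
#'
#' @param category_sets Named list of character vectors of CpG ids.
#' @param annotations Output of [annotate_cpgs()].
#' @return data.frame `category`, `kind` (genic/context), `feature_class`,
#'   `fractional_count`, `fraction_of_category`.
#' @export
fractional_composition <- function(category_sets, annotations) {
  gen <- annotations$genic
  k_by_cpg <- table(gen$cpg_id)
  if (any(k_by_cpg == 0))
    stop("fractional_composition: CpG with zero genic annotations")
  gen$weight <- 1 / as.numeric(k_by_cpg[gen$cpg_id])
  ctx <- annotations$context
  rows <- list()
  for (nm in names(category_sets)) {
    set <- unique(category_sets[[nm]])
    g <- gen[gen$cpg_id %in% set, ]
    if (nrow(g) > 0) {
      fc <- rowsum(g$weight, g$feature_class)
      rows[[length(rows) + 1]] <- data.frame(category = nm, kind = "genic",
        feature_class = rownames(fc), fractional_count = as.numeric(fc),
        fraction_of_category = as.numeric(fc) / sum(fc))
    }
    cx <- ctx[ctx$cpg_id %in% set, ]
    if (nrow(cx) > 0) {
      tc <- table(cx$context)
      rows[[length(rows) + 1]] <- data.frame(category = nm, kind = "context",
        feature_class = names(tc), fractional_count = as.numeric(tc),
        fraction_of_category = as.numeric(tc) / sum(tc))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Infinium design ratio per category
#'
#' Fraction of Infinium design-I probes in each CpG set, with a Fisher
#' exact test of the design-I/design-II split against the all-probe
#' background (cross-product odds ratio, see [fisher_exact_2x2()]).
#'
#' @param category_sets Named list of CpG-id vectors.
#' @param probes Probe metadata with `cpg_id` and `design` in `{"I","II"}`.
#' @return data.frame per category: `n`, `frac_design_I`,
#'   `background_frac_I`, `odds_ratio`, `p_value`; `NA`s for an empty
#'   category (undefined).
#' @export
probe_design_ratio <- function(category_sets, probes) {
  bg_I <- sum(probes$design == "I")
  bg_II <- sum(probes$design == "II")
  rows <- lapply(names(category_sets), function(nm) {
    set <- unique(category_sets[[nm]])
    des <- probes$design[probes$cpg_id %in% set]
    if (length(des) == 0)
      return(data.frame(category = nm, n = 0L, frac_design_I = NA_real_,
                        background_frac_I = bg_I / (bg_I + bg_II),
                        odds_ratio = NA_real_, p_value = NA_real_))
    a <- sum(des == "I"); b <- sum(des == "II")
    ft <- fisher_exact_2x2(a, b, bg_I, bg_II)
    data.frame(category = nm, n = length(des),
               frac_design_I = a / (a + b),
               background_frac_I = bg_I / (bg_I + bg_II),
               odds_ratio = ft$odds_ratio, p_value = ft$p_value)
  })
  do.call(rbind, rows)
}

#' Probe GC content per category
#'
#' Compares the GC fraction of each category's probes against all other
#' probes by a two-sided Wilcoxon rank-sum test.
#'
#' @param category_sets Named list of CpG-id vectors.
#' @param probes Probe metadata with `cpg_id` and `gc_fraction`.
#' @return data.frame per category: `n`, `median_gc`,
#'   `background_median_gc`, `p_value` (`NA` when the category has fewer
#'   than 2 probes).
#' @export
gc_content_compare <- function(category_sets, probes) {
  rows <- lapply(names(category_sets), function(nm) {
    set <- unique(category_sets[[nm]])
    inset <- probes$cpg_id %in% set
    gc_in <- probes$gc_fraction[inset]
    gc_out <- probes$gc_fraction[!inset]
    p <- if (length(gc_in) < 2 || length(gc_out) < 2) NA_real_ else
      suppressWarnings(wilcox.test(gc_in, gc_out)$p.value)
    data.frame(category = nm, n = length(gc_in),
               median_gc = if (length(gc_in)) median(gc_in) else NA_real_,
               background_median_gc = median(probes$gc_fraction),
               p_value = p)
  })
  do.call(rbind, rows)
}
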