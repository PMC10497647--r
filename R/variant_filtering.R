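#' Somatic variant filter configuration
#'
#' Thresholds implement the filtering protocol applied to annotated exome /
#' panel variant tables before interpretation. Boundary semantics follow the
#' protocol wording literally: depth strictly greater than 20 reads
#' ("more than 20 reads"), call quality at least 20, alternate-allele
#' fraction at least 1\%, and removal when any of the three population
#' databases (1000 Genomes, ExAC, NHLBI ESP) reports a frequency of at
#' least 10\%. ACMG benign and likely-benign calls are excluded. NGS copy
#' number events require 100x coverage and a sample tumor-cell ratio of at
#' least 30\%; SNV detection requires a 10\% tumor-cell ratio, enforced as a
#' sample-level warning (sample acceptance, not per-variant filtering).
#'
#' @param min_depth_exclusive keep variants with depth strictly above this
#'   (reads; default 20).
#' @param min_quality minimum phred-like call quality (default 20).
#' @param min_alt_fraction minimum alternate-allele fraction (default 0.01).
#' @param max_pop_freq remove when any population frequency is >= this
#'   (default 0.10).
#' @param excluded_acmg ACMG classes removed outright.
#' @param virtual_panel character vector of gene symbols: the interpretation
#'   gene list (the "virtual panel"); required, non-empty.
#' @param cnv_min_coverage minimum coverage for reporting a copy number event.
#' @param cnv_min_tumor_ratio minimum sample tumor-cell ratio for CNV calls.
#' @param snv_min_tumor_ratio minimum sample tumor-cell ratio for SNV calling
#'   adequacy (warning only).
#' @return A `dda_filter_config` list.
#' @export
filter_config <- function(min_depth_exclusive = 20L,
                          min_quality = 20,
                          min_alt_fraction = 0.01,
                          max_pop_freq = 0.10,
                          excluded_acmg = c("benign", "likely_benign"),
                          virtual_panel,
                          cnv_min_coverage = 100L,
                          cnv_min_tumor_ratio = 0.30,
                          snv_min_tumor_ratio = 0.10) {
  if (missing(virtual_panel) || length(virtual_panel) == 0)
    stop("filter_config: virtual_panel must be a non-empty gene set")
  stopifnot(min_depth_exclusive >= 0, min_quality >= 0,
            min_alt_fraction >= 0, max_pop_freq >= 0,
            cnv_min_coverage >= 0, cnv_min_tumor_ratio >= 0)
  structure(list(
    min_depth_exclusive = min_depth_exclusive,
    min_quality = min_quality,
    min_alt_fraction = min_alt_fraction,
    max_pop_freq = max_pop_freq,
    excluded_acmg = excluded_acmg,
    virtual_panel = toupper(unique(virtual_panel)),
    cnv_min_coverage = cnv_min_coverage,
    cnv_min_tumor_ratio = cnv_min_tumor_ratio,
    snv_min_tumor_ratio = snv_min_tumor_ratio), class = "dda_filter_config")
}

#' Per-sample metadata
#'
#' @param case_id case identifier.
#' @param tumor_type tumor-type code.
#' @param tumor_cell_ratio fraction of tumor nuclei in the specimen, in
#'   `[0, 1]`.
#' @param year calendar year of profiling.
#' @param test_type profiling modality.
#' @return A `dda_sample_meta` list.
#' @export
sample_meta <- function(case_id, tumor_type, tumor_cell_ratio = 0.5,
                        year = NA_integer_,
                        test_type = c("WES", "NGS-600", "NGS-50", "LB-600",
                                      "Sanger", "FISH-only")) {
  test_type <- match.arg(test_type)
  stopifnot(tumor_cell_ratio >= 0, tumor_cell_ratio <= 1)
  structure(list(case_id = as.character(case_id),
                 tumor_type = as.character(tumor_type),
                 tumor_cell_ratio = tumor_cell_ratio,
                 year = as.integer(year), test_type = test_type),
            class = "dda_sample_meta")
}

variant_template <- function(n = 0) {
  data.frame(gene = character(n), alteration = character(n),
             variant_type = character(n), depth = integer(n),
             quality = numeric(n), alt_allele_fraction = numeric(n),
             pop_freq_1kg = numeric(n), pop_freq_exac = numeric(n),
             pop_freq_esp = numeric(n), acmg_class = character(n),
             coverage = numeric(n), chrom = character(n), pos = integer(n),
             stringsAsFactors = FALSE)
}

# Coerce an arbitrary variant table to the canonical column set; missing
# nullable columns become NA. Used by every filter entry point so that
# hand-built fixtures can stay terse.
normalize_variants <- function(variants) {
  tmpl <- variant_template(0)
  if (is.null(variants) || nrow(as.data.frame(variants)) == 0) return(tmpl)
  v <- as.data.frame(variants, stringsAsFactors = FALSE)
  for (col in names(tmpl)) if (!col %in% names(v)) v[[col]] <- NA
  v <- v[, c(names(tmpl), intersect(".row_id", names(v)))]
  for (col in names(tmpl)) {  # pin column types to the template's
    cast <- switch(class(tmpl[[col]])[1], character = as.character,
                   integer = as.integer, numeric = as.numeric)
    v[[col]] <- cast(v[[col]])
  }
  bad_vaf <- !is.na(v$alt_allele_fraction) &
    (v$alt_allele_fraction < 0 | v$alt_allele_fraction > 1)
  if (any(bad_vaf)) stop("variant table: alt_allele_fraction outside [0, 1]")
  for (col in c("pop_freq_1kg", "pop_freq_exac", "pop_freq_esp")) {
    bad <- !is.na(v[[col]]) & (v[[col]] < 0 | v[[col]] > 1)
    if (any(bad)) stop("variant table: population frequency outside [0, 1]")
  }
  rownames(v) <- NULL
  v
}

split_kept <- function(variants, fail, reason) {
  removed <- variants[fail, , drop = FALSE]
  if (nrow(removed)) removed$filter_reason <- reason[fail]
  else removed$filter_reason <- character()
  list(kept = variants[!fail, , drop = FALSE], removed = removed)
}

#' Depth / quality / allele-fraction filter
#'
#' Keeps SNV/indel calls with depth strictly greater than
#' `min_depth_exclusive`, quality at least `min_quality` and alternate-allele
#' fraction at least `min_alt_fraction`. A record missing any of these three
#' fields is removed with reason `"missing_field"` — call quality that cannot
#' be certified is never silently kept. Removed records carry the first
#' failing rule (`depth`, `quality`, `vaf`).
#'
#' @param variants variant data.frame (SNV/indel rows).
#' @param config a [filter_config()].
#' @return `list(kept = , removed = )`; `removed` has a `filter_reason`
#'   column.
#' @export
apply_quality_filters <- function(variants, config) {
  v <- normalize_variants(variants)
  miss <- is.na(v$depth) | is.na(v$quality) | is.na(v$alt_allele_fraction)
  fail_depth <- !miss & v$depth <= config$min_depth_exclusive
  fail_qual <- !miss & !fail_depth & v$quality < config$min_quality
  fail_vaf <- !miss & !fail_depth & !fail_qual &
    v$alt_allele_fraction < config$min_alt_fraction
  reason <- rep(NA_character_, nrow(v))
  reason[fail_vaf] <- "vaf"
  reason[fail_qual] <- "quality"
  reason[fail_depth] <- "depth"
  reason[miss] <- "missing_field"
  split_kept(v, miss | fail_depth | fail_qual | fail_vaf, reason)
}

#' Population allele-frequency filter
#'
#' Removes a variant when any of the three population databases reports an
#' allele frequency of at least `max_pop_freq` (default 10\%): common
#' polymorphisms are not somatic candidates. A missing frequency never
#' triggers removal (absence of evidence passes).
#'
#' @inheritParams apply_quality_filters
#' @return `list(kept, removed)` with reason `"pop_freq"`.
#' @export
apply_population_filter <- function(variants, config) {
  v <- normalize_variants(variants)
  hit <- function(x) !is.na(x) & x >= config$max_pop_freq
  fail <- hit(v$pop_freq_1kg) | hit(v$pop_freq_exac) | hit(v$pop_freq_esp)
  split_kept(v, fail, rep("pop_freq", nrow(v)))
}

#' ACMG class filter
#'
#' Removes variants whose ACMG classification is in the excluded set
#' (benign / likely benign by default). Unknown class labels are treated as
#' `unclassified` and kept, with a warning.
#'
#' @inheritParams apply_quality_filters
#' @return `list(kept, removed)` with reason `"acmg"`.
#' @export
apply_acmg_filter <- function(variants, config) {
  v <- normalize_variants(variants)
  cls <- as.character(v$acmg_class)
  unknown <- !is.na(cls) & !cls %in% ACMG_CLASSES
  if (any(unknown)) {
    warning("apply_acmg_filter: unknown ACMG label(s) treated as unclassified: ",
            paste(unique(cls[unknown]), collapse = ", "))
    cls[unknown] <- "unclassified"
  }
  cls[is.na(cls)] <- "unclassified"
  fail <- cls %in% config$excluded_acmg
  split_kept(v, fail, rep("acmg", nrow(v)))
}

#' Virtual gene panel filter
#'
#' Keeps variants whose gene symbol is in the interpretation gene set; the
#' protocol interprets only a virtual panel of ~1000 tumorigenesis-linked
#' genes out of the whole exome. Matching is case-insensitive.
#'
#' @param variants variant data.frame.
#' @param gene_set character vector of gene symbols.
#' @return `list(kept, removed)` with reason `"panel"`.
#' @export
apply_virtual_panel <- function(variants, gene_set) {
  if (length(gene_set) == 0) stop("apply_virtual_panel: empty gene set")
  v <- normalize_variants(variants)
  fail <- !(toupper(v$gene) %in% toupper(gene_set))
  split_kept(v, fail, rep("panel", nrow(v)))
}

#' Copy-number record filter
#'
#' NGS copy-number events are reported only with at least
#' `cnv_min_coverage` coverage and in samples whose tumor-cell ratio is at
#' least `cnv_min_tumor_ratio`; when the sample fails the ratio, every CNV is
#' removed with reason `"tumor_ratio"`.
#'
#' @param cnvs CNV-type variant rows (must carry a `coverage` field).
#' @param meta a [sample_meta()].
#' @param config a [filter_config()].
#' @return `list(kept, removed)`.
#' @export
filter_cnv_records <- function(cnvs, meta, config) {
  v <- normalize_variants(cnvs)
  if (nrow(v) == 0) return(split_kept(v, logical(0), character(0)))
  if (meta$tumor_cell_ratio < config$cnv_min_tumor_ratio)
    return(split_kept(v, rep(TRUE, nrow(v)), rep("tumor_ratio", nrow(v))))
  fail <- is.na(v$coverage) | v$coverage < config$cnv_min_coverage
  split_kept(v, fail, rep("cnv_coverage", nrow(v)))
}

#' Classify microsatellite instability status
#'
#' MSI-high versus microsatellite-stable is called from five mononucleotide
#' repeat markers (NR-21, NR-24, BAT-25, BAT-26, MONO-27): MSI-H when
#' strictly more than 20\% of the markers are unstable, i.e. the
#' conventional 2-or-more-of-5 rule.
#'
#' @param msi named logical vector over the five markers (`TRUE` = unstable).
#' @return `"MSI-H"` or `"MSS"`.
#' @export
classify_msi <- function(msi) {
  if (length(msi) != 5 || !setequal(names(msi), MSI_MARKERS) || anyNA(msi))
    stop("incomplete_msi_panel: need boolean calls for exactly the markers ",
         paste(MSI_MARKERS, collapse = ", "))
  if (sum(msi) / 5 > 0.20) "MSI-H" else "MSS"
}

#' Convert non-NGS diagnostic results to variant records
#'
#' FISH amplifications become CNV records, FISH translocations fusion
#' records, positive IHC markers biomarker records, and an MSI-high call a
#' single `"MSI-H"` biomarker record. Negative or stable results contribute
#' nothing.
#'
#' @param fish_calls data.frame with columns `gene`, `kind`
#'   (`"amplification"` or `"translocation"`), `positive` (logical); may be
#'   `NULL`.
#' @param ihc_calls data.frame with columns `marker`, `positive`; may be
#'   `NULL`.
#' @param msi named logical vector as in [classify_msi()], or `NULL` when MSI
#'   was not tested.
#' @param meta a [sample_meta()].
#' @return data.frame of variant records (possibly zero rows).
#' @export
ingest_non_ngs_results <- function(fish_calls = NULL, ihc_calls = NULL,
                                   msi = NULL, meta) {
  out <- variant_template(0)
  add <- function(gene, alteration, type) {
    row <- variant_template(1)
    row[1, c("gene", "alteration", "variant_type")] <- c(gene, alteration, type)
    row$depth <- NA_integer_; row$quality <- NA_real_
    row$alt_allele_fraction <- NA_real_
    row[, c("pop_freq_1kg", "pop_freq_exac", "pop_freq_esp", "coverage", "pos")] <- NA
    row$acmg_class <- NA_character_; row$chrom <- NA_character_
    row
  }
  if (!is.null(fish_calls) && nrow(fish_calls)) {
    for (i in seq_len(nrow(fish_calls))) {
      if (!isTRUE(fish_calls$positive[i])) next
      if (fish_calls$kind[i] == "amplification")
        out <- rbind(out, add(fish_calls$gene[i], "amplification", "CNV"))
      else
        out <- rbind(out, add(fish_calls$gene[i], "translocation", "fusion"))
    }
  }
  if (!is.null(ihc_calls) && nrow(ihc_calls)) {
    for (i in seq_len(nrow(ihc_calls))) {
      if (!isTRUE(ihc_calls$positive[i])) next
      out <- rbind(out, add(ihc_calls$marker[i], "IHC_positive", "biomarker"))
    }
  }
  if (!is.null(msi) && classify_msi(msi) == "MSI-H")
    out <- rbind(out, add("MSI", "MSI-H", "biomarker"))
  rownames(out) <- NULL
  out
}

#' Run the full filtering pipeline on one case
#'
#' SNV/indel rows pass quality, then population-frequency, then ACMG, then
#' virtual-panel filters (the kept set is order-invariant; the fixed order
#' only determines first-failure attribution in the filter log). CNV rows
#' pass the coverage/tumor-ratio rule plus the virtual panel. Non-NGS
#' findings are merged unfiltered (they are assay-positive results, not
#' sequencing calls). The filter log partitions the input exactly: every
#' input row appears once, as kept or with its first failing rule.
#'
#' @param raw_variants raw annotated variant table.
#' @param meta a [sample_meta()].
#' @param config a [filter_config()].
#' @param non_ngs optional data.frame from [ingest_non_ngs_results()].
#' @return A `dda_profile`: list with `meta`, `variants` (survivors),
#'   `non_ngs_findings`, `filter_log`, `warnings`.
#' @export
run_filter_pipeline <- function(raw_variants, meta, config, non_ngs = NULL) {
  v <- normalize_variants(raw_variants)
  v$.row_id <- seq_len(nrow(v)) + 0L
  is_cnv <- !is.na(v$variant_type) & v$variant_type == "CNV"
  snv <- v[!is_cnv, , drop = FALSE]
  cnv <- v[is_cnv, , drop = FALSE]

  removed_all <- list()
  s1 <- apply_quality_filters(snv, config); removed_all$q <- s1$removed
  s2 <- apply_population_filter(s1$kept, config); removed_all$p <- s2$removed
  s3 <- apply_acmg_filter(s2$kept, config); removed_all$a <- s3$removed
  s4 <- apply_virtual_panel(s3$kept, config$virtual_panel); removed_all$g <- s4$removed

  c1 <- filter_cnv_records(cnv, meta, config); removed_all$c <- c1$removed
  c2 <- apply_virtual_panel(c1$kept, config$virtual_panel); removed_all$cg <- c2$removed

  kept <- rbind(s4$kept, c2$kept)
  removed <- do.call(rbind, removed_all)
  log <- rbind(
    if (nrow(kept)) data.frame(row_id = kept$.row_id, gene = kept$gene,
                               alteration = kept$alteration, status = "kept",
                               reason = NA_character_, stringsAsFactors = FALSE),
    if (nrow(removed)) data.frame(row_id = removed$.row_id, gene = removed$gene,
                                  alteration = removed$alteration,
                                  status = "removed", reason = removed$filter_reason,
                                  stringsAsFactors = FALSE))
  if (is.null(log)) log <- data.frame(row_id = integer(), gene = character(),
                                      alteration = character(), status = character(),
                                      reason = character(), stringsAsFactors = FALSE)
  log <- log[order(log$row_id), , drop = FALSE]
  rownames(log) <- NULL
  kept$.row_id <- NULL
  rownames(kept) <- NULL

  warnings <- character()
  if (meta$tumor_cell_ratio < config$snv_min_tumor_ratio)
    warnings <- c(warnings, sprintf(
      "tumor cell ratio %.2f below SNV adequacy threshold %.2f",
      meta$tumor_cell_ratio, config$snv_min_tumor_ratio))

  structure(list(meta = meta, variants = kept,
                 non_ngs_findings = normalize_variants(non_ngs),
                 filter_log = log, warnings = warnings),
            class = "dda_profile")
}

#' @export
print.dda_profile <- function(x, ...) {
  cat(sprintf("<dda_profile %s/%s> %d filtered variants, %d non-NGS findings, %d input rows logged\n",
              x$meta$case_id, x$meta$tumor_type, nrow(x$variants),
              nrow(x$non_ngs_findings), nrow(x$filter_log)))
  invisible(x)
}
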