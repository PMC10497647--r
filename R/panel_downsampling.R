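#' Construct a gene panel
#'
#' @param name panel name.
#' @param genes character vector of gene symbols; deduplicated and
#'   uppercase-normalized.
#' @return A `dda_gene_panel` list.
#' @export
gene_panel <- function(name, genes) {
  genes <- unique(toupper(trimws(genes)))
  genes <- genes[nzchar(genes)]
  if (length(genes) == 0) stop("gene_panel: empty gene set")
  structure(list(name = as.character(name), genes = genes),
            class = "dda_gene_panel")
}

#' Load a gene panel from a newline-delimited gene list
#'
#' Lines starting with `#` are comments; symbols are deduplicated and
#' uppercase-normalized. The panel name defaults to the file name without
#' extension.
#'
#' @param path file path.
#' @param name optional panel name.
#' @return A `dda_gene_panel`.
#' @export
load_panel <- function(path, name = NULL) {
  if (!file.exists(path)) stop("panel file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- trimws(lines[!grepl("^#", lines)])
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("load_panel: empty panel file ", path)
  gene_panel(name %||% tools::file_path_sans_ext(basename(path)), lines)
}

#' Write a gene panel to a newline-delimited list
#'
#' @param panel a `dda_gene_panel`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  writeLines(sort(panel$genes), path)
  invisible(path)
}

#' Restrict a filtered profile to a panel's gene set
#'
#' Emulates what a targeted panel would have seen: NGS-derived variants are
#' kept only when their gene is on the panel. Non-NGS findings (FISH, IHC,
#' MSI) are kept when `include_non_ngs` is `TRUE` — the scenario in which
#' the orthogonal tests are still performed alongside panel sequencing —
#' and dropped otherwise.
#'
#' @param profile a `dda_profile`.
#' @param panel a `dda_gene_panel`.
#' @param include_non_ngs logical.
#' @return A new `dda_profile` (the filter log records panel removals).
#' @export
downsample_profile <- function(profile, panel, include_non_ngs = TRUE) {
  keep <- toupper(profile$variants$gene) %in% panel$genes
  out <- profile
  out$variants <- profile$variants[keep, , drop = FALSE]
  rownames(out$variants) <- NULL
  out$non_ngs_findings <- if (include_non_ngs) profile$non_ngs_findings else
    profile$non_ngs_findings[0, , drop = FALSE]
  dropped <- profile$variants[!keep, , drop = FALSE]
  if (nrow(dropped))
    out$filter_log <- rbind(out$filter_log, data.frame(
      row_id = NA_integer_, gene = dropped$gene,
      alteration = dropped$alteration, status = "removed",
      reason = paste0("panel:", panel$name), stringsAsFactors = FALSE))
  out
}

#' Evaluate a panel against full-profile results
#'
#' Re-runs the scoring engine on each case's panel-restricted profile and
#' summarizes: actionability and resistance rates (VUS-inclusive,
#' all-evidence definitions), the fraction of cases whose full-profile
#' strongest driver gene is covered by the panel (non-NGS findings count as
#' covered when `include_non_ngs`), and MTB decision concordance — a
#' targeted decision is altered exactly when the panel does not cover the
#' gene the original recommendation was built on (unless rescued by a
#' non-NGS finding on that gene); standard and observation decisions are
#' never altered by downsampling.
#'
#' @param cases list of per-case lists with elements `profile`
#'   (`dda_profile`), `report` (full-profile `dda_case_report`) and
#'   `decision` (one-row MTB decision data.frame, may be `NULL`).
#' @param panel a `dda_gene_panel`.
#' @param kb a `dda_kb`.
#' @param params a [scoring_params()].
#' @param include_non_ngs logical.
#' @return One-row data.frame (`dda_panel_performance` fields).
#' @export
evaluate_panel <- function(cases, panel, kb, params = scoring_params(),
                           include_non_ngs = TRUE) {
  n <- length(cases)
  stopifnot(n > 0)
  actionable <- resistant <- covered <- concordant <- logical(n)
  has_decision <- logical(n)
  for (i in seq_len(n)) {
    cs <- cases[[i]]
    down <- downsample_profile(cs$profile, panel, include_non_ngs)
    rep_i <- build_case_report(down, kb, params)
    actionable[i] <- rep_i$actionable_vus_inclusive
    resistant[i] <- rep_i$resistant
    full_drivers <- cs$report$drivers
    if (nrow(full_drivers) == 0) {
      covered[i] <- TRUE  # nothing to miss
    } else {
      top_gene <- toupper(full_drivers$gene[1])
      non_ngs_genes <- toupper(cs$report$alterations$gene[
        cs$report$alterations$source == "non_ngs"])
      covered[i] <- top_gene %in% panel$genes ||
        (include_non_ngs && top_gene %in% non_ngs_genes)
    }
    dec <- cs$decision
    if (is.null(dec) || nrow(dec) == 0) {
      has_decision[i] <- FALSE
      concordant[i] <- NA
    } else {
      has_decision[i] <- TRUE
      if (dec$decision != "targeted" || is.na(dec$decision_driver_gene)) {
        concordant[i] <- TRUE
      } else {
        g <- toupper(dec$decision_driver_gene)
        non_ngs_genes <- toupper(cs$report$alterations$gene[
          cs$report$alterations$source == "non_ngs"])
        concordant[i] <- g %in% panel$genes ||
          (include_non_ngs && g %in% non_ngs_genes)
      }
    }
  }
  data.frame(
    panel_name = panel$name,
    n_cases = n,
    n_genes = length(panel$genes),
    actionability_rate = mean(actionable),
    resistance_rate = mean(resistant),
    top_driver_covered_rate = mean(covered),
    mtb_concordance_rate = if (any(has_decision))
      mean(concordant[has_decision]) else NA_real_,
    include_non_ngs = include_non_ngs,
    stringsAsFactors = FALSE)
}

#' Evaluate several panels into a comparison table
#'
#' @param cases as in [evaluate_panel()].
#' @param panels list of `dda_gene_panel` objects.
#' @param kb a `dda_kb`.
#' @param params a [scoring_params()].
#' @param modes logical vector of `include_non_ngs` settings to run.
#' @return data.frame, one row per panel x mode.
#' @export
evaluate_panels <- function(cases, panels, kb, params = scoring_params(),
                            modes = c(TRUE, FALSE)) {
  do.call(rbind, lapply(panels, function(p)
    do.call(rbind, lapply(modes, function(m)
      evaluate_panel(cases, p, kb, params, include_non_ngs = m)))))
}
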