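#' Assemble the per-case cohort table
#'
#' One row per case, carrying every report flag plus the top driver and top
#' compound AELs and (when provided) the MTB decision — the single source of
#' truth for every cohort-level statistic.
#'
#' @param reports list of `dda_case_report` objects.
#' @param decisions optional data.frame of MTB decisions (`case_id`,
#'   `decision`, `chosen_compound`, `decision_driver_gene`).
#' @return data.frame of class `dda_cohort_table`.
#' @export
cohort_table <- function(reports, decisions = NULL) {
  rows <- lapply(reports, function(r) data.frame(
    case_id = r$meta$case_id,
    tumor_type = r$meta$tumor_type,
    year = r$meta$year,
    actionable_driver_based = r$actionable_driver_based,
    actionable_vus_inclusive = r$actionable_vus_inclusive,
    actionable_preclinical_plus = r$actionable_preclinical_plus,
    actionable_clinical_only = r$actionable_clinical_only,
    resistant = r$resistant,
    escat_tier = r$escat_tier,
    n_associated_registered_drugs = r$n_associated_registered_drugs,
    n_drivers = nrow(r$drivers),
    top_driver_ael = r$top_driver_ael,
    top_compound_ael = r$top_compound_ael,
    top_compound_id = r$top_compound_id,
    stringsAsFactors = FALSE))
  tab <- do.call(rbind, rows)
  if (anyDuplicated(tab$case_id)) stop("cohort_table: duplicate case ids")
  if (!is.null(decisions)) {
    m <- match(tab$case_id, decisions$case_id)
    tab$decision <- decisions$decision[m]
    tab$chosen_compound <- decisions$chosen_compound[m]
    tab$decision_driver_gene <- decisions$decision_driver_gene[m]
  } else {
    tab$decision <- NA_character_
    tab$chosen_compound <- NA_character_
    tab$decision_driver_gene <- NA_character_
  }
  rownames(tab) <- NULL
  class(tab) <- c("dda_cohort_table", "data.frame")
  tab
}

#' Actionability rate by group
#'
#' @param cohort a [cohort_table()].
#' @param group_key `"year"` or `"tumor_type"`.
#' @param flag which actionability flag to rate.
#' @return data.frame of (group, actionable_fraction, n); empty groups are
#'   omitted.
#' @export
actionability_by_group <- function(cohort,
                                   group_key = c("year", "tumor_type"),
                                   flag = "actionable_driver_based") {
  group_key <- match.arg(group_key)
  g <- cohort[[group_key]]
  keep <- !is.na(g)
  g <- g[keep]; f <- cohort[[flag]][keep]
  if (!length(g))
    return(data.frame(group = character(), actionable_fraction = numeric(),
                      n = integer(), stringsAsFactors = FALSE))
  agg <- tapply(f, g, mean)
  n <- tapply(f, g, length)
  out <- data.frame(group = names(agg),
                    actionable_fraction = as.numeric(agg),
                    n = as.integer(n), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Two-sided Mann-Whitney U test
#'
#' U is computed from rank sums over the pooled values (average ranks for
#' ties). The p-value is exact (full enumeration) when both groups have at
#' most 8 observations and there are no ties, and otherwise uses the normal
#' approximation with tie and continuity corrections; `method` records
#' which path ran.
#'
#' @param group_a,group_b numeric vectors (both non-empty).
#' @return list of class `dda_test_result`: `statistic` (U of `group_a`),
#'   `p_value`, `method`, `n_per_group`.
#' @export
mann_whitney_u <- function(group_a, group_b) {
  if (!length(group_a) || !length(group_b))
    stop("mann_whitney_u: both groups must be non-empty")
  n1 <- length(group_a); n2 <- length(group_b)
  ranks <- rank(c(group_a, group_b))
  u <- sum(ranks[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(group_a, group_b)) > 0
  exact <- n1 <= 8 && n2 <= 8 && !ties
  p <- suppressWarnings(stats::wilcox.test(
    group_a, group_b, exact = exact, correct = TRUE,
    alternative = "two.sided"))$p.value
  structure(list(statistic = u, p_value = min(p, 1),
                 method = if (exact) "exact" else "normal_approx",
                 n_per_group = c(n1, n2)),
            class = "dda_test_result")
}

#' Pearson chi-square test on a contingency table
#'
#' @param tab numeric matrix of observed counts.
#' @return `dda_test_result` with the X-squared statistic and p-value.
#' @export
chi_square_test <- function(tab) {
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  structure(list(statistic = unname(res$statistic),
                 p_value = unname(res$p.value),
                 method = "pearson_chi_square",
                 n_per_group = rowSums(tab)),
            class = "dda_test_result")
}

#' @export
print.dda_test_result <- function(x, ...) {
  cat(sprintf("<%s> statistic = %.4g, p = %.4g (n = %s)\n", x$method,
              x$statistic, x$p_value, paste(x$n_per_group, collapse = "/")))
  invisible(x)
}

#' AEL-quartile by MTB-decision contingency analysis
#'
#' Cases with a targeted or standard decision (observation-only cases are
#' excluded from the denominator) are binned into four groups of similar
#' population density by the empirical quartiles of their top-compound net
#' AEL; values exactly on a boundary go to the lower bin, and cases with no
#' ranked compound enter the lowest bin with AEL 0. A Pearson chi-square
#' tests independence of bin and decision.
#'
#' @param cohort a [cohort_table()] with a `decision` column.
#' @return list: `table` (4 x 2 observed counts), `test`
#'   (`dda_test_result`), `bins` (per-case bin assignment), `note`
#'   (degrees-of-freedom note when a bin is empty, else `NULL`).
#' @export
ael_quartile_decision_table <- function(cohort) {
  keep <- cohort$decision %in% c("targeted", "standard")
  d <- cohort[keep, , drop = FALSE]
  if (nrow(d) < 8)
    stop("ael_quartile_decision_table: need at least 8 targeted/standard cases")
  ael <- d$top_compound_ael
  ael[is.na(ael)] <- 0
  qs <- stats::quantile(ael, probs = c(0.25, 0.5, 0.75), type = 7)
  breaks <- unique(c(-Inf, qs, Inf))
  bins <- cut(ael, breaks = breaks, labels = FALSE, right = TRUE)
  bins <- factor(paste0("Q", bins), levels = paste0("Q", seq_len(length(breaks) - 1)))
  tab <- table(bin = bins, decision = factor(d$decision,
                                             levels = c("standard", "targeted")))
  note <- NULL
  if (any(rowSums(tab) == 0))
    note <- sprintf("empty AEL bin(s): %s; chi-square df reduced accordingly",
                    paste(rownames(tab)[rowSums(tab) == 0], collapse = ", "))
  test <- chi_square_test(tab[rowSums(tab) > 0, , drop = FALSE])
  list(table = tab, test = test, bins = bins, note = note)
}

#' Driver landscape tally
#'
#' Counts, for each gene and tumor group, the number of cases carrying at
#' least one driver alteration in that gene, with alteration types
#' preserved as categories; genes missing from the pathway map land in
#' bucket `"other"`.
#'
#' @param reports list of `dda_case_report` objects.
#' @param tumor_group_map named character vector: tumor-type code -> group
#'   label (unmapped types keep their own code).
#' @param pathway_map named character vector: gene symbol -> pathway label.
#' @return data.frame: `gene`, `pathway`, `tumor_group`, `variant_types`,
#'   `n_cases`.
#' @export
driver_landscape_tally <- function(reports, tumor_group_map = character(),
                                   pathway_map = character()) {
  rows <- list()
  for (r in reports) {
    d <- r$drivers
    if (is.null(d) || nrow(d) == 0) next
    tt <- r$meta$tumor_type
    grp <- if (tt %in% names(tumor_group_map)) tumor_group_map[[tt]] else tt
    for (g in unique(d$gene)) {
      vt <- sort(unique(d$variant_type[d$gene == g]))
      rows[[length(rows) + 1L]] <- data.frame(
        case_id = r$meta$case_id, gene = g, tumor_group = grp,
        variant_types = paste(vt, collapse = ","), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(gene = character(), pathway = character(),
                      tumor_group = character(), variant_types = character(),
                      n_cases = integer(), stringsAsFactors = FALSE))
  flat <- do.call(rbind, rows)
  key <- paste(flat$gene, flat$tumor_group, sep = "\r")
  n <- tapply(flat$case_id, key, function(x) length(unique(x)))
  vt <- tapply(flat$variant_types, key, function(x)
    paste(sort(unique(unlist(strsplit(x, ",")))), collapse = ","))
  parts <- strsplit(names(n), "\r", fixed = TRUE)
  gene <- vapply(parts, `[`, "", 1)
  out <- data.frame(
    gene = gene,
    pathway = ifelse(gene %in% names(pathway_map),
                     unname(pathway_map[gene]), "other"),
    tumor_group = vapply(parts, `[`, "", 2),
    variant_types = as.character(vt),
    n_cases = as.integer(n), stringsAsFactors = FALSE)
  out <- out[order(out$tumor_group, -out$n_cases, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  if (any(out$pathway == "other") && length(pathway_map))
    message("driver_landscape_tally: unmapped gene(s) bucketed as 'other': ",
            paste(unique(out$gene[out$pathway == "other"]), collapse = ", "))
  out
}
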