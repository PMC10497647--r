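#' ESCAT tier of one positive evidence link
#'
#' Maps one sensitivity evidence item to the ESMO Scale for Clinical
#' Actionability of molecular Targets, using the four coarse tiers:
#' tier I — the compound is approved for this biomarker in the case's own
#' indication (approved-class evidence plus indication match); tier II —
#' clinical evidence in the same tumor type; tier III — clinical evidence
#' in another (or unspecified) tumor type; tier IV — preclinical evidence,
#' including indirect (target-routed) preclinical links; `none` — only
#' in-silico or frequency support. Resistance (direction -1) evidence has
#' no sensitivity tier and raises an error.
#'
#' @param item list or one-row data.frame with `direction`,
#'   `evidence_class`, `tumor_type`.
#' @param compound one-row slice of `kb$compounds` (needs `registered` and
#'   `approved_indications`).
#' @param case_tumor_type the case's tumor-type code.
#' @return One of `"I"`, `"II"`, `"III"`, `"IV"`, `"none"`.
#' @export
classify_evidence_escat <- function(item, compound, case_tumor_type) {
  if (item$direction == -1L)
    stop("resistance_not_tiered: direction=-1 evidence has no ESCAT sensitivity tier")
  cls <- item$evidence_class
  same <- !is.na(item$tumor_type) && item$tumor_type == case_tumor_type
  indications <- split_csv_field(compound$approved_indications)
  if (cls == "clinical_approved" && case_tumor_type %in% indications) return("I")
  if (cls %in% CLINICAL_CLASSES) return(if (same) "II" else "III")
  if (cls == "preclinical") return("IV")
  "none"
}

# Tier every positive (driver, registered compound) link of a case and keep
# the best; vectorized version of classify_evidence_escat.
escat_tier_from_links <- function(links, kb, case_tumor_type) {
  reg <- registered_compounds(kb)
  l <- links[links$direction == 1L & links$alteration_class == "driver" &
               links$compound_id %in% reg, , drop = FALSE]
  if (nrow(l) == 0) return("none")
  ind <- stats::setNames(kb$compounds$approved_indications, kb$compounds$id)
  has_ind <- vapply(l$compound_id, function(id)
    case_tumor_type %in% split_csv_field(ind[[id]]), TRUE)
  same <- !is.na(l$item_tumor_type) & l$item_tumor_type == case_tumor_type
  tier <- rep("none", nrow(l))
  tier[l$evidence_class == "preclinical"] <- "IV"
  tier[l$evidence_class %in% CLINICAL_CLASSES & !same] <- "III"
  tier[l$evidence_class %in% CLINICAL_CLASSES & same] <- "II"
  tier[l$evidence_class == "clinical_approved" & has_ind] <- "I"
  ESCAT_LEVELS[min(match(tier, ESCAT_LEVELS))]
}

#' Best ESCAT tier of a case
#'
#' The strongest (lowest-ordinal) tier over all positively-tiered
#' (driver, registered compound) evidence links of the case; `"none"` when
#' no tiered evidence exists.
#'
#' @param report a `dda_case_report`.
#' @param kb the knowledgebase the report was built against; when omitted
#'   the tier stored on the report is returned.
#' @return One of `"I"`, `"II"`, `"III"`, `"IV"`, `"none"`.
#' @export
case_escat_tier <- function(report, kb = NULL) {
  if (is.null(kb)) return(report$escat_tier)
  escat_tier_from_links(report$links, kb, report$meta$tumor_type)
}

#' Cumulative actionability over ESCAT tier sets
#'
#' Fraction of cases whose tier falls in the included set; used to report
#' nested cumulative rates for tier sets such as \{II\}, \{II, III\},
#' \{II, III, IV\}.
#'
#' @param tiers character vector of per-case tiers.
#' @param included character vector of tiers to count; empty set gives 0.
#' @return Fraction in `[0, 1]`.
#' @export
cumulative_actionability <- function(tiers, included) {
  stopifnot(length(tiers) > 0, all(tiers %in% ESCAT_LEVELS))
  if (length(included) == 0) return(0)
  mean(tiers %in% included)
}

#' ESCAT cohort summary
#'
#' @param tiers character vector of per-case tiers.
#' @return data.frame with tier counts and the nested cumulative
#'   actionability fractions for \{II\}, \{II,III\}, \{II,III,IV\}.
#' @export
escat_summary <- function(tiers) {
  counts <- table(factor(tiers, levels = ESCAT_LEVELS))
  data.frame(
    tier_set = c("II", "II/III", "II/III/IV"),
    cumulative_actionability = c(
      cumulative_actionability(tiers, "II"),
      cumulative_actionability(tiers, c("II", "III")),
      cumulative_actionability(tiers, c("II", "III", "IV"))),
    n_cases = length(tiers),
    stringsAsFactors = FALSE)
}
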