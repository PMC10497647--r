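actionability_class_sets <- list(
  all = EVIDENCE_CLASSES,
  preclinical_plus = c("clinical_approved", "clinical", "preclinical"),
  clinical_only = c("clinical_approved", "clinical"))

# Core actionability predicate over a case link table.
actionable_from_links <- function(links, registered_ids,
                                  mode = c("driver_only", "vus_inclusive"),
                                  evidence_filter = c("all", "preclinical_plus",
                                                      "clinical_only")) {
  mode <- match.arg(mode)
  evidence_filter <- match.arg(evidence_filter)
  allowed_alt <- if (mode == "driver_only") "driver" else
    c("driver", "vus_in_driver_gene")
  allowed_cls <- actionability_class_sets[[evidence_filter]]
  any(links$direction == 1L &
        links$compound_id %in% registered_ids &
        links$alteration_class %in% allowed_alt &
        links$evidence_class %in% allowed_cls)
}

#' Assess case actionability
#'
#' A case is actionable when at least one alteration of the allowed
#' classification set (drivers only, or drivers plus VUS-in-driver-gene) is
#' linked by at least one positive evidence item of an allowed evidence
#' class to a registered compound (approved on- or off-label; developmental
#' compounds never confer actionability). The evidence filters narrow the
#' link classes: `clinical_only` = clinical/approved evidence,
#' `preclinical_plus` adds preclinical, `all` additionally counts in-silico
#' and frequency evidence. The definitions nest: `clinical_only` implies
#' `preclinical_plus` implies `all`.
#'
#' @param report a `dda_case_report` from [build_case_report()].
#' @param mode `"driver_only"` or `"vus_inclusive"`.
#' @param evidence_filter `"all"`, `"preclinical_plus"` or `"clinical_only"`.
#' @return Logical scalar.
#' @export
assess_actionability <- function(report,
                                 mode = c("driver_only", "vus_inclusive"),
                                 evidence_filter = c("all", "preclinical_plus",
                                                     "clinical_only")) {
  actionable_from_links(report$links, report$registered_ids,
                        match.arg(mode), match.arg(evidence_filter))
}

#' Count registered drugs associated with a case
#'
#' Distinct registered compounds with at least one positive or negative
#' evidence link to any driver or VUS-in-driver alteration of the case.
#'
#' @param report a `dda_case_report`.
#' @return Non-negative integer.
#' @export
count_associated_registered_drugs <- function(report) {
  l <- report$links
  length(unique(l$compound_id[l$compound_id %in% report$registered_ids &
                                l$alteration_class %in%
                                  c("driver", "vus_in_driver_gene")]))
}

#' Build the full per-case report
#'
#' Composes the whole per-case analysis: alteration classification, driver
#' and compound ranking, resistance pairs, the four actionability flags,
#' the ESCAT tier and the associated-drug count. Deterministic given
#' profile, knowledgebase and parameters.
#'
#' @param profile a `dda_profile` from [run_filter_pipeline()].
#' @param kb a `dda_kb`.
#' @param params a [scoring_params()].
#' @return A `dda_case_report` list.
#' @export
build_case_report <- function(profile, kb, params = scoring_params()) {
  alterations <- classify_profile_alterations(profile, kb, params)
  links <- case_compound_links(kb, alterations, profile$meta$tumor_type, params)
  reg <- registered_compounds(kb)
  drivers <- rank_drivers(profile, kb, params, alterations = alterations)
  compounds <- rank_compounds(profile, kb, params, alterations = alterations,
                              links = links)
  resistance <- detect_resistance(profile, kb, params,
                                  alterations = alterations, links = links)
  report <- structure(list(
    meta = profile$meta,
    alterations = alterations,
    drivers = drivers,
    compounds = compounds,
    resistance_pairs = resistance,
    links = links,
    registered_ids = reg,
    actionable_driver_based = actionable_from_links(links, reg, "driver_only", "all"),
    actionable_vus_inclusive = actionable_from_links(links, reg, "vus_inclusive", "all"),
    actionable_preclinical_plus = actionable_from_links(links, reg, "driver_only", "preclinical_plus"),
    actionable_clinical_only = actionable_from_links(links, reg, "driver_only", "clinical_only"),
    resistant = nrow(resistance) > 0,
    escat_tier = NA_character_,
    n_associated_registered_drugs = 0L,
    top_driver_ael = if (nrow(drivers)) drivers$ael_net[1] else 0,
    top_compound_ael = if (nrow(compounds)) compounds$ael_net[1] else 0,
    top_compound_id = if (nrow(compounds)) compounds$compound_id[1] else NA_character_),
    class = "dda_case_report")
  report$n_associated_registered_drugs <- count_associated_registered_drugs(report)
  report$escat_tier <- case_escat_tier(report, kb)
  report
}

#' @export
print.dda_case_report <- function(x, ...) {
  cat(sprintf("<dda_case_report %s/%s> %d drivers, %d ranked compounds, ESCAT %s\n",
              x$meta$case_id, x$meta$tumor_type, nrow(x$drivers),
              nrow(x$compounds), x$escat_tier))
  cat(sprintf("  actionable: driver=%s vus=%s preclin+=%s clinical=%s; resistant=%s; %d associated drugs\n",
              x$actionable_driver_based, x$actionable_vus_inclusive,
              x$actionable_preclinical_plus, x$actionable_clinical_only,
              x$resistant, x$n_associated_registered_drugs))
  invisible(x)
}

#' One MTB decision record
#'
#' @param case_id case identifier.
#' @param decision `"targeted"`, `"standard"` or `"observation"`.
#' @param chosen_compound compound id (required for targeted decisions).
#' @param decision_driver_gene gene the recommendation was built on.
#' @return A one-row data.frame.
#' @export
mtb_decision <- function(case_id, decision = c("targeted", "standard",
                                               "observation"),
                         chosen_compound = NA_character_,
                         decision_driver_gene = NA_character_) {
  decision <- match.arg(decision)
  if (decision == "targeted" && is.na(chosen_compound))
    stop("mtb_decision: targeted decision requires chosen_compound")
  data.frame(case_id = case_id, decision = decision,
             chosen_compound = chosen_compound,
             decision_driver_gene = decision_driver_gene,
             stringsAsFactors = FALSE)
}

#' Serialize a case report to JSON
#'
#' @param report a `dda_case_report`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_case_report <- function(report, path) {
  x <- unclass(report)
  x$meta <- unclass(x$meta)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", na = "null", pretty = TRUE)
  invisible(path)
}

#' Read back a serialized case report
#'
#' @param path JSON file written by [write_case_report()].
#' @return A `dda_case_report`.
#' @export
read_case_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$meta <- structure(x$meta, class = "dda_sample_meta")
  for (nm in c("alterations", "drivers", "compounds", "resistance_pairs", "links"))
    x[[nm]] <- as.data.frame(x[[nm]], stringsAsFactors = FALSE)
  structure(x, class = "dda_case_report")
}
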