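#' Synthetic cohort configuration
#'
#' The defaults describe the emulated study population: 100 high-risk
#' pediatric cases with tumor-type mix CNS 38\%, sarcoma 28\%, neuroblastoma
#' 18\%, other solid 11\%, hematologic 5\%; on average 52 variants per case
#' surviving the filter pipeline, of which about 3 are proven drivers and 6
#' are VUS in driver genes. The decision model is logistic in
#' `log(1 + top compound AEL)`: the study reports a monotone association
#' between AEL and targeted tumor-board decisions, not a functional form;
#' the log damps the influence of a few very large AELs.
#'
#' @param seed integer master seed; per-stage child seeds are derived from
#'   it (see [derive_seed()]).
#' @param n_cases number of cases.
#' @param tumor_type_mix named probability vector over tumor-type codes.
#' @param mean_filtered_variants Poisson mean of post-filter variant counts.
#' @param mean_drivers Poisson mean of planted proven drivers per case.
#' @param mean_vus_drivers Poisson mean of planted VUS-in-driver-gene per
#'   case.
#' @param mean_failing_variants Poisson mean of planted QC/annotation
#'   failures per case (exercise every filter rule).
#' @param low_burden_prob probability a case is driver-poor (no proven
#'   drivers, very few VUS). Pediatric tumors are frequently low-burden and
#'   the emulated cohort was not fully actionable (72\% driver-based, 83\%
#'   VUS-inclusive); the non-low-burden means are inflated so the
#'   cohort-wide driver and VUS means stay at their configured values.
#' @param evidence_class_mix named probability vector over evidence classes
#'   for generated compound links.
#' @param resistance_edge_prob probability a generated compound link is a
#'   resistance (direction -1) edge.
#' @param untargetable_fraction fraction of driver genes with no compound or
#'   target links at all — proven drivers in untargetable genes are a real
#'   feature of the emulated cohort.
#' @param evidence_richness_sdlog log-sd of the per-gene evidence-richness
#'   factor: well-studied hotspot genes carry many strong links, rare
#'   drivers few weak ones, spreading compound AELs over orders of
#'   magnitude as observed.
#' @param registered_fraction fraction of generated compounds that are
#'   registered.
#' @param approved_indication_prob probability a registered compound gets an
#'   approved indication; 0 by default — the emulated cohort contained no
#'   on-indication (ESCAT I) approvals.
#' @param decision_logit numeric `c(alpha, beta)` of the targeted-decision
#'   model.
#' @param observation_prob probability a case gets an observation-only
#'   recommendation (the study had one such case in 100).
#' @param fish_positive_prob probability a case has a positive FISH
#'   amplification finding (5 of ~80 in the study).
#' @param n_driver_genes,n_target_genes,n_compounds,n_panel_genes,n_offpanel_genes
#'   knowledgebase dimensions; the interpretation list defaults to 995
#'   genes.
#' @return A `dda_synth_config` list.
#' @export
synth_config <- function(seed = 1L,
                         n_cases = 100L,
                         tumor_type_mix = c(CNS = 0.38, sarcoma = 0.28,
                                            neuroblastoma = 0.18,
                                            other_solid = 0.11,
                                            hematologic = 0.05),
                         mean_filtered_variants = 52,
                         mean_drivers = 3,
                         mean_vus_drivers = 6,
                         mean_failing_variants = 25,
                         low_burden_prob = 0.15,
                         evidence_class_mix = c(clinical_approved = 0.05,
                                                clinical = 0.25,
                                                preclinical = 0.40,
                                                in_silico = 0.20,
                                                frequency = 0.10),
                         resistance_edge_prob = 0.25,
                         untargetable_fraction = 0.25,
                         evidence_richness_sdlog = 1.25,
                         registered_fraction = 0.6,
                         approved_indication_prob = 0,
                         decision_logit = c(alpha = -2, beta = 1.5),
                         observation_prob = 0.01,
                         fish_positive_prob = 0.05,
                         n_driver_genes = 60L,
                         n_target_genes = 30L,
                         n_compounds = 80L,
                         n_panel_genes = 995L,
                         n_offpanel_genes = 120L) {
  stopifnot(abs(sum(tumor_type_mix) - 1) < 1e-9,
            abs(sum(evidence_class_mix) - 1) < 1e-9,
            mean_filtered_variants > 0, mean_drivers > 0, mean_vus_drivers > 0,
            resistance_edge_prob >= 0, resistance_edge_prob <= 1,
            registered_fraction >= 0, registered_fraction <= 1,
            length(decision_logit) == 2)
  structure(as.list(environment()), class = "dda_synth_config")
}

#' Derive a child seed from a master seed and a stage label
#'
#' A documented deterministic fan-out so each pipeline stage is
#' independently reproducible from the one master seed. The result is a
#' positive integer below 2^31.
#'
#' @param seed integer master seed.
#' @param salt stage label string.
#' @return Integer child seed.
#' @export
derive_seed <- function(seed, salt) {
  h <- sum(utf8ToInt(salt) * seq_along(utf8ToInt(salt)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483629)
}

sample_class <- function(n, mix) {
  sample(names(mix), n, replace = TRUE, prob = mix)
}

#' Generate a synthetic evidence knowledgebase
#'
#' Builds a knowledgebase with the structure the scoring engine expects:
#' driver genes carrying gene-level oncogenicity evidence plus two exact
#' hotspot alterations each whose evidence guarantees a net oncogenicity
#' AEL above the driver threshold in any tumor-type context; a subset of
#' driver genes amplification-capable (exact `"amplification"` evidence,
#' the FISH-detectable lesions); target genes routed from drivers; and
#' registered plus developmental compounds connected by positive and
#' resistance edges at the configured class mix and rates. Off-panel genes
#' carry the `OFFP` prefix so the interpretation list is derivable from
#' the knowledgebase alone (see [virtual_panel_genes()]).
#'
#' @param config a [synth_config()].
#' @param seed integer; defaults to the config's master seed.
#' @return A validated `dda_kb`.
#' @export
generate_knowledgebase <- function(config, seed = config$seed) {
  set.seed(derive_seed(seed, "knowledgebase"))
  tt <- names(config$tumor_type_mix)
  drv <- sprintf("DG%03d", seq_len(config$n_driver_genes))
  tgt <- sprintf("TG%03d", seq_len(config$n_target_genes))
  n_pass <- max(0L, config$n_panel_genes - length(drv) - length(tgt))
  pass <- sprintf("PG%04d", seq_len(n_pass))
  offp <- sprintf("OFFP%03d", seq_len(config$n_offpanel_genes))
  symbols <- c(drv, tgt, pass, offp)
  aliases <- rep("", length(symbols))
  aliases[seq_len(5)] <- paste0(symbols[seq_len(5)], "-ALIAS")
  genes <- data.frame(symbol = symbols, aliases = aliases,
                      stringsAsFactors = FALSE)

  n_cp <- config$n_compounds
  registered <- seq_len(n_cp) <= round(config$registered_fraction * n_cp)
  indications <- ifelse(registered &
                          stats::runif(n_cp) < config$approved_indication_prob,
                        sample(tt, n_cp, replace = TRUE), "")
  compounds <- data.frame(
    id = sprintf("C%03d", seq_len(n_cp)),
    name = sprintf("compound_%03d", seq_len(n_cp)),
    registered = registered,
    approved_indications = indications, stringsAsFactors = FALSE)

  ev <- list()
  eid <- 0L
  add <- function(subject_gene, subject_alteration, object_kind, object_id,
                  direction, evidence_class, tumor_type, base_reliability) {
    eid <<- eid + 1L
    ev[[eid]] <<- data.frame(
      id = sprintf("E%05d", eid), subject_gene = subject_gene,
      subject_alteration = subject_alteration, object_kind = object_kind,
      object_id = object_id, direction = as.integer(direction),
      evidence_class = evidence_class, tumor_type = tumor_type,
      base_reliability = base_reliability,
      source_ref = sprintf("synthetic:%05d", eid), stringsAsFactors = FALSE)
  }
  amp_capable <- drv[seq_len(min(5L, length(drv)))]
  untargetable <- drv[stats::runif(length(drv)) < config$untargetable_fraction]
  richness <- stats::setNames(
    stats::rlnorm(length(drv), 0, config$evidence_richness_sdlog), drv)
  for (g in drv) {
    # gene-level oncogenicity (supports the VUS-in-driver-gene class)
    add(g, NA, "oncogenicity", NA, 1L,
        sample(c("preclinical", "clinical"), 1), NA, NA)
    # two hotspots; two tumor-agnostic clinical items of base 6 give
    # 2 x (6 x 1 x 2) = 24 > 20 net AEL whatever the case tumor type
    hotspots <- sprintf("p.%s%d%s", sample(LETTERS, 2, TRUE),
                        sample(100:900, 2), sample(LETTERS, 2, TRUE))
    for (h in unique(hotspots)) {
      add(g, h, "oncogenicity", NA, 1L, "clinical", NA, 6)
      add(g, h, "oncogenicity", NA, 1L, "clinical", NA, 6)
      if (stats::runif(1) < 0.5)
        add(g, h, "oncogenicity", NA, 1L, "preclinical", sample(tt, 1), NA)
    }
    if (g %in% amp_capable) {
      add(g, "amplification", "oncogenicity", NA, 1L, "clinical", NA, 6)
      add(g, "amplification", "oncogenicity", NA, 1L, "clinical", NA, 6)
    }
    if (g %in% untargetable) next  # proven driver, nothing to target
    # driver -> target routing
    for (t in sample(tgt, sample(1:2, 1)))
      add(g, NA, "target", t, 1L, "preclinical", NA, NA)
    # direct gene-level compound links; count scales with the gene's
    # evidence richness, strength is calibrated so that per-case top
    # compound AELs land where the decision logit reproduces the emulated
    # cohort's targeted-decision rate (see the methods vignette)
    n_links <- 1L + stats::rpois(1, richness[[g]])
    cps <- sample(compounds$id, min(n_links, nrow(compounds)))
    for (cp in cps) {
      dir <- if (stats::runif(1) < config$resistance_edge_prob) -1L else 1L
      cls <- sample_class(1, config$evidence_class_mix)
      tumor <- if (stats::runif(1) < 0.5) sample(tt, 1) else NA
      base <- round(unname(scoring_params()$class_base_scores[cls]) *
                      stats::runif(1, 0.3, 1.2), 2)
      add(g, NA, "compound", cp, dir, cls, tumor, max(base, 0.1))
    }
    # one exact-alteration compound link per first hotspot (tier II/III fodder)
    if (stats::runif(1) < 0.6)
      add(g, hotspots[1], "compound", sample(compounds$id, 1), 1L,
          "clinical", sample(c(sample(tt, 1), NA), 1), NA)
  }
  for (t in tgt) {
    # gene-level target -> compound edges (the indirect route's second leg)
    for (cp in sample(compounds$id, sample(1:2, 1))) {
      dir <- if (stats::runif(1) < config$resistance_edge_prob) -1L else 1L
      cls <- sample_class(1, config$evidence_class_mix)
      base <- round(unname(scoring_params()$class_base_scores[cls]) *
                      stats::runif(1, 0.3, 1.2), 2)
      add(t, NA, "compound", cp, dir, cls,
          if (stats::runif(1) < 0.3) sample(tt, 1) else NA, max(base, 0.1))
    }
  }
  knowledgebase(genes, compounds, do.call(rbind, ev),
                version = sprintf("synthetic-%d", seed), tumor_types = tt)
}

#' Interpretation gene list of a synthetic knowledgebase
#'
#' All knowledgebase genes except the deliberately off-panel ones
#' (`OFFP` prefix); stands in for the ~995-gene virtual panel.
#'
#' @param kb a `dda_kb` from [generate_knowledgebase()].
#' @return Character vector of gene symbols.
#' @export
virtual_panel_genes <- function(kb) {
  kb$genes$symbol[!grepl("^OFFP", kb$genes$symbol)]
}

# Known exact hotspot alterations of the knowledgebase: one row per
# (gene, alteration) with exact positive oncogenicity evidence.
kb_hotspots <- function(kb) {
  ev <- kb$evidence
  h <- ev[ev$object_kind == "oncogenicity" & !is.na(ev$subject_alteration) &
            ev$direction == 1L, c("subject_gene", "subject_alteration")]
  unique(h)
}

kb_driver_genes <- function(kb) {
  ev <- kb$evidence
  unique(ev$subject_gene[ev$object_kind == "oncogenicity" &
                           is.na(ev$subject_alteration) & ev$direction == 1L])
}

passing_qc <- function(n) {
  data.frame(depth = sample(40:250, n, replace = TRUE),
             quality = round(stats::runif(n, 30, 60), 1),
             alt_allele_fraction = round(stats::runif(n, 0.10, 0.60), 3),
             pop_freq_1kg = NA_real_, pop_freq_exac = NA_real_,
             pop_freq_esp = NA_real_, stringsAsFactors = FALSE)
}

#' Generate a synthetic case cohort
#'
#' Per case: planted proven drivers (known hotspots), planted VUS in driver
#' genes (novel alterations), and panel-gene passengers, all with QC fields
#' drawn from the passing component so the planted variants survive
#' filtering by construction; plus a Poisson number of deliberate failures,
#' one per filter rule (low depth, low quality, low allele fraction, common
#' polymorphism, benign ACMG class, off-panel gene) so the filter log is
#' exercised on every case. Occasional positive FISH amplification findings
#' on amplification-capable driver genes emulate the orthogonal assays; MSI
#' is stable throughout, as in the emulated cohort.
#'
#' @param config a [synth_config()].
#' @param kb the matching [generate_knowledgebase()] output.
#' @param seed integer; defaults to the config's master seed.
#' @return List of per-case lists: `variants` (raw annotated table),
#'   `meta` ([sample_meta()]), `fish_calls`, `ihc_calls`, `msi`.
#' @export
generate_cohort <- function(config, kb, seed = config$seed) {
  set.seed(derive_seed(seed, "cohort"))
  hot <- kb_hotspots(kb)
  drv_genes <- kb_driver_genes(kb)
  panel <- virtual_panel_genes(kb)
  passenger_pool <- setdiff(panel, drv_genes)
  offpanel_pool <- setdiff(kb$genes$symbol, panel)
  tt <- names(config$tumor_type_mix)
  amp_genes <- unique(kb$evidence$subject_gene[
    !is.na(kb$evidence$subject_alteration) &
      kb$evidence$subject_alteration == "amplification"])

  lapply(seq_len(config$n_cases), function(i) {
    meta <- sample_meta(
      case_id = sprintf("CASE%03d", i),
      tumor_type = sample(tt, 1, prob = config$tumor_type_mix),
      tumor_cell_ratio = round(stats::runif(1, 0.35, 0.95), 2),
      year = sample(2017:2020, 1), test_type = "WES")

    p_low <- config$low_burden_prob
    if (stats::runif(1) < p_low) {
      k_d <- 0L
      k_v <- stats::rpois(1, 0.5)
    } else {
      # inflate so the cohort-wide means remain at the configured values
      k_d <- stats::rpois(1, config$mean_drivers / (1 - p_low))
      k_v <- stats::rpois(1, (config$mean_vus_drivers - 0.5 * p_low) / (1 - p_low))
    }
    k_total <- stats::rpois(1, config$mean_filtered_variants)
    k_p <- max(0L, k_total - k_d - k_v)

    rows <- list()
    if (k_d > 0) {
      idx <- sample(nrow(hot), min(k_d, nrow(hot)))
      rows$drivers <- cbind(
        data.frame(gene = hot$subject_gene[idx],
                   alteration = hot$subject_alteration[idx],
                   variant_type = "SNV", stringsAsFactors = FALSE),
        passing_qc(length(idx)),
        data.frame(acmg_class = sample(c("pathogenic", "likely_pathogenic", "vus"),
                                       length(idx), TRUE, prob = c(0.4, 0.3, 0.3)),
                   stringsAsFactors = FALSE))
    }
    if (k_v > 0) {
      rows$vus <- cbind(
        data.frame(gene = sample(drv_genes, k_v, replace = TRUE),
                   alteration = sprintf("p.V%dX", sample(1000:9999, k_v)),
                   variant_type = sample(c("SNV", "indel"), k_v, TRUE,
                                         prob = c(0.85, 0.15)),
                   stringsAsFactors = FALSE),
        passing_qc(k_v),
        data.frame(acmg_class = "vus", stringsAsFactors = FALSE))
    }
    if (k_p > 0) {
      rows$passengers <- cbind(
        data.frame(gene = sample(passenger_pool, k_p, replace = TRUE),
                   alteration = sprintf("p.P%dY", sample(1000:9999, k_p)),
                   variant_type = sample(c("SNV", "indel"), k_p, TRUE,
                                         prob = c(0.85, 0.15)),
                   stringsAsFactors = FALSE),
        passing_qc(k_p),
        data.frame(acmg_class = sample(c("vus", "unclassified"), k_p, TRUE),
                   stringsAsFactors = FALSE))
    }
    k_f <- stats::rpois(1, config$mean_failing_variants)
    if (k_f > 0) {
      modes <- sample(c("depth", "quality", "vaf", "pop_freq", "acmg", "panel"),
                      k_f, replace = TRUE)
      f <- cbind(
        data.frame(gene = sample(panel, k_f, replace = TRUE),
                   alteration = sprintf("p.F%dZ", sample(1000:9999, k_f)),
                   variant_type = "SNV", stringsAsFactors = FALSE),
        passing_qc(k_f),
        data.frame(acmg_class = "vus", stringsAsFactors = FALSE))
      f$depth[modes == "depth"] <- sample(1:20, sum(modes == "depth"), TRUE)
      f$quality[modes == "quality"] <- round(stats::runif(sum(modes == "quality"), 1, 19.9), 1)
      f$alt_allele_fraction[modes == "vaf"] <-
        round(stats::runif(sum(modes == "vaf"), 0, 0.009), 4)
      f$pop_freq_exac[modes == "pop_freq"] <-
        round(stats::runif(sum(modes == "pop_freq"), 0.10, 0.60), 3)
      f$acmg_class[modes == "acmg"] <-
        sample(c("benign", "likely_benign"), sum(modes == "acmg"), TRUE)
      if (any(modes == "panel") && length(offpanel_pool))
        f$gene[modes == "panel"] <- sample(offpanel_pool,
                                           sum(modes == "panel"), TRUE)
      rows$failing <- f
    }
    variants <- do.call(rbind, rows)
    if (is.null(variants)) variants <- variant_template(0)
    rownames(variants) <- NULL

    fish <- NULL
    if (length(amp_genes) && stats::runif(1) < config$fish_positive_prob)
      fish <- data.frame(gene = sample(amp_genes, 1), kind = "amplification",
                         positive = TRUE, stringsAsFactors = FALSE)
    msi <- stats::setNames(rep(FALSE, 5), MSI_MARKERS)
    list(variants = variants, meta = meta, fish_calls = fish,
         ihc_calls = NULL, msi = msi)
  })
}

#' Filter and score a generated cohort
#'
#' Convenience wrapper running [run_filter_pipeline()] and
#' [build_case_report()] over every case of a synthetic cohort.
#'
#' @param cohort output of [generate_cohort()].
#' @param kb a `dda_kb`.
#' @param params a [scoring_params()].
#' @param config the [filter_config()]; defaults to the standard thresholds
#'   with the knowledgebase-derived virtual panel.
#' @return List of per-case lists: `profile`, `report`.
#' @export
process_cohort <- function(cohort, kb, params = scoring_params(),
                           config = NULL) {
  if (is.null(config))
    config <- filter_config(virtual_panel = virtual_panel_genes(kb))
  lapply(cohort, function(cs) {
    non_ngs <- ingest_non_ngs_results(cs$fish_calls, cs$ihc_calls, cs$msi,
                                      cs$meta)
    profile <- run_filter_pipeline(cs$variants, cs$meta, config,
                                   non_ngs = non_ngs)
    list(profile = profile, report = build_case_report(profile, kb, params))
  })
}

#' Simulate molecular tumor board decisions
#'
#' Actionable cases (VUS-inclusive definition) receive a targeted
#' recommendation with probability `plogis(alpha + beta * log(1 +
#' top compound net AEL))` — choosing the rank-1 compound and its strongest
#' driver gene — and a standard-of-care recommendation otherwise;
#' non-actionable cases are always standard. A small fraction of cases gets
#' an observation-only recommendation.
#'
#' @param reports list of `dda_case_report` objects.
#' @param config a [synth_config()].
#' @param seed integer; defaults to the config's master seed.
#' @return data.frame of MTB decisions, one row per case.
#' @export
simulate_mtb_decisions <- function(reports, config, seed = config$seed) {
  set.seed(derive_seed(seed, "decisions"))
  alpha <- config$decision_logit[[1]]
  beta <- config$decision_logit[[2]]
  rows <- lapply(reports, function(r) {
    if (stats::runif(1) < config$observation_prob)
      return(mtb_decision(r$meta$case_id, "observation"))
    if (!r$actionable_vus_inclusive)
      return(mtb_decision(r$meta$case_id, "standard"))
    p <- stats::plogis(alpha + beta * log1p(max(r$top_compound_ael, 0)))
    if (stats::runif(1) < p) {
      drv_gene <- if (nrow(r$drivers)) r$drivers$gene[1] else
        r$alterations$gene[match("vus_in_driver_gene",
                                 r$alterations$classification)]
      mtb_decision(r$meta$case_id, "targeted",
                   chosen_compound = r$top_compound_id,
                   decision_driver_gene = drv_gene)
    } else {
      mtb_decision(r$meta$case_id, "standard")
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
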