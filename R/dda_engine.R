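#' Evidence scoring parameters
#'
#' Every evidence item contributes `base x tumor_multiplier x
#' specificity_multiplier` to the aggregated evidence level (AEL) of the
#' alteration, target or compound it concerns. The base reflects data
#' reliability (clinical study > preclinical > in-silico / frequency); the
#' multipliers weight relevance in the case: evidence from the same tumor
#' type and about the exact mutation (rather than the gene in general)
#' counts double by default. The published system does not disclose its
#' numeric weights; these defaults preserve the stated orderings and every
#' downstream property is weight-independent or scale-equivariant.
#'
#' @param class_base_scores named vector of per-class base scores; an
#'   item-level `base_reliability` overrides its class default.
#' @param same_tumor_multiplier weight for evidence from the case's tumor
#'   type (>= `other_tumor_multiplier`).
#' @param other_tumor_multiplier weight for other or unspecified tumor types.
#' @param exact_alteration_multiplier weight for evidence about the exact
#'   alteration (>= `gene_level_multiplier`).
#' @param gene_level_multiplier weight for gene-level evidence.
#' @param driver_ael_threshold net oncogenicity AEL that must be strictly
#'   exceeded to call a proven driver (default 20).
#' @return A `dda_scoring_params` list.
#' @export
scoring_params <- function(class_base_scores = c(clinical_approved = 8,
                                                 clinical = 4,
                                                 preclinical = 2,
                                                 in_silico = 1,
                                                 frequency = 1),
                           same_tumor_multiplier = 2.0,
                           other_tumor_multiplier = 1.0,
                           exact_alteration_multiplier = 2.0,
                           gene_level_multiplier = 1.0,
                           driver_ael_threshold = 20) {
  stopifnot(all(class_base_scores > 0),
            same_tumor_multiplier > 0, other_tumor_multiplier > 0,
            exact_alteration_multiplier > 0, gene_level_multiplier > 0,
            same_tumor_multiplier >= other_tumor_multiplier,
            exact_alteration_multiplier >= gene_level_multiplier)
  structure(list(class_base_scores = class_base_scores,
                 same_tumor_multiplier = same_tumor_multiplier,
                 other_tumor_multiplier = other_tumor_multiplier,
                 exact_alteration_multiplier = exact_alteration_multiplier,
                 gene_level_multiplier = gene_level_multiplier,
                 driver_ael_threshold = driver_ael_threshold),
            class = "dda_scoring_params")
}

item_base <- function(evidence_class, base_reliability, params) {
  base <- params$class_base_scores[evidence_class]
  if (anyNA(base))
    stop("unscorable_item: unknown evidence_class with no base_reliability: ",
         paste(unique(evidence_class[is.na(base)]), collapse = ", "))
  out <- ifelse(is.na(base_reliability), base, base_reliability)
  unname(out)
}

#' Score one evidence item in case context
#'
#' @param item one-row data.frame (or list) with `evidence_class`,
#'   `base_reliability`, `tumor_type`, `direction`.
#' @param case_tumor_type the case's tumor-type code.
#' @param exact_match `TRUE` when the item concerns the exact queried
#'   alteration, `FALSE` for gene-level evidence.
#' @param params a [scoring_params()].
#' @return The positive weighted score (direction is tracked separately by
#'   the aggregator).
#' @export
score_evidence_item <- function(item, case_tumor_type, exact_match, params) {
  base <- item_base(item$evidence_class, item$base_reliability, params)
  same <- !is.na(item$tumor_type) & item$tumor_type == case_tumor_type
  tumor_mult <- ifelse(same, params$same_tumor_multiplier,
                       params$other_tumor_multiplier)
  spec_mult <- ifelse(exact_match, params$exact_alteration_multiplier,
                      params$gene_level_multiplier)
  as.numeric(base * tumor_mult * spec_mult)
}

# Vectorized scoring over a query_evidence() result (has exact_match /
# same_tumor flags already).
score_items <- function(items, params) {
  if (nrow(items) == 0) return(numeric())
  base <- item_base(items$evidence_class, items$base_reliability, params)
  tumor_mult <- ifelse(items$same_tumor, params$same_tumor_multiplier,
                       params$other_tumor_multiplier)
  spec_mult <- ifelse(items$exact_match, params$exact_alteration_multiplier,
                      params$gene_level_multiplier)
  base * tumor_mult * spec_mult
}

#' Aggregate scored evidence into an AEL
#'
#' The aggregated evidence level is the weighted sum of the item scores,
#' split by direction: sensitivity / driver-supporting items accumulate in
#' `ael_positive`, resistance / negative items in `ael_negative`, and
#' `ael_net = ael_positive - ael_negative` is what ranking uses by default.
#'
#' @param scored data.frame with columns `id`, `direction`, `score`
#'   (all scores positive; direction carries the sign).
#' @param entity_kind `"alteration"`, `"target"` or `"compound"`.
#' @param entity_id identifier of the scored entity.
#' @return A `dda_ael` list with `ael_positive`, `ael_negative`, `ael_net`
#'   and `contributing_items`.
#' @export
aggregate_ael <- function(scored, entity_kind = "alteration",
                          entity_id = NA_character_) {
  if (is.null(scored) || nrow(scored) == 0)
    scored <- data.frame(id = character(), direction = integer(),
                         score = numeric(), stringsAsFactors = FALSE)
  pos <- sum(scored$score[scored$direction == 1L])
  neg <- sum(scored$score[scored$direction == -1L])
  structure(list(entity_kind = entity_kind, entity_id = entity_id,
                 ael_positive = pos, ael_negative = neg, ael_net = pos - neg,
                 contributing_items = scored[, c("id", "direction", "score")]),
            class = "dda_ael")
}

weaker_class <- function(a, b) {
  # evidence-class strength order; the weaker (larger index) label wins,
  # so an indirect link never claims more reliability than its weakest edge
  ia <- match(a, EVIDENCE_CLASSES)
  ib <- match(b, EVIDENCE_CLASSES)
  EVIDENCE_CLASSES[pmax(ia, ib)]
}

#' Classify one alteration as driver / VUS-in-driver-gene / other
#'
#' A proven driver needs exact-alteration oncogenicity evidence and a net
#' oncogenicity AEL strictly above `driver_ael_threshold` (gene-level
#' oncogenicity evidence also contributes to the sum). A variant that fails
#' that test but sits in a gene carrying gene-level driver-supporting
#' evidence is a VUS in a driver gene; anything else — including genes
#' absent from the knowledgebase — is `other`.
#'
#' @param variant one-row variant data.frame (needs `gene`, `alteration`).
#' @param kb a `dda_kb`.
#' @param case_tumor_type tumor-type code of the case.
#' @param params a [scoring_params()].
#' @return A `dda_alteration_call` list: `variant`, `classification`,
#'   `oncogenicity_ael`.
#' @export
classify_alteration <- function(variant, kb, case_tumor_type, params) {
  gene <- variant$gene
  sym <- resolve_gene(kb, gene)
  if (is.na(sym)) {
    return(structure(list(variant = variant, classification = "other",
                          oncogenicity_ael = aggregate_ael(NULL, "alteration",
                                                           variant$alteration)),
                     class = "dda_alteration_call"))
  }
  items <- query_evidence(kb, sym, variant$alteration, case_tumor_type)
  onco <- items[items$object_kind == "oncogenicity", , drop = FALSE]
  scored <- data.frame(id = onco$id, direction = onco$direction,
                       score = score_items(onco, params),
                       stringsAsFactors = FALSE)
  ael <- aggregate_ael(scored, "alteration",
                       paste0(sym, ":", variant$alteration))
  exact_present <- any(onco$exact_match & onco$direction == 1L)
  gene_driver_evidence <- any(!onco$exact_match & onco$direction == 1L)
  classification <-
    if (exact_present && ael$ael_net > params$driver_ael_threshold) "driver"
    else if (gene_driver_evidence) "vus_in_driver_gene"
    else "other"
  structure(list(variant = variant, classification = classification,
                 oncogenicity_ael = ael),
            class = "dda_alteration_call")
}

# Classify every alteration in a profile (filtered NGS variants plus
# non-NGS findings). Returns a flat data.frame, one row per alteration.
classify_profile_alterations <- function(profile, kb, params) {
  v <- rbind(cbind(profile$variants, source = rep("ngs", nrow(profile$variants))),
             cbind(profile$non_ngs_findings,
                   source = rep("non_ngs", nrow(profile$non_ngs_findings))))
  if (nrow(v) == 0)
    return(data.frame(gene = character(), alteration = character(),
                      variant_type = character(), source = character(),
                      classification = character(), ael_positive = numeric(),
                      ael_negative = numeric(), ael_net = numeric(),
                      stringsAsFactors = FALSE))
  calls <- lapply(seq_len(nrow(v)), function(i)
    classify_alteration(v[i, , drop = FALSE], kb,
                        profile$meta$tumor_type, params))
  data.frame(gene = v$gene, alteration = v$alteration,
             variant_type = v$variant_type, source = v$source,
             classification = vapply(calls, `[[`, "", "classification"),
             ael_positive = vapply(calls, function(x) x$oncogenicity_ael$ael_positive, 0),
             ael_negative = vapply(calls, function(x) x$oncogenicity_ael$ael_negative, 0),
             ael_net = vapply(calls, function(x) x$oncogenicity_ael$ael_net, 0),
             stringsAsFactors = FALSE)
}

# Build the per-case evidence link table connecting driver / VUS-in-driver
# alterations to compounds, both directly and routed through a target
# (alteration -> target, then gene-level target -> compound evidence).
# Composed links take the minimum tumor and specificity multiplier along the
# path, the weaker evidence class, the product of directions, and the
# compound edge's base score.
case_compound_links <- function(kb, alterations, case_tumor_type, params) {
  out <- list()
  cols <- c("compound_id", "evidence_id", "direction", "evidence_class",
            "score", "path", "alteration_gene", "alteration",
            "alteration_class", "item_tumor_type", "same_tumor")
  empty <- data.frame(compound_id = character(), evidence_id = character(),
                      direction = integer(), evidence_class = character(),
                      score = numeric(), path = character(),
                      alteration_gene = character(), alteration = character(),
                      alteration_class = character(),
                      item_tumor_type = character(), same_tumor = logical(),
                      stringsAsFactors = FALSE)
  alt <- alterations[alterations$classification %in%
                       c("driver", "vus_in_driver_gene"), , drop = FALSE]
  if (nrow(alt) == 0) return(empty)
  for (i in seq_len(nrow(alt))) {
    g <- alt$gene[i]; a <- alt$alteration[i]; cls <- alt$classification[i]
    sym <- resolve_gene(kb, g)
    if (is.na(sym)) next
    items <- query_evidence(kb, sym, a, case_tumor_type)
    direct <- items[items$object_kind == "compound", , drop = FALSE]
    if (nrow(direct)) {
      out[[length(out) + 1L]] <- data.frame(
        compound_id = direct$object_id, evidence_id = direct$id,
        direction = direct$direction, evidence_class = direct$evidence_class,
        score = score_items(direct, params), path = "direct",
        alteration_gene = sym, alteration = a, alteration_class = cls,
        item_tumor_type = direct$tumor_type, same_tumor = direct$same_tumor,
        stringsAsFactors = FALSE)
    }
    tlinks <- items[items$object_kind == "target", , drop = FALSE]
    if (nrow(tlinks) == 0) next
    t_tm <- ifelse(tlinks$same_tumor, params$same_tumor_multiplier,
                   params$other_tumor_multiplier)
    t_sm <- ifelse(tlinks$exact_match, params$exact_alteration_multiplier,
                   params$gene_level_multiplier)
    for (j in seq_len(nrow(tlinks))) {
      tgene <- resolve_gene(kb, tlinks$object_id[j])
      if (is.na(tgene)) next
      ev <- kb$evidence
      t2 <- ev[ev$subject_gene == tgene & is.na(ev$subject_alteration) &
                 ev$object_kind == "compound", , drop = FALSE]
      if (nrow(t2) == 0) next
      t2_same <- !is.na(t2$tumor_type) & t2$tumor_type == case_tumor_type
      t2_tm <- ifelse(t2_same, params$same_tumor_multiplier,
                      params$other_tumor_multiplier)
      t2_sm <- params$gene_level_multiplier
      base2 <- item_base(t2$evidence_class, t2$base_reliability, params)
      score <- base2 * pmin(t_tm[j], t2_tm) * pmin(t_sm[j], t2_sm)
      out[[length(out) + 1L]] <- data.frame(
        compound_id = t2$object_id,
        evidence_id = paste(tlinks$id[j], t2$id, sep = "+"),
        direction = as.integer(tlinks$direction[j] * t2$direction),
        evidence_class = weaker_class(tlinks$evidence_class[j],
                                      t2$evidence_class),
        score = score, path = "indirect",
        alteration_gene = sym, alteration = a, alteration_class = cls,
        item_tumor_type = t2$tumor_type, same_tumor = t2_same & tlinks$same_tumor[j],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)[, cols]
  rownames(res) <- NULL
  res
}

#' Rank registered compounds by aggregated evidence level
#'
#' For each registered compound, all evidence linking it — directly or via a
#' target — to the case's drivers and VUS-in-driver alterations is scored
#' and summed into an AEL; compounds are ordered by net AEL descending
#' (rank 1 = strongest support). Ties break on the larger clinical-class
#' positive subtotal, then lexicographically on compound id, so reports are
#' deterministic. Only compounds with at least one contributing link are
#' ranked.
#'
#' @param profile a `dda_profile` from [run_filter_pipeline()].
#' @param kb a `dda_kb`.
#' @param params a [scoring_params()].
#' @param alterations optional precomputed classification table (from the
#'   internal classifier); computed from `profile` when `NULL`.
#' @param links optional precomputed link table; computed when `NULL`.
#' @return data.frame: `compound_id`, `ael_positive`, `ael_negative`,
#'   `ael_net`, `clinical_subtotal`, `rank`, `registered`.
#' @export
rank_compounds <- function(profile, kb, params, alterations = NULL,
                           links = NULL) {
  if (is.null(alterations))
    alterations <- classify_profile_alterations(profile, kb, params)
  if (is.null(links))
    links <- case_compound_links(kb, alterations, profile$meta$tumor_type, params)
  reg <- registered_compounds(kb)
  links <- links[links$compound_id %in% reg, , drop = FALSE]
  if (nrow(links) == 0)
    return(data.frame(compound_id = character(), ael_positive = numeric(),
                      ael_negative = numeric(), ael_net = numeric(),
                      clinical_subtotal = numeric(), rank = integer(),
                      registered = logical(), stringsAsFactors = FALSE))
  pos <- tapply(links$score * (links$direction == 1L), links$compound_id, sum)
  neg <- tapply(links$score * (links$direction == -1L), links$compound_id, sum)
  clin <- tapply(links$score * (links$direction == 1L &
                                  links$evidence_class %in% CLINICAL_CLASSES),
                 links$compound_id, sum)
  df <- data.frame(compound_id = names(pos), ael_positive = as.numeric(pos),
                   ael_negative = as.numeric(neg),
                   ael_net = as.numeric(pos) - as.numeric(neg),
                   clinical_subtotal = as.numeric(clin),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$ael_net, -df$clinical_subtotal, df$compound_id), ,
           drop = FALSE]
  df$rank <- seq_len(nrow(df))
  df$registered <- TRUE
  rownames(df) <- NULL
  df
}

#' Rank the case's driver alterations by oncogenicity AEL
#'
#' @inheritParams rank_compounds
#' @return data.frame of driver rows sorted by `ael_net` descending (ties:
#'   gene, then alteration); the first row is the case's strongest driver.
#' @export
rank_drivers <- function(profile, kb, params, alterations = NULL) {
  if (is.null(alterations))
    alterations <- classify_profile_alterations(profile, kb, params)
  d <- alterations[alterations$classification == "driver", , drop = FALSE]
  d <- d[order(-d$ael_net, d$gene, d$alteration), , drop = FALSE]
  if (nrow(d)) d$rank <- seq_len(nrow(d))
  else d$rank <- integer()
  rownames(d) <- NULL
  d
}

#' Detect resistance pairs
#'
#' A case carries a resistance finding when at least one registered compound
#' is negatively associated (direction -1 evidence, direct or via target)
#' with one of its drivers. Returns one row per (compound, driver gene)
#' pair with the aggregated negative AEL.
#'
#' @inheritParams rank_compounds
#' @return data.frame: `compound_id`, `driver_gene`, `negative_ael`.
#' @export
detect_resistance <- function(profile, kb, params, alterations = NULL,
                              links = NULL) {
  if (is.null(alterations))
    alterations <- classify_profile_alterations(profile, kb, params)
  if (is.null(links))
    links <- case_compound_links(kb, alterations, profile$meta$tumor_type, params)
  reg <- registered_compounds(kb)
  neg <- links[links$direction == -1L & links$compound_id %in% reg &
                 links$alteration_class == "driver", , drop = FALSE]
  if (nrow(neg) == 0)
    return(data.frame(compound_id = character(), driver_gene = character(),
                      negative_ael = numeric(), stringsAsFactors = FALSE))
  key <- paste(neg$compound_id, neg$alteration_gene, sep = "\r")
  s <- tapply(neg$score, key, sum)
  parts <- strsplit(names(s), "\r", fixed = TRUE)
  out <- data.frame(compound_id = vapply(parts, `[`, "", 1),
                    driver_gene = vapply(parts, `[`, "", 2),
                    negative_ael = as.numeric(s), stringsAsFactors = FALSE)
  out <- out[order(out$compound_id, out$driver_gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
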