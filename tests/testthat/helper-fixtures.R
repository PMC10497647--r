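# Hand-built fixtures and independent oracles shared across test files.

# A small hand-written knowledgebase covering every edge the engine handles:
# exact + gene-level oncogenicity, direct + indirect compound links,
# resistance edges, registered + developmental compounds, aliases.
tiny_kb <- function() {
  genes <- data.frame(
    symbol = c("BRAF", "KRAS", "EGFR", "MET", "TP53"),
    aliases = c("B-RAF", "", "ERBB1", "", ""),
    stringsAsFactors = FALSE)
  compounds <- data.frame(
    id = c("CPD_VEMU", "CPD_TRAM", "CPD_DEV"),
    name = c("vemurafenib-like", "trametinib-like", "dev-compound"),
    registered = c(TRUE, TRUE, FALSE),
    approved_indications = c("melanoma", "", ""),
    stringsAsFactors = FALSE)
  ev <- function(id, g, alt, kind, obj, dir, cls, tt, base) {
    data.frame(id = id, subject_gene = g, subject_alteration = alt,
               object_kind = kind, object_id = obj, direction = as.integer(dir),
               evidence_class = cls, tumor_type = tt, base_reliability = base,
               source_ref = paste0("ref:", id), stringsAsFactors = FALSE)
  }
  evidence <- rbind(
    ev("E01", "BRAF", "p.V600E", "oncogenicity", NA, 1, "clinical", NA, NA),
    ev("E02", "BRAF", "p.V600E", "oncogenicity", NA, 1, "clinical", "melanoma", 8),
    ev("E03", "BRAF", NA, "oncogenicity", NA, 1, "preclinical", NA, NA),
    ev("E04", "BRAF", "p.V600E", "compound", "CPD_VEMU", 1, "clinical", "melanoma", NA),
    ev("E05", "BRAF", NA, "compound", "CPD_DEV", 1, "preclinical", NA, NA),
    ev("E06", "BRAF", NA, "target", "MET", 1, "preclinical", NA, NA),
    ev("E07", "MET", NA, "compound", "CPD_TRAM", 1, "preclinical", NA, NA),
    ev("E08", "KRAS", NA, "oncogenicity", NA, 1, "clinical", NA, NA),
    ev("E09", "KRAS", NA, "compound", "CPD_VEMU", -1, "clinical", NA, NA),
    ev("E10", "EGFR", "p.L858R", "oncogenicity", NA, 1, "clinical", "lung", 6),
    ev("E11", "EGFR", "p.L858R", "oncogenicity", NA, 1, "clinical", NA, 6),
    ev("E12", "EGFR", NA, "oncogenicity", NA, 1, "preclinical", NA, NA),
    ev("E13", "EGFR", NA, "compound", "CPD_TRAM", 1, "in_silico", NA, NA))
  knowledgebase(genes, compounds, evidence, version = "tiny-1",
                tumor_types = c("melanoma", "lung", "CRC"))
}

# One QC-passing variant row.
ok_variant <- function(gene = "BRAF", alteration = "p.V600E",
                       variant_type = "SNV", depth = 100, quality = 40,
                       vaf = 0.3, acmg = "vus", pop_freq_1kg = NA_real_,
                       pop_freq_exac = NA_real_, pop_freq_esp = NA_real_,
                       ...) {
  data.frame(gene = gene, alteration = alteration, variant_type = variant_type,
             depth = depth, quality = quality, alt_allele_fraction = vaf,
             acmg_class = acmg, pop_freq_1kg = pop_freq_1kg,
             pop_freq_exac = pop_freq_exac, pop_freq_esp = pop_freq_esp,
             ..., stringsAsFactors = FALSE)
}

# The six-variant fixture: exactly one variant fails each of the five
# SNV rules and one passes everything.
six_variant_fixture <- function() {
  rbind(
    ok_variant("BRAF", "p.pass"),
    ok_variant("BRAF", "p.depth", depth = 20),
    ok_variant("BRAF", "p.qual", quality = 19.9),
    ok_variant("BRAF", "p.vaf", vaf = 0.009),
    ok_variant("BRAF", "p.popfreq", pop_freq_exac = 0.10),
    ok_variant("BRAF", "p.benign", acmg = "likely_benign"))
}

tiny_meta <- function(tumor_type = "melanoma", ...) {
  sample_meta(case_id = "T01", tumor_type = tumor_type, ...)
}

tiny_filter_config <- function(...) {
  filter_config(virtual_panel = c("BRAF", "KRAS", "EGFR", "MET", "TP53"), ...)
}

# Profile with one proven driver (BRAF p.V600E) plus one VUS in KRAS.
tiny_profile <- function(tumor_type = "melanoma") {
  run_filter_pipeline(
    rbind(ok_variant("BRAF", "p.V600E"),
          ok_variant("KRAS", "p.Q61X")),
    tiny_meta(tumor_type), tiny_filter_config())
}

# ---- independent oracles -------------------------------------------------

# Scalar weighting helpers used only by the oracles below.
.o_base <- function(cls, br, params) {
  if (!is.na(br)) br else unname(params$class_base_scores[[cls]])
}
.o_tm <- function(tt, case_tt, params) {
  if (!is.na(tt) && tt == case_tt) params$same_tumor_multiplier
  else params$other_tumor_multiplier
}
.o_sm <- function(exact, params) {
  if (exact) params$exact_alteration_multiplier else params$gene_level_multiplier
}

# Naive one-pass weighted-sum oracle for per-compound AELs: nested loops over
# alterations and evidence items, composing indirect links explicitly.
# Independent of case_compound_links / rank_compounds.
oracle_compound_aels <- function(kb, alterations, case_tt, params) {
  acc <- list()
  add <- function(cp, dir, s) {
    if (is.null(acc[[cp]])) acc[[cp]] <<- c(pos = 0, neg = 0)
    if (dir == 1) acc[[cp]]["pos"] <<- acc[[cp]]["pos"] + s
    else acc[[cp]]["neg"] <<- acc[[cp]]["neg"] + s
  }
  alt <- alterations[alterations$classification %in%
                       c("driver", "vus_in_driver_gene"), , drop = FALSE]
  ev <- kb$evidence
  ev_rows <- lapply(seq_len(nrow(ev)), function(j) as.list(ev[j, ]))
  for (i in seq_len(nrow(alt))) {
    for (j in seq_along(ev_rows)) {
      e <- ev_rows[[j]]
      if (toupper(e$subject_gene) != toupper(alt$gene[i])) next
      exact <- !is.na(e$subject_alteration)
      if (exact && e$subject_alteration != alt$alteration[i]) next
      w1_tm <- .o_tm(e$tumor_type, case_tt, params)
      w1_sm <- .o_sm(exact, params)
      if (e$object_kind == "compound") {
        add(e$object_id, e$direction,
            .o_base(e$evidence_class, e$base_reliability, params) * w1_tm * w1_sm)
      } else if (e$object_kind == "target") {
        for (k in seq_along(ev_rows)) {
          e2 <- ev_rows[[k]]
          if (e2$object_kind != "compound") next
          if (toupper(e2$subject_gene) != toupper(e$object_id)) next
          if (!is.na(e2$subject_alteration)) next
          s <- .o_base(e2$evidence_class, e2$base_reliability, params) *
            min(w1_tm, .o_tm(e2$tumor_type, case_tt, params)) *
            min(w1_sm, .o_sm(FALSE, params))
          add(e2$object_id, e$direction * e2$direction, s)
        }
      }
    }
  }
  if (!length(acc))
    return(data.frame(compound_id = character(), ael_net = numeric(),
                      stringsAsFactors = FALSE))
  df <- data.frame(compound_id = names(acc),
                   ael_positive = sapply(acc, `[[`, "pos"),
                   ael_negative = sapply(acc, `[[`, "neg"),
                   stringsAsFactors = FALSE)
  df$ael_net <- df$ael_positive - df$ael_negative
  rownames(df) <- NULL
  df[order(df$compound_id), , drop = FALSE]
}

# Naive oncogenicity AEL for a single (gene, alteration): plain loop-sum.
oracle_oncogenicity_ael <- function(kb, gene, alteration, case_tt, params) {
  net <- 0
  ev <- kb$evidence
  for (j in seq_len(nrow(ev))) {
    e <- ev[j, ]
    if (e$object_kind != "oncogenicity") next
    if (toupper(e$subject_gene) != toupper(gene)) next
    exact <- !is.na(e$subject_alteration)
    if (exact && e$subject_alteration != alteration) next
    s <- .o_base(e$evidence_class, e$base_reliability, params) *
      .o_tm(e$tumor_type, case_tt, params) * .o_sm(exact, params)
    net <- net + e$direction * s
  }
  net
}

# Monte-Carlo permutation oracle for the two-sided Mann-Whitney p-value.
oracle_permutation_p <- function(a, b, n_perm = 1e5) {
  n1 <- length(a); n <- n1 + length(b)
  ranks <- rank(c(a, b))
  u_of <- function(idx) sum(ranks[idx]) - n1 * (n1 + 1) / 2
  mu <- n1 * (n - n1) / 2
  obs <- abs(u_of(seq_len(n1)) - mu)
  hits <- 0L
  for (r in seq_len(n_perm))
    if (abs(u_of(sample.int(n, n1)) - mu) >= obs - 1e-12) hits <- hits + 1L
  hits / n_perm
}

# Shared synthetic world, built once per test run (processing dominates).
.shared_worlds <- new.env(parent = emptyenv())
shared_world <- function(n_cases = 60, seed = 11) {
  key <- sprintf("w_%d_%d", n_cases, seed)
  if (is.null(.shared_worlds[[key]])) {
    cfg <- synth_config(seed = seed, n_cases = n_cases)
    kb <- generate_knowledgebase(cfg)
    cohort <- generate_cohort(cfg, kb)
    proc <- process_cohort(cohort, kb)
    reports <- lapply(proc, `[[`, "report")
    decisions <- simulate_mtb_decisions(reports, cfg)
    .shared_worlds[[key]] <- list(cfg = cfg, kb = kb, cohort = cohort,
                                  proc = proc, reports = reports,
                                  decisions = decisions)
  }
  .shared_worlds[[key]]
}
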