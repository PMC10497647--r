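params <- scoring_params()

test_that("evidence item scoring multiplies base, tumor and specificity weights", {
  clin <- list(evidence_class = "clinical", base_reliability = NA_real_,
               tumor_type = "melanoma", direction = 1L)
  # 4 (clinical base) x 2 (same tumor) x 2 (exact) = 16
  expect_equal(score_evidence_item(clin, "melanoma", TRUE, params), 16)
  pre <- list(evidence_class = "preclinical", base_reliability = NA_real_,
              tumor_type = "lung", direction = 1L)
  # 2 x 1 (other tumor) x 1 (gene-level) = 2
  expect_equal(score_evidence_item(pre, "melanoma", FALSE, params), 2)
  # identity multipliers: score equals the base
  flat <- scoring_params(same_tumor_multiplier = 1, exact_alteration_multiplier = 1)
  expect_equal(score_evidence_item(clin, "melanoma", TRUE, flat), 4)
  # item-level base_reliability overrides the class default
  clin$base_reliability <- 7
  expect_equal(score_evidence_item(clin, "other", FALSE, params), 7)
  expect_error(score_evidence_item(
    list(evidence_class = "mystery", base_reliability = NA_real_,
         tumor_type = NA, direction = 1L), "x", TRUE, params),
    "unscorable_item")
})

test_that("aggregate_ael sums by direction and records contributors", {
  empty <- aggregate_ael(NULL)
  expect_equal(c(empty$ael_positive, empty$ael_negative, empty$ael_net),
               c(0, 0, 0))
  two <- aggregate_ael(data.frame(id = c("a", "b"), direction = c(1L, -1L),
                                  score = c(16, 2)))
  expect_equal(two$ael_positive, 16)
  expect_equal(two$ael_negative, 2)
  expect_equal(two$ael_net, 14)
  expect_equal(nrow(two$contributing_items), 2)

  # naive-summation oracle over 500 random items
  set.seed(21)
  items <- data.frame(id = paste0("i", 1:500),
                      direction = sample(c(-1L, 1L), 500, TRUE),
                      score = runif(500, 0.1, 20))
  ael <- aggregate_ael(items)
  pos <- 0; neg <- 0
  for (i in 1:500) {
    if (items$direction[i] == 1) pos <- pos + items$score[i]
    else neg <- neg + items$score[i]
  }
  expect_equal(ael$ael_positive, pos, tolerance = 1e-12)
  expect_equal(ael$ael_net, pos - neg, tolerance = 1e-12)
})

test_that("alteration classification follows the driver / VUS-DR rules", {
  kb <- tiny_kb()
  # BRAF p.V600E in melanoma: E01 4x2=8? no - tumor NA -> 4x1x2=8; E02 8x2x2=32;
  # E03 gene-level 2; net 42 > 20 with exact evidence present -> driver
  call <- classify_alteration(ok_variant("BRAF", "p.V600E"), kb, "melanoma", params)
  expect_equal(call$classification, "driver")
  expect_equal(call$oncogenicity_ael$ael_net,
               oracle_oncogenicity_ael(kb, "BRAF", "p.V600E", "melanoma", params))

  # novel alteration in KRAS: gene-level driver evidence only -> VUS-DR
  expect_equal(classify_alteration(ok_variant("KRAS", "p.Q61X"), kb,
                                   "melanoma", params)$classification,
               "vus_in_driver_gene")
  # gene absent from the knowledgebase -> other
  expect_equal(classify_alteration(ok_variant("NOSUCH", "p.A1B"), kb,
                                   "melanoma", params)$classification,
               "other")
  # exact evidence present but AEL below threshold: EGFR p.L858R in CRC
  # = 6x1x2 + 6x1x2 + 2 (gene) = 26 > 20 -> driver even off-tumor
  expect_equal(classify_alteration(ok_variant("EGFR", "p.L858R"), kb,
                                   "CRC", params)$classification, "driver")
})

test_that("compound ranking orders by net AEL with the documented tie-break", {
  kb <- tiny_kb()
  prof <- tiny_profile("melanoma")
  ranked <- rank_compounds(prof, kb, params)
  # CPD_VEMU: direct exact link E04 (4x2x2=16) minus KRAS VUS resistance E09
  # (4x1x1=4) = 12; CPD_TRAM: indirect E06+E07 (2x1x1=2); CPD_DEV developmental
  expect_equal(ranked$compound_id, c("CPD_VEMU", "CPD_TRAM"))
  expect_equal(ranked$rank, c(1L, 2L))
  expect_equal(ranked$ael_net[ranked$compound_id == "CPD_VEMU"], 12)
  expect_equal(ranked$ael_net[ranked$compound_id == "CPD_TRAM"], 2)
  expect_false("CPD_DEV" %in% ranked$compound_id)

  # single compound with positive evidence is rank 1
  one <- rank_compounds(run_filter_pipeline(ok_variant("EGFR", "p.L858R"),
                                            tiny_meta("lung"),
                                            tiny_filter_config()),
                        kb, params)
  expect_equal(one$rank[one$compound_id == "CPD_TRAM"], 1L)
})

test_that("tie-break prefers the larger clinical subtotal then lexicographic id", {
  genes <- data.frame(symbol = "G1", aliases = "", stringsAsFactors = FALSE)
  compounds <- data.frame(id = c("CA", "CB", "CC"),
                          name = c("a", "b", "c"), registered = TRUE,
                          approved_indications = "", stringsAsFactors = FALSE)
  ev <- rbind(
    data.frame(id = "h1", subject_gene = "G1", subject_alteration = "p.A1",
               object_kind = "oncogenicity", object_id = NA, direction = 1L,
               evidence_class = "clinical", tumor_type = NA,
               base_reliability = 15, source_ref = "", stringsAsFactors = FALSE),
    # CA: 30 via clinical; CB and CC both 12, but CB's is clinical, CC's preclinical
    data.frame(id = c("e1", "e2", "e3"), subject_gene = "G1",
               subject_alteration = NA, object_kind = "compound",
               object_id = c("CA", "CB", "CC"), direction = 1L,
               evidence_class = c("clinical", "clinical", "preclinical"),
               tumor_type = NA, base_reliability = c(30, 12, 12),
               source_ref = "", stringsAsFactors = FALSE))
  kb <- knowledgebase(genes, compounds, ev, tumor_types = "melanoma")
  prof <- run_filter_pipeline(ok_variant("G1", "p.A1"), tiny_meta(),
                              filter_config(virtual_panel = "G1"))
  ranked <- rank_compounds(prof, kb, params)
  expect_equal(ranked$compound_id, c("CA", "CB", "CC"))
  expect_equal(ranked$ael_net, c(30, 12, 12))
})

test_that("driver ranking and resistance detection", {
  kb <- tiny_kb()
  prof <- run_filter_pipeline(
    rbind(ok_variant("BRAF", "p.V600E"), ok_variant("EGFR", "p.L858R")),
    tiny_meta("melanoma"), tiny_filter_config())
  drv <- rank_drivers(prof, kb, params)
  expect_equal(drv$gene, c("BRAF", "EGFR"))  # 42 vs 26
  expect_equal(drv$rank, 1:2)

  # KRAS is only a VUS here, so its resistance edge must not fire (driver-only)
  expect_equal(nrow(detect_resistance(tiny_profile("melanoma"), kb, params)), 0)

  # make KRAS a driver via an exact hotspot in a custom kb copy
  kb2 <- tiny_kb()
  kb2$evidence <- rbind(kb2$evidence, data.frame(
    id = "E99", subject_gene = "KRAS", subject_alteration = "p.G12D",
    object_kind = "oncogenicity", object_id = NA, direction = 1L,
    evidence_class = "clinical", tumor_type = NA, base_reliability = 15,
    source_ref = "", stringsAsFactors = FALSE))
  kb2 <- validate_knowledgebase(kb2)
  prof2 <- run_filter_pipeline(ok_variant("KRAS", "p.G12D"),
                               tiny_meta("melanoma"), tiny_filter_config())
  res <- detect_resistance(prof2, kb2, params)
  expect_equal(res$compound_id, "CPD_VEMU")
  expect_equal(res$driver_gene, "KRAS")
  expect_gt(res$negative_ael, 0)

  # negative evidence to a developmental compound must not flag resistance
  kb3 <- kb2
  kb3$evidence$object_id[kb3$evidence$id == "E09"] <- "CPD_DEV"
  kb3 <- validate_knowledgebase(kb3)
  expect_equal(nrow(detect_resistance(prof2, kb3, params)), 0)
})

test_that("AEL additivity, monotonicity and scale equivariance", {
  kb <- tiny_kb()
  prof <- tiny_profile("melanoma")
  base_ranked <- rank_compounds(prof, kb, params)

  # additivity: AEL over a union of disjoint item sets is the sum of parts
  set.seed(3)
  items <- data.frame(id = paste0("i", 1:60),
                      direction = sample(c(-1L, 1L), 60, TRUE),
                      score = runif(60, 0.5, 10))
  split_at <- 25
  a <- aggregate_ael(items[1:split_at, ])
  b <- aggregate_ael(items[(split_at + 1):60, ])
  whole <- aggregate_ael(items)
  expect_equal(whole$ael_net, a$ael_net + b$ael_net, tolerance = 1e-12)

  # monotonicity: adding a positive item never decreases net AEL
  more <- aggregate_ael(rbind(items, data.frame(id = "extra", direction = 1L,
                                                score = 5)))
  expect_gte(more$ael_net, whole$ael_net)
  fewer <- aggregate_ael(rbind(items, data.frame(id = "extra", direction = -1L,
                                                 score = 5)))
  expect_lte(fewer$ael_net, whole$ael_net)

  # scale equivariance: c x base scores and c x threshold leave rankings and
  # classifications unchanged and scale every AEL by c
  c_ <- 3.7
  scaled <- scoring_params(
    class_base_scores = params$class_base_scores * c_,
    driver_ael_threshold = params$driver_ael_threshold * c_)
  # item-level base_reliability must be scaled too for full equivariance
  kb_s <- kb
  kb_s$evidence$base_reliability <- kb_s$evidence$base_reliability * c_
  kb_s <- validate_knowledgebase(kb_s)
  ranked_s <- rank_compounds(prof, kb_s, scaled)
  expect_equal(ranked_s$compound_id, base_ranked$compound_id)
  expect_equal(ranked_s$ael_net, base_ranked$ael_net * c_, tolerance = 1e-9)
  drv <- rank_drivers(prof, kb, params)
  drv_s <- rank_drivers(prof, kb_s, scaled)
  expect_equal(drv_s$gene, drv$gene)
  expect_equal(drv_s$classification, drv$classification)
})

test_that("engine AELs equal the naive weighted-sum oracle on random kbs", {
  for (seed in c(101, 202, 303)) {
    cfg <- synth_config(seed = seed, n_driver_genes = 10L, n_target_genes = 8L,
                        n_panel_genes = 40L, n_offpanel_genes = 5L,
                        n_compounds = 20L)
    kb <- generate_knowledgebase(cfg)
    cohort <- generate_cohort(cfg, kb)[1:3]
    for (cs in cohort) {
      prof <- run_filter_pipeline(cs$variants, cs$meta,
                                  filter_config(virtual_panel = virtual_panel_genes(kb)))
      alt <- oncodda:::classify_profile_alterations(prof, kb, params)
      got <- rank_compounds(prof, kb, params, alterations = alt)
      ref <- oracle_compound_aels(kb, alt, cs$meta$tumor_type, params)
      ref <- ref[ref$compound_id %in% registered_compounds(kb), ]
      got <- got[order(got$compound_id), ]
      expect_equal(got$compound_id, ref$compound_id)
      expect_equal(got$ael_net, ref$ael_net, tolerance = 1e-9)
    }
  }
})
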