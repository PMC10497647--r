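test_that("minimal knowledgebase file round-trips through load", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    "[meta]", "version", "mini-1",
    "[tumor_types]", "melanoma",
    "[genes]", "symbol\taliases", "BRAF\tB-RAF",
    "[compounds]", "id\tname\tregistered\tapproved_indications",
    "C1\tdrug1\tTRUE\t",
    "[evidence]",
    paste("id", "subject_gene", "subject_alteration", "object_kind",
          "object_id", "direction", "evidence_class", "tumor_type",
          "base_reliability", "source_ref", sep = "\t"),
    "E1\tBRAF\tp.V600E\tcompound\tC1\t+1\tclinical\tmelanoma\t\tpmid:1"),
    path)
  kb <- load_knowledgebase(path)
  expect_s3_class(kb, "dda_kb")
  expect_equal(nrow(kb$evidence), 1)
  expect_equal(kb$version, "mini-1")
  expect_true(is.na(kb$evidence$base_reliability))
})

test_that("write/load round trip is the identity field-by-field", {
  for (kb in list(tiny_kb(),
                  generate_knowledgebase(synth_config(seed = 42,
                                                      n_driver_genes = 12L,
                                                      n_panel_genes = 60L,
                                                      n_offpanel_genes = 10L)))) {
    path <- withr::local_tempfile(fileext = ".txt")
    write_knowledgebase(kb, path)
    kb2 <- load_knowledgebase(path)
    expect_equal(kb2$genes, kb$genes)
    expect_equal(kb2$compounds, kb$compounds)
    expect_equal(kb2$evidence, kb$evidence)
    expect_equal(kb2$version, kb$version)
    expect_equal(kb2$tumor_types, kb$tumor_types)
  }
})

test_that("validation rejects dangling references and ambiguous aliases", {
  kb <- tiny_kb()
  bad_ev <- kb$evidence
  bad_ev$object_id[bad_ev$id == "E04"] <- "CPD_MISSING"
  expect_error(
    knowledgebase(kb$genes, kb$compounds, bad_ev, tumor_types = kb$tumor_types),
    "E04")
  bad_genes <- kb$genes
  bad_genes$aliases[bad_genes$symbol == "KRAS"] <- "B-RAF"  # BRAF's alias
  expect_error(
    knowledgebase(bad_genes, kb$compounds, kb$evidence,
                  tumor_types = kb$tumor_types),
    "ambiguous alias")
  dev_with_ind <- kb$compounds
  dev_with_ind$approved_indications[dev_with_ind$id == "CPD_DEV"] <- "lung"
  expect_error(
    knowledgebase(kb$genes, dev_with_ind, kb$evidence,
                  tumor_types = kb$tumor_types),
    "CPD_DEV")
})

test_that("query_evidence matches gene-level and exact items with flags", {
  kb <- tiny_kb()
  hits <- query_evidence(kb, "BRAF", "p.V600E", "melanoma")
  expect_setequal(hits$id, c("E01", "E02", "E03", "E04", "E05", "E06"))
  expect_true(all(hits$exact_match[hits$id %in% c("E01", "E02", "E04")]))
  expect_false(any(hits$exact_match[hits$id %in% c("E03", "E05", "E06")]))
  expect_true(all(hits$same_tumor[hits$id %in% c("E02", "E04")]))

  # alias and case-insensitive resolution
  expect_setequal(query_evidence(kb, "b-raf", "p.V600E", "lung")$id, hits$id)

  # gene-level query is a subset of the exact-alteration query
  gl <- query_evidence(kb, "BRAF", NULL, "melanoma")
  expect_true(all(gl$id %in% hits$id))

  # no evidence / unknown gene
  expect_equal(nrow(query_evidence(kb, "TP53", "p.R175H", "lung")), 0)
  expect_warning(res <- query_evidence(kb, "NOSUCH", "p.X", "lung"),
                 "unknown gene")
  expect_equal(nrow(res), 0)
})

test_that("query_evidence equals a brute-force linear scan on a random kb", {
  cfg <- synth_config(seed = 7, n_driver_genes = 15L, n_panel_genes = 60L,
                      n_offpanel_genes = 10L)
  kb <- generate_knowledgebase(cfg)
  expect_gt(nrow(kb$evidence), 150)
  hot <- kb$evidence[!is.na(kb$evidence$subject_alteration), ]
  set.seed(1)
  for (i in sample(nrow(hot), 10)) {
    g <- hot$subject_gene[i]; a <- hot$subject_alteration[i]
    got <- query_evidence(kb, g, a, "CNS")
    ref_ids <- character()
    for (j in seq_len(nrow(kb$evidence))) {   # oracle: plain linear scan
      e <- kb$evidence[j, ]
      if (e$subject_gene == g &&
          (is.na(e$subject_alteration) || e$subject_alteration == a))
        ref_ids <- c(ref_ids, e$id)
    }
    expect_setequal(got$id, ref_ids)
  }
})

test_that("registered_compounds matches the filter oracle and is stable", {
  kb <- tiny_kb()
  expect_setequal(registered_compounds(kb), c("CPD_VEMU", "CPD_TRAM"))
  kb_rand <- generate_knowledgebase(synth_config(seed = 3, n_driver_genes = 10L,
                                                 n_panel_genes = 40L,
                                                 n_offpanel_genes = 5L))
  oracle <- kb_rand$compounds$id[which(kb_rand$compounds$registered)]
  expect_setequal(registered_compounds(kb_rand), oracle)
  # idempotent / order-independent
  shuffled <- kb_rand
  shuffled$compounds <- shuffled$compounds[rev(seq_len(nrow(shuffled$compounds))), ]
  expect_setequal(registered_compounds(shuffled), oracle)
  expect_identical(registered_compounds(kb_rand), registered_compounds(kb_rand))
})

test_that("kb with no compounds yields empty registered set", {
  kb <- knowledgebase(
    data.frame(symbol = "BRAF", aliases = "", stringsAsFactors = FALSE),
    empty_compounds <- data.frame(id = character(), name = character(),
                                  registered = logical(),
                                  approved_indications = character(),
                                  stringsAsFactors = FALSE),
    tiny_kb()$evidence[0, ], tumor_types = "melanoma")
  expect_length(registered_compounds(kb), 0)
})
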