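cfg <- filter_config(virtual_panel = c("BRAF", "KRAS", "EGFR", "MET", "TP53"))

test_that("quality filter boundaries follow the protocol wording", {
  v <- rbind(
    ok_variant("BRAF", "a", depth = 21, quality = 20, vaf = 0.01),  # exactly at thresholds
    ok_variant("BRAF", "b", depth = 20),                            # "more than 20 reads"
    ok_variant("BRAF", "c", quality = 19.99),
    ok_variant("BRAF", "d", vaf = 0.0099))
  res <- apply_quality_filters(v, cfg)
  expect_equal(res$kept$alteration, "a")
  expect_equal(res$removed$filter_reason[match(c("b", "c", "d"),
                                               res$removed$alteration)],
               c("depth", "quality", "vaf"))

  # missing QC fields are rejected, never kept
  miss <- ok_variant("BRAF", "e"); miss$depth <- NA
  expect_equal(apply_quality_filters(miss, cfg)$removed$filter_reason,
               "missing_field")

  empty <- apply_quality_filters(NULL, cfg)
  expect_equal(nrow(empty$kept), 0)
  expect_equal(nrow(empty$removed), 0)
})

test_that("population filter removes at >= 10% in any database", {
  v <- rbind(ok_variant("BRAF", "hit", pop_freq_exac = 0.10),
             ok_variant("BRAF", "edge", pop_freq_1kg = 0.099),
             ok_variant("BRAF", "nulls"))
  res <- apply_population_filter(v, cfg)
  expect_setequal(res$kept$alteration, c("edge", "nulls"))
  expect_equal(res$removed$alteration, "hit")
  expect_equal(res$removed$filter_reason, "pop_freq")
})

test_that("ACMG filter removes benign classes, keeps the rest", {
  v <- rbind(ok_variant("BRAF", "a", acmg = "likely_benign"),
             ok_variant("BRAF", "b", acmg = "benign"),
             ok_variant("BRAF", "c", acmg = "vus"),
             ok_variant("BRAF", "d", acmg = "pathogenic"))
  res <- apply_acmg_filter(v, cfg)
  expect_setequal(res$removed$alteration, c("a", "b"))
  expect_setequal(res$kept$alteration, c("c", "d"))
  expect_warning(res2 <- apply_acmg_filter(ok_variant("BRAF", "x", acmg = "odd"), cfg),
                 "unknown ACMG")
  expect_equal(nrow(res2$kept), 1)
})

test_that("virtual panel filter is case-insensitive set membership", {
  v <- rbind(ok_variant("braf", "in"), ok_variant("ZZZ9", "out"))
  res <- apply_virtual_panel(v, cfg$virtual_panel)
  expect_equal(res$kept$alteration, "in")
  expect_equal(res$removed$filter_reason, "panel")

  # kept set equals the set-intersection oracle on 1000 random variants
  set.seed(5)
  pool <- c(cfg$virtual_panel, paste0("G", 1:20))
  v <- ok_variant(sample(pool, 1000, replace = TRUE),
                  paste0("alt", seq_len(1000)))
  res <- apply_virtual_panel(v, cfg$virtual_panel)
  expect_setequal(res$kept$alteration,
                  v$alteration[v$gene %in% cfg$virtual_panel])
})

test_that("CNV rule enforces coverage and tumor-cell ratio", {
  cnv <- cbind(ok_variant("MET", "amp", variant_type = "CNV"), coverage = 100)
  ok_meta <- tiny_meta(tumor_cell_ratio = 0.30)
  expect_equal(nrow(filter_cnv_records(cnv, ok_meta, cfg)$kept), 1)

  low_ratio <- tiny_meta(tumor_cell_ratio = 0.29)
  res <- filter_cnv_records(cnv, low_ratio, cfg)
  expect_equal(nrow(res$kept), 0)
  expect_equal(res$removed$filter_reason, "tumor_ratio")

  low_cov <- cnv; low_cov$coverage <- 99
  expect_equal(filter_cnv_records(low_cov, ok_meta, cfg)$removed$filter_reason,
               "cnv_coverage")
  empty <- filter_cnv_records(NULL, ok_meta, cfg)
  expect_equal(nrow(empty$kept) + nrow(empty$removed), 0)
})

test_that("MSI classifier implements the strict >20% of five markers rule", {
  msi <- function(k) setNames(seq_len(5) <= k, c("NR-21", "NR-24", "BAT-25",
                                                 "BAT-26", "MONO-27"))
  expect_equal(classify_msi(msi(0)), "MSS")
  expect_equal(classify_msi(msi(1)), "MSS")   # exactly 20% is stable
  expect_equal(classify_msi(msi(2)), "MSI-H") # 40% > 20%
  expect_error(classify_msi(msi(2)[1:4]), "incomplete_msi_panel")
})

test_that("non-NGS results convert to variant records", {
  meta <- tiny_meta()
  fish <- data.frame(gene = c("ERBB2", "ALK"),
                     kind = c("amplification", "translocation"),
                     positive = c(TRUE, FALSE), stringsAsFactors = FALSE)
  out <- ingest_non_ngs_results(fish, NULL, NULL, meta)
  expect_equal(nrow(out), 1)
  expect_equal(out$gene, "ERBB2")
  expect_equal(out$variant_type, "CNV")
  expect_equal(out$alteration, "amplification")

  all_neg <- ingest_non_ngs_results(
    data.frame(gene = "MET", kind = "amplification", positive = FALSE),
    data.frame(marker = "PD-L1", positive = FALSE),
    setNames(rep(FALSE, 5), c("NR-21", "NR-24", "BAT-25", "BAT-26", "MONO-27")),
    meta)
  expect_equal(nrow(all_neg), 0)

  msi_h <- ingest_non_ngs_results(NULL, NULL,
    setNames(c(TRUE, TRUE, TRUE, FALSE, FALSE),
             c("NR-21", "NR-24", "BAT-25", "BAT-26", "MONO-27")), meta)
  expect_equal(msi_h$alteration, "MSI-H")
  expect_equal(msi_h$variant_type, "biomarker")
})

test_that("pipeline on the six-variant fixture keeps exactly one survivor", {
  prof <- run_filter_pipeline(six_variant_fixture(), tiny_meta(), cfg)
  expect_equal(nrow(prof$variants), 1)
  expect_equal(prof$variants$alteration, "p.pass")
  removed <- prof$filter_log[prof$filter_log$status == "removed", ]
  expect_setequal(removed$reason,
                  c("depth", "quality", "vaf", "pop_freq", "acmg"))
  # partition: every input row logged exactly once
  expect_equal(sort(prof$filter_log$row_id), 1:6)
})

test_that("pipeline handles empty input and flags inadequate tumor ratio", {
  prof <- run_filter_pipeline(NULL, tiny_meta(), cfg)
  expect_equal(nrow(prof$variants), 0)
  expect_equal(nrow(prof$filter_log), 0)
  low <- run_filter_pipeline(ok_variant(), tiny_meta(tumor_cell_ratio = 0.05), cfg)
  expect_match(low$warnings, "SNV adequacy")
})

random_profile <- function(n) {
  genes <- sample(c(cfg$virtual_panel, "OFF1", "OFF2"), n, replace = TRUE)
  data.frame(
    gene = genes, alteration = paste0("p.R", seq_len(n)),
    variant_type = sample(c("SNV", "indel", "CNV"), n, TRUE, prob = c(0.7, 0.2, 0.1)),
    depth = sample(0:60, n, TRUE), quality = runif(n, 0, 60),
    alt_allele_fraction = runif(n, 0, 0.3),
    pop_freq_1kg = ifelse(runif(n) < 0.3, runif(n, 0, 0.3), NA),
    pop_freq_exac = ifelse(runif(n) < 0.3, runif(n, 0, 0.3), NA),
    pop_freq_esp = NA_real_,
    acmg_class = sample(ACMG <- c("benign", "likely_benign", "vus",
                                  "pathogenic", "unclassified"), n, TRUE),
    coverage = sample(50:150, n, TRUE), stringsAsFactors = FALSE)
}

test_that("partition, idempotence and monotonicity hold on random profiles", {
  set.seed(99)
  tighter <- filter_config(min_depth_exclusive = 30,
                           virtual_panel = cfg$virtual_panel)
  meta <- tiny_meta(tumor_cell_ratio = 0.5)
  for (rep in 1:50) {  # the acceptance suite runs the same properties at 1000
    v <- random_profile(sample(1:25, 1))
    prof <- run_filter_pipeline(v, meta, cfg)
    # partition
    expect_equal(nrow(prof$filter_log), nrow(v))
    expect_equal(sort(prof$filter_log$row_id), seq_len(nrow(v)))
    expect_equal(sum(prof$filter_log$status == "kept"), nrow(prof$variants))
    # idempotence
    again <- run_filter_pipeline(prof$variants, meta, cfg)
    expect_equal(again$variants, prof$variants)
    # monotonicity: tightening depth never increases the kept count
    expect_lte(nrow(run_filter_pipeline(v, meta, tighter)$variants),
               nrow(prof$variants))
  }
})
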