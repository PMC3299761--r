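test_that("variant calling enforces coverage, artifact-fraction and length rules", {
  cfg <- filter_config()
  # 19% alt fraction: below the artifact rule
  expect_equal(nrow(call_variants(obs_row(ref_count = 81L, alt_count = 19L), cfg)), 0L)
  # at exactly 20% the allele is called
  expect_equal(nrow(call_variants(obs_row(ref_count = 80L, alt_count = 20L), cfg)), 1L)
  # coverage floor of 5
  expect_equal(nrow(call_variants(obs_row(ref_count = 0L, alt_count = 4L), cfg)), 0L)
  expect_equal(nrow(call_variants(obs_row(ref_count = 0L, alt_count = 5L), cfg)), 1L)
  # reference-only site never calls
  expect_equal(nrow(call_variants(obs_row(alt = ".", alt_count = 0L), cfg)), 0L)

  # a 42-base deletion is visible at 74-base reads, invisible at 41
  long <- obs_row(ref_count = 20L, alt_count = 20L, event_length = 42L)
  expect_equal(nrow(call_variants(long, filter_config(max_detectable_event = 74L))), 1L)
  expect_equal(nrow(call_variants(long, filter_config(max_detectable_event = 41L))), 0L)

  expect_equal(nrow(call_variants(obs_row()[0, ], cfg)), 0L)
})

test_that("the artifact rule and the calling rule commute", {
  set.seed(11)
  obs <- do.call(rbind, lapply(1:60, function(i) {
    obs_row(site = paste0("s", i),
            ref_count = sample(0:60, 1), alt_count = sample(0:30, 1))
  }))
  frac_only <- filter_config(call_min_coverage = 0L)
  cov_only <- filter_config(artifact_max_fraction = 0)
  both <- filter_config()
  a <- call_variants(call_variants(obs, frac_only), cov_only)
  b <- call_variants(call_variants(obs, cov_only), frac_only)
  c <- call_variants(obs, both)
  expect_setequal(a$site, c$site)
  expect_setequal(b$site, c$site)
})

test_that("tumor-unique filtering applies the reference-frequency drop", {
  cfg <- filter_config()
  # heterozygous somatic: tumor ref-freq 0.50 vs normal 1.00 -> kept
  p1 <- paired_site("s1", t_ref = 50L, t_alt = 50L, n_ref = 100L, n_alt = 0L)
  calls <- call_variants(p1[p1$tissue == "tumor", ], cfg)
  res <- tumor_unique(calls, p1, cfg)
  expect_equal(nrow(res$kept), 1L)

  # drop of 0.20 < 0.25 -> dropped
  p2 <- paired_site("s2", t_ref = 80L, t_alt = 20L, n_ref = 100L, n_alt = 0L)
  res <- tumor_unique(call_variants(p2[p2$tissue == "tumor", ], cfg), p2, cfg)
  expect_equal(nrow(res$kept), 0L)
  expect_equal(res$dropped$drop_reason, "ref_freq_drop")

  # tumor coverage below 20 -> dropped regardless of frequencies
  p3 <- paired_site("s3", t_ref = 9L, t_alt = 10L, n_ref = 100L, n_alt = 0L)
  res <- tumor_unique(call_variants(p3[p3$tissue == "tumor", ], cfg), p3, cfg)
  expect_equal(nrow(res$kept), 0L)
  expect_equal(res$dropped$drop_reason, "low_coverage_pair")

  # germline variant present in the normal call set -> dropped
  p4 <- paired_site("s4", t_ref = 50L, t_alt = 50L, n_ref = 50L, n_alt = 50L)
  res <- tumor_unique(call_variants(p4[p4$tissue == "tumor", ], cfg), p4, cfg)
  expect_equal(nrow(res$kept), 0L)

  # normal ref-freq 0.90 (sub-threshold alt reads): the two readings differ
  # at tumor ref-freq 0.67 (absolute needs <= 0.65, relative <= 0.675)
  p5 <- paired_site("s5", t_ref = 67L, t_alt = 33L, n_ref = 90L, n_alt = 10L)
  calls5 <- call_variants(p5[p5$tissue == "tumor", ], cfg)
  expect_equal(nrow(tumor_unique(calls5, p5, cfg)$kept), 0L)
  rel <- filter_config(ref_freq_rule = "relative")
  expect_equal(nrow(tumor_unique(calls5, p5, rel)$kept), 1L)

  # unpaired sample is an error
  lone <- obs_row(site = "s9")
  expect_error(tumor_unique(call_variants(lone, cfg), lone[0, ], cfg),
               class = "med12scan_pairing_error")
})

test_that("region, dbSNP and synonymy filtering categorizes survivors", {
  cfg <- filter_config()
  m <- fixture_model()
  vars <- rbind(
    obs_row(site = "known", dbsnp = TRUE),
    obs_row(site = "silent", synonymous = TRUE, ref_aa = "G", alt_aa = "G"),
    obs_row(site = "deep", region = "deep_intronic"),
    obs_row(site = "splice_snv", region = "splice_region"),
    obs_row(site = "keeper"),
    obs_row(site = "indel", event_length = 6L, synonymous = NA),
    obs_row(site = "spl_indel", region = "splice_region", event_length = 4L,
            synonymous = NA))
  res <- filter_region_dbsnp_synonymous(vars, m, cfg)
  expect_setequal(res$dropped$site, c("known", "silent", "deep"))
  expect_equal(res$kept$category[res$kept$site == "splice_snv"], "intronic_snv")
  expect_equal(res$kept$category[res$kept$site == "keeper"], "exonic_snv")
  expect_equal(res$kept$category[res$kept$site == "indel"], "exonic_del_indel")
  expect_equal(res$kept$category[res$kept$site == "spl_indel"], "intronic_del_indel")

  # model-gene rows with missing region/synonymy resolve through the model
  mg <- rbind(
    obs_row(site = "m1", gene = "MED12", pos = 132L, region = NA,
            synonymous = NA, ref = "T", alt = "C"), # third base of codon 44
    obs_row(site = "m2", gene = "MED12", pos = 131L, region = NA,
            synonymous = NA, ref = "G", alt = "A"),
    obs_row(site = "m3", gene = "MED12", pos = 100L, offset = -8L,
            region = NA, synonymous = NA, ref = "T", alt = "A"))
  res <- filter_region_dbsnp_synonymous(mg, m, cfg)
  expect_setequal(res$dropped$site, "m1") # synonymous via the model
  expect_equal(res$kept$category[res$kept$site == "m2"], "exonic_snv")
  expect_equal(res$kept$category[res$kept$site == "m3"], "intronic_snv")
})

test_that("damaging filter consults the predicate for missense only", {
  vars <- rbind(
    cbind(obs_row(site = "gd", ref_aa = "G", alt_aa = "D"), category = "exonic_snv"),
    cbind(obs_row(site = "gv", ref_aa = "G", alt_aa = "V"), category = "exonic_snv"),
    cbind(obs_row(site = "li", ref_aa = "L", alt_aa = "I"), category = "exonic_snv"),
    cbind(obs_row(site = "indel", event_length = 3L, ref_aa = NA, alt_aa = NA),
          category = "exonic_del_indel"),
    cbind(obs_row(site = "spl", region = "splice_region", ref_aa = NA, alt_aa = NA),
          category = "intronic_snv"))
  res <- damaging_filter(vars)
  # Grantham: G-D 94, G-V 109 damaging; L-I 5 benign; non-missense pass
  expect_setequal(res$kept$site, c("gd", "gv", "indel", "spl"))
  expect_equal(res$dropped$site, "li")

  never <- damaging_filter(vars[1:3, ], predicate = function(row) FALSE)
  expect_equal(nrow(never$kept), 0L)
})

test_that("grantham distances back the default predicate", {
  expect_equal(grantham_distance("G", "V"), 109)
  expect_equal(grantham_distance("G", "D"), 94)
  expect_equal(grantham_distance("G", "S"), 56)
  expect_equal(grantham_distance("L", "I"), 5)
  expect_equal(grantham_distance("A", "A"), 0)
  expect_error(grantham_distance("G", "B"), class = "med12scan_contract_error")
})

test_that("recurrently hit genes are found across samples", {
  pairs <- lapply(1:5, function(i) {
    simulate_pair(n_sites = 300L, n_somatic = 3L, n_germline = 20L,
                  n_artifacts = 5L, n_long_deletions = 0L,
                  sample_id = paste0("S", i), seed = 100L + i,
                  model = fixture_model(),
                  hotspot_descriptor = if (i <= 2) "c.131G>A" else NULL)
  })
  obs <- do.call(rbind, lapply(pairs, `[[`, "observations"))
  res <- run_cascade(obs, fixture_model())
  rec <- recurrent_genes(res$variants, k = 2L)
  expect_true("MED12" %in% rec$gene)
  expect_true(all(rec$n_samples >= 2L))
  expect_equal(nrow(recurrent_genes(res$variants, k = 6L)), 0L)
  expect_error(recurrent_genes(res$variants, k = 1L),
               class = "med12scan_contract_error")
})

test_that("the cascade recovers planted truth and rejects everything else", {
  m <- fixture_model()
  pair <- simulate_pair(seed = 5L, model = m, noise = FALSE)
  res <- run_cascade(pair$observations, m)
  expected <- pair$truth$site[pair$truth$expected_to_survive_cascade]
  expect_setequal(res$variants$site, expected)

  # self-pairing: identical tumor and normal yields no somatic calls
  obs <- pair$observations
  tum <- obs[obs$tissue == "tumor", ]
  self <- rbind(tum, transform(tum, tissue = "normal"))
  res_self <- run_cascade(self, m)
  expect_equal(nrow(res_self$variants), 0L)
})

test_that("trace counts are monotone and categories partition the filtered set", {
  m <- fixture_model()
  for (seed in c(21L, 22L)) {
    pair <- simulate_pair(seed = seed, model = m)
    tr <- run_cascade(pair$observations, m)$trace
    expect_true(tr$raw_in_region >= tr$unique_to_tumor)
    expect_true(tr$unique_to_tumor >= tr$filtered)
    expect_true(tr$filtered >= tr$damaging)
    expect_equal(tr$filtered, tr$exonic_snv + tr$intronic_snv +
                   tr$exonic_del_indel + tr$intronic_del_indel)
  }
  # empty input: zero-row trace, no error
  empty <- run_cascade(obs_row()[0, ], m)
  expect_equal(nrow(empty$trace), 0L)
  expect_equal(nrow(empty$variants), 0L)
})

test_that("the long-deletion blind spot follows the read-length cutoff", {
  m <- fixture_model()
  pair <- simulate_pair(seed = 9L, model = m, noise = FALSE)
  truth_del <- pair$truth[pair$truth$planted_class == "long_deletion", ]
  expect_equal(nrow(truth_del), 1L)

  seen <- run_cascade(pair$observations, m)$variants
  expect_true(truth_del$site %in% seen$site)

  blind <- filter_config(max_detectable_event = 41L)
  unseen <- run_cascade(pair$observations, m, blind)$variants
  expect_false(truth_del$site %in% unseen$site)
  # the annotation path still resolves the event from its descriptor
  cons <- apply_and_consequence(m, truth_del$descriptor)
  expect_identical(format_consequence(cons), "p.V41_D54del")
})

test_that("filter configuration validates its ranges", {
  expect_error(filter_config(artifact_max_fraction = 1.2),
               class = "med12scan_contract_error")
  expect_error(filter_config(ref_freq_drop = 0),
               class = "med12scan_contract_error")
})
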