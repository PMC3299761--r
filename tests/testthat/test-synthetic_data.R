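test_that("the pair generator is deterministic under a fixed seed", {
  m <- fixture_model()
  a <- simulate_pair(seed = 3L, model = m)
  b <- simulate_pair(seed = 3L, model = m)
  expect_identical(a, b)
  c <- simulate_pair(seed = 4L, model = m)
  expect_false(identical(a$observations, c$observations))
})

test_that("planted classes carry the intended read-count structure", {
  m <- fixture_model()
  pair <- simulate_pair(seed = 17L, model = m, noise = FALSE,
                        mean_coverage = 100)
  obs <- pair$observations
  tr <- pair$truth
  t_obs <- obs[obs$tissue == "tumor", ]
  n_obs <- obs[obs$tissue == "normal", ]
  t_at <- t_obs[match(tr$site, t_obs$site), ]
  n_at <- n_obs[match(tr$site, n_obs$site), ]
  t_frac <- t_at$alt_count / (t_at$ref_count + t_at$alt_count)
  n_frac <- n_at$alt_count / (n_at$ref_count + n_at$alt_count)

  som <- tr$planted_class %in% c("somatic_het", "long_deletion")
  expect_true(all(abs(t_frac[som] - 0.5) < 0.02))
  expect_true(all(n_frac[som] == 0))
  het <- tr$planted_class == "germline_het"
  expect_true(all(abs(t_frac[het] - 0.5) < 0.02))
  expect_true(all(abs(n_frac[het] - 0.5) < 0.02))
  hom <- tr$planted_class == "germline_hom"
  expect_true(all(t_frac[hom] == 1 & n_frac[hom] == 1))
  art <- tr$planted_class == "artifact"
  expect_true(all(t_frac[art] < 0.20 & n_frac[art] == 0))

  # purity dilutes the somatic fraction
  dil <- simulate_pair(seed = 17L, model = m, noise = FALSE, tumor_purity = 0.6)
  d_obs <- dil$observations[dil$observations$tissue == "tumor", ]
  d_tr <- dil$truth[dil$truth$planted_class == "somatic_het", ]
  d_at <- d_obs[match(d_tr$site, d_obs$site), ]
  expect_true(all(abs(d_at$alt_count / (d_at$ref_count + d_at$alt_count) - 0.3) < 0.02))
})

test_that("a priori survival labels match actual cascade behaviour without noise", {
  m <- fixture_model()
  pair <- simulate_pair(seed = 31L, model = m, noise = FALSE)
  got <- run_cascade(pair$observations, m)$variants$site
  expect_setequal(got, pair$truth$site[pair$truth$expected_to_survive_cascade])
  # survival labels are class + config functions only
  expect_true(all(pair$truth$expected_to_survive_cascade ==
                    expected_survival(pair$truth$planted_class,
                                      pair$truth$event_length)))
  expect_false(any(expected_survival(c("germline_het", "germline_hom", "artifact"))))
  expect_false(expected_survival("long_deletion", 42L,
                                 filter_config(max_detectable_event = 41L)))
})

test_that("infeasible generator parameterizations are contract errors", {
  expect_error(simulate_pair(n_sites = 10L, n_somatic = 20L, seed = 1L,
                             model = fixture_model()),
               class = "med12scan_contract_error")
  expect_error(simulate_pair(tumor_purity = 0, seed = 1L, model = fixture_model()),
               class = "med12scan_contract_error")
  expect_error(simulate_pair(artifact_fraction_range = c(0.1, 0.3), seed = 1L,
                             model = fixture_model()),
               class = "med12scan_contract_error")
  expect_error(cohort_spec(n_tumors = 50L), class = "med12scan_contract_error")
})

test_that("no somatic plantings means an empty cascade output", {
  m <- fixture_model()
  pair <- simulate_pair(n_somatic = 0L, n_long_deletions = 0L, seed = 8L,
                        model = m, noise = FALSE)
  expect_equal(nrow(run_cascade(pair$observations, m)$variants), 0L)
})

test_that("cohort generation conserves the spectrum exactly and is deterministic", {
  coh1 <- simulate_cohort(cohort_spec(seed = 5L))
  coh2 <- simulate_cohort(cohort_spec(seed = 5L))
  expect_identical(coh1, coh2)
  expect_false(identical(coh1$sample[coh1$med12_status != "WT"],
                         simulate_cohort(cohort_spec(seed = 6L))$sample[
                           simulate_cohort(cohort_spec(seed = 6L))$med12_status != "WT"]))

  expect_equal(nrow(coh1), 148L)
  expect_equal(attr(coh1, "n_normals"), 73L)
  counts <- table(coh1$med12_status[coh1$med12_status != "WT"])
  spectrum <- med12_spectrum()
  expect_equal(sum(coh1$med12_status != "WT"), 100L)
  for (d in names(spectrum)) {
    expect_equal(as.integer(counts[[d]]), unname(spectrum[[d]]), label = d)
  }
})

test_that("default cohort reproduces every published stratum margin", {
  coh <- simulate_cohort(cohort_spec(seed = 2L))
  mut <- coh$med12_status != "WT"
  margin <- function(col, level) {
    c(sum(mut & !is.na(coh[[col]]) & coh[[col]] == level),
      sum(!is.na(coh[[col]]) & coh[[col]] == level))
  }
  expect_equal(margin("karyotype", "normal"), c(59L, 85L))
  expect_equal(margin("karyotype", "abnormal"), c(31L, 49L))
  expect_equal(margin("race", "B"), c(18L, 23L))
  expect_equal(margin("race", "W"), c(79L, 120L))
  expect_equal(margin("multiplicity", "multiple"), c(87L, 120L))
  expect_equal(margin("multiplicity", "single"), c(9L, 22L))
})

test_that("non-default cohort sizes scale proportionally and stay consistent", {
  coh <- simulate_cohort(cohort_spec(n_tumors = 200L, seed = 3L))
  expect_equal(nrow(coh), 200L)
  expect_equal(sum(coh$med12_status != "WT"), 100L) # exact assignment
  small <- cohort_spec(n_tumors = 148L,
                       spectrum = c("c.131G>A" = 10L), seed = 4L)
  coh_small <- simulate_cohort(small)
  expect_equal(sum(coh_small$med12_status != "WT"), 10L)
  empty <- simulate_cohort(cohort_spec(spectrum = integer(0), seed = 4L))
  expect_equal(sum(empty$med12_status != "WT"), 0L)
})

test_that("expression labels model exclusive mutant-allele expression", {
  coh <- simulate_cohort(cohort_spec(seed = 12L))
  lab <- expression_labels(coh)
  mut <- coh$med12_status != "WT"
  expect_true(all(lab$expressed_allele[mut] == "mutant_expressed"))
  expect_true(all(is.na(lab$expressed_allele[!mut])))
  # any random draw of mutated tumors is fully mutant-expressed
  pick <- sample(which(mut), 10L)
  expect_equal(sum(lab$expressed_allele[pick] == "mutant_expressed"), 10L)
})
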