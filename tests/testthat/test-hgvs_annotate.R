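test_that("descriptor grammar parses SNVs, deletions, delins and IVS forms", {
  v <- parse_cdna("c.122_163del42")
  expect_equal(v$kind, "del")
  expect_equal(v$start$base, 122L)
  expect_equal(v$end$base, 163L)
  expect_equal(v$end$base - v$start$base + 1L, 42L)

  v <- parse_cdna("c.130G>A")
  expect_equal(v$kind, "snv")
  expect_equal(v$start$base, 130L)
  expect_equal(v$ref, "G")
  expect_equal(v$alt, "A")

  v <- parse_cdna("c.107_111del5insGC")
  expect_equal(v$kind, "delins")
  expect_equal(v$alt, "GC")

  v <- parse_cdna("IVS1-8T>A")
  expect_equal(v$start$offset, -8L)
  expect_equal(v$intron, 1L)

  v <- parse_cdna("IVS1-2_141del44insAG")
  expect_equal(v$kind, "delins")
  expect_equal(v$start$offset, -2L)
  expect_equal(v$end$base, 141L)
  expect_equal(v$stated_len, 44L)

  v <- parse_cdna("c.130G>T;c.131G>T")
  expect_equal(v$kind, "mnv")
  expect_length(v$snvs, 2L)
})

test_that("inconsistent or malformed descriptors are rejected with named errors", {
  # the erratum form: span 43 but stated length 42
  expect_error(parse_cdna("c.122_164del42"), "spans 43",
               class = "med12scan_consistency_error")
  expect_error(parse_cdna("c.130G>G"), class = "med12scan_parse_error")
  expect_error(parse_cdna("g.130G>A"), "g\\.130G>A",
               class = "med12scan_parse_error")
  expect_error(parse_cdna("c.163_122del42"), class = "med12scan_parse_error")
  expect_error(parse_cdna(""), class = "med12scan_parse_error")
  expect_error(parse_cdna("c.130G>A;c.118_132del15"),
               class = "med12scan_parse_error")
  # splice-spanning length checks happen at annotation (anchor needed)
  expect_error(apply_and_consequence(fixture_model(), "IVS1-1_139del42"),
               class = "med12scan_consistency_error")
})

test_that("every published descriptor/protein pair round-trips byte-identically", {
  m <- fixture_model()
  pairs <- spectrum_pairs()
  for (i in seq_len(nrow(pairs))) {
    v <- parse_cdna(pairs$descriptor[i])
    expect_identical(format_cdna(v), pairs$descriptor[i],
                     label = paste("descriptor", pairs$descriptor[i]))
    got <- format_consequence(apply_and_consequence(m, v))
    expect_identical(got, pairs$protein[i],
                     label = paste(pairs$descriptor[i], "->", got))
  }
})

test_that("consequences agree with the independent mutate/translate/diff oracle", {
  m <- fixture_model()
  pairs <- spectrum_pairs()
  exonic <- pairs$descriptor[!startsWith(pairs$descriptor, "IVS")]
  for (d in exonic) {
    cons <- apply_and_consequence(m, d)
    ora <- oracle_consequence(m, d)
    if (cons$klass == "missense") {
      expect_equal(nchar(ora$deleted), 1L)
      expect_identical(ora$deleted, cons$start_res)
      expect_identical(ora$inserted, cons$inserted)
      expect_equal(ora$del_start, cons$start_idx)
    } else if (cons$klass == "inframe_del") {
      expect_identical(ora$inserted, "")
      expect_equal(ora$del_start, cons$start_idx, label = d)
      expect_equal(ora$del_end, cons$end_idx, label = d)
    } else if (cons$klass == "inframe_delins") {
      expect_identical(ora$inserted, cons$inserted, label = d)
      expect_equal(ora$del_start, cons$start_idx, label = d)
      expect_equal(ora$del_end, cons$end_idx, label = d)
    }
  }
})

test_that("in-frame deletion bookkeeping follows the span arithmetic", {
  m <- fixture_model()
  pairs <- spectrum_pairs()
  dels <- grep("^c\\.\\d+_\\d+del\\d+$", pairs$descriptor, value = TRUE)
  for (d in dels) {
    v <- parse_cdna(d)
    span <- v$end$base - v$start$base + 1L
    cons <- apply_and_consequence(m, v)
    if (cons$klass == "inframe_del") {
      expect_equal(cons$end_idx - cons$start_idx + 1L, span %/% 3L, label = d)
    } else if (cons$klass == "inframe_delins") {
      # composite codon inserts exactly one residue
      expect_equal(cons$end_idx - cons$start_idx + 1L, span %/% 3L + 1L, label = d)
      expect_equal(nchar(cons$inserted), 1L, label = d)
    }
  }
  # codon-aligned single-codon deletion
  cons <- apply_and_consequence(m, "c.130_132del3")
  expect_equal(cons$klass, "inframe_del")
  expect_equal(cons$start_idx, 44L)
  expect_equal(cons$end_idx, 44L)
  expect_identical(format_consequence(cons), "p.G44del")
})

test_that("consequence naming is invariant under shifted equivalent descriptors", {
  # a Lys-Lys repeat makes two distinct cDNA deletions protein-equivalent
  exons <- data.frame(exon = 1L, cdna_start = 1L, cdna_end = 12L)
  mm <- transcript_model("TOY", exons, "ATGAAAAAATGG")
  a <- apply_and_consequence(mm, "c.4_6del3")
  b <- apply_and_consequence(mm, "c.7_9del3")
  expect_identical(format_consequence(a), format_consequence(b))
  expect_identical(format_consequence(a), "p.K3del") # most 3' representation
  expect_equal(a$start_idx, b$start_idx)
})

test_that("frame-disrupting deletions are flagged as frameshift", {
  m <- fixture_model()
  cons <- apply_and_consequence(m, "c.130_133del4")
  expect_equal(cons$klass, "frameshift")
  expect_match(format_consequence(cons), "fs$")
})

test_that("splice-site SNVs are resolved through the cryptic-acceptor rule", {
  m <- fixture_model()
  cons <- apply_and_consequence(m, "IVS1-8T>A")
  expect_equal(cons$klass, "splice_alteration_ins")
  expect_identical(cons$inserted, "PQ")
  expect_identical(format_consequence(cons), "p.E33_D34insPQ")
  # modern alias is accepted
  alias <- apply_and_consequence(m, "c.100-8T>A")
  expect_identical(format_consequence(alias), "p.E33_D34insPQ")
  # a substitution that creates no AG stays an unresolved splice alteration
  cons2 <- apply_and_consequence(m, "IVS1-5C>A")
  expect_equal(cons2$klass, "splice_alteration")
  # reference mismatch in the intron tail is caught
  expect_error(apply_and_consequence(m, "IVS1-8G>A"),
               class = "med12scan_coord_error")
})

test_that("synonymy detection enumerates codon 44 correctly", {
  m <- fixture_model()
  expect_false(is_synonymous(m, "c.130G>A"))
  expect_true(is_synonymous(m, "c.132T>C")) # glycine is 4-fold degenerate
  expect_error(is_synonymous(m, "c.118_132del15"),
               class = "med12scan_contract_error")

  # exhaustive: all 9 SNVs in codon 44; only third-position changes are silent
  n_nonsyn <- 0L
  for (p in 130:132) {
    ref <- substr(m$cds_sequence, p, p)
    for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
      d <- sprintf("c.%d%s>%s", p, ref, alt)
      if (!is_synonymous(m, d)) {
        n_nonsyn <- n_nonsyn + 1L
        expect_equal(apply_and_consequence(m, d)$klass, "missense")
      } else {
        expect_equal(codon_of(p)$phase, 3L)
      }
    }
  }
  expect_equal(n_nonsyn, 6L)
})

test_that("formatting normalizes degenerate consequences", {
  m <- fixture_model()
  # delins with empty insertion prints as a plain deletion
  cons <- apply_and_consequence(m, "c.118_132del15")
  cons$klass <- "inframe_delins"
  cons$inserted <- ""
  expect_identical(format_consequence(cons), "p.N40_G44del")
  # synonymous SNV names the unchanged residue
  syn <- apply_and_consequence(m, "c.132T>C")
  expect_identical(format_consequence(syn), "p.G44=")
})

test_that("reference mismatches and out-of-range variants are coordinate errors", {
  m <- fixture_model()
  expect_error(apply_and_consequence(m, "c.130A>C"),
               class = "med12scan_coord_error")
  expect_error(apply_and_consequence(m, "c.9990G>A"),
               class = "med12scan_coord_error")
  expect_error(apply_and_consequence(m, "c.6530_6540del11"),
               class = "med12scan_coord_error")
})

test_that("annotate_variants survives per-record failures", {
  m <- fixture_model()
  ann <- annotate_variants(m, c("c.131G>A", "nonsense", "c.122_164del42"))
  expect_equal(nrow(ann), 3L)
  expect_identical(ann$protein_change[1], "p.G44D")
  expect_true(all(!is.na(ann$error[2:3])))
  expect_true(is.na(ann$error[1]))
})
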