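# Shared fixtures: the published exon 2 descriptor -> protein pairs, a
# memoized fixture model, and an independent consequence oracle built on
# Biostrings translation (the package's own engine uses its own codon
# table and string surgery; the oracle shares neither).

fixture_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_fixture_model()
    cache
  }
})

# All descriptor/protein pairs of the exon 2 mutation spectrum.
spectrum_pairs <- function() {
  data.frame(rbind(
    c("IVS1-8T>A", "p.E33_D34insPQ"),
    c("IVS1-1_139del41", "Splice acceptor loss"),
    c("IVS1-2_141del44insAG", "Splice acceptor loss"),
    c("c.107T>G", "p.L36R"),
    c("c.128A>C", "p.Q43P"),
    c("c.130G>C", "p.G44R"),
    c("c.130G>A", "p.G44S"),
    c("c.130G>T", "p.G44C"),
    c("c.131G>C", "p.G44A"),
    c("c.131G>A", "p.G44D"),
    c("c.131G>T", "p.G44V"),
    c("c.130G>T;c.131G>T", "p.G44F"),
    c("c.103_138del36", "p.E35_N46del"),
    c("c.107_111del5insGC", "p.L36_T37delinsR"),
    c("c.111_155del45", "p.A38_S52del"),
    c("c.113_121del9", "p.A38_N40del"),
    c("c.117_122del6", "p.N40_V41del"),
    c("c.118_132del15", "p.N40_G44del"),
    c("c.118_134del17insTA", "p.N40_F45delinsY"),
    c("c.118_146del29insTT", "p.N40_P49delinsF"),
    c("c.122_148del27", "p.V41_P49del"),
    c("c.122_163del42", "p.V41_D54del"),
    c("c.123_152del30", "p.K42_V51del"),
    c("c.126_131del6", "p.K42_G44delinsN"),
    c("c.126_140del15", "p.K42_F45del"),
    c("c.129_137del9", "p.Q43_N46delinsH"),
    c("c.129_143del15", "p.G44_Q48del"),
    c("c.133_144del12", "p.F45_Q48del"),
    c("c.149_163del15", "p.A50_D54del")
  )) |> stats::setNames(c("descriptor", "protein"))
}

# Published carrier counts with both percentage columns as printed
# (n / % of 148 genotyped / % of 100 mutated).
spectrum_percent_rows <- function() {
  data.frame(
    descriptor = c("IVS1-8T>A", "c.107T>G", "c.128A>C", "c.130G>C",
                   "c.130G>A", "c.130G>T", "c.131G>C", "c.131G>A",
                   "c.131G>T", "c.130G>T;c.131G>T", "c.122_163del42"),
    n = c(2L, 3L, 5L, 7L, 9L, 8L, 5L, 32L, 9L, 1L, 1L),
    pct_total = c(1.4, 2.0, 3.4, 4.7, 6.1, 5.4, 3.4, 21.6, 6.1, 0.7, 0.7),
    pct_mutated = c(2.0, 3.0, 5.0, 7.0, 9.0, 8.0, 5.0, 32.0, 9.0, 1.0, 1.0))
}

# Independent translation via Biostrings (GENETIC_CODE), not the package's
# codon table.
bs_translate <- function(seq) {
  as.character(Biostrings::translate(Biostrings::DNAString(seq)))
}

# Independent consequence oracle for fully exonic variants: mutate the CDS,
# translate both strands with Biostrings, and extract the difference by
# scanning matched positions from both ends.
oracle_consequence <- function(model, descriptor) {
  v <- parse_cdna(descriptor)
  cds <- model$cds_sequence
  mut <- if (v$kind == "mnv") {
    m <- cds
    for (s in v$snvs) substr(m, s$start$base, s$start$base) <- s$alt
    m
  } else if (v$kind == "snv") {
    m <- cds
    substr(m, v$start$base, v$start$base) <- v$alt
    m
  } else {
    paste0(substr(cds, 1, v$start$base - 1), v$alt,
           substr(cds, v$end$base + 1, nchar(cds)))
  }
  ref_aa <- strsplit(bs_translate(cds), "")[[1]]
  mut_aa <- strsplit(bs_translate(mut), "")[[1]]
  i <- 1
  while (i <= min(length(ref_aa), length(mut_aa)) && ref_aa[i] == mut_aa[i]) {
    i <- i + 1
  }
  j_r <- length(ref_aa); j_m <- length(mut_aa)
  while (j_r >= i && j_m >= i && ref_aa[j_r] == mut_aa[j_m]) {
    j_r <- j_r - 1; j_m <- j_m - 1
  }
  list(deleted = if (j_r >= i) paste0(ref_aa[i:j_r], collapse = "") else "",
       inserted = if (j_m >= i) paste0(mut_aa[i:j_m], collapse = "") else "",
       del_start = i, del_end = j_r)
}

# Minimal observation row builder for filter tests.
obs_row <- function(sample_id = "S1", tissue = "tumor", gene = "GENE001",
                    site = "s1", pos = NA_integer_, offset = 0L,
                    region = "exonic", ref = "G", alt = "A",
                    ref_count = 50L, alt_count = 50L, dbsnp = FALSE,
                    event_length = 0L, synonymous = FALSE,
                    ref_aa = "G", alt_aa = "D", descriptor = NA_character_) {
  data.frame(sample_id = sample_id, tissue = tissue, gene = gene, site = site,
             pos = pos, offset = offset, region = region, ref = ref, alt = alt,
             ref_count = ref_count, alt_count = alt_count, dbsnp = dbsnp,
             event_length = event_length, synonymous = synonymous,
             ref_aa = ref_aa, alt_aa = alt_aa, descriptor = descriptor)
}

# A paired site: tumor row + matching normal row.
paired_site <- function(site, t_ref, t_alt, n_ref, n_alt, ...) {
  rbind(obs_row(site = site, tissue = "tumor", ref_count = t_ref,
                alt_count = t_alt, ...),
        obs_row(site = site, tissue = "normal", ref_count = n_ref,
                alt_count = n_alt, ...))
}
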