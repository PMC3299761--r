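# Synthetic paired-exome generator: per-site tumor/normal read-count tables
# with planted truth, and cohort genotype/stratum tables reproducing the
# published exon 2 mutation spectrum. Every downstream stage is testable
# without any sequencing download.

#' The reference exon 2 mutation spectrum
#'
#' Per-descriptor carrier counts for the MED12 exon 2 variants observed in
#' a cohort of 148 genotyped leiomyomas (100 mutated). Counts sum to 100.
#'
#' @return Named integer vector: descriptor -> number of carrier tumors.
#' @export
med12_spectrum <- function() {
  c("IVS1-8T>A"            = 2L,
    "IVS1-1_139del41"      = 1L,
    "IVS1-2_141del44insAG" = 1L,
    "c.107T>G"             = 3L,
    "c.128A>C"             = 5L,
    "c.130G>C"             = 7L,
    "c.130G>A"             = 9L,
    "c.130G>T"             = 8L,
    "c.131G>C"             = 5L,
    "c.131G>A"             = 32L,
    "c.131G>T"             = 9L,
    "c.130G>T;c.131G>T"    = 1L,
    "c.103_138del36"       = 1L,
    "c.107_111del5insGC"   = 1L,
    "c.111_155del45"       = 1L,
    "c.113_121del9"        = 1L,
    "c.117_122del6"        = 1L,
    "c.118_132del15"       = 1L,
    "c.118_134del17insTA"  = 1L,
    "c.118_146del29insTT"  = 1L,
    "c.122_148del27"       = 1L,
    "c.122_163del42"       = 1L,
    "c.123_152del30"       = 1L,
    "c.126_131del6"        = 1L,
    "c.126_140del15"       = 1L,
    "c.129_137del9"        = 1L,
    "c.129_143del15"       = 1L,
    "c.133_144del12"       = 1L,
    "c.149_163del15"       = 1L)
}

#' Cohort generation parameters
#'
#' Defaults reproduce the reference study conditions: 148 genotyped tumors,
#' 73 matched normal tissues, the [med12_spectrum()] carrier counts
#' (assigned exactly, not sampled), and stratum margins of 59/85 mutated in
#' karyotypically normal vs 31/49 in abnormal tumors (14 tumors without
#' karyotype), 18/23 in black vs 79/120 in white American women (5 without
#' race), and 87/120 with multiple tumors vs 9/22 with a single tumor
#' (6 without multiplicity data).
#'
#' @param n_tumors Number of genotyped tumors (default 148).
#' @param n_normals Number of matched normal myometrial samples (default 73).
#' @param spectrum Named integer vector descriptor -> carrier count; its sum
#'   must not exceed `n_tumors`.
#' @param seed Integer seed.
#' @return List of class `cohort_spec`.
#' @export
cohort_spec <- function(n_tumors = 148L, n_normals = 73L,
                        spectrum = med12_spectrum(), seed = 1L) {
  n_tumors <- as.integer(n_tumors)
  if (sum(spectrum) > n_tumors) {
    stop_med12("contract_error", "spectrum assigns ", sum(spectrum),
               " carriers to only ", n_tumors, " tumors")
  }
  structure(list(n_tumors = n_tumors, n_normals = as.integer(n_normals),
                 spectrum = spectrum, seed = as.integer(seed)),
            class = "cohort_spec")
}

# Scale a carrier spectrum to a smaller total by largest remainder,
# preserving the relative descriptor frequencies.
scale_spectrum <- function(spectrum, target) {
  target <- max(0L, as.integer(target))
  if (sum(spectrum) <= target) return(spectrum)
  x <- spectrum / sum(spectrum) * target
  out <- floor(x)
  rem <- target - sum(out)
  if (rem > 0) {
    o <- order(x - out, decreasing = TRUE)
    out[o[seq_len(rem)]] <- out[o[seq_len(rem)]] + 1
  }
  stats::setNames(as.integer(out), names(spectrum))[out > 0]
}

# Stratum counts (mutated / wild-type x level1 / level2 / missing) at the
# reference margins, scaled proportionally for other cohort sizes.
.stratum_counts <- function(n_mut, n_wt, mut_ref, wt_ref) {
  scale_to <- function(ref, n) {
    if (n == sum(ref)) return(ref)
    x <- ref / sum(ref) * n
    out <- floor(x)
    rem <- n - sum(out)
    if (rem > 0) {
      o <- order(x - out, decreasing = TRUE)
      out[o[seq_len(rem)]] <- out[o[seq_len(rem)]] + 1
    }
    out
  }
  list(mut = scale_to(mut_ref, n_mut), wt = scale_to(wt_ref, n_wt))
}

#' Generate a cohort genotype/stratum table
#'
#' Each spectrum descriptor is assigned to exactly its count of tumors
#' (assignment without sampling, so the spectrum is conserved); remaining
#' tumors are wild-type. Karyotype, race and multiplicity are assigned per
#' MED12 status so that at the default size every published 2x2 margin is
#' reproduced exactly. Tumor size and patient age are drawn from documented
#' placeholder distributions and carry no reference values.
#'
#' @param spec A [cohort_spec()].
#' @return `data.frame` with columns `sample`, `karyotype`
#'   (`normal`/`abnormal`/NA), `race` (`B`/`W`/NA), `multiplicity`
#'   (`multiple`/`single`/NA), `size_cm`, `age`, `med12_status` (descriptor
#'   or `"WT"`). The number of normal samples is attached as attribute
#'   `n_normals` (none of which carries a variant).
#' @export
simulate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    n <- spec$n_tumors
    status <- c(rep(names(spec$spectrum), spec$spectrum),
                rep("WT", n - sum(spec$spectrum)))
    n_mut <- sum(status != "WT"); n_wt <- n - n_mut

    assign_stratum <- function(levels2, mut_ref, wt_ref) {
      cnt <- .stratum_counts(n_mut, n_wt, mut_ref, wt_ref)
      lv <- c(levels2, NA_character_)
      out <- character(n)
      out[status != "WT"] <- sample(rep(lv, cnt$mut))
      out[status == "WT"] <- sample(rep(lv, cnt$wt))
      out
    }
    karyotype <- assign_stratum(c("normal", "abnormal"),
                                mut_ref = c(59, 31, 10), wt_ref = c(26, 18, 4))
    race <- assign_stratum(c("B", "W"),
                           mut_ref = c(18, 79, 3), wt_ref = c(5, 41, 2))
    multiplicity <- assign_stratum(c("multiple", "single"),
                                   mut_ref = c(87, 9, 4), wt_ref = c(33, 13, 2))

    cohort <- data.frame(
      sample = sprintf("LM%03d", seq_len(n)),
      karyotype = karyotype,
      race = race,
      multiplicity = multiplicity,
      size_cm = round(stats::rlnorm(n, log(4), 0.5), 1), # placeholder
      age = pmin(70L, pmax(25L, round(stats::rnorm(n, 45, 8)))), # placeholder
      med12_status = status)
    cohort <- cohort[sample.int(n), , drop = FALSE]
    rownames(cohort) <- NULL
    attr(cohort, "n_normals") <- spec$n_normals
    cohort
  })
}

#' Expressed-allele labels for mutated tumors
#'
#' Models the X-inactivation observation as a fixed truth label: every
#' MED12-mutated tumor expresses solely the mutant allele. This is a label,
#' not a mechanism; no allelic expression is simulated.
#'
#' @param cohort Output of [simulate_cohort()].
#' @param seed Unused placeholder for interface symmetry (labelling is
#'   deterministic).
#' @return `data.frame` with `sample` and `expressed_allele`
#'   (`"mutant_expressed"` for mutated tumors, NA otherwise).
#' @export
expression_labels <- function(cohort, seed = 1L) {
  data.frame(sample = cohort$sample,
             expressed_allele = ifelse(cohort$med12_status != "WT",
                                       "mutant_expressed", NA_character_))
}

# Damaging-looking amino-acid pairs for planted nonsynonymous variants
# (all Grantham >= 50).
.damaging_aa_pairs <- matrix(c("G", "D", "G", "V", "L", "R", "Q", "P",
                               "G", "C", "R", "W", "A", "E", "S", "F"),
                             ncol = 2L, byrow = TRUE)
# Conservative pairs (Grantham < 50) for benign germline missense.
.benign_aa_pairs <- matrix(c("L", "I", "D", "E", "F", "Y", "K", "R",
                             "S", "T", "V", "I", "N", "D", "Q", "E"),
                           ncol = 2L, byrow = TRUE)

#' A priori cascade survival of a planted variant class
#'
#' @param planted_class One of `somatic_het`, `germline_het`,
#'   `germline_hom`, `artifact`, `long_deletion`.
#' @param event_length Event length in bases (0 for SNV).
#' @param cfg A [filter_config()].
#' @return Logical: should the cascade report this planted variant?
#' @export
expected_survival <- function(planted_class, event_length = 0L, cfg = filter_config()) {
  vapply(seq_along(planted_class), function(i) {
    switch(planted_class[i],
           somatic_het = event_length[i] <= cfg$max_detectable_event,
           long_deletion = event_length[i] <= cfg$max_detectable_event,
           germline_het = FALSE,
           germline_hom = FALSE,
           artifact = FALSE,
           stop_med12("contract_error", "unknown planted class '",
                      planted_class[i], "'"))
  }, logical(1))
}

#' Simulate one paired tumor/normal read-count table with planted truth
#'
#' Sites are assigned to pseudo-genes; a subset carries planted events:
#' clonal heterozygous somatic SNVs (tumor-only, expected allele fraction
#' `purity/2`), germline SNVs (both tissues, heterozygous at fraction 1/2
#' or homozygous at 1, flagged as known polymorphisms with probability
#' `dbsnp_prob`), low-fraction artifacts (tumor-only, fraction drawn
#' uniformly from `artifact_fraction_range`), and somatic deletions longer
#' than the read length, which the caller stage cannot detect. Coverage is
#' drawn per site from a negative binomial with mean `mean_coverage` and
#' dispersion `size = coverage_size` (exome capture is overdispersed);
#' allele read counts are binomial around the expected fractions, or exact
#' rounded values with `noise = FALSE`.
#'
#' @param n_sites Total sites (default 1200).
#' @param n_somatic,n_germline,n_artifacts,n_long_deletions Planted event
#'   counts (defaults 10, 100, 20, 1).
#' @param mean_coverage Mean site coverage (default 100).
#' @param coverage_size Negative-binomial size parameter (default 20).
#' @param tumor_purity Tumor cell fraction in (0, 1] (default 1).
#' @param germline_hom_fraction Fraction of germline sites that are
#'   homozygous (default 0.3).
#' @param dbsnp_prob Probability a germline site is a known polymorphism
#'   (default 0.95).
#' @param artifact_fraction_range Range of expected artifact read fractions
#'   (default `c(0.01, 0.10)`).
#' @param long_deletion_length Length of planted long deletions (default
#'   42); planted on the modelled gene with descriptor
#'   `long_deletion_descriptor`.
#' @param long_deletion_descriptor Descriptor for the long deletion
#'   (default `"c.122_163del42"`).
#' @param hotspot_descriptor Optional exonic SNV descriptor planted on the
#'   modelled gene as an extra somatic event (e.g. `"c.131G>A"`), NULL for
#'   none.
#' @param model Transcript model supplying the modelled gene label and
#'   coordinates (default [build_fixture_model()]).
#' @param sample_id Sample label (default `"S1"`).
#' @param noise Logical; FALSE makes read counts deterministic rounded
#'   expectations (default TRUE).
#' @param seed Integer seed.
#' @return List with `observations` (two rows per site: tumor and normal)
#'   and `truth` (one row per planted event: `sample_id`, `site`, `gene`,
#'   `planted_class`, `descriptor`, `event_length`,
#'   `expected_to_survive_cascade` under the default [filter_config()]).
#' @export
simulate_pair <- function(n_sites = 1200L, n_somatic = 10L, n_germline = 100L,
                          n_artifacts = 20L, n_long_deletions = 1L,
                          mean_coverage = 100, coverage_size = 20,
                          tumor_purity = 1, germline_hom_fraction = 0.3,
                          dbsnp_prob = 0.95,
                          artifact_fraction_range = c(0.01, 0.10),
                          long_deletion_length = 42L,
                          long_deletion_descriptor = "c.122_163del42",
                          hotspot_descriptor = NULL,
                          model = build_fixture_model(),
                          sample_id = "S1", noise = TRUE, seed = 1L) {
  n_extra <- n_long_deletions + as.integer(!is.null(hotspot_descriptor))
  n_planted <- n_somatic + n_germline + n_artifacts + n_extra
  if (n_planted > n_sites) {
    stop_med12("contract_error", "cannot plant ", n_planted, " events in ",
               n_sites, " sites")
  }
  if (tumor_purity <= 0 || tumor_purity > 1) {
    stop_med12("contract_error", "tumor_purity must be in (0, 1]")
  }
  if (max(artifact_fraction_range) >= 0.20) {
    stop_med12("contract_error",
               "artifact fractions must stay below the 20% calling rule")
  }

  with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    site <- sprintf("%s_site%05d", sample_id, seq_len(n_sites))
    gene <- sprintf("GENE%03d", sample.int(400L, n_sites, replace = TRUE))
    region <- sample(c("exonic", "splice_region", "deep_intronic"), n_sites,
                     replace = TRUE, prob = c(0.90, 0.08, 0.02))
    ref <- sample(bases, n_sites, replace = TRUE)

    planted_class <- rep(NA_character_, n_sites)
    idx <- sample.int(n_sites, n_planted)
    take <- function(k) {
      if (k == 0L) return(integer(0))
      out <- idx[seq_len(k)]
      idx <<- idx[-seq_len(k)]
      out
    }
    i_som <- take(n_somatic)
    i_ger <- take(n_germline)
    i_art <- take(n_artifacts)
    i_long <- take(n_long_deletions)
    i_hot <- take(as.integer(!is.null(hotspot_descriptor)))
    planted_class[i_som] <- "somatic_het"
    planted_class[i_ger] <- ifelse(stats::runif(n_germline) < germline_hom_fraction,
                                   "germline_hom", "germline_het")
    planted_class[i_art] <- "artifact"
    planted_class[i_long] <- "long_deletion"
    planted_class[i_hot] <- "somatic_het"

    alt <- rep(".", n_sites)
    has_alt <- !is.na(planted_class)
    alt[has_alt] <- vapply(which(has_alt), function(i) {
      sample(setdiff(bases, ref[i]), 1L)
    }, character(1))

    event_length <- rep(0L, n_sites)
    event_length[i_long] <- as.integer(long_deletion_length)
    descriptor <- rep(NA_character_, n_sites)
    pos <- rep(NA_integer_, n_sites)
    offset <- rep(0L, n_sites)

    # planted somatic events must be filterable hits: exonic (or splice
    # region), nonsynonymous, not known polymorphisms
    region[c(i_som, i_hot)] <- "exonic"
    region[i_long] <- "exonic"
    dbsnp <- rep(FALSE, n_sites)
    dbsnp[i_ger] <- stats::runif(n_germline) < dbsnp_prob
    synonymous <- rep(NA, n_sites)
    synonymous[c(i_som, i_hot)] <- FALSE
    ger_snv <- i_ger[region[i_ger] == "exonic"]
    synonymous[ger_snv] <- stats::runif(length(ger_snv)) < 0.5
    synonymous[i_art] <- FALSE

    ref_aa <- rep(NA_character_, n_sites)
    alt_aa <- rep(NA_character_, n_sites)
    dmg <- .damaging_aa_pairs[sample.int(nrow(.damaging_aa_pairs),
                                         length(c(i_som, i_hot)), replace = TRUE), ,
                              drop = FALSE]
    ref_aa[c(i_som, i_hot)] <- dmg[, 1L]; alt_aa[c(i_som, i_hot)] <- dmg[, 2L]
    ben_idx <- ger_snv[!is.na(synonymous[ger_snv]) & !synonymous[ger_snv]]
    if (length(ben_idx) > 0L) {
      ben <- .benign_aa_pairs[sample.int(nrow(.benign_aa_pairs), length(ben_idx),
                                         replace = TRUE), , drop = FALSE]
      ref_aa[ben_idx] <- ben[, 1L]; alt_aa[ben_idx] <- ben[, 2L]
    }

    # model-gene events carry cDNA coordinates and descriptors
    attach_descriptor <- function(i, d) {
      v <- parse_cdna(d)
      v <- resolve_anchor(model, v)
      gene[i] <<- model$gene_label
      descriptor[i] <<- d
      pos[i] <<- v$start$base
      offset[i] <<- v$start$offset
      region[i] <<- classify_region(model, v$start)
      if (v$kind %in% c("del", "delins")) {
        ev <- if (v$start$offset < 0L) {
          abs(v$start$offset) + v$end$base - v$start$base + 1L
        } else {
          v$end$base - v$start$base + 1L
        }
        event_length[i] <<- as.integer(ev)
        synonymous[i] <<- NA
        ref_aa[i] <<- NA_character_; alt_aa[i] <<- NA_character_
      } else {
        ref[i] <<- v$ref; alt[i] <<- v$alt
      }
    }
    if (n_long_deletions > 0L) {
      for (i in i_long) attach_descriptor(i, long_deletion_descriptor)
      event_length[i_long] <- as.integer(long_deletion_length)
    }
    if (!is.null(hotspot_descriptor)) {
      for (i in i_hot) attach_descriptor(i, hotspot_descriptor)
      cons <- apply_and_consequence(model, hotspot_descriptor)
      if (cons$klass == "missense") {
        ref_aa[i_hot] <- cons$start_res; alt_aa[i_hot] <- cons$inserted
        synonymous[i_hot] <- FALSE
      }
    }

    # expected allele fractions
    tumor_f <- rep(0, n_sites); normal_f <- rep(0, n_sites)
    som <- c(i_som, i_long, i_hot)
    tumor_f[som] <- 0.5 * tumor_purity
    het <- which(planted_class == "germline_het")
    hom <- which(planted_class == "germline_hom")
    tumor_f[het] <- 0.5; normal_f[het] <- 0.5
    tumor_f[hom] <- 1; normal_f[hom] <- 1
    tumor_f[i_art] <- stats::runif(n_artifacts, artifact_fraction_range[1L],
                                   artifact_fraction_range[2L])

    draw <- function(f) {
      cov <- stats::rnbinom(n_sites, size = coverage_size, mu = mean_coverage)
      cov <- pmax(cov, 1L)
      alt_n <- if (noise) stats::rbinom(n_sites, cov, f) else round(cov * f)
      list(cov = cov, alt = as.integer(alt_n))
    }
    td <- draw(tumor_f); nd <- draw(normal_f)

    mk <- function(tissue, d) {
      data.frame(sample_id = sample_id, tissue = tissue, gene = gene,
                 site = site, pos = pos, offset = offset, region = region,
                 ref = ref, alt = alt,
                 ref_count = d$cov - d$alt, alt_count = d$alt,
                 dbsnp = dbsnp, event_length = event_length,
                 synonymous = synonymous, ref_aa = ref_aa, alt_aa = alt_aa,
                 descriptor = descriptor)
    }
    observations <- rbind(mk("tumor", td), mk("normal", nd))
    rownames(observations) <- NULL

    planted <- which(!is.na(planted_class))
    truth <- data.frame(sample_id = sample_id, site = site[planted],
                        gene = gene[planted],
                        planted_class = planted_class[planted],
                        descriptor = descriptor[planted],
                        event_length = event_length[planted])
    truth$expected_to_survive_cascade <-
      expected_survival(truth$planted_class, truth$event_length, filter_config())
    rownames(truth) <- NULL
    list(observations = observations, truth = truth)
  })
}
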