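# Tumor-unique variant filtering cascade for paired tumor/normal exome
# read-count tables, with a per-sample stage-wise trace.
#
# Observation tables are plain data.frames, one row per sample x tissue x
# site, with per-allele read counts. The schema (see `simulate_pair()` and
# `read_observations()`):
#   sample_id, tissue ("tumor"/"normal"), gene, site (unique site key),
#   pos (cDNA base or NA), offset (intronic offset, 0 exonic), region
#   ("exonic"/"splice_region"/"deep_intronic"), ref, alt ("." if reference
#   only), ref_count, alt_count, dbsnp (logical), event_length (0 for SNV),
#   synonymous (logical, NA for indels), ref_aa, alt_aa, descriptor.

#' Filtering thresholds for the somatic cascade
#'
#' Defaults follow the published analysis protocol: variant calling needs
#' coverage of at least 5 reads and a non-reference allele fraction of at
#' least 20% (lower fractions are treated as sequencing artifacts); the
#' tumor/normal comparison needs 20x coverage in both tissues and a tumor
#' reference-allele frequency at least 25 percentage points below the
#' normal one; the junction window is 10 bp; events longer than the 74-bp
#' read length are invisible to the caller.
#'
#' @param call_min_coverage Minimum reads for variant calling (default 5).
#' @param artifact_max_fraction Allele fractions strictly below this are
#'   artifacts (default 0.20).
#' @param filter_min_coverage Minimum reads in *both* tissues for the
#'   tumor/normal comparison stage (default 20).
#' @param ref_freq_drop Required drop in reference-allele frequency,
#'   tumor vs normal (default 0.25).
#' @param ref_freq_rule `"absolute"` (default): tumor ref-freq must be at
#'   least `ref_freq_drop` percentage points below normal;
#'   `"relative"`: tumor ref-freq must be at most
#'   `(1 - ref_freq_drop)` times normal.
#' @param junction_window Splice-region window in bases (default 10).
#' @param max_detectable_event Longest deletion the caller can see; events
#'   longer than one read length go undetected (default 74).
#' @param damaging_predicate Function over a variant row (see
#'   [damaging_filter()]); default [default_damaging_predicate()].
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(call_min_coverage = 5L,
                          artifact_max_fraction = 0.20,
                          filter_min_coverage = 20L,
                          ref_freq_drop = 0.25,
                          ref_freq_rule = c("absolute", "relative"),
                          junction_window = 10L,
                          max_detectable_event = 74L,
                          damaging_predicate = default_damaging_predicate) {
  ref_freq_rule <- match.arg(ref_freq_rule)
  if (artifact_max_fraction < 0 || artifact_max_fraction >= 1) {
    stop_med12("contract_error", "artifact_max_fraction must be in [0, 1)")
  }
  if (ref_freq_drop <= 0 || ref_freq_drop > 1) {
    stop_med12("contract_error", "ref_freq_drop must be in (0, 1]")
  }
  structure(list(call_min_coverage = as.integer(call_min_coverage),
                 artifact_max_fraction = artifact_max_fraction,
                 filter_min_coverage = as.integer(filter_min_coverage),
                 ref_freq_drop = ref_freq_drop,
                 ref_freq_rule = ref_freq_rule,
                 junction_window = as.integer(junction_window),
                 max_detectable_event = as.integer(max_detectable_event),
                 damaging_predicate = damaging_predicate),
            class = "filter_config")
}

obs_coverage <- function(obs) obs$ref_count + obs$alt_count
obs_alt_frac <- function(obs) {
  cov <- obs_coverage(obs)
  ifelse(cov > 0, obs$alt_count / cov, 0)
}
obs_ref_freq <- function(obs) {
  cov <- obs_coverage(obs)
  ifelse(cov > 0, obs$ref_count / cov, 1)
}

#' Call variants from per-site read counts
#'
#' A non-reference allele is called when site coverage is at least
#' `call_min_coverage`, its read fraction is at least
#' `artifact_max_fraction`, and the event is short enough to be visible to
#' read alignment (`event_length <= max_detectable_event`; a deletion
#' longer than one read length is silently invisible at this stage).
#'
#' @param obs Observation `data.frame` (any mix of tissues).
#' @param cfg A [filter_config()].
#' @return The called subset of `obs`, with `coverage` and `alt_frac`
#'   columns added.
#' @export
call_variants <- function(obs, cfg = filter_config()) {
  stopifnot(inherits(cfg, "filter_config"))
  if (nrow(obs) == 0L) return(cbind(obs, coverage = integer(0), alt_frac = numeric(0)))
  obs$coverage <- obs_coverage(obs)
  obs$alt_frac <- obs_alt_frac(obs)
  keep <- obs$alt != "." &
    obs$coverage >= cfg$call_min_coverage &
    obs$alt_frac >= cfg$artifact_max_fraction &
    obs$event_length <= cfg$max_detectable_event
  obs[keep, , drop = FALSE]
}

#' Keep tumor calls absent from the matched normal tissue
#'
#' Both tissues must reach `filter_min_coverage` at the site (sites failing
#' this floor are dropped and tallied separately); the variant must be
#' absent from the normal call set; and the tumor reference-allele
#' frequency must undercut the normal one by `ref_freq_drop` (absolute
#' percentage points by default, or relatively with
#' `ref_freq_rule = "relative"`).
#'
#' @param tumor_calls Output of [call_variants()] on tumor observations.
#' @param normal_obs All normal-tissue observations of the paired samples
#'   (not only calls: reference coverage at the site is needed).
#' @param cfg A [filter_config()].
#' @return List with `kept` (tumor-unique variants) and `dropped`
#'   (data.frame of dropped rows with a `drop_reason` column:
#'   `low_coverage_pair`, `present_in_normal`, `ref_freq_drop`).
#' @export
tumor_unique <- function(tumor_calls, normal_obs, cfg = filter_config()) {
  stopifnot(inherits(cfg, "filter_config"))
  if (nrow(tumor_calls) == 0L) {
    return(list(kept = tumor_calls,
                dropped = cbind(tumor_calls[0, ], drop_reason = character(0))))
  }
  normal_obs <- normal_obs[normal_obs$tissue == "normal", , drop = FALSE]
  key <- function(d) paste(d$sample_id, d$site, sep = "\r")
  nk <- key(normal_obs)
  idx <- match(key(tumor_calls), nk)
  if (anyNA(idx)) {
    bad <- tumor_calls$sample_id[is.na(idx)][1L]
    stop_med12("pairing_error", "no matched normal observation for sample '",
               bad, "' at site '", tumor_calls$site[is.na(idx)][1L], "'")
  }
  normal_at <- normal_obs[idx, , drop = FALSE]
  normal_calls <- call_variants(normal_obs, cfg)
  in_normal_calls <- paste(key(tumor_calls), tumor_calls$alt) %in%
    paste(key(normal_calls), normal_calls$alt)

  t_cov <- obs_coverage(tumor_calls)
  n_cov <- obs_coverage(normal_at)
  t_rf <- obs_ref_freq(tumor_calls)
  n_rf <- obs_ref_freq(normal_at)
  freq_ok <- if (cfg$ref_freq_rule == "absolute") {
    t_rf <= n_rf - cfg$ref_freq_drop
  } else {
    t_rf <= (1 - cfg$ref_freq_drop) * n_rf
  }

  reason <- rep(NA_character_, nrow(tumor_calls))
  reason[!freq_ok] <- "ref_freq_drop"
  reason[in_normal_calls] <- "present_in_normal"
  reason[t_cov < cfg$filter_min_coverage | n_cov < cfg$filter_min_coverage] <-
    "low_coverage_pair"
  kept <- is.na(reason)
  dropped <- tumor_calls[!kept, , drop = FALSE]
  dropped$drop_reason <- reason[!kept]
  list(kept = tumor_calls[kept, , drop = FALSE], dropped = dropped)
}

#' Region, dbSNP and synonymy filter with category labels
#'
#' Removes deep-intronic variants, known polymorphisms (`dbsnp` flag), and
#' synonymous SNVs; surviving variants are labelled `exonic_snv`,
#' `intronic_snv`, `exonic_del_indel` or `intronic_del_indel`. Region and
#' synonymy are taken from the observation columns when present and
#' non-missing; rows on the modelled gene with a cDNA position are resolved
#' against `model` ([classify_region()], [is_synonymous()]).
#'
#' @param vars Variant `data.frame` (tumor-unique calls).
#' @param model Optional [transcript_model()] used to resolve rows with
#'   missing `region`/`synonymous` on the modelled gene.
#' @param cfg A [filter_config()].
#' @return List with `kept` (with a `category` column) and `dropped`
#'   (`drop_reason`: `deep_intronic`, `dbsnp`, `synonymous`).
#' @export
filter_region_dbsnp_synonymous <- function(vars, model = NULL, cfg = filter_config()) {
  if (nrow(vars) == 0L) {
    kept <- cbind(vars, category = character(0))
    return(list(kept = kept, dropped = cbind(vars[0, ], drop_reason = character(0))))
  }
  region <- as.character(vars$region)
  synonymous <- vars$synonymous
  if (!is.null(model)) {
    resolvable <- vars$gene == model$gene_label & !is.na(vars$pos)
    for (i in which(resolvable & (is.na(region) | is.na(synonymous)))) {
      p <- cdna_pos(vars$pos[i], vars$offset[i])
      if (is.na(region[i])) {
        region[i] <- classify_region(model, p, cfg$junction_window)
      }
      if (is.na(synonymous[i]) && vars$event_length[i] == 0L &&
          p$offset == 0L && vars$alt[i] %in% c("A", "C", "G", "T")) {
        v <- parse_cdna(sprintf("c.%d%s>%s", vars$pos[i], vars$ref[i], vars$alt[i]))
        synonymous[i] <- is_synonymous(model, v)
      }
    }
  }
  synonymous[is.na(synonymous)] <- FALSE # indels and splice variants
  region[is.na(region)] <- "exonic"      # unresolvable rows default to exonic

  reason <- rep(NA_character_, nrow(vars))
  reason[vars$event_length == 0L & synonymous & region == "exonic"] <- "synonymous"
  reason[vars$dbsnp] <- "dbsnp"
  reason[region == "deep_intronic"] <- "deep_intronic"
  kept <- is.na(reason)

  out <- vars[kept, , drop = FALSE]
  is_snv <- out$event_length == 0L
  out$category <- ifelse(is_snv,
                         ifelse(region[kept] == "exonic", "exonic_snv", "intronic_snv"),
                         ifelse(region[kept] == "exonic", "exonic_del_indel",
                                "intronic_del_indel"))
  dropped <- vars[!kept, , drop = FALSE]
  dropped$drop_reason <- reason[!kept]
  list(kept = out, dropped = dropped)
}

#' Default damaging predicate: Grantham distance of at least 50
#'
#' A stand-in for external protein-impact predictors: a missense
#' substitution is considered potentially damaging when the Grantham
#' chemical distance between the reference and alternate residues is at
#' least 50. Rows without resolvable residues are retained (conservative).
#'
#' @param row One-row variant `data.frame` with `ref_aa`, `alt_aa`.
#' @return Logical scalar.
#' @export
default_damaging_predicate <- function(row) {
  if (is.na(row$ref_aa) || is.na(row$alt_aa)) return(TRUE)
  grantham_distance(row$ref_aa, row$alt_aa) >= 50
}

#' Retain variants predicted to damage the protein
#'
#' The predicate is consulted for missense SNVs only; in-frame
#' deletions/indels and splice-region variants pass through as damaging by
#' default (they alter the protein or its splicing by construction).
#'
#' @param vars Categorized variants ([filter_region_dbsnp_synonymous()]).
#' @param predicate Function of a one-row data.frame returning a logical.
#' @return List with `kept` and `dropped` (`drop_reason = "benign"`).
#' @export
damaging_filter <- function(vars, predicate = default_damaging_predicate) {
  if (nrow(vars) == 0L) {
    return(list(kept = vars, dropped = cbind(vars[0, ], drop_reason = character(0))))
  }
  is_missense <- vars$event_length == 0L & vars$category == "exonic_snv"
  keep <- rep(TRUE, nrow(vars))
  for (i in which(is_missense)) {
    keep[i] <- isTRUE(predicate(vars[i, , drop = FALSE]))
  }
  dropped <- vars[!keep, , drop = FALSE]
  dropped$drop_reason <- rep("benign", nrow(dropped))
  list(kept = vars[keep, , drop = FALSE], dropped = dropped)
}

#' Genes with damaging variants in at least k samples
#'
#' @param final_vars Damaging variant `data.frame` across samples.
#' @param k Minimum number of distinct carrier samples (default 2).
#' @return `data.frame` with `gene` and `n_samples`, sorted by carrier
#'   count (descending) then gene label.
#' @export
recurrent_genes <- function(final_vars, k = 2L) {
  if (k < 2L) stop_med12("contract_error", "k must be at least 2")
  if (nrow(final_vars) == 0L) {
    return(data.frame(gene = character(0), n_samples = integer(0)))
  }
  carriers <- unique(final_vars[, c("gene", "sample_id")])
  tab <- as.data.frame(table(gene = carriers$gene), stringsAsFactors = FALSE)
  names(tab)[2L] <- "n_samples"
  tab <- tab[tab$n_samples >= k, , drop = FALSE]
  tab <- tab[order(-tab$n_samples, tab$gene), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Run the full somatic filtering cascade on paired observations
#'
#' Composes calling, the region restriction, the tumor/normal comparison,
#' the dbSNP/synonymy filter and the damaging filter, and produces a
#' per-sample stage-wise trace whose successive total counts are
#' monotonically non-increasing.
#'
#' @param paired_obs Observation `data.frame` holding both tissues for one
#'   or more sample pairs.
#' @param model Optional [transcript_model()] (see
#'   [filter_region_dbsnp_synonymous()]).
#' @param cfg A [filter_config()].
#' @return List with elements:
#'   \describe{
#'     \item{variants}{final damaging tumor-unique variants;}
#'     \item{trace}{per-sample `data.frame` with columns `sample_id`,
#'       `raw_in_region`, `low_coverage_pair`, `unique_to_tumor`,
#'       `filtered`, `exonic_snv`, `intronic_snv`, `exonic_del_indel`,
#'       `intronic_del_indel`, `damaging`;}
#'     \item{dropped}{all dropped rows with stage and reason.}
#'   }
#' @export
run_cascade <- function(paired_obs, model = NULL, cfg = filter_config()) {
  stopifnot(inherits(cfg, "filter_config"))
  samples <- sort(unique(paired_obs$sample_id))
  trace_cols <- c("raw_in_region", "low_coverage_pair", "unique_to_tumor",
                  "filtered", "exonic_snv", "intronic_snv",
                  "exonic_del_indel", "intronic_del_indel", "damaging")
  if (length(samples) == 0L) {
    trace <- as.data.frame(c(list(sample_id = character(0)),
                             stats::setNames(rep(list(integer(0)), length(trace_cols)),
                                             trace_cols)))
    return(list(variants = paired_obs[0, ], trace = trace, dropped = paired_obs[0, ]))
  }

  all_kept <- list(); all_trace <- list(); all_dropped <- list()
  for (s in samples) {
    obs <- paired_obs[paired_obs$sample_id == s, , drop = FALSE]
    tumor <- obs[obs$tissue == "tumor", , drop = FALSE]
    if (!any(obs$tissue == "normal")) {
      stop_med12("pairing_error", "sample '", s, "' has no normal tissue rows")
    }

    calls <- call_variants(tumor, cfg)
    region <- as.character(calls$region)
    if (!is.null(model) && any(is.na(region))) {
      fixme <- which(is.na(region) & calls$gene == model$gene_label & !is.na(calls$pos))
      for (i in fixme) {
        region[i] <- classify_region(model, cdna_pos(calls$pos[i], calls$offset[i]),
                                     cfg$junction_window)
      }
      calls$region <- region
    }
    in_region <- !is.na(region) & region != "deep_intronic"
    calls <- calls[in_region, , drop = FALSE]

    uniq <- tumor_unique(calls, obs, cfg)
    filt <- filter_region_dbsnp_synonymous(uniq$kept, model, cfg)
    dmg <- damaging_filter(filt$kept, cfg$damaging_predicate)

    cat_n <- function(cat) sum(filt$kept$category == cat)
    all_trace[[s]] <- data.frame(
      sample_id = s,
      raw_in_region = nrow(calls),
      low_coverage_pair = sum(uniq$dropped$drop_reason == "low_coverage_pair"),
      unique_to_tumor = nrow(uniq$kept),
      filtered = nrow(filt$kept),
      exonic_snv = cat_n("exonic_snv"),
      intronic_snv = cat_n("intronic_snv"),
      exonic_del_indel = cat_n("exonic_del_indel"),
      intronic_del_indel = cat_n("intronic_del_indel"),
      damaging = nrow(dmg$kept))
    all_kept[[s]] <- dmg$kept
    stage_drop <- function(d, stage) {
      if (nrow(d) == 0L) return(NULL)
      d$stage <- stage
      d
    }
    all_dropped[[s]] <- do.call(rbind, Filter(Negate(is.null), list(
      stage_drop(uniq$dropped, "tumor_unique"),
      stage_drop(filt$dropped, "region_dbsnp_synonymy"),
      stage_drop(dmg$dropped, "damaging"))))
  }
  trace <- do.call(rbind, all_trace)
  rownames(trace) <- NULL
  variants <- do.call(rbind, Filter(function(d) nrow(d) > 0L, all_kept))
  if (is.null(variants)) variants <- cbind(paired_obs[0, ], category = character(0))
  dropped <- do.call(rbind, Filter(Negate(is.null), all_dropped))
  if (is.null(dropped)) {
    dropped <- cbind(paired_obs[0, ], drop_reason = character(0), stage = character(0))
  }
  rownames(variants) <- NULL
  list(variants = variants, trace = trace, dropped = dropped)
}
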