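# Cohort-level mutation-spectrum summaries and one-tailed Fisher exact
# association tests.

#' Round half away from zero
#'
#' Printed percentages in the summaries use conventional half-up rounding
#' (21.65 -> 21.7), not banker's rounding.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Summarize a cohort's mutation spectrum
#'
#' Classifies every carried descriptor with the consequence engine on the
#' given transcript model and tallies: per-descriptor carrier counts with
#' percentages against both denominators (all genotyped tumors and mutated
#' tumors only); per-class carrier counts (missense SNV, exonic in-frame
#' deletion/indel, splice-site SNV, splice-spanning deletion/indel); and
#' per-codon SNV carrier counts (a compound same-allele SNV counts as one
#' carrier at its codon). Records whose descriptor fails to parse or
#' annotate are excluded with a log entry in `errors`.
#'
#' @param cohort Cohort `data.frame` from [simulate_cohort()] (or
#'   [read_cohort()]), with a `med12_status` column holding `"WT"` or a
#'   descriptor.
#' @param model A [transcript_model()].
#' @return Object of class `spectrum_summary`: list with `table`
#'   (descriptor, location, type, protein_change, n, pct_total,
#'   pct_mutated), `class_counts`, `codon_snv_counts`, `n_total`,
#'   `n_mutated`, `errors`.
#' @export
summarize_spectrum <- function(cohort, model) {
  stopifnot(inherits(model, "transcript_model"))
  status <- cohort$med12_status
  mutated <- status[status != "WT"]
  n_total <- nrow(cohort)
  n_mutated <- length(mutated)

  counts <- table(mutated)
  descriptors <- names(counts)
  errors <- character(0)
  rows <- list()
  class_counts <- c(missense_snv = 0L, inframe_del_exonic = 0L,
                    splice_snv = 0L, splice_del = 0L)
  codon_counts <- integer(0)

  for (d in descriptors) {
    n <- as.integer(counts[[d]])
    cons <- tryCatch(apply_and_consequence(model, d),
                     med12scan_error = function(e) e)
    if (inherits(cons, "condition")) {
      errors <- c(errors, paste0(d, ": ", conditionMessage(cons)))
      next
    }
    v <- parse_cdna(d)
    is_snv <- v$kind %in% c("snv", "mnv")
    intronic_start <- v$start$offset < 0L
    klass <- if (is_snv && intronic_start) {
      "splice_snv"
    } else if (is_snv) {
      if (cons$klass == "missense") "missense_snv" else cons$klass
    } else if (intronic_start) {
      "splice_del"
    } else {
      "inframe_del_exonic"
    }
    if (klass %in% names(class_counts)) {
      class_counts[klass] <- class_counts[klass] + n
    }
    if (is_snv && !intronic_start) {
      cod <- as.character(codon_of(v$start)$codon)
      codon_counts[cod] <- (if (cod %in% names(codon_counts))
                              codon_counts[[cod]] else 0L) + n
    }
    location <- if (intronic_start) "Splice site" else "Exon 2"
    type <- if (is_snv) "SNV" else "Deletion/Indel"
    rows[[d]] <- data.frame(
      descriptor = d, location = location, type = type,
      protein_change = format_consequence(cons), n = n,
      pct_total = round_half_up(100 * n / n_total, 1L),
      pct_mutated = round_half_up(100 * n / n_mutated, 1L))
  }

  tab <- do.call(rbind, rows)
  if (!is.null(tab)) {
    tab <- tab[order(tab$location, tab$type, tab$descriptor), , drop = FALSE]
    rownames(tab) <- NULL
  } else {
    tab <- data.frame(descriptor = character(0), location = character(0),
                      type = character(0), protein_change = character(0),
                      n = integer(0), pct_total = numeric(0),
                      pct_mutated = numeric(0))
  }
  codon_counts <- codon_counts[order(as.integer(names(codon_counts)))]
  structure(list(table = tab, class_counts = class_counts,
                 codon_snv_counts = codon_counts,
                 n_total = n_total, n_mutated = n_mutated,
                 errors = errors),
            class = "spectrum_summary")
}

#' @export
print.spectrum_summary <- function(x, ...) {
  cat("Mutation spectrum: ", x$n_mutated, "/", x$n_total, " tumors mutated (",
      round_half_up(100 * x$n_mutated / x$n_total, 1L), "%)\n", sep = "")
  cat("Classes: ", paste(names(x$class_counts), x$class_counts,
                         sep = "=", collapse = ", "), "\n", sep = "")
  if (length(x$codon_snv_counts)) {
    cat("SNV carriers by codon: ",
        paste(names(x$codon_snv_counts), x$codon_snv_counts,
              sep = ":", collapse = ", "), "\n", sep = "")
  }
  print(x$table, row.names = FALSE)
  if (length(x$errors)) cat(length(x$errors), "record(s) failed annotation\n")
  invisible(x)
}

#' One-tailed Fisher exact test on a 2x2 table
#'
#' Exact hypergeometric tail probability computed with log-binomial
#' coefficients. Rows are the two strata, columns are mutated/wild-type
#' counts. With `direction = "greater"` (default) the alternative is that
#' the first row is enriched for the first column (the tail sums
#' `P(X >= a)` over tables with the observed margins); `"less"` sums
#' `P(X <= a)`.
#'
#' @param tab 2x2 numeric matrix (or vector a, b, c, d by row).
#' @param direction `"greater"` or `"less"`.
#' @return The exact one-tailed p-value.
#' @examples
#' fisher_one_tailed(matrix(c(100, 48, 0, 73), 2, byrow = TRUE)) # < 1e-4
#' @export
fisher_one_tailed <- function(tab, direction = c("greater", "less")) {
  direction <- match.arg(direction)
  if (!is.matrix(tab)) {
    if (length(tab) != 4L) stop_med12("contract_error", "need a 2x2 table")
    tab <- matrix(as.numeric(tab), nrow = 2L, byrow = TRUE)
  }
  if (any(dim(tab) != c(2L, 2L))) {
    stop_med12("contract_error", "need a 2x2 table")
  }
  tab <- matrix(as.numeric(tab), nrow = 2L)
  if (any(tab < 0) || any(tab != floor(tab))) {
    stop_med12("contract_error", "table entries must be non-negative integers")
  }
  a <- tab[1L, 1L]; b <- tab[1L, 2L]; cc <- tab[2L, 1L]; d <- tab[2L, 2L]
  m <- a + cc        # column 1 margin (mutated)
  n1 <- a + b        # row 1 margin
  N <- a + b + cc + d
  if (N == 0) return(1)
  ks <- max(0, n1 + m - N):min(n1, m)
  logp <- lchoose(m, ks) + lchoose(N - m, n1 - ks) - lchoose(N, n1)
  sel <- if (direction == "greater") ks >= a else ks <= a
  min(1, sum(exp(logp[sel])))
}

#' Stratified association report
#'
#' Builds the cohort's four 2x2 association tables — tumor-vs-normal
#' tissue, karyotype, race, and tumor multiplicity — with mutated counts,
#' percentages (half-up, one decimal) and one-tailed Fisher exact p-values.
#' Rows with a missing stratum are excluded from that table only; a
#' stratum with fewer than two observed levels is skipped with a log
#' entry. The alternative hypothesis is always that the first-listed group
#' has the higher mutation frequency (tumor tissue, normal karyotype,
#' black American women, multiple tumors); the tested direction is echoed
#' in each table.
#'
#' @param cohort Cohort `data.frame` with `med12_status` and stratum
#'   columns `karyotype`, `race`, `multiplicity`.
#' @param n_normals Number of normal tissue samples (default: the cohort's
#'   `n_normals` attribute, else 73).
#' @param n_normal_mutated Mutated normals (default 0).
#' @return Object of class `association_report`: list of per-table lists
#'   (`table`, `groups`, `mutated`, `total`, `pct`, `p_value`,
#'   `direction`) plus `skipped`.
#' @export
association_report <- function(cohort, n_normals = NULL, n_normal_mutated = 0L) {
  if (is.null(n_normals)) {
    n_normals <- attr(cohort, "n_normals")
    if (is.null(n_normals)) n_normals <- 73L
  }
  mutated <- cohort$med12_status != "WT"
  out <- list()
  skipped <- character(0)

  mk_table <- function(name, groups, mut, tot) {
    mut <- unname(mut); tot <- unname(tot)
    tab <- matrix(c(mut[1L], tot[1L] - mut[1L],
                    mut[2L], tot[2L] - mut[2L]), nrow = 2L, byrow = TRUE,
                  dimnames = list(groups, c("mutated", "wild_type")))
    list(table = tab, groups = groups, mutated = mut, total = tot,
         pct = round_half_up(100 * mut / tot, 1L),
         p_value = fisher_one_tailed(tab, "greater"),
         direction = paste0("enrichment in ", groups[1L]))
  }

  out$tissue <- mk_table("tissue", c("leiomyoma", "myometrium"),
                         c(sum(mutated), as.integer(n_normal_mutated)),
                         c(nrow(cohort), as.integer(n_normals)))

  stratum <- function(name, col, first) {
    lev <- cohort[[col]]
    keep <- !is.na(lev)
    lv <- unique(lev[keep])
    if (length(lv) < 2L) {
      skipped <<- c(skipped, paste0(name, ": fewer than two levels observed"))
      return(NULL)
    }
    groups <- c(first, setdiff(lv, first))
    mut <- vapply(groups, function(g) sum(mutated & keep & lev == g), integer(1))
    tot <- vapply(groups, function(g) sum(keep & lev == g), integer(1))
    mk_table(name, groups, mut, tot)
  }
  for (sp in list(c("karyotype", "karyotype", "normal"),
                  c("race", "race", "B"),
                  c("multiplicity", "multiplicity", "multiple"))) {
    t <- stratum(sp[1L], sp[2L], sp[3L])
    if (!is.null(t)) out[[sp[1L]]] <- t
  }
  structure(c(out, list(skipped = skipped)), class = "association_report")
}

#' @export
print.association_report <- function(x, ...) {
  for (nm in setdiff(names(x), "skipped")) {
    t <- x[[nm]]
    cat(nm, ": ", sep = "")
    cat(paste0(t$groups, " ", t$mutated, "/", t$total,
               " (", t$pct, "%)", collapse = " vs "), sep = "")
    cat("; one-tailed p = ", format(t$p_value, digits = 3),
        " (", t$direction, ")\n", sep = "")
  }
  if (length(x$skipped)) cat("skipped:", paste(x$skipped, collapse = "; "), "\n")
  invisible(x)
}
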