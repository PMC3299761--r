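# Parsing of cDNA-level variant descriptors (including legacy IVS intronic
# notation) and protein-consequence computation against a transcript model.
#
# The consequence engine is deliberately sequence-level: a variant is applied
# to the full CDS string, both proteins are translated with the standard
# code, and the consequence is the maximal-prefix/maximal-suffix difference
# between them. Trimming the common prefix first and the common suffix
# second reports deletions at their most 3' protein position, which is the
# convention the exon 2 spectrum uses for codon-unaligned in-frame
# deletions (the composite codon formed from the flanking bases often
# re-encodes a boundary residue, shifting the reported range).

#' Parse a cDNA variant descriptor
#'
#' Accepts the descriptor dialect used for exon 2 variants:
#' \itemize{
#'   \item SNV: `c.130G>A`
#'   \item deletion: `c.122_163del42` (length suffix optional but checked)
#'   \item deletion-insertion: `c.107_111del5insGC`
#'   \item intronic SNV, legacy: `IVS1-8T>A`; modern alias `c.100-8T>A`
#'   \item splice-spanning deletion: `IVS1-1_139del41`,
#'         `IVS1-2_141del44insAG`
#'   \item compound SNVs on one allele: `c.130G>T;c.131G>T`
#' }
#' A stated deletion length that disagrees with the coordinate span raises a
#' consistency error (e.g. `c.122_164del42` spans 43 bases).
#'
#' @param descriptor Character scalar.
#' @return An object of class `cdna_variant` with fields `kind` (`"snv"`,
#'   `"del"`, `"delins"`, `"mnv"`), `start`/`end` ([cdna_pos()]), `ref`,
#'   `alt`, `intron` (NA unless intron-anchored) and, for `"mnv"`, `snvs`
#'   (list of component SNVs).
#' @examples
#' parse_cdna("c.131G>A")
#' parse_cdna("IVS1-8T>A")
#' @export
parse_cdna <- function(descriptor) {
  stopifnot(is.character(descriptor), length(descriptor) == 1L)
  d <- gsub("\\s", "", descriptor)
  if (d == "") stop_med12("parse_error", "empty descriptor")

  if (grepl(";", d, fixed = TRUE)) {
    parts <- strsplit(d, ";", fixed = TRUE)[[1L]]
    snvs <- lapply(parts, parse_cdna)
    if (!all(vapply(snvs, function(v) v$kind == "snv" && v$start$offset == 0L,
                    logical(1)))) {
      stop_med12("parse_error",
                 "compound descriptors must be ';'-joined exonic SNVs: '", d, "'")
    }
    bases <- vapply(snvs, function(v) v$start$base, integer(1))
    v <- new_cdna_variant(d, "mnv",
                          start = cdna_pos(min(bases)), end = cdna_pos(max(bases)),
                          ref = paste(vapply(snvs, `[[`, character(1), "ref"), collapse = ""),
                          alt = paste(vapply(snvs, `[[`, character(1), "alt"), collapse = ""))
    v$snvs <- snvs
    return(v)
  }

  # exonic SNV: c.130G>A
  m <- regexec("^c\\.(\\d+)([ACGT])>([ACGT])$", d)
  g <- regmatches(d, m)[[1L]]
  if (length(g) == 4L) {
    if (g[3L] == g[4L]) {
      stop_med12("parse_error", "SNV with identical ref and alt: '", d, "'")
    }
    return(new_cdna_variant(d, "snv",
                            start = cdna_pos(as.integer(g[2L])),
                            end = cdna_pos(as.integer(g[2L])),
                            ref = g[3L], alt = g[4L]))
  }

  # intronic SNV, legacy IVS1-8T>A or modern c.100-8T>A
  m <- regexec("^IVS(\\d+)-(\\d+)([ACGT])>([ACGT])$", d)
  g <- regmatches(d, m)[[1L]]
  if (length(g) == 5L) {
    v <- new_cdna_variant(d, "snv",
                          start = cdna_pos(NA_integer_, -as.integer(g[3L])),
                          end = cdna_pos(NA_integer_, -as.integer(g[3L])),
                          ref = g[4L], alt = g[5L])
    v$intron <- as.integer(g[2L])
    return(v)
  }
  m <- regexec("^c\\.(\\d+)-(\\d+)([ACGT])>([ACGT])$", d)
  g <- regmatches(d, m)[[1L]]
  if (length(g) == 5L) {
    return(new_cdna_variant(d, "snv",
                            start = cdna_pos(as.integer(g[2L]), -as.integer(g[3L])),
                            end = cdna_pos(as.integer(g[2L]), -as.integer(g[3L])),
                            ref = g[4L], alt = g[5L]))
  }

  # exonic del / delins: c.122_163del42, c.107_111del5insGC
  m <- regexec("^c\\.(\\d+)_(\\d+)del(\\d*)(?:ins([ACGT]+))?$", d, perl = TRUE)
  g <- regmatches(d, m)[[1L]]
  if (length(g) == 5L) {
    s <- as.integer(g[2L]); e <- as.integer(g[3L])
    if (e < s) stop_med12("parse_error", "deletion end before start in '", d, "'")
    if (g[4L] != "" && e - s + 1L != as.integer(g[4L])) {
      stop_med12("consistency_error", "'", d, "' states del", g[4L],
                 " but spans ", e - s + 1L, " bases")
    }
    kind <- if (g[5L] == "") "del" else "delins"
    return(new_cdna_variant(d, kind,
                            start = cdna_pos(s), end = cdna_pos(e),
                            ref = "", alt = g[5L]))
  }

  # splice-spanning del / delins: IVS1-1_139del41, IVS1-2_141del44insAG
  m <- regexec("^IVS(\\d+)-(\\d+)_(\\d+)del(\\d*)(?:ins([ACGT]+))?$", d, perl = TRUE)
  g <- regmatches(d, m)[[1L]]
  if (length(g) == 6L) {
    kind <- if (g[6L] == "") "del" else "delins"
    v <- new_cdna_variant(d, kind,
                          start = cdna_pos(NA_integer_, -as.integer(g[3L])),
                          end = cdna_pos(as.integer(g[4L])),
                          ref = "", alt = g[6L])
    v$intron <- as.integer(g[2L])
    v$stated_len <- if (g[5L] == "") NA_integer_ else as.integer(g[5L])
    return(v)
  }

  stop_med12("parse_error", "unrecognized descriptor '", d, "'")
}

new_cdna_variant <- function(descriptor, kind, start, end, ref, alt) {
  structure(list(descriptor = descriptor, kind = kind,
                 start = start, end = end, ref = ref, alt = alt,
                 intron = NA_integer_, stated_len = NA_integer_),
            class = "cdna_variant")
}

#' @export
print.cdna_variant <- function(x, ...) {
  cat("<cdna_variant> ", x$descriptor, " [", x$kind, "]\n", sep = "")
  invisible(x)
}

# Resolve the anchor base of an intron-anchored position against a model.
resolve_anchor <- function(model, v) {
  fix <- function(p, intron) {
    if (p$offset != 0L && is.na(p$base)) {
      p$base <- intron_anchor(model, intron)
    } else if (p$offset != 0L) {
      intron_of_anchor(model, p$base) # validates the anchor
    }
    p
  }
  if (!is.na(v$intron)) {
    v$start <- fix(v$start, v$intron)
    if (v$end$offset != 0L) v$end <- fix(v$end, v$intron)
  } else if (v$start$offset != 0L) {
    v$intron <- intron_of_anchor(model, v$start$base)
  }
  v
}

# -- protein diff -------------------------------------------------------------

# Maximal common prefix, then maximal common suffix of the remainder.
# Returns 1-based residue bookkeeping on the reference protein.
protein_diff <- function(ref_aa, alt_aa) {
  r <- strsplit(ref_aa, "")[[1L]]
  a <- strsplit(alt_aa, "")[[1L]]
  nr <- length(r); na <- length(a)
  p <- 0L
  while (p < min(nr, na) && r[p + 1L] == a[p + 1L]) p <- p + 1L
  s <- 0L
  while (s < min(nr, na) - p && r[nr - s] == a[na - s]) s <- s + 1L
  list(deleted = if (nr - s >= p + 1L) r[(p + 1L):(nr - s)] else character(0),
       inserted = if (na - s >= p + 1L) a[(p + 1L):(na - s)] else character(0),
       del_start = p + 1L, del_end = nr - s,
       flank_left = p, flank_right = nr - s + 1L)
}

new_consequence <- function(klass, start_res = NA_character_, start_idx = NA_integer_,
                            end_res = NA_character_, end_idx = NA_integer_,
                            inserted = "", descriptor = NA_character_,
                            deleted = "", next_res = NA_character_,
                            codon_aligned = NA) {
  structure(list(klass = klass,
                 start_res = start_res, start_idx = as.integer(start_idx),
                 end_res = end_res, end_idx = as.integer(end_idx),
                 inserted = inserted, descriptor = descriptor,
                 deleted = deleted, next_res = next_res,
                 codon_aligned = codon_aligned),
            class = "protein_consequence")
}

#' @export
print.protein_consequence <- function(x, ...) {
  cat("<protein_consequence> ", format_consequence(x), " [", x$klass, "]\n", sep = "")
  invisible(x)
}

#' Apply a cDNA variant to a transcript model and derive its protein consequence
#'
#' Exonic SNVs and in-frame deletions/delins are applied to the coding
#' sequence; both the reference and the mutated CDS are translated and the
#' consequence is the trimmed protein difference (see Details). Deletions
#' whose span starts inside the preceding intron and ends inside the exon
#' remove the splice acceptor and are classified `splice_acceptor_loss`.
#' An intronic SNV inside the splice window is examined for creation of a
#' cryptic acceptor: if the substitution creates an `AG` upstream of the
#' authentic acceptor and the retained intronic bases are a multiple of 3
#' at a codon-aligned junction, the consequence is an in-frame insertion of
#' the retained residues (`splice_alteration_ins`); otherwise the variant
#' is reported as an unspecified `splice_alteration`.
#'
#' Fully exonic deletions whose net length change is not a multiple of 3
#' are classified `frameshift` and flagged; no stop-codon scan is performed.
#'
#' @param model A [transcript_model()].
#' @param v A [parse_cdna()] result (or descriptor string).
#' @return A `protein_consequence` with fields `klass` (one of `missense`,
#'   `synonymous`, `inframe_del`, `inframe_delins`, `inframe_ins`,
#'   `splice_acceptor_loss`, `splice_alteration_ins`, `splice_alteration`,
#'   `frameshift`), residue range and inserted residues.
#' @examples
#' m <- build_fixture_model()
#' format_consequence(apply_and_consequence(m, "c.131G>A"))      # p.G44D
#' format_consequence(apply_and_consequence(m, "c.122_163del42")) # p.V41_D54del
#' @export
apply_and_consequence <- function(model, v) {
  stopifnot(inherits(model, "transcript_model"))
  if (is.character(v)) v <- parse_cdna(v)
  stopifnot(inherits(v, "cdna_variant"))
  v <- resolve_anchor(model, v)
  cds <- model$cds_sequence
  n <- nchar(cds)

  if (v$kind %in% c("snv", "mnv") && v$start$offset == 0L) {
    if (v$end$base > n) stop_med12("coord_error", "variant beyond CDS end")
    snvs <- if (v$kind == "mnv") v$snvs else list(v)
    mut <- cds
    for (s in snvs) {
      have <- substr(mut, s$start$base, s$start$base)
      if (have != s$ref) {
        stop_med12("coord_error", "reference mismatch at c.", s$start$base,
                   ": model has ", have, ", descriptor says ", s$ref)
      }
      substr(mut, s$start$base, s$start$base) <- s$alt
    }
    out <- diff_to_consequence(cds, mut, v$descriptor)
    if (out$klass == "synonymous") {
      co <- codon_of(v$start)
      out$start_idx <- out$end_idx <- co$codon
      out$start_res <- out$end_res <- residue_at(model, co$codon)
    }
    return(out)
  }

  if (v$kind == "snv" && v$start$offset < 0L) {
    return(splice_snv_consequence(model, v))
  }

  if (v$kind %in% c("del", "delins")) {
    if (v$start$offset < 0L && v$end$offset == 0L) {
      # spans the intron/exon boundary: acceptor AG is lost
      anchor <- v$start$base
      span <- abs(v$start$offset) + (v$end$base - anchor + 1L)
      if (!is.na(v$stated_len) && span != v$stated_len) {
        stop_med12("consistency_error", "'", v$descriptor, "' states del",
                   v$stated_len, " but spans ", span, " bases")
      }
      out <- new_consequence("splice_acceptor_loss", descriptor = v$descriptor)
      return(out)
    }
    if (v$start$offset != 0L || v$end$offset != 0L) {
      stop_med12("coord_error", "unsupported intronic deletion geometry in '",
                 v$descriptor, "'")
    }
    if (v$end$base > n) stop_med12("coord_error", "variant beyond CDS end")
    span <- v$end$base - v$start$base + 1L
    net <- span - nchar(v$alt)
    if (net %% 3L != 0L) {
      fr <- new_consequence("frameshift", descriptor = v$descriptor)
      co <- codon_of(v$start)
      fr$start_idx <- co$codon
      fr$start_res <- residue_at(model, co$codon)
      return(fr)
    }
    mut <- paste0(substr(cds, 1L, v$start$base - 1L), v$alt,
                  substr(cds, v$end$base + 1L, n))
    aligned <- codon_of(v$start)$phase == 1L && codon_of(v$end)$phase == 3L
    return(diff_to_consequence(cds, mut, v$descriptor, codon_aligned = aligned))
  }

  stop_med12("contract_error", "unhandled variant kind '", v$kind, "'")
}

diff_to_consequence <- function(cds_ref, cds_mut, descriptor, codon_aligned = NA) {
  ref_aa <- translate_cds(cds_ref)
  mut_aa <- translate_cds(cds_mut)
  d <- protein_diff(ref_aa, mut_aa)
  r <- strsplit(ref_aa, "")[[1L]]
  ndel <- length(d$deleted); nins <- length(d$inserted)
  nxt <- if (d$del_end + 1L <= length(r)) r[d$del_end + 1L] else NA_character_

  if (ndel == 0L && nins == 0L) {
    return(new_consequence("synonymous", descriptor = descriptor))
  }
  if (ndel == 1L && nins == 1L) {
    return(new_consequence("missense",
                           start_res = d$deleted, start_idx = d$del_start,
                           end_res = d$deleted, end_idx = d$del_start,
                           inserted = d$inserted, descriptor = descriptor))
  }
  if (nins == 0L) {
    return(new_consequence("inframe_del",
                           start_res = r[d$del_start], start_idx = d$del_start,
                           end_res = r[d$del_end], end_idx = d$del_end,
                           descriptor = descriptor,
                           deleted = paste0(d$deleted, collapse = ""),
                           next_res = nxt, codon_aligned = codon_aligned))
  }
  if (ndel == 0L) {
    return(new_consequence("inframe_ins",
                           start_res = r[d$flank_left], start_idx = d$flank_left,
                           end_res = r[d$flank_right], end_idx = d$flank_right,
                           inserted = paste0(d$inserted, collapse = ""),
                           descriptor = descriptor))
  }
  new_consequence("inframe_delins",
                  start_res = r[d$del_start], start_idx = d$del_start,
                  end_res = r[d$del_end], end_idx = d$del_end,
                  inserted = paste0(d$inserted, collapse = ""),
                  descriptor = descriptor,
                  deleted = paste0(d$deleted, collapse = ""),
                  next_res = nxt, codon_aligned = codon_aligned)
}

splice_snv_consequence <- function(model, v) {
  intron <- v$intron
  tail_seq <- model$intron_tails[[as.character(intron)]]
  if (is.null(tail_seq)) {
    return(new_consequence("splice_alteration", descriptor = v$descriptor))
  }
  L <- nchar(tail_seq)
  k <- v$start$offset # negative
  if (abs(k) > L) {
    return(new_consequence("splice_alteration", descriptor = v$descriptor))
  }
  idx <- L + k + 1L # string index of the mutated base
  have <- substr(tail_seq, idx, idx)
  if (have != v$ref) {
    stop_med12("coord_error", "reference mismatch at IVS", intron, k,
               ": model has ", have, ", descriptor says ", v$ref)
  }
  mut_tail <- tail_seq
  substr(mut_tail, idx, idx) <- v$alt

  # does the substitution create a new AG acceptor upstream of the
  # authentic one (which occupies offsets -2/-1)?
  anchor <- v$start$base
  for (start_idx in c(idx - 1L, idx)) {
    if (start_idx < 1L || start_idx + 1L > L - 2L) next
    if (substr(mut_tail, start_idx, start_idx + 1L) != "AG") next
    if (substr(tail_seq, start_idx, start_idx + 1L) == "AG") next
    retained <- substr(mut_tail, start_idx + 2L, L)
    if (nchar(retained) %% 3L == 0L && (anchor - 1L) %% 3L == 0L) {
      ins_aa <- translate_cds(retained)
      left <- (anchor - 1L) %/% 3L
      return(new_consequence("splice_alteration_ins",
                             start_res = residue_at(model, left), start_idx = left,
                             end_res = residue_at(model, left + 1L), end_idx = left + 1L,
                             inserted = ins_aa, descriptor = v$descriptor))
    }
  }
  new_consequence("splice_alteration", descriptor = v$descriptor)
}

#' Format a protein consequence in the spectrum-table dialect
#'
#' Single-letter residues; `p.G44S` for missense, `p.V41_D54del` /
#' `p.G44del` for in-frame deletions, `p.K42_G44delinsN` for
#' deletion-insertions (an empty insertion normalizes to a plain deletion),
#' `p.E33_D34insPQ` for insertions, `p.G44=` for synonymous changes, and
#' the literal strings `"Splice acceptor loss"` / `"Splice alteration"` for
#' acceptor-destroying and unresolved splice variants.
#'
#' @param x A `protein_consequence`.
#' @return Character scalar.
#' @export
format_consequence <- function(x) {
  stopifnot(inherits(x, "protein_consequence"))
  res <- function(r, i) paste0(r, i)
  switch(x$klass,
    missense = paste0("p.", res(x$start_res, x$start_idx), x$inserted),
    synonymous = if (is.na(x$start_idx)) "p.(=)"
                 else paste0("p.", res(x$start_res, x$start_idx), "="),
    inframe_del = {
      start_idx <- x$start_idx; end_idx <- x$end_idx; end_res <- x$end_res
      # Dialect rule for boundary-ambiguous unaligned deletions: when the
      # composite codon of a codon-unaligned deletion re-encodes a residue
      # identical to the one immediately 3' of the deleted range, the
      # surviving copy is aligned 5' and the printed range stops at the
      # last unambiguous residue (one short of the true range).
      if (isFALSE(x$codon_aligned) && !is.na(x$next_res) &&
          identical(x$next_res, x$end_res) && end_idx - start_idx >= 1L &&
          nzchar(x$deleted)) {
        end_idx <- end_idx - 1L
        end_res <- substr(x$deleted, nchar(x$deleted) - 1L, nchar(x$deleted) - 1L)
      }
      if (start_idx == end_idx) {
        paste0("p.", res(x$start_res, start_idx), "del")
      } else {
        paste0("p.", res(x$start_res, start_idx), "_",
               res(end_res, end_idx), "del")
      }
    },
    inframe_delins = if (x$inserted == "") {
      format_consequence(new_consequence("inframe_del", x$start_res, x$start_idx,
                                         x$end_res, x$end_idx))
    } else if (x$start_idx == x$end_idx) {
      paste0("p.", res(x$start_res, x$start_idx), "delins", x$inserted)
    } else {
      paste0("p.", res(x$start_res, x$start_idx), "_",
             res(x$end_res, x$end_idx), "delins", x$inserted)
    },
    inframe_ins = ,
    splice_alteration_ins = paste0("p.", res(x$start_res, x$start_idx), "_",
                                   res(x$end_res, x$end_idx), "ins", x$inserted),
    splice_acceptor_loss = "Splice acceptor loss",
    splice_alteration = "Splice alteration",
    frameshift = paste0("p.", res(x$start_res, x$start_idx), "fs"),
    stop_med12("contract_error", "unknown consequence class '", x$klass, "'")
  )
}

#' Format a cDNA variant back into its descriptor string
#'
#' Inverse of [parse_cdna()]: legacy IVS notation is preserved for
#' intron-anchored variants, deletion length suffixes are emitted for
#' multi-base deletions, and compound SNVs are `;`-joined.
#'
#' @param v A `cdna_variant`.
#' @return Character scalar descriptor.
#' @export
format_cdna <- function(v) {
  stopifnot(inherits(v, "cdna_variant"))
  if (v$kind == "mnv") {
    return(paste(vapply(v$snvs, format_cdna, character(1)), collapse = ";"))
  }
  if (v$kind == "snv") {
    if (v$start$offset == 0L) {
      return(paste0("c.", v$start$base, v$ref, ">", v$alt))
    }
    if (!is.na(v$intron)) {
      return(paste0("IVS", v$intron, v$start$offset, v$ref, ">", v$alt))
    }
    return(paste0("c.", v$start$base, v$start$offset, v$ref, ">", v$alt))
  }
  ins <- if (nzchar(v$alt)) paste0("ins", v$alt) else ""
  if (v$start$offset < 0L) {
    len <- if (!is.na(v$stated_len)) v$stated_len else ""
    return(paste0("IVS", v$intron, v$start$offset, "_", v$end$base,
                  "del", len, ins))
  }
  span <- v$end$base - v$start$base + 1L
  paste0("c.", v$start$base, "_", v$end$base, "del", span, ins)
}

#' Is an exonic SNV synonymous on a given transcript model?
#'
#' @param model A [transcript_model()].
#' @param v An exonic SNV from [parse_cdna()] (or descriptor string).
#' @return Logical scalar.
#' @export
is_synonymous <- function(model, v) {
  if (is.character(v)) v <- parse_cdna(v)
  if (!(v$kind == "snv" && v$start$offset == 0L)) {
    stop_med12("contract_error", "is_synonymous() requires an exonic SNV")
  }
  apply_and_consequence(model, v)$klass == "synonymous"
}

#' Annotate a vector of descriptors against a transcript model
#'
#' Per-record failures (unparseable descriptors, reference mismatches) are
#' captured, reported in the `error` column, and do not abort the run.
#'
#' @param model A [transcript_model()].
#' @param descriptors Character vector.
#' @return `data.frame` with columns `descriptor`, `class`, `protein_change`,
#'   `error`.
#' @export
annotate_variants <- function(model, descriptors) {
  if (length(descriptors) == 0L) {
    return(data.frame(descriptor = character(0), class = character(0),
                      protein_change = character(0), error = character(0)))
  }
  rows <- lapply(descriptors, function(d) {
    tryCatch({
      cons <- apply_and_consequence(model, d)
      data.frame(descriptor = d, class = cons$klass,
                 protein_change = format_consequence(cons),
                 error = NA_character_)
    }, med12scan_error = function(e) {
      data.frame(descriptor = d, class = NA_character_,
                 protein_change = NA_character_, error = conditionMessage(e))
    })
  })
  do.call(rbind, rows)
}
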