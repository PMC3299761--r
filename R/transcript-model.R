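# Coding-transcript geometry: exon layout in cDNA space, codon mapping,
# splice-region windows. The model lives entirely in cDNA coordinates
# (1-based, inclusive, restricted to coding positions); genomic liftover is
# out of scope because every variant handled by the package is described at
# the cDNA level.

#' Construct a coding transcript model
#'
#' A transcript model holds the exon layout of a coding sequence in cDNA
#' coordinates, the coding sequence itself, and the terminal bases of each
#' intron (needed to interpret intronic-offset variants such as `IVS1-8T>A`
#' and to reason about splice acceptors). Exon intervals must be contiguous,
#' ascending, and concatenate to cover `1..nchar(cds_sequence)`; the CDS
#' length must be a multiple of 3. Codon `n` occupies cDNA positions
#' `3n-2..3n`.
#'
#' @param gene_label Character scalar naming the gene.
#' @param exons `data.frame` with columns `exon` (1-based index),
#'   `cdna_start`, `cdna_end` (1-based inclusive cDNA coordinates).
#' @param cds_sequence Character scalar over A/C/G/T, length divisible by 3.
#' @param intron_tails Named character vector: for intron `i` (between exon
#'   `i` and exon `i+1`), the final bases of the intron, 3' end last. The
#'   last two bases are the splice acceptor dinucleotide (canonically `AG`).
#' @return An object of class `transcript_model`.
#' @seealso [build_fixture_model()], [codon_of()], [classify_region()]
#' @export
transcript_model <- function(gene_label, exons, cds_sequence, intron_tails = character()) {
  stopifnot(is.character(gene_label), length(gene_label) == 1L)
  stopifnot(is.data.frame(exons),
            all(c("exon", "cdna_start", "cdna_end") %in% names(exons)))
  cds_sequence <- toupper(cds_sequence)
  n <- nchar(cds_sequence)
  if (n %% 3L != 0L) {
    stop_med12("contract_error", "CDS length ", n, " is not a multiple of 3")
  }
  if (grepl("[^ACGT]", cds_sequence)) {
    stop_med12("contract_error", "CDS contains characters outside A/C/G/T")
  }
  exons <- exons[order(exons$cdna_start), , drop = FALSE]
  if (exons$cdna_start[1L] != 1L || exons$cdna_end[nrow(exons)] != n ||
      any(exons$cdna_start[-1L] != exons$cdna_end[-nrow(exons)] + 1L)) {
    stop_med12("contract_error",
               "exon intervals must tile 1..", n, " contiguously")
  }
  if (any(exons$cdna_end < exons$cdna_start)) {
    stop_med12("contract_error", "exon with negative extent")
  }
  model <- structure(
    list(gene_label = gene_label,
         exons = exons,
         cds_sequence = cds_sequence,
         intron_tails = intron_tails),
    class = "transcript_model"
  )
  model
}

#' @export
print.transcript_model <- function(x, ...) {
  cat("<transcript_model> ", x$gene_label, "\n", sep = "")
  cat("  CDS: ", nchar(x$cds_sequence), " bp / ",
      nchar(x$cds_sequence) %/% 3L, " aa, ",
      nrow(x$exons), " coding exons\n", sep = "")
  invisible(x)
}

#' cDNA position, optionally with an intronic offset
#'
#' `offset = 0` denotes an exonic coding position `base`. A negative offset
#' denotes a position inside the intron preceding `base`, counted backwards
#' from the first base of the following exon (so the legacy `IVS1-8`
#' equals `cdna_pos(100, -8)` on a model whose exon 2 starts at c.100).
#'
#' @param base Positive integer cDNA coordinate. For intronic positions this
#'   is the anchor: the first cDNA base of the exon that follows the intron.
#' @param offset Integer, 0 for exonic; negative for intronic positions
#'   upstream of `base`.
#' @return An object of class `cdna_pos`.
#' @export
cdna_pos <- function(base, offset = 0L) {
  base <- as.integer(base); offset <- as.integer(offset)
  stopifnot(length(base) == 1L, length(offset) == 1L)
  if (is.na(base) && offset == 0L) {
    stop_med12("coord_error", "exonic position requires a cDNA base")
  }
  if (!is.na(base) && base < 1L) {
    stop_med12("coord_error", "cDNA base must be positive")
  }
  if (offset > 0L) {
    stop_med12("coord_error", "positive (donor-side) intronic offsets are not supported")
  }
  structure(list(base = base, offset = offset), class = "cdna_pos")
}

#' @export
print.cdna_pos <- function(x, ...) {
  if (x$offset == 0L) cat("c.", x$base, "\n", sep = "")
  else cat("c.", x$base, x$offset, "\n", sep = "")
  invisible(x)
}

as_cdna_pos <- function(pos) {
  if (inherits(pos, "cdna_pos")) return(pos)
  cdna_pos(pos)
}

#' Codon index and within-codon phase of an exonic cDNA position
#'
#' Codon `n` occupies cDNA positions `3n-2..3n`, so position `p` maps to
#' codon `ceiling(p/3)` with phase `((p-1) %% 3) + 1`.
#'
#' @param pos A [cdna_pos()] (or bare integer) with `offset == 0`.
#' @return List with integer elements `codon` and `phase` (1, 2 or 3).
#' @examples
#' codon_of(131) # codon 44, phase 2
#' @export
codon_of <- function(pos) {
  pos <- as_cdna_pos(pos)
  if (pos$offset != 0L) {
    stop_med12("coord_error", "codon_of() requires an exonic position; got intronic offset ",
               pos$offset)
  }
  list(codon = as.integer(ceiling(pos$base / 3)),
       phase = ((pos$base - 1L) %% 3L) + 1L)
}

#' Reference residue at a codon
#'
#' @param model A [transcript_model()].
#' @param codon_index Integer in `1..nchar(cds)/3`.
#' @return One-letter amino-acid code.
#' @export
residue_at <- function(model, codon_index) {
  stopifnot(inherits(model, "transcript_model"))
  codon_index <- as.integer(codon_index)
  n_codons <- nchar(model$cds_sequence) %/% 3L
  if (any(codon_index < 1L | codon_index > n_codons)) {
    stop_med12("coord_error", "codon index out of range 1..", n_codons)
  }
  vapply(codon_index, function(i) {
    translate_cds(substr(model$cds_sequence, 3L * i - 2L, 3L * i))
  }, character(1))
}

#' Classify a cDNA position as exonic, splice-region, or deep intronic
#'
#' Positions with offset 0 are exonic; intronic positions within `window`
#' bases of the exon-intron junction are splice-region; all other intronic
#' positions are deep intronic. The default 10-base window matches the
#' junction-flank focus of the variant analysis.
#'
#' @inheritParams codon_of
#' @param model A [transcript_model()].
#' @param window Non-negative integer, default 10.
#' @return One of `"exonic"`, `"splice_region"`, `"deep_intronic"`.
#' @export
classify_region <- function(model, pos, window = 10L) {
  stopifnot(window >= 0L)
  pos <- as_cdna_pos(pos)
  if (pos$offset == 0L) return("exonic")
  if (abs(pos$offset) <= window) "splice_region" else "deep_intronic"
}

#' Intron index anchored at a cDNA base, and vice versa
#'
#' For intron `i`, the anchor is the first cDNA base of exon `i + 1`;
#' negative intronic offsets count backwards from it.
#'
#' @param model A [transcript_model()].
#' @param intron Intron index (1 = between exons 1 and 2).
#' @return Integer cDNA anchor base.
#' @export
intron_anchor <- function(model, intron) {
  intron <- as.integer(intron)
  if (intron < 1L || intron >= nrow(model$exons)) {
    stop_med12("coord_error", "no intron ", intron, " in model with ",
               nrow(model$exons), " exons")
  }
  model$exons$cdna_start[model$exons$exon == intron + 1L]
}

intron_of_anchor <- function(model, base) {
  hit <- which(model$exons$cdna_start == base & model$exons$exon > 1L)
  if (length(hit) != 1L) {
    stop_med12("coord_error", "c.", base,
               " is not the first base of any internal exon; cannot anchor an intronic offset")
  }
  model$exons$exon[hit] - 1L
}

# -- fixture ------------------------------------------------------------------

# Codons 33..55 of the fixture CDS. These are the residues constrained by
# the exon 2 mutation spectrum; everything else is filled pseudo-randomly.
# Codon 39 (Ser, TCG) and the third bases of several codons are tied
# together so that every codon-unaligned in-frame deletion re-encodes the
# residue its published name requires (e.g. c.117 == c.123 so deleting
# c.117_122 leaves Ser39 intact).
.fixture_core_codons <- c(
  "GAG", # 33 E
  "GAC", # 34 D
  "GAG", # 35 E
  "CTG", # 36 L
  "ACC", # 37 T
  "GCT", # 38 A
  "TCG", # 39 S (third base ties to c.123)
  "AAC", # 40 N
  "GTG", # 41 V
  "AAG", # 42 K
  "CAG", # 43 Q
  "GGT", # 44 G (third base in {T,C}: composite codons need AGy/GAy/...)
  "TTC", # 45 F
  "AAT", # 46 N
  "AAT", # 47 N (c.141 in {T,C}; the N46/N47 doublet makes the composite
         #      codon of c.126_140del15 boundary-ambiguous, see formatter)
  "CAG", # 48 Q (c.144 in {A,G})
  "CCT", # 49 P (c.147 in {T,C})
  "GCA", # 50 A
  "GTC", # 51 V
  "TCC", # 52 S
  "AAA", # 53 K
  "GAC", # 54 D
  "GGA"  # 55 G (c.163 = G so deletions ending at c.163 re-encode Gly55)
)

#' Build the MED12-like fixture transcript model
#'
#' Returns a 45-exon coding transcript of 6,531 bp (2,177 residues) whose
#' exon 2 spans c.100-c.204 (105 bp / 35 residues). Codons 33-55 are fixed
#' to the residues required by the exon 2 mutation spectrum (E33, D34, E35,
#' L36, T37, A38, N40, V41, K42, Q43, G44, F45, N46, ..., D54), codon 1 is
#' ATG, and the tail of intron 1 is fixed so that the T>A substitution 8
#' bases upstream of exon 2 creates a cryptic splice acceptor that retains
#' six intronic bases encoding Pro-Gln. All positions not constrained by
#' the spectrum are filled deterministically from `seed` with stop-free
#' codons.
#'
#' @param seed Integer seed for the unconstrained sequence fill.
#' @return A [transcript_model()].
#' @examples
#' m <- build_fixture_model()
#' residue_at(m, 44) # "G"
#' @export
build_fixture_model <- function(seed = 2012L) {
  n_codons <- 2177L
  with_seed(seed, {
    safe <- names(.codon_table)[.codon_table != "*"]
    codons <- sample(safe, n_codons, replace = TRUE)
    codons[1L] <- "ATG"
    codons[33:55] <- .fixture_core_codons
    cds <- paste0(codons, collapse = "")

    # exon 1 c.1-99, exon 2 c.100-204, exons 3..45 tile the remainder
    n_exons <- 45L
    rest <- nchar(cds) - 204L
    k <- n_exons - 2L
    sizes <- rep(rest %/% k, k)
    sizes[seq_len(rest %% k)] <- sizes[seq_len(rest %% k)] + 1L
    ends <- 204L + cumsum(sizes)
    starts <- c(1L, 100L, 205L + c(0L, cumsum(sizes)[-k]))
    exons <- data.frame(exon = seq_len(n_exons),
                        cdna_start = starts,
                        cdna_end = c(99L, 204L, ends))

    # intron tails: 10 bases each, acceptor AG last. Intron 1 is fixed:
    # ...T(-8) G(-7) C C C C A G; T>A at -8 yields a new AG acceptor whose
    # use retains CCCCAG (Pro-Gln) in the message.
    tails <- vapply(seq_len(n_exons - 1L), function(i) {
      paste0(paste0(sample(c("T", "C"), 8L, replace = TRUE), collapse = ""), "AG")
    }, character(1))
    tails[1L] <- "TTTGCCCCAG"
    names(tails) <- as.character(seq_len(n_exons - 1L))

    transcript_model("MED12", exons, cds, tails)
  })
}

# Run code with a private RNG stream, restoring the caller's state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  code
}

# -- serialization ------------------------------------------------------------

#' Write / read a transcript model
#'
#' The model is stored as two small text files: a JSON document (gene label,
#' exon table, intron tails) and a FASTA file holding the CDS.
#'
#' @param model A [transcript_model()].
#' @param json_path,fasta_path Output paths.
#' @return `write_transcript_model()` returns the paths invisibly;
#'   `read_transcript_model()` returns a [transcript_model()].
#' @export
write_transcript_model <- function(model, json_path, fasta_path) {
  stopifnot(inherits(model, "transcript_model"))
  doc <- list(gene_label = model$gene_label,
              exons = model$exons,
              intron_tails = as.list(model$intron_tails),
              cds_fasta = basename(fasta_path))
  jsonlite::write_json(doc, json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  dna <- Biostrings::DNAStringSet(stats::setNames(model$cds_sequence, model$gene_label))
  Biostrings::writeXStringSet(dna, fasta_path)
  invisible(c(json = json_path, fasta = fasta_path))
}

#' @rdname write_transcript_model
#' @export
read_transcript_model <- function(json_path, fasta_path = NULL) {
  doc <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  if (is.null(fasta_path)) {
    fasta_path <- file.path(dirname(json_path), doc$cds_fasta)
  }
  dna <- Biostrings::readDNAStringSet(fasta_path)
  tails <- unlist(doc$intron_tails)
  transcript_model(doc$gene_label,
                   as.data.frame(doc$exons),
                   as.character(dna[[1L]]),
                   tails)
}
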