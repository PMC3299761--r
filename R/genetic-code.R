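# Standard genetic code and amino-acid distance tables.

.codon_table <- local({
  bases <- c("T", "C", "A", "G")
  codons <- character(64)
  aa <- character(64)
  i <- 0L
  aa_by_row <- c(
    "FFLL", "SSSS", "YY**", "CC*W", # Txx
    "LLLL", "PPPP", "HHQQ", "RRRR", # Cxx
    "IIIM", "TTTT", "NNKK", "SSRR", # Axx
    "VVVV", "AAAA", "DDEE", "GGGG"  # Gxx
  )
  row <- 0L
  for (b1 in bases) for (b2 in bases) {
    row <- row + 1L
    letters4 <- strsplit(aa_by_row[row], "")[[1]]
    for (k in 1:4) {
      i <- i + 1L
      codons[i] <- paste0(b1, b2, bases[k])
      aa[i] <- letters4[k]
    }
  }
  stats::setNames(aa, codons)
})

#' Translate a coding sequence with the standard genetic code
#'
#' Translates an in-frame nucleotide string (A/C/G/T, length divisible by 3)
#' to a one-letter amino-acid string. Stop codons translate to `*`. Human
#' nuclear genes only: no alternative codes, no selenocysteine.
#'
#' @param cds Character scalar, nucleotide sequence over A/C/G/T with
#'   `nchar(cds) %% 3 == 0`.
#' @return Character scalar of `nchar(cds)/3` one-letter residues.
#' @examples
#' translate_cds("ATGGGT") # "MG"
#' @export
translate_cds <- function(cds) {
  stopifnot(is.character(cds), length(cds) == 1L)
  cds <- toupper(cds)
  n <- nchar(cds)
  if (n %% 3L != 0L) {
    stop_med12("contract_error", "sequence length ", n, " is not a multiple of 3")
  }
  if (n == 0L) return("")
  starts <- seq.int(1L, n, by = 3L)
  codons <- substring(cds, starts, starts + 2L)
  aa <- unname(.codon_table[codons])
  if (anyNA(aa)) {
    bad <- codons[is.na(aa)][1L]
    stop_med12("contract_error", "unrecognized codon '", bad, "'")
  }
  paste0(aa, collapse = "")
}

# Grantham (1974) amino-acid chemical distance, full symmetric matrix.
# Row/column order follows the original publication.
.grantham <- local({
  ord <- c("S", "R", "L", "P", "T", "A", "V", "G", "I", "F",
           "Y", "C", "H", "Q", "N", "K", "D", "E", "M", "W")
  upper <- list(
    S = c(R = 110, L = 145, P = 74, T = 58, A = 99, V = 124, G = 56, I = 142,
          F = 155, Y = 144, C = 112, H = 89, Q = 68, N = 46, K = 121, D = 65,
          E = 80, M = 135, W = 177),
    R = c(L = 102, P = 103, T = 71, A = 112, V = 96, G = 125, I = 97, F = 97,
          Y = 77, C = 180, H = 29, Q = 43, N = 86, K = 26, D = 96, E = 54,
          M = 91, W = 101),
    L = c(P = 98, T = 92, A = 96, V = 32, G = 138, I = 5, F = 22, Y = 36,
          C = 198, H = 99, Q = 113, N = 153, K = 107, D = 172, E = 138,
          M = 15, W = 61),
    P = c(T = 38, A = 27, V = 68, G = 42, I = 95, F = 114, Y = 110, C = 169,
          H = 77, Q = 76, N = 91, K = 103, D = 108, E = 93, M = 87, W = 147),
    T = c(A = 58, V = 69, G = 59, I = 89, F = 103, Y = 92, C = 149, H = 47,
          Q = 42, N = 65, K = 78, D = 85, E = 65, M = 81, W = 128),
    A = c(V = 64, G = 60, I = 94, F = 113, Y = 112, C = 195, H = 86, Q = 91,
          N = 111, K = 106, D = 126, E = 107, M = 84, W = 148),
    V = c(G = 109, I = 29, F = 50, Y = 55, C = 192, H = 84, Q = 96, N = 133,
          K = 97, D = 152, E = 121, M = 21, W = 88),
    G = c(I = 135, F = 153, Y = 147, C = 159, H = 98, Q = 87, N = 80, K = 127,
          D = 94, E = 98, M = 127, W = 184),
    I = c(F = 21, Y = 33, C = 198, H = 94, Q = 109, N = 149, K = 102, D = 168,
          E = 134, M = 10, W = 61),
    F = c(Y = 22, C = 205, H = 100, Q = 116, N = 158, K = 102, D = 177,
          E = 140, M = 28, W = 40),
    Y = c(C = 194, H = 83, Q = 99, N = 143, K = 85, D = 160, E = 122, M = 36,
          W = 37),
    C = c(H = 174, Q = 154, N = 139, K = 202, D = 154, E = 170, M = 196,
          W = 215),
    H = c(Q = 24, N = 68, K = 32, D = 81, E = 40, M = 87, W = 115),
    Q = c(N = 46, K = 53, D = 61, E = 29, M = 101, W = 130),
    N = c(K = 94, D = 23, E = 42, M = 142, W = 174),
    K = c(D = 101, E = 56, M = 95, W = 110),
    D = c(E = 45, M = 160, W = 181),
    E = c(M = 126, W = 192),
    M = c(W = 67)
  )
  m <- matrix(0, 20, 20, dimnames = list(ord, ord))
  for (a in names(upper)) for (b in names(upper[[a]])) {
    m[a, b] <- upper[[a]][[b]]
    m[b, a] <- upper[[a]][[b]]
  }
  m
})

#' Grantham chemical distance between two amino acids
#'
#' Distance between residues based on composition, polarity and molecular
#' volume; identical residues have distance 0. Used by the default damaging
#' predicate of the somatic filter (missense substitutions with distance
#' >= 50 are treated as potentially damaging).
#'
#' @param ref,alt One-letter amino-acid codes.
#' @return Numeric distance.
#' @examples
#' grantham_distance("G", "V") # 109
#' @export
grantham_distance <- function(ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  ok <- ref %in% rownames(.grantham) & alt %in% rownames(.grantham)
  if (!all(ok)) {
    stop_med12("contract_error", "unknown amino acid code in (",
               paste(ref[!ok], alt[!ok], collapse = ", "), ")")
  }
  .grantham[cbind(ref, alt)]
}

# Condition helper: all package errors carry a subclass so callers and the
# command-line front end can map them to exit codes.
stop_med12 <- function(class, ...) {
  msg <- paste0(...)
  cond <- structure(
    class = c(paste0("med12scan_", class), "med12scan_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
  stop(cond)
}
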