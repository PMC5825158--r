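## Grantham (1974) physico-chemical distances between amino acids, built from
## side-chain composition, polarity and molecular volume.  Published as an
## integer matrix; embedded verbatim rather than recomputed so that scores
## are bit-exact.  Range 0 (identity) to 215 (Cys-Trp).

.grantham_order <- c("S", "R", "L", "P", "T", "A", "V", "G", "I", "F",
                     "Y", "C", "H", "Q", "N", "K", "D", "E", "M", "W")

.grantham_upper <- list(
  S = c(R = 110, L = 145, P = 74,  T = 58,  A = 99,  V = 124, G = 56,
        I = 142, F = 155, Y = 144, C = 112, H = 89,  Q = 68,  N = 46,
        K = 121, D = 65,  E = 80,  M = 135, W = 177),
  R = c(L = 102, P = 103, T = 71,  A = 112, V = 96,  G = 125, I = 97,
        F = 97,  Y = 77,  C = 180, H = 29,  Q = 43,  N = 86,  K = 26,
        D = 96,  E = 54,  M = 91,  W = 101),
  L = c(P = 98,  T = 92,  A = 96,  V = 32,  G = 138, I = 5,   F = 22,
        Y = 36,  C = 198, H = 99,  Q = 113, N = 153, K = 107, D = 172,
        E = 138, M = 15,  W = 61),
  P = c(T = 38,  A = 27,  V = 68,  G = 42,  I = 95,  F = 114, Y = 110,
        C = 169, H = 77,  Q = 76,  N = 91,  K = 103, D = 108, E = 93,
        M = 87,  W = 147),
  T = c(A = 58,  V = 69,  G = 59,  I = 89,  F = 103, Y = 92,  C = 149,
        H = 47,  Q = 42,  N = 65,  K = 78,  D = 85,  E = 65,  M = 81,
        W = 128),
  A = c(V = 64,  G = 60,  I = 94,  F = 113, Y = 112, C = 195, H = 86,
        Q = 91,  N = 111, K = 106, D = 126, E = 107, M = 84,  W = 148),
  V = c(G = 109, I = 29,  F = 50,  Y = 55,  C = 192, H = 84,  Q = 96,
        N = 133, K = 97,  D = 152, E = 121, M = 21,  W = 88),
  G = c(I = 135, F = 153, Y = 147, C = 159, H = 98,  Q = 87,  N = 80,
        K = 127, D = 94,  E = 98,  M = 127, W = 184),
  I = c(F = 21,  Y = 33,  C = 198, H = 94,  Q = 109, N = 149, K = 102,
        D = 168, E = 134, M = 10,  W = 61),
  F = c(Y = 22,  C = 205, H = 100, Q = 116, N = 158, K = 102, D = 177,
        E = 140, M = 28,  W = 40),
  Y = c(C = 194, H = 83,  Q = 99,  N = 143, K = 85,  D = 160, E = 122,
        M = 36,  W = 37),
  C = c(H = 174, Q = 154, N = 139, K = 202, D = 154, E = 170, M = 196,
        W = 215),
  H = c(Q = 24,  N = 68,  K = 32,  D = 81,  E = 40,  M = 87,  W = 115),
  Q = c(N = 46,  K = 53,  D = 61,  E = 29,  M = 101, W = 130),
  N = c(K = 94,  D = 23,  E = 42,  M = 142, W = 174),
  K = c(D = 101, E = 56,  M = 95,  W = 110),
  D = c(E = 45,  M = 160, W = 181),
  E = c(M = 126, W = 152),
  M = c(W = 67))

.build_grantham <- function() {
  aa <- sort(.grantham_order)
  m <- matrix(0L, 20, 20, dimnames = list(aa, aa))
  for (a in names(.grantham_upper)) {
    v <- .grantham_upper[[a]]
    m[a, names(v)] <- as.integer(v)
    m[names(v), a] <- as.integer(v)
  }
  m
}

#' The Grantham amino-acid distance matrix
#'
#' Returns the 20x20 symmetric, zero-diagonal integer matrix of Grantham
#' (1974) distances between the standard amino acids (one-letter codes,
#' alphabetical order).  Values range from 0 to 215 (cysteine-tryptophan);
#' larger values indicate more radical substitutions.
#'
#' @return integer matrix with one-letter amino-acid dimnames
#' @export
grantham_matrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- .build_grantham()
    cache
  }
})

#' Grantham distance between two amino acids
#'
#' @param aa_from,aa_to standard one-letter amino-acid codes (case
#'   insensitive); vectors are recycled elementwise
#' @return integer Grantham score(s); 0 for identical residues
#' @examples
#' grantham_score("C", "W")  # 215, the most radical substitution
#' grantham_score("Y", "S")  # 144
#' @export
grantham_score <- function(aa_from, aa_to) {
  m <- grantham_matrix()
  f <- toupper(aa_from); t <- toupper(aa_to)
  bad <- setdiff(unique(c(f, t)), rownames(m))
  if (length(bad))
    stop("unknown amino acid code(s): ", paste(bad, collapse = ", "))
  m[cbind(f, t)]
}
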