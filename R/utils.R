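# Internal helpers: deterministic seeding, genetic code, random CDR3 synthesis.

#' Derive a labelled RNG seed from a master seed
#'
#' Stable 31-bit hash of the master seed plus any number of labels (group,
#' mouse, side, timepoint, ...), used throughout the generator so that every
#' sample has its own reproducible RNG stream and adding samples never
#' perturbs existing ones. Polynomial rolling hash mod the Mersenne prime
#' 2^31 - 1; stable across platforms and R sessions.
#'
#' @param master Integer master seed.
#' @param ... Further labels (coerced to character).
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(master, ...) {
  stopifnot(is.numeric(master), length(master) == 1L)
  s <- paste(c(format(master, scientific = FALSE), ...), collapse = "/")
  h <- 0
  for (code in utf8ToInt(s)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

# Evaluate expr under a temporary RNG state so callers' streams are untouched.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Standard genetic code, amino acid -> synonymous codons.
AA_CODONS <- list(
  A = c("GCT", "GCC", "GCA", "GCG"),
  C = c("TGT", "TGC"),
  D = c("GAT", "GAC"),
  E = c("GAA", "GAG"),
  F = c("TTT", "TTC"),
  G = c("GGT", "GGC", "GGA", "GGG"),
  H = c("CAT", "CAC"),
  I = c("ATT", "ATC", "ATA"),
  K = c("AAA", "AAG"),
  L = c("TTA", "TTG", "CTT", "CTC", "CTA", "CTG"),
  M = c("ATG"),
  N = c("AAT", "AAC"),
  P = c("CCT", "CCC", "CCA", "CCG"),
  Q = c("CAA", "CAG"),
  R = c("CGT", "CGC", "CGA", "CGG", "AGA", "AGG"),
  S = c("TCT", "TCC", "TCA", "TCG", "AGT", "AGC"),
  T = c("ACT", "ACC", "ACA", "ACG"),
  V = c("GTT", "GTC", "GTA", "GTG"),
  W = c("TGG"),
  Y = c("TAT", "TAC")
)

CODON_TO_AA <- local({
  aa <- rep(names(AA_CODONS), lengths(AA_CODONS))
  stats::setNames(aa, unlist(AA_CODONS, use.names = FALSE))
})

#' Translate an in-frame nucleotide string
#'
#' Standard-code translation used to validate that a productive CDR3
#' nucleotide sequence is consistent with its reported amino-acid sequence.
#' Stop codons translate to `"*"`.
#'
#' @param nt Uppercase nucleotide string whose length is a multiple of 3.
#' @return The translated amino-acid string.
#' @export
translate_nt <- function(nt) {
  stopifnot(is.character(nt), length(nt) == 1L)
  if (nchar(nt) %% 3 != 0) {
    stop("nucleotide length ", nchar(nt), " is not a multiple of 3")
  }
  codons <- substring(nt, seq(1, nchar(nt), 3), seq(3, nchar(nt), 3))
  aa <- CODON_TO_AA[codons]
  aa[is.na(aa)] <- "*"
  paste(aa, collapse = "")
}

AA_CODONS_FLAT <- unlist(AA_CODONS, use.names = FALSE)
AA_CODON_OFFSET <- stats::setNames(
  c(0L, cumsum(lengths(AA_CODONS)))[seq_along(AA_CODONS)],
  names(AA_CODONS))
AA_CODON_N <- stats::setNames(lengths(AA_CODONS), names(AA_CODONS))

# Generate n random in-frame CDR3s. Amino-acid sequences follow the canonical
# C...F motif with lengths drawn uniformly on aa_len (11-17 aa, i.e. 33-51 nt);
# nucleotides are a random synonymous back-translation, so translation is
# consistent by construction and contains no stop codon. Fully vectorized:
# one RNG draw stream for all residues, one for all codon choices.
random_cdr3 <- function(n, aa_len = 11:17) {
  if (n == 0L) {
    return(data.frame(cdr3_nt = character(0), cdr3_aa = character(0),
                      stringsAsFactors = FALSE))
  }
  alphabet <- names(AA_CODONS)
  lens <- sample(aa_len, n, replace = TRUE)
  grp <- rep.int(seq_len(n), lens)
  pos <- sequence(lens)
  chars <- sample(alphabet, length(grp), replace = TRUE)
  chars[pos == 1L] <- "C"
  chars[pos == rep.int(lens, lens)] <- "F"
  aa <- vapply(split(chars, grp), paste, character(1), collapse = "")
  codon_idx <- AA_CODON_OFFSET[chars] +
    floor(stats::runif(length(chars)) * AA_CODON_N[chars]) + 1L
  codons <- AA_CODONS_FLAT[codon_idx]
  nt <- vapply(split(codons, grp), paste, character(1), collapse = "")
  data.frame(cdr3_nt = unname(nt), cdr3_aa = unname(aa),
             stringsAsFactors = FALSE)
}

# Out-of-frame decoy CDR3s (length = 3k + 1) with no translation; these
# emulate nonproductive rearrangements and exercise the annotation filter.
random_cdr3_nonproductive <- function(n, nt_len = seq(34, 52, by = 3)) {
  if (n == 0L) {
    return(data.frame(cdr3_nt = character(0), cdr3_aa = character(0),
                      stringsAsFactors = FALSE))
  }
  lens <- sample(nt_len, n, replace = TRUE)
  grp <- rep.int(seq_len(n), lens)
  bases <- sample(c("A", "C", "G", "T"), length(grp), replace = TRUE)
  nt <- vapply(split(bases, grp), paste, character(1), collapse = "")
  data.frame(cdr3_nt = unname(nt), cdr3_aa = character(n),
             stringsAsFactors = FALSE)
}

# Zipf (power-law) weights over ranks 1..n, exponent alpha, normalised to 1.
zipf_weights <- function(n, alpha = 1) {
  if (n == 0L) return(numeric(0))
  w <- (seq_len(n))^(-alpha)
  w / sum(w)
}
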