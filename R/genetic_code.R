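# Genetic-code bookkeeping shared by the codon-bias machinery.
#
# Everything is derived from Biostrings' genetic-code tables so that codes
# other than the bacterial/archaeal table 11 (the default throughout) work
# unchanged. Synonymous families are grouped at full degeneracy (Wright's
# convention: 9 twofold, 1 threefold, 5 fourfold, 3 sixfold families plus the
# Met/Trp singletons for the standard code).

ALL_CODONS <- as.vector(outer(outer(c("T", "C", "A", "G"), c("T", "C", "A", "G"),
                                    paste0), c("T", "C", "A", "G"), paste0))

# The four two-codon amino acids used by the S index. C1 is the
# Watson-Crick-matched (translationally optimal) codon, C2 its wobble partner.
S_CODON_PAIRS <- tibble::tibble(
  amino_acid = c("Phe", "Ile", "Tyr", "Asn"),
  c1 = c("TTC", "ATC", "TAC", "AAC"),
  c2 = c("TTT", "ATT", "TAT", "AAT")
)

AA3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
         E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
         M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
         Y = "Tyr", V = "Val")

#' Codon table for a genetic code
#'
#' Sense codons, their amino acids and synonymous-family sizes for a genetic
#' code, plus the derived quantities used by the effective-number-of-codons
#' computation (floor = number of amino acids, ceiling = number of sense
#' codons; 20 and 61 for the standard and bacterial codes).
#'
#' @param genetic_code Genetic-code identifier as understood by
#'   [Biostrings::getGeneticCode()]; default `"11"` (bacteria/archaea).
#' @return A list with elements `codons` (tibble: codon, aa, family size),
#'   `families` (list of codon character vectors per degenerate family),
#'   `stops`, `n_singletons`, `floor`, `ceiling`.
#' @keywords internal
#' @noRd
genetic_code_info <- function(genetic_code = "11") {
  gc <- Biostrings::getGeneticCode(as.character(genetic_code))
  codons <- tibble(codon = names(gc), aa = unname(gc))
  stops <- codons$codon[codons$aa == "*"]
  sense <- codons[codons$aa != "*", ]
  fam_sizes <- table(sense$aa)
  sense$family_size <- as.integer(fam_sizes[sense$aa])
  families <- split(sense$codon, sense$aa)
  families <- families[vapply(families, length, 1L) > 1L]
  list(
    codons = sense,
    families = families,
    stops = stops,
    n_singletons = sum(fam_sizes == 1L),
    floor = length(fam_sizes),
    ceiling = nrow(sense)
  )
}

# memoised per code id: the table lookup is called in per-gene loops
code_cache <- new.env(parent = emptyenv())
code_info <- function(genetic_code = "11") {
  key <- as.character(genetic_code)
  if (is.null(code_cache[[key]])) code_cache[[key]] <- genetic_code_info(key)
  code_cache[[key]]
}

# number of A/C/G/T in each of the 64 codons; used to turn codon counts into
# coding nucleotide composition
codon_base_matrix <- function() {
  m <- vapply(c("A", "C", "G", "T"), function(b) {
    vapply(strsplit(ALL_CODONS, ""), function(x) sum(x == b), 1L)
  }, integer(64))
  rownames(m) <- ALL_CODONS
  m
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
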