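# Independent brute-force oracle for the background-corrected effective
# number of codons, written as plain loops over hand-listed synonymous
# families (deliberately not sharing code with the package internals).

oracle_families <- list(
  Phe = c("TTT", "TTC"), Tyr = c("TAT", "TAC"), His = c("CAT", "CAC"),
  Gln = c("CAA", "CAG"), Asn = c("AAT", "AAC"), Lys = c("AAA", "AAG"),
  Asp = c("GAT", "GAC"), Glu = c("GAA", "GAG"), Cys = c("TGT", "TGC"),
  Ile = c("ATT", "ATC", "ATA"),
  Val = c("GTT", "GTC", "GTA", "GTG"), Pro = c("CCT", "CCC", "CCA", "CCG"),
  Thr = c("ACT", "ACC", "ACA", "ACG"), Ala = c("GCT", "GCC", "GCA", "GCG"),
  Gly = c("GGT", "GGC", "GGA", "GGG"),
  Leu = c("TTA", "TTG", "CTT", "CTC", "CTA", "CTG"),
  Ser = c("TCT", "TCC", "TCA", "TCG", "AGT", "AGC"),
  Arg = c("CGT", "CGC", "CGA", "CGG", "AGA", "AGG")
)

# counts: named vector over (a subset of) the 61 sense codons
# background: named A/C/G/T frequency vector; if NULL, derived from counts
oracle_enc_prime <- function(counts, background = NULL) {
  get_count <- function(codon) {
    v <- counts[codon]
    if (is.na(v)) 0 else as.numeric(v)
  }
  if (is.null(background)) {
    nt <- c(A = 0, C = 0, G = 0, T = 0)
    for (codon in names(counts)) {
      for (b in strsplit(codon, "")[[1]]) nt[b] <- nt[b] + counts[codon]
    }
    background <- nt / sum(nt)
  }
  f_by_class <- list(`2` = c(), `3` = c(), `4` = c(), `6` = c())
  for (fam in oracle_families) {
    k <- length(fam)
    n_i <- vapply(fam, get_count, 1)
    n <- sum(n_i)
    if (n < 2) next
    e_i <- vapply(fam, function(codon) {
      p <- 1
      for (b in strsplit(codon, "")[[1]]) p <- p * background[[b]]
      p
    }, 1)
    e_i <- e_i / sum(e_i)
    chi2 <- 0
    for (i in seq_len(k)) {
      expd <- n * e_i[i]
      if (expd > 0) chi2 <- chi2 + (n_i[i] - expd)^2 / expd
    }
    f_hat <- (chi2 + n - k) / (k * (n - 1))
    if (f_hat <= 0) next
    kk <- as.character(k)
    f_by_class[[kk]] <- c(f_by_class[[kk]], f_hat)
  }
  fbar <- vapply(f_by_class, function(v) {
    if (length(v) == 0) NA_real_ else mean(v)
  }, 1)
  if (is.na(fbar["2"]) || is.na(fbar["4"])) return(NA_real_)
  if (is.na(fbar["3"])) fbar["3"] <- (fbar["2"] + fbar["4"]) / 2
  if (is.na(fbar["6"])) fbar["6"] <- (fbar["2"] + fbar["4"]) / 2
  enc <- 2 + 9 / fbar["2"] + 1 / fbar["3"] + 5 / fbar["4"] + 3 / fbar["6"]
  unname(min(max(enc, 20), 61))
}

# enumeration oracle for the uniform-random classification null: expected
# proportions from the full 4x4 observed-class x predicted-class table
oracle_null_expectations <- function(sizes) {
  acc <- matrix(0, 4, 4)  # acc[obs, pred] = 1 if |obs - pred| <= 1
  wrg <- matrix(0, 4, 4)
  for (o in 1:4) for (p in 1:4) {
    if (abs(o - p) <= 1) acc[o, p] <- 1
    if ((o == 4 && p <= 2) || (o <= 2 && p == 4)) wrg[o, p] <- 1
  }
  exact <- sum(vapply(1:4, function(o) sizes[o] * 0.25, 1)) / sum(sizes)
  approx <- sum(vapply(1:4, function(o) sizes[o] * sum(acc[o, ]) / 4, 1)) /
    sum(sizes)
  wrong <- sum(vapply(1:4, function(o) sizes[o] * sum(wrg[o, ]) / 4, 1)) /
    sum(sizes)
  100 * c(exact = exact, approx = approx, wrong = wrong)
}

# small deterministic fixtures shared across test files
fixture_genome <- function(s_strength = 2, seed = 101, n_genes = 60,
                           n_heg = 12) {
  synth_genome(n_genes = n_genes, n_heg = n_heg, gene_len = 600,
               s_strength = s_strength, seed = seed)
}

fixture_composite <- function() {
  tbl <- synth_training_table(n_species = 60, seed = 7)
  fit_composite(tbl)
}
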