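# Synthetic data with controlled translational selection, so every pipeline
# stage is testable offline with known truth.

#' Optimal codons used by the synthetic generator
#'
#' The C1 codons of the four two-codon amino acids scored by the S index
#' (TTC, ATC, TAC, AAC) plus, for every other degenerate family, the codon
#' with the highest third-position G+C (ties broken C before G): selection
#' toward this set moves both ΔENC′ and S.
#'
#' @param genetic_code Genetic-code id.
#' @return Character vector of codons.
#' @export
synth_optimal_codons <- function(genetic_code = "11") {
  info <- code_info(genetic_code)
  rank3 <- c(C = 4, G = 3, T = 2, A = 1)
  picks <- map_chr(info$families, function(codons) {
    third <- substr(codons, 3, 3)
    codons[order(-rank3[third])][1]
  })
  s_aa_codons <- setNames(S_CODON_PAIRS$c1,
                          names(AA3)[match(S_CODON_PAIRS$amino_acid, AA3)])
  picks[names(s_aa_codons)] <- s_aa_codons
  unname(picks)
}

#' Generate a synthetic genome with controlled codon-usage selection
#'
#' Emulates the mutation–selection structure of codon usage bias. Background
#' genes draw synonymous codons in proportion to a G+C-driven mutational
#' background; a designated highly-expressed subset reweights the optimal
#' codon of each family (see [synth_optimal_codons()]) by
#' `exp(s_strength)`. Selection acts only on the synonymous choice — the
#' amino-acid composition of HEG and background genes is identical in
#' distribution — so differences in ΔENC′ and S are pure codon-bias
#' signals. Every gene starts with ATG, ends with TAA, and has length a
#' multiple of 3 of at least 450 nt.
#'
#' @param n_genes Total number of genes (default 200).
#' @param n_heg Number of highly expressed genes among them (default 30,
#'   roughly the ribosomal-protein share of a small genome).
#' @param gene_len Mean gene length, nt (default 900; lengths are drawn
#'   around it with ~15% spread).
#' @param gc Background G+C fraction in (0, 1) (default 0.5).
#' @param s_strength Selection coefficient (>= 0) applied to optimal codons
#'   in HEG (default 1).
#' @param seed Integer seed; output is reproducible.
#' @param genetic_code Genetic-code id.
#' @return Gene tibble (`id`, `seq`, `is_heg`) ready for [bias_indices()].
#' @examples
#' g <- synth_genome(n_genes = 50, n_heg = 10, s_strength = 2, seed = 1)
#' bias_indices(g)
#' @export
synth_genome <- function(n_genes = 200L, n_heg = 30L, gene_len = 900L,
                         gc = 0.5, s_strength = 1, seed = 1L,
                         genetic_code = "11") {
  if (gc <= 0 || gc >= 1) abort("`gc` must be strictly between 0 and 1")
  if (n_heg > n_genes) abort("`n_heg` cannot exceed `n_genes`")
  if (s_strength < 0) abort("`s_strength` must be non-negative")
  info <- code_info(genetic_code)
  sense <- info$codons$codon
  # mutational background: independent positions, G+C-driven
  base_p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  bm <- codon_base_matrix()[sense, ]
  q <- exp(bm %*% log(base_p))[, 1]          # P(codon) under the background
  q <- q / sum(q)
  aa <- info$codons$aa
  aa_p <- tapply(q, aa, sum)                  # amino-acid usage, shared
  opt <- sense %in% synth_optimal_codons(genetic_code)
  codon_dist <- function(sel) {
    w <- q * exp(sel * opt)
    # renormalise within each family so amino-acid content is untouched
    fam_tot <- tapply(w, aa, sum)
    as.numeric(w / fam_tot[aa] * aa_p[aa])
  }
  p_bg <- codon_dist(0)
  p_heg <- codon_dist(s_strength)
  withr::with_seed(seed, {
    n_codons <- pmax(150L, as.integer(round(
      rnorm(n_genes, gene_len / 3, gene_len / 20)
    )))
    is_heg <- c(rep(TRUE, n_heg), rep(FALSE, n_genes - n_heg))
    seqs <- map_chr(seq_len(n_genes), function(i) {
      p <- if (is_heg[i]) p_heg else p_bg
      body <- sample(sense, n_codons[i] - 2L, replace = TRUE, prob = p)
      paste0("ATG", paste(body, collapse = ""), "TAA")
    })
    tibble(id = sprintf("%s_%03d", ifelse(is_heg, "heg", "bg"),
                        seq_len(n_genes)),
           seq = seqs, is_heg = is_heg)
  })
}

#' Generate a synthetic community of genomes
#'
#' Convenience wrapper drawing one synthetic genome per element of
#' `s_strengths` and stacking them, emulating a metagenome whose member
#' species differ in selection for translational optimisation (and may
#' differ in G+C, hence in preferred background codons).
#'
#' @param s_strengths Numeric vector, one selection coefficient per genome.
#' @param gcs Background G+C per genome (recycled; default 0.5).
#' @param seed Integer seed.
#' @param ... Passed to [synth_genome()] (`n_genes`, `n_heg`, `gene_len`).
#' @return Gene tibble with an extra `source` column naming the genome.
#' @export
synth_community <- function(s_strengths, gcs = 0.5, seed = 1L, ...) {
  gcs <- rep_len(gcs, length(s_strengths))
  out <- map(seq_along(s_strengths), function(i) {
    g <- synth_genome(s_strength = s_strengths[i], gc = gcs[i],
                      seed = seed + i, ...)
    g$id <- paste0("sp", i, "_", g$id)
    g$source <- paste0("sp", i)
    g
  })
  list_rbind(out)
}

#' Generate a synthetic training table with known regression truth
#'
#' Samples composite index values F from a standard normal, inverts them to
#' (ΔENC′, S) pairs through fixed equal loadings and realistic index
#' scales, and produces doubling times from
#' `Phi = intercept + slope * F + noise` followed by the inverse Box-Cox
#' transform. Enables parameter-recovery tests of [fit_predictor()] against
#' a known truth.
#'
#' @param n_species Number of rows (at least 10).
#' @param intercept,slope,lambda Truth of the generating model (defaults:
#'   the published mesophilic coefficients, log-limit transform).
#' @param noise_sd Gaussian noise standard deviation on the transformed
#'   scale (default 0.3; 0 gives exact interpolation).
#' @param seed Integer seed.
#' @return Tibble with columns `species`, `delta_enc`, `s`, `f_true`, `d`,
#'   `ogt`.
#' @export
synth_training_table <- function(n_species = 200L, intercept = 0.8741,
                                 slope = -0.6496, lambda = 0,
                                 noise_sd = 0.3, seed = 1L) {
  if (n_species < 10) abort("`n_species` must be at least 10")
  if (noise_sd < 0) abort("`noise_sd` must be non-negative")
  withr::with_seed(seed, {
    f <- rnorm(n_species)
    z <- f / sqrt(2)                 # equal unit-norm loadings
    delta_enc <- 0.15 + 0.08 * z     # typical ΔENC′ scale (~0–0.35)
    s <- 0.5 + 0.4 * z               # typical S scale (~-0.3–1.5)
    phi <- intercept + slope * f + rnorm(n_species, 0, noise_sd)
    tibble(
      species = sprintf("sp%03d", seq_len(n_species)),
      delta_enc = delta_enc, s = s, f_true = f,
      d = inv_box_cox(phi, lambda),
      ogt = pmin(pmax(rnorm(n_species, 37, 6), 16), 59)
    )
  })
}
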