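# Codon-usage-bias indices: background-corrected effective number of codons
# (ENC'), the differential dENC' contrasting highly expressed genes (HEG)
# with the rest, the optimal-codon frequencies P over the two-codon amino
# acids Phe/Ile/Tyr/Asn, and the selection-strength index S.

#' Count codons in a set of genes
#'
#' Counts the sense codons of each in-frame coding sequence. Stop codons are
#' never counted; codons containing `N` are skipped (the rest of the gene is
#' kept). The background is the nucleotide composition of the counted codons
#' ("average coding nucleotide frequency").
#'
#' @param genes Tibble with columns `id` and `seq`, a FASTA path, or a
#'   character vector of sequences.
#' @param concatenate If `TRUE` (default) all genes are pooled into a single
#'   count vector with a common background; if `FALSE` a list of per-gene
#'   counts is returned, each with the gene's own background.
#' @param genetic_code Genetic-code id (default `"11"`).
#' @return A `codon_counts` object (fields `counts`, `background`,
#'   `n_codons`, `genetic_code`) or a named list of them.
#' @examples
#' codon_counts(c(g1 = "ATGAAATAA"))
#' @export
codon_counts <- function(genes, concatenate = TRUE, genetic_code = "11") {
  genes <- as_gene_tbl(genes, require_heg = FALSE)
  if (nrow(genes) == 0L) abort("empty gene list")
  m <- codon_count_matrix(genes$seq)
  info <- code_info(genetic_code)
  sense <- info$codons$codon
  if (concatenate) {
    cnt <- colSums(m)[sense]
    new_codon_counts(cnt, genetic_code)
  } else {
    zero <- rowSums(m[, sense, drop = FALSE]) == 0L
    if (any(zero)) {
      warn(paste0("gene(s) with zero countable codons excluded: ",
                  paste(genes$id[zero], collapse = ", ")))
    }
    keep <- which(!zero)
    out <- lapply(keep, function(i) new_codon_counts(m[i, sense], genetic_code))
    names(out) <- genes$id[keep]
    out
  }
}

new_codon_counts <- function(counts, genetic_code) {
  counts <- as.integer(counts) |> setNames(names(counts))
  bg <- background_from_counts(matrix(counts, nrow = 1,
                                      dimnames = list(NULL, names(counts))))
  structure(
    list(counts = counts, background = bg[1, ], n_codons = sum(counts),
         genetic_code = as.character(genetic_code)),
    class = "codon_counts"
  )
}

#' @export
print.codon_counts <- function(x, ...) {
  cat("<codon_counts> ", x$n_codons, " codons, genetic code ",
      x$genetic_code, "\n", sep = "")
  cat("background (A,C,G,T): ",
      paste(sprintf("%.3f", x$background), collapse = ", "), "\n", sep = "")
  invisible(x)
}

# genes x 64 codon count matrix; N-containing codons fall out automatically
codon_count_matrix <- function(seqs) {
  dss <- Biostrings::DNAStringSet(seqs)
  m <- Biostrings::oligonucleotideFrequency(dss, width = 3, step = 3)
  m[, ALL_CODONS, drop = FALSE]
}

# per-row A/C/G/T composition of the counted codons
background_from_counts <- function(cnt) {
  bm <- codon_base_matrix()[colnames(cnt), , drop = FALSE]
  nt <- cnt %*% bm
  tot <- rowSums(nt)
  sweep(nt, 1, pmax(tot, 1), "/")
}

#' Background-corrected effective number of codons (ENC′)
#'
#' Computes the effective number of codons corrected for background
#' nucleotide composition. For each synonymous family, codon frequencies
#' expected from the background composition are compared with the observed
#' counts by a chi-square statistic; the resulting corrected homozygosity
#' per family is averaged within degeneracy classes and combined by Wright's
#' formula (for the bacterial code: `2 + 9/F2 + 1/F3 + 5/F4 + 3/F6`). A
#' missing threefold or sixfold class mean is estimated as the average of
#' the twofold and fourfold means; with two or more classes missing the
#' index is undefined (`NA`). Values are capped to the theoretical range
#' (20–61): 20 means one codon per amino acid (maximal bias), 61 means
#' usage matching the background expectation.
#'
#' @param counts A `codon_counts` object (see [codon_counts()]), or a named
#'   vector of sense-codon counts (the background is then derived from the
#'   counts themselves unless `background` is given).
#' @param genetic_code Genetic-code id; ignored when `counts` is a
#'   `codon_counts` object.
#' @param background Optional A/C/G/T frequency vector overriding the
#'   background derived from the counts.
#' @return A single ENC′ value.
#' @references Novembre JA (2002) Mol Biol Evol 19:1390-1394; Wright F
#'   (1990) Gene 87:23-29.
#' @export
enc_prime <- function(counts, genetic_code = "11", background = NULL) {
  if (inherits(counts, "codon_counts")) {
    genetic_code <- counts$genetic_code
    background <- background %||% counts$background
    counts <- counts$counts
  }
  info <- code_info(genetic_code)
  cnt <- matrix(0, nrow = 1, ncol = nrow(info$codons),
                dimnames = list(NULL, info$codons$codon))
  common <- intersect(names(counts), colnames(cnt))
  cnt[1, common] <- counts[common]
  if (sum(cnt) == 0) abort("no countable codons; ENC' undefined")
  bg <- if (is.null(background)) background_from_counts(cnt) else {
    matrix(background[c("A", "C", "G", "T")], nrow = 1,
           dimnames = list(NULL, c("A", "C", "G", "T")))
  }
  enc_prime_matrix(cnt, bg, info)[1]
}

# Vectorised ENC' over rows of a gene x sense-codon count matrix.
# `bg` is the matching rows x ACGT composition matrix.
enc_prime_matrix <- function(cnt, bg, info) {
  n <- nrow(cnt)
  fams <- info$families
  fam_k <- vapply(fams, length, 1L)
  fhat <- matrix(NA_real_, n, length(fams))
  for (j in seq_along(fams)) {
    codons <- fams[[j]]
    k <- fam_k[j]
    sub <- cnt[, codons, drop = FALSE]
    nf <- rowSums(sub)
    # expected within-family frequencies from the background composition
    e <- matrix(1, n, k)
    for (ci in seq_len(k)) {
      bases <- strsplit(codons[ci], "")[[1]]
      e[, ci] <- bg[, bases[1]] * bg[, bases[2]] * bg[, bases[3]]
    }
    esum <- rowSums(e)
    e <- e / ifelse(esum > 0, esum, 1)
    exp_cnt <- e * nf
    dev <- (sub - exp_cnt)^2
    term <- ifelse(exp_cnt > 0, dev / exp_cnt, 0)
    chi2 <- rowSums(term)
    f <- (chi2 + nf - k) / (k * (nf - 1))
    f[nf < 2 | f <= 0] <- NA_real_
    fhat[, j] <- f
  }
  class_sizes <- sort(unique(fam_k))
  fbar <- sapply(class_sizes, function(k) {
    cols <- fhat[, fam_k == k, drop = FALSE]
    rowMeans(cols, na.rm = TRUE)
  })
  fbar <- matrix(fbar, nrow = n)
  fbar[is.nan(fbar)] <- NA_real_
  colnames(fbar) <- class_sizes
  # Wright's convention: estimate a missing 3- or 6-fold class mean from the
  # 2- and 4-fold means; give up when two or more classes are missing
  have24 <- !is.na(fbar[, "2"]) & !is.na(fbar[, "4"])
  for (k in setdiff(class_sizes, c(2L, 4L))) {
    kk <- as.character(k)
    miss <- is.na(fbar[, kk]) & have24
    fbar[miss, kk] <- (fbar[miss, "2"] + fbar[miss, "4"]) / 2
  }
  n_missing <- rowSums(is.na(fbar))
  k_counts <- table(fam_k)[as.character(class_sizes)]
  contrib <- sweep(1 / fbar, 2, as.numeric(k_counts), "*")
  enc <- info$n_singletons + rowSums(contrib)
  enc[n_missing > 0] <- NA_real_
  pmin(pmax(enc, info$floor), info$ceiling)
}

#' Differential ENC′ between all genes and highly expressed genes
#'
#' `delta_enc_prime = (enc_all - enc_heg) / enc_all`: the relative reduction
#' of the effective number of codons in highly expressed genes. Larger
#' values indicate stronger translation-associated selection on codon usage.
#'
#' @param enc_all,enc_heg ENC′ of the all-gene and HEG sets (each in
#'   20–61).
#' @return ΔENC′ (dimensionless, at most 1).
#' @export
delta_enc_prime <- function(enc_all, enc_heg) {
  stopifnot(all(enc_all >= 20 - 1e-9 & enc_all <= 61 + 1e-9),
            all(enc_heg >= 20 - 1e-9 & enc_heg <= 61 + 1e-9))
  (enc_all - enc_heg) / enc_all
}

#' Optimal-codon frequencies P for the two-codon amino acids
#'
#' For Phe (C1 = TTC, C2 = TTT), Ile (ATC/ATT), Tyr (TAC/TAT) and Asn
#' (AAC/AAT), computes `P = C1 / (C1 + C2)`, the frequency of the
#' Watson-Crick-matched, translationally optimal codon. When exactly one of
#' the two counts is zero a pseudocount of 0.5 is added to both, keeping the
#' downstream log-odds finite; when both are zero the amino acid is flagged
#' absent (`P = NA`).
#'
#' @param counts A `codon_counts` object or named codon count vector.
#' @return Tibble with columns `amino_acid`, `n_c1`, `n_c2`, `p`, `absent`.
#' @export
p_optimal <- function(counts) {
  if (inherits(counts, "codon_counts")) counts <- counts$counts
  n1 <- as.numeric(counts[S_CODON_PAIRS$c1])
  n2 <- as.numeric(counts[S_CODON_PAIRS$c2])
  n1[is.na(n1)] <- 0; n2[is.na(n2)] <- 0
  p <- p_with_pseudocount(n1, n2)
  tibble(amino_acid = S_CODON_PAIRS$amino_acid,
         n_c1 = n1, n_c2 = n2, p = p, absent = (n1 + n2) == 0)
}

p_with_pseudocount <- function(n1, n2) {
  zero_one <- (n1 == 0) != (n2 == 0)
  a1 <- ifelse(zero_one, n1 + 0.5, n1)
  a2 <- ifelse(zero_one, n2 + 0.5, n2)
  ifelse(n1 + n2 == 0, NA_real_, a1 / (a1 + a2))
}

#' Selection-strength index S
#'
#' For each two-codon amino acid, `S_i` is the log odds ratio of optimal
#' codon use in highly expressed genes relative to all genes:
#' `S_i = ln[(P_heg/(1-P_heg)) / (P_all/(1-P_all))]`. `S` is the mean of the
#' `S_i` weighted by the number of C1+C2 codons observed in the HEG set.
#'
#' @param p_heg,p_all Named numeric vectors (or [p_optimal()] tibbles) of
#'   optimal-codon frequencies for the HEG and all-gene sets.
#' @param weights Named vector of C1+C2 codon counts in the HEG set, used as
#'   weights; amino acids with zero weight or undefined P are dropped.
#' @return List with `components` (tibble: `amino_acid`, `s_i`, `weight`)
#'   and `s` (the weighted mean).
#' @references Sharp PM et al. (2005) Nucleic Acids Res 33:1141-1153.
#' @export
s_index <- function(p_heg, p_all, weights) {
  as_p_vec <- function(p) {
    if (is.data.frame(p)) setNames(p$p, p$amino_acid) else p
  }
  ph <- as_p_vec(p_heg); pa <- as_p_vec(p_all)
  aa <- S_CODON_PAIRS$amino_acid
  ph <- ph[aa]; pa <- pa[aa]; w <- as.numeric(weights[aa])
  w[is.na(w)] <- 0
  usable <- !is.na(ph) & !is.na(pa) & ph > 0 & ph < 1 & pa > 0 & pa < 1 & w > 0
  if (!any(usable)) abort("no usable amino acid for the S index")
  s_i <- ifelse(usable,
                log((ph / (1 - ph)) / (pa / (1 - pa))),
                NA_real_)
  s <- sum(s_i[usable] * w[usable]) / sum(w[usable])
  list(components = tibble(amino_acid = aa, s_i = s_i, weight = w), s = s)
}

#' Per-gene codon-bias quantities
#'
#' Computes, for every gene separately, the ENC′ (against the gene's own
#' nucleotide composition — genes in a metagenome come from different
#' genomes), the optimal-codon frequencies P of the four two-codon amino
#' acids, and the underlying C1/C2 counts. This is the gene-level input to
#' [bias_indices()] in `"gene-averaged"` mode and to the bootstrap and
#' subsampling routines, where resampling reduces to resampling rows.
#'
#' @param genes Tibble with `id`, `seq` and optionally `is_heg`.
#' @param genetic_code Genetic-code id (default `"11"`).
#' @return Tibble with one row per gene: `id`, `is_heg` (if supplied),
#'   `n_codons`, `enc`, and per amino acid `p_<aa>`, `c1_<aa>`, `c2_<aa>`.
#' @export
per_gene_indices <- function(genes, genetic_code = "11") {
  genes <- as_gene_tbl(genes, require_heg = FALSE)
  if (nrow(genes) == 0L) abort("empty gene list")
  info <- code_info(genetic_code)
  m <- codon_count_matrix(genes$seq)[, info$codons$codon, drop = FALSE]
  n_codons <- rowSums(m)
  zero <- n_codons == 0
  if (any(zero)) {
    warn(paste0("gene(s) with zero countable codons excluded: ",
                paste(genes$id[zero], collapse = ", ")))
    genes <- genes[!zero, , drop = FALSE]
    m <- m[!zero, , drop = FALSE]
    n_codons <- n_codons[!zero]
  }
  bg <- background_from_counts(m)
  out <- tibble(id = genes$id)
  if ("is_heg" %in% names(genes)) out$is_heg <- genes$is_heg
  out$n_codons <- as.integer(n_codons)
  out$enc <- enc_prime_matrix(m, bg, info)
  for (i in seq_len(nrow(S_CODON_PAIRS))) {
    aa <- S_CODON_PAIRS$amino_acid[i]
    n1 <- m[, S_CODON_PAIRS$c1[i]]
    n2 <- m[, S_CODON_PAIRS$c2[i]]
    out[[paste0("p_", aa)]] <- p_with_pseudocount(n1, n2)
    out[[paste0("c1_", aa)]] <- as.integer(n1)
    out[[paste0("c2_", aa)]] <- as.integer(n2)
  }
  out
}

#' Codon-usage-bias index set for a partitioned gene collection
#'
#' Computes ENC′ for the all-gene and HEG sets, their differential ΔENC′,
#' the optimal-codon frequencies P and the selection-strength index S, in
#' one of two modes. In `"concatenated"` mode (whole genomes) each set is
#' pooled into a single count vector with a common background. In
#' `"gene-averaged"` mode (metagenomes, partial data) ENC′ and P are
#' computed gene by gene — pooling sequences from organisms with different
#' preferred codons would inflate the apparent effective number of codons —
#' and the set-level values are the means of the per-gene values; genes with
#' an undefined per-gene index are dropped from the mean.
#'
#' The "all-gene" set is the non-HEG (background/control) rows; set
#' `include_heg_in_all = TRUE` to pool the HEG into it, as when the all-gene
#' set is the concatenation of every coding sequence of a genome.
#'
#' @param genes Tibble with `id`, `seq` and logical `is_heg` (see
#'   [select_heg()]), or a [per_gene_indices()] table in `"gene-averaged"`
#'   mode.
#' @param mode `"concatenated"` or `"gene-averaged"`.
#' @param genetic_code Genetic-code id.
#' @param include_heg_in_all Pool HEG rows into the all-gene set (default
#'   `FALSE`).
#' @return One-row tibble: `n_genes_all`, `n_genes_heg`, `enc_all`,
#'   `enc_heg`, `delta_enc`, `p_all_<aa>`, `p_heg_<aa>`, `s_<aa>`, `s`,
#'   `mode`.
#' @export
bias_indices <- function(genes, mode = c("concatenated", "gene-averaged"),
                         genetic_code = "11", include_heg_in_all = FALSE) {
  mode <- match.arg(mode)
  if (mode == "gene-averaged") {
    pg <- if (is.data.frame(genes) && "enc" %in% names(genes)) genes
          else per_gene_indices(genes, genetic_code)
    if (!"is_heg" %in% names(pg)) abort("gene table needs an `is_heg` column")
    return(gene_averaged_indices(pg, include_heg_in_all))
  }
  genes <- as_gene_tbl(genes)
  heg <- genes[genes$is_heg, , drop = FALSE]
  all_set <- if (include_heg_in_all) genes else genes[!genes$is_heg, , drop = FALSE]
  if (nrow(heg) == 0L) abort("HEG set is empty")
  if (nrow(all_set) == 0L) abort("all-gene set is empty")
  cc_all <- codon_counts(all_set, genetic_code = genetic_code)
  cc_heg <- codon_counts(heg, genetic_code = genetic_code)
  enc_all <- enc_prime(cc_all)
  enc_heg <- enc_prime(cc_heg)
  if (is.na(enc_all) || is.na(enc_heg)) {
    abort("ENC' undefined for one of the sets (too few synonymous families)")
  }
  p_all <- p_optimal(cc_all)
  p_heg <- p_optimal(cc_heg)
  w <- setNames(p_heg$n_c1 + p_heg$n_c2, p_heg$amino_acid)
  s <- s_index(p_heg, p_all, w)
  index_row(nrow(all_set), nrow(heg), enc_all, enc_heg, p_all, p_heg, s,
            "concatenated")
}

gene_averaged_indices <- function(pg, include_heg_in_all = FALSE) {
  heg <- pg[pg$is_heg, , drop = FALSE]
  all_set <- if (include_heg_in_all) pg else pg[!pg$is_heg, , drop = FALSE]
  if (nrow(heg) == 0L) abort("HEG set is empty")
  if (nrow(all_set) == 0L) abort("all-gene set is empty")
  enc_all <- mean(all_set$enc, na.rm = TRUE)
  enc_heg <- mean(heg$enc, na.rm = TRUE)
  if (is.nan(enc_all) || is.nan(enc_heg)) {
    abort("no gene with a defined ENC' in one of the sets")
  }
  aa <- S_CODON_PAIRS$amino_acid
  p_bar <- function(set) {
    vapply(aa, function(a) {
      p <- set[[paste0("p_", a)]]
      if (all(is.na(p))) NA_real_ else mean(p, na.rm = TRUE)
    }, 1)
  }
  pa <- p_bar(all_set); ph <- p_bar(heg)
  w <- vapply(aa, function(a) {
    sum(heg[[paste0("c1_", a)]] + heg[[paste0("c2_", a)]])
  }, 1)
  s <- s_index(ph, pa, w)
  p_tbl <- function(p) tibble(amino_acid = aa, p = unname(p))
  index_row(nrow(all_set), nrow(heg), enc_all, enc_heg,
            p_tbl(pa), p_tbl(ph), s, "gene-averaged")
}

index_row <- function(n_all, n_heg, enc_all, enc_heg, p_all, p_heg, s, mode) {
  out <- tibble(n_genes_all = n_all, n_genes_heg = n_heg,
                enc_all = enc_all, enc_heg = enc_heg,
                delta_enc = delta_enc_prime(enc_all, enc_heg))
  for (i in seq_len(nrow(S_CODON_PAIRS))) {
    aa <- S_CODON_PAIRS$amino_acid[i]
    out[[paste0("p_all_", aa)]] <- p_all$p[p_all$amino_acid == aa]
    out[[paste0("p_heg_", aa)]] <- p_heg$p[p_heg$amino_acid == aa]
    out[[paste0("s_", aa)]] <- s$components$s_i[s$components$amino_acid == aa]
  }
  out$s <- s$s
  out$mode <- mode
  out
}
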