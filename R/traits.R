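# Non-codon growth-associated genome traits: stable-RNA gene multiplicity
# and replication-origin-relative gene positions.

#' Relative distance of a gene to the replication origin
#'
#' Smallest circular distance between a position and the origin of
#' replication, divided by half the replicon length: 0 is at the origin,
#' 0.5 a quarter-replicon away, 1 diametrically opposite (typically the
#' terminus). Genes near the origin enjoy a replication-associated dosage
#' advantage in fast growers.
#'
#' @param gene_pos,ori_pos Coordinates in `[0, chrom_len)` (vectors
#'   recycled).
#' @param chrom_len Replicon length, nt; the replicon is treated as
#'   circular.
#' @return Relative distances in `[0, 1]`.
#' @examples
#' relative_ori_distance(c(0, 1e6, 2e6), 0, 4e6)
#' @export
relative_ori_distance <- function(gene_pos, ori_pos, chrom_len) {
  if (chrom_len <= 0) abort("`chrom_len` must be positive")
  if (any(gene_pos < 0 | gene_pos >= chrom_len) ||
      any(ori_pos < 0 | ori_pos >= chrom_len)) {
    abort("positions must lie in [0, chrom_len)")
  }
  d <- abs(gene_pos - ori_pos)
  d <- pmin(d, chrom_len - d)
  d / (chrom_len / 2)
}

#' The packaged ubi-tRNA anticodon list (synthetic reconstruction)
#'
#' Anticodons of the tRNA species that are nearly ubiquitous across
#' bacterial genomes and match the generally preferred codons. The shipped
#' list is a reconstruction built from wobble-pairing reasoning, labelled
#' synthetic; supply your own list (one anticodon per line, 5'→3' DNA
#' alphabet) to reproduce a specific published set.
#'
#' @return Character vector of anticodons.
#' @export
ubi_trna_anticodons <- function() {
  path <- system.file("extdata", "ubi_trna_anticodons_synthetic.tsv",
                      package = "codongrowth")
  tbl <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  toupper(tbl$anticodon)
}

#' Count stable-RNA genes and growth-associated trait positions
#'
#' From a feature annotation table, counts 16S-anchored rRNA operons
#' (16S genes within `operon_gap` of one another are merged into one
#' operon), total tRNA genes and their split into ubiquitous ("ubi",
#' anticodon on the ubi-tRNA list) and non-ubiquitous tRNAs. When an origin
#' of replication is supplied, mean origin-relative distances are computed
#' per gene category (rRNA genes, rRNA operons, tRNAs, ubi-tRNAs, ribosomal
#' proteins, RNA polymerase).
#'
#' @param annotation Tibble with columns `id`, `start`, `end`, `strand`,
#'   `product` and optionally `type` (`rRNA`/`tRNA`/`CDS`; inferred from
#'   `product` when absent) and `anticodon` (tRNA rows).
#' @param ubi_anticodons Character vector of ubiquitous anticodons (default:
#'   the packaged list, [ubi_trna_anticodons()]).
#' @param ori_position Origin coordinate on the replicon, or `NULL` (origin
#'   unknown: distance columns are `NA`). Origins are inputs, never
#'   predicted; for archaea, with multiple ill-defined origins, leave
#'   `NULL`.
#' @param chrom_len Replicon length, nt (required with `ori_position`).
#' @param operon_gap Maximum distance between 16S genes merged into one
#'   operon (default 3000 nt).
#' @return One-row tibble: `rrna_genes`, `rrna_operons`, `trna_total`,
#'   `trna_ubi`, `trna_nonubi`, and `dist_<category>` columns (`NA` without
#'   an origin).
#' @export
count_stable_rna <- function(annotation, ubi_anticodons = NULL,
                             ori_position = NULL, chrom_len = NULL,
                             operon_gap = 3000L) {
  annotation <- as_tibble(annotation)
  if (!"type" %in% names(annotation)) {
    annotation$type <- dplyr::case_when(
      grepl("rRNA|ribosomal RNA", annotation$product, ignore.case = TRUE) ~ "rRNA",
      grepl("tRNA", annotation$product, ignore.case = TRUE) ~ "tRNA",
      TRUE ~ "CDS"
    )
  }
  ubi_anticodons <- toupper(ubi_anticodons %||% ubi_trna_anticodons())
  rrna <- filter(annotation, .data$type == "rRNA")
  s16 <- filter(rrna, grepl("16S", .data$product))
  trna <- filter(annotation, .data$type == "tRNA")
  if (nrow(rrna) == 0 && nrow(trna) == 0) {
    warn("annotation has no rRNA or tRNA features; counts are zero")
  }
  is_ubi <- if (nrow(trna) > 0 && "anticodon" %in% names(trna)) {
    toupper(trna$anticodon) %in% ubi_anticodons
  } else rep(FALSE, nrow(trna))
  operon_starts <- merge_operons(s16$start, operon_gap)
  rp <- filter(annotation, .data$type == "CDS",
               grepl("ribosomal protein", .data$product, ignore.case = TRUE))
  rnap <- filter(annotation, .data$type == "CDS",
                 grepl("RNA polymerase", .data$product, ignore.case = TRUE))
  mid <- function(tbl) (tbl$start + tbl$end) / 2
  mean_dist <- function(pos) {
    if (is.null(ori_position) || length(pos) == 0) return(NA_real_)
    mean(relative_ori_distance(pos %% chrom_len, ori_position, chrom_len))
  }
  if (!is.null(ori_position) && is.null(chrom_len)) {
    abort("`chrom_len` is required with `ori_position`")
  }
  tibble(
    rrna_genes = nrow(s16),
    rrna_operons = length(operon_starts),
    trna_total = nrow(trna),
    trna_ubi = sum(is_ubi),
    trna_nonubi = sum(!is_ubi),
    dist_rrna_genes = mean_dist(mid(s16)),
    dist_rrna_operons = mean_dist(operon_starts),
    dist_trna = mean_dist(mid(trna)),
    dist_ubi_trna = mean_dist(mid(trna[is_ubi, , drop = FALSE])),
    dist_ribosomal_protein = mean_dist(mid(rp)),
    dist_rna_polymerase = mean_dist(mid(rnap))
  )
}

# cluster sorted 16S anchor positions: new operon when gap exceeded;
# returns one representative (first) position per operon
merge_operons <- function(starts, gap) {
  if (length(starts) == 0) return(numeric(0))
  s <- sort(starts)
  breaks <- c(TRUE, diff(s) > gap)
  s[breaks]
}
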