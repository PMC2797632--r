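#' Read a nucleotide or protein FASTA file into a tibble
#'
#' Thin tibble-returning wrapper around [Biostrings::readDNAStringSet()] /
#' [Biostrings::readAAStringSet()]. Sequences are upper-cased and record order
#' is preserved; duplicated identifiers are kept (with a warning) since
#' downstream computations are positional.
#'
#' @param path Path to a FASTA file.
#' @param type `"DNA"` (default) or `"AA"`.
#' @return A tibble with columns `id` (first whitespace-delimited token of the
#'   header), `desc` (full header) and `seq`.
#' @examples
#' fa <- tempfile(fileext = ".fna")
#' writeLines(c(">g1 demo", "atgaaataa", ">g2", "ATGCCCTAA"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path, type = c("DNA", "AA")) {
  type <- match.arg(type)
  if (!file.exists(path)) abort(paste0("FASTA file not found: ", path))
  set <- tryCatch(
    if (type == "DNA") Biostrings::readDNAStringSet(path)
    else Biostrings::readAAStringSet(path),
    error = function(e) abort(paste0("malformed FASTA in '", path, "': ",
                                     conditionMessage(e)))
  )
  if (length(set) == 0L) abort(paste0("empty FASTA file: ", path))
  desc <- names(set)
  id <- vapply(strsplit(desc, "\\s+"), `[[`, "", 1L)
  if (anyDuplicated(id)) {
    warn(paste0("duplicate sequence ids in '", path, "': ",
                paste(unique(id[duplicated(id)]), collapse = ", ")))
  }
  tibble(id = id, desc = desc,
         seq = unname(toupper(as.character(set))))
}

#' Write a gene tibble to FASTA
#'
#' @param genes Tibble with columns `id` and `seq`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genes, path) {
  stopifnot(all(c("id", "seq") %in% names(genes)))
  writeLines(paste0(">", genes$id, "\n", genes$seq), path)
  invisible(path)
}

#' Read a lightweight tab-separated annotation table
#'
#' Accepted as an alternative to GenBank feature parsing. Expected columns:
#' `id`, `start`, `end`, `strand`, `product`; optional `type` (e.g. `CDS`,
#' `rRNA`, `tRNA`) and `anticodon` for tRNA features.
#'
#' @param path Path to a TSV file with a header line.
#' @return A tibble.
#' @export
read_annotation <- function(path) {
  tbl <- as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
  required <- c("id", "start", "end", "strand", "product")
  missing <- setdiff(required, names(tbl))
  if (length(missing) > 0) {
    abort(paste0("annotation table lacks column(s): ",
                 paste(missing, collapse = ", ")))
  }
  tbl
}

#' Extract open reading frames from contigs
#'
#' Scans all six reading frames of each contig for maximal stop-bounded
#' regions, in the manner of EMBOSS `getorf`. By default each region is
#' trimmed to its first start codon (`ATG`/`GTG`/`TTG` for the bacterial
#' code); regions without a start codon are discarded. Every emitted ORF
#' therefore begins with a start codon and ends with a stop codon, and its
#' length (start and stop codons included) is at least `min_len`.
#'
#' @param contigs A tibble with columns `id` and `seq`, a path to a FASTA
#'   file, or a named character vector of sequences.
#' @param min_len Minimum ORF length in nucleotides (default 450, the value
#'   used throughout the metagenome workflow). Must be a positive multiple
#'   of 3.
#' @param genetic_code Genetic-code id (default `"11"`).
#' @param mode `"start-to-stop"` (default; trim to first start codon) or
#'   `"stop-to-stop"` (keep the whole stop-bounded region, no start
#'   requirement).
#' @param start_codons Start codons used in `"start-to-stop"` mode.
#' @return Tibble of gene records: `id`, `seq`, `source`, `frame_start`,
#'   `frame_end` (0-based half-open on the forward strand), `strand`,
#'   `length`. Contigs shorter than `min_len` simply contribute no rows.
#' @examples
#' ctg <- paste0("CCC", "ATG", strrep("GCT", 149), "TAA", "CCC")
#' extract_orfs(tibble::tibble(id = "c1", seq = ctg))
#' @export
extract_orfs <- function(contigs, min_len = 450L, genetic_code = "11",
                         mode = c("start-to-stop", "stop-to-stop"),
                         start_codons = c("ATG", "GTG", "TTG")) {
  mode <- match.arg(mode)
  if (min_len < 3L || min_len %% 3L != 0L) {
    abort("`min_len` must be a positive multiple of 3")
  }
  contigs <- as_gene_tbl(contigs, require_heg = FALSE)
  bad <- grepl("[^ACGTN]", contigs$seq)
  if (any(bad)) {
    abort(paste0("contig(s) with non-ACGTN symbols: ",
                 paste(contigs$id[bad], collapse = ", ")))
  }
  stops <- code_info(genetic_code)$stops
  out <- pmap(list(contigs$id, contigs$seq), function(cid, cseq) {
    orfs_one_contig(cid, cseq, min_len, stops, start_codons, mode)
  })
  res <- list_rbind(out)
  if (nrow(res) == 0L) {
    return(tibble(id = character(), seq = character(), source = character(),
                  frame_start = integer(), frame_end = integer(),
                  strand = character(), length = integer()))
  }
  res
}

# six-frame scan of a single contig
orfs_one_contig <- function(cid, cseq, min_len, stops, start_codons, mode) {
  L <- nchar(cseq)
  if (L < min_len) return(NULL)
  scan_strand <- function(seq, strand) {
    hits <- list()
    for (frame in 0:2) {
      n_codon <- (nchar(seq) - frame) %/% 3L
      if (n_codon < min_len %/% 3L) next
      starts_nt <- frame + 3L * (seq_len(n_codon) - 1L) + 1L
      codons <- substring(seq, starts_nt, starts_nt + 2L)
      is_stop <- codons %in% stops
      # stop-bounded maximal regions: an ORF must end with a stop codon
      stop_idx <- which(is_stop)
      if (length(stop_idx) == 0L) next
      region_begin <- c(1L, head(stop_idx, -1L) + 1L)
      for (k in seq_along(stop_idx)) {
        b <- region_begin[k]; e <- stop_idx[k]   # codon indices, stop included
        if (mode == "start-to-stop") {
          cand <- which(codons[b:(e - 1L)] %in% start_codons)
          if (e == b || length(cand) == 0L) next
          b <- b + cand[1L] - 1L
        }
        len_nt <- (e - b + 1L) * 3L
        if (len_nt < min_len) next
        from <- frame + 3L * (b - 1L)            # 0-based on this strand
        to <- from + len_nt
        hits[[length(hits) + 1L]] <- tibble(
          seq = substr(seq, from + 1L, to),
          from = from, to = to, strand = strand
        )
      }
    }
    list_rbind(hits)
  }
  fwd <- scan_strand(cseq, "+")
  rev <- scan_strand(revcomp_chr(cseq), "-")
  if (!is.null(rev) && nrow(rev) > 0L) {
    # mirror reverse-strand coordinates back onto the forward strand
    new_from <- L - rev$to
    rev$to <- L - rev$from
    rev$from <- new_from
  }
  res <- bind_rows(fwd, rev)
  if (is.null(res) || nrow(res) == 0L) return(NULL)
  res <- arrange(res, .data$from, .data$strand)
  tibble(
    id = paste0(cid, "_orf", seq_len(nrow(res))),
    seq = res$seq,
    source = cid,
    frame_start = as.integer(res$from),
    frame_end = as.integer(res$to),
    strand = res$strand,
    length = nchar(res$seq)
  )
}

#' Partition genes into highly expressed (HEG) and background sets
#'
#' The highly-expressed set — ribosomal protein genes in the intended use —
#' can be selected by an explicit identifier list, by a keyword match on an
#' annotation table, or by protein-level similarity against a reference set
#' of ribosomal proteins.
#'
#' @param genes Tibble with columns `id` and `seq`.
#' @param method `"id-list"`, `"annotation-keyword"` or `"similarity"`.
#' @param ids Character vector of HEG gene ids (`id-list` method). Every id
#'   must be present in `genes`.
#' @param annotation Annotation tibble with `id` and `product`
#'   (`annotation-keyword` method).
#' @param keyword Regular expression matched (case-insensitively) against
#'   `product`; default `"ribosomal protein"`.
#' @param reference Protein reference set (`similarity` method): tibble with
#'   `id`/`seq` (amino-acid sequences) or a protein FASTA path. See
#'   [ribosomal_reference()] for the packaged demonstration set.
#' @param min_score Minimum best local-alignment score (BLOSUM62, gap open
#'   10 / extend 0.5) for a gene to be flagged HEG in `similarity` mode;
#'   stands in for the customary BLAST e-value < 1e-5 cutoff. The default
#'   (100) sits well above chance-level scores of unrelated proteins of
#'   typical gene length while any genuine ribosomal-protein homologue
#'   scores several-fold higher.
#' @param genetic_code Genetic-code id used to translate genes in
#'   `similarity` mode.
#' @return The `genes` tibble with a logical `is_heg` column; the selection
#'   method is recorded in attribute `selection_method`. Errors if no gene is
#'   selected, since every downstream index needs a nonempty HEG set.
#' @export
select_heg <- function(genes,
                       method = c("id-list", "annotation-keyword", "similarity"),
                       ids = NULL, annotation = NULL,
                       keyword = "ribosomal protein",
                       reference = NULL, min_score = 100,
                       genetic_code = "11") {
  method <- match.arg(method)
  genes <- as_gene_tbl(genes, require_heg = FALSE)
  is_heg <- switch(method,
    "id-list" = {
      if (is.null(ids)) abort("`ids` is required for method = 'id-list'")
      missing <- setdiff(ids, genes$id)
      if (length(missing) > 0) {
        abort(paste0("HEG ids absent from `genes`: ",
                     paste(missing, collapse = ", ")))
      }
      genes$id %in% ids
    },
    "annotation-keyword" = {
      if (is.null(annotation)) {
        abort("`annotation` is required for method = 'annotation-keyword'")
      }
      hit <- annotation$id[grepl(keyword, annotation$product, ignore.case = TRUE)]
      genes$id %in% hit
    },
    "similarity" = {
      if (is.null(reference)) {
        abort("`reference` is required for method = 'similarity'")
      }
      if (is.character(reference) && length(reference) == 1L) {
        reference <- read_fasta(reference, type = "AA")
      }
      similarity_hits(genes, reference, min_score, genetic_code)
    }
  )
  if (!any(is_heg)) {
    abort("no highly expressed genes selected; downstream indices are undefined")
  }
  out <- mutate(genes, is_heg = is_heg)
  attr(out, "selection_method") <- method
  out
}

# best local protein alignment of each translated gene against the reference
similarity_hits <- function(genes, reference, min_score, genetic_code) {
  gcode <- Biostrings::getGeneticCode(as.character(genetic_code))
  dna <- Biostrings::DNAStringSet(genes$seq)
  prot <- Biostrings::translate(dna, genetic.code = gcode,
                                if.fuzzy.codon = "solve")
  prot <- sub("\\*$", "", as.character(prot))
  prot <- Biostrings::AAStringSet(gsub("\\*", "X", prot))
  best <- rep(-Inf, length(prot))
  for (r in reference$seq) {
    sc <- Biostrings::pairwiseAlignment(
      prot, Biostrings::AAString(r), type = "local",
      substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
      scoreOnly = TRUE
    )
    best <- pmax(best, sc)
  }
  best >= min_score
}

#' Packaged ribosomal-protein reference (synthetic demonstration set)
#'
#' A small protein FASTA shipped for examples and tests of similarity-based
#' HEG detection. The sequences are translations of synthetic highly
#' expressed genes (see [synth_genome()]), not real ribosomal proteins; for
#' real analyses supply a reference of ribosomal proteins from sequenced
#' genomes.
#'
#' @return Tibble of protein records (`id`, `desc`, `seq`).
#' @export
ribosomal_reference <- function() {
  read_fasta(system.file("extdata", "ribosomal_protein_reference_synthetic.faa",
                         package = "codongrowth"),
             type = "AA")
}

# coerce the accepted gene-table inputs to a tibble with id/seq (+ is_heg)
as_gene_tbl <- function(x, require_heg = TRUE) {
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    x <- read_fasta(x)
  } else if (is.character(x)) {
    ids <- names(x) %||% paste0("seq", seq_along(x))
    x <- tibble(id = ids, seq = unname(toupper(x)))
  } else if (inherits(x, "DNAStringSet")) {
    x <- tibble(id = names(x) %||% paste0("seq", seq_along(x)),
                seq = as.character(x))
  }
  if (!is.data.frame(x) || !all(c("id", "seq") %in% names(x))) {
    abort("expected a tibble with columns `id` and `seq` (or a FASTA path)")
  }
  x <- as_tibble(x)
  x$seq <- toupper(x$seq)
  if (require_heg && !"is_heg" %in% names(x)) {
    abort("gene table needs an `is_heg` column; see select_heg()")
  }
  x
}
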