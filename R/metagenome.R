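# Community-level growth-rate prediction: gene-averaged indices on
# contig-derived ORFs, bootstrap averages, environment comparisons, and the
# subsampling accuracy experiments.

#' Predict the community-average minimal generation time of a metagenome
#'
#' Computes gene-averaged ΔENC′ and S over the sample's background and
#' highly expressed gene sets, composes the F index, and predicts the
#' average minimal doubling time. Because genes enter unweighted, species
#' contribute in proportion to their sequence abundance (the
#' whole-metagenome reading of a community).
#'
#' @param sample Gene tibble with `id`, `seq`, `is_heg` (see [select_heg()]
#'   and [extract_orfs()]), or a precomputed [per_gene_indices()] table.
#' @param model A `growth_model` with a composite attached (or pass
#'   `composite`).
#' @param composite Optional `codon_composite` overriding the model's.
#' @param genetic_code Genetic-code id.
#' @return One-row tibble: the [bias_indices()] columns plus `f`, `d_hours`
#'   and `class`.
#' @export
predict_metagenome <- function(sample, model, composite = NULL,
                               genetic_code = "11") {
  composite <- composite %||% model$composite
  if (is.null(composite)) abort("no codon_composite available; see fit_composite()")
  idx <- bias_indices(sample, mode = "gene-averaged",
                      genetic_code = genetic_code)
  f <- compose_F(idx$delta_enc, idx$s, composite)
  d <- predict_d(f, model)
  mutate(idx, f = f, d_hours = d, class = classify_growth(d))
}

#' Bootstrap the community prediction
#'
#' Resamples the background genes and the highly expressed genes with
#' replacement — independently, each to its original cardinality — and
#' recomputes the community prediction for each replicate. The spread of
#' the replicates quantifies the sampling uncertainty contributed by both
#' gene sets. Deterministic under a fixed seed.
#'
#' @param sample Gene tibble (`id`, `seq`, `is_heg`) or a
#'   [per_gene_indices()] table.
#' @param model A `growth_model`.
#' @param B Number of bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @param composite Optional `codon_composite` overriding the model's.
#' @param genetic_code Genetic-code id.
#' @param name Sample label carried into reports.
#' @return A `growth_bootstrap` object: tibble `replicates` (columns
#'   `iteration`, `delta_enc`, `s`, `f`, `d_hours`), `point` (the
#'   un-resampled prediction row), `mean_d`, `sd_d`, `B`, `seed`, `name`.
#' @export
bootstrap_community <- function(sample, model, B = 1000L, seed = 1L,
                                composite = NULL, genetic_code = "11",
                                name = "sample") {
  if (B < 1) abort("`B` must be at least 1")
  composite <- composite %||% model$composite
  if (is.null(composite)) abort("no codon_composite available; see fit_composite()")
  pg <- if (is.data.frame(sample) && "enc" %in% names(sample)) sample
        else per_gene_indices(sample, genetic_code)
  if (!"is_heg" %in% names(pg)) abort("sample needs an `is_heg` column")
  bg_rows <- which(!pg$is_heg)
  heg_rows <- which(pg$is_heg)
  if (length(heg_rows) == 0L || length(bg_rows) == 0L) {
    abort("both background and HEG sets must be nonempty")
  }
  point <- predict_metagenome(pg, model, composite)
  reps <- withr::with_seed(seed, {
    map(seq_len(B), function(b) {
      take <- c(sample(bg_rows, length(bg_rows), replace = TRUE),
                sample(heg_rows, length(heg_rows), replace = TRUE))
      idx <- gene_averaged_indices(pg[take, , drop = FALSE])
      f <- compose_F(idx$delta_enc, idx$s, composite)
      tibble(iteration = b, delta_enc = idx$delta_enc, s = idx$s, f = f,
             d_hours = predict_d(f, model))
    }) |> list_rbind()
  })
  structure(
    list(replicates = reps, point = point,
         mean_d = mean(reps$d_hours), sd_d = sd(reps$d_hours),
         B = as.integer(B), seed = as.integer(seed), name = name),
    class = "growth_bootstrap"
  )
}

#' @export
print.growth_bootstrap <- function(x, ...) {
  cat("<growth_bootstrap> ", x$name, ": d = ", sprintf("%.2f", x$point$d_hours),
      " h (bootstrap mean ", sprintf("%.2f", x$mean_d),
      ", sd ", sprintf("%.2f", x$sd_d), "; B = ", x$B, ", seed ", x$seed,
      ")\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.growth_bootstrap <- function(x, ...) x$replicates

#' @exportS3Method generics::glance
glance.growth_bootstrap <- function(x, ...) {
  tibble(name = x$name, d_point = x$point$d_hours, d_mean = x$mean_d,
         d_sd = x$sd_d, B = x$B, seed = x$seed)
}

#' Compare two bootstrapped communities
#'
#' Pairs the replicates of two [bootstrap_community()] results by iteration
#' index, computes the per-iteration difference in predicted doubling time,
#' and reports as p-value the proportion of iterations whose difference
#' contradicts the sign of the observed mean difference (e.g. 10 of 1000
#' contradicting gives p = 0.01). When no iteration contradicts, the p-value
#' is reported as below `1/B`. For paired differences to be meaningful the
#' two bootstraps should share `B` (enforced).
#'
#' @param a,b `growth_bootstrap` objects with equal `B`.
#' @return One-row tibble: `name_a`, `name_b`, `mean_diff` (hours, a minus
#'   b), `p_value`, `p_label` (`"<1/B"` form when zero contradictions).
#' @export
compare_communities <- function(a, b) {
  stopifnot(inherits(a, "growth_bootstrap"), inherits(b, "growth_bootstrap"))
  if (a$B != b$B) abort("bootstrap replicate counts differ")
  diffs <- a$replicates$d_hours - b$replicates$d_hours
  md <- mean(diffs)
  contradict <- if (md >= 0) sum(diffs < 0) else sum(diffs > 0)
  p <- contradict / a$B
  tibble(
    name_a = a$name, name_b = b$name, mean_diff = md,
    p_value = p,
    p_label = if (contradict == 0) paste0("<", format(1 / a$B)) else format(p)
  )
}

#' Accuracy of the composite index under subsampling
#'
#' Recomputes the gene-averaged composite index F on random subsets of one
#' gene population while holding the other fixed: either subsets of the
#' background ("all genes") set against the full HEG set, or subsets of the
#' HEG set against the full background. The dispersion of F across
#' iterations, as a function of subset size, measures how much partial data
#' (short contigs, few genes) degrade the estimate.
#'
#' @param sample Gene tibble (`id`, `seq`, `is_heg`) or a
#'   [per_gene_indices()] table.
#' @param sizes Integer vector of subset sizes (each at most the size of the
#'   varied pool).
#' @param iterations Random subsets per size (default 100).
#' @param vary `"background"` or `"heg"`: which population is subsampled.
#' @param composite Optional `codon_composite`; when supplied an `f` column
#'   is added.
#' @param seed Integer seed.
#' @param genetic_code Genetic-code id.
#' @return Tibble with one row per (size, iteration): `size`, `iteration`,
#'   `delta_enc`, `s` and (given a composite) `f`.
#' @export
subsample_accuracy <- function(sample, sizes, iterations = 100L,
                               vary = c("background", "heg"),
                               composite = NULL, seed = 1L,
                               genetic_code = "11") {
  vary <- match.arg(vary)
  pg <- if (is.data.frame(sample) && "enc" %in% names(sample)) sample
        else per_gene_indices(sample, genetic_code)
  pool <- if (vary == "background") which(!pg$is_heg) else which(pg$is_heg)
  fixed <- setdiff(seq_len(nrow(pg)), pool)
  if (any(sizes > length(pool))) {
    abort(paste0("subset size exceeds the ", vary, " pool (",
                 length(pool), " genes)"))
  }
  if (any(sizes < 1)) abort("subset sizes must be positive")
  grid <- tidyr::expand_grid(size = as.integer(sizes),
                             iteration = seq_len(iterations))
  out <- withr::with_seed(seed, {
    pmap(grid, function(size, iteration) {
      take <- c(sample(pool, size), fixed)
      idx <- gene_averaged_indices(pg[take, , drop = FALSE])
      tibble(size = size, iteration = iteration,
             delta_enc = idx$delta_enc, s = idx$s)
    }) |> list_rbind()
  })
  if (!is.null(composite)) {
    out$f <- compose_F(out$delta_enc, out$s, composite)
  }
  out
}

#' Discrete classification accuracy from minimal gene sets
#'
#' For each genome with a known minimal generation time, repeatedly draws a
#' small random sample of highly expressed genes and of other genes
#' (default 5 + 5), predicts the doubling time from that mini-set, classifies
#' it, and compares with the class of the observed doubling time. Accuracy
#' is summarised as the proportions of exact classifications, of exact or
#' adjacent ("approximate") classifications, and of gross errors (slow
#' growers predicted fast/very fast or vice versa).
#'
#' @param genomes Named list of gene tibbles (`id`, `seq`, `is_heg`) or of
#'   [per_gene_indices()] tables, one per genome.
#' @param d_observed Numeric vector of observed minimal generation times
#'   (hours), parallel to `genomes`.
#' @param model A `growth_model`.
#' @param n_heg,n_bg Genes drawn from the HEG and background pools (default
#'   5 and 5). Genomes with fewer genes than requested are skipped with a
#'   warning.
#' @param experiments Random draws per genome (default 1000).
#' @param composite Optional `codon_composite` overriding the model's.
#' @param seed Integer seed.
#' @param genetic_code Genetic-code id.
#' @return List with `summary` (one-row tibble: `exact`, `approx`, `wrong`
#'   in percent, `n_genomes`, `experiments`) and `calls` (per-draw tibble
#'   with predicted and observed classes).
#' @export
minimal_gene_classification <- function(genomes, d_observed, model,
                                        n_heg = 5L, n_bg = 5L,
                                        experiments = 1000L,
                                        composite = NULL, seed = 1L,
                                        genetic_code = "11") {
  stopifnot(length(genomes) == length(d_observed))
  composite <- composite %||% model$composite
  if (is.null(composite)) abort("no codon_composite available; see fit_composite()")
  names(genomes) <- names(genomes) %||% paste0("genome", seq_along(genomes))
  pgs <- map(genomes, function(g) {
    if (is.data.frame(g) && "enc" %in% names(g)) g
    else per_gene_indices(g, genetic_code)
  })
  usable <- map_dbl(pgs, function(pg) {
    sum(pg$is_heg) >= n_heg && sum(!pg$is_heg) >= n_bg
  }) == 1
  if (!all(usable)) {
    warn(paste0("genome(s) skipped (too few genes): ",
                paste(names(genomes)[!usable], collapse = ", ")))
  }
  pgs <- pgs[usable]
  d_observed <- d_observed[usable]
  if (length(pgs) == 0L) abort("no genome with enough genes")
  obs_class <- classify_growth(d_observed)
  calls <- withr::with_seed(seed, {
    imap(pgs, function(pg, nm) {
      heg_rows <- which(pg$is_heg)
      bg_rows <- which(!pg$is_heg)
      gi <- match(nm, names(pgs))
      map(seq_len(experiments), function(e) {
        take <- c(sample(bg_rows, n_bg), sample(heg_rows, n_heg))
        idx <- gene_averaged_indices(pg[take, , drop = FALSE])
        f <- compose_F(idx$delta_enc, idx$s, composite)
        d <- predict_d(f, model)
        tibble(genome = nm, experiment = e, d_pred = d,
               class_pred = classify_growth(d), class_obs = obs_class[gi])
      }) |> list_rbind()
    }) |> list_rbind()
  })
  list(summary = classification_accuracy(calls$class_pred, calls$class_obs,
                                         n_genomes = length(pgs),
                                         experiments = experiments),
       calls = calls)
}

#' Exact, approximate and gross-error classification proportions
#'
#' Compares predicted and observed growth classes: `exact` is the
#' proportion of matching classes, `approx` the proportion matching the
#' observed class or an adjacent one, and `wrong` the proportion of slow
#' growers predicted fast or very fast, or vice versa.
#'
#' @param class_pred,class_obs Vectors of growth classes (values of
#'   [classify_growth()] or their labels).
#' @param n_genomes,experiments Optional bookkeeping carried into the
#'   output.
#' @return One-row tibble with `exact`, `approx`, `wrong` (percent).
#' @export
classification_accuracy <- function(class_pred, class_obs, n_genomes = NA,
                                    experiments = NA) {
  ip <- as.integer(factor(class_pred, levels = growth_class_levels))
  io <- as.integer(factor(class_obs, levels = growth_class_levels))
  exact <- ip == io
  approx <- abs(ip - io) <= 1L
  wrong <- (io == 4L & ip <= 2L) | (io <= 2L & ip == 4L)
  tibble(exact = 100 * mean(exact), approx = 100 * mean(approx),
         wrong = 100 * mean(wrong), n_genomes = n_genomes,
         experiments = experiments)
}
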