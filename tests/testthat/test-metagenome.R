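test_that("degenerate sample: identical background and HEG give d = exp(intercept)", {
  gene <- synth_genome(n_genes = 1, n_heg = 1, s_strength = 0, seed = 2)
  sample_tbl <- dplyr::bind_rows(
    dplyr::mutate(gene, id = "bg", is_heg = FALSE),
    dplyr::mutate(gene, id = "heg", is_heg = TRUE)
  )
  comp <- fixture_composite()
  m <- published_growth_model(composite = comp)
  out <- predict_metagenome(sample_tbl, m)
  expect_equal(out$delta_enc, 0)
  expect_equal(out$s, 0)
  # delta = 0 and s = 0 map through the composite, not necessarily to F = 0
  f0 <- compose_F(0, 0, comp)
  expect_equal(out$d_hours, exp(0.8741 - 0.6496 * f0))
})

test_that("communities of fast growers are predicted faster than slow ones", {
  comp <- fixture_composite()
  m <- published_growth_model(composite = comp)
  fast <- synth_community(s_strengths = c(2.5, 3), seed = 41,
                          n_genes = 60, n_heg = 12)
  slow <- synth_community(s_strengths = c(0, 0.2), seed = 43,
                          n_genes = 60, n_heg = 12)
  d_fast <- predict_metagenome(fast, m)$d_hours
  d_slow <- predict_metagenome(slow, m)$d_hours
  expect_lt(d_fast, d_slow)
})

test_that("whole-genome subsets predict close to the whole-genome value", {
  g <- fixture_genome(s_strength = 1.5, n_genes = 120, n_heg = 20)
  comp <- fixture_composite()
  m <- published_growth_model(composite = comp)
  full <- predict_metagenome(g, m)
  pg <- per_gene_indices(g)
  withr::with_seed(55, {
    sub <- dplyr::bind_rows(
      pg[sample(which(!pg$is_heg), 60), ],
      pg[pg$is_heg, ]
    )
  })
  part <- predict_metagenome(sub, m)
  expect_lt(abs(part$d_hours - full$d_hours) / full$d_hours, 0.25)
})

test_that("the bootstrap is deterministic under a fixed seed", {
  g <- fixture_genome()
  m <- published_growth_model(composite = fixture_composite())
  b1 <- bootstrap_community(g, m, B = 25, seed = 7)
  b2 <- bootstrap_community(g, m, B = 25, seed = 7)
  b3 <- bootstrap_community(g, m, B = 25, seed = 8)
  expect_identical(b1$replicates$d_hours, b2$replicates$d_hours)
  expect_false(identical(b1$replicates$d_hours, b3$replicates$d_hours))
  expect_error(bootstrap_community(g, m, B = 0), "at least 1")
  expect_true(b1$mean_d >= min(b1$replicates$d_hours) &&
                b1$mean_d <= max(b1$replicates$d_hours))
  expect_gte(b1$sd_d, 0)
})

test_that("bootstrap mean converges to the point prediction with B", {
  pg <- per_gene_indices(fixture_genome(n_genes = 80, n_heg = 16))
  m <- published_growth_model(composite = fixture_composite())
  point <- predict_metagenome(pg, m)$d_hours
  errs <- purrr::map_dbl(c(10, 100, 500), function(B) {
    abs(bootstrap_community(pg, m, B = B, seed = 13)$mean_d - point)
  })
  expect_lt(errs[3], 0.05 * point)           # tight at B = 500
  expect_lt(errs[3], errs[1] + 0.05 * point) # no divergence with B
})

test_that("bootstrap dispersion shrinks as one over the square root of n", {
  m <- published_growth_model(composite = fixture_composite())
  sds <- purrr::map_dbl(c(50, 200, 800), function(n) {
    g <- synth_genome(n_genes = n + n / 5, n_heg = n / 5, gene_len = 600,
                      s_strength = 1, seed = 1000 + n)
    bootstrap_community(per_gene_indices(g), m, B = 300, seed = n)$sd_d
  })
  expect_true(all(diff(sds) < 0))
  ratios <- sds[-3] / sds[-1]   # expected 2 under 1/sqrt(n) scaling
  expect_true(all(ratios > 1.4 & ratios < 2.8))
})

test_that("community comparison reports paired-sign p-values symmetrically", {
  comp <- fixture_composite()
  m <- published_growth_model(composite = comp)
  fast <- synth_community(s_strengths = c(2.5, 3), seed = 41,
                          n_genes = 60, n_heg = 12)
  slow <- synth_community(s_strengths = c(0, 0.2), seed = 43,
                          n_genes = 60, n_heg = 12)
  bf <- bootstrap_community(fast, m, B = 200, seed = 5, name = "fast")
  bs <- bootstrap_community(slow, m, B = 200, seed = 6, name = "slow")
  ab <- compare_communities(bf, bs)
  ba <- compare_communities(bs, bf)
  expect_equal(ab$p_value, ba$p_value)           # antisymmetric pairing
  expect_equal(ab$mean_diff, -ba$mean_diff)
  expect_lt(ab$mean_diff, 0)                     # fast community grows faster
  expect_equal(ab$p_value, 0)
  expect_equal(ab$p_label, "<0.005")             # reported as < 1/B
  # same sample bootstrapped twice: null comparison, p near one half
  b1 <- bootstrap_community(fast, m, B = 200, seed = 9)
  b2 <- bootstrap_community(fast, m, B = 200, seed = 10)
  expect_gt(compare_communities(b1, b2)$p_value, 0.25)
  expect_error(compare_communities(bf, bootstrap_community(slow, m, B = 10,
                                                           seed = 1)),
               "differ")
})

test_that("subsampling the background tightens F with sample size", {
  g <- fixture_genome(s_strength = 1.5, n_genes = 120, n_heg = 20)
  comp <- fixture_composite()
  pg <- per_gene_indices(g)
  tbl <- subsample_accuracy(pg, sizes = c(5, 25, 100), iterations = 60,
                            vary = "background", composite = comp, seed = 19)
  sds <- tbl |>
    dplyr::group_by(size) |>
    dplyr::summarise(sd = sd(f), .groups = "drop") |>
    dplyr::arrange(size)
  expect_true(all(diff(sds$sd) < 0))
  # full-pool subsample reproduces the full-data value every iteration
  full <- subsample_accuracy(pg, sizes = 100, iterations = 3,
                             vary = "background", composite = comp, seed = 20)
  f_full <- predict_metagenome(pg, published_growth_model(composite = comp))$f
  expect_equal(unique(round(full$f, 12)), round(f_full, 12))
  expect_error(subsample_accuracy(pg, sizes = 1000), "exceeds")
})

test_that("subsampled F is an unbiased estimate of full-data F at modest size", {
  g <- fixture_genome(s_strength = 1.5, n_genes = 120, n_heg = 20)
  comp <- fixture_composite()
  pg <- per_gene_indices(g)
  f_full <- predict_metagenome(pg, published_growth_model(composite = comp))$f
  tbl <- subsample_accuracy(pg, sizes = 50, iterations = 100,
                            vary = "background", composite = comp, seed = 23)
  expect_lt(abs(mean(tbl$f) - f_full), 2 * sd(tbl$f) / sqrt(100))
  # varying the HEG pool instead: dispersion still shrinks with size
  heg_tbl <- subsample_accuracy(pg, sizes = c(4, 16), iterations = 60,
                                vary = "heg", composite = comp, seed = 24)
  sds <- tapply(heg_tbl$f, heg_tbl$size, sd)
  expect_lt(sds[["16"]], sds[["4"]])
})

test_that("minimal-gene classification is perfect in the noise-free limit", {
  comp <- fixture_composite()
  strengths <- c(0.2, 1, 2, 3.5)
  genomes <- purrr::map(seq_along(strengths), function(i) {
    per_gene_indices(synth_genome(n_genes = 40, n_heg = 8, gene_len = 600,
                                  s_strength = strengths[i], seed = 500 + i))
  })
  # fit a model that reproduces these genomes' observed times exactly
  idx <- purrr::map(genomes, function(pg) {
    out <- bias_indices(pg, mode = "gene-averaged")
    tibble::tibble(f = compose_F(out$delta_enc, out$s, comp))
  }) |> purrr::list_rbind()
  d_obs <- c(0.5, 1.5, 3, 8)
  fit <- stats::lm(log(d_obs) ~ idx$f)
  m <- published_growth_model(composite = comp)
  m$intercept <- unname(coef(fit)[1]); m$slope_F <- unname(coef(fit)[2])
  # drawing the complete sets leaves no sampling noise
  res <- minimal_gene_classification(genomes, d_obs, m, n_heg = 8, n_bg = 32,
                                     experiments = 3, seed = 3)
  expect_equal(res$summary$exact, 100)
  expect_equal(res$summary$wrong, 0)
})

test_that("small random gene sets still rank growth classes usefully", {
  comp <- fixture_composite()
  strengths <- c(0.2, 1, 2, 3.5)
  genomes <- purrr::map(seq_along(strengths), function(i) {
    per_gene_indices(synth_genome(n_genes = 40, n_heg = 8, gene_len = 600,
                                  s_strength = strengths[i], seed = 500 + i))
  })
  idx <- purrr::map(genomes, function(pg) {
    out <- bias_indices(pg, mode = "gene-averaged")
    tibble::tibble(f = compose_F(out$delta_enc, out$s, comp))
  }) |> purrr::list_rbind()
  d_obs <- c(0.5, 1.5, 3, 8)
  fit <- stats::lm(log(d_obs) ~ idx$f)
  m <- published_growth_model(composite = comp)
  m$intercept <- unname(coef(fit)[1]); m$slope_F <- unname(coef(fit)[2])
  res <- minimal_gene_classification(genomes, d_obs, m, n_heg = 5, n_bg = 5,
                                     experiments = 60, seed = 29)
  null <- null_classification_expectations(rep(1, 4) * 60)
  expect_gt(res$summary$exact, null$expected_exact)   # beats the null
  expect_gt(res$summary$approx, res$summary$exact)
  expect_lt(res$summary$wrong, null$expected_wrong)
  # genomes with too few genes are skipped with a warning
  expect_error(
    suppressWarnings(
      minimal_gene_classification(genomes[1:2], d_obs[1:2], m,
                                  n_heg = 50, n_bg = 5, experiments = 2,
                                  seed = 1)
    ),
    "no genome"
  )
})
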