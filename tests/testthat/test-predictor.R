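test_that("Box-Cox transform handles its limits and round-trips", {
  expect_equal(box_cox(1, 0.37), 0)
  expect_equal(box_cox(3, 1), 2)
  expect_equal(box_cox(exp(1), 0), 1)
  for (lam in c(-0.5, 0, 0.26, 1)) {
    d <- c(0.2, 1, 2.4, 27, 240)
    expect_equal(inv_box_cox(box_cox(d, lam), lam), d, tolerance = 1e-9)
  }
  expect_error(box_cox(-1, 0), "positive")
})

test_that("composite fitting recovers the symmetric loadings and orientation", {
  withr::with_seed(31, {
    z <- rnorm(50)
    perfect <- tibble::tibble(delta_enc = 0.1 + 0.05 * z, s = 0.4 + 0.3 * z)
    comp <- fit_composite(perfect)
    expect_equal(unname(comp$loadings), c(1, 1) / sqrt(2), tolerance = 1e-9)
    anti <- tibble::tibble(delta_enc = perfect$delta_enc, s = -perfect$s)
    comp2 <- fit_composite(anti)
    expect_equal(unname(abs(comp2$loadings)), c(1, 1) / sqrt(2),
                 tolerance = 1e-9)
    expect_gt(comp2$loadings["delta_enc"], 0)  # orientation invariant
    # first-PC variance = largest eigenvalue of the 2x2 correlation matrix
    rnd <- tibble::tibble(delta_enc = rnorm(10), s = rnorm(10))
    comp3 <- fit_composite(rnd)
    r <- cor(rnd$delta_enc, rnd$s)
    expect_equal(2 * comp3$var_explained, 1 + abs(r), tolerance = 1e-9)
  })
  expect_error(fit_composite(tibble::tibble(delta_enc = 1:2, s = 2:1)),
               "3 rows")
  expect_error(fit_composite(tibble::tibble(delta_enc = rep(1, 5),
                                            s = rnorm(5))), "variance")
})

test_that("F centres at the training means and rejects bad loadings", {
  comp <- fixture_composite()
  expect_equal(compose_F(comp$center["delta_enc"], comp$center["s"], comp), 0)
  broken <- comp
  broken$loadings <- broken$loadings * 2
  expect_error(compose_F(0.1, 0.5, broken), "unit norm")
})

test_that("the published model reproduces the worked predictions", {
  m <- published_growth_model()
  expect_equal(predict_d(-0.20, m), exp(0.8741 + 0.6496 * 0.20),
               tolerance = 1e-12)
  expect_equal(predict_d(0, m), exp(0.8741), tolerance = 1e-12)
  trio <- predict_d(c(-0.23, -0.20, -0.25), m)
  expect_equal(round(trio), c(3, 3, 3))
  expect_error(predict_d(0, m, ogt = 37), "no temperature term")
})

test_that("predicted doubling time is strictly decreasing in F", {
  f <- seq(-3, 3, length.out = 25)
  d <- predict_d(f, published_growth_model())
  expect_true(all(diff(d) < 0))
})

test_that("refit recovers known coefficients exactly without noise", {
  tbl <- synth_training_table(n_species = 40, noise_sd = 0, seed = 8)
  # supplying F directly makes the coefficients identifiable
  m <- fit_predictor(dplyr::rename(tbl, f = f_true), lambda_mode = "log")
  expect_equal(m$intercept, 0.8741, tolerance = 1e-9)
  expect_equal(m$slope_F, -0.6496, tolerance = 1e-9)
  expect_equal(m$r_squared, 1, tolerance = 1e-9)
  # via the internal composite the fitted predictions still interpolate
  m2 <- fit_predictor(dplyr::select(tbl, -dplyr::all_of("f_true")),
                      lambda_mode = "log")
  pred <- predict(m2, dplyr::select(tbl, dplyr::all_of(c("delta_enc", "s"))))
  expect_equal(pred$d_hours, tbl$d, tolerance = 1e-6)
})

test_that("refit recovers the slope within 3 standard errors under noise", {
  tbl <- synth_training_table(n_species = 200, noise_sd = 0.3, seed = 12)
  m <- fit_predictor(dplyr::rename(tbl, f = f_true), lambda_mode = "log")
  # analytic standard error of the OLS slope
  se <- 0.3 / (sd(tbl$f_true) * sqrt(200))
  expect_lt(abs(m$slope_F - (-0.6496)), 3 * se)
  expect_lt(abs(m$intercept - 0.8741), 3 * 0.3 / sqrt(200))
})

test_that("profile-likelihood lambda lands near the generating transform", {
  tbl <- synth_training_table(n_species = 300, noise_sd = 0.2, seed = 17)
  m <- fit_predictor(dplyr::rename(tbl, f = f_true), lambda_mode = "mle")
  expect_lt(abs(m$lambda), 0.15)  # generated with the log transform
})

test_that("row-count boundary: 5 rows fit, 4 rows error", {
  tbl <- synth_training_table(n_species = 40, noise_sd = 0, seed = 9)[1:5, ]
  expect_s3_class(fit_predictor(tbl, lambda_mode = "log"), "growth_model")
  expect_error(fit_predictor(tbl[1:4, ], lambda_mode = "log"), "5 training")
})

test_that("temperature models require OGT and mesophilic models refuse it", {
  tbl <- synth_training_table(n_species = 60, noise_sd = 0.1, seed = 14)
  tbl$d <- tbl$d * exp(0.01 * (tbl$ogt - 37))  # inject a temperature effect
  m_ogt <- fit_predictor(tbl, include_ogt = TRUE, lambda_mode = "log")
  expect_error(predict_d(0, m_ogt), "supply `ogt`")
  expect_s3_class(predict(m_ogt, tbl[1:3, ]), "tbl_df")
  m_plain <- fit_predictor(tbl, lambda_mode = "log")
  expect_error(predict_d(0, m_plain, ogt = 37), "no temperature")
})

test_that("growth classes apply the documented boundaries", {
  d <- c(0.5, 0.999, 1, 1.999, 2, 4.999, 5, 100)
  expect_equal(as.character(classify_growth(d)),
               c("very_fast", "very_fast", "fast", "fast",
                 "intermediate", "intermediate", "slow", "slow"))
  expect_error(classify_growth(-1), "positive")
})

test_that("classification and back-transform are mutually consistent", {
  for (lam in c(0, 0.26)) {
    m <- published_growth_model()
    m$lambda <- lam
    f <- seq(-2, 2, length.out = 21)
    d <- predict_d(f, m)
    phi <- m$intercept + m$slope_F * f
    expect_equal(classify_growth(d),
                 classify_growth(inv_box_cox(phi, lam)))
  }
})

test_that("null classification expectations match explicit enumeration", {
  for (sizes in list(c(46, 26, 41, 74), c(10, 10, 10, 10), c(1, 1, 1, 97))) {
    got <- null_classification_expectations(sizes)
    want <- oracle_null_expectations(sizes)
    expect_equal(got$expected_exact, unname(want["exact"]))
    expect_equal(got$expected_approx, unname(want["approx"]))
    expect_equal(got$expected_wrong, unname(want["wrong"]))
  }
  # end-loaded and balanced closed forms
  expect_equal(null_classification_expectations(c(100, 1e-9, 1e-9, 1e-9)
               )$expected_approx, 50, tolerance = 1e-6)
  expect_equal(null_classification_expectations(rep(25, 4))$expected_approx,
               62.5)
})

test_that("empirical uniform-random classification matches the analytic null", {
  sizes <- c(46, 26, 41, 74)
  obs <- rep(c("very_fast", "fast", "intermediate", "slow"), times = sizes)
  withr::with_seed(77, {
    reps <- 300
    pred <- sample(c("very_fast", "fast", "intermediate", "slow"),
                   length(obs) * reps, replace = TRUE)
    acc <- classification_accuracy(pred, rep(obs, reps))
  })
  null <- null_classification_expectations(sizes)
  n <- sum(sizes) * 300
  se_pct <- function(p) 100 * sqrt(p / 100 * (1 - p / 100) / n)
  expect_lt(abs(acc$exact - null$expected_exact),
            4 * se_pct(null$expected_exact))
  expect_lt(abs(acc$approx - null$expected_approx),
            4 * se_pct(null$expected_approx))
  expect_lt(abs(acc$wrong - null$expected_wrong),
            4 * se_pct(null$expected_wrong))
})

test_that("pairwise relative differences normalise to [0, 1]", {
  v <- c(a = 0.4, b = 2.4, c = 24)
  m <- pairwise_relative_differences(v, lambda = 0)
  expect_equal(diag(m), c(a = 0, b = 0, c = 0))
  expect_equal(max(m), 1)
  expect_equal(m["a", "c"], 1)  # log-scale extreme pair
  expect_equal(m["a", "b"], log(2.4 / 0.4) / log(24 / 0.4))
  expect_warning(m0 <- pairwise_relative_differences(c(1, 1, 1)), "identical")
  expect_true(all(m0 == 0))
  expect_error(pairwise_relative_differences(1), "at least 2")
})

test_that("a growth model survives the JSON round trip", {
  tbl <- synth_training_table(n_species = 60, noise_sd = 0.2, seed = 23)
  m <- fit_predictor(tbl, lambda_mode = "log")
  path <- withr::local_tempfile(fileext = ".json")
  write_growth_model(m, path)
  m2 <- read_growth_model(path)
  expect_equal(m2$intercept, m$intercept)
  expect_equal(m2$slope_F, m$slope_F)
  expect_equal(m2$lambda, m$lambda)
  expect_equal(m2$composite$loadings, m$composite$loadings)
  newdata <- tibble::tibble(delta_enc = c(0.1, 0.2), s = c(0.3, 0.9))
  expect_equal(predict(m2, newdata)$d_hours, predict(m, newdata)$d_hours)
})

test_that("tidy and glance summarise fitted objects", {
  tbl <- synth_training_table(n_species = 60, noise_sd = 0.2, seed = 24)
  m <- fit_predictor(tbl, lambda_mode = "log")
  td <- generics::tidy(m)
  expect_equal(td$term, c("(Intercept)", "F"))
  gl <- generics::glance(m)
  expect_equal(gl$nobs, 60)
  expect_equal(generics::tidy(m$composite)$term, c("delta_enc", "s"))
})
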