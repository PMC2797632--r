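# Composite codon-bias index F and the Box-Cox linear predictor of minimal
# generation time.

#' Box-Cox power transform and its inverse
#'
#' `box_cox(d, lambda)` returns `(d^lambda - 1)/lambda` for `lambda != 0`
#' and `log(d)` for `lambda = 0`; `inv_box_cox` reverses it. Used to
#' linearise the relation between minimal generation time `d` (hours) and
#' the codon-bias indices; on this data set the fitted transform is close to
#' the log limit.
#'
#' @param d Positive doubling times, hours.
#' @param phi Transformed values.
#' @param lambda Box-Cox exponent.
#' @return Transformed (resp. back-transformed) numeric vector.
#' @export
box_cox <- function(d, lambda = 0) {
  if (any(d <= 0)) abort("`d` must be positive")
  if (lambda == 0) log(d) else (d^lambda - 1) / lambda
}

#' @rdname box_cox
#' @export
inv_box_cox <- function(phi, lambda = 0) {
  if (lambda == 0) return(exp(phi))
  base <- lambda * phi + 1
  if (any(base <= 0)) abort("back-transform undefined: lambda*phi + 1 <= 0")
  base^(1 / lambda)
}

#' Fit the composite codon-bias index F
#'
#' Standardises ΔENC′ and S (z-scores, i.e. PCA on the correlation matrix —
#' the two indices live on different scales) and extracts their first
#' principal component. The component is oriented so that larger F means
#' stronger translational selection (positive loading on ΔENC′), hence
#' shorter predicted generation times.
#'
#' @param index_table Tibble with columns `delta_enc` and `s`, one row per
#'   genome (at least 3 rows, both columns with nonzero variance).
#' @return A `codon_composite` object: `center`, `scale`, `loadings` (unit
#'   vector), `var_explained`.
#' @export
fit_composite <- function(index_table) {
  stopifnot(all(c("delta_enc", "s") %in% names(index_table)))
  x <- cbind(delta_enc = index_table$delta_enc, s = index_table$s)
  if (nrow(x) < 3) abort("need at least 3 rows to fit the composite index")
  if (any(apply(x, 2, sd) == 0)) abort("zero variance in an index column")
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  load <- pc$rotation[, 1]
  if (load["delta_enc"] < 0) load <- -load
  structure(
    list(center = pc$center, scale = pc$scale, loadings = load,
         var_explained = pc$sdev[1]^2 / sum(pc$sdev^2), n = nrow(x)),
    class = "codon_composite"
  )
}

#' @export
print.codon_composite <- function(x, ...) {
  cat("<codon_composite> first PC of z-scored (dENC', S), n =", x$n, "\n")
  cat(sprintf("loadings: dENC' %.3f, S %.3f; variance explained %.1f%%\n",
              x$loadings["delta_enc"], x$loadings["s"],
              100 * x$var_explained))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.codon_composite <- function(x, ...) {
  tibble(term = c("delta_enc", "s"),
         center = unname(x$center), scale = unname(x$scale),
         loading = unname(x$loadings))
}

#' Compose the F index from ΔENC′ and S
#'
#' `F = loadings . z`, where `z` are the indices standardised with the
#' composite's training center/scale. Index pairs equal to the training
#' means map to `F = 0`.
#'
#' @param delta_enc,s Numeric vectors of indices (recycled together).
#' @param composite A `codon_composite` (from [fit_composite()]) or a
#'   `growth_model` carrying one.
#' @return Numeric vector of F values.
#' @export
compose_F <- function(delta_enc, s, composite) {
  if (inherits(composite, "growth_model")) composite <- composite$composite
  if (!inherits(composite, "codon_composite")) {
    abort("`composite` must be a codon_composite (see fit_composite())")
  }
  if (abs(sum(composite$loadings^2) - 1) > 1e-8) {
    abort("composite loadings must have unit norm")
  }
  z1 <- (delta_enc - composite$center["delta_enc"]) / composite$scale["delta_enc"]
  z2 <- (s - composite$center["s"]) / composite$scale["s"]
  unname(composite$loadings["delta_enc"] * z1 + composite$loadings["s"] * z2)
}

#' Growth-rate predictor models
#'
#' `published_growth_model()` returns the fixed-coefficient model
#' `Phi(d) = 0.8741 - 0.6496 F` with the log-limit Box-Cox transform
#' (`lambda = 0`), i.e. `d = exp(0.8741 - 0.6496 F)` hours — the mesophilic
#' predictor fitted on 214 prokaryotes. Since the loadings and
#' standardisation of the original composite are not part of the published
#' coefficients, predictions with this model take F directly, or a
#' `codon_composite` fitted on a user-supplied training table can be
#' attached to map raw (ΔENC′, S) pairs to F.
#'
#' `fit_predictor()` refits the model on a training table by ordinary least
#' squares of the Box-Cox-transformed doubling time on F (and optionally on
#' optimal growth temperature, OGT).
#'
#' @param composite Optional `codon_composite` to attach.
#' @return A `growth_model` object with fields `lambda`, `intercept`,
#'   `slope_F`, `slope_OGT` (`NULL` without temperature term), `composite`,
#'   `provenance` (`"published"` or `"refit"`), `training_n`, `r_squared`.
#' @export
published_growth_model <- function(composite = NULL) {
  new_growth_model(lambda = 0, intercept = 0.8741, slope_F = -0.6496,
                   slope_OGT = NULL, composite = composite,
                   provenance = "published", training_n = 214L,
                   r_squared = 0.47)
}

new_growth_model <- function(lambda, intercept, slope_F, slope_OGT,
                             composite, provenance, training_n, r_squared,
                             training = NULL) {
  structure(
    list(lambda = lambda, intercept = intercept, slope_F = slope_F,
         slope_OGT = slope_OGT, composite = composite,
         provenance = provenance, training_n = training_n,
         r_squared = r_squared, training = training),
    class = "growth_model"
  )
}

#' @param training Tibble with columns `delta_enc`, `s`, `d` (hours, > 0)
#'   and, when `include_ogt = TRUE`, `ogt` (degrees C). At least 5 rows. An
#'   `f` column, when present, is used directly as the composite index
#'   (bypassing the internal [fit_composite()] standardisation).
#' @param include_ogt Add a linear optimal-growth-temperature term.
#' @param lambda_mode `"mle"` (profile-likelihood choice of the Box-Cox
#'   exponent) or `"log"` (fix `lambda = 0`).
#' @rdname published_growth_model
#' @export
fit_predictor <- function(training, include_ogt = FALSE,
                          lambda_mode = c("mle", "log")) {
  lambda_mode <- match.arg(lambda_mode)
  has_f <- "f" %in% names(training)
  needed <- c(if (!has_f) c("delta_enc", "s"), "d", if (include_ogt) "ogt")
  stopifnot(all(needed %in% names(training)))
  if (nrow(training) < 5) abort("need at least 5 training rows")
  if (any(training$d <= 0)) abort("doubling times must be positive")
  if (has_f) {
    # F supplied directly (e.g. from an external composite); attach a
    # composite only if the raw indices are also present
    comp <- if (all(c("delta_enc", "s") %in% names(training))) {
      fit_composite(training)
    } else NULL
    f <- training$f
  } else {
    comp <- fit_composite(training)
    f <- compose_F(training$delta_enc, training$s, comp)
  }
  X <- tibble(f = f, d = training$d)
  if (include_ogt) X$ogt <- training$ogt
  lambda <- if (lambda_mode == "log") 0 else {
    fm <- if (include_ogt) d ~ f + ogt else d ~ f
    bc <- MASS::boxcox(fm, data = X, lambda = seq(-2, 2, 0.01),
                       plotit = FALSE)
    lam <- bc$x[which.max(bc$y)]
    if (abs(lam) < 0.02) 0 else lam   # snap to the log limit
  }
  X$phi <- box_cox(X$d, lambda)
  fit <- if (include_ogt) lm(phi ~ f + ogt, data = X) else lm(phi ~ f, data = X)
  if (any(is.na(coef(fit)))) abort("singular design in predictor fit")
  cf <- coef(fit)
  new_growth_model(
    lambda = lambda, intercept = unname(cf["(Intercept)"]),
    slope_F = unname(cf["f"]),
    slope_OGT = if (include_ogt) unname(cf["ogt"]) else NULL,
    composite = comp, provenance = "refit", training_n = nrow(training),
    r_squared = 1 - sum(fit$residuals^2) / sum((X$phi - mean(X$phi))^2),
    training = X
  )
}

#' @export
print.growth_model <- function(x, ...) {
  cat("<growth_model> (", x$provenance, ", n = ", x$training_n, ")\n", sep = "")
  cat(sprintf("Phi_%s(d) = %.4f %+.4f F", format(x$lambda), x$intercept,
              x$slope_F))
  if (!is.null(x$slope_OGT)) cat(sprintf(" %+.4f OGT", x$slope_OGT))
  cat(sprintf("   [R^2 = %.2f]\n", x$r_squared))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.growth_model <- function(x, ...) {
  terms <- c("(Intercept)", "F", if (!is.null(x$slope_OGT)) "OGT")
  tibble(term = terms,
         estimate = c(x$intercept, x$slope_F,
                      if (!is.null(x$slope_OGT)) x$slope_OGT))
}

#' @exportS3Method generics::glance
glance.growth_model <- function(x, ...) {
  tibble(r.squared = x$r_squared, lambda = x$lambda, nobs = x$training_n,
         provenance = x$provenance)
}

#' Predict minimal generation time from the composite index
#'
#' Evaluates `Phi = intercept + slope_F * F (+ slope_OGT * OGT)` and
#' back-transforms with the model's Box-Cox exponent. The published
#' (mesophilic) model carries no temperature term and refuses `ogt` input;
#' its domain is mesophiles (OGT between 15 and 60 degrees C) — predictions
#' for psychrophiles and thermophiles are systematically biased.
#'
#' @param f Numeric vector of F values.
#' @param model A `growth_model`.
#' @param ogt Optimal growth temperature (degrees C); required when and only
#'   when the model has a temperature term.
#' @return Predicted minimal doubling times, hours.
#' @examples
#' predict_d(c(-0.23, -0.20, -0.25), published_growth_model())
#' @export
predict_d <- function(f, model, ogt = NULL) {
  stopifnot(inherits(model, "growth_model"))
  if (!is.null(model$slope_OGT) && is.null(ogt)) {
    abort("this model includes a temperature term: supply `ogt`")
  }
  if (is.null(model$slope_OGT) && !is.null(ogt)) {
    abort(paste0("the ", model$provenance, " model has no temperature term; ",
                 "refit with include_ogt = TRUE or drop `ogt`"))
  }
  phi <- model$intercept + model$slope_F * f
  if (!is.null(model$slope_OGT)) phi <- phi + model$slope_OGT * ogt
  inv_box_cox(phi, model$lambda)
}

#' Predict from raw index pairs
#'
#' Convenience data-frame-first wrapper: composes F from `delta_enc`/`s`
#' via the model's composite (or takes an `f` column directly) and predicts
#' doubling time and growth class.
#'
#' @param object A `growth_model`.
#' @param newdata Tibble with either an `f` column or `delta_enc` + `s`
#'   (and `ogt` for temperature models).
#' @param ... Unused.
#' @return `newdata` with added columns `f`, `phi`, `d_hours`, `class`.
#' @export
predict.growth_model <- function(object, newdata, ...) {
  newdata <- as_tibble(newdata)
  f <- if ("f" %in% names(newdata)) newdata$f else {
    if (is.null(object$composite)) {
      abort("model has no composite attached: supply an `f` column")
    }
    compose_F(newdata$delta_enc, newdata$s, object$composite)
  }
  ogt <- if (!is.null(object$slope_OGT)) newdata$ogt else NULL
  d <- predict_d(f, object, ogt = ogt)
  mutate(newdata, f = f,
         phi = object$intercept + object$slope_F * f +
           (if (is.null(object$slope_OGT)) 0 else object$slope_OGT * ogt),
         d_hours = d, class = classify_growth(d))
}

#' Discrete growth classes
#'
#' Minimal generation times are discretised into four classes: very fast
#' (`d < 1` h), fast (`1 <= d < 2` h), intermediate (`2 <= d < 5` h) and
#' slow (`d >= 5` h).
#'
#' @param d Positive doubling times, hours.
#' @return Ordered factor with levels `very_fast < fast < intermediate <
#'   slow`.
#' @export
classify_growth <- function(d) {
  if (any(d <= 0)) abort("`d` must be positive")
  cut(d, breaks = c(0, 1, 2, 5, Inf), right = FALSE,
      labels = c("very_fast", "fast", "intermediate", "slow"),
      ordered_result = TRUE)
}

growth_class_levels <- c("very_fast", "fast", "intermediate", "slow")

#' Expected classification accuracy under a uniformly random predictor
#'
#' For observed class sizes `n_c`, a predictor that assigns one of the four
#' classes uniformly at random achieves: exact = 25%; exact-or-adjacent =
#' `sum(n_c * a_c) / (4 * sum(n_c))` with `a_c` the number of acceptable
#' classes (the class itself plus its neighbours: 2 at the ends, 3 in the
#' middle); gross misclassification = probability that an observed slow
#' grower is predicted fast or very fast, or vice versa.
#'
#' @param class_sizes Numeric vector of 4 positive class sizes, ordered
#'   `very_fast, fast, intermediate, slow`.
#' @return One-row tibble with `expected_exact`, `expected_approx`,
#'   `expected_wrong`, in percent, and `n_total`.
#' @examples
#' null_classification_expectations(c(46, 26, 41, 74))
#' @export
null_classification_expectations <- function(class_sizes) {
  stopifnot(length(class_sizes) == 4, all(class_sizes > 0))
  n <- sum(class_sizes)
  acceptable <- c(2, 3, 3, 2)
  # wrong: observed slow predicted {very_fast, fast} (2 of 4 classes), and
  # observed {very_fast, fast} predicted slow (1 of 4)
  wrong_classes <- c(1, 1, 0, 2)
  tibble(
    expected_exact = 100 * sum(class_sizes) / (4 * n),
    expected_approx = 100 * sum(class_sizes * acceptable) / (4 * n),
    expected_wrong = 100 * sum(class_sizes * wrong_classes) / (4 * n),
    n_total = n
  )
}

#' Normalised pairwise differences of a per-species quantity
#'
#' `Delta_ij = |t(v_i) - t(v_j)|` over all unordered pairs, normalised by
#' the maximum observed difference, so the most dissimilar pair maps to
#' exactly 1 and the diagonal to 0. `t` is the identity or a Box-Cox
#' transform (used for doubling times).
#'
#' @param values Numeric vector (length >= 2), optionally named.
#' @param lambda If non-`NULL`, Box-Cox-transform the values with this
#'   exponent first.
#' @return A symmetric matrix of relative differences in `[0, 1]`. All-equal
#'   input yields an all-zero matrix with a warning (degenerate
#'   normalisation).
#' @export
pairwise_relative_differences <- function(values, lambda = NULL) {
  if (length(values) < 2) abort("need at least 2 values")
  t_v <- if (is.null(lambda)) values else box_cox(values, lambda)
  m <- abs(outer(t_v, t_v, "-"))
  mx <- max(m)
  if (mx == 0) {
    warn("all values identical: degenerate normalisation, returning zeros")
    return(m)
  }
  m / mx
}

#' Serialise / restore a growth model as JSON
#'
#' @param model A `growth_model`.
#' @param path Output (input) path.
#' @return `read_growth_model` returns a `growth_model`;
#'   `write_growth_model` returns `path` invisibly.
#' @export
write_growth_model <- function(model, path) {
  stopifnot(inherits(model, "growth_model"))
  doc <- list(
    lambda = model$lambda, intercept = model$intercept,
    slope_F = model$slope_F, slope_OGT = model$slope_OGT,
    provenance = model$provenance, training_n = model$training_n,
    r_squared = model$r_squared,
    composite = if (!is.null(model$composite)) list(
      center = as.list(model$composite$center),
      scale = as.list(model$composite$scale),
      loadings = as.list(model$composite$loadings),
      var_explained = model$composite$var_explained,
      n = model$composite$n
    )
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_growth_model
#' @export
read_growth_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  comp <- NULL
  if (!is.null(doc$composite)) {
    comp <- structure(
      list(center = unlist(doc$composite$center),
           scale = unlist(doc$composite$scale),
           loadings = unlist(doc$composite$loadings),
           var_explained = doc$composite$var_explained,
           n = doc$composite$n),
      class = "codon_composite"
    )
  }
  new_growth_model(
    lambda = doc$lambda, intercept = doc$intercept, slope_F = doc$slope_F,
    slope_OGT = doc$slope_OGT, composite = comp,
    provenance = doc$provenance, training_n = doc$training_n,
    r_squared = doc$r_squared
  )
}
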