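#' Fit a univariate linear structure-property model
#'
#' Ordinary least squares for P = A + b * TI on pairwise-complete
#' observations: records where either value is missing are dropped for this
#' model only (pairwise deletion). The fit is delegated to [stats::lm()];
#' r is the Pearson correlation of the retained pairs, the standard error of
#' estimate is sqrt(SSE / (n - 2)), and the F statistic is the
#' single-predictor test on (1, n - 2) degrees of freedom with upper-tail
#' p value.
#'
#' @param x numeric vector of index values (the descriptor TI).
#' @param y numeric vector of property values, paired with `x` by molecule.
#' @param index,property optional labels carried into the result.
#' @return a [TopoRegression-class] object.
#' @examples
#' fitPropertyModel(c(1, 2, 3), c(5, 7, 9))  # exact line: A = 3, b = 2
#' @export
fitPropertyModel <- function(x, y, index = "TI", property = "P") {
  stopifnot(length(x) == length(y))
  keep <- stats::complete.cases(x, y)
  x <- as.numeric(x[keep]); y <- as.numeric(y[keep])
  n <- length(x)
  if (n < 3L)
    stop(sprintf("insufficient data for %s ~ %s: %d complete pairs (need 3)",
      property, index, n))
  if (stats::var(x) == 0)
    stop("degenerate predictor: ", index, " has zero variance")
  if (stats::var(y) == 0)
    stop("degenerate response: ", property,
         " has zero variance (r undefined)")
  fit <- stats::lm(y ~ x)
  A <- unname(stats::coef(fit)[1L]); b <- unname(stats::coef(fit)[2L])
  r <- stats::cor(x, y)
  r2 <- r^2
  sse <- sum(stats::residuals(fit)^2)
  se <- sqrt(sse / (n - 2L))
  if (se > 0) {
    fstat <- r2 * (n - 2L) / (1 - r2)
    pval <- stats::pf(fstat, 1, n - 2L, lower.tail = FALSE)
  } else {                      # exact linear relationship
    fstat <- Inf
    pval <- 0
  }
  new("TopoRegression", intercept = A, slope = b, n = n, r = r, r2 = r2,
    se = se, fstat = fstat, pvalue = pval, index = as.character(index),
    property = as.character(property))
}

#' Predict property values from a fitted model
#'
#' Returns A + b * x. With `coefDigits` set, the coefficients are first
#' rounded half-up to that many decimals; the published prediction tables
#' were computed from 3-decimal coefficients, so `coefDigits = 3` reproduces
#' them exactly while the default uses full precision.
#'
#' @param fit a [TopoRegression-class].
#' @param x numeric index value(s).
#' @param coefDigits NULL (full precision) or integer decimals for the
#'   coefficients.
#' @return numeric vector of predicted property values.
#' @export
predictProperty <- function(fit, x, coefDigits = NULL) {
  stopifnot(is(fit, "TopoRegression"))
  A <- fit@intercept; b <- fit@slope
  if (!is.null(coefDigits)) {
    A <- roundHalfUp(A, coefDigits)
    b <- roundHalfUp(b, coefDigits)
  }
  A + b * as.numeric(x)
}

#' Regression-fit accessors
#'
#' @param fit a [TopoRegression-class].
#' @return `fitCoefficients`: named numeric c(intercept, slope);
#'   `fitStatistics`: named numeric with n, r, r2, se, fstat, pvalue.
#' @export
fitCoefficients <- function(fit) {
  c(intercept = fit@intercept, slope = fit@slope)
}

#' @rdname fitCoefficients
#' @export
fitStatistics <- function(fit) {
  c(n = fit@n, r = fit@r, r2 = fit@r2, se = fit@se, fstat = fit@fstat,
    pvalue = fit@pvalue)
}

.modeled_properties <- c("refractivity", "enthalpy", "molar_volume",
                         "polarity", "complexity")

#' All 45 index-property fits
#'
#' Fits every (index, property) pair of the nine indices against the five
#' modeled properties, with pairwise deletion per pair.
#'
#' @param ti data.frame with a `name` column plus the nine index columns
#'   (as from [loadTiTable()]).
#' @param props data.frame with a `name` column plus property columns (as
#'   from [loadPropertyTable()]); joined to `ti` on `name`.
#' @param properties character vector of property columns to model.
#' @return named list (index, then property) of [TopoRegression-class] fits.
#' @export
fitAllModels <- function(ti, props, properties = .modeled_properties) {
  d <- merge(ti, props, by = "name", sort = FALSE)
  lapply(stats::setNames(nm = indexNames()), function(ix)
    lapply(stats::setNames(nm = properties), function(pr)
      fitPropertyModel(d[[ix]], d[[pr]], index = ix, property = pr)))
}

.fit_matrix <- function(fits, stat) {
  props <- names(fits[[1L]])
  vals <- unlist(lapply(fits, function(byProp)
    vapply(byProp, function(f) fitStatistics(f)[[stat]], numeric(1))))
  matrix(vals, nrow = length(fits), ncol = length(props), byrow = TRUE,
         dimnames = list(names(fits), props))
}

#' Correlation matrix between indices and properties
#'
#' Pearson r per (index, property) pair under pairwise deletion; the sample
#' size used for each cell is attached as the `"n"` attribute.
#'
#' @inheritParams fitAllModels
#' @return 9 x 5 numeric matrix of r values with attribute `n` (matrix of
#'   per-cell sample sizes).
#' @export
correlationTable <- function(ti, props, properties = .modeled_properties) {
  fits <- fitAllModels(ti, props, properties)
  r <- .fit_matrix(fits, "r")
  nmat <- .fit_matrix(fits, "n")
  storage.mode(nmat) <- "integer"
  attr(r, "n") <- nmat
  r
}

#' Per-index statistical parameter table
#'
#' One row per property for a given index: sample size, intercept, slope, r,
#' r^2, F, p, and a significance flag. A model is flagged significant when
#' p < 0.05 or r > 0.6 (both sub-conditions are reported); the r > 0.6
#' working rule matches the published convention, which labels rows
#' significant even where p alone would not. No multiple-testing correction
#' is applied, matching the published analysis.
#'
#' @inheritParams fitAllModels
#' @param index index identifier, one of [indexNames()].
#' @return data.frame with columns property, N, A, b, r, r2, F, p,
#'   sig_p (p < 0.05), sig_r (r > 0.6), significant.
#' @export
regressionTable <- function(ti, props, index,
                            properties = .modeled_properties) {
  index <- .match_index(index)
  d <- merge(ti, props, by = "name", sort = FALSE)
  rows <- lapply(properties, function(pr) {
    f <- fitPropertyModel(d[[index]], d[[pr]], index = index, property = pr)
    s <- fitStatistics(f)
    data.frame(property = pr, N = f@n, A = f@intercept, b = f@slope,
      r = f@r, r2 = f@r2, F = f@fstat, p = f@pvalue,
      sig_p = f@pvalue < 0.05, sig_r = f@r > 0.6,
      significant = f@pvalue < 0.05 || f@r > 0.6)
  })
  do.call(rbind, rows)
}

#' Standard-error and coefficient-of-determination matrices
#'
#' @inheritParams fitAllModels
#' @return 9 x 5 numeric matrix of standard errors of estimate
#'   (`seTable`) or r^2 values (`r2Table`).
#' @export
seTable <- function(ti, props, properties = .modeled_properties) {
  .fit_matrix(fitAllModels(ti, props, properties), "se")
}

#' @rdname seTable
#' @export
r2Table <- function(ti, props, properties = .modeled_properties) {
  .fit_matrix(fitAllModels(ti, props, properties), "r2")
}

#' Actual-vs-predicted table for one property
#'
#' For every molecule, the observed property value and its prediction under
#' each of the nine index models. Predictions default to 3-decimal
#' coefficients, the convention of the published comparison tables; pass
#' `coefDigits = NULL` for full-precision predictions. Molecules with a
#' missing observed value still receive predictions (the fit itself uses
#' only complete pairs).
#'
#' @inheritParams fitAllModels
#' @param property one property column name.
#' @param coefDigits decimals for prediction coefficients (default 3).
#' @return data.frame: name, actual, then one prediction column per index.
#' @export
predictionTable <- function(ti, props, property, coefDigits = 3) {
  stopifnot(property %in% names(props))
  d <- merge(ti, props, by = "name", sort = FALSE)
  out <- data.frame(name = d$name, actual = d[[property]])
  for (ix in indexNames()) {
    f <- fitPropertyModel(d[[ix]], d[[property]], index = ix,
                          property = property)
    out[[ix]] <- predictProperty(f, d[[ix]], coefDigits = coefDigits)
  }
  out
}
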