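#' Root-mean-square error
#' @param predicted,actual aligned non-empty numeric vectors.
#' @return single numeric RMSE.
#' @export
rmse <- function(predicted, actual) {
  if (length(predicted) != length(actual))
    stop("predicted and actual must have the same length")
  if (!length(predicted)) stop("empty input")
  sqrt(mean((predicted - actual)^2))
}

#' RMSE stratified by chemical domain and applicability
#'
#' Computes the RMSE per stratum tag (e.g. sulphone-carbonyl /
#' nitrile-carbonyl / di-carbonyl / other, from [classifySiteMotif()]) and
#' overall, each both on all records and on the in-domain subset.
#' Empty strata are simply absent from the table, never reported as 0.
#'
#' @param predictions list of [PkaPrediction-class].
#' @param actual aligned numeric vector of experimental values.
#' @param tags aligned character vector of stratum labels.
#' @return data.frame with columns `tag`, `scope` (`all` / `inDomain`),
#'   `n`, `rmse`.
#' @export
stratifiedRmse <- function(predictions, actual, tags) {
  if (length(predictions) != length(actual) ||
      length(actual) != length(tags))
    stop("predictions, actual and tags must be aligned")
  pred <- vapply(predictions, function(p) p@pka, numeric(1))
  dom <- vapply(predictions, function(p) p@inDomain, logical(1))
  out <- data.frame(tag = character(), scope = character(), n = integer(),
                    rmse = numeric())
  add <- function(tag, scope, idx) {
    if (!length(idx)) return()
    out <<- rbind(out, data.frame(tag = tag, scope = scope,
                                  n = length(idx),
                                  rmse = rmse(pred[idx], actual[idx])))
  }
  for (tag in c("overall", sort(unique(tags)))) {
    idx <- if (tag == "overall") seq_along(tags) else which(tags == tag)
    add(tag, "all", idx)
    add(tag, "inDomain", idx[dom[idx]])
  }
  out
}

#' Y-scrambling (response permutation) check
#'
#' Randomly permutes the training pKa values, refits the coefficient model
#' on the unchanged design matrix, and evaluates the RMSE on an untouched
#' test set, `nReps` times. A real model's RMSE should be far below the
#' scrambled distribution; comparable values would indicate a chance
#' correlation. One master seed spawns a per-replicate sub-seed, so any
#' single replicate is individually reproducible.
#'
#' @param records training list of [PkaRecord-class].
#' @param test list of [PkaRecord-class] used for evaluation (their pKa
#'   values are never permuted).
#' @param nReps number of scramble replicates (default 1000).
#' @param seed master RNG seed.
#' @param .permutation test hook: a fixed permutation (integer vector) used
#'   for every replicate instead of a random one.
#' @return list with `mean`, `sd`, `rmses` (per replicate), `trueRmse`
#'   (unscrambled model on the same test set), `nFailed` and `subSeeds`.
#' @export
yScramble <- function(records, test, nReps = 1000L, seed = 1L,
                      .permutation = NULL) {
  if (nReps < 1L) stop("nReps must be >= 1")
  fm <- buildFeatureMatrix(records)
  test_fm <- buildFeatureMatrix(test)
  test_actual <- test_fm$y
  evalModel <- function(model) {
    pred <- vapply(seq_len(nrow(test_fm$X)), function(i) {
      w <- test_fm$X[i, ]
      known <- intersect(names(w)[w > 0], names(model@coefficients))
      model@intercept + sum(model@coefficients[known] * w[known])
    }, numeric(1))
    rmse(pred, test_actual)
  }
  trueRmse <- evalModel(.fitFromMatrix(fm$X, fm$y))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  subSeeds <- sample.int(.Machine$integer.max - 1L, nReps)
  rmses <- rep(NA_real_, nReps)
  for (r in seq_len(nReps)) {
    perm <- if (is.null(.permutation)) {
      set.seed(subSeeds[r]); sample.int(length(fm$y))
    } else .permutation
    m <- tryCatch(.fitFromMatrix(fm$X, fm$y[perm]),
                  error = function(e) NULL)
    if (!is.null(m)) rmses[r] <- evalModel(m)
  }
  ok <- rmses[!is.na(rmses)]
  if (!length(ok)) stop("every scramble replicate failed to refit")
  list(mean = mean(ok), sd = if (length(ok) > 1L) stats::sd(ok) else 0,
       rmses = rmses, trueRmse = trueRmse,
       nFailed = sum(is.na(rmses)), subSeeds = subSeeds)
}

#' Bin predictions by absolute error
#'
#' Absolute errors are classed Good (< 1 pKa unit), Fair ([1, 2)),
#' Poor ([2, 3)) or Bad (>= 3); the intervals are left-closed/right-open,
#' so they are exhaustive and mutually exclusive.
#'
#' @param predictions list of [PkaPrediction-class].
#' @param actual aligned numeric vector.
#' @param scope `"all"` or `"inDomain"` (restrict to in-domain
#'   predictions).
#' @return an [ErrorBinSummary-class].
#' @export
binErrors <- function(predictions, actual, scope = c("all", "inDomain")) {
  scope <- match.arg(scope)
  if (length(predictions) != length(actual))
    stop("predictions and actual must be aligned")
  pred <- vapply(predictions, function(p) p@pka, numeric(1))
  dom <- vapply(predictions, function(p) p@inDomain, logical(1))
  keep <- if (scope == "inDomain") dom else rep(TRUE, length(pred))
  e <- abs(pred[keep] - actual[keep])
  counts <- c(Good = sum(e < 1), Fair = sum(e >= 1 & e < 2),
              Poor = sum(e >= 2 & e < 3), Bad = sum(e >= 3))
  new("ErrorBinSummary", counts = as.integer(counts) |>
        stats::setNames(names(counts)),
      n = length(e), scope = scope)
}

#' Bin model coefficients by absolute magnitude
#'
#' Magnitude classes: < 10, [10, 20), [20, 30), >= 30. A healthy model has
#' most of its mass in the small-magnitude classes, so that no single
#' atom-type can dominate a prediction.
#'
#' @param model a [CoefficientModel-class].
#' @return a [CoefficientBinSummary-class].
#' @export
binCoefficients <- function(model) {
  a <- abs(model@coefficients)
  counts <- c(lt10 = sum(a < 10), lt20 = sum(a >= 10 & a < 20),
              lt30 = sum(a >= 20 & a < 30), ge30 = sum(a >= 30))
  new("CoefficientBinSummary",
      counts = as.integer(counts) |> stats::setNames(names(counts)))
}

#' Summarise bin counts as a data.frame
#' @param object an [ErrorBinSummary-class] or
#'   [CoefficientBinSummary-class].
#' @return data.frame of bin names and counts.
#' @export
binCounts <- function(object)
  data.frame(bin = names(object@counts), count = unname(object@counts))
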