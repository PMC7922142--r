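#' Assemble distance spectra into a design matrix
#'
#' Rows align with the input records; columns align with the sorted union
#' of atom-type codes across all spectra, with 0 where a record's spectrum
#' lacks a type. The response vector collects the pKa values.
#'
#' @param records list of [PkaRecord-class] objects.
#' @param spectra optional pre-computed list of [DistanceSpectrum-class]
#'   aligned with `records` (computed from the records when omitted).
#' @return list with elements `X` (numeric matrix, one row per record),
#'   `atomTypes` (character, column order), `y` (numeric response).
#' @export
buildFeatureMatrix <- function(records, spectra = NULL) {
  if (!length(records)) stop("no records supplied")
  if (is.null(spectra))
    spectra <- lapply(records, function(r)
      computeDistanceSpectrum(r@molecule, r@site))
  types <- sort(unique(unlist(lapply(spectra, function(s) names(s@weights)))))
  if (!length(types)) stop("all spectra are empty; no atom-types to fit")
  X <- matrix(0, nrow = length(records), ncol = length(types),
              dimnames = list(NULL, types))
  for (i in seq_along(spectra)) {
    w <- spectra[[i]]@weights
    if (length(w)) X[i, names(w)] <- w
  }
  y <- vapply(records, function(r) r@pka, numeric(1))
  list(X = X, atomTypes = types, y = y)
}

#' Fit atom-type coefficients by QR least squares
#'
#' Solves the linear system spectrum-matrix times alpha ~ pKa in the
#' least-squares sense via a QR decomposition with column pivoting. The
#' solve is deterministic: refitting identical input reproduces
#' bit-identical coefficients. There is no intercept by default (the
#' prediction equation has none) and no regularisation. Rank-deficient
#' columns (R-diagonal below tolerance) receive a coefficient of exactly 0
#' and are reported in the model's `deficientTypes` slot; the fitted values
#' remain least-squares optimal.
#'
#' The reported R^2 is 1 - SS_res/SS_tot with SS_tot taken about the mean
#' response, truncated below at 0.
#'
#' @param records list of [PkaRecord-class] objects (all pKa values finite).
#' @param useIntercept add a free intercept term (default `FALSE`).
#' @param tol rank tolerance passed to [qr()].
#' @return a [CoefficientModel-class].
#' @examples
#' m <- molecularGraph(c("C", "O"),
#'                     data.frame(from = 1, to = 2, order = 1))
#' rec <- pkaRecord(m, ionisationSite(1), pka = 16)
#' fitCoefficientModel(list(rec))
#' @export
fitCoefficientModel <- function(records, useIntercept = FALSE, tol = 1e-10) {
  fm <- buildFeatureMatrix(records)
  .fitFromMatrix(fm$X, fm$y, useIntercept = useIntercept, tol = tol)
}

#' Solve for coefficients from an explicit design matrix
#'
#' Matrix-level entry point behind [fitCoefficientModel()]: least squares
#' of `y` on `X` via pivoted QR. Useful when the design matrix is built by
#' other means (e.g. nested-column comparisons).
#'
#' @param X numeric matrix with atom-type codes as column names.
#' @param y numeric response (pKa values).
#' @param useIntercept add a free intercept column.
#' @param tol rank tolerance passed to [qr()].
#' @return a [CoefficientModel-class].
#' @export
solveCoefficients <- function(X, y, useIntercept = FALSE, tol = 1e-10)
  .fitFromMatrix(X, y, useIntercept = useIntercept, tol = tol)

# Core solve, shared with yScramble (which refits on a fixed design).
.fitFromMatrix <- function(X, y, useIntercept = FALSE, tol = 1e-10) {
  if (any(!is.finite(y))) stop("non-finite pKa value in training records")
  if (all(X == 0)) stop("design matrix is all zero; nothing to fit")
  types <- colnames(X)
  Xfit <- if (useIntercept) cbind(`(Intercept)` = 1, X) else X
  qrX <- qr(Xfit, tol = tol)
  beta <- qr.coef(qrX, y)
  deficient <- names(beta)[is.na(beta)]
  beta[is.na(beta)] <- 0
  fitted <- drop(Xfit %*% beta)
  ss_res <- sum((y - fitted)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) max(0, min(1, 1 - ss_res / ss_tot)) else
    as.numeric(ss_res <= .Machine$double.eps * length(y))
  intercept <- if (useIntercept) unname(beta["(Intercept)"]) else 0
  coefs <- beta[types]
  new("CoefficientModel", coefficients = coefs, intercept = intercept,
      rSquared = r2, nRecords = length(y), nAtomTypes = length(coefs),
      typingSchemeVersion = typingSchemeVersion(),
      deficientTypes = setdiff(deficient, "(Intercept)"))
}

#' Predict the pKa of an ionisation site
#'
#' The prediction is the inner product of the model coefficients with the
#' site's distance spectrum (plus the intercept, when one was fitted).
#' Atom-types present in the spectrum but absent from the model contribute
#' zero; such a prediction is flagged out-of-domain (`inDomain = FALSE`)
#' and the missing types are listed, but a value is always returned.
#'
#' @param object a [CoefficientModel-class].
#' @param molecule a [MolecularGraph-class].
#' @param site an [IonisationSite-class] or bare atom index.
#' @param ... unused.
#' @return a [PkaPrediction-class].
#' @export
setMethod("predict", "CoefficientModel",
          function(object, molecule, site, ...) {
  if (is.numeric(site)) site <- ionisationSite(site)
  spec <- computeDistanceSpectrum(molecule, site)
  predictFromSpectrum(object, spec)
})

#' Predict from a pre-computed distance spectrum
#'
#' @param model a [CoefficientModel-class].
#' @param spectrum a [DistanceSpectrum-class] computed with the same typing
#'   scheme version as the model (a mismatch is a hard error).
#' @return a [PkaPrediction-class].
#' @rdname predict-CoefficientModel-method
#' @export
predictFromSpectrum <- function(model, spectrum) {
  if (model@typingSchemeVersion != typingSchemeVersion())
    stop(sprintf(
      "model typing scheme '%s' does not match the current scheme '%s'",
      model@typingSchemeVersion, typingSchemeVersion()))
  w <- spectrum@weights
  if (!length(w))
    stop("empty spectrum: no basis for a prediction")
  known <- names(w) %in% names(model@coefficients)
  missing <- sort(names(w)[!known])
  pka <- model@intercept +
    sum(model@coefficients[names(w)[known]] * w[known])
  new("PkaPrediction", pka = unname(pka), inDomain = !length(missing),
      missingAtomTypes = missing, siteIndex = spectrum@site@atomIndex)
}

#' Append virtual records to a training set
#'
#' Concatenates base-then-virtual, preserving order and provenance. Since
#' the atom-type set of a fit is the union over all training spectra,
#' refitting after augmentation can only grow the coefficient set. A
#' duplicated molecule-site pair across the two lists raises a warning but
#' both copies are kept.
#'
#' @param base list of [PkaRecord-class] (typically experimental).
#' @param virtual list of [PkaRecord-class] with provenance `"virtual"`.
#' @return concatenated list of records.
#' @export
augmentRecords <- function(base, virtual) {
  if (length(virtual)) {
    prov <- vapply(virtual, function(r) r@provenance, character(1))
    if (any(prov != "virtual"))
      stop("all augmentation records must carry provenance 'virtual'")
    tags <- vapply(virtual, function(r) r@sourceTag, character(1))
    if (any(!nzchar(tags)))
      stop("all augmentation records must carry a source tag")
    key <- function(r) paste0(r@molecule@id, "#", r@site@atomIndex)
    dup <- intersect(vapply(base, key, character(1)),
                     vapply(virtual, key, character(1)))
    if (length(dup))
      warning("duplicate molecule-site pair(s) across base and virtual: ",
              paste(dup, collapse = ", "), " (both kept)")
  }
  c(base, virtual)
}
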