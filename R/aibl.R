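#' Fit an AIBL local bond-length model
#'
#' Ordinary least squares of pKa on a single bond length within a
#' congeneric series: pKa = m*R + c. Bond lengths come from externally
#' supplied (quantum-chemically optimised) geometries and are consumed as
#' data. The training length range is recorded as the model's
#' applicability range.
#'
#' @param lengths numeric vector of bond lengths (Angstrom).
#' @param pkas numeric vector of pKa values, aligned with `lengths`.
#' @param bondLabel which bond the lengths refer to.
#' @param groupLabel subgroup label (series are often split into geometry
#'   classes fitted separately).
#' @return an [AIBLModel-class].
#' @examples
#' fitAibl(c(1.50, 1.52), c(10, 8), "C-C carbonyl-to-site", "group1")
#' @export
fitAibl <- function(lengths, pkas, bondLabel = "bond", groupLabel = "all") {
  if (length(lengths) != length(pkas))
    stop("lengths and pkas must be aligned")
  if (length(lengths) < 2L)
    stop("degenerate fit: need >= 2 points")
  if (any(!is.finite(lengths)) || any(!is.finite(pkas)))
    stop("non-finite input")
  if (stats::var(lengths) == 0)
    stop("degenerate fit: zero variance in bond lengths")
  fit <- stats::lm(pkas ~ lengths)
  ss_tot <- sum((pkas - mean(pkas))^2)
  r2 <- if (ss_tot == 0) 0 else 1 - sum(stats::residuals(fit)^2) / ss_tot
  cf <- stats::coef(fit)
  new("AIBLModel", slope = unname(cf[2L]), intercept = unname(cf[1L]),
      bondLabel = bondLabel, rSquared = max(0, min(1, r2)),
      lengthRange = range(lengths), groupLabel = groupLabel,
      n = length(lengths))
}

#' Select the best-correlating bond for an AIBL model
#'
#' Fits one model per candidate bond and returns the one with the highest
#' r^2; ties are broken by lexicographic bond label. Candidates whose fit
#' is degenerate (fewer than 2 points or zero length variance) are skipped.
#'
#' @param candidates named list: bond label -> numeric vector of lengths,
#'   each aligned with `pkas`.
#' @param pkas numeric vector of pKa values.
#' @param groupLabel forwarded to [fitAibl()].
#' @return list with elements `bondLabel` and `model` (an
#'   [AIBLModel-class]).
#' @export
selectBestBond <- function(candidates, pkas, groupLabel = "all") {
  if (!length(candidates)) stop("no candidate bonds supplied")
  if (is.null(names(candidates)) || any(!nzchar(names(candidates))))
    stop("candidates must be a named list of length vectors")
  fits <- list()
  for (lab in sort(names(candidates))) {
    m <- tryCatch(fitAibl(candidates[[lab]], pkas, bondLabel = lab,
                          groupLabel = groupLabel),
                  error = function(e) NULL)
    if (!is.null(m)) fits[[lab]] <- m
  }
  if (!length(fits)) stop("all candidate bonds gave degenerate fits")
  r2 <- vapply(fits, function(m) m@rSquared, numeric(1))
  best <- names(fits)[which.max(r2)]  # ties: first in sorted label order
  list(bondLabel = best, model = fits[[best]])
}

#' Fit a mixed-solvent to water pKa correction
#'
#' Linear map from pKa measured in a mixed solvent to the aqueous value,
#' fitted by OLS on paired observations (water regressed on mixed).
#'
#' @param mixed numeric pKa values in the mixed solvent.
#' @param water aligned numeric aqueous pKa values.
#' @param label description of the mixed solvent.
#' @return a [SolventCorrection-class].
#' @export
fitSolventCorrection <- function(mixed, water, label = "mixed solvent") {
  if (length(mixed) != length(water)) stop("unpaired observations")
  if (length(mixed) < 2L) stop("degenerate fit: need >= 2 pairs")
  if (stats::var(mixed) == 0)
    stop("degenerate fit: zero variance in mixed-solvent values")
  cf <- stats::coef(stats::lm(water ~ mixed))
  new("SolventCorrection", slope = unname(cf[2L]),
      intercept = unname(cf[1L]), solventLabel = label,
      n = length(mixed))
}

#' Apply a solvent correction to pKa values
#' @param correction a [SolventCorrection-class].
#' @param pka numeric vector of mixed-solvent pKa values.
#' @return corrected aqueous pKa values.
#' @export
applySolventCorrection <- function(correction, pka)
  correction@slope * pka + correction@intercept

#' Generate virtual training records from an AIBL model
#'
#' Assigns each input molecule the pKa its bond length implies under the
#' local model (then solvent-corrects it when a correction is supplied) and
#' wraps it as a virtual [PkaRecord-class] ready for [augmentRecords()].
#' Inputs whose bond length falls outside the model's training range are
#' flagged; under `policy = "allow"` (the default, matching the deliberate
#' use of extrapolation to reach extreme pKa values) they are kept, under
#' `policy = "strict"` they are dropped and the drop count reported.
#'
#' @param model an [AIBLModel-class].
#' @param inputs list of entries, each a list with elements `molecule`
#'   (a [MolecularGraph-class]), `site` (an [IonisationSite-class] or atom
#'   index) and `bondLength` (Angstrom).
#' @param correction optional [SolventCorrection-class].
#' @param policy `"allow"` or `"strict"`.
#' @param sourceTag tag stored on each record (defaults to the model's
#'   group label).
#' @return list with elements `records` (list of [PkaRecord-class]),
#'   `outOfRange` (logical, aligned with `records`) and `nDropped`
#'   (integer).
#' @export
generateVirtualRecords <- function(model, inputs, correction = NULL,
                                   policy = c("allow", "strict"),
                                   sourceTag = NULL) {
  policy <- match.arg(policy)
  if (is.null(sourceTag)) sourceTag <- model@groupLabel
  lens <- vapply(inputs, function(x) as.numeric(x$bondLength), numeric(1))
  if (any(!is.finite(lens))) stop("non-finite bond length in inputs")
  pka <- model@slope * lens + model@intercept
  if (!is.null(correction)) pka <- applySolventCorrection(correction, pka)
  oor <- lens < model@lengthRange[1] | lens > model@lengthRange[2]
  keep <- if (policy == "strict") !oor else rep(TRUE, length(inputs))
  nDropped <- sum(!keep)
  if (nDropped)
    message(nDropped, " out-of-range input(s) dropped under policy=strict")
  records <- vector("list", sum(keep))
  kk <- which(keep)
  for (i in seq_along(kk)) {
    inp <- inputs[[kk[i]]]
    site <- if (is.numeric(inp$site)) ionisationSite(inp$site) else inp$site
    records[[i]] <- pkaRecord(inp$molecule, site, pka[kk[i]],
                              provenance = "virtual",
                              sourceTag = sourceTag)
  }
  list(records = records, outOfRange = oor[keep], nDropped = nDropped)
}
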