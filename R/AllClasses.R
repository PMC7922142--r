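#' @import methods
NULL

# ---------------------------------------------------------------------------
# MolecularGraph
# ---------------------------------------------------------------------------

#' Heavy-atom molecular graph
#'
#' A hydrogen-suppressed molecular graph. Atoms are rows of `atoms`
#' (columns `element`, `charge`, `aromatic`, `nH`) and bonds are rows of
#' `bonds` (columns `from`, `to`, `order`, 1-based atom indices). Hydrogens
#' are never graph nodes: the attached-hydrogen count is carried on each
#' heavy atom instead, which keeps distance spectra compact.
#'
#' @slot atoms data.frame with one row per heavy atom: `element` (symbol),
#'   `charge` (integer formal charge), `aromatic` (logical), `nH` (integer
#'   attached hydrogens).
#' @slot bonds data.frame with columns `from`, `to` (1-based atom indices)
#'   and `order` (1, 2 or 3).
#' @slot id single character identifier.
#'
#' @seealso [molecularGraph()], [parseSmiles()], [assignAtomType()]
#' @export
setClass("MolecularGraph",
         representation(atoms = "data.frame", bonds = "data.frame",
                        id = "character"))

setValidity("MolecularGraph", function(object) {
  a <- object@atoms; b <- object@bonds
  msgs <- character()
  need_a <- c("element", "charge", "aromatic", "nH")
  if (!all(need_a %in% names(a)))
    msgs <- c(msgs, sprintf("atoms must have columns %s",
                            paste(need_a, collapse = ", ")))
  if (nrow(a) < 1L) msgs <- c(msgs, "molecule must contain >= 1 heavy atom")
  if (length(object@id) != 1L) msgs <- c(msgs, "id must be a single string")
  if (nrow(b) > 0L) {
    need_b <- c("from", "to", "order")
    if (!all(need_b %in% names(b))) {
      msgs <- c(msgs, sprintf("bonds must have columns %s",
                              paste(need_b, collapse = ", ")))
    } else {
      idx <- c(b$from, b$to)
      if (any(idx < 1L | idx > nrow(a)))
        msgs <- c(msgs, "bond endpoints must be valid atom indices")
      if (any(b$from == b$to)) msgs <- c(msgs, "self-bonds are not allowed")
      if (any(!b$order %in% c(1L, 2L, 3L)))
        msgs <- c(msgs, "bond order must be 1, 2 or 3")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a MolecularGraph
#'
#' @param atoms data.frame of atoms (see [MolecularGraph-class]); a character
#'   vector of element symbols is also accepted, in which case neutral,
#'   non-aromatic atoms with `nH = 0` are created.
#' @param bonds data.frame with columns `from`, `to`, `order`; may be empty
#'   for a single-atom molecule.
#' @param id molecule identifier.
#' @return A [MolecularGraph-class] object.
#' @examples
#' m <- molecularGraph(c("C", "C", "O"),
#'                     data.frame(from = c(1, 2), to = c(2, 3), order = 1),
#'                     id = "ethanol")
#' @export
molecularGraph <- function(atoms, bonds = emptyBonds(), id = "mol") {
  if (is.character(atoms))
    atoms <- data.frame(element = atoms, charge = 0L, aromatic = FALSE,
                        nH = 0L, stringsAsFactors = FALSE)
  atoms$charge <- as.integer(atoms$charge)
  atoms$nH <- as.integer(atoms$nH)
  atoms$aromatic <- as.logical(atoms$aromatic)
  if (nrow(bonds) > 0L) {
    bonds$from <- as.integer(bonds$from)
    bonds$to <- as.integer(bonds$to)
    bonds$order <- as.integer(bonds$order)
  }
  new("MolecularGraph", atoms = atoms, bonds = bonds, id = as.character(id))
}

#' @rdname molecularGraph
#' @export
emptyBonds <- function()
  data.frame(from = integer(), to = integer(), order = integer())

#' @describeIn molecularGraph number of heavy atoms.
#' @param x,object a `MolecularGraph`.
#' @export
setMethod("length", "MolecularGraph", function(x) nrow(x@atoms))

#' Accessors for MolecularGraph
#'
#' `atoms()` and `bonds()` return the atom and bond tables; `moleculeId()`
#' the identifier.
#'
#' @param object a [MolecularGraph-class].
#' @return data.frame (atoms, bonds) or character (moleculeId).
#' @export
atoms <- function(object) object@atoms

#' @rdname atoms
#' @export
bonds <- function(object) object@bonds

#' @rdname atoms
#' @export
moleculeId <- function(object) object@id

setMethod("show", "MolecularGraph", function(object) {
  cat(sprintf("MolecularGraph '%s': %d heavy atoms, %d bonds\n",
              object@id, nrow(object@atoms), nrow(object@bonds)))
  cat("  formula (heavy): ",
      paste(sprintf("%s%d", names(tab <- table(object@atoms$element)), tab),
            collapse = " "), "\n", sep = "")
})

# ---------------------------------------------------------------------------
# IonisationSite
# ---------------------------------------------------------------------------

.SITE_CLASSES <- c("carbon_acid", "oxyacid", "amine_acid", "sulphur_acid",
                   "alkylamine", "aromatic_amine", "imine")

#' Ionisation site of a molecule
#'
#' Marks the atom undergoing the (de)protonation event together with its
#' protonation-class label. Each class gives rise to its own coefficient
#' model; the machinery is identical across classes.
#'
#' @slot atomIndex 1-based index into the heavy-atom graph.
#' @slot siteClass one of `carbon_acid`, `oxyacid`, `amine_acid`,
#'   `sulphur_acid`, `alkylamine`, `aromatic_amine`, `imine`.
#' @export
setClass("IonisationSite",
         representation(atomIndex = "integer", siteClass = "character"))

setValidity("IonisationSite", function(object) {
  msgs <- character()
  if (length(object@atomIndex) != 1L || is.na(object@atomIndex) ||
      object@atomIndex < 1L)
    msgs <- c(msgs, "atomIndex must be a single positive integer")
  if (!object@siteClass %in% .SITE_CLASSES)
    msgs <- c(msgs, sprintf("siteClass must be one of: %s",
                            paste(.SITE_CLASSES, collapse = ", ")))
  if (length(msgs)) msgs else TRUE
})

#' @param atomIndex 1-based heavy-atom index.
#' @param siteClass protonation-class label, default `"carbon_acid"`.
#' @rdname IonisationSite-class
#' @export
ionisationSite <- function(atomIndex, siteClass = "carbon_acid")
  new("IonisationSite", atomIndex = as.integer(atomIndex),
      siteClass = siteClass)

#' @rdname atoms
#' @export
siteIndex <- function(object) object@atomIndex

setMethod("show", "IonisationSite", function(object)
  cat(sprintf("IonisationSite: atom %d (%s)\n",
              object@atomIndex, object@siteClass)))

# ---------------------------------------------------------------------------
# DistanceSpectrum
# ---------------------------------------------------------------------------

#' Distance spectrum of an ionisation site
#'
#' Sparse feature vector indexed by six-digit atom-type code. Each heavy
#' atom j (other than the site itself) at through-bond distance d
#' contributes 1/d^2 to the entry of its atom-type; atoms disconnected from
#' the site (counter-ions in salt forms) contribute nothing. Zero-weight
#' types are omitted, so every stored weight is strictly positive.
#'
#' @slot weights named numeric vector; names are atom-type codes.
#' @slot site the [IonisationSite-class] the spectrum was computed for.
#' @slot moleculeId identifier of the source molecule.
#' @seealso [computeDistanceSpectrum()]
#' @export
setClass("DistanceSpectrum",
         representation(weights = "numeric", site = "IonisationSite",
                        moleculeId = "character"))

setValidity("DistanceSpectrum", function(object) {
  w <- object@weights
  msgs <- character()
  if (length(w) && (is.null(names(w)) || any(!nzchar(names(w)))))
    msgs <- c(msgs, "weights must be named by atom-type code")
  if (any(w <= 0) || any(!is.finite(w)))
    msgs <- c(msgs, "weights must be strictly positive and finite")
  if (anyDuplicated(names(w)))
    msgs <- c(msgs, "atom-type codes must be unique")
  if (length(msgs)) msgs else TRUE
})

#' @rdname atoms
#' @export
spectrumWeights <- function(object) object@weights

setMethod("show", "DistanceSpectrum", function(object) {
  cat(sprintf("DistanceSpectrum for '%s' site atom %d: %d atom-types, total weight %.4f\n",
              object@moleculeId, object@site@atomIndex,
              length(object@weights), sum(object@weights)))
  if (length(object@weights)) {
    df <- data.frame(atomType = names(object@weights),
                     weight = unname(object@weights))
    print(utils::head(df[order(-df$weight), ], 8L), row.names = FALSE)
  }
})

# ---------------------------------------------------------------------------
# PkaRecord
# ---------------------------------------------------------------------------

#' A single training observation
#'
#' One pKa value attached to one ionisation site of one molecule, with the
#' provenance (`experimental` for literature measurements, `virtual` for
#' values produced by an AIBL local model) and a free-form source tag so
#' augmentation experiments can be replayed set-by-set.
#'
#' @slot molecule a [MolecularGraph-class].
#' @slot site an [IonisationSite-class].
#' @slot pka numeric pKa value.
#' @slot provenance `"experimental"` or `"virtual"`.
#' @slot sourceTag free-form label, e.g. `"set1_sulphone"`.
#' @export
setClass("PkaRecord",
         representation(molecule = "MolecularGraph", site = "IonisationSite",
                        pka = "numeric", provenance = "character",
                        sourceTag = "character"))

setValidity("PkaRecord", function(object) {
  msgs <- character()
  if (!is.finite(object@pka)) msgs <- c(msgs, "pka must be finite")
  if (!object@provenance %in% c("experimental", "virtual"))
    msgs <- c(msgs, "provenance must be 'experimental' or 'virtual'")
  if (object@site@atomIndex > nrow(object@molecule@atoms))
    msgs <- c(msgs, "site atom index outside molecule")
  if (length(msgs)) msgs else TRUE
})

#' @param molecule,site,pka,provenance,sourceTag see slots.
#' @rdname PkaRecord-class
#' @export
pkaRecord <- function(molecule, site, pka, provenance = "experimental",
                      sourceTag = "") {
  new("PkaRecord", molecule = molecule, site = site, pka = as.numeric(pka),
      provenance = provenance, sourceTag = as.character(sourceTag))
}

setMethod("show", "PkaRecord", function(object)
  cat(sprintf("PkaRecord '%s' site %d: pKa = %.3f [%s%s]\n",
              object@molecule@id, object@site@atomIndex, object@pka,
              object@provenance,
              if (nzchar(object@sourceTag))
                paste0(", ", object@sourceTag) else "")))

# ---------------------------------------------------------------------------
# CoefficientModel / PkaPrediction
# ---------------------------------------------------------------------------

#' Atom-type coefficient model
#'
#' The fitted pKa model: one coefficient per atom-type observed in the
#' training spectra, obtained from a deterministic QR least-squares solve.
#' The prediction for a site is the inner product of these coefficients with
#' the site's distance spectrum.
#'
#' @slot coefficients named numeric; names are atom-type codes.
#' @slot intercept numeric; 0 unless the model was fitted with an intercept.
#' @slot rSquared coefficient of determination on the training set.
#' @slot nRecords number of training records.
#' @slot nAtomTypes number of atom-types (= number of coefficients).
#' @slot typingSchemeVersion version string of the atom-typing scheme the
#'   training spectra were computed with; a persisted model refuses to score
#'   spectra from a different scheme.
#' @slot deficientTypes atom-types whose design column was flagged rank
#'   deficient (coefficient fixed to 0).
#' @seealso [fitCoefficientModel()], [predict,CoefficientModel-method]
#' @export
setClass("CoefficientModel",
         representation(coefficients = "numeric", intercept = "numeric",
                        rSquared = "numeric", nRecords = "integer",
                        nAtomTypes = "integer",
                        typingSchemeVersion = "character",
                        deficientTypes = "character"))

setValidity("CoefficientModel", function(object) {
  msgs <- character()
  if (is.null(names(object@coefficients)) && length(object@coefficients))
    msgs <- c(msgs, "coefficients must be named by atom-type code")
  if (length(object@rSquared) != 1L || object@rSquared < 0 ||
      object@rSquared > 1)
    msgs <- c(msgs, "rSquared must lie in [0, 1]")
  if (object@nAtomTypes != length(object@coefficients))
    msgs <- c(msgs, "nAtomTypes must equal the number of coefficients")
  if (length(msgs)) msgs else TRUE
})

#' @rdname atoms
#' @export
setMethod("coefficients", "CoefficientModel", function(object, ...)
  object@coefficients)

#' @rdname atoms
#' @export
rSquared <- function(object) object@rSquared

#' @rdname atoms
#' @export
nAtomTypes <- function(object) object@nAtomTypes

#' @rdname atoms
#' @export
typingVersion <- function(object) object@typingSchemeVersion

setMethod("show", "CoefficientModel", function(object) {
  cat(sprintf("CoefficientModel (%s): %d atom-types from %d records, R^2 = %.4f\n",
              object@typingSchemeVersion, object@nAtomTypes,
              object@nRecords, object@rSquared))
  if (length(object@deficientTypes))
    cat("  rank-deficient types (coefficient fixed to 0): ",
        paste(object@deficientTypes, collapse = ", "), "\n", sep = "")
})

#' A pKa prediction with applicability-domain flag
#'
#' @slot pka predicted pKa.
#' @slot inDomain `TRUE` iff every atom-type in the query spectrum has a
#'   learned coefficient; out-of-domain predictions are still returned but
#'   should be used with caution.
#' @slot missingAtomTypes codes present in the spectrum but absent from the
#'   model (their coefficient is taken as zero).
#' @slot siteIndex the queried site atom.
#' @export
setClass("PkaPrediction",
         representation(pka = "numeric", inDomain = "logical",
                        missingAtomTypes = "character",
                        siteIndex = "integer"))

setValidity("PkaPrediction", function(object) {
  if (object@inDomain != (length(object@missingAtomTypes) == 0L))
    "inDomain must be TRUE iff missingAtomTypes is empty" else TRUE
})

#' @rdname atoms
#' @export
predictedPka <- function(object) object@pka

#' @rdname atoms
#' @export
inDomain <- function(object) object@inDomain

#' @rdname atoms
#' @export
missingAtomTypes <- function(object) object@missingAtomTypes

setMethod("show", "PkaPrediction", function(object)
  cat(sprintf("PkaPrediction: pKa = %.3f at atom %d [%s]%s\n",
              object@pka, object@siteIndex,
              if (object@inDomain) "inDomain" else "out of domain",
              if (length(object@missingAtomTypes))
                paste0(" missing: ",
                       paste(object@missingAtomTypes, collapse = ", "))
              else "")))

# ---------------------------------------------------------------------------
# AIBLModel / SolventCorrection
# ---------------------------------------------------------------------------

#' AIBL local linear model
#'
#' A linear free-energy relationship pKa = m*R + c mapping a single bond
#' length R (in Angstrom, from an externally supplied geometry) to pKa
#' within a congeneric series. The applicability range is the range of
#' training bond lengths; extrapolation beyond it is permitted but flagged.
#'
#' @slot slope m, in pKa units per Angstrom.
#' @slot intercept c, in pKa units.
#' @slot bondLabel which bond the length refers to, e.g.
#'   `"C-C carbonyl-to-site"` or `"C#N nitrile"`.
#' @slot rSquared fit diagnostic on the training series.
#' @slot lengthRange `c(min, max)` of training bond lengths (Angstrom).
#' @slot groupLabel subgroup label (congeneric series are often split into
#'   geometry classes fitted separately).
#' @slot n number of training points.
#' @seealso [fitAibl()], [generateVirtualRecords()]
#' @export
setClass("AIBLModel",
         representation(slope = "numeric", intercept = "numeric",
                        bondLabel = "character", rSquared = "numeric",
                        lengthRange = "numeric", groupLabel = "character",
                        n = "integer"))

setValidity("AIBLModel", function(object) {
  msgs <- character()
  if (object@n < 2L) msgs <- c(msgs, "model must be fitted on >= 2 points")
  if (length(object@lengthRange) != 2L ||
      object@lengthRange[1] > object@lengthRange[2])
    msgs <- c(msgs, "lengthRange must be c(min, max)")
  if (object@rSquared < 0 || object@rSquared > 1)
    msgs <- c(msgs, "rSquared must lie in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "AIBLModel", function(object)
  cat(sprintf("AIBLModel [%s / %s]: pKa = %.3f * R %+.3f  (r^2 = %.3f, n = %d, range %.3f-%.3f A)\n",
              object@bondLabel, object@groupLabel, object@slope,
              object@intercept, object@rSquared, object@n,
              object@lengthRange[1], object@lengthRange[2])))

#' Mixed-solvent to water pKa correction
#'
#' Affine map from pKa values measured in a mixed solvent (e.g. 95% aqueous
#' ethanol, aqueous DMSO) to aqueous values, fitted on paired observations.
#'
#' @slot slope,intercept parameters of water = slope * mixed + intercept.
#' @slot solventLabel description of the mixed solvent.
#' @slot n number of training pairs.
#' @seealso [fitSolventCorrection()]
#' @export
setClass("SolventCorrection",
         representation(slope = "numeric", intercept = "numeric",
                        solventLabel = "character", n = "integer"))

setMethod("show", "SolventCorrection", function(object)
  cat(sprintf("SolventCorrection [%s]: water = %.4f * mixed %+.4f (n = %d)\n",
              object@solventLabel, object@slope, object@intercept, object@n)))

# ---------------------------------------------------------------------------
# Bin summaries
# ---------------------------------------------------------------------------

#' Absolute-error bin summary
#'
#' Counts of predictions by absolute error: Good < 1 pKa unit,
#' 1 <= Fair < 2, 2 <= Poor < 3, Bad >= 3. The four intervals partition the
#' non-negative reals, so the counts always sum to `n`.
#'
#' @slot counts named integer vector (`Good`, `Fair`, `Poor`, `Bad`).
#' @slot n number of predictions summarised.
#' @slot scope `"all"` or `"inDomain"`.
#' @seealso [binErrors()]
#' @export
setClass("ErrorBinSummary",
         representation(counts = "integer", n = "integer",
                        scope = "character"))

setValidity("ErrorBinSummary", function(object) {
  msgs <- character()
  if (!identical(names(object@counts), c("Good", "Fair", "Poor", "Bad")))
    msgs <- c(msgs, "counts must be named Good, Fair, Poor, Bad")
  if (sum(object@counts) != object@n)
    msgs <- c(msgs, "counts must sum to n")
  if (!object@scope %in% c("all", "inDomain"))
    msgs <- c(msgs, "scope must be 'all' or 'inDomain'")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "ErrorBinSummary", function(object) {
  cat(sprintf("ErrorBinSummary (%s, n = %d):\n", object@scope, object@n))
  print(object@counts)
})

#' Coefficient-magnitude bin summary
#'
#' Counts of model coefficients by absolute magnitude: < 10, [10, 20),
#' [20, 30), >= 30. Small magnitudes are desirable: no single atom-type
#' should dominate a prediction.
#'
#' @slot counts named integer vector (`lt10`, `lt20`, `lt30`, `ge30`).
#' @seealso [binCoefficients()]
#' @export
setClass("CoefficientBinSummary", representation(counts = "integer"))

setValidity("CoefficientBinSummary", function(object) {
  if (!identical(names(object@counts), c("lt10", "lt20", "lt30", "ge30")))
    "counts must be named lt10, lt20, lt30, ge30" else TRUE
})

setMethod("show", "CoefficientBinSummary", function(object) {
  cat("CoefficientBinSummary (|alpha| bins):\n")
  print(object@counts)
})

# ---------------------------------------------------------------------------
# SyntheticSpec
# ---------------------------------------------------------------------------

#' Specification for synthetic fixtures
#'
#' Controls the synthetic molecule/record generator used for testing and
#' calibration. Molecules are random connected heavy-atom graphs (random
#' trees plus optional ring-closure edges); pKa values are generated from a
#' known ground-truth coefficient map plus Gaussian noise, so parameter
#' recovery can be checked exactly.
#'
#' @slot nMolecules number of molecules to generate.
#' @slot atomTypePool optional character vector of atom-type codes that the
#'   generated set must cover (an error is raised if it cannot).
#' @slot trueCoefficients named numeric map atom-type -> coefficient; when
#'   empty, coefficients are drawn uniformly from [-15, 15] for every
#'   emitted type.
#' @slot noiseSd standard deviation of the Gaussian pKa noise (pKa units).
#' @slot maxAtoms maximum heavy atoms per molecule.
#' @slot ringProb probability of adding each candidate ring-closure edge.
#' @slot seed RNG seed; all generation is deterministic given the seed.
#' @seealso [generateMolecules()], [generateRecords()]
#' @export
setClass("SyntheticSpec",
         representation(nMolecules = "integer", atomTypePool = "character",
                        trueCoefficients = "numeric", noiseSd = "numeric",
                        maxAtoms = "integer", ringProb = "numeric",
                        seed = "integer"))

setValidity("SyntheticSpec", function(object) {
  msgs <- character()
  if (object@nMolecules < 1L) msgs <- c(msgs, "nMolecules must be >= 1")
  if (!is.finite(object@noiseSd) || object@noiseSd < 0)
    msgs <- c(msgs, "noiseSd must be finite and >= 0")
  if (object@maxAtoms < 2L) msgs <- c(msgs, "maxAtoms must be >= 2")
  if (object@ringProb < 0 || object@ringProb > 1)
    msgs <- c(msgs, "ringProb must lie in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' @param nMolecules,atomTypePool,trueCoefficients,noiseSd,maxAtoms,ringProb,seed
#'   see slots of [SyntheticSpec-class].
#' @rdname SyntheticSpec-class
#' @export
syntheticSpec <- function(nMolecules, noiseSd = 0, maxAtoms = 10L,
                          seed = 1L, atomTypePool = character(),
                          trueCoefficients = numeric(), ringProb = 0.2) {
  new("SyntheticSpec", nMolecules = as.integer(nMolecules),
      atomTypePool = as.character(atomTypePool),
      trueCoefficients = trueCoefficients, noiseSd = as.numeric(noiseSd),
      maxAtoms = as.integer(maxAtoms), ringProb = as.numeric(ringProb),
      seed = as.integer(seed))
}

setMethod("show", "SyntheticSpec", function(object)
  cat(sprintf("SyntheticSpec: %d molecules (<= %d atoms), noise sd %.2f, seed %d\n",
              object@nMolecules, object@maxAtoms, object@noiseSd,
              object@seed)))
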