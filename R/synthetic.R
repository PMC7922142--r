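# Run expr with a fixed seed, restoring the caller's RNG state afterwards.
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(expr)
}

.SYN_ELEMENTS <- c("C", "N", "O", "S")
.SYN_WEIGHTS <- c(0.62, 0.14, 0.18, 0.06)
.BASE_VALENCE <- c(C = 4L, N = 3L, O = 2L, S = 2L, F = 1L, Cl = 1L)
.SYN_MAX_DEGREE <- 3L   # bounds the local-environment digit universe so
                        # the atom-type set saturates as molecules accrue
.SYN_CHARGE_PROB <- 0.05

# One random connected molecule on the current RNG stream: a random
# attachment tree plus optional ring-closure chords, with vertex degree
# capped at .SYN_MAX_DEGREE. Atom 1 is always a carbon and serves as the
# designated ionisation site.
.randomMolecule <- function(maxAtoms, ringProb, id) {
  n <- sample.int(maxAtoms - 1L, 1L) + 1L  # uniform in 2..maxAtoms
  element <- c("C", sample(.SYN_ELEMENTS, n - 1L, replace = TRUE,
                           prob = .SYN_WEIGHTS))
  charge <- integer(n)
  flip <- stats::runif(n)
  charge[element == "N" & flip < .SYN_CHARGE_PROB] <- 1L
  charge[element == "O" & flip < .SYN_CHARGE_PROB] <- -1L
  from <- integer(0); to <- integer(0); order <- integer(0)
  degree <- integer(n)
  for (k in 2:n) {
    open <- which(degree[seq_len(k - 1L)] < .SYN_MAX_DEGREE)
    a <- if (length(open) == 1L) open else sample(open, 1L)
    from <- c(from, a); to <- c(to, k)
    o <- sample(c(1L, 2L, 3L), 1L, prob = c(0.72, 0.24, 0.04))
    # triple bonds only between C/N partners, as in nitriles/alkynes
    if (o == 3L && !(element[a] %in% c("C", "N") &&
                     element[k] %in% c("C", "N"))) o <- 1L
    order <- c(order, o)
    degree[a] <- degree[a] + 1L; degree[k] <- degree[k] + 1L
  }
  for (dummy in seq_len(max(0L, n - 4L))) {
    if (stats::runif(1) >= ringProb) next
    open <- which(degree < .SYN_MAX_DEGREE)
    if (length(open) < 2L) next
    pair <- sample(open, 2L)
    i <- min(pair); j <- max(pair)
    if (any(from == i & to == j)) next
    from <- c(from, i); to <- c(to, j); order <- c(order, 1L)
    degree[i] <- degree[i] + 1L; degree[j] <- degree[j] + 1L
  }
  bonds <- data.frame(from = from, to = to, order = order)
  # attached hydrogens from a simple organic valence model
  vsum <- integer(n)
  for (k in seq_along(from)) {
    vsum[from[k]] <- vsum[from[k]] + order[k]
    vsum[to[k]] <- vsum[to[k]] + order[k]
  }
  nH <- pmax(0L, .BASE_VALENCE[element] + charge - vsum)
  atoms <- data.frame(element = element, charge = charge,
                      aromatic = FALSE, nH = as.integer(nH))
  molecularGraph(atoms, bonds, id = id)
}

.generateMoleculesRaw <- function(n, maxAtoms, ringProb, idOffset = 0L) {
  lapply(seq_len(n), function(i) {
    mol <- .randomMolecule(maxAtoms, ringProb,
                           id = sprintf("syn%04d", i + idOffset))
    list(molecule = mol, site = ionisationSite(1L, "carbon_acid"))
  })
}

#' Generate random synthetic molecules with designated sites
#'
#' Produces random connected heavy-atom graphs (random attachment trees
#' plus ring-closure chords added with probability `ringProb`), decorated
#' with elements, occasional formal charges and valence-derived hydrogen
#' counts. Atom 1 of every molecule is a carbon and is designated the
#' ionisation site. Output is deterministic given the spec's seed. When
#' `atomTypePool` is non-empty, the generated set must emit every pool
#' type, otherwise an error is raised.
#'
#' @param spec a [SyntheticSpec-class].
#' @return list of entries `list(molecule = , site = )`.
#' @export
generateMolecules <- function(spec) {
  validObject(spec)
  mols <- .withSeed(spec@seed,
                    .generateMoleculesRaw(spec@nMolecules, spec@maxAtoms,
                                          spec@ringProb))
  if (length(spec@atomTypePool)) {
    emitted <- unique(unlist(lapply(mols, function(m)
      typeAllAtoms(m$molecule))))
    missing <- setdiff(spec@atomTypePool, emitted)
    if (length(missing))
      stop("unsatisfiable atom-type pool request; types never emitted: ",
           paste(missing, collapse = ", "))
  }
  mols
}

#' Generate synthetic pKa records with known ground truth
#'
#' Molecules come from [generateMolecules()]; each record's pKa is the
#' inner product of the ground-truth coefficients with the site's distance
#' spectrum, plus Gaussian noise of standard deviation `noiseSd`. With
#' `noiseSd = 0` the records are exactly consistent with the prediction
#' equation under the true coefficients, so a subsequent fit must recover
#' them to numerical precision. When the spec supplies no
#' `trueCoefficients`, a coefficient is drawn uniformly from [-15, 15] for
#' every emitted atom-type; types absent from a supplied map contribute 0.
#'
#' With `ensureFullRank = TRUE` (default) additional molecules are
#' appended (same deterministic stream) until the design matrix has full
#' column rank, so coefficient recovery is well posed.
#'
#' @param spec a [SyntheticSpec-class].
#' @param ensureFullRank grow the set until the design has full column
#'   rank (bounded number of attempts).
#' @return list with `records` (list of [PkaRecord-class]),
#'   `trueCoefficients` (named numeric), `molecules` and `spectra`.
#' @export
generateRecords <- function(spec, ensureFullRank = TRUE) {
  validObject(spec)
  .withSeed(spec@seed, {
    mols <- .generateMoleculesRaw(spec@nMolecules, spec@maxAtoms,
                                  spec@ringProb)
    spectra <- lapply(mols, function(m)
      computeDistanceSpectrum(m$molecule, m$site))
    buildX <- function(spectra) {
      types <- sort(unique(unlist(lapply(spectra, function(s)
        names(s@weights)))))
      X <- matrix(0, length(spectra), length(types),
                  dimnames = list(NULL, types))
      for (i in seq_along(spectra))
        X[i, names(spectra[[i]]@weights)] <- spectra[[i]]@weights
      X
    }
    X <- buildX(spectra)
    if (ensureFullRank) {
      # phase 1: append molecules so rows outgrow columns
      attempts <- 0L
      while (qr(X)$rank < ncol(X) && attempts < 6L) {
        extra <- .generateMoleculesRaw(max(25L, spec@nMolecules %/% 5L),
                                       spec@maxAtoms, spec@ringProb,
                                       idOffset = length(mols))
        mols <- c(mols, extra)
        spectra <- c(spectra, lapply(extra, function(m)
          computeDistanceSpectrum(m$molecule, m$site)))
        X <- buildX(spectra)
        attempts <- attempts + 1L
      }
      # phase 2: drop the few records carrying still-deficient columns
      # (rare types whose every occurrence is tied to another rare type);
      # each pass removes at least one column, so this terminates
      repeat {
        q <- qr(X)
        if (q$rank == ncol(X)) break
        bad_cols <- q$pivot[(q$rank + 1L):ncol(X)]
        bad_rows <- which(rowSums(X[, bad_cols, drop = FALSE] > 0) > 0)
        if (!length(bad_rows) || length(bad_rows) >= length(mols))
          stop("could not reach a full-column-rank design; ",
               "increase nMolecules or reduce maxAtoms")
        mols <- mols[-bad_rows]
        spectra <- spectra[-bad_rows]
        X <- buildX(spectra)
      }
    }
    if (length(spec@atomTypePool)) {
      missing <- setdiff(spec@atomTypePool, colnames(X))
      if (length(missing))
        stop("unsatisfiable atom-type pool request; types never emitted: ",
             paste(missing, collapse = ", "))
    }
    tc <- spec@trueCoefficients
    if (!length(tc))
      tc <- stats::setNames(stats::runif(ncol(X), -15, 15), colnames(X))
    alpha <- stats::setNames(rep(0, ncol(X)), colnames(X))
    alpha[intersect(names(tc), colnames(X))] <-
      tc[intersect(names(tc), colnames(X))]
    pka <- drop(X %*% alpha)
    if (spec@noiseSd > 0)
      pka <- pka + stats::rnorm(length(pka), 0, spec@noiseSd)
    records <- lapply(seq_along(mols), function(i)
      pkaRecord(mols[[i]]$molecule, mols[[i]]$site, pka[i],
                provenance = "experimental", sourceTag = "synthetic"))
    list(records = records, trueCoefficients = tc, molecules = mols,
         spectra = spectra)
  })
}

#' Generate a synthetic AIBL congeneric series
#'
#' Bond lengths are drawn uniformly from `lengthRange`; pKa values follow
#' pKa = m*length + c plus Gaussian noise. Deterministic given `seed`.
#'
#' @param m,c slope (pKa per Angstrom) and intercept of the underlying
#'   line.
#' @param n number of points (>= 2).
#' @param lengthRange `c(min, max)` bond-length range in Angstrom.
#' @param noiseSd Gaussian noise standard deviation (pKa units).
#' @param seed RNG seed.
#' @return list with numeric vectors `lengths` and `pkas`.
#' @export
generateAiblSeries <- function(m, c, n, lengthRange = c(1.45, 1.55),
                               noiseSd = 0, seed = 1L) {
  if (n < 2L) stop("n must be >= 2")
  if (length(lengthRange) != 2L || lengthRange[1] >= lengthRange[2])
    stop("degenerate length range")
  .withSeed(seed, {
    lengths <- stats::runif(n, lengthRange[1], lengthRange[2])
    pkas <- m * lengths + c +
      (if (noiseSd > 0) stats::rnorm(n, 0, noiseSd) else 0)
    list(lengths = lengths, pkas = pkas)
  })
}
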