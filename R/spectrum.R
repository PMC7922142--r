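#' Through-bond distances from a source atom
#'
#' Breadth-first shortest path length, counted in bonds over the
#' heavy-atom graph (bond order is ignored: a double bond is one edge).
#' Atoms in other connected components are absent from the result.
#'
#' @param molecule a [MolecularGraph-class].
#' @param source 1-based source atom index.
#' @return named integer vector of distances, names = atom indices of the
#'   source's connected component (the source itself has distance 0).
#' @export
topologicalDistances <- function(molecule, source) {
  n <- nrow(molecule@atoms)
  source <- as.integer(source)
  if (length(source) != 1L || is.na(source) || source < 1L || source > n)
    stop("source atom index out of range: ", source)
  adj <- .adjacency(molecule)
  dist <- rep(NA_integer_, n)
  dist[source] <- 0L
  queue <- source
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    for (w in adj[[v]]) {
      if (is.na(dist[w])) {
        dist[w] <- dist[v] + 1L
        queue <- c(queue, w)
      }
    }
  }
  keep <- which(!is.na(dist))
  stats::setNames(dist[keep], keep)
}

.adjacency <- function(molecule) {
  n <- nrow(molecule@atoms)
  adj <- vector("list", n)
  b <- molecule@bonds
  if (nrow(b) > 0L)
    for (k in seq_len(nrow(b))) {
      adj[[b$from[k]]] <- c(adj[[b$from[k]]], b$to[k])
      adj[[b$to[k]]] <- c(adj[[b$to[k]]], b$from[k])
    }
  adj
}

#' Compute the distance spectrum of an ionisation site
#'
#' Every heavy atom j other than the site, in the site's connected
#' component, contributes 1/d(j)^2 to the entry of j's atom-type, where
#' d(j) is the through-bond distance to the site. The site atom is excluded
#' structurally (its distance is zero), and atoms of disconnected fragments
#' (e.g. counter-ions of a salt form) contribute nothing, the natural limit
#' of 1/d^2 as d grows without bound.
#'
#' @param molecule a [MolecularGraph-class].
#' @param site an [IonisationSite-class] (or a bare atom index, which is
#'   promoted to a carbon-acid site).
#' @return a [DistanceSpectrum-class]. If the site atom is isolated the
#'   spectrum is empty and a warning is raised.
#' @examples
#' m <- molecularGraph(c("C", "C", "O"),
#'                     data.frame(from = c(1, 2), to = c(2, 3), order = 1))
#' computeDistanceSpectrum(m, ionisationSite(1))
#' @export
computeDistanceSpectrum <- function(molecule, site) {
  if (is.numeric(site)) site <- ionisationSite(site)
  s <- site@atomIndex
  if (s > nrow(molecule@atoms))
    stop("site atom index outside molecule: ", s)
  types <- typeAllAtoms(molecule)
  d <- topologicalDistances(molecule, s)
  d <- d[names(d) != as.character(s)]
  if (!length(d)) {
    warning("site atom is isolated; returning an empty spectrum")
    return(new("DistanceSpectrum", weights = stats::setNames(numeric(), character()),
               site = site, moleculeId = molecule@id))
  }
  idx <- as.integer(names(d))
  contrib <- 1 / as.numeric(d)^2
  w <- vapply(split(contrib, types[idx]), sum, numeric(1))
  w <- w[sort(names(w))]
  new("DistanceSpectrum", weights = w, site = site,
      moleculeId = molecule@id)
}

# ---------------------------------------------------------------------------
# Carbon-acid site perception helpers
# ---------------------------------------------------------------------------

# Is atom i a carbonyl carbon (C doubly bonded to O)?
.isCarbonylC <- function(molecule, i) {
  a <- molecule@atoms; b <- molecule@bonds
  if (a$element[i] != "C") return(FALSE)
  hit <- (b$from == i | b$to == i) & b$order == 2L
  any(vapply(which(hit), function(k) {
    j <- if (b$from[k] == i) b$to[k] else b$from[k]
    a$element[j] == "O"
  }, logical(1)))
}

# Is atom i a sulphone sulphur (S with two S=O bonds)?
.isSulphoneS <- function(molecule, i) {
  a <- molecule@atoms; b <- molecule@bonds
  if (a$element[i] != "S") return(FALSE)
  hit <- (b$from == i | b$to == i) & b$order == 2L
  sum(vapply(which(hit), function(k) {
    j <- if (b$from[k] == i) b$to[k] else b$from[k]
    a$element[j] == "O"
  }, logical(1))) >= 2L
}

# Is atom i a nitrile carbon (C triply bonded to N)?
.isNitrileC <- function(molecule, i) {
  a <- molecule@atoms; b <- molecule@bonds
  if (a$element[i] != "C") return(FALSE)
  hit <- (b$from == i | b$to == i) & b$order == 3L
  any(vapply(which(hit), function(k) {
    j <- if (b$from[k] == i) b$to[k] else b$from[k]
    a$element[j] == "N"
  }, logical(1)))
}

.neighbours <- function(molecule, i) {
  b <- molecule@bonds
  c(b$to[b$from == i], b$from[b$to == i])
}

#' Locate candidate carbon-acid sites
#'
#' A convenience matcher for the activated C-H motifs of classic carbon
#' acids: an sp3 carbon bearing at least one hydrogen whose neighbours
#' include at least one activating group, where activating groups are
#' carbonyl carbons (C=O), sulphone sulphurs (S(=O)(=O)) and nitrile
#' carbons (C#N). Sites are primarily user-supplied; this helper covers the
#' common sulphone-carbonyl, nitrile-carbonyl and 1,3-dicarbonyl patterns.
#'
#' @param molecule a [MolecularGraph-class].
#' @param minActivating minimum number of activating neighbours (default 1).
#' @return integer vector of candidate site atom indices (possibly empty).
#' @export
findCarbonAcidSites <- function(molecule, minActivating = 1L) {
  a <- molecule@atoms
  out <- integer()
  for (i in seq_len(nrow(a))) {
    if (a$element[i] != "C" || a$nH[i] < 1L || a$aromatic[i]) next
    nb <- .neighbours(molecule, i)
    nact <- sum(vapply(nb, function(j)
      .isCarbonylC(molecule, j) || .isSulphoneS(molecule, j) ||
        .isNitrileC(molecule, j), logical(1)))
    if (nact >= minActivating) out <- c(out, i)
  }
  out
}

#' Classify the activating motif around a carbon-acid site
#'
#' Labels a site by the activating groups flanking it:
#' `"sulphone-carbonyl"` (sulphone on one side, carbonyl on the other),
#' `"nitrile-carbonyl"`, `"di-carbonyl"` (two carbonyl neighbours), or
#' `"other"`. Used to stratify test-set errors by chemical domain.
#'
#' @param molecule a [MolecularGraph-class].
#' @param atomIndex site atom index.
#' @return single character label.
#' @export
classifySiteMotif <- function(molecule, atomIndex) {
  nb <- .neighbours(molecule, atomIndex)
  has_carbonyl <- vapply(nb, function(j) .isCarbonylC(molecule, j), logical(1))
  has_sulphone <- vapply(nb, function(j) .isSulphoneS(molecule, j), logical(1))
  has_nitrile <- vapply(nb, function(j) .isNitrileC(molecule, j), logical(1))
  if (any(has_sulphone) && any(has_carbonyl)) return("sulphone-carbonyl")
  if (any(has_nitrile) && any(has_carbonyl)) return("nitrile-carbonyl")
  if (sum(has_carbonyl) >= 2L) return("di-carbonyl")
  "other"
}
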