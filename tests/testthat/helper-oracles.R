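# Independent oracles used to cross-check the implementation.

# All-pairs shortest bond-count distances by Floyd-Warshall (Inf between
# components). Deliberately independent of the package's BFS.
floydWarshall <- function(molecule) {
  n <- nrow(atoms(molecule))
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  b <- bonds(molecule)
  for (k in seq_len(nrow(b))) {
    D[b$from[k], b$to[k]] <- 1
    D[b$to[k], b$from[k]] <- 1
  }
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

# Naive spectrum: per-atom loop over Floyd-Warshall distances.
bruteForceSpectrum <- function(molecule, site) {
  D <- floydWarshall(molecule)
  types <- typeAllAtoms(molecule)
  w <- numeric(0)
  for (j in seq_len(nrow(atoms(molecule)))) {
    if (j == site) next
    d <- D[site, j]
    if (!is.finite(d)) next
    t <- types[j]
    w[t] <- (if (t %in% names(w)) w[t] else 0) + 1 / d^2
  }
  w[sort(names(w))]
}

# Normal-equations least squares, the textbook alternative to QR.
normalEquations <- function(X, y) drop(solve(crossprod(X), crossprod(X, y)))

# Apply a permutation to a MolecularGraph: atom i becomes atom perm[i].
permuteGraph <- function(molecule, perm) {
  a <- atoms(molecule)
  b <- bonds(molecule)
  inv <- order(perm)
  a2 <- a[inv, , drop = FALSE]
  rownames(a2) <- NULL
  b2 <- b
  if (nrow(b) > 0L) {
    b2$from <- perm[b$from]
    b2$to <- perm[b$to]
  }
  molecularGraph(a2, b2, id = moleculeId(molecule))
}

# A deterministic batch of synthetic molecules for property-style loops.
synMolecules <- function(n, seed = 101L, maxAtoms = 10L)
  generateMolecules(syntheticSpec(n, maxAtoms = maxAtoms, seed = seed))
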