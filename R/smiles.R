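#' @importClassesFrom ChemmineR SDF SDFset
NULL

# Structure input/output via ChemmineR/OpenBabel.
#
# SMILES and SDF V2000 records are parsed with ChemmineR (OpenBabel
# underneath, kekulized bond orders); aromaticity is taken from ChemmineR
# ring perception, and attached-hydrogen counts are filled in from a simple
# organic valence model (base valence + formal charge - bond-order sum).

# old-style SDF charge codes <-> formal charge
.CHG_FROM_CODE <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L,
                    `5` = -1L, `6` = -2L, `7` = -3L)
.codeFromCharge <- function(q)
  vapply(q, function(x) switch(as.character(x), `3` = 1L, `2` = 2L,
                               `1` = 3L, `-1` = 5L, `-2` = 6L, `-3` = 7L,
                               0L), integer(1))

.VALENCE <- c(C = 4L, N = 3L, O = 2L, S = 2L, F = 1L, Cl = 1L, Br = 1L,
              I = 1L, P = 3L, B = 3L, Si = 4L)

.implicitH <- function(element, charge, bondOrderSum) {
  base <- .VALENCE[element]
  base[is.na(base)] <- 0L
  pmax(0L, as.integer(base) + as.integer(charge) -
         as.integer(bondOrderSum))
}

# Convert one ChemmineR SDF object to a MolecularGraph.
.sdfToGraph <- function(sdf, id) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  n <- nrow(ab)
  if (n < 1L) stop("structure has no atoms")
  element <- sub("_[0-9]+$", "", rownames(ab))
  charge <- if ("C6" %in% colnames(ab)) {
    unname(.CHG_FROM_CODE[as.character(ab[, "C6"])])
  } else rep(0L, n)
  charge[is.na(charge)] <- 0L
  bonds <- if (length(bb) && nrow(bb) > 0L) {
    data.frame(from = as.integer(bb[, 1L]), to = as.integer(bb[, 2L]),
               order = as.integer(bb[, 3L]))
  } else emptyBonds()
  # order-4 ("aromatic") SDF bonds are rare from OpenBabel but legal input
  bonds$order[bonds$order == 4L] <- 1L
  vsum <- integer(n)
  for (k in seq_len(nrow(bonds))) {
    vsum[bonds$from[k]] <- vsum[bonds$from[k]] + bonds$order[k]
    vsum[bonds$to[k]] <- vsum[bonds$to[k]] + bonds$order[k]
  }
  aromatic <- rep(FALSE, n)
  if (nrow(bonds) >= 3L) {
    ri <- tryCatch(ChemmineR::rings(sdf, type = "all", arom = TRUE),
                   error = function(e) NULL)
    if (!is.null(ri) && length(ri$RINGS)) {
      arom_atoms <- unique(unlist(ri$RINGS[ri$AROMATIC]))
      if (length(arom_atoms)) {
        idx <- as.integer(sub("^[A-Za-z]+_", "", arom_atoms))
        aromatic[idx] <- TRUE
      }
    }
  }
  atoms <- data.frame(element = element, charge = charge,
                      aromatic = aromatic,
                      nH = .implicitH(element, charge, vsum))
  molecularGraph(atoms, bonds, id = id)
}

#' Parse SMILES strings into molecular graphs
#'
#' @param smiles character vector of SMILES strings.
#' @param id identifier(s), recycled to the length of `smiles`.
#' @return a single [MolecularGraph-class] when one SMILES is given, else a
#'   list of them. Unparseable SMILES raise an error.
#' @examples
#' \dontrun{parseSmiles("CC(=O)CC(=O)C", id = "acetylacetone")}
#' @export
parseSmiles <- function(smiles, id = NULL) {
  if (is.null(id)) id <- sprintf("mol%d", seq_along(smiles))
  id <- rep_len(as.character(id), length(smiles))
  sdfs <- ChemmineR::smiles2sdf(stats::setNames(smiles, id))
  out <- lapply(seq_along(smiles), function(i)
    .sdfToGraph(sdfs[[i]], id = id[i]))
  if (length(out) == 1L) out[[1L]] else out
}

# Build a ChemmineR SDF object from a MolecularGraph (zero coordinates).
.graphToSdf <- function(molecule) {
  a <- molecule@atoms; b <- molecule@bonds
  n <- nrow(a)
  cols <- c("C1", "C2", "C3", paste0("C", 5:16))
  ab <- matrix(0, nrow = n, ncol = length(cols),
               dimnames = list(paste(a$element, seq_len(n), sep = "_"),
                               cols))
  ab[, "C6"] <- .codeFromCharge(a$charge)
  bb <- if (nrow(b) > 0L) {
    matrix(c(b$from, b$to, b$order), ncol = 3L,
           dimnames = list(NULL, c("C1", "C2", "C3")))
  } else matrix(numeric(), ncol = 3L,
                dimnames = list(NULL, c("C1", "C2", "C3")))
  counts <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                    n, nrow(b))
  new("SDF",
      header = c(Molecule_Name = molecule@id, Source = "pKaSpectra",
                 Comment = "", Counts_Line = counts),
      atomblock = ab, bondblock = bb, datablock = character())
}

#' Write molecular graphs to an SDF (V2000) file
#'
#' Coordinates are written as zeros: the package only ever uses graph
#' topology, never geometry.
#'
#' @param molecules a [MolecularGraph-class] or list of them.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
writeSdf <- function(molecules, path) {
  if (is(molecules, "MolecularGraph")) molecules <- list(molecules)
  sdfs <- lapply(molecules, .graphToSdf)
  ids <- vapply(molecules, moleculeId, character(1))
  sdfset <- new("SDFset", SDF = sdfs, ID = ids)
  ChemmineR::write.SDF(sdfset, file = path)
  invisible(path)
}

#' Read an SDF (V2000) file into molecular graphs
#'
#' @param path SDF file.
#' @return list of [MolecularGraph-class], named by molecule id.
#' @export
readSdf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sdfset <- ChemmineR::read.SDFset(path)
  ids <- ChemmineR::sdfid(sdfset)
  ids[!nzchar(ids)] <- sprintf("mol%d", which(!nzchar(ids)))
  out <- lapply(seq_along(sdfset), function(i)
    .sdfToGraph(sdfset[[i]], id = ids[i]))
  stats::setNames(out, ids)
}

#' Render a molecular graph as a SMILES string
#'
#' @param molecule a [MolecularGraph-class].
#' @return single character SMILES.
#' @export
graphToSmiles <- function(molecule) {
  sdf <- .graphToSdf(molecule)
  smi <- ChemmineR::sdf2smiles(new("SDFset", SDF = list(sdf),
                                   ID = molecule@id))
  unname(as.character(smi))[1]
}
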