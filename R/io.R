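# Tabular and JSON input/output.
#
# CSV dialect: UTF-8, header row required, comma separator, "." decimal.
# The SMILES column is `smiles`; the site column `site_atom_index` is a
# 1-based index into the parsed heavy-atom graph (R convention, stated in
# every reader's documentation).

#' Read molecules from a SMILES CSV or an SDF file
#'
#' For `format = "smiles_csv"` the file must have a `smiles` column;
#' optional columns are `id`, `site_atom_index` (1-based heavy-atom index)
#' and `pka`. Rows whose SMILES fails to parse, or whose site index is out
#' of range, are skipped with a logged reason, never silently dropped; a
#' file with zero parseable rows is an error.
#'
#' @param path input file.
#' @param format `"smiles_csv"` or `"sdf"`.
#' @return list with `entries` (each a list `molecule`, `site` (or NULL),
#'   `pka` (or NA), `id`) and `skipped` (data.frame `id`, `reason`).
#' @export
readMolecules <- function(path, format = c("smiles_csv", "sdf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  entries <- list()
  skipped <- data.frame(id = character(), reason = character())
  skip <- function(id, why)
    skipped <<- rbind(skipped, data.frame(id = id, reason = why))
  if (format == "smiles_csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!"smiles" %in% names(df)) stop("missing required column 'smiles'")
    if (!"id" %in% names(df)) df$id <- sprintf("row%d", seq_len(nrow(df)))
    for (i in seq_len(nrow(df))) {
      mol <- tryCatch(parseSmiles(df$smiles[i], id = df$id[i]),
                      error = function(e) NULL)
      if (is.null(mol)) { skip(df$id[i], "unparseable SMILES"); next }
      site <- NULL
      if ("site_atom_index" %in% names(df) &&
          !is.na(df$site_atom_index[i])) {
        si <- as.integer(df$site_atom_index[i])
        if (si < 1L || si > length(mol)) {
          skip(df$id[i], sprintf("site index %d out of range (1..%d)",
                                 si, length(mol)))
          next
        }
        site <- ionisationSite(si)
      }
      pka <- if ("pka" %in% names(df)) as.numeric(df$pka[i]) else NA_real_
      entries[[length(entries) + 1L]] <-
        list(molecule = mol, site = site, pka = pka, id = df$id[i])
    }
  } else {
    mols <- readSdf(path)
    entries <- lapply(mols, function(m)
      list(molecule = m, site = NULL, pka = NA_real_, id = moleculeId(m)))
    names(entries) <- NULL
  }
  if (!length(entries)) stop("zero parseable records in ", path)
  if (nrow(skipped))
    message(nrow(skipped), " row(s) skipped while reading ", path)
  list(entries = entries, skipped = skipped)
}

#' Read training records from CSV
#'
#' Expected columns: `id`, `smiles`, `site_atom_index` (1-based), `pka`;
#' optional `provenance` (default `experimental`) and `source_tag`.
#' When an SDF sidecar written by [writeRecords()] (`<path>.sdf`) is
#' present, molecules are taken from it by id, which preserves the exact
#' atom order the site indices refer to; otherwise the `smiles` column is
#' parsed.
#'
#' @param path CSV file in the training dialect.
#' @return list with `records` (list of [PkaRecord-class]) and `skipped`
#'   (data.frame `id`, `reason`).
#' @export
readRecords <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "smiles", "site_atom_index", "pka")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  if (!"provenance" %in% names(df)) df$provenance <- "experimental"
  if (!"source_tag" %in% names(df)) df$source_tag <- ""
  sidecar <- paste0(path, ".sdf")
  sideMols <- if (file.exists(sidecar)) readSdf(sidecar) else NULL
  records <- list()
  skipped <- data.frame(id = character(), reason = character())
  for (i in seq_len(nrow(df))) {
    mol <- if (!is.null(sideMols) && df$id[i] %in% names(sideMols)) {
      sideMols[[df$id[i]]]
    } else {
      tryCatch(parseSmiles(df$smiles[i], id = df$id[i]),
               error = function(e) NULL)
    }
    if (is.null(mol)) {
      skipped <- rbind(skipped, data.frame(id = df$id[i],
                                           reason = "unparseable SMILES"))
      next
    }
    si <- as.integer(df$site_atom_index[i])
    if (si < 1L || si > length(mol) || !is.finite(df$pka[i])) {
      skipped <- rbind(skipped, data.frame(
        id = df$id[i], reason = "invalid site index or pKa"))
      next
    }
    records[[length(records) + 1L]] <-
      pkaRecord(mol, ionisationSite(si), df$pka[i],
                provenance = df$provenance[i],
                sourceTag = df$source_tag[i])
  }
  if (!length(records)) stop("zero parseable records in ", path)
  if (nrow(skipped))
    message(nrow(skipped), " row(s) skipped while reading ", path)
  list(records = records, skipped = skipped)
}

#' Write training records to CSV (plus an SDF sidecar)
#'
#' The CSV carries a SMILES rendering for human inspection, but because a
#' canonical SMILES may renumber atoms, the exact graphs (and the atom
#' order the `site_atom_index` column refers to) are written to an SDF
#' sidecar at `<path>.sdf`. [readRecords()] uses the sidecar when present,
#' making the write/read round trip exact.
#'
#' @param records list of [PkaRecord-class].
#' @param path output CSV.
#' @return invisibly, `path`.
#' @export
writeRecords <- function(records, path) {
  df <- data.frame(
    id = vapply(records, function(r) r@molecule@id, character(1)),
    smiles = vapply(records, function(r) graphToSmiles(r@molecule),
                    character(1)),
    site_atom_index = vapply(records, function(r) r@site@atomIndex,
                             integer(1)),
    pka = sprintf("%.17g", vapply(records, function(r) r@pka, numeric(1))),
    provenance = vapply(records, function(r) r@provenance, character(1)),
    source_tag = vapply(records, function(r) r@sourceTag, character(1)))
  utils::write.csv(df, path, row.names = FALSE)
  writeSdf(lapply(records, function(r) r@molecule), paste0(path, ".sdf"))
  invisible(path)
}

#' Persist a coefficient model as JSON
#'
#' Coefficients are written at full double precision, so a write/read
#' round trip reproduces predictions bit-for-bit. The typing scheme
#' version is stored and checked on use.
#'
#' @param model a [CoefficientModel-class].
#' @param path output JSON file.
#' @return invisibly, `path`.
#' @export
writeModel <- function(model, path) {
  doc <- list(
    typing_scheme_version = model@typingSchemeVersion,
    coefficients = unname(Map(function(code, a) list(code, a),
                              names(model@coefficients),
                              unname(model@coefficients))),
    intercept = model@intercept,
    r_squared = model@rSquared,
    n_records = model@nRecords,
    n_atom_types = model@nAtomTypes,
    deficient_types = as.list(model@deficientTypes))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Read a coefficient model from JSON
#'
#' @param path JSON file written by [writeModel()]. A missing or malformed
#'   field raises a schema error naming the offending field.
#' @return a [CoefficientModel-class].
#' @export
readModel <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  doc <- tryCatch(jsonlite::read_json(path),
                  error = function(e)
                    stop("corrupt model file: ", conditionMessage(e)))
  for (field in c("typing_scheme_version", "coefficients", "r_squared",
                  "n_records", "n_atom_types"))
    if (is.null(doc[[field]]))
      stop("model schema error: missing field '", field, "'")
  codes <- vapply(doc$coefficients, function(p) {
    if (length(p) != 2L)
      stop("model schema error: malformed entry in 'coefficients'")
    as.character(p[[1L]])
  }, character(1))
  alphas <- vapply(doc$coefficients, function(p) as.numeric(p[[2L]]),
                   numeric(1))
  new("CoefficientModel",
      coefficients = stats::setNames(alphas, codes),
      intercept = if (is.null(doc$intercept)) 0 else
        as.numeric(doc$intercept),
      rSquared = as.numeric(doc$r_squared),
      nRecords = as.integer(doc$n_records),
      nAtomTypes = as.integer(doc$n_atom_types),
      typingSchemeVersion = as.character(doc$typing_scheme_version),
      deficientTypes = as.character(unlist(doc$deficient_types)))
}

#' Read an AIBL training table
#'
#' Expected columns: `id`, `bond_label`, `bond_length_angstrom`, `pka`;
#' optional `group_label`.
#'
#' @param path CSV file.
#' @return data.frame.
#' @export
readAiblTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "bond_label", "bond_length_angstrom", "pka")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  if (!"group_label" %in% names(df)) df$group_label <- "all"
  df
}

#' Write predictions to CSV
#'
#' Columns: `id`, `site_atom_index`, `pka_pred`, `in_domain`,
#' `missing_atom_types` (semicolon-separated codes).
#'
#' @param ids character vector of molecule ids.
#' @param predictions aligned list of [PkaPrediction-class].
#' @param path output CSV.
#' @return invisibly, `path`.
#' @export
writePredictions <- function(ids, predictions, path) {
  df <- data.frame(
    id = ids,
    site_atom_index = vapply(predictions, function(p) p@siteIndex,
                             integer(1)),
    pka_pred = vapply(predictions, function(p) p@pka, numeric(1)),
    in_domain = vapply(predictions, function(p) p@inDomain, logical(1)),
    missing_atom_types = vapply(predictions, function(p)
      paste(p@missingAtomTypes, collapse = ";"), character(1)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Persist AIBL models as JSON
#'
#' @param models named list of [AIBLModel-class] (names are group labels).
#' @param path output JSON file.
#' @return invisibly, `path`.
#' @export
writeAiblModels <- function(models, path) {
  doc <- lapply(models, function(m) list(
    slope = m@slope, intercept = m@intercept, bond_label = m@bondLabel,
    r_squared = m@rSquared, length_min = m@lengthRange[1],
    length_max = m@lengthRange[2], group_label = m@groupLabel, n = m@n))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Read AIBL models from JSON
#' @param path JSON written by [writeAiblModels()].
#' @return named list of [AIBLModel-class].
#' @export
readAiblModels <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  doc <- jsonlite::read_json(path)
  lapply(doc, function(d) {
    for (field in c("slope", "intercept", "bond_label", "r_squared",
                    "length_min", "length_max", "group_label", "n"))
      if (is.null(d[[field]]))
        stop("AIBL model schema error: missing field '", field, "'")
    new("AIBLModel", slope = as.numeric(d$slope),
        intercept = as.numeric(d$intercept),
        bondLabel = as.character(d$bond_label),
        rSquared = as.numeric(d$r_squared),
        lengthRange = c(as.numeric(d$length_min),
                        as.numeric(d$length_max)),
        groupLabel = as.character(d$group_label), n = as.integer(d$n))
  })
}

#' Write a validation report as JSON (plus a plain-text summary)
#'
#' @param report named list of validation results (numbers, tables).
#' @param path output JSON path; a `.txt` summary is written alongside.
#' @return invisibly, `path`.
#' @export
writeValidationReport <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  txt <- sub("\\.json$", ".txt", path)
  if (identical(txt, path)) txt <- paste0(path, ".txt")
  lines <- c("pKaSpectra validation report",
             paste0("  ", names(report), ": ",
                    vapply(report, function(x)
                      if (is.data.frame(x))
                        paste0("<table: ", nrow(x), " rows>")
                      else paste(format(unlist(x)), collapse = " "),
                      character(1))))
  writeLines(lines, txt)
  invisible(path)
}
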