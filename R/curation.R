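#' Damped averaging of replicate pKa measurements
#'
#' Collapses a sorted list of replicate measurements into the accepted
#' values. Walking the sorted list, adjacent values whose gap is at most
#' `tolerance` join the current cluster; the k-th value absorbed into a
#' cluster enters the running mean with weight 1/k, so each cluster reduces
#' to its ordinary mean, computed incrementally. Genuinely distinct
#' macro-pKa values (gaps above the tolerance) survive as separate accepted
#' values.
#'
#' @param values numeric vector sorted ascending (an error otherwise).
#' @param tolerance maximum gap (pKa units) merged into one cluster;
#'   default 1.0.
#' @return numeric vector of accepted values, ascending, one per cluster.
#' @examples
#' dampedAverage(c(4.9, 5.0, 5.1))        # 5.0
#' dampedAverage(c(4.0, 4.2, 9.0))        # 4.1 9.0
#' @export
dampedAverage <- function(values, tolerance = 1.0) {
  if (!length(values)) stop("empty value list")
  if (any(!is.finite(values))) stop("non-finite value")
  if (is.unsorted(values)) stop("values must be sorted ascending")
  if (!is.finite(tolerance) || tolerance <= 0)
    stop("tolerance must be > 0")
  accepted <- numeric()
  mean_k <- values[1L]; k <- 1L; last <- values[1L]
  for (v in values[-1L]) {
    if (v - last <= tolerance) {        # absorb into current cluster
      k <- k + 1L
      mean_k <- mean_k + (v - mean_k) / k
    } else {                            # close cluster, start a new one
      accepted <- c(accepted, mean_k)
      mean_k <- v; k <- 1L
    }
    last <- v
  }
  c(accepted, mean_k)
}

#' Greedy assignment of experimental values to ionisation sites
#'
#' Repeatedly picks the globally smallest absolute error between any
#' unassigned experimental value and any unassigned site prediction,
#' records the pair, and removes both, until the experimental values (or
#' the sites) are exhausted. Ties are broken by lower site index, then by
#' lower experimental value. Callers are expected to have filtered
#' compounds to those with one site or with as many sites as experimental
#' values (see [curateTestSet()]).
#'
#' @param experimental numeric vector of accepted experimental pKa values.
#' @param predictions data.frame with columns `siteIndex` and `predicted`.
#' @return data.frame with columns `experimental`, `siteIndex`,
#'   `predicted`, `absError`, in pick order (non-decreasing `absError`).
#' @export
assignValuesToSites <- function(experimental, predictions) {
  stopifnot(is.data.frame(predictions),
            all(c("siteIndex", "predicted") %in% names(predictions)))
  exp_left <- experimental
  pred_left <- predictions
  out <- data.frame(experimental = numeric(), siteIndex = integer(),
                    predicted = numeric(), absError = numeric())
  while (length(exp_left) && nrow(pred_left)) {
    err <- abs(outer(exp_left, pred_left$predicted, "-"))
    # tie-break: among minimal errors prefer lower site index, then lower
    # experimental value
    cand <- which(err == min(err), arr.ind = TRUE)
    ord <- order(pred_left$siteIndex[cand[, 2L]], exp_left[cand[, 1L]])
    ei <- cand[ord[1L], 1L]; pi <- cand[ord[1L], 2L]
    out <- rbind(out, data.frame(
      experimental = exp_left[ei],
      siteIndex = pred_left$siteIndex[pi],
      predicted = pred_left$predicted[pi],
      absError = abs(exp_left[ei] - pred_left$predicted[pi])))
    exp_left <- exp_left[-ei]
    pred_left <- pred_left[-pi, , drop = FALSE]
  }
  out
}

#' Curate a replicate test-set table into training-dialect records
#'
#' Full curation pipeline for a table of possibly replicated experimental
#' measurements: per compound, (i) honour the manual drop-list, (ii) parse
#' the structure, (iii) reduce replicate values by [dampedAverage()],
#' (iv) locate candidate carbon-acid sites and predict each with the given
#' model, (v) keep only compounds with one site or with as many sites as
#' accepted values, and (vi) match values to sites greedily by smallest
#' error ([assignValuesToSites()]). Every rejection is logged with its
#' reason, never silently dropped.
#'
#' @param df data.frame with columns `compound_id`, `smiles`, `pka_value`
#'   (repeated `compound_id` rows are replicates). Alternatively columns
#'   `compound_id`, `molecule` (list of [MolecularGraph-class]),
#'   `pka_value`.
#' @param model a [CoefficientModel-class] used to predict candidate sites.
#' @param tolerance damped-averaging tolerance (pKa units).
#' @param dropList character vector of compound ids to remove (manual
#'   curation hook).
#' @param siteFinder function mapping a [MolecularGraph-class] to the
#'   integer vector of candidate site indices; defaults to
#'   [findCarbonAcidSites()]. Synthetic pipelines with designated sites
#'   can pass their own.
#' @return list with `records` (list of experimental [PkaRecord-class]) and
#'   `rejections` (data.frame `compound_id`, `reason`).
#' @export
curateTestSet <- function(df, model, tolerance = 1.0,
                          dropList = character(),
                          siteFinder = findCarbonAcidSites) {
  stopifnot(all(c("compound_id", "pka_value") %in% names(df)))
  has_smiles <- "smiles" %in% names(df)
  records <- list()
  rejections <- data.frame(compound_id = character(), reason = character())
  reject <- function(id, why)
    rejections <<- rbind(rejections,
                         data.frame(compound_id = id, reason = why))
  for (id in unique(df$compound_id)) {
    rows <- df[df$compound_id == id, , drop = FALSE]
    if (id %in% dropList) { reject(id, "on drop-list"); next }
    mol <- if (has_smiles) {
      tryCatch(parseSmiles(rows$smiles[1L], id = id),
               error = function(e) NULL)
    } else rows$molecule[[1L]]
    if (is.null(mol)) { reject(id, "unparseable structure"); next }
    accepted <- dampedAverage(sort(rows$pka_value), tolerance = tolerance)
    sites <- siteFinder(mol)
    if (!length(sites)) { reject(id, "no candidate carbon-acid site"); next }
    if (length(sites) != 1L && length(sites) != length(accepted)) {
      reject(id, sprintf("site/value count mismatch (%d sites, %d values)",
                         length(sites), length(accepted)))
      next
    }
    preds <- data.frame(
      siteIndex = sites,
      predicted = vapply(sites, function(s)
        predict(model, mol, s)@pka, numeric(1)))
    assigned <- assignValuesToSites(accepted, preds)
    for (k in seq_len(nrow(assigned)))
      records[[length(records) + 1L]] <-
        pkaRecord(mol, ionisationSite(assigned$siteIndex[k]),
                  assigned$experimental[k], provenance = "experimental",
                  sourceTag = "curated")
  }
  list(records = records, rejections = rejections)
}
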