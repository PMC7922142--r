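#' Full validation report for a fitted model
#'
#' Predicts the test records, stratifies RMSE by the activating motif
#' around each site ([classifySiteMotif()]) and by applicability, bins
#' absolute errors and coefficient magnitudes, and (optionally) runs a
#' Y-scrambling check against the training records.
#'
#' @param model a [CoefficientModel-class].
#' @param test list of [PkaRecord-class].
#' @param train optional list of [PkaRecord-class]; required for
#'   Y-scrambling.
#' @param nScramble number of Y-scramble replicates (0 = skip).
#' @param seed RNG seed for the scramble.
#' @return named list (JSON-serialisable) of validation results.
#' @export
validateModel <- function(model, test, train = NULL, nScramble = 0L,
                          seed = 17L) {
  preds <- lapply(test, function(r) predict(model, r@molecule, r@site))
  actual <- vapply(test, function(r) r@pka, numeric(1))
  tags <- vapply(test, function(r)
    classifySiteMotif(r@molecule, r@site@atomIndex), character(1))
  dom <- vapply(preds, inDomain, logical(1))
  strat <- stratifiedRmse(preds, actual, tags)
  report <- list(
    n_test = length(test),
    n_in_domain = sum(dom),
    rmse_all = rmse(vapply(preds, predictedPka, numeric(1)), actual),
    rmse_in_domain = if (any(dom))
      rmse(vapply(preds[dom], predictedPka, numeric(1)), actual[dom])
      else NA,
    stratified_rmse = strat,
    error_bins_all = binCounts(binErrors(preds, actual, "all")),
    error_bins_in_domain = binCounts(binErrors(preds, actual, "inDomain")),
    coefficient_bins = binCounts(binCoefficients(model)),
    model_r_squared = model@rSquared,
    model_n_atom_types = model@nAtomTypes)
  if (nScramble > 0L && !is.null(train)) {
    ys <- yScramble(train, test, nReps = nScramble, seed = seed)
    report$y_scramble <- list(n_reps = nScramble, mean = ys$mean,
                              sd = ys$sd, true_rmse = ys$trueRmse,
                              n_failed = ys$nFailed)
  }
  report
}

.cfgGet <- function(cfg, key, default) {
  v <- cfg
  for (k in strsplit(key, ".", fixed = TRUE)[[1L]]) {
    v <- v[[k]]
    if (is.null(v)) return(default)
  }
  v
}

#' Run the full synthetic pipeline from one configuration
#'
#' End-to-end driver over synthetic fixtures:
#' generate ground-truth records -> curate a replicate table -> train a
#' base model -> fit an AIBL series and generate virtual records ->
#' augment and retrain -> predict a held-out test set -> validate. All
#' intermediate artefacts (CSV/SDF/JSON) are written under the configured
#' output directory, and every source of randomness flows from the
#' configured seed.
#'
#' @param config path to a YAML file, or an equivalent named list.
#'   Recognised keys (all optional): `outdir`, `seed`,
#'   `synth: {n_train, n_test, noise_sd, max_atoms}`,
#'   `curate: {tolerance}`, `aibl: {slope, intercept, n, noise_sd}`,
#'   `validate: {y_scramble}`.
#' @return invisibly, a named list with the fitted models, the validation
#'   report and the paths of all written artefacts.
#' @export
runPipeline <- function(config = list()) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  outdir <- .cfgGet(cfg, "outdir", file.path(tempdir(), "pka-pipeline"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(.cfgGet(cfg, "seed", 1L))
  nTrain <- as.integer(.cfgGet(cfg, "synth.n_train", 120L))
  nTest <- as.integer(.cfgGet(cfg, "synth.n_test", 40L))
  noiseSd <- as.numeric(.cfgGet(cfg, "synth.noise_sd", 0.3))
  maxAtoms <- as.integer(.cfgGet(cfg, "synth.max_atoms", 10L))
  tolerance <- as.numeric(.cfgGet(cfg, "curate.tolerance", 1.0))
  nScramble <- as.integer(.cfgGet(cfg, "validate.y_scramble", 50L))
  paths <- list()
  p <- function(name) { paths[[name]] <<- file.path(outdir, name);
                        paths[[name]] }

  # 1. synthetic ground truth: training set, then a test set generated
  #    from the same true coefficients
  .cliLog("pipeline[1/7] synth: %d train + %d test molecules", nTrain,
          nTest)
  genTrain <- generateRecords(syntheticSpec(nTrain, noiseSd = noiseSd,
                                            maxAtoms = maxAtoms,
                                            seed = seed))
  genTest <- generateRecords(
    syntheticSpec(nTest, noiseSd = noiseSd, maxAtoms = maxAtoms,
                  seed = seed + 1L,
                  trueCoefficients = genTrain$trueCoefficients),
    ensureFullRank = FALSE)
  writeRecords(genTrain$records, p("synthetic_train.csv"))
  writeRecords(genTest$records, p("synthetic_test.csv"))

  # 2. curation: replicate measurements of each training compound are
  #    collapsed by damped averaging and matched back to their site using
  #    a bootstrap model fitted on the raw records
  .cliLog("pipeline[2/7] curate (tolerance %.2f)", tolerance)
  bootModel <- fitCoefficientModel(genTrain$records)
  repl <- do.call(rbind, lapply(genTrain$records, function(r)
    data.frame(compound_id = r@molecule@id,
               pka_value = r@pka + c(-0.05, 0.05))))
  repl$molecule <- rep(lapply(genTrain$records, function(r) r@molecule),
                       each = 2L)
  cur <- curateTestSet(repl, bootModel, tolerance = tolerance,
                       siteFinder = function(mol) 1L)
  utils::write.csv(cur$rejections, p("curation_rejections.csv"),
                   row.names = FALSE)

  # 3. base model on curated records
  baseModel <- fitCoefficientModel(cur$records)
  writeModel(baseModel, p("model_base.json"))
  .cliLog("pipeline[3/7] train: %d curated records, %d atom-types, R^2 = %.4f",
          length(cur$records), baseModel@nAtomTypes, baseModel@rSquared)

  # 4. AIBL local model on a synthetic congeneric series, then virtual
  #    records for fresh molecules with assigned bond lengths
  aiblSlope <- as.numeric(.cfgGet(cfg, "aibl.slope", -80))
  aiblInt <- as.numeric(.cfgGet(cfg, "aibl.intercept", 130))
  aiblN <- as.integer(.cfgGet(cfg, "aibl.n", 24L))
  aiblNoise <- as.numeric(.cfgGet(cfg, "aibl.noise_sd", 0.15))
  series <- generateAiblSeries(aiblSlope, aiblInt, aiblN,
                               noiseSd = aiblNoise, seed = seed + 2L)
  aiblModel <- fitAibl(series$lengths, series$pkas,
                       bondLabel = "C-C carbonyl-to-site",
                       groupLabel = "synthetic_series")
  writeAiblModels(list(synthetic_series = aiblModel),
                  p("aibl_models.json"))
  .cliLog("pipeline[4/7] aibl-fit: r^2 = %.3f over %d points",
          aiblModel@rSquared, aiblModel@n)
  nVirtual <- as.integer(.cfgGet(cfg, "aibl.n_virtual", 30L))
  virtMols <- generateMolecules(syntheticSpec(nVirtual, maxAtoms = maxAtoms,
                                              seed = seed + 3L))
  # The premise of augmentation is that the local model's labels are
  # accurate: each virtual molecule's bond length is the one its
  # ground-truth pKa implies under the fitted line, plus a small
  # geometric perturbation (~0.003 A) playing the role of QM imprecision.
  tc <- genTrain$trueCoefficients
  virtTruePka <- vapply(virtMols, function(m) {
    w <- spectrumWeights(computeDistanceSpectrum(m$molecule, m$site))
    known <- intersect(names(w), names(tc))
    sum(tc[known] * w[known])
  }, numeric(1))
  virtLens <- .withSeed(seed + 4L,
                        (virtTruePka - aiblModel@intercept) /
                          aiblModel@slope +
                          stats::rnorm(nVirtual, 0, 0.003))
  virtInputs <- lapply(seq_len(nVirtual), function(i) {
    mol <- virtMols[[i]]$molecule
    mol@id <- sprintf("virt%04d", i)   # ids distinct from the training set
    list(molecule = mol, site = virtMols[[i]]$site,
         bondLength = virtLens[i])
  })
  gen <- generateVirtualRecords(aiblModel, virtInputs, policy = "allow",
                                sourceTag = "set1_synthetic")
  writeRecords(gen$records, p("virtual_records.csv"))

  # 5-6. augment and retrain
  allRecords <- augmentRecords(cur$records, gen$records)
  fullModel <- fitCoefficientModel(allRecords)
  writeModel(fullModel, p("model_augmented.json"))
  .cliLog("pipeline[5/7] augment: %d -> %d records; [6/7] retrain: %d atom-types, R^2 = %.4f",
          length(cur$records), length(allRecords), fullModel@nAtomTypes,
          fullModel@rSquared)

  # 7. predict the held-out test set and validate
  preds <- lapply(genTest$records, function(r)
    predict(fullModel, r@molecule, r@site))
  writePredictions(vapply(genTest$records, function(r) r@molecule@id,
                          character(1)), preds, p("predictions.csv"))
  report <- validateModel(fullModel, genTest$records, train = allRecords,
                          nScramble = nScramble, seed = seed + 5L)
  writeValidationReport(report, p("validation_report.json"))
  .cliLog("pipeline[7/7] validate: RMSE %.3f (all), %d/%d inDomain",
          report$rmse_all, report$n_in_domain, report$n_test)
  invisible(list(baseModel = baseModel, fullModel = fullModel,
                 aiblModel = aiblModel, report = report, paths = paths))
}
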