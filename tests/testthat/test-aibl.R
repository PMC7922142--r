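test_that("two points define the line exactly", {
  m <- fitAibl(c(1.50, 1.52), c(10.0, 8.0), "C-C carbonyl-to-site", "g1")
  expect_equal(m@slope, -100.0)
  expect_equal(m@intercept, 160.0)
  expect_equal(m@rSquared, 1)
  expect_equal(m@lengthRange, c(1.50, 1.52))
})

test_that("degenerate and constant-response fits behave as specified", {
  expect_error(fitAibl(1.5, 9.0), "degenerate")
  expect_error(fitAibl(c(1.5, 1.5), c(9, 10)), "zero variance")
  flat <- fitAibl(c(1.50, 1.51, 1.52), c(7, 7, 7))
  expect_equal(flat@slope, 0)
  expect_equal(flat@rSquared, 0)
})

test_that("noisy series recover the slope within 3 standard errors", {
  m_true <- -80; c_true <- 130; sigma <- 0.5; n <- 30L
  hits <- 0L
  for (s in 1:100) {
    ser <- generateAiblSeries(m_true, c_true, n, noiseSd = sigma,
                              seed = 1000L + s)
    fit <- fitAibl(ser$lengths, ser$pkas)
    # closed-form OLS slope standard error
    se <- sigma / sqrt(sum((ser$lengths - mean(ser$lengths))^2))
    if (abs(fit@slope - m_true) <= 3 * se) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("both slope signs are handled", {
  neg <- generateAiblSeries(-80, 130, 20, noiseSd = 0, seed = 4L)
  pos <- generateAiblSeries(60, -80, 20, noiseSd = 0, seed = 4L)
  expect_lt(fitAibl(neg$lengths, neg$pkas)@slope, 0)
  expect_gt(fitAibl(pos$lengths, pos$pkas)@slope, 0)
  expect_equal(fitAibl(pos$lengths, pos$pkas)@slope, 60, tolerance = 1e-10)
})

test_that("selectBestBond maximises r2 and matches an exhaustive refit", {
  ser <- generateAiblSeries(-90, 145, 25, noiseSd = 0, seed = 21L)
  set.seed(22)
  candidates <- list(
    "C-C carbonyl-to-site" = ser$lengths,                 # perfect
    "C=O carbonyl" = runif(25, 1.20, 1.25),               # pure noise
    "C-S sulphone" = ser$lengths + rnorm(25, 0, 0.05))    # diluted
  sel <- selectBestBond(candidates, ser$pkas)
  expect_identical(sel$bondLabel, "C-C carbonyl-to-site")
  expect_equal(sel$model@rSquared, 1)
  # exhaustive refit oracle
  r2s <- vapply(names(candidates), function(lab)
    fitAibl(candidates[[lab]], ser$pkas)@rSquared, numeric(1))
  expect_true(all(sel$model@rSquared >= r2s))
  # single candidate returned unconditionally
  one <- selectBestBond(candidates["C=O carbonyl"], ser$pkas)
  expect_identical(one$bondLabel, "C=O carbonyl")
})

test_that("solvent corrections recover exact and noisy affine maps", {
  mixed <- c(4.0, 6.0, 8.0, 10.0)
  ident <- fitSolventCorrection(mixed, mixed, "identity")
  expect_equal(ident@slope, 1)
  expect_equal(ident@intercept, 0, tolerance = 1e-12)
  water <- 0.9 * mixed - 0.5
  corr <- fitSolventCorrection(mixed, water, "95% aqueous ethanol")
  expect_equal(corr@slope, 0.9)
  expect_equal(corr@intercept, -0.5)
  expect_equal(applySolventCorrection(corr, 7), 0.9 * 7 - 0.5)
  set.seed(5)
  mx <- runif(40, 2, 12)
  wt <- 0.85 * mx - 0.3 + rnorm(40, 0, 0.1)
  noisy <- fitSolventCorrection(mx, wt, "aqueous DMSO")
  expect_equal(noisy@slope, 0.85, tolerance = 0.05)
  expect_error(fitSolventCorrection(c(1, 1), c(2, 3)), "degenerate")
})

test_that("virtual record generation is an affine plug-in with range flags", {
  model <- fitAibl(c(1.50, 1.52), c(10.0, 8.0), "C-C", "g1")
  mols <- synMolecules(3, seed = 30L)
  inputs <- lapply(seq_along(mols), function(i)
    list(molecule = mols[[i]]$molecule, site = mols[[i]]$site,
         bondLength = c(1.51, 1.505, 1.60)[i]))
  out <- generateVirtualRecords(model, inputs)
  expect_length(out$records, 3L)
  expect_equal(out$records[[1]]@pka, 9.0)           # -100*1.51 + 160
  expect_identical(out$outOfRange, c(FALSE, FALSE, TRUE))
  expect_identical(out$records[[1]]@provenance, "virtual")
  # strict policy drops the extrapolated input and reports the count
  expect_message(strict <- generateVirtualRecords(model, inputs,
                                                  policy = "strict"),
                 "dropped")
  expect_length(strict$records, 2L)
  expect_identical(strict$nDropped, 1L)
  # solvent correction composes affinely
  corr <- fitSolventCorrection(c(0, 1), c(0.5, 1.4), "etoh")
  outc <- generateVirtualRecords(model, inputs, correction = corr)
  expect_equal(outc$records[[1]]@pka, 0.9 * 9.0 + 0.5)
  # affine shift property: shifting lengths by delta shifts pKa by m*delta
  delta <- 0.004
  shifted <- lapply(inputs, function(x) {
    x$bondLength <- x$bondLength + delta; x })
  outs <- generateVirtualRecords(model, shifted)
  expect_equal(vapply(outs$records, function(r) r@pka, numeric(1)),
               vapply(out$records, function(r) r@pka, numeric(1)) +
                 model@slope * delta)
})

test_that("batch generation preserves the input count under policy allow", {
  model <- fitAibl(c(1.14, 1.18), c(2, 13), "C#N nitrile", "nitrile_full")
  mols <- synMolecules(97, seed = 44L, maxAtoms = 6L)
  set.seed(45)
  lens <- runif(97, 1.10, 1.22)   # some deliberately outside the range
  inputs <- lapply(1:97, function(i)
    list(molecule = mols[[i]]$molecule, site = mols[[i]]$site,
         bondLength = lens[i]))
  out <- generateVirtualRecords(model, inputs, policy = "allow",
                                sourceTag = "set2_nitrile")
  expect_length(out$records, 97L)
  expect_identical(unique(vapply(out$records, function(r) r@sourceTag,
                                 character(1))), "set2_nitrile")
})
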