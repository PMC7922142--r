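# Small hand-built records with controlled spectra: a C-C-X chain whose
# site sees a shared middle-carbon type plus one X-specific terminal type.
chainRecord <- function(x, pka, id) {
  m <- molecularGraph(c("C", "C", x),
                      data.frame(from = c(1, 2), to = c(2, 3), order = 1),
                      id = id)
  pkaRecord(m, ionisationSite(1), pka)
}

test_that("the design matrix aligns rows, columns and zeros as expected", {
  r1 <- chainRecord("O", 5, "r1")
  r2 <- chainRecord("S", 7, "r2")
  fm <- buildFeatureMatrix(list(r1, r2))
  expect_identical(dim(fm$X), c(2L, 3L))
  expect_identical(fm$y, c(5, 7))
  expect_identical(rowSums(fm$X == 0), c(1, 1))  # one private type each
  # duplicated records give duplicated rows
  fm2 <- buildFeatureMatrix(list(r1, r1))
  expect_identical(fm2$X[1, ], fm2$X[2, ])
  expect_error(buildFeatureMatrix(list()), "no records")
})

test_that("matrix column sums equal brute-force per-type accumulation", {
  gen <- generateRecords(syntheticSpec(100, seed = 31L),
                         ensureFullRank = FALSE)
  fm <- buildFeatureMatrix(gen$records)
  acc <- numeric(0)
  for (r in gen$records) {
    w <- bruteForceSpectrum(r@molecule, siteIndex(r@site))
    for (t in names(w)) acc[t] <- (if (t %in% names(acc)) acc[t] else 0) + w[[t]]
  }
  expect_equal(colSums(fm$X), acc[colnames(fm$X)])
})

test_that("a single one-type record solves exactly to alpha = pka/weight", {
  two <- molecularGraph(c("C", "C"),
                        data.frame(from = 1, to = 2, order = 1))
  rec <- pkaRecord(two, ionisationSite(1), 12.5)
  model <- fitCoefficientModel(list(rec))
  expect_identical(nAtomTypes(model), 1L)
  expect_equal(unname(coefficients(model)), 12.5)  # weight is exactly 1
})

test_that("noiseless synthetic coefficients are recovered to 1e-8", {
  gen <- generateRecords(syntheticSpec(150, noiseSd = 0, seed = 13L))
  model <- fitCoefficientModel(gen$records)
  expect_lt(max(abs(coefficients(model)[names(gen$trueCoefficients)] -
                      gen$trueCoefficients)), 1e-8)
  expect_equal(rSquared(model), 1)
  # consistency: every training record is reproduced
  for (r in gen$records[seq(1, length(gen$records), by = 25)])
    expect_lt(abs(predictedPka(predict(model, r@molecule, r@site)) -
                    r@pka), 1e-8)
})

test_that("QR solve matches a normal-equations oracle on random systems", {
  set.seed(99)
  for (rep in 1:20) {
    X <- matrix(rnorm(50 * 10), 50, 10,
                dimnames = list(NULL, sprintf("t%02d", 1:10)))
    y <- rnorm(50)
    model <- solveCoefficients(abs(X), y)   # spectra are non-negative
    oracle <- normalEquations(abs(X), y)
    expect_lt(max(abs(unname(coefficients(model)) - oracle)) /
                max(abs(oracle)), 1e-6)
  }
})

test_that("prediction is the inner product, with zero for unknown types", {
  model <- solveCoefficients(matrix(1.5, 1, 1, dimnames = list(NULL, "T")),
                             6.0)  # alpha = 4
  spec1 <- new("DistanceSpectrum", weights = c(T = 1.5),
               site = ionisationSite(1), moleculeId = "x")
  p1 <- predictFromSpectrum(model, spec1)
  expect_equal(predictedPka(p1), 6.0)
  expect_true(inDomain(p1))
  spec2 <- new("DistanceSpectrum", weights = c(T = 1.0, U = 2.0),
               site = ionisationSite(1), moleculeId = "y")
  p2 <- predictFromSpectrum(model, spec2)
  expect_equal(predictedPka(p2), 4.0)
  expect_false(inDomain(p2))
  expect_identical(missingAtomTypes(p2), "U")
  empty <- new("DistanceSpectrum",
               weights = stats::setNames(numeric(), character()),
               site = ionisationSite(1), moleculeId = "z")
  expect_error(predictFromSpectrum(model, empty), "empty spectrum")
})

test_that("refitting identical input is bit-identical", {
  gen <- generateRecords(syntheticSpec(60, noiseSd = 0.3, seed = 3L),
                         ensureFullRank = FALSE)
  m1 <- fitCoefficientModel(gen$records)
  m2 <- fitCoefficientModel(gen$records)
  expect_identical(coefficients(m1), coefficients(m2))
  expect_identical(rSquared(m1), rSquared(m2))
})

test_that("augmentation preserves order, provenance and grows the type set", {
  base <- lapply(1:3, function(i) chainRecord("O", i, paste0("b", i)))
  virt <- lapply(1:2, function(i) {
    r <- chainRecord("S", i + 10, paste0("v", i))
    pkaRecord(r@molecule, r@site, r@pka, provenance = "virtual",
              sourceTag = "set1")
  })
  all <- augmentRecords(base, virt)
  expect_length(all, 5L)
  expect_identical(vapply(all, function(r) r@provenance, character(1)),
                   c(rep("experimental", 3), rep("virtual", 2)))
  # the sulphur terminal type is new: exactly one extra coefficient
  m0 <- fitCoefficientModel(base)
  m1 <- fitCoefficientModel(all)
  expect_identical(nAtomTypes(m1), nAtomTypes(m0) + 1L)
  expect_true(all(names(coefficients(m0)) %in% names(coefficients(m1))))
  # empty augmentation changes nothing, bit for bit
  m2 <- fitCoefficientModel(augmentRecords(base, list()))
  expect_identical(coefficients(m2), coefficients(m0))
  # provenance and tags are enforced
  expect_error(augmentRecords(base, base), "provenance 'virtual'")
  expect_warning(augmentRecords(base, list(pkaRecord(
    base[[1]]@molecule, base[[1]]@site, 1, "virtual", "dup"))),
    "duplicate molecule-site")
})

test_that("adding records never flips an in-domain spectrum out of domain", {
  gen <- generateRecords(syntheticSpec(40, seed = 8L),
                         ensureFullRank = FALSE)
  base <- gen$records[1:30]
  extra <- lapply(gen$records[31:40], function(r)
    pkaRecord(r@molecule, r@site, r@pka, "virtual", "extra"))
  m0 <- fitCoefficientModel(base)
  m1 <- fitCoefficientModel(augmentRecords(base, extra))
  probes <- synMolecules(10, seed = 9L)
  for (pr in probes) {
    p0 <- predict(m0, pr$molecule, pr$site)
    p1 <- predict(m1, pr$molecule, pr$site)
    if (inDomain(p0)) expect_true(inDomain(p1))
  }
})
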