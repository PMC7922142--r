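mkPred <- function(pka, dom = TRUE, site = 1L)
  new("PkaPrediction", pka = pka, inDomain = dom,
      missingAtomTypes = if (dom) character() else "999999",
      siteIndex = site)

test_that("rmse matches closed forms and a direct loop", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(3, 4), c(0, 0)), sqrt(25 / 2))
  set.seed(2)
  p <- rnorm(50); a <- rnorm(50)
  expect_equal(rmse(p, a), sqrt(sum((p - a)^2) / 50))
  expect_error(rmse(1:3, 1:2), "same length")
})

test_that("stratified RMSE matches a hand-computed fixture", {
  preds <- list(mkPred(5.0), mkPred(6.0), mkPred(20.0, dom = FALSE),
                mkPred(8.0))
  actual <- c(5.5, 6.0, 10.0, 9.0)
  tags <- c("sulphone-carbonyl", "sulphone-carbonyl", "other", "other")
  tab <- stratifiedRmse(preds, actual, tags)
  get <- function(tag, scope)
    tab$rmse[tab$tag == tag & tab$scope == scope]
  expect_equal(get("sulphone-carbonyl", "all"), sqrt(mean(c(0.25, 0))))
  expect_equal(get("other", "all"), sqrt(mean(c(100, 1))))
  expect_equal(get("other", "inDomain"), 1)     # huge error was out of domain
  expect_equal(get("overall", "all"), rmse(c(5, 6, 20, 8), actual))
  expect_lt(get("overall", "inDomain"), get("overall", "all"))
  # single stratum, all in-domain: table equals plain rmse
  tab2 <- stratifiedRmse(preds[1:2], actual[1:2], c("x", "x"))
  expect_equal(tab2$rmse[tab2$tag == "x" & tab2$scope == "all"],
               rmse(c(5, 6), actual[1:2]))
  # empty strata are absent, not zero
  expect_false("inDomain" %in% tab$scope[tab$tag == "nitrile-carbonyl"])
})

test_that("error bins implement left-closed right-open intervals", {
  preds <- lapply(c(0.5, 1.5, 2.5, 3.5), mkPred)
  bins <- binErrors(preds, rep(0, 4))
  expect_identical(unname(bins@counts), rep(1L, 4))
  allgood <- binErrors(lapply(rep(7, 5), mkPred), rep(7, 5))
  expect_identical(unname(allgood@counts), c(5L, 0L, 0L, 0L))
  # exact boundaries fall into the right-hand bin
  edge <- binErrors(lapply(c(1, 2, 3), mkPred), rep(0, 3))
  expect_identical(unname(edge@counts), c(0L, 1L, 1L, 1L))
})

test_that("bin counts always partition n (errors and coefficients)", {
  set.seed(41)
  for (rep in 1:25) {
    n <- sample(1:40, 1)
    e <- runif(n, 0, 4)
    preds <- lapply(e, function(x) mkPred(x, dom = runif(1) > 0.3))
    bins <- binErrors(preds, rep(0, n))
    expect_identical(sum(bins@counts), bins@n)
    expect_identical(bins@n, n)
    # brute-force classifier oracle
    expect_identical(unname(bins@counts),
                     c(sum(e < 1), sum(e >= 1 & e < 2),
                       sum(e >= 2 & e < 3), sum(e >= 3)) |> as.integer())
    binsd <- binErrors(preds, rep(0, n), scope = "inDomain")
    expect_identical(sum(binsd@counts), binsd@n)
    k <- sample(1:30, 1)
    cf <- runif(k, -45, 45)
    model <- new("CoefficientModel",
                 coefficients = stats::setNames(cf, sprintf("t%d", 1:k)),
                 intercept = 0, rSquared = 0.5, nRecords = 10L,
                 nAtomTypes = k, typingSchemeVersion = typingSchemeVersion(),
                 deficientTypes = character())
    cb <- binCoefficients(model)
    expect_identical(sum(cb@counts), k)
    expect_identical(unname(cb@counts),
                     c(sum(abs(cf) < 10), sum(abs(cf) >= 10 & abs(cf) < 20),
                       sum(abs(cf) >= 20 & abs(cf) < 30),
                       sum(abs(cf) >= 30)) |> as.integer())
  }
  probe <- new("CoefficientModel",
               coefficients = c(a = 5, b = -15, c = 25, d = -40),
               intercept = 0, rSquared = 1, nRecords = 4L, nAtomTypes = 4L,
               typingSchemeVersion = typingSchemeVersion(),
               deficientTypes = character())
  expect_identical(unname(binCoefficients(probe)@counts), rep(1L, 4))
})

test_that("y-scrambling with the identity permutation reproduces the model", {
  gen <- generateRecords(syntheticSpec(50, noiseSd = 0.3, seed = 14L),
                         ensureFullRank = FALSE)
  train <- gen$records[1:35]; test <- gen$records[36:50]
  ys <- yScramble(train, test, nReps = 3, seed = 5L,
                  .permutation = seq_along(train))
  expect_equal(ys$rmses, rep(ys$trueRmse, 3))
})

test_that("scrambling a constant response changes nothing", {
  gen <- generateRecords(syntheticSpec(30, seed = 16L),
                         ensureFullRank = FALSE)
  const <- lapply(gen$records[1:20], function(r)
    pkaRecord(r@molecule, r@site, 7.0))
  test <- lapply(gen$records[21:30], function(r)
    pkaRecord(r@molecule, r@site, 7.0))
  ys <- yScramble(const, test, nReps = 5, seed = 2L)
  expect_equal(ys$rmses, rep(ys$trueRmse, 5))
  expect_equal(ys$sd, 0)
})

test_that("on data with signal, scrambled models are consistently worse", {
  gen <- generateRecords(syntheticSpec(120, noiseSd = 0.3, seed = 18L))
  n <- length(gen$records)
  train <- gen$records[seq_len(n - 30)]
  test <- gen$records[seq(n - 29, n)]
  ys <- yScramble(train, test, nReps = 50, seed = 7L)
  expect_gte(mean(ys$rmses > ys$trueRmse, na.rm = TRUE), 0.99)
  expect_gt(ys$mean, ys$trueRmse)
  # determinism: rerun reproduces the replicate list exactly
  ys2 <- yScramble(train, test, nReps = 50, seed = 7L)
  expect_identical(ys$rmses, ys2$rmses)
  # different seed, different replicates
  ys3 <- yScramble(train, test, nReps = 50, seed = 8L)
  expect_false(identical(ys$rmses, ys3$rmses))
})
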