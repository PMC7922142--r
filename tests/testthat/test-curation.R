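test_that("damped averaging collapses clusters to incremental means", {
  expect_equal(dampedAverage(5.0), 5.0)
  expect_equal(dampedAverage(c(4.9, 5.0, 5.1)), 5.0)
  expect_equal(dampedAverage(c(4.0, 4.2, 9.0)), c(4.1, 9.0))
  # incremental mean == ordinary cluster mean, order of absorption fixed
  v <- c(3.0, 3.4, 3.9, 8.0, 8.6)
  expect_equal(dampedAverage(v), c(mean(c(3.0, 3.4, 3.9)),
                                   mean(c(8.0, 8.6))))
  expect_error(dampedAverage(c(5, 4)), "sorted")
  expect_error(dampedAverage(numeric()), "empty")
  expect_error(dampedAverage(5, tolerance = 0), "tolerance")
})

test_that("damped averaging limits: huge tolerance, tiny tolerance", {
  set.seed(12)
  for (rep in 1:20) {
    v <- sort(round(runif(sample(1:8, 1), 0, 12), 2))
    out <- dampedAverage(v)
    expect_lte(length(out), length(v))
    expect_true(all(out >= min(v) & out <= max(v)))
    expect_false(is.unsorted(out))
    expect_equal(dampedAverage(v, tolerance = 1e9), mean(v))
    expect_equal(dampedAverage(v, tolerance = 1e-9), unique(v))
  }
})

test_that("greedy site assignment picks globally smallest errors first", {
  one <- assignValuesToSites(5.0, data.frame(siteIndex = 3L,
                                             predicted = 4.8))
  expect_equal(one$absError, 0.2)
  expect_identical(one$siteIndex, 3L)
  duo <- assignValuesToSites(c(5.0, 11.0),
                             data.frame(siteIndex = c(2L, 7L),
                                        predicted = c(10.5, 5.5)))
  expect_identical(duo$siteIndex[duo$experimental == 5.0], 7L)
  expect_identical(duo$siteIndex[duo$experimental == 11.0], 2L)
  # matches exhaustive enumeration of both complete matchings
  err_greedy <- sum(duo$absError)
  err_other <- abs(5.0 - 10.5) + abs(11.0 - 5.5)
  expect_lt(err_greedy, err_other)
  # tie broken by the lower site index
  tie <- assignValuesToSites(5.0, data.frame(siteIndex = c(1L, 2L),
                                             predicted = c(4.0, 6.0)))
  expect_identical(tie$siteIndex, 1L)
})

test_that("assignment errors are non-decreasing and site order is irrelevant", {
  set.seed(33)
  for (rep in 1:15) {
    k <- sample(2:5, 1)
    exp_v <- round(runif(k, 0, 14), 2)
    preds <- data.frame(siteIndex = sample(1:20, k),
                        predicted = round(runif(k, 0, 14), 2))
    a1 <- assignValuesToSites(exp_v, preds)
    expect_false(is.unsorted(a1$absError))
    shuffle <- preds[sample(k), , drop = FALSE]
    a2 <- assignValuesToSites(exp_v, shuffle)
    expect_equal(a1[order(a1$siteIndex), ], a2[order(a2$siteIndex), ],
                 ignore_attr = TRUE)
  }
})

test_that("the curation pipeline reproduces a hand-worked fixture", {
  # model fitted on three chain molecules so their sites predict exactly
  mk <- function(x, id) molecularGraph(
    c("C", "C", x), data.frame(from = c(1, 2), to = c(2, 3), order = 1),
    id = id)
  train <- list(pkaRecord(mk("O", "t1"), ionisationSite(1), 5.0),
                pkaRecord(mk("S", "t2"), ionisationSite(1), 9.0),
                pkaRecord(mk("N", "t3"), ionisationSite(1), 12.0))
  model <- fitCoefficientModel(train)
  df <- data.frame(
    compound_id = c("a", "a", "a", "b", "drop_me", "c", "c", "c"),
    pka_value = c(4.9, 5.0, 5.1, 9.2, 1.0, 2.0, 6.0, 11.0))
  df$molecule <- c(list(mk("O", "a")), list(mk("O", "a")),
                   list(mk("O", "a")), list(mk("S", "b")),
                   list(mk("O", "drop_me")), list(mk("N", "c")),
                   list(mk("N", "c")), list(mk("N", "c")))
  out <- curateTestSet(df, model, tolerance = 1.0,
                       dropList = "drop_me",
                       siteFinder = function(m) 1L)
  # a: replicates collapse to 5.0, single site -> one record
  # b: single value, single site
  # c: three distinct values but one site -> count mismatch is fine for
  #    one-site compounds: greedy assigns the closest value only
  ids <- vapply(out$records, function(r) r@molecule@id, character(1))
  pkas <- vapply(out$records, function(r) r@pka, numeric(1))
  expect_equal(pkas[ids == "a"], 5.0)
  expect_equal(pkas[ids == "b"], 9.2)
  expect_length(pkas[ids == "c"], 1L)   # closest to the prediction (12.0)
  expect_equal(pkas[ids == "c"], 11.0)
  expect_identical(out$rejections$compound_id, "drop_me")
  expect_identical(out$rejections$reason, "on drop-list")
})

test_that("compounds with mismatched site/value counts are rejected with a reason", {
  two_site <- parseSmiles("CC(=O)CC(=O)CC(=O)C", id = "mism")
  expect_length(findCarbonAcidSites(two_site, minActivating = 2L), 2L)
  model <- fitCoefficientModel(list(
    pkaRecord(two_site, ionisationSite(4), 6.0)))
  df <- data.frame(compound_id = rep("mism", 3),
                   pka_value = c(3.0, 6.0, 10.5))
  df$molecule <- rep(list(two_site), 3)
  out <- curateTestSet(df, model, tolerance = 1.0,
                       siteFinder = function(m)
                         findCarbonAcidSites(m, minActivating = 2L))
  expect_length(out$records, 0L)
  expect_match(out$rejections$reason, "mismatch")
})
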