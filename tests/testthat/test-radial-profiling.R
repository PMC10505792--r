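mkRecords <- function(d, v, id = "c1") {
  data.frame(colony_id = id, label = seq_along(d), x_um = d, y_um = 0,
             area_um2 = 50, distance_um = d, median_SMAD23 = v,
             mean_SMAD23 = v)
}

test_that("binning is half-open and constant intensities pass through", {
  p <- radialProfile(mkRecords(c(5, 15, 25), c(5, 5, 5)),
                     binWidth = 10, maxRadius = 30)
  expect_equal(p@binMeans, c(5, 5, 5))
  # a nucleus at exactly a bin edge lands in the upper bin
  p2 <- radialProfile(mkRecords(12, 3), binWidth = 10, maxRadius = 30)
  expect_equal(p2@binCounts, c(0L, 1L, 0L))
  expect_true(is.na(p2@binMeans[1]) && is.na(p2@binMeans[3]))
  p3 <- radialProfile(mkRecords(10, 3), binWidth = 10, maxRadius = 30)
  expect_equal(p3@binCounts, c(0L, 1L, 0L))
  # beyond max radius: excluded and tallied
  p4 <- radialProfile(mkRecords(c(5, 99), c(1, 9)), binWidth = 10,
                      maxRadius = 30)
  expect_equal(p4@overflow, 1L)
  expect_equal(sum(p4@binCounts), 1L)
  expect_error(radialProfile(mkRecords(1, 1)[0, ]), "no nucleus")
})

test_that("normalization divides by the max, exactly and idempotently", {
  p <- radialProfile(mkRecords(c(5, 15, 25), c(2, 4, 8)),
                     binWidth = 10, maxRadius = 30)
  np <- normalizeProfile(p)
  expect_identical(np@binMeans, c(0.25, 0.5, 1))
  expect_true(isNormalized(np))
  expect_identical(normalizeProfile(np)@binMeans, np@binMeans)
  one <- normalizeProfile(radialProfile(mkRecords(5, 7), binWidth = 10,
                                        maxRadius = 10))
  expect_identical(one@binMeans, 1)
  neg <- radialProfile(mkRecords(5, -3), binWidth = 10, maxRadius = 10)
  expect_error(normalizeProfile(neg), "not positive")
})

test_that("profiles are invariant to record order and to rescaling after normalization", {
  set.seed(61)
  d <- runif(200, 0, 240); v <- runif(200, 10, 200)
  p1 <- radialProfile(mkRecords(d, v))
  perm <- sample(200)
  p2 <- radialProfile(mkRecords(d[perm], v[perm]))
  expect_equal(p1@binMeans, p2@binMeans)
  expect_identical(p1@binCounts, p2@binCounts)
  n1 <- normalizeProfile(p1)
  n3 <- normalizeProfile(radialProfile(mkRecords(d, 37.5 * v)))
  expect_equal(n1@binMeans, n3@binMeans)
  expect_equal(order(n1@binMeans), order(p1@binMeans))  # monotone transform
})

test_that("band summaries follow generator truth", {
  # uniform intensity: center equals edge
  u <- bandSummary(mkRecords(c(15, 20, 180, 200), rep(6, 4)))
  expect_equal(u$center_mean, u$edge_mean)
  # noiseless WT with the whole edge band activated
  lay <- generateColonyLayout(250, 1500, minSeparation = 8, seed = 62)
  ph <- noiselessParams("WT", edgeBandWidth = 75)
  act <- assignActivation(lay, ph, seed = 63)
  rec <- simulateNucleusRecords(lay, act, ph, seed = 64, measSd = 0)
  b <- bandSummary(rec)
  expect_equal(b$center_mean, ph@intensityOff)
  expect_equal(b$edge_mean, ph@intensityOn)
  # KO: uniform activation, center near edge
  ko <- noiselessParams("KO")
  actK <- assignActivation(lay, ko, seed = 65)
  bK <- bandSummary(simulateNucleusRecords(lay, actK, ko, seed = 66))
  expect_lt(abs(bK$center_mean / bK$edge_mean - 1), 0.05)
  # overlapping bands are rejected; empty bands are NA
  expect_error(bandSummary(rec, centerBand = c(10, 180)), "overlap")
  empt <- bandSummary(mkRecords(100, 5))
  expect_true(is.na(empt$center_mean) && is.na(empt$edge_mean))
})

test_that("profile aggregation averages across colonies and flags grid clashes", {
  p1 <- radialProfile(mkRecords(c(5, 15), c(0, 1)), binWidth = 10, maxRadius = 20)
  p2 <- radialProfile(mkRecords(c(5, 15), c(1, 0)), binWidth = 10, maxRadius = 20)
  agg <- aggregateProfiles(list(p1, p2))
  expect_equal(agg$mean, c(0.5, 0.5))
  expect_equal(agg$n, c(2, 2))
  solo <- aggregateProfiles(list(p1))
  expect_equal(solo$mean, p1@binMeans)
  expect_equal(solo$sd, c(0, 0))
  p3 <- radialProfile(mkRecords(5, 1), binWidth = 5, maxRadius = 20)
  expect_error(aggregateProfiles(list(p1, p3)), "bin grid")
})

test_that("WT mean profiles rise towards the colony edge", {
  ph <- phenotypeParams("WT")
  profs <- lapply(1:15, function(i) {
    lay <- generateColonyLayout(250, 1500, minSeparation = 8, seed = 70 + i)
    act <- assignActivation(lay, ph, seed = 170 + i)
    rec <- simulateNucleusRecords(lay, act, ph, seed = 270 + i,
                                  colonyId = paste0("c", i))
    normalizeProfile(radialProfile(rec))
  })
  agg <- aggregateProfiles(profs)
  outer <- agg$mean[agg$bin_lo >= 200]
  expect_true(all(diff(outer) > -0.01))   # non-decreasing up to band noise
  expect_gt(max(outer), 0.95)
  expect_lt(agg$mean[agg$bin_lo == 100], 0.3)
})
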