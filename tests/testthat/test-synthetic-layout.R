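test_that("poisson-disc layouts honor separation, count and determinism", {
  lay <- generateColonyLayout(250, 2000, minSeparation = 8, seed = 1)
  n <- nucleusCount(lay)
  expect_gte(n, 1900)
  expect_lte(n, 2100)
  # brute-force pairwise check of the non-overlap guarantee
  d <- dist(lay@nucleusCenters)
  expect_gte(min(d), 8)
  r <- sqrt(rowSums(sweep(lay@nucleusCenters, 2, lay@colonyCenter)^2))
  expect_lte(max(r), 250)
  expect_true(all(lay@nucleusRadii >= 3.5 & lay@nucleusRadii <= 4.5))
  lay2 <- generateColonyLayout(250, 2000, minSeparation = 8, seed = 1)
  expect_identical(lay@nucleusCenters, lay2@nucleusCenters)
  expect_identical(lay@nucleusRadii, lay2@nucleusRadii)
})

test_that("degenerate and infeasible layouts are handled explicitly", {
  one <- generateColonyLayout(250, 1, minSeparation = 10, seed = 0)
  expect_equal(nucleusCount(one), 1)
  expect_lte(sqrt(sum((one@nucleusCenters[1, ] - one@colonyCenter)^2)), 250)
  expect_error(generateColonyLayout(10, 500, minSeparation = 10, seed = 0),
               "infeasible packing: at most ~\\d+ nuclei")
})

test_that("activation rules follow the phenotype presets", {
  lay <- generateColonyLayout(250, 1500, minSeparation = 8, seed = 3)
  d <- sqrt(rowSums(sweep(lay@nucleusCenters, 2, lay@colonyCenter)^2))
  wt <- assignActivation(lay, phenotypeParams("WT"), seed = 4)
  interior <- d < 250 - 50
  expect_false(any(wt[interior]))          # p_center = 0
  expect_true(all(wt[!interior]))          # p_edge = 1
  ko <- assignActivation(lay, phenotypeParams("KO"), seed = 4)
  expect_true(all(ko))                     # p = 1 everywhere
  # HET interior fraction tracks p_center
  lay2 <- generateColonyLayout(250, 2000, minSeparation = 8, seed = 5)
  het <- assignActivation(lay2, phenotypeParams("HET"), seed = 6)
  d2 <- sqrt(rowSums(sweep(lay2@nucleusCenters, 2, lay2@colonyCenter)^2))
  fracInterior <- mean(het[d2 < 200])
  expect_lt(abs(fracInterior - 0.4), 0.05)
  # determinism
  expect_identical(het, assignActivation(lay2, phenotypeParams("HET"), seed = 6))
})

test_that("patchy interior activation is spatially clustered", {
  lay <- generateColonyLayout(250, 2000, minSeparation = 8, seed = 7)
  d <- sqrt(rowSums(sweep(lay@nucleusCenters, 2, lay@colonyCenter)^2))
  interior <- d < 200
  patchy <- assignActivation(lay, phenotypeParams("HET"), seed = 8)[interior]
  iid <- assignActivation(lay, phenotypeParams("HET", patchiness = 0),
                          seed = 8)[interior]
  pts <- lay@nucleusCenters[interior, ]
  agree <- function(lab) {
    dm <- as.matrix(dist(pts))
    diag(dm) <- Inf
    nn <- apply(dm, 1, which.min)
    mean(lab == lab[nn])
  }
  p <- 0.4
  iidExpect <- p^2 + (1 - p)^2           # 0.52 for independent labels
  expect_lt(abs(agree(iid) - iidExpect), 0.06)
  expect_gt(agree(patchy), iidExpect + 0.2)
})

test_that("empirical activation fractions converge to the preset rates", {
  # large colony so 5000 nuclei fit at 8 um separation
  lay <- generateColonyLayout(420, 5000, minSeparation = 8, seed = 9)
  ph <- phenotypeParams("HET", pEdge = 0.7, pCenter = 0.3, patchiness = 40,
                        edgeBandWidth = 60)
  act <- assignActivation(lay, ph, seed = 10)
  d <- sqrt(rowSums(sweep(lay@nucleusCenters, 2, lay@colonyCenter)^2))
  edge <- d >= 420 - 60
  expect_lt(abs(mean(act[edge]) - 0.7), 0.03)
  expect_lt(abs(mean(act[!edge]) - 0.3), 0.03)
})

test_that("phenotype presets validate their fields", {
  expect_error(phenotypeParams("WT", pCenter = 1.5), "\\[0, 1\\]")
  expect_error(phenotypeParams("WT", intensityOn = 10, intensityOff = 20),
               "intensityOn")
  expect_error(phenotypeParams("WT", bogus = 1), "unknown")
})
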