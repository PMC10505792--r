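test_that("watershed splits touching nuclei and counts isolated ones", {
  # two discs overlapping by 20% of their radius
  r <- 4
  m <- drawDiscs(40, 40, rbind(c(16, 20), c(16 + 1.8 * r, 20)), c(r, r))
  expect_equal(max(segmentNuclei(m, pixelSize = 1)), 2)
  # one isolated disc: single label, area near pi r^2
  one <- drawDiscs(40, 40, cbind(20, 20), 4.5)
  lab <- segmentNuclei(one, pixelSize = 1)
  expect_equal(max(lab), 1)
  expect_lt(abs(sum(lab == 1) / (pi * 4.5^2) - 1), 0.15)
  # blank image: empty labelling with a warning
  expect_warning(lab0 <- segmentNuclei(matrix(0, 32, 32)), "foreground")
  expect_equal(max(lab0), 0)
})

test_that("the size filter removes debris and logs reasons", {
  m <- drawDiscs(60, 60, rbind(c(15, 15), c(45, 45), c(30, 10)),
                 c(4.5, 4.5, 1))
  lab <- segmentNuclei(m, pixelSize = 1)
  expect_equal(max(lab), 3)
  filt <- filterNuclei(lab, minArea = 30, maxArea = 300, pixelSize = 1)
  expect_equal(max(filt$labels), 2)
  expect_equal(filt$removed$reason, "too-small")
  # all within bounds: identity
  id <- filterNuclei(lab, minArea = 1, maxArea = 300, pixelSize = 1)
  expect_identical(id$labels, lab)
  expect_equal(nrow(id$removed), 0)
  # min above every area: empty labelling
  none <- filterNuclei(lab, minArea = 299, maxArea = 300, pixelSize = 1)
  expect_equal(max(none$labels), 0)
})

test_that("nucleus measurements honour conventions", {
  lab <- matrix(0L, 10, 10)
  lab[3:4, 3:4] <- 1L
  ch <- matrix(0, 10, 10)
  ch[3:4, 3:4] <- c(1, 2, 3, 4)
  rec <- measureNuclei(lab, list(SMAD23 = ch), colonyCenter = c(3, 3))
  expect_equal(rec$median_SMAD23, 2)    # lower median of {1,2,3,4}
  expect_equal(rec$mean_SMAD23, 2.5)
  expect_equal(rec$area_um2, 4)
  expect_equal(rec$x_um, 3); expect_equal(rec$y_um, 3)
  expect_equal(rec$distance_um, 0)      # centered on the colony center
  # constant-intensity nucleus: median equals that value
  ch2 <- matrix(0, 10, 10); ch2[3:4, 3:4] <- 7
  expect_equal(measureNuclei(lab, list(S = ch2), c(0, 0))$median_S, 7)
  expect_error(measureNuclei(lab, list(S = matrix(0, 5, 5)), c(0, 0)),
               "identical shapes")
})

test_that("median intensity is invariant to intensity permutations in the mask", {
  lab <- matrix(0L, 8, 8); lab[2:5, 2:5] <- 1L
  v <- c(5, 1, 9, 3, 7, 2, 8, 6, 4, 10, 11, 13, 12, 16, 15, 14)
  ch <- matrix(0, 8, 8)
  set.seed(1)
  ch[lab == 1L] <- v
  m1 <- measureNuclei(lab, list(S = ch), c(0, 0))$median_S
  ch[lab == 1L] <- sample(v)
  m2 <- measureNuclei(lab, list(S = ch), c(0, 0))$median_S
  expect_identical(m1, m2)
})

test_that("nucleus counts are recovered within five percent on dense colonies", {
  lay <- generateColonyLayout(250, 1800, minSeparation = 8, seed = 51)
  ph <- phenotypeParams("WT")
  s <- renderColonyImage(lay, assignActivation(lay, ph, 52), ph, seed = 53)
  rec <- measureSample(s)
  expect_lt(abs(nrow(rec) / nucleusCount(lay) - 1), 0.05)
})

test_that("activation labels are recovered near-perfectly without noise", {
  lay <- generateColonyLayout(250, 1000, minSeparation = 9, seed = 54)
  ph <- noiselessParams("HET", pCenter = 0.5, patchiness = 0)
  act <- assignActivation(lay, ph, seed = 55)
  s <- renderColonyImage(lay, act, ph, seed = 56)
  rec <- measureSample(s)
  truth <- s@truth
  mid <- (ph@intensityOn + ph@intensityOff) / 2
  # match detected nuclei to truth by nearest centroid
  ok <- 0L
  for (i in seq_len(nrow(rec))) {
    j <- which.min((truth$x_um - rec$x_um[i])^2 + (truth$y_um - rec$y_um[i])^2)
    call <- rec$median_SMAD23[i] > mid
    if (call == truth$activated[j]) ok <- ok + 1L
  }
  expect_gte(ok / nrow(rec), 0.98)
})
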