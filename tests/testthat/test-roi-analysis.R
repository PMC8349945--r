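roiOf <- function(dm, sel) {
  vox <- array(FALSE, dm); vox[sel] <- TRUE
  ROIMask("L1", vox)
}

test_that("ROI means equal brute-force voxel averages", {
  dm <- c(4, 4, 1)
  idx <- new("IndexMap", kind = "I_Df",
             values = array(c(100, 100, 0, 0, rep(0, 12)), dm),
             valid = array(TRUE, dm), cutoff = c(Dprime = 1e-3))
  roi <- roiOf(dm, 1:4)
  expect_equal(roiMean(idx, roi), 50)

  cm <- makeParamMap(array(1.3e-3, dm), "Dprime")
  expect_equal(roiMean(cm, roi), 1.3e-3)

  set.seed(4)
  vals <- sample(c(0, 100), prod(dm), replace = TRUE)
  rnd <- new("IndexMap", kind = "I_D", values = array(vals, dm),
             valid = array(TRUE, dm), cutoff = c(Dprime = 1e-3))
  sel <- sample(prod(dm), 7)
  roi2 <- roiOf(dm, sel)
  cnt <- 0L
  for (i in sel) if (vals[i] == 100) cnt <- cnt + 1L
  expect_equal(roiMean(rnd, roi2), 100 * cnt / 7)
})

test_that("empty analysed sets raise an error naming the lesion", {
  dm <- c(3, 3, 1)
  m <- makeParamMap(array(1e-3, dm), "ADC", valid = array(FALSE, dm))
  expect_error(roiMean(m, roiOf(dm, 1:3)), "L1")
})

test_that("hyperintensity mask isolates bright-lesion voxels", {
  set.seed(2)
  dm <- c(16, 16, 4)
  liver <- 400
  b800 <- array(rnorm(prod(dm), liver, 10), dm)
  lesion <- array(FALSE, dm); lesion[6:9, 6:9, 2] <- TRUE
  b800[lesion] <- 2 * liver
  ref <- array(FALSE, dm); ref[1:4, 1:4, ] <- TRUE

  mask <- hyperintensityMask(b800, ref, kSD = 2)
  expect_true(all(mask[lesion]))

  expect_equal(sum(hyperintensityMask(b800, ref, kSD = Inf)), 0)

  uni <- array(7, dm)
  expect_warning(m0 <- hyperintensityMask(uni, ref), "degenerate")
  expect_equal(sum(m0), 0)
})

test_that("exclusion mask removes the necrotic core but keeps the rim", {
  sc <- buildScene(dim = c(32, 32, 10),
                   lesions = data.frame(class = "metastasis_CRC", radius = 5,
                                        x = 16, y = 16, z = 5, core = TRUE),
                   seed = 20)
  stk <- simulateDWI(sc, sigma = 0)
  b0 <- getVolume(stk, 0); b800 <- getVolume(stk, 800)

  dm <- dim(sc@labels)
  vox <- array(FALSE, dm)
  vox[, , 5] <- sc@labels[, , 5] == 2L
  roi <- ROIMask("met1", vox)
  excl <- exclusionMask(b0, b800, roi, kSD = 2)

  # ground truth: core voxels have the free-fluid parameter signature
  core <- vox & sc@D > 2.5e-3
  rim <- vox & !core
  expect_true(any(core))
  expect_true(all(excl[core]))
  expect_lt(mean(excl[rim]), 0.1)
  expect_true(all(!excl | vox))              # containment: excl subset of ROI

  # lesion without core: nothing excluded on noiseless data
  sc2 <- buildScene(dim = c(24, 24, 8),
                    lesions = data.frame(class = "HCC", radius = 4,
                                         x = 12, y = 12, z = 4),
                    seed = 21, withinLesionCV = 0)
  stk2 <- simulateDWI(sc2, sigma = 0)
  vox2 <- array(FALSE, dim(sc2@labels)); vox2[, , 4] <- sc2@labels[, , 4] == 2L
  excl2 <- exclusionMask(getVolume(stk2, 0), getVolume(stk2, 800),
                         ROIMask("h", vox2), kSD = 2)
  expect_equal(sum(excl2), 0)

  roi3 <- applyExclusion(roi, b0, b800)
  expect_true(any(analysedVoxels(roi3)))
  expect_equal(roi3@exclusion, excl)
})

test_that("quantitative lesion calls follow the published decision rules", {
  cuts <- referenceCutoffs()
  expect_equal(classifyLesion(list(mean_Dprime = 1057e-6,
                                   mean_fprime = 63e-3), cuts), "malignant")
  expect_equal(classifyLesion(list(mean_Dprime = 1580e-6,
                                   mean_fprime = 63e-3), cuts), "benign")
  expect_equal(classifyLesion(list(mean_ADC = 1692e-6), cuts,
                              rule = "adc_mean"), "benign")
  expect_equal(classifyLesion(list(mean_ADC = 1124e-6), cuts,
                              rule = "adc_mean"), "malignant")
  expect_equal(classifyLesion(list(pct_IDf = 76), cuts,
                              rule = "index_pct"), "malignant")
  expect_equal(classifyLesion(list(pct_IDf = 20), cuts,
                              rule = "index_pct"), "benign")
  # tie at the percent cutoff is benign (mirrors the strict-less voxel rule)
  expect_equal(classifyLesion(list(pct_IDf = 50.2), cuts,
                              rule = "index_pct"), "benign")
  expect_equal(classifyLesion(list(pct_IADC = 60), cuts,
                              rule = "iadc_pct"), "malignant")
  expect_error(classifyLesion(list(mean_Dprime = 1e-3), cuts), "mean_fprime")
})

test_that("ROI-mean rule and voxel-wise I_Df agree on homogeneous lesions", {
  cuts <- referenceCutoffs()
  cases <- expand.grid(D = c(1000e-6, 1700e-6), f = c(60e-3, 150e-3))
  dm <- c(5, 5, 1)
  for (i in seq_len(nrow(cases))) {
    dmap <- makeParamMap(array(cases$D[i], dm), "Dprime")
    fmap <- makeParamMap(array(cases$f[i], dm), "fprime")
    idf <- combineDf(binarizeMap(dmap, cuts@cD), binarizeMap(fmap, cuts@cF))
    roi <- roiOf(dm, 1:25)
    byMeans <- classifyLesion(list(mean_Dprime = cases$D[i],
                                   mean_fprime = cases$f[i]), cuts)
    byPct <- classifyLesion(list(pct_IDf = roiMean(idf, roi)), cuts,
                            rule = "index_pct")
    expect_equal(byMeans, byPct)
  }
})

test_that("visual surrogate bands and majority rule behave as documented", {
  expect_equal(as.character(visualSurrogate(100)$rating),
               "definitely_malignant")
  expect_equal(as.character(visualSurrogate(0)$rating), "definitely_benign")
  expect_equal(as.character(visualSurrogate(60)$rating),
               "probably_malignant")
  expect_equal(as.character(visualSurrogate(75)$rating),
               "definitely_malignant")
  expect_equal(as.character(visualSurrogate(50)$rating), "probably_benign")
  expect_equal(as.character(visualSurrogate(25)$rating), "definitely_benign")
  expect_equal(visualSurrogate(50)$call, "benign")
  expect_equal(visualSurrogate(50.1)$call, "malignant")
  expect_error(visualSurrogate(101), "redFraction")

  # rating monotone in red fraction
  lv <- vapply(seq(0, 100, by = 0.5),
               function(x) as.integer(visualSurrogate(x)$rating), integer(1))
  expect_true(all(diff(lv) >= 0))
})
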