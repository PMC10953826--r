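test_that("shape features match closed-form circle and annulus values", {
  lab <- segmentObjects(rasterShape(30), noSmoothParams())
  f <- extractFeatures(lab)
  expect_equal(nrow(f), 1L)
  expect_gt(f$form_factor, 0.95)
  expect_lt(f$form_factor, 1.05)
  expect_lt(f$lumen_ratio, 0.02)
  expect_lt(f$eccentricity, 0.1)
  expect_gt(f$solidity, 0.95)

  # disk area: radius 20 px within 3% of 400 pi
  f20 <- extractFeatures(segmentObjects(rasterShape(20), noSmoothParams()))
  expect_lt(abs(f20$area - 400 * pi) / (400 * pi), 0.03)

  # annulus outer 30 / inner 15: lumen ratio near (15/30)^2 = 0.25
  fa <- extractFeatures(segmentObjects(rasterShape(30, 15), noSmoothParams()))
  expect_gt(fa$lumen_ratio, 0.22)
  expect_lt(fa$lumen_ratio, 0.28)
  expect_lt(fa$form_factor, 0.6)
})

test_that("dimensionless features are stable under linear rescaling", {
  small <- extractFeatures(segmentObjects(rasterShape(14, 7),
                                          noSmoothParams()))
  big <- extractFeatures(segmentObjects(rasterShape(28, 14),
                                        noSmoothParams()))
  for (feat in c("form_factor", "solidity", "eccentricity", "lumen_ratio"))
    expect_lt(abs(small[[feat]] - big[[feat]]), 0.05)
})

test_that("segmentation contracts: inputs, empty images, small objects, borders", {
  expect_error(segmentObjects(array(0, c(4, 4, 2))), "2-D")

  flat <- matrix(500, 256, 256)
  expect_equal(attr(segmentObjects(flat), "nObjects"), 0L)

  # sub-minimum objects are removed
  tiny <- rasterShape(3, size = 64)
  expect_equal(attr(segmentObjects(tiny, noSmoothParams(minObjectArea = 50)),
                    "nObjects"), 0L)

  # border policy: object touching the edge kept by default, dropped on demand
  m <- matrix(0, 128, 128)
  m[1:30, 50:80] <- 20000
  expect_equal(attr(segmentObjects(m, noSmoothParams()), "nObjects"), 1L)
  expect_equal(attr(segmentObjects(m, noSmoothParams(borderPolicy = "drop")),
                    "nObjects"), 0L)

  # two overlapping disks merge into one object (no declumping)
  two <- pmax(rasterShape(15, size = 120), {
    mm <- matrix(0, 120, 120); mm[40:70, 70:100] <- 20000; mm
  })
  expect_equal(attr(segmentObjects(two, noSmoothParams()), "nObjects"), 1L)
})

test_that("label conservation: pixels belong to one object and counts are stable", {
  res <- renderAndAnalyze(41, makeRecord(shiftInh = 40, cytotox = 0))
  labels <- res$labels
  expect_true(all(labels >= 0))
  expect_equal(sort(unique(as.integer(labels[labels > 0]))),
               seq_len(attr(labels, "nObjects")))
  expect_equal(nrow(res$objects), attr(labels, "nObjects"))
})

test_that("rule classifier separates rendered ducts from clusters", {
  # accumulate a mixed labeled benchmark across rendered wells
  objs <- list(); truths <- list()
  for (s in 1:6) {
    res <- renderAndAnalyze(200 + s, makeRecord(shiftInh = 40, cytotox = 0))
    objs[[s]] <- res$objects
    truths[[s]] <- res$truth$true_class[res$match]
  }
  objects <- do.call(rbind, objs)
  trueClass <- unlist(truths)
  expect_gt(length(trueClass), 200)
  expect_gt(min(table(trueClass)), 50)
  acc <- mean(objects$predicted_class == trueClass)
  expect_gte(acc, 0.95)

  # a trained tree does at least as well as chance and close to the rule
  fit <- trainOrganoidClassifier(objects, trueClass)
  pred <- classifyObjects(objects, classifier = fit)
  expect_gte(mean(pred$predicted_class == trueClass), 0.95)
})

test_that("classifier input contracts", {
  f <- extractFeatures(segmentObjects(rasterShape(30, 15), noSmoothParams()))
  expect_equal(classifyObjects(f)$predicted_class, "duct")
  fc <- extractFeatures(segmentObjects(rasterShape(10), noSmoothParams()))
  expect_equal(classifyObjects(fc)$predicted_class, "cluster")
  expect_error(classifyObjects(data.frame(area = 1)), "missing")
  expect_error(classifyObjects(f, classifier = "model-7"), "rpart")
})

test_that("viability scoring follows the green channel", {
  lab <- segmentObjects(rasterShape(20), noSmoothParams())
  dark <- matrix(0, nrow(lab), ncol(lab))
  bright <- matrix(60000, nrow(lab), ncol(lab))
  f <- extractFeatures(lab)
  expect_false(scoreViability(f, lab, dark)$live)
  expect_true(scoreViability(f, lab, bright)$live)
  expect_error(scoreViability(f, lab, matrix(0, 2, 2)), "dimensions")
})

test_that("viability recovery matches configured cytotoxicity", {
  liveFrac <- vapply(1:10, function(s) {
    res <- renderAndAnalyze(300 + s, makeRecord(shiftInh = 40, cytotox = 0.5))
    mean(res$objects$live)
  }, numeric(1))
  expect_gte(mean(liveFrac), 0.45)
  expect_lte(mean(liveFrac), 0.55)
})
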