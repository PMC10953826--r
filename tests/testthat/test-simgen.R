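test_that("library fixture has the designed composition", {
  lib <- generateLibraryFixture()
  expect_equal(nrow(lib), 144L)
  expect_equal(sum(lib$target_class == "HDAC_Zn"), 34L)
  expect_equal(sum(lib$target_class == "HDAC_NAD"), 9L)
  expect_true(all(lib$cytotox_frac >= 0 & lib$cytotox_frac <= 1))
  expect_true(all(lib$duct_size_factor > 0))
  expect_false(anyDuplicated(lib$compound_id) > 0)

  sigInh <- lib[lib$cluster_shift_inh > 0, ]
  expect_setequal(sigInh$name,
                  c("chaetocin", "apicidin", "IBET151", "OTX015",
                    "3-deazaneplanocin A", "B32B3"))
  expect_equal(sum(sigInh$cytotox_frac > 0.5), 4L)
  expect_setequal(sigInh$name[sigInh$cytotox_frac <= 0.5],
                  c("apicidin", "chaetocin"))

  sigRev <- lib[lib$cluster_shift_rev > 0, ]
  expect_setequal(sigRev$name, c("chaetocin", "apicidin", "tubastatin A"))
  expect_setequal(sigRev$name[sigRev$cytotox_frac > 0.5], "tubastatin A")

  others <- lib[lib$cluster_shift_inh == 0 & lib$cluster_shift_rev == 0, ]
  expect_true(all(others$cytotox_frac <= 0.2))
  # shifts keep expected percentages inside [0, 100] at the defaults
  np <- noiseParams()
  expect_true(all(np$baselineInhibition + lib$cluster_shift_inh <= 100))
  expect_true(all(np$baselineReversal + lib$cluster_shift_rev <= 100))
})

test_that("packaged library CSV matches the generator", {
  path <- system.file("extdata", "compound_library.csv",
                      package = "admscreen")
  onDisk <- readCompoundLibrary(path)
  lib <- generateLibraryFixture()
  for (col in names(lib))
    expect_equal(onDisk[[col]], lib[[col]], tolerance = 1e-12,
                 ignore_attr = TRUE)
})

test_that("well simulation honors designed truth and is seed-deterministic", {
  veh <- simulateWellObjects(wellSpec(), NULL, noiseParams(), seed = 11)
  expect_true(all(veh$truth$true_live == 1L))
  expect_true(all(veh$truth$lumen_radius < veh$truth$radius))

  again <- simulateWellObjects(wellSpec(), NULL, noiseParams(), seed = 11)
  expect_identical(veh$truth, again$truth)

  # saturating shift: expected percent clusters is exactly 100
  rec <- makeRecord(shiftInh = 90, cytotox = 0)
  pct <- vapply(1:200, function(s) {
    tr <- simulateWellObjects(wellSpec(compoundId = "TEST", dose = 1),
                              rec, noiseParams(), seed = s)
    100 * mean(tr$truth$true_class == "cluster")
  }, numeric(1))
  expect_lt(abs(mean(pct) - 100), 1)

  # binomial dead fraction around the configured cytotoxicity
  recTox <- makeRecord(cytotox = 0.5)
  dead <- unlist(lapply(1:1000, function(s) {
    tr <- simulateWellObjects(wellSpec(compoundId = "TEST", dose = 1),
                              recTox, noiseParams(), seed = s)
    1L - tr$truth$true_live
  }))
  expect_gte(mean(dead), 0.48)
  expect_lte(mean(dead), 0.52)
})

test_that("well simulation rejects out-of-range expected percentages", {
  rec <- makeRecord(shiftInh = 95)
  expect_error(simulateWellObjects(wellSpec(compoundId = "TEST", dose = 1),
                                   rec, noiseParams(), seed = 1),
               "outside")
})

test_that("rendering is deterministic and empty wells stay background", {
  tr <- simulateWellObjects(wellSpec(), NULL, noiseParams(), seed = 21)
  img1 <- renderWellImage(tr, seed = 21)
  img2 <- renderWellImage(tr, seed = 21)
  expect_identical(img1[, , 1], img2[, , 1])
  expect_true(all(img1 >= 0 & img1 <= 65535))

  empty <- tr
  empty$truth <- tr$truth[0, ]
  img0 <- renderWellImage(empty, seed = 1)
  labels <- segmentObjects(img0[, , 1])
  expect_equal(attr(labels, "nObjects"), 0L)
})

test_that("rendered ducts carry a hole and clusters do not", {
  rec <- makeRecord()
  tr <- simulateWellObjects(wellSpec(), NULL, noiseParams(), seed = 31)
  img <- renderWellImage(tr, seed = 31)
  res <- analyzeWellImage(img)
  tt <- tr$truth
  m <- vapply(seq_len(nrow(res$objects)), function(i)
    which.min((tt$cy - res$objects$centroid_row[i])^2 +
              (tt$cx - res$objects$centroid_col[i])^2), integer(1))
  ducts <- res$objects[tt$true_class[m] == "duct", ]
  clusters <- res$objects[tt$true_class[m] == "cluster", ]
  expect_true(all(ducts$lumen_ratio > 0.1))
  if (nrow(clusters)) expect_true(all(clusters$lumen_ratio < 0.1))
})

test_that("qPCR generator inverts the ddCT model", {
  eff <- list(drug = c(Amy2a = 3, Cela1 = 3.321928, Cpa2 = 3.584963,
                       Krt19 = -1, Krt7 = 0, Sox9 = -1, `18S` = 0))
  # noiseless: the ADMRI of the recovered fold changes is the closed form
  ct <- simulateQpcr(eff, replicates = 3, noiseSd = 0, seed = 5)
  fc <- deltaDeltaCt(ct, vehicleLabel = "VEHICLE")
  adm <- computeAdmri(fc)
  expect_equal(adm$admri, 15, tolerance = 1e-5)

  # null effects, no noise: fold change 1 everywhere
  null <- list(drug = c(Amy2a = 0, Krt19 = 0, `18S` = 0))
  fc0 <- deltaDeltaCt(simulateQpcr(null, replicates = 3, noiseSd = 0,
                                   seed = 1))
  expect_equal(fc0$fc, rep(1, nrow(fc0)), tolerance = 1e-9)

  # with technical noise, many replicates recover the configured log2FC
  ctN <- simulateQpcr(eff, replicates = 1000, noiseSd = 0.15, seed = 7)
  fcN <- deltaDeltaCt(ctN)
  rec <- log2(fcN$fc[match(c("Amy2a", "Krt19"), fcN$gene)])
  expect_lt(max(abs(rec - c(3, -1))), 0.05)

  expect_error(simulateQpcr(list(drug = c(Amy2a = 1)), seed = 1),
               "reference gene")
})

test_that("DE table generator calibrates null and strong signatures", {
  panel <- genePanel()
  nPanel <- length(panel$acinar) + length(panel$ductal_pdac)
  hitFrac <- vapply(1:100, function(s) {
    de <- simulateDeTable(panel, reversalStrength = 0, seed = s)
    ann <- annotateVolcano(de, panel)
    sum(ann$table$panel != "background" & ann$table$status != "ns") / nPanel
  }, numeric(1))
  expect_lte(mean(hitFrac), 0.20)

  de <- simulateDeTable(panel, reversalStrength = 4, seed = 3)
  ann <- annotateVolcano(de, panel)
  up <- ann$table$panel == "acinar" & ann$table$status == "up-significant"
  dn <- ann$table$panel == "ductal_pdac" &
    ann$table$status == "down-significant"
  expect_equal(sum(up), 27L)
  expect_equal(sum(dn), 23L)
  expect_equal(ann$concordance, 1)

  emptyPanel <- genePanel(acinar = character(0), ductalPdac = character(0))
  de0 <- simulateDeTable(emptyPanel, reversalStrength = 1,
                         nBackgroundGenes = 0L, seed = 1)
  expect_equal(nrow(de0), 0L)
})
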