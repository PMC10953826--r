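test_that("well summaries count live and total objects correctly", {
  allDucts <- data.frame(predicted_class = rep("duct", 10), live = TRUE)
  s1 <- summarizeWell(allDucts)
  expect_equal(s1$pct_live_ducts, 100)
  expect_equal(s1$viability_frac, 1)
  expect_false(s1$flagged)

  mixed <- data.frame(
    predicted_class = c(rep("duct", 20), rep("cluster", 20), rep("duct", 10)),
    live = c(rep(TRUE, 40), rep(FALSE, 10)))
  s2 <- summarizeWell(mixed)
  expect_equal(s2$pct_live_clusters, 50)
  expect_equal(s2$viability_frac, 0.8)
  expect_equal(s2$pct_live_ducts + s2$pct_live_clusters, 100)

  s3 <- summarizeWell(mixed[0, ])
  expect_true(s3$flagged)
  allDead <- data.frame(predicted_class = "cluster", live = FALSE)
  expect_true(summarizeWell(rbind(allDead, allDead))$flagged)
})

test_that("Welch test matches the independent oracle and its symmetries", {
  res <- welchTest(c(1, 2, 3, 4), c(2, 3, 4, 5))
  expect_equal(res$t, -1.0954451, tolerance = 1e-6)
  expect_equal(res$df, 6)
  expect_equal(res$p, 0.3153336, tolerance = 1e-6)

  same <- welchTest(c(3, 5, 7), c(3, 5, 7))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  swapped <- welchTest(c(2, 3, 4, 5), c(1, 2, 3, 4))
  expect_equal(swapped$t, -res$t, tolerance = 1e-12)
  expect_equal(swapped$p, res$p, tolerance = 1e-12)

  expect_error(welchTest(1, c(1, 2)), "at least 2")
  expect_equal(welchTest(c(1, 1), c(1, 1))$p, 1)
})

test_that("Z-prime matches hand computation and behaves monotonically", {
  # construct samples with exact means/SDs: mean 90 sd 3 vs mean 10 sd 4
  neg <- 90 + c(-3, 3) / sqrt(2); pos <- 10 + c(-4, 4) / sqrt(2)
  expect_equal(sd(neg), 3)
  expect_equal(sd(pos), 4)
  qc <- zPrimeFactor(pos, neg)
  expect_equal(zPrime(qc), 0.7375, tolerance = 1e-12)

  expect_equal(zPrime(zPrimeFactor(c(10, 10), c(90, 90))), 1)
  expect_error(zPrimeFactor(c(5, 5), c(5, 5)), "equal")

  # widening either SD strictly lowers Z'; rescaling both groups does not
  wider <- zPrimeFactor(pos * c(0.5, 1.5), neg)
  expect_lt(zPrime(wider), zPrime(qc))
  scaled <- zPrimeFactor(pos * 3, neg * 3)
  expect_equal(zPrime(scaled), zPrime(qc), tolerance = 1e-12)
})

test_that("selection criteria gate on direction, significance and viability", {
  veh <- do.call(rbind, lapply(1:4, function(r) simSummary(NULL, seed = r)))

  # identical-to-vehicle compound: never a hit
  nullSm <- veh
  nullSm$compound_id <- "NULLCMP"
  h0 <- applySelectionCriteria(nullSm, veh)
  expect_false(h0$pass_i)
  expect_false(h0$is_hit)

  # large cluster excess but heavy cytotoxicity: passes i & ii, fails iii
  recTox <- makeRecord(shiftInh = 60, cytotox = 0.7, id = "TOXIC")
  toxSm <- do.call(rbind, lapply(1:4, function(r)
    simSummary(recTox, seed = 100 + r)))
  toxSm$compound_id <- "TOXIC"
  hTox <- applySelectionCriteria(toxSm, veh)
  expect_true(hTox$pass_i)
  expect_true(hTox$pass_ii)
  expect_false(hTox$pass_iii)
  expect_false(hTox$is_hit)

  expect_error(applySelectionCriteria(nullSm, veh[0, ]), "vehicle")
})

test_that("false-positive rate of criterion i is controlled at alpha", {
  nullRec <- makeRecord(id = "NULLCMP", cytotox = 0.05)
  hits <- vapply(1:200, function(s) {
    sm <- do.call(rbind, lapply(1:4, function(r)
      simSummary(nullRec, seed = wellSeed(s, r))))
    sm$compound_id <- "NULLCMP"
    veh <- do.call(rbind, lapply(1:4, function(r)
      simSummary(NULL, seed = wellSeed(s, r + 50))))
    applySelectionCriteria(sm, veh)$pass_i
  }, logical(1))
  expect_lte(mean(hits), 0.05)
})

test_that("designed effects are detected with near-certain power", {
  rec <- makeRecord(shiftInh = 50, cytotox = 0.1, id = "DESIGNED")
  hits <- vapply(1:200, function(s) {
    sm <- do.call(rbind, lapply(1:4, function(r)
      simSummary(rec, seed = wellSeed(s, r))))
    sm$compound_id <- "DESIGNED"
    veh <- do.call(rbind, lapply(1:4, function(r)
      simSummary(NULL, seed = wellSeed(s, r + 50))))
    applySelectionCriteria(sm, veh)$pass_i
  }, logical(1))
  expect_gte(mean(hits), 0.99)
})

test_that("screen runs are reproducible and internally consistent", {
  res1 <- runScreen(mode = "reversal", seed = 99)
  res2 <- runScreen(mode = "reversal", seed = 99)
  expect_identical(hitTable(res1), hitTable(res2))
  expect_identical(wellTable(res1), wellTable(res2))

  wt <- wellTable(res1)
  ok <- !wt$flagged
  expect_equal(wt$pct_live_ducts[ok] + wt$pct_live_clusters[ok],
               rep(100, sum(ok)))
  expect_s4_class(assayQC(res1), "AssayQC")
  expect_lte(zPrime(res1), 1)
  h <- hitTable(res1)
  expect_equal(h$is_hit, h$pass_i & h$pass_ii & h$pass_iii)
})
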