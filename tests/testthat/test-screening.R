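test_that("immobilization index is the clipped vehicle-relative light response", {
  dmso <- generateControlPlates(0, 24, seed = 31)
  stats0 <- dmsoReferenceStats(dmso)
  battery <- defaultBattery()

  # a well at the vehicle median light response scores 0
  med <- stats0$median_violet_mag
  mi <- rep(0, 3000)
  for (onset in c(65, 85, 105)) {
    mi[phenoscreen:::eventWindow(3000, 25, onset, 10)] <- med
  }
  expect_equal(immobilizationIndex(mi, stats0, train = battery), 0)

  # an immobilized (all-zero) well scores 1; half response scores 0.5
  expect_equal(immobilizationIndex(rep(0, 3000), stats0, train = battery), 1)
  expect_equal(immobilizationIndex(mi / 2, stats0, train = battery), 0.5)

  ii <- immobilizationIndex(dmso, stats0)
  expect_true(all(ii >= 0 & ii <= 1))

  noViolet <- StimulusTrain(data.frame(type = "acoustic_low", onset_s = 5,
                                       duration_s = 0.1, amplitude = 1),
                            totalDuration = 60)
  expect_error(immobilizationIndex(mi[1:1500], stats0, train = noViolet),
               "no violet events")
})

test_that("hit calling returns exactly k hits with deterministic tie-breaks", {
  tab <- data.frame(
    compound_id = sprintf("C%03d", 1:200), well_id = sprintf("W%03d", 1:200),
    phenoscore = rep(0.5, 200), degenerate = FALSE,
    immobilization_index = 0.2, total_mi = 1, concentration_uM = 10,
    is_control = FALSE
  )
  called <- rankAndCall(tab, kHits = 125)
  expect_equal(sum(attr(called, "compounds")$call == "hit"), 125)
  # all-tied scores: top-k purely lexicographic, stable across runs
  agg <- attr(called, "compounds")
  expect_equal(agg$compound_id[1:3], c("C001", "C002", "C003"))
  expect_identical(agg, attr(rankAndCall(tab, kHits = 125), "compounds"))
  expect_error(rankAndCall(tab, kHits = 0), "positive")
  expect_error(rankAndCall(tab, kHits = 300), "exceeds")
})

test_that("calls partition compounds and hit status is monotone in phenoscore", {
  set.seed(8)
  n <- 60
  tab <- data.frame(
    compound_id = sprintf("C%03d", 1:n), well_id = sprintf("W%03d", 1:n),
    phenoscore = runif(n, -0.2, 0.9), degenerate = FALSE,
    immobilization_index = runif(n), total_mi = 1, concentration_uM = 10,
    is_control = FALSE
  )
  called <- rankAndCall(tab, kHits = 15)
  agg <- attr(called, "compounds")
  expect_true(all(table(agg$compound_id) == 1))
  expect_true(all(agg$call %in% c("hit", "toxic", "inactive")))
  expect_equal(sum(agg$call == "hit"), 15)

  # raising one non-hit compound's score never demotes it
  victim <- agg$compound_id[agg$rank == 16]
  tab2 <- tab
  tab2$phenoscore[tab2$compound_id == victim] <- max(tab$phenoscore) + 0.1
  agg2 <- attr(rankAndCall(tab2, kHits = 15), "compounds")
  expect_equal(agg2$call[agg2$compound_id == victim], "hit")
})

test_that("the default screen pipeline recovers planted hits and toxics", {
  fix <- referenceFixture()
  scr <- generateScreen(200, 0.1, 0.05, seed = 14)
  tab <- screenTable(scr$profiles, fix$reference)
  truth <- libraryTruth(scr$library)
  called <- rankAndCall(tab, kHits = 20)
  agg <- attr(called, "compounds")
  hits <- agg$compound_id[agg$call == "hit"]
  planted <- truth$compound_id[truth$class == "etomidate_like"]
  precision <- length(intersect(hits, planted)) / length(hits)
  recall <- length(intersect(hits, planted)) / length(planted)
  expect_gte(precision, 0.95)
  expect_gte(recall, 0.95)
  # toxic wells sit in the immobilized, low-phenoscore region
  toxCalled <- agg$compound_id[agg$call == "toxic"]
  toxTruth <- truth$compound_id[truth$class == "toxic"]
  expect_gte(length(intersect(toxCalled, toxTruth)) / length(toxTruth), 0.9)
  # control wells pass through with the control call
  expect_true(all(called$call[called$is_control] == "control"))
})

test_that("4PL fitting recovers noise-free truth and respects unit rescaling", {
  conc <- 10^seq(-1, 2, by = 0.5)
  y <- doseFactor(doseLaw(1, 2), conc)
  fit <- fitDoseResponse(conc, y)
  expect_true(fit$converged)
  expect_equal(fit$ec50_uM, 1, tolerance = 0.01)
  expect_equal(fit$hill, 2, tolerance = 0.05)

  # nM relabeling scales EC50 by 1000 and leaves shape parameters alone
  fitNM <- fitDoseResponse(conc * 1000, y)
  expect_equal(fitNM$ec50_uM / fit$ec50_uM, 1000, tolerance = 0.01)
  expect_equal(fitNM$hill, fit$hill, tolerance = 0.01)

  flat <- fitDoseResponse(conc, rep(0.4, length(conc)))
  expect_false(flat$converged)
  expect_error(fitDoseResponse(c(1, 2, 3), c(0, 1, 2)), "4 distinct")
})

test_that("4PL parameter recovery stays tight under 10% noise", {
  conc <- rep(10^seq(-1, 2, by = 0.5), each = 4)
  errs <- sapply(1:100, function(s) {
    set.seed(s)
    ec50 <- 10^runif(1, -0.5, 1)
    y <- doseFactor(doseLaw(ec50, 2), conc) + rnorm(length(conc), 0, 0.1)
    fit <- fitDoseResponse(conc, y)
    abs(log10(fit$ec50_uM / ec50))
  })
  expect_lte(median(errs), 0.15)
})

test_that("efficacy windows are contiguous and bell-shaped compounds lose the top dose", {
  dt <- data.frame(concentration_uM = c(1, 2, 4, 8),
                   phenoscore = c(0.2, 0.8, 0.9, 0.1))
  win <- efficacyWindow(dt, strongCutoff = 0.5)
  expect_equal(win$window, c(2, 4))
  allWeak <- efficacyWindow(dt, strongCutoff = 0.95)
  expect_length(allWeak$window, 0)
  expect_error(efficacyWindow(dt[0, ], 0.5), "empty")

  # seeded bell-shaped compound: strong mid-ladder, weak top concentration
  fix <- referenceFixture()
  bell <- doseLaw(1, 2, ec50Hi = 20, hillHi = 4)
  ds <- generateDoseSeries(phenotypeClassParams("etomidate_like"), bell,
                           replicates = 6, seed = 21)
  sc <- phenoscore(ds, fix$reference)
  dtBell <- data.frame(concentration_uM = wellData(ds)$concentration_uM,
                       phenoscore = sc$phenoscore)
  winBell <- efficacyWindow(dtBell, strongCutoff = 0.5)
  expect_gt(length(winBell$window), 0)
  expect_false(100 %in% winBell$window)
})

test_that("reproducibility rate is exact bookkeeping over retested hits", {
  # the printed-count fixture: 46 of 57 primary hits reproduce
  hits <- sprintf("H%02d", 1:57)
  retest <- expand.grid(compound_id = hits, concentration_uM = c(1, 10),
                        stringsAsFactors = FALSE)
  retest$phenoscore <- 0.1
  retest$phenoscore[retest$compound_id %in% hits[1:46] &
                      retest$concentration_uM == 10] <- 0.8
  rate <- reproducibilityRate(hits, retest, criterion = 0.5)
  expect_equal(rate, 46 / 57)
  expect_equal(round(rate, 3), 0.807)
  expect_equal(reproducibilityRate(hits[1:46], retest, criterion = 0.5), 1)
  expect_error(reproducibilityRate(c(hits, "H99"), retest, 0.5), "H99")

  # ground-truth bookkeeping: planted hits keep their dose law, decoys flat
  planted <- sprintf("P%02d", 1:8)
  decoys <- sprintf("D%02d", 1:12)
  rt <- rbind(
    data.frame(compound_id = rep(planted, each = 2), concentration_uM = c(1, 10),
               phenoscore = rep(c(0.3, 0.75), 8)),
    data.frame(compound_id = rep(decoys, each = 2), concentration_uM = c(1, 10),
               phenoscore = 0.05)
  )
  expect_equal(reproducibilityRate(c(planted, decoys), rt, 0.6),
               length(planted) / (length(planted) + length(decoys)))
})
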