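test_that("pointwise t-tests match hand-computed references", {
    tt <- c(0, 30)
    m <- rbind(
        makeMeasurements("P[1-5]_1", "A", paste0("R", 1:3), 30, c(1, 2, 3)),
        makeMeasurements("P[1-5]_1", "B", paste0("R", 1:3), 30, c(4, 5, 6)),
        makeMeasurements("P[1-5]_1", "A", paste0("R", 1:3), 0, c(1, 1, 1)),
        makeMeasurements("P[1-5]_1", "B", paste0("R", 1:3), 0, c(1, 1, 1)))
    ds <- HDXDataset(m, conditions = c("A", "B"))
    # pooled-variance form: |t| = 3.674, df = 4
    res <- pointwiseTTest(ds, "P[1-5]_1", varEqual = TRUE)
    expect_equal(res$p[res$time == 30], 0.02131164, tolerance = 1e-4)
    # degenerate identical groups at t = 0
    expect_equal(res$p[res$time == 0], 1)

    # identical group values: p = 1
    m2 <- rbind(
        makeMeasurements("Q[1-5]_1", "A", paste0("R", 1:2), 30, c(1, 2)),
        makeMeasurements("Q[1-5]_1", "B", paste0("R", 1:2), 30, c(1, 2)))
    expect_equal(pointwiseTTest(HDXDataset(m2), "Q[1-5]_1",
                                varEqual = TRUE)$p, 1, tolerance = 1e-10)

    # one replicate in a group gives NA at that time point
    m3 <- rbind(
        makeMeasurements("S[1-5]_1", "A", "R1", 30, 1),
        makeMeasurements("S[1-5]_1", "B", paste0("R", 1:2), 30, c(2, 3)))
    expect_true(is.na(pointwiseTTest(HDXDataset(m3), "S[1-5]_1")$p))
})

test_that("harmonic mean combination follows its closed form", {
    expect_equal(harmonicMeanP(c(0.1, 0.3)), 0.15)
    expect_equal(harmonicMeanP(rep(0.2, 5)), 0.2)
    expect_equal(harmonicMeanP(c(0.4, NA)), 0.4)
    expect_true(is.na(harmonicMeanP(c(NA_real_, NA_real_))))
    expect_equal(harmonicMeanP(c(0, 0.5)), 0)
    # bounded by the extremes
    set.seed(6)
    for (i in 1:30) {
        p <- runif(sample(2:6, 1))
        h <- harmonicMeanP(p)
        expect_gte(h, min(p)); expect_lte(h, max(p))
    }
})

test_that("mixed-model comparator is calibrated on null data and degrades
           gracefully", {
    sim <- simulateExperiment(hdxScenario(m = 4, R = 3, nPeptides = 150,
                                          nullProb = 1, seed = 44))
    # raw coefficient p-values should be roughly uniform under the null
    # (the harmonic-mean combination is deliberately anti-conservative,
    # so uniformity is checked before combination)
    p <- unlist(lapply(analyteIds(sim$dataset), function(id)
        suppressWarnings(lmmTest(sim$dataset, id)$coefficients$p)))
    p <- p[!is.na(p)]
    expect_gt(length(p), 400)
    ks <- suppressWarnings(ks.test(p, "punif")$statistic)
    expect_lt(unname(ks), 0.15)

    # unreplicated designs are inapplicable
    m <- makeMeasurements("U[1-5]_1", rep(c("A", "B"), each = 3), "R1",
                          rep(c(0, 30, 300), 2), rnorm(6))
    expect_warning(out <- lmmTest(HDXDataset(m), "U[1-5]_1"),
                   "unreplicated")
    expect_true(is.na(out$p_combined))
})

test_that("mixed model with one time point mirrors the t-test direction", {
    set.seed(17)
    m <- rbind(
        makeMeasurements("V[1-5]_1", "A", paste0("R", 1:4), 30,
                         rnorm(4, 1, 0.3)),
        makeMeasurements("V[1-5]_1", "B", paste0("R", 1:4), 30,
                         rnorm(4, 2, 0.3)))
    ds <- HDXDataset(m, conditions = c("A", "B"))
    out <- suppressWarnings(lmmTest(ds, "V[1-5]_1"))
    expect_equal(nrow(out$coefficients), 1)
    # B > A so the conditionB coefficient is positive, like the t statistic
    expect_gt(out$coefficients$estimate, 0)
    t_p <- pointwiseTTest(ds, "V[1-5]_1", varEqual = TRUE)$p
    expect_lt(abs(out$p_combined - t_p), 0.2)
    expect_lt(out$p_combined, 0.05)
})

test_that("F-score arithmetic and conventions", {
    truth <- data.frame(analyte = c("a", "b", "c"),
                        perturbed = c(TRUE, TRUE, FALSE))
    calls <- data.frame(analyte = c("a", "b", "c"),
                        significant = c(TRUE, TRUE, FALSE))
    expect_equal(fScore(truth, calls)$f_score, 1)
    # tp = 1, fp = 1, fn = 1
    calls2 <- data.frame(analyte = c("a", "b", "c"),
                         significant = c(TRUE, FALSE, TRUE))
    row <- fScore(truth, calls2)
    expect_equal(c(row$precision, row$recall, row$f_score),
                 c(0.5, 0.5, 0.5))
    # no calls with real positives: F = 0
    calls3 <- data.frame(analyte = c("a", "b", "c"), significant = FALSE)
    expect_equal(fScore(truth, calls3)$f_score, 0)
    # permutation invariance
    expect_equal(fScore(truth, calls2[c(3, 1, 2), ]), row)
    expect_error(fScore(truth, data.frame(analyte = "x",
                                          significant = TRUE)),
                 "same analyte set")
})

test_that("benchmark harness scores methods deterministically", {
    sc <- hdxScenario(m = 4, R = 2, nPeptides = 40, nullProb = 1)
    rep1 <- runBenchmark(sc, methods = c("functional", "t_test"),
                         nReps = 1, seed = 5)
    rep2 <- runBenchmark(sc, methods = c("functional", "t_test"),
                         nReps = 1, seed = 5)
    expect_identical(rep1, rep2)
    # fully null: essentially no false positives for either method
    expect_true(all(rep1$fp <= 1))
    expect_equal(nrow(runBenchmark(sc, methods = character(), nReps = 1)),
                 0)
})

test_that("null permutation harness relabels replicates reproducibly", {
    # single-condition dataset with 7 replicates
    sim <- simulateExperiment(hdxScenario(m = 4, R = 7, C = 1,
                                          nPeptides = 25, seed = 21))
    out1 <- nullPermutationExperiment(sim$dataset, nPerms = 2, seed = 4,
                                      methods = "t_test")
    out2 <- nullPermutationExperiment(sim$dataset, nPerms = 2, seed = 4,
                                      methods = "t_test")
    expect_identical(out1, out2)
    expect_equal(nrow(out1), 2)
    expect_true(all(out1$false_positives <= 1))
    empty <- nullPermutationExperiment(sim$dataset, nPerms = 0)
    expect_equal(nrow(empty), 0)
    expect_error(nullPermutationExperiment(sim$dataset, split = c(5, 5)),
                 "replicates")
})
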