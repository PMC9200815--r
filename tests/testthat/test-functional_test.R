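test_that("nested fits satisfy the RSS nesting contract", {
    # identical data in both conditions: condition adds nothing
    ds <- makeCurveDataset(refParams, refParams, noise = 0.05, seed = 1)
    pair <- nestedFit(ds, analyteIds(ds)[1])
    expect_gte(pair$rss0, pair$rss1 - 1e-6)
    dof <- degreesOfFreedom(modelSpec("weibull"), 2, pair$n)
    f <- fStatistic(pair$rss0, pair$rss1, dof$d1, dof$d2)
    expect_lt(f, 10)   # no real signal

    # visibly different noise-free curves: alternative fits perfectly
    ds2 <- makeCurveDataset(refParams, c(a = 2, b = 0.01, q = 1, d = 1))
    pair2 <- nestedFit(ds2, analyteIds(ds2)[1])
    expect_lt(pair2$rss1, 1e-8)
    expect_gt(pair2$rss0, 1)
})

test_that("analytes missing a condition are flagged as untestable", {
    m <- makeMeasurements("P[1-5]_1", "A", rep(c("R1", "R2"), each = 6),
                          rep(c(0, 10, 30, 100, 300, 1000), 2),
                          rnorm(12, 1))
    ds <- HDXDataset(m, conditions = c("A", "B"))
    expect_error(nestedFit(ds, "P[1-5]_1"),
                 class = "hdxInsufficientObservations")
})

test_that("degrees of freedom follow the nested parameter counts", {
    expo <- modelSpec("exponential")
    wei <- modelSpec("weibull")
    d <- degreesOfFreedom(expo, C = 2, n = 24)
    expect_equal(d[c("p1", "p2", "d1", "d2")], list(p1 = 3, p2 = 6,
                                                    d1 = 3, d2 = 18))
    d <- degreesOfFreedom(wei, C = 2, n = 24)
    expect_equal(d[c("p1", "p2", "d1")], list(p1 = 4, p2 = 8, d1 = 4))
    # reduced epitope-mapping configuration: only the amplitude free
    epi <- modelSpec("weibull", fixed = c(b = 0.5, q = 1, d = 0))
    d <- degreesOfFreedom(epi, C = 2, n = 6)
    expect_equal(d[c("p1", "p2", "d1", "d2")], list(p1 = 1, p2 = 2,
                                                    d1 = 1, d2 = 4))
    # multi-level designs scale p2 with C
    d <- degreesOfFreedom(expo, C = 3, n = 30)
    expect_equal(d$p2, 9)
    expect_error(degreesOfFreedom(wei, C = 2, n = 8),
                 class = "hdxInsufficientObservations")
})

test_that("F-statistic matches brute-force arithmetic", {
    expect_equal(fStatistic(2, 1, 3, 6), 2)
    expect_equal(fStatistic(1, 1, 3, 6), 0)
    expect_identical(fStatistic(1, 0, 3, 6), Inf)
    # oracle equivalence on random inputs
    set.seed(8)
    for (i in 1:50) {
        rss1 <- runif(1, 0.01, 5)
        rss0 <- rss1 + runif(1, 0, 5)
        d1 <- sample(1:6, 1); d2 <- sample(1:30, 1)
        brute <- (rss0 - rss1) / rss1 * d2 / d1
        expect_equal(fStatistic(rss0, rss1, d1, d2), brute,
                     tolerance = 1e-10)
    }
})

test_that("EB hyperparameters are recovered from scaled-F draws", {
    set.seed(123)
    d0 <- 4; s0 <- 0.01; d2 <- 8
    s_sq <- s0 * rf(5000, d2, d0)
    hy <- estimateEBHyperparams(s_sq, d2)
    expect_lt(abs(hy$d0 - d0) / d0, 0.25)
    expect_lt(abs(hy$s0_sq - s0) / s0, 0.10)
})

test_that("EB fit agrees with an independent moment-matching routine", {
    skip_if_not_installed("limma")
    set.seed(21)
    s_sq <- 0.02 * rf(2000, 10, 6)
    hy <- estimateEBHyperparams(s_sq, 10)
    ref <- limma::fitFDist(s_sq, df1 = 10)
    expect_equal(hy$d0, ref$df2, tolerance = 1e-6)
    expect_equal(hy$s0_sq, ref$scale, tolerance = 1e-6)
})

test_that("EB degenerate inputs follow the documented conventions", {
    hy <- estimateEBHyperparams(rep(0.5, 10), 8)
    expect_identical(hy$d0, Inf)
    expect_equal(hy$s0_sq, 0.5)
    expect_error(estimateEBHyperparams(0.5, 8), "cannot moderate")
})

test_that("variance moderation shrinks between the two variance scales", {
    expect_equal(moderateVariance(3, 8, list(d0 = 0, s0_sq = 1)), 3)
    expect_equal(moderateVariance(3, 8, list(d0 = 8, s0_sq = 1)), 2)
    expect_equal(moderateVariance(3, 8, list(d0 = Inf, s0_sq = 1)), 1)
    set.seed(2)
    for (i in 1:30) {
        s <- runif(1, 1e-4, 10); s0 <- runif(1, 1e-4, 10)
        d0 <- runif(1, 0, 50); d2 <- sample(1:30, 1)
        st <- moderateVariance(s, d2, list(d0 = d0, s0_sq = s0))
        expect_gte(st, min(s, s0) - 1e-12)
        expect_lte(st, max(s, s0) + 1e-12)
    }
})

test_that("moderated F reduces to the ordinary F when d0 = 0", {
    expect_equal(moderatedF(2, 1, 3, 0.2), 5 / 3)
    expect_equal(moderatedF(1, 1, 3, 0.2), 0)
    set.seed(4)
    for (i in 1:20) {
        rss1 <- runif(1, 0.01, 5); rss0 <- rss1 + runif(1, 0, 5)
        d1 <- sample(1:6, 1); d2 <- sample(2:30, 1)
        s_tilde <- rss1 / d2   # d0 = 0 posterior
        expect_equal(moderatedF(rss0, rss1, d1, s_tilde),
                     fStatistic(rss0, rss1, d1, d2), tolerance = 1e-12)
    }
})

test_that("F p-values obey distributional identities", {
    expect_equal(fPvalue(0, 3, 10), 1)
    # F(k, k) is symmetric about 1
    for (k in c(2, 5, 9)) expect_equal(fPvalue(1, k, k), 0.5)
    # monotone decreasing tail
    p <- sapply(c(0.5, 1, 2, 5, 20, 100), fPvalue, d1 = 4, df2 = 12)
    expect_true(all(diff(p) < 0))
    expect_equal(fPvalue(Inf, 4, 12), 0)
    # chi-square limit at infinite denominator df
    expect_equal(fPvalue(2, 4, Inf), pchisq(8, 4, lower.tail = FALSE))
})

test_that("BH adjustment matches hand computation and propagates NA", {
    expect_equal(adjustBH(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
    expect_equal(adjustBH(rep(1, 5)), rep(1, 5))
    expect_equal(adjustBH(0.2), 0.2)
    out <- adjustBH(c(0.01, NA, 0.04))
    expect_true(is.na(out[2]))
    # NA excluded from the family size: equivalent to BH on the pair
    expect_equal(out[c(1, 3)], p.adjust(c(0.01, 0.04), "BH"))
    expect_error(adjustBH(c(0.5, 1.2)), "0, 1")
})

test_that("full test run orders signal above null analytes", {
    sc <- hdxScenario(m = 4, R = 3, nPeptides = 30, nullProb = 1,
                      seed = 31)
    sim <- simulateExperiment(sc)
    # inject a large shift into one analyte's condition B
    m <- measurements(sim$dataset)
    target <- analyteIds(sim$dataset)[5]
    shift <- m$analyte == target & m$condition == "B" & m$exposure > 0
    m$value[shift] <- m$value[shift] + 3
    ds <- HDXDataset(m, conditions = hdxConditions(sim$dataset))
    res <- runFunctionalTest(ds)
    expect_equal(res$analyte[which.min(res$p_adjusted)], target)
    expect_true(res$significant[res$analyte == target])
})

test_that("unmoderated pipeline equals the d0 = 0 limit exactly", {
    sim <- simulateExperiment(hdxScenario(m = 4, R = 3, nPeptides = 12,
                                          seed = 7))
    res <- runFunctionalTest(sim$dataset, moderate = FALSE)
    ok <- res$status == "ok" & res$rss1 > 0
    expect_equal(res$p_value[ok],
                 mapply(fPvalue, res$F[ok], res$d1[ok], res$d2[ok]))
    expect_equal(res$F_moderated[ok], res$F[ok], tolerance = 1e-10)
})

test_that("functional ANOVA generalises to three conditions", {
    sc <- hdxScenario(m = 5, R = 3, C = 3, nPeptides = 15, seed = 13)
    sim <- simulateExperiment(sc)
    res <- runFunctionalTest(sim$dataset)
    ok <- res$status == "ok"
    expect_gt(sum(ok), 0)
    # p2 = C * k = 12 for the weibull form
    expect_equal(unique(res$d1[ok]), 12 - 4)
    expect_true(all(res$rss0[ok] >= res$rss1[ok] - 1e-6))
    expect_true(all(res$p_value[ok] >= 0 & res$p_value[ok] <= 1))
    expect_true(all(res$p_adjusted[ok] >= res$p_value[ok] - 1e-12))
})

test_that("a single-condition dataset cannot be tested", {
    m <- makeMeasurements("P[1-5]_1", "A", "R1", c(0, 30, 300), c(1, 2, 3))
    ds <- HDXDataset(m)
    expect_error(runFunctionalTest(ds), "two conditions")
})
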