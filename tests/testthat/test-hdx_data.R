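test_that("centroid mass follows the intensity-weighted mean arithmetic", {
    # single peak: 500.5 * 2 - 2
    expect_equal(computeCentroidMass(IsotopeSpectrum(500.5, 1, 2L)), 999)
    # two equal peaks at z = 1: mean 100.5 - 1
    expect_equal(computeCentroidMass(IsotopeSpectrum(c(100, 101), c(1, 1))),
                 99.5)
    # zero-intensity peaks carry no weight
    with_zero <- IsotopeSpectrum(c(100, 100.5, 101), c(1, 0, 1))
    expect_equal(computeCentroidMass(with_zero), 99.5)
})

test_that("centroid is invariant under intensity scaling", {
    set.seed(11)
    for (i in 1:20) {
        n <- sample(2:8, 1)
        sp <- IsotopeSpectrum(sort(runif(n, 400, 410)), runif(n, 0.01, 1),
                              sample(1:3, 1))
        k <- runif(1, 0.1, 50)
        scaled <- IsotopeSpectrum(sp@mz, sp@intensity * k, sp@charge)
        expect_equal(computeCentroidMass(scaled), computeCentroidMass(sp))
    }
})

test_that("degenerate spectra are rejected", {
    expect_error(IsotopeSpectrum(c(100, 101), c(0, 0)), "empty spectrum")
    expect_error(IsotopeSpectrum(c(101, 100), c(1, 1)), "increasing")
    expect_error(IsotopeSpectrum(c(100, 101), 1), "equal length")
})

test_that("long CSV reading validates and round-trips", {
    path <- withr::local_tempfile(fileext = ".csv")
    writeLines(c(
        "analyte_sequence,start,end,charge,condition,replicate,exposure_s,value,value_kind",
        "PEPX,1,4,2,A,R1,0,1000.2,centroid",
        "PEPX,1,4,2,A,R1,30,1002.5,centroid"), path)
    ds <- readLongCSV(path)
    expect_s4_class(ds, "HDXDataset")
    expect_length(analyteIds(ds), 1)
    expect_equal(exposureTimes(ds), c(0, 30))

    # round-trip preserves measurements (including NA) bit-exactly
    m <- makeMeasurements("AB[1-5]_1", rep(c("A", "B"), each = 2), "R1",
                          c(0, 30, 0, 30), c(0.1, NA, 0.3, 0.4))
    ds2 <- HDXDataset(m)
    out <- withr::local_tempfile(fileext = ".csv")
    writeLongCSV(ds2, out)
    back <- readLongCSV(out, columnMap = NULL)
    expect_equal(measurements(back)$value, measurements(ds2)$value)
    expect_equal(measurements(back)$exposure, measurements(ds2)$exposure)
    expect_equal(hdxConditions(back), hdxConditions(ds2))
})

test_that("long CSV reader reports structural errors precisely", {
    path <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("analyte_sequence,start,end,charge,condition,replicate,value",
                 "PEP,1,3,1,A,R1,0.5"), path)
    expect_error(readLongCSV(path), "exposure_s")

    path2 <- withr::local_tempfile(fileext = ".csv")
    writeLines(c(
        "analyte_sequence,start,end,charge,condition,replicate,exposure_s,value",
        "PEP,1,3,1,A,R1,abc,0.5"), path2)
    expect_error(readLongCSV(path2), "line")

    # duplicated design cells are named
    path3 <- withr::local_tempfile(fileext = ".csv")
    writeLines(c(
        "analyte_sequence,start,end,charge,condition,replicate,exposure_s,value",
        "PEP,1,3,1,A,R1,30,0.5",
        "PEP,1,3,1,A,R1,30,0.6"), path3)
    expect_error(readLongCSV(path3), "duplicated")
})

test_that("state-data CSV dialect maps states and units", {
    path <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("Protein,Sequence,Start,End,State,Exposure,Charge,Center",
                 "prot,PEPA,1,4,Apo,0,2,501.0",
                 "prot,PEPA,1,4,Apo,0.5,2,502.0",
                 "prot,PEPA,1,4,Bound,5,2,503.0"), path)
    ds <- readStateCSV(path, exposureUnit = "min")
    expect_setequal(hdxConditions(ds), c("Apo", "Bound"))
    expect_equal(sort(unique(measurements(ds)$exposure)), c(0, 30, 300))
    # Center m/z converted to neutral mass
    expect_equal(measurements(ds)$value[1], 501 * 2 - 2)

    # unknown extra columns are ignored with a warning
    path2 <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("Sequence,Start,End,State,Exposure,Uptake,Mystery",
                 "PEPA,1,4,A,0,0.0,x",
                 "PEPA,1,4,B,0,0.1,y"), path2)
    expect_warning(ds2 <- readStateCSV(path2), "Mystery")
    expect_equal(measurements(ds2)$value_kind[1], "uptake")

    path3 <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("Sequence,Start,End,State,Exposure",
                 "PEPA,1,4,A,0"), path3)
    expect_error(readStateCSV(path3), "Center|Uptake")
})

test_that("results CSV round-trips with deterministic column order", {
    res <- data.frame(analyte = c("p1", "p2"), rss0 = c(2, 3),
                      rss1 = c(1, 2), d1 = 4, d2 = 8,
                      F = c(2, 1), F_moderated = c(2.2, 1.1),
                      p_value = c(0.01, 0.5), p_adjusted = c(0.02, 0.5),
                      status = "ok", stringsAsFactors = FALSE)
    path <- withr::local_tempfile(fileext = ".csv")
    writeResultsCSV(res, path)
    back <- readResultsCSV(path)
    expect_equal(names(back)[1:2], c("analyte", "rss0"))
    expect_equal(back$p_value, res$p_value)
    expect_equal(back$analyte, res$analyte)
})

test_that("dataset validation rejects invalid designs", {
    m <- makeMeasurements("P[1-5]_1", "A", "R1", c(0, -5), c(0.1, 0.2))
    expect_error(HDXDataset(m), "non-negative")
    m2 <- makeMeasurements("P[1-5]_1", "A", "R1", c(0, 30), c(0.1, 0.2))
    expect_error(HDXDataset(m2, conditions = character()), "condition")
})
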