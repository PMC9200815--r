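# Fixture builders used across the test files. All datasets are generated
# in code; nothing is read from disk except files the tests write first.

# A two-condition dataset whose condition means follow given kinetic
# parameter sets exactly, plus optional iid Gaussian noise.
makeCurveDataset <- function(paramsA, paramsB = paramsA,
                             times = c(0, 10, 30, 100, 300, 1000),
                             reps = 2, noise = 0, seed = NULL,
                             analyte = "PEPTIDE[1-7]_1") {
    if (!is.null(seed)) set.seed(seed)
    grid <- expand.grid(replicate = paste0("R", seq_len(reps)),
                        exposure = times, condition = c("A", "B"),
                        stringsAsFactors = FALSE)
    mu <- ifelse(grid$condition == "A",
                 evaluateModel(paramsA, grid$exposure),
                 evaluateModel(paramsB, grid$exposure))
    value <- mu + if (noise > 0) rnorm(nrow(grid), 0, noise) else 0
    m <- data.frame(analyte = analyte, sequence = "PEPTIDE", start = 1L,
                    end = 7L, charge = 1L, condition = grid$condition,
                    replicate = grid$replicate, exposure = grid$exposure,
                    value = value, value_kind = "uptake",
                    stringsAsFactors = FALSE)
    HDXDataset(m, conditions = c("A", "B"))
}

# Minimal long-format measurement table for hand-built datasets.
makeMeasurements <- function(analyte, condition, replicate, exposure,
                             value) {
    data.frame(analyte = analyte, sequence = sub("\\[.*", "", analyte),
               start = 1L, end = 5L, charge = 1L, condition = condition,
               replicate = replicate, exposure = exposure, value = value,
               value_kind = "uptake", stringsAsFactors = FALSE)
}

refParams <- c(a = 5, b = 0.1, q = 1, d = 0)
refWeibull <- c(a = 5, b = 0.05, q = 1.4, d = 2)
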