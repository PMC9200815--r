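## Residue-level summaries, plot-ready tables and the command-line entry
## point.

.parseSpans <- function(analyte) {
    m <- regmatches(analyte, regexec("\\[(\\d+)-(\\d+)\\]", analyte))
    start <- vapply(m, function(x) if (length(x) == 3L)
        as.integer(x[2]) else NA_integer_, integer(1))
    end <- vapply(m, function(x) if (length(x) == 3L)
        as.integer(x[3]) else NA_integer_, integer(1))
    data.frame(analyte = analyte, start = start, end = end,
               stringsAsFactors = FALSE)
}

#' Residue-level p-value summaries
#'
#' For each residue of the protein, the p-values of all covering peptides
#' are combined with the harmonic mean — once on raw p-values and once on
#' BH-adjusted ones. Uncovered residues get \code{NA}. The
#' \code{neg_log10} column (used for heatmap-style visualisation) is the
#' \eqn{-\log_{10}} of the adjusted summary.
#'
#' @param results Test results from [runFunctionalTest] (columns
#'   \code{analyte}, \code{p_value}, \code{p_adjusted}).
#' @param spans Optional data frame \code{analyte}, \code{start},
#'   \code{end}; parsed from the analyte identifiers when omitted.
#' @param proteinLength Total number of residues J.
#' @return Data frame: \code{residue}, \code{coverage}, \code{p_hm},
#'   \code{p_hm_adjusted}, \code{neg_log10}.
#' @export
residuePvalues <- function(results, proteinLength, spans = NULL) {
    if (is.null(spans)) spans <- .parseSpans(results$analyte)
    spans <- spans[match(results$analyte, spans$analyte), ]
    ok <- !is.na(spans$start)
    if (any(spans$start[ok] < 1 | spans$end[ok] > proteinLength))
        stop("peptide span outside [1, proteinLength]")
    out <- data.frame(residue = seq_len(proteinLength), coverage = 0L,
                      p_hm = NA_real_, p_hm_adjusted = NA_real_,
                      neg_log10 = NA_real_)
    for (j in seq_len(proteinLength)) {
        cover <- ok & spans$start <= j & spans$end >= j &
            !is.na(results$p_value)
        out$coverage[j] <- sum(cover)
        if (any(cover)) {
            out$p_hm[j] <- harmonicMeanP(results$p_value[cover])
            out$p_hm_adjusted[j] <- harmonicMeanP(results$p_adjusted[cover])
            out$neg_log10[j] <- -log10(out$p_hm_adjusted[j])
        }
    }
    out
}

#' Manhattan-plot table of peptide significance
#'
#' Orders peptides along the sequence (by start, then end) and tabulates
#' the BH-adjusted p-value, its \eqn{-\log_{10}}, and a significance flag
#' under strict inequality at \code{threshold}.
#'
#' @param results Test results from [runFunctionalTest].
#' @param spans Optional span table as in [residuePvalues].
#' @param threshold Significance threshold on adjusted p (default 0.05).
#' @return Plot-ready data frame: \code{analyte}, \code{start},
#'   \code{end}, \code{p_adjusted}, \code{neg_log10_p_adjusted},
#'   \code{significant}.
#' @export
manhattanTable <- function(results, spans = NULL, threshold = 0.05) {
    if (is.null(spans)) spans <- .parseSpans(results$analyte)
    spans <- spans[match(results$analyte, spans$analyte), ]
    out <- data.frame(analyte = results$analyte, start = spans$start,
                      end = spans$end, p_adjusted = results$p_adjusted,
                      neg_log10_p_adjusted = -log10(results$p_adjusted),
                      significant = !is.na(results$p_adjusted) &
                          results$p_adjusted < threshold,
                      stringsAsFactors = FALSE)
    out <- out[order(out$start, out$end, out$analyte), ]
    rownames(out) <- NULL
    out
}

#' Observed points and fitted curves for a kinetic plot
#'
#' Returns the observed measurements of one analyte together with the
#' null (condition-blind) and per-condition alternative curves evaluated
#' on a log-spaced grid, ready for plotting.
#'
#' @param dataset An [HDXDataset-class].
#' @param analyte Analyte identifier.
#' @param fits Optional \code{NestedFitPair} from [nestedFit]; when
#'   omitted only the observed points are returned.
#' @param n Grid size.
#' @return List with \code{points} (condition, replicate, time, value) and
#'   \code{curves} (model, condition, time, value); \code{curves} is empty
#'   without fits.
#' @export
kineticPlotData <- function(dataset, analyte, fits = NULL, n = 200) {
    s <- .seriesFor(dataset, analyte)
    points <- data.frame(condition = s$condition, replicate = s$replicate,
                         time = s$exposure, value = s$value)
    curves <- data.frame(model = character(), condition = character(),
                         time = numeric(), value = numeric())
    if (!is.null(fits)) {
        grid <- effectsGrid(range(s$exposure), n)
        curves <- data.frame(model = "null", condition = "pooled",
                             time = grid,
                             value = evaluateModel(fits$null_fit, grid))
        for (cc in names(fits$alt_fits)) {
            curves <- rbind(curves, data.frame(
                model = "alternative", condition = cc, time = grid,
                value = evaluateModel(fits$alt_fits[[cc]], grid)))
        }
    }
    list(points = points, curves = curves)
}

.cliUsage <- function() {
    paste(
        "usage: hdxanova <command> [options]",
        "",
        "commands:",
        "  simulate  --scenario 1..6 | --m M --R R  [--seed S] --out FILE",
        "            [--truth-out FILE] [--n-peptides N] [--missing F]",
        "            [--null-prob P]",
        "  test      --in FILE [--model exponential|weibull]",
        "            [--fix a=..,b=..,q=..,d=..] [--fdr F]",
        "            [--no-moderation] --out FILE",
        "  report    --in RESULTS [--manhattan FILE]",
        "            [--residue FILE --protein-length J]",
        "  benchmark --scenarios 1,2 [--reps N] [--methods m1,m2]",
        "            [--seed S] --out FILE",
        sep = "\n")
}

.cliArgs <- function(argv) {
    opts <- list()
    i <- 1L
    while (i <= length(argv)) {
        a <- argv[i]
        if (!startsWith(a, "--"))
            stop("unexpected argument: ", a)
        key <- substring(a, 3)
        if (key %in% c("no-moderation")) {
            opts[[key]] <- TRUE
            i <- i + 1L
        } else {
            if (i == length(argv)) stop("missing value for --", key)
            opts[[key]] <- argv[i + 1L]
            i <- i + 2L
        }
    }
    opts
}

.cliFix <- function(s) {
    if (is.null(s)) return(numeric())
    parts <- strsplit(s, ",")[[1]]
    kv <- strsplit(parts, "=")
    vals <- vapply(kv, function(x) as.numeric(x[2]), numeric(1))
    names(vals) <- vapply(kv, function(x) trimws(x[1]), character(1))
    vals
}

#' Command-line entry point
#'
#' Thin dispatcher over the package functions; see
#' \code{inst/scripts/hdxanova-cli.R} for the executable wrapper. Supports
#' \code{simulate}, \code{test}, \code{report} and \code{benchmark}
#' subcommands; every run logs its parameters and seed to stderr.
#'
#' @param argv Character vector of command-line arguments.
#' @return Integer exit code (0 on success), invisibly.
#' @export
cliMain <- function(argv) {
    code <- tryCatch({
        if (!length(argv) || argv[1] %in% c("-h", "--help", "help")) {
            cat(.cliUsage(), "\n")
            return(invisible(0L))
        }
        cmd <- argv[1]
        opts <- .cliArgs(argv[-1])
        getOpt <- function(key, default = NULL) {
            if (!is.null(opts[[key]])) opts[[key]] else default
        }
        if (cmd == "simulate") {
            seed <- as.integer(getOpt("seed", "1"))
            if (!is.null(getOpt("scenario"))) {
                sc <- scenarioPresets(seed)[[as.integer(opts$scenario)]]
            } else {
                sc <- hdxScenario(
                    m = as.integer(getOpt("m", "4")),
                    R = as.integer(getOpt("R", "3")),
                    missingFrac = as.numeric(getOpt("missing", "0")),
                    nullProb = as.numeric(getOpt("null-prob", "0.95")),
                    nPeptides = as.integer(getOpt("n-peptides", "500")),
                    seed = seed)
            }
            sc$nPeptides <- as.integer(getOpt("n-peptides", sc$nPeptides))
            message("simulate: seed = ", sc$seed, ", peptides = ",
                    sc$nPeptides, ", m = ", sc$m, ", R = ", sc$R)
            sim <- simulateExperiment(sc)
            writeLongCSV(sim$dataset, getOpt("out", stop("--out required")))
            if (!is.null(getOpt("truth-out")))
                utils::write.csv(sim$truth, opts[["truth-out"]],
                                 row.names = FALSE)
        } else if (cmd == "test") {
            ds <- readLongCSV(getOpt("in", stop("--in required")))
            spec <- modelSpec(getOpt("model", "weibull"),
                              fixed = .cliFix(getOpt("fix")))
            message("test: model = ", spec@form, ", fixed = {",
                    paste(names(spec@fixed), spec@fixed, sep = "=",
                          collapse = ", "), "}")
            res <- runFunctionalTest(
                ds, spec, fdrLevel = as.numeric(getOpt("fdr", "0.05")),
                moderate = is.null(opts[["no-moderation"]]))
            writeResultsCSV(res, getOpt("out", stop("--out required")))
        } else if (cmd == "report") {
            res <- readResultsCSV(getOpt("in", stop("--in required")))
            if (!is.null(getOpt("manhattan")))
                utils::write.csv(manhattanTable(res), opts$manhattan,
                                 row.names = FALSE)
            if (!is.null(getOpt("residue"))) {
                J <- as.integer(getOpt("protein-length",
                                       stop("--protein-length required")))
                utils::write.csv(residuePvalues(res, J), opts$residue,
                                 row.names = FALSE)
            }
        } else if (cmd == "benchmark") {
            seed <- as.integer(getOpt("seed", "1"))
            idx <- as.integer(strsplit(getOpt("scenarios", "1"),
                                       ",")[[1]])
            methods <- strsplit(getOpt("methods", "functional,t_test"),
                                ",")[[1]]
            message("benchmark: scenarios = ", paste(idx, collapse = ","),
                    ", seed = ", seed)
            rep <- runBenchmark(scenarioPresets(seed)[idx],
                                methods = methods,
                                nReps = as.integer(getOpt("reps", "10")),
                                seed = seed)
            utils::write.csv(rep, getOpt("out", stop("--out required")),
                             row.names = FALSE)
        } else {
            stop("unknown command: ", cmd)
        }
        0L
    }, error = function(e) {
        message("error: ", conditionMessage(e))
        message(.cliUsage())
        1L
    })
    invisible(code)
}
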