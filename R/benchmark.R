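## Comparator methods (pointwise t-tests combined by harmonic mean, linear
## mixed models) and the F-score simulation harness used to benchmark the
## functional ANOVA against them.

#' Pointwise two-sample t-tests across the time course
#'
#' Applies a two-sample t-test at every measured exposure time between the
#' first two conditions of the dataset. Time points with fewer than two
#' replicates in either group, or where both groups are degenerate (zero
#' variance, e.g. the undeuterated t = 0 point), yield \code{NA}.
#'
#' @param dataset An [HDXDataset-class].
#' @param analyte Analyte identifier.
#' @param varEqual Logical; \code{FALSE} (default) uses the Welch test,
#'   \code{TRUE} the pooled-variance form.
#' @return Data frame with columns \code{time} and \code{p}.
#' @export
pointwiseTTest <- function(dataset, analyte, varEqual = FALSE) {
    conds <- hdxConditions(dataset)
    if (length(conds) < 2L) stop("need two conditions for a t-test")
    s <- .seriesFor(dataset, analyte, conds[1:2])
    times <- sort(unique(s$exposure))
    p <- vapply(times, function(tt) {
        x <- s$value[s$exposure == tt & s$condition == conds[1]]
        y <- s$value[s$exposure == tt & s$condition == conds[2]]
        if (length(x) < 2L || length(y) < 2L) return(NA_real_)
        if (stats::var(x) == 0 && stats::var(y) == 0) {
            if (isTRUE(all.equal(mean(x), mean(y)))) return(1)
            return(NA_real_)
        }
        stats::t.test(x, y, var.equal = varEqual)$p.value
    }, numeric(1))
    data.frame(time = times, p = p)
}

#' Harmonic mean combination of p-values
#'
#' \eqn{p_{HM} = k / \sum_j 1/p_j} over the \code{k} non-\code{NA} values.
#' Any zero p-value gives 0; an all-\code{NA} input gives \code{NA}. The
#' result always lies between the smallest and largest input.
#'
#' @param p Numeric p-values in \eqn{[0, 1]}; \code{NA} dropped.
#' @return Combined p-value.
#' @export
harmonicMeanP <- function(p) {
    p <- p[!is.na(p)]
    if (!length(p)) return(NA_real_)
    if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
    if (any(p == 0)) return(0)
    length(p) / sum(1 / p)
}

#' Linear mixed-model test for one analyte
#'
#' Fits the comparator mixed model: fixed effects for time, condition and
#' their interaction, with a random intercept per replicate. By default
#' time is a factor; with \code{timeAsFactor = FALSE} time enters
#' continuously after a shifted log transform \eqn{t \to \log(t + \delta)}
#' with \eqn{\delta} the smallest positive observed time. The p-values of
#' the condition and condition-by-time coefficients are combined with the
#' harmonic mean. This comparator is prior art and delegates the fit to
#' \pkg{lmerTest}.
#'
#' @param dataset An [HDXDataset-class].
#' @param analyte Analyte identifier.
#' @param timeAsFactor Logical (default \code{TRUE}).
#' @return List with \code{coefficients} (data frame of term, estimate, p)
#'   and \code{p_combined}; \code{NA} entries when the fit is singular or
#'   the design is unreplicated.
#' @export
lmmTest <- function(dataset, analyte, timeAsFactor = TRUE) {
    s <- .seriesFor(dataset, analyte)
    empty <- list(coefficients = data.frame(term = character(),
                                            estimate = numeric(),
                                            p = numeric()),
                  p_combined = NA_real_)
    if (!nrow(s)) return(empty)
    nrep <- tapply(s$replicate, paste(s$condition, s$exposure),
                   function(x) length(unique(x)))
    if (max(nrep, na.rm = TRUE) < 2L) {
        warning("unreplicated design: linear mixed model inapplicable")
        return(empty)
    }
    d <- s
    d$condition <- factor(d$condition)
    one_time <- length(unique(d$exposure)) < 2L
    if (timeAsFactor) {
        d$time <- factor(d$exposure)
    } else {
        delta <- min(d$exposure[d$exposure > 0])
        d$time <- log(d$exposure + delta)
    }
    form <- if (one_time) value ~ condition + (1 | replicate)
            else value ~ time * condition + (1 | replicate)
    fit <- tryCatch(
        suppressMessages(suppressWarnings(
            lmerTest::lmer(form, data = d))),
        error = function(e) NULL)
    if (is.null(fit)) {
        warning("singular or failed mixed-model fit for ", analyte)
        return(empty)
    }
    cf <- tryCatch(stats::coef(summary(fit)), error = function(e) NULL)
    if (is.null(cf) || !"Pr(>|t|)" %in% colnames(cf)) {
        warning("no denominator df available for ", analyte)
        return(empty)
    }
    terms <- rownames(cf)
    keep <- grepl("condition", terms)
    coefs <- data.frame(term = terms[keep], estimate = cf[keep, "Estimate"],
                        p = cf[keep, "Pr(>|t|)"], stringsAsFactors = FALSE)
    list(coefficients = coefs, p_combined = harmonicMeanP(coefs$p))
}

#' F-score of a set of significance calls against ground truth
#'
#' Precision is \eqn{tp/(tp+fp)}, recall \eqn{tp/(tp+fn)}, and the F-score
#' their harmonic mean, with the conventions F = 1 when
#' \eqn{tp = fp = fn = 0} and F = 0 when \eqn{tp = 0} but errors exist.
#'
#' @param truth Data frame with columns \code{analyte} and
#'   \code{perturbed} (logical ground truth).
#' @param calls Data frame with columns \code{analyte} and
#'   \code{significant} (logical calls at the FDR threshold); must cover
#'   exactly the same analytes as \code{truth}.
#' @return One-row data frame: \code{tp}, \code{fp}, \code{fn},
#'   \code{precision}, \code{recall}, \code{f_score}.
#' @export
fScore <- function(truth, calls) {
    if (!setequal(truth$analyte, calls$analyte))
        stop("truth and calls must cover the same analyte set")
    calls <- calls[match(truth$analyte, calls$analyte), ]
    pos <- truth$perturbed
    sig <- calls$significant
    sig[is.na(sig)] <- FALSE
    tp <- sum(sig & pos); fp <- sum(sig & !pos); fn <- sum(!sig & pos)
    precision <- if (tp + fp > 0) tp / (tp + fp) else as.numeric(fn == 0)
    recall <- if (tp + fn > 0) tp / (tp + fn) else as.numeric(fp == 0)
    f <- if (tp == 0) as.numeric(fp + fn == 0) else
        2 * precision * recall / (precision + recall)
    data.frame(tp = tp, fp = fp, fn = fn, precision = precision,
               recall = recall, f_score = f)
}

## Per-analyte significance calls for one method on one dataset.
.methodCalls <- function(dataset, method, spec, fdrLevel = 0.05,
                         varEqual = FALSE) {
    ids <- analyteIds(dataset)
    if (method == "functional") {
        res <- runFunctionalTest(dataset, spec, fdrLevel = fdrLevel)
        return(data.frame(analyte = res$analyte,
                          p_adjusted = res$p_adjusted,
                          significant = res$significant))
    }
    p <- vapply(ids, function(id) {
        if (method == "t_test")
            harmonicMeanP(pointwiseTTest(dataset, id, varEqual)$p)
        else if (method == "lmm")
            suppressWarnings(lmmTest(dataset, id)$p_combined)
        else stop("unknown method: ", method)
    }, numeric(1))
    adj <- adjustBH(p)
    data.frame(analyte = ids, p_adjusted = adj,
               significant = !is.na(adj) & adj < fdrLevel)
}

#' Benchmark methods over simulated scenarios
#'
#' For every scenario and repetition this simulates a dataset, runs each
#' requested method, calls significance at BH-adjusted p below
#' \code{fdrLevel}, and scores the calls against the simulation truth.
#' Repetition seeds are derived deterministically from \code{seed}.
#'
#' @param scenarios List of \code{HDXScenario} objects (or a single one).
#' @param methods Character subset of
#'   \code{c("functional", "t_test", "lmm")}.
#' @param nReps Repetitions per scenario (default 10).
#' @param seed Master seed.
#' @param spec [ModelSpec-class] used by the functional method.
#' @param fdrLevel Call threshold on adjusted p-values (default 0.05).
#' @return Data frame: \code{scenario}, \code{method}, \code{rep},
#'   \code{tp}, \code{fp}, \code{fn}, \code{precision}, \code{recall},
#'   \code{f_score}.
#' @export
runBenchmark <- function(scenarios, methods = c("functional", "t_test"),
                         nReps = 10, seed = 1L,
                         spec = modelSpec("weibull"),
                         fdrLevel = 0.05) {
    if (inherits(scenarios, "HDXScenario")) scenarios <- list(scenarios)
    out <- list()
    for (si in seq_along(scenarios)) {
        for (r in seq_len(nReps)) {
            sc <- scenarios[[si]]
            sc$seed <- as.integer((seed * 1000L + si * 100L + r) %% .Machine$integer.max)
            sim <- simulateExperiment(sc)
            for (method in methods) {
                calls <- .methodCalls(sim$dataset, method, spec, fdrLevel)
                row <- fScore(sim$truth, calls)
                out[[length(out) + 1L]] <- cbind(
                    data.frame(scenario = si, method = method, rep = r),
                    row)
            }
        }
    }
    if (!length(out))
        return(data.frame(scenario = integer(), method = character(),
                          rep = integer(), tp = integer(), fp = integer(),
                          fn = integer(), precision = numeric(),
                          recall = numeric(), f_score = numeric()))
    do.call(rbind, out)
}

#' Null permutation experiment
#'
#' Splits the replicates of a single-condition dataset falsely into two
#' pseudo-conditions (sizes given by \code{split}), repeats the random
#' relabelling \code{nPerms} times, runs each method on every permuted
#' dataset, and counts analytes with adjusted p below \code{fdrLevel}.
#' Since all replicates come from one condition, every significant call is
#' a false positive.
#'
#' @param dataset Single-condition [HDXDataset-class] with at least
#'   \code{sum(split)} replicates.
#' @param split Integer pair, pseudo-condition sizes (default
#'   \code{c(3, 4)}).
#' @param nPerms Number of random permutations (default 6).
#' @param methods Methods to run (see [runBenchmark]).
#' @param seed Seed for the permutation draws.
#' @param spec [ModelSpec-class] for the functional method.
#' @param fdrLevel Call threshold.
#' @return Data frame: \code{perm}, \code{method},
#'   \code{false_positives}.
#' @export
nullPermutationExperiment <- function(dataset, split = c(3, 4), nPerms = 6,
                                      methods = c("functional", "t_test"),
                                      seed = 1L,
                                      spec = modelSpec("weibull"),
                                      fdrLevel = 0.05) {
    m <- measurements(dataset)
    reps <- unique(m$replicate)
    if (length(split) != 2L || sum(split) > length(reps))
        stop("dataset must have at least sum(split) replicates")
    if (nPerms < 1L)
        return(data.frame(perm = integer(), method = character(),
                          false_positives = integer()))
    set.seed(seed)
    out <- list()
    for (perm in seq_len(nPerms)) {
        chosen <- sample(reps, sum(split))
        groupA <- chosen[seq_len(split[1])]
        groupB <- chosen[split[1] + seq_len(split[2])]
        mm <- m[m$replicate %in% c(groupA, groupB), ]
        mm$condition <- ifelse(mm$replicate %in% groupA, "A", "B")
        pseudo <- HDXDataset(mm, conditions = c("A", "B"))
        for (method in methods) {
            calls <- .methodCalls(pseudo, method, spec, fdrLevel)
            out[[length(out) + 1L]] <- data.frame(
                perm = perm, method = method,
                false_positives = sum(calls$significant, na.rm = TRUE))
        }
    }
    do.call(rbind, out)
}
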