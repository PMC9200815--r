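#' Nested condition-blind and condition-specific fits
#'
#' Fits the uptake model twice for one analyte: once pooling all conditions
#' (the null model, blind to condition) and once per condition (the
#' alternative). The residual sum of squares of the alternative is the sum
#' over conditions. Because the fits are nonlinear, the alternative can in
#' rare cases land on a worse optimum than the null; in that case every
#' condition is refitted starting from the null solution and the better of
#' the two kept, which restores the nesting guarantee
#' \eqn{RSS_0 \ge RSS_1} up to optimizer tolerance.
#'
#' @param dataset An [HDXDataset-class].
#' @param analyte Analyte identifier.
#' @param spec A [ModelSpec-class].
#' @return A list of class \code{"NestedFitPair"} with elements
#'   \code{null_fit}, \code{alt_fits} (named by condition), \code{rss0},
#'   \code{rss1}, \code{n} (total observations) and \code{conditions}.
#' @export
nestedFit <- function(dataset, analyte, spec = modelSpec("weibull")) {
    k <- length(freeParams(spec))
    s_all <- .seriesFor(dataset, analyte)
    conds <- intersect(hdxConditions(dataset), unique(s_all$condition))
    if (length(conds) < 2L)
        stop(errorCondition(
            "analyte has observations in fewer than two conditions",
            class = "hdxInsufficientObservations"))
    null_fit <- fitKinetics(s_all$exposure, s_all$value, spec)
    alt_fits <- list()
    for (cc in conds) {
        s <- s_all[s_all$condition == cc, ]
        alt_fits[[cc]] <- fitKinetics(s$exposure, s$value, spec)
    }
    rss1 <- sum(vapply(alt_fits, function(f) f@rss, numeric(1)))
    if (rss1 > null_fit@rss + 1e-12) {
        for (cc in conds) {
            s <- s_all[s_all$condition == cc, ]
            refit <- fitKinetics(s$exposure, s$value, spec,
                                 init = coef(null_fit))
            if (refit@rss < alt_fits[[cc]]@rss) alt_fits[[cc]] <- refit
        }
        rss1 <- sum(vapply(alt_fits, function(f) f@rss, numeric(1)))
    }
    structure(list(null_fit = null_fit, alt_fits = alt_fits,
                   rss0 = null_fit@rss, rss1 = rss1,
                   n = nrow(s_all), conditions = conds),
              class = "NestedFitPair")
}

#' Degrees of freedom of the functional ANOVA
#'
#' The null model has \eqn{p_1 = k} free parameters (3 for the exponential
#' form, 4 for the Weibull, 1 in the reduced epitope configuration); the
#' alternative has \eqn{p_2 = C k}, one parameter set per condition. The
#' numerator degrees of freedom are \eqn{d_1 = p_2 - p_1} and the
#' denominator \eqn{d_2 = n_i - p_2}.
#'
#' @param spec A [ModelSpec-class].
#' @param C Number of conditions (design levels).
#' @param n Total number of observations for the analyte.
#' @return List with \code{p1}, \code{p2}, \code{d1}, \code{d2}.
#' @export
degreesOfFreedom <- function(spec, C, n) {
    k <- length(freeParams(spec))
    p1 <- k
    p2 <- C * k
    if (n <= p2)
        stop(errorCondition(
            sprintf("insufficient observations: n = %d <= p2 = %d", n, p2),
            class = "hdxInsufficientObservations"))
    list(p1 = p1, p2 = p2, d1 = p2 - p1, d2 = n - p2)
}

#' F-statistic of the nested fits
#'
#' \eqn{F = (d_2/d_1)\,(RSS_0 - RSS_1)/RSS_1}, floored at zero. A perfect
#' alternative fit (\eqn{RSS_1 = 0}) yields \code{Inf}.
#'
#' @param rss0,rss1 Residual sums of squares of the null and alternative
#'   fits.
#' @param d1,d2 Numerator and denominator degrees of freedom.
#' @return The F-statistic (possibly \code{Inf}).
#' @export
fStatistic <- function(rss0, rss1, d1, d2) {
    if (rss1 <= 0) {
        if (rss0 <= 0) return(0)
        return(Inf)
    }
    max((d2 / d1) * (rss0 - rss1) / rss1, 0)
}

## Newton inversion of the trigamma function, used to solve the
## method-of-moments equation for the prior degrees of freedom.
.trigammaInverse <- function(x) {
    if (x > 1e7) return(1 / sqrt(x))
    if (x < 1e-6) return(1 / x)
    y <- 0.5 + 1 / x
    for (i in 1:50) {
        tri <- trigamma(y)
        dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2)
        y <- y + dif
        if (abs(dif / y) < 1e-10) break
    }
    y
}

#' Empirical Bayes hyperparameters of the variance prior
#'
#' Assumes the true residual variances are drawn from a scaled inverse
#' chi-square prior with \code{d0} degrees of freedom and scale \code{s0_sq},
#' so the observed variances follow \eqn{s_i^2 \sim s_0^2 F(d_{i,2}, d_0)}.
#' The hyperparameters are estimated by matching the mean and variance of
#' \eqn{\log s_i^2} to their digamma/trigamma expressions under that law,
#' with \code{d0} obtained by Newton inversion of the trigamma function.
#' Each analyte's own denominator degrees of freedom enter the moment
#' equations, so unequal observation counts (missingness) are handled.
#'
#' When the excess spread of the log variances is non-positive the prior is
#' degenerate (\code{d0 = Inf}); with exactly zero spread the common value
#' itself is returned as \code{s0_sq}.
#'
#' @param s_sq Positive observed variances (\eqn{RSS_1/d_2} per analyte).
#' @param d2 Denominator degrees of freedom, scalar or per-analyte vector.
#' @return List with \code{d0} and \code{s0_sq}.
#' @export
estimateEBHyperparams <- function(s_sq, d2) {
    ok <- is.finite(s_sq) & s_sq > 0
    s_sq <- s_sq[ok]
    d2 <- rep_len(d2, length(ok))[ok]
    if (length(s_sq) < 2L)
        stop("cannot moderate: need at least two finite positive variances")
    z <- log(s_sq)
    if (stats::var(z) == 0)
        return(list(d0 = Inf, s0_sq = s_sq[[1]]))
    e <- z - digamma(d2 / 2) + log(d2 / 2)
    emean <- mean(e)
    evar <- sum((e - emean)^2) / (length(e) - 1) - mean(trigamma(d2 / 2))
    if (evar > 0) {
        d0 <- 2 * .trigammaInverse(evar)
        s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
    } else {
        d0 <- Inf
        s0_sq <- exp(emean)
    }
    list(d0 = d0, s0_sq = s0_sq)
}

#' Posterior (moderated) variance
#'
#' Shrinks an analyte's variance towards the prior scale:
#' \eqn{\tilde s^2 = (d_0 s_0^2 + d_2 s_i^2)/(d_0 + d_2)}. With
#' \code{d0 = 0} the observed variance is returned unchanged; with
#' \code{d0 = Inf} the prior scale is returned.
#'
#' @param s_sq Observed variance(s).
#' @param d2 Denominator degrees of freedom (vectorised with \code{s_sq}).
#' @param hyper List with \code{d0} and \code{s0_sq}, as returned by
#'   [estimateEBHyperparams].
#' @return Moderated variance(s).
#' @export
moderateVariance <- function(s_sq, d2, hyper) {
    if (is.infinite(hyper$d0)) return(rep_len(hyper$s0_sq, length(s_sq)))
    (hyper$d0 * hyper$s0_sq + d2 * s_sq) / (hyper$d0 + d2)
}

#' Moderated F-statistic
#'
#' \eqn{\tilde F = (RSS_0 - RSS_1)/(\tilde s^2 d_1)}, floored at zero. With
#' \code{d0 = 0} (so \eqn{\tilde s^2 = RSS_1/d_2}) this reduces exactly to
#' the ordinary F-statistic.
#'
#' @param rss0,rss1 Residual sums of squares.
#' @param d1 Numerator degrees of freedom.
#' @param s_tilde_sq Moderated variance.
#' @return The moderated F-statistic.
#' @export
moderatedF <- function(rss0, rss1, d1, s_tilde_sq) {
    if (s_tilde_sq <= 0) return(if (rss0 > rss1) Inf else 0)
    max((rss0 - rss1) / (s_tilde_sq * d1), 0)
}

#' Upper-tail F-test p-value
#'
#' For the ordinary statistic the reference distribution is
#' \eqn{F(d_1, d_2)}; for the moderated statistic the denominator degrees
#' of freedom are \eqn{d_0 + d_2}. An infinite denominator df is evaluated
#' through the chi-square limit \eqn{d_1 F \sim \chi^2_{d_1}}.
#'
#' @param f F-statistic value (non-negative; \code{Inf} gives p = 0).
#' @param d1 Numerator degrees of freedom.
#' @param df2 Denominator degrees of freedom (may be \code{Inf}).
#' @return Upper-tail probability.
#' @export
fPvalue <- function(f, d1, df2) {
    if (is.na(f)) return(NA_real_)
    if (is.infinite(f)) return(0)
    if (f < 0) stop("F-statistic must be non-negative")
    if (is.infinite(df2))
        stats::pchisq(d1 * f, df = d1, lower.tail = FALSE)
    else
        stats::pf(f, d1, df2, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment. \code{NA} values are propagated and excluded
#' from the family size.
#'
#' @param p Numeric vector of p-values in \eqn{[0, 1]} (\code{NA} allowed).
#' @return Adjusted p-values, same length and order as \code{p}.
#' @export
adjustBH <- function(p) {
    if (any(p < 0 | p > 1, na.rm = TRUE))
        stop("p-values must lie in [0, 1]")
    out <- rep(NA_real_, length(p))
    ok <- !is.na(p)
    out[ok] <- stats::p.adjust(p[ok], method = "BH")
    out
}

#' Run the empirical Bayes functional ANOVA over a dataset
#'
#' For every analyte with observations in at least two conditions this fits
#' the nested condition-blind/condition-specific models, computes the
#' F-statistic, moderates the denominator variance with an empirical Bayes
#' prior estimated from all testable analytes, converts the moderated
#' statistic to a p-value on \eqn{F(d_1, d_0 + d_2)} and applies
#' Benjamini-Hochberg correction across the analytes.
#'
#' Analytes that cannot be fitted (too few observations in some condition,
#' or overall \eqn{n \le p_2}) are reported with status
#' \code{"insufficient_data"} and \code{NA} p-values; they are excluded
#' from the empirical Bayes pool and from the BH family. Perfect
#' alternative fits (\eqn{RSS_1 = 0}) are assigned p = 0 and excluded from
#' the hyperparameter fit, whose log-moment equations they would break.
#'
#' @param dataset An [HDXDataset-class] with at least two conditions.
#' @param spec A [ModelSpec-class]; default Weibull form.
#' @param fdrLevel Significance threshold recorded in the
#'   \code{significant} column (default 0.05).
#' @param moderate Logical; \code{FALSE} gives the unmoderated F-test
#'   (equivalent to a prior with \code{d0 = 0}).
#' @return A data frame with one row per analyte: \code{analyte},
#'   \code{rss0}, \code{rss1}, \code{d1}, \code{d2}, \code{s_sq},
#'   \code{s_tilde_sq}, \code{F}, \code{F_moderated}, \code{p_value},
#'   \code{p_adjusted}, \code{significant}, \code{status}; the estimated
#'   hyperparameters are attached as attribute \code{"hyperparams"}.
#' @export
runFunctionalTest <- function(dataset, spec = modelSpec("weibull"),
                              fdrLevel = 0.05, moderate = TRUE) {
    C <- length(hdxConditions(dataset))
    if (C < 2L)
        stop("differential testing requires at least two conditions")
    ids <- analyteIds(dataset)
    rows <- lapply(ids, function(id) {
        res <- list(analyte = id, rss0 = NA_real_, rss1 = NA_real_,
                    d1 = NA_real_, d2 = NA_real_, s_sq = NA_real_,
                    F = NA_real_, status = "ok")
        pair <- tryCatch(nestedFit(dataset, id, spec),
                         hdxInsufficientObservations = function(e) e,
                         error = function(e) e)
        if (inherits(pair, "condition")) {
            res$status <- if (inherits(pair, "hdxInsufficientObservations"))
                "insufficient_data" else "fit_failed"
            return(res)
        }
        dof <- tryCatch(degreesOfFreedom(spec, length(pair$conditions),
                                         pair$n),
                        hdxInsufficientObservations = function(e) e)
        if (inherits(dof, "condition")) {
            res$status <- "insufficient_data"
            return(res)
        }
        res$rss0 <- pair$rss0
        res$rss1 <- pair$rss1
        res$d1 <- dof$d1
        res$d2 <- dof$d2
        res$s_sq <- pair$rss1 / dof$d2
        res$F <- fStatistic(pair$rss0, pair$rss1, dof$d1, dof$d2)
        res
    })
    out <- do.call(rbind, lapply(rows, function(r)
        as.data.frame(r, stringsAsFactors = FALSE)))
    testable <- out$status == "ok"
    perfect <- testable & out$rss1 <= 0
    pool <- testable & !perfect & is.finite(out$s_sq) & out$s_sq > 0
    if (moderate && sum(pool) >= 2L) {
        hyper <- estimateEBHyperparams(out$s_sq[pool], out$d2[pool])
    } else {
        if (moderate && any(testable))
            warning("too few analytes to moderate; ",
                    "falling back to the unmoderated F-test")
        hyper <- list(d0 = 0, s0_sq = NA_real_)
    }
    out$s_tilde_sq <- NA_real_
    out$F_moderated <- NA_real_
    out$p_value <- NA_real_
    idx <- which(testable & !perfect)
    if (length(idx)) {
        d0 <- hyper$d0
        out$s_tilde_sq[idx] <- if (d0 == 0) out$s_sq[idx] else
            moderateVariance(out$s_sq[idx], out$d2[idx], hyper)
        out$F_moderated[idx] <- mapply(moderatedF, out$rss0[idx],
                                       out$rss1[idx], out$d1[idx],
                                       out$s_tilde_sq[idx])
        out$p_value[idx] <- mapply(function(f, d1, d2)
            fPvalue(f, d1, d0 + d2),
            out$F_moderated[idx], out$d1[idx], out$d2[idx])
    }
    if (any(perfect)) {
        out$F_moderated[perfect] <- Inf
        out$p_value[perfect] <- 0
    }
    out$p_adjusted <- adjustBH(ifelse(testable, out$p_value, NA_real_))
    out$significant <- !is.na(out$p_adjusted) & out$p_adjusted < fdrLevel
    attr(out, "hyperparams") <- hyper
    attr(out, "spec") <- spec
    out
}
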