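## Effect sizes read off a pair of condition-specific fits, with Wald /
## delta-method confidence intervals. HDX kinetics vary on log-time, so the
## evaluation grid for the sup/integral effects is log-spaced with t = 0
## appended.

#' Evaluation grid over an observed time range
#'
#' @param tRange Numeric range (seconds) of observed exposures.
#' @param n Number of grid points (default 1001).
#' @return Sorted times: 0 (when in range) plus log-spaced points over the
#'   positive part of the range.
#' @export
effectsGrid <- function(tRange, n = 1001) {
    tRange <- range(tRange)
    if (diff(tRange) <= 0) stop("time range must have positive width")
    lo <- max(tRange[1], min(tRange[tRange > 0], Inf))
    if (!is.finite(lo)) stop("time range must contain a positive time")
    grid <- exp(seq(log(lo), log(tRange[2]), length.out = n))
    if (tRange[1] == 0) grid <- c(0, grid)
    grid
}

## Variance of the fitted curve at times t (delta method, free params only).
.curveVar <- function(fit, t) {
    if (!nrow(vcov(fit))) return(rep(NA_real_, length(t)))
    g <- .modelGradient(coef(fit), t)[, fit@free, drop = FALSE]
    rowSums((g %*% vcov(fit)) * g)
}

## Wald theory is invalid at the non-negativity boundary.
.atBoundary <- function(fit) {
    p <- coef(fit)[fit@free]
    any(p <= 1e-10) || ("q" %in% fit@free && p[["q"]] >= 10 - 1e-8)
}

.residDf <- function(fit) fit@nobs - length(fit@free)

.ciRow <- function(name, estimate, se, df, level, t_star = NA_real_) {
    if (is.na(se) || df < 1) {
        lo <- hi <- NA_real_
    } else {
        tq <- stats::qt(1 - (1 - level) / 2, df)
        lo <- estimate - tq * se
        hi <- estimate + tq * se
    }
    data.frame(name = name, t_star = t_star, estimate = estimate,
               confL = lo, confU = hi, level = level,
               stringsAsFactors = FALSE)
}

#' Parameter-difference effect sizes
#'
#' Differences between two condition-specific fits in the directly
#' interpretable parameters: initial (undeuterated) mass \code{d}, maximum
#' uptake \code{a + d}, rate constant \code{b} and, when the Weibull form
#' was fitted, the stretch exponent \code{q}. Confidence intervals are Wald
#' intervals from the summed covariances of the two independent fits, with
#' the t-quantile taken at the smaller of the two residual degrees of
#' freedom. Effects are reported as fit1 minus fit2; fits at the
#' non-negativity boundary get \code{NA} intervals (Wald theory is invalid
#' there).
#'
#' @param fit1,fit2 [KineticFit-class] objects for the two conditions.
#' @param level Confidence level (default 0.95).
#' @return Data frame with columns \code{name}, \code{t_star},
#'   \code{estimate}, \code{confL}, \code{confU}, \code{level}.
#' @export
parameterEffects <- function(fit1, fit2, level = 0.95) {
    pvar <- function(fit, p) {
        if (!p %in% fit@free) return(0)
        if (!nrow(vcov(fit))) return(NA_real_)
        vcov(fit)[p, p]
    }
    sumvar <- function(fit) {  # var(a + d)
        v <- pvar(fit, "a") + pvar(fit, "d")
        if (all(c("a", "d") %in% fit@free) && nrow(vcov(fit)))
            v <- v + 2 * vcov(fit)["a", "d"]
        v
    }
    df <- min(.residDf(fit1), .residDf(fit2))
    bad <- .atBoundary(fit1) || .atBoundary(fit2) ||
        !fit1@converged || !fit2@converged
    mkse <- function(v) if (bad || is.na(v)) NA_real_ else sqrt(v)
    p1 <- coef(fit1); p2 <- coef(fit2)
    out <- rbind(
        .ciRow("initial_mass_diff", p1[["d"]] - p2[["d"]],
               mkse(pvar(fit1, "d") + pvar(fit2, "d")), df, level),
        .ciRow("max_uptake_diff",
               (p1[["a"]] + p1[["d"]]) - (p2[["a"]] + p2[["d"]]),
               mkse(sumvar(fit1) + sumvar(fit2)), df, level),
        .ciRow("rate_b_diff", p1[["b"]] - p2[["b"]],
               mkse(pvar(fit1, "b") + pvar(fit2, "b")), df, level))
    if ("q" %in% fit1@free || "q" %in% fit2@free)
        out <- rbind(out,
            .ciRow("stretch_q_diff", p1[["q"]] - p2[["q"]],
                   mkse(pvar(fit1, "q") + pvar(fit2, "q")), df, level))
    out
}

#' Maximum absolute difference between two fitted curves
#'
#' \eqn{\Delta_{max} = \sup_t |\mu_1(t) - \mu_2(t)|}, taken over a
#' deterministic log-spaced grid restricted to the observed time range (the
#' fitted curve is unvalidated outside it). The confidence interval is a
#' delta-method interval at the grid argmax.
#'
#' @param fit1,fit2 [KineticFit-class] objects.
#' @param tRange Observed time range (seconds).
#' @param level Confidence level.
#' @param n Grid size.
#' @return One-row effect data frame (see [parameterEffects]).
#' @export
deltaMax <- function(fit1, fit2, tRange, level = 0.95, n = 1001) {
    grid <- effectsGrid(tRange, n)
    diff <- evaluateModel(fit1, grid) - evaluateModel(fit2, grid)
    j <- which.max(abs(diff))
    est <- abs(diff[j])
    v <- .curveVar(fit1, grid[j]) + .curveVar(fit2, grid[j])
    bad <- .atBoundary(fit1) || .atBoundary(fit2)
    se <- if (bad || is.na(v)) NA_real_ else sqrt(v)
    .ciRow("delta_max", est, se, min(.residDf(fit1), .residDf(fit2)),
           level, t_star = grid[j])
}

#' Integrated absolute difference between two fitted curves
#'
#' \eqn{\Delta_{int} = \int |\mu_1(t) - \mu_2(t)|\,dt} by the trapezoidal
#' rule on the same grid as [deltaMax]; the delta-method gradient
#' integrates the signed curve gradients.
#'
#' @inheritParams deltaMax
#' @return One-row effect data frame.
#' @export
deltaInt <- function(fit1, fit2, tRange, level = 0.95, n = 1001) {
    grid <- effectsGrid(tRange, n)
    diff <- evaluateModel(fit1, grid) - evaluateModel(fit2, grid)
    w <- diff(grid)
    trapz <- function(v) sum((v[-1] + v[-length(v)]) / 2 * w)
    est <- trapz(abs(diff))
    sgn <- sign(diff)
    v <- NA_real_
    if (nrow(vcov(fit1)) && nrow(vcov(fit2))) {
        g1 <- .modelGradient(coef(fit1), grid)[, fit1@free, drop = FALSE]
        g2 <- .modelGradient(coef(fit2), grid)[, fit2@free, drop = FALSE]
        G1 <- apply(sgn * g1, 2, trapz)
        G2 <- apply(-sgn * g2, 2, trapz)
        v <- drop(G1 %*% vcov(fit1) %*% G1 + G2 %*% vcov(fit2) %*% G2)
    }
    bad <- .atBoundary(fit1) || .atBoundary(fit2)
    se <- if (bad || is.na(v)) NA_real_ else sqrt(v)
    .ciRow("delta_int", est, se, min(.residDf(fit1), .residDf(fit2)), level)
}

#' Difference between fitted curves at a specific time
#'
#' \eqn{\Delta_{t_*} = \mu_1(t_*) - \mu_2(t_*)} (signed), with a
#' delta-method confidence interval from both fits' covariances.
#'
#' @param fit1,fit2 [KineticFit-class] objects.
#' @param tStar Non-negative time(s) of interest (seconds).
#' @param level Confidence level.
#' @return Effect data frame, one row per \code{tStar}.
#' @export
deltaAt <- function(fit1, fit2, tStar, level = 0.95) {
    if (any(tStar < 0)) stop("tStar must be non-negative")
    est <- evaluateModel(fit1, tStar) - evaluateModel(fit2, tStar)
    v <- .curveVar(fit1, tStar) + .curveVar(fit2, tStar)
    bad <- .atBoundary(fit1) || .atBoundary(fit2)
    df <- min(.residDf(fit1), .residDf(fit2))
    do.call(rbind, lapply(seq_along(tStar), function(j) {
        se <- if (bad || is.na(v[j])) NA_real_ else sqrt(v[j])
        .ciRow("delta_at", est[j], se, df, level, t_star = tStar[j])
    }))
}

#' Assemble effects into a forest-plot table
#'
#' Stacks effect rows in a stable display order: the parameter effects
#' first (initial mass, max uptake, rate, stretch), then the global curve
#' differences, then the local differences ordered by their time point.
#'
#' @param effects A data frame of effect rows (possibly concatenated from
#'   several calls), or a list of such data frames.
#' @return The re-ordered effects data frame with a \code{display_order}
#'   column.
#' @export
forestTable <- function(effects) {
    if (is.list(effects) && !is.data.frame(effects))
        effects <- do.call(rbind, effects)
    if (is.null(effects) || !nrow(effects)) {
        out <- data.frame(name = character(), t_star = numeric(),
                          estimate = numeric(), confL = numeric(),
                          confU = numeric(), level = numeric(),
                          display_order = integer())
        return(out)
    }
    rank <- match(effects$name,
                  c("initial_mass_diff", "max_uptake_diff", "rate_b_diff",
                    "stretch_q_diff", "delta_max", "delta_int", "delta_at"))
    ord <- order(rank, effects$t_star, na.last = FALSE)
    out <- effects[ord, , drop = FALSE]
    out$display_order <- seq_len(nrow(out))
    rownames(out) <- NULL
    out
}
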