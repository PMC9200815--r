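## Synthetic HDX-MS experiment generator. Peptides get a random number of
## exchangeable amides, a Dirichlet-derived incorporation schedule over the
## time grid, binomial isotope envelopes, and centroids corrupted by
## Gaussian noise. Condition effects are injected by re-sampling the
## incorporation at randomly selected time points.

.AA <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I", "L", "K", "M",
         "F", "P", "S", "T", "W", "Y", "V")
## residue monoisotopic masses (Da) and carbon counts
.AA_MASS <- c(A = 71.03711, R = 156.10111, N = 114.04293, D = 115.02694,
              C = 103.00919, E = 129.04259, Q = 128.05858, G = 57.02146,
              H = 137.05891, I = 113.08406, L = 113.08406, K = 128.09496,
              M = 131.04049, F = 147.06841, P = 97.05276, S = 87.03203,
              T = 101.04768, W = 186.07931, Y = 163.06333, V = 99.06841)
.AA_CARBON <- c(A = 3, R = 6, N = 4, D = 4, C = 3, E = 5, Q = 5, G = 2,
                H = 6, I = 6, L = 6, K = 6, M = 5, F = 9, P = 5, S = 3,
                T = 4, W = 11, Y = 9, V = 5)
.MASS_WATER <- 18.010565
.MASS_C13_SHIFT <- 1.003355   # 13C - 12C
.MASS_D_SHIFT <- 1.00628      # D - H
.P_C13 <- 0.0107              # natural 13C abundance

.defaultTimes <- function(m) {
    base <- c(0, 30, 240, 1800, 14400, 86400)
    if (m > length(base))
        stop("supply an explicit time grid for more than 6 time points")
    base[seq_len(m)]
}

#' Simulation scenario
#'
#' Bundle of design parameters for [simulateExperiment]. Defaults follow
#' the simulation protocol used to validate the method: 500 peptides, two
#' conditions, centroid noise of sd 0.05 Da, and per-time-point condition
#' effects injected with probability \code{1 - nullProb}.
#'
#' @param m Number of time points (first time is 0).
#' @param R Replicates per condition.
#' @param C Conditions (2 in all standard designs).
#' @param missingFrac Fraction of observations deleted completely at
#'   random.
#' @param nullProb Per-time-point probability that condition kinetics are
#'   unperturbed, \eqn{p(z = 0)} (default 0.95).
#' @param nPeptides Number of simulated peptides (default 500).
#' @param noiseSd Gaussian noise sd on centroids, Da (default 0.05).
#' @param times Exposure time grid (seconds); defaults to the first
#'   \code{m} of 0, 30, 240, 1800, 14400, 86400 s, log-spaced grids of the
#'   kind used in real labelling experiments.
#' @param seed Integer RNG seed for reproducibility.
#' @return A list of class \code{"HDXScenario"}.
#' @export
hdxScenario <- function(m = 4, R = 3, C = 2, missingFrac = 0,
                        nullProb = 0.95, nPeptides = 500, noiseSd = 0.05,
                        times = NULL, seed = 1L) {
    if (m < 2) stop("need at least two time points")
    if (R < 1) stop("need at least one replicate")
    if (C < 1) stop("need at least one condition")
    if (missingFrac < 0 || missingFrac >= 1)
        stop("missingFrac must be in [0, 1)")
    if (nullProb <= 0 || nullProb > 1) stop("nullProb must be in (0, 1]")
    if (is.null(times)) times <- .defaultTimes(m)
    times <- sort(as.numeric(times))
    if (length(times) != m || times[1] != 0)
        stop("times must have length m and start at 0")
    structure(list(m = m, R = R, C = C, missingFrac = missingFrac,
                   nullProb = nullProb, nPeptides = nPeptides,
                   noiseSd = noiseSd, times = times,
                   seed = as.integer(seed)),
              class = "HDXScenario")
}

#' @export
print.HDXScenario <- function(x, ...) {
    cat(sprintf(paste0("HDXScenario: %d peptides, %d time points, %d",
                       " replicates, %d conditions\n"),
                x$nPeptides, x$m, x$R, x$C))
    cat(sprintf("  times (s): %s\n", paste(x$times, collapse = ", ")))
    cat(sprintf("  p(z=0) = %g, missing = %g, noise sd = %g Da, seed = %d\n",
                x$nullProb, x$missingFrac, x$noiseSd, x$seed))
    invisible(x)
}

#' The six preset simulation designs
#'
#' Scenario 1: 4 time points, 3 replicates; Scenarios 2-4: 2 replicates
#' with 4, 5 and 6 time points; Scenario 5 adds 5\% missing values;
#' Scenario 6 additionally sets \eqn{p(z=0) = 0.99}. All use 2 conditions
#' and 500 peptides.
#'
#' @param seed Seed stored in every preset.
#' @return List of six \code{HDXScenario} objects.
#' @export
scenarioPresets <- function(seed = 1L) {
    list(
        hdxScenario(m = 4, R = 3, seed = seed),
        hdxScenario(m = 4, R = 2, seed = seed),
        hdxScenario(m = 5, R = 2, seed = seed),
        hdxScenario(m = 6, R = 2, seed = seed),
        hdxScenario(m = 6, R = 2, missingFrac = 0.05, seed = seed),
        hdxScenario(m = 6, R = 2, missingFrac = 0.05, nullProb = 0.99,
                    seed = seed))
}

#' Sample an incorporation schedule
#'
#' Draws proportions \eqn{\pi} from an (m-1)-variate Dirichlet with
#' concentration \eqn{\alpha_j = 20/j} (earlier times more concentrated,
#' matching fast-then-plateau kinetics) and returns their cumulative sums
#' as the schedule: \eqn{D_1 = 0} at \eqn{t_1 = 0}, \eqn{D_m = 1}, and
#' \eqn{D} non-decreasing by construction.
#'
#' @param m Number of time points (at least 2).
#' @return Numeric vector of length \code{m} in \eqn{[0, 1]}.
#' @export
sampleIncorporationSchedule <- function(m) {
    if (m < 2) stop("need at least two time points")
    alpha <- 20 / seq_len(m - 1)
    g <- stats::rgamma(m - 1, shape = alpha, rate = 1)
    pi <- g / sum(g)
    D <- c(0, cumsum(pi))
    D[m] <- 1   # guard against cumulative rounding
    D
}

#' Simulate an isotope envelope at a given incorporation level
#'
#' The undeuterated envelope follows a binomial heavy-carbon model
#' (\code{nCarbon} trials at natural 13C abundance); deuteration convolves
#' it with a Binomial(\code{nExchangeable}, \code{D}) distribution of
#' incorporated deuteriums (mass shift 1.00628 Da each). Peaks are grouped
#' by nominal heavy-atom count with intensity-weighted positions, so the
#' envelope centroid equals the exact expectation
#' \eqn{M_0 + n_C\,0.0107\,\Delta m_{13C} + n_{ex} D\,\Delta m_D}.
#'
#' @param monoMass Monoisotopic (all-light) peptide mass, Da.
#' @param nCarbon Number of carbon atoms.
#' @param nExchangeable Number of exchangeable amides.
#' @param D Incorporation level in \eqn{[0, 1]}.
#' @param charge Charge state of the simulated ion.
#' @return An [IsotopeSpectrum-class].
#' @export
simulateEnvelope <- function(monoMass, nCarbon, nExchangeable, D,
                             charge = 1L) {
    if (D < 0 || D > 1) stop("incorporation D must lie in [0, 1]")
    pC <- stats::dbinom(0:nCarbon, nCarbon, .P_C13)
    pD <- stats::dbinom(0:nExchangeable, nExchangeable, D)
    jc <- rep(0:nCarbon, times = nExchangeable + 1L)
    jd <- rep(0:nExchangeable, each = nCarbon + 1L)
    w <- as.vector(outer(pC, pD))
    mass <- monoMass + jc * .MASS_C13_SHIFT + jd * .MASS_D_SHIFT
    k <- jc + jd
    int_k <- tapply(w, k, sum)
    mass_k <- tapply(w * mass, k, sum) / int_k
    keep <- int_k > 1e-12
    z <- as.integer(charge)
    IsotopeSpectrum(mz = (mass_k[keep] + z) / z,
                    intensity = int_k[keep] / max(int_k),
                    charge = z)
}

## Expected centroid of the envelope above, used in the bulk simulation
## (verified against simulateEnvelope + computeCentroidMass in the tests).
.expectedCentroid <- function(monoMass, nCarbon, nExchangeable, D) {
    monoMass + nCarbon * .P_C13 * .MASS_C13_SHIFT +
        nExchangeable * D * .MASS_D_SHIFT
}

#' Simulate a full HDX-MS experiment with ground truth
#'
#' Generates \code{nPeptides} peptides (random sequences of 5-25
#' exchangeable amides), per-condition incorporation schedules, and
#' replicate centroid measurements corrupted by Gaussian noise. Condition 1
#' carries the reference schedule; for every other condition and every
#' post-zero time point an indicator \eqn{z} is drawn with
#' \eqn{p(z=1) = 1 - nullProb}, and where \eqn{z = 1} the incorporation at
#' that time point is re-drawn from the schedule-generating law, after
#' which the schedule is re-monotonised by sorting. Because the terminal
#' incorporation is pinned at 1, an indicator firing at the last time
#' point regenerates the whole condition-2 schedule instead (the
#' perturbation shows in the approach to saturation), so every fired
#' indicator produces a real signal. A peptide is labelled perturbed when
#' any of its indicators fired. Observations are then
#' deleted completely at random at rate \code{missingFrac} (stored as
#' explicit \code{NA}). The generator is fully deterministic given the
#' scenario seed.
#'
#' @param scenario An \code{HDXScenario} from [hdxScenario].
#' @return List with elements \code{dataset} (an [HDXDataset-class]) and
#'   \code{truth} (data frame: \code{analyte}, \code{perturbed}, \code{z},
#'   a "/"-separated indicator string over post-zero time points).
#' @export
simulateExperiment <- function(scenario) {
    stopifnot(inherits(scenario, "HDXScenario"))
    set.seed(scenario$seed)
    m <- scenario$m; R <- scenario$R; C <- scenario$C
    times <- scenario$times
    conds <- LETTERS[seq_len(C)]
    reps <- paste0("R", seq_len(R))
    rows <- vector("list", scenario$nPeptides)
    truth <- vector("list", scenario$nPeptides)
    for (i in seq_len(scenario$nPeptides)) {
        n_ex <- sample(5:25, 1)
        seqc <- sample(.AA, n_ex, replace = TRUE)
        sequence <- paste(seqc, collapse = "")
        mono <- sum(.AA_MASS[seqc]) + .MASS_WATER
        nC <- sum(.AA_CARBON[seqc])
        charge <- sample(1:3, 1)
        start <- sample(1:200, 1)
        analyte <- paste0(sequence, "[", start, "-", start + n_ex - 1L,
                          "]_", charge)
        D_ref <- sampleIncorporationSchedule(m)
        sched <- matrix(rep(D_ref, C), nrow = C, byrow = TRUE)
        z_any <- rep(0L, m - 1L)
        for (cc in seq_len(C)[-1]) {
            z <- stats::rbinom(m - 1L, 1L, 1 - scenario$nullProb)
            if (any(z == 1L)) {
                # terminal incorporation is pinned at 1, so a resample at
                # t_m regenerates the whole approach to saturation instead
                D_new <- if (z[m - 1L] == 1L) sampleIncorporationSchedule(m)
                         else sched[cc, ]
                for (j in setdiff(which(z == 1L) + 1L, m))
                    D_new[j] <- sampleIncorporationSchedule(m)[j]
                D_new[-1] <- sort(D_new[-1])
                D_new[m] <- 1
                sched[cc, ] <- D_new
                z_any <- pmax(z_any, z)
            }
        }
        base <- .expectedCentroid(mono, nC, n_ex, 0)
        grid <- expand.grid(replicate = reps, exposure = times,
                            condition = conds, stringsAsFactors = FALSE)
        Dv <- sched[cbind(match(grid$condition, conds),
                          match(grid$exposure, times))]
        mu <- base + n_ex * Dv * .MASS_D_SHIFT
        value <- mu + stats::rnorm(nrow(grid), 0, scenario$noiseSd)
        rows[[i]] <- data.frame(
            analyte = analyte, sequence = sequence, start = start,
            end = start + n_ex - 1L, charge = charge,
            condition = grid$condition, replicate = grid$replicate,
            exposure = grid$exposure, value = value,
            value_kind = "centroid", stringsAsFactors = FALSE)
        truth[[i]] <- data.frame(
            analyte = analyte, perturbed = any(z_any == 1L),
            z = paste(z_any, collapse = "/"), stringsAsFactors = FALSE)
    }
    meas <- do.call(rbind, rows)
    if (scenario$missingFrac > 0) {
        drop <- stats::runif(nrow(meas)) < scenario$missingFrac
        meas$value[drop] <- NA_real_
    }
    list(dataset = HDXDataset(meas, conditions = conds, times = times),
         truth = do.call(rbind, truth))
}
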