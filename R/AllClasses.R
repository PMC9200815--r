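#' @import methods
NULL

## Central S4 classes. Measurements are kept in long format: HDX-MS designs
## are ragged (missingness, per-condition replicate counts), so a long table
## is the natural container rather than a rectangular assay.

#' Isotope spectrum of a peptide ion
#'
#' Container for a centroided isotope envelope: mass-to-charge values (Th),
#' their relative intensities and the precursor charge state.
#'
#' @slot mz Numeric, strictly increasing mass-to-charge values (Th).
#' @slot intensity Numeric, non-negative relative abundances; at least one
#'   must be strictly positive.
#' @slot charge Integer scalar, positive precursor charge.
#'
#' @examples
#' sp <- IsotopeSpectrum(mz = c(500.5, 501.0), intensity = c(1, 0.5),
#'                       charge = 2L)
#' computeCentroidMass(sp)
#' @export
setClass("IsotopeSpectrum",
         representation(mz = "numeric", intensity = "numeric",
                        charge = "integer"))

setValidity("IsotopeSpectrum", function(object) {
    msg <- character()
    if (length(object@mz) != length(object@intensity))
        msg <- c(msg, "mz and intensity must have equal length")
    if (length(object@mz) == 0L)
        msg <- c(msg, "spectrum must contain at least one peak")
    if (anyNA(object@mz) || anyNA(object@intensity))
        msg <- c(msg, "mz and intensity must be finite")
    else {
        if (any(object@intensity < 0))
            msg <- c(msg, "intensities must be non-negative")
        if (!any(object@intensity > 0))
            msg <- c(msg, "empty spectrum: all intensities are zero")
        if (is.unsorted(object@mz, strictly = TRUE))
            msg <- c(msg, "mz values must be strictly increasing")
    }
    if (length(object@charge) != 1L || is.na(object@charge) ||
        object@charge < 1L)
        msg <- c(msg, "charge must be a single positive integer")
    if (length(msg)) msg else TRUE
})

#' @param mz,intensity,charge See slot descriptions.
#' @rdname IsotopeSpectrum-class
#' @export
IsotopeSpectrum <- function(mz, intensity, charge = 1L) {
    new("IsotopeSpectrum", mz = as.numeric(mz),
        intensity = as.numeric(intensity), charge = as.integer(charge))
}

setMethod("show", "IsotopeSpectrum", function(object) {
    cat("IsotopeSpectrum:", length(object@mz), "peaks, charge",
        object@charge, "\n")
    cat("  m/z range: [", min(object@mz), ", ", max(object@mz), "]\n",
        sep = "")
})

#' Dataset of centroided HDX-MS measurements
#'
#' Long-format container for deuterium-uptake time courses. Each row of the
#' measurement table is one observation y_icr(t): an analyte (peptide
#' sequence, residue span, charge state) measured in one condition and
#' replicate at one exposure time. Missing observations are stored explicitly
#' as \code{NA} values and dropped at fit time.
#'
#' @slot measurements A \code{data.frame} with columns \code{analyte},
#'   \code{sequence}, \code{start}, \code{end}, \code{charge},
#'   \code{condition}, \code{replicate}, \code{exposure} (seconds),
#'   \code{value} (Da, possibly \code{NA}) and \code{value_kind}.
#' @slot conditions Ordered character vector of condition labels.
#' @slot times Sorted numeric vector of the design exposure times (seconds).
#'
#' @details Residue coordinates \code{start}/\code{end} are 1-based inclusive.
#' Each (sequence, start, end, charge) tuple is a distinct analyte, matching
#' the convention of fitting charge states independently.
#' @export
setClass("HDXDataset",
         representation(measurements = "data.frame", conditions = "character",
                        times = "numeric"))

.MEAS_COLS <- c("analyte", "sequence", "start", "end", "charge",
                "condition", "replicate", "exposure", "value", "value_kind")

setValidity("HDXDataset", function(object) {
    msg <- character()
    m <- object@measurements
    missing_cols <- setdiff(.MEAS_COLS, names(m))
    if (length(missing_cols))
        return(paste("missing measurement columns:",
                     paste(missing_cols, collapse = ", ")))
    if (length(object@conditions) < 1L)
        msg <- c(msg, "at least one condition is required")
    if (anyDuplicated(object@conditions))
        msg <- c(msg, "condition labels must be unique")
    if (nrow(m)) {
        if (anyNA(m$exposure) || any(m$exposure < 0))
            msg <- c(msg, "exposure times must be non-negative and finite")
        if (!all(m$condition %in% object@conditions))
            msg <- c(msg, "measurement conditions outside the declared set")
        if (any(m$start > m$end, na.rm = TRUE))
            msg <- c(msg, "analyte start must be <= end")
        key <- paste(m$analyte, m$condition, m$replicate, m$exposure,
                     sep = "\r")
        if (anyDuplicated(key)) {
            dup <- unique(key[duplicated(key)])
            msg <- c(msg, paste0("duplicated (analyte, condition, replicate,",
                                 " exposure) rows: ",
                                 paste(utils::head(gsub("\r", "/", dup), 5),
                                       collapse = "; ")))
        }
    }
    if (length(msg)) msg else TRUE
})

#' @param measurements,conditions,times See slot descriptions; defaults are
#'   derived from \code{measurements} when omitted.
#' @rdname HDXDataset-class
#' @export
HDXDataset <- function(measurements, conditions = NULL, times = NULL) {
    measurements <- as.data.frame(measurements)
    if (is.null(conditions))
        conditions <- unique(as.character(measurements$condition))
    if (is.null(times))
        times <- sort(unique(measurements$exposure))
    measurements$analyte <- as.character(measurements$analyte)
    measurements$condition <- as.character(measurements$condition)
    new("HDXDataset", measurements = measurements,
        conditions = as.character(conditions), times = as.numeric(times))
}

setMethod("show", "HDXDataset", function(object) {
    m <- object@measurements
    cat("HDXDataset with", length(unique(m$analyte)), "analytes,",
        length(object@conditions), "conditions,",
        length(object@times), "time points\n")
    cat("  conditions:", paste(object@conditions, collapse = ", "), "\n")
    cat("  times (s):", paste(signif(object@times, 4), collapse = ", "), "\n")
    cat("  measurements:", nrow(m),
        sprintf("(%d missing)\n", sum(is.na(m$value))))
})

#' Kinetic model specification
#'
#' Describes the functional form used to model deuterium uptake and any
#' parameters held fixed during fitting. The exponential form is
#' \eqn{\mu(t) = a(1 - e^{-bt}) + d} (the stretch exponent \eqn{q} fixed at
#' 1); the Weibull form frees \eqn{q}: \eqn{\mu(t) = a(1 - e^{-bt^q}) + d}.
#'
#' @slot form Either \code{"exponential"} or \code{"weibull"}.
#' @slot fixed Named numeric vector of parameters (among \code{a}, \code{b},
#'   \code{q}, \code{d}) held at fixed values.
#' @export
setClass("ModelSpec",
         representation(form = "character", fixed = "numeric"))

setValidity("ModelSpec", function(object) {
    msg <- character()
    if (length(object@form) != 1L ||
        !object@form %in% c("exponential", "weibull"))
        msg <- c(msg, "form must be 'exponential' or 'weibull'")
    if (length(object@fixed)) {
        if (is.null(names(object@fixed)) ||
            !all(names(object@fixed) %in% c("a", "b", "q", "d")))
            msg <- c(msg, "fixed parameters must be named among a, b, q, d")
        if (any(object@fixed < 0, na.rm = TRUE))
            msg <- c(msg, "fixed parameter values must be non-negative")
    }
    if (identical(object@form, "exponential") &&
        !isTRUE(all.equal(unname(object@fixed["q"]), 1)))
        msg <- c(msg, "exponential form requires q fixed at 1")
    if (length(setdiff(c("a", "b", "q", "d"), names(object@fixed))) < 1L)
        msg <- c(msg, "at least one parameter must remain free")
    if (length(msg)) msg else TRUE
})

#' @param form,fixed See slot descriptions. For the exponential form
#'   \code{q = 1} is added to \code{fixed} automatically.
#' @rdname ModelSpec-class
#' @export
modelSpec <- function(form = c("exponential", "weibull"), fixed = numeric()) {
    form <- match.arg(form)
    fixed <- fixed[!is.na(fixed)]
    if (form == "exponential" && !"q" %in% names(fixed))
        fixed <- c(fixed, q = 1)
    new("ModelSpec", form = form, fixed = fixed)
}

#' Names of the free parameters of a model specification
#' @param spec A \code{ModelSpec}.
#' @return Character vector, subset of \code{c("a","b","q","d")}.
#' @export
freeParams <- function(spec) {
    setdiff(c("a", "b", "q", "d"), names(spec@fixed))
}

setMethod("show", "ModelSpec", function(object) {
    cat("ModelSpec:", object@form, "form;",
        length(freeParams(object)), "free parameters\n")
    if (length(object@fixed))
        cat("  fixed:", paste(names(object@fixed), "=", object@fixed,
                              collapse = ", "), "\n")
})

#' Fitted kinetic curve
#'
#' Result of a bounded nonlinear least-squares fit of the uptake model to one
#' series of (time, value) observations.
#'
#' @slot params Named numeric of length 4 (\code{a}, \code{b}, \code{q},
#'   \code{d}), fixed parameters included at their fixed values.
#' @slot free Character vector naming the parameters that were estimated.
#' @slot cov Covariance matrix of the free parameters (Gauss-Newton
#'   approximation), or a 0x0 matrix when unavailable.
#' @slot rss Residual sum of squares at the solution.
#' @slot nobs Number of observations used.
#' @slot converged Logical convergence flag.
#' @slot iterations Iterations used by the optimizer.
#' @export
setClass("KineticFit",
         representation(params = "numeric", free = "character",
                        cov = "matrix", rss = "numeric", nobs = "integer",
                        converged = "logical", iterations = "integer"))

setValidity("KineticFit", function(object) {
    msg <- character()
    if (!identical(sort(names(object@params)), c("a", "b", "d", "q")))
        msg <- c(msg, "params must be named a, b, q, d")
    if (length(object@rss) != 1L || is.na(object@rss) || object@rss < -1e-12)
        msg <- c(msg, "rss must be a non-negative scalar")
    if (object@nobs < length(object@free))
        msg <- c(msg, "nobs must be >= the number of free parameters")
    if (nrow(object@cov) &&
        !isTRUE(all.equal(object@cov, t(object@cov), tolerance = 1e-8)))
        msg <- c(msg, "covariance must be symmetric")
    if (length(msg)) msg else TRUE
})

setMethod("show", "KineticFit", function(object) {
    cat("KineticFit (", length(object@free), " free params, ",
        object@nobs, " obs)\n", sep = "")
    print(signif(object@params, 6))
    cat("  rss:", signif(object@rss, 6),
        "converged:", object@converged, "\n")
})

#' @describeIn KineticFit-class Fitted parameters (all four, fixed included).
#' @param object A \code{KineticFit}.
#' @param ... Ignored.
#' @export
setMethod("coef", "KineticFit", function(object, ...) object@params)

#' @describeIn KineticFit-class Covariance of the free parameters.
#' @export
setMethod("vcov", "KineticFit", function(object, ...) object@cov)

## --- light accessors -------------------------------------------------------

#' Accessors for HDXDataset
#'
#' @param object An \code{HDXDataset}.
#' @return \code{hdxConditions}: character vector of condition labels;
#'   \code{exposureTimes}: numeric vector of design times (s);
#'   \code{analyteIds}: character vector of analyte identifiers;
#'   \code{measurements}: the long measurement table.
#' @name hdx-accessors
NULL

#' @rdname hdx-accessors
#' @export
hdxConditions <- function(object) object@conditions

#' @rdname hdx-accessors
#' @export
exposureTimes <- function(object) object@times

#' @rdname hdx-accessors
#' @export
analyteIds <- function(object) unique(object@measurements$analyte)

#' @rdname hdx-accessors
#' @export
measurements <- function(object) object@measurements
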