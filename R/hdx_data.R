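#' Centroid (neutral) mass of an isotope spectrum
#'
#' Summarises an isotope envelope into a single mass: the intensity-weighted
#' mean of the m/z values, multiplied by the charge and reduced by the mass
#' of the charging protons (taken as 1 Da per charge, the convention of
#' centroided HDX uptake tables).
#'
#' @param spectrum An [IsotopeSpectrum-class] object.
#' @return Centroid mass in Da.
#' @examples
#' computeCentroidMass(IsotopeSpectrum(500.5, 1, charge = 2L))  # 999
#' @export
computeCentroidMass <- function(spectrum) {
    stopifnot(is(spectrum, "IsotopeSpectrum"))
    validObject(spectrum)
    w <- spectrum@intensity
    if (!any(w > 0)) stop("empty spectrum: all intensities are zero")
    z <- as.numeric(spectrum@charge)
    sum(spectrum@mz * w) / sum(w) * z - z
}

#' Read a long-format HDX-MS CSV
#'
#' Canonical reader for the package's long format: one row per observation
#' with columns \code{analyte_sequence}, \code{start}, \code{end},
#' \code{charge}, \code{condition}, \code{replicate}, \code{exposure_s},
#' \code{value}, \code{value_kind}. Other column names can be mapped via
#' \code{columnMap}.
#'
#' @param path Path to a CSV file.
#' @param columnMap Named character vector mapping canonical names (the
#'   names) to file column names (the values); defaults to the canonical
#'   names themselves.
#' @return An [HDXDataset-class].
#' @export
readLongCSV <- function(path, columnMap = NULL) {
    canonical <- c(analyte_sequence = "analyte_sequence", start = "start",
                   end = "end", charge = "charge", condition = "condition",
                   replicate = "replicate", exposure_s = "exposure_s",
                   value = "value", value_kind = "value_kind")
    if (!is.null(columnMap)) canonical[names(columnMap)] <- columnMap
    raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
    required <- canonical[setdiff(names(canonical), "value_kind")]
    missing_cols <- required[!required %in% names(raw)]
    if (length(missing_cols))
        stop("missing required column(s): ",
             paste(missing_cols, collapse = ", "))
    exposure <- suppressWarnings(as.numeric(raw[[canonical["exposure_s"]]]))
    bad <- which(is.na(exposure) & !is.na(raw[[canonical["exposure_s"]]]))
    if (length(bad))
        stop("non-numeric exposure time at line(s): ",
             paste(bad + 1L, collapse = ", "))
    if (anyNA(exposure))
        stop("missing exposure time at line(s): ",
             paste(which(is.na(exposure)) + 1L, collapse = ", "))
    kind <- if (canonical["value_kind"] %in% names(raw))
        as.character(raw[[canonical["value_kind"]]]) else "centroid"
    m <- data.frame(
        sequence = as.character(raw[[canonical["analyte_sequence"]]]),
        start = as.integer(raw[[canonical["start"]]]),
        end = as.integer(raw[[canonical["end"]]]),
        charge = as.integer(raw[[canonical["charge"]]]),
        condition = as.character(raw[[canonical["condition"]]]),
        replicate = as.character(raw[[canonical["replicate"]]]),
        exposure = exposure,
        value = suppressWarnings(as.numeric(raw[[canonical["value"]]])),
        value_kind = kind,
        stringsAsFactors = FALSE)
    m$analyte <- paste0(m$sequence, "[", m$start, "-", m$end, "]_", m$charge)
    HDXDataset(m[, .MEAS_COLS])
}

#' Write an HDXDataset as the canonical long CSV
#'
#' Inverse of [readLongCSV]; round-trips every measurement, including
#' explicit missing values.
#'
#' @param dataset An [HDXDataset-class].
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
writeLongCSV <- function(dataset, path) {
    m <- measurements(dataset)
    out <- data.frame(analyte_sequence = m$sequence, start = m$start,
                      end = m$end, charge = m$charge,
                      condition = m$condition, replicate = m$replicate,
                      exposure_s = m$exposure, value = m$value,
                      value_kind = m$value_kind)
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Read a vendor-style state-data CSV
#'
#' Reads cluster/state exports with columns \code{Protein}, \code{Sequence},
#' \code{Start}, \code{End}, \code{State}, \code{Exposure}, \code{Charge}
#' and either \code{Center} (centroid m/z; converted to neutral mass using
#' the charge) or \code{Uptake} (Da). The \code{State} column becomes the
#' condition. Replicate labels are taken from a \code{File} or
#' \code{Replicate} column when present, otherwise enumerated per
#' (analyte, state, exposure).
#'
#' @param path Path to the CSV.
#' @param exposureUnit \code{"s"} (default) or \code{"min"}; exposures are
#'   converted to seconds internally.
#' @return An [HDXDataset-class].
#' @export
readStateCSV <- function(path, exposureUnit = c("s", "min")) {
    exposureUnit <- match.arg(exposureUnit)
    raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
    required <- c("Sequence", "Start", "End", "State", "Exposure")
    missing_cols <- setdiff(required, names(raw))
    if (length(missing_cols))
        stop("missing required column(s): ",
             paste(missing_cols, collapse = ", "))
    has_center <- "Center" %in% names(raw)
    has_uptake <- "Uptake" %in% names(raw)
    if (!has_center && !has_uptake)
        stop("neither 'Center' nor 'Uptake' column present")
    known <- c(required, "Protein", "Charge", "Center", "Uptake", "File",
               "Replicate", "MaxUptake")
    extra <- setdiff(names(raw), known)
    if (length(extra))
        warning("ignoring unknown column(s): ", paste(extra, collapse = ", "))
    charge <- if ("Charge" %in% names(raw)) as.integer(raw$Charge) else 1L
    exposure <- as.numeric(raw$Exposure)
    if (exposureUnit == "min") exposure <- exposure * 60
    if (has_center) {
        value <- as.numeric(raw$Center) * charge - charge
        kind <- "centroid"
    } else {
        value <- as.numeric(raw$Uptake)
        kind <- "uptake"
    }
    rep_lab <- if ("Replicate" %in% names(raw)) as.character(raw$Replicate)
               else if ("File" %in% names(raw)) as.character(raw$File)
               else NA_character_
    m <- data.frame(sequence = as.character(raw$Sequence),
                    start = as.integer(raw$Start),
                    end = as.integer(raw$End),
                    charge = charge,
                    condition = as.character(raw$State),
                    replicate = rep_lab,
                    exposure = exposure, value = value, value_kind = kind,
                    stringsAsFactors = FALSE)
    if (anyNA(m$replicate)) {
        key <- paste(m$sequence, m$charge, m$condition, m$exposure)
        m$replicate <- as.character(stats::ave(seq_len(nrow(m)), key,
                                               FUN = seq_along))
    }
    m$analyte <- paste0(m$sequence, "[", m$start, "-", m$end, "]_", m$charge)
    HDXDataset(m[, .MEAS_COLS])
}

#' Write a results table to CSV
#'
#' Serialises the per-analyte test results (and, if supplied, effect
#' estimates merged on analyte) with a deterministic column order.
#'
#' @param results Data frame as returned by [runFunctionalTest].
#' @param path Output file path.
#' @param effects Optional effects table as returned by [forestTable]
#'   with an \code{analyte} column; written alongside as wide columns.
#' @return \code{path}, invisibly.
#' @export
writeResultsCSV <- function(results, path, effects = NULL) {
    lead <- c("analyte", "rss0", "rss1", "d1", "d2", "s_sq", "s_tilde_sq",
              "F", "F_moderated", "p_value", "p_adjusted", "status")
    cols <- c(intersect(lead, names(results)),
              sort(setdiff(names(results), lead)))
    out <- results[, cols, drop = FALSE]
    if (!is.null(effects) && nrow(effects)) {
        key <- ifelse(is.na(effects$t_star), effects$name,
                      paste0(effects$name, "_t", effects$t_star))
        for (field in c("estimate", "confL", "confU")) {
            w <- stats::reshape(
                data.frame(analyte = effects$analyte, key = key,
                           v = effects[[field]]),
                idvar = "analyte", timevar = "key", direction = "wide")
            names(w) <- sub("^v\\.", paste0(field, "."), names(w))
            out <- merge(out, w, by = "analyte", all.x = TRUE, sort = FALSE)
        }
    }
    utils::write.csv(out, path, row.names = FALSE)
    invisible(path)
}

#' Read back a results CSV written by [writeResultsCSV]
#' @param path Path to the CSV.
#' @return A data frame.
#' @export
readResultsCSV <- function(path) {
    utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

## Internal: observed (t, y) series for one analyte, optionally one condition
.seriesFor <- function(dataset, analyte, condition = NULL) {
    m <- measurements(dataset)
    keep <- m$analyte == analyte & !is.na(m$value)
    if (!is.null(condition)) keep <- keep & m$condition %in% condition
    m[keep, c("exposure", "value", "condition", "replicate")]
}
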