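#' Lead names of the standard 12-lead ECG
#'
#' Order used throughout the package: limb leads, augmented limb leads,
#' precordial leads.
#' @export
ECG_LEADS <- c("I", "II", "III", "aVR", "aVL", "aVF",
               "V1", "V2", "V3", "V4", "V5", "V6")

# The 8 linearly independent leads; III/aVR/aVL/aVF are derived from I and II.
INDEPENDENT_LEADS <- c("I", "II", "V1", "V2", "V3", "V4", "V5", "V6")

#' Construct a 12-lead ECG record
#'
#' @param signals numeric matrix, one column per lead, columns named with
#'   [ECG_LEADS] (any order, all 12 required).
#' @param rate sampling rate in Hz.
#' @return An object of class `ecg_record`: the signal matrix (columns in
#'   canonical lead order) with attributes `rate` (Hz) and `duration` (s).
#' @export
ecg_record <- function(signals, rate) {
  stopifnot(is.matrix(signals), rate > 0)
  if (!all(ECG_LEADS %in% colnames(signals)))
    stop("signals must contain all 12 leads: missing ",
         paste(setdiff(ECG_LEADS, colnames(signals)), collapse = ", "))
  x <- signals[, ECG_LEADS, drop = FALSE]
  structure(x, rate = rate, duration = nrow(x) / rate, class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> 12 leads, %.1f s @ %g Hz (%d samples)\n",
              attr(x, "duration"), attr(x, "rate"), nrow(x)))
  invisible(x)
}

#' Construct a 3-lead vectorcardiogram record
#'
#' @param xyz numeric matrix with columns X, Y, Z (mV).
#' @param rate sampling rate in Hz.
#' @return Object of class `vcg_record`.
#' @export
vcg_record <- function(xyz, rate) {
  stopifnot(is.matrix(xyz), ncol(xyz) == 3, rate > 0)
  colnames(xyz) <- c("X", "Y", "Z")
  structure(xyz, rate = rate, duration = nrow(xyz) / rate, class = "vcg_record")
}

#' @export
print.vcg_record <- function(x, ...) {
  cat(sprintf("<vcg_record> X/Y/Z, %.1f s @ %g Hz (%d samples)\n",
              attr(x, "duration"), attr(x, "rate"), nrow(x)))
  invisible(x)
}

#' Sampling rate of a record
#' @param x an `ecg_record`, `vcg_record` or `paper_ecg` object.
#' @return Sampling rate in Hz.
#' @export
sample_rate <- function(x) attr(x, "rate")

#' Paper-ECG signal bundle
#'
#' The content of a standard 3x4 simultaneous-lead paper printout after
#' digitization: each of the 12 leads carries only its 2.5-s column segment,
#' plus one full-length rhythm (reference) lead.
#'
#' @param segments named list (one entry per lead) of
#'   `list(samples = numeric, offset = seconds)`; offsets must be one of
#'   0, 2.5, 5, 7.5 per the 3x4 layout.
#' @param reference_lead lead name of the rhythm strip.
#' @param reference full-length samples of the reference lead (>= 10 s).
#' @param rate sampling rate in Hz.
#' @return Object of class `paper_ecg`.
#' @export
paper_ecg <- function(segments, reference_lead, reference, rate) {
  stopifnot(rate > 0)
  if (!all(ECG_LEADS %in% names(segments)))
    stop("segments must cover all 12 leads")
  offs <- vapply(segments, function(s) s$offset, numeric(1))
  if (!all(offs %in% c(0, 2.5, 5, 7.5)))
    stop("segment offsets must lie on the 2.5-s column grid")
  if (!reference_lead %in% ECG_LEADS) stop("unknown reference lead")
  if (length(reference) < 10 * rate)
    stop("reference lead must cover at least 10 s")
  structure(list(segments = segments[ECG_LEADS],
                 reference_lead = reference_lead,
                 reference = reference),
            rate = rate, class = "paper_ecg")
}

#' @export
print.paper_ecg <- function(x, ...) {
  r <- attr(x, "rate")
  cat(sprintf("<paper_ecg> 12 x 2.5-s segments + %s rhythm strip (%.1f s) @ %g Hz\n",
              x$reference_lead, length(x$reference) / r, r))
  invisible(x)
}

#' Write a 12-lead record as CSV
#'
#' One column per lead, header row of lead names; a JSON sidecar carries the
#' sampling rate.
#' @param record an `ecg_record`.
#' @param path CSV output path.
#' @export
write_ecg_csv <- function(record, path) {
  utils::write.csv(as.data.frame(unclass(record)[, , drop = FALSE]),
                   path, row.names = FALSE)
  jsonlite::write_json(list(rate = attr(record, "rate"), leads = ECG_LEADS),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a 12-lead record from CSV written by [write_ecg_csv()]
#' @param path CSV path (expects `<path>.json` sidecar with the rate).
#' @param rate sampling rate; taken from the sidecar when NULL.
#' @return An `ecg_record`.
#' @export
read_ecg_csv <- function(path, rate = NULL) {
  x <- as.matrix(utils::read.csv(path, check.names = FALSE))
  if (is.null(rate)) {
    side <- paste0(path, ".json")
    if (!file.exists(side)) stop("no rate given and no JSON sidecar found")
    rate <- jsonlite::read_json(side)$rate
  }
  ecg_record(x, rate)
}

#' Write / read a paper-ECG bundle as JSON
#'
#' Serialises the twelve 2.5-s segments with their column offsets, the
#' reference lead and the sampling rate.
#' @param paper a [paper_ecg()] bundle.
#' @param path JSON file path.
#' @export
write_paper_json <- function(paper, path) {
  jsonlite::write_json(
    list(rate = attr(paper, "rate"), reference_lead = paper$reference_lead,
         reference = paper$reference, segments = paper$segments),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_paper_json
#' @return `read_paper_json()` returns the [paper_ecg()] bundle.
#' @export
read_paper_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  segs <- lapply(j$segments, function(s)
    list(samples = as.numeric(s$samples), offset = as.numeric(s$offset)))
  paper_ecg(segs, j$reference_lead, as.numeric(j$reference), j$rate)
}
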