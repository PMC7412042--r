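# 12-lead ECG <-> 3-lead VCG affine transformation.

#' Inverse Dower transformation matrix
#'
#' The standard 3 x 8 linear map from the eight independent leads
#' (I, II, V1-V6) to the orthogonal (X, Y, Z) vectorcardiogram channels
#' (Edenbrandt-Pahlm coefficients).  Used as the documented default; a
#' customised infarction-aware matrix can be injected wherever a
#' `transform_matrix` is accepted.
#'
#' @export
INVERSE_DOWER <- local({
  m <- matrix(c(
    # V1      V2      V3      V4      V5      V6      I       II
    -0.172, -0.074,  0.122,  0.231,  0.239,  0.194,  0.156, -0.010,  # X
     0.057, -0.019, -0.106, -0.022,  0.041,  0.048, -0.227,  0.887,  # Y
    -0.229, -0.310, -0.246, -0.063,  0.055,  0.108,  0.022,  0.102), # Z
    nrow = 3, byrow = TRUE,
    dimnames = list(c("X", "Y", "Z"),
                    c("V1", "V2", "V3", "V4", "V5", "V6", "I", "II")))
  m[, INDEPENDENT_LEADS]
})

#' Construct a lead-to-VCG transformation matrix
#'
#' @param coef 3 x 8 numeric matrix; columns must be named with the eight
#'   independent leads (any order), rows map to X, Y, Z.
#' @param name provenance tag.
#' @return Object of class `transform_matrix`.
#' @export
transform_matrix <- function(coef, name = "custom") {
  stopifnot(is.matrix(coef), nrow(coef) == 3)
  if (!all(INDEPENDENT_LEADS %in% colnames(coef)))
    stop("transform matrix must have columns for leads: ",
         paste(INDEPENDENT_LEADS, collapse = ", "))
  coef <- coef[, INDEPENDENT_LEADS, drop = FALSE]
  if (!all(is.finite(coef))) stop("non-finite transform coefficients")
  if (qr(coef)$rank < 3) stop("transform matrix must have full row rank")
  rownames(coef) <- c("X", "Y", "Z")
  structure(coef, name = name, class = "transform_matrix")
}

#' Transform a 12-lead ECG record into a VCG record
#'
#' Each VCG channel is the stated linear combination of the eight independent
#' leads, sample-wise.  The redundant limb leads (III, aVR, aVL, aVF) are not
#' consumed: they are linear in I and II by definition, and using
#' independently reconstructed copies would re-introduce inconsistency.
#'
#' @param record an [ecg_record()].
#' @param matrix a [transform_matrix()] or a plain 3 x 8 matrix with lead
#'   column names; default [INVERSE_DOWER].
#' @return A [vcg_record()] of the same length and rate.
#' @export
ecg_to_vcg <- function(record, matrix = INVERSE_DOWER) {
  stopifnot(inherits(record, "ecg_record"))
  if (!inherits(matrix, "transform_matrix"))
    matrix <- transform_matrix(matrix, name = "inverse_dower")
  e8 <- unclass(record)[, INDEPENDENT_LEADS, drop = FALSE]
  vcg_record(e8 %*% t(unclass(matrix)), attr(record, "rate"))
}

#' Read a transform matrix from CSV (rows X,Y,Z; columns = lead names)
#' @param path CSV file.
#' @return A [transform_matrix()].
#' @export
read_transform_matrix <- function(path) {
  m <- as.matrix(utils::read.csv(path, row.names = 1, check.names = FALSE))
  transform_matrix(m, name = basename(path))
}
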