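# Paper-ECG rendering and digitization.
#
# Rendering produces a standard 3x4 simultaneous-lead page (25 mm/s,
# 10 mm/mV, red millimetre grid, black traces, plus a 10-s rhythm strip) as
# an in-memory RGB raster; digitization inverts it: grid/background removal
# by colour thresholding, column-wise pixel tracing, and calibration from a
# three-point reference frame.  Rendering exists so that digitization can be
# validated by round-trip against known signals.

PAPER_SPEED_MM_S <- 25     # paper speed
PAPER_GAIN_MM_MV <- 10     # amplitude gain

ROW_LEADS <- list(c("I", "aVR", "V1", "V4"),
                  c("II", "aVL", "V2", "V5"),
                  c("III", "aVF", "V3", "V6"))

#' Three-point calibration frame
#'
#' Pixel coordinates of three reference points: the origin, a point 1 mV
#' above it, and a point 200 ms to its right — the standard calibration
#' markers of a paper ECG.  Millivolt- and millisecond-per-pixel factors are
#' derived from them.
#'
#' @param origin,one_mv,ms200 numeric `c(x, y)` pixel coordinates (y grows
#'   downward) of the points mapping to (0 ms, 0 mV), (0 ms, 1 mV) and
#'   (200 ms, 0 mV).
#' @return Object of class `calibration_frame` with `mv_per_px` and
#'   `ms_per_px`.
#' @export
calibration_frame <- function(origin, one_mv, ms200) {
  a <- one_mv - origin; b <- ms200 - origin
  if (abs(a[1] * b[2] - a[2] * b[1]) < 1e-9)
    stop("calibration points are collinear")
  dy <- origin[2] - one_mv[2]      # pixels per mV (y grows downward)
  dx <- ms200[1] - origin[1]       # pixels per 200 ms
  if (dy <= 0 || dx <= 0) stop("calibration factors must be positive")
  structure(list(origin = origin, one_mv = one_mv, ms200 = ms200,
                 mv_per_px = 1 / dy, ms_per_px = 200 / dx),
            class = "calibration_frame")
}

#' RGB colour thresholds separating waveform from grid/background
#'
#' @param lower,upper length-3 numeric vectors (red, green, blue in
#'   \[0, 1\]); a pixel is waveform when every channel lies inside its
#'   bounds.  Defaults select near-black pixels (the trace) and reject the
#'   white background and red grid.
#' @return Object of class `color_thresholds`.
#' @export
color_thresholds <- function(lower = c(0, 0, 0), upper = c(0.45, 0.45, 0.45)) {
  stopifnot(length(lower) == 3, length(upper) == 3)
  if (any(lower > upper)) stop("lower bounds must not exceed upper bounds")
  structure(list(lower = lower, upper = upper), class = "color_thresholds")
}

#' Render a paper-ECG page from signals
#'
#' Standard layout: three lead rows of four 2.5-s columns plus a full 10-s
#' rhythm strip of the reference lead, drawn at 25 mm/s and 10 mm/mV over a
#' millimetre grid.
#'
#' @param signals a [paper_ecg()] bundle.
#' @param dpi rendering resolution (default 144, the digitization resolution).
#' @param grid `"standard"` (red mm grid) or `"none"`.
#' @return Object of class `paper_image`: `pixels` (h x w x 3 array in
#'   \[0, 1\]), `dpi`, `layout` (per-lead pixel geometry), `calib`
#'   (a [calibration_frame()]).
#' @export
render_paper_image <- function(signals, dpi = 144, grid = "standard") {
  stopifnot(inherits(signals, "paper_ecg"), dpi > 0)
  grid <- match.arg(grid, c("standard", "none"))
  rate <- attr(signals, "rate")
  ppmm <- dpi / 25.4
  px_s <- PAPER_SPEED_MM_S * ppmm
  px_mv <- PAPER_GAIN_MM_MV * ppmm
  margin <- round(5 * ppmm)
  row_h <- round(30 * ppmm)
  w <- 2 * margin + round(250 * ppmm)   # 10 s at 25 mm/s
  h <- 2 * margin + 4 * row_h           # 3 lead rows + rhythm strip
  img <- array(1, c(h, w, 3))

  if (grid == "standard") {
    minor <- round(seq(margin, w - margin, by = ppmm))
    major <- round(seq(margin, w - margin, by = 5 * ppmm))
    vminor <- round(seq(margin, h - margin, by = ppmm))
    vmajor <- round(seq(margin, h - margin, by = 5 * ppmm))
    cols_mi <- c(1.00, 0.80, 0.80); cols_ma <- c(0.95, 0.55, 0.55)
    for (ch in 1:3) {
      img[vminor, margin:(w - margin), ch] <- cols_mi[ch]
      img[margin:(h - margin), minor, ch] <- cols_mi[ch]
      img[vmajor, margin:(w - margin), ch] <- cols_ma[ch]
      img[margin:(h - margin), major, ch] <- cols_ma[ch]
    }
  }

  draw_trace <- function(samples, x0, baseline) {
    nx <- round(length(samples) / rate * px_s)
    tt <- (seq_len(nx) - 0.5) / px_s
    v <- stats::approx((seq_along(samples) - 1) / rate, samples, xout = tt,
                       rule = 2)$y
    ys <- round(baseline - v * px_mv)
    ys <- pmin(pmax(ys, 1), h)
    # each column is inked from the midpoint toward its left neighbour to the
    # midpoint toward its right neighbour: the trace stays 8-connected while
    # each column only covers its own half-sample span (less smear than
    # naive column-pair line filling, so column-wise tracing stays faithful)
    for (i in seq_len(nx)) {
      ml <- if (i == 1) ys[i] else round((ys[i] + ys[i - 1]) / 2)
      mr <- if (i == nx) ys[i] else round((ys[i] + ys[i + 1]) / 2)
      lo <- min(ys[i], ml, mr); hi <- max(ys[i], ml, mr)
      img[lo:hi, x0 + i - 1L, ] <<- 0
    }
  }

  layout <- list()
  baselines <- margin + (seq_len(4) - 0.5) * row_h
  for (r in 1:3) {
    for (cc in 1:4) {
      lead <- ROW_LEADS[[r]][cc]
      seg <- signals$segments[[lead]]
      x0 <- margin + round((cc - 1) * 62.5 * ppmm) + 1L
      draw_trace(seg$samples, x0, baselines[r])
      layout[[lead]] <- list(x0 = x0,
                             x1 = x0 + round(2.5 * px_s) - 1L,
                             baseline = baselines[r], row = r,
                             offset = seg$offset)
    }
  }
  x0r <- margin + 1L
  draw_trace(signals$reference[seq_len(round(10 * rate))], x0r, baselines[4])
  layout[["rhythm"]] <- list(x0 = x0r, x1 = x0r + round(10 * px_s) - 1L,
                             baseline = baselines[4], row = 4, offset = 0)
  # nearest-baseline row bands for trace disambiguation
  bounds <- c(0, (baselines[-4] + baselines[-1]) / 2, h)
  for (nm in names(layout)) {
    r <- layout[[nm]]$row
    layout[[nm]]$rows <- c(floor(bounds[r]) + 1L, floor(bounds[r + 1]))
  }

  calib <- calibration_frame(
    origin = c(margin + 1, baselines[1]),
    one_mv = c(margin + 1, baselines[1] - px_mv),
    ms200 = c(margin + 1 + 0.2 * px_s, baselines[1]))
  structure(list(pixels = img, dpi = dpi, layout = layout, calib = calib,
                 reference_lead = signals$reference_lead),
            class = "paper_image")
}

#' @export
print.paper_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<paper_image> %d x %d px @ %d dpi\n", d[1], d[2], x$dpi))
  invisible(x)
}

#' Remove grid and background, keeping waveform pixels
#'
#' @param image a `paper_image`, or an h x w x 3 array in \[0, 1\], or a
#'   grayscale h x w matrix (thresholded by Otsu's method when `thresholds`
#'   is NULL).
#' @param thresholds a [color_thresholds()] object (default: near-black).
#' @return Logical h x w mask of waveform pixels.
#' @export
remove_grid <- function(image, thresholds = color_thresholds()) {
  px <- if (inherits(image, "paper_image")) image$pixels else image
  if (length(dim(px)) == 2) {
    # grayscale: automatic Otsu threshold fallback
    thr <- otsu_threshold(px)
    mask <- px <= thr
  } else {
    mask <- px[, , 1] >= thresholds$lower[1] & px[, , 1] <= thresholds$upper[1] &
            px[, , 2] >= thresholds$lower[2] & px[, , 2] <= thresholds$upper[2] &
            px[, , 3] >= thresholds$lower[3] & px[, , 3] <= thresholds$upper[3]
  }
  if (!any(mask)) stop("empty trace: no pixels within the colour thresholds")
  mask
}

# Otsu's threshold on a grayscale matrix in [0, 1].
otsu_threshold <- function(px, bins = 256) {
  hgram <- tabulate(findInterval(px, seq(0, 1, length.out = bins + 1),
                                 rightmost.closed = TRUE, all.inside = TRUE),
                    nbins = bins)
  p <- hgram / sum(hgram)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(bins))
  mu_t <- mu[bins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  which.max(sigma_b) / bins
}

#' Trace waveforms from a binary mask into calibrated signals
#'
#' Per image column inside each lead region, trace pixels are reduced to
#' their mean row (robust to trace thickness) and scaled to mV/ms by the
#' calibration frame; overlap between adjacent rows is resolved by
#' nearest-baseline row bands.  The traced samples are resampled to `rate`
#' by linear interpolation.
#'
#' @param mask logical pixel mask from [remove_grid()].
#' @param calib a [calibration_frame()].
#' @param layout per-lead pixel geometry as produced by
#'   [render_paper_image()] (fields `x0`, `x1`, `baseline`, `rows`,
#'   `offset` per lead, plus a `rhythm` entry).
#' @param reference_lead name of the lead shown in the rhythm strip.
#' @param rate output sampling rate, Hz.
#' @return A [paper_ecg()] bundle.
#' @export
trace_waveforms <- function(mask, calib, layout, reference_lead = "II",
                            rate = 500) {
  stopifnot(inherits(calib, "calibration_frame"))
  px_s <- 1000 / calib$ms_per_px        # pixels per second

  trace_region <- function(lg, dur) {
    xs <- lg$x0:lg$x1
    v <- rep(NA_real_, length(xs))
    for (i in seq_along(xs)) {
      rr <- which(mask[lg$rows[1]:lg$rows[2], xs[i]])
      if (length(rr))
        v[i] <- (lg$baseline - (mean(rr) + lg$rows[1] - 1)) * calib$mv_per_px
    }
    if (!any(!is.na(v)))
      stop("missing lead: no trace pixels in a lead region")
    v <- fill_na_linear(v)
    tt <- (seq_along(xs) - 0.5) / px_s
    n <- round(dur * rate)
    stats::approx(tt, v, xout = (seq_len(n) - 1) / rate, rule = 2)$y
  }

  segs <- lapply(ECG_LEADS, function(lead) {
    lg <- layout[[lead]]
    if (is.null(lg)) stop("missing lead: ", lead, " absent from layout")
    list(samples = trace_region(lg, 2.5), offset = lg$offset)
  })
  names(segs) <- ECG_LEADS
  ref <- trace_region(layout$rhythm, 10)
  paper_ecg(segs, reference_lead, ref, rate)
}

#' Digitize a rendered or loaded paper-ECG image
#'
#' Convenience wrapper: [remove_grid()] then [trace_waveforms()].
#'
#' @param image a `paper_image` (or array plus explicit `layout`/`calib`).
#' @param thresholds colour thresholds.
#' @param rate output sampling rate.
#' @param layout,calib required when `image` is a plain array.
#' @return A [paper_ecg()] bundle.
#' @export
digitize_paper_image <- function(image, thresholds = color_thresholds(),
                                 rate = 500, layout = NULL, calib = NULL) {
  if (inherits(image, "paper_image")) {
    layout <- layout %||% image$layout
    calib <- calib %||% image$calib
    ref <- image$reference_lead
  } else ref <- "II"
  mask <- remove_grid(image, thresholds)
  trace_waveforms(mask, calib, layout, reference_lead = ref, rate = rate)
}

#' Write a paper image to PNG
#' @param image a `paper_image`.
#' @param path output file; a JSON sidecar `<path>.json` stores layout,
#'   calibration and dpi so the image can be digitized after reloading.
#' @export
write_paper_png <- function(image, path) {
  png::writePNG(image$pixels, path)
  jsonlite::write_json(list(dpi = image$dpi, layout = image$layout,
                            calib = unclass(image$calib),
                            reference_lead = image$reference_lead),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a paper image written by [write_paper_png()]
#' @param path PNG file with its JSON sidecar.
#' @return A `paper_image`.
#' @export
read_paper_png <- function(path) {
  px <- png::readPNG(path)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  layout <- lapply(side$layout, as.list)
  calib <- calibration_frame(unlist(side$calib$origin),
                             unlist(side$calib$one_mv),
                             unlist(side$calib$ms200))
  structure(list(pixels = px, dpi = side$dpi, layout = layout, calib = calib,
                 reference_lead = side$reference_lead),
            class = "paper_image")
}
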