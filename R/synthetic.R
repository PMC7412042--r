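# Synthetic 12-lead ECG / VCG generator.
#
# The cardiac source is modelled as a rotating 3-D dipole whose trajectory is a
# sum of Gaussian wave deflections (P, Q, R, S, T) per beat, each along a fixed
# spatial direction (ECGSYN-style closed form).  The 12-lead ECG is the forward
# lead-matrix projection of that dipole, so the VCG ground truth is known
# exactly and every downstream stage can be validated without clinical data.
# Disease classes are implanted as closed-form morphology perturbations:
# rotation of the mean electrical axis (20-90 degrees for infarct classes),
# an ST-segment shift and an optional T-wave inversion.

# Forward lead matrix (Dower): rows I, II, V1..V6; columns X, Y, Z.
DOWER_FORWARD <- matrix(c(
   0.632, -0.235,  0.059,
   0.235,  1.066, -0.132,
  -0.515,  0.157, -0.917,
   0.044,  0.164, -1.387,
   0.882,  0.098, -1.277,
   1.213,  0.127, -0.601,
   1.125,  0.127, -0.086,
   0.831,  0.076,  0.230), ncol = 3, byrow = TRUE,
  dimnames = list(INDEPENDENT_LEADS, c("X", "Y", "Z")))

#' Parameters of the synthetic cardiac dipole
#'
#' Defaults describe a resting adult rhythm: 72 +/- 3 bpm, 10 s at 500 Hz,
#' with Gaussian P/Q/R/S/T deflections whose amplitudes (mV), widths (s) and
#' temporal offsets (s, relative to the R peak) approximate textbook ECG
#' morphology.
#'
#' @param rate sampling rate, Hz.
#' @param duration record length, s.
#' @param hr_mean,hr_sd heart-rate mean and beat-to-beat SD, bpm. The RR jitter
#'   is i.i.d. Gaussian truncated at +/- 3 SD so the rhythm stays near-periodic.
#' @param azimuth,elevation baseline dipole orientation, degrees.
#' @param waves data.frame with columns `wave`, `amp` (mV), `width` (s),
#'   `offset` (s) and unit direction columns `dx`, `dy`, `dz`.
#' @return Object of class `dipole_params`.
#' @export
dipole_params <- function(rate = 500, duration = 10, hr_mean = 72, hr_sd = 3,
                          azimuth = 0, elevation = 0, waves = NULL) {
  if (rate <= 0) stop("sampling rate must be positive")
  if (duration <= 0) stop("duration must be positive")
  if (hr_mean <= 0) stop("heart-rate mean must be positive")
  if (is.null(waves)) {
    waves <- data.frame(
      wave   = c("P", "Q", "R", "S", "T"),
      amp    = c(0.12, -0.12, 1.10, -0.22, 0.30),
      width  = c(0.025, 0.012, 0.016, 0.014, 0.055),
      offset = c(-0.18, -0.033, 0.0, 0.030, 0.28),
      dx = c(0.55, 0.75, 0.75, 0.75, 0.60),
      dy = c(0.80, 0.55, 0.55, 0.55, 0.65),
      dz = c(-0.15, -0.35, -0.35, -0.35, 0.00))
  }
  if (any(waves$width <= 0)) stop("wave widths must be positive")
  structure(list(rate = rate, duration = duration, hr_mean = hr_mean,
                 hr_sd = hr_sd, azimuth = azimuth, elevation = elevation,
                 waves = waves),
            class = "dipole_params")
}

#' Class-dependent morphology perturbation
#'
#' Infarct classes rotate the mean electrical axis by 20-90 degrees; healthy
#' controls are unrotated by definition.
#'
#' @param label one of `"HC"`, `"E"`, `"LAD"`, `"LCX"`, `"RCA"`.
#' @param angle axis-rotation angle in degrees (frontal-plane rotation);
#'   magnitude must lie in \[20, 90\] for infarct classes and be 0 for HC.
#' @param st_mv ST-segment offset, mV, applied as a wide deflection between
#'   the S and T waves.
#' @param t_flip logical; invert the T wave.
#' @param noise_sd additive measurement-noise SD per ECG lead, mV.
#' @return Object of class `class_perturbation`.
#' @export
class_perturbation <- function(label, angle = 0, st_mv = 0, t_flip = FALSE,
                               noise_sd = 0.01) {
  label <- match.arg(label, IRA_CLASSES)
  if (label == "HC") {
    if (angle != 0) stop("HC perturbation must have zero axis rotation")
  } else if (abs(angle) < 20 || abs(angle) > 90) {
    stop("infarct-class axis rotation magnitude must lie in [20, 90] degrees")
  }
  structure(list(label = label, angle = angle, st_mv = st_mv,
                 t_flip = isTRUE(t_flip), noise_sd = noise_sd),
            class = "class_perturbation")
}

#' The five localization classes
#' @export
IRA_CLASSES <- c("HC", "E", "LAD", "LCX", "RCA")

#' Default per-class perturbations
#'
#' The three artery classes get distinct (rotation, ST, T-inversion) tuples;
#' class E ("exact location not discernible") is drawn as a mixture of the
#' three artery perturbations at half magnitude, since no generative
#' description of E exists.
#'
#' @param noise_sd per-lead noise SD in mV.
#' @return Named list of `class_perturbation` objects (E entries are the three
#'   half-magnitude mixture components).
#' @export
default_perturbations <- function(noise_sd = 0.01) {
  list(
    HC  = class_perturbation("HC",  0,    0.00, FALSE, noise_sd),
    LAD = class_perturbation("LAD", 50,   0.20, TRUE,  noise_sd),
    LCX = class_perturbation("LCX", -40, -0.15, FALSE, noise_sd),
    RCA = class_perturbation("RCA", 80,   0.10, TRUE,  noise_sd),
    E   = list(class_perturbation("E", 25,   0.10, TRUE,  noise_sd),
               class_perturbation("E", -20, -0.075, FALSE, noise_sd),
               class_perturbation("E", 40,   0.05, TRUE,  noise_sd)))
}

rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3, byrow = TRUE)
}
rot_y <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), 0, sin(a), 0, 1, 0, -sin(a), 0, cos(a)), 3, 3, byrow = TRUE)
}

# Project a 3-channel dipole onto the 12 leads: the 8 independent leads via the
# forward matrix, the redundant limb leads from I and II.
project_to_leads <- function(vcg_mat) {
  e8 <- vcg_mat %*% t(DOWER_FORWARD)
  out <- matrix(0, nrow(vcg_mat), 12, dimnames = list(NULL, ECG_LEADS))
  out[, INDEPENDENT_LEADS] <- e8
  out[, "III"] <- out[, "II"] - out[, "I"]
  out[, "aVR"] <- -(out[, "I"] + out[, "II"]) / 2
  out[, "aVL"] <- out[, "I"] - out[, "II"] / 2
  out[, "aVF"] <- out[, "II"] - out[, "I"] / 2
  out
}

#' Generate one synthetic 12-lead ECG with its ground-truth VCG
#'
#' @param params a [dipole_params()] object.
#' @param perturbation a [class_perturbation()] object.
#' @param seed integer seed; identical inputs give bit-identical records.
#' @param amp_scale global amplitude multiplier (per-subject variability).
#' @return list with elements `ecg` (an [ecg_record()], noise added),
#'   `vcg` (the noise-free [vcg_record()] ground truth), `r_peaks`
#'   (true R-peak times, s), `label`.
#' @export
generate_dipole_record <- function(params, perturbation, seed = 1,
                                   amp_scale = 1) {
  stopifnot(inherits(params, "dipole_params"),
            inherits(perturbation, "class_perturbation"))
  with_seed(seed, {
    rate <- params$rate; dur <- params$duration
    n <- round(rate * dur)
    t <- (seq_len(n) - 1) / rate

    # beat train with truncated-Gaussian RR jitter
    rr_mean <- 60 / params$hr_mean
    rr_sd <- params$hr_sd * 60 / params$hr_mean^2
    tb <- 0.35
    beats <- numeric(0)
    while (tb < dur + 0.6) {
      beats <- c(beats, tb)
      jit <- if (rr_sd > 0) max(-3 * rr_sd, min(3 * rr_sd, stats::rnorm(1, 0, rr_sd))) else 0
      tb <- tb + rr_mean + jit
    }

    w <- params$waves
    if (perturbation$t_flip) w$amp[w$wave == "T"] <- -w$amp[w$wave == "T"]
    # ST shift: a wide deflection centred between S and T along the QRS axis
    if (perturbation$st_mv != 0) {
      w <- rbind(w, data.frame(wave = "ST", amp = perturbation$st_mv,
                               width = 0.045, offset = 0.13,
                               dx = 0.70, dy = 0.50, dz = -0.50))
    }

    vcg <- matrix(0, n, 3)
    for (k in seq_len(nrow(w))) {
      g <- numeric(n)
      for (b in beats) {
        g <- g + exp(-((t - b - w$offset[k])^2) / (2 * w$width[k]^2))
      }
      d <- c(w$dx[k], w$dy[k], w$dz[k])
      d <- d / sqrt(sum(d^2))
      vcg <- vcg + (amp_scale * w$amp[k] * g) %o% d
    }

    R <- rot_z(params$azimuth + perturbation$angle) %*% rot_y(params$elevation)
    vcg <- vcg %*% t(R)

    ecg <- project_to_leads(vcg)
    if (perturbation$noise_sd > 0)
      ecg <- ecg + matrix(stats::rnorm(length(ecg), 0, perturbation$noise_sd),
                          nrow(ecg))

    list(ecg = ecg_record(ecg, rate), vcg = vcg_record(vcg, rate),
         r_peaks = beats[beats >= 0 & beats < dur],
         label = perturbation$label)
  })
}

#' Generate a labeled synthetic cohort
#'
#' Per-record variability: dipole azimuth/elevation jitter (SD 4 degrees),
#' heart-rate jitter (SD 3 bpm), global amplitude scale (SD 5%), and for
#' infarct classes a rotation-angle jitter (SD 4 degrees, clamped so the
#' magnitude stays in \[20, 90\]).  E records draw one of the three
#' half-magnitude artery perturbations at random.
#'
#' @param n_per_class named integer vector, e.g. `c(HC = 20, LAD = 20)`;
#'   names must be in [IRA_CLASSES].
#' @param params baseline [dipole_params()].
#' @param seed integer seed.
#' @param perturbations per-class perturbation set, see
#'   [default_perturbations()].
#' @return Object of class `ecg_cohort`: list of records (each as returned by
#'   [generate_dipole_record()] plus a per-record seed) with the generation
#'   seed and per-class counts.
#' @export
make_cohort <- function(n_per_class, params = dipole_params(), seed = 1,
                        perturbations = default_perturbations()) {
  if (is.null(names(n_per_class)) || !all(names(n_per_class) %in% IRA_CLASSES))
    stop("n_per_class must be named with labels among: ",
         paste(IRA_CLASSES, collapse = ", "))
  if (any(n_per_class < 0)) stop("counts must be >= 0")
  total <- sum(n_per_class)
  records <- vector("list", total)
  if (total > 0) {
    plan <- rep(names(n_per_class), times = n_per_class)
    with_seed(seed, {
      rec_seeds <- sample.int(2^30, total)
      for (i in seq_len(total)) {
        lab <- plan[i]
        pert <- perturbations[[lab]]
        if (lab == "E") pert <- pert[[sample.int(length(pert), 1)]]
        if (lab != "HC") {
          ang <- pert$angle + stats::rnorm(1, 0, 4)
          ang <- sign(ang) * max(20, min(90, abs(ang)))
          pert$angle <- ang
        }
        p <- params
        p$azimuth <- params$azimuth + stats::rnorm(1, 0, 4)
        p$elevation <- params$elevation + stats::rnorm(1, 0, 4)
        p$hr_mean <- max(40, params$hr_mean + stats::rnorm(1, 0, 3))
        scl <- max(0.5, stats::rnorm(1, 1, 0.05))
        records[[i]] <- c(generate_dipole_record(p, pert, seed = rec_seeds[i],
                                                 amp_scale = scl),
                          list(seed = rec_seeds[i]))
      }
    })
  }
  structure(list(records = records,
                 labels = vapply(records, `[[`, character(1), "label"),
                 seed = seed, n_per_class = n_per_class),
            class = "ecg_cohort")
}

#' @export
print.ecg_cohort <- function(x, ...) {
  cat(sprintf("<ecg_cohort> %d records (seed %d)\n", length(x$records), x$seed))
  if (length(x$records)) print(table(x$labels))
  invisible(x)
}

#' Mask a full record to the paper-ECG layout
#'
#' Emulates the 3x4 simultaneous-lead printout: successive 2.5-s columns of a
#' continuous 10-s record — leads I/II/III keep \[0, 2.5) s, aVR/aVL/aVF keep
#' \[2.5, 5) s, V1-V3 keep \[5, 7.5) s, V4-V6 keep \[7.5, 10) s — while the
#' rhythm lead additionally keeps its full 10 s.
#'
#' @param record an [ecg_record()] of duration >= 10 s.
#' @param reference_lead rhythm-strip lead name (default "II").
#' @return A [paper_ecg()] object.
#' @export
mask_to_paper_layout <- function(record, reference_lead = "II") {
  stopifnot(inherits(record, "ecg_record"))
  rate <- attr(record, "rate")
  if (attr(record, "duration") < 10) stop("record must cover at least 10 s")
  offsets <- paper_layout_offsets()
  segs <- lapply(ECG_LEADS, function(lead) {
    off <- offsets[[lead]]
    idx <- seq.int(round(off * rate) + 1, round((off + 2.5) * rate))
    list(samples = unclass(record)[idx, lead], offset = off)
  })
  names(segs) <- ECG_LEADS
  ref <- unclass(record)[seq_len(round(10 * rate)), reference_lead]
  paper_ecg(segs, reference_lead, ref, rate)
}

#' Column time offsets of the 3x4 paper layout
#' @return Named list mapping each lead to its column start time (s).
#' @export
paper_layout_offsets <- function() {
  as.list(c(I = 0, II = 0, III = 0,
            aVR = 2.5, aVL = 2.5, aVF = 2.5,
            V1 = 5, V2 = 5, V3 = 5,
            V4 = 7.5, V5 = 7.5, V6 = 7.5))
}

#' Write a cohort to disk (CSV per record + JSON manifest)
#' @param cohort an `ecg_cohort`.
#' @param dir output directory.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- lapply(seq_along(cohort$records), function(i) {
    rec <- cohort$records[[i]]
    f <- file.path(dir, sprintf("record_%03d.csv", i))
    write_ecg_csv(rec$ecg, f)
    list(file = basename(f), label = rec$label, seed = rec$seed)
  })
  jsonlite::write_json(list(seed = cohort$seed, records = manifest),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}
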