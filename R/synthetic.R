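#' Scenario configuration for synthetic patients
#'
#' Bundles every knob of the synthetic-patient generator. The defaults
#' describe a typical 30-fraction head-and-neck VMAT course on a
#' high-resolution panel: a centred high-dose plateau with a smooth
#' penumbra, weight loss emulated as a uniform per-fraction transmission
#' gain, an elliptical body contour shrinking a little every fraction, and
#' small couch-rotation drifts well inside the |angle| <= 4 degree range
#' seen clinically.
#'
#' @param scenario one of \code{"stable"}, \code{"weight_loss"},
#'   \code{"replan"}, \code{"rotation_drift"}, \code{"mixed"}; selects
#'   scenario-specific defaults for the drift parameters below.
#' @param n_fractions number of treatment fractions (default 30).
#' @param image_size EPID composite matrix size, pixels (default 256).
#' @param pixel_pitch_mm EPID pixel pitch, mm (default 0.336).
#' @param max_dose_cu plateau dose of one fraction composite, CU
#'   (default 100).
#' @param plateau_fraction plateau extent relative to the image
#'   (default 0.4).
#' @param penumbra_sigma_mm penumbra fall-off width, mm (default 3).
#' @param per_fraction_transmission_gain uniform transmission gain step
#'   alpha per fraction (scenario default; 0.002 for weight-loss-like
#'   scenarios, emulating slow weight loss).
#' @param alpha_ramp relative left-right asymmetry of the transmission
#'   gain (0 = spatially uniform; >0 spreads the ROI pixel distribution
#'   and yields non-zero GDSA standard deviations).
#' @param contour_axes_cm reference body-contour (A-P, lateral) axes, cm
#'   (default c(20, 28)).
#' @param axis_shrink_cm_per_fraction per-fraction (A-P, lateral) axis
#'   decrements, cm (scenario default; c(0.13, 0.13) for weight loss,
#'   reaching a few cm over a course).
#' @param rotation_drift_deg_per_fraction per-fraction (pitch, roll, yaw)
#'   drift, degrees (scenario default; c(0.1, 0.05, 0.05) for
#'   rotation-drift scenarios).
#' @param rotation_jitter_sd_deg per-fraction random setup jitter sd,
#'   degrees (default 0).
#' @param noise_sd_pct additive Gaussian image noise, percent of the
#'   plateau dose (default 0 so closed-form expectations are exact).
#' @param replan_fraction fraction starting the new plan in the
#'   \code{"replan"} scenario (default two thirds through the course).
#' @param seed integer seed; mandatory, every stochastic draw derives
#'   from it.
#'
#' @return A list of class \code{"ScenarioConfig"}.
#' @seealso [generatePatient()]
#' @export
scenarioConfig <- function(scenario = c("stable", "weight_loss", "replan",
                                        "rotation_drift", "mixed"),
                           n_fractions = 30L, image_size = 256L,
                           pixel_pitch_mm = 0.336, max_dose_cu = 100,
                           plateau_fraction = 0.4, penumbra_sigma_mm = 3,
                           per_fraction_transmission_gain = NULL,
                           alpha_ramp = NULL,
                           contour_axes_cm = c(20, 28),
                           axis_shrink_cm_per_fraction = NULL,
                           rotation_drift_deg_per_fraction = NULL,
                           rotation_jitter_sd_deg = 0,
                           noise_sd_pct = 0,
                           replan_fraction = NULL,
                           seed) {
  scenario <- match.arg(scenario)
  if (missing(seed)) stop("'seed' is mandatory", call. = FALSE)
  gain <- if (!is.null(per_fraction_transmission_gain))
    per_fraction_transmission_gain
  else switch(scenario, stable = 0, rotation_drift = 0, 0.002)
  shrink <- if (!is.null(axis_shrink_cm_per_fraction))
    axis_shrink_cm_per_fraction
  else switch(scenario, stable = c(0, 0), rotation_drift = c(0, 0),
              c(0.13, 0.13))
  drift <- if (!is.null(rotation_drift_deg_per_fraction))
    rotation_drift_deg_per_fraction
  else switch(scenario, rotation_drift = c(0.1, 0.05, 0.05),
              mixed = c(0.1, 0.05, 0.05), c(0, 0, 0))
  if (is.null(alpha_ramp))
    alpha_ramp <- if (scenario == "mixed") 0.2 else 0
  if (scenario == "replan" && is.null(replan_fraction))
    replan_fraction <- max(2L, ceiling(2 * n_fractions / 3))
  cfg <- list(scenario = scenario, n_fractions = as.integer(n_fractions),
              image_size = as.integer(image_size),
              pixel_pitch_mm = pixel_pitch_mm, max_dose_cu = max_dose_cu,
              plateau_fraction = plateau_fraction,
              penumbra_sigma_mm = penumbra_sigma_mm,
              per_fraction_transmission_gain = gain,
              alpha_ramp = alpha_ramp,
              contour_axes_cm = contour_axes_cm,
              axis_shrink_cm_per_fraction = shrink,
              rotation_drift_deg_per_fraction = drift,
              rotation_jitter_sd_deg = rotation_jitter_sd_deg,
              noise_sd_pct = noise_sd_pct,
              replan_fraction = replan_fraction,
              seed = as.integer(seed))
  stopifnot(cfg$n_fractions >= 1L, cfg$image_size >= 8L,
            cfg$pixel_pitch_mm > 0, cfg$max_dose_cu > 0,
            cfg$plateau_fraction > 0, cfg$plateau_fraction < 1,
            cfg$penumbra_sigma_mm > 0, cfg$noise_sd_pct >= 0,
            length(cfg$contour_axes_cm) == 2L,
            all(cfg$contour_axes_cm > 0),
            length(cfg$axis_shrink_cm_per_fraction) == 2L,
            length(cfg$rotation_drift_deg_per_fraction) == 3L,
            cfg$rotation_jitter_sd_deg >= 0)
  class(cfg) <- "ScenarioConfig"
  cfg
}

# flat-top profile along one axis: exactly 1 on the plateau, Gaussian
# shoulder of width sigma (px) outside it
.plateauProfile <- function(n, halfWidthPx, sigmaPx) {
  u <- pmax(0, abs(seq_len(n) - (n + 1) / 2) - halfWidthPx)
  exp(-u^2 / (2 * sigmaPx^2))
}

#' Synthetic reference composite
#'
#' A centred rectangular plateau at \code{max_dose_cu} with smooth
#' penumbral shoulders of width \code{penumbra_sigma_mm}, plus optional
#' seeded zero-mean Gaussian noise (clipped at zero dose). The flat
#' plateau interior is guaranteed high-dose and zero-gradient at the
#' default segmentation thresholds when noise is zero.
#'
#' @param config a [scenarioConfig()].
#'
#' @return A [CompositeImage-class] with fraction index 1.
#' @export
makeReferenceComposite <- function(config) {
  stopifnot(inherits(config, "ScenarioConfig"))
  n <- config$image_size
  half <- config$plateau_fraction * n / 2
  if (2 * half < 3)
    stop("plateau too small to contain any low-gradient pixel",
         call. = FALSE)
  sigmaPx <- config$penumbra_sigma_mm / config$pixel_pitch_mm
  prof <- .plateauProfile(n, half, sigmaPx)
  px <- config$max_dose_cu * outer(prof, prof)
  if (config$noise_sd_pct > 0) {
    set.seed(config$seed)
    px <- px + stats::rnorm(n * n,
                            sd = config$noise_sd_pct / 100 *
                              config$max_dose_cu)
    px <- pmax(px, 0)
  }
  CompositeImage(px, pixelPitchMm = config$pixel_pitch_mm,
                 fractionIndex = 1L, nArcs = 1L)
}

#' Synthetic comparison composite with a known transmission gain
#'
#' The comparison fraction is \code{(1 + alpha_n)} times the reference
#' (optionally with a small left-right gain ramp controlled by
#' \code{config$alpha_ramp}), plus seeded noise — the uniform-transmission
#' model of gradual weight loss, which admits an exact closed-form GDSA
#' expectation.
#'
#' @param reference the reference [CompositeImage-class].
#' @param alpha_n transmission gain of this fraction (> -1).
#' @param config a [scenarioConfig()].
#' @param fractionIndex fraction number recorded on the output.
#'
#' @return A [CompositeImage-class].
#' @export
makeComparisonComposite <- function(reference, alpha_n, config,
                                    fractionIndex = 2L) {
  stopifnot(inherits(config, "ScenarioConfig"),
            is(reference, "CompositeImage"), alpha_n > -1)
  px <- reference@pixels
  nc <- ncol(px)
  ramp <- 1 + config$alpha_ramp * (seq_len(nc) - (nc + 1) / 2) /
    ((nc - 1) / 2)
  gain <- 1 + alpha_n * rep(ramp, each = nrow(px))
  out <- px * gain
  if (config$noise_sd_pct > 0) {
    set.seed(config$seed + 7919L * as.integer(fractionIndex))
    out <- out + stats::rnorm(length(out),
                              sd = config$noise_sd_pct / 100 *
                                config$max_dose_cu)
    out <- pmax(out, 0)
  }
  CompositeImage(out, pixelPitchMm = reference@pixelPitchMm,
                 fractionIndex = as.integer(fractionIndex), nArcs = 1L)
}

#' Synthetic shrinking-ellipse contour series
#'
#' Axis-aligned elliptical body masks on a fixed 1 mm grid, with the A-P
#' and lateral axes shrunk by the configured per-fraction decrements —
#' the body-contour signature of continuous weight loss.
#'
#' @param config a [scenarioConfig()].
#'
#' @return List of [ContourSlice-class], one per fraction.
#' @export
makeContourSeries <- function(config) {
  stopifnot(inherits(config, "ScenarioConfig"))
  apAxes <- config$contour_axes_cm[1L] -
    config$axis_shrink_cm_per_fraction[1L] * (seq_len(config$n_fractions) - 1L)
  latAxes <- config$contour_axes_cm[2L] -
    config$axis_shrink_cm_per_fraction[2L] * (seq_len(config$n_fractions) - 1L)
  if (any(apAxes <= 0) || any(latAxes <= 0))
    stop("shrink schedule drives a contour axis non-positive",
         call. = FALSE)
  nr <- round(config$contour_axes_cm[1L] * 10) + 21L
  nc <- round(config$contour_axes_cm[2L] * 10) + 21L
  cr <- (nr + 1) / 2
  cc <- (nc + 1) / 2
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  lapply(seq_len(config$n_fractions), function(k) {
    a <- apAxes[k] * 10 / 2   # semi-axis in px (1 mm spacing)
    b <- latAxes[k] * 10 / 2
    ContourSlice(((rows - cr) / a)^2 + ((cols - cc) / b)^2 <= 1,
                 rowSpacingMm = 1, colSpacingMm = 1)
  })
}

#' Synthetic registration-matrix series with known rotations
#'
#' Per-fraction true pitch/roll/yaw are a deterministic drift (zero at
#' fraction 1) plus optional seeded Gaussian jitter; matrices are built
#' with the package's yaw-roll-pitch convention.
#'
#' @param config a [scenarioConfig()].
#'
#' @return List with \code{matrices} (4x4 matrices per fraction) and
#'   \code{angles} (data.frame \code{fraction}, \code{pitch_deg},
#'   \code{roll_deg}, \code{yaw_deg}).
#' @export
makeRegistrationSeries <- function(config) {
  stopifnot(inherits(config, "ScenarioConfig"))
  n <- config$n_fractions
  drift <- config$rotation_drift_deg_per_fraction
  ang <- outer(seq_len(n) - 1L, drift)
  if (config$rotation_jitter_sd_deg > 0) {
    set.seed(config$seed + 104729L)
    ang <- ang + matrix(stats::rnorm(3L * n,
                                     sd = config$rotation_jitter_sd_deg),
                        n, 3L)
  }
  angles <- data.frame(fraction = seq_len(n), pitch_deg = ang[, 1L],
                       roll_deg = ang[, 2L], yaw_deg = ang[, 3L])
  matrices <- lapply(seq_len(n), function(k)
    matrixFromAngles(ang[k, 1L], ang[k, 2L], ang[k, 3L]))
  list(matrices = matrices, angles = angles)
}

#' Generate a full synthetic patient with ground truth
#'
#' Bundles per-fraction EPID composites, body-contour slices and
#' registration matrices into a [PatientSeries-class], together with the
#' ground-truth parameters that produced them. In the \code{"replan"}
#' scenario the transmission gain restarts at zero at
#' \code{replan_fraction} (the new plan's first fraction, which also
#' becomes the natural re-baseline reference for the analysis).
#'
#' @param config a [scenarioConfig()].
#' @param patientId,siteLabel labels for the series.
#'
#' @return List with \code{series} (a [PatientSeries-class]),
#'   \code{ground_truth} (data.frame: \code{fraction}, \code{alpha},
#'   \code{ap_axis_cm}, \code{lat_axis_cm}, \code{pitch_deg},
#'   \code{roll_deg}, \code{yaw_deg}, \code{is_reference}) and
#'   \code{reference_fractions} (integer vector of re-baseline points).
#' @examples
#' pat <- generatePatient(scenarioConfig("weight_loss", n_fractions = 5,
#'                                       image_size = 64, seed = 42))
#' pat$ground_truth$alpha
#' @export
generatePatient <- function(config, patientId = "synthetic",
                            siteLabel = "larynx") {
  stopifnot(inherits(config, "ScenarioConfig"))
  n <- config$n_fractions
  refFracs <- 1L
  if (config$scenario == "replan") {
    if (is.null(config$replan_fraction) || config$replan_fraction > n ||
        config$replan_fraction < 2L)
      stop("inconsistent scenario parameters: invalid replan fraction",
           call. = FALSE)
    refFracs <- c(1L, as.integer(config$replan_fraction))
  }
  lastRef <- vapply(seq_len(n), function(k) max(refFracs[refFracs <= k]),
                    integer(1L))
  alpha <- config$per_fraction_transmission_gain * (seq_len(n) - lastRef)

  reference <- makeReferenceComposite(config)
  fractions <- lapply(seq_len(n), function(k) {
    if (alpha[k] == 0 && config$noise_sd_pct == 0) {
      CompositeImage(reference@pixels, reference@pixelPitchMm,
                     fractionIndex = k, nArcs = 1L)
    } else {
      makeComparisonComposite(reference, alpha[k], config,
                              fractionIndex = k)
    }
  })
  contours <- makeContourSeries(config)
  reg <- makeRegistrationSeries(config)

  apAxes <- config$contour_axes_cm[1L] -
    config$axis_shrink_cm_per_fraction[1L] * (seq_len(n) - 1L)
  latAxes <- config$contour_axes_cm[2L] -
    config$axis_shrink_cm_per_fraction[2L] * (seq_len(n) - 1L)
  gt <- data.frame(fraction = seq_len(n), alpha = alpha,
                   ap_axis_cm = apAxes, lat_axis_cm = latAxes,
                   pitch_deg = reg$angles$pitch_deg,
                   roll_deg = reg$angles$roll_deg,
                   yaw_deg = reg$angles$yaw_deg,
                   is_reference = seq_len(n) %in% refFracs)
  series <- PatientSeries(fractions, patientId = patientId,
                          siteLabel = siteLabel, referenceFraction = 1L,
                          contours = contours,
                          registrations = reg$matrices)
  list(series = series, ground_truth = gt,
       reference_fractions = refFracs)
}

#' Write a synthetic patient to disk as portable fixtures
#'
#' Writes per-fraction portable composite arrays, contour masks (0/1
#' text), plain-text registration matrices and a ground-truth CSV, so a
#' synthetic patient can be re-read through the same file readers used
#' for clinical exports.
#'
#' @param patient result of [generatePatient()].
#' @param dir output directory (created if missing).
#'
#' @return \code{dir}, invisibly.
#' @export
writeSyntheticPatient <- function(patient, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (k in seq_along(patient$series@fractions)) {
    comp <- patient$series@fractions[[k]]
    img <- EpidImage(comp@pixels, comp@pixelPitchMm, comp@fractionIndex,
                     arcLabel = "composite")
    writePortableImage(img, file.path(dir, sprintf("epid_f%03d.txt",
                                                   comp@fractionIndex)))
    if (length(patient$series@contours)) {
      m <- patient$series@contours[[k]]@mask
      utils::write.table(m * 1L,
                         file.path(dir, sprintf("contour_f%03d.txt",
                                                comp@fractionIndex)),
                         row.names = FALSE, col.names = FALSE)
    }
    if (length(patient$series@registrations))
      writeRegistrationMatrix(patient$series@registrations[[k]],
                              file.path(dir, sprintf("reg_f%03d.txt",
                                                     comp@fractionIndex)))
  }
  utils::write.csv(patient$ground_truth,
                   file.path(dir, "ground_truth.csv"), row.names = FALSE)
  invisible(dir)
}
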