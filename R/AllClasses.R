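#' @import methods
NULL

#' Gamma-variate arterial input function model
#'
#' Parametric model of the arterial tracer concentration driving the kinetic
#' models: a peak-normalised gamma-variate, optionally smeared by a
#' single-exponential dispersion kernel (the standard description of
#' catheter/sampler dispersion).  The curve is
#' \deqn{C_a(t) = A \, u^{\alpha} e^{\alpha (1 - u)}, \quad
#'       u = (t - d)/t_p,}
#' zero for \eqn{t < d}, so `amplitude` is the (pre-dispersion) peak value
#' reached at `delay + timeToPeak`.
#'
#' @slot amplitude peak concentration (kBq/mL); 0 gives the all-zero curve
#' @slot delay onset delay (s); the curve is identically zero before it
#' @slot shape gamma-variate shape \eqn{\alpha > 0} (dimensionless)
#' @slot timeToPeak time from onset to peak (s)
#' @slot dispersion exponential dispersion time constant (s), `>= 0`
#'
#' @seealso [aifModel()], [sampleAIF()], [aifIntegral()]
#' @export
setClass("AIFModel",
  representation(
    amplitude = "numeric",
    delay = "numeric",
    shape = "numeric",
    timeToPeak = "numeric",
    dispersion = "numeric"
  ),
  prototype(amplitude = 1, delay = 0, shape = 3, timeToPeak = 10,
            dispersion = 0)
)

setValidity("AIFModel", function(object) {
  msg <- character()
  for (s in c("amplitude", "delay", "shape", "timeToPeak", "dispersion")) {
    v <- slot(object, s)
    if (length(v) != 1 || !is.finite(v))
      msg <- c(msg, sprintf("'%s' must be a single finite number", s))
  }
  if (length(msg)) return(msg)
  if (object@amplitude < 0) msg <- c(msg, "amplitude must be >= 0")
  if (object@delay < 0) msg <- c(msg, "delay must be >= 0")
  if (object@shape <= 0) msg <- c(msg, "shape must be > 0")
  if (object@timeToPeak <= 0) msg <- c(msg, "timeToPeak must be > 0")
  if (object@dispersion < 0) msg <- c(msg, "dispersion must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Framed dynamic PET scan for one tracer
#'
#' Frame-averaged activity concentrations for a region of interest (single
#' row) or a voxel grid (one row per voxel), together with the frame timing
#' and the arterial input model(s) needed to quantify the scan.  For the
#' oxygen study the `aif` list carries two curves: the whole-blood
#' \eqn{^{15}O_2} activity (`"o2"`) and the recirculating metabolic water
#' (`"water"`); the water curve must lag the oxygen curve.
#'
#' @slot tracer one of `"H2O"`, `"O2"`, `"CO"`
#' @slot frameStart frame start times (s), contiguous and non-overlapping
#' @slot frameDuration frame durations (s), all positive
#' @slot activity numeric matrix, voxels x frames (kBq/mL); a ROI scan has a
#'   single row.  May carry a `dim3` attribute with the voxel grid shape.
#' @slot aif named list of [AIFModel-class] objects
#' @slot o2Content arterial oxygen content (mL O2/mL blood); O2 study only
#' @slot decayCorrected logical; whether activities are decay corrected
#'
#' @seealso [dynamicScan()], [fitCBF()], [fitOEF()], [computeCBV()]
#' @export
setClass("DynamicScan",
  representation(
    tracer = "character",
    frameStart = "numeric",
    frameDuration = "numeric",
    activity = "matrix",
    aif = "list",
    o2Content = "numeric",
    decayCorrected = "logical"
  ),
  prototype(tracer = "H2O", o2Content = numeric(), decayCorrected = TRUE)
)

setValidity("DynamicScan", function(object) {
  msg <- character()
  if (!object@tracer %in% c("H2O", "O2", "CO"))
    msg <- c(msg, "tracer must be one of 'H2O', 'O2', 'CO'")
  n <- length(object@frameStart)
  if (n == 0) msg <- c(msg, "at least one frame is required")
  if (length(object@frameDuration) != n)
    msg <- c(msg, "frameStart and frameDuration lengths differ")
  else {
    if (any(object@frameDuration <= 0))
      msg <- c(msg, "frame durations must be positive")
    if (n > 1) {
      ends <- object@frameStart + object@frameDuration
      if (any(abs(object@frameStart[-1] - ends[-n]) > 1e-9))
        msg <- c(msg, "frames must be contiguous and non-overlapping")
    }
  }
  if (ncol(object@activity) != n)
    msg <- c(msg, "activity must have one column per frame")
  if (length(object@aif) && !all(vapply(object@aif, is, TRUE, "AIFModel")))
    msg <- c(msg, "aif must be a list of AIFModel objects")
  if (object@tracer == "O2" && length(object@aif) &&
      !all(c("o2", "water") %in% names(object@aif)))
    msg <- c(msg, "O2 scans need aif elements named 'o2' and 'water'")
  if (object@tracer == "O2" && all(c("o2", "water") %in% names(object@aif))) {
    d_o2 <- object@aif[["o2"]]@delay
    d_w <- object@aif[["water"]]@delay
    if (d_w < d_o2)
      msg <- c(msg, "recirculating-water curve must lag the O2 curve")
  }
  if (length(msg)) msg else TRUE
})

#' Transcranial Doppler CO2-reactivity recording
#'
#' Middle-cerebral-artery blood-flow-velocity envelope samples for the two
#' phases of a CO2-reactivity study -- a 5-s spectral recording after
#' breathing room air and another after 1.5 min of carbogene inhalation --
#' plus the end-tidal CO2 and blood-pressure readings taken around the
#' stimulus.
#'
#' @slot patientId patient identifier
#' @slot side `"left"` or `"right"` MCA
#' @slot baseline baseline velocity samples (cm/s), all `>= 0`
#' @slot hypercapnia hypercapnic velocity samples (cm/s), all `>= 0`
#' @slot etco2Before,etco2After end-tidal CO2 (mmHg)
#' @slot sbpBefore,sbpAfter systolic blood pressure (mmHg)
#' @slot dbpBefore,dbpAfter diastolic blood pressure (mmHg)
#'
#' @seealso [bfvRecording()], [computeReactivity()]
#' @export
setClass("BFVRecording",
  representation(
    patientId = "character",
    side = "character",
    baseline = "numeric",
    hypercapnia = "numeric",
    etco2Before = "numeric", etco2After = "numeric",
    sbpBefore = "numeric", sbpAfter = "numeric",
    dbpBefore = "numeric", dbpAfter = "numeric"
  )
)

setValidity("BFVRecording", function(object) {
  msg <- character()
  if (!object@side %in% c("left", "right"))
    msg <- c(msg, "side must be 'left' or 'right'")
  if (length(object@baseline) < 1 || length(object@hypercapnia) < 1)
    msg <- c(msg, "each phase needs at least one velocity sample")
  if (any(object@baseline < 0) || any(object@hypercapnia < 0))
    msg <- c(msg, "velocity samples must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Synthetic cohort configuration
#'
#' All knobs of the cohort generator.  Defaults reproduce the structure of
#' the study population: 24 patients, ipsilateral true-stage prevalence
#' 9/24, 13/24, 2/24, and a 9/24 fraction of haemodynamically abnormal
#' contralateral hemispheres (contralateral carotid stenosis).
#'
#' @slot nPatients number of patients (>= 1)
#' @slot seed integer RNG seed; the same seed reproduces the cohort exactly
#' @slot stagePrevalence probabilities of ipsilateral true stage 0/1/2
#'   (must sum to 1)
#' @slot reactivityNoiseSd measurement noise added to the true reactivity
#'   (percentage-point SD); 0 gives noiseless recordings
#' @slot tacNoiseModel `"none"`, `"gaussian_frame"` (per-frame Gaussian with
#'   SD proportional to `sqrt(mean / duration)`) or `"poisson_like"`
#'   (same scaling, but drawn as a scaled Poisson count)
#' @slot tacNoiseScale scale of the frame-noise SD (kBq/mL at 1 kBq/mL mean
#'   and 1 s duration)
#' @slot contralateralAbnormalFraction probability that the contralateral
#'   hemisphere is mildly abnormal
#' @slot stage1SubtypeProp proportions of stage-1 subtypes
#'   (decreased CBF only, increased CBV only, both)
#' @slot frameScheduleH2o,frameScheduleO2,frameScheduleCo frame schedules as
#'   two-column matrices `(start, duration)` in seconds
#'
#' @seealso [cohortConfig()], [generateCohort()]
#' @export
setClass("CohortConfig",
  representation(
    nPatients = "numeric",
    seed = "numeric",
    stagePrevalence = "numeric",
    reactivityNoiseSd = "numeric",
    tacNoiseModel = "character",
    tacNoiseScale = "numeric",
    contralateralAbnormalFraction = "numeric",
    stage1SubtypeProp = "numeric",
    frameScheduleH2o = "matrix",
    frameScheduleO2 = "matrix",
    frameScheduleCo = "matrix"
  )
)

setValidity("CohortConfig", function(object) {
  msg <- character()
  if (length(object@nPatients) != 1 || object@nPatients < 1 ||
      object@nPatients != round(object@nPatients))
    msg <- c(msg, "nPatients must be a positive integer")
  if (length(object@stagePrevalence) != 3 ||
      any(object@stagePrevalence < 0) ||
      abs(sum(object@stagePrevalence) - 1) > 1e-8)
    msg <- c(msg, "stagePrevalence must be 3 non-negative values summing to 1")
  if (!object@tacNoiseModel %in% c("none", "gaussian_frame", "poisson_like"))
    msg <- c(msg, "unknown tacNoiseModel")
  if (object@reactivityNoiseSd < 0 || object@tacNoiseScale < 0)
    msg <- c(msg, "noise scales must be >= 0")
  if (object@contralateralAbnormalFraction < 0 ||
      object@contralateralAbnormalFraction > 1)
    msg <- c(msg, "contralateralAbnormalFraction must be in [0, 1]")
  if (length(object@stage1SubtypeProp) != 3 ||
      any(object@stage1SubtypeProp < 0) ||
      sum(object@stage1SubtypeProp) <= 0)
    msg <- c(msg, "stage1SubtypeProp must be 3 non-negative weights")
  for (s in c("frameScheduleH2o", "frameScheduleO2", "frameScheduleCo")) {
    m <- slot(object, s)
    if (ncol(m) != 2 || any(m[, 2] <= 0))
      msg <- c(msg, sprintf("%s must be a (start, duration) matrix", s))
  }
  if (length(msg)) msg else TRUE
})

#' Normal ranges for haemodynamic staging
#'
#' One-sided normal limits for grey-matter MCA-territory CBF, CBV and OEF,
#' derived from normal controls as mean +/- 1.96 SD.  Defaults are the
#' study's printed limits: CBF >= 31.1 mL/min/100 mL, CBV <= 3.9 mL/100 mL,
#' OEF <= 55.7%.  Values exactly at a limit are normal for that parameter.
#'
#' @slot cbfLower lower normal limit for CBF (mL/min/100 mL)
#' @slot cbvUpper upper normal limit for CBV (mL/100 mL)
#' @slot oefUpper upper normal limit for OEF (%)
#'
#' @seealso [normalRanges()], [deriveRanges()], [classifyStage()]
#' @export
setClass("NormalRanges",
  representation(cbfLower = "numeric", cbvUpper = "numeric",
                 oefUpper = "numeric"),
  prototype(cbfLower = 31.1, cbvUpper = 3.9, oefUpper = 55.7)
)

setValidity("NormalRanges", function(object) {
  v <- c(object@cbfLower, object@cbvUpper, object@oefUpper)
  if (length(v) != 3 || any(!is.finite(v)) || any(v <= 0))
    "all bounds must be single positive finite numbers"
  else TRUE
})

#' 2x2 concordance between TCD and PET classification
#'
#' Cross-classification of patients by binary TCD impairment (reactivity
#' <= 20%) against binary PET compromise (haemodynamic stage 1 or 2), with
#' the agreement summary and Cohen's kappa (an added summary beyond the
#' original agreement count).
#'
#' @slot a TCD impaired and PET compromised (stage >= 1)
#' @slot b TCD impaired and PET stage 0
#' @slot c TCD normal and PET compromised
#' @slot d TCD normal and PET stage 0
#'
#' @seealso [crossClassify()], [agreementPct()], [cohenKappa()]
#' @export
setClass("ConcordanceTable",
  representation(a = "integer", b = "integer", c = "integer", d = "integer")
)

setValidity("ConcordanceTable", function(object) {
  v <- c(object@a, object@b, object@c, object@d)
  if (length(v) != 4 || any(is.na(v)) || any(v < 0))
    "all four counts must be single non-negative integers"
  else TRUE
})

#' Synthetic cohort
#'
#' Container for one generated cohort: the ground-truth per-hemisphere
#' states, the TCD recordings and the dynamic PET scans, plus the arterial
#' input models and the generating configuration.  Recordings are named
#' `"<patient>.<side>"` and scans `"<patient>.<side>.<tracer>"`.
#'
#' @slot truth data.frame, one row per patient x hemisphere, with the true
#'   CBF/CBV/OEF, partition coefficient, reactivity, baseline velocity,
#'   infarct fraction and true stage
#' @slot recordings named list of [BFVRecording-class]
#' @slot scans named list of [DynamicScan-class] (empty if scan simulation
#'   was skipped)
#' @slot aifs per-patient named list of AIF models by tracer
#' @slot config the [CohortConfig-class] used
#'
#' @seealso [generateCohort()], [writeCohort()], [readCohort()]
#' @export
setClass("Cohort",
  representation(
    truth = "data.frame",
    recordings = "list",
    scans = "list",
    aifs = "list",
    config = "CohortConfig"
  )
)
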