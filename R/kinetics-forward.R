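#' @include aif.R
NULL

## physical and model constants
.O15_HALFLIFE <- 122.24      # s
.R_HCT_DEFAULT <- 0.85       # small-to-large-vessel haematocrit ratio
.O2_VASC_CORR <- 0.835       # vascular correction factor of the O2 model
.GRID_DT <- 0.05             # s, internal fine grid for convolutions

## CBF in mL/min/100 mL -> flow per mL tissue per second
.flowPerSec <- function(cbf) cbf / (100 * 60)

## causal convolution (x * y)(t) on a uniform grid, trapezoid-corrected,
## returning the first length(x) samples scaled by dt
.gridConvolve <- function(x, y, dt) {
  n <- length(x)
  m <- stats::nextn(2L * n, 2L)     # pad to a fast FFT length
  xp <- c(x, numeric(m - n))
  yp <- c(y, numeric(m - n))
  full <- Re(stats::fft(stats::fft(xp) * stats::fft(yp),
                        inverse = TRUE))[seq_len(n)] / m
  ## trapezoid correction for the two endpoint samples of each sum
  dt * (full - 0.5 * x[1] * y - 0.5 * y[1] * x)
}

## frame averages of a curve sampled on grid tg (uniform, step dt), using
## the cumulative trapezoid integral interpolated at frame boundaries
.frameAverage <- function(tg, curve, frameStart, frameDuration) {
  n <- length(tg)
  dt <- tg[2] - tg[1]
  cumint <- c(0, cumsum((curve[-1] + curve[-n]) / 2)) * dt
  at <- function(t) {
    ## linear interpolation of the cumulative integral; frame boundaries
    ## normally sit exactly on the grid
    pos <- pmin(pmax((t - tg[1]) / dt, 0), n - 1)
    i <- pmin(floor(pos), n - 2)
    w <- pos - i
    cumint[i + 1] * (1 - w) + cumint[i + 2] * w
  }
  (at(frameStart + frameDuration) - at(frameStart)) / frameDuration
}

## tissue impulse-response convolution term: Ca (x) exp(-k2 t) on the grid
.tissueConv <- function(ca, k2, tg, dt) {
  .gridConvolve(ca, exp(-k2 * tg), dt)
}

## shared grid for a frame schedule
.modelGrid <- function(frameStart, frameDuration, dt = .GRID_DT) {
  seq(0, max(frameStart + frameDuration), by = dt)
}

#' Construct a dynamic scan object
#'
#' @param tracer `"H2O"`, `"O2"` or `"CO"`
#' @param frameStart,frameDuration frame timing (s)
#' @param activity numeric vector (ROI scan) or voxels-x-frames matrix
#' @param aif named list of [AIFModel-class]; H2O and CO scans take a single
#'   (arbitrarily named) model, O2 scans need `"o2"` and `"water"`
#' @param o2Content arterial oxygen content (mL O2/mL blood), O2 study only
#' @param decayCorrected whether activities are decay corrected (default)
#' @return a [DynamicScan-class]
#' @export
dynamicScan <- function(tracer, frameStart, frameDuration, activity,
                        aif = list(), o2Content = numeric(),
                        decayCorrected = TRUE) {
  if (is.null(dim(activity))) activity <- matrix(activity, nrow = 1)
  new("DynamicScan", tracer = tracer, frameStart = as.numeric(frameStart),
      frameDuration = as.numeric(frameDuration), activity = activity,
      aif = aif, o2Content = as.numeric(o2Content),
      decayCorrected = decayCorrected)
}

#' @rdname scan-accessors
#' @param x a [DynamicScan-class]
#' @name scan-accessors
#' @title Dynamic scan accessors
#' @return `tracer`: the tracer label; `frameStart`/`frameDuration`/
#'   `frameMid`: frame timing (s); `activity`: the voxels-x-frames activity
#'   matrix; `nFrames`: number of frames.
#' @export
setMethod("tracer", "DynamicScan", function(x) x@tracer)

#' @rdname scan-accessors
#' @export
setMethod("frameStart", "DynamicScan", function(x) x@frameStart)

#' @rdname scan-accessors
#' @export
setMethod("frameDuration", "DynamicScan", function(x) x@frameDuration)

#' @rdname scan-accessors
#' @export
setMethod("frameMid", "DynamicScan",
          function(x) x@frameStart + x@frameDuration / 2)

#' @rdname scan-accessors
#' @export
setMethod("activity", "DynamicScan", function(x) x@activity)

#' @rdname scan-accessors
#' @export
setMethod("nFrames", "DynamicScan", function(x) length(x@frameStart))

setMethod("show", "DynamicScan", function(object) {
  cat(sprintf("DynamicScan [%s]: %d frames over %.0f s, %d voxel(s)%s\n",
              object@tracer, nFrames(object),
              max(object@frameStart + object@frameDuration),
              nrow(object@activity),
              if (object@decayCorrected) ", decay corrected" else ""))
})

#' Forward-simulate a [15O]H2O time-activity curve
#'
#' One-tissue Kety model for freely diffusible water:
#' \deqn{C(t) = f \, (C_a \otimes e^{-(f/\lambda) t}),}
#' with flow `f` converted internally to per-second, per-mL-tissue units.
#' Frame values are the time averages of `C(t)` over each frame.
#'
#' @param cbf cerebral blood flow (mL/min/100 mL); may be 0
#' @param lambda blood-tissue partition coefficient of water (mL/mL), > 0
#' @param aif an [AIFModel-class] for the arterial water concentration
#' @param frameStart,frameDuration frame schedule (s)
#' @param dt internal integration step (s)
#' @return a [DynamicScan-class] with tracer `"H2O"`
#' @examples
#' sch <- defaultFrameSchedule("H2O")
#' scan <- simulateH2oTac(32, 0.9, aifModel(), sch[, 1], sch[, 2])
#' @export
simulateH2oTac <- function(cbf, lambda, aif, frameStart, frameDuration,
                           dt = .GRID_DT) {
  if (lambda <= 0) stop("partition coefficient lambda must be positive")
  if (cbf < 0) stop("CBF must be non-negative")
  tg <- .modelGrid(frameStart, frameDuration, dt)
  ca <- sampleAIF(aif, tg)
  f <- .flowPerSec(cbf)
  tac <- if (f == 0) numeric(length(tg)) else
    f * .tissueConv(ca, f / lambda, tg, dt)
  vals <- .frameAverage(tg, tac, frameStart, frameDuration)
  dynamicScan("H2O", frameStart, frameDuration, vals, aif = list(blood = aif))
}

#' Forward-simulate a [15O]O2 time-activity curve
#'
#' Mintun-type oxygen model with a vascular component:
#' \deqn{C(t) = E f (C_{a,O_2} \otimes e^{-(f/\lambda)t})
#'   + f (C_{a,w} \otimes e^{-(f/\lambda)t})
#'   + V_b R_{Hct} C_{a,O_2}(t) (1 - 0.835 E),}
#' where `E` is the oxygen extraction fraction, \eqn{C_{a,w}} the
#' recirculating metabolic-water input and \eqn{V_b} the blood volume
#' fraction.  Frame values are frame averages.
#'
#' @param oef oxygen extraction fraction as a fraction in `[0, 1]`
#' @param cbf cerebral blood flow (mL/min/100 mL)
#' @param cbv cerebral blood volume (mL/100 mL)
#' @param lambda partition coefficient (mL/mL)
#' @param aifO2 [AIFModel-class] for whole-blood 15O2 activity
#' @param aifWater [AIFModel-class] for recirculating water (must lag
#'   `aifO2`)
#' @param frameStart,frameDuration frame schedule (s)
#' @param o2Content arterial oxygen content (mL O2/mL blood), carried as
#'   metadata
#' @param rHct small-to-large-vessel haematocrit ratio
#' @param dt internal integration step (s)
#' @return a [DynamicScan-class] with tracer `"O2"`
#' @export
simulateO2Tac <- function(oef, cbf, cbv, lambda, aifO2, aifWater,
                          frameStart, frameDuration, o2Content = 0.18,
                          rHct = .R_HCT_DEFAULT, dt = .GRID_DT) {
  if (lambda <= 0) stop("partition coefficient lambda must be positive")
  if (aifWater@delay < aifO2@delay)
    stop("recirculating-water curve must lag the O2 curve")
  tg <- .modelGrid(frameStart, frameDuration, dt)
  caO2 <- sampleAIF(aifO2, tg)
  caW <- sampleAIF(aifWater, tg)
  f <- .flowPerSec(cbf)
  k2 <- f / lambda
  convO2 <- if (f == 0) numeric(length(tg)) else .tissueConv(caO2, k2, tg, dt)
  convW <- if (f == 0) numeric(length(tg)) else .tissueConv(caW, k2, tg, dt)
  vb <- cbv / 100
  tac <- oef * f * convO2 + f * convW +
    vb * rHct * caO2 * (1 - .O2_VASC_CORR * oef)
  vals <- .frameAverage(tg, tac, frameStart, frameDuration)
  dynamicScan("O2", frameStart, frameDuration, vals,
              aif = list(o2 = aifO2, water = aifWater),
              o2Content = o2Content)
}

#' Forward-simulate a [15O]CO blood-volume scan
#'
#' After CO inhalation the tracer is bound to haemoglobin, so the tissue
#' signal is purely vascular: \eqn{C(t) = (V_b/100) R_{Hct} C_b(t)}, with
#' \eqn{C_b} the whole-blood activity.
#'
#' @param cbv cerebral blood volume (mL/100 mL)
#' @param aifBlood [AIFModel-class] for the whole-blood CO activity
#' @param frameStart,frameDuration frame schedule (s)
#' @param rHct small-to-large-vessel haematocrit ratio
#' @param dt internal integration step (s)
#' @return a [DynamicScan-class] with tracer `"CO"`
#' @export
simulateCoTac <- function(cbv, aifBlood, frameStart, frameDuration,
                          rHct = .R_HCT_DEFAULT, dt = .GRID_DT) {
  if (cbv < 0) stop("CBV must be non-negative")
  tg <- .modelGrid(frameStart, frameDuration, dt)
  cb <- sampleAIF(aifBlood, tg)
  tac <- (cbv / 100) * rHct * cb
  vals <- .frameAverage(tg, tac, frameStart, frameDuration)
  dynamicScan("CO", frameStart, frameDuration, vals,
              aif = list(blood = aifBlood))
}

#' Apply or remove 15O radioactive decay
#'
#' Synthetic scans are generated decay corrected.  `applyDecay()` multiplies
#' each frame by its exact frame-average decay factor
#' \eqn{(e^{-\mu t_0} - e^{-\mu t_1})/(\mu \Delta t)} (half-life 122.24 s),
#' producing a non-corrected scan; `correctDecay()` divides it back out.
#'
#' @param scan a [DynamicScan-class]
#' @param halfLife radionuclide half-life (s)
#' @return the scan with decay applied or corrected and the
#'   `decayCorrected` flag updated
#' @export
applyDecay <- function(scan, halfLife = .O15_HALFLIFE) {
  if (!scan@decayCorrected)
    stop("scan is already in non-decay-corrected units")
  fac <- .decayFactor(frameStart(scan), frameDuration(scan), halfLife)
  scan@activity <- sweep(scan@activity, 2, fac, `*`)
  scan@decayCorrected <- FALSE
  scan
}

#' @rdname applyDecay
#' @export
correctDecay <- function(scan, halfLife = .O15_HALFLIFE) {
  if (scan@decayCorrected) stop("scan is already decay corrected")
  fac <- .decayFactor(frameStart(scan), frameDuration(scan), halfLife)
  scan@activity <- sweep(scan@activity, 2, fac, `/`)
  scan@decayCorrected <- TRUE
  scan
}

.decayFactor <- function(frameStart, frameDuration, halfLife) {
  mu <- log(2) / halfLife
  t0 <- frameStart
  t1 <- frameStart + frameDuration
  (exp(-mu * t0) - exp(-mu * t1)) / (mu * frameDuration)
}

#' Default three-tracer frame schedules
#'
#' The acquisition layout emulated by the generator: a 25-frame dynamic
#' water scan over 600 s, a 20-frame dynamic oxygen scan over 600 s, and a
#' 3-frame carbon monoxide scan over 360 s.
#'
#' @param tracer `"H2O"`, `"O2"` or `"CO"`
#' @return a two-column matrix `(start, duration)` in seconds
#' @examples
#' nrow(defaultFrameSchedule("H2O"))  # 25
#' @export
defaultFrameSchedule <- function(tracer = c("H2O", "O2", "CO")) {
  tracer <- match.arg(tracer)
  durs <- switch(tracer,
    H2O = c(rep(5, 12), rep(10, 6), rep(30, 4), rep(120, 3)),
    O2 = c(rep(5, 8), rep(15, 6), rep(30, 4), rep(175, 2)),
    CO = rep(120, 3))
  cbind(start = cumsum(c(0, durs[-length(durs)])), duration = durs)
}
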