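#' @include kinetics-forward.R
NULL

#' Construct a cohort configuration
#'
#' Defaults emulate the study population: 24 patients with ipsilateral true
#' haemodynamic stages drawn with prevalence 9/24, 13/24, 2/24, a 9/24
#' fraction of mildly abnormal contralateral hemispheres, normal-control
#' reactivity Normal(36, 8) so that mean minus two SD equals the 20%
#' impairment cut-off, and the three-tracer frame schedules (25 frames /
#' 600 s water, 20 frames / 600 s oxygen, 3 frames / 360 s carbon
#' monoxide).
#'
#' @param nPatients number of patients
#' @param seed RNG seed (integer)
#' @param stagePrevalence probability triple for true ipsilateral stage
#'   0/1/2
#' @param reactivityNoiseSd SD of the reactivity measurement noise
#'   (percentage points); 0 for noiseless recordings
#' @param tacNoiseModel `"none"`, `"gaussian_frame"` or `"poisson_like"`
#' @param tacNoiseScale frame-noise scale (see [CohortConfig-class])
#' @param contralateralAbnormalFraction probability of a mildly abnormal
#'   contralateral hemisphere
#' @param stage1SubtypeProp weights of stage-1 subtypes (decreased CBF,
#'   increased CBV, both); normalised internally
#' @param frameScheduleH2o,frameScheduleO2,frameScheduleCo `(start,
#'   duration)` matrices in seconds
#' @return a [CohortConfig-class]
#' @examples
#' cohortConfig(nPatients = 6, seed = 7)
#' @export
cohortConfig <- function(nPatients = 24, seed = 1,
                         stagePrevalence = c(9, 13, 2) / 24,
                         reactivityNoiseSd = 3,
                         tacNoiseModel = c("gaussian_frame", "none",
                                           "poisson_like"),
                         tacNoiseScale = 0.5,
                         contralateralAbnormalFraction = 9 / 24,
                         stage1SubtypeProp = c(10, 3, 2),
                         frameScheduleH2o = defaultFrameSchedule("H2O"),
                         frameScheduleO2 = defaultFrameSchedule("O2"),
                         frameScheduleCo = defaultFrameSchedule("CO")) {
  if (length(nPatients) != 1 || !is.finite(nPatients) || nPatients < 1)
    stop("nPatients must be a positive integer")
  if (abs(sum(stagePrevalence) - 1) > 1e-8)
    stop("stagePrevalence must sum to 1")
  tacNoiseModel <- match.arg(tacNoiseModel)
  new("CohortConfig", nPatients = as.numeric(nPatients),
      seed = as.numeric(seed), stagePrevalence = stagePrevalence,
      reactivityNoiseSd = reactivityNoiseSd, tacNoiseModel = tacNoiseModel,
      tacNoiseScale = tacNoiseScale,
      contralateralAbnormalFraction = contralateralAbnormalFraction,
      stage1SubtypeProp = stage1SubtypeProp / sum(stage1SubtypeProp),
      frameScheduleH2o = frameScheduleH2o, frameScheduleO2 = frameScheduleO2,
      frameScheduleCo = frameScheduleCo)
}

setMethod("show", "CohortConfig", function(object) {
  cat(sprintf(
    "CohortConfig: %d patients, seed %d, stage prevalence %.3f/%.3f/%.3f\n",
    object@nPatients, object@seed, object@stagePrevalence[1],
    object@stagePrevalence[2], object@stagePrevalence[3]))
  cat(sprintf("  TAC noise: %s (scale %.3g); reactivity noise SD %.3g%%\n",
              object@tacNoiseModel, object@tacNoiseScale,
              object@reactivityNoiseSd))
})

#' Construct a TCD recording
#'
#' @param patientId patient identifier
#' @param side `"left"` or `"right"`
#' @param baseline,hypercapnia velocity envelope samples (cm/s)
#' @param etco2Before,etco2After end-tidal CO2 readings (mmHg)
#' @param sbpBefore,sbpAfter,dbpBefore,dbpAfter blood-pressure readings
#'   (mmHg)
#' @return a [BFVRecording-class]
#' @export
bfvRecording <- function(patientId, side, baseline, hypercapnia,
                         etco2Before = NA_real_, etco2After = NA_real_,
                         sbpBefore = NA_real_, sbpAfter = NA_real_,
                         dbpBefore = NA_real_, dbpAfter = NA_real_) {
  new("BFVRecording", patientId = as.character(patientId), side = side,
      baseline = as.numeric(baseline), hypercapnia = as.numeric(hypercapnia),
      etco2Before = etco2Before, etco2After = etco2After,
      sbpBefore = sbpBefore, sbpAfter = sbpAfter,
      dbpBefore = dbpBefore, dbpAfter = dbpAfter)
}

## run expr with a fixed seed, restoring the caller's RNG state afterwards
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

## one-at-a-time truncated normal by rejection (bounds guaranteed wide
## enough for the generator's parameter choices)
.rtnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(pmin(pmax(rep(mean, n), lower), upper))
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      x <- stats::rnorm(1, mean, sd)
      if (x >= lower && x <= upper) break
    }
    out[i] <- x
  }
  out
}

## true haemodynamic state of one hemisphere, given its stage and (for
## stage 1) subtype.  Distributions are anchored on the printed normal
## limits being control mean +/- 1.96 SD.
.drawHemisphereTruth <- function(stage, subtype = "lowCBF") {
  eps <- 1e-6
  if (stage == 0) {
    list(cbf = .rtnorm(1, 40, 4.5, 31.1, 70),
         cbv = .rtnorm(1, 3.2, 0.35, 1.5, 3.9),
         oef = .rtnorm(1, 45, 5, 20, 55.7))
  } else if (stage == 1) {
    cbf <- switch(subtype,
      lowCBF = .rtnorm(1, 27, 2.5, 15, 31.1 - eps),
      highCBV = .rtnorm(1, 36, 3.5, 31.1, 70),
      both = .rtnorm(1, 27, 2.5, 15, 31.1 - eps))
    cbv <- switch(subtype,
      lowCBF = .rtnorm(1, 3.3, 0.3, 1.5, 3.9),
      highCBV = .rtnorm(1, 4.4, 0.3, 3.9 + eps, 6),
      both = .rtnorm(1, 4.4, 0.3, 3.9 + eps, 6))
    list(cbf = cbf, cbv = cbv, oef = .rtnorm(1, 48, 4, 20, 55.7))
  } else {
    list(cbf = .rtnorm(1, 26, 3, 15, 45),
         cbv = .rtnorm(1, 4.2, 0.5, 1.5, 6.5),
         oef = .rtnorm(1, 62, 4, 55.7 + eps, 80))
  }
}

.drawContralateralTruth <- function(abnormal) {
  if (abnormal) {
    list(cbf = .rtnorm(1, 33, 2.5, 29, 45),
         cbv = .rtnorm(1, 3.6, 0.3, 1.5, 4.2),
         oef = .rtnorm(1, 48, 4, 20, 57))
  } else {
    .drawHemisphereTruth(0)
  }
}

## true reactivity by hemisphere state; normal controls are Normal(36, 8)
## so mean - 2 SD = 20 (the impairment cut-off)
.drawReactivity <- function(stage) {
  switch(as.character(stage),
         "0" = stats::rnorm(1, 36, 8),
         "1" = stats::rnorm(1, 10, 7),
         "2" = stats::rnorm(1, 0, 6))
}

.drawPatientAifs <- function() {
  o2Delay <- .rtnorm(1, 15, 2, 5, 30)
  list(
    h2o = aifModel(amplitude = .rtnorm(1, 60, 5, 30, 90),
                   delay = .rtnorm(1, 15, 2, 5, 30),
                   shape = 3, timeToPeak = .rtnorm(1, 8, 1, 4, 14),
                   dispersion = 5),
    o2 = aifModel(amplitude = .rtnorm(1, 25, 3, 10, 40), delay = o2Delay,
                  shape = 2.5, timeToPeak = .rtnorm(1, 10, 1.5, 5, 18),
                  dispersion = 5),
    water = aifModel(amplitude = .rtnorm(1, 7.5, 1, 3, 12),
                     delay = o2Delay + 25, shape = 2, timeToPeak = 40,
                     dispersion = 5),
    co = aifModel(amplitude = .rtnorm(1, 30, 3, 15, 45),
                  delay = .rtnorm(1, 20, 3, 8, 35),
                  shape = 1.2, timeToPeak = 150, dispersion = 5),
    o2Content = .rtnorm(1, 0.18, 0.015, 0.12, 0.24)
  )
}

## add frame noise in place
.addFrameNoise <- function(scan, model, scale) {
  if (model == "none" || scale == 0) return(scan)
  vals <- scan@activity
  dur <- frameDuration(scan)
  for (v in seq_len(nrow(vals))) {
    m <- pmax(vals[v, ], 1e-6)
    if (model == "gaussian_frame") {
      vals[v, ] <- vals[v, ] + stats::rnorm(length(m), 0,
                                            scale * sqrt(m / dur))
    } else {                     # poisson_like
      lam <- m * dur / scale^2
      vals[v, ] <- stats::rpois(length(lam), lam) * scale^2 / dur
    }
  }
  scan@activity <- vals
  scan
}

## velocity envelope samples with an exactly centred within-recording
## jitter, so the phase mean is hit exactly (noise enters via the measured
## reactivity, not the sample mean)
.velocitySamples <- function(mean, n = 50, withinSd = 0) {
  if (withinSd == 0) return(rep(mean, n))
  r <- stats::rnorm(n, 0, withinSd)
  pmax(mean + (r - mean(r)), 0)
}

#' Generate a synthetic cohort
#'
#' Draws per-patient ground truth (stage-dependent CBF/CBV/OEF, partition
#' coefficient, baseline MCA velocity, true reactivity, infarct fraction),
#' synthesises the TCD recordings, and forward-simulates the three-tracer
#' dynamic PET scans for both hemispheres.  All randomness flows from
#' `config`'s seed; the same configuration reproduces the cohort exactly.
#'
#' @param config a [CohortConfig-class]
#' @param scans simulate the PET scans (`TRUE`, default) or generate truth
#'   and TCD only (useful for large statistical checks)
#' @return a [Cohort-class]
#' @examples
#' coh <- generateCohort(cohortConfig(nPatients = 2, seed = 7))
#' head(cohortTruth(coh))
#' @export
generateCohort <- function(config, scans = TRUE) {
  validObject(config)
  n <- as.integer(config@nPatients)
  .withSeed(config@seed, {
    truthRows <- vector("list", 2L * n)
    recordings <- list()
    scanList <- list()
    aifs <- list()
    subtypes <- c("lowCBF", "highCBV", "both")
    for (i in seq_len(n)) {
      pid <- sprintf("pt%03d", i)
      sympSide <- sample(c("left", "right"), 1)
      contraSide <- setdiff(c("left", "right"), sympSide)
      ipsiStage <- sample(0:2, 1, prob = config@stagePrevalence)
      subtype <- sample(subtypes, 1, prob = config@stage1SubtypeProp)
      ipsi <- .drawHemisphereTruth(ipsiStage, subtype)
      contraAbnormal <-
        stats::runif(1) < config@contralateralAbnormalFraction
      contra <- .drawContralateralTruth(contraAbnormal)
      pat <- list()
      pat[[sympSide]] <- c(ipsi, role = "ipsilateral", stage = ipsiStage)
      ## the contralateral label is derived from its drawn values, so a
      ## mildly abnormal contralateral hemisphere is labelled consistently
      pat[[contraSide]] <- c(contra, role = "contralateral",
                             stage = classifyStage(contra$cbf, contra$cbv,
                                                   contra$oef))
      aif <- .drawPatientAifs()
      aifs[[pid]] <- aif
      for (side in c("left", "right")) {
        h <- pat[[side]]
        lambda <- .rtnorm(1, 0.9, 0.05, 0.6, 1.1)
        vb <- .rtnorm(1, 55, 10, 25, 95)
        rTrue <- .drawReactivity(h$stage)
        infarct <- if (h$role == "ipsilateral" && stats::runif(1) < 0.3)
          stats::runif(1, 0.05, 0.3) else 0
        truthRows[[2 * (i - 1) + (side == "right") + 1]] <- data.frame(
          patient_id = pid, side = side, role = h$role,
          symptomatic_side = sympSide, true_stage = h$stage,
          cbf = h$cbf, cbv = h$cbv, oef = h$oef, lambda = lambda,
          baseline_velocity_cms = vb, reactivity_pct = rTrue,
          infarct_fraction = infarct, stringsAsFactors = FALSE)

        rMeas <- rTrue + if (config@reactivityNoiseSd > 0)
          stats::rnorm(1, 0, config@reactivityNoiseSd) else 0
        withinSd <- if (config@reactivityNoiseSd > 0) 2 else 0
        etBefore <- .rtnorm(1, 40, 3, 30, 50)
        sb <- .rtnorm(1, 158, 28, 100, 220)
        db <- .rtnorm(1, 86, 14, 50, 120)
        rec <- bfvRecording(
          pid, side,
          baseline = .velocitySamples(vb, withinSd = withinSd),
          hypercapnia = .velocitySamples(vb * (1 + rMeas / 100),
                                         withinSd = withinSd),
          etco2Before = etBefore,
          etco2After = etBefore + .rtnorm(1, 12, 6, 2, 30),
          sbpBefore = sb, sbpAfter = sb + stats::rnorm(1, 2, 12),
          dbpBefore = db, dbpAfter = db + stats::rnorm(1, 1, 6))
        recordings[[paste(pid, side, sep = ".")]] <- rec

        if (scans) {
          sH <- simulateH2oTac(h$cbf, lambda, aif$h2o,
                               config@frameScheduleH2o[, 1],
                               config@frameScheduleH2o[, 2])
          sO <- simulateO2Tac(h$oef / 100, h$cbf, h$cbv, lambda,
                              aif$o2, aif$water,
                              config@frameScheduleO2[, 1],
                              config@frameScheduleO2[, 2],
                              o2Content = aif$o2Content)
          sC <- simulateCoTac(h$cbv, aif$co,
                              config@frameScheduleCo[, 1],
                              config@frameScheduleCo[, 2])
          for (s in list(sH, sO, sC)) {
            s <- .addFrameNoise(s, config@tacNoiseModel,
                                config@tacNoiseScale)
            scanList[[paste(pid, side, tracer(s), sep = ".")]] <- s
          }
        }
      }
    }
    new("Cohort", truth = do.call(rbind, truthRows),
        recordings = recordings, scans = scanList, aifs = aifs,
        config = config)
  })
}

#' @rdname cohort-accessors
#' @param x a [Cohort-class]
#' @name cohort-accessors
#' @title Cohort accessors
#' @return `cohortTruth`: the ground-truth data.frame; `cohortRecordings`:
#'   named list of TCD recordings; `cohortScans`: named list of dynamic
#'   scans; `cohortConfigOf`: the generating configuration.
#' @export
setMethod("cohortTruth", "Cohort", function(x) x@truth)

#' @rdname cohort-accessors
#' @export
setMethod("cohortRecordings", "Cohort", function(x) x@recordings)

#' @rdname cohort-accessors
#' @export
setMethod("cohortScans", "Cohort", function(x) x@scans)

#' @rdname cohort-accessors
#' @export
setMethod("cohortConfigOf", "Cohort", function(x) x@config)

setMethod("show", "Cohort", function(object) {
  n <- object@config@nPatients
  cat(sprintf("Synthetic cohort: %d patients (%d hemisphere records)\n",
              n, nrow(object@truth)))
  tab <- table(factor(
    object@truth$true_stage[object@truth$role == "ipsilateral"],
    levels = 0:2))
  cat(sprintf("  ipsilateral true stages 0/1/2: %d/%d/%d; %d PET scan(s)\n",
              tab[1], tab[2], tab[3], length(object@scans)))
})
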