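#' @include synthetic-cohort.R
NULL

.aifToList <- function(m) {
  list(amplitude = m@amplitude, delay = m@delay, shape = m@shape,
       timeToPeak = m@timeToPeak, dispersion = m@dispersion)
}

.aifFromList <- function(l) {
  aifModel(amplitude = l$amplitude, delay = l$delay, shape = l$shape,
           timeToPeak = l$timeToPeak, dispersion = l$dispersion)
}

.scheduleToList <- function(m) {
  list(start = as.numeric(m[, 1]), duration = as.numeric(m[, 2]))
}

.scheduleFromList <- function(l) {
  cbind(start = as.numeric(l$start), duration = as.numeric(l$duration))
}

#' Serialise a cohort configuration to / from a plain list
#'
#' Used for the JSON sidecar and the pipeline configuration file; the
#' round trip is lossless.
#'
#' @param config a [CohortConfig-class]
#' @return `configToList`: a plain list; `configFromList`: the rebuilt
#'   [CohortConfig-class]
#' @export
configToList <- function(config) {
  list(nPatients = config@nPatients, seed = config@seed,
       stagePrevalence = config@stagePrevalence,
       reactivityNoiseSd = config@reactivityNoiseSd,
       tacNoiseModel = config@tacNoiseModel,
       tacNoiseScale = config@tacNoiseScale,
       contralateralAbnormalFraction =
         config@contralateralAbnormalFraction,
       stage1SubtypeProp = config@stage1SubtypeProp,
       frameScheduleH2o = .scheduleToList(config@frameScheduleH2o),
       frameScheduleO2 = .scheduleToList(config@frameScheduleO2),
       frameScheduleCo = .scheduleToList(config@frameScheduleCo))
}

#' @rdname configToList
#' @param x a plain list as produced by `configToList` (or parsed from
#'   JSON)
#' @export
configFromList <- function(x) {
  cohortConfig(nPatients = x$nPatients, seed = x$seed,
               stagePrevalence = as.numeric(x$stagePrevalence),
               reactivityNoiseSd = x$reactivityNoiseSd,
               tacNoiseModel = x$tacNoiseModel,
               tacNoiseScale = x$tacNoiseScale,
               contralateralAbnormalFraction =
                 x$contralateralAbnormalFraction,
               stage1SubtypeProp = as.numeric(x$stage1SubtypeProp),
               frameScheduleH2o = .scheduleFromList(x$frameScheduleH2o),
               frameScheduleO2 = .scheduleFromList(x$frameScheduleO2),
               frameScheduleCo = .scheduleFromList(x$frameScheduleCo))
}

.joinSamples <- function(x) paste(format(x, digits = 17, trim = TRUE,
                                         scientific = FALSE),
                                  collapse = ";")
.splitSamples <- function(s) as.numeric(strsplit(s, ";", fixed = TRUE)[[1]])

#' Write a cohort to disk
#'
#' Persists the cohort as plain-text files: `patients.csv` (one row per
#' patient x hemisphere: ground truth plus the TCD recording, velocity
#' samples semicolon-joined), `tacs.csv` (long-format frame table:
#' patient, hemisphere, tracer, frame_start_s, frame_duration_s,
#' activity), and `cohort.json` (per-patient AIF parameters, arterial
#' oxygen content and a configuration echo).
#'
#' @param cohort a [Cohort-class]
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @seealso [readCohort()]
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  truth <- cohortTruth(cohort)
  recs <- cohortRecordings(cohort)
  key <- paste(truth$patient_id, truth$side, sep = ".")
  tcd <- do.call(rbind, lapply(recs[key], function(r) data.frame(
    bfv_baseline = .joinSamples(r@baseline),
    bfv_hypercapnia = .joinSamples(r@hypercapnia),
    etco2_before = r@etco2Before, etco2_after = r@etco2After,
    sbp_before = r@sbpBefore, sbp_after = r@sbpAfter,
    dbp_before = r@dbpBefore, dbp_after = r@dbpAfter,
    stringsAsFactors = FALSE)))
  utils::write.csv(cbind(truth, tcd),
                   file.path(dir, "patients.csv"), row.names = FALSE)

  scans <- cohortScans(cohort)
  tacRows <- lapply(names(scans), function(nm) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    s <- scans[[nm]]
    data.frame(patient = parts[1], hemisphere = parts[2],
               tracer = parts[3], frame_start_s = frameStart(s),
               frame_duration_s = frameDuration(s),
               activity = as.numeric(activity(s)[1, ]),
               stringsAsFactors = FALSE)
  })
  tacs <- if (length(tacRows)) do.call(rbind, tacRows) else
    data.frame(patient = character(), hemisphere = character(),
               tracer = character(), frame_start_s = numeric(),
               frame_duration_s = numeric(), activity = numeric())
  utils::write.csv(tacs, file.path(dir, "tacs.csv"), row.names = FALSE)

  sidecar <- list(
    config = configToList(cohortConfigOf(cohort)),
    aifs = lapply(cohort@aifs, function(a) list(
      h2o = .aifToList(a$h2o), o2 = .aifToList(a$o2),
      water = .aifToList(a$water), co = .aifToList(a$co),
      o2Content = a$o2Content)))
  jsonlite::write_json(sidecar, file.path(dir, "cohort.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a cohort written by [writeCohort()]
#'
#' Rebuilds the full [Cohort-class], including [DynamicScan-class] objects
#' re-attached to their AIF models, so every downstream stage can consume
#' a cohort from disk exactly as it consumes one from memory.
#'
#' @param dir directory containing `patients.csv`, `tacs.csv` and
#'   `cohort.json`
#' @return a [Cohort-class]
#' @export
readCohort <- function(dir) {
  pats <- utils::read.csv(file.path(dir, "patients.csv"),
                          stringsAsFactors = FALSE)
  tacs <- utils::read.csv(file.path(dir, "tacs.csv"),
                          stringsAsFactors = FALSE)
  sidecar <- jsonlite::read_json(file.path(dir, "cohort.json"),
                                 simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE)
  config <- configFromList(sidecar$config)
  truthCols <- c("patient_id", "side", "role", "symptomatic_side",
                 "true_stage", "cbf", "cbv", "oef", "lambda",
                 "baseline_velocity_cms", "reactivity_pct",
                 "infarct_fraction")
  truth <- pats[, truthCols]
  recordings <- list()
  for (i in seq_len(nrow(pats))) {
    recordings[[paste(pats$patient_id[i], pats$side[i], sep = ".")]] <-
      bfvRecording(pats$patient_id[i], pats$side[i],
                   .splitSamples(pats$bfv_baseline[i]),
                   .splitSamples(pats$bfv_hypercapnia[i]),
                   etco2Before = pats$etco2_before[i],
                   etco2After = pats$etco2_after[i],
                   sbpBefore = pats$sbp_before[i],
                   sbpAfter = pats$sbp_after[i],
                   dbpBefore = pats$dbp_before[i],
                   dbpAfter = pats$dbp_after[i])
  }
  aifs <- lapply(sidecar$aifs, function(a) list(
    h2o = .aifFromList(a$h2o), o2 = .aifFromList(a$o2),
    water = .aifFromList(a$water), co = .aifFromList(a$co),
    o2Content = a$o2Content))
  scans <- list()
  if (nrow(tacs)) {
    splitKey <- paste(tacs$patient, tacs$hemisphere, tacs$tracer, sep = ".")
    for (nm in unique(splitKey)) {
      sub <- tacs[splitKey == nm, ]
      sub <- sub[order(sub$frame_start_s), ]
      pid <- sub$patient[1]
      trc <- sub$tracer[1]
      a <- aifs[[pid]]
      aifList <- switch(trc,
        H2O = list(blood = a$h2o),
        O2 = list(o2 = a$o2, water = a$water),
        CO = list(blood = a$co))
      scans[[nm]] <- dynamicScan(trc, sub$frame_start_s,
                                 sub$frame_duration_s, sub$activity,
                                 aif = aifList,
                                 o2Content = if (trc == "O2") a$o2Content
                                 else numeric())
    }
  }
  new("Cohort", truth = truth, recordings = recordings, scans = scans,
      aifs = aifs, config = config)
}
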