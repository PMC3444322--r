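#' @include concordance.R staging.R kinetics-fit.R cohort-io.R
NULL

#' Quantify a cohort's PET scans
#'
#' Runs the tracer-kinetic quantification for every patient and
#' hemisphere: CBF (and partition coefficient) from the dynamic water
#' scan, CBV from the carbon monoxide scan, and OEF from the oxygen scan
#' with flow and blood volume fixed at their estimates.  With
#' `useTruth = TRUE` the generator's ground-truth values are copied
#' instead of fitted -- a fast path for statistical checks in which
#' quantification error is not under study.
#'
#' @param cohort a [Cohort-class] with scans
#' @param fitLambda,fitDelay passed to [fitCBF()]
#' @param useTruth copy true values instead of fitting
#' @return data.frame with one row per hemisphere: `patient_id`, `side`,
#'   `role`, `cbf`, `cbv`, `oef`, `converged`
#' @export
quantifyCohort <- function(cohort, fitLambda = TRUE, fitDelay = FALSE,
                           useTruth = FALSE) {
  truth <- cohortTruth(cohort)
  if (useTruth) {
    out <- truth[, c("patient_id", "side", "role", "cbf", "cbv", "oef")]
    out$converged <- TRUE
    rownames(out) <- NULL
    return(out)
  }
  scans <- cohortScans(cohort)
  if (!length(scans)) stop("cohort has no scans; regenerate with scans = TRUE")
  rows <- lapply(seq_len(nrow(truth)), function(i) {
    key <- paste(truth$patient_id[i], truth$side[i], sep = ".")
    sH <- scans[[paste0(key, ".H2O")]]
    sO <- scans[[paste0(key, ".O2")]]
    sC <- scans[[paste0(key, ".CO")]]
    if (is.null(sH) || is.null(sO) || is.null(sC))
      stop("missing scan(s) for ", key)
    fh <- fitCBF(sH, fitLambda = fitLambda, fitDelay = fitDelay)
    cbv <- computeCBV(sC)
    oef <- if (fh$converged)
      fitOEF(sO, cbf = fh$cbf, cbv = cbv, lambda = fh$lambda)$oef
    else NA_real_
    data.frame(patient_id = truth$patient_id[i], side = truth$side[i],
               role = truth$role[i], cbf = fh$cbf, cbv = cbv, oef = oef,
               converged = fh$converged, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Pipeline configuration
#'
#' Bundles everything one run needs: the cohort configuration, normal
#' ranges, the variable->test and variable->correlation maps, the outlier
#' exclusion list and the quantification mode.  Serialises losslessly to
#' JSON via [writePipelineConfig()] / [readPipelineConfig()].
#'
#' @param seed master seed; also seeds the cohort configuration unless one
#'   is supplied
#' @param cohort a [CohortConfig-class]
#' @param ranges a [NormalRanges-class]
#' @param testMap variable->test map for [compareGroups()]
#' @param corMap variable->method map for [correlateReactivity()]
#' @param exclude patient ids excluded in the secondary correlation run
#' @param quantify `"fit"` (kinetic fits) or `"truth"` (copy ground truth)
#' @param fitLambda,fitDelay kinetic-fit options
#' @return a list of class `"pipelineConfig"`
#' @export
pipelineConfig <- function(seed = 1, cohort = NULL,
                           ranges = normalRanges(),
                           testMap = .defaultTestMap(),
                           corMap = .defaultCorMap(),
                           exclude = character(),
                           quantify = c("fit", "truth"),
                           fitLambda = TRUE, fitDelay = FALSE) {
  if (is.null(cohort)) cohort <- cohortConfig(seed = seed)
  quantify <- match.arg(quantify)
  structure(list(seed = seed, cohort = cohort, ranges = ranges,
                 testMap = testMap, corMap = corMap, exclude = exclude,
                 quantify = quantify, fitLambda = fitLambda,
                 fitDelay = fitDelay),
            class = "pipelineConfig")
}

#' @rdname pipelineConfig
#' @param config a `pipelineConfig`
#' @param file JSON path
#' @export
writePipelineConfig <- function(config, file) {
  x <- list(seed = config$seed, cohort = configToList(config$cohort),
            ranges = list(cbfLower = config$ranges@cbfLower,
                          cbvUpper = config$ranges@cbvUpper,
                          oefUpper = config$ranges@oefUpper),
            testMap = as.list(config$testMap),
            corMap = as.list(config$corMap),
            exclude = as.list(config$exclude),
            quantify = config$quantify, fitLambda = config$fitLambda,
            fitDelay = config$fitDelay)
  jsonlite::write_json(x, file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(file)
}

#' @rdname pipelineConfig
#' @export
readPipelineConfig <- function(file) {
  x <- jsonlite::read_json(file, simplifyVector = FALSE)
  pipelineConfig(
    seed = x$seed, cohort = configFromList(x$cohort),
    ranges = normalRanges(x$ranges$cbfLower, x$ranges$cbvUpper,
                          x$ranges$oefUpper),
    testMap = unlist(x$testMap), corMap = unlist(x$corMap),
    exclude = as.character(unlist(x$exclude)),
    quantify = x$quantify, fitLambda = x$fitLambda,
    fitDelay = x$fitDelay)
}

.stageLog <- function(stage, t0) {
  message(sprintf("[%s] done in %.2f s", stage,
                  as.numeric(proc.time()[3]) - t0))
}

#' Assemble the patient-level analysis table
#'
#' Joins the symptomatic-hemisphere reactivity results with the staged
#' PET measures into one row per patient: reactivity, category, stage,
#' hemispheric ratios, blood-pressure deltas and the TCD/PET agreement
#' flag.
#'
#' @param reactivity data.frame from [reactivityTable()] (ipsilateral rows)
#' @param staged data.frame from [stageMeasures()]
#' @return patient-level data.frame
#' @export
patientTable <- function(reactivity, staged) {
  ipsi <- staged[staged$role == "ipsilateral", , drop = FALSE]
  m <- match(ipsi$patient_id, reactivity$patient_id)
  if (any(is.na(m)))
    stop("patient present in only one modality: ",
         paste(ipsi$patient_id[is.na(m)], collapse = ", "))
  out <- data.frame(
    patient_id = ipsi$patient_id,
    reactivity_pct = reactivity$reactivity_pct[m],
    category = reactivity$category[m],
    d_etco2 = reactivity$d_etco2[m],
    d_sbp = reactivity$d_sbp[m], d_dbp = reactivity$d_dbp[m],
    cbf = ipsi$cbf, cbv = ipsi$cbv, oef = ipsi$oef, mtt = ipsi$mtt_min,
    cbf_ratio = ipsi$cbf_ratio, oef_ratio = ipsi$oef_ratio,
    mtt_ratio = ipsi$mtt_ratio, stage = ipsi$stage,
    stringsAsFactors = FALSE)
  out$tcd_impaired <- isImpaired(out$reactivity_pct)
  out$pet_compromised <- out$stage >= 1
  out$agreement <- out$tcd_impaired == out$pet_compromised
  out
}

#' Run the full pipeline
#'
#' simulate -> quantify -> reactivity -> stage -> concordance, persisting
#' each stage's outputs under `outDir` (cohort files, reactivity CSV,
#' estimates CSV, staging CSV, and a JSON + text report).  Deterministic
#' under a fixed configuration; any stage failure halts with a
#' stage-tagged error.
#'
#' @param config a [pipelineConfig()]
#' @param outDir output directory
#' @return invisibly, a list with `cohort`, `reactivity`, `measures`,
#'   `staged`, `patients`, `concordance`, `groupComparisons`,
#'   `correlations`, `bpComparison`
#' @export
runPipeline <- function(config, outDir) {
  stopifnot(inherits(config, "pipelineConfig"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  run <- function(stage, expr) {
    t0 <- as.numeric(proc.time()[3])
    r <- tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE))
    .stageLog(stage, t0)
    r
  }
  cohort <- run("simulate", {
    ch <- generateCohort(config$cohort)
    writeCohort(ch, file.path(outDir, "cohort"))
    ch
  })
  reactivity <- run("tcd", {
    tab <- reactivityTable(cohort, sides = "both")
    writeReactivity(tab, file.path(outDir, "reactivity.csv"))
    tab
  })
  measures <- run("pet", {
    m <- quantifyCohort(cohort, fitLambda = config$fitLambda,
                        fitDelay = config$fitDelay,
                        useTruth = config$quantify == "truth")
    utils::write.csv(m, file.path(outDir, "estimates.csv"),
                     row.names = FALSE)
    m
  })
  staged <- run("stage", {
    s <- stageMeasures(measures, config$ranges)
    writeStaging(s, file.path(outDir, "staging.csv"))
    s
  })
  res <- run("agree", {
    ipsiReact <- reactivity[reactivity$role == "ipsilateral", ,
                            drop = FALSE]
    patients <- patientTable(ipsiReact, staged)
    conc <- crossClassify(patients$reactivity_pct, patients$stage)
    groups <- lapply(c(impaired = 20, absent_or_steal = 0),
                     function(th) tryCatch(
                       compareGroups(patients, threshold = th,
                                     testMap = config$testMap),
                       error = function(e) conditionMessage(e)))
    corrAll <- correlateReactivity(patients, corMap = config$corMap)
    corrExcl <- if (length(config$exclude))
      correlateReactivity(patients, corMap = config$corMap,
                          exclude = config$exclude) else NULL
    bp <- tryCatch(compareBpChange(patients),
                   error = function(e) conditionMessage(e))
    list(patients = patients, concordance = conc,
         groupComparisons = groups, correlations = corrAll,
         correlationsExcluded = corrExcl, bpComparison = bp)
  })
  writeReport(res, outDir)
  invisible(c(list(cohort = cohort, reactivity = reactivity,
                   measures = measures, staged = staged), res))
}

#' Write the concordance report
#'
#' Persists the analysis results as machine-readable JSON
#' (`report.json`) and a short human-readable summary (`report.txt`).
#'
#' @param res result list from the agreement stage of [runPipeline()]
#' @param outDir output directory
#' @return `outDir`, invisibly
#' @export
writeReport <- function(res, outDir) {
  conc <- res$concordance
  k <- suppressWarnings(cohenKappa(conc))
  json <- list(
    concordance = list(a = conc@a, b = conc@b, c = conc@c, d = conc@d,
                       agreement = agreementCount(conc),
                       agreement_pct = agreementPct(conc),
                       kappa = if (is.na(k)) NULL else k),
    group_comparisons = res$groupComparisons,
    correlations = res$correlations,
    correlations_excluded = res$correlationsExcluded,
    bp_comparison = res$bpComparison)
  jsonlite::write_json(json, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  n <- conc@a + conc@b + conc@c + conc@d
  txt <- c(
    "TCD CO2-reactivity vs oxygen-15 PET haemodynamic staging",
    sprintf("patients: %d", n),
    sprintf("agreement: %d/%d (%.1f%%)", agreementCount(conc), n,
            agreementPct(conc)),
    sprintf("concordant compromised: %d; concordant normal: %d",
            conc@a, conc@d),
    sprintf("Cohen's kappa: %s",
            if (is.na(k)) "undefined (no variation)" else
              sprintf("%.3f", k)))
  writeLines(txt, file.path(outDir, "report.txt"))
  invisible(outDir)
}
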