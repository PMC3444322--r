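#' @include synthetic-cohort.R
NULL

#' Classify a CO2-reactivity value
#'
#' Category rules: reactivity above 20% is `normal`; values in `(0, 20]`
#' are `impaired` (20% is the normal-control mean minus two SD, and the
#' boundary is inclusive); exactly 0% is `absent`; negative values are
#' `steal` (flow diverted away from the insonated territory under the
#' vasodilatory stimulus).  Every finite value maps to exactly one
#' category.
#'
#' @param reactivity numeric vector of reactivity values (%)
#' @return character vector of categories (`"normal"`, `"impaired"`,
#'   `"absent"`, `"steal"`)
#' @examples
#' classifyReactivity(c(36, 20, 5, 0, -4))
#' @export
classifyReactivity <- function(reactivity) {
  if (any(!is.finite(reactivity))) stop("reactivity must be finite")
  ifelse(reactivity > 20, "normal",
         ifelse(reactivity < 0, "steal",
                ifelse(reactivity == 0, "absent", "impaired")))
}

#' Binary impairment of CO2-reactivity
#'
#' `TRUE` iff reactivity is at most 20% -- absent reactivity and steal
#' count as impaired.  Equivalent to `classifyReactivity(r) != "normal"`.
#'
#' @param reactivity numeric vector of reactivity values (%)
#' @return logical vector
#' @export
isImpaired <- function(reactivity) {
  if (any(!is.finite(reactivity))) stop("reactivity must be finite")
  reactivity <= 20
}

#' Compute CO2-reactivity from a TCD recording
#'
#' Reactivity is the relative change in mean MCA blood-flow velocity from
#' baseline to hypercapnia, expressed as a percentage:
#' \deqn{100 (\bar v_{hyper} - \bar v_{base}) / \bar v_{base}.}
#' Both phases are summarised by the arithmetic mean of the 5-s envelope
#' samples.  End-tidal CO2 and blood-pressure deltas (after minus before)
#' are carried along as metadata.
#'
#' @param rec a [BFVRecording-class]
#' @return one-row data.frame with columns `patient_id`, `side`,
#'   `reactivity_pct`, `category`, `d_etco2`, `d_sbp`, `d_dbp`
#' @examples
#' rec <- bfvRecording("p1", "left", baseline = rep(50, 5),
#'                     hypercapnia = rep(60, 5))
#' computeReactivity(rec)$reactivity_pct  # +20
#' @export
computeReactivity <- function(rec) {
  stopifnot(is(rec, "BFVRecording"))
  vBase <- mean(rec@baseline)
  if (!is.finite(vBase) || vBase <= 0)
    stop("unusable recording: mean baseline velocity must be positive")
  vHyper <- mean(rec@hypercapnia)
  r <- 100 * (vHyper - vBase) / vBase
  data.frame(patient_id = rec@patientId, side = rec@side,
             reactivity_pct = r, category = classifyReactivity(r),
             d_etco2 = rec@etco2After - rec@etco2Before,
             d_sbp = rec@sbpAfter - rec@sbpBefore,
             d_dbp = rec@dbpAfter - rec@dbpBefore,
             stringsAsFactors = FALSE)
}

#' Per-patient reactivity table for a cohort
#'
#' Applies [computeReactivity()] to every recording of the cohort.  By
#' default only the hemisphere ipsilateral to the occlusion enters the
#' comparison with PET, but both sides are returned and flagged.
#'
#' @param cohort a [Cohort-class]
#' @param sides `"ipsilateral"` (default), `"contralateral"` or `"both"`
#' @return data.frame with one row per recording, including a `role`
#'   column
#' @export
reactivityTable <- function(cohort,
                            sides = c("ipsilateral", "contralateral",
                                      "both")) {
  sides <- match.arg(sides)
  truth <- cohortTruth(cohort)
  out <- do.call(rbind, lapply(cohortRecordings(cohort),
                               computeReactivity))
  key <- paste(out$patient_id, out$side, sep = ".")
  tkey <- paste(truth$patient_id, truth$side, sep = ".")
  out$role <- truth$role[match(key, tkey)]
  rownames(out) <- NULL
  if (sides != "both") out <- out[out$role == sides, , drop = FALSE]
  out[order(out$patient_id, out$side), , drop = FALSE]
}

#' Write a reactivity table as CSV
#'
#' @param tab data.frame from [reactivityTable()]
#' @param file output path
#' @return `file`, invisibly
#' @export
writeReactivity <- function(tab, file) {
  utils::write.csv(tab, file, row.names = FALSE)
  invisible(file)
}
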