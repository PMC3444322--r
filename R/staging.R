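#' @include AllClasses.R
NULL

#' Construct normal ranges
#'
#' With no arguments, returns the printed study limits (CBF lower
#' 31.1 mL/min/100 mL, CBV upper 3.9 mL/100 mL, OEF upper 55.7%).
#'
#' @param cbfLower,cbvUpper,oefUpper explicit bounds
#' @return a [NormalRanges-class]
#' @examples
#' normalRanges()
#' @export
normalRanges <- function(cbfLower = 31.1, cbvUpper = 3.9,
                         oefUpper = 55.7) {
  new("NormalRanges", cbfLower = cbfLower, cbvUpper = cbvUpper,
      oefUpper = oefUpper)
}

#' Derive normal ranges from control summaries
#'
#' A patient value is abnormal when beyond the control mean by more than
#' 1.96 standard deviations, in the direction that matters clinically:
#' low CBF, high CBV, high OEF.  Hence `cbfLower = mean - 1.96 sd` and
#' `cbvUpper`/`oefUpper = mean + 1.96 sd`.
#'
#' @param cbfMean,cbfSd control CBF summary (mL/min/100 mL)
#' @param cbvMean,cbvSd control CBV summary (mL/100 mL)
#' @param oefMean,oefSd control OEF summary (%)
#' @return a [NormalRanges-class]
#' @examples
#' deriveRanges(10, 1, 10, 1, 10, 1)  # bounds 8.04 / 11.96 / 11.96
#' @export
deriveRanges <- function(cbfMean, cbfSd, cbvMean, cbvSd, oefMean, oefSd) {
  sds <- c(cbfSd, cbvSd, oefSd)
  if (any(!is.finite(sds)) || any(sds <= 0))
    stop("control standard deviations must be positive")
  normalRanges(cbfLower = cbfMean - 1.96 * cbfSd,
               cbvUpper = cbvMean + 1.96 * cbvSd,
               oefUpper = oefMean + 1.96 * oefSd)
}

setMethod("show", "NormalRanges", function(object) {
  cat(sprintf(
    "NormalRanges: CBF >= %.4g mL/min/100 mL, CBV <= %.4g mL/100 mL, OEF <= %.4g%%\n",
    object@cbfLower, object@cbvUpper, object@oefUpper))
})

#' Classify haemodynamic stage
#'
#' Staging of the grey-matter MCA-territory values of the symptomatic
#' hemisphere: increased OEF (above the upper limit) is stage 2 --
#' autoregulation failure ("misery perfusion") -- and takes precedence
#' over any CBF/CBV finding; otherwise decreased CBF or increased CBV
#' (either sign of autoregulatory vasodilatation) is stage 1; otherwise
#' stage 0.  Values exactly at a limit are normal for that parameter.
#'
#' @param cbf cerebral blood flow (mL/min/100 mL)
#' @param cbv cerebral blood volume (mL/100 mL)
#' @param oef oxygen extraction fraction (%)
#' @param ranges a [NormalRanges-class]; defaults to the printed limits
#' @return integer vector of stages (0, 1 or 2)
#' @examples
#' classifyStage(28, 3.5, 66)  # 2
#' classifyStage(35, 3.5, 50)  # 0
#' classifyStage(29, 3.5, 50)  # 1
#' @export
classifyStage <- function(cbf, cbv, oef, ranges = normalRanges()) {
  n <- max(length(cbf), length(cbv), length(oef))
  cbf <- rep_len(cbf, n); cbv <- rep_len(cbv, n); oef <- rep_len(oef, n)
  if (any(!is.finite(cbf)) || any(!is.finite(cbv)) || any(!is.finite(oef)))
    stop("CBF, CBV and OEF must all be finite (missing parameter?)")
  if (any(cbf <= 0) || any(cbv <= 0) || any(oef <= 0))
    stop("CBF, CBV and OEF must be positive")
  ifelse(oef > ranges@oefUpper, 2L,
         ifelse(cbf < ranges@cbfLower | cbv > ranges@cbvUpper, 1L, 0L))
}

#' Hemispheric ratio
#'
#' Ipsilateral over contralateral value of a haemodynamic parameter.
#'
#' @param ipsi,contra parameter values; `contra` must be positive
#' @return `ipsi / contra`
#' @examples
#' hemisphericRatio(28, 32)  # 0.875
#' @export
hemisphericRatio <- function(ipsi, contra) {
  if (any(!is.finite(contra)) || any(contra <= 0))
    stop("contralateral value must be positive")
  ipsi / contra
}

#' Mean transit time
#'
#' CBV/CBF, in minutes when CBF is given in mL/min/100 mL and CBV in
#' mL/100 mL; a prolonged transit time indicates haemodynamic compromise.
#'
#' @param cbv cerebral blood volume (mL/100 mL)
#' @param cbf cerebral blood flow (mL/min/100 mL)
#' @return mean transit time (min)
#' @examples
#' meanTransitTime(3.0, 30)  # 0.10 min
#' @export
meanTransitTime <- function(cbv, cbf) {
  if (any(!is.finite(cbf)) || any(cbf <= 0))
    stop("CBF must be positive")
  cbv / cbf
}

#' Stage a table of hemisphere measures
#'
#' Takes per-patient-per-hemisphere quantified values (columns
#' `patient_id`, `side`, `role`, `cbf`, `cbv`, `oef`), classifies the
#' stage of each hemisphere and attaches the mean transit time and the
#' ipsilateral/contralateral ratios of CBF, OEF and CBV/CBF to the
#' ipsilateral rows.
#'
#' @param measures data.frame of quantified hemisphere values
#' @param ranges a [NormalRanges-class]
#' @return the input with columns `mtt_min`, `stage`, and (ipsilateral
#'   rows) `cbf_ratio`, `oef_ratio`, `mtt_ratio`
#' @export
stageMeasures <- function(measures, ranges = normalRanges()) {
  need <- c("patient_id", "side", "role", "cbf", "cbv", "oef")
  if (!all(need %in% names(measures)))
    stop("measures must have columns: ", paste(need, collapse = ", "))
  measures$mtt_min <- meanTransitTime(measures$cbv, measures$cbf)
  measures$stage <- classifyStage(measures$cbf, measures$cbv,
                                  measures$oef, ranges)
  measures$cbf_ratio <- NA_real_
  measures$oef_ratio <- NA_real_
  measures$mtt_ratio <- NA_real_
  for (pid in unique(measures$patient_id)) {
    ii <- which(measures$patient_id == pid & measures$role == "ipsilateral")
    ic <- which(measures$patient_id == pid &
                  measures$role == "contralateral")
    if (length(ii) == 1 && length(ic) == 1) {
      measures$cbf_ratio[ii] <- hemisphericRatio(measures$cbf[ii],
                                                 measures$cbf[ic])
      measures$oef_ratio[ii] <- hemisphericRatio(measures$oef[ii],
                                                 measures$oef[ic])
      measures$mtt_ratio[ii] <- hemisphericRatio(measures$mtt_min[ii],
                                                 measures$mtt_min[ic])
    }
  }
  measures
}

#' Write a staging table as CSV
#'
#' @param staged data.frame from [stageMeasures()]
#' @param file output path
#' @return `file`, invisibly
#' @export
writeStaging <- function(staged, file) {
  cols <- c("patient_id", "side", "role", "cbf", "cbv", "oef", "mtt_min",
            "cbf_ratio", "oef_ratio", "mtt_ratio", "stage")
  utils::write.csv(staged[, intersect(cols, names(staged))], file,
                   row.names = FALSE)
  invisible(file)
}
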