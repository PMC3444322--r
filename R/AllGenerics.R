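#' @include AllClasses.R
NULL

#' Sample an arterial input function
#'
#' Evaluate the model concentration at arbitrary (non-decreasing) times.
#' With zero dispersion the gamma-variate is evaluated in closed form;
#' otherwise the curve is propagated through the exponential dispersion
#' kernel on an internal fine grid and interpolated.
#'
#' @param model an [AIFModel-class]
#' @param times numeric vector of times (s), non-negative and non-decreasing
#' @return concentrations at `times` (kBq/mL), non-negative, zero before the
#'   onset delay
#' @examples
#' aif <- aifModel(amplitude = 60, delay = 15, shape = 3, timeToPeak = 8)
#' sampleAIF(aif, c(0, 10, 20, 30, 60))
#' @export
setGeneric("sampleAIF", function(model, times) standardGeneric("sampleAIF"))

#' Closed-form time integral of an AIF model
#'
#' Total area under the gamma-variate, \eqn{A e^{\alpha} t_p
#' \Gamma(\alpha + 1) / \alpha^{\alpha + 1}}.  Dispersion redistributes but
#' does not change the area, so the value applies for any dispersion
#' constant.
#'
#' @param model an [AIFModel-class]
#' @return the integral over \eqn{[0, \infty)} (kBq s/mL)
#' @export
setGeneric("aifIntegral", function(model) standardGeneric("aifIntegral"))

#' @rdname scan-accessors
#' @export
setGeneric("tracer", function(x) standardGeneric("tracer"))

#' @rdname scan-accessors
#' @export
setGeneric("frameStart", function(x) standardGeneric("frameStart"))

#' @rdname scan-accessors
#' @export
setGeneric("frameDuration", function(x) standardGeneric("frameDuration"))

#' @rdname scan-accessors
#' @export
setGeneric("frameMid", function(x) standardGeneric("frameMid"))

#' @rdname scan-accessors
#' @export
setGeneric("activity", function(x) standardGeneric("activity"))

#' @rdname scan-accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname concordance-accessors
#' @export
setGeneric("agreementCount", function(x) standardGeneric("agreementCount"))

#' @rdname concordance-accessors
#' @export
setGeneric("agreementPct", function(x) standardGeneric("agreementPct"))

#' @rdname concordance-accessors
#' @export
setGeneric("cohenKappa", function(x) standardGeneric("cohenKappa"))

#' @rdname cohort-accessors
#' @export
setGeneric("cohortTruth", function(x) standardGeneric("cohortTruth"))

#' @rdname cohort-accessors
#' @export
setGeneric("cohortRecordings", function(x) standardGeneric("cohortRecordings"))

#' @rdname cohort-accessors
#' @export
setGeneric("cohortScans", function(x) standardGeneric("cohortScans"))

#' @rdname cohort-accessors
#' @export
setGeneric("cohortConfigOf", function(x) standardGeneric("cohortConfigOf"))
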