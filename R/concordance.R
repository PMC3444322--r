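#' @include AllGenerics.R tcd-reactivity.R
NULL

#' Cross-classify TCD impairment against PET compromise
#'
#' Builds the 2x2 table of binary TCD impairment (reactivity <= 20%)
#' against binary PET compromise (haemodynamic stage 1 or 2), one
#' observation per patient (the symptomatic hemisphere).  Patients must be
#' present in both modalities.
#'
#' @param reactivity numeric reactivity values (%) or their categories, one
#'   per patient, named or aligned with `stage` by `patientId`
#' @param stage integer stages (0/1/2), one per patient
#' @param patientId optional patient identifiers for both vectors; when
#'   given, the vectors are matched on it and any patient present in only
#'   one modality is an error
#' @return a [ConcordanceTable-class]
#' @examples
#' tab <- crossClassify(c(10, 25, -4, 15), c(1, 0, 2, 0))
#' agreementPct(tab)
#' @export
crossClassify <- function(reactivity, stage, patientId = NULL) {
  if (!is.null(patientId)) {
    stopifnot(is.list(patientId), all(c("tcd", "pet") %in% names(patientId)))
    if (!setequal(patientId$tcd, patientId$pet))
      stop("patients present in only one modality: ",
           paste(c(setdiff(patientId$tcd, patientId$pet),
                   setdiff(patientId$pet, patientId$tcd)), collapse = ", "))
    stage <- stage[match(patientId$tcd, patientId$pet)]
  }
  if (length(reactivity) != length(stage))
    stop("one TCD result and one stage per patient are required")
  imp <- if (is.numeric(reactivity)) isImpaired(reactivity)
         else reactivity != "normal"
  comp <- stage >= 1
  new("ConcordanceTable",
      a = sum(imp & comp), b = sum(imp & !comp),
      c = sum(!imp & comp), d = sum(!imp & !comp))
}

#' @rdname concordance-accessors
#' @param x a [ConcordanceTable-class]
#' @name concordance-accessors
#' @title Concordance table summaries
#' @return `agreementCount`: number of concordant patients (a + d);
#'   `agreementPct`: 100 (a + d) / n; `cohenKappa`: Cohen's kappa, `NA`
#'   with a warning when a margin has no variation.
#' @export
setMethod("agreementCount", "ConcordanceTable",
          function(x) x@a + x@d)

#' @rdname concordance-accessors
#' @export
setMethod("agreementPct", "ConcordanceTable", function(x) {
  n <- x@a + x@b + x@c + x@d
  if (n == 0) stop("empty table")
  100 * (x@a + x@d) / n
})

#' @rdname concordance-accessors
#' @export
setMethod("cohenKappa", "ConcordanceTable", function(x) {
  n <- x@a + x@b + x@c + x@d
  if (n == 0) stop("empty table")
  po <- (x@a + x@d) / n
  pe <- ((x@a + x@b) * (x@a + x@c) + (x@c + x@d) * (x@b + x@d)) / n^2
  if (abs(1 - pe) < .Machine$double.eps^0.5) {
    warning("kappa undefined: no variation in at least one margin")
    return(NA_real_)
  }
  (po - pe) / (1 - pe)
})

setMethod("show", "ConcordanceTable", function(object) {
  n <- object@a + object@b + object@c + object@d
  cat("TCD vs PET concordance (2x2)\n")
  cat(sprintf("                    PET compromised  PET stage 0\n"))
  cat(sprintf("  TCD impaired      %15d  %11d\n", object@a, object@b))
  cat(sprintf("  TCD normal        %15d  %11d\n", object@c, object@d))
  k <- suppressWarnings(cohenKappa(object))
  cat(sprintf("  agreement %d/%d (%.1f%%), Cohen's kappa %s\n",
              agreementCount(object), n, agreementPct(object),
              if (is.na(k)) "undefined" else sprintf("%.3f", k)))
})

## Mann-Whitney U p value: exact when tie-free, otherwise the mid-rank
## normal approximation (the documented tie convention)
.uTestP <- function(x, y) {
  ties <- anyDuplicated(c(x, y)) > 0
  stats::wilcox.test(x, y, exact = !ties)$p.value
}

## default variable -> test assignments (the printed Test column)
.defaultTestMap <- function() {
  c(cbf = "t", cbf_ratio = "t", oef = "U", oef_ratio = "U",
    mtt = "t", mtt_ratio = "t")
}

## default variable -> correlation method assignments
.defaultCorMap <- function() {
  c(cbf_ratio = "pearson", oef_ratio = "spearman", mtt_ratio = "pearson")
}

#' Compare PET values between reactivity groups
#'
#' Splits patients at a reactivity threshold (20% for impaired vs normal,
#' 0% for absent/steal vs the rest) and compares each haemodynamic
#' variable between the groups with the test given by the variable->test
#' map: two-sided Student's t (equal-variance by default) or Mann-Whitney
#' U (normal approximation with mid-ranks for ties, exact where possible).
#' No multiplicity correction is applied.
#'
#' @param data data.frame with `reactivity_pct` plus the variables in
#'   `testMap`
#' @param threshold grouping threshold on reactivity (%), group A is
#'   `<= threshold`
#' @param testMap named character vector mapping variable -> `"t"` or
#'   `"U"`; defaults to t for CBF, CBF ratio, CBV/CBF and its ratio, U for
#'   OEF and its ratio
#' @param varEqual use the equal-variance t statistic (default)
#' @return data.frame with one row per variable: group sizes, mean/SD (t)
#'   or median/IQR (U) per group, test label and two-sided p value
#' @export
compareGroups <- function(data, threshold = 20,
                          testMap = .defaultTestMap(), varEqual = TRUE) {
  stopifnot("reactivity_pct" %in% names(data))
  gA <- data$reactivity_pct <= threshold
  if (sum(gA) < 2 || sum(!gA) < 2)
    stop("each reactivity group needs at least two patients")
  vars <- intersect(names(testMap), names(data))
  if (!length(vars)) stop("no mapped variable found in data")
  rows <- lapply(vars, function(v) {
    xa <- data[[v]][gA]; xb <- data[[v]][!gA]
    xa <- xa[is.finite(xa)]; xb <- xb[is.finite(xb)]
    if (!length(xa) || !length(xb)) stop("empty group for ", v)
    if (testMap[[v]] == "t") {
      p <- stats::t.test(xa, xb, var.equal = varEqual)$p.value
      data.frame(variable = v, test = "t",
                 n_low = length(xa), n_high = length(xb),
                 low_center = mean(xa), low_spread = stats::sd(xa),
                 high_center = mean(xb), high_spread = stats::sd(xb),
                 summary = "mean (SD)", p_value = p,
                 stringsAsFactors = FALSE)
    } else {
      p <- .uTestP(xa, xb)
      data.frame(variable = v, test = "U",
                 n_low = length(xa), n_high = length(xb),
                 low_center = stats::median(xa),
                 low_spread = stats::IQR(xa),
                 high_center = stats::median(xb),
                 high_spread = stats::IQR(xb),
                 summary = "median (IQR)", p_value = p,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  attr(out, "threshold") <- threshold
  out
}

#' Correlate reactivity with hemispheric ratios
#'
#' Pearson or Spearman (mid-rank ties) correlation of CO2-reactivity with
#' each mapped ratio, with an optional caller-supplied exclusion list for
#' re-running the analysis without outlying patients (exclusion is never
#' automatic).  Excluding nobody reproduces the full-cohort results
#' exactly.
#'
#' @param data data.frame with `patient_id`, `reactivity_pct` and the
#'   mapped ratio variables (ipsilateral rows)
#' @param corMap named character vector mapping variable ->
#'   `"pearson"`/`"spearman"`; defaults to Pearson for the CBF and CBV/CBF
#'   ratios and Spearman for the OEF ratio
#' @param exclude character vector of `patient_id`s to drop before
#'   correlating (default none)
#' @return data.frame with one row per variable: method, n, estimate, p
#'   value
#' @export
correlateReactivity <- function(data, corMap = .defaultCorMap(),
                                exclude = character()) {
  stopifnot(all(c("patient_id", "reactivity_pct") %in% names(data)))
  keep <- !(data$patient_id %in% exclude)
  data <- data[keep, , drop = FALSE]
  vars <- intersect(names(corMap), names(data))
  rows <- lapply(vars, function(v) {
    ok <- is.finite(data$reactivity_pct) & is.finite(data[[v]])
    x <- data$reactivity_pct[ok]; y <- data[[v]][ok]
    if (length(x) < 3) stop("fewer than 3 pairs for ", v)
    ct <- suppressWarnings(
      stats::cor.test(x, y, method = corMap[[v]], exact = FALSE))
    data.frame(variable = v, method = corMap[[v]], n = length(x),
               estimate = unname(ct$estimate), p_value = ct$p.value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Compare blood-pressure changes between agreement groups
#'
#' Median and IQR of the systolic and diastolic pressure changes during
#' the TCD study, in patients with versus without TCD/PET agreement, with
#' a Mann-Whitney U p value.  Patients with missing blood-pressure
#' readings are excluded with a message.
#'
#' @param data data.frame with `d_sbp`, `d_dbp` and a logical `agreement`
#'   column
#' @return data.frame with one row per variable (`d_sbp`, `d_dbp`):
#'   medians, IQRs and p value
#' @export
compareBpChange <- function(data) {
  stopifnot(all(c("d_sbp", "d_dbp", "agreement") %in% names(data)))
  rows <- lapply(c("d_sbp", "d_dbp"), function(v) {
    ok <- is.finite(data[[v]])
    if (any(!ok))
      message(sum(!ok), " patient(s) excluded from ", v,
              " comparison (missing blood-pressure readings)")
    x <- data[[v]][ok & data$agreement]
    y <- data[[v]][ok & !data$agreement]
    if (!length(x) || !length(y)) stop("empty agreement group for ", v)
    p <- .uTestP(x, y)
    data.frame(variable = v,
               agree_median = stats::median(x), agree_iqr = stats::IQR(x),
               disagree_median = stats::median(y),
               disagree_iqr = stats::IQR(y),
               p_value = p, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
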